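# Synthetic FCS data with known ground truth: Brownian-dynamics photon
# traces from mixtures of diffusers in a 3D Gaussian detection volume,
# direct and multi-tau correlators, and a fast closed-form curve generator.
#
# The simulator exists to close the loop of the fouling assay: a mixture of
# a fast dim species (free labelled serum protein) and a slow bright one
# (protein bound to ~100 nm vesicles) is simulated, correlated and fitted,
# and the fitted particle fraction is compared with the analytic amplitude
# fraction of the configuration.

#' @useDynLib oxafoul, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Configuration of a Brownian-dynamics FCS simulation
#'
#' @param species `data.frame` with columns `count` (particles in the box,
#'   >= 0 integers), `D` (diffusion coefficient, m^2/s; 0 pins the
#'   particles), `brightness` (kHz at the focus centre) and optionally
#'   `init_center` (logical; start at the focus centre instead of uniform).
#' @param box box edge lengths, um; each lateral axis must be at least
#'   8 x `w_xy` and the axial one at least 4 x `w_z` to bound periodic
#'   artifacts.
#' @param dt time step and trace bin width, s. A warning is issued when the
#'   rms step of the fastest species exceeds `w_xy / 4`.
#' @param n_steps number of steps.
#' @param volume a [detection_volume()].
#' @param background background rate, kHz.
#' @param photon_sampling `"expected"` (deterministic expected rate per
#'   bin; the default -- fitting consumes correlation functions, not
#'   photons) or `"poisson"` (shot noise).
#' @param seed integer seed; the trace is bit-reproducible per seed.
#' @return object of class `fcs_sim_config`.
#' @export
fcs_sim_config <- function(species, box = c(2, 2, 5), dt = 4e-6,
                           n_steps = 2^20, volume = detection_volume(),
                           background = 0,
                           photon_sampling = c("expected", "poisson"),
                           seed = 1L) {
  photon_sampling <- match.arg(photon_sampling)
  stopifnot(is.data.frame(species),
            all(c("count", "D", "brightness") %in% names(species)))
  if (!"init_center" %in% names(species)) species$init_center <- FALSE
  if (any(species$count < 0) || any(species$count != round(species$count)))
    stop("species counts must be non-negative integers")
  if (any(species$D < 0) || any(species$brightness < 0))
    stop("D and brightness must be >= 0")
  if (dt <= 0 || n_steps < 2) stop("dt must be > 0 and n_steps >= 2")
  stopifnot(inherits(volume, "detection_volume"), length(box) == 3)
  if (any(box[1:2] < 8 * volume$w_xy))
    stop("lateral box dimensions must be >= 8 x w_xy")
  if (box[3] < 4 * volume$w_z)
    stop("axial box dimension too small versus w_z (need >= 4 x w_z)")
  step_rms <- sqrt(2 * max(species$D) * dt) * 1e6  # um
  if (step_rms > volume$w_xy / 4)
    warning(sprintf("time step too coarse: rms step %.3g um exceeds w_xy/4", step_rms))
  structure(list(species = species, box = as.numeric(box), dt = dt,
                 n_steps = as.integer(n_steps), volume = volume,
                 background = background, photon_sampling = photon_sampling,
                 seed = as.integer(seed)),
            class = "fcs_sim_config")
}

#' Simulate a binned fluorescence intensity trace
#'
#' Particles take independent Gaussian steps of per-axis variance `2 D dt`
#' with periodic wrapping; the instantaneous detected rate is
#' `background + sum_p B_p exp(-2 (x^2 + y^2)/w_xy^2 - 2 z^2/w_z^2)`
#' about the focus at the box centre. In `"expected"` mode each bin holds
#' that rate (kHz); in `"poisson"` mode, a Poisson draw of the expected
#' counts, converted back to kHz.
#'
#' @param cfg an [fcs_sim_config()].
#' @return object of class `intensity_trace`: `values` (kHz), `bin_width`
#'   (s), `duration` (s), `truth` (the config).
#' @export
simulate_fcs_trace <- function(cfg) {
  stopifnot(inherits(cfg, "fcs_sim_config"))
  set.seed(cfg$seed)
  rate <- bd_trace_cpp(cfg$n_steps, as.integer(cfg$species$count),
                       cfg$species$D * 1e12, cfg$species$brightness,
                       as.logical(cfg$species$init_center), cfg$dt, cfg$box,
                       cfg$volume$w_xy, cfg$volume$w_z, cfg$background)
  if (cfg$photon_sampling == "poisson") {
    counts <- stats::rpois(cfg$n_steps, rate * 1000 * cfg$dt)
    rate <- counts / (1000 * cfg$dt)
  }
  structure(list(values = rate, bin_width = cfg$dt,
                 duration = cfg$n_steps * cfg$dt, truth = cfg),
            class = "intensity_trace")
}

#' Analytic expectations for a simulation configuration
#'
#' Returns the quantities an ideal, infinitely long experiment would give:
#' the mean detected rate
#' `background + sum_p count_p B_p (pi/2)^(3/2) w_xy^2 w_z / V_box`,
#' per-species effective occupancies `N_i = count_i V_eff / V_box` with
#' `V_eff = pi^(3/2) w_xy^2 w_z`, the brightness^2-weighted amplitude
#' fractions `f_i = N_i B_i^2 / sum_j N_j B_j^2` (what a correlation fit
#' reports), the apparent occupancy
#' `N_app = (sum N_i B_i)^2 / sum N_i B_i^2`, and per-species diffusion
#' times.
#'
#' @param cfg an [fcs_sim_config()].
#' @return list with `mean_rate`, `N`, `amplitude_fractions`, `N_app`,
#'   `tau_d`.
#' @export
fcs_sim_truth <- function(cfg) {
  stopifnot(inherits(cfg, "fcs_sim_config"))
  v <- cfg$volume
  vbox <- prod(cfg$box)
  mean_rate <- cfg$background + sum(cfg$species$count * cfg$species$brightness) *
    (pi / 2)^1.5 * v$w_xy^2 * v$w_z / vbox
  N <- cfg$species$count * effective_volume(v) / vbox
  B <- cfg$species$brightness
  nb2 <- N * B^2
  fr <- if (sum(nb2) > 0) nb2 / sum(nb2) else rep(NA_real_, length(N))
  tau_d <- ifelse(cfg$species$D > 0,
                  (v$w_xy * 1e-6)^2 / (4 * cfg$species$D), Inf)
  list(mean_rate = mean_rate, N = N, amplitude_fractions = fr,
       N_app = if (sum(nb2) > 0) sum(N * B)^2 / sum(nb2) else NA_real_,
       tau_d = tau_d)
}

# Windowed global-mean covariance estimator shared by both correlators:
# G(k) = mean_t[(I_t - Ibar)(I_{t+k} - Ibar)] / Ibar^2 with Ibar the mean
# of the full trace.
.acf_est <- function(values, lags_bins) {
  n <- length(values)
  m <- mean(values)
  if (m == 0) stop("zero-mean trace cannot be normalized")
  d <- values - m
  vapply(lags_bins, function(k) {
    if (k >= n) stop("lag exceeds trace length")
    sum(d[seq_len(n - k)] * d[(k + 1):n]) / ((n - k) * m^2)
  }, numeric(1))
}

#' Direct (brute-force) autocorrelation at requested lags
#'
#' Literal `mean(dI_t dI_{t+k}) / mean(I)^2` with the deviations taken from
#' the full-trace mean; the O(N L) reference implementation against which
#' the multi-tau correlator is checked.
#'
#' @param trace an `intensity_trace`.
#' @param lags_bins integer lags in units of the bin width (0 allowed:
#'   `G(0)` is the variance over squared mean).
#' @return a [correlation_curve()] (lag-0 point dropped, if requested, from
#'   the curve but available as attribute `G0`).
#' @export
autocorrelate_direct <- function(trace, lags_bins) {
  stopifnot(inherits(trace, "intensity_trace"))
  lags_bins <- as.integer(lags_bins)
  if (any(lags_bins < 0)) stop("lags must be >= 0")
  if (max(lags_bins) >= length(trace$values)) stop("max lag exceeds trace length")
  G <- .acf_est(trace$values, lags_bins)
  keep <- lags_bins > 0
  cc <- correlation_curve(lags_bins[keep] * trace$bin_width, G[keep],
                          mean_count_rate = mean(trace$values),
                          duration = trace$duration, label = "direct")
  attr(cc, "G0") <- if (any(!keep)) G[!keep][[1L]] else NA_real_
  cc
}

#' Multi-tau autocorrelation of an intensity trace
#'
#' Standard multi-tau scheme: the first stage evaluates lags `1..2m` at the
#' raw bin width; each later stage halves the time resolution (pairwise
#' bin averaging) and evaluates lags `m+1..2m` at that resolution, covering
#' decades of lag on a quasi-logarithmic grid. Each stage uses the same
#' global-mean covariance estimator as [autocorrelate_direct()] applied to
#' its coarsened trace, so stage-0 values are exactly the direct ones.
#'
#' @param trace an `intensity_trace` (length >= 2 m).
#' @param m points per stage (default 16).
#' @param stages number of coarsening stages; default as many as the trace
#'   supports, capped so the longest lag is at most an eighth of the trace.
#' @return a [correlation_curve()].
#' @export
autocorrelate_multitau <- function(trace, m = 16L, stages = NULL) {
  stopifnot(inherits(trace, "intensity_trace"))
  m <- as.integer(m)
  vals <- trace$values
  if (length(vals) < 2L * m) stop("trace shorter than 2*m bins")
  if (mean(vals) == 0) stop("zero-mean trace cannot be normalized")
  max_stages <- 0L
  len <- length(vals) %/% 2L
  while (len >= 2L * m) { max_stages <- max_stages + 1L; len <- len %/% 2L }
  if (is.null(stages)) stages <- max_stages
  stages <- min(stages, max_stages)

  tau <- (1:(2L * m)) * trace$bin_width
  G <- .acf_est(vals, 1:(2L * m))
  cur <- vals
  width <- trace$bin_width
  for (s in seq_len(stages)) {
    n2 <- (length(cur) %/% 2L) * 2L
    cur <- (cur[seq(1L, n2, 2L)] + cur[seq(2L, n2, 2L)]) / 2
    width <- 2 * width
    lag_bins <- (m + 1L):(2L * m)
    if (max(lag_bins) * width > trace$duration / 8) break
    tau <- c(tau, lag_bins * width)
    G <- c(G, .acf_est(cur, lag_bins))
  }
  correlation_curve(tau, G, mean_count_rate = mean(vals),
                    duration = trace$duration, label = "multitau")
}

#' Generate a noisy model correlation curve
#'
#' Fast fixture path that bypasses Brownian dynamics: evaluates
#' [g_model()] on a lag grid and adds seeded Gaussian noise.
#'
#' @param spec an [fcs_model_spec()].
#' @param lag_grid lag times, s; default 200 log-spaced points covering
#'   1e-6..1 s.
#' @param noise_sd noise standard deviation; absolute, or relative to the
#'   local amplitude when `relative = TRUE`.
#' @param relative interpret `noise_sd` relatively.
#' @param mean_count_rate optional kHz recorded on the curve.
#' @param seed optional integer seed.
#' @param label curve label.
#' @return a [correlation_curve()] with `sigma_G` populated.
#' @export
generate_fcs_curve <- function(spec, lag_grid = 10^seq(-6, 0, length.out = 200),
                               noise_sd = 0, relative = FALSE,
                               mean_count_rate = NA_real_, seed = NULL,
                               label = "synthetic") {
  stopifnot(inherits(spec, "fcs_model_spec"))
  if (!is.null(seed)) set.seed(seed)
  g <- g_model(lag_grid, spec)
  sg <- if (relative) abs(noise_sd * g) else rep(noise_sd, length(g))
  noise <- if (noise_sd > 0) stats::rnorm(length(g), 0, pmax(sg, 1e-300)) else 0
  correlation_curve(lag_grid, g + noise,
                    sigma_G = if (noise_sd > 0) sg else NULL,
                    mean_count_rate = mean_count_rate, label = label)
}

#' Write / read an intensity trace as CSV
#'
#' `#`-prefixed metadata (`bin_width_s`, `duration_s`) followed by one
#' `value_khz` column.
#'
#' @param trace an `intensity_trace`.
#' @param path file path.
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(inherits(trace, "intensity_trace"))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(sprintf("# bin_width_s: %.12g", trace$bin_width),
               sprintf("# duration_s: %.12g", trace$duration),
               "value_khz"), con)
  writeLines(sprintf("%.10g", trace$values), con)
  invisible(path)
}

#' @rdname write_trace_csv
#' @return `read_trace_csv` returns an `intensity_trace` (without truth).
#' @export
read_trace_csv <- function(path) {
  lines <- readLines(path)
  grab <- function(key) as.numeric(sub(sprintf("^#\\s*%s:\\s*", key), "",
                                       grep(sprintf("^#\\s*%s:", key), lines,
                                            value = TRUE)[[1L]]))
  vals <- as.numeric(lines[!grepl("^#|^value_khz$", lines)])
  structure(list(values = vals, bin_width = grab("bin_width_s"),
                 duration = grab("duration_s"), truth = NULL),
            class = "intensity_trace")
}
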