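# Constrained fitting of FCS correlation curves and the fouling-assay
# statistics derived from the fits.
#
# The assay readout is the particle fraction F2: the fitted amplitude
# fraction of the slow (vesicle-bound) component of a two-component fit in
# which both diffusion times are held fixed -- the fast one at the free
# labelled-protein value, the slow one at the vesicle value -- so that only
# the occupancy N and the amplitude split are free. Because the correlation
# amplitude weights species by brightness^2, even a small number fraction of
# bound label on bright, slow vesicles produces a large F2; the statistic is
# reported as fitted, without brightness de-weighting.

#' Construct a correlation curve
#'
#' @param tau lag times, s; strictly increasing, all > 0.
#' @param G correlation amplitudes.
#' @param sigma_G optional per-point standard deviations (> 0).
#' @param mean_count_rate mean detected count rate, kHz.
#' @param duration measurement duration, s.
#' @param label text label.
#' @return object of class `correlation_curve`.
#' @export
correlation_curve <- function(tau, G, sigma_G = NULL, mean_count_rate = NA_real_,
                              duration = NA_real_, label = "") {
  tau <- as.numeric(tau); G <- as.numeric(G)
  if (length(tau) != length(G)) stop("tau and G lengths differ")
  if (any(tau <= 0)) stop("lag times must be > 0")
  if (any(diff(tau) <= 0)) stop("lag times must be strictly increasing")
  if (!is.null(sigma_G)) {
    sigma_G <- as.numeric(sigma_G)
    if (length(sigma_G) != length(tau)) stop("sigma_G length differs from tau")
    if (any(sigma_G < 0)) stop("sigma_G must be >= 0")
  }
  if (!is.na(mean_count_rate) && mean_count_rate < 0)
    stop("mean_count_rate must be >= 0")
  structure(list(tau = tau, G = G, sigma_G = sigma_G,
                 mean_count_rate = mean_count_rate, duration = duration,
                 label = as.character(label)),
            class = "correlation_curve")
}

#' Write a correlation curve to CSV
#'
#' Dialect: `#`-prefixed metadata lines (`label`, `mean_count_rate_khz`,
#' `duration_s`) followed by a `tau_s,G,sigma_G` table; one curve per file.
#'
#' @param curve a [correlation_curve()].
#' @param path output file.
#' @export
write_fcs_csv <- function(curve, path) {
  stopifnot(inherits(curve, "correlation_curve"))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(sprintf("# label: %s", curve$label),
               sprintf("# mean_count_rate_khz: %.10g", curve$mean_count_rate),
               sprintf("# duration_s: %.10g", curve$duration),
               "tau_s,G,sigma_G"), con)
  sg <- if (is.null(curve$sigma_G)) rep(NA_real_, length(curve$tau)) else curve$sigma_G
  writeLines(sprintf("%.12g,%.12g,%.12g", curve$tau, curve$G, sg), con)
  invisible(path)
}

#' Read a correlation curve from CSV
#'
#' @param path file in the [write_fcs_csv()] dialect.
#' @return a [correlation_curve()].
#' @export
read_fcs_csv <- function(path) {
  lines <- readLines(path)
  meta <- grep("^#", lines, value = TRUE)
  get_meta <- function(key, default = NA_real_) {
    m <- grep(sprintf("^#\\s*%s:", key), meta, value = TRUE)
    if (length(m) == 0L) return(default)
    sub(sprintf("^#\\s*%s:\\s*", key), "", m[[1L]])
  }
  body <- lines[!grepl("^#", lines)]
  tab <- utils::read.csv(text = paste(body, collapse = "\n"))
  sg <- if (all(is.na(tab$sigma_G))) NULL else tab$sigma_G
  correlation_curve(tab$tau_s, tab$G, sigma_G = sg,
                    mean_count_rate = as.numeric(get_meta("mean_count_rate_khz")),
                    duration = as.numeric(get_meta("duration_s")),
                    label = as.character(get_meta("label", "")))
}

# Update a model spec with a named parameter vector (the fit's free
# parameters); returns the evaluated spec.
.apply_pars <- function(spec, par) {
  if ("N" %in% names(par)) spec$N <- par[["N"]]
  if ("f_slow" %in% names(par)) {
    slow <- which.max(vapply(spec$components, function(x) x$tau_d, numeric(1)))
    fs <- par[["f_slow"]]
    for (i in seq_along(spec$components))
      spec$components[[i]]$fraction <- if (i == slow) fs else 1 - fs
  }
  for (i in seq_along(spec$components)) {
    key <- sprintf("tau_d%d", i)
    if (key %in% names(par)) spec$components[[i]]$tau_d <- par[[key]]
  }
  if ("T" %in% names(par)) spec$triplet_fraction <- par[["T"]]
  if ("tau_T" %in% names(par)) spec$triplet_time <- par[["tau_T"]]
  spec
}

#' Restrict a correlation curve to a lag window
#'
#' Correlations of simulated traces from closed periodic boxes deviate from
#' the open-volume model at lags approaching the box traversal time; fits
#' of such curves should be restricted to shorter lags.
#'
#' @param curve a [correlation_curve()].
#' @param tau_min,tau_max inclusive lag bounds, s.
#' @return the windowed [correlation_curve()].
#' @export
subset_curve <- function(curve, tau_min = 0, tau_max = Inf) {
  stopifnot(inherits(curve, "correlation_curve"))
  keep <- curve$tau >= tau_min & curve$tau <= tau_max
  if (!any(keep)) stop("empty lag window")
  correlation_curve(curve$tau[keep], curve$G[keep],
                    sigma_G = if (!is.null(curve$sigma_G)) curve$sigma_G[keep],
                    mean_count_rate = curve$mean_count_rate,
                    duration = curve$duration, label = curve$label)
}

#' Fit an FCS model to a correlation curve
#'
#' Bounded Levenberg-Marquardt least squares (via [minpack.lm::nls.lm]).
#' Free parameters: the occupancy `N`, the slow-component amplitude fraction
#' `f_slow` (two-component specs; parameterised as a single number in
#' `[0, 1]` so the fractions always sum to 1), any component diffusion time
#' whose `fixed_tau_d` flag is `FALSE`, and the triplet parameters when the
#' spec enables the triplet term. For two-component specs both diffusion
#' times must be fixed: that constraint is what makes the fouling assay
#' well-posed.
#'
#' Weights are `1/sigma_G^2` when the curve carries positive uncertainties,
#' uniform otherwise. Non-convergence is reported via the `converged` flag,
#' not an exception.
#'
#' @param curve a [correlation_curve()].
#' @param spec an [fcs_model_spec()]; component fractions and `N` are used
#'   as initial values unless overridden by `init`.
#' @param init optional named list of initial values (`N`, `f_slow`,
#'   `tau_d1`, `tau_d2`, `T`, `tau_T`).
#' @param fix_N,fix_fractions hold `N` / the amplitude split fixed at their
#'   spec values (used e.g. for direct residual evaluation).
#' @param fit_triplet fit the triplet term; defaults to `TRUE` when the spec
#'   has a positive triplet fraction.
#' @param fit_baseline additionally fit a constant offset `G_inf` (bounded
#'   to `[-0.5, 0.5]`). Useful for curves measured from finite closed
#'   systems, whose correlation sits a constant `~1/n_particles` below the
#'   open-volume model; see [subset_curve()].
#' @return object of class `fcs_fit_result` with elements `spec_out`, `N`,
#'   `F2` (percent; `NA` for one-component fits), `cpp` (kHz,
#'   `mean_count_rate / N`), `chi2_reduced`, `converged`, `n_free`,
#'   `curve_label`, `fitted` (model values on the curve's lag grid) and
#'   `residuals`.
#' @export
fit_curve <- function(curve, spec, init = list(), fix_N = FALSE,
                      fix_fractions = FALSE,
                      fit_triplet = spec$triplet_fraction > 0,
                      fit_baseline = FALSE) {
  stopifnot(inherits(curve, "correlation_curve"), inherits(spec, "fcs_model_spec"))
  if (all(curve$G <= 0)) stop("curve has no positive amplitudes; nothing to fit")
  nc <- length(spec$components)
  free_tau <- which(!vapply(spec$components, function(x) x$fixed_tau_d, logical(1)))
  if (nc == 2L && length(free_tau) > 0L)
    stop("two-component fits require both diffusion times fixed")

  par <- c(); lower <- c(); upper <- c()
  add <- function(name, value, lo, hi) {
    par[[name]] <<- value; lower[[name]] <<- lo; upper[[name]] <<- hi
  }
  if (!fix_N) {
    n0 <- init$N
    if (is.null(n0)) {
      gmax <- max(curve$G)
      n0 <- if (gmax > 0) 1 / gmax else spec$N
    }
    add("N", n0, 1e-8, Inf)
  }
  if (nc == 2L && !fix_fractions) {
    slow <- which.max(vapply(spec$components, function(x) x$tau_d, numeric(1)))
    f0 <- init$f_slow
    if (is.null(f0)) f0 <- spec$components[[slow]]$fraction
    if (f0 <= 0 || f0 >= 1) f0 <- 0.5
    add("f_slow", f0, 0, 1)
  }
  for (i in free_tau) {
    key <- sprintf("tau_d%d", i)
    t0 <- if (!is.null(init[[key]])) init[[key]] else spec$components[[i]]$tau_d
    add(key, t0, min(curve$tau) / 100, max(curve$tau) * 100)
  }
  if (fit_triplet) {
    add("T", if (!is.null(init$T)) init$T else max(spec$triplet_fraction, 0.05),
        0, 0.999)
    add("tau_T", if (!is.null(init$tau_T)) init$tau_T else spec$triplet_time,
        1e-9, min(vapply(spec$components, function(x) x$tau_d, numeric(1))))
  }
  if (fit_baseline)
    add("G_inf", if (!is.null(init$G_inf)) init$G_inf else 0, -0.5, 0.5)
  n_free <- length(par)
  if (length(curve$tau) <= n_free)
    stop(sprintf("curve has %d points but %d free parameters", length(curve$tau), n_free))

  w <- rep(1, length(curve$tau))
  if (!is.null(curve$sigma_G) && all(curve$sigma_G > 0)) w <- 1 / curve$sigma_G
  resid_fun <- function(p) {
    p <- stats::setNames(p, names(par))
    sp <- .apply_pars(spec, p)
    base <- if ("G_inf" %in% names(p)) p[["G_inf"]] else 0
    w * (g_model(curve$tau, sp) + base - curve$G)
  }

  baseline <- 0
  if (n_free == 0L) {
    res <- resid_fun(numeric(0))
    spec_out <- spec
    converged <- TRUE
  } else {
    fit <- minpack.lm::nls.lm(
      par = unlist(par), lower = unlist(lower), upper = unlist(upper),
      fn = resid_fun,
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-12,
                                           ptol = 1e-12))
    spec_out <- .apply_pars(spec, stats::setNames(fit$par, names(par)))
    if (fit_baseline) baseline <- fit$par[[which(names(par) == "G_inf")]]
    res <- resid_fun(fit$par)
    converged <- fit$info %in% 1:4
  }

  dof <- length(curve$tau) - n_free
  chi2_red <- if (dof > 0) sum(res^2) / dof else NA_real_
  slow <- which.max(vapply(spec_out$components, function(x) x$tau_d, numeric(1)))
  F2 <- if (nc == 2L) 100 * spec_out$components[[slow]]$fraction else NA_real_
  cpp <- if (!is.na(curve$mean_count_rate)) curve$mean_count_rate / spec_out$N
         else NA_real_
  structure(list(spec_out = spec_out, N = spec_out$N, F2 = F2, cpp = cpp,
                 baseline = baseline, chi2_reduced = chi2_red,
                 converged = converged, n_free = n_free,
                 curve_label = curve$label,
                 fitted = g_model(curve$tau, spec_out) + baseline,
                 residuals = res),
            class = "fcs_fit_result")
}

#' @export
print.fcs_fit_result <- function(x, ...) {
  taus <- vapply(x$spec_out$components, function(cmp) cmp$tau_d, numeric(1))
  cat(sprintf("FCS fit '%s': N = %.4g, tau_D = %s s%s, cpp = %.3g kHz, red. chi2 = %.3g, %s\n",
              x$curve_label, x$N, paste(signif(taus, 4), collapse = "/"),
              if (!is.na(x$F2)) sprintf(", F2 = %.2f%%", x$F2) else "",
              x$cpp, x$chi2_reduced,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Calibrate the free-dye diffusion time and hydrodynamic diameter
#'
#' Fits each curve with a one-component model whose diffusion time is free,
#' then reports the spread of the recovered `tau_D` and of the
#' Stokes-Einstein diameter. Non-converged curves are excluded and counted.
#'
#' @param curves list of [correlation_curve()]s (>= 1).
#' @param spec one-component [fcs_model_spec()]; its `tau_d` is the initial
#'   value.
#' @param temperature,viscosity passed to [stokes_einstein_diameter()].
#' @param ... further arguments passed to [fit_curve()] (e.g.
#'   `fit_baseline = TRUE` for curves from finite simulated systems).
#' @return list with `tau_d_mean`, `tau_d_sd`, `diameter_mean_nm`,
#'   `diameter_sd_nm`, `D_mean`, `n_used`, `n_excluded`, and per-curve
#'   `tau_d` values.
#' @export
calibrate_free_dye <- function(curves, spec, temperature = 298.15,
                               viscosity = 8.9e-4, ...) {
  if (length(curves) == 0L) stop("no curves supplied")
  stopifnot(inherits(spec, "fcs_model_spec"))
  if (length(spec$components) != 1L)
    stop("calibration uses a one-component model")
  spec$components[[1L]]$fixed_tau_d <- FALSE
  fits <- lapply(curves, function(cv)
    tryCatch(fit_curve(cv, spec, ...), error = function(e) NULL))
  ok <- vapply(fits, function(f) !is.null(f) && isTRUE(f$converged), logical(1))
  if (!any(ok)) stop("no curve converged")
  tds <- vapply(fits[ok], function(f) f$spec_out$components[[1L]]$tau_d, numeric(1))
  Ds <- diffusion_from_tau_d(tds, spec$volume)
  dias <- stokes_einstein_diameter(Ds, temperature, viscosity)
  sd0 <- function(x) if (length(x) > 1L) stats::sd(x) else 0
  list(tau_d_mean = mean(tds), tau_d_sd = sd0(tds),
       D_mean = mean(Ds),
       diameter_mean_nm = mean(dias), diameter_sd_nm = sd0(dias),
       n_used = sum(ok), n_excluded = sum(!ok), tau_d = tds)
}

#' Exclude aggregate-dominated fit results
#'
#' Technical repeats whose particle fraction (or counts-per-particle)
#' exceeds a threshold are interpreted as having caught an aggregate and
#' removed before averaging. The ordering of both returned lists follows
#' the input.
#'
#' @param results list of `fcs_fit_result`s.
#' @param f2_threshold percent in `(0, 100]`; results with `F2` strictly
#'   above it are excluded. Default 50.
#' @param cpp_threshold optional kHz cut; `Inf` disables.
#' @return list with `kept` and `excluded` lists of results.
#' @export
exclude_aggregates <- function(results, f2_threshold = 50, cpp_threshold = Inf) {
  if (f2_threshold <= 0 || f2_threshold > 100)
    stop("f2_threshold must be in (0, 100]")
  bad <- vapply(results, function(r) {
    (!is.na(r$F2) && r$F2 > f2_threshold) ||
      (!is.na(r$cpp) && r$cpp > cpp_threshold)
  }, logical(1))
  if (all(bad) && length(results) > 0L)
    warning("all results exceeded the aggregate threshold; nothing kept")
  list(kept = results[!bad], excluded = results[bad])
}

#' Aggregate particle fractions over technical repeats
#'
#' Follows the convention of taking the median F2 over the technical
#' repeats of each independent experiment, then reporting mean +/- s.e.m.
#' of those per-experiment medians per timepoint. With a single experiment
#' the per-experiment median is reported with `sem = 0`.
#'
#' @param results list of `fcs_fit_result`s (post-exclusion).
#' @param timepoints grouping labels (e.g. hours), one per result.
#' @param experiments optional independent-experiment labels, one per
#'   result; defaults to a single experiment.
#' @param n_excluded optional named vector of excluded counts per timepoint.
#' @param exclusion_rule text recorded in the output.
#' @return `data.frame` with one row per timepoint: `timepoint`,
#'   `median_F2` (mean of per-experiment medians), `sem_F2`,
#'   `n_experiments`, `n_used`, `n_excluded`, `exclusion_rule`.
#' @export
aggregate_repeats <- function(results, timepoints, experiments = NULL,
                              n_excluded = NULL, exclusion_rule = "") {
  if (length(results) == 0L) stop("no results to aggregate")
  if (length(timepoints) != length(results))
    stop("one timepoint label per result required")
  if (is.null(experiments)) experiments <- rep("exp1", length(results))
  if (length(experiments) != length(results))
    stop("one experiment label per result required")
  f2 <- vapply(results, function(r) r$F2, numeric(1))
  if (any(is.na(f2))) stop("all results must carry an F2 (two-component fits)")
  groups <- unique(timepoints)
  rows <- lapply(groups, function(tp) {
    sel <- timepoints == tp
    if (!any(sel)) stop(sprintf("empty group '%s'", tp))
    med <- tapply(f2[sel], experiments[sel], stats::median)
    sem <- if (length(med) > 1L) stats::sd(med) / sqrt(length(med)) else 0
    nexc <- if (!is.null(n_excluded) && as.character(tp) %in% names(n_excluded))
      n_excluded[[as.character(tp)]] else 0L
    data.frame(timepoint = tp, median_F2 = mean(med), sem_F2 = sem,
               n_experiments = length(med), n_used = sum(sel),
               n_excluded = nexc, exclusion_rule = exclusion_rule,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
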