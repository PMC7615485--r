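# Parametric membrane-slab generator with analytic ground truth.
#
# Pseudo-atoms realise a layered slab: a uniform PDMS core of half-width h,
# PMOXA brush layers on both faces (density plateau with an exponential or
# linear tail), and water at uniform density everywhere outside the core.
# Per-frame Gaussian positional fluctuations (iid or Ornstein-Uhlenbeck in
# time) animate the slab. This is a geometric fixture for validating the
# profile/metric analysers, not a physical model: densities of overlapping
# layers superpose and there are no excluded-volume interactions.

#' Configuration of a synthetic membrane slab
#'
#' @param core_half_width PDMS core half-width h, nm; the true membrane
#'   (core) thickness is `2 h`.
#' @param core_density PDMS core density, kg/m^3.
#' @param brush_anchor_offset gap between the core edge and the brush
#'   plateau start, nm.
#' @param brush_extent brush plateau length E, nm.
#' @param brush_plateau_density PMOXA plateau density, kg/m^3.
#' @param brush_decay `"exponential"` or `"linear"` tail beyond the
#'   plateau; both are truncated at `3 * brush_decay_length`.
#' @param brush_decay_length tail decay length lambda, nm.
#' @param water_density kg/m^3; water occupies everything outside the core.
#' @param interfacial_band nm; recorded in the ground truth as the margin
#'   beyond the brush reach within which water is expected to classify as
#'   interfacial.
#' @param fluct_sigma named per-component positional fluctuation sd
#'   (per axis), nm.
#' @param temporal `"iid"` frame noise or `"ou"` (AR(1) with correlation
#'   time `ou_tau_frames`, stationary sd `fluct_sigma`).
#' @param ou_tau_frames OU correlation time in frames.
#' @param box box dimensions, nm; the normal (z) extent must accommodate
#'   core + brush + a water margin on both sides.
#' @param n_frames number of frames.
#' @param atom_mass pseudo-atom mass, amu (sets the sampling resolution).
#' @param seed integer seed.
#' @return object of class `membrane_sim_config`.
#' @export
membrane_sim_config <- function(core_half_width = 2, core_density = 965,
                                brush_anchor_offset = 0, brush_extent = 1.5,
                                brush_plateau_density = 550,
                                brush_decay = c("exponential", "linear"),
                                brush_decay_length = 0.1,
                                water_density = 997, interfacial_band = 0.4,
                                fluct_sigma = c(PDMS = 0.05, PMOXA = 0.08,
                                                WATER = 0.12),
                                temporal = c("iid", "ou"), ou_tau_frames = 5,
                                box = c(4, 4, 12), n_frames = 20,
                                atom_mass = 18, seed = 1L) {
  brush_decay <- match.arg(brush_decay)
  temporal <- match.arg(temporal)
  dens <- c(core_density, brush_plateau_density, water_density)
  if (any(dens < 0)) stop("densities must be >= 0")
  if (any(dens > 2000))
    stop("density exceeds the close-packing heuristic (2000 kg/m^3)")
  if (core_half_width <= 0 || brush_extent <= 0 || brush_decay_length <= 0)
    stop("extents must be > 0")
  if (any(fluct_sigma < 0)) stop("fluctuation sigmas must be >= 0")
  stopifnot(length(box) == 3, all(box > 0), n_frames >= 1, atom_mass > 0)
  reach <- core_half_width + brush_anchor_offset + brush_extent +
    3 * brush_decay_length
  if (box[3] / 2 < reach + interfacial_band + 0.5)
    stop("box normal too small for core + brush + water margin")
  structure(list(core_half_width = core_half_width,
                 core_density = core_density,
                 brush_anchor_offset = brush_anchor_offset,
                 brush_extent = brush_extent,
                 brush_plateau_density = brush_plateau_density,
                 brush_decay = brush_decay,
                 brush_decay_length = brush_decay_length,
                 water_density = water_density,
                 interfacial_band = interfacial_band,
                 fluct_sigma = fluct_sigma, temporal = temporal,
                 ou_tau_frames = ou_tau_frames, box = as.numeric(box),
                 n_frames = as.integer(n_frames), atom_mass = atom_mass,
                 seed = as.integer(seed)),
            class = "membrane_sim_config")
}

# atoms realising areal mass density rho*thickness over lateral area
.n_atoms <- function(rho, volume_nm3, atom_mass) {
  round(rho * volume_nm3 / (1.66053906660 * atom_mass))
}

# stratified (inverse-CDF at mid-quantiles) brush offsets u >= 0 relative
# to the plateau start; stratification realises the parametric density
# without per-bin Poisson noise
.sample_brush_u <- function(n, E, lam, decay) {
  if (n == 0L) return(numeric(0))
  m_tail <- if (decay == "exponential") lam * (1 - exp(-3)) else 1.5 * lam
  M <- E + m_tail
  p <- ((seq_len(n) - 0.5) / n) * M
  u <- numeric(n)
  plateau <- p <= E
  u[plateau] <- p[plateau]
  q <- p[!plateau] - E
  u[!plateau] <- if (decay == "exponential") E - lam * log(1 - q / lam)
                 else E + 3 * lam * (1 - sqrt(1 - q / (1.5 * lam)))
  u
}

# stratified uniform positions on (a, b)
.strat_unif <- function(n, a, b) a + (b - a) * (seq_len(n) - 0.5) / n

#' Generate a synthetic membrane slab trajectory
#'
#' Pseudo-atoms are placed to realise the configured layer densities
#' (stratified inverse-CDF placement along the normal, so the realised
#' mean profile carries no per-bin Poisson noise); each
#' frame displaces every atom from its base site by Gaussian noise of the
#' component's `fluct_sigma` (iid across frames, or an AR(1)
#' Ornstein-Uhlenbeck sequence with the same stationary sd). The analytic
#' layer structure is attached as attribute `"truth"`.
#'
#' @param cfg a [membrane_sim_config()].
#' @return a [trajectory()]; `attr(, "truth")` holds `membrane_thickness`
#'   (= 2 h), layer edges (`brush_start`, `brush_plateau_end`,
#'   `brush_reach`), the plateau densities, and `truth_profile(z,
#'   component)` giving the analytic mean density at membrane-centred z.
#' @export
generate_membrane_trajectory <- function(cfg) {
  stopifnot(inherits(cfg, "membrane_sim_config"))
  set.seed(cfg$seed)
  box <- cfg$box
  area <- box[1] * box[2]
  h <- cfg$core_half_width
  E <- cfg$brush_extent
  lam <- cfg$brush_decay_length
  u0 <- cfg$brush_anchor_offset
  half_z <- box[3] / 2

  n_core <- .n_atoms(cfg$core_density, area * 2 * h, cfg$atom_mass)
  m_tail <- if (cfg$brush_decay == "exponential") lam * (1 - exp(-3)) else 1.5 * lam
  n_brush <- .n_atoms(cfg$brush_plateau_density, area * (E + m_tail), cfg$atom_mass)
  n_water <- .n_atoms(cfg$water_density, area * (half_z - h), cfg$atom_mass)

  z_core <- .strat_unif(n_core, -h, h)
  z_brush <- c(h + u0 + .sample_brush_u(n_brush, E, lam, cfg$brush_decay),
               -(h + u0 + .sample_brush_u(n_brush, E, lam, cfg$brush_decay)))
  z_water <- c(.strat_unif(n_water, h, half_z), .strat_unif(n_water, -half_z, -h))
  z <- c(z_core, z_brush, z_water)
  labels <- c(rep("PDMS", n_core), rep("PMOXA", 2L * n_brush),
              rep("WATER", 2L * n_water))
  n <- length(z)
  base <- cbind(stats::runif(n, 0, box[1]), stats::runif(n, 0, box[2]),
                z + half_z)
  sig <- unname(cfg$fluct_sigma[labels])

  frames <- vector("list", cfg$n_frames)
  if (cfg$temporal == "iid") {
    for (f in seq_len(cfg$n_frames))
      frames[[f]] <- base + matrix(stats::rnorm(3L * n, 0, sig), n, 3L)
  } else {
    phi <- exp(-1 / cfg$ou_tau_frames)
    disp <- matrix(stats::rnorm(3L * n, 0, sig), n, 3L)
    frames[[1L]] <- base + disp
    for (f in seq_len(cfg$n_frames - 1L)) {
      disp <- phi * disp + sqrt(1 - phi^2) * matrix(stats::rnorm(3L * n, 0, sig), n, 3L)
      frames[[f + 1L]] <- base + disp
    }
  }
  traj <- trajectory(frames, labels, cfg$atom_mass, box, normal_axis = 3L)

  truth_profile <- function(z, component) {
    u <- abs(z)
    switch(component,
      PDMS = ifelse(u <= h, cfg$core_density, 0),
      PMOXA = {
        v <- u - h - u0
        plateau <- v >= 0 & v <= E
        tail <- v > E & v <= E + 3 * lam
        out <- numeric(length(u))
        out[plateau] <- cfg$brush_plateau_density
        out[tail] <- if (cfg$brush_decay == "exponential")
          cfg$brush_plateau_density * exp(-(v[tail] - E) / lam)
        else cfg$brush_plateau_density * (1 - (v[tail] - E) / (3 * lam))
        out
      },
      WATER = ifelse(u > h & u <= half_z, cfg$water_density, 0),
      stop(sprintf("unknown component '%s'", component)))
  }
  attr(traj, "truth") <- list(
    membrane_thickness = 2 * h,
    brush_start = h + u0,
    brush_plateau_end = h + u0 + E,
    brush_reach = h + u0 + E + 3 * lam,
    interfacial_band = cfg$interfacial_band,
    core_density = cfg$core_density,
    brush_plateau_density = cfg$brush_plateau_density,
    water_density = cfg$water_density,
    truth_profile = truth_profile)
  traj
}
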