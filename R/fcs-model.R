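# Closed-form FCS correlation models for diffusion in a 3D Gaussian
# confocal detection volume, plus diffusion <-> size conversions.
#
# The canonical model used throughout is the triplet-corrected
# multi-component 3D diffusion autocorrelation
#
#   G(tau) = (1/N) [1 + T exp(-tau/tau_T)/(1 - T)]
#            sum_i f_i (1 + tau/tau_Di)^-1 (1 + tau/(S^2 tau_Di))^-1/2
#
# with N the mean occupancy of the effective volume, f_i amplitude
# fractions summing to 1, tau_Di per-species diffusion times and
# S = w_z/w_xy the structure parameter. Amplitude fractions are reported
# as fitted, i.e. brightness^2-weighted; no de-weighting is attempted.

.KB <- 1.380649e-23  # Boltzmann constant, J/K

#' Confocal detection volume geometry
#'
#' @param w_xy lateral 1/e^2 radius of the Gaussian detection volume, um.
#' @param S structure parameter, `w_z / w_xy` (dimensionless, >= 1).
#'   S is a fixed calibration constant of the instrument, never fitted.
#' @return object of class `detection_volume` with fields `w_xy`, `S`, `w_z`.
#' @export
detection_volume <- function(w_xy = 0.25, S = 5) {
  if (!is.numeric(w_xy) || w_xy <= 0) stop("w_xy must be > 0")
  if (!is.numeric(S) || S < 1) stop("structure parameter S must be >= 1")
  structure(list(w_xy = w_xy, S = S, w_z = S * w_xy),
            class = "detection_volume")
}

#' Effective detection volume
#'
#' `V_eff = pi^(3/2) w_xy^2 w_z`, the normalization for which the
#' correlation amplitude is `G(0) = 1/(C V_eff)` at concentration C.
#'
#' @param vol a [detection_volume()].
#' @return volume in um^3.
#' @export
effective_volume <- function(vol) {
  stopifnot(inherits(vol, "detection_volume"))
  pi^1.5 * vol$w_xy^2 * vol$w_z
}

#' One diffusing species of an FCS model
#'
#' @param tau_d diffusion (dwell) time, s.
#' @param fraction amplitude fraction in `[0, 1]`.
#' @param fixed_tau_d should `tau_d` be held fixed during fitting? The
#'   fouling assay fixes both diffusion times (free protein and vesicle)
#'   and fits only occupancy and fractions.
#' @return object of class `fcs_component`.
#' @export
fcs_component <- function(tau_d, fraction = 1, fixed_tau_d = TRUE) {
  if (!is.numeric(tau_d) || tau_d <= 0) stop("tau_d must be > 0")
  if (fraction < 0 || fraction > 1) stop("fraction must be in [0, 1]")
  structure(list(tau_d = tau_d, fraction = fraction,
                 fixed_tau_d = isTRUE(fixed_tau_d)),
            class = "fcs_component")
}

#' Full FCS model specification
#'
#' @param components list of one or two [fcs_component()]s; fractions must
#'   sum to 1 (within 1e-9).
#' @param N mean occupancy (> 0).
#' @param volume a [detection_volume()].
#' @param triplet_fraction T in `[0, 1)`; 0 disables the triplet term.
#' @param triplet_time tau_T, s; must be below the smallest tau_d when the
#'   triplet term is enabled.
#' @return object of class `fcs_model_spec`.
#' @export
fcs_model_spec <- function(components, N = 1, volume = detection_volume(),
                           triplet_fraction = 0, triplet_time = 1e-6) {
  if (inherits(components, "fcs_component")) components <- list(components)
  if (length(components) < 1L || length(components) > 2L)
    stop("1 or 2 components supported")
  if (!all(vapply(components, inherits, logical(1), "fcs_component")))
    stop("components must be fcs_component objects")
  fr <- vapply(components, function(cmp) cmp$fraction, numeric(1))
  if (abs(sum(fr) - 1) > 1e-9) stop("component fractions must sum to 1")
  if (!is.numeric(N) || N <= 0) stop("N must be > 0")
  stopifnot(inherits(volume, "detection_volume"))
  if (triplet_fraction < 0 || triplet_fraction >= 1)
    stop("triplet fraction must be in [0, 1)")
  if (triplet_fraction > 0) {
    if (!is.numeric(triplet_time) || triplet_time <= 0)
      stop("triplet_time must be > 0")
    if (triplet_time >= min(vapply(components, function(cmp) cmp$tau_d, numeric(1))))
      stop("triplet_time must be below the smallest diffusion time")
  }
  structure(list(components = components, N = N, volume = volume,
                 triplet_fraction = triplet_fraction,
                 triplet_time = triplet_time),
            class = "fcs_model_spec")
}

#' Evaluate the FCS autocorrelation model
#'
#' @param tau lag times, s (vectorised; `tau >= 0`).
#' @param spec an [fcs_model_spec()].
#' @return correlation amplitudes `G(tau)`.
#' @export
g_model <- function(tau, spec) {
  stopifnot(inherits(spec, "fcs_model_spec"))
  if (any(tau < 0)) stop("lag times must be >= 0")
  S2 <- spec$volume$S^2
  g <- 0
  for (cmp in spec$components) {
    g <- g + cmp$fraction /
      ((1 + tau / cmp$tau_d) * sqrt(1 + tau / (S2 * cmp$tau_d)))
  }
  trip <- 1
  if (spec$triplet_fraction > 0) {
    Tt <- spec$triplet_fraction
    trip <- 1 + Tt * exp(-tau / spec$triplet_time) / (1 - Tt)
  }
  trip * g / spec$N
}

#' Diffusion time from diffusion coefficient
#'
#' `tau_D = w_xy^2 / (4 D)`.
#'
#' @param D diffusion coefficient, m^2/s.
#' @param vol a [detection_volume()] (lateral radius in um).
#' @return diffusion time, s.
#' @export
tau_d_from_diffusion <- function(D, vol = detection_volume()) {
  stopifnot(inherits(vol, "detection_volume"))
  if (any(D <= 0)) stop("D must be > 0")
  (vol$w_xy * 1e-6)^2 / (4 * D)
}

#' Diffusion coefficient from diffusion time
#'
#' Inverse of [tau_d_from_diffusion()].
#'
#' @param tau_d diffusion time, s.
#' @param vol a [detection_volume()].
#' @return D, m^2/s.
#' @export
diffusion_from_tau_d <- function(tau_d, vol = detection_volume()) {
  stopifnot(inherits(vol, "detection_volume"))
  if (any(tau_d <= 0)) stop("tau_d must be > 0")
  (vol$w_xy * 1e-6)^2 / (4 * tau_d)
}

#' Stokes-Einstein hydrodynamic diameter
#'
#' `d = k_B T / (3 pi eta D)`, reported in nm. Defaults are water at 25 C.
#'
#' @param D diffusion coefficient, m^2/s.
#' @param temperature absolute temperature, K.
#' @param viscosity dynamic viscosity, Pa s.
#' @return hydrodynamic diameter, nm.
#' @export
stokes_einstein_diameter <- function(D, temperature = 298.15,
                                     viscosity = 8.9e-4) {
  if (any(D <= 0) || temperature <= 0 || viscosity <= 0)
    stop("D, temperature and viscosity must be > 0")
  1e9 * .KB * temperature / (3 * pi * viscosity * D)
}

#' Diffusion coefficient from hydrodynamic diameter
#'
#' Inverse of [stokes_einstein_diameter()].
#'
#' @param d_nm hydrodynamic diameter, nm.
#' @param temperature absolute temperature, K.
#' @param viscosity dynamic viscosity, Pa s.
#' @return D, m^2/s.
#' @export
diffusion_from_diameter <- function(d_nm, temperature = 298.15,
                                    viscosity = 8.9e-4) {
  if (any(d_nm <= 0) || temperature <= 0 || viscosity <= 0)
    stop("diameter, temperature and viscosity must be > 0")
  .KB * temperature / (3 * pi * viscosity * d_nm * 1e-9)
}
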