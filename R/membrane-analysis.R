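# Structural observables of polymersome membrane slabs: cross-sectional
# mass-density profiles with an interfacial/bulk water split, core
# thickness, interfacial water-layer metrics, and RMSF of the brush.
#
# Conventions: the membrane normal is the trajectory's `normal_axis`
# (default z); every frame is re-centred on the PDMS centre of mass so the
# core sits at z = 0; boxes are orthorhombic and binning uses the
# minimum-image wrapped coordinate. Water within `interfacial_cutoff`
# (default 0.4 nm) of any PMOXA atom in a frame is classed as interfacial
# water, the rest as bulk -- the distance cutoff is the one methodological
# free parameter of the split.

.AMU_KG <- 1.66053906660  # amu -> kg with the nm^3 -> m^3 factor folded in

# weighted histogram over 1..n_bins
.whist <- function(bin, w, n_bins) {
  out <- numeric(n_bins)
  tb <- rowsum(w, bin)
  out[as.integer(rownames(tb))] <- tb
  out
}

# minimum-image distance-based interfacial water classification; returns a
# logical over water atoms (TRUE = interfacial)
.classify_interfacial <- function(xyz, labels, box, cutoff, normal_axis) {
  water <- which(labels == "WATER")
  pmoxa <- which(labels == "PMOXA")
  is_int <- logical(length(water))
  if (length(pmoxa) == 0L || length(water) == 0L || cutoff <= 0)
    return(is_int)
  zc <- xyz[, normal_axis]
  zrange <- range(zc[pmoxa])
  cand <- which(zc[water] >= zrange[1L] - cutoff & zc[water] <= zrange[2L] + cutoff)
  if (length(cand) == 0L) return(is_int)
  pm <- xyz[pmoxa, , drop = FALSE]
  c2 <- cutoff^2
  chunk <- max(1L, floor(2e6 / length(pmoxa)))
  for (start in seq(1L, length(cand), by = chunk)) {
    idx <- cand[start:min(start + chunk - 1L, length(cand))]
    wa <- xyz[water[idx], , drop = FALSE]
    d2 <- matrix(0, nrow(wa), nrow(pm))
    for (ax in 1:3) {
      dd <- outer(wa[, ax], pm[, ax], "-")
      dd <- dd - box[ax] * round(dd / box[ax])
      d2 <- d2 + dd * dd
    }
    is_int[idx] <- matrixStats_rowMins(d2) <= c2
  }
  is_int
}

# row minima without extra dependencies
matrixStats_rowMins <- function(m) do.call(pmin, as.data.frame(m))

#' Cross-sectional density profile of a membrane slab
#'
#' Per frame, the slab is centred on the PDMS centre of mass along the
#' membrane normal, each component's mass is histogrammed into uniform
#' bins, and the histogram is converted to mass density by the bin slab
#' volume. Water is split into interfacial (within `interfacial_cutoff` of
#' any PMOXA atom, minimum-image) and bulk. Means and standard deviations
#' are taken across frames.
#'
#' @param traj a [trajectory()] with a constant box.
#' @param bin_width target bin width, nm; the actual width divides the box
#'   evenly and is reported in the result.
#' @param interfacial_cutoff nm; water-PMOXA distance defining interfacial
#'   water.
#' @param keep_frames retain per-frame profiles (needed for metric
#'   uncertainties).
#' @param center `"pdms"` (default): centre each frame on the PDMS centre
#'   of mass, an error if no PDMS atoms exist; `"none"`: centre on the box
#'   midplane (for homogeneous control systems).
#' @return object of class `density_profile`: `z_centers` (nm,
#'   membrane-centred), `rho` and `rho_sd` (bins x components, kg/m^3, for
#'   `PDMS`, `PMOXA`, `WATER_INT`, `WATER_BULK`), `bin_width`, `box`,
#'   `n_frames`, and (optionally) `rho_frames`.
#' @export
density_profile <- function(traj, bin_width = 0.1, interfacial_cutoff = 0.4,
                            keep_frames = TRUE, center = c("pdms", "none")) {
  stopifnot(inherits(traj, "trajectory"))
  center <- match.arg(center)
  if (bin_width <= 0) stop("bin_width must be > 0")
  if (nrow(unique(traj$box)) != 1L)
    stop("density_profile requires a constant box across frames")
  if (center == "pdms" && !any(traj$labels == "PDMS"))
    stop("no PDMS atoms: cannot centre the profile on the core")
  ax <- traj$normal_axis
  box <- traj$box[1L, ]
  Lz <- box[ax]
  lat <- prod(box[-ax])
  n_bins <- max(2L, round(Lz / bin_width))
  bw <- Lz / n_bins
  comp <- c("PDMS", "PMOXA", "WATER_INT", "WATER_BULK")
  n_frames <- length(traj$coords)
  rho_frames <- array(0, dim = c(n_bins, length(comp), n_frames),
                      dimnames = list(NULL, comp, NULL))
  pdms <- traj$labels == "PDMS"
  for (f in seq_len(n_frames)) {
    xyz <- traj$coords[[f]]
    z <- xyz[, ax]
    com <- if (center == "pdms")
      sum(traj$masses[pdms] * z[pdms]) / sum(traj$masses[pdms])
    else Lz / 2
    zc <- z - com
    zc <- zc - Lz * round(zc / Lz)  # minimum image about the core
    bin <- pmin(pmax(floor((zc + Lz / 2) / bw) + 1L, 1L), n_bins)
    is_int_w <- .classify_interfacial(xyz, traj$labels, box,
                                      interfacial_cutoff, ax)
    lab <- traj$labels
    lab[lab == "WATER"] <- ifelse(is_int_w, "WATER_INT", "WATER_BULK")
    for (k in seq_along(comp)) {
      sel <- lab == comp[k]
      if (any(sel))
        rho_frames[, k, f] <- .whist(bin[sel], traj$masses[sel], n_bins) *
          .AMU_KG / (lat * bw)
    }
  }
  rho <- apply(rho_frames, c(1, 2), mean)
  rho_sd <- if (n_frames > 1L) apply(rho_frames, c(1, 2), stats::sd)
            else rho * 0
  structure(list(z_centers = seq(-Lz / 2 + bw / 2, Lz / 2 - bw / 2, length.out = n_bins),
                 rho = rho, rho_sd = rho_sd, bin_width = bw, box = box,
                 n_frames = n_frames,
                 interfacial_cutoff = interfacial_cutoff,
                 rho_frames = if (keep_frames) rho_frames else NULL),
            class = "density_profile")
}

#' Construct a density profile directly from component curves
#'
#' Convenience constructor for analytic or hand-built profiles (used for
#' oracle checks of the metric definitions).
#'
#' @param z_centers uniform bin centres, nm.
#' @param rho matrix or data.frame of densities with (a subset of) columns
#'   `PDMS`, `PMOXA`, `WATER_INT`, `WATER_BULK`, kg/m^3.
#' @return a `density_profile`.
#' @export
density_profile_from_curves <- function(z_centers, rho) {
  rho <- as.matrix(rho)
  if (nrow(rho) != length(z_centers)) stop("row count must match z_centers")
  bws <- diff(z_centers)
  if (any(abs(bws - bws[1L]) > 1e-9)) stop("bins must be uniform")
  comp <- c("PDMS", "PMOXA", "WATER_INT", "WATER_BULK")
  full <- matrix(0, length(z_centers), length(comp), dimnames = list(NULL, comp))
  full[, colnames(rho)] <- rho
  structure(list(z_centers = as.numeric(z_centers), rho = full,
                 rho_sd = full * 0, bin_width = bws[1L], box = NULL,
                 n_frames = 1L, interfacial_cutoff = NA_real_,
                 rho_frames = NULL),
            class = "density_profile")
}

#' Write a density profile as CSV
#'
#' Columns `z_nm`, per-component densities and their across-frame
#' standard deviations.
#'
#' @param profile a `density_profile`.
#' @param path output file.
#' @export
write_profile_csv <- function(profile, path) {
  stopifnot(inherits(profile, "density_profile"))
  out <- data.frame(z_nm = profile$z_centers,
                    rho_PDMS = profile$rho[, "PDMS"],
                    rho_PMOXA = profile$rho[, "PMOXA"],
                    rho_water_int = profile$rho[, "WATER_INT"],
                    rho_water_bulk = profile$rho[, "WATER_BULK"],
                    sd_PDMS = profile$rho_sd[, "PDMS"],
                    sd_PMOXA = profile$rho_sd[, "PMOXA"],
                    sd_water_int = profile$rho_sd[, "WATER_INT"],
                    sd_water_bulk = profile$rho_sd[, "WATER_BULK"])
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

# linear interpolation of the z at which y crosses 'level' between bins
# i and i+1
.cross_z <- function(z, y, i, level) {
  z[i] + (level - y[i]) * (z[i + 1L] - z[i]) / (y[i + 1L] - y[i])
}

#' Hydrophobic core thickness from a density profile
#'
#' Distance between the two membrane-normal positions where the mean PDMS
#' density crosses 50% of its plateau maximum (linear interpolation
#' between bins).
#'
#' @param profile a `density_profile`.
#' @return thickness, nm.
#' @export
membrane_thickness <- function(profile) {
  stopifnot(inherits(profile, "density_profile"))
  .thickness_one(profile$z_centers, profile$rho[, "PDMS"])
}

.thickness_one <- function(z, rho) {
  peak <- max(rho)
  if (peak <= 0) stop("PDMS density is zero everywhere")
  half <- peak / 2
  above <- which(rho >= half)
  lo <- above[1L]; hi <- above[length(above)]
  z_left <- if (lo > 1L) .cross_z(z, rho, lo - 1L, half) else z[lo]
  z_right <- if (hi < length(z)) .cross_z(z, rho, hi, half) else z[hi]
  z_right - z_left
}

# per-leaflet metrics from one set of component curves; leaflet is +1/-1
.leaflet_metrics <- function(z, rho, leaflet) {
  sel <- if (leaflet > 0) z >= 0 else z <= 0
  zz <- abs(z[sel]); ord <- order(zz)
  zz <- zz[ord]
  wi <- rho[sel, "WATER_INT"][ord]
  pm <- rho[sel, "PMOXA"][ord]
  wb <- rho[sel, "WATER_BULK"][ord]

  # FWHM of the interfacial-water peak
  peak <- max(wi)
  if (peak <= 0) {
    fwhm <- 0
  } else {
    half <- peak / 2
    ip <- which.max(wi)
    inner <- zz[1L]
    if (ip > 1L) for (i in ip:2L) if (wi[i - 1L] < half) {
      inner <- .cross_z(zz, wi, i - 1L, half); break
    }
    outer_z <- zz[length(zz)]
    if (ip < length(zz)) for (i in seq(ip, length(zz) - 1L)) if (wi[i + 1L] < half) {
      outer_z <- .cross_z(zz, wi, i, half); break
    }
    fwhm <- outer_z - inner
  }

  # innermost PMOXA / bulk-water intersection walking outward
  d <- pm - wb
  crossover <- NA_real_
  seen_pos <- FALSE
  for (i in seq_along(d)) {
    if (d[i] > 0) seen_pos <- TRUE
    if (seen_pos && i < length(d) && d[i] > 0 && d[i + 1L] <= 0) {
      crossover <- .cross_z(zz, d, i, 0); break
    }
  }

  auc <- if (length(zz) > 1L) sum(diff(zz) * (wi[-1L] + wi[-length(wi)]) / 2) else 0
  c(water_layer_thickness = fwhm, crossover_height = crossover,
    interfacial_auc = auc)
}

#' Interfacial-water metrics of a membrane profile
#'
#' Per leaflet: the interfacial water-layer thickness (full width at half
#' maximum of the interfacial-water density peak), the cross-over height
#' (|z| at which the PMOXA density falls to the bulk-water density;
#' innermost intersection walking outward from the core, linearly
#' interpolated) and the interfacial-water area under the curve
#' (trapezoidal integral of density over z). Reported values are leaflet
#' means; uncertainties are across-frame standard deviations when the
#' profile retains per-frame data.
#'
#' @param profile a `density_profile` containing PMOXA, interfacial-water
#'   and bulk-water components.
#' @return object of class `interface_metrics`: `membrane_thickness`,
#'   `water_layer_thickness`, `crossover_height`, `interfacial_auc`
#'   (kg/m^3 nm, per leaflet mean), `per_leaflet` (2-row matrix),
#'   `uncertainties`, `crossover_found`.
#' @export
interface_metrics <- function(profile) {
  stopifnot(inherits(profile, "density_profile"))
  z <- profile$z_centers
  per <- rbind(lower = .leaflet_metrics(z, profile$rho, -1),
               upper = .leaflet_metrics(z, profile$rho, +1))
  if (all(profile$rho[, "WATER_INT"] == 0))
    warning("no interfacial water: zero layer thickness and AUC")
  crossover_found <- !anyNA(per[, "crossover_height"])
  if (!crossover_found)
    warning("no PMOXA/bulk-water intersection found in at least one leaflet")
  thick <- tryCatch(membrane_thickness(profile), error = function(e) NA_real_)

  unc <- c(membrane_thickness = NA_real_, water_layer_thickness = NA_real_,
           crossover_height = NA_real_, interfacial_auc = NA_real_)
  if (!is.null(profile$rho_frames) && dim(profile$rho_frames)[3L] > 1L) {
    fm <- apply(profile$rho_frames, 3, function(rho_f) {
      p <- rbind(.leaflet_metrics(z, rho_f, -1), .leaflet_metrics(z, rho_f, +1))
      c(tryCatch(.thickness_one(z, rho_f[, "PDMS"]), error = function(e) NA_real_),
        colMeans(p))
    })
    unc <- apply(fm, 1, stats::sd, na.rm = TRUE)
    names(unc) <- c("membrane_thickness", "water_layer_thickness",
                    "crossover_height", "interfacial_auc")
  }
  structure(list(membrane_thickness = thick,
                 water_layer_thickness = mean(per[, "water_layer_thickness"]),
                 crossover_height = mean(per[, "crossover_height"]),
                 interfacial_auc = mean(per[, "interfacial_auc"]),
                 per_leaflet = per, uncertainties = unc,
                 crossover_found = crossover_found),
            class = "interface_metrics")
}

#' @export
print.interface_metrics <- function(x, ...) {
  cat(sprintf(paste0("membrane thickness %.3f nm; interfacial water layer ",
                     "%.3f nm; crossover height %.3f nm; interfacial AUC %.1f kg/m^3 nm\n"),
              x$membrane_thickness, x$water_layer_thickness,
              x$crossover_height, x$interfacial_auc))
  invisible(x)
}

#' Root mean-squared fluctuations of a component
#'
#' After removing the per-frame membrane centre-of-mass translation
#' (membrane = PDMS + PMOXA atoms; all atoms if no membrane components are
#' present), each selected atom's RMSF is the root of the mean over frames
#' of its squared displacement from its own time-averaged position. The
#' selection mean is the headline value.
#'
#' @param traj a [trajectory()] with at least 2 frames.
#' @param selection component tag (default `"PMOXA"`).
#' @return object of class `rmsf_result`: `per_atom` (nm),
#'   `mean_over_selection` (nm), `selection`, `alignment`.
#' @export
rmsf <- function(traj, selection = "PMOXA") {
  stopifnot(inherits(traj, "trajectory"))
  n_frames <- length(traj$coords)
  if (n_frames < 2L) stop("RMSF needs at least 2 frames")
  sel <- traj$labels == selection
  if (!any(sel)) stop(sprintf("no atoms with label '%s'", selection))
  memb <- traj$labels %in% c("PDMS", "PMOXA")
  if (!any(memb)) memb <- rep(TRUE, length(traj$labels))
  wm <- traj$masses[memb] / sum(traj$masses[memb])
  # unwrap against frame 1 (minimum image) so periodic jumps do not count
  # as displacement
  ref_xyz <- traj$coords[[1L]]
  pos <- array(0, dim = c(sum(sel), 3, n_frames))
  for (f in seq_len(n_frames)) {
    d <- traj$coords[[f]] - ref_xyz
    for (axis in 1:3)
      d[, axis] <- d[, axis] - traj$box[f, axis] * round(d[, axis] / traj$box[f, axis])
    xyz <- ref_xyz + d
    com <- colSums(xyz[memb, , drop = FALSE] * wm)
    pos[, , f] <- sweep(xyz[sel, , drop = FALSE], 2, com)
  }
  ref <- apply(pos, c(1, 2), mean)
  sq <- sapply(seq_len(n_frames), function(f) rowSums((pos[, , f] - ref)^2))
  per_atom <- sqrt(rowMeans(sq))
  structure(list(per_atom = per_atom,
                 mean_over_selection = mean(per_atom),
                 selection = selection,
                 alignment = "per-frame membrane COM translation removed"),
            class = "rmsf_result")
}
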