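test_that("a uniform water box profiles flat at the imposed bulk density", {
  set.seed(31)
  n <- 2e5
  box <- c(4, 4, 10)
  rho_target <- 800  # kg/m^3
  # place exactly the atom count that realises the target density
  mass <- rho_target * prod(box) / (1.66053906660 * n)
  coords <- list(cbind(runif(n, 0, 4), runif(n, 0, 4), runif(n, 0, 10)))
  traj <- trajectory(coords, rep("WATER", n), mass, box)
  prof <- density_profile(traj, bin_width = 0.5, center = "none")
  tot <- prof$rho[, "WATER_INT"] + prof$rho[, "WATER_BULK"]
  expect_true(all(abs(tot / rho_target - 1) < 0.05))
})

test_that("density profiles conserve mass and split water exactly", {
  m <- default_membrane()
  prof <- m$prof
  lat <- prod(prof$box[-3])
  total_mass <- sum(prof$rho) * lat * prof$bin_width / 1.66053906660
  expect_equal(total_mass, sum(m$traj$masses), tolerance = 1e-9)
  # interfacial + bulk water equals the profile of all water atoms bin-wise
  traj_all_bulk <- m$traj
  prof0 <- density_profile(traj_all_bulk, interfacial_cutoff = 0)
  expect_equal(prof$rho[, "WATER_INT"] + prof$rho[, "WATER_BULK"],
               prof0$rho[, "WATER_BULK"], tolerance = 1e-9)
})

test_that("membrane thickness recovers the generator core width and scales with z", {
  m <- default_membrane()
  expect_equal(membrane_thickness(m$prof), m$truth$membrane_thickness,
               tolerance = 0.1 / m$truth$membrane_thickness)
  # doubling z coordinates and the normal box dimension doubles the thickness
  scaled <- m$traj
  scaled$coords <- lapply(scaled$coords, function(xyz) {
    xyz[, 3] <- xyz[, 3] * 2; xyz
  })
  scaled$box[, 3] <- scaled$box[, 3] * 2
  expect_equal(membrane_thickness(density_profile(scaled)),
               2 * m$truth$membrane_thickness, tolerance = 0.05)
})

test_that("symmetric membranes give mirror-symmetric profiles and crossings", {
  m <- default_membrane()
  rho <- m$prof$rho
  for (comp in c("PDMS", "PMOXA")) {
    v <- rho[, comp]
    asym <- sum(abs(v - rev(v))) / sum(v)
    expect_lt(asym, 0.05)
  }
  # 50%-crossings of the PDMS profile are symmetric about 0 within a bin
  met <- interface_metrics(m$prof)
  per <- met$per_leaflet
  expect_lt(abs(per["lower", "crossover_height"] -
                per["upper", "crossover_height"]), 2 * m$prof$bin_width)
})

test_that("constructed profiles reproduce the interface metric definitions", {
  z <- seq(-5.95, 5.95, by = 0.1)
  # triangular interfacial peak centred at |z| = 3 with FWHM 1.2
  tri <- function(u, c0, half_base) pmax(0, 1 - abs(u - c0) / half_base)
  wi <- 500 * (tri(abs(z), 3, 1.2))
  # PMOXA falls linearly, bulk water rises; lines cross exactly at |z| = 3
  pm <- pmax(0, 600 - 100 * abs(z))
  wb <- pmax(0, 100 * abs(z))  # equals pm at |z| = 3
  pd <- ifelse(abs(z) < 2, 900, 0)
  prof <- density_profile_from_curves(z, cbind(PDMS = pd, PMOXA = pm,
                                               WATER_INT = wi, WATER_BULK = wb))
  met <- interface_metrics(prof)
  expect_equal(met$water_layer_thickness, 1.2, tolerance = 0.1 / 1.2)
  expect_equal(met$crossover_height, 3.0, tolerance = 0.1 / 3)
  # trapezoid AUC of the triangle: area = 500 * 1.2
  expect_equal(met$interfacial_auc, 500 * 1.2, tolerance = 0.01)

  # zero interfacial water: zero thickness and AUC, with a warning
  prof0 <- density_profile_from_curves(z, cbind(PDMS = pd, PMOXA = pm,
                                                WATER_INT = wi * 0,
                                                WATER_BULK = wb))
  expect_warning(met0 <- interface_metrics(prof0), "no interfacial water")
  expect_equal(met0$water_layer_thickness, 0)
  expect_equal(met0$interfacial_auc, 0)
})

test_that("missing PMOXA/bulk-water crossings are flagged rather than fatal", {
  z <- seq(-4.95, 4.95, by = 0.1)
  pd <- ifelse(abs(z) < 2, 900, 0)
  pm <- ifelse(abs(z) >= 2 & abs(z) < 3, 50, 0)
  wb <- rep(800, length(z))  # bulk always above PMOXA
  prof <- density_profile_from_curves(z, cbind(PDMS = pd, PMOXA = pm,
                                               WATER_INT = pm, WATER_BULK = wb))
  expect_warning(met <- interface_metrics(prof), "intersection")
  expect_false(met$crossover_found)
  expect_true(is.na(met$crossover_height))
})

test_that("profiles require PDMS for centring unless centring is disabled", {
  coords <- list(cbind(runif(50, 0, 4), runif(50, 0, 4), runif(50, 0, 10)))
  traj <- trajectory(coords, rep("WATER", 50), 18, c(4, 4, 10))
  expect_error(density_profile(traj), "no PDMS")
  expect_s3_class(density_profile(traj, center = "none"), "density_profile")
})

test_that("RMSF vanishes for frozen or rigidly translated trajectories", {
  base <- generate_membrane_trajectory(membrane_sim_config(
    n_frames = 1, atom_mass = 300, seed = 5))
  xyz <- base$coords[[1]]
  frozen <- trajectory(list(xyz, xyz, xyz), base$labels, base$masses[1],
                       c(4, 4, 12))
  expect_equal(rmsf(frozen, "PMOXA")$mean_over_selection, 0)
  # rigid translation of whole frames is removed by COM alignment
  shifted <- trajectory(list(xyz, sweep(xyz, 2, c(0.3, -0.2, 0.5), "+"),
                             sweep(xyz, 2, c(-0.4, 0.1, 1.0), "+")),
                        base$labels, base$masses[1], c(4, 4, 12))
  expect_lt(rmsf(shifted, "PMOXA")$mean_over_selection, 1e-10)
  expect_error(rmsf(trajectory(list(xyz), base$labels, base$masses[1],
                               c(4, 4, 12))), "2 frames")
})

test_that("RMSF is invariant to frame order", {
  traj <- generate_membrane_trajectory(membrane_sim_config(
    n_frames = 8, atom_mass = 300, seed = 6))
  r1 <- rmsf(traj, "PMOXA")
  shuffled <- traj
  shuffled$coords <- traj$coords[c(5, 2, 8, 1, 7, 3, 6, 4)]
  shuffled$box <- traj$box[c(5, 2, 8, 1, 7, 3, 6, 4), ]
  r2 <- rmsf(shuffled, "PMOXA")
  expect_equal(r2$per_atom, r1$per_atom, tolerance = 1e-12)
})
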