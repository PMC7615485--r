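# Shared fixtures, built in code and cached for the session.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# the two-species fouling mixture used across FCS tests
fouling_species <- function(n_slow = 3) {
  data.frame(count = c(60, n_slow),
             D = c(diffusion_from_tau_d(4e-5), diffusion_from_tau_d(2e-3)),
             brightness = c(4, 20))
}

fouling_spec <- function() {
  fcs_model_spec(list(fcs_component(4e-5, 0.5, fixed_tau_d = TRUE),
                      fcs_component(2e-3, 0.5, fixed_tau_d = TRUE)))
}

# one default synthetic membrane slab + its density profile
default_membrane <- function() {
  cached("membrane", {
    traj <- generate_membrane_trajectory(membrane_sim_config(seed = 3))
    list(traj = traj, prof = density_profile(traj),
         truth = attr(traj, "truth"))
  })
}

# tiny deterministic trace for correlator tests
poisson_trace <- function(n = 4096, seed = 42) {
  set.seed(seed)
  structure(list(values = stats::rpois(n, 20) + stats::runif(n),
                 bin_width = 1e-5, duration = n * 1e-5, truth = NULL),
            class = "intensity_trace")
}

# write a tiny 2-frame xyz fixture, returning its path
write_xyz_fixture <- function(path = tempfile(fileext = ".xyz")) {
  lines <- c()
  for (f in 1:2) {
    z <- c(4.9, 5.1, 5.4, 5.6, 4.4, 4.6, 3.5, 6.5, 2.0, 8.0) + (f - 1) * 0.01
    nm <- c("C", "C", "P", "P", "P", "P", "W", "W", "W", "W")
    lines <- c(lines, "10", sprintf("frame %d", f),
               sprintf("%s %.3f %.3f %.3f", nm, seq(0.5, 5, length.out = 10),
                       rep(2.5, 10), z))
  }
  writeLines(lines, path)
  path
}

xyz_map <- c(C = "PDMS", P = "PMOXA", W = "WATER")

# GRO fixture: 4 atoms, 1 frame
write_gro_fixture <- function(path = tempfile(fileext = ".gro")) {
  atoms <- sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                   c(1, 1, 2, 2), c("PDM", "PDM", "SOL", "SOL"),
                   c("C1", "C2", "OW", "OW"), 1:4,
                   c(1.0, 2.0, 1.5, 2.5), c(1.0, 1.0, 2.0, 2.0),
                   c(2.5, 2.6, 4.0, 1.0))
  writeLines(c("slab", "4", atoms, "5.000 5.000 5.000"), path)
  path
}
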