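test_that("noiseless two-component curves round-trip through the constrained fit", {
  fit_spec <- fcs_model_spec(list(fcs_component(4e-5, 0.5, fixed_tau_d = TRUE),
                                  fcs_component(5e-3, 0.5, fixed_tau_d = TRUE)))
  truth <- fcs_model_spec(list(fcs_component(4e-5, 0.7), fcs_component(5e-3, 0.3)),
                          N = 2)
  curve <- generate_fcs_curve(truth, mean_count_rate = 40)
  fit <- fit_curve(curve, fit_spec)
  expect_true(fit$converged)
  expect_equal(fit$F2, 30, tolerance = 1e-6)
  expect_equal(fit$N, 2, tolerance = 1e-6)
  expect_equal(fit$cpp, 20, tolerance = 1e-5)

  # other compositions on the ladder of generated curves
  for (fs in c(0.05, 0.5, 0.95)) {
    tr <- fcs_model_spec(list(fcs_component(4e-5, 1 - fs),
                              fcs_component(5e-3, fs)), N = 1.3)
    ft <- fit_curve(generate_fcs_curve(tr), fit_spec)
    expect_equal(ft$F2, 100 * fs, tolerance = 1e-5)
  }
})

test_that("a pure free-dye curve fitted with two components yields F2 near zero", {
  truth <- fcs_model_spec(fcs_component(4e-5), N = 1.5)
  curve <- generate_fcs_curve(truth, noise_sd = 2e-3, seed = 7)
  fit <- fit_curve(curve, fouling_spec())
  expect_true(fit$converged)
  expect_lte(fit$F2, 2)
})

test_that("two-component fits require fixed diffusion times and enough points", {
  spec_free <- fcs_model_spec(list(fcs_component(4e-5, 0.5, fixed_tau_d = FALSE),
                                   fcs_component(5e-3, 0.5)))
  curve <- generate_fcs_curve(fcs_model_spec(fcs_component(4e-5)))
  expect_error(fit_curve(curve, spec_free), "fixed")
  tiny <- correlation_curve(c(1e-5, 1e-4), c(0.5, 0.4))
  expect_error(fit_curve(tiny, fouling_spec()), "free parameters")
  neg <- correlation_curve(curve$tau, -abs(curve$G) - 0.01)
  expect_error(fit_curve(neg, fouling_spec()), "positive amplitudes")
})

test_that("fully fixed evaluation reproduces the direct residual chi-square", {
  truth <- fcs_model_spec(list(fcs_component(4e-5, 0.6), fcs_component(5e-3, 0.4)),
                          N = 1.2)
  curve <- generate_fcs_curve(truth, noise_sd = 5e-3, seed = 3)
  fit <- fit_curve(curve, truth, fix_N = TRUE, fix_fractions = TRUE)
  expect_equal(fit$n_free, 0)
  direct <- sum(((g_model(curve$tau, truth) - curve$G) / curve$sigma_G)^2) /
    length(curve$tau)
  expect_equal(fit$chi2_reduced, direct, tolerance = 1e-12)
})

test_that("brightness-squared weighting makes small bound number fractions dominate F2", {
  # 5% of particles bound to 10x-brighter slow vesicles
  cfg <- fcs_sim_config(data.frame(count = c(95, 5), D = c(4e-10, 8e-12),
                                   brightness = c(2, 20)))
  tru <- fcs_sim_truth(cfg)
  number_fraction <- 5 / 100
  expect_gt(tru$amplitude_fractions[2], number_fraction)
  # and the fit of the corresponding model curve reports that amplitude share
  spec_true <- fcs_model_spec(list(
    fcs_component(tru$tau_d[1], tru$amplitude_fractions[1]),
    fcs_component(tru$tau_d[2], tru$amplitude_fractions[2])), N = tru$N_app)
  ft <- fit_curve(generate_fcs_curve(spec_true),
                  fcs_model_spec(list(fcs_component(tru$tau_d[1], 0.5),
                                      fcs_component(tru$tau_d[2], 0.5))))
  expect_gt(ft$F2, 100 * number_fraction)
})

test_that("counts per particle are higher for bright slow samples than dim fast ones", {
  rate <- 100  # same detected count rate, kHz
  slow_bright <- fit_curve(
    generate_fcs_curve(fcs_model_spec(fcs_component(5e-3), N = 1),
                       mean_count_rate = rate),
    fcs_model_spec(fcs_component(5e-3)))
  fast_dim <- fit_curve(
    generate_fcs_curve(fcs_model_spec(fcs_component(4e-5), N = 10),
                       mean_count_rate = rate),
    fcs_model_spec(fcs_component(4e-5)))
  expect_gt(slow_bright$cpp, fast_dim$cpp)
})

test_that("free-dye calibration recovers the diffusion time and diameter spread", {
  truth_tau <- 3.8e-5
  spec1 <- fcs_model_spec(fcs_component(truth_tau), N = 1.5)
  curves <- lapply(1:6, function(s)
    generate_fcs_curve(spec1, noise_sd = 2e-3, seed = s))
  cal <- calibrate_free_dye(curves, fcs_model_spec(fcs_component(5e-5)))
  expect_equal(cal$n_used, 6)
  expect_equal(cal$tau_d_mean, truth_tau, tolerance = 0.05)
  d_expect <- stokes_einstein_diameter(diffusion_from_tau_d(truth_tau))
  expect_equal(cal$diameter_mean_nm, d_expect, tolerance = 0.05)

  # single noiseless curve: zero spread
  cal1 <- calibrate_free_dye(list(generate_fcs_curve(spec1)),
                             fcs_model_spec(fcs_component(5e-5)))
  expect_equal(cal1$tau_d_sd, 0)
  expect_equal(cal1$diameter_sd_nm, 0)
  expect_error(calibrate_free_dye(list(), fcs_model_spec(fcs_component(5e-5))),
               "no curves")
})

test_that("aggregate exclusion removes high-F2 repeats and preserves order", {
  mk <- function(f2, cpp = 5) structure(list(F2 = f2, cpp = cpp),
                                        class = "fcs_fit_result")
  results <- c(lapply(rep(10, 12), mk), lapply(rep(90, 3), mk),
               lapply(rep(20, 10), mk))
  out <- exclude_aggregates(results, f2_threshold = 50)
  expect_length(out$kept, 22)
  expect_length(out$excluded, 3)
  expect_true(all(vapply(out$excluded, function(r) r$F2, numeric(1)) == 90))
  # order preserved among kept
  expect_equal(vapply(out$kept, function(r) r$F2, numeric(1)),
               c(rep(10, 12), rep(20, 10)))

  expect_length(exclude_aggregates(results, 100)$excluded, 0)
  expect_warning(out2 <- exclude_aggregates(lapply(rep(90, 3), mk), 50),
                 "nothing kept")
  expect_length(out2$kept, 0)
  # cpp-based exclusion
  out3 <- exclude_aggregates(lapply(c(5, 500), mk, f2 = 10), 50,
                             cpp_threshold = 100)
  expect_length(out3$excluded, 1)
})

test_that("repeat aggregation takes per-experiment medians then mean and sem", {
  mk <- function(f2) structure(list(F2 = f2), class = "fcs_fit_result")
  res <- lapply(c(10, 20, 30), mk)
  agg <- aggregate_repeats(res, timepoints = rep(1, 3))
  expect_equal(agg$median_F2, 20)
  expect_equal(agg$sem_F2, 0)

  agg1 <- aggregate_repeats(list(mk(42)), timepoints = "4h")
  expect_equal(agg1$median_F2, 42)
  expect_equal(agg1$sem_F2, 0)

  # two experiments with medians 20 and 30 -> mean 25, sem 5
  res2 <- lapply(c(15, 20, 25, 28, 30, 32), mk)
  agg2 <- aggregate_repeats(res2, timepoints = rep("1h", 6),
                            experiments = rep(c("A", "B"), each = 3))
  expect_equal(agg2$median_F2, 25)
  expect_equal(agg2$sem_F2, 5)

  expect_error(aggregate_repeats(list(), timepoints = character(0)), "no results")
})

test_that("correlation curves survive a CSV round trip", {
  spec1 <- fcs_model_spec(fcs_component(4e-5), N = 2)
  curve <- generate_fcs_curve(spec1, noise_sd = 1e-3, seed = 1,
                              mean_count_rate = 33.5, label = "dye ctrl")
  curve$duration <- 10
  p <- tempfile(fileext = ".csv")
  write_fcs_csv(curve, p)
  back <- read_fcs_csv(p)
  expect_equal(back$tau, curve$tau, tolerance = 1e-10)
  expect_equal(back$G, curve$G, tolerance = 1e-10)
  expect_equal(back$sigma_G, curve$sigma_G, tolerance = 1e-10)
  expect_equal(back$mean_count_rate, 33.5)
  expect_equal(back$label, "dye ctrl")
})
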