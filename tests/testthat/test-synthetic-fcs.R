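test_that("direct correlator matches hand-computed values", {
  tr <- structure(list(values = rep(c(1, 2), 8), bin_width = 1, duration = 16,
                       truth = NULL), class = "intensity_trace")
  cc <- autocorrelate_direct(tr, 0:1)
  # alternating 1,2: mean 1.5, var 0.25 -> G(1) = -0.25/2.25 = -1/9
  expect_equal(cc$G[1], -1 / 9)
  # lag 0: variance / mean^2
  expect_equal(attr(cc, "G0"), 0.25 / 2.25)
})

test_that("white-noise traces have a correlation floor scaling as 1/sqrt(n)", {
  set.seed(5)
  n <- 8192
  tr <- structure(list(values = stats::rnorm(n, 50, 3), bin_width = 1e-5,
                       duration = n * 1e-5, truth = NULL),
                  class = "intensity_trace")
  cc <- autocorrelate_direct(tr, c(50, 500, 3000))
  expect_true(all(abs(cc$G) < 3 / sqrt(n)))
})

test_that("multi-tau agrees with the direct correlator", {
  tr <- poisson_trace()
  mt <- autocorrelate_multitau(tr, m = 16)
  # full-resolution stage: identical estimator on the raw trace
  stage0 <- 1:32
  dr <- autocorrelate_direct(tr, round(mt$tau[stage0] / tr$bin_width))
  expect_lt(max(abs(mt$G[stage0] - dr$G)), 1e-10)
  # a coarsened stage equals the direct correlator on the coarsened trace
  half <- (tr$values[seq(1, 4096, 2)] + tr$values[seq(2, 4096, 2)]) / 2
  tr2 <- structure(list(values = half, bin_width = 2e-5, duration = tr$duration,
                        truth = NULL), class = "intensity_trace")
  stage1 <- 33:48
  dr2 <- autocorrelate_direct(tr2, round(mt$tau[stage1] / tr2$bin_width))
  expect_lt(max(abs(mt$G[stage1] - dr2$G)), 1e-10)
})

test_that("constant traces decorrelate to zero and zero-mean traces error", {
  tr <- structure(list(values = rep(7, 1024), bin_width = 1e-5,
                       duration = 1024e-5, truth = NULL),
                  class = "intensity_trace")
  cc <- autocorrelate_multitau(tr, m = 8)
  expect_true(all(abs(cc$G) < 1e-14))
  tr0 <- structure(list(values = rep(0, 64), bin_width = 1, duration = 64,
                        truth = NULL), class = "intensity_trace")
  expect_error(autocorrelate_multitau(tr0), "zero-mean")
})

test_that("a pinned static emitter produces a constant trace at its brightness", {
  cfg <- fcs_sim_config(data.frame(count = 1, D = 0, brightness = 5,
                                   init_center = TRUE),
                        n_steps = 256, seed = 1)
  tr <- simulate_fcs_trace(cfg)
  expect_equal(tr$values, rep(5, 256), tolerance = 1e-12)
})

test_that("traces are bit-reproducible per seed and differ across seeds", {
  sp <- data.frame(count = 5, D = 4e-10, brightness = 10)
  t1 <- simulate_fcs_trace(fcs_sim_config(sp, n_steps = 2048, seed = 9))
  t2 <- simulate_fcs_trace(fcs_sim_config(sp, n_steps = 2048, seed = 9))
  t3 <- simulate_fcs_trace(fcs_sim_config(sp, n_steps = 2048, seed = 10))
  expect_identical(t1$values, t2$values)
  expect_false(identical(t1$values, t3$values))
})

test_that("the mean trace rate matches the analytic Gaussian-volume average", {
  cfg <- fcs_sim_config(data.frame(count = 200, D = 4e-10, brightness = 10),
                        n_steps = 2^18, background = 0.5, seed = 21)
  tr <- simulate_fcs_trace(cfg)
  expect_equal(mean(tr$values), fcs_sim_truth(cfg)$mean_rate, tolerance = 0.05)
})

test_that("simulation configs enforce box geometry and step-size sanity", {
  sp <- data.frame(count = 1, D = 4e-10, brightness = 1)
  expect_error(fcs_sim_config(sp, box = c(1, 2, 5)), "8 x w_xy")
  expect_error(fcs_sim_config(sp, box = c(2, 2, 2)), "w_z")
  expect_warning(fcs_sim_config(data.frame(count = 1, D = 1e-7, brightness = 1)),
                 "step")
})

test_that("poisson photon sampling adds shot noise around the expected trace", {
  sp <- data.frame(count = 30, D = 4e-10, brightness = 50)
  te <- simulate_fcs_trace(fcs_sim_config(sp, n_steps = 2^14, seed = 4))
  tp <- simulate_fcs_trace(fcs_sim_config(sp, n_steps = 2^14, seed = 4,
                                          photon_sampling = "poisson"))
  expect_false(identical(te$values, tp$values))
  expect_equal(mean(tp$values), mean(te$values), tolerance = 0.1)
  expect_true(all(tp$values >= 0))
})

test_that("generated model curves round-trip and are seed-reproducible", {
  truth <- fcs_model_spec(list(fcs_component(4e-5, 0.8), fcs_component(5e-3, 0.2)),
                          N = 1.4)
  clean <- generate_fcs_curve(truth)
  ft <- fit_curve(clean,
                  fcs_model_spec(list(fcs_component(4e-5, 0.5, fixed_tau_d = TRUE),
                                      fcs_component(5e-3, 0.5, fixed_tau_d = TRUE))))
  expect_equal(ft$F2, 20, tolerance = 1e-5)
  # zero slow fraction reduces to the one-component curve
  spec0 <- fcs_model_spec(list(fcs_component(4e-5, 1), fcs_component(5e-3, 0)),
                          N = 1.4)
  one <- generate_fcs_curve(fcs_model_spec(fcs_component(4e-5), N = 1.4))
  expect_equal(generate_fcs_curve(spec0)$G, one$G, tolerance = 1e-12)
  n1 <- generate_fcs_curve(truth, noise_sd = 0.01, seed = 11)
  n2 <- generate_fcs_curve(truth, noise_sd = 0.01, seed = 11)
  expect_identical(n1$G, n2$G)
})

test_that("intensity traces survive a CSV round trip", {
  sp <- data.frame(count = 3, D = 4e-10, brightness = 8)
  tr <- simulate_fcs_trace(fcs_sim_config(sp, n_steps = 512, seed = 2))
  p <- tempfile(fileext = ".csv")
  write_trace_csv(tr, p)
  back <- read_trace_csv(p)
  expect_equal(back$values, tr$values, tolerance = 1e-9)
  expect_equal(back$bin_width, tr$bin_width)
})
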