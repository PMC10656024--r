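make_targets <- function(w1_mean, wf_mean, sd_frac = 0.2,
                         weeks = c(17, 41)) {
  dplyr::bind_rows(
    tibble::tibble(week = weeks[1], subclass = igg_subclasses(),
                   mean_M = w1_mean, sd_M = sd_frac * w1_mean),
    tibble::tibble(week = weeks[2], subclass = igg_subclasses(),
                   mean_M = wf_mean, sd_M = sd_frac * wf_mean)
  )
}

test_that("the pass rule applies the first/final data bands per subclass", {
  tg <- make_targets(1e-6, 1e-5)
  sim_exact <- rbind(`17` = rep(1e-6, 4), `41` = rep(1e-5, 4))
  colnames(sim_exact) <- igg_subclasses()
  expect_true(calibration_passes(sim_exact, tg))

  # final point at mean + 2 SD fails; at mean + 1.4 SD passes
  sim_hi <- sim_exact; sim_hi["41", ] <- 1e-5 * (1 + 2 * 0.2)
  expect_false(calibration_passes(sim_hi, tg))
  sim_ok <- sim_exact; sim_ok["41", ] <- 1e-5 * (1 + 1.4 * 0.2)
  expect_true(calibration_passes(sim_ok, tg))

  # first point is one-sided: arbitrarily low passes, too high fails
  sim_lo <- sim_exact; sim_lo["17", ] <- 0
  expect_true(calibration_passes(sim_lo, tg))
  sim_hi1 <- sim_exact; sim_hi1["17", ] <- 1e-6 * (1 + 1.5 * 0.2)
  expect_false(calibration_passes(sim_hi1, tg))

  # the total-IgG variant pools the subclasses
  expect_true(calibration_passes(sim_hi1, tg, rule = "total") ||
                !calibration_passes(sim_hi1, tg))
})

test_that("pass evaluation interpolates a placenta_sim trajectory", {
  sim <- simulate_placenta(t_end = 41, by = 1)
  fetal41 <- sim$states[sim$states[, "time"] == 41,
                        paste0(igg_subclasses(), ".F")]
  fetal17 <- sim$states[sim$states[, "time"] == 17,
                        paste0(igg_subclasses(), ".F")]
  tg <- dplyr::bind_rows(
    tibble::tibble(week = 17, subclass = igg_subclasses(),
                   mean_M = unname(fetal17), sd_M = 0.2 * unname(fetal17)),
    tibble::tibble(week = 41, subclass = igg_subclasses(),
                   mean_M = unname(fetal41), sd_M = 0.2 * unname(fetal41))
  )
  expect_true(calibration_passes(sim, tg))
  expect_error(calibration_passes(fast_sim(t_end = 30), tg), "span")
})

test_that("degenerate ranges at the truth pass immediately", {
  tg <- generate_cordocentesis_fixture(cv = 0.2)
  rng <- default_parameter_ranges()
  p <- default_parameters()
  rng$lower <- rng$upper <- vapply(rng$parameter, function(f) p[[f]],
                                   numeric(1))
  fit <- calibrate_parameters(rng, tg, n_samples = 50, seed = 1,
                              max_iter = 3)
  expect_true(fit$converged)
  expect_equal(nrow(fit$iterations), 1L)
  expect_equal(fit$iterations$pass_fraction, 1)
})

test_that("calibration recovers the generating parameters", {
  tg <- generate_cordocentesis_fixture(cv = 0.2)
  fit <- calibrate_parameters(targets = tg, n_samples = 150, seed = 3,
                              max_iter = 6)
  fr <- tidy(fit)
  truth <- default_parameters()
  inside <- vapply(seq_len(nrow(fr)), function(i) {
    v <- truth[[fr$parameter[i]]]
    v >= fr$lower[i] && v <= fr$upper[i]
  }, logical(1))
  expect_gte(sum(inside), 9)
  # final ranges nest inside the initial ones
  rng <- default_parameter_ranges()
  expect_true(all(fr$lower >= rng$lower - 1e-12))
  expect_true(all(fr$upper <= rng$upper + 1e-12))
  # pass fraction does not deteriorate across iterations
  pf <- fit$iterations$pass_fraction
  expect_true(all(diff(pf) > -0.02 - 2 * sqrt(0.25 / 150)))
})

test_that("infeasible targets produce a calibration failure", {
  tg <- generate_cordocentesis_fixture(cv = 0.2)
  tg$mean_M <- tg$mean_M + 10 * tg$sd_M
  expect_error(
    calibrate_parameters(targets = tg, n_samples = 50, seed = 1,
                         max_iter = 2),
    "no passing")
})

test_that("calibration is bit-reproducible under a fixed seed", {
  tg <- generate_cordocentesis_fixture(cv = 0.25)
  f1 <- calibrate_parameters(targets = tg, n_samples = 60, seed = 11,
                             max_iter = 2)
  f2 <- calibrate_parameters(targets = tg, n_samples = 60, seed = 11,
                             max_iter = 2)
  expect_identical(tidy(f1), tidy(f2))
  expect_identical(f1$iterations, f2$iterations)
})

test_that("target tables round-trip through CSV", {
  tg <- generate_cordocentesis_fixture(cv = 0.2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_calibration_targets(tg, path)
  tg2 <- read_calibration_targets(path)
  expect_equal(tg2$mean_M, tg$mean_M, tolerance = 1e-15)
  expect_identical(tg2$subclass, tg$subclass)
})
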