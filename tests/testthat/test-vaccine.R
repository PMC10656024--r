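test_that("no antigen means pure exponential decay of existing IgG", {
  resp <- simulate_vaccine_response(vaccine_parameters(Ag0 = 0),
                                    days = 0:30, IgG0 = 2)
  expect_equal(resp$IgG_PT, 2 * exp(-0.033 * resp$day), tolerance = 1e-6)
})

test_that("the default response spikes transiently, peaking day 14-28", {
  resp <- simulate_vaccine_response(days = seq(0, 120, 0.5))
  pk <- which.max(resp$IgG_PT)
  expect_gt(resp$day[pk], 14)
  expect_lt(resp$day[pk], 28)
  # strict interior maximum: rises before, falls after
  expect_gt(resp$IgG_PT[pk], resp$IgG_PT[pk - 10])
  expect_gt(resp$IgG_PT[pk], resp$IgG_PT[pk + 10])
  # transient: by one year the titer has fallen well below the peak
  expect_lt(resp$IgG_PT[resp$day == 120], 0.5 * max(resp$IgG_PT))
})

test_that("the cascade is exactly linear in the antigen dose", {
  d1 <- simulate_vaccine_response(vaccine_parameters(Ag0 = 100),
                                  days = seq(0, 60, 2))
  d3 <- simulate_vaccine_response(vaccine_parameters(Ag0 = 300),
                                  days = seq(0, 60, 2))
  expect_equal(d3$IgG_PT, 3 * d1$IgG_PT, tolerance = 1e-8)
})

test_that("long-lived plasma cells flatten the response as rho falls", {
  lo <- simulate_vaccine_response(vaccine_parameters(rho = 0),
                                  days = seq(0, 300, 1))
  # quasi-plateau: late decline is slow (L_ASC half-life ~ 1050 days)
  late <- lo$IgG_PT[lo$day >= 200]
  expect_lt((max(late) - min(late)) / max(late), 0.12)
})

test_that("vaccination timing must precede delivery", {
  expect_error(simulate_vaccinated_pregnancy(t_vax = 40,
                                             gestational_length = 40),
               "t_vax")
  expect_error(simulate_vaccinated_pregnancy(t_vax = 0), "t_vax")
})

test_that("fetal vaccine-induced IgG is causal and non-negative", {
  sim <- simulate_vaccinated_pregnancy(t_vax = 25, by = 1)
  apt <- rowSums(sim$states[, paste0("aPT_", igg_subclasses(), ".F")])
  expect_true(all(apt[sim$times <= 25] < 1e-20))
  expect_true(all(apt >= 0))
  expect_gt(fetal_apt_igg(sim), 0)
})

test_that("longer gestation transfers more vaccine-induced IgG", {
  f40 <- fetal_apt_igg(simulate_vaccinated_pregnancy(
    t_vax = 25, gestational_length = 40, by = 1))
  f30 <- fetal_apt_igg(simulate_vaccinated_pregnancy(
    t_vax = 25, gestational_length = 30, by = 1))
  expect_gt(f40, f30)
})

test_that("delivery titers vary smoothly with vaccination week", {
  tv <- seq(18, 30, 0.5)
  vals <- vapply(tv, function(t) {
    fetal_apt_igg(simulate_vaccinated_pregnancy(t_vax = t, by = 2))
  }, numeric(1))
  jumps <- abs(diff(vals)) / pmax(vals[-1], vals[-length(vals)])
  expect_lt(max(jumps), 0.05)
})

test_that("optimize_tvax returns the grid argmax and its curve", {
  opt <- optimize_tvax(sweep = seq(20, 30, 2), refine = FALSE, by = 1)
  expect_equal(opt$optimal_t_vax,
               opt$curve$t_vax[which.max(opt$curve$fetal_aPT_M)])
  expect_error(optimize_tvax(gestational_length = 9), "empty")
})

test_that("scenario baselines are identities", {
  fd <- fcr_deficiency_scenario(receptor = "FcRnSTB", fold_grid = 1,
                                by = 1)
  expect_equal(fd$pct_change, 0, tolerance = 1e-8)
  aff <- affinity_scenario(target = "FcRn", kd_fold_decrease = 1, by = 1)
  expect_equal(aff$pct_change, 0, tolerance = 1e-8)
  dc <- dose_compensation(receptor = "FcRnSTB", deficiency_fold = 1,
                          dose_grid = 1:2, by = 1)
  expect_equal(dc$restoring_fold, 1)
})

test_that("fetal vaccine-induced IgG is non-decreasing in dose", {
  folds <- c(1, 2, 4, 8)
  vals <- vapply(folds, function(f) {
    fetal_apt_igg(simulate_vaccinated_pregnancy(
      vax = vaccine_parameters(Ag0 = 100 * f), t_vax = 25, by = 2))
  }, numeric(1))
  expect_true(all(diff(vals) > 0))
})
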