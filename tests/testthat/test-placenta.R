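test_that("the all-zero IgG state is absorbing", {
  state <- placental_state()
  state[] <- 0
  d <- placental_rhs(20, state)$derivatives
  expect_true(all(d == 0))
})

test_that("compiled and R right-hand sides agree along a trajectory", {
  simc <- simulate_placenta(by = 5)
  simr <- simulate_placenta(by = 5, use_compiled = FALSE)
  nm <- paste0(rep(igg_subclasses(), each = 2), c(".F", ".STR"))
  for (cn in nm) {
    expect_equal(simc$states[, cn], simr$states[, cn], tolerance = 1e-6)
  }
})

test_that("IgG moles are conserved when degradation and decay are off", {
  p <- placenta_parameters(k_deg = 0, delta_Ab = 0)
  sch <- constant_schedules(p)  # receptor totals constant in time
  sim <- simulate_placenta(p, schedules = sch, by = 2,
                           maternal_dynamics = TRUE,
                           rtol = 1e-10, atol = 1e-16)
  tot <- igtransfer:::.total_moles(sim)
  drift <- abs(tot - tot[1]) / tot[1]
  expect_lt(max(drift), 1e-8)
})

test_that("single-subclass system with huge receptors conserves moles", {
  p <- placenta_parameters(k_deg = 0, delta_Ab = 0)
  p$IgG0[c("IgG2", "IgG3", "IgG4")] <- 0
  p <- igtransfer:::.validate_parameters(p)
  big <- placenta_parameters(FcRnSTBtotal_end = 1e-2,
                             FcgRIIbECtotal_end = 1e-2,
                             FcRnECtotal_end = 1e-2,
                             k_deg = 0, delta_Ab = 0)
  big$IgG0[c("IgG2", "IgG3", "IgG4")] <- 0
  big <- igtransfer:::.validate_parameters(big)
  sim <- simulate_placenta(big, schedules = constant_schedules(big),
                           by = 2, maternal_dynamics = TRUE,
                           rtol = 1e-10, atol = 1e-16)
  tot <- igtransfer:::.total_moles(sim)
  expect_lt(max(abs(tot - tot[1]) / tot[1]), 1e-8)
})

test_that("default simulation reproduces the subclass transfer hierarchy", {
  g <- glance(fast_sim())
  expect_identical(g$hierarchy, "IgG1 > IgG3 > IgG4 > IgG2")
  # fetal IgG1 still accumulating at term
  sim <- simulate_placenta(by = 0.5)
  f1 <- sim$states[, "IgG1.F"]
  expect_gt(f1[length(f1)], f1[length(f1) - 1])
})

test_that("no maternal IgG means no fetal IgG", {
  p <- default_parameters()
  p$IgG0[] <- 0
  p <- igtransfer:::.validate_parameters(p)
  sim <- fast_sim(p)
  expect_true(all(abs(sim$states[, paste0(igg_subclasses(), ".F")]) < 1e-30))
  expect_true(is.na(glance(sim)$entropy))
})

test_that("states stay non-negative and complexes within scheduled totals", {
  set.seed(42)
  X <- lhs_design(default_parameter_ranges(), 12, seed = 99)
  for (i in seq_len(nrow(X))) {
    p <- igtransfer:::.params_from_row(default_parameters(),
                                       X[i, , drop = FALSE])
    sim <- fast_sim(p)
    states <- sim$states[, grep("\\.", colnames(sim$states))]
    expect_gt(min(states), -1e-12)
    # free receptor outputs stay non-negative (bound <= total + slack)
    frees <- sim$states[, c("free_FcRn_STB", "free_FcgRIIb_EC",
                            "free_FcRn_EC")]
    expect_gt(min(frees), -1e-9)
  }
})

test_that("fetal IgG responds monotonically to transport parameters", {
  base <- fetal_total_at_term(default_parameters())
  up <- with_param(default_parameters(), "k_trans", 0.0743)
  expect_gt(fetal_total_at_term(up), base)
  # halving every receptor R_end strictly decreases fetal IgG
  p <- default_parameters()
  for (f in c("FcRnSTBtotal_end", "FcgRIIbECtotal_end", "FcRnECtotal_end")) {
    p[[f]] <- p[[f]] / 2
  }
  p <- igtransfer:::.validate_parameters(p)
  expect_lt(fetal_total_at_term(p), base)
  # volumes dilute: larger fetal volume, lower concentration
  vol <- with_param(default_parameters(), "V_F", 0.271 * 1.5)
  expect_lt(fetal_total_at_term(vol), base)
})

test_that("solution is converged with respect to solver tolerance", {
  a <- glance(simulate_placenta(by = 5))$fetal_total_M
  b <- glance(simulate_placenta(by = 5, rtol = 1e-10,
                                atol = 1e-16))$fetal_total_M
  expect_lt(abs(a - b) / b, 1e-3)
})

test_that("subclass entropy follows the proportion formula", {
  expect_equal(subclass_entropy(c(3, 3, 3, 3)), log(4))
  expect_equal(subclass_entropy(c(5, 0, 0, 0)), 0)
  # -(0.5 log 0.5 + 2 * 0.25 log 0.25), direct evaluation
  expect_equal(subclass_entropy(c(2, 1, 1, 0)), 1.0397208, tolerance = 1e-6)
  expect_error(subclass_entropy(c(0, 0, 0, 0)), "positive")
  expect_error(subclass_entropy(c(-1, 1, 1, 1)), ">= 0")
})

test_that("tidy trajectories are long, complete and labelled", {
  sim <- fast_sim()
  td <- tidy(sim)
  expect_named(td, c("t_weeks", "species", "subclass", "concentration_M"))
  expect_setequal(unique(td$subclass), igg_subclasses())
  expect_equal(nrow(td), length(sim$times) * 4 * 8)
  fm <- fm_ratios(sim)
  expect_setequal(unique(fm$subclass), igg_subclasses())
})
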