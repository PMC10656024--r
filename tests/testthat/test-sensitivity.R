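test_that("the LHS design stratifies every margin", {
  rng <- default_parameter_ranges()
  X <- lhs_design(rng, 1000, seed = 2)
  expect_equal(dim(as.matrix(X)), c(1000L, 11L))
  for (j in seq_len(nrow(rng))) {
    x <- X[[rng$parameter[j]]]
    expect_gte(min(x), rng$lower[j])
    expect_lte(max(x), rng$upper[j])
    u <- (x - rng$lower[j]) / (rng$upper[j] - rng$lower[j])
    # exact stratification: one draw per n-quantile bin
    expect_identical(tabulate(ceiling(u * 1000), 1000), rep(1L, 1000))
    ks <- suppressWarnings(stats::ks.test(u, "punif"))
    expect_lt(unname(ks$statistic), 0.05)
  }
  # deterministic given seed; degenerate range gives a constant column
  expect_identical(lhs_design(rng, 100, seed = 5),
                   lhs_design(rng, 100, seed = 5))
  rng2 <- rng; rng2$upper[1] <- rng2$lower[1]
  expect_equal(var(lhs_design(rng2, 100, seed = 1)[[rng$parameter[1]]]), 0)
})

test_that("a single informative column dominates the VIP spectrum", {
  rng <- default_parameter_ranges()
  X <- lhs_design(rng, 400, seed = 8)
  set.seed(8)
  y <- 2 * X$k_trans + rnorm(400, 0, 1e-4 * sd(X$k_trans))
  m <- fit_oplsr(X, y)
  td <- tidy(m)
  expect_identical(td$parameter[which.max(td$vip)], "k_trans")
  expect_identical(td$parameter[td$vip > 1], "k_trans")
  expect_gt(m$q2, 0.99)
})

test_that("VIP scores are normalized to the parameter count", {
  rng <- default_parameter_ranges()
  X <- lhs_design(rng, 200, seed = 4)
  set.seed(4)
  y <- X$k_up - 2 * X$V_F + rnorm(200, 0, 0.3 * sd(X$V_F))
  m <- fit_oplsr(X, y)
  expect_equal(sum(tidy(m)$vip^2), 11, tolerance = 1e-9)
  # signs follow the LV1 loadings
  td <- tidy(m)
  expect_gt(td$vip_signed[td$parameter == "k_up"], 0)
  expect_lt(td$vip_signed[td$parameter == "V_F"], 0)
})

test_that("shuffled outcomes carry no predictive power", {
  rng <- default_parameter_ranges()
  X <- lhs_design(rng, 300, seed = 6)
  q2s <- vapply(1:5, function(k) {
    set.seed(100 + k)
    fit_oplsr(X, rnorm(300), seed = k)$q2
  }, numeric(1))
  expect_lt(mean(q2s), 0.05)
  expect_lt(max(q2s), 0.15)
})

test_that("orthogonalization is a rotation: predictions match plain PLS1", {
  rng <- default_parameter_ranges()
  X <- lhs_design(rng, 250, seed = 9)
  set.seed(9)
  y <- X$k_trans * 3 + X$V_M + rnorm(250, 0, 0.1 * sd(X$V_M))
  m <- fit_oplsr(X, y)
  Xs <- scale(as.matrix(X))
  ys <- (y - mean(y)) / sd(y)
  pls <- igtransfer:::.pls1(Xs, ys, 2)
  pred_pls <- drop(Xs %*% pls$B) * sd(y) + mean(y)
  expect_equal(unname(predict(m, X)), unname(pred_pls), tolerance = 1e-9)
  # LV1/LV2 scores span the same plane as the PLS scores
  Q <- qr(cbind(pls$T))
  resid <- cbind(m$scores$lv1, m$scores$lv2) -
    qr.fitted(Q, cbind(m$scores$lv1, m$scores$lv2))
  expect_lt(max(abs(resid)), 1e-8)
})

test_that("the model agrees with an independent PLS implementation", {
  skip_if_not_installed("mixOmics")
  rng <- default_parameter_ranges()
  X <- lhs_design(rng, 200, seed = 12)
  set.seed(12)
  y <- X$k_up + 0.5 * X$k_deg + rnorm(200, 0, 0.2 * sd(X$k_deg))
  m <- fit_oplsr(X, y)
  mo <- mixOmics::pls(as.matrix(X), y, ncomp = 2, mode = "regression",
                      scale = TRUE)
  pred_mo <- predict(mo, as.matrix(X))$predict[, 1, 2]
  expect_equal(unname(predict(m, X)), unname(pred_mo), tolerance = 1e-6)
})

test_that("Q2 equals the printed formula evaluated on held-out folds", {
  rng <- default_parameter_ranges()
  X <- lhs_design(rng, 150, seed = 13)
  set.seed(13)
  y <- X$V_STB + rnorm(150, 0, 0.3 * sd(X$V_STB))
  m <- fit_oplsr(X, y, cv_folds = 5, seed = 21)
  # recompute by hand with the same folds
  set.seed(21)
  folds <- sample(rep(1:5, length.out = 150))
  press <- igtransfer:::.cv_press(as.matrix(X), y, folds, 2)
  expect_equal(m$q2, 1 - press / sum((y - mean(y))^2), tolerance = 1e-12)
})

test_that("the permutation test is reproducible and detects signal", {
  rng <- default_parameter_ranges()
  X <- lhs_design(rng, 150, seed = 14)
  set.seed(14)
  y <- X$k_trans + rnorm(150, 0, 0.1 * sd(X$k_trans))
  m1 <- fit_oplsr(X, y, n_permutations = 60, seed = 5)
  m2 <- fit_oplsr(X, y, n_permutations = 60, seed = 5)
  expect_identical(m1$perm_mse, m2$perm_mse)
  expect_identical(m1$permutation_p, m2$permutation_p)
  expect_lt(m1$permutation_p, 1 / 60 + 1e-12)
})

test_that("degenerate inputs are rejected", {
  rng <- default_parameter_ranges()
  X <- lhs_design(rng, 50, seed = 1)
  expect_error(fit_oplsr(X, rep(1, 50)), "constant")
  expect_error(fit_oplsr(X, rnorm(49)), "nrow")
})

test_that("sensitivity experiments wire simulation into the regression", {
  se <- sensitivity_experiment("total_igg", n = 60, seed = 17)
  expect_s3_class(se$model, "oplsr")
  expect_equal(se$n_failed, 0)
  expect_equal(length(se$y), 60)
  # transport capacity must rank above the volumes at small n already
  td <- dplyr::arrange(tidy(se$model), dplyr::desc(vip))
  expect_true("k_trans" %in% td$parameter[1:3])
})
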