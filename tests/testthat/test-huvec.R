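test_that("empty apical chambers stay empty", {
  y0 <- c(IgG1 = 0, IgG4 = 0, FcRn = 2200, C1 = 0, C4 = 0,
          IgG1_T = 0, IgG4_T = 0)
  expect_true(all(huvec_rhs(0, y0) == 0))
})

test_that("total receptor is conserved along any trajectory", {
  sim <- simulate_huvec(igg1_mg_ml = 0.1, igg4_mg_ml = 0.3,
                        duration_min = 120, by = 5)
  tot <- sim$FcRn + sim$C1 + sim$C4
  expect_lt(max(abs(tot - 2200)) / 2200, 1e-9)
})

test_that("single-subclass equilibrium matches the Langmuir isotherm", {
  # no transcytosis: complexes settle at FcRn0 * I / (K_D + I)
  p <- huvec_parameters(k_trans_per_min = 0)
  conc <- igg_mass_to_molar(0.05) * 1e9  # nM
  sim <- simulate_huvec(p, igg4_mg_ml = 0.05, duration_min = 120, by = 120)
  fin <- sim[nrow(sim), ]
  # free ligand at equilibrium, not the initial load, enters the isotherm
  expect_equal(fin$C4, p$FcRn0 * fin$IgG4 / (p$KD4_nM + fin$IgG4),
               tolerance = 1e-6)
  expect_equal(fin$IgG4 + fin$C4, conc, tolerance = 1e-9)
})

test_that("closed-form competition matches a brute-force QSS solve", {
  # oracle: the QSS balance is linear in (C1, C4); solve it directly
  set.seed(7)
  for (i in 1:1000) {
    I1 <- runif(1, 0, 5000); I4 <- runif(1, 0, 5000)
    F0 <- runif(1, 100, 5000)
    K1 <- runif(1, 5, 100); K4 <- runif(1, 5, 100)
    A <- rbind(c(1 + I1 / K1, I1 / K1),
               c(I4 / K4, 1 + I4 / K4))
    b <- c(F0 * I1 / K1, F0 * I4 / K4)
    oracle <- solve(A, b)
    cf <- closed_form_complex(I1, I4, F0, K1, K4)
    expect_equal(cf$C1, oracle[1], tolerance = 1e-9)
    expect_equal(cf$C4, oracle[2], tolerance = 1e-9)
  }
})

test_that("closed form obeys its limits and symmetry", {
  expect_equal(closed_form_complex(100, 0, 2200, 12.5, 50)$C4, 0)
  # saturation: IgG4 alone and huge occupies every receptor
  expect_equal(closed_form_complex(0, 1e12, 2200, 12.5, 50)$C4, 2200,
               tolerance = 1e-6)
  sym <- closed_form_complex(300, 300, 2200, 40, 40)
  expect_identical(sym$C1, sym$C4)
  expect_error(closed_form_complex(-1, 1, 1, 1, 1), "non-negative")
})

test_that("closed form approximates the kinetic model QSS in IgG excess", {
  p <- huvec_parameters()
  sim <- simulate_huvec(p, igg1_mg_ml = 3, igg4_mg_ml = 3,
                        duration_min = 120, by = 120)
  fin <- sim[nrow(sim), ]
  cf <- closed_form_complex(fin$IgG1, fin$IgG4, p$FcRn0, p$KD1_nM,
                            p$KD4_nM)
  expect_equal(fin$C4, cf$C4, tolerance = 0.01)
  expect_equal(fin$C1, cf$C1, tolerance = 0.01)
})

test_that("transcytosis saturates where apical IgG4 matches total FcRn", {
  sat <- find_saturation_point()
  expect_equal(sat$saturation_mg_ml, 0.33, tolerance = 0.05 / 0.33)
  # the marginal-slope reading sits above the breakpoint by construction
  sat2 <- find_saturation_point(method = "marginal_slope",
                                grid_mg_ml = seq(0.05, 1, by = 0.05))
  expect_gt(sat2$saturation_mg_ml, sat$saturation_mg_ml)
  # more receptor, later saturation
  sat_hi <- find_saturation_point(huvec_parameters(FcRn0_nM = 4400),
                                  grid_mg_ml = seq(0.05, 2, by = 0.05))
  expect_gt(sat_hi$saturation_mg_ml, 1.5 * sat$saturation_mg_ml)
})

test_that("no transcytosis means no saturation point", {
  expect_error(
    find_saturation_point(huvec_parameters(k_trans_per_min = 0),
                          grid_mg_ml = seq(0.05, 0.5, by = 0.05)),
    "undefined")
})

test_that("IgG1 competes IgG4 away only beyond the saturation point", {
  cc <- competition_curve(igg1_grid = seq(0, 0.6, by = 0.01))
  # consistency at IgG1 = 0 with a pure IgG4 run
  pure <- simulate_huvec(igg4_mg_ml = 0.2, duration_min = 120, by = 120)
  expect_equal(cc$transcytosed_IgG4_nM[1], pure$IgG4_T[nrow(pure)],
               tolerance = 1e-9)
  # IgG4 transcytosis never increases with competitor
  expect_true(all(diff(cc$transcytosed_IgG4_nM) < 1e-9))
  thr_total <- attr(cc, "threshold_total_mg_ml")
  expect_equal(thr_total, 0.33, tolerance = 0.05 / 0.33)
})
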