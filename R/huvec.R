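# Transwell endothelial (HUVEC) transcytosis model: FcRn-mediated
# apical-to-basolateral transport of IgG1 and IgG4, with a closed-form
# quasi-steady-state solution for two subclasses competing for one
# receptor. Units: nM and minutes; the assay horizon is 120 minutes.

#' HUVEC transcytosis model parameters
#'
#' Defaults are the optimized in vitro values: total FcRn of 2200 nM, a
#' lysosomal degradation rate of 0.01/min and a transcytosis rate of
#' 2.5e-5/min, with the same IgG1/IgG4-FcRn affinities used by the
#' placental model. Binding rates are converted to per-nM-per-minute.
#'
#' @param FcRn0_nM Total FcRn expression (nM).
#' @param k_deg_per_min Lysosomal degradation rate (1/min); only active
#'   when a simulation opts into the degradation variant.
#' @param k_trans_per_min Transcytosis rate (1/min).
#' @param KD1_M,KD4_M Dissociation constants of IgG1 and IgG4 for FcRn
#'   (molar).
#' @param k_off_per_s Dissociation rate (1/s), shared by both subclasses.
#' @return An object of class `huvec_params`.
#' @export
huvec_parameters <- function(FcRn0_nM = 2200, k_deg_per_min = 0.01,
                             k_trans_per_min = 2.5e-5,
                             KD1_M = 1.25e-8, KD4_M = 5e-8,
                             k_off_per_s = 0.15) {
  vals <- c(FcRn0_nM, k_deg_per_min, k_trans_per_min, KD1_M, KD4_M,
            k_off_per_s)
  if (any(!is.finite(vals)) || any(vals < 0) || FcRn0_nM <= 0 ||
      KD1_M <= 0 || KD4_M <= 0 || k_off_per_s <= 0) {
    stop("HUVEC parameters must be positive", call. = FALSE)
  }
  koff_min <- k_off_per_s * 60
  structure(list(
    FcRn0 = FcRn0_nM,
    k_deg = k_deg_per_min,
    k_trans = k_trans_per_min,
    KD1_nM = KD1_M * 1e9, KD4_nM = KD4_M * 1e9,
    kon1 = koff_min / (KD1_M * 1e9),  # 1/(nM min)
    kon4 = koff_min / (KD4_M * 1e9),
    koff = koff_min
  ), class = "huvec_params")
}

#' Time derivatives of the HUVEC transcytosis model
#'
#' The printed kinetic system: apical IgG binds free FcRn; complexes
#' either dissociate or transcytose, accumulating basolateral IgG; the
#' receptor balance gains back `(k_off + k_trans) C` for each complex, so
#' total receptor `FcRn + C1 + C4` is exactly conserved. The optional
#' degradation variant additionally removes free apical IgG at `k_deg`
#' (the parameter table reports `k_deg` although the printed equations do
#' not carry it; the verbatim system is the default).
#'
#' @param t Minutes (unused; autonomous system).
#' @param state Named vector `IgG1, IgG4, FcRn, C1, C4, IgG1_T, IgG4_T`
#'   (nM).
#' @param p A `huvec_params` object.
#' @param with_degradation Apply `-k_deg * IgG` to the free apical pools.
#' @return Named derivative vector (nM/min).
#' @export
huvec_rhs <- function(t, state, p = huvec_parameters(),
                      with_degradation = FALSE) {
  I1 <- state[["IgG1"]]; I4 <- state[["IgG4"]]; Fr <- state[["FcRn"]]
  C1 <- state[["C1"]]; C4 <- state[["C4"]]
  deg1 <- if (with_degradation) p$k_deg * I1 else 0
  deg4 <- if (with_degradation) p$k_deg * I4 else 0
  c(
    IgG1 = -p$kon1 * I1 * Fr + p$koff * C1 - deg1,
    IgG4 = -p$kon4 * I4 * Fr + p$koff * C4 - deg4,
    FcRn = -Fr * (p$kon1 * I1 + p$kon4 * I4) +
      (p$koff + p$k_trans) * C1 + (p$koff + p$k_trans) * C4,
    C1 = p$kon1 * I1 * Fr - (p$koff + p$k_trans) * C1,
    C4 = p$kon4 * I4 * Fr - (p$koff + p$k_trans) * C4,
    IgG1_T = p$k_trans * C1,
    IgG4_T = p$k_trans * C4
  )
}

#' Simulate Transwell IgG transcytosis
#'
#' Integrates the HUVEC kinetic system from given apical IgG1/IgG4
#' loads over the assay horizon.
#'
#' @param p A `huvec_params` object.
#' @param igg1_mg_ml,igg4_mg_ml Apical loads (mg/ml; converted to nM via
#'   the 150 kDa convention).
#' @param duration_min Assay duration (minutes).
#' @param by Output resolution (minutes).
#' @param with_degradation Use the degradation variant of the equations.
#' @return A tibble with columns `t_min`, `IgG1`, `IgG4`, `FcRn`, `C1`,
#'   `C4`, `IgG1_T`, `IgG4_T` (nM).
#' @export
simulate_huvec <- function(p = huvec_parameters(), igg1_mg_ml = 0,
                           igg4_mg_ml = 0, duration_min = 120, by = 1,
                           with_degradation = FALSE) {
  to_nM <- function(mg) igg_mass_to_molar(mg) * 1e9
  y0 <- c(IgG1 = to_nM(igg1_mg_ml), IgG4 = to_nM(igg4_mg_ml),
          FcRn = p$FcRn0, C1 = 0, C4 = 0, IgG1_T = 0, IgG4_T = 0)
  out <- deSolve::lsoda(
    y0, seq(0, duration_min, by = by),
    function(t, y, pp) list(huvec_rhs(t, y, pp, with_degradation)),
    p, rtol = 1e-10, atol = 1e-10
  )
  dplyr::rename(as_tibble(as.data.frame(out)), t_min = "time")
}

#' Closed-form receptor competition at quasi-steady state
#'
#' When both subclasses are in excess of receptor and complexes are at
#' quasi-steady state, the bound-IgG4 concentration has the closed form
#' `C4 = FcRn0 (I4/K4) / (1 + I4/K4 + I1/K1)` (and symmetrically for C1):
#' raising the competitor's abundance or affinity depresses complex
#' formation, hence transcytosis.
#'
#' @param IgG1,IgG4 Free subclass concentrations (any unit, consistent
#'   with `KD1`/`KD4`).
#' @param FcRn0 Total receptor concentration.
#' @param KD1,KD4 Dissociation constants in the same unit.
#' @return A tibble with columns `C1`, `C4`.
#' @examples
#' closed_form_complex(0, 100, 2200, 12.5, 50)
#' @export
closed_form_complex <- function(IgG1, IgG4, FcRn0, KD1, KD4) {
  if (any(c(IgG1, IgG4) < 0) || any(c(FcRn0, KD1, KD4) <= 0)) {
    stop("concentrations must be non-negative and constants positive",
         call. = FALSE)
  }
  den <- 1 + IgG4 / KD4 + IgG1 / KD1
  tibble(C1 = FcRn0 * (IgG1 / KD1) / den,
         C4 = FcRn0 * (IgG4 / KD4) / den)
}

#' Transcytosis saturation point
#'
#' Sweeps the apical IgG4 load and finds the concentration at which
#' basolateral accumulation at the end of the assay stops responding to
#' further apical increases. The default `"breakpoint"` method
#' intersects the low-dose linear response (a line through the origin
#' with the initial slope) with the high-dose plateau: below the
#' breakpoint essentially every apical molecule finds free receptor, and
#' above it the receptor pool is the limiting reagent, so the breakpoint
#' sits where apical IgG4 matches total FcRn. The `"marginal_slope"`
#' alternative reports the smallest concentration at which the marginal
#' transcytosis gain per unit apical increase falls below `slope_frac` of
#' the low-dose slope; because receptor occupancy approaches its ceiling
#' hyperbolically, that criterion triggers noticeably above the
#' breakpoint.
#'
#' @param p A `huvec_params` object.
#' @param grid_mg_ml Apical IgG4 grid (mg/ml), monotone increasing.
#' @param duration_min Assay duration (minutes).
#' @param method `"breakpoint"` (default) or `"marginal_slope"`.
#' @param slope_frac Slope fraction for the `"marginal_slope"` method,
#'   also used to verify that the response has actually flattened.
#' @return A list with `saturation_mg_ml` and `curve` (tibble
#'   `apical_IgG4_mg_ml`, `transcytosed_IgG4_nM`).
#' @export
find_saturation_point <- function(p = huvec_parameters(),
                                  grid_mg_ml = seq(0.05, 1, by = 0.01),
                                  duration_min = 120,
                                  method = c("breakpoint",
                                             "marginal_slope"),
                                  slope_frac = 0.05) {
  method <- match.arg(method)
  if (is.unsorted(grid_mg_ml, strictly = TRUE)) {
    stop("grid must be strictly increasing", call. = FALSE)
  }
  t4 <- vapply(grid_mg_ml, function(a) {
    sim <- simulate_huvec(p, igg1_mg_ml = 0, igg4_mg_ml = a,
                          duration_min = duration_min, by = duration_min)
    sim$IgG4_T[nrow(sim)]
  }, numeric(1))
  curve <- tibble(apical_IgG4_mg_ml = grid_mg_ml, transcytosed_IgG4_nM = t4)
  if (max(t4) <= 0) {
    stop("no transcytosis on the grid; saturation point undefined",
         call. = FALSE)
  }
  slopes <- diff(t4) / diff(grid_mg_ml)
  if (any(slopes < -1e-6 * max(abs(slopes)))) {
    stop("transcytosis response is non-monotone on the grid", call. = FALSE)
  }
  s0 <- t4[1] / grid_mg_ml[1]  # response passes through the origin
  below <- which(slopes < slope_frac * s0)
  if (!length(below)) {
    stop("response does not saturate on the tested grid", call. = FALSE)
  }
  sat <- if (method == "breakpoint") {
    max(t4) / s0
  } else {
    i <- below[1]
    (grid_mg_ml[i] + grid_mg_ml[i + 1]) / 2
  }
  list(saturation_mg_ml = sat, curve = curve)
}

#' IgG1-IgG4 competition curve
#'
#' Holds apical IgG4 fixed (just below the saturation point by default)
#' and sweeps apical IgG1, recording both subclasses' basolateral
#' accumulation at the end of the assay. IgG1 depresses IgG4 transcytosis
#' only once the total apical IgG exceeds the receptor saturation point;
#' the attribute `threshold_igg1_mg_ml` flags the first IgG1 level at
#' which IgG4 transcytosis drops more than `drop_frac` below its
#' IgG1-free value (`threshold_total_mg_ml` adds the fixed IgG4).
#'
#' @param p A `huvec_params` object.
#' @param igg4_mg_ml Fixed apical IgG4 (mg/ml).
#' @param igg1_grid Apical IgG1 sweep (mg/ml), starting at 0.
#' @param duration_min Assay duration (minutes).
#' @param drop_frac Relative drop defining the competition onset.
#' @return A tibble `apical_IgG1_mg_ml`, `apical_IgG4_mg_ml`,
#'   `transcytosed_IgG1_nM`, `transcytosed_IgG4_nM`, with threshold
#'   attributes.
#' @export
competition_curve <- function(p = huvec_parameters(), igg4_mg_ml = 0.2,
                              igg1_grid = seq(0, 0.8, by = 0.01),
                              duration_min = 120, drop_frac = 0.05) {
  res <- purrr::map_dfr(igg1_grid, function(a1) {
    sim <- simulate_huvec(p, igg1_mg_ml = a1, igg4_mg_ml = igg4_mg_ml,
                          duration_min = duration_min, by = duration_min)
    fin <- sim[nrow(sim), ]
    tibble(apical_IgG1_mg_ml = a1, apical_IgG4_mg_ml = igg4_mg_ml,
           transcytosed_IgG1_nM = fin$IgG1_T,
           transcytosed_IgG4_nM = fin$IgG4_T)
  })
  ref <- res$transcytosed_IgG4_nM[res$apical_IgG1_mg_ml == 0][1]
  hit <- which(res$transcytosed_IgG4_nM < (1 - drop_frac) * ref)
  thr <- if (length(hit)) res$apical_IgG1_mg_ml[hit[1]] else NA_real_
  attr(res, "threshold_igg1_mg_ml") <- thr
  attr(res, "threshold_total_mg_ml") <- thr + igg4_mg_ml
  res
}
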