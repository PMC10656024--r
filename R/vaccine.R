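# Plasma-cell vaccine-response model (antigen -> short/long-lived
# antibody-secreting cells -> IgG) and its coupling into the maternal
# compartment of the placental transport model.

#' Vaccine-response model parameters
#'
#' Linear mass-action cascade: an antigen bolus decays exponentially while
#' stimulating the generation of short-lived (proportion `rho`, in percent)
#' and long-lived antibody-secreting cells (ASC), which secrete
#' antigen-specific IgG. Rates are per day; the defaults reproduce the
#' anti-pertussis-toxin (alpha-PT) IgG response to a Tdap booster in women
#' of child-bearing age, peaking 14-28 days after the dose.
#'
#' @param k_ASC ASC generation rate (1 / 1e6 PBMC / day / antigen unit).
#' @param k_IgG IgG secretion rate (mg/ml * 1e6 PBMC / day).
#' @param Ag0 Antigen dose (arbitrary dose units; 100 = one standard dose).
#' @param rho Percentage of ASCs that are short-lived.
#' @param delta_Ag,delta_IgG,delta_S_ASC,delta_L_ASC Decay rates (1/day).
#' @return An object of class `vaccine_params`.
#' @export
vaccine_parameters <- function(k_ASC = 0.6, k_IgG = 0.0475, Ag0 = 100,
                               rho = 96, delta_Ag = 0.15, delta_IgG = 0.033,
                               delta_S_ASC = 0.173, delta_L_ASC = 6.6e-4) {
  vals <- c(k_ASC = k_ASC, k_IgG = k_IgG, Ag0 = Ag0, delta_Ag = delta_Ag,
            delta_IgG = delta_IgG, delta_S_ASC = delta_S_ASC,
            delta_L_ASC = delta_L_ASC)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    stop("vaccine parameters must be non-negative", call. = FALSE)
  }
  if (rho < 0 || rho > 100) stop("rho must be in [0, 100]", call. = FALSE)
  structure(list(k_ASC = k_ASC, k_IgG = k_IgG, Ag0 = Ag0, rho = rho,
                 delta_Ag = delta_Ag, delta_IgG = delta_IgG,
                 delta_S_ASC = delta_S_ASC, delta_L_ASC = delta_L_ASC),
            class = "vaccine_params")
}

#' Time derivatives of the vaccine-response model
#'
#' @param t Days since vaccination (unused; the system is autonomous).
#' @param state Named vector `c(Ag, S_ASC, L_ASC, IgG_PT)`.
#' @param vax A `vaccine_params` object.
#' @return Named derivative vector (per day).
#' @export
vaccine_rhs <- function(t, state, vax = vaccine_parameters()) {
  stopifnot(inherits(vax, "vaccine_params"))
  Ag <- state[["Ag"]]; S <- state[["S_ASC"]]; L <- state[["L_ASC"]]
  IgG <- state[["IgG_PT"]]
  r <- vax$rho / 100
  c(
    Ag = -vax$delta_Ag * Ag,
    S_ASC = r * vax$k_ASC * Ag - vax$delta_S_ASC * S,
    L_ASC = (1 - r) * vax$k_ASC * Ag - vax$delta_L_ASC * L,
    IgG_PT = vax$k_IgG * (S + L) - vax$delta_IgG * IgG
  )
}

#' Simulate the maternal antibody response to vaccination
#'
#' Integrates the plasma-cell cascade from a single antigen dose at day 0.
#'
#' @param vax A `vaccine_params` object.
#' @param days Output time grid (days since vaccination).
#' @param IgG0 Baseline antigen-specific IgG at day 0 (mg/ml).
#' @return A tibble with columns `day`, `Ag`, `S_ASC`, `L_ASC`, `IgG_PT`.
#' @examples
#' resp <- simulate_vaccine_response()
#' resp$day[which.max(resp$IgG_PT)]  # peak between day 14 and 28
#' @export
simulate_vaccine_response <- function(vax = vaccine_parameters(),
                                      days = seq(0, 365, by = 0.5),
                                      IgG0 = 0) {
  y0 <- c(Ag = vax$Ag0, S_ASC = 0, L_ASC = 0, IgG_PT = IgG0)
  out <- deSolve::lsoda(y0, days,
                        function(t, y, p) list(vaccine_rhs(t, y, p)),
                        vax, rtol = 1e-10, atol = 1e-10)
  as_tibble(as.data.frame(out))[, c("time", "Ag", "S_ASC", "L_ASC", "IgG_PT")] |>
    dplyr::rename(day = "time")
}

#' Simulate a vaccinated pregnancy
#'
#' Couples the vaccine-response cascade into the placental transport
#' model: an antigen dose at gestational week `t_vax` elicits maternal
#' antigen-specific IgG (mg/ml, converted to molar via the 150 kDa
#' convention), which is split into equal parts IgG1-4 and carried as four
#' vaccine-induced sub-species transported with each subclass's own
#' affinities, competing with the constant baseline subclass pool for free
#' receptor. The vaccine-induced sub-species decay in the fetus with a
#' 31-day half-life by default; the baseline pool keeps the parameter
#' set's `delta_Ab`.
#'
#' @param params A `placenta_params` object.
#' @param vax A `vaccine_params` object.
#' @param t_vax Vaccination time (weeks gestational age).
#' @param gestational_length Delivery time (weeks).
#' @param apt_halflife_days Fetal half-life of the vaccine-induced IgG.
#' @param kd_fold_fcrn,kd_fold_fcgr2b Affinity gain of the vaccine-induced
#'   IgG for each receptor, applied as a fold-decrease of K_D (a value of
#'   10 means 10-fold tighter binding). The baseline pool is unchanged.
#' @param by Output resolution (weeks).
#' @param use_compiled Use the compiled right-hand side.
#' @return A `vax_sim` object (inherits `placenta_sim`); `glance()` adds
#'   the fetal and maternal antigen-specific IgG at delivery.
#' @export
simulate_vaccinated_pregnancy <- function(params = default_parameters(),
                                          vax = vaccine_parameters(),
                                          t_vax, gestational_length = 40,
                                          apt_halflife_days = 31,
                                          kd_fold_fcrn = 1,
                                          kd_fold_fcgr2b = 1,
                                          by = 0.5, use_compiled = TRUE) {
  if (t_vax <= 0 || t_vax >= gestational_length) {
    stop("t_vax must lie strictly inside (0, gestational_length)",
         call. = FALSE)
  }
  schedules <- default_schedules(params, gestational_length)
  delta_apt <- fetal_decay_clearance(apt_halflife_days, params$V_F)
  species <- c(
    .baseline_species(params),
    .baseline_species(params, kd_fold_fcrn = kd_fold_fcrn,
                      kd_fold_fcgr2b = kd_fold_fcgr2b,
                      driven = TRUE, prefix = "aPT_",
                      delta_F = delta_apt)
  )
  times <- seq(0, gestational_length, by = by)
  out <- .sim_core(params, schedules, times, species,
                   vaccine = vax, t_vax = t_vax,
                   use_compiled = use_compiled)
  structure(
    list(times = out[, "time"], states = out, params = params,
         schedules = schedules, t_end = gestational_length,
         species = species, vax = vax, t_vax = t_vax),
    class = c("vax_sim", "placenta_sim")
  )
}

#' Fetal antigen-specific IgG at delivery
#'
#' @param sim A `vax_sim` object.
#' @return Molar fetal vaccine-induced IgG (sum of the four sub-species)
#'   at the end of the simulation.
#' @export
fetal_apt_igg <- function(sim) {
  stopifnot(inherits(sim, "vax_sim"))
  fin <- .final_state(sim)
  sum(fin[paste0("aPT_", igg_subclasses(), ".F")])
}

#' @export
glance.vax_sim <- function(x, ...) {
  fin <- .final_state(x)
  tibble(
    t_vax = x$t_vax,
    gestational_length = x$t_end,
    fetal_aPT_M = fetal_apt_igg(x),
    fetal_aPT_mg_ml = igg_molar_to_mass(fetal_apt_igg(x)),
    maternal_IgG_PT_mg_ml = unname(fin[["IgG_PT"]])
  )
}

#' Optimize vaccination timing
#'
#' Sweeps the vaccination week over `sweep` and returns the timing that
#' maximizes fetal antigen-specific IgG at delivery, refining around the
#' coarse optimum at quarter-week resolution.
#'
#' @inheritParams simulate_vaccinated_pregnancy
#' @param sweep Candidate vaccination weeks (gestational age).
#' @param refine Refine around the grid optimum at 0.25-week resolution.
#' @return A list with `optimal_t_vax`, `optimal_fetal_aPT_M`, and `curve`
#'   (a tibble `t_vax`, `fetal_aPT_M`).
#' @export
optimize_tvax <- function(params = default_parameters(),
                          vax = vaccine_parameters(),
                          gestational_length = 40, sweep = NULL,
                          refine = TRUE, ...) {
  if (is.null(sweep)) {
    hi <- min(38, gestational_length - 1)
    sweep <- if (hi >= 10) seq(10, hi, 1) else numeric(0)
  }
  sweep <- sweep[sweep < gestational_length & sweep > 0]
  if (!length(sweep)) stop("empty feasible t_vax grid", call. = FALSE)
  evalf <- function(tv) {
    fetal_apt_igg(simulate_vaccinated_pregnancy(
      params, vax, t_vax = tv, gestational_length = gestational_length, ...))
  }
  vals <- vapply(sweep, evalf, numeric(1))
  best <- sweep[which.max(vals)]
  curve <- tibble(t_vax = sweep, fetal_aPT_M = vals)
  if (refine) {
    fine <- setdiff(seq(max(min(sweep), best - 1), min(max(sweep), best + 1),
                        by = 0.25), sweep)
    if (length(fine)) {
      fvals <- vapply(fine, evalf, numeric(1))
      curve <- dplyr::arrange(
        dplyr::bind_rows(curve, tibble(t_vax = fine, fetal_aPT_M = fvals)),
        .data$t_vax
      )
    }
  }
  i <- which.max(curve$fetal_aPT_M)
  list(optimal_t_vax = curve$t_vax[i],
       optimal_fetal_aPT_M = curve$fetal_aPT_M[i],
       curve = curve)
}

.receptor_fields <- c(FcRnSTB = "FcRnSTBtotal_end",
                      FcgRIIbEC = "FcgRIIbECtotal_end",
                      FcRnEC = "FcRnECtotal_end")

.match_receptor_field <- function(receptor) {
  if (receptor %in% .receptor_fields) return(receptor)
  if (receptor %in% names(.receptor_fields)) {
    return(unname(.receptor_fields[receptor]))
  }
  stop("unknown receptor field: ", receptor, call. = FALSE)
}

#' Fc receptor deficiency scenario
#'
#' Scales one receptor's term expression over a fold-change grid (1 =
#' baseline) with vaccination fixed at `t_vax` and reports the percent
#' change in fetal antigen-specific IgG at delivery relative to the
#' unmodified simulation.
#'
#' @inheritParams simulate_vaccinated_pregnancy
#' @param receptor One of `"FcRnSTBtotal_end"`, `"FcgRIIbECtotal_end"`,
#'   `"FcRnECtotal_end"` (short forms `"FcRnSTB"`, `"FcgRIIbEC"`,
#'   `"FcRnEC"` accepted).
#' @param fold_grid Receptor expression fold-changes (e.g. 0.1 = 10-fold
#'   deficiency).
#' @return A tibble `fold`, `fetal_aPT_M`, `pct_change`.
#' @export
fcr_deficiency_scenario <- function(params = default_parameters(),
                                    vax = vaccine_parameters(),
                                    receptor,
                                    fold_grid = 10^seq(-1, 1, length.out = 9),
                                    t_vax = 25, gestational_length = 40,
                                    ...) {
  field <- .match_receptor_field(receptor)
  baseline <- fetal_apt_igg(simulate_vaccinated_pregnancy(
    params, vax, t_vax = t_vax, gestational_length = gestational_length, ...))
  vals <- vapply(fold_grid, function(f) {
    p <- params
    p[[field]] <- params[[field]] * f
    p <- .validate_parameters(p)
    fetal_apt_igg(simulate_vaccinated_pregnancy(
      p, vax, t_vax = t_vax, gestational_length = gestational_length, ...))
  }, numeric(1))
  tibble(fold = fold_grid, fetal_aPT_M = vals,
         pct_change = 100 * (vals / baseline - 1))
}

#' Vaccine dose compensation for an Fc receptor deficiency
#'
#' With one receptor reduced `deficiency_fold`-fold, scales the antigen
#' dose over `dose_grid` and returns the smallest fold that restores fetal
#' antigen-specific IgG at delivery to at least the unmodified-receptor,
#' unit-dose baseline. If no tested dose restores the baseline the result
#' is flagged unbounded and the largest tested fold is reported.
#'
#' @inheritParams fcr_deficiency_scenario
#' @param deficiency_fold Receptor expression divisor (default 10).
#' @param dose_grid Dose fold-changes to test (multiplies `Ag0`).
#' @return A list with `restoring_fold` (NA if unbounded), `unbounded`,
#'   `max_tested`, `baseline_fetal_aPT_M` and `curve` (tibble `dose_fold`,
#'   `fetal_aPT_M`, `relative_to_baseline`).
#' @export
dose_compensation <- function(params = default_parameters(),
                              vax = vaccine_parameters(),
                              receptor, deficiency_fold = 10,
                              dose_grid = 1:20,
                              t_vax = 25, gestational_length = 40, ...) {
  field <- .match_receptor_field(receptor)
  baseline <- fetal_apt_igg(simulate_vaccinated_pregnancy(
    params, vax, t_vax = t_vax, gestational_length = gestational_length, ...))
  p <- params
  p[[field]] <- params[[field]] / deficiency_fold
  p <- .validate_parameters(p)
  vals <- vapply(sort(dose_grid), function(f) {
    v <- vax
    v$Ag0 <- vax$Ag0 * f
    fetal_apt_igg(simulate_vaccinated_pregnancy(
      p, v, t_vax = t_vax, gestational_length = gestational_length, ...))
  }, numeric(1))
  curve <- tibble(dose_fold = sort(dose_grid), fetal_aPT_M = vals,
                  relative_to_baseline = vals / baseline)
  hit <- which(vals >= baseline)
  list(
    restoring_fold = if (length(hit)) curve$dose_fold[hit[1]] else NA_real_,
    unbounded = !length(hit),
    max_tested = max(curve$dose_fold),
    baseline_fetal_aPT_M = baseline,
    curve = curve
  )
}

#' Vaccine-induced IgG affinity scenario
#'
#' Decreases the vaccine-induced IgG's dissociation constant for FcRn,
#' FcgRIIb, or both by `kd_fold_decrease` (the baseline subclass pool is
#' unchanged — e.g. an adjuvant-driven glycosylation change on the
#' vaccine-elicited antibodies only) and reports the percent change in
#' fetal antigen-specific IgG at delivery.
#'
#' @inheritParams fcr_deficiency_scenario
#' @param target `"FcRn"`, `"FcgRIIb"` or `"both"`.
#' @param kd_fold_decrease Fold-decrease of K_D (10 = 10-fold tighter).
#' @return A one-row tibble `target`, `kd_fold_decrease`, `fetal_aPT_M`,
#'   `pct_change`.
#' @export
affinity_scenario <- function(params = default_parameters(),
                              vax = vaccine_parameters(),
                              target = c("FcRn", "FcgRIIb", "both"),
                              kd_fold_decrease = 10,
                              t_vax = 25, gestational_length = 40, ...) {
  target <- match.arg(target)
  baseline <- fetal_apt_igg(simulate_vaccinated_pregnancy(
    params, vax, t_vax = t_vax, gestational_length = gestational_length, ...))
  kn <- if (target %in% c("FcRn", "both")) kd_fold_decrease else 1
  kb <- if (target %in% c("FcgRIIb", "both")) kd_fold_decrease else 1
  val <- fetal_apt_igg(simulate_vaccinated_pregnancy(
    params, vax, t_vax = t_vax, gestational_length = gestational_length,
    kd_fold_fcrn = kn, kd_fold_fcgr2b = kb, ...))
  tibble(target = target, kd_fold_decrease = kd_fold_decrease,
         fetal_aPT_M = val, pct_change = 100 * (val / baseline - 1))
}
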