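# Five-compartment, four-subclass mass-action model of transplacental IgG
# transport. The compiled right-hand side (src/igtransfer_ode.c) is the
# default integration path; an R implementation of the same equations is
# kept for testing and inspection.

.state_suffixes <- c("M", "STB", "C_STB", "STR", "EC", "C_EC_Rn",
                     "C_EC_R2b", "F")

# Per-species kinetic description used by the simulation core. A "species"
# is one transported IgG pool: the four baseline subclasses, plus (in
# vaccinated simulations) four vaccine-induced sub-species that share the
# subclass affinities but are driven by the maternal vaccine response.
.baseline_species <- function(params, kd_fold_fcrn = 1, kd_fold_fcgr2b = 1,
                              driven = FALSE, prefix = "",
                              delta_F = params$delta_Ab) {
  aff <- params$affinities
  lapply(igg_subclasses(), function(s) {
    rn <- aff[aff$receptor == "FcRn" & aff$subclass == s, ]
    rb <- aff[aff$receptor == "FcgRIIb" & aff$subclass == s, ]
    list(
      name = paste0(prefix, s),
      IgG0 = if (driven) 0 else unname(params$IgG0[[s]]),
      # a K_D decrease (affinity gain) is applied as a k_on increase
      konN = rn$k_on_per_M_wk * kd_fold_fcrn,
      koffN = rn$k_off_per_wk,
      konB = rb$k_on_per_M_wk * kd_fold_fcgr2b,
      koffB = rb$k_off_per_wk,
      delta_F = delta_F,
      driven = driven
    )
  })
}

.build_parms <- function(params, schedules, species,
                         maternal_dynamics = FALSE, vaccine = NULL) {
  p <- numeric(80)
  p[1] <- length(species)
  p[2] <- as.integer(maternal_dynamics)
  p[3] <- as.integer(!is.null(vaccine))
  p[4:6] <- c(params$k_up, params$k_trans, params$k_deg)
  p[7:11] <- c(params$V_M, params$V_STB, params$V_STR, params$V_EC,
               params$V_F)
  sched_coef <- function(s) c(s$a, s$b, s$c)
  p[12:14] <- sched_coef(schedules$FcRn_STB)
  p[15:17] <- sched_coef(schedules$FcgRIIb_EC)
  p[18:20] <- sched_coef(schedules$FcRn_EC)
  if (!is.null(vaccine)) {
    p[22:28] <- c(vaccine$k_ASC, vaccine$k_IgG, vaccine$rho / 100,
                  vaccine$delta_Ag, vaccine$delta_IgG,
                  vaccine$delta_S_ASC, vaccine$delta_L_ASC) *
      c(7, 7, 1, 7, 7, 7, 7)
    p[29] <- 1 / (igg_molecular_weight() * 4)
  }
  for (i in seq_along(species)) {
    sp <- species[[i]]
    p[31:36 + (i - 1) * 6] <- c(sp$konN, sp$koffN, sp$konB, sp$koffB,
                                sp$delta_F, as.integer(sp$driven))
  }
  p
}

.state_names <- function(species, vaccine = FALSE) {
  nm <- unlist(lapply(species, function(sp) {
    paste(sp$name, .state_suffixes, sep = ".")
  }))
  if (vaccine) nm <- c(nm, "Ag", "S_ASC", "L_ASC", "IgG_PT")
  nm
}

# R implementation of the compiled derivatives; species-generic.
.rhs_r <- function(t, y, pv) {
  ns <- as.integer(pv[1]); mdyn <- pv[2] > 0; vax <- pv[3] > 0
  k_up <- pv[4]; k_trans <- pv[5]; k_deg <- pv[6]
  V_M <- pv[7]; V_STB <- pv[8]; V_STR <- pv[9]; V_EC <- pv[10]; V_F <- pv[11]
  quad <- function(off) max(pv[off] * t^2 + pv[off + 1] * t + pv[off + 2], 0)
  idx <- function(k) seq.int(k, by = 8, length.out = ns)
  fSTB <- max(quad(12) - sum(y[idx(3)]), 0)
  fR2b <- max(quad(15) - sum(y[idx(7)]), 0)
  fRn  <- max(quad(18) - sum(y[idx(6)]), 0)
  dy <- numeric(length(y))
  dIgGPT <- 0
  if (vax) {
    v0 <- ns * 8
    Ag <- y[v0 + 1]; S <- y[v0 + 2]; L <- y[v0 + 3]; IgGPT <- y[v0 + 4]
    dy[v0 + 1] <- -pv[25] * Ag
    dy[v0 + 2] <- pv[24] * pv[22] * Ag - pv[27] * S
    dy[v0 + 3] <- (1 - pv[24]) * pv[22] * Ag - pv[28] * L
    dIgGPT <- pv[23] * (S + L) - pv[26] * IgGPT
    dy[v0 + 4] <- dIgGPT
  }
  for (s in seq_len(ns)) {
    b <- (s - 1) * 8
    konN <- pv[31 + (s - 1) * 6]; koffN <- pv[32 + (s - 1) * 6]
    konB <- pv[33 + (s - 1) * 6]; koffB <- pv[34 + (s - 1) * 6]
    dlt <- pv[35 + (s - 1) * 6]; driven <- pv[36 + (s - 1) * 6] > 0
    M <- y[b + 1]; STB <- y[b + 2]; C <- y[b + 3]; STR <- y[b + 4]
    EC <- y[b + 5]; Cn <- y[b + 6]; Cb <- y[b + 7]; F <- y[b + 8]
    dy[b + 1] <- if (driven) pv[29] * dIgGPT else
      if (mdyn) -(k_up / V_M) * M else 0
    dy[b + 2] <- (k_up / V_STB) * M - konN * STB * fSTB + koffN * C -
      (k_deg / V_STB) * STB
    dy[b + 3] <- konN * STB * fSTB - koffN * C - (k_trans / V_STB) * C
    dy[b + 4] <- (k_trans / V_STR) * C - (k_up / V_STR) * STR -
      (V_EC / V_STR) * (konB * STR * fR2b - koffB * Cb)
    dy[b + 5] <- (k_up / V_EC) * STR - konN * EC * fRn + koffN * Cn -
      (k_deg / V_EC) * EC
    dy[b + 6] <- konN * EC * fRn - koffN * Cn - (k_trans / V_EC) * Cn
    dy[b + 7] <- konB * STR * fR2b - koffB * Cb - (k_trans / V_EC) * Cb
    dy[b + 8] <- (k_trans / V_F) * (Cn + Cb) - (dlt / V_F) * F
  }
  list(dy, free_FcRn_STB = fSTB, free_FcgRIIb_EC = fR2b, free_FcRn_EC = fRn)
}

# Integration core shared by all placental experiments.
.sim_core <- function(params, schedules, times, species,
                      maternal_dynamics = FALSE,
                      vaccine = NULL, t_vax = NULL,
                      use_compiled = TRUE, rtol = 1e-8, atol = 1e-14) {
  pv <- .build_parms(params, schedules, species, maternal_dynamics, vaccine)
  nm <- .state_names(species, vaccine = !is.null(vaccine))
  y0 <- setNames(numeric(length(nm)), nm)
  for (sp in species) if (!sp$driven) y0[paste0(sp$name, ".M")] <- sp$IgG0
  events <- NULL
  if (!is.null(vaccine)) {
    stopifnot(!is.null(t_vax))
    times <- sort(unique(c(times, t_vax)))
    events <- list(data = data.frame(var = "Ag", time = t_vax,
                                     value = vaccine$Ag0, method = "add"))
    atol <- c(rep(atol, length(nm) - 4), rep(1e-8, 4))
  }
  out <- if (use_compiled) {
    deSolve::lsoda(
      y0, times, func = "ig_derivs", parms = pv,
      dllname = "igtransfer", initfunc = "ig_initmod",
      nout = 3,
      outnames = c("free_FcRn_STB", "free_FcgRIIb_EC", "free_FcRn_EC"),
      rtol = rtol, atol = atol, events = events, maxsteps = 50000
    )
  } else {
    deSolve::lsoda(y0, times, func = function(t, y, p) .rhs_r(t, y, p),
                   parms = pv, rtol = rtol, atol = atol, events = events,
                   maxsteps = 50000)
  }
  if (attr(out, "istate")[1] < 0) {
    stop("ODE integration failed; solver diagnostics: istate = ",
         attr(out, "istate")[1], call. = FALSE)
  }
  out
}

#' Time derivatives of the placental transport system
#'
#' The instantaneous right-hand side of the five-compartment mass-action
#' model, exposed for inspection and testing. The state carries, for each
#' IgG subclass, maternal blood (`M`), free and FcRn-bound IgG in STB
#' endosomes (`STB`, `C_STB`), stromal IgG (`STR`), free and FcRn-bound
#' IgG in EC endosomes (`EC`, `C_EC_Rn`), FcgRIIb-bound IgG at the EC
#' surface (`C_EC_R2b`) and fetal blood (`F`), named
#' `"<subclass>.<compartment>"`. Maternal concentrations are held constant
#' by default (the maternal derivative is zero, or the supplied `source`);
#' `maternal_dynamics = TRUE` enables maternal depletion for
#' mass-balance checks.
#'
#' @param t Gestational week.
#' @param state Named numeric state vector (see [placental_state()]).
#' @param params A `placenta_params` object.
#' @param schedules Receptor schedules, as from [default_schedules()].
#' @param source Optional function `source(t)` returning a length-4 molar
#'   influx rate added to the maternal derivative of each subclass.
#' @param maternal_dynamics Allow maternal depletion by placental uptake.
#' @return Named list: derivative vector plus the three free receptor
#'   concentrations.
#' @export
placental_rhs <- function(t, state, params = default_parameters(),
                          schedules = default_schedules(params),
                          source = NULL, maternal_dynamics = FALSE) {
  species <- .baseline_species(params)
  nm <- .state_names(species)
  if (is.null(names(state)) || !all(nm %in% names(state))) {
    stop("state must be a named vector with the layout of placental_state()",
         call. = FALSE)
  }
  pv <- .build_parms(params, schedules, species, maternal_dynamics)
  res <- .rhs_r(t, unname(state[nm]), pv)
  d <- setNames(res[[1]], nm)
  if (!is.null(source)) {
    d[paste0(igg_subclasses(), ".M")] <-
      d[paste0(igg_subclasses(), ".M")] + source(t)
  }
  list(derivatives = d,
       free_FcRn_STB = res$free_FcRn_STB,
       free_FcgRIIb_EC = res$free_FcgRIIb_EC,
       free_FcRn_EC = res$free_FcRn_EC)
}

#' Initial placental state
#'
#' All compartments empty except maternal blood at the parameter set's
#' subclass concentrations.
#'
#' @param params A `placenta_params` object.
#' @return Named numeric vector of 32 states.
#' @export
placental_state <- function(params = default_parameters()) {
  species <- .baseline_species(params)
  nm <- .state_names(species)
  y0 <- setNames(numeric(length(nm)), nm)
  for (sp in species) y0[paste0(sp$name, ".M")] <- sp$IgG0
  y0
}

#' Simulate transplacental IgG transfer across gestation
#'
#' Integrates the four-subclass transport system from conception to
#' `t_end` with maternal subclass concentrations held constant, free
#' receptor recovered algebraically from the gestational expression
#' schedules, and a stiff solver (the binding kinetics live on a
#' per-second scale, transport on a per-week scale).
#'
#' @param params A `placenta_params` object.
#' @param schedules Receptor schedules; defaults to the quadratic
#'   schedules implied by `params` and `t_end`.
#' @param t_end Gestational length (weeks).
#' @param by Output resolution (weeks).
#' @param maternal_dynamics Allow maternal depletion (off by default).
#' @param use_compiled Use the compiled right-hand side (default) or the
#'   reference R implementation.
#' @param rtol,atol Solver tolerances.
#' @return A `placenta_sim` object. `tidy()` gives the long trajectory
#'   (`t_weeks`, `species`, `subclass`, `concentration_M`), `glance()` a
#'   one-row summary (fetal total, subclass entropy, F:M ratios and the
#'   transfer hierarchy at `t_end`), and `autoplot()` the fetal
#'   trajectories.
#' @examples
#' \donttest{
#' sim <- simulate_placenta()
#' glance(sim)$hierarchy  # "IgG1 > IgG3 > IgG4 > IgG2"
#' }
#' @export
simulate_placenta <- function(params = default_parameters(),
                              schedules = NULL, t_end = 40, by = 0.5,
                              maternal_dynamics = FALSE,
                              use_compiled = TRUE,
                              rtol = 1e-8, atol = 1e-14) {
  if (is.null(schedules)) schedules <- default_schedules(params, t_end)
  species <- .baseline_species(params)
  times <- seq(0, t_end, by = by)
  out <- .sim_core(params, schedules, times, species,
                   maternal_dynamics = maternal_dynamics,
                   use_compiled = use_compiled, rtol = rtol, atol = atol)
  structure(
    list(times = out[, "time"], states = out, params = params,
         schedules = schedules, t_end = t_end, species = species),
    class = "placenta_sim"
  )
}

.final_state <- function(sim) sim$states[nrow(sim$states), ]

.fetal_matrix <- function(sim, prefix = "") {
  cols <- paste0(prefix, igg_subclasses(), ".F")
  sim$states[, cols, drop = FALSE]
}

#' Fetal-to-maternal concentration ratios
#'
#' F:M ratio per subclass over the saved trajectory; values above 1
#' indicate preferential transfer.
#'
#' @param sim A `placenta_sim` object.
#' @return A tibble with columns `t_weeks`, `subclass`, `fm_ratio`.
#' @export
fm_ratios <- function(sim) {
  stopifnot(inherits(sim, "placenta_sim"))
  purrr::map_dfr(igg_subclasses(), function(s) {
    tibble(
      t_weeks = sim$states[, "time"],
      subclass = s,
      fm_ratio = sim$states[, paste0(s, ".F")] /
        sim$states[, paste0(s, ".M")]
    )
  })
}

.hierarchy_string <- function(fm) {
  if (any(!is.finite(fm))) return(NA_character_)
  ord <- order(fm, decreasing = TRUE)
  sorted <- fm[ord]
  if (any(diff(sorted) == 0)) return(NA_character_)  # ties: not satisfied
  paste(names(fm)[ord], collapse = " > ")
}

#' Shannon entropy of the fetal subclass distribution
#'
#' `E = -sum(P_i log P_i)` over the fetal subclass proportions, with
#' natural logarithm and the convention `0 log 0 = 0`. Low entropy means
#' selective transfer; `log(4)` means all four subclasses are equally
#' represented.
#'
#' @param fetal Non-negative numeric vector of fetal subclass
#'   concentrations, at least one positive.
#' @return Entropy (dimensionless, nats).
#' @examples
#' subclass_entropy(c(1, 1, 1, 1))  # log(4)
#' subclass_entropy(c(2, 1, 1, 0))  # 1.0397
#' @export
subclass_entropy <- function(fetal) {
  if (any(fetal < 0)) stop("fetal concentrations must be >= 0", call. = FALSE)
  tot <- sum(fetal)
  if (tot <= 0) stop("at least one fetal concentration must be positive",
                     call. = FALSE)
  p <- fetal / tot
  p <- p[p > 0]
  -sum(p * log(p))
}

#' @export
tidy.placenta_sim <- function(x, ...) {
  nm <- setdiff(colnames(x$states),
                c("time", "free_FcRn_STB", "free_FcgRIIb_EC", "free_FcRn_EC",
                  "Ag", "S_ASC", "L_ASC", "IgG_PT"))
  long <- tibble(
    t_weeks = rep(x$states[, "time"], times = length(nm)),
    key = rep(nm, each = nrow(x$states)),
    concentration_M = as.vector(x$states[, nm])
  )
  tidyr::separate(long, "key", into = c("subclass", "species"), sep = "\\.",
                  extra = "merge")[, c("t_weeks", "species", "subclass",
                                       "concentration_M")]
}

#' @export
glance.placenta_sim <- function(x, ...) {
  fin <- .final_state(x)
  fm <- setNames(
    fin[paste0(igg_subclasses(), ".F")] / fin[paste0(igg_subclasses(), ".M")],
    igg_subclasses()
  )
  fetal <- fin[paste0(igg_subclasses(), ".F")]
  out <- tibble(
    t_end = x$t_end,
    fetal_total_M = sum(fetal),
    entropy = if (sum(fetal) > 0) subclass_entropy(fetal) else NA_real_,
    hierarchy = .hierarchy_string(fm)
  )
  for (s in igg_subclasses()) out[[paste0("fm_", s)]] <- unname(fm[[s]])
  out
}

#' @export
autoplot.placenta_sim <- function(object, ...) {
  df <- tidy(object)
  df <- df[df$species == "F", ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t_weeks,
                                   y = .data$concentration_M,
                                   colour = .data$subclass)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(x = "gestational week", y = "fetal IgG (M)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @export
print.placenta_sim <- function(x, ...) {
  g <- glance(x)
  cat("<placenta_sim> 0-", x$t_end, " weeks\n", sep = "")
  cat(sprintf("  fetal total %.3g M, entropy %.3f\n",
              g$fetal_total_M, g$entropy))
  cat("  F:M at term:",
      paste(sprintf("%s %.3f", igg_subclasses(),
                    unlist(g[paste0("fm_", igg_subclasses())])),
            collapse = "  "), "\n")
  cat("  hierarchy:", g$hierarchy, "\n")
  invisible(x)
}

# Total IgG moles over all compartments (for conservation checks).
.total_moles <- function(sim) {
  p <- sim$params
  vols <- c(M = p$V_M, STB = p$V_STB, C_STB = p$V_STB, STR = p$V_STR,
            EC = p$V_EC, C_EC_Rn = p$V_EC, C_EC_R2b = p$V_EC, F = p$V_F)
  tot <- numeric(nrow(sim$states))
  for (sp in sim$species) {
    for (suf in .state_suffixes) {
      tot <- tot + sim$states[, paste0(sp$name, ".", suf)] * vols[[suf]]
    }
  }
  tot
}
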