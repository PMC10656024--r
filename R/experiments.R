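# In silico experiments on the placental model: endothelial-cell receptor
# variants (which receptor does the EC layer need to reproduce the human
# subclass transfer hierarchy?) and subclass-competition runs.

.canonical_hierarchy <- function(fm) {
  # strict ordering IgG1 > IgG3 > IgG4 > IgG2; ties fail
  fm[["IgG1"]] > fm[["IgG3"]] && fm[["IgG3"]] > fm[["IgG4"]] &&
    fm[["IgG4"]] > fm[["IgG2"]]
}

.fm_at_term <- function(params, schedules, t_end = 40, species = NULL) {
  if (is.null(species)) species <- .baseline_species(params)
  out <- .sim_core(params, schedules, c(0, t_end), species)
  fin <- out[nrow(out), ]
  active <- vapply(species, function(sp) sp$IgG0 > 0, logical(1))
  fm <- rep(NA_real_, length(species))
  names(fm) <- vapply(species, `[[`, character(1), "name")
  for (i in seq_along(species)) {
    if (active[i]) {
      nmi <- species[[i]]$name
      fm[nmi] <- fin[[paste0(nmi, ".F")]] / fin[[paste0(nmi, ".M")]]
    }
  }
  fm
}

#' Endothelial-cell receptor variant experiment
#'
#' Simulates IgG transfer with ECs expressing both FcRn and FcgRIIb
#' (`"co_expressed"`), FcRn alone (`"FcRn_only"`), or FcgRIIb alone
#' (`"FcgRIIb_only"`), sweeping the EC receptor expression level, and
#' reports the fetal-to-maternal ratio of each subclass at term. In the
#' co-expression variant the sweep is over the EC FcRn : FcgRIIb term
#' expression ratio (percent) and the experiment reports the largest
#' percentage at which the strict hierarchy IgG1 > IgG3 > IgG4 > IgG2
#' holds (as the midpoint between the last passing and first failing grid
#' ratio). In the single-receptor variants the sweep scales the remaining
#' receptor's term expression relative to its default.
#'
#' @param params A `placenta_params` object.
#' @param variant One of `"co_expressed"`, `"FcRn_only"`, `"FcgRIIb_only"`.
#' @param grid Sweep grid: percent of FcgRIIb expression for
#'   `"co_expressed"`; fold-change of the expressed receptor otherwise.
#' @param t_end Gestational length (weeks).
#' @return A tibble with columns `grid`, `subclass`, `fm_ratio`,
#'   `hierarchy_ok`. For `"co_expressed"` the attribute
#'   `threshold_percent` carries the reported hierarchy threshold.
#' @export
ec_receptor_variant <- function(params = default_parameters(),
                                variant = c("co_expressed", "FcRn_only",
                                            "FcgRIIb_only"),
                                grid = NULL, t_end = 40) {
  variant <- match.arg(variant)
  if (is.null(grid)) {
    grid <- switch(variant,
      co_expressed = seq(1, 50, by = 1),
      10^seq(-2, 1, length.out = 46))
  }
  if (!length(grid)) stop("empty sweep grid", call. = FALSE)
  run_one <- function(g) {
    p <- params
    if (variant == "co_expressed") {
      p$FcRnECtotal_end <- params$FcgRIIbECtotal_end * g / 100
    } else if (variant == "FcRn_only") {
      p$FcRnECtotal_end <- params$FcRnECtotal_end * g
    } else {
      p$FcgRIIbECtotal_end <- params$FcgRIIbECtotal_end * g
    }
    p <- .validate_parameters(p)
    schedules <- default_schedules(p, t_end)
    if (variant == "FcRn_only") {
      schedules$FcgRIIb_EC <- fcr_schedule(1e-30, t_end, a = 0, b = 0,
                                           c = 1e-30,
                                           receptor = "FcgRIIb_EC")
    }
    if (variant == "FcgRIIb_only") {
      schedules$FcRn_EC <- fcr_schedule(1e-30, t_end, a = 0, b = 0,
                                        c = 1e-30, receptor = "FcRn_EC")
    }
    fm <- .fm_at_term(p, schedules, t_end)
    tibble(grid = g, subclass = names(fm), fm_ratio = unname(fm),
           hierarchy_ok = .canonical_hierarchy(fm))
  }
  res <- purrr::map_dfr(grid, run_one)
  if (variant == "co_expressed") {
    ok <- dplyr::distinct(res[, c("grid", "hierarchy_ok")])
    pass <- ok$grid[ok$hierarchy_ok]
    fail <- ok$grid[!ok$hierarchy_ok]
    threshold <- if (!length(pass)) {
      NA_real_
    } else if (!length(fail) || min(fail) < max(pass)) {
      max(pass)
    } else {
      (max(pass) + min(fail[fail > max(pass)])) / 2
    }
    attr(res, "threshold_percent") <- threshold
  }
  res
}

#' Subclass competition experiment
#'
#' Compares the fetal-to-maternal ratio of each subclass transported in
#' isolation (all other subclasses' maternal concentrations zeroed)
#' against the full mixture, over a sweep of EC FcgRIIb term expression.
#' Competition for limited receptor makes every subclass transfer less
#' efficiently in the mixture; the isolated-minus-mixed delta shrinks as
#' receptor expression grows out of limitation.
#'
#' @param params A `placenta_params` object.
#' @param r2b_fold_grid Fold-changes applied to the EC FcgRIIb term
#'   expression.
#' @param t_end Gestational length (weeks).
#' @return A tibble with columns `r2b_fold`, `subclass`, `fm_isolated`,
#'   `fm_mixed`, `delta`.
#' @export
competition_experiment <- function(params = default_parameters(),
                                   r2b_fold_grid = 1, t_end = 40) {
  purrr::map_dfr(r2b_fold_grid, function(f) {
    p <- params
    p$FcgRIIbECtotal_end <- params$FcgRIIbECtotal_end * f
    p <- .validate_parameters(p)
    schedules <- default_schedules(p, t_end)
    mixed <- .fm_at_term(p, schedules, t_end)
    iso <- vapply(igg_subclasses(), function(s) {
      pi <- p
      pi$IgG0[setdiff(igg_subclasses(), s)] <- 0
      # skip full validation: zero concentrations are intended here
      class(pi) <- "placenta_params"
      .fm_at_term(pi, schedules, t_end)[[s]]
    }, numeric(1))
    tibble(r2b_fold = f, subclass = igg_subclasses(),
           fm_isolated = unname(iso), fm_mixed = unname(mixed),
           delta = unname(iso - mixed))
  })
}
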