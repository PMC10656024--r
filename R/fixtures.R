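# Synthetic data generation: gestational-age-indexed fetal IgG targets
# emulating a cordocentesis study (for calibration tests) and noisy
# maternal vaccine-response samples (for refitting tests). All synthetic;
# no measured data ship with the package.

.write_csv_full <- function(df, path) {
  out <- df
  for (nm in names(out)) {
    if (is.double(out[[nm]])) out[[nm]] <- sprintf("%.17g", out[[nm]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Generate a synthetic cordocentesis calibration target set
#'
#' Simulates a known "truth" parameter set, samples the fetal subclass
#' trajectory at the given gestational weeks, and reports cohort-style
#' targets: the mean is the simulated value (optionally perturbed by
#' multiplicative lognormal noise of coefficient of variation
#' `noise_cv`), and the standard deviation is synthesised as
#' `cv * mean`, emulating the inter-subject spread of a cordocentesis
#' cohort. The default weeks span 17-41, the window covered by published
#' cohorts. With `noise_cv = 0` the means equal the simulated trajectory
#' exactly.
#'
#' @param truth A `placenta_params` object: the generating parameters.
#' @param weeks Sampling weeks.
#' @param cv Coefficient of variation used to synthesise the reported
#'   standard deviations.
#' @param noise_cv Coefficient of variation of the lognormal noise on
#'   the reported means (0 = noiseless).
#' @param seed Integer seed.
#' @param n_subjects Emulated cohort size (metadata only).
#' @return A calibration target tibble (`week`, `subclass`, `mean_M`,
#'   `sd_M`) with attributes `truth`, `cv`, `noise_cv`, `seed`,
#'   `n_subjects`.
#' @export
generate_cordocentesis_fixture <- function(truth = default_parameters(),
                                           weeks = seq(17, 41, by = 4),
                                           cv = 0.2, noise_cv = 0,
                                           seed = 1, n_subjects = 107) {
  if (cv < 0 || noise_cv < 0) stop("cv must be >= 0", call. = FALSE)
  if (any(weeks < 0)) stop("weeks must be non-negative", call. = FALSE)
  fetal <- .fetal_at_weeks(truth, weeks, t_end = max(weeks))
  set.seed(seed)
  sdlog <- sqrt(log(1 + noise_cv^2))
  out <- purrr::map_dfr(seq_along(weeks), function(i) {
    noise <- if (noise_cv > 0) exp(stats::rnorm(4, 0, sdlog)) else rep(1, 4)
    m <- fetal[i, ] * noise
    tibble(week = weeks[i], subclass = igg_subclasses(),
           mean_M = unname(m), sd_M = cv * unname(m))
  })
  attr(out, "truth") <- truth
  attr(out, "cv") <- cv
  attr(out, "noise_cv") <- noise_cv
  attr(out, "seed") <- seed
  attr(out, "n_subjects") <- n_subjects
  out
}

#' Generate a synthetic maternal vaccine-response sample
#'
#' Noisy samples of the simulated antigen-specific maternal IgG time
#' course, emulating replicate titers from a vaccination cohort.
#'
#' @param vax A `vaccine_params` object.
#' @param sample_days Days post-vaccination at which to sample.
#' @param noise_cv Coefficient of variation of multiplicative lognormal
#'   noise.
#' @param seed Integer seed.
#' @return A tibble `day`, `IgG_PT_mg_ml`.
#' @export
generate_vaccine_response_fixture <- function(vax = vaccine_parameters(),
                                              sample_days = c(0, 7, 14, 21,
                                                              28, 42, 60,
                                                              90),
                                              noise_cv = 0.1, seed = 1) {
  if (noise_cv < 0) stop("noise_cv must be >= 0", call. = FALSE)
  resp <- simulate_vaccine_response(vax, days = sort(unique(c(0,
                                                              sample_days))))
  base <- resp$IgG_PT[match(sample_days, resp$day)]
  set.seed(seed)
  sdlog <- sqrt(log(1 + noise_cv^2))
  noise <- if (noise_cv > 0) {
    exp(stats::rnorm(length(sample_days), 0, sdlog))
  } else {
    rep(1, length(sample_days))
  }
  tibble(day = sample_days, IgG_PT_mg_ml = base * noise)
}

#' Refit vaccine-response parameters to sampled maternal IgG titers
#'
#' Least-squares refit of selected vaccine-response parameters against a
#' sampled IgG time course (e.g. from
#' [generate_vaccine_response_fixture()]). Note the cascade is linear, so
#' `k_ASC`, `k_IgG` and `Ag0` enter the IgG trajectory only through their
#' product: refitting more than one of them at once is degenerate, and
#' the default refits the dose alone.
#'
#' @param fixture Tibble `day`, `IgG_PT_mg_ml`.
#' @param vax_init Starting `vaccine_params`.
#' @param free Character vector of parameters to refit (subset of
#'   `k_ASC`, `k_IgG`, `Ag0`).
#' @return A refitted `vaccine_params` object with attribute `sse`.
#' @export
refit_vaccine_parameters <- function(fixture,
                                     vax_init = vaccine_parameters(),
                                     free = "Ag0") {
  stopifnot(all(c("day", "IgG_PT_mg_ml") %in% names(fixture)),
            all(free %in% c("k_ASC", "k_IgG", "Ag0")))
  obj <- function(logtheta) {
    v <- vax_init
    for (i in seq_along(free)) v[[free[i]]] <- exp(logtheta[i])
    sim <- simulate_vaccine_response(
      v, days = sort(unique(c(0, fixture$day))))
    pred <- sim$IgG_PT[match(fixture$day, sim$day)]
    sum((pred - fixture$IgG_PT_mg_ml)^2)
  }
  start <- log(vapply(free, function(f) vax_init[[f]], numeric(1)))
  fit <- if (length(free) == 1L) {
    o <- optimize(function(z) obj(z), interval = start + c(-5, 5),
                  tol = 1e-10)
    list(par = o$minimum, value = o$objective)
  } else {
    o <- stats::optim(start, obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-12, maxit = 2000))
    list(par = o$par, value = o$value)
  }
  v <- vax_init
  for (i in seq_along(free)) v[[free[i]]] <- exp(fit$par[i])
  attr(v, "sse") <- fit$value
  v
}

#' Write / read a run manifest
#'
#' A JSON document capturing everything needed to reproduce a run:
#' configuration, seeds, solver options and package version. Two runs
#' with identical manifests produce identical outputs.
#'
#' @param config Named list of run configuration.
#' @param seeds Named or unnamed integer vector of seeds.
#' @param solver Named list of solver options.
#' @param path Optional path; when given the manifest is written as JSON.
#' @return The manifest list (invisibly when written).
#' @export
run_manifest <- function(config = list(), seeds = integer(),
                         solver = list(rtol = 1e-8, atol = 1e-14),
                         path = NULL) {
  manifest <- list(
    package = "igtransfer",
    version = as.character(utils::packageVersion("igtransfer")),
    config = config,
    seeds = as.list(seeds),
    solver = solver
  )
  if (!is.null(path)) {
    jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    return(invisible(manifest))
  }
  manifest
}

#' @rdname run_manifest
#' @export
read_manifest <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Write a tidy trajectory CSV
#'
#' Long-format export (`t_weeks`, `species`, `subclass`,
#' `concentration_M`) at full double precision; numbers round-trip
#' losslessly through [utils::read.csv()].
#'
#' @param sim A `placenta_sim` object.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(sim, path) {
  .write_csv_full(tidy(sim), path)
}
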