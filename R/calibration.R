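# Iterative pass/fail calibration of the free placental parameters
# against longitudinal fetal IgG targets: Latin-hypercube sample the
# current plausible ranges, simulate, classify each run against the data
# band, narrow the ranges to the envelope of passing sets, repeat until a
# target fraction of runs passes.

#' Read / write calibration target tables
#'
#' Targets are gestational-week-indexed per-subclass means and standard
#' deviations of fetal IgG concentration (molar), stored as CSV with
#' columns `week`, `subclass`, `mean_M`, `sd_M`.
#'
#' @param path CSV file path.
#' @param targets Target tibble (for the writer).
#' @return A validated tibble (reader); `path` invisibly (writer).
#' @export
read_calibration_targets <- function(path) {
  .validate_targets(as_tibble(utils::read.csv(path)))
}

#' @rdname read_calibration_targets
#' @export
write_calibration_targets <- function(targets, path) {
  .validate_targets(targets)
  .write_csv_full(targets, path)
  invisible(path)
}

.validate_targets <- function(targets) {
  need <- c("week", "subclass", "mean_M", "sd_M")
  if (!all(need %in% names(targets))) {
    stop("targets must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (any(targets$sd_M < 0)) stop("sd_M must be >= 0", call. = FALSE)
  weeks <- sort(unique(targets$week))
  if (length(weeks) < 2) {
    stop("targets need at least a first and a final time point",
         call. = FALSE)
  }
  targets
}

.fetal_at_weeks <- function(params, weeks, t_end = max(weeks),
                            schedules = NULL) {
  if (is.null(schedules)) schedules <- default_schedules(params, t_end)
  species <- .baseline_species(params)
  times <- sort(unique(c(0, weeks, t_end)))
  out <- .sim_core(params, schedules, times, species)
  idx <- match(weeks, out[, "time"])
  m <- out[idx, paste0(igg_subclasses(), ".F"), drop = FALSE]
  rownames(m) <- as.character(weeks)
  colnames(m) <- igg_subclasses()
  m
}

#' Pass/fail criterion for a simulated trajectory against targets
#'
#' A simulation passes when, for every subclass, the simulated fetal
#' concentration at the first target week does not exceed the data mean
#' plus one standard deviation (one-sided: early-gestation fetal IgG is
#' near zero, so only the upper band binds), and at the final target week
#' lies within the mean plus or minus 1.5 standard deviations.
#' Intermediate target weeks do not enter the criterion. The
#' `"total"` rule applies the same bands to total IgG (summed means and
#' standard deviations).
#'
#' @param sim A `placenta_sim`, or a matrix of fetal concentrations as
#'   produced internally (weeks in rows, subclasses in columns).
#' @param targets Target tibble (see [read_calibration_targets()]).
#' @param rule `"per_subclass"` (default, stricter) or `"total"`.
#' @return Logical scalar.
#' @export
calibration_passes <- function(sim, targets,
                               rule = c("per_subclass", "total")) {
  rule <- match.arg(rule)
  targets <- .validate_targets(targets)
  weeks <- sort(unique(targets$week))
  w1 <- weeks[1]
  wf <- weeks[length(weeks)]
  if (inherits(sim, "placenta_sim")) {
    if (max(sim$times) < wf || min(sim$times) > w1) {
      stop("simulation does not span the target weeks", call. = FALSE)
    }
    fetal <- vapply(igg_subclasses(), function(s) {
      approx(sim$times, sim$states[, paste0(s, ".F")],
             xout = c(w1, wf))$y
    }, numeric(2))
    rownames(fetal) <- as.character(c(w1, wf))
  } else {
    fetal <- sim
    if (!all(as.character(c(w1, wf)) %in% rownames(fetal))) {
      stop("fetal matrix lacks the first/final target weeks", call. = FALSE)
    }
  }
  band <- function(w) {
    tw <- targets[targets$week == w, ]
    list(mean = setNames(tw$mean_M, tw$subclass),
         sd = setNames(tw$sd_M, tw$subclass))
  }
  b1 <- band(w1)
  bf <- band(wf)
  if (rule == "total") {
    s1 <- sum(fetal[as.character(w1), ])
    sf <- sum(fetal[as.character(wf), ])
    return(s1 <= sum(b1$mean) + sum(b1$sd) &&
             abs(sf - sum(bf$mean)) <= 1.5 * sum(bf$sd))
  }
  all(vapply(igg_subclasses(), function(s) {
    fetal[as.character(w1), s] <= b1$mean[[s]] + b1$sd[[s]] &&
      abs(fetal[as.character(wf), s] - bf$mean[[s]]) <= 1.5 * bf$sd[[s]]
  }, logical(1)))
}

.params_from_row <- function(base, row) {
  p <- base
  for (nm in names(row)) p[[nm]] <- unname(row[[nm]])
  .validate_parameters(p)
}

#' Iterative range-narrowing calibration
#'
#' Each iteration draws `n_samples` parameter sets by Latin hypercube
#' sampling from the current plausible ranges, simulates each, classifies
#' it with [calibration_passes()], and narrows every free parameter's
#' range to the central percentile envelope of the passing sets.
#' Iteration stops when at least `pass_target` of runs pass (or
#' `max_iter` is reached). Fully deterministic given `seed`.
#'
#' @param ranges Tibble `parameter`, `lower`, `upper` for the free
#'   parameters (degenerate ranges, lower = upper, are held fixed).
#' @param targets Calibration target tibble.
#' @param n_samples Samples per iteration (>= 50).
#' @param seed Integer seed.
#' @param max_iter Maximum iterations.
#' @param pass_target Termination pass fraction (default 0.95).
#' @param envelope Percentile envelope used to narrow ranges.
#' @param rule Pass rule, see [calibration_passes()].
#' @param base_params Parameter set supplying every field not in `ranges`.
#' @return A `calipro_fit` object: `iterations` (tibble `iteration`,
#'   `pass_fraction`), `final_ranges`, `accepted` (passing sets of the
#'   last iteration), `converged`, plus the call configuration. `tidy()`
#'   returns the final ranges, `glance()` the convergence summary.
#' @export
calibrate_parameters <- function(ranges = default_parameter_ranges(),
                                 targets, n_samples = 1000, seed = 1,
                                 max_iter = 10, pass_target = 0.95,
                                 envelope = c(0.025, 0.975),
                                 rule = c("per_subclass", "total"),
                                 base_params = default_parameters()) {
  rule <- match.arg(rule)
  targets <- .validate_targets(targets)
  if (n_samples < 50) stop("n_samples must be >= 50", call. = FALSE)
  if (any(ranges$lower > ranges$upper)) {
    stop("ranges must satisfy lower <= upper", call. = FALSE)
  }
  t_end <- max(targets$week)
  weeks <- sort(unique(targets$week))
  cur <- ranges
  history <- list()
  accepted <- NULL
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    X <- lhs_design(cur, n_samples, seed = seed + it - 1)
    pass <- vapply(seq_len(n_samples), function(i) {
      p <- .params_from_row(base_params, X[i, , drop = FALSE])
      fetal <- tryCatch(.fetal_at_weeks(p, weeks, t_end),
                        error = function(e) NULL)
      !is.null(fetal) && calibration_passes(fetal, targets, rule)
    }, logical(1))
    frac <- mean(pass)
    history[[it]] <- tibble(iteration = it, pass_fraction = frac)
    if (!any(pass)) {
      marg <- purrr::map_dfr(names(X), function(nm) {
        tibble(parameter = nm, min_sampled = min(X[[nm]]),
               max_sampled = max(X[[nm]]))
      })
      stop("calibration failed: no passing parameter sets in iteration ",
           it, "; sampled ranges:\n",
           paste(utils::capture.output(print(marg)), collapse = "\n"),
           call. = FALSE)
    }
    accepted <- X[pass, , drop = FALSE]
    if (frac >= pass_target) {
      converged <- TRUE
      break
    }
    cur <- purrr::map_dfr(seq_len(nrow(cur)), function(j) {
      nm <- cur$parameter[j]
      if (cur$lower[j] == cur$upper[j]) return(cur[j, ])
      q <- quantile(accepted[[nm]], envelope, names = FALSE, type = 7)
      tibble(parameter = nm, lower = q[1], upper = q[2])
    })
  }
  structure(list(
    iterations = dplyr::bind_rows(history),
    final_ranges = cur,
    accepted = accepted,
    converged = converged,
    initial_ranges = ranges,
    n_samples = n_samples, seed = seed, rule = rule,
    pass_target = pass_target
  ), class = "calipro_fit")
}

#' @export
tidy.calipro_fit <- function(x, ...) x$final_ranges

#' @export
glance.calipro_fit <- function(x, ...) {
  tibble(
    iterations = nrow(x$iterations),
    final_pass_fraction = x$iterations$pass_fraction[nrow(x$iterations)],
    converged = x$converged,
    n_samples = x$n_samples,
    n_accepted = nrow(x$accepted)
  )
}

#' @export
print.calipro_fit <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "<calipro_fit> %d iteration(s), final pass fraction %.3f (%s)\n",
    g$iterations, g$final_pass_fraction,
    if (g$converged) "converged" else "max_iter reached"))
  invisible(x)
}

#' @export
autoplot.calipro_fit <- function(object, ...) {
  ggplot2::ggplot(object$iterations,
                  ggplot2::aes(x = .data$iteration,
                               y = .data$pass_fraction)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = object$pass_target,
                        linetype = "dashed") +
    ggplot2::labs(x = "iteration", y = "pass fraction") +
    ggplot2::theme_minimal()
}
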