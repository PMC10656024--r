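# Global sensitivity analysis: Latin hypercube perturbation of the free
# parameters, forward simulation of an outcome, and an orthogonalized
# partial least squares regression (two latent variables: one predictive,
# one orthogonal) with VIP scores, cross-validated Q2, and an empirical
# permutation test.

#' Latin hypercube perturbation design
#'
#' Uniform stratified draws within each parameter's range (one draw per
#' stratum, random pairing across columns); deterministic given `seed`.
#' Degenerate ranges give constant columns.
#'
#' @param ranges Tibble `parameter`, `lower`, `upper`.
#' @param n Number of samples (at least the number of parameters).
#' @param seed Integer seed.
#' @return A tibble with one column per parameter; attributes `ranges`
#'   and `seed`.
#' @export
lhs_design <- function(ranges, n, seed = 1) {
  if (!all(c("parameter", "lower", "upper") %in% names(ranges))) {
    stop("ranges must have columns parameter, lower, upper", call. = FALSE)
  }
  if (any(ranges$lower > ranges$upper)) {
    stop("ranges must satisfy lower <= upper", call. = FALSE)
  }
  if (n < nrow(ranges)) stop("n must be >= number of parameters",
                             call. = FALSE)
  set.seed(seed)
  U <- lhs::randomLHS(n, nrow(ranges))
  X <- sweep(U, 2, ranges$upper - ranges$lower, `*`)
  X <- sweep(X, 2, ranges$lower, `+`)
  colnames(X) <- ranges$parameter
  out <- as_tibble(as.data.frame(X))
  attr(out, "ranges") <- ranges
  attr(out, "seed") <- seed
  out
}

# --- PLS1 (NIPALS) and its one-predictive + one-orthogonal rotation ----

.pls1 <- function(Xs, ys, n_lv = 2) {
  p <- ncol(Xs)
  W <- matrix(0, p, n_lv)
  P <- matrix(0, p, n_lv)
  Q <- numeric(n_lv)
  Tm <- matrix(0, nrow(Xs), n_lv)
  Xd <- Xs
  yd <- ys
  for (a in seq_len(n_lv)) {
    w <- crossprod(Xd, yd)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) {
      # no remaining covariance; keep a null component
      w <- rep(0, p)
      w[a] <- 1
    } else {
      w <- w / nw
    }
    t <- Xd %*% w
    tt <- sum(t^2)
    pl <- crossprod(Xd, t) / tt
    q <- sum(yd * t) / tt
    Xd <- Xd - t %*% t(pl)
    yd <- yd - q * t
    W[, a] <- w
    P[, a] <- pl
    Q[a] <- q
    Tm[, a] <- t
  }
  # regression vector on the original (scaled) X
  B <- W %*% solve(crossprod(P, W), Q)
  list(W = W, P = P, Q = Q, T = Tm, B = B)
}

.oplsr_fit_core <- function(Xs, ys, n_lv = 2) {
  fit <- .pls1(Xs, ys, n_lv)
  # predictive direction: the composite regression direction; LV1 scores
  # carry all modelled y-covariance (orthogonalization is a rotation of
  # the PLS score plane, predictions are unchanged)
  w_pred <- fit$B / sqrt(sum(fit$B^2))
  t_pred <- Xs %*% w_pred
  # orthogonal component: part of the PLS score plane orthogonal to t_pred
  t2 <- fit$T[, n_lv]
  t_orth <- t2 - t_pred * sum(t_pred * t2) / sum(t_pred^2)
  if (sqrt(sum(t_orth^2)) < 1e-12) t_orth <- rep(0, length(t2))
  w_orth <- crossprod(Xs, t_orth)
  nw <- sqrt(sum(w_orth^2))
  w_orth <- if (nw < 1e-12) rep(0, ncol(Xs)) else w_orth / nw
  # y-variance explained by each rotated component (sequential)
  ssy <- sum(ys^2)
  q1 <- sum(ys * t_pred) / sum(t_pred^2)
  r1 <- ys - q1 * t_pred
  ssy1 <- (ssy - sum(r1^2)) / ssy
  tot2 <- sum(t_orth^2)
  if (tot2 > 0) {
    q2 <- sum(r1 * t_orth) / tot2
    r2 <- r1 - q2 * t_orth
  } else {
    r2 <- r1
  }
  ssy2 <- (sum(r1^2) - sum(r2^2)) / ssy
  load1 <- crossprod(Xs, t_pred) / sum(t_pred^2)
  p <- ncol(Xs)
  wts <- c(ssy1, ssy2)
  if (sum(wts) <= 0) wts <- c(1, 0)
  vip <- sqrt(p * (wts[1] * w_pred^2 + wts[2] * w_orth^2) / sum(wts))
  list(pls = fit, w_pred = drop(w_pred), w_orth = drop(w_orth),
       t_pred = drop(t_pred), t_orth = drop(t_orth),
       loading_lv1 = drop(load1), r2y = ssy1 + ssy2,
       ssy_per_lv = wts, vip = drop(vip))
}

.zscore <- function(x) {
  mu <- colMeans(x)
  sg <- apply(x, 2, sd)
  sg[sg == 0] <- 1
  list(x = sweep(sweep(x, 2, mu), 2, sg, `/`), mu = mu, sg = sg)
}

.cv_press <- function(X, y, folds_idx, n_lv) {
  press <- 0
  for (f in unique(folds_idx)) {
    tr <- folds_idx != f
    zx <- .zscore(X[tr, , drop = FALSE])
    ym <- mean(y[tr]); ysd <- sd(y[tr]); if (ysd == 0) ysd <- 1
    fit <- .pls1(zx$x, (y[tr] - ym) / ysd, n_lv)
    Xt <- sweep(sweep(X[!tr, , drop = FALSE], 2, zx$mu), 2, zx$sg, `/`)
    pred <- drop(Xt %*% fit$B) * ysd + ym
    press <- press + sum((y[!tr] - pred)^2)
  }
  press
}

#' Fit an orthogonalized PLS regression model
#'
#' Predictors and outcome are z-scored; a two-latent-variable PLS1 model
#' is fitted by NIPALS and rotated so that the first latent variable
#' carries the full y-predictive direction and the second is orthogonal
#' to it (the rotation leaves predictions unchanged). Variable importance
#' in projection (VIP) scores are computed across the two components,
#' weighted by the y-variance each explains, and signed by each
#' parameter's loading on LV1 for presentation. Predictive power Q2 is
#' estimated by k-fold cross-validation using
#' `Q2 = 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)` on held-out
#' predictions, and significance by comparing the cross-validated error
#' against models refitted to label-permuted outcomes (ties count in
#' favour of the null).
#'
#' @param X Predictor matrix or data frame (n x p).
#' @param y Outcome vector.
#' @param n_lv Number of latent variables (2).
#' @param cv_folds Cross-validation folds.
#' @param n_permutations Label permutations for the empirical null
#'   (0 skips the test).
#' @param seed Integer seed controlling fold assignment and permutations.
#' @param log_scale Log-transform X columns before z-scoring.
#' @return An `oplsr` object; see `tidy()`, `glance()`, `autoplot()`.
#' @export
fit_oplsr <- function(X, y, n_lv = 2, cv_folds = 5, n_permutations = 0,
                      seed = 1, log_scale = FALSE) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (anyNA(X) || anyNA(y)) stop("X and y must be complete", call. = FALSE)
  if (length(y) != nrow(X)) stop("length(y) must equal nrow(X)",
                                 call. = FALSE)
  if (sd(y) == 0) stop("outcome is constant", call. = FALSE)
  if (log_scale) {
    if (any(X <= 0)) stop("log_scale requires positive X", call. = FALSE)
    X <- log(X)
  }
  zx <- .zscore(X)
  ym <- mean(y); ysd <- sd(y)
  core <- .oplsr_fit_core(zx$x, (y - ym) / ysd, n_lv)
  set.seed(seed)
  folds <- sample(rep(seq_len(cv_folds), length.out = nrow(X)))
  press <- .cv_press(X, y, folds, n_lv)
  q2 <- 1 - press / sum((y - ym)^2)
  perm_p <- NA_real_
  perm_mse <- NULL
  if (n_permutations > 0) {
    mse_real <- press / length(y)
    perm_mse <- vapply(seq_len(n_permutations), function(k) {
      yp <- sample(y)
      .cv_press(X, yp, folds, n_lv) / length(y)
    }, numeric(1))
    perm_p <- mean(perm_mse <= mse_real)
  }
  structure(list(
    core = core, scaling = list(mu = zx$mu, sg = zx$sg, ym = ym, ysd = ysd),
    parameters = colnames(X), n = nrow(X), n_lv = n_lv,
    y = y, scores = tibble(lv1 = core$t_pred, lv2 = core$t_orth, y = y),
    q2 = q2, permutation_p = perm_p, perm_mse = perm_mse,
    cv_folds = cv_folds, n_permutations = n_permutations, seed = seed,
    log_scale = log_scale
  ), class = "oplsr")
}

#' Predict method for oplsr models
#'
#' @param object An `oplsr` object.
#' @param newdata Matrix or data frame with the training columns.
#' @param ... Unused.
#' @return Numeric predictions on the outcome scale.
#' @export
predict.oplsr <- function(object, newdata, ...) {
  X <- as.matrix(newdata)[, object$parameters, drop = FALSE]
  if (object$log_scale) X <- log(X)
  sc <- object$scaling
  Xs <- sweep(sweep(X, 2, sc$mu), 2, sc$sg, `/`)
  drop(Xs %*% object$core$pls$B) * sc$ysd + sc$ym
}

#' @export
tidy.oplsr <- function(x, ...) {
  sgn <- sign(x$core$loading_lv1)
  sgn[sgn == 0] <- 1
  tibble(
    parameter = x$parameters,
    vip = x$core$vip,
    vip_signed = x$core$vip * sgn,
    loading_lv1 = x$core$loading_lv1,
    weight_lv1 = x$core$w_pred
  )
}

#' @export
glance.oplsr <- function(x, ...) {
  tibble(
    n = x$n, n_params = length(x$parameters), n_lv = x$n_lv,
    r2y = x$core$r2y, q2 = x$q2,
    permutation_p = x$permutation_p,
    cv_folds = x$cv_folds, n_permutations = x$n_permutations
  )
}

#' @export
print.oplsr <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("<oplsr> n = %d, p = %d; R2Y = %.3f, Q2 = %.3f",
              g$n, g$n_params, g$r2y, g$q2))
  if (!is.na(g$permutation_p)) {
    cat(sprintf(", permutation p %s",
                if (g$permutation_p == 0)
                  sprintf("< %.3g", 1 / g$n_permutations)
                else sprintf("= %.3g", g$permutation_p)))
  }
  cat("\n  top VIP:",
      paste(head(dplyr::arrange(tidy(x), dplyr::desc(.data$vip))$parameter,
                 3), collapse = ", "), "\n")
  invisible(x)
}

#' @export
autoplot.oplsr <- function(object, ...) {
  td <- tidy(object)
  td$parameter <- factor(td$parameter,
                         levels = td$parameter[order(abs(td$vip_signed))])
  ggplot2::ggplot(td, ggplot2::aes(x = .data$parameter,
                                   y = .data$vip_signed)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = c(-1, 1), linetype = "dashed") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "VIP (signed by LV1 loading)") +
    ggplot2::theme_minimal()
}

#' Run a full sensitivity experiment
#'
#' Draws an LHS perturbation design over the free-parameter ranges, runs
#' the forward model on every row, and fits the orthogonalized PLS model
#' for one of three outcomes: total fetal IgG at term, fetal subclass
#' entropy at term, or the optimal vaccination week (which runs the full
#' timing sweep per row and is accordingly much slower). Rows whose
#' simulation fails are dropped pairwise (an error is raised if more than
#' 5 percent fail).
#'
#' @param outcome `"total_igg"`, `"entropy"` or `"optimal_tvax"`.
#' @param ranges Free-parameter ranges.
#' @param n Number of LHS rows.
#' @param seed Integer seed (design, folds and permutations).
#' @param t_end Gestational length (weeks).
#' @param vax Vaccine parameters (optimal-timing outcome only).
#' @param tvax_sweep Candidate weeks (optimal-timing outcome only).
#' @param cv_folds,n_permutations,log_scale Passed to [fit_oplsr()].
#' @param base_params Parameter set supplying the fields not in `ranges`.
#' @return A list with `model` (an `oplsr`), `design`, `y`, `outcome`,
#'   and `n_failed`.
#' @export
sensitivity_experiment <- function(outcome = c("total_igg", "entropy",
                                               "optimal_tvax"),
                                   ranges = default_parameter_ranges(),
                                   n = 1000, seed = 11, t_end = 40,
                                   vax = vaccine_parameters(),
                                   tvax_sweep = seq(10, 38, 1),
                                   cv_folds = 5, n_permutations = 0,
                                   log_scale = FALSE,
                                   base_params = default_parameters()) {
  outcome <- match.arg(outcome)
  design <- lhs_design(ranges, n, seed)
  eval_row <- function(i) {
    p <- .params_from_row(base_params, design[i, , drop = FALSE])
    switch(outcome,
      total_igg = sum(.fetal_at_weeks(p, t_end, t_end)),
      entropy = subclass_entropy(.fetal_at_weeks(p, t_end, t_end)[1, ]),
      optimal_tvax = optimize_tvax(p, vax, gestational_length = t_end,
                                   sweep = tvax_sweep,
                                   refine = FALSE)$optimal_t_vax
    )
  }
  y <- vapply(seq_len(n), function(i) {
    tryCatch(eval_row(i), error = function(e) NA_real_)
  }, numeric(1))
  bad <- !is.finite(y)
  if (mean(bad) > 0.05) {
    stop("more than 5% of simulations failed (", sum(bad), " of ", n, ")",
         call. = FALSE)
  }
  model <- fit_oplsr(design[!bad, , drop = FALSE], y[!bad],
                     cv_folds = cv_folds, n_permutations = n_permutations,
                     seed = seed, log_scale = log_scale)
  list(model = model, design = design, y = y, outcome = outcome,
       n_failed = sum(bad))
}
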