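# Gestation-dependent Fc receptor expression. Total receptor is an
# "offline" variable: a convex quadratic in gestational week, zero at
# conception and reaching the optimized term value at t_end. Free receptor
# is recovered algebraically downstream (free = total - bound), which is
# equivalent to integrating a synthesis source that adds only free
# receptor.

#' Construct a gestational Fc receptor expression schedule
#'
#' Total receptor expression is modelled as a quadratic
#' `R(t) = a t^2 + b t + c` in gestational week `t`. The default shape is
#' `R_end * (t / t_end)^2`: zero at conception, convex, monotone
#' non-decreasing, and equal to `R_end` at term, consistent with the
#' parabolic rise of placental FcRn observed in rodent expression data.
#' Custom coefficients are accepted provided they keep the curve convex,
#' non-negative and non-decreasing on `[0, t_end]` and hit `R_end` at
#' `t_end`.
#'
#' @param R_end Receptor expression at `t_end` (molar).
#' @param t_end Gestational length (weeks).
#' @param a,b,c Optional quadratic coefficients overriding the default
#'   shape.
#' @param receptor Optional label (`"FcRn_STB"`, `"FcgRIIb_EC"`,
#'   `"FcRn_EC"`).
#' @return An object of class `fcr_schedule`.
#' @examples
#' s <- fcr_schedule(4.135e-5, 40)
#' receptor_total(s, 20)  # R_end / 4
#' @export
fcr_schedule <- function(R_end, t_end = 40, a = NULL, b = NULL, c = NULL,
                         receptor = NA_character_) {
  if (R_end <= 0 || t_end <= 0) {
    stop("R_end and t_end must be positive", call. = FALSE)
  }
  if (is.null(a) && is.null(b) && is.null(c)) {
    a <- R_end / t_end^2
    b <- 0
    c <- 0
  } else {
    a <- a %||% 0; b <- b %||% 0; c <- c %||% 0
  }
  if (a < 0) stop("schedule must be convex (a >= 0)", call. = FALSE)
  tt <- seq(0, t_end, length.out = 201)
  v <- a * tt^2 + b * tt + c
  if (any(v < -1e-15 * R_end)) {
    stop("schedule must be non-negative on [0, t_end]", call. = FALSE)
  }
  dv <- 2 * a * tt + b
  if (any(dv < -1e-12 * R_end / t_end)) {
    stop("schedule must be monotone non-decreasing on [0, t_end]",
         call. = FALSE)
  }
  end <- a * t_end^2 + b * t_end + c
  if (abs(end - R_end) > 1e-9 * R_end) {
    stop("schedule must equal R_end at t_end (got ", signif(end, 6), ")",
         call. = FALSE)
  }
  structure(
    list(receptor = receptor, a = a, b = b, c = c,
         t_end = t_end, R_end = R_end),
    class = "fcr_schedule"
  )
}

#' Evaluate a receptor schedule
#'
#' `receptor_total()` evaluates total receptor expression at gestational
#' week `t`; `receptor_synthesis_rate()` returns its time derivative, the
#' rate at which newly synthesised receptor is added as the placenta grows.
#' Both error outside `[0, t_end]`.
#'
#' @param schedule An `fcr_schedule`.
#' @param t Gestational week(s).
#' @return Numeric vector (molar, or molar/week for the synthesis rate).
#' @export
receptor_total <- function(schedule, t) {
  stopifnot(inherits(schedule, "fcr_schedule"))
  if (any(t < 0) || any(t > schedule$t_end)) {
    stop("t outside [0, t_end]", call. = FALSE)
  }
  pmax(schedule$a * t^2 + schedule$b * t + schedule$c, 0)
}

#' @rdname receptor_total
#' @export
receptor_synthesis_rate <- function(schedule, t) {
  stopifnot(inherits(schedule, "fcr_schedule"))
  if (any(t < 0) || any(t > schedule$t_end)) {
    stop("t outside [0, t_end]", call. = FALSE)
  }
  pmax(2 * schedule$a * t + schedule$b, 0)
}

#' Default receptor schedules for a parameter set
#'
#' Builds the three gestational expression schedules (STB FcRn, EC
#' FcgRIIb, EC FcRn) from the term expression levels in `params`, each
#' with the default quadratic-through-origin shape.
#'
#' @param params A `placenta_params` object.
#' @param t_end Gestational length (weeks).
#' @return Named list of three `fcr_schedule` objects
#'   (`FcRn_STB`, `FcgRIIb_EC`, `FcRn_EC`).
#' @export
default_schedules <- function(params = default_parameters(), t_end = 40) {
  list(
    FcRn_STB = fcr_schedule(params$FcRnSTBtotal_end, t_end,
                            receptor = "FcRn_STB"),
    FcgRIIb_EC = fcr_schedule(params$FcgRIIbECtotal_end, t_end,
                              receptor = "FcgRIIb_EC"),
    FcRn_EC = fcr_schedule(params$FcRnECtotal_end, t_end,
                           receptor = "FcRn_EC")
  )
}

#' Constant (gestation-independent) receptor schedules
#'
#' Mainly for conservation tests: expression is held at `R_end` for the
#' whole simulation, so receptor totals are constant in time.
#'
#' @inheritParams default_schedules
#' @return Named list of three `fcr_schedule` objects.
#' @export
constant_schedules <- function(params = default_parameters(), t_end = 40) {
  const <- function(R_end, receptor) {
    fcr_schedule(R_end, t_end, a = 0, b = 0, c = R_end, receptor = receptor)
  }
  list(
    FcRn_STB = const(params$FcRnSTBtotal_end, "FcRn_STB"),
    FcgRIIb_EC = const(params$FcgRIIbECtotal_end, "FcgRIIb_EC"),
    FcRn_EC = const(params$FcRnECtotal_end, "FcRn_EC")
  )
}

#' @export
print.fcr_schedule <- function(x, ...) {
  cat(sprintf(
    "<fcr_schedule %s> R(t) = %.3g t^2 + %.3g t + %.3g on [0, %g]; R_end = %.3g M\n",
    x$receptor, x$a, x$b, x$c, x$t_end, x$R_end))
  invisible(x)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
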