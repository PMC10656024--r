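# Placental model parameters. The packaged defaults take the midpoint of
# each optimized range from the published parameter table; literature-derived
# values (maternal subclass concentrations, affinities, fetal decay) are
# point values.

.table1_ranges <- tibble::tribble(
  ~parameter,            ~lower,    ~upper,
  "k_up",                0.0872,    0.0982,
  "k_trans",             0.0569,    0.0743,
  "k_deg",               8.4733,    9.0809,
  "FcRnSTBtotal_end",    3.33e-5,   4.94e-5,
  "FcgRIIbECtotal_end",  2.73e-5,   3.33e-5,
  "FcRnECtotal_end",     2.36e-6,   2.86e-6,
  "V_M",                 5.552,     5.619,
  "V_STB",               0.224,     0.258,
  "V_STR",               0.165,     0.179,
  "V_EC",                0.247,     0.275,
  "V_F",                 0.254,     0.271
)

.igg_subclasses <- c("IgG1", "IgG2", "IgG3", "IgG4")

#' IgG subclass labels
#'
#' The four human IgG subclasses carried by every per-subclass container in
#' the package, in canonical order.
#'
#' @return Character vector of length four.
#' @export
igg_subclasses <- function() .igg_subclasses

#' Fc receptor / IgG subclass binding affinities
#'
#' Equilibrium dissociation constants for FcRn (measured at endosomal pH)
#' and FcgRIIb against each IgG subclass, with association/dissociation
#' rates derived via k_on = k_off / K_D (k_off = 0.15/s for all pairs).
#' FcRn binds every subclass orders of magnitude more tightly than
#' FcgRIIb; FcgRIIb prefers IgG3 and IgG4 over IgG1 and strongly disfavours
#' IgG2.
#'
#' @return A tibble with columns `receptor`, `subclass`, `K_D` (molar),
#'   `k_on_per_M_s`, `k_on_per_M_wk`, `k_off_per_wk`.
#' @export
default_affinities <- function() {
  kd <- tibble::tribble(
    ~receptor,  ~subclass, ~K_D,
    "FcRn",     "IgG1",    1.25e-8,
    "FcRn",     "IgG2",    2e-8,
    "FcRn",     "IgG3",    3.3e-8,
    "FcRn",     "IgG4",    5e-8,
    "FcgRIIb",  "IgG1",    1e-5,
    "FcgRIIb",  "IgG2",    5e-5,
    "FcgRIIb",  "IgG3",    5e-6,
    "FcgRIIb",  "IgG4",    5e-6
  )
  dplyr::bind_cols(kd[, c("receptor", "subclass")],
                   derive_kinetic_rates(kd$K_D))
}

.validate_affinities <- function(aff) {
  stopifnot(is.data.frame(aff))
  need <- c("receptor", "subclass", "K_D", "k_on_per_M_wk", "k_off_per_wk")
  if (!all(need %in% names(aff))) {
    stop("affinity table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(aff) != 8L ||
      !setequal(unique(aff$receptor), c("FcRn", "FcgRIIb")) ||
      !all(table(aff$receptor, aff$subclass) == 1)) {
    stop("affinity table must contain exactly one row per receptor x subclass",
         call. = FALSE)
  }
  if (any(aff$K_D <= 0) || any(aff$k_on_per_M_wk <= 0) ||
      any(aff$k_off_per_wk <= 0)) {
    stop("affinities must be strictly positive", call. = FALSE)
  }
  rel <- abs(aff$k_on_per_M_wk * aff$K_D - aff$k_off_per_wk) /
    aff$k_off_per_wk
  if (any(rel > 1e-10)) {
    stop("affinity table violates k_on * K_D = k_off", call. = FALSE)
  }
  invisible(aff)
}

.scalar_fields <- c("k_up", "k_trans", "k_deg",
                    "FcRnSTBtotal_end", "FcgRIIbECtotal_end", "FcRnECtotal_end",
                    "V_M", "V_STB", "V_STR", "V_EC", "V_F", "delta_Ab")

#' Construct a validated placental parameter set
#'
#' All transport rates are volumetric clearances in L/week, receptor
#' expression levels and maternal subclass concentrations are molar, and
#' volumes are litres. Defaults for any field left `NULL` come from
#' [default_parameters()].
#'
#' @param k_up,k_trans,k_deg Uptake, transcytosis and lysosomal degradation
#'   clearances (L/week).
#' @param FcRnSTBtotal_end,FcgRIIbECtotal_end,FcRnECtotal_end Receptor
#'   expression at term (molar).
#' @param IgG0 Named numeric vector of maternal subclass concentrations
#'   (molar), names `IgG1`..`IgG4`.
#' @param V_M,V_STB,V_STR,V_EC,V_F Compartment volumes (L).
#' @param delta_Ab Fetal IgG decay clearance (L/week).
#' @param affinities Affinity table as produced by [default_affinities()].
#' @return An object of class `placenta_params` (a named list).
#' @export
placenta_parameters <- function(k_up = NULL, k_trans = NULL, k_deg = NULL,
                                FcRnSTBtotal_end = NULL,
                                FcgRIIbECtotal_end = NULL,
                                FcRnECtotal_end = NULL,
                                IgG0 = NULL,
                                V_M = NULL, V_STB = NULL, V_STR = NULL,
                                V_EC = NULL, V_F = NULL,
                                delta_Ab = NULL, affinities = NULL) {
  def <- .default_parameter_list()
  supplied <- list(
    k_up = k_up, k_trans = k_trans, k_deg = k_deg,
    FcRnSTBtotal_end = FcRnSTBtotal_end,
    FcgRIIbECtotal_end = FcgRIIbECtotal_end,
    FcRnECtotal_end = FcRnECtotal_end,
    IgG0 = IgG0, V_M = V_M, V_STB = V_STB, V_STR = V_STR,
    V_EC = V_EC, V_F = V_F, delta_Ab = delta_Ab, affinities = affinities
  )
  p <- utils::modifyList(def, supplied[!vapply(supplied, is.null, logical(1))])
  .validate_parameters(p)
}

.default_parameter_list <- function() {
  mid <- setNames((.table1_ranges$lower + .table1_ranges$upper) / 2,
                  .table1_ranges$parameter)
  list(
    k_up = mid[["k_up"]], k_trans = mid[["k_trans"]], k_deg = mid[["k_deg"]],
    FcRnSTBtotal_end = mid[["FcRnSTBtotal_end"]],
    FcgRIIbECtotal_end = mid[["FcgRIIbECtotal_end"]],
    FcRnECtotal_end = mid[["FcRnECtotal_end"]],
    IgG0 = c(IgG1 = 3.78e-5, IgG2 = 1.81e-5, IgG3 = 2.35e-6, IgG4 = 2.27e-6),
    V_M = mid[["V_M"]], V_STB = mid[["V_STB"]], V_STR = mid[["V_STR"]],
    V_EC = mid[["V_EC"]], V_F = mid[["V_F"]],
    delta_Ab = 0.02,
    affinities = default_affinities()
  )
}

.validate_parameters <- function(p) {
  # degradation/decay clearances may be switched off (zero) for
  # conservation analyses; everything else must be strictly positive
  zero_ok <- c("k_deg", "delta_Ab")
  for (f in .scalar_fields) {
    v <- p[[f]]
    if (is.null(v)) stop("missing required parameter: ", f, call. = FALSE)
    lo_ok <- if (f %in% zero_ok) v >= 0 else v > 0
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || !lo_ok) {
      stop("parameter ", f, " must be a single positive number", call. = FALSE)
    }
  }
  if (!is.numeric(p$IgG0) || length(p$IgG0) != 4L ||
      !setequal(names(p$IgG0), .igg_subclasses)) {
    stop("IgG0 must be a numeric vector named IgG1..IgG4", call. = FALSE)
  }
  if (any(p$IgG0 < 0)) stop("IgG0 must be non-negative", call. = FALSE)
  p$IgG0 <- p$IgG0[.igg_subclasses]
  vols <- p$V_M + p$V_STB + p$V_STR + p$V_EC + p$V_F
  if (vols >= 10) {
    stop("compartment volumes sum to ", signif(vols, 3),
         " L; physiologic total must be < 10 L", call. = FALSE)
  }
  .validate_affinities(p$affinities)
  structure(p[c(.scalar_fields[1:11], "IgG0", "delta_Ab", "affinities")],
            class = "placenta_params")
}

#' Packaged default placental parameters
#'
#' Returns the midpoint of each optimized parameter range together with the
#' literature-derived maternal subclass concentrations, affinities, and
#' fetal decay clearance. The optimized ranges themselves are available
#' from [default_parameter_ranges()].
#'
#' @return A `placenta_params` object.
#' @examples
#' p <- default_parameters()
#' p$k_up  # 0.0927 L/week
#' @export
default_parameters <- function() .validate_parameters(.default_parameter_list())

#' Optimized parameter ranges for the 11 free placental parameters
#'
#' The calibrated range for each free parameter (transport clearances,
#' term receptor expression, compartment volumes). These ranges bound the
#' calibration search space and the Latin-hypercube perturbation designs.
#'
#' @return A tibble with columns `parameter`, `lower`, `upper`.
#' @export
default_parameter_ranges <- function() .table1_ranges

#' Flatten / rebuild a parameter set as a tibble
#'
#' `parameter_table()` serializes a `placenta_params` object into a
#' two-column tibble (one row per scalar, `IgG1_0`..`IgG4_0` for the
#' maternal concentrations, `KD_<receptor>_<subclass>` for affinities);
#' useful for CSV export and round-tripping.
#'
#' @param params A `placenta_params` object.
#' @return A tibble with columns `parameter`, `value`.
#' @export
parameter_table <- function(params) {
  stopifnot(inherits(params, "placenta_params"))
  sc <- tibble(
    parameter = .scalar_fields,
    value = vapply(.scalar_fields, function(f) params[[f]], numeric(1))
  )
  ig <- tibble(parameter = paste0(.igg_subclasses, "_0"),
               value = unname(params$IgG0))
  kd <- tibble(
    parameter = paste0("KD_", params$affinities$receptor, "_",
                       params$affinities$subclass),
    value = params$affinities$K_D
  )
  dplyr::bind_rows(sc, ig, kd)
}

#' Read / write parameter configurations
#'
#' Parameter sets are stored as flat key-value YAML documents whose keys
#' follow the published symbol names (`k_up`, `FcRnSTBtotal_end`,
#' `IgG1_0`, `KD_FcRn_IgG1`, ...). Keys that are omitted fall back to the
#' packaged defaults; `use_defaults: true` alone yields
#' [default_parameters()]. Writing then reading a parameter set is the
#' identity.
#'
#' @param path File path of the YAML configuration.
#' @param params A `placenta_params` object (for `write_parameters`).
#' @return `load_parameters()` returns a `placenta_params` object;
#'   `write_parameters()` returns `path` invisibly.
#' @export
load_parameters <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  known <- c(.scalar_fields, paste0(.igg_subclasses, "_0"),
             paste0("KD_", rep(c("FcRn", "FcgRIIb"), each = 4), "_",
                    .igg_subclasses),
             "use_defaults", "k_off_per_s")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  p <- .default_parameter_list()
  for (f in .scalar_fields) if (!is.null(cfg[[f]])) p[[f]] <- cfg[[f]]
  for (s in .igg_subclasses) {
    k <- paste0(s, "_0")
    if (!is.null(cfg[[k]])) p$IgG0[[s]] <- cfg[[k]]
  }
  koff <- if (is.null(cfg$k_off_per_s)) 0.15 else cfg$k_off_per_s
  aff <- p$affinities
  for (i in seq_len(nrow(aff))) {
    k <- paste0("KD_", aff$receptor[i], "_", aff$subclass[i])
    if (!is.null(cfg[[k]])) {
      if (cfg[[k]] <= 0) stop("K_D must be positive: ", k, call. = FALSE)
      kin <- derive_kinetic_rates(cfg[[k]], koff)
      aff[i, c("K_D", "k_on_per_M_s", "k_on_per_M_wk", "k_off_per_wk")] <- kin
    }
  }
  p$affinities <- aff
  .validate_parameters(p)
}

#' @rdname load_parameters
#' @export
write_parameters <- function(params, path) {
  stopifnot(inherits(params, "placenta_params"))
  tab <- parameter_table(params)
  yaml::write_yaml(as.list(setNames(tab$value, tab$parameter)), path,
                   precision = 15)
  invisible(path)
}

#' @export
print.placenta_params <- function(x, ...) {
  cat("<placenta_params>\n")
  cat(sprintf("  k_up %.4g  k_trans %.4g  k_deg %.4g L/week\n",
              x$k_up, x$k_trans, x$k_deg))
  cat(sprintf("  receptors at term (M): FcRn_STB %.3g  FcgRIIb_EC %.3g  FcRn_EC %.3g\n",
              x$FcRnSTBtotal_end, x$FcgRIIbECtotal_end, x$FcRnECtotal_end))
  cat(sprintf("  volumes (L): M %.3g STB %.3g STR %.3g EC %.3g F %.3g\n",
              x$V_M, x$V_STB, x$V_STR, x$V_EC, x$V_F))
  cat(sprintf("  maternal IgG1-4 (M): %s\n",
              paste(signif(x$IgG0, 3), collapse = " ")))
  cat(sprintf("  delta_Ab %.3g L/week\n", x$delta_Ab))
  invisible(x)
}
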