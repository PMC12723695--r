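#' Analysis configuration
#'
#' Bundles every tunable constant of the pipeline: the grain-economics
#' parameters behind the ESV base value, the regional correction
#' coefficient, the subsystem weights of the coupling model, the
#' nine-rung classification ladder, and the random seed. Every constant
#' can be overridden; the defaults are the study values.
#'
#' @param grain_price Average grain purchase price P (yuan/kg). Default 3.05.
#' @param base_value Economic value of grain production per unit cropland
#'   area Ea (yuan/ha), i.e. one seventh of the per-hectare grain value.
#'   Default 2418.58 (national figure before regional correction).
#' @param lambda Regional correction coefficient: ratio of regional to
#'   national grain yield per unit area. Default 0.968. Must be > 0.
#' @param alpha,beta Subsystem weights in the comprehensive coordination
#'   index T = alpha*f + beta*g. Must be non-negative and sum to 1.
#'   Default 0.5/0.5 (the two subsystems treated as equally important).
#' @param ccd_form `"sqrt"` (default) computes D = sqrt(C*T), the
#'   conventional coupling-coordination degree; `"product"` computes the
#'   literal D = C*T.
#' @param esv_normalization `"pooled"` (default) min-max rescales ESV over
#'   all city-years on one scale; `"per_city"` rescales within each city.
#' @param weight_scope `"pooled"` (default) computes entropy weights from
#'   the pooled city-year panel; `"per_city"` computes them per city.
#' @param sig_levels Two-element numeric vector: p-value thresholds for
#'   `*` and `**` significance markers. Default `c(0.05, 0.01)`.
#' @param alpha_select Significance level used by [select_model()].
#' @param seed Integer seed for any stochastic stage.
#' @param ladder Classification ladder, a data frame as returned by
#'   [ccd_ladder()]. Intervals must partition [0, 1].
#'
#' @return An object of class `"analysis_config"` (a named list).
#' @seealso [ccd_ladder()], [read_config()], [write_config()]
#' @examples
#' cfg <- analysis_config()
#' cfg$lambda
#' @export
analysis_config <- function(grain_price = 3.05,
                            base_value = 2418.58,
                            lambda = 0.968,
                            alpha = 0.5,
                            beta = 0.5,
                            ccd_form = c("sqrt", "product"),
                            esv_normalization = c("pooled", "per_city"),
                            weight_scope = c("pooled", "per_city"),
                            sig_levels = c(0.05, 0.01),
                            alpha_select = 0.05,
                            seed = 1L,
                            ladder = ccd_ladder()) {
  ccd_form <- match.arg(ccd_form)
  esv_normalization <- match.arg(esv_normalization)
  weight_scope <- match.arg(weight_scope)
  if (lambda <= 0) stopf("`lambda` must be > 0, got %g", lambda)
  if (alpha < 0 || beta < 0) stopf("alpha and beta must be non-negative")
  if (abs(alpha + beta - 1) > 1e-9)
    stopf("alpha + beta must equal 1 (got %g + %g)", alpha, beta)
  validate_ladder(ladder)
  structure(list(
    grain_price = grain_price,
    base_value = base_value,
    lambda = lambda,
    alpha = alpha, beta = beta,
    ccd_form = ccd_form,
    esv_normalization = esv_normalization,
    weight_scope = weight_scope,
    sig_levels = sig_levels,
    alpha_select = alpha_select,
    seed = as.integer(seed),
    ladder = ladder
  ), class = "analysis_config")
}

#' Nine-rung CCD classification ladder
#'
#' The default ladder partitions [0, 1] into half-open deciles (the top
#' rung closed at 1) mapped to three stages and nine coordination types.
#'
#' @return A data frame with columns `lower`, `upper`, `stage`, `type`.
#'   Intervals are `[lower, upper)` except the last, which is
#'   `[lower, upper]`.
#' @export
ccd_ladder <- function() {
  data.frame(
    lower = c(0.0, 0.2, 0.3, 0.4, 0.5, 0.6, 0.7, 0.8, 0.9),
    upper = c(0.2, 0.3, 0.4, 0.5, 0.6, 0.7, 0.8, 0.9, 1.0),
    stage = c(rep("Disorder", 3), rep("Run-in", 2), rep("Coordination", 4)),
    type = c("Severe disorder", "Moderate disorder", "Mild disorder",
             "Borderline disorder", "Bare coordinate",
             "Elementary coordinate", "Intermediate coordinate",
             "Good coordinate", "Excellent coordinate"),
    stringsAsFactors = FALSE
  )
}

validate_ladder <- function(ladder) {
  need <- c("lower", "upper", "stage", "type")
  if (!all(need %in% names(ladder)))
    stopf("ladder must have columns %s", paste(need, collapse = ", "))
  o <- order(ladder$lower)
  ladder <- ladder[o, ]
  if (abs(ladder$lower[1]) > 1e-12 || abs(ladder$upper[nrow(ladder)] - 1) > 1e-12)
    stopf("classification intervals must span [0, 1]")
  if (any(abs(ladder$upper[-nrow(ladder)] - ladder$lower[-1]) > 1e-12))
    stopf("classification intervals must partition [0, 1] without gaps")
  invisible(ladder)
}

#' Read / write an analysis configuration as YAML
#'
#' The on-disk format is a flat YAML mapping mirroring
#' [analysis_config()]; the ladder is stored as parallel lists. Fields
#' absent from the file take their defaults.
#'
#' @param path File path.
#' @param config An `analysis_config` object.
#' @return `read_config()` returns an `analysis_config`; `write_config()`
#'   returns `path` invisibly.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  ladder <- if (!is.null(raw$ladder)) {
    as.data.frame(lapply(raw$ladder, unlist), stringsAsFactors = FALSE)
  } else ccd_ladder()
  args <- raw[setdiff(names(raw), "ladder")]
  do.call(analysis_config, c(args, list(ladder = ladder)))
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "analysis_config"))
  x <- unclass(config)
  x$ladder <- as.list(config$ladder)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @export
print.analysis_config <- function(x, ...) {
  cat("Analysis configuration\n")
  cat(sprintf("  grain price P:        %.2f yuan/kg\n", x$grain_price))
  cat(sprintf("  base value Ea:        %.2f yuan/ha (corrected: %.2f)\n",
              x$base_value, x$base_value * x$lambda))
  cat(sprintf("  correction lambda:    %.3f\n", x$lambda))
  cat(sprintf("  coupling weights:     alpha = %g, beta = %g\n", x$alpha, x$beta))
  cat(sprintf("  CCD form:             %s\n",
              if (x$ccd_form == "sqrt") "D = sqrt(C*T)" else "D = C*T"))
  cat(sprintf("  ladder:               %d types / %d stages\n",
              nrow(x$ladder), length(unique(x$ladder$stage))))
  invisible(x)
}
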