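#' Min-max standardisation of an indicator panel
#'
#' Benefit-type indicators are rescaled as `(x - min)/(max - min)`,
#' cost-type indicators as `(max - x)/(max - min)`, with the extremes
#' taken over the pooled city-year panel so that scores are comparable
#' across both cities and years (set `scope = "per_city"` to rescale
#' within each city instead). Constant columns carry no information:
#' they are set to zero and flagged.
#'
#' @param panel An [indicator_panel()] with no missing values.
#' @param scope `"pooled"` (default) or `"per_city"`.
#' @return Numeric matrix `y` (rows = city-years, columns = indicators)
#'   with values in [0, 1]; attributes `keys` (city/year data frame) and
#'   `zero_information` (logical per column).
#' @export
normalize_indicators <- function(panel, scope = c("pooled", "per_city")) {
  stopifnot(inherits(panel, "indicator_panel"))
  scope <- match.arg(scope)
  if (nrow(panel) < 2) stopf("need at least 2 observations to standardise")
  ind <- attr(panel, "indicators")
  dirs <- attr(panel, "directions")
  X <- as.matrix(as.data.frame(panel)[, ind, drop = FALSE])
  if (anyNA(X)) stopf("panel contains missing values; interpolate first")
  Y <- matrix(0, nrow(X), ncol(X), dimnames = dimnames(X))
  zero_info <- logical(ncol(X))
  names(zero_info) <- ind
  groups <- if (scope == "pooled") list(seq_len(nrow(X))) else
    split(seq_len(nrow(X)), panel$city)
  for (g in groups) {
    for (j in seq_along(ind)) {
      x <- X[g, j]
      rng <- range(x)
      if (diff(rng) == 0) {
        zero_info[j] <- TRUE
        Y[g, j] <- 0
      } else {
        Y[g, j] <- if (dirs[j] > 0) (x - rng[1]) / diff(rng)
                   else (rng[2] - x) / diff(rng)
      }
    }
  }
  if (any(zero_info))
    warnf("constant (zero-information) indicator(s): %s",
          paste(ind[zero_info], collapse = ", "))
  structure(Y, keys = data.frame(city = panel$city, year = panel$year,
                                 stringsAsFactors = FALSE),
            zero_information = zero_info)
}

#' Entropy weights for a standardised indicator matrix
#'
#' For each indicator the observation proportions are
#' `Y_ij = y_ij / sum_i y_ij`, the entropy is
#' `e_j = -(1/ln m) sum_i Y_ij ln Y_ij` (with `0 ln 0 = 0`), the
#' information utility is `d_j = 1 - e_j`, and the weights
#' `W_j = d_j / sum_j d_j`. Indicators with more dispersion carry more
#' information and receive larger weights. Zero-information (constant)
#' columns get `e_j = 1` and weight 0.
#'
#' @param normalized Matrix from [normalize_indicators()], values in
#'   [0, 1].
#' @return An object of class `"entropy_weights"`: data frame with
#'   columns `indicator`, `entropy`, `utility`, `weight`. Weights are
#'   non-negative and sum to 1.
#' @examples
#' y <- cbind(a = c(0, 0.5, 1), b = c(1, 0, 1))
#' entropy_weights(y)
#' @export
entropy_weights <- function(normalized) {
  Y <- as.matrix(normalized)
  if (any(Y < -1e-12 | Y > 1 + 1e-12)) stopf("standardised values must lie in [0, 1]")
  m <- nrow(Y)
  if (m < 2) stopf("need at least 2 observations")
  p <- ncol(Y)
  e <- numeric(p)
  colsum <- colSums(Y)
  for (j in seq_len(p)) {
    if (colsum[j] == 0) { e[j] <- 1; next }  # zero-information column
    pr <- Y[, j] / colsum[j]
    term <- ifelse(pr > 0, pr * log(pr), 0)
    e[j] <- -sum(term) / log(m)
  }
  d <- 1 - e
  if (all(d <= 0)) stopf("all indicators are zero-information; no usable signal")
  w <- d / sum(d)
  structure(data.frame(
    indicator = colnames(Y) %||% paste0("V", seq_len(p)),
    entropy = e, utility = d, weight = w,
    stringsAsFactors = FALSE
  ), class = c("entropy_weights", "data.frame"))
}

#' @export
print.entropy_weights <- function(x, digits = 4, ...) {
  cat(sprintf("Entropy weights for %d indicators (sum = %g)\n",
              nrow(x), sum(x$weight)))
  print(format(as.data.frame(x), digits = digits), ...)
  invisible(x)
}

#' Composite evaluation score
#'
#' The weighted sum `S_i = sum_j W_j y_ij` of standardised indicator
#' values; with min-max standardised inputs and weights summing to 1,
#' scores lie in [0, 1].
#'
#' @param normalized Matrix from [normalize_indicators()].
#' @param weights An [entropy_weights()] object (or numeric vector of
#'   per-indicator weights).
#' @return Data frame with `city`, `year` (when available) and `score`.
#' @export
composite_index <- function(normalized, weights) {
  Y <- as.matrix(normalized)
  w <- if (inherits(weights, "entropy_weights")) weights$weight else as.numeric(weights)
  if (length(w) != ncol(Y))
    stopf("weight vector has length %d but matrix has %d columns",
          length(w), ncol(Y))
  s <- as.numeric(Y %*% w)
  keys <- attr(normalized, "keys")
  if (!is.null(keys)) cbind(keys, score = s)
  else data.frame(score = s)
}

#' Entropy-weight composite index of a tourism indicator panel
#'
#' Convenience wrapper chaining [normalize_indicators()],
#' [entropy_weights()] and [composite_index()]: one weight vector is
#' computed from the study-period panel and applied to every city-year.
#'
#' @param panel An [indicator_panel()].
#' @param config An [analysis_config()]; `weight_scope` selects pooled or
#'   per-city standardisation.
#' @return List with `scores` (city, year, score) and `weights`
#'   (an [entropy_weights()] data frame).
#' @export
tourism_index <- function(panel, config = analysis_config()) {
  y <- normalize_indicators(panel, scope = config$weight_scope)
  w <- entropy_weights(y)
  list(scores = composite_index(y, w), weights = w)
}
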