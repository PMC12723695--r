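#' Construct an indicator panel
#'
#' An indicator panel holds the raw city-year indicator matrix together
#' with the per-indicator orientation: `+1` for benefit-type indicators
#' (larger is better) and `-1` for cost-type indicators (such as a PM2.5
#' concentration).
#'
#' @param df Data frame with columns `city`, `year` and one numeric
#'   column per indicator.
#' @param directions Numeric or character vector of indicator directions,
#'   one per indicator column, each `+1`/`-1` (or `"+"`/`"-"`).
#' @return An object of class `"indicator_panel"`: a data frame with
#'   attributes `directions` (named numeric vector) and `indicators`
#'   (column names).
#' @export
indicator_panel <- function(df, directions) {
  if (!all(c("city", "year") %in% names(df)))
    stopf("indicator panel needs `city` and `year` columns")
  ind <- setdiff(names(df), c("city", "year"))
  if (!length(ind)) stopf("indicator panel has no indicator columns")
  if (is.character(directions))
    directions <- ifelse(trimws(directions) == "-", -1, 1)
  directions <- as.numeric(directions)
  if (length(directions) != length(ind))
    stopf("direction vector has length %d but there are %d indicators",
          length(directions), length(ind))
  if (!all(directions %in% c(-1, 1)))
    stopf("directions must be +1 or -1")
  key <- paste(df$city, df$year)
  if (anyDuplicated(key))
    stopf("duplicate (city, year) rows: %s",
          paste(unique(key[duplicated(key)]), collapse = "; "))
  out <- data.frame(city = as.character(df$city), year = as.integer(df$year),
                    stringsAsFactors = FALSE)
  for (j in ind) out[[j]] <- as.numeric(df[[j]])
  names(directions) <- ind
  structure(out, directions = directions, indicators = ind,
            class = c("indicator_panel", "data.frame"))
}

#' Read or write an indicator panel (CSV)
#'
#' @param path File path; CSV with header `city,year,<indicator names>`.
#' @param directions Per-indicator direction vector, see
#'   [indicator_panel()].
#' @param x An `indicator_panel`.
#' @return `read_indicator_panel()` returns an `indicator_panel`;
#'   `write_indicator_panel()` returns `path` invisibly.
#' @export
read_indicator_panel <- function(path, directions) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  indicator_panel(df, directions)
}

#' @rdname read_indicator_panel
#' @export
write_indicator_panel <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' Fill gaps in a yearly series by linear interpolation
#'
#' Interior gaps are linearly interpolated along the year axis; leading
#' and trailing gaps are filled with the nearest observed value (no
#' extrapolation). Each filled value is reported via `message()`.
#'
#' @param values Numeric vector, possibly containing `NA`.
#' @param years Numeric vector of the same length giving the ordering
#'   axis; defaults to the element index.
#' @param label Optional label used in log messages and errors
#'   (e.g. `"cityA/indicator3"`).
#' @return Numeric vector with all `NA` filled. Filled values always lie
#'   within the observed range of the series, and the operation is
#'   idempotent.
#' @examples
#' interpolate_missing(c(1, NA, 3))         # 1 2 3
#' interpolate_missing(c(NA, 2, 4))         # 2 2 4
#' @export
interpolate_missing <- function(values, years = seq_along(values),
                                label = "series") {
  stopifnot(length(values) == length(years))
  obs <- !is.na(values)
  if (!any(obs)) stopf("all values missing in %s", label)
  if (all(obs)) return(values)
  o <- order(years)
  filled <- values
  filled[o] <- stats::approx(years[o][obs[o]], values[o][obs[o]],
                             xout = years[o], rule = 2)$y
  for (k in which(!obs))
    message(sprintf("interpolate_missing: filled %s year %s with %g",
                    label, years[k], filled[k]))
  filled
}

#' Fill all gaps in an indicator panel
#'
#' Applies [interpolate_missing()] to every (city, indicator) series in
#' year order.
#'
#' @param panel An `indicator_panel`.
#' @return The panel with no missing values.
#' @export
interpolate_panel <- function(panel) {
  stopifnot(inherits(panel, "indicator_panel"))
  for (ind in attr(panel, "indicators")) {
    for (ct in unique(panel$city)) {
      rows <- which(panel$city == ct)
      panel[[ind]][rows] <- interpolate_missing(
        panel[[ind]][rows], panel$year[rows],
        label = sprintf("%s/%s", ct, ind))
    }
  }
  panel
}
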