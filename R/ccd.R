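#' Min-max normalisation of an ESV series
#'
#' Rescales total ESV to [0, 1] so it can be coupled with the [0, 1]
#' tourism composite score. Pooled scaling (default) uses the extremes
#' over all city-years; per-city scaling uses each city's own extremes.
#' Negative ESV values are allowed.
#'
#' @param esv An [total_esv()] result, or a data frame with `city`,
#'   `year` and a numeric value column.
#' @param scope `"pooled"` or `"per_city"`.
#' @param value Name of the value column (default `"esv_total"`).
#' @return Data frame `city`, `year`, `g` with `g` in [0, 1].
#' @export
normalize_esv <- function(esv, scope = c("pooled", "per_city"),
                          value = "esv_total") {
  scope <- match.arg(scope)
  df <- as.data.frame(esv)
  if (!value %in% names(df)) stopf("no `%s` column in esv input", value)
  v <- df[[value]]
  if (length(v) < 2 || length(unique(v)) < 2)
    stopf("need at least 2 distinct ESV values to rescale")
  rescale <- function(x) {
    rng <- range(x)
    if (diff(rng) == 0) stopf("constant ESV series cannot be rescaled")
    (x - rng[1]) / diff(rng)
  }
  g <- if (scope == "pooled") rescale(v) else {
    out <- numeric(length(v))
    for (ct in unique(df$city)) {
      i <- df$city == ct
      out[i] <- rescale(v[i])
    }
    out
  }
  data.frame(city = df$city, year = df$year, g = g, stringsAsFactors = FALSE)
}

#' Coupling degree of two subsystem scores
#'
#' `C = 2 sqrt(f g) / (f + g)`: how balanced the two subsystem levels
#' are. C lies in [0, 1] and equals 1 exactly when `f = g > 0`; it is 0
#' when either subsystem is 0. The degenerate pair `f = g = 0` is
#' defined as C = 0 (a dead system pair is fully uncoordinated) with a
#' warning.
#'
#' @param f,g Subsystem scores, non-negative (vectorised).
#' @return Coupling degree C in [0, 1].
#' @examples
#' coupling_degree(0.2, 0.8)  # 0.8
#' @export
coupling_degree <- function(f, g) {
  if (any(f < 0 | g < 0)) stopf("subsystem scores must be non-negative")
  both0 <- f == 0 & g == 0
  if (any(both0)) warnf("f = g = 0: coupling degree set to 0 by convention")
  C <- ifelse(both0, 0, 2 * sqrt(f * g) / (f + g))
  as.numeric(C)
}

#' Comprehensive coordination index
#'
#' `T = alpha f + beta g`, the weighted joint level of the two
#' subsystems; with `alpha = beta = 0.5` both are treated as equally
#' important.
#'
#' @param f,g Subsystem scores (vectorised).
#' @param alpha,beta Non-negative weights summing to 1.
#' @return T.
#' @export
comprehensive_index <- function(f, g, alpha = 0.5, beta = 0.5) {
  if (alpha < 0 || beta < 0 || abs(alpha + beta - 1) > 1e-9)
    stopf("alpha and beta must be non-negative and sum to 1")
  alpha * f + beta * g
}

#' Coupling coordination degree
#'
#' `D = sqrt(C * T)` by default — the conventional form, under which D
#' spans [0, 1] and supports the full nine-rung classification ladder.
#' `form = "product"` gives the literal `D = C * T`.
#'
#' @param C Coupling degree in [0, 1].
#' @param T_ Comprehensive coordination index in [0, 1].
#' @param form `"sqrt"` (default) or `"product"`.
#' @return D in [0, 1].
#' @examples
#' coordination_degree(0.8, 0.5)  # sqrt(0.4)
#' @export
coordination_degree <- function(C, T_, form = c("sqrt", "product")) {
  form <- match.arg(form)
  if (any(C < -1e-12 | C > 1 + 1e-12) || any(T_ < -1e-12 | T_ > 1 + 1e-12))
    stopf("C and T must lie in [0, 1]")
  if (form == "sqrt") sqrt(pmax(C * T_, 0)) else C * T_
}

#' Classify a coupling coordination degree
#'
#' Maps D onto the three-stage, nine-type ladder. Intervals are
#' half-open deciles `[lower, upper)`, the top rung closed at 1, so
#' every D in [0, 1] receives exactly one label (a D of 0.20 is
#' "Moderate disorder", not "Severe").
#'
#' @param D Coordination degree in [0, 1] (vectorised).
#' @param ladder Ladder data frame, see [ccd_ladder()].
#' @return Data frame with columns `D`, `stage`, `type`.
#' @examples
#' classify_ccd(c(0.45, 0.75))
#' @export
classify_ccd <- function(D, ladder = ccd_ladder()) {
  if (any(D < 0 | D > 1)) stopf("D must lie in [0, 1]")
  ladder <- validate_ladder(ladder)
  idx <- findInterval(D, c(ladder$lower, 1), rightmost.closed = TRUE)
  data.frame(D = D, stage = ladder$stage[idx], type = ladder$type[idx],
             stringsAsFactors = FALSE)
}

#' Coupling-coordination series for aligned subsystem scores
#'
#' Joins the tourism score series `f` and the normalised ESV series `g`
#' on (city, year) keys, computes C, T and D per row, classifies every
#' D, and attaches a per-year summary (mean D and max-min gap across
#' cities, mirroring the usual study-period trend and disparity plots).
#'
#' @param f Data frame `city`, `year`, `score` (tourism composite).
#' @param g Data frame `city`, `year`, `g` (normalised ESV).
#' @param config An [analysis_config()] (weights alpha/beta, D form,
#'   ladder).
#' @return An object of class `"ccd_series"`: data frame `city`, `year`,
#'   `f`, `g`, `C`, `T`, `D`, `stage`, `type`, with attribute
#'   `year_summary` (`year`, `mean_D`, `gap_D`).
#' @export
ccd_pipeline <- function(f, g, config = analysis_config()) {
  fk <- paste(f$city, f$year)
  gk <- paste(g$city, g$year)
  if (!setequal(fk, gk) || length(fk) != length(gk)) {
    offenders <- c(setdiff(fk, gk), setdiff(gk, fk))
    stopf("city-year keys do not align; offending keys: %s",
          paste(unique(offenders), collapse = "; "))
  }
  g <- g[match(fk, gk), ]
  sc_f <- f$score %||% f$f
  sc_g <- g$g %||% g$score
  C <- coupling_degree(sc_f, sc_g)
  T_ <- comprehensive_index(sc_f, sc_g, config$alpha, config$beta)
  D <- coordination_degree(C, T_, form = config$ccd_form)
  cls <- classify_ccd(D, config$ladder)
  out <- data.frame(city = f$city, year = f$year, f = sc_f, g = sc_g,
                    C = C, T = T_, D = D,
                    stage = cls$stage, type = cls$type,
                    stringsAsFactors = FALSE)
  ys <- do.call(rbind, lapply(split(out, out$year), function(d)
    data.frame(year = d$year[1], mean_D = mean(d$D),
               gap_D = max(d$D) - min(d$D))))
  rownames(ys) <- NULL
  structure(out, year_summary = ys, class = c("ccd_series", "data.frame"))
}

#' @export
print.ccd_series <- function(x, ...) {
  cat(sprintf("Coupling-coordination series: %d city-years, D in [%.3f, %.3f]\n",
              nrow(x), min(x$D), max(x$D)))
  tab <- table(x$stage)
  cat("  stages:", paste(sprintf("%s = %d", names(tab), tab), collapse = ", "), "\n")
  print(utils::head(as.data.frame(x), ...))
  invisible(x)
}

#' @export
summary.ccd_series <- function(object, ...) {
  ys <- attr(object, "year_summary")
  cat("Per-year mean coordination degree and cross-city gap:\n")
  print(ys, row.names = FALSE)
  invisible(ys)
}

#' Plot a coupling-coordination series
#'
#' Draws each city's D trajectory over years plus the cross-city yearly
#' mean, with the stage boundaries (0.4, 0.6) as reference lines.
#'
#' @param x A `ccd_series`.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.ccd_series <- function(x, ...) {
  wide <- stats::reshape(as.data.frame(x)[, c("city", "year", "D")],
                         idvar = "year", timevar = "city", direction = "wide")
  wide <- wide[order(wide$year), ]
  graphics::matplot(wide$year, as.matrix(wide[, -1]), type = "l", lty = 1,
                    col = grDevices::grey.colors(ncol(wide) - 1, 0.2, 0.7),
                    xlab = "year", ylab = "coupling coordination degree D",
                    ylim = c(0, 1), ...)
  ys <- attr(x, "year_summary")
  graphics::lines(ys$year, ys$mean_D, lwd = 2)
  graphics::abline(h = c(0.4, 0.6), lty = 3)
  invisible(x)
}
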