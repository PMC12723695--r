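#' Panel regression of the coupling coordination degree on its drivers
#'
#' Fits `D_it = b0 + x_it' b + u_i + e_it` on a balanced city-year panel
#' by one of three estimators: pooled OLS, the within (fixed-effects)
#' estimator, or Swamy-Arora feasible-GLS random effects. The RE
#' estimator derives the idiosyncratic variance from the within
#' residuals and the effect variance from the between regression
#' (truncated at zero), then applies quasi-demeaning with
#' `theta = 1 - sqrt(sigma_eps^2 / (sigma_eps^2 + T sigma_u^2))`.
#'
#' @param formula Model formula, e.g. `D ~ ED + IS + GER + UE`.
#' @param data Data frame holding the response, regressors and index
#'   columns.
#' @param index Length-2 character vector naming the individual (city)
#'   and time (year) columns. Default `c("city", "year")`.
#' @param model `"random"` (default), `"fixed"` or `"pooled"`.
#' @return An object of class `"panel_fit"`; see [summary.panel_fit()].
#'   Components include `coefficients`, `se`, `vcov`, `residuals`,
#'   `fitted`, `rss`, `sigma2_eps`, `sigma2_u`, `theta`, `r.squared`
#'   (overall/within/between) and the panel dimensions `N`, `T`, `k`.
#' @examples
#' d <- gen_ccd_dgp(synthetic_spec(seed = 7))
#' fit <- ccd_panel(D ~ ED + IS + GER + UE, d)
#' coef(fit)
#' @export
ccd_panel <- function(formula, data, index = c("city", "year"),
                      model = c("random", "fixed", "pooled")) {
  model <- match.arg(model)
  if (!all(index %in% names(data)))
    stopf("index columns %s not found in data", paste(index, collapse = ", "))
  mf <- stats::model.frame(formula, data = data)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  X <- X[, colnames(X) != "(Intercept)", drop = FALSE]
  ids <- as.character(data[[index[1]]])
  times <- data[[index[2]]]
  fit <- switch(model,
    pooled = fit_pooled(y, X),
    fixed = fit_fixed(y, X, ids),
    random = fit_random(y, X, ids))
  fit$call <- match.call()
  fit$formula <- formula
  fit$terms <- attr(mf, "terms")
  fit$index <- index
  fit$times <- times
  fit
}

check_balanced <- function(ids) {
  tab <- table(ids)
  if (length(unique(tab)) != 1)
    stopf("unbalanced panel: cities observed %s times; balanced panels only",
          paste(sort(unique(as.integer(tab))), collapse = "/"))
  c(N = length(tab), T = unname(tab[1]))
}

ols_core <- function(y, X) {
  qr_ <- qr(X)
  if (qr_$rank < ncol(X))
    stopf("rank-deficient design: regressors are perfectly collinear")
  b <- qr.coef(qr_, y)
  fitted <- as.numeric(X %*% b)
  res <- y - fitted
  XtXinv <- chol2inv(qr.R(qr_))
  dimnames(XtXinv) <- list(colnames(X), colnames(X))
  list(coef = b, fitted = fitted, residuals = res, rss = sum(res^2),
       XtXinv = XtXinv)
}

new_panel_fit <- function(kind, core, y, X, ids, sigma2, extra = list()) {
  se <- sqrt(diag(core$XtXinv) * sigma2)
  vc <- core$XtXinv * sigma2
  out <- c(list(model = kind, coefficients = core$coef, se = se, vcov = vc,
                residuals = core$residuals, fitted = core$fitted,
                rss = core$rss, y = y, X = X, ids = ids,
                n = length(y), k = ncol(X)), extra)
  class(out) <- "panel_fit"
  out
}

#' Pooled OLS on a panel
#'
#' Ordinary least squares with an intercept, ignoring the panel
#' structure.
#'
#' @param y Numeric response vector.
#' @param X Numeric regressor matrix (no intercept column).
#' @param ids Optional individual identifiers, kept for the specification
#'   tests.
#' @return A `"panel_fit"` of kind `"pooled"`.
#' @export
fit_pooled <- function(y, X, ids = NULL) {
  X <- as.matrix(X)
  Xi <- cbind(`(Intercept)` = 1, X)
  core <- ols_core(y, Xi)
  df <- length(y) - ncol(Xi)
  sigma2 <- core$rss / df
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss > 0) 1 - core$rss / tss else NA_real_
  if (!is.null(ids)) check_balanced(ids)
  new_panel_fit("pooled", core, y, Xi, ids, sigma2,
                list(df.residual = df, sigma2_eps = sigma2, sigma2_u = 0,
                     theta = 0,
                     r.squared = list(overall = r2, within = NA_real_,
                                      between = NA_real_)))
}

group_means <- function(v, ids) {
  if (is.matrix(v)) apply(v, 2, function(col) tapply(col, ids, mean))
  else tapply(v, ids, mean)
}

demean <- function(v, ids) {
  gm <- group_means(v, ids)
  if (is.matrix(v)) v - gm[ids, , drop = FALSE] else v - gm[ids]
}

#' Within (fixed-effects) estimator
#'
#' Demeans response and regressors by city and runs OLS on the
#' transformed data, sweeping out the city effects. Slopes are invariant
#' to adding any per-city constant to the response.
#'
#' @inheritParams fit_pooled
#' @param ids Individual (city) identifiers, one per row.
#' @return A `"panel_fit"` of kind `"fixed"`, with per-city effects in
#'   `$city_effects`.
#' @export
fit_fixed <- function(y, X, ids) {
  X <- as.matrix(X)
  nt <- check_balanced(ids)
  Xw <- demean(X, ids)
  const <- apply(Xw, 2, function(col) all(abs(col) < 1e-10))
  if (any(const))
    stopf("regressor(s) time-invariant within city: %s",
          paste(colnames(X)[const], collapse = ", "))
  yw <- demean(y, ids)
  core <- ols_core(yw, Xw)
  df <- unname(nt["N"] * nt["T"] - nt["N"] - ncol(X))
  sigma2 <- core$rss / df
  alpha_i <- group_means(y, ids) -
    as.numeric(group_means(X, ids) %*% core$coef)
  fitted_full <- alpha_i[ids] + as.numeric(X %*% core$coef)
  tssw <- sum(yw^2)
  core$fitted <- unname(fitted_full)
  core$residuals <- y - core$fitted
  new_panel_fit("fixed", core, y, X, ids, sigma2,
                list(df.residual = unname(df), sigma2_eps = sigma2, sigma2_u = NA_real_,
                     theta = 1, city_effects = alpha_i,
                     N = unname(nt["N"]), T = unname(nt["T"]),
                     r.squared = list(
                       overall = stats::cor(fitted_full, y)^2,
                       within = if (tssw > 0) 1 - core$rss / tssw else NA_real_,
                       between = NA_real_)))
}

#' Swamy-Arora random-effects estimator
#'
#' Feasible GLS: `sigma_eps^2` comes from the within residuals,
#' `sigma_u^2` from the between regression (negative estimates truncated
#' to zero with a warning), and the coefficients from OLS on
#' quasi-demeaned data. When the effect variance is estimated as zero
#' the fit coincides with pooled OLS.
#'
#' @inheritParams fit_fixed
#' @return A `"panel_fit"` of kind `"random"`, with `sigma2_u`,
#'   `sigma2_eps` and the quasi-demeaning parameter `theta`. `r.squared`
#'   reports overall (squared correlation of fitted and observed
#'   response), within and between flavours.
#' @export
fit_random <- function(y, X, ids) {
  X <- as.matrix(X)
  nt <- check_balanced(ids)
  N <- unname(nt["N"]); T_ <- unname(nt["T"]); k <- ncol(X)
  # within step
  Xw <- demean(X, ids); yw <- demean(y, ids)
  within <- ols_core(yw, Xw)
  sigma2_eps <- within$rss / (N * T_ - N - k)
  # between step: city means, intercept included
  Xb <- cbind(1, group_means(X, ids))
  yb <- group_means(y, ids)
  if (N <= k + 1)
    stopf("too few cities (%d) for the between regression with %d regressors", N, k)
  between <- ols_core(yb, Xb)
  sigma2_1 <- between$rss / (N - k - 1)       # estimates sigma_eps^2/T + sigma_u^2
  sigma2_u <- sigma2_1 - sigma2_eps / T_
  if (sigma2_u < 0) {
    warnf("negative Swamy-Arora effect-variance estimate (%.3g) truncated to 0",
          sigma2_u)
    sigma2_u <- 0
  }
  theta <- 1 - sqrt(sigma2_eps / (sigma2_eps + T_ * sigma2_u))
  # quasi-demeaned GLS
  ybar <- group_means(y, ids); xbar <- group_means(X, ids)
  ystar <- y - theta * ybar[ids]
  Xstar <- cbind(`(Intercept)` = 1 - theta,
                 X - theta * xbar[ids, , drop = FALSE])
  core <- ols_core(ystar, Xstar)
  fitted_orig <- as.numeric(cbind(1, X) %*% core$coef)
  res_orig <- y - fitted_orig
  fw <- demean(fitted_orig, ids)
  r2 <- list(
    overall = stats::cor(fitted_orig, y)^2,
    within = stats::cor(fw, yw)^2,
    between = stats::cor(as.numeric(group_means(fitted_orig, ids)),
                         as.numeric(ybar))^2)
  core$fitted <- fitted_orig
  core$residuals <- res_orig
  new_panel_fit("random", core, y, X, ids, sigma2_eps,
                list(df.residual = length(y) - k - 1,
                     sigma2_eps = sigma2_eps, sigma2_u = sigma2_u,
                     theta = theta, N = N, T = T_, r.squared = r2,
                     gls_rss = sum((ystar - as.numeric(Xstar %*% core$coef))^2)))
}

#' Variance inflation factors
#'
#' For each driver, `VIF_k = 1 / (1 - R^2_k)` where `R^2_k` comes from
#' regressing that driver on all the others (with intercept); the
#' tolerance is its reciprocal. Perfect collinearity is reported as an
#' infinite VIF rather than an error.
#'
#' @param X Numeric matrix of drivers (>= 2 columns, no constant
#'   column).
#' @return Data frame with columns `variable`, `vif`, `tolerance`.
#' @examples
#' X <- cbind(a = rnorm(50), b = rnorm(50))
#' vif(X)
#' @export
vif <- function(X) {
  X <- as.matrix(X)
  if (ncol(X) < 2) stopf("need at least 2 regressors for VIF")
  if (any(apply(X, 2, stats::sd) == 0)) stopf("constant column in driver matrix")
  out <- data.frame(variable = colnames(X) %||% paste0("V", seq_len(ncol(X))),
                    vif = NA_real_, tolerance = NA_real_,
                    stringsAsFactors = FALSE)
  for (j in seq_len(ncol(X))) {
    yj <- X[, j]
    Zj <- cbind(1, X[, -j, drop = FALSE])
    fit <- stats::lsfit(Zj, yj, intercept = FALSE)
    rss <- sum(fit$residuals^2)
    tss <- sum((yj - mean(yj))^2)
    r2 <- 1 - rss / tss
    out$vif[j] <- if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
    out$tolerance[j] <- 1 / out$vif[j]
  }
  out
}

#' F test of fixed effects against the pooled model
#'
#' `F = [(RSS_pooled - RSS_FE)/(N - 1)] / [RSS_FE/(NT - N - k)]`,
#' testing whether the city intercepts jointly matter. On a 9-city,
#' 12-year panel with 4 drivers the degrees of freedom are (8, 95).
#'
#' @param pooled,fe `"panel_fit"` objects of kinds `"pooled"` and
#'   `"fixed"` on the same data.
#' @return List with `statistic`, `df1`, `df2`, `p.value`.
#' @export
f_test_fe_vs_pooled <- function(pooled, fe) {
  stopifnot(pooled$model == "pooled", fe$model == "fixed")
  if (pooled$n != fe$n || !isTRUE(all.equal(pooled$y, fe$y)))
    stopf("the two fits are not on the same data")
  N <- fe$N; T_ <- fe$T; k <- fe$k
  df1 <- N - 1
  df2 <- N * T_ - N - k
  stat <- ((pooled$rss - fe$rss) / df1) / (fe$rss / df2)
  list(statistic = stat, df1 = df1, df2 = df2,
       p.value = stats::pf(stat, df1, df2, lower.tail = FALSE))
}

#' Breusch-Pagan LM test for random effects
#'
#' Tests `sigma_u^2 = 0` from the pooled residuals:
#' `LM = [NT / (2(T-1))] * [(sum_i (sum_t e_it)^2 / sum e_it^2) - 1]^2`,
#' chi-squared with 1 degree of freedom under the null.
#'
#' @param pooled A pooled `"panel_fit"` carrying city ids.
#' @param ids Individual identifiers; defaults to those stored in the
#'   fit.
#' @return List with `statistic`, `df` (always 1), `p.value`.
#' @export
bp_lm_test <- function(pooled, ids = pooled$ids) {
  stopifnot(pooled$model == "pooled")
  if (is.null(ids)) stopf("city ids required for the LM test")
  nt <- check_balanced(ids)
  N <- unname(nt["N"]); T_ <- unname(nt["T"])
  if (T_ < 2) stopf("LM test needs at least 2 periods")
  e <- pooled$residuals
  num <- sum(tapply(e, ids, sum)^2)
  stat <- (N * T_ / (2 * (T_ - 1))) * (num / sum(e^2) - 1)^2
  list(statistic = stat, df = 1L,
       p.value = stats::pchisq(stat, 1, lower.tail = FALSE))
}

#' Hausman test of fixed against random effects
#'
#' Compares the slope vectors:
#' `chi2 = (b_FE - b_RE)' [V_FE - V_RE]^-1 (b_FE - b_RE)` with degrees
#' of freedom equal to the number of compared coefficients. A
#' significant value indicates correlation between the drivers and the
#' city effects, favouring fixed effects. A non-positive-definite
#' variance difference is inverted by pseudo-inverse with a warning.
#'
#' @param fe,re `"panel_fit"` objects of kinds `"fixed"` and
#'   `"random"`.
#' @return List with `statistic`, `df`, `p.value`.
#' @export
hausman_test <- function(fe, re) {
  stopifnot(fe$model == "fixed", re$model == "random")
  common <- intersect(names(fe$coefficients),
                      setdiff(names(re$coefficients), "(Intercept)"))
  if (!length(common)) stopf("no common time-varying regressors to compare")
  d <- fe$coefficients[common] - re$coefficients[common]
  V <- fe$vcov[common, common, drop = FALSE] -
       re$vcov[common, common, drop = FALSE]
  ev <- eigen(V, symmetric = TRUE)
  if (any(ev$values <= 1e-12)) {
    warnf("variance difference not positive definite; using pseudo-inverse")
    pos <- ev$values > 1e-12
    Vinv <- ev$vectors[, pos, drop = FALSE] %*%
      diag(1 / ev$values[pos], sum(pos)) %*% t(ev$vectors[, pos, drop = FALSE])
  } else {
    Vinv <- solve(V)
  }
  stat <- as.numeric(t(d) %*% Vinv %*% d)
  df <- length(common)
  list(statistic = stat, df = df,
       p.value = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Model recommendation from the specification-test battery
#'
#' Decision rule: a significant Hausman test selects fixed effects;
#' otherwise a significant LM test selects random effects; otherwise a
#' significant F test selects fixed effects; otherwise pooled OLS.
#'
#' @param f_test,lm_test,hausman Results of [f_test_fe_vs_pooled()],
#'   [bp_lm_test()] and [hausman_test()].
#' @param alpha Significance level (default 0.05).
#' @return An object of class `"panel_selection"`: list with the three
#'   tests and `recommendation` in `c("pooled", "fixed", "random")`.
#' @export
select_model <- function(f_test, lm_test, hausman, alpha = 0.05) {
  rec <- if (hausman$p.value < alpha) "fixed"
         else if (lm_test$p.value < alpha) "random"
         else if (f_test$p.value < alpha) "fixed"
         else "pooled"
  structure(list(f_test = f_test, lm_test = lm_test, hausman = hausman,
                 alpha = alpha, recommendation = rec),
            class = "panel_selection")
}

#' Run the full specification-test battery on a panel
#'
#' Fits the pooled, fixed- and random-effects models, runs the three
#' selection tests and returns the recommendation together with all
#' fits.
#'
#' @inheritParams ccd_panel
#' @param alpha Significance level for [select_model()].
#' @return A `"panel_selection"` with the additional element `fits`
#'   (named list of the three `"panel_fit"` objects).
#' @export
panel_battery <- function(formula, data, index = c("city", "year"),
                          alpha = 0.05) {
  pooled <- ccd_panel(formula, data, index, model = "pooled")
  pooled$ids <- as.character(data[[index[1]]])
  fe <- ccd_panel(formula, data, index, model = "fixed")
  re <- ccd_panel(formula, data, index, model = "random")
  sel <- select_model(f_test_fe_vs_pooled(pooled, fe),
                      bp_lm_test(pooled),
                      hausman_test(fe, re), alpha = alpha)
  sel$fits <- list(pooled = pooled, fixed = fe, random = re)
  sel
}

#' @export
print.panel_selection <- function(x, ...) {
  cat("Panel model selection\n")
  cat(sprintf("  F test (FE vs pooled):  F(%d, %d) = %.3f, p = %.4g\n",
              x$f_test$df1, x$f_test$df2, x$f_test$statistic, x$f_test$p.value))
  cat(sprintf("  BP-LM test (RE vs pooled): chi2(%d) = %.3f, p = %.4g\n",
              x$lm_test$df, x$lm_test$statistic, x$lm_test$p.value))
  cat(sprintf("  Hausman test (FE vs RE): chi2(%d) = %.3f, p = %.4g\n",
              x$hausman$df, x$hausman$statistic, x$hausman$p.value))
  cat(sprintf("  recommended model (alpha = %g): %s\n", x$alpha,
              x$recommendation))
  invisible(x)
}

# ---- panel_fit methods -----------------------------------------------------

#' @export
coef.panel_fit <- function(object, ...) object$coefficients

#' @export
vcov.panel_fit <- function(object, ...) object$vcov

#' @export
fitted.panel_fit <- function(object, ...) object$fitted

#' @export
residuals.panel_fit <- function(object, ...) object$residuals

#' @export
print.panel_fit <- function(x, digits = 4, ...) {
  kind <- c(pooled = "Pooled OLS", fixed = "Within (fixed effects)",
            random = "Swamy-Arora random effects")[x$model]
  cat(kind, "panel fit\n")
  if (!is.null(x$call)) cat("Call:", deparse(x$call), "\n")
  cat("Coefficients:\n")
  print(round(x$coefficients, digits))
  invisible(x)
}

#' Summary of a panel fit
#'
#' Coefficient table with standard errors, t statistics, p-values and
#' significance markers, plus variance components and R-squared
#' (overall; within/between where defined).
#'
#' @param object A `"panel_fit"`.
#' @param sig_levels Thresholds for `*` and `**` markers.
#' @param ... Unused.
#' @export
summary.panel_fit <- function(object, sig_levels = c(0.05, 0.01), ...) {
  tstat <- object$coefficients / object$se
  pval <- 2 * stats::pt(abs(tstat), object$df.residual, lower.tail = FALSE)
  stars <- ifelse(pval < sig_levels[2], "**",
                  ifelse(pval < sig_levels[1], "*", ""))
  tab <- data.frame(estimate = object$coefficients, std.error = object$se,
                    t.value = tstat, p.value = pval, sig = stars,
                    stringsAsFactors = FALSE)
  out <- list(model = object$model, coefficients = tab,
              sigma2_eps = object$sigma2_eps, sigma2_u = object$sigma2_u,
              theta = object$theta, r.squared = object$r.squared,
              N = object$N, T = object$T, n = object$n)
  class(out) <- "summary.panel_fit"
  out
}

#' @export
print.summary.panel_fit <- function(x, digits = 4, ...) {
  cat(sprintf("%s panel model (n = %d%s)\n", switch(x$model,
      pooled = "Pooled OLS", fixed = "Fixed-effects",
      random = "Random-effects"), x$n,
      if (!is.null(x$N)) sprintf(", N = %d cities x T = %d", x$N, x$T) else ""))
  tab <- x$coefficients
  tab[, 1:4] <- round(tab[, 1:4], digits)
  print(tab)
  if (x$model == "random")
    cat(sprintf("sigma2_u = %.5g, sigma2_eps = %.5g, theta = %.4f\n",
                x$sigma2_u, x$sigma2_eps, x$theta))
  r2 <- x$r.squared
  cat(sprintf("R-squared: overall %.4f", r2$overall))
  if (is.finite(r2$within %||% NA)) cat(sprintf(", within %.4f", r2$within))
  if (is.finite(r2$between %||% NA)) cat(sprintf(", between %.4f", r2$between))
  cat("\n")
  invisible(x)
}

#' @export
predict.panel_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  if (is.null(object$terms))
    stopf("predict() with newdata requires a fit from ccd_panel()")
  tt <- stats::delete.response(object$terms)
  mm <- stats::model.matrix(tt, stats::model.frame(tt, newdata))
  b <- object$coefficients
  if (object$model == "fixed") {
    mm <- mm[, colnames(mm) != "(Intercept)", drop = FALSE]
    eff <- object$city_effects[as.character(newdata[[object$index[1]]])]
    if (anyNA(eff)) stopf("newdata contains cities not present in the fit")
    as.numeric(mm %*% b[colnames(mm)]) + unname(eff)
  } else {
    as.numeric(mm[, names(b), drop = FALSE] %*% b)
  }
}

#' Simulate responses from a fitted panel model
#'
#' Draws new responses holding the design fixed: random-effects fits
#' redraw both the city effect and the idiosyncratic error from their
#' estimated variances; pooled and fixed-effects fits redraw the
#' idiosyncratic error only.
#'
#' @param object A `"panel_fit"`.
#' @param nsim Number of simulated response vectors.
#' @param seed Optional integer seed.
#' @param ... Unused.
#' @return Data frame with `nsim` columns, one simulated response per
#'   column.
#' @export
simulate.panel_fit <- function(object, nsim = 1, seed = NULL, ...) {
  draw <- function() {
    mu <- object$fitted
    if (object$model == "random") {
      cities <- unique(object$ids)
      u <- stats::rnorm(length(cities), 0, sqrt(object$sigma2_u))
      names(u) <- cities
      mu + u[object$ids] + stats::rnorm(object$n, 0, sqrt(object$sigma2_eps))
    } else {
      mu + stats::rnorm(object$n, 0, sqrt(object$sigma2_eps))
    }
  }
  run <- function() as.data.frame(replicate(nsim, draw()))
  out <- if (is.null(seed)) run() else with_seed(seed, run())
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}
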