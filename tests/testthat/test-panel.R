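test_that("pooled OLS matches the dense normal-equations oracle", {
  p <- fixture_panel()
  fit <- fit_pooled(p$y, p$X)
  expect_equal(unname(coef(fit)), ols_oracle(p$y, cbind(1, p$X)),
               tolerance = 1e-10)
  # constant response: zero slopes
  fit0 <- fit_pooled(rep(2, 9), p$X)
  expect_equal(unname(coef(fit0)), c(2, 0, 0), tolerance = 1e-10)
  expect_error(fit_pooled(p$y, cbind(p$X, p$X[, 1])), "collinear")
})

test_that("the within estimator equals demeaned OLS and sweeps city effects", {
  p <- fixture_panel()
  fit <- fit_fixed(p$y, p$X, p$ids)
  dm <- function(v) v - ave(v, p$ids)
  Xw <- apply(p$X, 2, dm)
  expect_equal(unname(coef(fit)), ols_oracle(dm(p$y), Xw), tolerance = 1e-10)
  # adding arbitrary per-city constants leaves slopes unchanged
  shift <- c(c1 = 10, c2 = -40, c3 = 3)[p$ids]
  fit2 <- fit_fixed(p$y + shift, p$X, p$ids)
  expect_equal(coef(fit2), coef(fit), tolerance = 1e-10)
  expect_equal(as.numeric(fit2$city_effects - fit$city_effects),
               c(10, -40, 3), tolerance = 1e-8)
  # with large distinct effects and zero noise the slopes are exact
  q <- fixture_panel(seed = 7, sigma_u = 5, sigma_eps = 0)
  expect_equal(unname(coef(fit_fixed(q$y, q$X, q$ids))), c(1, 2),
               tolerance = 1e-10)
  # time-invariant regressor is refused by name
  Xbad <- cbind(p$X, cityvar = rep(c(1, 2, 3), each = 3))
  expect_error(fit_fixed(p$y, Xbad, p$ids), "cityvar")
  expect_error(fit_fixed(p$y[-1], p$X[-1, ], p$ids[-1]), "unbalanced")
})

test_that("Swamy-Arora RE matches an independent dense GLS oracle", {
  p <- fixture_panel(seed = 103, N = 6, T_ = 5)
  fit <- fit_random(p$y, p$X, p$ids)
  expect_equal(unname(coef(fit)), gls_oracle(p$y, p$X, p$ids),
               tolerance = 1e-10)
  expect_gte(fit$sigma2_u, 0)
  expect_gte(fit$sigma2_eps, 0)
  expect_true(fit$theta > 0 && fit$theta < 1)
})

test_that("RE collapses to pooled at theta = 0 and approaches FE as T grows", {
  # between variation below within noise: sigma_u^2 truncates to 0
  p <- fixture_panel(seed = 11, N = 4, T_ = 6, sigma_u = 0, sigma_eps = 1)
  fit <- suppressWarnings(fit_random(p$y, p$X, p$ids))
  if (fit$sigma2_u == 0)
    expect_equal(coef(fit), coef(fit_pooled(p$y, p$X)), tolerance = 1e-10)
  # long panel: RE slopes converge to the within slopes
  q <- fixture_panel(seed = 13, N = 5, T_ = 200, sigma_u = 1, sigma_eps = 0.2)
  re <- fit_random(q$y, q$X, q$ids)
  fe <- fit_fixed(q$y, q$X, q$ids)
  expect_equal(coef(re)[names(coef(fe))], coef(fe), tolerance = 1e-2)
  # single-regressor case: RE slope lies between pooled and FE slopes
  set.seed(17)
  ids <- rep(paste0("c", 1:6), each = 8)
  x <- rnorm(48) + c(-2, -1, 0, 1, 2, 3)[rep(1:6, each = 8)]
  y <- 0.5 * x + c(-3, -2, 0, 1, 2, 4)[rep(1:6, each = 8)] + rnorm(48, 0, 0.3)
  b_p <- coef(fit_pooled(y, cbind(x = x)))["x"]
  b_f <- coef(fit_fixed(y, cbind(x = x), ids))["x"]
  b_r <- coef(fit_random(y, cbind(x = x), ids))["x"]
  expect_true((b_r - min(b_p, b_f)) > -1e-10 && (max(b_p, b_f) - b_r) > -1e-10)
})

test_that("RE slopes agree with a mixed-model cross-check on a large panel", {
  d <- gen_ccd_dgp(synthetic_spec(n_cities = 60, seed = 19))
  X <- as.matrix(d[, c("ED", "IS", "GER", "UE")])
  re <- fit_random(d$D, X, d$city)
  lf <- lme4::lmer(D ~ ED + IS + GER + UE + (1 | city), data = d, REML = TRUE)
  expect_equal(unname(coef(re)), unname(lme4::fixef(lf)), tolerance = 0.01)
})

test_that("variance inflation factors follow the 1/(1 - R^2) closed form", {
  # exactly orthogonal, centred columns
  X <- cbind(a = c(-1, -1, 1, 1), b = c(-1, 1, -1, 1))
  v <- vif(X)
  expect_equal(v$vif, c(1, 1))
  expect_equal(v$tolerance, c(1, 1))
  # construct exact sample correlation 0.8
  set.seed(23)
  n <- 60
  z1 <- scale(rnorm(n))[, 1]
  z2r <- scale(resid(lm(rnorm(n) ~ z1)))[, 1]
  x2 <- 0.8 * z1 + sqrt(1 - 0.64) * z2r
  v2 <- vif(cbind(a = z1, b = x2))
  expect_equal(v2$vif, rep(1 / (1 - 0.64), 2), tolerance = 1e-10)
  # perfect collinearity reported as infinite, not an error
  v3 <- vif(cbind(a = 1:5, b = 2 * (1:5)))
  expect_true(all(is.infinite(v3$vif)))
  expect_error(vif(cbind(a = 1:5)), "at least 2")
})

test_that("the F test compares FE and pooled RSS with (N-1, NT-N-k) df", {
  p <- fixture_panel(seed = 29, N = 3, T_ = 5)
  pooled <- fit_pooled(p$y, p$X, p$ids)
  fe <- fit_fixed(p$y, p$X, p$ids)
  res <- f_test_fe_vs_pooled(pooled, fe)
  # independent route via lm/anova
  a <- anova(lm(p$y ~ p$X), lm(p$y ~ p$X + factor(p$ids)))
  expect_equal(res$statistic, a$F[2], tolerance = 1e-10)
  expect_equal(res$p.value, a$`Pr(>F)`[2], tolerance = 1e-10)
  expect_equal(res$df1, 2)
  expect_equal(res$df2, 15 - 3 - 2)
  q <- fixture_panel(seed = 31)
  expect_error(f_test_fe_vs_pooled(fit_pooled(q$y, q$X, q$ids), fe),
               "same data")
})

test_that("the BP-LM statistic follows its closed form with 1 df", {
  # residuals whose per-city sums vanish: LM = (NT / (2(T-1))) * 1 = 2
  e <- c(1, -1, 2, -2, 0.5, -0.5, 3, -3, 1, -1, 4, -4)
  ids <- rep(c("a", "b", "c"), each = 4)
  fake <- structure(list(model = "pooled", residuals = e, ids = ids),
                    class = "panel_fit")
  res <- bp_lm_test(fake)
  expect_equal(res$statistic, 2.0)
  expect_equal(res$df, 1L)
  # maximal clustering: per-city constant residuals make LM grow with N
  lm_for <- function(N) {
    T_ <- 4
    e <- rep(rnorm(N), each = T_)
    fk <- structure(list(model = "pooled", residuals = e,
                         ids = rep(seq_len(N), each = T_)),
                    class = "panel_fit")
    bp_lm_test(fk)$statistic
  }
  set.seed(37)
  expect_equal(lm_for(5), 5 * 4 / (2 * 3) * (4 - 1)^2)  # sums^2/sum^2 = T
  expect_gt(lm_for(40), lm_for(5))
})

test_that("the Hausman statistic compares slope vectors with k df", {
  p <- fixture_panel(seed = 41, N = 8, T_ = 6)
  fe <- fit_fixed(p$y, p$X, p$ids)
  re <- fit_random(p$y, p$X, p$ids)
  h <- suppressWarnings(hausman_test(fe, re))
  expect_equal(h$df, 2L)
  expect_gte(h$statistic, 0)
  # identical coefficient vectors give chi2 = 0
  fe0 <- structure(list(model = "fixed", coefficients = c(x = 1),
                        vcov = matrix(2, dimnames = list("x", "x"))),
                   class = "panel_fit")
  re0 <- structure(list(model = "random",
                        coefficients = c(`(Intercept)` = 0, x = 1),
                        vcov = matrix(c(1, 0, 0, 1), 2, 2,
                                      dimnames = list(c("(Intercept)", "x"),
                                                      c("(Intercept)", "x")))),
                   class = "panel_fit")
  expect_equal(hausman_test(fe0, re0)$statistic, 0)
  # scalar case reduces to (b_FE - b_RE)^2 / (v_FE - v_RE)
  x1 <- p$X[, 1, drop = FALSE]
  fe1 <- fit_fixed(p$y, x1, p$ids)
  re1 <- fit_random(p$y, x1, p$ids)
  h1 <- suppressWarnings(hausman_test(fe1, re1))
  d <- coef(fe1)[["x1"]] - coef(re1)[["x1"]]
  vdiff <- vcov(fe1)["x1", "x1"] - vcov(re1)["x1", "x1"]
  if (vdiff > 0) expect_equal(h1$statistic, d^2 / vdiff, tolerance = 1e-10)
})

test_that("model selection follows the decision tree", {
  mk <- function(p) list(statistic = 1, df = 1, df1 = 1, df2 = 1, p.value = p)
  expect_equal(select_model(mk(0.000), mk(0.000), mk(0.613))$recommendation,
               "random")
  expect_equal(select_model(mk(0.000), mk(0.000), mk(0.001))$recommendation,
               "fixed")
  expect_equal(select_model(mk(0.9), mk(0.9), mk(0.9))$recommendation,
               "pooled")
  expect_equal(select_model(mk(0.01), mk(0.9), mk(0.9))$recommendation,
               "fixed")
})

test_that("the formula interface and its methods behave like a model object", {
  d <- gen_ccd_dgp(synthetic_spec(seed = 43))
  fit <- ccd_panel(D ~ ED + IS + GER + UE, d)
  expect_s3_class(fit, "panel_fit")
  expect_named(coef(fit), c("(Intercept)", "ED", "IS", "GER", "UE"))
  expect_equal(predict(fit)[1:5], fitted(fit)[1:5])
  expect_equal(length(residuals(fit)), nrow(d))
  expect_equal(fitted(fit) + residuals(fit), d$D, tolerance = 1e-12,
               ignore_attr = TRUE)
  # predict on new data reproduces the linear predictor
  nd <- d[3:5, ]
  expect_equal(predict(fit, nd),
               as.numeric(cbind(1, as.matrix(nd[, c("ED", "IS", "GER", "UE")])) %*%
                            coef(fit)))
  sims <- simulate(fit, nsim = 3, seed = 5)
  expect_identical(dim(sims), c(nrow(d), 3L))
  expect_identical(sims, simulate(fit, nsim = 3, seed = 5))
  s <- summary(fit)
  expect_s3_class(s, "summary.panel_fit")
  expect_true(all(c("estimate", "std.error", "p.value") %in%
                    colnames(s$coefficients)))
  expect_output(print(s), "R-squared")
  # fixed-effects predictions use the recovered city intercepts
  fe <- ccd_panel(D ~ ED + IS + GER + UE, d, model = "fixed")
  expect_equal(predict(fe, d), fitted(fe), tolerance = 1e-10)
})
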