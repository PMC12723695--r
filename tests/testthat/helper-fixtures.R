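# Shared fixtures: all built in code, no files on disk beyond tempdir.

# A minimal land-use data frame with every class zero except as given.
make_landuse <- function(city = "a", year = 2011L, ...) {
  areas <- stats::setNames(rep(0, 7), landuse_classes())
  over <- list(...)
  areas[names(over)] <- unlist(over)
  landuse_table(cbind(data.frame(city = city, year = year), as.list(areas)))
}

# Random valid land-use table over given cities/years (seeded by caller).
random_landuse <- function(cities = c("a", "b"), years = 2011:2013,
                           scale = 1000) {
  grid <- expand.grid(city = cities, year = years, stringsAsFactors = FALSE)
  m <- matrix(runif(nrow(grid) * 7, 0, scale), ncol = 7,
              dimnames = list(NULL, landuse_classes()))
  landuse_table(cbind(grid, as.data.frame(m)))
}

# Small balanced panel with city effects, true slopes 1..k and intercept 1.
fixture_panel <- function(seed = 101, N = 3, T_ = 3, k = 2,
                          sigma_u = 0.3, sigma_eps = 0.1) {
  set.seed(seed)
  ids <- rep(paste0("c", seq_len(N)), each = T_)
  X <- matrix(rnorm(N * T_ * k), ncol = k,
              dimnames = list(NULL, paste0("x", seq_len(k))))
  u <- rnorm(N, 0, sigma_u)
  y <- 1 + X %*% seq_len(k) + u[rep(seq_len(N), each = T_)] +
    rnorm(N * T_, 0, sigma_eps)
  list(y = as.numeric(y), X = X, ids = ids)
}

# Dense-matrix least-squares oracle: solve the normal equations directly.
ols_oracle <- function(y, X) as.numeric(solve(t(X) %*% X, t(X) %*% y))

# Independent GLS oracle for the random-effects fit: builds the full
# error covariance Omega = sigma_eps^2 I + sigma_u^2 (block of ones per
# city) from independently computed Swamy-Arora components and solves
# the GLS normal equations by dense inversion.
gls_oracle <- function(y, X, ids) {
  X <- as.matrix(X)
  n <- length(y)
  cities <- unique(ids)
  N <- length(cities); T_ <- n / N; k <- ncol(X)
  # within residual variance from lm with city dummies
  fe_lm <- stats::lm(y ~ X + factor(ids))
  s2e <- sum(stats::resid(fe_lm)^2) / (n - N - k)
  # between regression on city means
  yb <- tapply(y, ids, mean)
  Xb <- apply(X, 2, function(cl) tapply(cl, ids, mean))
  be_lm <- stats::lm(yb ~ Xb)
  s2u <- max(0, sum(stats::resid(be_lm)^2) / (N - k - 1) - s2e / T_)
  Omega <- diag(s2e, n)
  for (ct in cities) {
    i <- which(ids == ct)
    Omega[i, i] <- Omega[i, i] + s2u
  }
  Oi <- solve(Omega)
  Z <- cbind(`(Intercept)` = 1, X)
  as.numeric(solve(t(Z) %*% Oi %*% Z, t(Z) %*% Oi %*% y))
}
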