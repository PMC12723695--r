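#' Specification for the synthetic study panel
#'
#' Defines the shape and ground truth of the synthetic city-year data:
#' land-use compositions that shift toward construction land, tourism
#' indicators driven by a latent per-city quality, and a linear panel
#' data-generating process with city random effects. Defaults mirror the
#' study design: nine prefecture-level cities observed 2011-2022.
#'
#' @param n_cities Number of cities (>= 2).
#' @param years Integer vector of consecutive years (>= 2).
#' @param seed Integer master seed; each generator draws from its own
#'   sub-stream derived from it, so stages can be regenerated
#'   independently.
#' @param total_area_per_city Total city area in hectares; each land-use
#'   row sums exactly to this.
#' @param construction_drift Per-year share of (cropland + water) area
#'   transferred into construction land (>= 0). Emulates encroachment on
#'   cropland and water bodies during urban expansion.
#' @param landuse_noise_sd SD of compositional noise, applied on the
#'   log-ratio scale and renormalised so shares stay in the simplex.
#' @param base_shares Named initial mean shares for the seven classes
#'   (must sum to 1); year-0 city compositions are Dirichlet draws
#'   around them.
#' @param dirichlet_conc Dirichlet concentration for year-0 shares.
#' @param n_indicators Number of tourism indicators; the last one is the
#'   cost-type (air-pollution analogue) indicator.
#' @param indicator_loading Per-indicator loading on latent city quality
#'   (recycled to length `n_indicators`).
#' @param indicator_noise_sd SD of indicator observation noise.
#' @param indicator_trend Common per-year linear drift of indicators.
#' @param dgp_beta Coefficients `(b0, b_ED, b_IS, b_GER, b_UE)` of the
#'   driver model for the coupling coordination degree.
#' @param sigma_u SD of the city random effect u_i.
#' @param sigma_eps SD of the idiosyncratic error e_it.
#' @param driver_cor Common pairwise cross-correlation of the drivers.
#' @return An object of class `"synthetic_spec"`.
#' @export
synthetic_spec <- function(n_cities = 9L,
                           years = 2011:2022,
                           seed = 1L,
                           total_area_per_city = 600000,
                           construction_drift = 0.01,
                           landuse_noise_sd = 0.02,
                           base_shares = c(cropland = 0.25, forests = 0.35,
                                           grassland = 0.05, water_bodies = 0.12,
                                           wetlands = 0.03,
                                           construction_land = 0.17,
                                           unused_land = 0.03),
                           dirichlet_conc = 300,
                           n_indicators = 21L,
                           indicator_loading = 1,
                           indicator_noise_sd = 0.05,
                           indicator_trend = 0.01,
                           dgp_beta = c(0.4, 0.069, 0.128, 0.035, -0.279),
                           sigma_u = 0.1,
                           sigma_eps = 0.05,
                           driver_cor = 0.3) {
  if (n_cities < 2) stopf("need at least 2 cities")
  years <- as.integer(years)
  if (length(years) < 2) stopf("need at least 2 years")
  if (construction_drift < 0) stopf("construction_drift must be >= 0")
  if (sigma_u < 0 || sigma_eps < 0) stopf("variance components must be >= 0")
  if (!setequal(names(base_shares), landuse_classes()))
    stopf("base_shares must name the 7 canonical classes")
  base_shares <- base_shares[landuse_classes()]
  if (abs(sum(base_shares) - 1) > 1e-9) stopf("base_shares must sum to 1")
  if (length(dgp_beta) != 5) stopf("dgp_beta must have length 5 (b0..b4)")
  structure(list(
    n_cities = as.integer(n_cities), years = years, seed = as.integer(seed),
    total_area_per_city = total_area_per_city,
    construction_drift = construction_drift,
    landuse_noise_sd = landuse_noise_sd,
    base_shares = base_shares, dirichlet_conc = dirichlet_conc,
    n_indicators = as.integer(n_indicators),
    indicator_loading = rep_len(indicator_loading, n_indicators),
    indicator_noise_sd = indicator_noise_sd,
    indicator_trend = indicator_trend,
    dgp_beta = dgp_beta, sigma_u = sigma_u, sigma_eps = sigma_eps,
    driver_cor = driver_cor
  ), class = "synthetic_spec")
}

city_names <- function(n) sprintf("city_%02d", seq_len(n))

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  g / sum(g)
}

#' Generate a synthetic land-use panel
#'
#' Year-0 shares per city are Dirichlet draws around the spec's base
#' shares. Each subsequent year transfers `construction_drift` times the
#' current (cropland + water) share into construction land — urban
#' expansion at the expense of cropland and water — then perturbs the
#' composition with log-ratio noise and renormalises. Row areas sum
#' exactly to `total_area_per_city`.
#'
#' @param spec A [synthetic_spec()].
#' @return A [landuse_table()] covering all cities and years.
#' @export
gen_landuse_panel <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(substream_seed(spec$seed, 1L), {
    classes <- landuse_classes()
    rows <- list()
    for (ci in seq_len(spec$n_cities)) {
      share <- rdirichlet1(spec$base_shares * spec$dirichlet_conc)
      names(share) <- classes
      for (yi in seq_along(spec$years)) {
        if (yi > 1) {
          pool <- share[["cropland"]] + share[["water_bodies"]]
          take <- if (pool > 0) spec$construction_drift * pool else 0
          if (take > 0) {
            share[["cropland"]] <- share[["cropland"]] -
              take * share[["cropland"]] / pool
            share[["water_bodies"]] <- share[["water_bodies"]] -
              take * share[["water_bodies"]] / pool
            share[["construction_land"]] <- share[["construction_land"]] + take
          }
          if (any(share < 0))
            stopf("construction_drift drove a land-use share negative")
          if (spec$landuse_noise_sd > 0) {
            lr <- log(pmax(share, 1e-12)) +
              stats::rnorm(length(share), 0, spec$landuse_noise_sd)
            share <- exp(lr) / sum(exp(lr))
          }
        }
        rows[[length(rows) + 1L]] <- c(
          list(city = city_names(spec$n_cities)[ci], year = spec$years[yi]),
          as.list(share * spec$total_area_per_city))
      }
    }
    df <- do.call(rbind, lapply(rows, function(r)
      as.data.frame(r, stringsAsFactors = FALSE)))
    landuse_table(df)
  })
}

#' Generate a synthetic tourism indicator panel
#'
#' Each city gets a latent quality level q_i; benefit-type indicators
#' increase in q_i and the single cost-type indicator (an air-pollution
#' analogue, the last column) decreases in it, plus a common year trend
#' and observation noise. The latent qualities are stored in the
#' `"quality"` attribute as ground truth.
#'
#' @param spec A [synthetic_spec()].
#' @return An [indicator_panel()] with `n_indicators` columns (the last
#'   has direction -1) and attribute `quality` (named per-city vector).
#' @export
gen_indicator_panel <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(substream_seed(spec$seed, 2L), {
    n <- spec$n_cities; yrs <- spec$years; p <- spec$n_indicators
    q <- stats::runif(n, 0.2, 0.8)
    names(q) <- city_names(n)
    dirs <- c(rep(1, p - 1L), -1)
    base <- stats::runif(p, 1, 5)
    grid <- expand.grid(year = yrs, city = city_names(n),
                        stringsAsFactors = FALSE)[, c("city", "year")]
    X <- matrix(NA_real_, nrow(grid), p)
    for (j in seq_len(p)) {
      mu <- base[j] + dirs[j] * spec$indicator_loading[j] * q[grid$city] +
        spec$indicator_trend * (grid$year - yrs[1])
      X[, j] <- mu + stats::rnorm(nrow(grid), 0, spec$indicator_noise_sd)
    }
    colnames(X) <- c(sprintf("indicator_%02d", seq_len(p - 1L)), "pm25")
    pan <- indicator_panel(cbind(grid, as.data.frame(X)), dirs)
    attr(pan, "quality") <- q
    pan
  })
}

#' Generate a synthetic driver panel with known coefficients
#'
#' Draws four drivers — economic development (ED), industrial structure
#' (IS), government environmental regulation (GER) and urban expansion
#' (UE) — with a common pairwise cross-correlation, then builds the
#' response `D = b0 + X b + u_i + e_it` with city random effects
#' `u_i ~ N(0, sigma_u^2)` and noise `e_it ~ N(0, sigma_eps^2)`.
#'
#' @param spec A [synthetic_spec()].
#' @return A data frame with columns `city`, `year`, `ED`, `IS`, `GER`,
#'   `UE`, `D`, and attributes `beta` (true coefficients), `u` (city
#'   effects) and `sigma` (c(sigma_u, sigma_eps)).
#' @export
gen_ccd_dgp <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(substream_seed(spec$seed, 3L), {
    n <- spec$n_cities; yrs <- spec$years; Tn <- length(yrs)
    grid <- expand.grid(year = yrs, city = city_names(n),
                        stringsAsFactors = FALSE)[, c("city", "year")]
    k <- 4L
    Sigma <- matrix(spec$driver_cor, k, k); diag(Sigma) <- 1
    Z <- matrix(stats::rnorm(nrow(grid) * k), ncol = k) %*% chol(Sigma)
    colnames(Z) <- c("ED", "IS", "GER", "UE")
    u <- stats::rnorm(n, 0, spec$sigma_u)
    names(u) <- city_names(n)
    eps <- stats::rnorm(nrow(grid), 0, spec$sigma_eps)
    b <- spec$dgp_beta
    D <- b[1] + Z %*% b[-1] + u[grid$city] + eps
    out <- cbind(grid, as.data.frame(Z))
    out$D <- as.numeric(D)
    attr(out, "beta") <- b
    attr(out, "u") <- u
    attr(out, "sigma") <- c(sigma_u = spec$sigma_u, sigma_eps = spec$sigma_eps)
    out
  })
}
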