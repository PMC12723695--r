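#' Ecosystem service categories
#'
#' The eleven service rows of the unit-value table, grouped into the four
#' Millennium-Assessment groups (provisioning, regulating, supporting,
#' cultural).
#'
#' @return Data frame with columns `service` and `group`.
#' @export
esv_services <- function() {
  data.frame(
    service = c("food_products", "material_products",
                "water_supply", "gas_regulation", "climate_regulation",
                "environmental_purification", "hydrological_regulation",
                "soil_conservation",
                "nutrient_cycling", "biodiversity",
                "aesthetic_landscape"),
    group = c(rep("provision", 2), rep("regulating", 6),
              rep("supporting", 2), rep("cultural", 1)),
    stringsAsFactors = FALSE
  )
}

# Canonical unit values VC (yuan/ha/yr), services x classes. Construction
# land carries negative water-supply/gas/purification values (it consumes
# those services); cropland's water supply is negative (irrigation draw).
default_vc_matrix <- function() {
  m <- matrix(c(
    # cropland, forests, grassland, water_bodies, wetlands, construction_land, unused_land
    3184.46,   679.04,  889.77,   1873.21,   1194.17,       0.00,    0.00,  # food products
     210.73,  1545.40, 1311.25,    538.54,   1170.76,       0.00,    0.00,  # material products
   -6158.19,   796.11,  725.87,  19411.20,   6064.53,  -17584.80,    0.00,  # water supply
    2599.08,  5081.09, 4612.79,   1802.97,   4448.88,   -5666.48,   46.83,  # gas regulation
    1334.66, 15219.88, 12199.32,  5362.08,   8429.47,       0.00,    0.00,  # climate regulation
     398.05,  4519.13, 4027.41,  12995.44,   8429.47,   -5760.14,  234.15,  # environmental purification
    6368.93, 11098.80, 8944.60, 239397.00,  56735.03,       0.00,   70.24,  # hydrological regulation
      23.41,  6205.02, 5619.64,   2177.61,   5408.91,      46.83,   46.83,  # soil conservation
     444.88,   468.30,  421.47,    163.90,    421.47,       0.00,    0.00,  # nutrient cycling
     491.71,  5643.06, 5104.51,   5970.87,  18427.76,     796.11,   46.83,  # biodiversity
     210.73,  2482.01, 2247.85,   4425.47,  11075.39,      23.41,   23.41   # aesthetic landscape
  ), nrow = 11, byrow = TRUE)
  rownames(m) <- esv_services()$service
  colnames(m) <- c("cropland", "forests", "grassland", "water_bodies",
                   "wetlands", "construction_land", "unused_land")
  m[, landuse_classes()]
}

#' Base value of ecosystem services per unit cropland area
#'
#' The base equivalent factor is defined as one seventh of the average
#' economic value of grain production per hectare:
#' `Ea = (1/7) * P * Q / S`.
#'
#' @param P Average grain purchase price (yuan/kg).
#' @param Q Total grain yield (kg).
#' @param S Total sown area of grain crops (ha).
#' @return Ea in yuan/ha.
#' @examples
#' compute_base_value(3.5, 7000, 1000)  # 3.5
#' @export
compute_base_value <- function(P, Q, S) {
  if (any(c(P, Q, S) <= 0)) stopf("P, Q and S must all be positive")
  (1 / 7) * P * Q / S
}

#' Regional correction of the base value
#'
#' Scales the national base value by the correction coefficient lambda,
#' the ratio of regional to national grain yield per unit area.
#'
#' @param Ea Base value (yuan/ha).
#' @param lambda Correction coefficient (> 0).
#' @return Corrected base value (yuan/ha).
#' @export
apply_regional_correction <- function(Ea, lambda) {
  if (lambda <= 0) stopf("lambda must be > 0")
  Ea * lambda
}

#' ESV coefficient table
#'
#' Per-class, per-service unit values VC (yuan per hectare per year). The
#' default table is the canonical regionalised unit-value table embedded
#' in the package. Alternatively an equivalent-factor matrix `e` (11
#' services x 7 classes) may be supplied, in which case
#' `VC = e * Ea * lambda` with the base value taken from `config`.
#'
#' @param config An [analysis_config()]; supplies the base-value
#'   parameters when building from equivalent factors.
#' @param equivalent_factors Optional 11 x 7 matrix of equivalent factors
#'   (rows = services, columns = canonical classes).
#' @return An object of class `"esv_coefficients"`: list with the `vc`
#'   matrix (services x classes), the `base` parameters and the per-class
#'   `class_totals`.
#' @export
coefficient_table <- function(config = analysis_config(),
                              equivalent_factors = NULL) {
  if (is.null(equivalent_factors)) {
    vc <- default_vc_matrix()
  } else {
    e <- as.matrix(equivalent_factors)
    if (!identical(dim(e), c(11L, 7L)))
      stopf("equivalent-factor matrix must be 11 services x 7 classes, got %dx%d",
            nrow(e), ncol(e))
    vc <- e * apply_regional_correction(config$base_value, config$lambda)
    rownames(vc) <- esv_services()$service
    colnames(vc) <- if (!is.null(colnames(e))) {
      cn <- normalize_class_name(colnames(e))
      if (anyNA(cn)) stopf("unknown class name in equivalent-factor matrix")
      cn
    } else landuse_classes()
    vc <- vc[, landuse_classes()]
  }
  structure(list(
    vc = vc,
    base = list(P = config$grain_price, Ea = config$base_value,
                lambda = config$lambda),
    class_totals = colSums(vc)
  ), class = "esv_coefficients")
}

#' @export
print.esv_coefficients <- function(x, ...) {
  cat("ESV unit values (yuan/ha/yr), per-class totals:\n")
  print(round(x$class_totals, 2))
  invisible(x)
}

#' Total ecosystem service value of a land-use table
#'
#' Aggregates `ESV = sum_i VC_i * A_i` per (city, year): each class area
#' (ha) times its total unit value (yuan/ha/yr). Per-class and
#' per-service contributions are additive and sum to the total.
#'
#' @param areas A [landuse_table()].
#' @param table An [coefficient_table()] (default table if omitted).
#' @return An object of class `"esv_result"`: data frame with `city`,
#'   `year`, `esv_total` (yuan/yr) and one `esv_<class>` column per
#'   class; attribute `services` holds the per-service breakdown.
#' @export
total_esv <- function(areas, table = coefficient_table()) {
  stopifnot(inherits(areas, "landuse_table"), inherits(table, "esv_coefficients"))
  classes <- landuse_classes()
  if (!all(classes %in% colnames(table$vc)))
    stopf("coefficient table missing class(es): %s",
          paste(setdiff(classes, colnames(table$vc)), collapse = ", "))
  A <- as.matrix(as.data.frame(areas)[, classes])
  per_class <- sweep(A, 2, table$class_totals[classes], `*`)
  per_service <- A %*% t(table$vc[, classes])
  out <- data.frame(city = areas$city, year = areas$year,
                    esv_total = rowSums(per_class),
                    stringsAsFactors = FALSE)
  colnames(per_class) <- paste0("esv_", classes)
  out <- cbind(out, as.data.frame(per_class))
  svc <- as.data.frame(per_service)
  colnames(svc) <- paste0("esv_", esv_services()$service)
  svc <- cbind(data.frame(city = areas$city, year = areas$year,
                          stringsAsFactors = FALSE), svc)
  structure(out, services = svc, class = c("esv_result", "data.frame"))
}

#' Per-service ESV breakdown
#'
#' @param areas A [landuse_table()].
#' @param table An [coefficient_table()].
#' @return Data frame `city`, `year` plus one column per service
#'   (yuan/yr); the eleven service columns sum to `esv_total`.
#' @export
service_breakdown <- function(areas, table = coefficient_table()) {
  attr(total_esv(areas, table), "services")
}
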