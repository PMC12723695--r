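#' Canonical land-use classes
#'
#' The seven-class legend used throughout the package: cropland, forests,
#' grassland, water bodies, wetlands, construction land and unused land.
#'
#' @return Character vector of the seven canonical class names.
#' @export
landuse_classes <- function() {
  c("cropland", "forests", "grassland", "water_bodies", "wetlands",
    "construction_land", "unused_land")
}

# Header tokens are lower-cased and separators squashed to "_" before
# lookup, so "Water bodies", "water.bodies" and "water_bodies" all match.
landuse_aliases <- c(
  cropland = "cropland", farmland = "cropland", cultivated_land = "cropland",
  forests = "forests", forest = "forests", woodland = "forests",
  grassland = "grassland", grass = "grassland",
  water_bodies = "water_bodies", water = "water_bodies",
  water_body = "water_bodies", waters = "water_bodies",
  wetlands = "wetlands", wetland = "wetlands",
  construction_land = "construction_land", construction = "construction_land",
  built_up = "construction_land", built_up_land = "construction_land",
  unused_land = "unused_land", unused = "unused_land", bare_land = "unused_land"
)

normalize_class_name <- function(x) {
  key <- gsub("[ .\\-]+", "_", tolower(trimws(x)))
  out <- unname(landuse_aliases[key])
  names(out) <- x
  out
}

#' Construct a validated land-use area table
#'
#' A land-use area table holds, per (city, year), the area in hectares of
#' each of the seven canonical classes. Missing class columns are filled
#' with zero (with a warning); negative areas and duplicated (city, year)
#' keys are errors.
#'
#' @param df Data frame with columns `city`, `year` and one column per
#'   land-use class (canonical names or recognised aliases).
#' @return A data frame of class `"landuse_table"` with columns `city`,
#'   `year` and the seven canonical classes, in canonical order.
#' @seealso [read_landuse_table()], [landuse_classes()]
#' @export
landuse_table <- function(df) {
  if (!all(c("city", "year") %in% names(df)))
    stopf("land-use table needs `city` and `year` columns")
  cls_cols <- setdiff(names(df), c("city", "year"))
  canon <- normalize_class_name(cls_cols)
  if (anyNA(canon))
    stopf("unknown land-use column(s): %s",
          paste(cls_cols[is.na(canon)], collapse = ", "))
  if (anyDuplicated(canon))
    stopf("duplicate land-use class column(s): %s",
          paste(canon[duplicated(canon)], collapse = ", "))
  out <- data.frame(city = as.character(df$city), year = as.integer(df$year),
                    stringsAsFactors = FALSE)
  for (k in seq_along(cls_cols)) out[[canon[k]]] <- as.numeric(df[[cls_cols[k]]])
  missing <- setdiff(landuse_classes(), canon)
  if (length(missing)) {
    warnf("land-use class(es) absent, treated as 0 ha: %s",
          paste(missing, collapse = ", "))
    for (m in missing) out[[m]] <- 0
  }
  out <- out[, c("city", "year", landuse_classes())]
  key <- paste(out$city, out$year)
  if (anyDuplicated(key))
    stopf("duplicate (city, year) rows: %s",
          paste(unique(key[duplicated(key)]), collapse = "; "))
  for (cl in landuse_classes()) {
    bad <- which(is.finite(out[[cl]]) & out[[cl]] < 0)
    if (length(bad))
      stopf("negative area for %s in city %s, year %d",
            cl, out$city[bad[1]], out$year[bad[1]])
  }
  class(out) <- c("landuse_table", "data.frame")
  out
}

#' Read or write a land-use area table (CSV)
#'
#' Comma-separated UTF-8 text with a header row `city,year,<classes>`.
#' Class headers may use recognised aliases; they are normalised to the
#' canonical names on read. A round trip through `write_landuse_table()`
#' and `read_landuse_table()` reproduces values to full precision.
#'
#' @param path File path.
#' @param x A `landuse_table`.
#' @return `read_landuse_table()` returns a `landuse_table`;
#'   `write_landuse_table()` returns `path` invisibly.
#' @export
read_landuse_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  landuse_table(df)
}

#' @rdname read_landuse_table
#' @export
write_landuse_table <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}
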