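#' Validate (and normalize) a geo-referenced trait table
#'
#' The universal input of the package is one row per culture/language/site:
#' a unique `id`, decimal-degree `lon`/`lat`, an outcome, and any number of
#' covariate columns. `as_geo_table()` checks ranges and uniqueness,
#' normalizes longitudes to `[-180, 180)`, and drops rows with missing
#' coordinates or missing values in the named analysis columns (listwise
#' deletion, with a message stating how many rows were removed).
#'
#' @param data A data frame.
#' @param id,lon,lat Names of the identifier and coordinate columns.
#' @param required Extra column names that must be present and complete
#'   (e.g. the outcome and covariates of a planned model).
#' @return A tibble with columns `id`, `lon`, `lat` first, invariant-checked.
#' @examples
#' as_geo_table(data.frame(id = c("a", "b"), lon = c(10, 200), lat = c(0, 5)))
#' @export
as_geo_table <- function(data, id = "id", lon = "lon", lat = "lat",
                         required = character()) {
  stopifnot(is.data.frame(data))
  need <- c(id, lon, lat, required)
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("Missing required column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  out <- tibble::as_tibble(data)
  out <- dplyr::rename(out, id = !!id, lon = !!lon, lat = !!lat)
  out$id <- as.character(out$id)

  keep <- complete.cases(out[, c("id", "lon", "lat",
                                 setdiff(required, c(id, lon, lat)))])
  if (any(!keep)) {
    message(sum(!keep), " row(s) dropped (missing id, coordinates, or ",
            "required analysis columns).")
    out <- out[keep, , drop = FALSE]
  }
  if (anyDuplicated(out$id)) {
    abort(paste0("Duplicate ids: ",
                 paste(unique(out$id[duplicated(out$id)]), collapse = ", ")))
  }
  out$lon <- ((out$lon + 180) %% 360) - 180
  if (any(out$lat < -90 | out$lat > 90)) {
    abort("Column 'lat' outside [-90, 90].")
  }
  dplyr::relocate(out, "id", "lon", "lat")
}

#' Read a geo-referenced table from CSV or TSV
#'
#' @inheritParams as_geo_table
#' @param path File path; delimiter inferred from the extension
#'   (`.tsv`/`.txt` tab, otherwise comma).
#' @return A validated tibble (see [as_geo_table()]).
#' @export
read_geo_table <- function(path, id = "id", lon = "lon", lat = "lat",
                           required = character()) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  delim <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  as_geo_table(raw, id = id, lon = lon, lat = lat, required = required)
}

#' Great-circle (haversine) distance in kilometres
#'
#' Distance on a sphere of radius `radius` (default: IUGG mean Earth radius,
#' 6371.0088 km). Vectorized over coordinates.
#'
#' @param lon1,lat1,lon2,lat2 Decimal degrees; longitudes in `[-360, 360]`
#'   (normalized internally), latitudes in `[-90, 90]`.
#' @param radius Sphere radius in km.
#' @return Distance(s) in km.
#' @examples
#' great_circle_distance(0, 0, 90, 0) # quarter circumference
#' @export
great_circle_distance <- function(lon1, lat1, lon2, lat2,
                                  radius = EARTH_RADIUS_KM) {
  check_coords(lon1, lat1)
  check_coords(lon2, lat2)
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2),
                           r = radius)
}

check_coords <- function(lon, lat) {
  if (any(!is.finite(lon)) || any(abs(lon) > 360)) {
    abort("Coordinate 'lon' out of range [-360, 360] or non-finite.")
  }
  if (any(!is.finite(lat)) || any(abs(lat) > 90)) {
    abort("Coordinate 'lat' out of range [-90, 90] or non-finite.")
  }
  invisible(TRUE)
}

#' Pairwise great-circle distance matrix
#'
#' @param table A geo table (see [as_geo_table()]) with >= 2 rows.
#' @param radius Sphere radius in km.
#' @return An n x n symmetric matrix in km with zero diagonal, dimnames set
#'   to the table's ids.
#' @export
distance_matrix <- function(table, radius = EARTH_RADIUS_KM) {
  table <- as_geo_table(table)
  if (nrow(table) < 2) abort("Need at least 2 rows for a distance matrix.")
  check_coords(table$lon, table$lat)
  D <- geosphere::distm(cbind(table$lon, table$lat),
                        fun = function(p1, p2) {
                          geosphere::distHaversine(p1, p2, r = radius)
                        })
  D <- (D + t(D)) / 2
  diag(D) <- 0
  dimnames(D) <- list(table$id, table$id)
  D
}

check_distance_matrix <- function(D) {
  if (!is.matrix(D) || nrow(D) != ncol(D)) abort("Distance matrix not square.")
  if (max(abs(D - t(D))) > 1e-8) abort("Distance matrix not symmetric.")
  if (any(diag(D) != 0)) abort("Distance matrix diagonal must be zero.")
  if (any(D < 0)) abort("Distance matrix has negative entries.")
  invisible(TRUE)
}
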