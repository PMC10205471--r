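#' Regular latitude-longitude field
#'
#' A minimal container for a field on a regular lat-lon grid: cell-centre
#' coordinates (strictly ascending) and an `n_lat x n_lon` matrix of values.
#' Used for gridded emission inventories (Mg/yr per cell), atmospheric
#' deposition, plankton MeHg and soil Hg fields.
#'
#' @param lat Numeric vector of cell-centre latitudes, strictly ascending.
#' @param lon Numeric vector of cell-centre longitudes, strictly ascending.
#' @param values Numeric matrix, `length(lat)` rows by `length(lon)` columns.
#' @param units Character label for the field's units.
#' @return An object of class `gridded_field`.
#' @export
gridded_field <- function(lat, lon, values, units = "") {
  if (!is.numeric(lat) || !is.numeric(lon)) {
    stop("lat and lon must be numeric", call. = FALSE)
  }
  if (length(lat) > 1 && any(diff(lat) <= 0)) {
    stop("lat must be strictly ascending", call. = FALSE)
  }
  if (length(lon) > 1 && any(diff(lon) <= 0)) {
    stop("lon must be strictly ascending", call. = FALSE)
  }
  values <- as.matrix(values)
  if (nrow(values) != length(lat) || ncol(values) != length(lon)) {
    stop("values must be an n_lat x n_lon matrix matching the coordinates",
         call. = FALSE)
  }
  if (!all(is.finite(values))) {
    stop("field values must be finite", call. = FALSE)
  }
  structure(list(lat = as.numeric(lat), lon = as.numeric(lon),
                 values = values, units = units),
            class = "gridded_field")
}

#' @export
print.gridded_field <- function(x, ...) {
  cat(sprintf("<gridded_field> %d x %d cells [%s], total = %.6g\n",
              length(x$lat), length(x$lon), x$units, sum(x$values)))
  invisible(x)
}

#' Global sum of a gridded field
#' @param field A `gridded_field`.
#' @return Sum of all cell values.
#' @export
global_sum <- function(field) {
  stopifnot(inherits(field, "gridded_field"))
  sum(field$values)
}

# shared-grid check used by every operation combining two fields
same_grid <- function(a, b) {
  isTRUE(all.equal(a$lat, b$lat)) && isTRUE(all.equal(a$lon, b$lon))
}

assert_same_grid <- function(a, b, what = "fields") {
  if (!same_grid(a, b)) {
    stop(sprintf("%s are on different grids", what), call. = FALSE)
  }
  invisible(TRUE)
}

#' Country mask on a lat-lon grid
#'
#' Per-country cell weights in `[0, 1]`; fractional weights support border
#' cells shared between countries. At every cell the weights summed over
#' countries may not exceed 1 (the remainder is unclaimed, e.g. open ocean).
#'
#' @param weights Named list of `n_lat x n_lon` weight matrices, one per
#'   country.
#' @return An object of class `country_mask`.
#' @export
country_mask <- function(weights) {
  if (!is.list(weights) || is.null(names(weights)) ||
      any(!nzchar(names(weights)))) {
    stop("weights must be a named list of matrices", call. = FALSE)
  }
  dims <- unique(lapply(weights, dim))
  if (length(dims) != 1) {
    stop("all country weight matrices must share one shape", call. = FALSE)
  }
  for (w in weights) {
    if (any(w < 0) || any(w > 1)) {
      stop("mask weights must lie in [0, 1]", call. = FALSE)
    }
  }
  total <- Reduce(`+`, weights)
  if (any(total > 1 + 1e-9)) {
    stop("per-cell mask weights summed over countries exceed 1", call. = FALSE)
  }
  structure(list(weights = weights), class = "country_mask")
}

#' @export
print.country_mask <- function(x, ...) {
  cat(sprintf("<country_mask> %d countries on a %s grid\n",
              length(x$weights), paste(dim(x$weights[[1]]), collapse = " x ")))
  invisible(x)
}

#' Per-country sums of a gridded field under a mask
#' @param field A `gridded_field`.
#' @param mask A `country_mask` on the same grid.
#' @return Named numeric vector of mask-weighted country sums.
#' @export
country_grid_sums <- function(field, mask) {
  stopifnot(inherits(field, "gridded_field"), inherits(mask, "country_mask"))
  if (!all(dim(mask$weights[[1]]) == dim(field$values))) {
    stop("mask and field are on different grids", call. = FALSE)
  }
  vapply(mask$weights, function(w) sum(w * field$values), numeric(1))
}

#' Write a gridded field to long-format CSV
#'
#' Serializes as `lat,lon,value` rows so grids survive as plain text.
#'
#' @param field A `gridded_field`.
#' @param path Output file path.
#' @export
write_gridded_csv <- function(field, path) {
  stopifnot(inherits(field, "gridded_field"))
  df <- expand.grid(lat = field$lat, lon = field$lon, KEEP.OUT.ATTRS = FALSE)
  df$value <- as.vector(field$values)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a gridded field from long-format CSV
#' @param path File written by [write_gridded_csv()].
#' @param units Units label to attach.
#' @return A `gridded_field`.
#' @export
read_gridded_csv <- function(path, units = "") {
  df <- utils::read.csv(path)
  lat <- sort(unique(df$lat))
  lon <- sort(unique(df$lon))
  m <- matrix(NA_real_, length(lat), length(lon))
  m[cbind(match(df$lat, lat), match(df$lon, lon))] <- df$value
  gridded_field(lat, lon, m, units = units)
}
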