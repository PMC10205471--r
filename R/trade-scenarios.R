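#' Counterfactual "no trade" gridded emission inventory
#'
#' Rescales each country's emission cells from its production-based total to
#' its consumption-based total, keeping the country's spatial pattern and
#' the global total unchanged: under autarky every country must produce at
#' home, with its own technology, what it currently consumes. Cells outside
#' all country masks are left untouched; fractional border cells are scaled
#' by their mask weight so no mass is double-counted.
#'
#' Countries with zero production but positive consumption have no spatial
#' pattern to scale; their consumption-based total is spread uniformly over
#' their masked cells (mask-weighted), with a warning.
#'
#' @param with_trade `gridded_field` of actual emissions (Mg/yr per cell).
#' @param mask `country_mask` on the same grid.
#' @param pba Named per-country production-based totals (Mg/yr); must match
#'   the masked grid sums to 1e-4 relative.
#' @param cba Named per-country consumption-based totals (Mg/yr),
#'   nonnegative, with the same global total as `pba` (1e-6 relative).
#' @return A `scenario_pair`: list with `with_trade` and `no_trade` fields
#'   whose global sums agree.
#' @export
no_trade_inventory <- function(with_trade, mask, pba, cba) {
  stopifnot(inherits(with_trade, "gridded_field"), inherits(mask, "country_mask"))
  countries <- names(mask$weights)
  if (!all(countries %in% names(pba)) || !all(countries %in% names(cba))) {
    stop("pba and cba must be named for every masked country", call. = FALSE)
  }
  pba <- pba[countries]
  cba <- cba[countries]
  if (any(cba < 0)) stop("cba totals must be nonnegative", call. = FALSE)
  if (!all(dim(mask$weights[[1]]) == dim(with_trade$values))) {
    stop("mask and emission grid shapes differ", call. = FALSE)
  }
  total <- sum(pba)
  if (abs(sum(cba) - total) > 1e-6 * max(abs(total), 1e-12)) {
    stop("global pba and cba totals differ: totals must be conserved",
         call. = FALSE)
  }
  grid_sums <- country_grid_sums(with_trade, mask)
  rel <- abs(grid_sums - pba) / pmax(abs(pba), 1e-12)
  bad <- pba > 0 & rel > 1e-4
  if (any(bad)) {
    stop("pba totals inconsistent with masked grid sums for: ",
         paste(countries[bad], collapse = ", "), call. = FALSE)
  }

  values <- with_trade$values
  out <- values
  for (i in seq_along(countries)) {
    w <- mask$weights[[i]]
    if (pba[i] > 0) {
      scale <- cba[i] / pba[i]
      out <- out + w * values * (scale - 1)
    } else if (cba[i] > 0) {
      if (sum(w) == 0) {
        stop(sprintf("allocation error: %s consumes %.4g Mg/yr but has no masked cells",
                     countries[i], cba[i]), call. = FALSE)
      }
      warning(sprintf(paste0("%s has no production pattern; spreading its ",
                             "consumption-based total uniformly over its cells"),
                      countries[i]), call. = FALSE)
      out <- out + w / sum(w) * cba[i]
    }
  }
  no_trade <- gridded_field(with_trade$lat, with_trade$lon, out,
                            units = with_trade$units)
  pair <- structure(list(with_trade = with_trade, no_trade = no_trade),
                    class = "scenario_pair")
  gs_wt <- global_sum(with_trade)
  gs_nt <- global_sum(no_trade)
  if (abs(gs_nt - gs_wt) > 1e-6 * max(abs(gs_wt), 1e-12)) {
    stop("scenario invariant violated: global totals differ between scenarios",
         call. = FALSE)
  }
  pair
}

#' Scenario difference field
#'
#' Per-cell `with_trade - no_trade`; the trade-induced relocation of
#' emissions (or any derived field). Its global sum is ~0 for emission
#' inventories by the conservation invariant.
#'
#' @param pair A `scenario_pair`.
#' @return A `gridded_field` of differences.
#' @export
scenario_delta <- function(pair) {
  stopifnot(inherits(pair, "scenario_pair"))
  assert_same_grid(pair$with_trade, pair$no_trade, "scenario fields")
  gridded_field(pair$with_trade$lat, pair$with_trade$lon,
                pair$with_trade$values - pair$no_trade$values,
                units = pair$with_trade$units)
}
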