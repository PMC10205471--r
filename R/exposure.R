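#' Population-weighted deposition per country
#'
#' The proxy scaling freshwater-fish MeHg: mean atmospheric Hg deposition
#' over a country's cells, weighted by where its people live.
#'
#' @param D Deposition `gridded_field`.
#' @param mask `country_mask` on the same grid.
#' @param population Population `gridded_field` on the same grid.
#' @return Named per-country values.
#' @export
population_weighted_deposition <- function(D, mask, population) {
  stopifnot(inherits(D, "gridded_field"), inherits(mask, "country_mask"),
            inherits(population, "gridded_field"))
  assert_same_grid(D, population, "deposition and population")
  if (!all(dim(mask$weights[[1]]) == dim(D$values))) {
    stop("mask and field are on different grids", call. = FALSE)
  }
  vapply(mask$weights, function(w) {
    denom <- sum(population$values * w)
    if (denom <= 0) {
      stop("weighting error: zero population under a country mask", call. = FALSE)
    }
    sum(D$values * population$values * w) / denom
  }, numeric(1))
}

#' Fish-catch-weighted plankton MeHg per country
#'
#' The proxy scaling seafood MeHg: global ocean plankton MeHg weighted by
#' each country's spatial distribution of fish catch. Countries absent from
#' the catch table are reported `NA` (missing), never zero.
#'
#' @param P Plankton MeHg `gridded_field`.
#' @param fishcatch Named list of per-country catch-weight matrices, each
#'   summing to 1 over ocean cells.
#' @param countries Countries to report; defaults to `names(fishcatch)`.
#' @return Named per-country values (`NA` where no catch distribution).
#' @export
catch_weighted_plankton <- function(P, fishcatch, countries = names(fishcatch)) {
  stopifnot(inherits(P, "gridded_field"))
  out <- stats::setNames(rep(NA_real_, length(countries)), countries)
  for (cc in intersect(countries, names(fishcatch))) {
    w <- fishcatch[[cc]]
    if (!all(dim(w) == dim(P$values))) {
      stop("catch weights and field are on different grids", call. = FALSE)
    }
    sw <- sum(w)
    if (sw <= 0) {
      stop(sprintf("weighting error: catch weights for %s sum to zero", cc),
           call. = FALSE)
    }
    if (abs(sw - 1) > 1e-6) {
      stop(sprintf("catch weights for %s must sum to 1 (got %.6f)", cc, sw),
           call. = FALSE)
    }
    out[cc] <- sum(P$values * w)
  }
  out
}

#' Mask-weighted mean soil Hg per country
#'
#' The proxy scaling rice MeHg: the mean soil Hg concentration over each
#' country's cells.
#'
#' @param S Soil Hg `gridded_field`.
#' @param mask `country_mask` on the same grid.
#' @return Named per-country values.
#' @export
mean_soil <- function(S, mask) {
  stopifnot(inherits(S, "gridded_field"), inherits(mask, "country_mask"))
  if (!all(dim(mask$weights[[1]]) == dim(S$values))) {
    stop("mask and field are on different grids", call. = FALSE)
  }
  vapply(mask$weights, function(w) {
    tw <- sum(w)
    if (tw <= 0) stop("weighting error: empty country mask", call. = FALSE)
    sum(S$values * w) / tw
  }, numeric(1))
}

exposure_pathways <- c("seafood", "fwfish", "rice")

check_food_table <- function(table) {
  need <- c("country", paste0("I_", exposure_pathways),
            paste0("C_", exposure_pathways))
  miss <- setdiff(need, names(table))
  if (length(miss)) {
    stop("food table missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  num <- as.matrix(table[, setdiff(need, "country")])
  if (any(num < 0)) stop("intakes and concentrations must be nonnegative",
                         call. = FALSE)
  invisible(table)
}

#' Dietary MeHg exposure under the "with trade" scenario
#'
#' Per-country exposure is the intake-weighted sum over the three food
#' pathways: `E = I_seafood * C_seafood + I_fwfish * C_fwfish +
#' I_rice * C_rice`, in ug/day.
#'
#' @param table Data frame with columns `country`, `I_seafood`, `I_fwfish`,
#'   `I_rice` (g/day) and `C_seafood`, `C_fwfish`, `C_rice` (ug MeHg per g).
#' @return Data frame with per-pathway exposures `E_seafood`, `E_fwfish`,
#'   `E_rice` and the total `E_WT` (ug/day).
#' @export
exposure_with_trade <- function(table) {
  check_food_table(table)
  out <- data.frame(country = table$country, stringsAsFactors = FALSE)
  for (p in exposure_pathways) {
    out[[paste0("E_", p)]] <- table[[paste0("I_", p)]] * table[[paste0("C_", p)]]
  }
  out$E_WT <- out$E_seafood + out$E_fwfish + out$E_rice
  out
}

#' Dietary MeHg exposure under the "no trade" scenario
#'
#' Scales each with-trade pathway exposure by the ratio of its environmental
#' proxy between scenarios: plankton MeHg for seafood, population-weighted
#' deposition for freshwater fish, mean soil Hg for rice. Food consumption
#' patterns are held fixed. Pathways with zero with-trade exposure are
#' skipped (no 0/0); a zero or missing with-trade proxy alongside positive
#' intake is an error.
#'
#' @param table Food table as for [exposure_with_trade()].
#' @param env Data frame with columns `country`, `P_WT`, `P_NT`, `D_WT`,
#'   `D_NT`, `S_WT`, `S_NT` (with-trade and no-trade proxy values).
#' @return Data frame with per-pathway no-trade exposures `E_seafood`,
#'   `E_fwfish`, `E_rice` and the total `E_NT` (ug/day).
#' @export
exposure_no_trade <- function(table, env) {
  check_food_table(table)
  wt <- exposure_with_trade(table)
  env <- env[match(wt$country, env$country), , drop = FALSE]
  proxy_of <- c(seafood = "P", fwfish = "D", rice = "S")
  out <- data.frame(country = wt$country, stringsAsFactors = FALSE)
  for (p in exposure_pathways) {
    base <- wt[[paste0("E_", p)]]
    num <- env[[paste0(proxy_of[p], "_NT")]]
    den <- env[[paste0(proxy_of[p], "_WT")]]
    ratio <- rep(1, length(base))
    active <- base > 0
    bad <- active & (is.na(den) | den <= 0)
    if (any(bad)) {
      stop("scaling error: zero or missing with-trade ", proxy_of[p],
           " proxy with positive ", p, " exposure for: ",
           paste(wt$country[bad], collapse = ", "), call. = FALSE)
    }
    ratio[active] <- num[active] / den[active]
    out[[paste0("E_", p)]] <- base * ratio
  }
  out$E_NT <- out$E_seafood + out$E_fwfish + out$E_rice
  out
}

#' Pathway decomposition of the scenario exposure change
#'
#' Splits the per-country exposure change `E_WT - E_NT` into the exact
#' per-pathway contributions (they sum to the total by construction).
#'
#' @param wt Output of [exposure_with_trade()].
#' @param nt Output of [exposure_no_trade()].
#' @return Data frame with per-pathway deltas `d_seafood`, `d_fwfish`,
#'   `d_rice` and `d_total` (with-trade minus no-trade, ug/day).
#' @export
exposure_delta_decomposition <- function(wt, nt) {
  if (!identical(wt$country, nt$country)) {
    stop("scenario tables cover different countries", call. = FALSE)
  }
  out <- data.frame(country = wt$country, stringsAsFactors = FALSE)
  for (p in exposure_pathways) {
    out[[paste0("d_", p)]] <- wt[[paste0("E_", p)]] - nt[[paste0("E_", p)]]
  }
  out$d_total <- out$d_seafood + out$d_fwfish + out$d_rice
  out
}

#' Country environmental proxies under both scenarios
#'
#' Convenience wrapper evaluating all three proxies on with-trade and
#' no-trade environmental fields.
#'
#' @param env_wt,env_nt `environmental_fields` for the two scenarios.
#' @param mask `country_mask`.
#' @param population Population `gridded_field`.
#' @param fishcatch Named list of per-country catch weights.
#' @param countries Countries to report.
#' @return Data frame with columns `country`, `D_WT`, `D_NT`, `P_WT`,
#'   `P_NT`, `S_WT`, `S_NT`.
#' @export
country_environment <- function(env_wt, env_nt, mask, population, fishcatch,
                                countries = names(mask$weights)) {
  data.frame(
    country = countries,
    D_WT = population_weighted_deposition(env_wt$D, mask, population)[countries],
    D_NT = population_weighted_deposition(env_nt$D, mask, population)[countries],
    P_WT = catch_weighted_plankton(env_wt$P, fishcatch, countries),
    P_NT = catch_weighted_plankton(env_nt$P, fishcatch, countries),
    S_WT = mean_soil(env_wt$S, mask)[countries],
    S_NT = mean_soil(env_nt$S, mask)[countries],
    stringsAsFactors = FALSE
  )
}
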