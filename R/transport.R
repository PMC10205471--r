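#' Parameters of the linear source-receptor transport surrogate
#'
#' The surrogate replaces a coupled 3-D atmosphere-ocean-land simulation by
#' a single annual-mean linear operator. Each source cell deposits a
#' latitude-dependent fraction `alpha(lat)` locally — rising from
#' `local_fraction_min` at the equator to `local_fraction_peak` at
#' `peak_latitude` (constant poleward), reflecting faster oxidation of
#' atmospheric Hg in the mid-latitude band and the greater local impact of
#' oxidized Hg — plus exponentially decaying shares over `advection_cells`
#' downwind (eastward) cells totalling `advection_fraction`, plus a
#' well-mixed share `global_mixing` deposited uniformly. The remainder is
#' tracked explicitly as undeposited.
#'
#' @param local_fraction_peak Locally deposited fraction at `peak_latitude`.
#' @param local_fraction_min Locally deposited fraction at the equator.
#' @param peak_latitude Latitude (degrees, absolute) of maximum oxidation.
#' @param advection_cells Number of downwind cells receiving decaying shares.
#' @param advection_fraction Total share advected and deposited downwind.
#' @param global_mixing Share entering the well-mixed global pool.
#' @param plankton_gain Ocean plankton MeHg response, pM per unit deposition
#'   anomaly.
#' @param soil_gain Dimensionless soil damping, < 0.01: soil responds by
#'   `soil_gain` times the relative deposition anomaly (the soil pool is
#'   vast and slow, so trade-scale perturbations move it by well under 1%).
#' @param background_D,background_P,background_S Baseline deposition (per
#'   cell), plankton MeHg (pM) and soil Hg (ng/g); scalars or matrices.
#'   Backgrounds represent natural and legacy re-emitted Hg and are held
#'   identical across scenarios. `background_D` must be positive.
#' @return An object of class `transport_params`.
#' @export
transport_params <- function(local_fraction_peak = 0.6,
                             local_fraction_min = 0.2,
                             peak_latitude = 40,
                             advection_cells = 3L,
                             advection_fraction = 0.1,
                             global_mixing = 0.1,
                             plankton_gain = 0.1,
                             soil_gain = 0.005,
                             background_D = 1,
                             background_P = 1,
                             background_S = 50) {
  fr <- c(local_fraction_peak = local_fraction_peak,
          local_fraction_min = local_fraction_min,
          advection_fraction = advection_fraction,
          global_mixing = global_mixing)
  if (any(fr < 0) || any(fr > 1)) {
    stop("all fractions must lie in [0, 1]", call. = FALSE)
  }
  if (local_fraction_min > local_fraction_peak) {
    stop("local_fraction_min must not exceed local_fraction_peak", call. = FALSE)
  }
  if (local_fraction_peak + advection_fraction + global_mixing > 1 + 1e-12) {
    stop("parameter error: per-source deposited shares would exceed 1",
         call. = FALSE)
  }
  if (soil_gain < 0 || soil_gain >= 0.01) {
    stop("soil_gain must lie in [0, 0.01)", call. = FALSE)
  }
  if (any(background_D <= 0)) {
    stop("background_D must be positive (soil response is relative to it)",
         call. = FALSE)
  }
  if (advection_cells < 0) stop("advection_cells must be >= 0", call. = FALSE)
  structure(list(local_fraction_peak = local_fraction_peak,
                 local_fraction_min = local_fraction_min,
                 peak_latitude = peak_latitude,
                 advection_cells = as.integer(advection_cells),
                 advection_fraction = advection_fraction,
                 global_mixing = global_mixing,
                 plankton_gain = plankton_gain,
                 soil_gain = soil_gain,
                 background_D = background_D,
                 background_P = background_P,
                 background_S = background_S),
            class = "transport_params")
}

# locally deposited fraction as a function of latitude
alpha_lat <- function(lat, params) {
  frac <- pmin(abs(lat) / params$peak_latitude, 1)
  params$local_fraction_min +
    (params$local_fraction_peak - params$local_fraction_min) * frac
}

#' Build the source-receptor operator for a grid
#'
#' @param lat,lon Grid cell-centre coordinates (strictly ascending).
#' @param params A `transport_params`.
#' @param ocean Logical `n_lat x n_lon` matrix marking ocean cells (plankton
#'   responds only there). Defaults to all-ocean.
#' @return An object of class `transfer_operator`.
#' @export
build_operator <- function(lat, lon, params, ocean = NULL) {
  stopifnot(inherits(params, "transport_params"))
  n_lat <- length(lat)
  n_lon <- length(lon)
  if (is.null(ocean)) ocean <- matrix(TRUE, n_lat, n_lon)
  if (!all(dim(ocean) == c(n_lat, n_lon))) {
    stop("ocean mask shape must match the grid", call. = FALSE)
  }
  alpha <- alpha_lat(lat, params)
  k <- params$advection_cells
  adv_w <- if (k > 0 && params$advection_fraction > 0) {
    w <- 0.5^seq_len(k)
    params$advection_fraction * w / sum(w)
  } else {
    numeric(0)
  }
  expand_bg <- function(bg) {
    if (length(bg) == 1) matrix(bg, n_lat, n_lon) else as.matrix(bg)
  }
  structure(list(lat = lat, lon = lon, alpha = alpha, adv_w = adv_w,
                 global_mixing = params$global_mixing,
                 plankton_gain = params$plankton_gain,
                 soil_gain = params$soil_gain,
                 bg_D = expand_bg(params$background_D),
                 bg_P = expand_bg(params$background_P),
                 bg_S = expand_bg(params$background_S),
                 ocean = ocean, params = params),
            class = "transfer_operator")
}

#' Per-source deposited share of the operator
#'
#' `alpha(lat) + advection_fraction + global_mixing` for every cell; the
#' complement is the undeposited remainder tracked by [apply_operator()].
#'
#' @param op A `transfer_operator`.
#' @return `n_lat x n_lon` matrix of deposited shares.
#' @export
deposited_share <- function(op) {
  stopifnot(inherits(op, "transfer_operator"))
  matrix(op$alpha, length(op$lat), length(op$lon)) +
    sum(op$adv_w) + op$global_mixing
}

#' Apply the transport operator to an emission field
#'
#' Maps gridded emissions to the three environmental fields the exposure
#' proxies need: atmospheric deposition `D` (background + local + advected +
#' well-mixed shares), ocean plankton MeHg `P` (background plus
#' `plankton_gain` times the deposition anomaly, ocean cells only, zero on
#' land), and soil Hg `S` (background scaled by `1 + soil_gain *` relative
#' deposition anomaly). The map is linear in the emission field about the
#' backgrounds.
#'
#' @param op A `transfer_operator`.
#' @param emissions A `gridded_field` on the operator's grid (Mg/yr).
#' @return An object of class `environmental_fields`: list with
#'   `gridded_field`s `D`, `P`, `S` plus the mass ledger entries
#'   `deposited_total` and `undeposited_total`.
#' @export
apply_operator <- function(op, emissions) {
  stopifnot(inherits(op, "transfer_operator"), inherits(emissions, "gridded_field"))
  if (!isTRUE(all.equal(op$lat, emissions$lat)) ||
      !isTRUE(all.equal(op$lon, emissions$lon))) {
    stop("emission field is not on the operator's grid", call. = FALSE)
  }
  E <- emissions$values
  n_lat <- length(op$lat)
  n_lon <- length(op$lon)

  D_anom <- op$alpha * E                       # local deposition, row-wise alpha
  if (length(op$adv_w)) {
    for (j in seq_along(op$adv_w)) {           # eastward, wrapping in longitude
      shift <- ((seq_len(n_lon) - 1 - j) %% n_lon) + 1
      D_anom <- D_anom + op$adv_w[j] * E[, shift, drop = FALSE]
    }
  }
  if (op$global_mixing > 0) {
    D_anom <- D_anom + op$global_mixing * sum(E) / (n_lat * n_lon)
  }

  deposited <- sum(D_anom)
  undeposited <- sum(E) - deposited

  D <- op$bg_D + D_anom
  P <- (op$bg_P + op$plankton_gain * D_anom) * op$ocean
  S <- op$bg_S * (1 + op$soil_gain * D_anom / op$bg_D)

  structure(list(
    D = gridded_field(op$lat, op$lon, D, units = "Mg/yr"),
    P = gridded_field(op$lat, op$lon, P, units = "pM"),
    S = gridded_field(op$lat, op$lon, S, units = "ng/g"),
    deposited_total = deposited,
    undeposited_total = undeposited
  ), class = "environmental_fields")
}

#' Deposition response to a unit emission in one cell
#'
#' The operator column for source cell (`i`, `j`): the deposition anomaly
#' field produced by 1 Mg/yr emitted there.
#'
#' @param op A `transfer_operator`.
#' @param i,j Row (latitude) and column (longitude) indices of the source.
#' @return `n_lat x n_lon` matrix of deposition anomalies.
#' @export
operator_column <- function(op, i, j) {
  stopifnot(inherits(op, "transfer_operator"))
  E <- matrix(0, length(op$lat), length(op$lon))
  E[i, j] <- 1
  unit <- gridded_field(op$lat, op$lon, E)
  apply_operator(op, unit)$D$values - op$bg_D
}
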