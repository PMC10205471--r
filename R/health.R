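#' Dose-response and valuation parameters
#'
#' Coefficient chain for the two MeHg health endpoints. `beta` links daily
#' dietary MeHg intake to blood Hg, `lambda` blood Hg to hair Hg, `gamma`
#' hair Hg to IQ decrement (linear, no safe threshold), `phi` hair Hg to
#' fatal-heart-attack (FHA) risk (log-linear), and `omega` is the subjective
#' probability that the FHA association is causal. The dose-response
#' coefficients carry no defaults: they are study inputs the user must
#' supply (the shipped example configuration uses illustrative values).
#'
#' `bw_mode` controls how body weight enters the dose term: `"multiply"`
#' follows the literal published form (exposure x BW); `"divide"` is
#' provided because the conventional intake-to-blood chain is stated per kg
#' body weight. Choose deliberately — the two differ by BW^2.
#'
#' @param gamma IQ points per (ug/g hair).
#' @param lambda (ug/g hair) per (ug/L blood).
#' @param beta (ug/L blood) per daily-intake dose unit.
#' @param phi FHA log-linear coefficient per (ug/g hair).
#' @param omega Causality probability in `[0, 1]`.
#' @param bw Body weight, kg.
#' @param bw_mode `"multiply"` (default) or `"divide"`.
#' @param el Lifetime earnings loss per IQ point, USD (2008 value).
#' @param vsl Value of a statistical life, USD (2005 value).
#' @param deflators Named vector with elements `"2008"` and `"2005"`: factors
#'   converting those bases to 2020 USD.
#' @param vsl_elasticity Income elasticity for country-specific VSL scaling
#'   (0 = flat global VSL).
#' @param gdp_ref Reference GDP per capita for the elasticity scaling
#'   (required when `vsl_elasticity > 0`).
#' @return An object of class `health_params`.
#' @export
health_params <- function(gamma, lambda, beta, phi, omega, bw,
                          bw_mode = c("multiply", "divide"),
                          el = 18832, vsl = 6.3e6,
                          deflators = c("2008" = 1, "2005" = 1),
                          vsl_elasticity = 0, gdp_ref = NULL) {
  bw_mode <- match.arg(bw_mode)
  vals <- c(gamma = gamma, lambda = lambda, beta = beta, phi = phi,
            omega = omega, bw = bw, el = el, vsl = vsl)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    stop("all health coefficients must be finite and nonnegative", call. = FALSE)
  }
  if (omega > 1) stop("omega must lie in [0, 1]", call. = FALSE)
  if (!all(c("2008", "2005") %in% names(deflators))) {
    stop("configuration error: deflators must cover 2008 and 2005 bases",
         call. = FALSE)
  }
  if (vsl_elasticity > 0 && is.null(gdp_ref)) {
    stop("gdp_ref required when vsl_elasticity > 0", call. = FALSE)
  }
  structure(list(gamma = gamma, lambda = lambda, beta = beta, phi = phi,
                 omega = omega, bw = bw, bw_mode = bw_mode, el = el,
                 vsl = vsl, deflators = deflators,
                 vsl_elasticity = vsl_elasticity, gdp_ref = gdp_ref),
            class = "health_params")
}

# exposure combined with body weight per the configured convention
dose_term <- function(exposure, params) {
  if (params$bw_mode == "multiply") exposure * params$bw
  else exposure / params$bw
}

#' IQ decrement from MeHg exposure
#'
#' Linear dose-response without a safe threshold: `dIQ = gamma * lambda *
#' beta * dose`, the dose being exposure combined with body weight per
#' `bw_mode`.
#'
#' @param exposure Dietary MeHg exposure, ug/day (vectorized).
#' @param params A `health_params`.
#' @return IQ points lost per fetus.
#' @export
iq_decrement <- function(exposure, params) {
  stopifnot(inherits(params, "health_params"))
  if (any(exposure < 0, na.rm = TRUE)) {
    stop("exposure must be nonnegative", call. = FALSE)
  }
  params$gamma * params$lambda * params$beta * dose_term(exposure, params)
}

#' Fatal-heart-attack deaths from MeHg exposure
#'
#' Log-linear dose-response summed over genders:
#' `dCF = sum_g POP_g * Cf_g * omega * (1 - exp(-phi*lambda*beta*dose))`,
#' bounded above by `omega * sum_g POP_g * Cf_g`.
#'
#' @param exposure Dietary MeHg exposure, ug/day (vectorized over countries).
#' @param demo Data frame with columns `pop_male`, `pop_female`, `cf_male`,
#'   `cf_female` (population and baseline FHA incidence by gender). A
#'   missing gender split can be supplied as `pop_total` instead, which is
#'   divided 50/50 with a warning.
#' @param params A `health_params`.
#' @return Deaths per year (vector over countries).
#' @export
fha_deaths <- function(exposure, demo, params) {
  stopifnot(inherits(params, "health_params"))
  if (any(exposure < 0, na.rm = TRUE)) {
    stop("exposure must be nonnegative", call. = FALSE)
  }
  if (!all(c("pop_male", "pop_female") %in% names(demo)) &&
      "pop_total" %in% names(demo)) {
    warning("no gender split supplied; assuming 50/50", call. = FALSE)
    demo$pop_male <- demo$pop_total / 2
    demo$pop_female <- demo$pop_total / 2
  }
  need <- c("pop_male", "pop_female", "cf_male", "cf_female")
  miss <- setdiff(need, names(demo))
  if (length(miss)) {
    stop("demographics missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (any(as.matrix(demo[, need]) < 0, na.rm = TRUE)) {
    stop("demographics must be nonnegative", call. = FALSE)
  }
  risk <- 1 - exp(-params$phi * params$lambda * params$beta *
                    dose_term(exposure, params))
  params$omega * (demo$pop_male * demo$cf_male +
                    demo$pop_female * demo$cf_female) * risk
}

#' Small-dose linearization error of the FHA dose-response
#'
#' For exponent `x = phi*lambda*beta*dose`, compares `1 - exp(-x)` with its
#' linearization `x`. The relative gap is second order (about `x/2`), so it
#' stays below `x` — under 1% for exponents up to 0.01.
#'
#' @param params A `health_params`.
#' @param dose Exposure in ug/day (scalar or vector); the exponent
#'   `phi*lambda*beta*dose_term` must not exceed 0.01.
#' @return Relative difference `(x - (1 - exp(-x))) / (1 - exp(-x))`
#'   (0 at dose 0).
#' @export
small_dose_limit_check <- function(params, dose) {
  stopifnot(inherits(params, "health_params"))
  x <- params$phi * params$lambda * params$beta * dose_term(dose, params)
  if (any(x > 0.01 + 1e-15)) {
    stop("dose exponent exceeds the small-dose regime (0.01)", call. = FALSE)
  }
  loglin <- 1 - exp(-x)
  out <- numeric(length(x))
  pos <- x > 0
  out[pos] <- (x[pos] - loglin[pos]) / loglin[pos]
  out
}

#' Monetized loss from IQ and FHA impacts
#'
#' `H = EL * dIQ_total + VSL * dCF`, with EL deflated from its 2008 base and
#' VSL from its 2005 base to 2020 USD. With `vsl_elasticity > 0` the VSL is
#' scaled per country by `(gdp_pc / gdp_ref)^elasticity`; at elasticity 0
#' the flat global VSL is used.
#'
#' @param d_iq_total Total IQ points lost (per country or global).
#' @param d_cf FHA deaths per year.
#' @param params A `health_params`.
#' @param gdp_pc Optional per-country GDP per capita for VSL scaling.
#' @return List with `loss_iq`, `loss_fha`, `loss_total` (2020 USD).
#' @export
economic_loss <- function(d_iq_total, d_cf, params, gdp_pc = NULL) {
  stopifnot(inherits(params, "health_params"))
  el2020 <- params$el * params$deflators[["2008"]]
  vsl2020 <- params$vsl * params$deflators[["2005"]]
  if (params$vsl_elasticity > 0) {
    if (is.null(gdp_pc)) {
      stop("gdp_pc required for VSL elasticity scaling", call. = FALSE)
    }
    vsl2020 <- vsl2020 * (gdp_pc / params$gdp_ref)^params$vsl_elasticity
  }
  loss_iq <- el2020 * d_iq_total
  loss_fha <- vsl2020 * d_cf
  list(loss_iq = loss_iq, loss_fha = loss_fha,
       loss_total = loss_iq + loss_fha)
}

#' Scenario health and economic impacts per country
#'
#' Evaluates the endpoint chain (IQ decrement per fetus, total IQ points
#' over births, FHA deaths, monetized losses) under each scenario's absolute
#' exposure and differences them (net = with-trade minus no-trade),
#' mirroring a per-scenario impact table. Countries missing demographics are
#' flagged and excluded from global sums with a reported count, never
#' silently zeroed.
#'
#' @param exposure Data frame with columns `country`, `E_WT`, `E_NT`
#'   (ug/day).
#' @param demo Demographics data frame with columns `country`, `births`,
#'   `pop_male`, `pop_female`, `cf_male`, `cf_female`, `gdp_pc`.
#' @param params A `health_params`.
#' @return An object of class `impact_table`: per-country data frame with
#'   `*_wt`, `*_nt` and `*_net` columns for the five endpoint quantities,
#'   a `missing` flag, and a `global` attribute of global aggregates.
#' @export
scenario_impacts <- function(exposure, demo, params) {
  stopifnot(inherits(params, "health_params"))
  if (!all(c("country", "E_WT", "E_NT") %in% names(exposure))) {
    stop("exposure must carry country, E_WT and E_NT", call. = FALSE)
  }
  m <- match(exposure$country, demo$country)
  missing_demo <- is.na(m)
  if (any(missing_demo)) {
    message(sum(missing_demo),
            " countr(ies) lack demographics and are excluded from global sums")
  }
  demo_m <- demo[ifelse(missing_demo, NA, m), , drop = FALSE]

  one_scenario <- function(E) {
    iq_pf <- iq_decrement(E, params)
    iq_total <- iq_pf * demo_m$births
    deaths <- rep(NA_real_, length(E))
    ok <- !missing_demo
    deaths[ok] <- fha_deaths(E[ok], demo_m[ok, , drop = FALSE], params)
    loss <- economic_loss(iq_total, deaths, params, gdp_pc = demo_m$gdp_pc)
    data.frame(iq_pf = iq_pf, iq_total = iq_total, deaths = deaths,
               loss_iq = loss$loss_iq, loss_fha = loss$loss_fha,
               loss_total = loss$loss_total)
  }
  wt <- one_scenario(exposure$E_WT)
  nt <- one_scenario(exposure$E_NT)
  wt[missing_demo, ] <- NA
  nt[missing_demo, ] <- NA

  out <- data.frame(country = exposure$country, missing = missing_demo,
                    stringsAsFactors = FALSE)
  for (col in names(wt)) {
    out[[paste0(col, "_wt")]] <- wt[[col]]
    out[[paste0(col, "_nt")]] <- nt[[col]]
    out[[paste0(col, "_net")]] <- wt[[col]] - nt[[col]]
  }

  ok <- !missing_demo
  glob <- list(n_missing = sum(missing_demo))
  for (sc in c("wt", "nt", "net")) {
    pick <- function(col) out[[paste0(col, "_", sc)]][ok]
    births <- demo_m$births[ok]
    glob[[paste0("iq_pf_", sc)]] <- sum(pick("iq_pf") * births) / sum(births)
    for (col in c("iq_total", "deaths", "loss_iq", "loss_fha", "loss_total")) {
      glob[[paste0(col, "_", sc)]] <- sum(pick(col))
    }
  }
  attr(out, "global") <- glob
  class(out) <- c("impact_table", class(out))
  out
}

#' Global scenario summary (with-trade / no-trade / net)
#'
#' Six endpoint rows by three scenario columns: per-fetus IQ decrement
#' (births-weighted), total IQ decrement, FHA deaths, IQ loss, VSL loss and
#' total loss, with net = with-trade minus no-trade exactly.
#'
#' @param impacts An `impact_table` from [scenario_impacts()].
#' @return Data frame with columns `quantity`, `with_trade`, `no_trade`,
#'   `net`.
#' @export
summarize_table1 <- function(impacts) {
  glob <- attr(impacts, "global")
  if (is.null(glob)) stop("impacts must come from scenario_impacts()", call. = FALSE)
  rows <- c(iq_pf = "Per-fetus IQ decrement (points)",
            iq_total = "IQ decrement (points)",
            deaths = "FHA deaths (deaths/yr)",
            loss_iq = "Economic loss from IQ (USD 2020)",
            loss_fha = "VSL loss from FHA (USD 2020)",
            loss_total = "Total loss (USD 2020)")
  data.frame(
    quantity = unname(rows),
    with_trade = vapply(names(rows), function(q) glob[[paste0(q, "_wt")]], numeric(1)),
    no_trade = vapply(names(rows), function(q) glob[[paste0(q, "_nt")]], numeric(1)),
    net = vapply(names(rows), function(q) glob[[paste0(q, "_net")]], numeric(1)),
    stringsAsFactors = FALSE
  )
}
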