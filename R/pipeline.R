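#' Run the full production-to-health assessment chain
#'
#' Orchestrates, in order: synthetic world generation, embodied-emission
#' accounting, the "no trade" counterfactual inventory, transport to
#' environmental fields under both scenarios, proxy-scaled dietary exposure,
#' health and economic valuation, and (optionally) Monte Carlo uncertainty.
#' The scenario step is fed production- and consumption-based totals taken
#' from the embodied-flow matrix itself (row and column sums), so the chain
#' is exactly self-consistent: an autarky world yields bitwise-identical
#' scenarios and exactly zero net impacts.
#'
#' @param world Either a `world_config` (a world is generated) or a
#'   ready-made `synthetic_world`.
#' @param transport A `transport_params`.
#' @param health A `health_params`.
#' @param uncertainty Optional `uncertainty_spec`; when supplied, global net
#'   quantities get Monte Carlo intervals.
#' @param out_dir Optional output directory; when given, all stage outputs
#'   are written as CSV plus a JSON summary.
#' @return A run report list: `world`, `flows`, `trade_share`,
#'   `net_transfers`, `pair` (scenario inventories), `env_wt`, `env_nt`,
#'   `exposure`, `impacts`, `table1`, `mc` (or NULL), `summary`, `paths`.
#' @export
run_pipeline <- function(world, transport = transport_params(),
                         health, uncertainty = NULL, out_dir = NULL) {
  if (inherits(world, "world_config")) world <- generate_world(world)
  stopifnot(inherits(world, "synthetic_world"),
            inherits(transport, "transport_params"),
            inherits(health, "health_params"))

  # 1. embodied-emission accounting
  flows <- embodied_flow_matrix(world$emissions, world$economy)
  trade_share <- tryCatch(embodied_trade_share(flows), error = function(e) NA_real_)
  nets <- net_transfers(flows)
  pba <- rowSums(flows)
  cba <- colSums(flows)

  # 2. counterfactual inventory
  pair <- no_trade_inventory(world$grid_inventory, world$masks, pba, cba)

  # 3. transport to environmental fields
  op <- build_operator(world$grid_inventory$lat, world$grid_inventory$lon,
                       transport, ocean = world$ocean)
  env_wt <- apply_operator(op, pair$with_trade)
  env_nt <- apply_operator(op, pair$no_trade)

  # 4. exposure under both scenarios
  food <- merge(world$diets, world$concentrations, by = "country", sort = FALSE)
  env_tab <- country_environment(env_wt, env_nt, world$masks,
                                 world$population_grid, world$fishcatch,
                                 countries = world$regions$country)
  ewt <- exposure_with_trade(food)
  ent <- exposure_no_trade(food, env_tab)
  exposure <- data.frame(country = ewt$country, E_WT = ewt$E_WT,
                         E_NT = ent$E_NT, stringsAsFactors = FALSE)
  decomp <- exposure_delta_decomposition(ewt, ent)

  # 5. health endpoints and valuation
  impacts <- scenario_impacts(exposure, world$demographics, health)
  table1 <- summarize_table1(impacts)

  # 6. optional Monte Carlo
  mc <- NULL
  if (!is.null(uncertainty)) {
    evaluator <- impact_evaluator(food, env_tab, world$demographics, health)
    mc <- run_monte_carlo(evaluator, uncertainty)
  }

  glob <- attr(impacts, "global")
  summary <- list(
    embodied_trade_share = trade_share,
    global_emissions_Mg = sum(world$emissions$pba),
    global_net_deposition_Mg = env_wt$deposited_total - env_nt$deposited_total,
    global_net_exposure_ug_day = sum(exposure$E_WT - exposure$E_NT),
    global_net_iq_points = glob$iq_total_net,
    global_net_fha_deaths = glob$deaths_net,
    global_net_total_loss_usd = glob$loss_total_net,
    n_missing_countries = glob$n_missing
  )

  paths <- NULL
  if (!is.null(out_dir)) {
    paths <- write_run_outputs(out_dir, flows, nets, pair, env_wt, env_nt,
                               exposure, decomp, impacts, table1, mc, summary)
  }

  list(world = world, flows = flows, trade_share = trade_share,
       net_transfers = nets, pair = pair, env_wt = env_wt, env_nt = env_nt,
       exposure = exposure, decomposition = decomp, impacts = impacts,
       table1 = table1, mc = mc, summary = summary, paths = paths)
}

#' Build a factor-perturbed global impact evaluator
#'
#' Returns a deterministic function of the four Monte Carlo component
#' factors. Food intake and concentration factors scale the exposure inputs
#' (systematically, across all countries), the dose-response factor scales
#' the IQ and FHA dose-response coefficients, and the valuation factor
#' scales EL and VSL. Output: global with-trade, no-trade and net totals.
#'
#' @param food Merged intake/concentration table.
#' @param env_tab Country environmental proxy table (both scenarios).
#' @param demo Demographics table.
#' @param params A `health_params`.
#' @return Function `factors -> named numeric vector`.
#' @export
impact_evaluator <- function(food, env_tab, demo, params) {
  force(food); force(env_tab); force(demo); force(params)
  function(factors) {
    f <- food
    for (p in exposure_pathways) {
      f[[paste0("I_", p)]] <- f[[paste0("I_", p)]] * factors$food_intake
      f[[paste0("C_", p)]] <- f[[paste0("C_", p)]] * factors$food_concentration
    }
    pp <- params
    pp$gamma <- pp$gamma * factors$dose_response
    pp$phi <- pp$phi * factors$dose_response
    pp$el <- pp$el * factors$valuation
    pp$vsl <- pp$vsl * factors$valuation
    ewt <- exposure_with_trade(f)
    ent <- exposure_no_trade(f, env_tab)
    exposure <- data.frame(country = ewt$country, E_WT = ewt$E_WT,
                           E_NT = ent$E_NT, stringsAsFactors = FALSE)
    imp <- suppressMessages(scenario_impacts(exposure, demo, pp))
    g <- attr(imp, "global")
    c(iq_total_net = g$iq_total_net,
      fha_deaths_net = g$deaths_net,
      loss_total_wt = g$loss_total_wt,
      loss_total_nt = g$loss_total_nt,
      loss_total_net = g$loss_total_net)
  }
}

write_run_outputs <- function(out_dir, flows, nets, pair, env_wt, env_nt,
                              exposure, decomp, impacts, table1, mc, summary) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  utils::write.csv(as.data.frame(unclass(flows)), p("embodied_flows.csv"))
  utils::write.csv(data.frame(country = names(nets), net_Mg = nets),
                   p("net_transfers.csv"), row.names = FALSE)
  write_gridded_csv(pair$with_trade, p("emissions_with_trade.csv"))
  write_gridded_csv(pair$no_trade, p("emissions_no_trade.csv"))
  for (sc in c("wt", "nt")) {
    env <- if (sc == "wt") env_wt else env_nt
    write_gridded_csv(env$D, p(sprintf("deposition_%s.csv", sc)))
    write_gridded_csv(env$P, p(sprintf("plankton_%s.csv", sc)))
    write_gridded_csv(env$S, p(sprintf("soil_%s.csv", sc)))
  }
  utils::write.csv(exposure, p("exposure.csv"), row.names = FALSE)
  utils::write.csv(decomp, p("exposure_decomposition.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(impacts), p("impacts.csv"), row.names = FALSE)
  utils::write.csv(table1, p("global_summary.csv"), row.names = FALSE)
  if (!is.null(mc)) {
    utils::write.csv(as.data.frame(mc), p("mc_intervals.csv"), row.names = FALSE)
  }
  jsonlite::write_json(summary, p("summary.json"), auto_unbox = TRUE,
                       digits = NA)
  list.files(out_dir, full.names = TRUE)
}

#' Read a pipeline configuration from YAML
#'
#' Maps a YAML file with `world`, `transport` and `health` blocks (fields as
#' in [world_config()], [transport_params()] and [health_params()]) onto the
#' corresponding parameter objects. The health block's `deflators` entry
#' must name the `2008` and `2005` bases.
#'
#' @param path YAML file path.
#' @return List with `world`, `transport`, `health` parameter objects.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  world <- do.call(world_config, cfg$world %||% list())
  transport <- do.call(transport_params, cfg$transport %||% list())
  h <- cfg$health
  if (is.null(h)) stop("configuration error: health block is required", call. = FALSE)
  if (!is.null(h$deflators)) h$deflators <- unlist(h$deflators)
  health <- do.call(health_params, h)
  list(world = world, transport = transport, health = health)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
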