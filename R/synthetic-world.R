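#' Configuration for the synthetic world generator
#'
#' @param n_regions Number of regions (countries), >= 1.
#' @param n_sectors Number of sectors per region, >= 1.
#' @param grid_shape Integer pair `(n_lat, n_lon)`; `n_lon` must be at least
#'   `n_regions` (each country occupies a contiguous longitude strip).
#' @param trade_share Fraction in `[0, 1)` of each region's demand (final and
#'   intermediate) sourced from abroad.
#' @param intensity_gap Ratio >= 1 of developing-country to developed-country
#'   emission intensity.
#' @param coastal_fraction Fraction of countries flagged coastal
#'   (fish-eating); the rest are inland (rice-growing).
#' @param seed Integer RNG seed.
#' @return An object of class `world_config`.
#' @export
world_config <- function(n_regions = 10, n_sectors = 4,
                         grid_shape = c(36, 72), trade_share = 0.3,
                         intensity_gap = 5, coastal_fraction = 0.5,
                         seed = 1L) {
  chk <- function(ok, field, msg) {
    if (!ok) stop(sprintf("invalid world_config field '%s': %s", field, msg),
                  call. = FALSE)
  }
  chk(length(n_regions) == 1 && n_regions >= 1, "n_regions", "must be >= 1")
  chk(length(n_sectors) == 1 && n_sectors >= 1, "n_sectors", "must be >= 1")
  chk(length(grid_shape) == 2 && all(grid_shape >= 1), "grid_shape",
      "must be two counts >= 1")
  chk(grid_shape[2] >= n_regions, "grid_shape",
      "n_lon must be >= n_regions (one longitude strip per country)")
  chk(length(trade_share) == 1 && trade_share >= 0 && trade_share < 1,
      "trade_share", "must lie in [0, 1)")
  chk(length(intensity_gap) == 1 && intensity_gap >= 1, "intensity_gap",
      "must be >= 1")
  chk(length(coastal_fraction) == 1 && coastal_fraction >= 0 &&
        coastal_fraction <= 1, "coastal_fraction", "must lie in [0, 1]")
  chk(length(seed) == 1 && is.finite(seed), "seed", "must be a finite integer")
  structure(list(n_regions = as.integer(n_regions),
                 n_sectors = as.integer(n_sectors),
                 grid_shape = as.integer(grid_shape),
                 trade_share = trade_share,
                 intensity_gap = intensity_gap,
                 coastal_fraction = coastal_fraction,
                 seed = as.integer(seed)),
            class = "world_config")
}

#' Generate a random multiregional input-output table
#'
#' Builds a balanced economy from the demand side: random final demand with
#' exactly `trade_share` of every region's demand sourced abroad, random
#' technical coefficients with column sums well below one (so the Leontief
#' system is invertible by construction), gross output solved from
#' `x = (I - A)^{-1} y`, and `Z = A diag(x)`. If a draw ever produces a
#' spectral radius at or above one it is rescaled by 1.1x the radius, with a
#' bounded number of retries.
#'
#' @param n_regions,n_sectors Economy dimensions.
#' @param trade_share Fraction in `[0, 1)` of demand sourced abroad
#'   (irrelevant for a single region).
#' @param seed Integer RNG seed.
#' @param max_retries Bound on rescale-and-retry attempts.
#' @return An `mrio_table`.
#' @export
generate_mrio <- function(n_regions, n_sectors, trade_share, seed = 1L,
                          max_retries = 5L) {
  if (trade_share < 0 || trade_share >= 1) {
    stop("trade_share must lie in [0, 1)", call. = FALSE)
  }
  set.seed(seed)
  R <- as.integer(n_regions)
  S <- as.integer(n_sectors)
  RS <- R * S
  regions <- sprintf("R%02d", seq_len(R))
  sectors <- sprintf("s%02d", seq_len(S))
  row_of <- function(r, i) (r - 1L) * S + i

  # sourcing split: home gets 1 - trade_share, abroad shares random
  source_weights <- function(home) {
    w <- numeric(R)
    if (R == 1L) {
      w[home] <- 1
    } else {
      w[home] <- 1 - trade_share
      u <- stats::runif(R - 1L)
      w[-home] <- u / sum(u) * trade_share
    }
    w
  }

  # final demand: region s demands fd[i, s] of sector-i goods in total
  fd <- matrix(stats::rlnorm(S * R, meanlog = log(1e4), sdlog = 0.4), S, R)
  Y <- matrix(0, RS, R)
  for (s in seq_len(R)) {
    w <- source_weights(s)
    for (r in seq_len(R)) Y[row_of(r, seq_len(S)), s] <- fd[, s] * w[r]
  }

  A <- matrix(0, RS, RS)
  for (s in seq_len(R)) {
    for (j in seq_len(S)) {
      total_input <- stats::runif(1, 0.3, 0.6)
      sec_w <- stats::rgamma(S, shape = 1)
      sec_w <- sec_w / sum(sec_w)
      reg_w <- source_weights(s)
      A[, row_of(s, j)] <- total_input *
        as.vector(vapply(seq_len(R), function(r) reg_w[r] * sec_w, numeric(S)))
    }
  }

  for (attempt in seq_len(max_retries + 1L)) {
    rho <- spectral_radius(A)
    if (rho < 1) break
    if (attempt > max_retries) {
      stop("generation error: spectral-radius condition could not be met",
           call. = FALSE)
    }
    A <- A / (1.1 * rho)
  }

  x <- solve(diag(RS) - A, rowSums(Y))
  Z <- A %*% diag(x, nrow = RS)
  mrio_table(regions, sectors, Z, Y, x)
}

#' Generate a self-consistent synthetic world
#'
#' Produces an economy, a sectoral emission account with a developed vs
#' developing intensity gap, a gridded emission inventory whose per-country
#' sums match the account exactly, country masks, population and fish-catch
#' grids, diet and MeHg concentration tables, and demographics — everything
#' the downstream assessment chain consumes. Developed countries sit near
#' 40 deg latitude (the high-oxidation band), developing countries near the
#' equator; coastal countries eat seafood, inland ones rice and freshwater
#' fish.
#'
#' @param config A `world_config`.
#' @return An object of class `synthetic_world`: list with elements
#'   `config`, `regions` (data frame of flags), `economy`, `emissions`,
#'   `grid_inventory`, `masks`, `population_grid`, `fishcatch`, `diets`,
#'   `concentrations`, `demographics`, `ocean` (logical matrix).
#' @export
generate_world <- function(config) {
  if (!inherits(config, "world_config")) {
    stop("config must be a world_config", call. = FALSE)
  }
  R <- config$n_regions
  S <- config$n_sectors
  economy <- generate_mrio(R, S, config$trade_share,
                           seed = fanout_seed(config$seed, "mrio"))

  set.seed(fanout_seed(config$seed, "world"))
  regions <- economy$regions

  developed <- seq_len(R) <= ceiling(R / 2)
  n_coastal <- round(config$coastal_fraction * R)
  coastal <- seq_len(R) %in% sample(seq_len(R), n_coastal)

  # emission intensities: log-normal per (region, sector) around a shared
  # sectoral base, multiplied by the development gap for developing regions
  sector_base <- stats::rlnorm(S, meanlog = log(5e-5), sdlog = 0.5)
  mult <- ifelse(developed, 1, config$intensity_gap)
  intensity <- as.vector(t(outer(mult, sector_base))) *
    stats::rlnorm(R * S, meanlog = 0, sdlog = 0.25)
  pba <- intensity * economy$x
  emissions <- emission_account(pba, economy)
  pba_country <- pba_totals(emissions)

  # grid: country r occupies a contiguous lon strip and a latitude band
  # centred near 40 deg (developed) or the equator (developing)
  n_lat <- config$grid_shape[1]
  n_lon <- config$grid_shape[2]
  lat <- seq(-90 + 180 / n_lat / 2, 90 - 180 / n_lat / 2, length.out = n_lat)
  lon <- seq(-180 + 360 / n_lon / 2, 180 - 360 / n_lon / 2, length.out = n_lon)
  strip_bounds <- floor(seq(0, n_lon, length.out = R + 1))
  band_half <- max(1, floor(n_lat / 8))

  land <- matrix(FALSE, n_lat, n_lon)
  weights <- vector("list", R)
  names(weights) <- regions
  for (r in seq_len(R)) {
    cols <- (strip_bounds[r] + 1):strip_bounds[r + 1]
    centre <- if (developed[r]) 40 else 0
    centre <- centre + stats::runif(1, -5, 5)
    row_centre <- which.min(abs(lat - centre))
    rows <- max(1, row_centre - band_half):min(n_lat, row_centre + band_half)
    w <- matrix(0, n_lat, n_lon)
    w[rows, cols] <- 1
    weights[[r]] <- w
    land[rows, cols] <- TRUE
  }
  masks <- country_mask(weights)
  ocean <- !land

  spread_over_cells <- function(total_by_country, jitter_shape = 2) {
    vals <- matrix(0, n_lat, n_lon)
    for (r in seq_len(R)) {
      cells <- which(weights[[r]] > 0)
      u <- stats::rgamma(length(cells), shape = jitter_shape) + 1e-3
      vals[cells] <- vals[cells] + total_by_country[r] * u / sum(u)
    }
    vals
  }

  grid_inventory <- gridded_field(lat, lon, spread_over_cells(pba_country),
                                  units = "Mg/yr")

  population <- stats::rlnorm(R, meanlog = log(2e7), sdlog = 0.8)
  population_grid <- gridded_field(lat, lon, spread_over_cells(population),
                                   units = "persons")

  # fish catch: coastal countries fish the ocean cells flanking their strip
  fishcatch <- list()
  for (r in which(coastal)) {
    cols <- (strip_bounds[r] + 1):strip_bounds[r + 1]
    w <- matrix(0, n_lat, n_lon)
    sel <- matrix(FALSE, n_lat, n_lon)
    sel[, cols] <- TRUE
    cells <- which(sel & ocean)
    if (length(cells) == 0) cells <- which(ocean)
    u <- stats::rgamma(length(cells), shape = 2) + 1e-3
    w[cells] <- u / sum(u)
    fishcatch[[regions[r]]] <- w
  }

  # diets: g/day per person; coastal weighted to seafood, inland to rice and
  # freshwater fish (inland seafood intake zero: no marine catch to weight)
  jit <- function(n, mean, sd = 0.3) stats::rlnorm(n, log(mean), sd)
  diets <- data.frame(
    country = regions,
    I_seafood = ifelse(coastal, jit(R, 80), 0),
    I_fwfish = ifelse(coastal, jit(R, 15), jit(R, 40)),
    I_rice = ifelse(coastal, jit(R, 120), jit(R, 300)),
    stringsAsFactors = FALSE
  )
  concentrations <- data.frame(
    country = regions,
    C_seafood = jit(R, 0.08, 0.2),
    C_fwfish = jit(R, 0.04, 0.2),
    C_rice = jit(R, 0.004, 0.2),
    stringsAsFactors = FALSE
  )

  frac_male <- stats::runif(R, 0.48, 0.52)
  demographics <- data.frame(
    country = regions,
    births = population * stats::runif(R, 0.009, 0.015),
    pop_male = population * frac_male,
    pop_female = population * (1 - frac_male),
    cf_male = stats::runif(R, 0.0015, 0.0025),
    cf_female = stats::runif(R, 0.001, 0.002),
    gdp_pc = ifelse(developed, jit(R, 4e4, 0.2), jit(R, 8e3, 0.3)),
    stringsAsFactors = FALSE
  )

  world <- structure(list(
    config = config,
    regions = data.frame(country = regions, developed = developed,
                         coastal = coastal, stringsAsFactors = FALSE),
    economy = economy,
    emissions = emissions,
    grid_inventory = grid_inventory,
    masks = masks,
    population_grid = population_grid,
    fishcatch = fishcatch,
    diets = diets,
    concentrations = concentrations,
    demographics = demographics,
    ocean = ocean
  ), class = "synthetic_world")
  validate_world(world)
  world
}

# internal consistency checks tying the grid to the sectoral account
validate_world <- function(world) {
  tot <- pba_totals(world$emissions)
  grid <- country_grid_sums(world$grid_inventory, world$masks)
  rel <- abs(grid - tot) / pmax(abs(tot), 1e-12)
  if (any(tot > 0 & rel > 1e-6)) {
    stop("world invariant violated: per-country grid sums differ from the account",
         call. = FALSE)
  }
  for (cc in names(world$fishcatch)) {
    s <- sum(world$fishcatch[[cc]])
    if (abs(s - 1) > 1e-9) {
      stop(sprintf("fish catch weights for %s sum to %.6f, not 1", cc, s),
           call. = FALSE)
    }
    if (any(world$fishcatch[[cc]][!world$ocean] != 0)) {
      stop(sprintf("fish catch weights for %s fall on land", cc), call. = FALSE)
    }
  }
  invisible(world)
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat(sprintf(paste0("<synthetic_world> %d regions x %d sectors, %d x %d grid, ",
                     "total emissions %.4g Mg/yr\n"),
              x$config$n_regions, x$config$n_sectors,
              x$config$grid_shape[1], x$config$grid_shape[2],
              sum(x$emissions$pba)))
  invisible(x)
}

#' Deterministic per-module seed fan-out
#'
#' Derives a module-specific 31-bit seed from a single global seed so every
#' stage of a pipeline run has an independent, reproducible RNG stream.
#'
#' @param seed Integer global seed.
#' @param module Character module name.
#' @return Integer seed below 2^31.
#' @export
fanout_seed <- function(seed, module) {
  h <- sum(utf8ToInt(module) * seq_along(utf8ToInt(module)))
  as.integer((abs(as.numeric(seed)) * 7919 + h * 104729) %% 2147483647)
}

#' Write a synthetic world to plain-text files
#'
#' Economy tables (Z, Y, x) as CSV with `region:sector` headers, gridded
#' fields as long-format CSV, masks and fish catch as long-format weight
#' tables, and country tables as CSV.
#'
#' @param world A `synthetic_world`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_world <- function(world, dir) {
  stopifnot(inherits(world, "synthetic_world"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  eco <- world$economy
  utils::write.csv(as.data.frame(eco$Z), file.path(dir, "Z.csv"))
  utils::write.csv(as.data.frame(eco$Y), file.path(dir, "Y.csv"))
  utils::write.csv(data.frame(sector = names(eco$x), x = eco$x),
                   file.path(dir, "x.csv"), row.names = FALSE)
  utils::write.csv(data.frame(sector = names(world$emissions$pba),
                              pba = world$emissions$pba,
                              intensity = world$emissions$intensity),
                   file.path(dir, "emissions.csv"), row.names = FALSE)
  write_gridded_csv(world$grid_inventory, file.path(dir, "grid_inventory.csv"))
  write_gridded_csv(world$population_grid, file.path(dir, "population.csv"))
  long_weights <- function(wl) {
    do.call(rbind, lapply(names(wl), function(cc) {
      idx <- which(wl[[cc]] > 0, arr.ind = TRUE)
      data.frame(country = cc,
                 lat = world$grid_inventory$lat[idx[, 1]],
                 lon = world$grid_inventory$lon[idx[, 2]],
                 weight = wl[[cc]][idx])
    }))
  }
  utils::write.csv(long_weights(world$masks$weights),
                   file.path(dir, "masks.csv"), row.names = FALSE)
  if (length(world$fishcatch)) {
    utils::write.csv(long_weights(world$fishcatch),
                     file.path(dir, "fishcatch.csv"), row.names = FALSE)
  }
  utils::write.csv(world$regions, file.path(dir, "regions.csv"), row.names = FALSE)
  utils::write.csv(world$diets, file.path(dir, "diets.csv"), row.names = FALSE)
  utils::write.csv(world$concentrations, file.path(dir, "concentrations.csv"),
                   row.names = FALSE)
  utils::write.csv(world$demographics, file.path(dir, "demographics.csv"),
                   row.names = FALSE)
  invisible(dir)
}
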