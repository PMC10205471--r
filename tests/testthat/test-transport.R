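grid_2x6 <- function() {
  list(lat = c(0, 40), lon = c(-150, -90, -30, 30, 90, 150))
}

test_that("parameter validation enforces the deposited-share budget", {
  expect_error(transport_params(local_fraction_peak = 0.8,
                                advection_fraction = 0.2,
                                global_mixing = 0.1),
               "exceed 1")
  expect_error(transport_params(local_fraction_min = 0.7,
                                local_fraction_peak = 0.6),
               "local_fraction_min")
  expect_error(transport_params(soil_gain = 0.02), "soil_gain")
  expect_error(transport_params(background_D = 0), "background_D")
})

test_that("well-mixed limit deposits every source uniformly", {
  g <- grid_2x6()
  params <- transport_params(local_fraction_peak = 0, local_fraction_min = 0,
                             advection_fraction = 0, global_mixing = 1)
  op <- build_operator(g$lat, g$lon, params)
  E <- matrix(0, 2, 6)
  E[2, 1] <- 12
  env <- apply_operator(op, gridded_field(g$lat, g$lon, E))
  expect_equal(env$D$values, matrix(1 + 12 / 12, 2, 6))
  expect_equal(env$deposited_total, 12)
  expect_equal(env$undeposited_total, 0)
})

test_that("a unit emission reproduces the operator column", {
  g <- grid_2x6()
  params <- transport_params(advection_cells = 2L, advection_fraction = 0.15,
                             global_mixing = 0.1)
  op <- build_operator(g$lat, g$lon, params)
  col <- operator_column(op, 2, 5)
  expected <- matrix(0.1 / 12, 2, 6)            # well-mixed share
  expected[2, 5] <- expected[2, 5] + 0.6        # alpha at 40 deg
  expected[2, 6] <- expected[2, 6] + 0.15 * 2 / 3  # first downwind cell
  expected[2, 1] <- expected[2, 1] + 0.15 * 1 / 3  # wraps in longitude
  expect_equal(col, expected, tolerance = 1e-12)
})

test_that("relocating emissions from the 40-degree band to the equator cuts deposition", {
  g <- grid_2x6()
  params <- transport_params(local_fraction_peak = 0.6,
                             local_fraction_min = 0.2,
                             advection_fraction = 0, global_mixing = 0)
  op <- build_operator(g$lat, g$lon, params)
  at40 <- matrix(0, 2, 6); at40[2, 1] <- 10
  at0 <- matrix(0, 2, 6); at0[1, 1] <- 10
  dep40 <- apply_operator(op, gridded_field(g$lat, g$lon, at40))$deposited_total
  dep0 <- apply_operator(op, gridded_field(g$lat, g$lon, at0))$deposited_total
  expect_lt(dep0, dep40)
  expect_equal(dep40 - dep0, (0.6 - 0.2) * 10, tolerance = 1e-12)
})

test_that("the operator is linear: superposition holds to 1e-10", {
  g <- grid_2x6()
  op <- build_operator(g$lat, g$lon,
                       transport_params(advection_cells = 3L,
                                        advection_fraction = 0.2,
                                        global_mixing = 0.1))
  set.seed(4)
  e1 <- matrix(runif(12), 2, 6)
  e2 <- matrix(runif(12), 2, 6)
  a <- 1.5; b <- 0.5
  mix <- a * e1 + b * e2
  f <- function(E) apply_operator(op, gridded_field(g$lat, g$lon, E))
  anom <- function(env, bg) env - bg
  for (fld in c("D", "P", "S")) {
    bg <- switch(fld, D = op$bg_D, P = op$bg_P * op$ocean, S = op$bg_S)
    lhs <- f(mix)[[fld]]$values - bg
    rhs <- a * (f(e1)[[fld]]$values - bg) + b * (f(e2)[[fld]]$values - bg)
    scale <- max(abs(rhs), 1e-12)
    expect_lt(max(abs(lhs - rhs)) / scale, 1e-10)
  }
  # zero emissions reproduce the backgrounds; doubling doubles anomalies
  z <- f(matrix(0, 2, 6))
  expect_equal(z$D$values, op$bg_D)
  expect_equal(z$S$values, op$bg_S)
  d1 <- f(e1)$D$values - op$bg_D
  d2 <- f(2 * e1)$D$values - op$bg_D
  expect_equal(d2, 2 * d1, tolerance = 1e-12)
})

test_that("the mass ledger balances deposited and undeposited emissions", {
  g <- grid_2x6()
  params <- transport_params(advection_cells = 2L, advection_fraction = 0.1,
                             global_mixing = 0.2)
  op <- build_operator(g$lat, g$lon, params)
  set.seed(5)
  E <- matrix(rexp(12), 2, 6)
  env <- apply_operator(op, gridded_field(g$lat, g$lon, E))
  share <- deposited_share(op)
  expect_equal(env$deposited_total, sum(share * E), tolerance = 1e-12)
  expect_equal(env$deposited_total + env$undeposited_total, sum(E),
               tolerance = 1e-12)
  expect_true(all(share <= 1 + 1e-12))
})

test_that("plankton responds on ocean cells only, in proportion to deposition", {
  g <- grid_2x6()
  ocean <- matrix(TRUE, 2, 6)
  ocean[2, 1] <- FALSE
  op <- build_operator(g$lat, g$lon,
                       transport_params(advection_cells = 1L,
                                        advection_fraction = 0.2,
                                        global_mixing = 0,
                                        plankton_gain = 0.1),
                       ocean = ocean)
  E <- matrix(0, 2, 6); E[2, 1] <- 5
  env <- apply_operator(op, gridded_field(g$lat, g$lon, E))
  d_anom <- env$D$values - op$bg_D
  expect_equal(env$P$values[2, 2], 1 + 0.1 * d_anom[2, 2])
  expect_equal(env$P$values[2, 1], 0)  # land cell
})

test_that("soil shifts stay below 1% for half-sized emission perturbations", {
  w <- generate_world(small_world_config(seed = 19))
  op <- build_operator(w$grid_inventory$lat, w$grid_inventory$lon,
                       transport_params(soil_gain = 0.009), ocean = w$ocean)
  base <- apply_operator(op, w$grid_inventory)$S$values
  half_more <- gridded_field(w$grid_inventory$lat, w$grid_inventory$lon,
                             w$grid_inventory$values * 1.5)
  pert <- apply_operator(op, half_more)$S$values
  expect_lt(max(abs(pert - base) / base), 0.01)
})
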