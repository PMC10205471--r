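two_cell <- function(vals) gridded_field(0, c(10, 20), matrix(vals, 1, 2))

test_that("country proxies match hand-weighted means", {
  mask <- country_mask(list(X = matrix(c(1, 1), 1, 2)))
  # population-weighted deposition: pop (1,3), D (4,8) -> 7
  expect_equal(population_weighted_deposition(two_cell(c(4, 8)), mask,
                                              two_cell(c(1, 3))),
               c(X = 7))
  # uniform field returns the constant; point-mass population picks its cell
  expect_equal(population_weighted_deposition(two_cell(c(6, 6)), mask,
                                              two_cell(c(2, 5))), c(X = 6))
  expect_equal(population_weighted_deposition(two_cell(c(4, 8)), mask,
                                              two_cell(c(0, 3))), c(X = 8))
  expect_error(population_weighted_deposition(two_cell(c(4, 8)), mask,
                                              two_cell(c(0, 0))),
               "zero population")

  # catch-weighted plankton: weights (0.25, 0.75), P (2,6) -> 5
  fc <- list(X = matrix(c(0.25, 0.75), 1, 2))
  expect_equal(catch_weighted_plankton(two_cell(c(2, 6)), fc), c(X = 5))
  expect_equal(catch_weighted_plankton(two_cell(c(3, 3)), fc), c(X = 3))
  expect_true(is.na(catch_weighted_plankton(two_cell(c(2, 6)), fc,
                                            countries = c("X", "Y"))["Y"]))
  expect_error(catch_weighted_plankton(two_cell(c(2, 6)),
                                       list(X = matrix(0, 1, 2))),
               "sum to zero")

  # mean soil: equal weights, S (3,5) -> 4
  expect_equal(mean_soil(two_cell(c(3, 5)), mask), c(X = 4))
  expect_equal(mean_soil(two_cell(c(9, 9)), mask), c(X = 9))
})

food_toy <- function() {
  data.frame(country = "X", I_seafood = 100, I_fwfish = 50, I_rice = 200,
             C_seafood = 0.10, C_fwfish = 0.05, C_rice = 0.01,
             stringsAsFactors = FALSE)
}

test_that("with-trade exposure is the intake-concentration sum", {
  wt <- exposure_with_trade(food_toy())
  expect_equal(wt$E_WT, 100 * 0.10 + 50 * 0.05 + 200 * 0.01)  # 14.5 ug/day
  zero <- food_toy()
  zero[, c("I_seafood", "I_fwfish", "I_rice")] <- 0
  expect_equal(exposure_with_trade(zero)$E_WT, 0)
  doubled <- food_toy()
  doubled[, c("C_seafood", "C_fwfish", "C_rice")] <-
    2 * doubled[, c("C_seafood", "C_fwfish", "C_rice")]
  expect_equal(exposure_with_trade(doubled)$E_WT, 2 * wt$E_WT)
  neg <- food_toy(); neg$I_rice <- -1
  expect_error(exposure_with_trade(neg), "nonnegative")
})

env_toy <- function(p = 2, d = 0.5, s = 1) {
  data.frame(country = "X", P_WT = 1, P_NT = p, D_WT = 1, D_NT = d,
             S_WT = 1, S_NT = s, stringsAsFactors = FALSE)
}

test_that("no-trade exposure scales each pathway by its proxy ratio", {
  # equal 1 ug/day per pathway, ratios (2, 0.5, 1) -> 3.5 ug/day
  tab <- data.frame(country = "X", I_seafood = 10, I_fwfish = 20, I_rice = 100,
                    C_seafood = 0.1, C_fwfish = 0.05, C_rice = 0.01)
  nt <- exposure_no_trade(tab, env_toy(2, 0.5, 1))
  expect_equal(nt$E_NT, 2 * 1 + 0.5 * 1 + 1 * 1)

  # identical scenarios leave exposure unchanged
  same <- exposure_no_trade(tab, env_toy(1, 1, 1))
  expect_equal(same$E_NT, exposure_with_trade(tab)$E_WT)

  # single-pathway diet: a soil ratio of 1 + eps moves exposure by eps
  rice_only <- data.frame(country = "X", I_seafood = 0, I_fwfish = 0,
                          I_rice = 100, C_seafood = 0, C_fwfish = 0,
                          C_rice = 0.01)
  eps <- 1e-3
  nt_r <- exposure_no_trade(rice_only, env_toy(1, 1, 1 + eps))
  expect_equal(nt_r$E_NT / exposure_with_trade(rice_only)$E_WT - 1, eps,
               tolerance = 1e-12)

  # a zero-intake pathway skips its ratio even when the proxy is missing
  env_na <- env_toy(); env_na$P_WT <- NA; env_na$P_NT <- NA
  expect_silent(nt_skip <- exposure_no_trade(rice_only, env_na))
  expect_equal(nt_skip$E_NT, 1)
  # but a zero with-trade proxy with positive intake is an error
  env_bad <- env_toy(); env_bad$P_WT <- 0
  expect_error(exposure_no_trade(tab, env_bad), "scaling error")
})

test_that("raising a no-trade proxy never lowers no-trade exposure", {
  tab <- data.frame(country = "X", I_seafood = 10, I_fwfish = 20, I_rice = 100,
                    C_seafood = 0.1, C_fwfish = 0.05, C_rice = 0.01)
  base <- exposure_no_trade(tab, env_toy(2, 0.5, 1))$E_NT
  for (col in c("P_NT", "D_NT", "S_NT")) {
    env_up <- env_toy(2, 0.5, 1)
    env_up[[col]] <- env_up[[col]] * 1.3
    expect_gte(exposure_no_trade(tab, env_up)$E_NT, base)
  }
})

test_that("pathway decomposition is exact and scenario swap inverts the scaling", {
  tab <- data.frame(country = "X", I_seafood = 10, I_fwfish = 20, I_rice = 100,
                    C_seafood = 0.1, C_fwfish = 0.05, C_rice = 0.01)
  env <- env_toy(2, 0.5, 1)
  wt <- exposure_with_trade(tab)
  nt <- exposure_no_trade(tab, env)
  dec <- exposure_delta_decomposition(wt, nt)
  expect_identical(dec$d_total, dec$d_seafood + dec$d_fwfish + dec$d_rice)
  expect_equal(dec$d_total, wt$E_WT - nt$E_NT)
  expect_equal(dec[, c("d_seafood", "d_fwfish", "d_rice")],
               data.frame(d_seafood = -1, d_fwfish = 0.5, d_rice = 0),
               ignore_attr = TRUE)

  # swapping the scenario labels and inverting the ratios recovers E_WT
  swapped <- data.frame(country = "X",
                        P_WT = env$P_NT, P_NT = env$P_WT,
                        D_WT = env$D_NT, D_NT = env$D_WT,
                        S_WT = env$S_NT, S_NT = env$S_WT)
  tab_nt <- tab
  # rebuild the intake side so with-trade exposure equals the NT pathways
  tab_nt$C_seafood <- nt$E_seafood / tab$I_seafood
  tab_nt$C_fwfish <- nt$E_fwfish / tab$I_fwfish
  tab_nt$C_rice <- nt$E_rice / tab$I_rice
  back <- exposure_no_trade(tab_nt, swapped)
  expect_equal(back$E_NT, wt$E_WT, tolerance = 1e-12)
})
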