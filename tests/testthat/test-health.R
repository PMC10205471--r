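hp <- function(...) {
  args <- list(gamma = 1, lambda = 1, beta = 0.1, phi = 0.01, omega = 1,
               bw = 70, deflators = c("2008" = 1, "2005" = 1))
  args[names(list(...))] <- list(...)
  do.call(health_params, args)
}

test_that("IQ decrement is linear in exposure with the configured BW convention", {
  # gamma*lambda*beta = 0.1, BW = 70, exposure 1 ug/day -> 7 points
  p <- hp()
  expect_equal(iq_decrement(1, p), 7)
  expect_equal(iq_decrement(0, p), 0)
  expect_equal(iq_decrement(2, p), 2 * iq_decrement(1, p))
  p_div <- hp(bw_mode = "divide")
  expect_equal(iq_decrement(1, p_div), 0.1 / 70)
  expect_error(iq_decrement(-1, p), "nonnegative")
})

test_that("FHA deaths follow the log-linear form and stay bounded", {
  demo1 <- data.frame(pop_male = 1e6, pop_female = 0,
                      cf_male = 0.002, cf_female = 0)
  # phi*lambda*beta*dose = 0.001 -> 1e6 * 0.002 * (1 - exp(-0.001)) deaths
  p <- hp(phi = 1, lambda = 1, beta = 1, bw = 1, omega = 1)
  expect_equal(fha_deaths(0.001, demo1, p),
               1e6 * 0.002 * (1 - exp(-0.001)))
  expect_lt(abs(fha_deaths(0.001, demo1, p) - 1.999), 1e-3)
  expect_equal(fha_deaths(0, demo1, p), 0)
  expect_equal(fha_deaths(100, demo1, hp(omega = 0)), 0)

  demo2 <- data.frame(pop_male = 3e6, pop_female = 4e6,
                      cf_male = 0.002, cf_female = 0.0015)
  cap <- 1 * (3e6 * 0.002 + 4e6 * 0.0015)
  expect_lt(fha_deaths(10, demo2, p), cap)
  expect_lte(fha_deaths(1e6, demo2, p), cap)

  expect_warning(
    d <- fha_deaths(0.001, data.frame(pop_total = 2e6, cf_male = 0.002,
                                      cf_female = 0.002), p),
    "50/50")
  expect_equal(d, 2e6 * 0.002 * (1 - exp(-0.001)))
})

test_that("small-dose linearization error is second order in the exponent", {
  p <- hp(phi = 1, lambda = 1, beta = 1, bw = 1)
  expect_equal(small_dose_limit_check(p, 0), 0)
  # Taylor: (x - (1 - e^-x)) / (1 - e^-x) ~ x/2
  expect_equal(small_dose_limit_check(p, 0.001), 5e-4, tolerance = 1e-3)
  expect_equal(small_dose_limit_check(p, 0.01), 5e-3, tolerance = 1e-2)
  gaps <- small_dose_limit_check(p, c(0.001, 0.005, 0.01))
  expect_true(all(gaps <= c(0.001, 0.005, 0.01)))
  expect_error(small_dose_limit_check(p, 0.5), "small-dose")
})

test_that("economic loss deflates EL and VSL and adds the endpoints", {
  p <- hp()
  loss <- economic_loss(100, 1, p)
  expect_equal(loss$loss_total, 18832 * 100 + 6.3e6)  # 8,183,200 USD
  expect_equal(loss$loss_total, loss$loss_iq + loss$loss_fha)
  expect_equal(economic_loss(0, 0, p)$loss_total, 0)
  expect_equal(economic_loss(200, 2, p)$loss_total, 2 * loss$loss_total)

  p_defl <- hp(deflators = c("2008" = 1.24, "2005" = 1.35))
  loss_d <- economic_loss(100, 1, p_defl)
  expect_equal(loss_d$loss_iq, 18832 * 1.24 * 100)
  expect_equal(loss_d$loss_fha, 6.3e6 * 1.35)

  expect_error(health_params(gamma = 1, lambda = 1, beta = 1, phi = 1,
                             omega = 1, bw = 70,
                             deflators = c("2008" = 1)),
               "configuration error")
})

test_that("country VSL scaling reduces to the flat case at elasticity zero", {
  p_flat <- hp()
  p_el <- hp(vsl_elasticity = 1, gdp_ref = 2e4)
  gdp <- c(4e4, 1e4)
  flat <- economic_loss(0, c(1, 1), p_flat)$loss_fha
  scaled <- economic_loss(0, c(1, 1), p_el, gdp_pc = gdp)$loss_fha
  expect_equal(flat, rep(6.3e6, 2))
  expect_equal(scaled, 6.3e6 * gdp / 2e4)
  expect_error(health_params(gamma = 1, lambda = 1, beta = 1, phi = 1,
                             omega = 1, bw = 70, vsl_elasticity = 1),
               "gdp_ref")
})

demo3 <- data.frame(
  country = c("AAA", "BBB", "CCC"),
  births = c(1e5, 2e5, 5e4),
  pop_male = c(5e6, 8e6, 2e6), pop_female = c(5e6, 8e6, 2e6),
  cf_male = c(0.002, 0.0018, 0.0025), cf_female = c(0.0015, 0.0012, 0.002),
  gdp_pc = c(4e4, 3e4, 8e3), stringsAsFactors = FALSE)

test_that("scenario impacts difference per-scenario endpoint chains", {
  p <- hp(gamma = 0.5, lambda = 0.2, beta = 0.001, phi = 0.05, omega = 0.5)
  expo <- data.frame(country = demo3$country,
                     E_WT = c(10, 8, 4), E_NT = c(11, 7.5, 4.2))
  imp <- scenario_impacts(expo, demo3, p)
  # hand chain for AAA: dose coefficients 1e-4 (IQ) and 1e-5 (FHA exponent)
  iq_wt <- 0.5 * 0.2 * 0.001 * 10 * 70
  iq_nt <- 0.5 * 0.2 * 0.001 * 11 * 70
  expect_equal(imp$iq_pf_wt[1], iq_wt)
  expect_equal(imp$iq_pf_net[1], iq_wt - iq_nt)
  expect_equal(imp$iq_total_net[1], (iq_wt - iq_nt) * 1e5)
  base_a <- 0.5 * (5e6 * 0.002 + 5e6 * 0.0015)
  d_wt <- base_a * (1 - exp(-0.05 * 0.2 * 0.001 * 10 * 70))
  d_nt <- base_a * (1 - exp(-0.05 * 0.2 * 0.001 * 11 * 70))
  expect_equal(imp$deaths_net[1], d_wt - d_nt)
  expect_equal(imp$loss_total_net[1],
               18832 * (iq_wt - iq_nt) * 1e5 + 6.3e6 * (d_wt - d_nt))
  # additivity and the loss identity
  glob <- attr(imp, "global")
  expect_equal(glob$deaths_net, sum(imp$deaths_net))
  expect_equal(glob$loss_total_net, glob$loss_iq_net + glob$loss_fha_net)
  # births-weighted global per-fetus decrement
  expect_equal(glob$iq_pf_wt,
               sum(imp$iq_pf_wt * demo3$births) / sum(demo3$births))
  # impact sign tracks the exposure change country by country
  expect_equal(sign(imp$loss_total_net), sign(expo$E_WT - expo$E_NT))
})

test_that("identical scenarios produce exactly zero nets and a clean summary", {
  p <- hp()
  expo <- data.frame(country = demo3$country, E_WT = c(10, 8, 4),
                     E_NT = c(10, 8, 4))
  imp <- scenario_impacts(expo, demo3, p)
  t1 <- summarize_table1(imp)
  expect_identical(t1$net, rep(0, 6))
  expect_identical(t1$net, t1$with_trade - t1$no_trade)
  expect_equal(nrow(t1), 6)
})

test_that("countries without demographics are flagged, not zeroed", {
  p <- hp()
  expo <- data.frame(country = c("AAA", "ZZZ"), E_WT = c(10, 5),
                     E_NT = c(9, 6))
  expect_message(imp <- scenario_impacts(expo, demo3, p), "lack demographics")
  expect_true(imp$missing[imp$country == "ZZZ"])
  expect_true(is.na(imp$loss_total_net[imp$country == "ZZZ"]))
  glob <- attr(imp, "global")
  expect_equal(glob$n_missing, 1)
  expect_equal(glob$deaths_net, imp$deaths_net[1])
})
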