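test_that("technical coefficients divide flows by gross output", {
  t11 <- mrio_table("R01", "s01", matrix(2), matrix(2), 4)
  expect_equal(technical_coefficients(t11), matrix(0.5, dimnames = dimnames(t11$Z)))

  tz <- mrio_table("R01", c("a", "b"), matrix(0, 2, 2),
                   matrix(c(1, 2), 2, 1), c(1, 2))
  expect_true(all(technical_coefficients(tz) == 0))
})

test_that("inputs into a zero-output sector are rejected", {
  bad <- mrio_table("R01", c("a", "b"),
                    rbind(c(0, 1), c(0, 0)),
                    matrix(c(0, 0), 2, 1), c(1, 0))
  expect_error(technical_coefficients(bad), "zero output")
})

test_that("Leontief inverse matches identity, geometric series and power series", {
  expect_equal(leontief_inverse(matrix(0, 3, 3)), diag(3))
  expect_equal(leontief_inverse(matrix(0.5)), matrix(2))

  set.seed(42)
  A <- matrix(runif(36), 6, 6)
  A <- A / max(Mod(eigen(A)$values)) * 0.7
  L <- leontief_inverse(A)
  series <- diag(6)
  term <- diag(6)
  for (k in 1:60) {
    term <- term %*% A
    series <- series + term
  }
  expect_equal(L, series, tolerance = 1e-8)
  expect_true(all(L - diag(6) >= -1e-12))
})

test_that("Leontief inverse rejects non-invertible systems", {
  expect_error(leontief_inverse(diag(2) * 1.2), "spectral radius")
  expect_error(leontief_inverse(matrix(c(0.1, -0.2, 0, 0.1), 2, 2)),
               "nonnegative")
})

test_that("embodied flows match the truncated power-series oracle", {
  toy <- toy_two_region()
  flows <- embodied_flow_matrix(toy$account, toy$table)
  oracle <- power_series_flows(toy$account, toy$table, n_terms = 200)
  expect_equal(unclass(flows), oracle, tolerance = 1e-10)

  set.seed(11)
  for (i in 1:5) {
    tab <- generate_mrio(sample(2:4, 1), sample(1:3, 1), runif(1, 0, 0.6),
                         seed = 100 + i)
    acc <- random_account(tab)
    expect_equal(unclass(embodied_flow_matrix(acc, tab)),
                 power_series_flows(acc, tab, n_terms = 120),
                 tolerance = 1e-6)
  }
})

test_that("embodied flows conserve emissions and respect degenerate cases", {
  toy <- toy_two_region()
  flows <- embodied_flow_matrix(toy$account, toy$table)
  expect_equal(sum(flows), sum(toy$account$pba), tolerance = 1e-10)
  expect_equal(rowSums(flows), pba_totals(toy$account), tolerance = 1e-10)

  single <- generate_mrio(1, 3, 0, seed = 3)
  acc1 <- random_account(single)
  f1 <- embodied_flow_matrix(acc1, single)
  expect_equal(dim(f1), c(1, 1))
  expect_equal(ncol(single$Y), 1)

  zero <- emission_account(rep(0, length(toy$table$x)), toy$table)
  expect_true(all(embodied_flow_matrix(zero, toy$table) == 0))
})

test_that("raising one sector's intensity never decreases any embodied flow", {
  tab <- generate_mrio(3, 2, 0.4, seed = 21)
  set.seed(22)
  acc <- random_account(tab)
  base <- embodied_flow_matrix(acc, tab)
  for (j in c(1, 4, 6)) {
    pba2 <- acc$pba
    pba2[j] <- pba2[j] * 2
    up <- embodied_flow_matrix(emission_account(pba2, tab), tab)
    expect_true(all(up - base >= -1e-12))
  }
})

test_that("net transfers subtract column from row sums and sum to zero", {
  sym <- matrix(c(1, 2, 2, 1), 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  expect_equal(net_transfers(sym), c(A = 0, B = 0))

  toy <- matrix(c(5, 1, 0,
                  2, 4, 1,
                  0, 3, 6), 3, 3, byrow = TRUE,
                dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  nets <- net_transfers(toy)
  expect_equal(nets, c(A = (5 + 1 + 0) - (5 + 2 + 0),
                       B = (2 + 4 + 1) - (1 + 4 + 3),
                       C = (0 + 3 + 6) - (0 + 1 + 6)))
  expect_equal(sum(nets), 0)
})

test_that("top net flows match brute-force pairwise enumeration", {
  sym <- matrix(1, 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  expect_equal(nrow(top_net_flows(sym, 5)), 0)

  toy <- matrix(c(0, 7, 1,
                  2, 0, 9,
                  5, 3, 0), 3, 3, byrow = TRUE,
                dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  expect_equal(nrow(top_net_flows(toy, 0)), 0)

  # brute force over all ordered pairs
  labs <- rownames(toy)
  pairs <- expand.grid(r = 1:3, s = 1:3)
  pairs <- pairs[pairs$r != pairs$s, ]
  pairs$net <- toy[cbind(pairs$r, pairs$s)] - toy[cbind(pairs$s, pairs$r)]
  pairs <- pairs[pairs$net > 0, ]
  pairs <- pairs[order(-pairs$net, labs[pairs$r], labs[pairs$s]), ]

  got <- top_net_flows(toy, 10)
  expect_equal(got$source, labs[pairs$r])
  expect_equal(got$destination, labs[pairs$s])
  expect_equal(got$net_flow, pairs$net)
  expect_equal(nrow(top_net_flows(toy, 2)), 2)
})

test_that("embodied trade share is the off-diagonal fraction", {
  expect_equal(embodied_trade_share(matrix(1, 2, 2)), 0.5)
  expect_equal(embodied_trade_share(matrix(4)), 0)
  expect_equal(embodied_trade_share(diag(c(3, 5))), 0)
  expect_error(embodied_trade_share(matrix(0, 2, 2)), "undefined")
})

test_that("source aggregation applies a many-to-one concordance", {
  em <- data.frame(region = c("A", "A", "B"),
                   source = c("smelting", "cement", "smelting"),
                   emissions = c(3, 1, 2))
  map <- data.frame(source = c("smelting", "cement"),
                    sector = c("metals", "minerals"))
  out <- aggregate_sources(em, map, c("A", "B"), c("metals", "minerals"))
  expect_equal(out, matrix(c(3, 2, 1, 0), 2, 2,
                           dimnames = list(c("A", "B"), c("metals", "minerals"))))
  expect_error(aggregate_sources(em, map[1, ], c("A", "B"), "metals"),
               "no sector mapping")
  expect_error(aggregate_sources(em, rbind(map, map[1, ]), c("A", "B"),
                                 c("metals", "minerals")),
               "many-to-one")
})
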