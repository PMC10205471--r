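# Independent oracles and small fixtures shared across tests.

# Truncated supply-chain power-series accounting: expands the Leontief
# series term by term with plain loops, independently of the package's
# factorization path.
power_series_flows <- function(account, table, n_terms = 60) {
  R <- length(table$regions)
  S <- length(table$sectors)
  RS <- R * S
  A <- matrix(0, RS, RS)
  for (j in seq_len(RS)) {
    if (table$x[j] > 0) A[, j] <- table$Z[, j] / table$x[j]
  }
  G <- table$Y
  term <- table$Y
  for (k in seq_len(n_terms)) {
    term <- A %*% term
    G <- G + term
  }
  flows <- matrix(0, R, R, dimnames = list(table$regions, table$regions))
  for (r in seq_len(R)) {
    rows <- ((r - 1) * S + 1):(r * S)
    for (s in seq_len(R)) {
      flows[r, s] <- sum(account$intensity[rows] * G[rows, s])
    }
  }
  flows
}

# hand-buildable 2-region, 1-sector economy with intermediate inputs
toy_two_region <- function() {
  A <- matrix(c(0.2, 0.1, 0.3, 0.2), 2, 2)
  Y <- matrix(c(10, 5, 2, 8), 2, 2)
  x <- solve(diag(2) - A, rowSums(Y))
  Z <- A %*% diag(x)
  table <- mrio_table(c("R01", "R02"), "s01", Z, Y, x)
  account <- emission_account(c(0.01, 0.05) * x, table)
  list(table = table, account = account, A = A, Y = Y, x = x)
}

# emission account with random intensities for a generated economy
random_account <- function(table) {
  emission_account(stats::rlnorm(length(table$x), log(1e-4), 0.5) * table$x,
                   table)
}

small_world_config <- function(seed = 7, trade_share = 0.3, n_regions = 5,
                               n_sectors = 2, grid = c(12, 24)) {
  world_config(n_regions = n_regions, n_sectors = n_sectors,
               grid_shape = grid, trade_share = trade_share,
               intensity_gap = 4, coastal_fraction = 0.5, seed = seed)
}
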