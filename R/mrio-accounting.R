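#' Technical coefficient matrix
#'
#' `A[i, j] = Z[i, j] / x[j]`: the input from (region, sector) row i needed
#' to produce one currency unit of output of column sector j. Columns with
#' zero gross output are all zero (an inactive sector demands nothing).
#'
#' @param table An `mrio_table`.
#' @return The (R*S) x (R*S) coefficient matrix.
#' @export
technical_coefficients <- function(table) {
  stopifnot(inherits(table, "mrio_table"))
  x <- table$x
  zero <- x == 0
  if (any(zero & colSums(table$Z) > 0)) {
    stop("inconsistent table: nonzero inputs into a sector with zero output",
         call. = FALSE)
  }
  denom <- ifelse(zero, 1, x)
  A <- sweep(table$Z, 2, denom, "/")
  A[, zero] <- 0
  A
}

#' Leontief inverse
#'
#' Solves `L = (I - A)^{-1}` by factorization. For nonnegative `A` with
#' spectral radius below one this is the convergent supply-chain series
#' `I + A + A^2 + ...`, so `L >= I` elementwise.
#'
#' @param A Nonnegative technical-coefficient matrix with spectral radius < 1.
#' @return The total-requirements matrix L.
#' @export
leontief_inverse <- function(A) {
  A <- as.matrix(A)
  if (nrow(A) != ncol(A)) stop("A must be square", call. = FALSE)
  if (any(A < 0)) stop("A must be nonnegative", call. = FALSE)
  rho <- spectral_radius(A)
  if (rho >= 1) {
    stop(sprintf("Leontief system not invertible: spectral radius %.4f >= 1", rho),
         call. = FALSE)
  }
  L <- solve(diag(nrow(A)) - A)
  # residual check guards against ill-conditioned near-unit spectral radius
  resid <- max(abs((diag(nrow(A)) - A) %*% L - diag(nrow(A))))
  if (resid > 1e-10 * max(1, max(abs(L)))) {
    stop(sprintf("Leontief solve residual %.3g too large (spectral radius %.4f)",
                 resid, rho), call. = FALSE)
  }
  L
}

spectral_radius <- function(A) {
  if (nrow(A) == 0) return(0)
  max(Mod(eigen(A, only.values = TRUE)$values))
}

#' Emissions embodied in final consumption, region by region
#'
#' Computes the full R x R embodied-flow matrix: entry (r, s) is the Hg
#' emitted by production in region r that is ultimately attributable to the
#' final consumption of region s, obtained by pushing region s's final
#' demand through the Leontief inverse and weighting by region r's emission
#' coefficients. The diagonal holds domestic footprints; row sums equal
#' production-based country totals and column sums consumption-based totals.
#'
#' @param account An `emission_account`.
#' @param table The matching `mrio_table`.
#' @return An R x R matrix of class `embodied_flows` (Mg/yr), regions as
#'   dimnames.
#' @export
embodied_flow_matrix <- function(account, table) {
  stopifnot(inherits(account, "emission_account"), inherits(table, "mrio_table"))
  if (!identical(account$regions, table$regions) ||
      !identical(account$sectors, table$sectors)) {
    stop("account and table use different region/sector classifications",
         call. = FALSE)
  }
  A <- technical_coefficients(table)
  L <- leontief_inverse(A)
  G <- L %*% table$Y                      # total output required per consuming region
  contrib <- account$intensity * G        # emissions per (producing row, consuming region)
  flows <- rowsum(contrib, region_of_rows(table), reorder = FALSE)
  dimnames(flows) <- list(table$regions, table$regions)
  class(flows) <- c("embodied_flows", class(flows))
  flows
}

#' Net embodied-emission transfers per region
#'
#' Production-based minus consumption-based totals: positive for net
#' exporters of embodied emissions (pollution produced for foreign
#' consumption), negative for net outsourcers. Sums to zero globally.
#'
#' @param flows An `embodied_flows` matrix.
#' @return Named vector of net transfers, Mg/yr.
#' @export
net_transfers <- function(flows) {
  flows <- validate_flows(flows)
  rowSums(flows) - colSums(flows)
}

#' Largest bilateral net flows of embodied emissions
#'
#' Pairwise net flow from r to s is `max(flows[r, s] - flows[s, r], 0)`
#' (emissions r produces for s's consumption beyond the reverse). Returns
#' the k largest strictly positive net flows, descending, ties broken by
#' (source, destination) label order.
#'
#' @param flows An `embodied_flows` matrix.
#' @param k Number of flows to return.
#' @return Data frame with columns `source`, `destination`, `net_flow`.
#' @export
top_net_flows <- function(flows, k) {
  flows <- validate_flows(flows)
  stopifnot(length(k) == 1, k >= 0)
  regions <- rownames(flows)
  net <- flows - t(flows)
  idx <- which(net > 0, arr.ind = TRUE)
  df <- data.frame(source = regions[idx[, 1]],
                   destination = regions[idx[, 2]],
                   net_flow = net[idx],
                   stringsAsFactors = FALSE)
  df <- df[order(-df$net_flow, df$source, df$destination), , drop = FALSE]
  df <- utils::head(df, k)
  rownames(df) <- NULL
  df
}

#' Share of emissions embodied in international trade
#'
#' Off-diagonal total of the embodied-flow matrix over its grand total:
#' the fraction of global emissions produced for consumption abroad.
#'
#' @param flows An `embodied_flows` matrix.
#' @return A fraction in `[0, 1]`.
#' @export
embodied_trade_share <- function(flows) {
  flows <- validate_flows(flows)
  total <- sum(flows)
  if (total <= 0) {
    stop("embodied trade share undefined for an all-zero flow matrix",
         call. = FALSE)
  }
  (total - sum(diag(flows))) / total
}

validate_flows <- function(flows) {
  flows <- as.matrix(flows)
  if (nrow(flows) != ncol(flows)) stop("flow matrix must be square", call. = FALSE)
  if (any(flows < 0)) stop("flow matrix must be nonnegative", call. = FALSE)
  if (is.null(rownames(flows))) {
    rownames(flows) <- colnames(flows) <- sprintf("R%02d", seq_len(nrow(flows)))
  }
  flows
}
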