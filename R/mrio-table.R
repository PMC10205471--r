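#' Multiregional input-output table
#'
#' Holds the economy used for consumption-based accounting: interindustry
#' flows `Z` ((R*S) x (R*S)), final demand `Y` ((R*S) x R, one column per
#' consuming region) and gross output `x` (length R*S), all in one currency
#' unit per year. Rows/columns are region-major: region 1's sectors first.
#' The accounting identity x_i = sum_j Z_ij + sum_s Y_is must hold.
#'
#' @param regions Character vector of region labels (length R).
#' @param sectors Character vector of sector labels (length S).
#' @param Z Interindustry flow matrix, (R*S) x (R*S), nonnegative.
#' @param Y Final demand matrix, (R*S) x R, nonnegative.
#' @param x Gross output vector, length R*S, nonnegative.
#' @param tol Relative tolerance for the balance check.
#' @return An object of class `mrio_table`.
#' @export
mrio_table <- function(regions, sectors, Z, Y, x, tol = 1e-8) {
  regions <- as.character(regions)
  sectors <- as.character(sectors)
  R <- length(regions)
  S <- length(sectors)
  RS <- R * S
  Z <- as.matrix(Z)
  Y <- as.matrix(Y)
  x <- as.numeric(x)
  if (!all(dim(Z) == c(RS, RS))) stop("Z must be (R*S) x (R*S)", call. = FALSE)
  if (!all(dim(Y) == c(RS, R))) stop("Y must be (R*S) x R", call. = FALSE)
  if (length(x) != RS) stop("x must have length R*S", call. = FALSE)
  if (any(Z < 0) || any(Y < 0) || any(x < 0)) {
    stop("Z, Y and x must be nonnegative", call. = FALSE)
  }
  supply <- rowSums(Z) + rowSums(Y)
  scale <- pmax(abs(x), 1)
  if (any(abs(supply - x) / scale > tol)) {
    stop("accounting identity violated: x must equal rowSums(Z) + rowSums(Y)",
         call. = FALSE)
  }
  labs <- sector_labels(regions, sectors)
  dimnames(Z) <- list(labs, labs)
  dimnames(Y) <- list(labs, regions)
  names(x) <- labs
  structure(list(regions = regions, sectors = sectors, Z = Z, Y = Y, x = x),
            class = "mrio_table")
}

#' @export
print.mrio_table <- function(x, ...) {
  cat(sprintf("<mrio_table> %d regions x %d sectors, gross output %.6g\n",
              length(x$regions), length(x$sectors), sum(x$x)))
  invisible(x)
}

# "REG:sector" labels in region-major order
sector_labels <- function(regions, sectors) {
  as.vector(t(outer(regions, sectors, paste, sep = ":")))
}

# region index (1..R) of each region-major row
region_of_rows <- function(table) {
  rep(seq_along(table$regions), each = length(table$sectors))
}

#' Sectoral emission account
#'
#' Production-based emissions per (region, sector) and the matching emission
#' coefficients (intensity = emissions per unit gross output, zero where
#' output is zero).
#'
#' @param pba Numeric vector of production-based emissions (Mg/yr), length
#'   R*S in region-major order, or an R x S matrix.
#' @param table The `mrio_table` supplying gross output and labels.
#' @return An object of class `emission_account` with elements `pba` and
#'   `intensity` (both length R*S named vectors), plus region/sector labels.
#' @export
emission_account <- function(pba, table) {
  stopifnot(inherits(table, "mrio_table"))
  if (is.matrix(pba)) pba <- as.vector(t(pba))
  pba <- as.numeric(pba)
  RS <- length(table$x)
  if (length(pba) != RS) {
    stop("pba must have one entry per (region, sector)", call. = FALSE)
  }
  if (any(pba < 0)) stop("pba must be nonnegative", call. = FALSE)
  if (any(pba > 0 & table$x == 0)) {
    stop("positive emissions from a sector with zero gross output", call. = FALSE)
  }
  intensity <- ifelse(table$x > 0, pba / table$x, 0)
  names(pba) <- names(table$x)
  names(intensity) <- names(table$x)
  structure(list(regions = table$regions, sectors = table$sectors,
                 pba = pba, intensity = intensity),
            class = "emission_account")
}

#' @export
print.emission_account <- function(x, ...) {
  cat(sprintf("<emission_account> %d regions x %d sectors, total PBA %.6g Mg/yr\n",
              length(x$regions), length(x$sectors), sum(x$pba)))
  invisible(x)
}

#' Per-country production-based totals of an emission account
#' @param account An `emission_account`.
#' @return Named vector (per region) of summed sectoral emissions, Mg/yr.
#' @export
pba_totals <- function(account) {
  stopifnot(inherits(account, "emission_account"))
  idx <- rep(seq_along(account$regions), each = length(account$sectors))
  tot <- as.vector(rowsum(account$pba, idx))
  names(tot) <- account$regions
  tot
}

#' Map source-resolved emissions onto MRIO sectors
#'
#' Applies a user-supplied many-to-one concordance from emission inventory
#' sources (e.g. fuel combustion, nonferrous smelting, waste burning) to the
#' MRIO sector classification, summing sources mapped to one sector. Sources
#' with no monetary output of their own (such as artisanal gold mining) are
#' handled through the same mapping: the caller decides which sector carries
#' them.
#'
#' @param emissions Data frame with columns `region`, `source`, `emissions`
#'   (Mg/yr).
#' @param mapping Data frame with columns `source`, `sector`; every source in
#'   `emissions` must appear exactly once.
#' @param regions,sectors Orderings for the output matrix.
#' @return R x S matrix of production-based emissions by (region, sector).
#' @export
aggregate_sources <- function(emissions, mapping, regions, sectors) {
  need <- setdiff(c("region", "source", "emissions"), names(emissions))
  if (length(need)) {
    stop("emissions is missing columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(mapping$source)) {
    stop("mapping must be many-to-one: duplicated source rows", call. = FALSE)
  }
  unmapped <- setdiff(unique(emissions$source), mapping$source)
  if (length(unmapped)) {
    stop("sources with no sector mapping: ", paste(unmapped, collapse = ", "),
         call. = FALSE)
  }
  sec <- mapping$sector[match(emissions$source, mapping$source)]
  bad <- setdiff(unique(sec), sectors)
  if (length(bad)) {
    stop("mapping targets unknown sectors: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  out <- matrix(0, length(regions), length(sectors),
                dimnames = list(regions, sectors))
  for (i in seq_len(nrow(emissions))) {
    out[emissions$region[i], sec[i]] <- out[emissions$region[i], sec[i]] +
      emissions$emissions[i]
  }
  out
}
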