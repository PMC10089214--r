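#' @keywords internal
"_PACKAGE"

# Shared validation helpers and the master-seed fan-out used by all
# stochastic stages.

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

assert_scalar_num <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stopf("'%s' must be a single finite number", name)
  if (x < lower || x > upper)
    stopf("'%s' must be in [%s, %s], got %s", name, lower, upper, x)
  invisible(x)
}

assert_count <- function(x, name, lower = 0) {
  assert_scalar_num(x, name, lower = lower)
  if (x != round(x)) stopf("'%s' must be an integer, got %s", name, x)
  invisible(as.integer(x))
}

#' Derive a child seed from a master seed
#'
#' All generators in the package draw their randomness from a single integer
#' master seed fanned out to per-stage child seeds by a fixed counter scheme,
#' so any stage can be regenerated independently of the others.
#'
#' @param master integer master seed.
#' @param k integer stage counter (>= 0).
#' @return an integer seed in \code{[1, 2^31 - 2]}.
#' @export
child_seed <- function(master, k) {
  master <- assert_count(master, "master")
  k <- assert_count(k, "k")
  # affine hash mod a Mersenne prime keeps children well inside 32-bit range
  s <- (as.numeric(master) * 48271 + as.numeric(k) * 104729) %% 2147483647
  as.integer(s) + 1L
}

# put two GRanges on the union of their seqlevels so pairwise operations
# never complain about disjoint Seqinfo
align_seqlevels <- function(a, b) {
  lev <- union(GenomeInfoDb::seqlevels(a), GenomeInfoDb::seqlevels(b))
  GenomeInfoDb::seqlevels(a) <- lev
  GenomeInfoDb::seqlevels(b) <- lev
  list(a = a, b = b)
}

# deterministic ordering helper: (chrom, start, end, name)
order_intervals <- function(chrom, start, end, name = NULL) {
  if (is.null(name)) order(chrom, start, end) else order(chrom, start, end, name)
}
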