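# Co-binding analysis of two peak sets: sub-kilobase co-bound calls,
# shared/unique (Venn-style) summaries with distance histograms,
# hypergeometric overlap significance, and the Mann-Whitney rank-sum test
# used to compare mark enrichment between co-bound and solo regions.

#' Classify peaks as co-bound or solo by nearest-partner distance
#'
#' For each region in \code{setA}, the distance to the nearest region of
#' \code{setB} is computed (edge gap by default, 0 on overlap); the region is
#' called \code{cobound} when that distance is strictly below
#' \code{max_dist} (the "< 1 kb proximity" rule), else \code{solo}.
#'
#' @param setA,setB \code{GRanges} peak sets.
#' @param max_dist co-binding distance threshold in bp (default 1000;
#'   strict \code{<}).
#' @param anchor \code{"edge"} (gap between closest edges) or
#'   \code{"midpoint"} (absolute midpoint-to-midpoint distance).
#' @return list with \code{calls} (data.frame: \code{distance},
#'   \code{partner_index}, \code{class}) and \code{fraction} (co-bound share
#'   of \code{setA}; 0 when \code{setA} is empty).
#' @export
classify_cobound <- function(setA, setB, max_dist = 1000,
                             anchor = c("edge", "midpoint")) {
  assert_count(max_dist, "max_dist")
  anchor <- match.arg(anchor)
  if (anchor == "edge") {
    nd <- nearest_distance(setA, setB)
  } else {
    # absolute midpoint-to-midpoint distance via a sorted neighbour scan
    midp <- function(gr)
      floor((GenomicRanges::start(gr) - 1 + GenomicRanges::end(gr)) / 2)
    mA <- midp(setA); mB <- midp(setB)
    chA <- as.character(GenomicRanges::seqnames(setA))
    chB <- as.character(GenomicRanges::seqnames(setB))
    nd <- data.frame(distance = rep(NA_real_, length(setA)),
                     subject_index = rep(NA_integer_, length(setA)))
    for (ch in unique(chA)) {
      jj <- which(chB == ch)
      if (!length(jj)) next
      o <- jj[order(mB[jj])]
      ii <- which(chA == ch)
      pos <- findInterval(mA[ii], mB[o])
      for (t in seq_along(ii)) {
        cand <- o[pmax(pmin(c(pos[t], pos[t] + 1L), length(o)), 1L)]
        d <- abs(mA[ii[t]] - mB[cand])
        best <- which.min(d)
        nd$distance[ii[t]] <- d[best]
        nd$subject_index[ii[t]] <- cand[best]
      }
    }
  }
  cls <- ifelse(!is.na(nd$distance) & nd$distance < max_dist, "cobound", "solo")
  calls <- data.frame(distance = nd$distance, partner_index = nd$subject_index,
                      class = factor(cls, levels = c("cobound", "solo")))
  frac <- if (length(setA)) mean(cls == "cobound") else 0
  list(calls = calls, fraction = frac)
}

#' Hypergeometric overlap test
#'
#' Upper-tail significance of observing \code{k} or more common elements
#' between a subset of size \code{K} and a subset of size \code{n} drawn
#' from a population of \code{N} (e.g. active enhancer/superenhancer domains
#' as the denominator, regions bound by each factor as the subsets).
#' Computed via the log-space hypergeometric tail, numerically stable for
#' large \code{N}.
#'
#' @param N population size.
#' @param K size of subset 1.
#' @param n size of subset 2.
#' @param k observed overlap.
#' @return an object of class \code{overlap_test}: list with \code{N, K, n,
#'   k}, \code{p_value} = P(X >= k), and \code{fold_enrichment} =
#'   \code{k / (K n / N)} (NA when the expectation is 0).
#' @export
hypergeometric_overlap <- function(N, K, n, k) {
  N <- assert_count(N, "N", lower = 0); K <- assert_count(K, "K")
  n <- assert_count(n, "n"); k <- assert_count(k, "k")
  if (K > N || n > N) stopf("K and n must not exceed N")
  if (k > min(K, n)) stopf("k must not exceed min(K, n)")
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  expect <- K * n / N
  structure(list(N = N, K = K, n = n, k = k, p_value = p,
                 fold_enrichment = if (expect > 0) k / expect else NA_real_),
            class = "overlap_test")
}

#' @export
print.overlap_test <- function(x, ...) {
  cat(sprintf(
    "overlap_test: k = %d of K = %d, n = %d, N = %d; fold %.3g; P(X >= k) = %.4g\n",
    x$k, x$K, x$n, x$N, x$fold_enrichment, x$p_value))
  invisible(x)
}

# exact rank-sum: enumerate all C(n+m, n) assignments of the pooled sample
# to the x role; returns the U distribution as (values, counts)
ranksum_exact_dist <- function(pooled, n) {
  idx <- utils::combn(length(pooled), n)
  r <- rank(pooled)            # midranks; ties handled naturally
  u <- colSums(matrix(r[idx], nrow = n)) - n * (n + 1) / 2
  u
}

#' Mann-Whitney rank-sum test
#'
#' U statistic for \code{x} versus \code{y} (number of (x, y) pairs with
#' x > y, ties counting 1/2).  For pooled sizes \code{n + m <= 12} the
#' p-value is exact, by enumeration of all \code{choose(n + m, n)} labelings
#' of the pooled sample (valid under ties); larger samples use the normal
#' approximation with tie and continuity corrections.
#'
#' @param x,y numeric samples (both nonempty).
#' @param alternative \code{"two_sided"}, \code{"greater"} (x tends larger)
#'   or \code{"less"}.
#' @param exact_max exact enumeration threshold on \code{n + m} (default 12).
#' @return list with \code{U}, \code{p_value}, \code{method} ("exact" or
#'   "normal_approx").
#' @export
rank_sum_test <- function(x, y, alternative = c("two_sided", "greater", "less"),
                          exact_max = 12) {
  alternative <- match.arg(alternative)
  if (length(x) == 0L || length(y) == 0L) stopf("both samples must be nonempty")
  if (any(!is.finite(c(x, y)))) stopf("samples must be finite")
  n <- length(x); m <- length(y)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  mu <- n * m / 2
  if (n + m <= exact_max) {
    u_all <- ranksum_exact_dist(c(x, y), n)
    p <- switch(alternative,
      greater = mean(u_all >= U),
      less = mean(u_all <= U),
      two_sided = mean(abs(u_all - mu) >= abs(U - mu) - 1e-9))
    return(list(U = U, p_value = p, method = "exact"))
  }
  N <- n + m
  ties <- table(c(x, y))
  sigma2 <- n * m / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  if (sigma2 <= 0)             # fully tied pooled sample
    return(list(U = U, p_value = 1, method = "normal_approx"))
  sd <- sqrt(sigma2)
  # upper tail with continuity correction plus an Edgeworth kurtosis term
  # (gamma2 of the no-tie U null), accurate to ~3e-3 at the exact boundary
  g2 <- -1.2 * (n^2 + m^2 + n * m + n + m) / (n * m * (N + 1))
  tailQ <- function(z)
    max(0, min(1, stats::pnorm(z, lower.tail = FALSE) +
                  g2 / 24 * (z^3 - 3 * z) * stats::dnorm(z)))
  p <- switch(alternative,
    greater = tailQ((U - mu - 0.5) / sd),
    less = tailQ((mu - U - 0.5) / sd),
    two_sided = min(1, 2 * tailQ((abs(U - mu) - 0.5) / sd)))
  list(U = U, p_value = p, method = "normal_approx")
}

#' Shared/unique region summary with distance histogram
#'
#' Groups regions of both sets into clusters (regions of either set within
#' \code{max_dist} of each other are merged) and counts clusters containing
#' both an A and a B region as shared; A-only and B-only counts are the
#' numbers of regions falling in single-set clusters, so that
#' \code{A_only + shared_A = |A|} (and symmetrically for B).  Also returns
#' the histogram of per-A-region nearest-B distances at the given bin edges
#' plus an overflow bin.
#'
#' @param setA,setB \code{GRanges}.
#' @param max_dist clustering/co-binding threshold in bp (default 1000).
#' @param breaks histogram bin edges in bp (default 0 to \code{max_dist} in
#'   10 bins).
#' @return list with \code{shared} (cluster count), \code{A_only},
#'   \code{B_only}, \code{shared_A}, \code{shared_B} (region counts), and
#'   \code{histogram} (data.frame \code{bin_start, bin_end, count}; last row
#'   is the overflow bin, unreachable distances excluded).
#' @export
overlap_summary <- function(setA, setB, max_dist = 1000, breaks = NULL) {
  assert_count(max_dist, "max_dist")
  if (is.null(breaks)) breaks <- seq(0, max_dist, length.out = 11L)
  al <- align_seqlevels(GenomicRanges::granges(setA),
                        GenomicRanges::granges(setB))
  pool <- c(al$a, al$b)
  origin <- rep(c("A", "B"), c(length(setA), length(setB)))
  shared <- 0L; sharedA <- 0L; sharedB <- 0L
  if (length(pool)) {
    # gap < max_dist clusters together, matching the strict co-bound rule
    clusters <- GenomicRanges::reduce(pool, min.gapwidth = max_dist,
                                      ignore.strand = TRUE)
    hits <- GenomicRanges::findOverlaps(pool, clusters, ignore.strand = TRUE)
    cl <- rep(NA_integer_, length(pool))
    cl[S4Vectors::queryHits(hits)] <- S4Vectors::subjectHits(hits)
    hasA <- tapply(origin == "A", cl, any)
    hasB <- tapply(origin == "B", cl, any)
    both <- names(hasA)[as.logical(hasA) & as.logical(hasB)]
    shared <- length(both)
    sharedA <- sum(origin == "A" & as.character(cl) %in% both)
    sharedB <- sum(origin == "B" & as.character(cl) %in% both)
  }
  d <- nearest_distance(setA, setB)$distance
  d <- d[!is.na(d)]
  counts <- if (length(breaks) >= 2L)
    as.integer(table(cut(d, breaks = c(breaks, Inf), right = FALSE)))
  else integer(0)
  hist <- data.frame(bin_start = breaks,
                     bin_end = c(breaks[-1L], Inf),
                     count = counts[seq_along(breaks)])
  list(shared = shared,
       A_only = length(setA) - sharedA, B_only = length(setB) - sharedB,
       shared_A = sharedA, shared_B = sharedB,
       histogram = hist)
}
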