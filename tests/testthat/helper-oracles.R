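# Fixture builders and independent brute-force oracles.  Every oracle here
# recomputes its quantity by a different route than the package (all-pairs
# scans, exhaustive enumeration, direct iteration) so agreement is evidence,
# not tautology.

# GRanges from 0-based half-open coordinates (the BED convention used in
# the on-disk formats), convenient for writing tests against edge gaps
gr0 <- function(chrom, start0, end0, strand = "*", ...) {
  GenomicRanges::GRanges(chrom,
                         IRanges::IRanges(start0 + 1L, end0),
                         strand = strand, ...)
}

df0 <- function(gr) {
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start0 = GenomicRanges::start(gr) - 1L,
             end0 = GenomicRanges::end(gr))
}

random_intervals <- function(n, n_chroms = 2, span = 1e5, max_w = 500) {
  chrom <- sample(paste0("chr", seq_len(n_chroms)), n, replace = TRUE)
  s <- sample.int(span, n, replace = TRUE)
  w <- sample.int(max_w, n, replace = TRUE)
  gr0(chrom, s, s + w)
}

# stitching oracle 1: plane-sweep on intervals sorted by start; a new
# cluster opens where the start exceeds the running max end + gap
sweep_merge <- function(chrom, start0, end0, gap) {
  out <- lapply(split(seq_along(chrom), chrom), function(i) {
    o <- order(start0[i], end0[i])
    s <- start0[i][o]; e <- end0[i][o]
    run_max <- cummax(e)
    brk <- c(TRUE, s[-1] > run_max[-length(run_max)] + gap)
    cl <- cumsum(brk)
    data.frame(chrom = chrom[i][1L],
               start0 = tapply(s, cl, min), end0 = tapply(e, cl, max),
               n = tabulate(cl))
  })
  out <- do.call(rbind, out)
  out[order(out$chrom, out$start0), , drop = FALSE]
}

# stitching oracle 2: all-pairs adjacency + union-find (independent of any
# sorting argument); only for small n
unionfind_merge <- function(chrom, start0, end0, gap) {
  n <- length(chrom)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j && chrom[i] == chrom[j]) {
      g <- max(start0[i], start0[j]) - min(end0[i], end0[j])
      if (g <= gap) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  out <- do.call(rbind, lapply(split(seq_len(n), root), function(i)
    data.frame(chrom = chrom[i][1L], start0 = min(start0[i]),
               end0 = max(end0[i]), n = length(i))))
  out[order(out$chrom, out$start0), , drop = FALSE]
}

# nearest-distance oracle: exhaustive pairwise edge-gap scan
brute_nearest <- function(q, s) {
  qd <- df0(q); sd <- df0(s)
  vapply(seq_len(nrow(qd)), function(i) {
    j <- which(sd$chrom == qd$chrom[i])
    if (!length(j)) return(NA_real_)
    gaps <- pmax(pmax(qd$start0[i], sd$start0[j]) -
                 pmin(qd$end0[i], sd$end0[j]), 0)
    min(gaps)
  }, numeric(1))
}

# hypergeometric upper tail by exhaustive enumeration of all C(N, n) draws
enum_hyper_tail <- function(N, K, n, k) {
  if (n == 0) return(if (k == 0) 1 else 0)
  draws <- utils::combn(N, n)
  overlap <- colSums(draws <= K)   # subset 1 = elements 1..K
  mean(overlap >= k)
}

# BH step-up recomputed literally from its definition
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    r <- which(o == i)               # rank of p[i]
    q[i] <- min(1, min(m / seq(r, m) * p[o][seq(r, m)]))
  }
  q
}

# rank-sum U by direct pair counting (no midrank formula)
brute_U <- function(x, y) {
  sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
}

# GSEA running sum recomputed by direct per-position iteration; same
# declared tie rule as the package (first extremum wins on a magnitude tie)
brute_es <- function(genes, scores, set, p) {
  N <- length(genes)
  hit <- genes %in% set
  tw <- sum(abs(scores[hit])^p)
  run <- numeric(N); cur <- 0
  for (i in seq_len(N)) {
    if (hit[i]) {
      cur <- cur + (if (tw > 0) abs(scores[i])^p / tw else 1 / sum(hit))
    } else {
      cur <- cur - 1 / (N - sum(hit))
    }
    run[i] <- cur
  }
  imax <- which.max(run); imin <- which.min(run)
  mx <- run[imax]; mn <- run[imin]
  if (abs(mx + mn) <= 1e-12 * max(1, abs(mx))) run[min(imax, imin)]
  else if (mx > -mn) mx else mn
}

# UPGMA agglomeration by direct exhaustive merging on a distance matrix
brute_upgma_heights <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  while (length(clusters) > 1L) {
    best <- c(NA, NA); bh <- Inf
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (i < j) {
        h <- mean(d[clusters[[i]], clusters[[j]]])
        if (h < bh) { bh <- h; best <- c(i, j) }
      }
    }
    heights <- c(heights, bh)
    clusters[[best[1L]]] <- c(clusters[[best[1L]]], clusters[[best[2L]]])
    clusters[[best[2L]]] <- NULL
  }
  heights
}

toy_gene_models <- function(chrom = "chr1", tss0 = 10000, strand = "+",
                            span = 5000, id = "geneA", biotype = "protein_coding") {
  # build a gene_models row from a 0-based TSS
  n <- length(tss0)
  chrom <- rep_len(chrom, n); strand <- rep_len(strand, n)
  span <- rep_len(span, n); biotype <- rep_len(biotype, n)
  start1 <- ifelse(strand == "+", tss0 + 1L, tss0 + 1L - span + 1L)
  end1 <- ifelse(strand == "+", tss0 + span, tss0 + 1L)
  g <- data.frame(gene_id = id, symbol = id, chrom = chrom, strand = strand,
                  start = as.integer(start1), end = as.integer(end1),
                  biotype = biotype, length = as.integer(span),
                  stringsAsFactors = FALSE)
  g$tss <- ifelse(g$strand == "+", g$start, g$end)
  class(g) <- c("gene_models", "data.frame")
  g
}

# constant-value track covering [0, len) on each chromosome
const_track <- function(value = 1, len = 1e5, chroms = "chr1",
                        total_reads = NULL) {
  gr <- gr0(chroms, rep(0, length(chroms)), rep(len, length(chroms)),
            score = value)
  signal_track(gr, total_reads)
}
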