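# RNA-seq stage: gene sanitization filters, TPM, median-of-ratios size
# factors, a simplified two-group negative-binomial Wald test (method-of-
# moments dispersion, no shrinkage), BH correction, the FDR/fold-change
# signature call, top-SD hierarchical sample clustering, and ortholog
# mapping for cross-species signature tracking.

#' Build a count-matrix container
#'
#' Wraps a genes x samples integer count matrix, per-gene metadata and
#' per-sample group labels into a \code{SummarizedExperiment}, the standard
#' Bioconductor container consumed by every expression-stage function here.
#'
#' @param counts integer matrix (genes x samples), row names = gene ids.
#' @param gene_meta data.frame with columns \code{gene_id, symbol, biotype,
#'   chrom, length}, one row per count row.
#' @param groups character/factor of per-sample group labels.
#' @return a \code{SummarizedExperiment} with assay \code{"counts"}.
#' @export
count_matrix <- function(counts, gene_meta, groups) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts)))
    stopf("counts must be non-negative integers")
  need <- c("gene_id", "symbol", "biotype", "chrom", "length")
  miss <- setdiff(need, names(gene_meta))
  if (length(miss)) stopf("gene_meta missing columns: %s", paste(miss, collapse = ", "))
  if (nrow(gene_meta) != nrow(counts))
    stopf("gene_meta rows (%d) != count rows (%d)", nrow(gene_meta), nrow(counts))
  if (length(groups) != ncol(counts))
    stopf("groups length (%d) != sample count (%d)", length(groups), ncol(counts))
  rownames(counts) <- gene_meta$gene_id
  SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts),
    rowData = gene_meta,
    colData = S4Vectors::DataFrame(group = as.character(groups),
                                   row.names = colnames(counts)))
}

#' Read a count TSV into a count-matrix container
#'
#' Expects a header of sample names with the first column holding gene ids.
#'
#' @param path count TSV path.
#' @param gene_meta per-gene metadata (matched to the TSV by \code{gene_id};
#'   all TSV genes must be present).
#' @param groups per-sample group labels in TSV column order.
#' @return a \code{SummarizedExperiment}.
#' @export
read_counts <- function(path, gene_meta, groups) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  ids <- df[[1L]]
  mat <- as.matrix(df[, -1L, drop = FALSE])
  rownames(mat) <- ids
  meta <- gene_meta[match(ids, gene_meta$gene_id), , drop = FALSE]
  if (anyNA(meta$gene_id))
    stopf("%s: %d gene ids missing from gene_meta", path, sum(is.na(meta$gene_id)))
  count_matrix(mat, meta, groups)
}

#' Write a count-matrix container as TSV
#' @param se a \code{SummarizedExperiment} with assay \code{"counts"}.
#' @param path output path.
#' @export
write_counts <- function(se, path) {
  mat <- SummarizedExperiment::assay(se, "counts")
  df <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Remove unwanted gene classes before expression analysis
#'
#' Reference-sanitization filters: drop genes by biotype class (e.g. rRNA,
#' miRNA, pseudogene, antisense, read-through), by chromosome (e.g. chrY),
#' by explicit gene-id list (e.g. imprinted chrX genes), and by symbol regex
#' (e.g. immunoglobulin V/D/J segments).  A gene is removed if it matches
#' any rule; the report attributes each removal to the first matching rule.
#'
#' @param se a \code{SummarizedExperiment} from \code{\link{count_matrix}}.
#' @param drop_biotypes character vector of biotypes to remove.
#' @param drop_chroms character vector of chromosomes to remove.
#' @param drop_gene_ids explicit gene ids to remove.
#' @param drop_symbol_regex optional regex on gene symbols.
#' @return list with \code{se} (filtered) and \code{report} (named removal
#'   counts per rule plus \code{retained}).
#' @export
filter_genes <- function(se, drop_biotypes = character(),
                         drop_chroms = character(),
                         drop_gene_ids = character(),
                         drop_symbol_regex = NULL) {
  rd <- as.data.frame(SummarizedExperiment::rowData(se))
  by_bio <- rd$biotype %in% drop_biotypes
  by_chr <- rd$chrom %in% drop_chroms
  by_id <- rd$gene_id %in% drop_gene_ids
  by_sym <- if (!is.null(drop_symbol_regex)) grepl(drop_symbol_regex, rd$symbol)
            else rep(FALSE, nrow(rd))
  first <- ifelse(by_bio, "biotype",
           ifelse(by_chr, "chrom",
           ifelse(by_id, "gene_id",
           ifelse(by_sym, "symbol_regex", "kept"))))
  drop <- first != "kept"
  report <- c(biotype = sum(first == "biotype"), chrom = sum(first == "chrom"),
              gene_id = sum(first == "gene_id"),
              symbol_regex = sum(first == "symbol_regex"),
              retained = sum(!drop))
  list(se = se[!drop, ], report = report)
}

#' TPM normalization
#'
#' Per sample: \code{rate_g = count_g / length_kb_g}; \code{TPM_g = rate_g *
#' 1e6 / sum(rates)}.  Columns of the result sum to 1e6 except for all-zero
#' samples, which stay zero with a warning.
#'
#' @param se a \code{SummarizedExperiment}; \code{rowData} must carry
#'   positive gene \code{length}s (bp).
#' @return genes x samples numeric matrix of TPM values.
#' @export
tpm_normalize <- function(se) {
  counts <- SummarizedExperiment::assay(se, "counts")
  len <- SummarizedExperiment::rowData(se)$length
  if (any(is.na(len) | len <= 0)) stopf("all gene lengths must be > 0")
  rate <- counts / (len / 1000)
  tot <- colSums(rate)
  if (any(tot == 0)) warnf("%d all-zero sample(s); TPM left at 0", sum(tot == 0))
  tot[tot == 0] <- 1
  sweep(rate, 2L, tot, "/") * 1e6
}

#' Median-of-ratios size factors
#'
#' For genes with nonzero counts in every sample, each sample's factor is
#' the median ratio of its counts to the per-gene geometric means, the
#' standard count-normalization for NB differential expression.
#'
#' @param counts integer matrix (genes x samples) or a
#'   \code{SummarizedExperiment}.
#' @return numeric vector of positive per-sample factors (unscaled).
#' @export
size_factors <- function(counts) {
  if (methods::is(counts, "SummarizedExperiment"))
    counts <- SummarizedExperiment::assay(counts, "counts")
  lc <- log(counts)
  ok <- rowSums(is.finite(lc)) == ncol(counts)
  if (!any(ok))
    stopf("no gene has nonzero counts in all samples; add a pseudocount or filter")
  lgeo <- rowMeans(lc[ok, , drop = FALSE])
  apply(lc[ok, , drop = FALSE], 2L, function(col) exp(stats::median(col - lgeo)))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment, \code{q_i = min_{j >= rank(i)} (m / j) p_(j)}
#' capped at 1, order-preserving with the input indexing.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return numeric vector of q-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (anyNA(p) || any(p < 0) || any(p > 1))
    stopf("p-values must lie in [0, 1] with no NA")
  stats::p.adjust(p, method = "BH")
}

#' Two-group negative-binomial Wald test
#'
#' A simplified NB differential-expression test: counts are normalized by
#' median-of-ratios size factors; per-gene dispersion is estimated by the
#' method of moments on normalized counts within each group (pooled across
#' groups with degrees-of-freedom weights, floored at 1e-8, or fixed);
#' \code{log2_fc} compares group means (group2 vs group1), with a
#' configurable pseudo-mean replacing an all-zero group mean; the Wald
#' statistic is \code{log2_fc / se} with the delta-method standard error,
#' and p-values are two-sided normal.  No dispersion shrinkage, LFC
#' shrinkage or independent filtering is applied.
#'
#' @param se a \code{SummarizedExperiment} with a \code{group} column.
#' @param group1,group2 group labels to contrast (fold changes are
#'   group2 / group1).
#' @param dispersion_mode \code{"moments"} or \code{"fixed"}.
#' @param dispersion_fixed dispersion used when \code{dispersion_mode =
#'   "fixed"}.
#' @param pseudo_mean normalized-count mean substituted for an all-zero
#'   group (default 0.125); such genes are flagged.
#' @return a \code{data.frame} of class \code{de_result}: per gene
#'   \code{gene_id, base_mean, log2_fc, se, wald, p, q, zero_group}.
#' @export
nb_wald_test <- function(se, group1, group2,
                         dispersion_mode = c("moments", "fixed"),
                         dispersion_fixed = 0.1, pseudo_mean = 0.125) {
  dispersion_mode <- match.arg(dispersion_mode)
  grp <- SummarizedExperiment::colData(se)$group
  i1 <- which(grp == group1); i2 <- which(grp == group2)
  if (length(i1) < 2L || length(i2) < 2L)
    stopf("each group needs >= 2 samples (got %d and %d)", length(i1), length(i2))
  counts <- SummarizedExperiment::assay(se, "counts")[, c(i1, i2), drop = FALSE]
  sf <- size_factors(counts)
  norm <- sweep(counts, 2L, sf, "/")
  n1 <- length(i1); n2 <- length(i2)
  c1 <- seq_len(n1); c2 <- n1 + seq_len(n2)
  mu1 <- rowMeans(norm[, c1, drop = FALSE])
  mu2 <- rowMeans(norm[, c2, drop = FALSE])
  v1 <- apply(norm[, c1, drop = FALSE], 1L, stats::var)
  v2 <- apply(norm[, c2, drop = FALSE], 1L, stats::var)
  if (dispersion_mode == "fixed") {
    alpha <- rep(dispersion_fixed, nrow(counts))
  } else {
    a1 <- ifelse(mu1 > 0, (v1 - mu1) / mu1^2, NA_real_)
    a2 <- ifelse(mu2 > 0, (v2 - mu2) / mu2^2, NA_real_)
    w1 <- ifelse(is.na(a1), 0, n1 - 1); w2 <- ifelse(is.na(a2), 0, n2 - 1)
    a1[is.na(a1)] <- 0; a2[is.na(a2)] <- 0
    denom <- pmax(w1 + w2, 1)
    alpha <- (w1 * a1 + w2 * a2) / denom
  }
  alpha <- pmax(alpha, 1e-8)
  zero_group <- mu1 == 0 | mu2 == 0
  m1 <- ifelse(mu1 == 0, pseudo_mean, mu1)
  m2 <- ifelse(mu2 == 0, pseudo_mean, mu2)
  log2_fc <- log2(m2 / m1)
  # Var(mean of normalized counts) under NB: (1/n^2) sum_j (mu/s_j + alpha mu^2)
  vm1 <- (m1 * sum(1 / sf[c1]) + n1 * alpha * m1^2) / n1^2
  vm2 <- (m2 * sum(1 / sf[c2]) + n2 * alpha * m2^2) / n2^2
  se_lfc <- sqrt(vm1 / m1^2 + vm2 / m2^2) / log(2)
  wald <- ifelse(se_lfc > 0, log2_fc / se_lfc, 0)
  p <- 2 * stats::pnorm(-abs(wald))
  out <- data.frame(gene_id = rownames(counts),
                    base_mean = rowMeans(norm),
                    log2_fc = log2_fc, se = se_lfc, wald = wald,
                    p = p, q = bh_adjust(p), zero_group = zero_group,
                    stringsAsFactors = FALSE)
  attr(out, "contrast") <- c(group1 = group1, group2 = group2)
  class(out) <- c("de_result", "data.frame")
  out
}

#' @export
print.de_result <- function(x, ...) {
  ct <- attr(x, "contrast")
  cat(sprintf("de_result: %d genes, contrast %s vs %s\n", nrow(x),
              ct[["group2"]], ct[["group1"]]))
  if (!is.null(x$called))
    cat(sprintf("  called: %d up, %d down\n",
                sum(x$called & x$direction == "up"),
                sum(x$called & x$direction == "down")))
  invisible(x)
}

#' Call a differential-expression signature
#'
#' A gene is called when \code{q < fdr} and its linear fold change satisfies
#' \code{|FC| >= min_fc}; direction follows the sign of \code{log2_fc}.
#'
#' @param results a \code{de_result} from \code{\link{nb_wald_test}}.
#' @param fdr BH q-value threshold (default 0.05, strict \code{<}).
#' @param min_fc linear fold-change threshold (default 1.2; applied as
#'   \code{2^|log2_fc| >= min_fc}).
#' @return list with \code{up} and \code{down} gene-id vectors (disjoint)
#'   and \code{results} (input plus \code{called} and \code{direction}).
#' @export
call_de <- function(results, fdr = 0.05, min_fc = 1.2) {
  assert_scalar_num(fdr, "fdr", lower = 0, upper = 1)
  assert_scalar_num(min_fc, "min_fc", lower = 1)
  called <- results$q < fdr & 2^abs(results$log2_fc) >= min_fc
  direction <- ifelse(!called, "ns", ifelse(results$log2_fc > 0, "up", "down"))
  results$called <- called
  results$direction <- factor(direction, levels = c("up", "down", "ns"))
  list(up = results$gene_id[called & direction == "up"],
       down = results$gene_id[called & direction == "down"],
       results = results)
}

#' Unsupervised sample clustering on top-variance genes
#'
#' Ranks genes by standard deviation across samples, keeps the top
#' \code{top_n}, and clusters samples by average-linkage (UPGMA)
#' agglomeration of the \code{1 - Pearson r} distance.  Constant gene rows
#' (undefined correlation contribution) are removed with a warning.
#'
#' @param expr numeric genes x samples matrix (e.g. TPM).
#' @param top_n number of highest-SD genes to keep (default 500).
#' @return list with \code{hclust} (the merge tree), \code{order} (sample
#'   ordering), \code{genes_used} (row indices or names kept).
#' @export
cluster_samples <- function(expr, top_n = 500) {
  if (ncol(expr) < 2L) stopf("need >= 2 samples to cluster")
  top_n <- assert_count(top_n, "top_n", lower = 1)
  sds <- apply(expr, 1L, stats::sd)
  keep <- order(sds, decreasing = TRUE)[seq_len(min(top_n, nrow(expr)))]
  sub <- expr[keep, , drop = FALSE]
  const <- apply(sub, 1L, stats::sd) == 0
  if (any(const)) {
    warnf("removed %d constant gene row(s) before correlation", sum(const))
    sub <- sub[!const, , drop = FALSE]
  }
  d <- stats::as.dist(1 - stats::cor(sub, method = "pearson"))
  hc <- stats::hclust(d, method = "average")
  list(hclust = hc, order = hc$order,
       genes_used = if (!is.null(rownames(expr))) rownames(expr)[keep] else keep)
}

#' Map genes across species through an ortholog table
#'
#' @param genes character vector of source-species gene identifiers.
#' @param mapping two-column data.frame (source, target).
#' @param policy \code{"keep_all"} emits every target of a 1:many source;
#'   \code{"first"} keeps the first listed target only.
#' @return list with \code{mapped} (unique targets, first-occurrence order)
#'   and \code{unmapped} (source genes absent from the table).
#' @export
map_orthologs <- function(genes, mapping, policy = c("keep_all", "first")) {
  policy <- match.arg(policy)
  if (ncol(mapping) < 2L) stopf("mapping needs two columns (source, target)")
  src <- as.character(mapping[[1L]]); tgt <- as.character(mapping[[2L]])
  if (policy == "first") {
    keep <- !duplicated(src)
    src <- src[keep]; tgt <- tgt[keep]
  }
  hits <- src %in% genes
  ord <- order(match(src[hits], genes))
  mapped <- unique(tgt[hits][ord])
  list(mapped = mapped, unmapped = setdiff(genes, src))
}
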