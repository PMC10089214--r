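# From-scratch preranked gene-set enrichment: weighted Kolmogorov-Smirnov
# running-sum enrichment score, size-matched permutation null, NES, FDR and
# leading edge.  Drives signature tests against external rankings.

#' Build a ranked gene list
#'
#' Orders (gene, score) pairs by descending score, ties broken by gene name;
#' duplicate genes are an error.
#'
#' @param genes character vector of unique gene identifiers.
#' @param scores numeric ranking metric (e.g. a Wald statistic).
#' @return a \code{data.frame} of class \code{ranked_list} with columns
#'   \code{gene}, \code{score}.
#' @export
ranked_list <- function(genes, scores) {
  if (length(genes) != length(scores)) stopf("genes and scores differ in length")
  if (anyDuplicated(genes)) stopf("duplicate gene in ranking: %s",
                                  genes[duplicated(genes)][1L])
  if (any(!is.finite(scores))) stopf("ranking scores must be finite")
  ord <- order(-scores, genes)
  out <- data.frame(gene = as.character(genes)[ord], score = scores[ord],
                    stringsAsFactors = FALSE)
  class(out) <- c("ranked_list", "data.frame")
  out
}

#' Read / write GMT gene-set collections
#'
#' GMT is tab-separated: set name, description, then member genes.  Members
#' are de-duplicated within each set on read.
#'
#' @param path GMT file path.
#' @return named list of character vectors (gene sets).
#' @export
read_gmt <- function(path) {
  body <- read_body_lines(path)
  sets <- lapply(strsplit(body$lines, "\t", fixed = TRUE), function(f) {
    if (length(f) < 3L)
      stopf("%s: GMT lines need name, description and >= 1 member", path)
    unique(f[-c(1L, 2L)])
  })
  names(sets) <- vapply(strsplit(body$lines, "\t", fixed = TRUE), `[`,
                        character(1), 1L)
  sets
}

#' @rdname read_gmt
#' @param collection named list of character vectors.
#' @param descriptions optional character vector of set descriptions.
#' @export
write_gmt <- function(collection, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(collection))
  lines <- vapply(seq_along(collection), function(i)
    paste(c(names(collection)[i], descriptions[i], collection[[i]]),
          collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

# core running-sum computation from hit positions; scores must be the
# ranking metric in ranked order.  Returns list(es, peak, running).
es_core <- function(scores, hit_pos, weight_p, keep_running = FALSE) {
  N <- length(scores)
  nh <- length(hit_pos)
  w <- abs(scores[hit_pos])^weight_p
  tw <- sum(w)
  if (tw == 0) { w <- rep(1, nh); tw <- nh }   # all-zero weights: unweighted
  inc <- numeric(N)
  inc[hit_pos] <- w / tw
  dec <- 1 / (N - nh)
  step <- inc
  step[-hit_pos] <- -dec
  running <- cumsum(step)
  imax <- which.max(running); imin <- which.min(running)
  mx <- running[imax]; mn <- running[imin]
  # maximal absolute deviation; on a |max| == |min| tie (to within fp noise)
  # the extremum reached first wins, so the sign is set by the first deviation
  peak <- if (abs(mx + mn) <= 1e-12 * max(1, abs(mx))) {
    min(imax, imin)
  } else if (mx > -mn) imax else imin
  list(es = running[peak], peak = peak,
       running = if (keep_running) running else NULL)
}

#' Weighted KS enrichment score of a gene set in a ranking
#'
#' Walks the ranking from top to bottom, incrementing by
#' \code{|score|^p / sum_hits |score|^p} at set members ("hits") and
#' decrementing by \code{1 / (N - N_hits)} at non-members.  The enrichment
#' score (ES) is the running-sum value of maximal absolute deviation from
#' zero (sign retained); the leading edge contains the hits at or before the
#' extremum (at or after it, for negative ES).
#'
#' @param ranked a \code{ranked_list}.
#' @param set character vector of member genes.
#' @param weight_p score weighting exponent (0 = unweighted KS, 1 =
#'   standard weighted statistic, 2 = over-weighted).
#' @return list with \code{es}, \code{running} (length-N running sum),
#'   \code{leading_edge} (character), \code{n_hits}.
#' @export
enrichment_score <- function(ranked, set, weight_p = 1) {
  assert_scalar_num(weight_p, "weight_p", lower = 0)
  hit <- ranked$gene %in% set
  nh <- sum(hit)
  if (nh == 0L) stopf("gene set has no member in the ranking")
  if (nh == nrow(ranked)) stopf("gene set covers the whole ranking")
  core <- es_core(ranked$score, which(hit), weight_p, keep_running = TRUE)
  le <- if (core$es >= 0) ranked$gene[hit & seq_len(nrow(ranked)) <= core$peak]
        else ranked$gene[hit & seq_len(nrow(ranked)) >= core$peak]
  list(es = core$es, running = core$running, leading_edge = le, n_hits = nh)
}

#' Preranked GSEA with a size-matched permutation null
#'
#' For each set, the observed ES is compared against \code{n_perm} ES values
#' of random gene sets of the same size drawn from the ranking (gene-label
#' permutation, seeded).  The permutation p-value is magnitude-based with
#' add-one smoothing, \code{p = (1 + #\{|ES_null| >= |ES|\}) / (n_perm + 1)},
#' so it is uniform under the null and its minimum attainable value is
#' \code{1 / (n_perm + 1)}.  NES divides the ES by the mean |null ES| of
#' matching sign, and FDR q follows the sign-stratified ratio-of-tails
#' scheme over the pooled null NES distribution.  Sets with no gene in the
#' ranking are skipped with a warning.
#'
#' @param ranked a \code{ranked_list}.
#' @param collection named list of gene sets.
#' @param n_perm number of permutations (>= 100; default 1000).
#' @param seed integer seed (required: results are deterministic given it).
#' @param weight_p score weighting exponent (default 1).
#' @return a \code{data.frame} ordered by decreasing NES: \code{set, n_hits,
#'   es, nes, p_perm, q_fdr, leading_edge} (comma-joined).
#' @export
preranked_gsea <- function(ranked, collection, n_perm = 1000, seed,
                           weight_p = 1) {
  n_perm <- assert_count(n_perm, "n_perm", lower = 100)
  if (missing(seed)) stopf("a seed is required for the permutation null")
  seed <- assert_count(seed, "seed")
  N <- nrow(ranked)
  keep <- vapply(collection, function(s) {
    nh <- sum(ranked$gene %in% s)
    nh > 0L && nh < N
  }, logical(1))
  if (any(!keep))
    warnf("skipping %d set(s) with no usable overlap with the ranking",
          sum(!keep))
  collection <- collection[keep]
  if (length(collection) == 0L)
    return(data.frame(set = character(0), n_hits = integer(0), es = numeric(0),
                      nes = numeric(0), p_perm = numeric(0),
                      q_fdr = numeric(0), leading_edge = character(0)))
  sizes <- vapply(collection, function(s) sum(ranked$gene %in% s), integer(1))
  set.seed(seed)
  # one null matrix per distinct set size, shared across same-size sets
  null_by_size <- lapply(sort(unique(sizes)), function(nh) {
    vapply(seq_len(n_perm), function(b)
      es_core(ranked$score, sort(sample.int(N, nh)), weight_p)$es, numeric(1))
  })
  names(null_by_size) <- as.character(sort(unique(sizes)))

  rows <- lapply(seq_along(collection), function(i) {
    obs <- enrichment_score(ranked, collection[[i]], weight_p)
    null <- null_by_size[[as.character(obs$n_hits)]]
    p <- (1 + sum(abs(null) >= abs(obs$es))) / (n_perm + 1)
    same <- if (obs$es >= 0) null[null >= 0] else null[null < 0]
    denom <- mean(abs(same))
    nes <- if (length(same) && denom > 0) obs$es / denom else NA_real_
    null_nes_pos <- null[null >= 0] / max(mean(null[null >= 0]), .Machine$double.eps)
    null_nes_neg <- null[null < 0] / max(mean(abs(null[null < 0])), .Machine$double.eps)
    list(set = names(collection)[i], n_hits = obs$n_hits, es = obs$es,
         nes = nes, p_perm = p,
         leading_edge = paste(obs$leading_edge, collapse = ","),
         null_nes = if (obs$es >= 0) null_nes_pos else null_nes_neg)
  })
  df <- data.frame(set = vapply(rows, `[[`, character(1), "set"),
                   n_hits = vapply(rows, `[[`, integer(1), "n_hits"),
                   es = vapply(rows, `[[`, numeric(1), "es"),
                   nes = vapply(rows, `[[`, numeric(1), "nes"),
                   p_perm = vapply(rows, `[[`, numeric(1), "p_perm"),
                   leading_edge = vapply(rows, `[[`, character(1), "leading_edge"),
                   stringsAsFactors = FALSE)
  # sign-stratified ratio-of-tails FDR over the pooled null NES
  pos_null <- unlist(lapply(rows, function(r) r$null_nes[r$null_nes >= 0]))
  neg_null <- unlist(lapply(rows, function(r) r$null_nes[r$null_nes < 0]))
  df$q_fdr <- vapply(seq_len(nrow(df)), function(i) {
    nes <- df$nes[i]
    if (is.na(nes)) return(NA_real_)
    if (nes >= 0) {
      num <- if (length(pos_null)) mean(pos_null >= nes) else 0
      den <- mean(df$nes >= nes, na.rm = TRUE)
    } else {
      num <- if (length(neg_null)) mean(neg_null <= nes) else 0
      den <- mean(df$nes <= nes, na.rm = TRUE)
    }
    min(1, if (den > 0) num / den else 1)
  }, numeric(1))
  df <- df[order(-df$nes), c("set", "n_hits", "es", "nes", "p_perm", "q_fdr",
                             "leading_edge")]
  rownames(df) <- NULL
  df
}

#' Run a panel of signatures against one ranking
#'
#' Wraps \code{\link{preranked_gsea}} and flags each set as significantly
#' enriched (\code{q_fdr < alpha}) with its direction, the summary used for
#' signature-panel overlays.
#'
#' @inheritParams preranked_gsea
#' @param alpha FDR significance threshold (default 0.05).
#' @return the \code{preranked_gsea} table plus \code{significant}
#'   (logical) and \code{direction} (\code{"up"}/\code{"down"}).
#' @export
run_signature_panel <- function(ranked, collection, alpha = 0.05,
                                n_perm = 1000, seed, weight_p = 1) {
  assert_scalar_num(alpha, "alpha", lower = 0, upper = 1)
  df <- preranked_gsea(ranked, collection, n_perm = n_perm, seed = seed,
                       weight_p = weight_p)
  df$significant <- !is.na(df$q_fdr) & df$q_fdr < alpha
  df$direction <- ifelse(df$es >= 0, "up", "down")
  df
}

#' Build a gene-set signature from called DE results
#'
#' @param de output of \code{\link{call_de}} (list with \code{results}).
#' @param direction \code{"up"} or \code{"down"}.
#' @param name optional set name; defaults to contrast + direction.
#' @return named list of length 1 (a one-set collection), possibly empty
#'   with a warning.
#' @export
make_signature <- function(de, direction = c("up", "down"), name = NULL) {
  direction <- match.arg(direction)
  members <- de[[direction]]
  if (is.null(name)) {
    ct <- attr(de$results, "contrast")
    name <- paste(ct[["group2"]], "vs", ct[["group1"]], direction, sep = "_")
  }
  if (length(members) == 0L) {
    warnf("no called genes in direction '%s'; empty signature", direction)
    return(stats::setNames(list(character(0)), name))
  }
  stats::setNames(list(members), name)
}
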