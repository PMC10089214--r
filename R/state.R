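# Chromatin-state classification of regions from histone-mark peak sets.
# Mark presence is overlap with the corresponding peak set; the state is a
# pure function of the three presence flags.

#' Classify regions by histone-mark combination
#'
#' Assigns each region one of four states from its overlap with H3K4me1,
#' H3K4me3 and H3K27ac peak sets: \code{active_enhancer}
#' (K4me1+/K4me3-/K27ac+), \code{poised_enhancer} (K4me1+/K4me3-/K27ac-),
#' \code{promoter_like} (K4me3+, dominant over the enhancer classes), else
#' \code{unmarked}.  Mark presence defaults to any (>= 1 bp) overlap; a
#' minimum overlap fraction of the region can be required instead.
#'
#' @param regions a \code{GRanges} (typically TSS-distal bound regions).
#' @param k4me1,k4me3,k27ac \code{GRanges} peak sets for each mark.
#' @param min_frac minimum fraction of the region that must be covered by a
#'   mark's peaks for the mark to count as present (default 0 = any overlap).
#' @return a \code{data.frame} with columns \code{has_k4me1, has_k4me3,
#'   has_k27ac} (logical) and \code{state} (factor with the four levels
#'   above), one row per region.
#' @export
classify_regions <- function(regions, k4me1, k4me3, k27ac, min_frac = 0) {
  assert_scalar_num(min_frac, "min_frac", lower = 0, upper = 1)
  lev <- c("active_enhancer", "poised_enhancer", "promoter_like", "unmarked")
  f1 <- mark_present(regions, k4me1, min_frac)
  f3 <- mark_present(regions, k4me3, min_frac)
  fa <- mark_present(regions, k27ac, min_frac)
  state <- ifelse(f3, "promoter_like",
           ifelse(f1 & fa, "active_enhancer",
           ifelse(f1, "poised_enhancer", "unmarked")))
  data.frame(has_k4me1 = f1, has_k4me3 = f3, has_k27ac = fa,
             state = factor(state, levels = lev))
}

# overlap-based mark presence; min_frac = 0 means any (>=1 bp) overlap
mark_present <- function(regions, marks, min_frac = 0) {
  if (length(regions) == 0L) return(logical(0))
  if (length(marks) == 0L) return(rep(FALSE, length(regions)))
  if (min_frac <= 0)
    return(GenomicRanges::countOverlaps(regions, marks, ignore.strand = TRUE) > 0)
  cov <- numeric(length(regions))
  hits <- GenomicRanges::findOverlaps(regions, marks, ignore.strand = TRUE)
  if (length(hits)) {
    qi <- S4Vectors::queryHits(hits)
    # per-query union of overlapping mark bases, so stacked peaks never
    # count twice toward the covered fraction
    ints <- GenomicRanges::pintersect(regions[qi],
                                      marks[S4Vectors::subjectHits(hits)],
                                      ignore.strand = TRUE)
    for (q in unique(qi)) {
      u <- GenomicRanges::reduce(ints[qi == q], ignore.strand = TRUE)
      cov[q] <- sum(GenomicRanges::width(u))
    }
  }
  cov / GenomicRanges::width(regions) >= min_frac
}

#' Tabulate chromatin-state calls
#'
#' @param calls output of \code{\link{classify_regions}}.
#' @return named integer vector of counts per state (sums to
#'   \code{nrow(calls)}).
#' @export
state_counts <- function(calls) {
  table(calls$state)
}

#' Write chromatin-state calls and their summary
#'
#' @param regions the classified \code{GRanges}.
#' @param calls output of \code{\link{classify_regions}}.
#' @param path TSV output path; a JSON state-count summary is written next
#'   to it with suffix \code{.counts.json}.
#' @export
write_state_calls <- function(regions, calls, path) {
  df <- cbind(data.frame(chrom = as.character(GenomicRanges::seqnames(regions)),
                         start = GenomicRanges::start(regions) - 1L,
                         end = GenomicRanges::end(regions)),
              calls)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  counts <- as.list(state_counts(calls))
  jsonlite::write_json(counts, paste0(path, ".counts.json"), auto_unbox = TRUE)
  invisible(path)
}
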