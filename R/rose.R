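# ROSE-style enhancer / superenhancer calling: promoter exclusion with the
# "embedded in a larger active domain" rescue, +/-12.5 kb stitching,
# input-subtracted per-million signal ranking, and the signal-vs-rank
# inflection-point cutoff separating superenhancers from typical enhancers.

#' Exclude promoter-proximal peaks, rescuing embedded ones
#'
#' Drops peaks overlapping any TSS +/- \code{tss_window} bp promoter window,
#' unless the peak is embedded in a larger active chromatin domain: after
#' provisionally stitching all peaks at \code{max_gap}, a promoter-overlapping
#' peak is rescued when its stitched domain also contains at least one
#' non-promoter peak.
#'
#' @param peaks a \code{GRanges} of candidate enhancer peaks (e.g. H3K27ac).
#' @param genes a \code{gene_models} data frame, or \code{NULL} (no
#'   exclusion, with a warning).
#' @param tss_window symmetric promoter half-window in bp (default 2000).
#' @param max_gap stitching gap for the embedding rescue (default 12500).
#' @return list with \code{retained} (\code{GRanges}) and \code{report}
#'   (data.frame: per-peak \code{promoter_overlap}, \code{rescued},
#'   \code{excluded}).
#' @export
exclude_promoter_peaks <- function(peaks, genes = NULL, tss_window = 2000,
                                   max_gap = 12500) {
  assert_count(tss_window, "tss_window"); assert_count(max_gap, "max_gap")
  n <- length(peaks)
  report <- data.frame(promoter_overlap = logical(n), rescued = logical(n),
                       excluded = logical(n))
  if (is.null(genes) || nrow(genes) == 0L) {
    warnf("no gene models supplied; all %d peaks retained", n)
    return(list(retained = peaks, report = report))
  }
  prom <- promoter_granges(genes, upstream = tss_window, downstream = tss_window)
  at_prom <- GenomicRanges::countOverlaps(peaks, prom, ignore.strand = TRUE) > 0
  # provisional stitching of ALL peaks defines the embedding domains
  domains <- GenomicRanges::reduce(peaks, min.gapwidth = max_gap + 1L,
                                   ignore.strand = TRUE)
  dom_of <- GenomicRanges::findOverlaps(peaks, domains, ignore.strand = TRUE)
  dom_idx <- rep(NA_integer_, n)
  dom_idx[S4Vectors::queryHits(dom_of)] <- S4Vectors::subjectHits(dom_of)
  dom_has_distal <- tapply(!at_prom, dom_idx, any)
  rescued <- at_prom & as.logical(dom_has_distal[as.character(dom_idx)])
  excluded <- at_prom & !rescued
  report$promoter_overlap <- at_prom
  report$rescued <- rescued
  report$excluded <- excluded
  list(retained = peaks[!excluded], report = report)
}

#' Stitch peaks and rank them by input-subtracted signal
#'
#' Peaks are stitched at \code{max_gap}; ChIP and input tracks are each
#' scaled to per-million library counts before the region sums are taken, so
#' the subtraction is meaningful across library sizes.  The enhancer score is
#' \code{max(chip - input, 0)}; ranks are assigned by descending score with
#' ties broken by genomic position.
#'
#' @param peaks retained (non-promoter) peaks, a \code{GRanges}.
#' @param chip,input \code{signal_track}s with \code{total_reads} set.
#' @param max_gap stitching gap in bp (default 12500).
#' @return a \code{data.frame} of class \code{stitched_enhancers}: columns
#'   \code{chrom, start, end, constituents, chip_signal, input_signal,
#'   score, rank} ordered by rank.
#' @export
score_stitched_enhancers <- function(peaks, chip, input, max_gap = 12500) {
  if (!inherits(chip, "signal_track") || !inherits(input, "signal_track"))
    stopf("chip and input must be signal_track objects")
  if (is.null(chip$total_reads) || is.null(input$total_reads))
    stopf("both tracks must carry total_reads (library size) for per-million scaling")
  stitched <- stitch(peaks, max_gap = max_gap)
  chip_pm <- region_signal(chip, stitched, "sum") * 1e6 / chip$total_reads
  input_pm <- region_signal(input, stitched, "sum") * 1e6 / input$total_reads
  score <- pmax(chip_pm - input_pm, 0)
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(stitched)),
                   start = GenomicRanges::start(stitched) - 1L,
                   end = GenomicRanges::end(stitched),
                   constituents = stitched$n_constituents,
                   chip_signal = chip_pm, input_signal = input_pm,
                   score = score, stringsAsFactors = FALSE)
  ord <- order(-df$score, df$chrom, df$start)
  df <- df[ord, ]
  df$rank <- seq_len(nrow(df))
  rownames(df) <- NULL
  class(df) <- c("stitched_enhancers", "data.frame")
  df
}

# Geometric cutoff on the unit-rescaled ascending signal-vs-rank curve: the
# point where a line of slope 1 is tangent to the (convex) curve, i.e. the
# point lying furthest below the diagonal.  Returns the score at that point.
se_cutoff_score <- function(scores_ascending) {
  n <- length(scores_ascending)
  x <- (seq_len(n) - 1) / (n - 1)
  rng <- range(scores_ascending)
  if (diff(rng) == 0) return(NA_real_)
  y <- (scores_ascending - rng[1L]) / diff(rng)
  dev <- x - y
  # ties broken toward the higher score: fewer, stronger superenhancer calls
  idx <- max(which(dev == max(dev)))
  scores_ascending[idx]
}

#' Call superenhancers at the signal-vs-rank inflection point
#'
#' Enhancer scores are sorted ascending against their rank index; both axes
#' are rescaled to [0, 1] and the cutoff is placed where a line of slope 1 is
#' tangent to the curve (the point of maximal vertical distance below the
#' diagonal -- the geometric "inflection point" of the hockey-stick curve).
#' Enhancers scoring strictly above the cutoff are flagged super.  Degenerate
#' inputs (fewer than 3 enhancers, or all scores equal) yield no
#' superenhancers.
#'
#' @param enhancers a \code{stitched_enhancers} data frame from
#'   \code{\link{score_stitched_enhancers}}.
#' @return an object of class \code{se_call}: list with \code{enhancers}
#'   (the input plus \code{is_super}), \code{cutoff_score}, \code{n_super}.
#' @export
call_superenhancers <- function(enhancers) {
  df <- as.data.frame(enhancers)
  n <- nrow(df)
  if (n < 3L) {
    if (n > 0L) warnf("fewer than 3 enhancers; all called non-super")
    df$is_super <- rep(FALSE, n)
    return(structure(list(enhancers = df, cutoff_score = NA_real_, n_super = 0L),
                     class = "se_call"))
  }
  cutoff <- se_cutoff_score(sort(df$score))
  if (is.na(cutoff)) {           # all scores equal: no separable regime
    df$is_super <- rep(FALSE, n)
    return(structure(list(enhancers = df, cutoff_score = NA_real_, n_super = 0L),
                     class = "se_call"))
  }
  df$is_super <- df$score > cutoff
  structure(list(enhancers = df, cutoff_score = cutoff,
                 n_super = sum(df$is_super)),
            class = "se_call")
}

#' @export
print.se_call <- function(x, ...) {
  cat(sprintf("se_call: %d stitched enhancers, %d super (cutoff score %.4g)\n",
              nrow(x$enhancers), x$n_super, x$cutoff_score))
  invisible(x)
}

#' Plot the enhancer signal-vs-rank curve
#'
#' The classic hockey-stick: ascending input-subtracted signal against rank,
#' with the superenhancer cutoff marked.
#'
#' @param x an \code{se_call}.
#' @param ... passed to \code{plot}.
#' @export
plot.se_call <- function(x, ...) {
  s <- sort(x$enhancers$score)
  plot(seq_along(s), s, type = "l", xlab = "enhancer rank (ascending signal)",
       ylab = "input-subtracted signal (per million)", ...)
  if (!is.na(x$cutoff_score)) {
    graphics::abline(h = x$cutoff_score, lty = 2)
    graphics::legend("topleft", bty = "n",
                     legend = sprintf("cutoff %.3g; %d SEs", x$cutoff_score,
                                      x$n_super))
  }
  invisible(x)
}

#' Write an enhancer table and the superenhancer BED
#'
#' @param se an \code{se_call}.
#' @param path TSV output path for the full ranked table; the superenhancer
#'   BED is written next to it with suffix \code{.se.bed}.
#' @export
write_se_call <- function(se, path) {
  df <- se$enhancers[order(se$enhancers$rank), ]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  sup <- df[df$is_super, , drop = FALSE]
  bed <- data.frame(sup$chrom, sup$start, sup$end,
                    paste0("SE_", seq_len(nrow(sup))), round(sup$score, 4), ".")
  utils::write.table(bed, paste0(path, ".se.bed"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Run the full enhancer-calling pipeline
#'
#' Convenience wrapper: promoter exclusion (with embedding rescue), stitching
#' and input-subtracted scoring, then the inflection-point superenhancer
#' call.
#'
#' @inheritParams exclude_promoter_peaks
#' @inheritParams score_stitched_enhancers
#' @return an \code{se_call} (see \code{\link{call_superenhancers}}); the
#'   exclusion report is attached as attribute \code{exclusion_report}.
#' @export
call_enhancers <- function(peaks, chip, input, genes = NULL,
                           tss_window = 2000, max_gap = 12500) {
  excl <- exclude_promoter_peaks(peaks, genes, tss_window, max_gap)
  enh <- score_stitched_enhancers(excl$retained, chip, input, max_gap)
  out <- call_superenhancers(enh)
  attr(out, "exclusion_report") <- excl$report
  out
}
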