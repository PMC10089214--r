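# Interval-valued coverage tracks (bedGraph) and binned, BPM-normalized
# read-distribution profiles centered on peak midpoints.

#' Construct a signal track
#'
#' A signal track is a set of non-overlapping, non-negative coverage steps
#' per chromosome.  \code{total_signal} is \code{sum(value * span)};
#' \code{total_reads} is the library size used for bins-per-million (BPM)
#' scaling and per-million region sums.
#'
#' @param gr a \code{GRanges} with a numeric \code{score} metadata column.
#' @param total_reads optional library size (positive integer-valued number).
#' @return an object of class \code{signal_track}.
#' @export
signal_track <- function(gr, total_reads = NULL) {
  if (is.null(gr$score)) stopf("signal_track requires a 'score' metadata column")
  if (any(!is.finite(gr$score)) || any(gr$score < 0))
    stopf("signal values must be finite and >= 0")
  gr <- sort_intervals(gr)
  # reject overlap within chromosome
  if (length(gr) > 1L) {
    same <- as.character(GenomicRanges::seqnames(gr))[-1L] ==
      as.character(GenomicRanges::seqnames(gr))[-length(gr)]
    ov <- same & GenomicRanges::start(gr)[-1L] <= GenomicRanges::end(gr)[-length(gr)]
    if (any(ov)) stopf("signal track steps overlap near %s:%d",
                       as.character(GenomicRanges::seqnames(gr))[which(ov)[1L] + 1L],
                       GenomicRanges::start(gr)[which(ov)[1L] + 1L])
  }
  if (!is.null(total_reads)) assert_scalar_num(total_reads, "total_reads", lower = 1)
  structure(list(gr = gr,
                 total_signal = sum(gr$score * GenomicRanges::width(gr)),
                 total_reads = total_reads),
            class = "signal_track")
}

#' @export
print.signal_track <- function(x, ...) {
  cat(sprintf("signal_track: %d steps, total signal %.4g%s\n",
              length(x$gr), x$total_signal,
              if (is.null(x$total_reads)) ""
              else sprintf(", library size %g", x$total_reads)))
  invisible(x)
}

#' Read a 4-column bedGraph into a signal track
#'
#' Input intervals may be unsorted but must not overlap; overlapping steps or
#' negative values are an error naming the offending line.  bedGraph 0-based
#' half-open coordinates are converted to the 1-based \code{GRanges}
#' convention.
#'
#' @param path bedGraph file path.
#' @param total_reads optional library size for BPM scaling.
#' @return a \code{signal_track}.
#' @export
read_bedgraph <- function(path, total_reads = NULL) {
  body <- read_body_lines(path)
  if (length(body$lines) == 0L)
    return(signal_track(GenomicRanges::GRanges(score = numeric(0)), total_reads))
  fields <- strsplit(body$lines, "\t", fixed = TRUE)
  ncol <- lengths(fields)
  if (any(ncol != 4L))
    stopf("%s line %d: bedGraph requires 4 columns", path,
          body$lineno[ncol != 4L][1L])
  m <- matrix(unlist(fields), ncol = 4L, byrow = TRUE)
  start0 <- parse_coord(m[, 2L], body$lineno, path)
  end0 <- parse_coord(m[, 3L], body$lineno, path)
  if (any(start0 >= end0))
    stopf("%s line %d: start >= end", path, body$lineno[start0 >= end0][1L])
  value <- as.numeric(m[, 4L])
  if (any(is.na(value) | value < 0))
    stopf("%s line %d: negative or non-numeric value", path,
          body$lineno[is.na(value) | value < 0][1L])
  gr <- GenomicRanges::GRanges(m[, 1L], IRanges::IRanges(start0 + 1L, end0),
                               score = value)
  tryCatch(signal_track(gr, total_reads),
           error = function(e) stopf("%s: %s", path, conditionMessage(e)))
}

#' Write a signal track as bedGraph
#' @param track a \code{signal_track}.
#' @param path output path.
#' @export
write_bedgraph <- function(track, path) {
  gr <- track$gr
  utils::write.table(
    data.frame(as.character(GenomicRanges::seqnames(gr)),
               GenomicRanges::start(gr) - 1L, GenomicRanges::end(gr), gr$score),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Summed or mean signal over regions
#'
#' \code{sum} is \eqn{\sum value \times overlap} over the track steps
#' intersecting each region (the per-region quantity ranked in enhancer
#' calling); \code{mean} divides by the region length.  Regions touching no
#' step return 0.
#'
#' @param track a \code{signal_track}.
#' @param regions a \code{GRanges} (one or more regions).
#' @param stat \code{"sum"} or \code{"mean"}.
#' @return numeric vector, one value per region.
#' @export
region_signal <- function(track, regions, stat = c("sum", "mean")) {
  stat <- match.arg(stat)
  out <- numeric(length(regions))
  if (length(regions) == 0L || length(track$gr) == 0L) {
    return(if (stat == "mean") out else out)
  }
  al <- align_seqlevels(regions, track$gr)
  hits <- GenomicRanges::findOverlaps(al$a, al$b, ignore.strand = TRUE)
  if (length(hits)) {
    qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
    ov <- pmin(GenomicRanges::end(regions)[qi], GenomicRanges::end(track$gr)[si]) -
      pmax(GenomicRanges::start(regions)[qi], GenomicRanges::start(track$gr)[si]) + 1
    contrib <- ov * track$gr$score[si]
    sums <- tapply(contrib, qi, sum)
    out[as.integer(names(sums))] <- as.numeric(sums)
  }
  if (stat == "mean") out <- out / GenomicRanges::width(regions)
  out
}

#' Binned signal profiles around region midpoints
#'
#' Centers a window of \code{window_bp} on each region midpoint, divides it
#' into \code{bin_bp} bins, and sums track signal per bin.  With
#' \code{normalize = "bpm"} bins are scaled to bins per million:
#' \code{raw * 1e6 / total_reads} (deepTools-compatible semantics).  Bins
#' falling before the chromosome start are zero-filled and counted in the
#' \code{n_clipped} attribute.
#'
#' @param track a \code{signal_track}; must carry \code{total_reads} for BPM.
#' @param regions a \code{GRanges}.
#' @param window_bp total window size (bp), divisible by \code{bin_bp}.
#' @param bin_bp bin size (bp).
#' @param normalize \code{"bpm"} or \code{"raw"}.
#' @return an object of class \code{profile_matrix}: list with \code{matrix}
#'   (regions x bins), \code{colmeans}, \code{window_bp}, \code{bin_bp},
#'   \code{normalization}.
#' @export
profile_matrix <- function(track, regions, window_bp = 3000, bin_bp = 100,
                           normalize = c("bpm", "raw")) {
  normalize <- match.arg(normalize)
  assert_count(window_bp, "window_bp", lower = 1)
  assert_count(bin_bp, "bin_bp", lower = 1)
  if (window_bp %% bin_bp != 0)
    stopf("window_bp (%d) must be divisible by bin_bp (%d)", window_bp, bin_bp)
  if (normalize == "bpm" && is.null(track$total_reads))
    stopf("BPM normalization requires a track with total_reads set")
  n_bins <- window_bp %/% bin_bp
  n <- length(regions)
  mid0 <- floor((GenomicRanges::start(regions) - 1 + GenomicRanges::end(regions)) / 2)
  chrom <- as.character(GenomicRanges::seqnames(regions))
  # bin b covers 0-based [mid - window/2 + b*bin, ... + (b+1)*bin)
  left0 <- rep(mid0 - window_bp %/% 2, each = n_bins) +
    rep(seq_len(n_bins) - 1L, times = n) * bin_bp
  bin_chrom <- rep(chrom, each = n_bins)
  clipped <- left0 < 0
  left0c <- pmax(left0, 0)
  right0 <- pmax(left0 + bin_bp, left0c + 1)   # keep valid width for clipped bins
  bins <- GenomicRanges::GRanges(bin_chrom, IRanges::IRanges(left0c + 1, right0))
  vals <- region_signal(track, bins, stat = "sum")
  vals[clipped & left0 + bin_bp <= 0] <- 0
  mat <- matrix(vals, nrow = n, ncol = n_bins, byrow = TRUE)
  if (normalize == "bpm") mat <- mat * 1e6 / track$total_reads
  rownames(mat) <- if (!is.null(regions$name)) regions$name else NULL
  out <- structure(list(matrix = mat,
                        colmeans = colMeans(mat),
                        window_bp = window_bp, bin_bp = bin_bp,
                        normalization = normalize),
                   class = "profile_matrix")
  attr(out, "n_clipped") <- sum(clipped)
  out
}

#' @export
print.profile_matrix <- function(x, ...) {
  cat(sprintf("profile_matrix: %d regions x %d bins (%d bp window, %d bp bins, %s)\n",
              nrow(x$matrix), ncol(x$matrix), x$window_bp, x$bin_bp,
              x$normalization))
  invisible(x)
}

#' Write a profile matrix and its column means as TSV
#' @param pm a \code{profile_matrix}.
#' @param path output path for the matrix; column means are written next to
#'   it with suffix \code{.colmeans.tsv}.
#' @export
write_profile_matrix <- function(pm, path) {
  utils::write.table(pm$matrix, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(t(pm$colmeans), paste0(path, ".colmeans.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
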