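# Readers and writers for the plain-text interval and gene-model formats
# used throughout the package.  Coordinates on disk follow each format's own
# convention (BED-family and the gene TSV dialect are 0-based half-open, GTF
# is 1-based closed); in memory everything is a GRanges in the Bioconductor
# 1-based closed convention.  The parsers are deliberately strict: malformed
# lines fail with the offending line number rather than being dropped.

read_body_lines <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))
  list(lines = lines[keep], lineno = which(keep))
}

parse_coord <- function(x, lineno, path) {
  v <- suppressWarnings(as.numeric(x))
  bad <- is.na(v) | v != floor(v) | v < 0
  if (any(bad))
    stopf("%s line %d: non-integer coordinate '%s'",
          path, lineno[bad][1L], x[bad][1L])
  v
}

#' Read a BED3/BED6/narrowPeak interval file
#'
#' Reads tab-separated peak/region files into a sorted \code{GRanges}.
#' narrowPeak files (BED6+4) map \code{signalValue} (column 7) to the
#' \code{score} metadata column.  Comment, \code{track} and \code{browser}
#' lines are skipped.  BED's 0-based half-open coordinates are converted to
#' the 1-based closed \code{GRanges} convention on read.
#'
#' @param path file path.
#' @param dialect one of \code{"auto"}, \code{"bed3"}, \code{"bed6"},
#'   \code{"narrowpeak"}; \code{"auto"} infers from the column count
#'   (3 = bed3, 6 = bed6, 10 = narrowPeak).
#' @return a \code{GRanges} sorted by (chrom, start, end, name), with
#'   \code{name} and \code{score} metadata columns where present.
#' @export
read_intervals <- function(path, dialect = c("auto", "bed3", "bed6", "narrowpeak")) {
  dialect <- match.arg(dialect)
  body <- read_body_lines(path)
  if (length(body$lines) == 0L)
    return(GenomicRanges::GRanges())
  fields <- strsplit(body$lines, "\t", fixed = TRUE)
  ncol <- lengths(fields)
  if (dialect == "auto") {
    dialect <- switch(as.character(ncol[1L]),
      "3" = "bed3", "6" = "bed6", "10" = "narrowpeak",
      stopf("%s line %d: cannot infer dialect from %d columns",
            path, body$lineno[1L], ncol[1L]))
  }
  need <- c(bed3 = 3L, bed6 = 6L, narrowpeak = 10L)[[dialect]]
  if (any(ncol != need))
    stopf("%s line %d: expected %d columns, got %d",
          path, body$lineno[ncol != need][1L], need, ncol[ncol != need][1L])
  m <- matrix(unlist(fields), ncol = need, byrow = TRUE)
  start0 <- parse_coord(m[, 2L], body$lineno, path)
  end0 <- parse_coord(m[, 3L], body$lineno, path)
  bad <- start0 >= end0
  if (any(bad))
    stopf("%s line %d: start >= end", path, body$lineno[bad][1L])
  chrom <- m[, 1L]
  name <- if (need >= 6L) m[, 4L] else NULL
  strand <- if (need >= 6L) ifelse(m[, 6L] %in% c("+", "-"), m[, 6L], "*") else "*"
  score <- if (dialect == "narrowpeak") as.numeric(m[, 7L])
           else if (need >= 6L) suppressWarnings(as.numeric(m[, 5L]))
           else NULL
  gr <- GenomicRanges::GRanges(chrom,
                               IRanges::IRanges(start0 + 1L, end0),
                               strand = strand)
  if (!is.null(name)) gr$name <- name
  if (!is.null(score)) gr$score <- score
  sort_intervals(gr)
}

#' Sort a GRanges by (chrom, start, end, name)
#'
#' @param gr a \code{GRanges}; ties beyond (chrom, start, end) are broken by
#'   the \code{name} metadata column when present, for reproducibility.
#' @return the sorted \code{GRanges}.
#' @export
sort_intervals <- function(gr) {
  nm <- if (!is.null(gr$name)) gr$name else NULL
  idx <- order_intervals(as.character(GenomicRanges::seqnames(gr)),
                         GenomicRanges::start(gr), GenomicRanges::end(gr), nm)
  gr[idx]
}

#' Write intervals as BED3/BED6
#'
#' Inverse of \code{\link{read_intervals}}: coordinates are converted back to
#' 0-based half-open on write, so a write/read round trip is exact.
#'
#' @param gr a \code{GRanges}.
#' @param path output file path.
#' @param dialect \code{"bed3"} or \code{"bed6"}.
#' @export
write_intervals <- function(gr, path, dialect = c("bed6", "bed3")) {
  dialect <- match.arg(dialect)
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr))
  if (dialect == "bed6") {
    df$name <- if (!is.null(gr$name)) gr$name else paste0("region_", seq_along(gr))
    df$score <- if (!is.null(gr$score)) gr$score else 0
    st <- as.character(GenomicRanges::strand(gr))
    df$strand <- ifelse(st == "*", ".", st)
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

gtf_attr <- function(attrs, key) {
  pat <- paste0(key, "[ =]+\"?([^\";]+)\"?")
  m <- regexec(pat, attrs)
  vapply(regmatches(attrs, m),
         function(x) if (length(x) >= 2L) x[2L] else NA_character_,
         character(1))
}

#' Read gene models from GTF, BED12 or a flat TSV
#'
#' Returns one row per gene with the transcription start site (TSS) resolved
#' per strand and the exonic length used for TPM normalization.  GTF input is
#' 1-based closed; BED12 and the TSV dialect (columns \code{gene_id, symbol,
#' chrom, strand, tx_start, tx_end, biotype, length}, header required) are
#' 0-based half-open and converted on read.  For GTF, the gene span is the
#' union of its exons and the length is the exon-union size.
#'
#' @param path file path.
#' @param format one of \code{"gtf"}, \code{"bed12"}, \code{"tsv"}.
#' @return a \code{data.frame} of class \code{"gene_models"} with columns
#'   \code{gene_id, symbol, chrom, strand, start, end, biotype, length, tss}
#'   (\code{start}/\code{end} 1-based closed; \code{tss} = \code{start} on
#'   \code{+}, \code{end} on \code{-}).
#' @export
read_gene_models <- function(path, format = c("gtf", "bed12", "tsv")) {
  format <- match.arg(format)
  out <- switch(format,
    tsv = read_gene_tsv(path),
    gtf = read_gene_gtf(path),
    bed12 = read_gene_bed12(path))
  if (any(out$start > out$end)) stopf("%s: gene with start > end", path)
  if (!all(out$strand %in% c("+", "-")))
    stopf("%s: gene strand must be '+' or '-'", path)
  out$tss <- ifelse(out$strand == "+", out$start, out$end)
  out <- out[order_intervals(out$chrom, out$start, out$end, out$gene_id), ]
  rownames(out) <- NULL
  class(out) <- c("gene_models", "data.frame")
  out
}

read_gene_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, quote = "")
  need <- c("gene_id", "symbol", "chrom", "strand", "tx_start", "tx_end",
            "biotype", "length")
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("%s: missing columns: %s", path, paste(miss, collapse = ", "))
  data.frame(gene_id = as.character(df$gene_id), symbol = as.character(df$symbol),
             chrom = as.character(df$chrom), strand = as.character(df$strand),
             start = df$tx_start + 1L, end = df$tx_end,
             biotype = as.character(df$biotype), length = df$length,
             stringsAsFactors = FALSE)
}

read_gene_gtf <- function(path) {
  body <- read_body_lines(path)
  if (length(body$lines) == 0L) stopf("%s: empty GTF", path)
  fields <- strsplit(body$lines, "\t", fixed = TRUE)
  ncol <- lengths(fields)
  if (any(ncol != 9L))
    stopf("%s line %d: GTF requires 9 columns, got %d",
          path, body$lineno[ncol != 9L][1L], ncol[ncol != 9L][1L])
  m <- matrix(unlist(fields), ncol = 9L, byrow = TRUE)
  type <- m[, 3L]
  keep <- type %in% c("gene", "exon")
  m <- m[keep, , drop = FALSE]
  lineno <- body$lineno[keep]
  if (nrow(m) == 0L) stopf("%s: no 'gene' or 'exon' features", path)
  gid <- gtf_attr(m[, 9L], "gene_id")
  if (anyNA(gid))
    stopf("%s line %d: missing gene_id attribute", path, lineno[is.na(gid)][1L])
  sym <- gtf_attr(m[, 9L], "gene_name")
  bt <- gtf_attr(m[, 9L], "gene_biotype")
  start1 <- as.integer(m[, 4L]); end1 <- as.integer(m[, 5L])
  exon <- m[, 3L] == "exon"
  # prefer exon rows for span + exon-union length; fall back to gene rows
  per_gene <- lapply(split(seq_len(nrow(m)), gid), function(i) {
    ie <- i[exon[i]]
    use <- if (length(ie)) ie else i
    len <- if (length(ie)) {
      ir <- IRanges::reduce(IRanges::IRanges(start1[ie], end1[ie]))
      sum(IRanges::width(ir))
    } else end1[i[1L]] - start1[i[1L]] + 1L
    data.frame(gene_id = gid[i[1L]],
               symbol = ifelse(is.na(sym[i[1L]]), gid[i[1L]], sym[i[1L]]),
               chrom = m[use[1L], 1L], strand = m[use[1L], 7L],
               start = min(start1[use]), end = max(end1[use]),
               biotype = ifelse(is.na(bt[i[1L]]), "protein_coding", bt[i[1L]]),
               length = len, stringsAsFactors = FALSE)
  })
  do.call(rbind, per_gene)
}

read_gene_bed12 <- function(path) {
  body <- read_body_lines(path)
  fields <- strsplit(body$lines, "\t", fixed = TRUE)
  ncol <- lengths(fields)
  if (any(ncol != 12L))
    stopf("%s line %d: BED12 requires 12 columns", path,
          body$lineno[ncol != 12L][1L])
  m <- matrix(unlist(fields), ncol = 12L, byrow = TRUE)
  block_len <- vapply(strsplit(m[, 11L], ",", fixed = TRUE),
                      function(x) sum(as.numeric(x)), numeric(1))
  data.frame(gene_id = m[, 4L], symbol = m[, 4L], chrom = m[, 1L],
             strand = m[, 6L],
             start = as.integer(m[, 2L]) + 1L, end = as.integer(m[, 3L]),
             biotype = "protein_coding", length = block_len,
             stringsAsFactors = FALSE)
}

#' Write gene models to the flat TSV dialect
#'
#' @param genes a \code{gene_models} data frame.
#' @param path output path.
#' @export
write_gene_models <- function(genes, path) {
  df <- data.frame(gene_id = genes$gene_id, symbol = genes$symbol,
                   chrom = genes$chrom, strand = genes$strand,
                   tx_start = genes$start - 1L, tx_end = genes$end,
                   biotype = genes$biotype, length = genes$length)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# gene bodies as GRanges
gene_body_granges <- function(genes) {
  GenomicRanges::GRanges(genes$chrom,
                         IRanges::IRanges(genes$start, genes$end),
                         strand = genes$strand, gene_id = genes$gene_id)
}

# strand-aware promoter windows around the TSS; width = upstream + downstream,
# with the TSS the first downstream base (GenomicRanges::promoters semantics)
promoter_granges <- function(genes, upstream = 2000, downstream = 1000) {
  tss <- GenomicRanges::GRanges(genes$chrom,
                                IRanges::IRanges(genes$tss, width = 1L),
                                strand = genes$strand, gene_id = genes$gene_id)
  gr <- GenomicRanges::promoters(tss, upstream = upstream, downstream = downstream)
  GenomicRanges::start(gr) <- pmax(GenomicRanges::start(gr), 1L)
  gr
}
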