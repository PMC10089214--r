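# Interval I/O, stitching, nearest distances, and gene-model annotation.

test_that("BED-family readers parse, sort, and round-trip exactly", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t100\t200", f)
  gr <- read_intervals(f)
  expect_equal(df0(gr), data.frame(chrom = "chr1", start0 = 100, end0 = 200))
  expect_equal(as.character(GenomicRanges::strand(gr)), "*")

  # unsorted input comes back sorted
  writeLines(c("chr1\t500\t600", "chr1\t100\t200"), f)
  gr <- read_intervals(f)
  expect_equal(df0(gr)$start0, c(100, 500))

  # narrowPeak maps signalValue (column 7) to score
  np <- paste(c("chr2", 10, 90, "pk1", 0, ".", 7.5, 3.2, 2.1, 40),
              collapse = "\t")
  writeLines(np, f)
  gr <- read_intervals(f)
  expect_equal(gr$score, 7.5)
  expect_equal(gr$name, "pk1")

  # write/read round trip preserves coordinates exactly
  set.seed(42)
  orig <- sort_intervals(random_intervals(50))
  orig$name <- sprintf("p%02d", seq_along(orig))
  out <- withr::local_tempfile(fileext = ".bed")
  write_intervals(orig, out, "bed6")
  back <- read_intervals(out)
  expect_equal(df0(back), df0(orig))
  expect_equal(back$name, orig$name)
})

test_that("malformed interval lines fail with the offending line number", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t200", "chr1\t300"), f)
  expect_error(read_intervals(f, "bed3"), "line 2")
  writeLines(c("track name=x", "chr1\t500\t400"), f)
  expect_error(read_intervals(f), "line 2.*start >= end")
  writeLines("chr1\tabc\t200", f)
  expect_error(read_intervals(f), "non-integer")
})

test_that("gene models normalize coordinate conventions per format", {
  # GTF is 1-based closed; exonic length is the exon union
  f <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(
    'chr1\tsrc\texon\t1001\t1100\t.\t+\t.\tgene_id "g1"; gene_name "G1";',
    'chr1\tsrc\texon\t1901\t2000\t.\t+\t.\tgene_id "g1"; gene_name "G1";'),
    f)
  g <- read_gene_models(f, "gtf")
  expect_equal(g$start, 1001)
  expect_equal(g$end, 2000)
  expect_equal(g$tss, 1001)
  expect_equal(g$length, 200)     # two 100-bp exons

  # minus-strand TSS sits at the transcript end
  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tsymbol\tchrom\tstrand\ttx_start\ttx_end\tbiotype\tlength",
               "g2\tG2\tchr1\t-\t1000\t2000\tprotein_coding\t800"), f2)
  g2 <- read_gene_models(f2, "tsv")
  expect_equal(g2$tss, 2000)      # 0-based 1999 in BED terms

  # missing gene_id is an error with the line number
  writeLines('chr1\tsrc\texon\t1\t10\t.\t+\t.\tfoo "bar";', f)
  expect_error(read_gene_models(f, "gtf"), "gene_id")

  # TSV round trip
  out <- withr::local_tempfile()
  write_gene_models(g2, out)
  expect_equal(read_gene_models(out, "tsv"), g2)
})

test_that("stitch merges by edge gap and reports constituents", {
  s <- stitch(gr0("chr1", c(100, 5000, 20000), c(200, 5100, 20100)),
              max_gap = 12500)
  expect_equal(df0(s),
               data.frame(chrom = "chr1", start0 = c(100, 20000),
                          end0 = c(5100, 20100)))
  expect_equal(s$n_constituents, c(2L, 1L))

  expect_length(stitch(GenomicRanges::GRanges(), 100), 0)

  # touching intervals have gap 0 and merge even at max_gap = 0
  s <- stitch(gr0("chr1", c(100, 200), c(200, 300)), max_gap = 0)
  expect_equal(df0(s), data.frame(chrom = "chr1", start0 = 100, end0 = 300))
})

test_that("stitch matches independent merge oracles and is idempotent", {
  set.seed(101)
  for (rep in 1:25) {
    gr <- random_intervals(sample(2:80, 1), span = 2e4, max_w = 800)
    gap <- sample(c(0, 10, 500, 5000), 1)
    got <- stitch(gr, gap)
    d <- df0(gr)
    want <- sweep_merge(d$chrom, d$start0, d$end0, gap)
    expect_equal(df0(got)$start0, want$start0, ignore_attr = TRUE)
    expect_equal(df0(got)$end0, want$end0, ignore_attr = TRUE)
    expect_equal(got$n_constituents, unname(want$n), ignore_attr = TRUE)
    # all-pairs union-find route agrees too
    uf <- unionfind_merge(d$chrom, d$start0, d$end0, gap)
    expect_equal(df0(got)$start0, uf$start0, ignore_attr = TRUE)
    # idempotence and conservation
    again <- stitch(got, gap)
    expect_equal(df0(again), df0(got))
    expect_lte(length(got), length(gr))
    expect_equal(sum(GenomicRanges::width(GenomicRanges::reduce(gr))) <=
                 sum(GenomicRanges::width(got)), TRUE)
  }
})

test_that("nearest_distance gives edge gaps, 0 on overlap, NA off-chrom", {
  q <- gr0("chr1", 1000, 1100)
  expect_equal(nearest_distance(q, gr0("chr1", 1150, 1250))$distance, 50)
  expect_equal(nearest_distance(q, gr0("chr1", 1050, 1250))$distance, 0)
  expect_true(is.na(nearest_distance(gr0("chr2", 0, 10),
                                     gr0("chr1", 0, 10))$distance))
})

test_that("nearest_distance agrees with the all-pairs oracle", {
  set.seed(7)
  for (rep in 1:20) {
    q <- random_intervals(sample(1:100, 1))
    s <- random_intervals(sample(1:100, 1))
    expect_equal(nearest_distance(q, s)$distance, brute_nearest(q, s))
  }
})

test_that("annotate_regions applies the -2/+1 kb promoter rule with precedence", {
  g <- toy_gene_models(tss0 = 10000, strand = "+", span = 5000)
  # promoter window is 0-based [8000, 11000)
  expect_equal(as.character(annotate_regions(gr0("chr1", 8500, 8600), g)),
               "tss_proximal")
  expect_equal(as.character(annotate_regions(gr0("chr1", 12000, 12100), g)),
               "intragenic")
  expect_equal(as.character(annotate_regions(gr0("chr1", 50000, 50100), g)),
               "intergenic")
  # window boundary: overlap needs >= 1 bp
  expect_equal(as.character(annotate_regions(gr0("chr1", 7900, 8000), g)),
               "intergenic")
  expect_equal(as.character(annotate_regions(gr0("chr1", 7900, 8001), g)),
               "tss_proximal")
  # minus strand mirrors the window: TSS 20000 (0-based), window [19001, 22001)
  gm <- toy_gene_models(tss0 = 20000, strand = "-", span = 5000, id = "geneB")
  expect_equal(as.character(annotate_regions(gr0("chr1", 21500, 21600), gm)),
               "tss_proximal")
  expect_equal(as.character(annotate_regions(gr0("chr1", 18000, 18100), gm)),
               "intragenic")
})

test_that("annotation partitions the region set", {
  set.seed(13)
  g <- rbind(toy_gene_models(tss0 = c(5000, 30000, 70000), id = c("a", "b", "c")),
             toy_gene_models(tss0 = 40000, strand = "-", id = "d"))
  class(g) <- c("gene_models", "data.frame")
  for (rep in 1:10) {
    r <- random_intervals(50, n_chroms = 1)
    ann <- annotate_regions(r, g)
    expect_equal(sum(table(ann)), length(r))
  }
})

test_that("assign_nearest_gene ranks by midpoint-TSS distance with id ties", {
  g <- rbind(toy_gene_models(tss0 = 10000, id = "gA"),
             toy_gene_models(tss0 = 30000, id = "gB"))
  class(g) <- c("gene_models", "data.frame")
  a <- assign_nearest_gene(gr0("chr1", 10000, 10100), g, k = 2)
  expect_equal(a$gene_id, c("gA", "gB"))
  expect_equal(a$distance[1], 50)      # midpoint 10050 vs TSS 10000
  # equidistant TSSs break ties lexicographically
  ge <- rbind(toy_gene_models(tss0 = 9000, id = "zz"),
              toy_gene_models(tss0 = 11000, id = "aa"))
  class(ge) <- c("gene_models", "data.frame")
  ae <- assign_nearest_gene(gr0("chr1", 9950, 10050), ge, k = 2)
  expect_equal(ae$gene_id, c("aa", "zz"))
  # k beyond the gene count returns everything
  expect_equal(nrow(assign_nearest_gene(gr0("chr1", 0, 100), g, k = 10)), 2)
  # global top-N selection by ascending distance
  top <- top_assigned_genes(a, n = 1)
  expect_equal(top, "gA")
})
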