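# Promoter exclusion with the embedding rescue, input-subtracted scoring,
# and the inflection-point superenhancer cutoff.

test_that("promoter-overlapping peaks are excluded unless embedded", {
  g <- toy_gene_models(tss0 = 10000)      # +/-2 kb window: 0-based [8000, 12001)
  # isolated peak inside the promoter window
  iso <- gr0("chr1", 9000, 9200)
  r <- exclude_promoter_peaks(iso, g)
  expect_length(r$retained, 0)
  expect_true(r$report$excluded)

  # promoter peak whose 12.5 kb stitched cluster holds a distal peak: rescued
  pk <- gr0("chr1", c(9000, 15000), c(9200, 15300))
  r <- exclude_promoter_peaks(pk, g)
  expect_length(r$retained, 2)
  expect_equal(r$report$rescued, c(TRUE, FALSE))
  expect_false(any(r$report$excluded))

  # without gene models everything is retained, with a warning
  expect_warning(r <- exclude_promoter_peaks(iso, NULL), "retained")
  expect_length(r$retained, 1)
})

test_that("scores are per-million input-subtracted sums, floored at zero", {
  # chip: 1000 reads over the peak out of 1e5 total -> 1e4 per million
  chip <- signal_track(gr0("chr1", 1000, 2000, score = 1), total_reads = 1e5)
  # input: 400 reads over the peak out of 1e5 total -> 4e3 per million
  input <- signal_track(gr0("chr1", 1000, 2000, score = 0.4), total_reads = 1e5)
  enh <- score_stitched_enhancers(gr0("chr1", 1000, 2000), chip, input)
  expect_equal(enh$score, 1000 * 1e6 / 1e5 - 400 * 1e6 / 1e5)

  # input above chip floors at 0
  enh0 <- score_stitched_enhancers(gr0("chr1", 1000, 2000), input, chip)
  expect_equal(enh0$score, 0)

  # equal scores rank by genomic position
  chip2 <- signal_track(gr0("chr1", c(1000, 50000), c(2000, 51000),
                            score = 1), total_reads = 1e5)
  zero <- signal_track(gr0("chr1", 0, 1, score = 0), total_reads = 1e5)
  enh2 <- score_stitched_enhancers(gr0("chr1", c(50000, 1000), c(51000, 2000)),
                                   chip2, zero)
  expect_equal(enh2$start, c(1000, 50000))
  expect_equal(enh2$rank, c(1, 2))

  # library sizes are mandatory
  expect_error(score_stitched_enhancers(gr0("chr1", 0, 10),
                                        signal_track(gr0("chr1", 0, 10, score = 1)),
                                        zero),
               "total_reads")
})

test_that("the cutoff separates a hockey-stick and degenerate cases are guarded", {
  mk <- function(scores) {
    n <- length(scores)
    df <- data.frame(chrom = "chr1", start = (seq_len(n) - 1) * 1e5,
                     end = (seq_len(n) - 1) * 1e5 + 1000,
                     constituents = 1L, chip_signal = scores, input_signal = 0,
                     score = scores)
    df <- df[order(-df$score, df$start), ]
    df$rank <- seq_len(n)
    class(df) <- c("stitched_enhancers", "data.frame")
    df
  }
  res <- call_superenhancers(mk(c(rep(1, 8), 50, 100)))
  expect_equal(res$n_super, 2)
  expect_equal(sort(res$enhancers$score[res$enhancers$is_super]), c(50, 100))

  expect_equal(call_superenhancers(mk(rep(3, 10)))$n_super, 0)
  expect_warning(res2 <- call_superenhancers(mk(c(1, 5))), "fewer than 3")
  expect_equal(res2$n_super, 0)
})

test_that("cutoff equals a brute-force scan over all candidate cut points", {
  brute_cutoff <- function(scores) {
    s <- sort(scores); n <- length(s)
    x <- (seq_len(n) - 1) / (n - 1)
    y <- (s - min(s)) / (max(s) - min(s))
    # scan all candidate cut points; keep the max deviation below the
    # diagonal, ties resolved toward the higher score
    dev <- numeric(n)
    for (i in seq_len(n)) dev[i] <- x[i] - y[i]
    cand <- which(abs(dev - max(dev)) < 1e-12)
    s[max(cand)]
  }
  set.seed(55)
  for (rep in 1:60) {
    n <- sample(3:60, 1)
    scores <- switch(sample(1:3, 1),
      round(rexp(n, 1 / 50), 3),
      c(rep(1, n - 2), 40, 90),
      round(runif(n, 0, 100), 2))
    mkdf <- data.frame(chrom = "chr1", start = seq_len(n), end = seq_len(n) + 1,
                       constituents = 1L, chip_signal = scores,
                       input_signal = 0, score = scores,
                       rank = rank(-scores, ties.method = "first"))
    class(mkdf) <- c("stitched_enhancers", "data.frame")
    got <- call_superenhancers(mkdf)
    if (max(scores) == min(scores)) {
      expect_equal(got$n_super, 0)
    } else {
      expect_equal(got$cutoff_score, brute_cutoff(scores))
      expect_equal(got$n_super, sum(scores > brute_cutoff(scores)))
    }
  }
})

test_that("the super/non-super partition is invariant to positive rescaling", {
  set.seed(66)
  scores <- c(rexp(40, 1 / 10), rexp(5, 1 / 500))
  mk <- function(s) {
    df <- data.frame(chrom = "chr1", start = seq_along(s), end = seq_along(s) + 1,
                     constituents = 1L, chip_signal = s, input_signal = 0,
                     score = s, rank = rank(-s, ties.method = "first"))
    class(df) <- c("stitched_enhancers", "data.frame")
    df
  }
  base <- call_superenhancers(mk(scores))
  for (c in c(0.01, 3, 1000)) {
    scaled <- call_superenhancers(mk(scores * c))
    expect_equal(scaled$enhancers$is_super, base$enhancers$is_super)
  }
  # adding a constant flattens the curve and never adds superenhancers
  shifted <- call_superenhancers(mk(scores + 50))
  expect_lte(shifted$n_super, base$n_super + 0)
})

test_that("every constituent peak base lies in exactly one stitched enhancer", {
  set.seed(77)
  peaks <- random_intervals(80, span = 5e5, max_w = 1000)
  chip <- const_track(1, 5e5, c("chr1", "chr2"), total_reads = 1e6)
  input <- const_track(0.1, 5e5, c("chr1", "chr2"), total_reads = 1e6)
  enh <- score_stitched_enhancers(peaks, chip, input)
  stitched <- gr0(enh$chrom, enh$start, enh$end)
  cov <- GenomicRanges::countOverlaps(peaks, stitched, ignore.strand = TRUE)
  expect_true(all(cov == 1))
  within <- GenomicRanges::findOverlaps(peaks, stitched, type = "within",
                                        ignore.strand = TRUE)
  expect_length(within, length(peaks))
})

test_that("planted superenhancers are recovered from synthetic tracks", {
  gen <- simulate_genome(seed = 3)
  sim <- simulate_se_signal(gen$chrom_sizes, n_enhancers = 60, se_clusters = 5,
                            enrichment_ratio = 10, seed = 9)
  se <- suppressWarnings(call_enhancers(sim$peaks, sim$chip, sim$input))
  sup <- se$enhancers[se$enhancers$is_super, ]
  sup_gr <- gr0(sup$chrom, sup$start, sup$end)
  truth_gr <- GenomicRanges::GRanges(sim$truth$chrom[sim$truth$is_se],
    IRanges::IRanges(sim$truth$start[sim$truth$is_se] + 1,
                     sim$truth$end[sim$truth$is_se]))
  hit <- GenomicRanges::countOverlaps(truth_gr, sup_gr) > 0
  expect_equal(mean(hit), 1)                       # recall
  fp <- GenomicRanges::countOverlaps(sup_gr, truth_gr) == 0
  expect_equal(mean(fp), 0)                        # precision
  # no separable regime at enrichment_ratio 1: few or no superenhancer calls
  sim1 <- simulate_se_signal(gen$chrom_sizes, n_enhancers = 60, se_clusters = 5,
                             enrichment_ratio = 1, seed = 9)
  se1 <- suppressWarnings(call_enhancers(sim1$peaks, sim1$chip, sim1$input))
  expect_lte(se1$n_super / nrow(se1$enhancers), 0.08)
})
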