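# Sanitization filters, TPM, size factors, the NB Wald test, BH, signature
# calling, clustering, ortholog mapping.

toy_se <- function(counts, biotype = "protein_coding", chrom = "chr1",
                   groups = NULL, length = 1000) {
  counts <- as.matrix(counts)
  n <- nrow(counts)
  if (is.null(rownames(counts))) rownames(counts) <- sprintf("g%03d", seq_len(n))
  if (is.null(colnames(counts)))
    colnames(counts) <- sprintf("s%02d", seq_len(ncol(counts)))
  meta <- data.frame(gene_id = rownames(counts), symbol = rownames(counts),
                     biotype = rep_len(biotype, n), chrom = rep_len(chrom, n),
                     length = rep_len(length, n), stringsAsFactors = FALSE)
  if (is.null(groups)) groups <- rep("g", ncol(counts))
  count_matrix(counts, meta, groups)
}

test_that("gene filters remove by biotype, chromosome, id and symbol", {
  se <- toy_se(matrix(1:10, 5, 2),
               biotype = c("protein_coding", "rRNA", "protein_coding",
                           "protein_coding", "protein_coding"),
               chrom = c("chr1", "chr1", "chrY", "chr1", "chr1"))
  f <- filter_genes(se, drop_biotypes = "rRNA", drop_chroms = "chrY",
                    drop_gene_ids = "g004")
  expect_equal(nrow(f$se), 2)
  expect_equal(unname(f$report[c("biotype", "chrom", "gene_id")]),
               c(1, 1, 1))
  # empty rules are the identity
  f0 <- filter_genes(se)
  expect_equal(nrow(f0$se), 5)
  # symbol regex (e.g. immunoglobulin V/D/J segments)
  se2 <- toy_se(matrix(1:4, 2, 2))
  SummarizedExperiment::rowData(se2)$symbol <- c("Ighv1-2", "Cd19")
  f2 <- filter_genes(se2, drop_symbol_regex = "^Ig[hkl][vdj]")
  expect_equal(nrow(f2$se), 1)
})

test_that("TPM columns behave per the closed form", {
  se <- toy_se(matrix(c(10, 10), 2, 1), length = c(1000, 2000))
  tpm <- tpm_normalize(se)
  expect_equal(unname(tpm[, 1]), c(2e6 / 3, 1e6 / 3), tolerance = 1e-9)
  # single gene gets everything
  expect_equal(unname(tpm_normalize(toy_se(matrix(7, 1, 1)))[1, 1]), 1e6)
  # columns sum to 1e6
  set.seed(5)
  se3 <- toy_se(matrix(rpois(60, 40), 20, 3), length = sample(500:2000, 20))
  expect_equal(unname(colSums(tpm_normalize(se3))), rep(1e6, 3))
  # all-zero sample warns and stays zero
  se0 <- toy_se(matrix(c(5, 3, 0, 0), 2, 2))
  expect_warning(t0 <- tpm_normalize(se0), "all-zero")
  expect_equal(unname(t0[, 2]), c(0, 0))
})

test_that("size factors follow median-of-ratios", {
  cts <- matrix(rep(c(2, 4), each = 3), 3, 2)
  sf <- size_factors(toy_se(cts))
  expect_equal(unname(sf), c(2 / sqrt(8), 4 / sqrt(8)), tolerance = 1e-12)
  # identical samples get equal factors; a 2x-scaled sample doubles its factor
  cts2 <- matrix(rpois(40, 50) + 1, 20, 2)
  cts2[, 2] <- cts2[, 1]
  expect_equal(diff(unname(size_factors(toy_se(cts2)))), 0)
  cts2[, 2] <- cts2[, 1] * 2
  sf2 <- size_factors(toy_se(cts2))
  expect_equal(unname(sf2[2] / sf2[1]), 2, tolerance = 1e-12)
  # all genes hit a zero somewhere: error advising a pseudocount
  expect_error(size_factors(toy_se(matrix(c(0, 1, 1, 0), 2, 2))), "pseudocount")
})

test_that("size factors agree with the reference median-of-ratios implementation", {
  skip_if_not_installed("DESeq2")
  set.seed(19)
  cts <- matrix(rnbinom(600, mu = 100, size = 5), 100, 6)
  expect_equal(unname(size_factors(toy_se(cts))),
               unname(DESeq2::estimateSizeFactorsForMatrix(cts)),
               tolerance = 1e-8)
})

test_that("the NB Wald test is null-centered and recovers planted effects", {
  # identical groups: lfc 0, p near 1
  cts <- matrix(rep(c(20L, 30L, 25L, 20L, 30L, 25L), 4), 4, 6, byrow = TRUE)
  se <- toy_se(cts, groups = rep(c("a", "b"), each = 3))
  de <- nb_wald_test(se, "a", "b")
  expect_equal(de$log2_fc, rep(0, 4))
  expect_true(all(de$p > 0.95))
  # planted LFC is recovered within tolerance
  sim <- simulate_counts(n_genes = 600, n_per_group = 10, frac_de = 0.2,
                         lfc = 2, dispersion = 0.1, seed = 41)
  de2 <- nb_wald_test(sim$se, "WT", "dHET")
  est <- de2$log2_fc[sim$truth$true_lfc > 0]
  expect_lt(abs(mean(est) - 2), 0.25)
  # group with < 2 samples errors
  expect_error(nb_wald_test(toy_se(matrix(1:8, 2, 4),
                                   groups = c("a", "b", "b", "b")), "a", "b"),
               ">= 2 samples")
})

test_that("BH adjustment matches a literal step-up and is monotone", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(c(1, 1)), c(1, 1))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(71)
  for (rep in 1:5) {
    p <- runif(sample(c(3, 10, 200), 1))
    expect_equal(bh_adjust(p), brute_bh(p), tolerance = 1e-12)
    # raising one p never lowers any q
    i <- sample(length(p), 1)
    p2 <- p; p2[i] <- min(1, p2[i] + 0.1)
    expect_true(all(bh_adjust(p2) >= bh_adjust(p) - 1e-12))
  }
})

test_that("signature calling applies both thresholds with direction", {
  res <- data.frame(gene_id = c("a", "b", "c", "d"),
                    base_mean = 10, log2_fc = c(log2(1.5), log2(1.1), log2(3), -1),
                    se = 1, wald = 1,
                    p = c(0.001, 0.001, 0.02, 0.001),
                    q = c(0.01, 0.01, 0.06, 0.01), zero_group = FALSE)
  attr(res, "contrast") <- c(group1 = "WT", group2 = "KO")
  class(res) <- c("de_result", "data.frame")
  called <- call_de(res, fdr = 0.05, min_fc = 1.2)
  expect_equal(called$up, "a")          # q ok, FC 1.5
  expect_equal(called$down, "d")        # q ok, FC 2 down
  expect_false("b" %in% c(called$up, called$down))   # FC 1.1 fails
  expect_false("c" %in% c(called$up, called$down))   # q 0.06 fails
  expect_length(intersect(called$up, called$down), 0)
})

test_that("sample clustering is UPGMA on 1 - Pearson distance", {
  set.seed(3)
  m <- matrix(rnorm(200), 50, 4, dimnames = list(NULL, paste0("s", 1:4)))
  # duplicated columns merge first at height 0
  m[, 2] <- m[, 1]
  cl <- cluster_samples(m, top_n = 50)
  expect_equal(cl$hclust$height[1], 0, tolerance = 1e-12)
  first <- sort(abs(cl$hclust$merge[1, ]))
  expect_equal(first, c(1, 2))
  # anticorrelated samples sit at distance 2
  m2 <- cbind(a = rnorm(30)); m2 <- cbind(m2, b = -m2[, 1], c = rnorm(30))
  d <- 1 - cor(m2)
  expect_equal(d["a", "b"], 2, tolerance = 1e-12)
  # merge heights match the exhaustive UPGMA oracle
  m3 <- matrix(rnorm(120), 30, 4)
  cl3 <- cluster_samples(m3, top_n = 30)
  d3 <- as.dist(1 - cor(m3))
  expect_equal(cl3$hclust$height, brute_upgma_heights(d3), tolerance = 1e-12)
  # constant rows are dropped with a warning, not an error
  m4 <- rbind(matrix(rnorm(40), 10, 4), matrix(1, 2, 4))
  expect_warning(cluster_samples(m4, top_n = 12), "constant")
})

test_that("ortholog mapping honours 1:many policy and reports unmapped", {
  map <- data.frame(src = c("Cd74", "Myc", "Dup", "Dup"),
                    tgt = c("CD74", "MYC", "D1", "D2"))
  r <- map_orthologs(c("Cd74", "Missing"), map)
  expect_equal(r$mapped, "CD74")
  expect_equal(r$unmapped, "Missing")
  expect_equal(map_orthologs("Dup", map, "keep_all")$mapped, c("D1", "D2"))
  expect_equal(map_orthologs("Dup", map, "first")$mapped, "D1")
  # duplicates emitted once, first-occurrence order preserved
  r2 <- map_orthologs(c("Myc", "Cd74"), map)
  expect_equal(r2$mapped, c("MYC", "CD74"))
})
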