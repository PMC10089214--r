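# End-to-end orchestration: the simulate / chromatin / expression workflows
# over a self-contained fixture directory, with fail-fast validation and a
# deterministic manifest (no timestamps) so identical config + seed gives
# byte-identical output.

#' Write a self-contained synthetic fixture directory
#'
#' Runs every generator off child seeds fanned out from the master seed and
#' writes all inputs the chromatin and expression workflows consume:
#' gene models, chromosome sizes, two co-occupancy peak sets, histone-mark
#' peak sets with planted states, enhancer constituent peaks with ChIP and
#' input bedGraphs (planted superenhancers), an NB count matrix with planted
#' fold changes, a GMT with one planted and several decoy sets, and
#' ground-truth tables for each planted quantity.
#'
#' @param dir output directory (created).
#' @param seed master integer seed.
#' @param n_A,n_B co-occupancy set sizes.
#' @param cobound_fraction planted co-bound fraction.
#' @param n_enhancers,se_clusters,enrichment_ratio superenhancer plant.
#' @param n_genes_expr,n_per_group,frac_de,lfc,dispersion count-matrix plant.
#' @return the fixture directory path, invisibly.
#' @export
simulate_fixture <- function(dir, seed = 1, n_A = 1000, n_B = 1000,
                             cobound_fraction = 0.6,
                             n_enhancers = 100, se_clusters = 5,
                             enrichment_ratio = 10,
                             n_genes_expr = 2000, n_per_group = 10,
                             frac_de = 0.1, lfc = 2, dispersion = 0.1) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  gen <- simulate_genome(seed = child_seed(seed, 1L))
  write_gene_models(gen$genes, file.path(dir, "genes.tsv"))
  utils::write.table(
    data.frame(chrom = names(gen$chrom_sizes), size = gen$chrom_sizes),
    file.path(dir, "chrom_sizes.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)

  co <- simulate_cooccupancy(gen$chrom_sizes, n_A = n_A, n_B = n_B,
                             cobound_fraction = cobound_fraction,
                             seed = child_seed(seed, 2L))
  write_intervals(co$A, file.path(dir, "peaks_A.bed"))
  write_intervals(co$B, file.path(dir, "peaks_B.bed"))
  utils::write.table(co$truth, file.path(dir, "truth_cooccupancy.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  marks <- simulate_mark_states(co$A, seed = child_seed(seed, 3L))
  write_intervals(marks$k4me1, file.path(dir, "marks_k4me1.bed"))
  write_intervals(marks$k4me3, file.path(dir, "marks_k4me3.bed"))
  write_intervals(marks$k27ac, file.path(dir, "marks_k27ac.bed"))
  utils::write.table(marks$truth, file.path(dir, "truth_states.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  sesim <- simulate_se_signal(gen$chrom_sizes, n_enhancers = n_enhancers,
                              se_clusters = se_clusters,
                              enrichment_ratio = enrichment_ratio,
                              seed = child_seed(seed, 4L))
  write_intervals(sesim$peaks, file.path(dir, "enhancer_peaks.bed"))
  write_bedgraph(sesim$chip, file.path(dir, "chip.bedgraph"))
  write_bedgraph(sesim$input, file.path(dir, "input.bedgraph"))
  utils::write.table(
    data.frame(total_reads_chip = sesim$chip$total_reads,
               total_reads_input = sesim$input$total_reads),
    file.path(dir, "library_sizes.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  utils::write.table(sesim$truth, file.path(dir, "truth_se.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  cts <- simulate_counts(n_genes = n_genes_expr, n_per_group = n_per_group,
                         frac_de = frac_de, lfc = lfc,
                         dispersion = dispersion,
                         seed = child_seed(seed, 5L))
  write_counts(cts$se, file.path(dir, "counts.tsv"))
  utils::write.table(
    as.data.frame(SummarizedExperiment::rowData(cts$se)),
    file.path(dir, "counts_genes.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  utils::write.table(
    data.frame(sample = colnames(cts$se),
               group = SummarizedExperiment::colData(cts$se)$group),
    file.path(dir, "groups.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  write_gmt(cts$sets, file.path(dir, "sets.gmt"))
  utils::write.table(cts$truth, file.path(dir, "truth_de.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

fixture_inputs <- list(
  chromatin = c("genes.tsv", "peaks_A.bed", "peaks_B.bed", "marks_k4me1.bed",
                "marks_k4me3.bed", "marks_k27ac.bed", "enhancer_peaks.bed",
                "chip.bedgraph", "input.bedgraph", "library_sizes.tsv"),
  expression = c("counts.tsv", "counts_genes.tsv", "groups.tsv", "sets.gmt"))

#' Run an end-to-end workflow
#'
#' \code{"simulate"} writes the default fixture under
#' \code{out_dir/fixture}.  \code{"chromatin"} runs peak annotation,
#' co-bound classification, the shared/unique overlap summary with its
#' hypergeometric test, chromatin-state classification, enhancer/
#' superenhancer calling and the binned signal profile.  \code{"expression"}
#' runs the sanitization filters, TPM, top-SD sample clustering, the NB Wald
#' test with signature calling, and the preranked GSEA panel.  All inputs
#' are validated before any stage runs; a deterministic \code{manifest.json}
#' (parameters, seed, input and output checksums) is written last.
#'
#' @param out_dir output directory.
#' @param workflow one of \code{"simulate"}, \code{"chromatin"},
#'   \code{"expression"}, \code{"all"}.
#' @param seed master integer seed.
#' @param fixture_dir directory holding the inputs (defaults to
#'   \code{out_dir/fixture}; for \code{"simulate"} and \code{"all"} it is
#'   created there).
#' @param params named list overriding stage defaults (\code{max_dist},
#'   \code{max_gap}, \code{fdr}, \code{min_fc}, \code{top_n},
#'   \code{n_perm}, \code{window_bp}, \code{bin_bp}, plus any
#'   \code{\link{simulate_fixture}} argument).
#' @return named list of the main computed quantities, invisibly; all stage
#'   artifacts and \code{manifest.json} are under \code{out_dir}.
#' @export
run_pipeline <- function(out_dir, workflow = c("all", "simulate", "chromatin",
                                               "expression"),
                         seed = 1, fixture_dir = NULL, params = list()) {
  workflow <- match.arg(workflow)
  seed <- assert_count(seed, "seed")
  p <- utils::modifyList(list(max_dist = 1000, max_gap = 12500, fdr = 0.05,
                              min_fc = 1.2, top_n = 500, n_perm = 1000,
                              window_bp = 3000, bin_bp = 100), params)
  if (is.null(fixture_dir)) fixture_dir <- file.path(out_dir, "fixture")
  # fail-fast validation before any stage writes anything
  if (workflow %in% c("chromatin", "expression")) {
    need <- file.path(fixture_dir, fixture_inputs[[workflow]])
    missing <- need[!file.exists(need)]
    if (length(missing))
      stopf("missing input(s): %s", paste(missing, collapse = ", "))
  }
  for (key in c("max_dist", "max_gap", "top_n", "n_perm", "window_bp", "bin_bp"))
    assert_count(p[[key]], key, lower = 1)
  assert_scalar_num(p$fdr, "fdr", lower = 0, upper = 1)
  assert_scalar_num(p$min_fc, "min_fc", lower = 1)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  results <- list()
  if (workflow %in% c("simulate", "all")) {
    sim_args <- params[names(params) %in% names(formals(simulate_fixture))]
    do.call(simulate_fixture,
            c(list(dir = fixture_dir, seed = seed), sim_args))
  }
  if (workflow %in% c("chromatin", "all"))
    results <- c(results, run_chromatin(out_dir, fixture_dir, p))
  if (workflow %in% c("expression", "all"))
    results <- c(results, run_expression(out_dir, fixture_dir, p, seed))
  write_manifest(out_dir, fixture_dir, workflow, seed, p)
  invisible(results)
}

run_chromatin <- function(out_dir, fx, p) {
  genes <- read_gene_models(file.path(fx, "genes.tsv"), "tsv")
  A <- read_intervals(file.path(fx, "peaks_A.bed"))
  B <- read_intervals(file.path(fx, "peaks_B.bed"))
  lib <- utils::read.table(file.path(fx, "library_sizes.tsv"), header = TRUE)
  chip <- read_bedgraph(file.path(fx, "chip.bedgraph"), lib$total_reads_chip)
  input <- read_bedgraph(file.path(fx, "input.bedgraph"), lib$total_reads_input)
  epk <- read_intervals(file.path(fx, "enhancer_peaks.bed"))

  ann <- annotate_regions(A, genes)
  utils::write.table(
    data.frame(name = A$name, category = ann),
    file.path(out_dir, "annotation_A.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)

  cb <- classify_cobound(A, B, max_dist = p$max_dist)
  utils::write.table(cbind(name = A$name, cb$calls),
                     file.path(out_dir, "cobound_calls.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  ov <- overlap_summary(A, B, max_dist = p$max_dist)
  utils::write.table(ov$histogram, file.path(out_dir, "distance_histogram.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  ht <- hypergeometric_overlap(N = ov$shared + ov$A_only + ov$B_only,
                               K = ov$shared + ov$A_only,
                               n = ov$shared + ov$B_only, k = ov$shared)
  jsonlite::write_json(
    list(cobound_fraction = cb$fraction, shared = ov$shared,
         A_only = ov$A_only, B_only = ov$B_only,
         hypergeometric_p = ht$p_value,
         fold_enrichment = ht$fold_enrichment),
    file.path(out_dir, "cooccupancy_summary.json"), auto_unbox = TRUE,
    digits = NA)

  marks1 <- read_intervals(file.path(fx, "marks_k4me1.bed"))
  marks3 <- read_intervals(file.path(fx, "marks_k4me3.bed"))
  marksa <- read_intervals(file.path(fx, "marks_k27ac.bed"))
  st <- classify_regions(A, marks1, marks3, marksa)
  write_state_calls(A, st, file.path(out_dir, "chromatin_states.tsv"))

  se <- call_enhancers(epk, chip, input, genes, max_gap = p$max_gap)
  write_se_call(se, file.path(out_dir, "enhancers.tsv"))

  prof <- profile_matrix(chip, epk[seq_len(min(50L, length(epk)))],
                         window_bp = p$window_bp, bin_bp = p$bin_bp)
  write_profile_matrix(prof, file.path(out_dir, "profile_matrix.tsv"))

  list(cobound_fraction = cb$fraction, n_enhancers = nrow(se$enhancers),
       n_super = se$n_super, hypergeometric_p = ht$p_value,
       annotation_counts = table(ann))
}

run_expression <- function(out_dir, fx, p, seed) {
  meta <- utils::read.table(file.path(fx, "counts_genes.tsv"), header = TRUE,
                            sep = "\t", stringsAsFactors = FALSE)
  grp <- utils::read.table(file.path(fx, "groups.tsv"), header = TRUE,
                           sep = "\t", stringsAsFactors = FALSE)
  se <- read_counts(file.path(fx, "counts.tsv"), meta, grp$group)
  flt <- filter_genes(se,
                      drop_biotypes = c("rRNA", "miRNA", "pseudogene",
                                        "antisense", "read_through"),
                      drop_chroms = "chrY",
                      drop_symbol_regex = "^Ig[hkl][vdj]")
  tpm <- tpm_normalize(flt$se)
  utils::write.table(data.frame(gene_id = rownames(tpm), round(tpm, 4),
                                check.names = FALSE),
                     file.path(out_dir, "tpm.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (ncol(tpm) >= 2L) {
    cl <- cluster_samples(tpm, top_n = p$top_n)
    utils::write.table(
      data.frame(order = cl$order, sample = colnames(tpm)[cl$order]),
      file.path(out_dir, "sample_clustering.tsv"), sep = "\t",
      quote = FALSE, row.names = FALSE)
  }
  glev <- unique(grp$group)
  de <- nb_wald_test(flt$se, glev[1L], glev[2L])
  called <- call_de(de, fdr = p$fdr, min_fc = p$min_fc)
  utils::write.table(called$results, file.path(out_dir, "de_results.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  sig <- c(make_signature(called, "up"), make_signature(called, "down"))
  write_gmt(sig[lengths(sig) > 0], file.path(out_dir, "signatures.gmt"))

  sets <- read_gmt(file.path(fx, "sets.gmt"))
  ranked <- ranked_list(called$results$gene_id, called$results$wald)
  panel <- run_signature_panel(ranked, sets, alpha = p$fdr,
                               n_perm = p$n_perm, seed = seed)
  utils::write.table(panel, file.path(out_dir, "gsea_panel.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  list(n_genes_tested = nrow(de), n_up = length(called$up),
       n_down = length(called$down),
       n_significant_sets = sum(panel$significant))
}

write_manifest <- function(out_dir, fixture_dir, workflow, seed, p) {
  checksum <- function(dir) {
    files <- sort(list.files(dir, recursive = FALSE))
    files <- files[file.exists(file.path(dir, files)) &
                   !dir.exists(file.path(dir, files))]
    files <- setdiff(files, "manifest.json")
    as.list(stats::setNames(unname(tools::md5sum(file.path(dir, files))),
                            files))
  }
  manifest <- list(package = "enhancerscape",
                   version = as.character(utils::packageVersion("enhancerscape")),
                   workflow = workflow, seed = seed,
                   params = p[order(names(p))],
                   inputs = if (dir.exists(fixture_dir)) checksum(fixture_dir)
                            else list(),
                   outputs = checksum(out_dir))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
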