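# Seeded synthetic-data generators with ground-truth tables.  Each
# generator is a pure function of (parameters, seed).  Planted objects are
# placed in disjoint "slots" along each chromosome so that the truth labels
# are unambiguous: solo peaks sit at least five co-binding thresholds away
# from any partner, and enhancer units sit further apart than the stitching
# gap so no two units ever merge.

# distribute n slot positions of pitch `spacing` across chromosomes;
# returns data.frame(chrom, slot_start) or errors when capacity is exceeded
allocate_slots <- function(chrom_sizes, n, spacing) {
  cap <- pmax(floor(chrom_sizes / spacing), 0)
  if (sum(cap) < n)
    stopf("placement infeasible: %d slots needed, %d available at %d bp pitch",
          n, sum(cap), spacing)
  chrom <- rep(names(chrom_sizes), cap)
  start0 <- unlist(lapply(cap, function(k) (seq_len(k) - 1) * spacing),
                   use.names = FALSE)
  data.frame(chrom = chrom, slot_start = start0,
             stringsAsFactors = FALSE)[seq_len(n), , drop = FALSE]
}

#' Simulate a genome annotation
#'
#' Places non-overlapping gene models uniformly along synthetic chromosomes;
#' strands are Bernoulli(0.5) and biotypes are drawn from \code{biotype_mix}
#' (including the rRNA/miRNA/pseudogene classes so that the sanitization
#' filters are exercised).
#'
#' @param n_chroms number of chromosomes.
#' @param chrom_len chromosome length in bp (recycled).
#' @param n_genes number of genes.
#' @param biotype_mix named numeric vector of biotype proportions.
#' @param gene_len_range min/max gene span in bp.
#' @param seed integer seed.
#' @return list with \code{genes} (a \code{gene_models} data frame) and
#'   \code{chrom_sizes} (named vector).
#' @export
simulate_genome <- function(n_chroms = 3, chrom_len = 6e6, n_genes = 300,
                            biotype_mix = c(protein_coding = 0.8, rRNA = 0.05,
                                            miRNA = 0.05, pseudogene = 0.05,
                                            antisense = 0.05),
                            gene_len_range = c(2000, 20000), seed = 1) {
  n_chroms <- assert_count(n_chroms, "n_chroms", lower = 1)
  n_genes <- assert_count(n_genes, "n_genes")
  set.seed(assert_count(seed, "seed"))
  chrom_sizes <- stats::setNames(rep_len(as.integer(chrom_len), n_chroms),
                                 paste0("chr", seq_len(n_chroms)))
  if (n_genes == 0L) {
    genes <- data.frame(gene_id = character(0), symbol = character(0),
                        chrom = character(0), strand = character(0),
                        start = integer(0), end = integer(0),
                        biotype = character(0), length = integer(0),
                        tss = integer(0))
    class(genes) <- c("gene_models", "data.frame")
    return(list(genes = genes, chrom_sizes = chrom_sizes))
  }
  lens <- sample(gene_len_range[1L]:gene_len_range[2L], n_genes, replace = TRUE)
  placed <- vector("list", n_genes)
  occupied <- lapply(chrom_sizes, function(x) IRanges::IRanges())
  tries <- 0L; cap <- 60L * n_genes
  i <- 1L
  while (i <= n_genes) {
    tries <- tries + 1L
    if (tries > cap)
      stopf("placement infeasible: could not fit %d genes without overlap", n_genes)
    ch <- sample(names(chrom_sizes), 1L)
    if (lens[i] >= chrom_sizes[[ch]]) next             # cannot fit here
    s1 <- sample.int(chrom_sizes[[ch]] - lens[i], 1L)  # 1-based start
    cand <- IRanges::IRanges(s1, s1 + lens[i] - 1L)
    if (length(IRanges::findOverlaps(cand, occupied[[ch]])) == 0L) {
      occupied[[ch]] <- c(occupied[[ch]], cand)
      placed[[i]] <- data.frame(chrom = ch, start = s1, end = s1 + lens[i] - 1L,
                                stringsAsFactors = FALSE)
      i <- i + 1L
    }
  }
  pos <- do.call(rbind, placed)
  genes <- data.frame(
    gene_id = sprintf("gene%04d", seq_len(n_genes)),
    symbol = sprintf("Sym%04d", seq_len(n_genes)),
    chrom = pos$chrom,
    strand = sample(c("+", "-"), n_genes, replace = TRUE),
    start = pos$start, end = pos$end,
    biotype = sample(names(biotype_mix), n_genes, replace = TRUE,
                     prob = biotype_mix),
    length = pmax(as.integer(round(0.5 * (pos$end - pos$start + 1L))), 200L),
    stringsAsFactors = FALSE)
  genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end)
  genes <- genes[order_intervals(genes$chrom, genes$start, genes$end,
                                 genes$gene_id), ]
  rownames(genes) <- NULL
  class(genes) <- c("gene_models", "data.frame")
  list(genes = genes, chrom_sizes = chrom_sizes)
}

#' Simulate two peak sets with a planted co-bound fraction
#'
#' A \code{cobound_fraction} share of A peaks is planted with a B partner at
#' an edge gap drawn uniformly from \code{0 .. max_dist - 1}; the remaining
#' A peaks (and the surplus B peaks) are placed at least \code{5 * max_dist}
#' from any peak of the other set, so the planted labels are unambiguous.
#'
#' @param chrom_sizes named vector of chromosome lengths.
#' @param n_A,n_B set sizes.
#' @param cobound_fraction planted co-bound share of A peaks, in [0, 1].
#' @param max_dist co-binding distance threshold in bp.
#' @param peak_width_range min/max peak width in bp.
#' @param seed integer seed.
#' @return list with \code{A}, \code{B} (\code{GRanges} with \code{name})
#'   and \code{truth} (data.frame: \code{name, cobound, planted_gap}).
#' @export
simulate_cooccupancy <- function(chrom_sizes, n_A = 1000, n_B = 1000,
                                 cobound_fraction = 0.6, max_dist = 1000,
                                 peak_width_range = c(200, 400), seed = 1) {
  n_A <- assert_count(n_A, "n_A"); n_B <- assert_count(n_B, "n_B")
  assert_scalar_num(cobound_fraction, "cobound_fraction", lower = 0, upper = 1)
  max_dist <- assert_count(max_dist, "max_dist", lower = 1)
  set.seed(assert_count(seed, "seed"))
  n_co <- round(cobound_fraction * n_A)
  if (n_co > n_B) stopf("n_B too small for the requested cobound_fraction")
  wmax <- peak_width_range[2L]
  # pitch leaves >= 5*max_dist between content of adjacent slots (see below)
  jitter_max <- max_dist
  spacing <- 5L * max_dist + 2L * wmax + max_dist + jitter_max + wmax
  n_slots <- n_co + (n_A - n_co) + (n_B - n_co)
  slots <- allocate_slots(chrom_sizes, n_slots, spacing)
  slots <- slots[sample.int(nrow(slots)), , drop = FALSE]   # shuffle roles
  rw <- function(n) sample(peak_width_range[1L]:peak_width_range[2L], n,
                           replace = TRUE)
  jit <- sample.int(jitter_max, n_slots, replace = TRUE) - 1L
  pos0 <- slots$slot_start + jit                      # 0-based content start
  idx_co <- seq_len(n_co)
  idx_soloA <- n_co + seq_len(n_A - n_co)
  idx_soloB <- n_A + seq_len(n_B - n_co)
  wA <- rw(n_A); wB <- rw(n_B)
  gaps <- if (n_co) sample.int(max_dist, n_co, replace = TRUE) - 1L else integer(0)
  a_chrom <- slots$chrom[c(idx_co, idx_soloA)]
  a_start0 <- pos0[c(idx_co, idx_soloA)]
  A <- GenomicRanges::GRanges(a_chrom,
         IRanges::IRanges(a_start0 + 1L, a_start0 + wA))
  A$name <- sprintf("A%05d", seq_len(n_A))
  b_chrom <- slots$chrom[c(idx_co, idx_soloB)]
  b_start0 <- c(pos0[idx_co] + wA[seq_len(n_co)] + gaps,
                pos0[idx_soloB])
  B <- GenomicRanges::GRanges(b_chrom,
         IRanges::IRanges(b_start0 + 1L, b_start0 + wB))
  B$name <- sprintf("B%05d", seq_len(n_B))
  truth <- data.frame(name = A$name,
                      cobound = seq_len(n_A) <= n_co,
                      planted_gap = c(gaps, rep(NA_integer_, n_A - n_co)),
                      stringsAsFactors = FALSE)
  list(A = sort_intervals(A), B = sort_intervals(B), truth = truth)
}

#' Simulate ChIP/input tracks with planted superenhancers
#'
#' Generates \code{n_enhancers} isolated typical-enhancer peaks plus
#' \code{se_clusters} clusters of 3-6 constituent peaks lying within the
#' stitching range of each other; constituents of a planted superenhancer
#' receive \code{enrichment_ratio} times the typical per-base signal
#' density.  The ChIP track carries Poisson-jittered peak signal over a low
#' uniform background; the input track is flat background with Poisson
#' jitter in 10-kb bins.  Adjacent units are placed further apart than the
#' stitching gap, so each unit stitches to exactly one candidate enhancer.
#'
#' @param chrom_sizes named vector of chromosome lengths.
#' @param n_enhancers number of typical (non-super) enhancer peaks.
#' @param se_clusters number of planted superenhancer clusters.
#' @param enrichment_ratio SE / typical signal-density ratio (> 0).
#' @param background per-base background density (reads/bp) for both tracks.
#' @param peak_width constituent peak width in bp.
#' @param base_density typical-enhancer signal density (reads/bp).
#' @param max_gap stitching gap the analysis will use (placement margin).
#' @param seed integer seed.
#' @return list with \code{peaks} (\code{GRanges} of all constituents,
#'   \code{name}, \code{unit}), \code{chip}, \code{input}
#'   (\code{signal_track}s with \code{total_reads}), and \code{truth}
#'   (data.frame of units: \code{unit, chrom, start, end, is_se}).
#' @export
simulate_se_signal <- function(chrom_sizes, n_enhancers = 100, se_clusters = 5,
                               enrichment_ratio = 10, background = 0.05,
                               peak_width = 500, base_density = 1,
                               max_gap = 12500, seed = 1) {
  n_enhancers <- assert_count(n_enhancers, "n_enhancers")
  se_clusters <- assert_count(se_clusters, "se_clusters")
  assert_scalar_num(enrichment_ratio, "enrichment_ratio", lower = 0)
  assert_scalar_num(background, "background", lower = 0)
  set.seed(assert_count(seed, "seed"))
  n_units <- n_enhancers + se_clusters
  unit_extent <- 6L * peak_width + 5L * 3000L
  spacing <- unit_extent + max_gap + 3000L
  slots <- allocate_slots(chrom_sizes, n_units, spacing)
  slots <- slots[sample.int(nrow(slots)), , drop = FALSE]
  is_se_unit <- seq_len(n_units) <= se_clusters
  peak_rows <- vector("list", n_units)
  unit_span <- vector("list", n_units)
  for (u in seq_len(n_units)) {
    nconst <- if (is_se_unit[u]) sample(3:6, 1L) else 1L
    gaps <- if (nconst > 1L) sample(500:3000, nconst - 1L, replace = TRUE)
            else integer(0)
    starts0 <- slots$slot_start[u] +
      cumsum(c(sample.int(1000L, 1L) - 1L, gaps + peak_width))
    dens <- base_density * (if (is_se_unit[u]) enrichment_ratio else 1)
    peak_rows[[u]] <- data.frame(chrom = slots$chrom[u], start0 = starts0,
                                 end0 = starts0 + peak_width,
                                 density = dens, unit = u,
                                 stringsAsFactors = FALSE)
    unit_span[[u]] <- data.frame(unit = u, chrom = slots$chrom[u],
                                 start = min(starts0), end = max(starts0) + peak_width,
                                 is_se = is_se_unit[u], stringsAsFactors = FALSE)
  }
  pk <- do.call(rbind, peak_rows)
  truth <- do.call(rbind, unit_span)
  # ChIP values: Poisson-jittered reads over each peak, plus background
  lev <- names(chrom_sizes)
  reads <- stats::rpois(nrow(pk), pk$density * peak_width)
  chip_val <- background + reads / peak_width
  chip_gr <- GenomicRanges::GRanges(factor(pk$chrom, levels = lev),
               IRanges::IRanges(pk$start0 + 1L, pk$end0), score = chip_val)
  # background steps between peaks, per chromosome
  bg_steps <- lapply(lev, function(ch) {
    pr <- IRanges::reduce(IRanges::IRanges(pk$start0[pk$chrom == ch] + 1L,
                                           pk$end0[pk$chrom == ch]))
    gaps <- IRanges::gaps(pr, start = 1L, end = chrom_sizes[[ch]])
    if (length(gaps) == 0L) return(NULL)
    GenomicRanges::GRanges(factor(rep(ch, length(gaps)), levels = lev),
                           gaps, score = background)
  })
  bg_steps <- bg_steps[!vapply(bg_steps, is.null, logical(1))]
  chip_all <- if (length(bg_steps)) c(chip_gr, do.call(c, bg_steps)) else chip_gr
  chip <- signal_track(chip_all)
  chip$total_reads <- max(round(chip$total_signal), 1)
  # input: flat background with Poisson jitter in 10-kb bins
  bin <- 10000L
  in_steps <- lapply(lev, function(ch) {
    n_bins <- ceiling(chrom_sizes[[ch]] / bin)
    s0 <- (seq_len(n_bins) - 1L) * bin
    e0 <- pmin(s0 + bin, chrom_sizes[[ch]])
    lam <- background * (e0 - s0)
    GenomicRanges::GRanges(factor(rep(ch, n_bins), levels = lev),
                           IRanges::IRanges(s0 + 1L, e0),
                           score = stats::rpois(n_bins, lam) / (e0 - s0))
  })
  input <- signal_track(do.call(c, in_steps))
  input$total_reads <- max(round(input$total_signal), 1)
  peaks <- GenomicRanges::GRanges(pk$chrom,
             IRanges::IRanges(pk$start0 + 1L, pk$end0))
  peaks$name <- sprintf("peak%05d", seq_len(nrow(pk)))
  peaks$unit <- pk$unit
  list(peaks = sort_intervals(peaks), chip = chip, input = input, truth = truth)
}

#' Simulate histone-mark peak sets with planted chromatin states
#'
#' Draws a state for each region and emits H3K4me1/H3K4me3/H3K27ac peaks
#' overlapping it according to the state's mark combination (active =
#' K4me1+/K27ac+, poised = K4me1+ only, promoter_like = K4me3+, unmarked =
#' none).
#'
#' @param regions a \code{GRanges}.
#' @param state_probs named probabilities over the four states.
#' @param seed integer seed.
#' @return list with \code{k4me1}, \code{k4me3}, \code{k27ac}
#'   (\code{GRanges}) and \code{truth} (data.frame: \code{region_index,
#'   state}).
#' @export
simulate_mark_states <- function(regions,
                                 state_probs = c(active_enhancer = 0.45,
                                                 poised_enhancer = 0.3,
                                                 promoter_like = 0.1,
                                                 unmarked = 0.15),
                                 seed = 1) {
  set.seed(assert_count(seed, "seed"))
  n <- length(regions)
  states <- sample(names(state_probs), n, replace = TRUE, prob = state_probs)
  # mark peak = the region, jittered inward/outward a little
  jitter_gr <- function(sel) {
    if (!any(sel)) return(GenomicRanges::GRanges())
    r <- regions[sel]
    off <- sample(-100:100, sum(sel), replace = TRUE)
    GenomicRanges::GRanges(GenomicRanges::seqnames(r),
      IRanges::IRanges(pmax(GenomicRanges::start(r) + off, 1L),
                       GenomicRanges::end(r) + off))
  }
  k4me1 <- jitter_gr(states %in% c("active_enhancer", "poised_enhancer"))
  k4me3 <- jitter_gr(states == "promoter_like")
  k27ac <- jitter_gr(states == "active_enhancer")
  list(k4me1 = sort_intervals(k4me1), k4me3 = sort_intervals(k4me3),
       k27ac = sort_intervals(k27ac),
       truth = data.frame(region_index = seq_len(n),
                          state = factor(states,
                                         levels = c("active_enhancer",
                                                    "poised_enhancer",
                                                    "promoter_like",
                                                    "unmarked"))))
}

#' Simulate an NB count matrix with planted differential expression
#'
#' Counts are drawn from a negative-binomial model \code{NB(mean = baseline
#' * size_factor * 2^(LFC * group), dispersion)}, with a \code{frac_de}
#' share of genes given the planted log2 fold change (random sign).
#' Planted enriched gene sets are composed predominantly of same-direction
#' DE genes; decoy sets are random draws.
#'
#' @param n_genes number of genes.
#' @param n_per_group samples per group.
#' @param frac_de fraction of genes with a planted LFC.
#' @param lfc planted |log2 fold change|.
#' @param dispersion NB dispersion (0 gives Poisson counts).
#' @param lib_size_range min/max relative library size (uniform).
#' @param n_sets total number of gene sets (planted + decoys).
#' @param n_planted_sets number of planted (truly enriched) sets.
#' @param set_size genes per set.
#' @param planted_purity fraction of a planted set drawn from
#'   same-direction DE genes (default 0.8).
#' @param groups two group labels.
#' @param seed integer seed.
#' @return list with \code{se} (a \code{SummarizedExperiment}), \code{sets}
#'   (named list; planted sets are named \code{set_planted*}), and
#'   \code{truth} (data.frame: \code{gene_id, true_lfc, is_de}).
#' @export
simulate_counts <- function(n_genes = 2000, n_per_group = 10, frac_de = 0.1,
                            lfc = 2, dispersion = 0.1,
                            lib_size_range = c(0.7, 1.3),
                            n_sets = 13, n_planted_sets = 1, set_size = 50,
                            planted_purity = 0.8,
                            groups = c("WT", "dHET"), seed = 1) {
  n_genes <- assert_count(n_genes, "n_genes", lower = 1)
  n_per_group <- assert_count(n_per_group, "n_per_group", lower = 1)
  assert_scalar_num(frac_de, "frac_de", lower = 0, upper = 1)
  assert_scalar_num(dispersion, "dispersion", lower = 0)
  set.seed(assert_count(seed, "seed"))
  gene_id <- sprintf("g%05d", seq_len(n_genes))
  baseline <- stats::rlnorm(n_genes, meanlog = log(100), sdlog = 1)
  n_de <- round(frac_de * n_genes)
  true_lfc <- numeric(n_genes)
  de_idx <- if (n_de) sample.int(n_genes, n_de) else integer(0)
  true_lfc[de_idx] <- lfc * sample(c(-1, 1), n_de, replace = TRUE)
  n_samp <- 2L * n_per_group
  grp <- rep(groups, each = n_per_group)
  sf <- stats::runif(n_samp, lib_size_range[1L], lib_size_range[2L])
  mu <- outer(baseline, sf) * 2^(true_lfc %o% as.numeric(grp == groups[2L]))
  counts <- if (dispersion > 0)
    matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion),
           nrow = n_genes)
  else matrix(stats::rpois(length(mu), mu), nrow = n_genes)
  dimnames(counts) <- list(gene_id,
                           sprintf("%s_%d", grp, rep(seq_len(n_per_group), 2)))
  meta <- data.frame(gene_id = gene_id, symbol = gene_id,
                     biotype = "protein_coding", chrom = "chrS",
                     length = sample(500:5000, n_genes, replace = TRUE),
                     stringsAsFactors = FALSE)
  se <- count_matrix(counts, meta, grp)
  # gene sets: planted sets favour down-regulated genes, decoys are random
  sets <- list()
  if (n_sets > 0) {
    down_pool <- gene_id[true_lfc < 0]
    for (s in seq_len(n_sets)) {
      if (s <= n_planted_sets && length(down_pool)) {
        n_sig <- min(round(planted_purity * set_size), length(down_pool))
        member <- c(sample(down_pool, n_sig),
                    sample(gene_id[true_lfc == 0], set_size - n_sig))
        sets[[sprintf("set_planted%02d", s)]] <- member
      } else {
        sets[[sprintf("set_decoy%02d", s)]] <- sample(gene_id, set_size)
      }
    }
  }
  list(se = se, sets = sets,
       truth = data.frame(gene_id = gene_id, true_lfc = true_lfc,
                          is_de = true_lfc != 0, stringsAsFactors = FALSE))
}
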