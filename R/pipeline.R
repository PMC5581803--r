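#' Run the full catalog pipeline on a file bundle
#'
#' Executes every stage on a directory of input files (such as one
#' written by [simulate_dataset()]): composite model building, length
#' filtering, single/multi-exon split, coding-potential filtering,
#' known/novel flagging, positional classification, expression and
#' differential-expression summaries, nearest-mRNA fold-change
#' correlation, repeat profiling and masking, microdomain discovery
#' against length/AT-matched random controls and protein-coding
#' sequences, chain liftover synteny, conservation aggregation, and
#' peak-overlap / TSS-metaprofile statistics.
#'
#' @param files named character vector of paths, with the names used by
#'   [simulate_dataset()] (`lnc_gtf`, `coding_gtf`, `ref_lnc_gtf`,
#'   `genome_a`, `fpkm`, `samples`, `de`, `coding_potential`, `repeats`,
#'   `peaks`, `coverage`, `scores`, `chain`, `lnc_b_gtf`).
#' @param seed seed for the stochastic stages (matched controls, K
#'   calibration).
#' @param fpkm_threshold expression cut-off (FPKM, strict `>`).
#' @param alpha differential-expression q-value threshold (strict `<`).
#' @param window positional-classification window (bp).
#' @param min_match liftover mapped-fraction threshold.
#' @param word_size,evalue_max microdomain alignment settings.
#' @return a list of per-stage results (see the package vignette).
#' @export
run_pipeline <- function(files, seed = 1, fpkm_threshold = 1.0, alpha = 0.05,
                         window = 5000, min_match = 0.95,
                         word_size = 11, evalue_max = 10) {
  ## -- build: composite models ------------------------------------------
  lnc_tx <- read_gtf(files[["lnc_gtf"]])
  coding_tx <- read_gtf(files[["coding_gtf"]])
  lnc_all <- build_gene_models(lnc_tx, biotype = "lncRNA_candidate")
  coding <- build_gene_models(coding_tx, biotype = "coding")
  genome <- read_genome_fasta(files[["genome_a"]])

  ## -- identification rules ----------------------------------------------
  lnc_len <- filter_min_length(lnc_all, 200)
  cp <- utils::read.delim(files[["coding_potential"]], stringsAsFactors = FALSE)
  lnc_nc <- apply_coding_filter(lnc_len, setNames(cp$label, cp$gene_id))
  parts <- partition_by_exon_count(lnc_nc)
  lnc_multi <- parts$multi

  ref_lnc <- build_gene_models(read_gtf(files[["ref_lnc_gtf"]]))
  catalog <- classify_catalog(lnc_multi, coding, ref_lnc, window = window)
  retained_ids <- catalog$gene_id[catalog$positional_class != "EXCLUDED_SAME_STRAND"]
  lnc_catalog <- lnc_multi[retained_ids]

  ## -- expression / differential expression -------------------------------
  fpkm <- read_fpkm_matrix(files[["fpkm"]])
  meta <- read_sample_meta(files[["samples"]])
  de_table <- read_de_table(files[["de"]])
  expressed <- expressed_genes(fpkm, meta, threshold = fpkm_threshold)
  de <- de_filter(de_table[de_table$gene_id %in% names(lnc_catalog), ],
                  alpha = alpha)
  de_mult <- multiplicity_summary(de$sets)
  de_lnc <- intersect(de$union, names(lnc_catalog))
  cls_dist <- class_distribution(catalog[catalog$gene_id %in% de_lnc, ])
  stats_lnc <- expression_stats(de_lnc, fpkm, meta)
  de_coding <- de_filter(de_table[de_table$gene_id %in% names(coding), ],
                         alpha = alpha)
  stats_coding <- if (length(de_coding$union) > 0) {
    expression_stats(de_coding$union, fpkm, meta)
  } else {
    NULL
  }

  ## nearest-mRNA pairing: for each DE lncRNA take the estimated log2fc in
  ## its most significant cell type, paired with the nearest coding gene's
  ## estimate in the same cell type
  pair_fc <- lapply(de_lnc, function(gid) {
    nn <- nearest_coding_gene(lnc_catalog[[gid]], coding, max_dist = 1e6)
    if (is.null(nn)) return(NULL)
    recs <- de_table[de_table$gene_id == gid, ]
    ct <- recs$cell_type[which.min(recs$q_value)]
    mr <- de_table[de_table$gene_id == nn$gene_id & de_table$cell_type == ct, ]
    if (nrow(mr) == 0L) return(NULL)
    data.frame(gene_id = gid, partner = nn$gene_id, cell_type = ct,
               lnc_fc = recs$log2fc[which.min(recs$q_value)],
               mrna_fc = mr$log2fc[1], distance = nn$distance,
               stringsAsFactors = FALSE)
  })
  pair_fc <- do.call(rbind, pair_fc)
  correlation <- if (!is.null(pair_fc) && nrow(pair_fc) >= 3) {
    fold_change_correlation(pair_fc$lnc_fc, pair_fc$mrna_fc)
  } else {
    NULL
  }

  ## -- repeats -------------------------------------------------------------
  repeats <- load_repeats(files[["repeats"]], format = "bed")
  repeat_profile <- catalog_repeat_profile(lnc_catalog, repeats)
  sequences <- vapply(lnc_catalog, extract_gene_sequence, "", genome = genome)
  masked <- vapply(names(sequences), function(gid) {
    mask_repeats(sequences[[gid]], lnc_catalog[[gid]], repeats)
  }, "")

  ## -- microdomains --------------------------------------------------------
  de_seqs <- masked[intersect(de_lnc, names(masked))]
  at_frac <- local({
    pooled <- paste(de_seqs, collapse = "")
    acgt <- sum(strsplit(pooled, "")[[1]] != "N")
    at <- lengths(regmatches(pooled, gregexpr("[AT]", pooled)))
    at / acgt
  })
  controls <- generate_matched_controls(nchar(de_seqs), at_frac,
                                        seed = stage_seed(seed, 101))
  coding_seqs <- vapply(coding[seq_len(min(length(coding), length(de_seqs)))],
                        extract_gene_sequence, "", genome = genome)
  params <- karlin_altschul_params(k_seed = stage_seed(seed, 102))
  hits <- lapply(
    list(lncRNA = de_seqs, control = controls, coding = coding_seqs),
    local_align_all_pairs, params = params, word_size = word_size,
    evalue_max = evalue_max
  )
  hist_stats <- lapply(hits, hit_length_stats)
  anova <- compare_hit_counts(lapply(hist_stats, `[[`, "histogram"))

  ## -- synteny / conservation ----------------------------------------------
  chains <- read_chain(files[["chain"]])
  lnc_b <- build_gene_models(read_gtf(files[["lnc_b_gtf"]]))
  synteny <- map_catalog_synteny(lnc_catalog, chains, lnc_b,
                                 min_match = min_match)
  genome_b <- read_genome_fasta(files[["genome_b"]])
  synteny$conservation_pct <- vapply(seq_len(nrow(synteny)), function(i) {
    pairwise_conservation_pct(
      extract_gene_sequence(lnc_catalog[[synteny$gene_a[i]]], genome),
      extract_gene_sequence(lnc_b[[synteny$gene_b[i]]], genome_b),
      params, word_size = word_size, evalue_max = evalue_max
    )
  }, 0)
  score_track <- read_bedgraph(files[["scores"]])
  cons_means <- vapply(lnc_catalog, mean_conservation_score, 0,
                       score_track = score_track)

  ## -- epigenome ------------------------------------------------------------
  peaks <- read_peaks(files[["peaks"]])
  coverage <- read_bedgraph(files[["coverage"]])
  overlap <- gene_peak_overlap_pct(lnc_catalog, peaks)
  profile <- tss_profile(lnc_catalog, coverage)

  list(
    models = list(lnc_all = lnc_all, coding = coding, catalog = lnc_catalog),
    partition = lapply(parts, names),
    catalog = catalog,
    expressed = expressed,
    de = de,
    de_multiplicity = de_mult,
    class_distribution = cls_dist,
    expression_stats = list(lncRNA = stats_lnc, coding = stats_coding),
    pairs = pair_fc,
    correlation = correlation,
    repeat_profile = repeat_profile,
    sequences = sequences,
    masked = masked,
    ka_params = params,
    hits = hits,
    hit_stats = hist_stats,
    anova = anova,
    synteny = synteny,
    conservation_means = cons_means,
    peak_overlap = overlap,
    tss_profile = profile
  )
}
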