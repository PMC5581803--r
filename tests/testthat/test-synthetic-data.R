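test_that("generation is byte-identical for a fixed seed", {
  d1 <- tempfile("det1_")
  d2 <- tempfile("det2_")
  s1 <- simulate_dataset(synthetic_config(seed = 4), d1)
  s2 <- simulate_dataset(synthetic_config(seed = 4), d2)
  for (f in names(s1$files)) {
    expect_identical(readLines(s1$files[[f]]), readLines(s2$files[[f]]),
                     info = f)
  }
})

test_that("infeasible geometry is rejected", {
  expect_error(synthetic_config(chrom_length = 1e5), "too many genes")
  expect_error(synthetic_config(rho = 1.5), "rho")
  expect_error(synthetic_config(n_coding = 10, n_lnc_per_class = 10),
               "coding genes")
})

test_that("every emitted file parses through its reader without warnings", {
  sim <- sim_bundle()
  expect_no_warning({
    lnc_tx <- read_gtf(sim$files[["lnc_gtf"]])
    read_gtf(sim$files[["coding_gtf"]])
    read_gtf(sim$files[["ref_lnc_gtf"]])
    read_gtf(sim$files[["lnc_b_gtf"]])
    genome <- read_genome_fasta(sim$files[["genome_a"]])
    read_genome_fasta(sim$files[["genome_b"]])
    read_fpkm_matrix(sim$files[["fpkm"]])
    read_sample_meta(sim$files[["samples"]])
    read_de_table(sim$files[["de"]])
    load_repeats(sim$files[["repeats"]], "bed")
    read_peaks(sim$files[["peaks"]])
    read_bedgraph(sim$files[["coverage"]])
    read_bedgraph(sim$files[["scores"]])
    read_chain(sim$files[["chain"]])
  })
  expect_equal(length(genome), sim$config$n_chroms)
  expect_gt(length(lnc_tx), 0)
})

test_that("planted positional classes are recovered exactly", {
  sim <- sim_bundle()
  lnc <- build_gene_models(read_gtf(sim$files[["lnc_gtf"]]))
  coding <- build_gene_models(read_gtf(sim$files[["coding_gtf"]]),
                              biotype = "coding")
  planted <- sim$truth$classes
  # the planted classes refer to the multi-exon retained + excluded genes
  check <- names(planted)[grepl("^LNC_(AS|UP|DN|LINC|EXCL)_", names(planted))]
  got <- vapply(check, function(gid) {
    classify_relative_position(lnc[[gid]], coding)
  }, "")
  expect_equal(unname(got), unname(planted[check]))
})

test_that("planted novelty, filters and DE multiplicities are recovered", {
  sim <- sim_bundle()
  lnc <- build_gene_models(read_gtf(sim$files[["lnc_gtf"]]))
  ref <- build_gene_models(read_gtf(sim$files[["ref_lnc_gtf"]]))
  lab <- flag_known_vs_novel(lnc, ref)
  expect_equal(unname(lab[names(sim$truth$novelty)]),
               unname(sim$truth$novelty))
  # length filter drops exactly the short genes
  kept <- filter_min_length(lnc)
  expect_setequal(setdiff(names(lnc), names(kept)), sim$truth$short)
  # exon partition singles out exactly the single-exon plants (the short
  # ones are single-exon too)
  parts <- partition_by_exon_count(lnc)
  expect_setequal(names(parts$single),
                  c(sim$truth$single, sim$truth$short))
  # multiplicity summary on the planted per-cell-type DE sets returns the
  # planted counts exactly
  cts <- sim$config$cell_types
  sets <- lapply(cts, function(ct) {
    names(Filter(function(x) ct %in% x, sim$truth$de_cts))
  })
  names(sets) <- cts
  ms <- multiplicity_summary(sets)
  expect_equal(ms$count, sim$truth$multiplicity)
})

test_that("the generator's own DE test has power on the planted genes", {
  sim <- sim_bundle()
  de <- de_filter(read_de_table(sim$files[["de"]]))
  planted <- names(sim$truth$de_cts)
  hits <- vapply(planted, function(g) {
    cts <- sim$truth$de_cts[[g]]
    mean(vapply(cts, function(ct) g %in% de$sets[[ct]], TRUE))
  }, 0)
  expect_gte(mean(hits), 0.9)
})

test_that("planted motifs are present in the extracted transcripts", {
  sim <- sim_bundle()
  genome <- read_genome_fasta(sim$files[["genome_a"]])
  lnc <- build_gene_models(read_gtf(sim$files[["lnc_gtf"]]))
  for (i in seq_len(nrow(sim$truth$motif$positions))) {
    gid <- sim$truth$motif$positions$gene_id[i]
    t0 <- sim$truth$motif$positions$t_start[i]
    seq <- extract_gene_sequence(lnc[[gid]], genome)
    expect_equal(substring(seq, t0 + 1, t0 + nchar(sim$truth$motif$motif)),
                 sim$truth$motif$motif, info = gid)
  }
})

test_that("plant_shared_motif is seeded, positional and reversible", {
  seqs <- generate_matched_controls(rep(100, 4), 0.5, seed = 2)
  # zero carriers: unchanged
  none <- plant_shared_motif(seqs, "ACGTACGTACGTACGTACGT", character(0))
  expect_identical(none$sequences, seqs)
  pl <- plant_shared_motif(seqs, "ACGTACGTACGTACGTACGT", c("ctrl_1", "ctrl_3"),
                           seed = 9)
  for (i in seq_len(nrow(pl$positions))) {
    expect_equal(
      substring(pl$sequences[[pl$positions$id[i]]],
                pl$positions$start[i] + 1, pl$positions$start[i] + 20),
      "ACGTACGTACGTACGTACGT"
    )
  }
  # a 20-nt motif planted in 2 carriers is found by the aligner, covering
  # both planted positions
  ka2 <- karlin_altschul_params(k_const = 0.48)
  h <- local_align_all_pairs(pl$sequences[c("ctrl_1", "ctrl_3")], ka2)
  i <- which(h$length >= 20)[1]
  expect_false(is.na(i))
  p1 <- pl$positions$start[pl$positions$id == "ctrl_1"]
  p3 <- pl$positions$start[pl$positions$id == "ctrl_3"]
  expect_lte(h$q_start[i], p1)
  expect_gte(h$q_end[i], p1 + 20)
  expect_lte(h$s_start[i], p3)
  expect_gte(h$s_end[i], p3 + 20)
  # reverse-complement planting surfaces as a '-'-strand hit
  motif <- "ACCGTTGACCGTAGGTTGCA"
  fwd <- plant_shared_motif(seqs["ctrl_2"], motif, "ctrl_2", seed = 10)
  rcp <- plant_shared_motif(seqs["ctrl_4"], motif, "ctrl_4", seed = 11,
                            revcomp_plant = TRUE)
  h2 <- local_align_all_pairs(
    c(fwd$sequences["ctrl_2"], rcp$sequences["ctrl_4"]), ka2
  )
  expect_true(any(h2$subject_strand == "-" & h2$length >= 20))
  expect_error(plant_shared_motif(c(a = "ACGT"), "ACGTTGCAGG", "a"), "longer")
})

test_that("planted synteny pairs are recovered exactly, decoys stay unpaired", {
  sim <- sim_bundle()
  lnc <- build_gene_models(read_gtf(sim$files[["lnc_gtf"]]))
  lnc_b <- build_gene_models(read_gtf(sim$files[["lnc_b_gtf"]]))
  chains <- read_chain(sim$files[["chain"]])
  retained <- lnc[sim$truth$retained]
  pairs <- map_catalog_synteny(retained, chains, lnc_b, min_match = 0.95)
  expect_setequal(
    paste(pairs$gene_a, pairs$gene_b),
    paste(sim$truth$syntenic$gene_a, sim$truth$syntenic$gene_b)
  )
  # no chains -> empty
  none <- map_catalog_synteny(retained, list(), lnc_b)
  expect_equal(nrow(none), 0)
})

test_that("planted conservation scores aggregate exactly per gene", {
  sim <- sim_bundle()
  track <- read_bedgraph(sim$files[["scores"]])
  lnc <- build_gene_models(read_gtf(sim$files[["lnc_gtf"]]))
  syn <- sim$truth$syntenic$gene_a
  other <- setdiff(sim$truth$retained, syn)
  for (gid in syn[1:3]) {
    expect_equal(mean_conservation_score(lnc[[gid]], track),
                 unname(sim$truth$cons_scores["lnc_syntenic"]), info = gid)
  }
  for (gid in other[1:3]) {
    expect_equal(mean_conservation_score(lnc[[gid]], track),
                 unname(sim$truth$cons_scores["lnc_other"]), info = gid)
  }
})

test_that("active genes carry peaks and TSS coverage, inactive do not", {
  sim <- sim_bundle()
  lnc <- build_gene_models(read_gtf(sim$files[["lnc_gtf"]]))
  coding <- build_gene_models(read_gtf(sim$files[["coding_gtf"]]),
                              biotype = "coding")
  all_models <- c(coding, lnc)
  peaks <- read_peaks(sim$files[["peaks"]])
  coverage <- read_bedgraph(sim$files[["coverage"]])
  active <- all_models[sim$truth$active]
  inactive <- all_models[setdiff(names(all_models), sim$truth$active)]
  expect_equal(gene_peak_overlap_pct(active, peaks)$pct, 100)
  expect_lt(gene_peak_overlap_pct(inactive, peaks)$pct,
            gene_peak_overlap_pct(active, peaks)$pct)
  pr <- tss_profile(active, coverage)
  mid <- length(pr$mean_profile) / 2
  expect_gt(mean(pr$mean_profile[(mid - 5):(mid + 5)]),
            mean(pr$mean_profile[c(1:10, 191:200)]) + 1)
})
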