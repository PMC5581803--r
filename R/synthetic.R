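## Synthetic two-species test-bed.
##
## The generator lays genes out in independent "cassettes": each slot of
## a fixed grid holds either one protein-coding gene (optionally with a
## lncRNA planted in a defined positional geometry against it) or a
## lone lncRNA. Slots are separated by gene-free margins wider than the
## classification window, so each lncRNA's class is determined by its
## own cassette alone and the planted label is recoverable by
## construction.

SIM_STAGES <- c(layout = 1, genome = 2, expression = 3, repeats = 4,
                motif = 5, conservation = 6, chain = 7, epigenome = 8)

#' Configuration for the synthetic dataset generator
#'
#' Defaults describe a compact but fully featured study: two 1-Mb
#' chromosomes per species, 60 protein-coding genes, 10 lncRNAs per
#' positional class, AT-rich background (58% AT), planted log2 fold
#' changes of magnitude ~2 with a planted lncRNA/nearest-mRNA
#' fold-change correlation of 0.7, a shared 20-nt motif in 12 carrier
#' lncRNAs, ~30% exonic repeat content, and a handful of
#' insertions/deletions/inversions separating the two genomes.
#'
#' @param seed master integer seed; every sub-stage derives its own
#'   stream from it.
#' @param n_chroms,chrom_length chromosomes per species and their length.
#' @param n_coding number of protein-coding genes.
#' @param n_lnc_per_class lncRNAs planted per positional class (AS,
#'   AS_UPSTREAM, AS_DOWNSTREAM, LINCRNA, EXCLUDED_SAME_STRAND).
#' @param n_short sub-200-nt lncRNA candidates (length-filter fodder).
#' @param n_single single-exon lncRNA candidates.
#' @param n_coding_decoys lncRNA candidates labelled `coding` in the
#'   coding-potential table.
#' @param at_fraction background AT fraction.
#' @param de_log2fc magnitude of planted log2 fold changes.
#' @param rho planted correlation between lncRNA and nearest-mRNA fold
#'   changes, in `[-1, 1]`.
#' @param n_reps replicates per (cell type, condition).
#' @param cell_types cell-type labels.
#' @param fpkm_noise_sdlog lognormal noise sd (natural-log scale) on
#'   FPKM values.
#' @param motif shared motif sequence planted into carrier lncRNAs.
#' @param n_motif_carriers carrier count.
#' @param repeat_density target repeat fraction of a lncRNA's first exon.
#' @param n_edits_per_chrom rearrangements (deletion, insertion,
#'   inversion) between the two genomes, per chromosome.
#' @param n_syntenic lncRNAs with planted syntenic copies in species B.
#' @param n_b_decoys species-B-only lncRNAs.
#' @param window classification window the geometry is built against.
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(seed = 1, n_chroms = 2, chrom_length = 1e6,
                             n_coding = 60, n_lnc_per_class = 10,
                             n_short = 3, n_single = 4, n_coding_decoys = 2,
                             at_fraction = 0.58, de_log2fc = 2, rho = 0.7,
                             n_reps = 3,
                             cell_types = c("ct1", "ct2", "ct3", "ct4"),
                             fpkm_noise_sdlog = 0.25,
                             motif = "ACGTTGCAGTCAGGCATTCG",
                             n_motif_carriers = 12,
                             repeat_density = 0.3,
                             n_edits_per_chrom = 3,
                             n_syntenic = 8, n_b_decoys = 6,
                             window = 5000) {
  cfg <- as.list(environment())
  if (rho < -1 || rho > 1) stop("rho must lie in [-1, 1]")
  if (any(c(n_chroms, chrom_length, n_coding, n_lnc_per_class, n_reps) <= 0)) {
    stop("counts must be positive")
  }
  if (n_coding < 4 * n_lnc_per_class) {
    stop("configuration error: need at least 4 * n_lnc_per_class coding genes")
  }
  n_slots <- n_coding + n_lnc_per_class + n_short + n_single + n_coding_decoys
  slots_per_chrom <- ceiling(n_slots / n_chroms)
  slot_width <- floor(chrom_length / slots_per_chrom)
  if (slot_width < 20500) {
    stop("configuration error: too many genes for chromosome length ",
         "(slot width ", slot_width, " < 20500)")
  }
  cfg$n_slots <- n_slots
  cfg$slots_per_chrom <- slots_per_chrom
  cfg$slot_width <- slot_width
  class(cfg) <- "synthetic_config"
  cfg
}

random_dna <- function(n, at_fraction) {
  probs <- c(A = at_fraction / 2, C = (1 - at_fraction) / 2,
             G = (1 - at_fraction) / 2, T = at_fraction / 2)
  paste(sample(names(probs), n, TRUE, probs), collapse = "")
}

## Exon layout helpers (coordinates relative to a start offset).
rand_exons <- function(origin, widths, introns) {
  starts <- origin + cumsum(c(0, widths[-length(widths)] + introns))
  data.frame(start = starts, end = starts + widths)
}

lnc_exon_widths <- function() sample(250:600, 2, TRUE)
lnc_intron <- function() sample(200:600, 1)

#' Paired fold changes with a planted correlation
#'
#' The lncRNA fold change is a random sign times
#' `de_log2fc + |N(0, 0.5)|`; the mRNA partner fold change is
#' `rho * lnc + sqrt(1 - rho^2) * sd(lnc) * z`, which has Pearson
#' correlation `rho` with the lncRNA values for any lncRNA fold-change
#' distribution.
#'
#' @param n number of pairs.
#' @param rho target correlation.
#' @param de_log2fc fold-change magnitude floor.
#' @param seed RNG seed.
#' @return data.frame with `lnc_fc`, `mrna_fc`.
#' @export
simulate_fold_changes <- function(n, rho, de_log2fc = 2, seed = 1) {
  with_stage_seed(seed, 0, {
    lnc_fc <- sample(c(-1, 1), n, TRUE) * (de_log2fc + abs(stats::rnorm(n, 0, 0.5)))
    s <- stats::sd(lnc_fc)
    mrna_fc <- rho * lnc_fc + sqrt(1 - rho^2) * s * stats::rnorm(n)
    data.frame(lnc_fc = lnc_fc, mrna_fc = mrna_fc)
  })
}

#' Overwrite a shared motif into carrier sequences
#'
#' The motif is written over the background at one seeded random offset
#' per carrier (length-preserving, so matched controls stay matched).
#'
#' @param sequences named character vector.
#' @param motif motif sequence (shorter than every carrier).
#' @param carriers names (or indices) of carrier sequences.
#' @param seed RNG seed.
#' @param revcomp_plant plant the reverse complement instead.
#' @return list with modified `sequences` and `positions` (data.frame
#'   `id`, `start`, 0-based offsets).
#' @export
plant_shared_motif <- function(sequences, motif, carriers, seed = 1,
                               revcomp_plant = FALSE) {
  if (length(carriers) == 0L) {
    return(list(sequences = sequences,
                positions = data.frame(id = character(0), start = numeric(0))))
  }
  if (is.numeric(carriers)) carriers <- names(sequences)[carriers]
  w <- nchar(motif)
  if (any(nchar(sequences[carriers]) <= w)) {
    stop("motif longer than a carrier sequence")
  }
  planted <- if (revcomp_plant) revcomp_chr(motif) else motif
  with_stage_seed(seed, 0, {
    pos <- vapply(carriers, function(id) {
      sample.int(nchar(sequences[[id]]) - w + 1L, 1L) - 1L
    }, 0L)
    for (id in carriers) {
      s <- sequences[[id]]
      sequences[[id]] <- paste0(
        substring(s, 1, pos[[id]]), planted,
        substring(s, pos[[id]] + w + 1, nchar(s))
      )
    }
    list(sequences = sequences,
         positions = data.frame(id = carriers, start = unname(pos),
                                stringsAsFactors = FALSE))
  })
}

#' Derive a second genome plus the exact chain describing the edits
#'
#' Genome B is built from genome A by applying non-overlapping
#' insertions, deletions and inversions; chain blocks are computed
#' exactly from the edit list (one `+` chain per chromosome for the
#' colinear blocks, plus one `-` chain per inversion).
#'
#' @param genome_a named character vector of chromosome sequences.
#' @param edits data.frame `chrom`, `start`, `end`, `type`
#'   (`deletion`/`insertion`/`inversion`), `seq` (inserted sequence;
#'   insertions have `end == start`).
#' @param b_suffix appended to chromosome names in genome B.
#' @return list with `genome_b`, `chains`, and `map` — a
#'   `function(chrom, pos)` giving the genome-B position of an A base in
#'   a colinear block (NA inside edits).
#' @export
make_chain_pair <- function(genome_a, edits, b_suffix = "_B") {
  if (nrow(edits) > 0) {
    bad <- !edits$type %in% c("deletion", "insertion", "inversion")
    if (any(bad)) stop("unknown edit type: ", edits$type[bad][1])
    if (any(edits$type != "insertion" & edits$end <= edits$start)) {
      stop("deletion/inversion edits need positive size")
    }
    if (any(edits$type == "insertion" &
            (edits$end != edits$start | nchar(edits$seq) == 0))) {
      stop("insertions need end == start and a non-empty seq")
    }
  }
  chains <- list()
  genome_b <- character(0)
  maps <- list()
  cid <- 0
  for (chrom in names(genome_a)) {
    a_seq <- genome_a[[chrom]]
    a_len <- nchar(a_seq)
    b_chrom <- paste0(chrom, b_suffix)
    ed <- edits[edits$chrom == chrom, , drop = FALSE]
    ed <- ed[order(ed$start), , drop = FALSE]
    if (nrow(ed) > 1 && any(ed$start[-1] < ed$end[-nrow(ed)])) {
      stop("overlapping edits on ", chrom)
    }
    if (nrow(ed) > 0 && any(ed$end > a_len)) {
      stop("edit beyond end of ", chrom)
    }
    pieces <- character(0)
    canon <- list()
    inv_canon <- list()
    src <- 0
    tgt <- 0
    emit_colinear <- function(upto) {
      if (upto > src) {
        pieces[[length(pieces) + 1L]] <<- substring(a_seq, src + 1, upto)
        canon[[length(canon) + 1L]] <<- data.frame(
          s_start = src, s_end = upto,
          t_start = tgt, t_end = tgt + (upto - src)
        )
        tgt <<- tgt + (upto - src)
        src <<- upto
      }
    }
    for (k in seq_len(nrow(ed))) {
      emit_colinear(ed$start[k])
      if (ed$type[k] == "deletion") {
        src <- ed$end[k]
      } else if (ed$type[k] == "insertion") {
        pieces[[length(pieces) + 1L]] <- ed$seq[k]
        tgt <- tgt + nchar(ed$seq[k])
      } else { # inversion
        seg <- substring(a_seq, ed$start[k] + 1, ed$end[k])
        pieces[[length(pieces) + 1L]] <- revcomp_chr(seg)
        inv_canon[[length(inv_canon) + 1L]] <- data.frame(
          s_start = ed$start[k], s_end = ed$end[k],
          t_start = tgt, t_end = tgt + nchar(seg)
        )
        tgt <- tgt + nchar(seg)
        src <- ed$end[k]
      }
    }
    emit_colinear(a_len)
    b_seq <- paste(pieces, collapse = "")
    genome_b[[b_chrom]] <- b_seq
    cid <- cid + 1
    chains[[length(chains) + 1L]] <- new_chain(
      1000, as.character(cid), chrom, a_len, b_chrom, nchar(b_seq),
      "+", do.call(rbind, canon)
    )
    for (ic in inv_canon) {
      cid <- cid + 1
      chains[[length(chains) + 1L]] <- new_chain(
        500, as.character(cid), chrom, a_len, b_chrom, nchar(b_seq), "-", ic
      )
    }
    maps[[chrom]] <- do.call(rbind, canon)
  }
  map <- function(chrom, pos) {
    cb <- maps[[chrom]]
    vapply(pos, function(p) {
      i <- which(cb$s_start <= p & p < cb$s_end)
      if (length(i) == 0L) NA_real_ else cb$t_start[i[1]] + (p - cb$s_start[i[1]])
    }, 0)
  }
  list(genome_b = genome_b, chains = chains, map = map)
}

## Write exon rows of transcript structures as GTF (1-based inclusive).
write_gtf <- function(transcripts, path, source = "lnccat_sim",
                      biotypes = NULL) {
  lines <- unlist(lapply(transcripts, function(tx) {
    bt <- if (!is.null(biotypes)) biotypes[[tx$gene_id]] else NULL
    attrs <- sprintf('gene_id "%s"; transcript_id "%s";%s',
                     tx$gene_id, tx$transcript_id,
                     if (is.null(bt)) "" else sprintf(' gene_biotype "%s";', bt))
    sprintf("%s\t%s\texon\t%d\t%d\t.\t%s\t.\t%s",
            tx$chrom, source, tx$exons$start + 1L, tx$exons$end,
            tx$strand, attrs)
  }))
  writeLines(lines, path)
  invisible(path)
}

## Two transcripts per multi-exon gene: the full structure plus a
## truncated first exon, so the merged model equals the planted exons
## while exercising exon merging.
gene_transcripts <- function(gene_id, chrom, strand, exons) {
  t1 <- list(transcript_id = paste0(gene_id, ".t1"), gene_id = gene_id,
             chrom = chrom, strand = strand, exons = exons)
  if (nrow(exons) < 2L) return(list(t1))
  half <- data.frame(
    start = exons$start[1],
    end = exons$start[1] + max(50, floor((exons$end[1] - exons$start[1]) / 2))
  )
  t2 <- list(transcript_id = paste0(gene_id, ".t2"), gene_id = gene_id,
             chrom = chrom, strand = strand, exons = half)
  list(t1, t2)
}

#' Generate the full synthetic input bundle
#'
#' Emits every file format the pipeline consumes — two genomes (FASTA),
#' lncRNA-candidate / protein-coding / reference-lncRNA / species-B GTFs,
#' an FPKM matrix with sample metadata, a differential-expression table
#' (two-sample t-test on log FPKM with Benjamini-Hochberg adjustment,
#' computed by the generator from its own replicates), repeat BED, peak
#' BED, coverage and conservation bedGraphs, a coding-potential table and
#' a UCSC chain file — together with the planted ground truth. Output is
#' deterministic given `config$seed`.
#'
#' @param config a [synthetic_config()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with `files` (named paths), `truth` and
#'   `config`.
#' @export
simulate_dataset <- function(config = synthetic_config(), out_dir) {
  stopifnot(inherits(config, "synthetic_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  W <- config$slot_width
  margin <- 2800
  zone <- function(slot_start) slot_start + margin

  ## ---- stage 1: layout -------------------------------------------------
  layout <- with_stage_seed(seed, SIM_STAGES["layout"], {
    n_per <- config$n_lnc_per_class
    slot_types <- c(
      rep("AS", n_per), rep("AS_UPSTREAM", n_per),
      rep("AS_DOWNSTREAM", n_per), rep("EXCLUDED_SAME_STRAND", n_per),
      rep("coding_plain", config$n_coding - 4 * n_per),
      rep("LINCRNA", n_per), rep("SHORT", config$n_short),
      rep("SINGLE", config$n_single), rep("DECOY", config$n_coding_decoys)
    )
    slot_types <- sample(slot_types)
    coding <- list()
    lnc <- list()
    classes <- character(0)
    counters <- c(coding = 0, AS = 0, UP = 0, DN = 0, EXCL = 0, LINC = 0,
                  SHORT = 0, SINGLE = 0, DECOY = 0)
    for (k in seq_along(slot_types) - 1L) {
      chrom <- paste0("chrA", k %/% config$slots_per_chrom + 1L)
      z <- zone((k %% config$slots_per_chrom) * W)
      type <- slot_types[k + 1L]
      has_coding <- type %in% c("AS", "AS_UPSTREAM", "AS_DOWNSTREAM",
                                "EXCLUDED_SAME_STRAND", "coding_plain")
      if (has_coding) {
        counters["coding"] <- counters["coding"] + 1
        cid <- sprintf("PC_%03d", counters["coding"])
        cstrand <- sample(c("+", "-"), 1)
        cex <- rand_exons(z + 5500, sample(400:800, 3, TRUE),
                          sample(300:700, 2, TRUE))
        coding[[cid]] <- gene_model(cid, chrom, cstrand, cex, "coding")
      }
      if (type == "coding_plain") next
      widths <- lnc_exon_widths()
      foot <- sum(widths) + lnc_intron()
      cs <- if (has_coding) coding[[cid]]$span[["start"]] else NA
      ce <- if (has_coding) coding[[cid]]$span[["end"]] else NA
      gap <- sample(800:3000, 1)
      geom <- switch(type,
        AS = {
          counters["AS"] <- counters["AS"] + 1
          list(sprintf("LNC_AS_%02d", counters["AS"]),
               if (cstrand == "+") "-" else "+", cs + 300)
        },
        AS_UPSTREAM = {
          counters["UP"] <- counters["UP"] + 1
          list(sprintf("LNC_UP_%02d", counters["UP"]),
               if (cstrand == "+") "-" else "+",
               if (cstrand == "+") cs - gap - foot else ce + gap)
        },
        AS_DOWNSTREAM = {
          counters["DN"] <- counters["DN"] + 1
          list(sprintf("LNC_DN_%02d", counters["DN"]),
               if (cstrand == "+") "-" else "+",
               if (cstrand == "+") ce + gap else cs - gap - foot)
        },
        EXCLUDED_SAME_STRAND = {
          counters["EXCL"] <- counters["EXCL"] + 1
          list(sprintf("LNC_EXCL_%02d", counters["EXCL"]), cstrand, ce + gap)
        },
        LINCRNA = {
          counters["LINC"] <- counters["LINC"] + 1
          list(sprintf("LNC_LINC_%02d", counters["LINC"]),
               sample(c("+", "-"), 1), z + 2000)
        },
        SHORT = {
          counters["SHORT"] <- counters["SHORT"] + 1
          list(sprintf("LNC_SHORT_%02d", counters["SHORT"]),
               sample(c("+", "-"), 1), z + 2000)
        },
        SINGLE = {
          counters["SINGLE"] <- counters["SINGLE"] + 1
          list(sprintf("LNC_SINGLE_%02d", counters["SINGLE"]),
               sample(c("+", "-"), 1), z + 2000)
        },
        DECOY = {
          counters["DECOY"] <- counters["DECOY"] + 1
          list(sprintf("LNC_DECOY_%02d", counters["DECOY"]),
               sample(c("+", "-"), 1), z + 2000)
        }
      )
      gid <- geom[[1]]
      exons <- if (type == "SHORT") {
        data.frame(start = geom[[3]], end = geom[[3]] + sample(80:150, 1))
      } else if (type == "SINGLE") {
        data.frame(start = geom[[3]], end = geom[[3]] + sample(400:900, 1))
      } else {
        rand_exons(geom[[3]], widths, foot - sum(widths))
      }
      lnc[[gid]] <- gene_model(gid, chrom, geom[[2]], exons, "lncRNA_candidate")
      classes[gid] <- if (type %in% c("SHORT", "SINGLE", "DECOY")) "LINCRNA" else type
    }
    known <- sort(sample(names(lnc), floor(length(lnc) / 2)))
    list(coding = coding, lnc = lnc, classes = classes, known = known)
  })
  coding <- layout$coding
  lnc <- layout$lnc
  lnc_ids <- names(lnc)
  retained <- lnc_ids[grepl("^LNC_(AS|UP|DN|LINC)_", lnc_ids)]

  ## ---- stage 2: genome A ----------------------------------------------
  genome_a <- with_stage_seed(seed, SIM_STAGES["genome"], {
    chroms <- paste0("chrA", seq_len(config$n_chroms))
    setNames(
      vapply(chroms, function(ch) random_dna(config$chrom_length,
                                             config$at_fraction), ""),
      chroms
    )
  })

  ## ---- stage 5: motif planting (genomic overwrite, exon 2) -------------
  motif_truth <- with_stage_seed(seed, SIM_STAGES["motif"], {
    carriers <- sort(sample(retained, min(config$n_motif_carriers,
                                          length(retained))))
    rows <- lapply(carriers, function(gid) {
      g <- lnc[[gid]]
      ex <- g$exons[nrow(g$exons), ] # last exon; repeats go in the first
      w <- nchar(config$motif)
      at <- ex$start + sample.int(ex$end - ex$start - w + 1L, 1L) - 1L
      planted <- if (g$strand == "-") revcomp_chr(config$motif) else config$motif
      s <- genome_a[[g$chrom]]
      genome_a[[g$chrom]] <<- paste0(
        substring(s, 1, at), planted, substring(s, at + w + 1, nchar(s))
      )
      tr <- project_to_transcript(g, g$chrom, at, at + w)
      data.frame(gene_id = gid, genome_start = at, t_start = tr$start[1],
                 stringsAsFactors = FALSE)
    })
    list(motif = config$motif, carriers = carriers,
         positions = do.call(rbind, rows))
  })

  ## ---- stage 3: expression ---------------------------------------------
  expr <- with_stage_seed(seed, SIM_STAGES["expression"], {
    cts <- config$cell_types
    n_de <- length(retained)
    n4 <- max(1, round(0.02 * n_de))
    n3 <- max(1, round(0.04 * n_de))
    n2 <- round(0.16 * n_de)
    mult <- sample(rep(c(1, 2, 3, 4), c(n_de - n2 - n3 - n4, n2, n3, n4)))
    names(mult) <- retained
    de_cts <- lapply(retained, function(g) sort(sample(cts, mult[[g]])))
    names(de_cts) <- retained

    fcs <- simulate_fold_changes(n_de, config$rho, config$de_log2fc,
                                 seed = stage_seed(seed, 30))
    lnc_fc <- setNames(fcs$lnc_fc, retained)
    partner <- vapply(retained, function(g) {
      nearest_coding_gene(lnc[[g]], coding, max_dist = Inf)$gene_id
    }, "")
    mrna_fc <- setNames(rep(0, length(coding)), names(coding))
    de_cts_coding <- setNames(vector("list", length(coding)), names(coding))
    for (i in seq_along(retained)) {
      p <- partner[[i]]
      if (is.null(de_cts_coding[[p]])) {
        mrna_fc[p] <- fcs$mrna_fc[i]
        de_cts_coding[[p]] <- de_cts[[retained[i]]]
      }
    }

    all_ids <- c(names(coding), lnc_ids)
    base <- c(
      10 + stats::rlnorm(length(coding), log(20), 0.5),
      2 + stats::rlnorm(length(lnc_ids), log(3), 0.5)
    )
    names(base) <- all_ids
    on <- matrix(TRUE, length(all_ids), length(cts),
                 dimnames = list(all_ids, cts))
    for (g in lnc_ids) {
      on[g, ] <- stats::runif(length(cts)) < 0.3
      if (g %in% retained) {
        on[g, de_cts[[g]]] <- TRUE
      } else if (!any(on[g, ])) {
        on[g, sample(length(cts), 1)] <- TRUE
      }
    }

    meta <- expand.grid(rep = seq_len(config$n_reps),
                        condition = c("control", "stimulated"),
                        cell_type = cts, stringsAsFactors = FALSE)
    meta$sample <- sprintf("%s_%s_r%d", meta$cell_type, meta$condition, meta$rep)
    meta <- meta[, c("sample", "cell_type", "condition")]

    fc_of <- function(g, ct) {
      if (g %in% retained && ct %in% de_cts[[g]]) return(lnc_fc[[g]])
      if (g %in% names(coding) && !is.null(de_cts_coding[[g]]) &&
          ct %in% de_cts_coding[[g]]) {
        return(mrna_fc[[g]])
      }
      0
    }
    m <- matrix(0, length(all_ids), nrow(meta),
                dimnames = list(all_ids, meta$sample))
    for (g in all_ids) {
      for (s in seq_len(nrow(meta))) {
        e <- if (on[g, meta$cell_type[s]]) base[[g]] else 0.02
        fc <- if (meta$condition[s] == "stimulated") fc_of(g, meta$cell_type[s]) else 0
        m[g, s] <- e * 2^fc * exp(stats::rnorm(1, 0, config$fpkm_noise_sdlog))
      }
    }

    de_rows <- lapply(cts, function(ct) {
      ctl <- meta$sample[meta$cell_type == ct & meta$condition == "control"]
      stm <- meta$sample[meta$cell_type == ct & meta$condition == "stimulated"]
      l2 <- log2(m + 0.01)
      fc <- rowMeans(l2[, stm, drop = FALSE]) - rowMeans(l2[, ctl, drop = FALSE])
      p <- vapply(all_ids, function(g) {
        stats::t.test(l2[g, stm], l2[g, ctl], var.equal = TRUE)$p.value
      }, 0)
      data.frame(gene_id = all_ids, cell_type = ct, log2fc = fc,
                 q_value = stats::p.adjust(p, "BH"),
                 row.names = NULL, stringsAsFactors = FALSE)
    })
    list(
      matrix = m, meta = meta, de_table = do.call(rbind, de_rows),
      de_cts = de_cts, lnc_fc = lnc_fc, partner = partner,
      mrna_fc = mrna_fc,
      pairs = data.frame(gene_id = retained, partner = unname(partner),
                         lnc_fc = unname(lnc_fc[retained]),
                         mrna_fc = unname(mrna_fc[partner]),
                         stringsAsFactors = FALSE),
      multiplicity = as.vector(table(factor(mult, levels = seq_along(cts))))
    )
  })

  ## ---- stage 4: repeats (first exon of retained lncRNAs) ---------------
  repeat_truth <- with_stage_seed(seed, SIM_STAGES["repeats"], {
    fams <- c("SINE/Alu", "LINE/L1", "LTR/ERVL", "DNA/hAT", "Simple_repeat")
    rows <- lapply(seq_along(retained), function(i) {
      g <- lnc[[retained[i]]]
      ex <- g$exons[1, ]
      w <- max(20, round(config$repeat_density * (ex$end - ex$start)))
      at <- ex$start + sample.int(ex$end - ex$start - w + 1L, 1L) - 1L
      data.frame(chrom = g$chrom, start = at, end = at + w,
                 family = fams[(i - 1) %% length(fams) + 1],
                 gene_id = g$gene_id, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    out$repeat_class <- map_repeat_class(out$family)
    out
  })

  ## ---- stage 7: edits, genome B, chain, species-B annotation -----------
  chain_part <- with_stage_seed(seed, SIM_STAGES["chain"], {
    types <- c("deletion", "insertion", "inversion")
    ed <- lapply(seq_len(config$n_chroms), function(ci) {
      chrom <- paste0("chrA", ci)
      ks <- sample(2:(config$slots_per_chrom - 1), config$n_edits_per_chrom)
      do.call(rbind, lapply(seq_along(ks), function(j) {
        type <- types[(j - 1) %% 3 + 1]
        a <- ks[j] * W + 500
        len <- sample(200:1200, 1)
        data.frame(
          chrom = chrom, start = a,
          end = if (type == "insertion") a else a + len,
          type = type,
          seq = if (type == "insertion") random_dna(len, config$at_fraction) else "",
          stringsAsFactors = FALSE
        )
      }))
    })
    edits <- do.call(rbind, ed)
    pair <- make_chain_pair(genome_a, edits)

    syntenic <- sort(sample(retained, min(config$n_syntenic, length(retained))))
    b_lnc <- lapply(syntenic, function(gid) {
      g <- lnc[[gid]]
      gene_model(paste0("B_", gid), paste0(g$chrom, "_B"), g$strand,
                 data.frame(start = pair$map(g$chrom, g$exons$start),
                            end = pair$map(g$chrom, g$exons$end - 1) + 1),
                 "lncRNA_candidate")
    })
    names(b_lnc) <- paste0("B_", syntenic)
    # species-B-only decoys: placed inside coding-only cassettes (slots
    # holding no A lncRNA) so they cannot overlap any lifted lncRNA locus
    lnc_tab <- models_table(lnc)
    free_by_chrom <- lapply(setNames(names(genome_a), names(genome_a)),
                            function(ch) {
      occ <- lnc_tab[lnc_tab$chrom == ch, ]
      occupied <- unique(c(occ$start %/% W, occ$end %/% W))
      setdiff(seq(1, config$slots_per_chrom - 2), occupied)
    })
    for (j in seq_len(config$n_b_decoys)) {
      ch <- names(genome_a)[(j - 1) %% config$n_chroms + 1]
      if (length(free_by_chrom[[ch]]) == 0L) next
      k <- free_by_chrom[[ch]][1]
      free_by_chrom[[ch]] <- free_by_chrom[[ch]][-1]
      gid <- sprintf("B_DECOY_%02d", j)
      b_lnc[[gid]] <- gene_model(
        gid, paste0(ch, "_B"), sample(c("+", "-"), 1),
        rand_exons(k * W + margin + 9500, lnc_exon_widths(), lnc_intron()),
        "lncRNA_candidate"
      )
    }
    list(edits = edits, genome_b = pair$genome_b, chains = pair$chains,
         syntenic = data.frame(gene_a = syntenic,
                               gene_b = paste0("B_", syntenic),
                               stringsAsFactors = FALSE),
         b_lnc = b_lnc)
  })

  ## ---- stage 6: conservation score track -------------------------------
  cons_scores <- c(coding = 0.8, lnc_other = 0.15, lnc_syntenic = 0.6)
  cons_rows <- local({
    paint <- lapply(setNames(names(genome_a), names(genome_a)), function(ch) {
      numeric(config$chrom_length)
    })
    paint_gene <- function(g, val) {
      for (i in seq_len(nrow(g$exons))) {
        paint[[g$chrom]][(g$exons$start[i] + 1):g$exons$end[i]] <<- val
      }
    }
    for (g in coding) paint_gene(g, cons_scores[["coding"]])
    for (gid in lnc_ids) {
      syn <- gid %in% chain_part$syntenic$gene_a
      paint_gene(lnc[[gid]],
                 if (syn) cons_scores[["lnc_syntenic"]] else cons_scores[["lnc_other"]])
    }
    do.call(rbind, lapply(names(paint), function(ch) {
      r <- rle(paint[[ch]])
      ends <- cumsum(r$lengths)
      keep <- r$values > 0
      data.frame(chrom = ch, start = ends[keep] - r$lengths[keep],
                 end = ends[keep], score = r$values[keep],
                 stringsAsFactors = FALSE)
    }))
  })

  ## ---- stage 8: epigenome (peaks + TSS coverage bumps) ------------------
  epi <- with_stage_seed(seed, SIM_STAGES["epigenome"], {
    active <- sort(unique(c(retained, unname(expr$partner))))
    all_models <- c(coding, lnc)
    tss_of <- function(g) {
      if (g$strand == "+") g$span[["start"]] else g$span[["end"]] - 1
    }
    peaks <- do.call(rbind, lapply(active, function(gid) {
      g <- all_models[[gid]]
      tss <- tss_of(g)
      data.frame(chrom = g$chrom, start = max(0, tss - 400), end = tss + 400,
                 name = paste0("peak_", gid), stringsAsFactors = FALSE)
    }))
    bin <- 50
    nbin <- config$chrom_length %/% bin
    cov <- lapply(setNames(names(genome_a), names(genome_a)),
                  function(ch) numeric(nbin))
    for (gid in active) {
      g <- all_models[[gid]]
      tss <- tss_of(g)
      centers <- (seq_len(nbin) - 0.5) * bin
      bump <- pmax(0, 10 * (1 - abs(centers - tss) / 1000))
      cov[[g$chrom]] <- cov[[g$chrom]] + bump
    }
    cov_rows <- do.call(rbind, lapply(names(cov), function(ch) {
      r <- rle(cov[[ch]])
      ends <- cumsum(r$lengths)
      keep <- r$values > 0
      data.frame(chrom = ch, start = (ends[keep] - r$lengths[keep]) * bin,
                 end = ends[keep] * bin, score = r$values[keep],
                 stringsAsFactors = FALSE)
    }))
    list(active = active, peaks = peaks, cov_rows = cov_rows)
  })

  ## ---- write the bundle -------------------------------------------------
  fp <- function(name) file.path(out_dir, name)
  files <- c(
    genome_a = fp("genome_a.fa"), genome_b = fp("genome_b.fa"),
    lnc_gtf = fp("lnc_a.gtf"), coding_gtf = fp("coding_a.gtf"),
    ref_lnc_gtf = fp("ref_lnc_a.gtf"), lnc_b_gtf = fp("lnc_b.gtf"),
    fpkm = fp("fpkm.tsv"), samples = fp("samples.tsv"), de = fp("de.tsv"),
    coding_potential = fp("coding_potential.tsv"),
    repeats = fp("repeats.bed"), peaks = fp("peaks.bed"),
    coverage = fp("coverage.bedgraph"), scores = fp("phastcons.bedgraph"),
    chain = fp("a_to_b.chain")
  )
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome_a),
                              files[["genome_a"]], width = 70)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(chain_part$genome_b),
                              files[["genome_b"]], width = 70)
  tx_of <- function(models) {
    unlist(lapply(models, function(g) {
      gene_transcripts(g$gene_id, g$chrom, g$strand, g$exons)
    }), recursive = FALSE)
  }
  write_gtf(tx_of(lnc), files[["lnc_gtf"]],
            biotypes = setNames(rep("lncRNA_candidate", length(lnc)), lnc_ids))
  write_gtf(tx_of(coding), files[["coding_gtf"]],
            biotypes = setNames(rep("protein_coding", length(coding)),
                                names(coding)))
  ref_models <- lapply(layout$known, function(gid) {
    g <- lnc[[gid]]
    gene_model(paste0("REF_", gid), g$chrom, g$strand, g$exons,
               "lncRNA_candidate")
  })
  write_gtf(tx_of(ref_models), files[["ref_lnc_gtf"]])
  write_gtf(tx_of(chain_part$b_lnc), files[["lnc_b_gtf"]])

  utils::write.table(
    data.frame(gene_id = rownames(expr$matrix),
               round(expr$matrix, 4), check.names = FALSE),
    files[["fpkm"]], sep = "\t", quote = FALSE, row.names = FALSE
  )
  utils::write.table(expr$meta, files[["samples"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  de_out <- expr$de_table
  de_out$log2fc <- round(de_out$log2fc, 6)
  de_out$q_value <- signif(de_out$q_value, 6)
  utils::write.table(de_out, files[["de"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(
    data.frame(gene_id = lnc_ids,
               label = ifelse(grepl("^LNC_DECOY_", lnc_ids),
                              "coding", "noncoding")),
    files[["coding_potential"]], sep = "\t", quote = FALSE, row.names = FALSE
  )
  writeLines(
    sprintf("%s\t%d\t%d\t%s\t0\t.", repeat_truth$chrom,
            repeat_truth$start, repeat_truth$end, repeat_truth$family),
    files[["repeats"]]
  )
  writeLines(
    sprintf("%s\t%d\t%d\t%s", epi$peaks$chrom, epi$peaks$start,
            epi$peaks$end, epi$peaks$name),
    files[["peaks"]]
  )
  writeLines(
    sprintf("%s\t%d\t%d\t%s", epi$cov_rows$chrom, epi$cov_rows$start,
            epi$cov_rows$end, format(epi$cov_rows$score, trim = TRUE)),
    files[["coverage"]]
  )
  writeLines(
    sprintf("%s\t%d\t%d\t%s", cons_rows$chrom, cons_rows$start,
            cons_rows$end, format(cons_rows$score, trim = TRUE)),
    files[["scores"]]
  )
  write_chain_file(chain_part$chains, files[["chain"]])

  truth <- list(
    classes = layout$classes,
    novelty = setNames(
      ifelse(lnc_ids %in% layout$known, "known", "novel"), lnc_ids
    ),
    retained = retained,
    short = lnc_ids[grepl("^LNC_SHORT_", lnc_ids)],
    single = lnc_ids[grepl("^LNC_SINGLE_", lnc_ids)],
    decoys = lnc_ids[grepl("^LNC_DECOY_", lnc_ids)],
    de_cts = expr$de_cts,
    multiplicity = expr$multiplicity,
    pairs = expr$pairs,
    motif = motif_truth,
    repeats = repeat_truth,
    syntenic = chain_part$syntenic,
    edits = chain_part$edits,
    active = epi$active,
    cons_scores = cons_scores,
    models = list(coding = coding, lnc = lnc, b_lnc = chain_part$b_lnc)
  )
  invisible(list(files = files, truth = truth, config = config))
}
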