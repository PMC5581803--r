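#' lncRNA identification rules
#'
#' The catalog rules applied after composite gene-model construction:
#' a minimum exonic-length filter (lncRNAs are defined as >200 nt; a
#' gene of exactly 200 nt is retained), a single/multi-exon split on the
#' merged model, known/novel flagging against a reference lncRNA
#' annotation, a coding-potential intake filter, and strand-aware
#' positional classification against protein-coding genes.
#'
#' @name catalog_rules
NULL

#' @describeIn catalog_rules Retain genes with `exonic_length >= min_len`.
#' @param genes named list of `gene_model`s.
#' @param min_len minimum exonic length in bases (default 200).
#' @export
filter_min_length <- function(genes, min_len = 200) {
  keep <- vapply(genes, function(g) g$exonic_length >= min_len, logical(1))
  genes[keep]
}

#' @describeIn catalog_rules Split into single-exon and multi-exon sets
#'   (on the merged model: a gene is multi-exonic iff `n_exons >= 2`).
#' @export
partition_by_exon_count <- function(genes) {
  multi <- vapply(genes, function(g) g$n_exons >= 2L, logical(1))
  list(single = genes[!multi], multi = genes[multi])
}

#' @describeIn catalog_rules Flag candidates as `known` (>= 1 bp of
#'   same-strand exonic overlap with a reference lncRNA exon) or `novel`.
#' @param candidates named list of candidate `gene_model`s.
#' @param reference_lncRNAs named list of reference `gene_model`s.
#' @export
flag_known_vs_novel <- function(candidates, reference_lncRNAs) {
  lab <- setNames(rep("novel", length(candidates)), names(candidates))
  if (length(candidates) > 0L && length(reference_lncRNAs) > 0L) {
    cand_gr <- models_exon_gr(candidates)
    ref_gr <- models_exon_gr(reference_lncRNAs)
    hits <- GenomicRanges::findOverlaps(cand_gr, ref_gr, ignore.strand = FALSE)
    known <- unique(S4Vectors::mcols(cand_gr)$gene_id[S4Vectors::queryHits(hits)])
    lab[known] <- "known"
  }
  lab
}

#' @describeIn catalog_rules Remove genes labelled `coding` in a
#'   coding-potential table; genes absent from the table are retained
#'   with a warning listing them.
#' @param coding_table named character vector, gene id to
#'   `"coding"`/`"noncoding"` (may be partial).
#' @export
apply_coding_filter <- function(genes, coding_table) {
  ids <- names(genes)
  missing <- setdiff(ids, names(coding_table))
  if (length(missing) > 0L) {
    warning(
      "coding-potential table missing ", length(missing),
      " gene(s), retained: ", paste(utils::head(missing, 5), collapse = ", "),
      if (length(missing) > 5) ", ..."
    )
  }
  drop <- ids[ids %in% names(coding_table)][
    coding_table[ids[ids %in% names(coding_table)]] == "coding"
  ]
  genes[setdiff(ids, drop)]
}

#' Positional classification of a lncRNA against protein-coding genes
#'
#' Classes follow the usual positional scheme: `AS` (overlapping a
#' protein-coding gene on the opposite strand), `AS_UPSTREAM` /
#' `AS_DOWNSTREAM` (within `window` of a protein-coding gene on the
#' opposite strand, on its 5' (TSS) or 3' side), `LINCRNA` (no
#' protein-coding gene within `window`), and `EXCLUDED_SAME_STRAND`
#' (same strand and overlapping or within `window`; such loci may be
#' unannotated extensions of the coding gene and are removed first).
#'
#' Decision order: (1) same-strand overlap-or-proximity wins
#' (exclusion); (2) opposite-strand span overlap gives `AS`; (3)
#' otherwise the nearest opposite-strand gene with span gap `<= window`
#' gives `AS_UPSTREAM`/`AS_DOWNSTREAM`, upstream/downstream taken
#' relative to the coding gene's orientation and ties resolved toward
#' upstream; (4) otherwise `LINCRNA`. Distances are span gaps (0 when
#' spans overlap).
#'
#' @param lnc a `gene_model` (stranded).
#' @param coding named list of protein-coding `gene_model`s.
#' @param window proximity window in bases (default 5000).
#' @param upstream_relative_to `"coding"` (default) or `"lnc"`: which
#'   gene's orientation defines upstream/downstream.
#' @return single classification label.
#' @export
classify_relative_position <- function(lnc, coding, window = 5000,
                                       upstream_relative_to = c("coding", "lnc")) {
  upstream_relative_to <- match.arg(upstream_relative_to)
  if (!lnc$strand %in% c("+", "-")) {
    stop("classification error: unstranded lncRNA ", lnc$gene_id)
  }
  ct <- models_table(coding)
  if (nrow(ct) > 0 && !all(ct$strand %in% c("+", "-"))) {
    stop("classification error: unstranded protein-coding gene")
  }
  ct <- ct[ct$chrom == lnc$chrom, , drop = FALSE]
  if (nrow(ct) == 0L) return("LINCRNA")

  ls <- lnc$span[["start"]]
  le <- lnc$span[["end"]]
  gap <- span_gap(ls, le, ct$start, ct$end)
  overlaps <- ct$start < le & ls < ct$end
  same <- ct$strand == lnc$strand

  # (1) potential same-strand gene extension
  if (any(same & (overlaps | gap <= window))) return("EXCLUDED_SAME_STRAND")
  # (2) antisense overlap
  if (any(!same & overlaps)) return("AS")
  # (3) antisense within the window
  near <- !same & gap <= window
  if (any(near)) {
    cn <- ct[near, , drop = FALSE]
    gn <- gap[near]
    cn <- cn[gn == min(gn), , drop = FALSE]
    side <- vapply(seq_len(nrow(cn)), function(i) {
      relative_side(ls, le, cn$start[i], cn$end[i],
                    cn$strand[i], lnc$strand,
                    upstream_relative_to)
    }, "")
    return(if (any(side == "up")) "AS_UPSTREAM" else "AS_DOWNSTREAM")
  }
  # (4) intergenic
  "LINCRNA"
}

## Which side of the anchor gene the lnc lies on, in the anchor's
## orientation ("up" = beyond its TSS). Anchor is the coding gene by
## default; `upstream_relative_to = "lnc"` swaps the reference frame.
relative_side <- function(lnc_start, lnc_end, cod_start, cod_end,
                          cod_strand, lnc_strand, upstream_relative_to) {
  if (upstream_relative_to == "coding") {
    lnc_before <- lnc_end <= cod_start # lnc entirely left of coding gene
    if (cod_strand == "+") {
      if (lnc_before) "up" else "down"
    } else {
      if (lnc_before) "down" else "up"
    }
  } else {
    cod_before <- cod_end <= lnc_start
    if (lnc_strand == "+") {
      if (cod_before) "up" else "down"
    } else {
      if (cod_before) "down" else "up"
    }
  }
}

#' Build the classified catalog table
#'
#' Applies [classify_relative_position()] and [flag_known_vs_novel()] to
#' every candidate and records the nearest protein-coding gene.
#'
#' @param lnc_genes named list of candidate `gene_model`s.
#' @param coding named list of protein-coding `gene_model`s.
#' @param reference_lncRNAs optional reference lncRNA models for novelty
#'   flagging (`NULL` marks everything novel).
#' @param window proximity window in bases.
#' @return data.frame with one row per candidate: `gene_id`,
#'   `positional_class`, `novelty`, `nearest_coding_gene_id`,
#'   `nearest_coding_distance` (NA when no coding gene shares the
#'   chromosome), `exonic_length`, `n_exons`.
#' @export
classify_catalog <- function(lnc_genes, coding, reference_lncRNAs = NULL,
                             window = 5000) {
  novelty <- if (is.null(reference_lncRNAs)) {
    setNames(rep("novel", length(lnc_genes)), names(lnc_genes))
  } else {
    flag_known_vs_novel(lnc_genes, reference_lncRNAs)
  }
  rows <- lapply(lnc_genes, function(g) {
    nn <- nearest_coding_gene(g, coding, max_dist = Inf)
    data.frame(
      gene_id = g$gene_id,
      positional_class = classify_relative_position(g, coding, window),
      novelty = novelty[[g$gene_id]],
      nearest_coding_gene_id = if (is.null(nn)) NA_character_ else nn$gene_id,
      nearest_coding_distance = if (is.null(nn)) NA_real_ else nn$distance,
      exonic_length = g$exonic_length,
      n_exons = g$n_exons,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
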