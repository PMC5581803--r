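#' Read peak calls from a BED file
#'
#' @param path BED3-BED6 peak file (e.g. exported MACS2 peaks).
#' @return data.frame `chrom`, `start`, `end`, `score` (NA when absent).
#' @export
read_peaks <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  md <- S4Vectors::mcols(gr)
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    score = if (!is.null(md$score)) as.numeric(md$score) else NA_real_,
    stringsAsFactors = FALSE
  )
}

#' Read a bedGraph coverage or score track
#'
#' @param path bedGraph file.
#' @return data.frame `chrom`, `start`, `end`, `score` (0-based
#'   half-open).
#' @export
read_bedgraph <- function(path) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    score = as.numeric(S4Vectors::mcols(gr)$score),
    stringsAsFactors = FALSE
  )
}

#' Percentage of genes whose span overlaps a peak
#'
#' A gene is flagged iff its genomic span shares >= 1 bp with >= 1 peak
#' (strand ignored).
#'
#' @param genes named list of `gene_model`s (non-empty).
#' @param peaks peak table from [read_peaks()] (or any data.frame with
#'   `chrom`, `start`, `end`).
#' @return list with `pct` and the per-gene logical `flags`.
#' @export
gene_peak_overlap_pct <- function(genes, peaks) {
  if (length(genes) == 0L) stop("gene_peak_overlap_pct: empty gene set")
  gt <- models_table(genes)
  flags <- setNames(rep(FALSE, nrow(gt)), gt$gene_id)
  if (nrow(peaks) > 0L) {
    gg <- GenomicRanges::GRanges(gt$chrom, IRanges::IRanges(gt$start + 1, gt$end))
    pg <- GenomicRanges::GRanges(peaks$chrom, IRanges::IRanges(peaks$start + 1, peaks$end))
    hit <- GenomicRanges::countOverlaps(gg, pg, ignore.strand = TRUE) > 0
    flags[gt$gene_id] <- hit
  }
  list(pct = 100 * mean(flags), flags = flags)
}

## Coverage values over [start0, start0+len) of one chromosome, zero
## padded beyond the track / chromosome ends.
track_window <- function(cov_rle, start0, len) {
  out <- numeric(len)
  lo <- max(start0 + 1, 1) # 1-based
  hi <- min(start0 + len, length(cov_rle))
  if (hi >= lo) {
    vals <- as.numeric(S4Vectors::window(cov_rle, lo, hi))
    out[(lo - start0):(hi - start0)] <- vals
  }
  out
}

#' TSS-centered coverage metaprofile
#'
#' Computes, for every gene, the per-bin mean coverage over
#' `[TSS - flank, TSS + flank)`. The TSS is the span start for `+`
#' genes and `span end - 1` for `-` genes; minus-strand profiles are
#' reversed so bins always run upstream -> downstream in gene
#' orientation. Positions beyond chromosome/track ends contribute 0, so
#' the matrix stays rectangular.
#'
#' @param genes named list of stranded `gene_model`s.
#' @param coverage bedGraph-style data.frame (see [read_bedgraph()]).
#' @param flank bases each side of the TSS (default 3000).
#' @param bin_width bin size in bases (default 30; must divide
#'   `2 * flank`).
#' @return list with `matrix` (genes x bins), `mean_profile` (per-bin
#'   mean over genes), `bin_centers` (bp relative to the TSS), `flank`,
#'   `bin_width`.
#' @export
tss_profile <- function(genes, coverage, flank = 3000, bin_width = 30) {
  if ((2 * flank) %% bin_width != 0) {
    stop("bin_width must divide 2*flank")
  }
  strands <- vapply(genes, `[[`, "", "strand")
  if (!all(strands %in% c("+", "-"))) {
    stop("tss_profile: unstranded gene in input")
  }
  n_bins <- 2 * flank / bin_width
  cov_gr <- GenomicRanges::GRanges(
    coverage$chrom, IRanges::IRanges(coverage$start + 1, coverage$end)
  )
  cov_by_chrom <- GenomicRanges::coverage(cov_gr, weight = coverage$score)
  mat <- matrix(0, nrow = length(genes), ncol = n_bins,
                dimnames = list(names(genes), NULL))
  for (i in seq_along(genes)) {
    g <- genes[[i]]
    tss <- if (g$strand == "+") g$span[["start"]] else g$span[["end"]] - 1
    v <- if (g$chrom %in% names(cov_by_chrom)) {
      track_window(cov_by_chrom[[g$chrom]], tss - flank, 2 * flank)
    } else {
      numeric(2 * flank)
    }
    if (g$strand == "-") v <- rev(v)
    mat[i, ] <- colMeans(matrix(v, nrow = bin_width))
  }
  list(
    matrix = mat,
    mean_profile = colMeans(mat),
    bin_centers = seq(-flank + bin_width / 2, flank - bin_width / 2,
                      by = bin_width),
    flank = flank,
    bin_width = bin_width
  )
}

#' Write a TSS matrix as tab-delimited text
#'
#' A small `#`-prefixed metadata header (flank, bin width) precedes the
#' gene x bin matrix.
#' @param profile result of [tss_profile()].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_tss_matrix <- function(profile, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# flank=%d bin_width=%d", profile$flank,
                     profile$bin_width), con)
  utils::write.table(
    data.frame(gene_id = rownames(profile$matrix), profile$matrix,
               check.names = FALSE),
    con, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}
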