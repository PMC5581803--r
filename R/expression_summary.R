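#' Read an FPKM matrix and its sample metadata
#'
#' The matrix is tab-delimited, genes in rows (first column holds gene
#' ids), samples in columns. The sidecar metadata table has columns
#' `sample`, `cell_type`, `condition` (`control` or `stimulated`).
#'
#' @param path matrix file.
#' @return numeric matrix, genes x samples.
#' @export
read_fpkm_matrix <- function(path) {
  d <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d[[1]]
  storage.mode(m) <- "double"
  if (any(m < 0)) stop("FPKM values must be non-negative")
  m
}

#' @rdname read_fpkm_matrix
#' @export
read_sample_meta <- function(path) {
  meta <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample", "cell_type", "condition")
  if (!all(need %in% names(meta))) {
    stop("sample metadata needs columns: ", paste(need, collapse = ", "))
  }
  if (!all(meta$condition %in% c("control", "stimulated"))) {
    stop("condition must be 'control' or 'stimulated'")
  }
  meta
}

#' Read a differential-expression table
#'
#' Tab-delimited with columns `gene_id`, `cell_type`, `log2fc`,
#' `q_value` (Cuffdiff-like intake; the test itself is upstream of this
#' package).
#' @param path table file.
#' @return data.frame of DE records.
#' @export
read_de_table <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "cell_type", "log2fc", "q_value")
  if (!all(need %in% names(d))) {
    stop("DE table needs columns: ", paste(need, collapse = ", "))
  }
  if (any(d$q_value < 0 | d$q_value > 1, na.rm = TRUE)) {
    stop("q_value must lie in [0,1]")
  }
  d
}

## Per-(cell_type, condition) mean FPKM: genes x (cell_type|condition).
condition_means <- function(matrix, meta) {
  if (!all(meta$sample %in% colnames(matrix))) {
    stop("samples in metadata missing from matrix: ",
         paste(setdiff(meta$sample, colnames(matrix)), collapse = ", "))
  }
  key <- paste(meta$cell_type, meta$condition, sep = "|")
  groups <- split(meta$sample, key)
  out <- vapply(groups, function(ss) {
    rowMeans(matrix[, ss, drop = FALSE])
  }, numeric(nrow(matrix)))
  out
}

#' Expressed genes per cell type
#'
#' A gene counts as expressed in a cell type iff its mean FPKM over that
#' cell type's replicates exceeds `threshold` strictly in the control
#' condition or in the stimulated condition.
#'
#' @param matrix genes x samples FPKM matrix.
#' @param meta sample metadata (see [read_sample_meta()]).
#' @param threshold FPKM cut-off (default 1.0, strict `>`).
#' @param cell_types optional subset; unknown names are an error.
#' @return named list of character vectors of gene ids, one per cell type.
#' @export
expressed_genes <- function(matrix, meta, threshold = 1.0, cell_types = NULL) {
  cm <- condition_means(matrix, meta)
  all_ct <- unique(meta$cell_type)
  if (is.null(cell_types)) cell_types <- all_ct
  if (!all(cell_types %in% all_ct)) {
    stop("unknown cell type(s): ",
         paste(setdiff(cell_types, all_ct), collapse = ", "))
  }
  sets <- lapply(cell_types, function(ct) {
    cols <- paste(ct, c("control", "stimulated"), sep = "|")
    cols <- intersect(cols, colnames(cm))
    expressed <- apply(cm[, cols, drop = FALSE] > threshold, 1, any)
    rownames(matrix)[expressed]
  })
  names(sets) <- cell_types
  sets
}

#' Multiplicity summary across cell-type gene sets
#'
#' For k = 1..number of sets, counts genes present in exactly k sets;
#' percentages are of the union, both unrounded and rounded half-up for
#' display.
#'
#' @param sets named list of gene-id vectors.
#' @return data.frame (`multiplicity`, `count`, `pct`, `pct_rounded`)
#'   with attribute `union_size`.
#' @export
multiplicity_summary <- function(sets) {
  if (length(sets) == 0L) stop("need at least one set")
  all_genes <- unique(unlist(sets, use.names = FALSE))
  k <- rowSums(vapply(sets, function(s) all_genes %in% s,
                      logical(length(all_genes))))
  counts <- vapply(seq_along(sets), function(i) sum(k == i), 0)
  out <- data.frame(
    multiplicity = seq_along(sets),
    count = counts,
    pct = if (length(all_genes) > 0) 100 * counts / length(all_genes) else counts * NA_real_,
    pct_rounded = NA_real_
  )
  out$pct_rounded <- round_half_up(out$pct)
  attr(out, "union_size") <- length(all_genes)
  out
}

#' Positional-class distribution of a classified catalog
#'
#' Counts and percentages per positional class;
#' `EXCLUDED_SAME_STRAND` records are dropped from the denominator (they
#' are not part of the catalog).
#'
#' @param records data.frame from [classify_catalog()], or any
#'   data.frame with a `positional_class` column.
#' @return data.frame (`positional_class`, `count`, `pct`,
#'   `pct_rounded`) with attribute `total`.
#' @export
class_distribution <- function(records) {
  keep <- records$positional_class != "EXCLUDED_SAME_STRAND"
  cls <- records$positional_class[keep]
  lev <- c("LINCRNA", "AS", "AS_DOWNSTREAM", "AS_UPSTREAM")
  lev <- c(lev, setdiff(unique(cls), lev))
  counts <- vapply(lev, function(l) sum(cls == l), 0)
  out <- data.frame(
    positional_class = lev,
    count = counts,
    pct = if (length(cls) > 0) 100 * counts / length(cls) else counts * NA_real_,
    row.names = NULL, stringsAsFactors = FALSE
  )
  out$pct_rounded <- round_half_up(out$pct)
  attr(out, "total") <- length(cls)
  out
}

#' Filter differential-expression records at a q-value threshold
#'
#' @param tables DE data.frame (`gene_id`, `cell_type`, `log2fc`,
#'   `q_value`).
#' @param alpha significance threshold; a gene is differentially
#'   expressed in a cell type iff `q_value < alpha` strictly.
#' @return list with `sets` (per-cell-type gene-id vectors) and `union`.
#' @export
de_filter <- function(tables, alpha = 0.05) {
  sig <- tables[!is.na(tables$q_value) & tables$q_value < alpha, , drop = FALSE]
  cts <- unique(tables$cell_type)
  sets <- lapply(cts, function(ct) unique(sig$gene_id[sig$cell_type == ct]))
  names(sets) <- cts
  list(sets = sets, union = unique(sig$gene_id))
}

#' Mean expression with standard error
#'
#' For each gene, the per-(cell type, condition) mean FPKMs are reduced
#' to their maximum ("peak condition mean"); the returned statistics are
#' the arithmetic mean and SEM (sample SD / sqrt(n)) of those per-gene
#' values.
#'
#' @param gene_set character vector of gene ids (non-empty).
#' @param matrix genes x samples FPKM matrix.
#' @param meta sample metadata.
#' @return list with `mean`, `sem`, `n`, and the per-gene `values`.
#' @export
expression_stats <- function(gene_set, matrix, meta) {
  if (length(gene_set) == 0L) stop("expression_stats: empty gene set")
  missing <- setdiff(gene_set, rownames(matrix))
  if (length(missing) > 0L) {
    stop("genes absent from matrix: ", paste(utils::head(missing, 5), collapse = ", "))
  }
  cm <- condition_means(matrix, meta)
  v <- apply(cm[gene_set, , drop = FALSE], 1, max)
  n <- length(v)
  list(
    mean = mean(v),
    sem = if (n > 1) stats::sd(v) / sqrt(n) else 0,
    n = n,
    values = v
  )
}

#' Nearest protein-coding gene
#'
#' Distance is the span gap on the shared chromosome (0 if the spans
#' overlap). Ties are broken by smaller start coordinate, then
#' lexicographic gene id.
#'
#' @param lnc a `gene_model`.
#' @param coding named list of protein-coding `gene_model`s.
#' @param max_dist maximum gap to report (default 1 Mb); `NULL`/none is
#'   returned beyond it.
#' @return `NULL`, or list with `gene_id`, `distance`, and
#'   `genes_within_window` (data.frame of all coding genes with gap
#'   `<= max_dist`, sorted by gap).
#' @export
nearest_coding_gene <- function(lnc, coding, max_dist = 1e6) {
  ct <- models_table(coding)
  ct <- ct[ct$chrom == lnc$chrom, , drop = FALSE]
  if (nrow(ct) == 0L) return(NULL)
  ct$gap <- span_gap(lnc$span[["start"]], lnc$span[["end"]], ct$start, ct$end)
  ct <- ct[order(ct$gap, ct$start, ct$gene_id), , drop = FALSE]
  if (ct$gap[1] > max_dist) return(NULL)
  within <- ct[ct$gap <= max_dist, c("gene_id", "gap", "start", "end", "strand")]
  rownames(within) <- NULL
  list(
    gene_id = ct$gene_id[1],
    distance = ct$gap[1],
    genes_within_window = within
  )
}

#' Pearson correlation between paired fold changes
#'
#' Product-moment correlation with the usual two-sided t test
#' (t = r * sqrt((n-2)/(1-r^2)) on n-2 df), via [stats::cor.test()].
#'
#' @param lnc_fc,mrna_fc numeric vectors of paired log2 fold changes
#'   (n >= 3, finite).
#' @return list with `r`, `p_value`, `n`.
#' @export
fold_change_correlation <- function(lnc_fc, mrna_fc) {
  if (length(lnc_fc) != length(mrna_fc)) stop("paired vectors differ in length")
  ok <- is.finite(lnc_fc) & is.finite(mrna_fc)
  lnc_fc <- lnc_fc[ok]
  mrna_fc <- mrna_fc[ok]
  n <- length(lnc_fc)
  if (n < 3) stop("need at least 3 finite pairs for a correlation")
  if (stats::sd(lnc_fc) == 0 || stats::sd(mrna_fc) == 0) {
    stop("undefined correlation: zero variance in one of the vectors")
  }
  ct <- stats::cor.test(lnc_fc, mrna_fc, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = n)
}
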