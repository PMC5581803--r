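#' Genomic intervals, 0-based half-open
#'
#' All coordinates inside the package are 0-based half-open (BED
#' convention): a base at offset `i` is covered by `[i, i+1)`.  GTF and
#' RepeatMasker input is converted at the parse boundary; IRanges
#' (1-based closed) only appear inside overlap helpers.
#'
#' @param chrom chromosome name.
#' @param start 0-based inclusive start offset (non-negative).
#' @param end exclusive end offset; must satisfy `start < end`.
#' @param strand `"+"`, `"-"`, or `"*"` when strand is irrelevant.
#' @return a data.frame with columns `chrom`, `start`, `end`, `strand`,
#'   one row per interval.
#' @examples
#' genomic_interval("chr1", 0, 100, "+")
#' @export
genomic_interval <- function(chrom, start, end, strand = "*") {
  n <- max(length(chrom), length(start), length(end), length(strand))
  gi <- data.frame(
    chrom = rep_len(as.character(chrom), n),
    start = rep_len(as.numeric(start), n),
    end = rep_len(as.numeric(end), n),
    strand = rep_len(as.character(strand), n),
    stringsAsFactors = FALSE
  )
  validate_intervals(gi)
  gi
}

validate_intervals <- function(gi, what = "interval") {
  if (!all(c("chrom", "start", "end") %in% names(gi))) {
    stop("malformed ", what, ": need chrom/start/end columns")
  }
  if (any(gi$start < 0)) {
    stop("coordinate error: negative start in ", what)
  }
  if (any(gi$start >= gi$end)) {
    bad <- which(gi$start >= gi$end)[1]
    stop(sprintf(
      "coordinate error: start >= end (%d >= %d) in %s",
      gi$start[bad], gi$end[bad], what
    ))
  }
  if ("strand" %in% names(gi) && !all(gi$strand %in% c("+", "-", "*"))) {
    stop("strand must be one of '+', '-', '*' in ", what)
  }
  invisible(gi)
}

#' @keywords internal
#' @noRd
gi_width <- function(gi) gi$end - gi$start

## 0-based half-open -> IRanges (1-based closed)
gi2ir <- function(gi) IRanges::IRanges(start = gi$start + 1L, end = gi$end)

ir2gi_df <- function(ir) {
  data.frame(
    start = IRanges::start(ir) - 1L,
    end = IRanges::end(ir),
    stringsAsFactors = FALSE
  )
}

gi2gr <- function(gi) {
  strand <- if ("strand" %in% names(gi)) gi$strand else "*"
  GenomicRanges::GRanges(
    seqnames = gi$chrom,
    ranges = gi2ir(gi),
    strand = strand
  )
}

gr2gi <- function(gr) {
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE
  )
}

## Gap between two spans on one chromosome: 0 if they overlap or touch,
## otherwise downstream.start - upstream.end (half-open arithmetic).
span_gap <- function(start1, end1, start2, end2) {
  pmax(pmax(start1, start2) - pmin(end1, end2), 0)
}

## Merge possibly overlapping/book-ended [start,end) rows into maximal
## disjoint blocks. Book-ended blocks ([0,100)+[100,200)) merge.
merge_blocks <- function(start, end) {
  if (length(start) == 0L) {
    return(data.frame(start = numeric(0), end = numeric(0)))
  }
  o <- order(start, end)
  start <- start[o]
  end <- end[o]
  ms <- start[1]
  me <- end[1]
  out_s <- numeric(0)
  out_e <- numeric(0)
  for (i in seq_along(start)[-1]) {
    if (start[i] <= me) { # overlap or book-ended
      me <- max(me, end[i])
    } else {
      out_s <- c(out_s, ms)
      out_e <- c(out_e, me)
      ms <- start[i]
      me <- end[i]
    }
  }
  data.frame(start = c(out_s, ms), end = c(out_e, me))
}

#' Round half away from zero
#'
#' Display rounding used for percentages: 0.5 always rounds up (base R
#' `round()` rounds half to even).
#' @param x numeric vector.
#' @param digits decimal digits to keep.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

## Derived per-stage RNG streams: one master integer seed, fixed stage
## ids, so adding a stage never perturbs earlier outputs.
stage_seed <- function(seed, stage) {
  as.integer((as.double(seed) * 1000003 + stage * 7919) %% 2147483629)
}

with_stage_seed <- function(seed, stage, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(stage_seed(seed, stage))
  force(expr)
}

## Reverse complement of an ACGTN character string (uppercase).
revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}
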