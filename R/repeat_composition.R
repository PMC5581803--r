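REPEAT_CLASSES <- c("SINE", "LINE", "LTR", "DNA", "other")

map_repeat_class <- function(class_family) {
  cls <- sub("/.*$", "", class_family)
  ifelse(cls %in% c("SINE", "LINE", "LTR", "DNA"), cls, "other")
}

#' Load repeat annotation
#'
#' Supports RepeatMasker `.out` (1-based inclusive coordinates,
#' converted to 0-based half-open) and 6-column BED with the
#' class/family string in the name column. Class/family strings are
#' mapped to the closed set SINE/LINE/LTR/DNA/other on the prefix
#' before `/` (`"SINE/Alu"` -> SINE; anything unrecognised -> other).
#'
#' @param path annotation file.
#' @param format `"rm_out"` or `"bed"`.
#' @return data.frame with `chrom`, `start`, `end`, `repeat_class`,
#'   `family`.
#' @export
load_repeats <- function(path, format = c("rm_out", "bed")) {
  format <- match.arg(format)
  empty <- data.frame(
    chrom = character(0), start = numeric(0), end = numeric(0),
    repeat_class = character(0), family = character(0),
    stringsAsFactors = FALSE
  )
  if (format == "bed") {
    lines <- readLines(path)
    lines <- lines[nzchar(lines) & !grepl("^(#|track|browser)", lines)]
    if (length(lines) == 0L) return(empty)
    f <- strsplit(lines, "\t", fixed = TRUE)
    if (any(lengths(f) < 4L)) {
      stop(sprintf("repeat BED parse error at line %d: need >= 4 columns",
                   which(lengths(f) < 4L)[1]))
    }
    out <- data.frame(
      chrom = vapply(f, `[[`, "", 1L),
      start = as.numeric(vapply(f, `[[`, "", 2L)),
      end = as.numeric(vapply(f, `[[`, "", 3L)),
      family = vapply(f, `[[`, "", 4L),
      stringsAsFactors = FALSE
    )
  } else {
    lines <- readLines(path)
    keep <- which(grepl("^\\s*\\d", lines)) # data rows start with the SW score
    if (length(keep) == 0L) return(empty)
    f <- strsplit(trimws(lines[keep]), "\\s+")
    if (any(lengths(f) < 11L)) {
      stop(sprintf("RepeatMasker .out parse error at line %d: need >= 11 fields",
                   keep[which(lengths(f) < 11L)[1]]))
    }
    begin <- suppressWarnings(as.numeric(vapply(f, `[[`, "", 6L)))
    end <- suppressWarnings(as.numeric(vapply(f, `[[`, "", 7L)))
    if (anyNA(begin) || anyNA(end)) {
      stop(sprintf("RepeatMasker .out parse error at line %d: non-numeric coordinates",
                   keep[which(is.na(begin) | is.na(end))[1]]))
    }
    out <- data.frame(
      chrom = vapply(f, `[[`, "", 5L),
      start = begin - 1, # 1-based inclusive -> 0-based half-open
      end = end,
      family = vapply(f, `[[`, "", 11L),
      stringsAsFactors = FALSE
    )
  }
  if (any(out$start < 0 | out$start >= out$end)) {
    stop("coordinate error in repeat annotation")
  }
  out$repeat_class <- map_repeat_class(out$family)
  out[, c("chrom", "start", "end", "repeat_class", "family")]
}

## Exonic repeat ranges per class, with fixed precedence so every base
## is counted once: SINE > LINE > LTR > DNA > other.
exonic_repeat_ranges <- function(gene, repeats) {
  exon_ir <- gi2ir(gene$exons)
  reps <- repeats[repeats$chrom == gene$chrom, , drop = FALSE]
  assigned <- IRanges::IRanges()
  out <- list()
  for (cls in REPEAT_CLASSES) {
    r <- reps[reps$repeat_class == cls, , drop = FALSE]
    if (nrow(r) == 0L) {
      out[[cls]] <- IRanges::IRanges()
      next
    }
    ir <- IRanges::reduce(gi2ir(r))
    ir <- IRanges::intersect(ir, IRanges::reduce(exon_ir))
    ir <- IRanges::setdiff(ir, assigned)
    assigned <- IRanges::union(assigned, ir)
    out[[cls]] <- ir
  }
  out
}

#' Repeat-class composition of a gene's exonic sequence
#'
#' Every exonic base is assigned to at most one repeat class (precedence
#' SINE > LINE > LTR > DNA > other when annotations overlap); the
#' remainder is `non_repeat`. Fractions are of `exonic_length` and sum
#' to 1.
#'
#' @param gene a `gene_model`.
#' @param repeats repeat table from [load_repeats()].
#' @return list with `fractions` (named over the five classes) and
#'   `non_repeat`.
#' @export
repeat_fraction <- function(gene, repeats) {
  rr <- exonic_repeat_ranges(gene, repeats)
  frac <- vapply(rr, function(ir) sum(IRanges::width(ir)), 0) / gene$exonic_length
  list(fractions = frac, non_repeat = 1 - sum(frac))
}

#' Repeat profile of a whole catalog
#'
#' `pooled` (default) weights every exonic base of the pooled catalog
#' equally; `per_gene` averages the per-gene fractions.
#'
#' @param genes named list of `gene_model`s.
#' @param repeats repeat table.
#' @param method `"pooled"` or `"per_gene"`.
#' @return as [repeat_fraction()].
#' @export
catalog_repeat_profile <- function(genes, repeats,
                                   method = c("pooled", "per_gene")) {
  method <- match.arg(method)
  profs <- lapply(genes, repeat_fraction, repeats = repeats)
  fr <- do.call(rbind, lapply(profs, `[[`, "fractions"))
  if (method == "pooled") {
    w <- vapply(genes, `[[`, 0, "exonic_length")
    frac <- colSums(fr * w) / sum(w)
  } else {
    frac <- colMeans(fr)
  }
  list(fractions = frac, non_repeat = 1 - sum(frac))
}

## Project genomic ranges onto transcript coordinates of a gene
## (0-based, strand-aware: position 0 is the 5' end of the spliced
## sequence). Returns a data.frame of transcript-coordinate intervals.
project_to_transcript <- function(gene, chrom, start, end) {
  L <- gene$exonic_length
  offs <- cumsum(c(0, utils::head(gene$exons$end - gene$exons$start, -1)))
  pieces <- list()
  for (i in seq_len(nrow(gene$exons))) {
    a <- max(gene$exons$start[i], start)
    b <- min(gene$exons$end[i], end)
    if (a < b && chrom == gene$chrom) {
      ts <- offs[i] + (a - gene$exons$start[i])
      te <- offs[i] + (b - gene$exons$start[i])
      if (gene$strand == "-") {
        pieces[[length(pieces) + 1L]] <- c(L - te, L - ts)
      } else {
        pieces[[length(pieces) + 1L]] <- c(ts, te)
      }
    }
  }
  if (length(pieces) == 0L) {
    return(data.frame(start = numeric(0), end = numeric(0)))
  }
  m <- do.call(rbind, pieces)
  data.frame(start = m[, 1], end = m[, 2])
}

#' Mask repeat-covered positions in a spliced gene sequence
#'
#' Repeat annotation is projected from genomic to transcript coordinates
#' (strand-aware) and the covered positions replaced by `N` (hard
#' masking, the default, matching removal of repeats before microdomain
#' seeding) or lower-cased (soft).
#'
#' @param gene_sequence spliced sequence, length `exonic_length`.
#' @param gene the corresponding `gene_model`.
#' @param repeats repeat table.
#' @param hard hard-mask with `N` (`TRUE`) or soft-mask to lower case.
#' @return masked sequence, same length.
#' @export
mask_repeats <- function(gene_sequence, gene, repeats, hard = TRUE) {
  if (nchar(gene_sequence) != gene$exonic_length) {
    stop("sequence length does not match exonic_length of ", gene$gene_id)
  }
  reps <- repeats[repeats$chrom == gene$chrom, , drop = FALSE]
  if (nrow(reps) == 0L) return(gene_sequence)
  chars <- strsplit(gene_sequence, "")[[1]]
  for (i in seq_len(nrow(reps))) {
    tr <- project_to_transcript(gene, reps$chrom[i], reps$start[i], reps$end[i])
    for (j in seq_len(nrow(tr))) {
      if (tr$start[j] < 0 || tr$end[j] > length(chars)) {
        stop("internal consistency error: repeat projection outside sequence")
      }
      idx <- (tr$start[j] + 1L):tr$end[j]
      chars[idx] <- if (hard) "N" else tolower(chars[idx])
    }
  }
  paste(chars, collapse = "")
}
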