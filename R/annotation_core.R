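#' Read exon structures from a GTF file
#'
#' Parses an Ensembl/Gencode-dialect GTF (1-based inclusive coordinates,
#' `gene_id`/`transcript_id` attributes) and returns per-transcript exon
#' structures in the package's internal 0-based half-open convention.
#' Parsing of the attribute column is delegated to
#' [rtracklayer::import()]; a light pre-scan produces line-numbered
#' errors for structurally broken rows.
#'
#' @param path path to a GTF file.
#' @param feature_filter optional biotype label; when given, only
#'   transcripts whose `gene_biotype` (or `gene_type`) attribute equals
#'   the label are returned.
#' @return a named list of transcripts; each transcript is a list with
#'   `transcript_id`, `gene_id`, `chrom`, `strand` and an `exons`
#'   data.frame (`start`, `end`, 0-based half-open, sorted,
#'   non-overlapping).
#' @seealso [build_gene_models()]
#' @export
read_gtf <- function(path, feature_filter = NULL) {
  if (!file.exists(path)) stop("GTF file not found: ", path)
  lines <- readLines(path)
  dat <- which(!grepl("^#", lines) & nzchar(lines))
  if (length(dat) == 0L) return(structure(list(), names = character(0)))
  fields <- strsplit(lines[dat], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 9L)) {
    stop(sprintf(
      "GTF parse error at line %d: expected 9 tab-separated columns, got %d",
      dat[which(nf < 9L)[1]], nf[which(nf < 9L)[1]]
    ))
  }
  s <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 4L)))
  e <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 5L)))
  if (anyNA(s) || anyNA(e)) {
    stop(sprintf(
      "GTF parse error at line %d: non-numeric coordinates",
      dat[which(is.na(s) | is.na(e))[1]]
    ))
  }
  if (any(s > e)) {
    stop(sprintf(
      "GTF coordinate error at line %d: start > end after conversion",
      dat[which(s > e)[1]]
    ))
  }

  gr <- rtracklayer::import(path, format = "gtf")
  md <- S4Vectors::mcols(gr)
  if ("type" %in% names(md)) gr <- gr[as.character(md$type) == "exon"]
  md <- S4Vectors::mcols(gr)
  if (!is.null(feature_filter)) {
    bio_col <- intersect(c("gene_biotype", "gene_type"), names(md))
    if (length(bio_col) == 0L) {
      warning("no gene_biotype/gene_type attribute in GTF; feature_filter ignored")
    } else {
      gr <- gr[!is.na(md[[bio_col[1]]]) & md[[bio_col[1]]] == feature_filter]
      md <- S4Vectors::mcols(gr)
    }
  }
  if (length(gr) == 0L) return(structure(list(), names = character(0)))
  if (is.null(md$transcript_id) || is.null(md$gene_id)) {
    stop("GTF parse error: gene_id/transcript_id attributes missing")
  }

  ex <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L, # 1-based inclusive -> 0-based half-open
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    transcript_id = as.character(md$transcript_id),
    gene_id = as.character(md$gene_id),
    stringsAsFactors = FALSE
  )
  by_tx <- split(ex, ex$transcript_id)
  tx <- lapply(by_tx, function(d) {
    d <- d[order(d$start, d$end), ]
    if (length(unique(d$chrom)) > 1L || length(unique(d$strand)) > 1L) {
      stop("consistency error: transcript ", d$transcript_id[1],
           " spans multiple chromosomes or strands")
    }
    if (nrow(d) > 1L && any(d$start[-1] < d$end[-nrow(d)])) {
      stop("consistency error: overlapping exons within transcript ",
           d$transcript_id[1])
    }
    list(
      transcript_id = d$transcript_id[1],
      gene_id = d$gene_id[1],
      chrom = d$chrom[1],
      strand = d$strand[1],
      exons = data.frame(start = d$start, end = d$end)
    )
  })
  tx
}

#' Construct a composite gene model
#'
#' @param gene_id gene identifier.
#' @param chrom chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exons data.frame with `start`/`end` (0-based half-open);
#'   overlapping or book-ended rows are merged into maximal disjoint
#'   blocks.
#' @param biotype `"coding"` or `"lncRNA_candidate"`.
#' @return an object of class `gene_model`: a list with the merged
#'   `exons`, the covering `span`, `exonic_length` (sum of exon widths)
#'   and `n_exons`.
#' @export
gene_model <- function(gene_id, chrom, strand, exons,
                       biotype = c("lncRNA_candidate", "coding")) {
  biotype <- match.arg(biotype)
  if (!strand %in% c("+", "-")) {
    stop("gene ", gene_id, ": strand must be '+' or '-'")
  }
  exons <- merge_blocks(exons$start, exons$end)
  validate_intervals(cbind(chrom = chrom, exons), what = paste("gene", gene_id))
  structure(
    list(
      gene_id = gene_id,
      chrom = chrom,
      strand = strand,
      exons = exons,
      span = c(start = min(exons$start), end = max(exons$end)),
      exonic_length = sum(exons$end - exons$start),
      biotype = biotype,
      n_exons = nrow(exons)
    ),
    class = "gene_model"
  )
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf(
    "<gene_model> %s %s:%d-%d(%s) %s, %d exon(s), %d nt exonic\n",
    x$gene_id, x$chrom, x$span["start"], x$span["end"], x$strand,
    x$biotype, x$n_exons, x$exonic_length
  ))
  invisible(x)
}

#' Merge transcripts into composite gene models
#'
#' All exons of all transcripts sharing a `gene_id` are pooled and
#' overlapping or book-ended exons merged into maximal disjoint blocks,
#' giving one composite model per gene.
#'
#' @param transcripts list of transcripts as returned by [read_gtf()].
#' @param biotype biotype assigned to every resulting model.
#' @return named list of `gene_model` objects, keyed by gene id.
#' @export
build_gene_models <- function(transcripts,
                              biotype = c("lncRNA_candidate", "coding")) {
  biotype <- match.arg(biotype)
  if (length(transcripts) == 0L) return(structure(list(), names = character(0)))
  gid <- vapply(transcripts, `[[`, "", "gene_id")
  by_gene <- split(transcripts, gid)
  models <- lapply(by_gene, function(txs) {
    chrom <- unique(vapply(txs, `[[`, "", "chrom"))
    strand <- unique(vapply(txs, `[[`, "", "strand"))
    if (length(chrom) > 1L) {
      stop("consistency error: gene ", txs[[1]]$gene_id,
           " has transcripts on multiple chromosomes")
    }
    if (length(strand) > 1L) {
      stop("consistency error: gene ", txs[[1]]$gene_id,
           " has transcripts on both strands")
    }
    ex <- do.call(rbind, lapply(txs, `[[`, "exons"))
    gene_model(txs[[1]]$gene_id, chrom, strand, ex, biotype)
  })
  models[order(names(models))]
}

## Compact data.frame view of a model list (one row per gene).
models_table <- function(genes) {
  if (length(genes) == 0L) {
    return(data.frame(
      gene_id = character(0), chrom = character(0), strand = character(0),
      start = numeric(0), end = numeric(0),
      exonic_length = numeric(0), n_exons = integer(0)
    ))
  }
  data.frame(
    gene_id = vapply(genes, `[[`, "", "gene_id"),
    chrom = vapply(genes, `[[`, "", "chrom"),
    strand = vapply(genes, `[[`, "", "strand"),
    start = vapply(genes, function(g) g$span[["start"]], 0),
    end = vapply(genes, function(g) g$span[["end"]], 0),
    exonic_length = vapply(genes, `[[`, 0, "exonic_length"),
    n_exons = vapply(genes, `[[`, 0L, "n_exons"),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

## GRanges of merged exons across a model list (gene_id carried in mcols).
models_exon_gr <- function(genes) {
  tab <- lapply(genes, function(g) {
    data.frame(
      chrom = g$chrom, start = g$exons$start, end = g$exons$end,
      strand = g$strand, gene_id = g$gene_id, stringsAsFactors = FALSE
    )
  })
  tab <- do.call(rbind, tab)
  gr <- gi2gr(tab)
  S4Vectors::mcols(gr)$gene_id <- tab$gene_id
  gr
}

#' Extract the spliced gene sequence
#'
#' Exon sequences are concatenated in genomic order; for minus-strand
#' genes the concatenation is reverse-complemented so the result always
#' reads 5'->3'. Lower-case genome bases are accepted and upper-cased;
#' characters outside A/C/G/T/N are rejected.
#'
#' @param gene a `gene_model`.
#' @param genome named character vector or [Biostrings::DNAStringSet]
#'   mapping chromosome name to sequence.
#' @return single character string, the spliced 5'->3' sequence.
#' @export
extract_gene_sequence <- function(gene, genome) {
  if (methods::is(genome, "DNAStringSet")) {
    genome <- as.character(genome)
  }
  if (!gene$chrom %in% names(genome)) {
    stop("chromosome ", gene$chrom, " not present in genome")
  }
  chrseq <- genome[[gene$chrom]]
  if (any(gene$exons$end > nchar(chrseq))) {
    stop("bounds error: exon of gene ", gene$gene_id,
         " extends beyond end of ", gene$chrom)
  }
  pieces <- substring(chrseq, gene$exons$start + 1L, gene$exons$end)
  seq <- toupper(paste(pieces, collapse = ""))
  if (grepl("[^ACGTN]", seq)) {
    stop("invalid characters in genome sequence for gene ", gene$gene_id)
  }
  if (gene$strand == "-") seq <- revcomp_chr(seq)
  seq
}

#' Write a catalog as BED12 + FASTA
#'
#' Emits `<prefix>.bed` (one BED12 record per gene, blocks = merged
#' exons) and `<prefix>.fa` (gene sequences under `gene_id` headers).
#' [read_catalog_bed()] on the BED reproduces the input models.
#'
#' @param genes named list of `gene_model`s (non-empty).
#' @param sequences named character vector of gene sequences (same
#'   names); pass `NULL` to skip the FASTA.
#' @param prefix output path prefix.
#' @param fasta_width line-wrap width for the FASTA.
#' @return invisibly, the paths written.
#' @export
write_catalog <- function(genes, sequences, prefix, fasta_width = 60) {
  if (length(genes) == 0L) stop("write_catalog: empty gene collection")
  bed_path <- paste0(prefix, ".bed")
  writeLines(vapply(genes, bed12_line, ""), bed_path)
  paths <- bed_path
  if (!is.null(sequences)) {
    fa_path <- paste0(prefix, ".fa")
    ss <- Biostrings::DNAStringSet(sequences[names(genes)])
    Biostrings::writeXStringSet(ss, fa_path, width = fasta_width)
    paths <- c(paths, fa_path)
  }
  invisible(paths)
}

bed12_line <- function(g) {
  rel <- g$exons$start - g$span[["start"]]
  paste(
    g$chrom, g$span[["start"]], g$span[["end"]], g$gene_id, 0, g$strand,
    g$span[["start"]], g$span[["end"]], "0,0,0", nrow(g$exons),
    paste0(paste(g$exons$end - g$exons$start, collapse = ","), ","),
    paste0(paste(rel, collapse = ","), ","),
    sep = "\t"
  )
}

#' Read gene models back from a BED12 (or BED6) file
#'
#' @param path BED file path.
#' @param biotype biotype to stamp on the models.
#' @return named list of `gene_model`s.
#' @export
read_catalog_bed <- function(path, biotype = c("lncRNA_candidate", "coding")) {
  biotype <- match.arg(biotype)
  gr <- rtracklayer::import(path, format = "bed")
  md <- S4Vectors::mcols(gr)
  models <- lapply(seq_along(gr), function(i) {
    chrom <- as.character(GenomicRanges::seqnames(gr)[i])
    gstart <- GenomicRanges::start(gr)[i] - 1L
    strand <- as.character(GenomicRanges::strand(gr)[i])
    if (!is.null(md$blocks)) {
      bl <- md$blocks[[i]] # 1-based, relative to range start
      exons <- data.frame(
        start = gstart + IRanges::start(bl) - 1L,
        end = gstart + IRanges::end(bl)
      )
    } else {
      exons <- data.frame(start = gstart, end = GenomicRanges::end(gr)[i])
    }
    gene_model(as.character(md$name[i]), chrom, strand, exons, biotype)
  })
  names(models) <- vapply(models, `[[`, "", "gene_id")
  models[order(names(models))]
}

#' Read a genome FASTA
#'
#' @param path FASTA file.
#' @return named character vector, chromosome name (first header word)
#'   to sequence.
#' @export
read_genome_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  out <- as.character(ss)
  names(out) <- sub("\\s.*$", "", names(ss))
  out
}
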