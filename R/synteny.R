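## UCSC chain handling and liftover.
##
## A chain is stored with both genomes in FORWARD 0-based half-open
## coordinates: `canon` has one row per aligned block
## (s_start, s_end, t_start, t_end). `orient` is the target strand: for
## "-" a source position p inside a block maps to
## t_end - 1 - (p - s_start). Source strand must be "+", as in chain
## files produced by UCSC tools.

new_chain <- function(score, id, s_chrom, s_size, t_chrom, t_size,
                      orient, canon) {
  canon <- canon[order(canon$s_start), , drop = FALSE]
  rownames(canon) <- NULL
  if (any(canon$s_end - canon$s_start != canon$t_end - canon$t_start)) {
    stop("chain format error: block sizes differ between genomes")
  }
  if (any(canon$s_end - canon$s_start <= 0)) {
    stop("chain format error: non-positive block size")
  }
  structure(
    list(
      score = score, id = id,
      s = list(chrom = s_chrom, size = s_size,
               start = min(canon$s_start), end = max(canon$s_end)),
      t = list(chrom = t_chrom, size = t_size,
               start = min(canon$t_start), end = max(canon$t_end)),
      orient = orient,
      canon = canon
    ),
    class = "ucsc_chain"
  )
}

#' @export
print.ucsc_chain <- function(x, ...) {
  cat(sprintf(
    "<chain %s> %s:%d-%d -> %s:%d-%d (%s), %d block(s), score %g\n",
    x$id, x$s$chrom, x$s$start, x$s$end,
    x$t$chrom, x$t$start, x$t$end, x$orient, nrow(x$canon), x$score
  ))
  invisible(x)
}

#' Read a UCSC chain file
#'
#' Parses `chain` headers and their block lines, verifies that block
#' sums match the header spans, and returns chains with both genomes in
#' forward 0-based half-open coordinates.
#'
#' @param path chain file.
#' @return list of chain objects.
#' @export
read_chain <- function(path) {
  lines <- trimws(readLines(path))
  heads <- which(grepl("^chain\\b", lines))
  if (length(heads) == 0L) stop("chain format error: no chain header found")
  bounds <- c(heads, length(lines) + 1L)
  chains <- vector("list", length(heads))
  for (ci in seq_along(heads)) {
    h <- strsplit(lines[heads[ci]], "\\s+")[[1]]
    if (length(h) < 13L) {
      stop("chain format error: malformed header at line ", heads[ci])
    }
    score <- as.numeric(h[2])
    s_chrom <- h[3]; s_size <- as.numeric(h[4]); s_strand <- h[5]
    s_start <- as.numeric(h[6]); s_end <- as.numeric(h[7])
    t_chrom <- h[8]; t_size <- as.numeric(h[9]); t_strand <- h[10]
    t_start <- as.numeric(h[11]); t_end <- as.numeric(h[12])
    id <- h[13]
    if (s_strand != "+") {
      stop("chain format error: source strand must be '+' (chain ", id, ")")
    }
    if (!t_strand %in% c("+", "-")) {
      stop("chain format error: bad target strand (chain ", id, ")")
    }
    body <- lines[(heads[ci] + 1L):(bounds[ci + 1L] - 1L)]
    body <- body[nzchar(body)]
    if (length(body) == 0L) stop("chain format error: chain ", id, " has no blocks")
    rows <- strsplit(body, "\\s+")
    if (any(lengths(rows[-length(rows)]) != 3L) ||
        !lengths(rows)[length(rows)] %in% c(1L, 3L)) {
      stop("chain format error: malformed block line in chain ", id)
    }
    size <- as.numeric(vapply(rows, `[[`, "", 1L))
    dt <- c(vapply(rows[-length(rows)], function(r) as.numeric(r[2]), 0), 0)
    dq <- c(vapply(rows[-length(rows)], function(r) as.numeric(r[3]), 0), 0)
    if (sum(size) + sum(dt) != s_end - s_start) {
      stop("chain format error: source span does not match block sums (chain ",
           id, ")")
    }
    if (sum(size) + sum(dq) != t_end - t_start) {
      stop("chain format error: target span does not match block sums (chain ",
           id, ")")
    }
    s_cur <- s_start
    t_cur <- t_start # strand coordinates of the target
    canon <- vector("list", length(size))
    for (k in seq_along(size)) {
      tf <- if (t_strand == "+") {
        c(t_cur, t_cur + size[k])
      } else {
        c(t_size - (t_cur + size[k]), t_size - t_cur)
      }
      canon[[k]] <- data.frame(
        s_start = s_cur, s_end = s_cur + size[k],
        t_start = tf[1], t_end = tf[2]
      )
      s_cur <- s_cur + size[k] + dt[k]
      t_cur <- t_cur + size[k] + dq[k]
    }
    chains[[ci]] <- new_chain(score, id, s_chrom, s_size, t_chrom, t_size,
                              t_strand, do.call(rbind, canon))
  }
  chains
}

#' Write chains to a UCSC chain file
#'
#' @param chains list of chain objects.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_chain_file <- function(chains, path) {
  fmt <- function(x) format(x, scientific = FALSE, trim = TRUE)
  out <- unlist(lapply(chains, function(ch) {
    canon <- ch$canon
    size <- canon$s_end - canon$s_start
    t_strand_start <- if (ch$orient == "+") {
      canon$t_start
    } else {
      # strand coordinates: measured from the far end of the target
      ch$t$size - canon$t_end
    }
    n <- nrow(canon)
    dt <- if (n > 1) canon$s_start[-1] - canon$s_end[-n] else numeric(0)
    dq <- if (n > 1) t_strand_start[-1] - (t_strand_start[-n] + size[-n]) else numeric(0)
    if (any(c(dt, dq) < 0)) {
      stop("chain blocks are not colinear; cannot serialise chain ", ch$id)
    }
    t0 <- t_strand_start[1]
    t1 <- t_strand_start[n] + size[n]
    header <- paste(
      "chain", fmt(ch$score), ch$s$chrom, fmt(ch$s$size), "+",
      fmt(ch$s$start), fmt(ch$s$end), ch$t$chrom, fmt(ch$t$size), ch$orient,
      fmt(t0), fmt(t1), ch$id
    )
    body <- if (n > 1) {
      c(paste(fmt(size[-n]), fmt(dt), fmt(dq), sep = "\t"), fmt(size[n]))
    } else {
      fmt(size)
    }
    c(header, body, "")
  }))
  writeLines(out, path)
  invisible(path)
}

#' Invert a chain
#'
#' Swaps the two genomes; lifting an interval through a chain and then
#' through its inverse recovers the original coordinates on fully
#' mapped intervals.
#'
#' @param chain a chain object.
#' @return the inverted chain.
#' @export
invert_chain <- function(chain) {
  canon <- data.frame(
    s_start = chain$canon$t_start, s_end = chain$canon$t_end,
    t_start = chain$canon$s_start, t_end = chain$canon$s_end
  )
  new_chain(chain$score, paste0(chain$id, "_inv"),
            chain$t$chrom, chain$t$size,
            chain$s$chrom, chain$s$size,
            chain$orient, canon)
}

## Map a source interval through one chain. Returns data.frame of target
## forward pieces (possibly 0 rows).
chain_map_pieces <- function(chain, start, end) {
  cb <- chain$canon
  a <- pmax(cb$s_start, start)
  b <- pmin(cb$s_end, end)
  keep <- a < b
  if (!any(keep)) {
    return(data.frame(start = numeric(0), end = numeric(0)))
  }
  a <- a[keep]; b <- b[keep]; cb <- cb[keep, , drop = FALSE]
  if (chain$orient == "+") {
    data.frame(
      start = cb$t_start + (a - cb$s_start),
      end = cb$t_start + (b - cb$s_start)
    )
  } else {
    data.frame(
      start = cb$t_end - (b - cb$s_start),
      end = cb$t_end - (a - cb$s_start)
    )
  }
}

#' Lift an interval onto the target genome
#'
#' Bases are mapped block by block; the result is reported iff the
#' mapped-base fraction reaches `min_match` (unmapped is a normal
#' outcome, returned as `NULL`). Among chains on the right chromosome
#' the one mapping the most bases wins (ties by chain score).
#'
#' @param interval list or one-row data.frame with `chrom`, `start`,
#'   `end` (0-based half-open).
#' @param chains list of chain objects (see [read_chain()]).
#' @param min_match minimum mapped fraction (default 0.95, the usual
#'   same-species liftOver setting; lower it for cross-species use).
#' @return `NULL`, or a list with `chrom`, `span` (minimal covering
#'   target interval, 0-based half-open), `pieces` (per-block target
#'   intervals), `mapped_fraction`, `strand` (chain orientation) and
#'   `chain_id`.
#' @export
liftover_interval <- function(interval, chains, min_match = 0.95) {
  width <- interval$end - interval$start
  if (width <= 0) stop("coordinate error: empty interval")
  cand <- Filter(function(ch) ch$s$chrom == interval$chrom, chains)
  if (length(cand) == 0L) return(NULL)
  mapped <- lapply(cand, chain_map_pieces,
                   start = interval$start, end = interval$end)
  nbases <- vapply(mapped, function(p) sum(p$end - p$start), 0)
  best <- order(-nbases, -vapply(cand, `[[`, 0, "score"))[1]
  frac <- nbases[best] / width
  if (frac < min_match || nbases[best] == 0) return(NULL)
  pieces <- mapped[[best]]
  pieces <- pieces[order(pieces$start), , drop = FALSE]
  rownames(pieces) <- NULL
  list(
    chrom = cand[[best]]$t$chrom,
    span = c(start = min(pieces$start), end = max(pieces$end)),
    pieces = pieces,
    mapped_fraction = frac,
    strand = cand[[best]]$orient,
    chain_id = cand[[best]]$id
  )
}

#' Map synteny between two gene catalogs through a chain set
#'
#' Each gene of catalog A whose span lifts onto the target genome (at
#' `min_match`) is paired with every catalog-B gene whose span overlaps
#' the lifted span by at least 1 bp; strand is ignored (orientation is
#' carried by the chain).
#'
#' @param genes_a named list of `gene_model`s on the chains' source
#'   genome.
#' @param chains list of chain objects.
#' @param genes_b named list of `gene_model`s on the target genome.
#' @param min_match minimum mapped fraction for the liftover.
#' @return data.frame of pairs: `gene_a`, `gene_b`, `overlap_bp`,
#'   `chrom`, `lift_start`, `lift_end`, `mapped_fraction`.
#' @export
map_catalog_synteny <- function(genes_a, chains, genes_b, min_match = 0.95) {
  bt <- models_table(genes_b)
  out <- list()
  for (g in genes_a) {
    lift <- liftover_interval(
      list(chrom = g$chrom, start = g$span[["start"]], end = g$span[["end"]]),
      chains, min_match
    )
    if (is.null(lift)) next
    cand <- bt[bt$chrom == lift$chrom, , drop = FALSE]
    if (nrow(cand) == 0L) next
    ov <- pmin(cand$end, lift$span[["end"]]) - pmax(cand$start, lift$span[["start"]])
    hit <- ov > 0
    if (!any(hit)) next
    out[[length(out) + 1L]] <- data.frame(
      gene_a = g$gene_id, gene_b = cand$gene_id[hit],
      overlap_bp = ov[hit], chrom = lift$chrom,
      lift_start = lift$span[["start"]], lift_end = lift$span[["end"]],
      mapped_fraction = lift$mapped_fraction,
      stringsAsFactors = FALSE
    )
  }
  if (length(out) == 0L) {
    return(data.frame(
      gene_a = character(0), gene_b = character(0), overlap_bp = numeric(0),
      chrom = character(0), lift_start = numeric(0), lift_end = numeric(0),
      mapped_fraction = numeric(0)
    ))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Pairwise sequence conservation percentage
#'
#' Aligns two gene sequences with [local_align_all_pairs()], merges the
#' query intervals of all retained hits and reports the covered
#' percentage of the FIRST (query) sequence.
#'
#' @param seq_a,seq_b gene sequences (non-empty).
#' @param params `ka_params`; default scoring when `NULL`.
#' @param word_size,evalue_max alignment settings.
#' @return percentage in `[0, 100]`.
#' @export
pairwise_conservation_pct <- function(seq_a, seq_b, params = NULL,
                                      word_size = 11, evalue_max = 10) {
  if (nchar(seq_a) == 0L || nchar(seq_b) == 0L) {
    stop("empty sequence in conservation comparison")
  }
  hits <- local_align_all_pairs(c(a = seq_a, b = seq_b), params,
                                word_size = word_size,
                                evalue_max = evalue_max)
  if (nrow(hits) == 0L) return(0)
  covered <- IRanges::reduce(IRanges::IRanges(hits$q_start + 1L, hits$q_end))
  100 * sum(IRanges::width(covered)) / nchar(seq_a)
}

#' Mean per-base conservation score over exons
#'
#' Averages a per-base score track (e.g. PhastCons, 0-1 scale) over the
#' exonic positions of a gene; positions absent from the track are
#' excluded from numerator and denominator.
#'
#' @param gene a `gene_model`.
#' @param score_track data.frame `chrom`, `start`, `end`, `score`
#'   (bedGraph semantics, see [read_bedgraph()]).
#' @return mean score.
#' @export
mean_conservation_score <- function(gene, score_track) {
  tr <- score_track[score_track$chrom == gene$chrom, , drop = FALSE]
  if (nrow(tr) == 0L) stop("undefined score: no covered exonic base")
  exon_ir <- IRanges::reduce(gi2ir(gene$exons))
  tr_ir <- gi2ir(tr)
  ov <- IRanges::findOverlaps(tr_ir, exon_ir)
  if (length(ov) == 0L) stop("undefined score: no covered exonic base")
  w <- IRanges::width(IRanges::pintersect(
    tr_ir[S4Vectors::queryHits(ov)], exon_ir[S4Vectors::subjectHits(ov)]
  ))
  sum(w * tr$score[S4Vectors::queryHits(ov)]) / sum(w)
}
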