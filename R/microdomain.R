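#' Karlin-Altschul parameters for an ungapped match/mismatch scheme
#'
#' For scores s(i,j) = `match` when i = j and `mismatch` otherwise and
#' background base probabilities p, lambda is the unique positive root
#' of sum_ij p_i p_j exp(lambda s(i,j)) = 1 (solved numerically to
#' |f| < 1e-10). K is estimated by a seeded Monte-Carlo calibration on
#' random sequences (see [calibrate_k()]) unless a constant is supplied
#' via `k_const`; E-values are therefore approximate, which is
#' sufficient for ranking and thresholding 12-50 nt microdomain hits.
#'
#' @param base_probs probabilities of A, C, G, T (sum to 1).
#' @param match match score (> 0).
#' @param mismatch mismatch score (< 0).
#' @param k_const optional constant K override; `NULL` runs the
#'   Monte-Carlo calibration.
#' @param k_seed seed for the calibration.
#' @return list of class `ka_params`: `lambda`, `k_const`, `base_probs`,
#'   `match_score`, `mismatch_score`.
#' @examples
#' p <- karlin_altschul_params(match = 1, mismatch = -1, k_const = 0.33)
#' abs(p$lambda - log(3)) < 1e-9
#' @export
karlin_altschul_params <- function(base_probs = rep(0.25, 4), match = 2,
                                   mismatch = -3, k_const = NULL,
                                   k_seed = 1) {
  if (length(base_probs) != 4 || abs(sum(base_probs) - 1) > 1e-9 ||
      any(base_probs < 0)) {
    stop("base_probs must be 4 non-negative values summing to 1")
  }
  if (match <= 0) stop("parameter error: match score must be positive")
  if (mismatch >= 0) stop("parameter error: mismatch score must be negative")
  p_match <- sum(base_probs^2)
  if (p_match * match + (1 - p_match) * mismatch >= 0) {
    stop("parameter error: expected pairwise score must be negative")
  }
  f <- function(l) p_match * exp(l * match) + (1 - p_match) * exp(l * mismatch) - 1
  hi <- 1
  while (f(hi) < 0) hi <- hi * 2
  lambda <- stats::uniroot(f, c(1e-12, hi), tol = 1e-14)$root
  stopifnot(abs(f(lambda)) < 1e-10)
  params <- structure(
    list(
      lambda = lambda, k_const = k_const, base_probs = base_probs,
      match_score = match, mismatch_score = mismatch
    ),
    class = "ka_params"
  )
  if (is.null(k_const)) {
    params$k_const <- calibrate_k(params, seed = k_seed)
  }
  params
}

#' Monte-Carlo calibration of the Karlin-Altschul K constant
#'
#' Simulates pairs of i.i.d. sequences from the background composition,
#' counts locally maximal ungapped segments scoring at least a pivot s0,
#' and inverts the expected-count identity E[N(S >= s0)] =
#' K m n exp(-lambda s0). Fully reproducible from `seed`.
#'
#' @param params a `ka_params` (lambda already solved).
#' @param len simulated sequence length.
#' @param nsim number of simulated pairs.
#' @param seed RNG seed.
#' @return estimated K (> 0).
#' @export
calibrate_k <- function(params, len = 400, nsim = 30, seed = 1) {
  lambda <- params$lambda
  params$k_const <- 1 # E-values unused during calibration
  # pivot chosen so the expected segment count per pair is O(1)
  s0 <- ceiling(log(0.3 * len^2 / 2) / lambda)
  s0 <- max(s0, 2 * params$match_score)
  word <- max(4L, floor(s0 / params$match_score / 2))
  emax <- len^2 * exp(-lambda * s0) # with K=1: keeps exactly score >= s0
  counts <- with_stage_seed(seed, 0, {
    vapply(seq_len(nsim), function(i) {
      a <- paste(sample(c("A", "C", "G", "T"), len, TRUE, params$base_probs),
                 collapse = "")
      b <- paste(sample(c("A", "C", "G", "T"), len, TRUE, params$base_probs),
                 collapse = "")
      hits <- align_pair(prep_align_seq(a, word), prep_align_seq(b, word),
                         params, word_size = word, x_drop = 20,
                         evalue_max = emax)
      sum(hits$score >= s0)
    }, 0)
  })
  k <- mean(counts) / (len^2 * exp(-lambda * s0))
  max(k, 1e-4)
}

#' Length- and AT-matched random control sequences
#'
#' One i.i.d. sequence per requested length with
#' P(A) = P(T) = `at_fraction`/2 and P(G) = P(C) = (1-`at_fraction`)/2,
#' reproducible from `seed`.
#'
#' @param lengths vector of sequence lengths (> 0).
#' @param at_fraction target AT fraction in `[0, 1]`.
#' @param seed RNG seed.
#' @return named character vector (`ctrl_1`, `ctrl_2`, ...).
#' @export
generate_matched_controls <- function(lengths, at_fraction, seed = 1) {
  if (at_fraction < 0 || at_fraction > 1) {
    stop("at_fraction must lie in [0, 1]")
  }
  if (any(lengths <= 0)) stop("lengths must be positive")
  probs <- c(A = at_fraction / 2, C = (1 - at_fraction) / 2,
             G = (1 - at_fraction) / 2, T = at_fraction / 2)
  with_stage_seed(seed, 0, {
    out <- vapply(lengths, function(L) {
      paste(sample(names(probs), L, TRUE, probs), collapse = "")
    }, "")
    names(out) <- paste0("ctrl_", seq_along(out))
    out
  })
}

## Pre-computed per-sequence structures for seeding and extension.
prep_align_seq <- function(seq, word_size) {
  seq <- toupper(seq)
  n <- nchar(seq)
  chars <- utf8ToInt(seq)
  kmers <- if (n >= word_size) {
    substring(seq, 1:(n - word_size + 1), word_size:n)
  } else {
    character(0)
  }
  kmers[grepl("N", kmers, fixed = TRUE)] <- NA_character_ # masked bases never seed
  list(seq = seq, n = n, chars = chars, kmers = kmers)
}

## X-drop extension along one diagonal. sc: per-position scores along
## the diagonal overlap; seed occupies t positions [s0, s1] (1-based).
## Returns c(l, r) 1-based inclusive bounds of the retained segment.
xdrop_extend <- function(sc, s0, s1, x_drop) {
  r <- s1
  if (s1 < length(sc)) {
    cs <- cumsum(sc[(s1 + 1):length(sc)])
    run_max <- cummax(cs)
    stop_at <- which(run_max - cs > x_drop)[1]
    upto <- if (is.na(stop_at)) length(cs) else stop_at
    best <- which.max(cs[seq_len(upto)])
    if (cs[best] > 0) r <- s1 + best
  }
  l <- s0
  if (s0 > 1) {
    cs <- cumsum(sc[(s0 - 1):1])
    run_max <- cummax(cs)
    stop_at <- which(run_max - cs > x_drop)[1]
    upto <- if (is.na(stop_at)) length(cs) else stop_at
    best <- which.max(cs[seq_len(upto)])
    if (cs[best] > 0) l <- s0 - best
  }
  c(l, r)
}

N_INT <- utf8ToInt("N")

## Ungapped seed-and-extend between two prepared sequences (forward
## orientation). Returns hits in 0-based half-open coordinates of q/s.
align_pair <- function(q, s, params, word_size, x_drop, evalue_max,
                       m = q$n, n = s$n) {
  empty <- data.frame(
    q_start = numeric(0), q_end = numeric(0),
    s_start = numeric(0), s_end = numeric(0),
    length = numeric(0), n_ident = numeric(0), pident = numeric(0),
    score = numeric(0), evalue = numeric(0)
  )
  if (q$n < word_size || s$n < word_size) return(empty)
  shared <- intersect(q$kmers[!is.na(q$kmers)], s$kmers[!is.na(s$kmers)])
  if (length(shared) == 0L) return(empty)
  qpos <- which(q$kmers %in% shared)
  seed_list <- lapply(qpos, function(qp) {
    sp <- which(s$kmers == q$kmers[qp])
    cbind(qp = qp, sp = sp)
  })
  seeds <- do.call(rbind, seed_list) # 1-based start positions
  diag <- seeds[, "qp"] - seeds[, "sp"]

  hits <- list()
  for (d in unique(diag)) {
    ds <- sort(seeds[diag == d, "qp"])
    qlo <- max(1L, 1L + d) # first q position (1-based) on this diagonal
    qhi <- min(q$n, s$n + d)
    qi <- qlo:qhi
    si <- qi - d
    is_match <- q$chars[qi] == s$chars[si] &
      q$chars[qi] != N_INT & s$chars[si] != N_INT
    sc <- ifelse(is_match, params$match_score, params$mismatch_score)
    covered_to <- 0L
    for (qp in ds) {
      t0 <- qp - qlo + 1L
      if (t0 <= covered_to) next # seed already inside a reported hit
      ext <- xdrop_extend(sc, t0, t0 + word_size - 1L, x_drop)
      covered_to <- ext[2]
      score <- sum(sc[ext[1]:ext[2]])
      len <- ext[2] - ext[1] + 1L
      ev <- params$k_const * m * n * exp(-params$lambda * score)
      if (score > 0 && ev <= evalue_max) {
        qs <- qlo + ext[1] - 2L
        hits[[length(hits) + 1L]] <-
          c(qs, qs + len, qs - d, qs - d + len, len,
            sum(is_match[ext[1]:ext[2]]), score, ev)
      }
    }
  }
  if (length(hits) == 0L) return(empty)
  out <- unique(do.call(rbind, hits))
  out <- data.frame(
    q_start = out[, 1], q_end = out[, 2], s_start = out[, 3],
    s_end = out[, 4], length = out[, 5], n_ident = out[, 6],
    score = out[, 7], evalue = out[, 8]
  )
  out$pident <- 100 * out$n_ident / out$length
  out[order(out$evalue, out$q_start),
      c("q_start", "q_end", "s_start", "s_end", "length", "n_ident",
        "pident", "score", "evalue")]
}

#' All-vs-all ungapped local alignment (seed and extend)
#'
#' For every unordered sequence pair and both subject strands, exact
#' `word_size`-mer seeds (N never seeds) are extended ungapped in both
#' directions with an X-drop rule; retained segments are locally maximal
#' and non-overlapping per diagonal. Scores are converted to E-values
#' with E = K m n exp(-lambda S), m and n being the pair's lengths.
#' Self-pairs and reciprocal duplicates are excluded. Defaults mirror
#' megablast-style short-match searching of `blastn`: word size 11,
#' match +2 / mismatch -3, E <= 10.
#'
#' @param sequences named character vector (>= 2 non-empty sequences;
#'   empty ones are skipped with a warning).
#' @param params `ka_params` from [karlin_altschul_params()].
#' @param word_size exact-seed length.
#' @param evalue_max maximum reported E-value.
#' @param x_drop score drop-off terminating extension.
#' @param strands subject strands searched.
#' @return data.frame of hits: `query_id`, `subject_id`, `q_start`,
#'   `q_end`, `s_start`, `s_end` (0-based half-open on the forward
#'   subject), `subject_strand`, `length`, `n_ident`, `pident`, `score`,
#'   `evalue`.
#' @export
local_align_all_pairs <- function(sequences, params = NULL, word_size = 11,
                                  evalue_max = 10, x_drop = 20,
                                  strands = c("+", "-")) {
  if (is.null(params)) params <- karlin_altschul_params()
  if (is.null(names(sequences)) || anyNA(names(sequences))) {
    names(sequences) <- paste0("seq_", seq_along(sequences))
  }
  empty <- nchar(sequences) == 0L
  if (any(empty)) {
    warning("skipping ", sum(empty), " empty sequence(s): ",
            paste(names(sequences)[empty], collapse = ", "))
    sequences <- sequences[!empty]
  }
  if (length(sequences) < 2L) {
    stop("need at least 2 non-empty sequences")
  }
  fwd <- lapply(sequences, prep_align_seq, word_size = word_size)
  rev <- if ("-" %in% strands) {
    lapply(sequences, function(x) prep_align_seq(revcomp_chr(toupper(x)), word_size))
  } else {
    NULL
  }
  ids <- names(sequences)
  out <- list()
  for (i in seq_along(ids)[-length(ids)]) {
    for (j in (i + 1):length(ids)) {
      for (strand in strands) {
        subj <- if (strand == "+") fwd[[j]] else rev[[j]]
        h <- align_pair(fwd[[i]], subj, params, word_size, x_drop,
                        evalue_max, m = fwd[[i]]$n, n = subj$n)
        if (nrow(h) == 0L) next
        if (strand == "-") { # back to forward subject coordinates
          sn <- subj$n
          tmp <- h$s_start
          h$s_start <- sn - h$s_end
          h$s_end <- sn - tmp
        }
        h$query_id <- ids[i]
        h$subject_id <- ids[j]
        h$subject_strand <- strand
        out[[length(out) + 1L]] <- h
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(
      query_id = character(0), subject_id = character(0),
      q_start = numeric(0), q_end = numeric(0),
      s_start = numeric(0), s_end = numeric(0),
      subject_strand = character(0), length = numeric(0),
      n_ident = numeric(0), pident = numeric(0),
      score = numeric(0), evalue = numeric(0)
    ))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[, c("query_id", "subject_id", "q_start", "q_end", "s_start", "s_end",
          "subject_strand", "length", "n_ident", "pident", "score", "evalue")]
}

#' Hit-length histogram over a closed length window
#'
#' @param hits hit table from [local_align_all_pairs()].
#' @param min_len,max_len closed length bounds (defaults 12 and 50 nt).
#' @return list with `histogram` (named counts, one bin per length) and
#'   `total`.
#' @export
hit_length_stats <- function(hits, min_len = 12, max_len = 50) {
  lens <- hits$length[hits$length >= min_len & hits$length <= max_len]
  bins <- min_len:max_len
  histogram <- vapply(bins, function(L) sum(lens == L), 0)
  names(histogram) <- bins
  list(histogram = histogram, total = length(lens))
}

#' One-way ANOVA on per-length-bin hit counts across groups
#'
#' Treats the per-length-bin counts of each group's histogram as
#' observations and compares group means with a one-way analysis of
#' variance.
#'
#' @param histograms named list (>= 2 entries) of equal-length count
#'   vectors, e.g. the `histogram` elements of [hit_length_stats()].
#' @return list with `F`, `p_value`, `df`.
#' @export
compare_hit_counts <- function(histograms) {
  if (length(histograms) < 2L) stop("need at least 2 groups")
  if (length(unique(lengths(histograms))) != 1L) {
    stop("groups must share the same length bins")
  }
  d <- data.frame(
    count = unlist(histograms, use.names = FALSE),
    group = factor(rep(names(histograms), lengths(histograms)))
  )
  fit <- stats::aov(count ~ group, data = d)
  s <- summary(fit)[[1]]
  list(F = s$`F value`[1], p_value = s$`Pr(>F)`[1], df = s$Df)
}

#' Export hit subsequences as FASTA
#'
#' One record per hit, sequence taken from the query; the header encodes
#' query/subject ids, coordinates and subject strand
#' (`query|q_start-q_end|subject|s_start-s_end|strand`), ready for
#' external motif discovery.
#'
#' @param hits hit table.
#' @param sequences the named sequences the hits refer to.
#' @param path output FASTA path.
#' @return invisibly, `path`.
#' @export
export_hits_fasta <- function(hits, sequences, path) {
  if (nrow(hits) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  if (!all(hits$query_id %in% names(sequences))) {
    stop("hit query ids missing from sequences")
  }
  qlen <- nchar(sequences[hits$query_id])
  if (any(hits$q_start < 0 | hits$q_end > qlen)) {
    stop("hit coordinates out of range of the query sequence")
  }
  recs <- substring(sequences[hits$query_id], hits$q_start + 1, hits$q_end)
  ss <- Biostrings::DNAStringSet(recs)
  names(ss) <- sprintf(
    "%s|%d-%d|%s|%d-%d|%s",
    hits$query_id, hits$q_start, hits$q_end,
    hits$subject_id, hits$s_start, hits$s_end, hits$subject_strand
  )
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Write a blastn-style tabular hit table
#'
#' Columns mirror `-outfmt "6 qacc sacc sseq pident qlen length evalue"`.
#' @param hits hit table.
#' @param sequences named sequences (for `sseq` and `qlen`).
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_hit_table <- function(hits, sequences, path) {
  d <- data.frame(
    qacc = hits$query_id,
    sacc = hits$subject_id,
    sseq = substring(sequences[hits$query_id], hits$q_start + 1, hits$q_end),
    pident = sprintf("%.3f", hits$pident),
    qlen = nchar(sequences[hits$query_id]),
    length = hits$length,
    evalue = sprintf("%.3g", hits$evalue)
  )
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
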