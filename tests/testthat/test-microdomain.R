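ka <- karlin_altschul_params(k_const = 0.48) # +2/-3 defaults, fixed K

test_that("lambda solves the Karlin-Altschul equation", {
  # uniform composition, +1/-1: (1/4)e^l + (3/4)e^-l = 1 has root ln 3
  p <- karlin_altschul_params(match = 1, mismatch = -1, k_const = 0.33)
  expect_equal(p$lambda, log(3), tolerance = 1e-10)

  # +2/-3 against an independent bisection oracle
  f <- function(l) 0.25 * exp(2 * l) + 0.75 * exp(-3 * l) - 1
  lo <- 1e-9; hi <- 5
  for (i in 1:80) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) hi <- mid else lo <- mid
  }
  expect_equal(ka$lambda, (lo + hi) / 2, tolerance = 1e-6)

  # skewed composition still satisfies the defining equation
  p2 <- karlin_altschul_params(c(0.3, 0.2, 0.2, 0.3), 2, -3, k_const = 0.4)
  pm <- sum(c(0.3, 0.2, 0.2, 0.3)^2)
  expect_equal(pm * exp(2 * p2$lambda) + (1 - pm) * exp(-3 * p2$lambda), 1,
               tolerance = 1e-9)

  expect_error(karlin_altschul_params(match = 0, mismatch = -1), "match")
  expect_error(karlin_altschul_params(match = 3, mismatch = -1),
               "expected pairwise score")
})

test_that("Monte-Carlo K calibration is seeded and in a plausible range", {
  k1 <- calibrate_k(ka, len = 300, nsim = 12, seed = 5)
  k2 <- calibrate_k(ka, len = 300, nsim = 12, seed = 5)
  expect_identical(k1, k2)
  expect_gt(k1, 0.05)
  expect_lt(k1, 2)
})

test_that("matched controls have exact lengths and the requested AT fraction", {
  lens <- c(120, 333, 1000)
  ctl <- generate_matched_controls(lens, 0.58, seed = 3)
  expect_equal(unname(nchar(ctl)), lens)
  expect_identical(ctl, generate_matched_controls(lens, 0.58, seed = 3))

  at_only <- generate_matched_controls(50, 1, seed = 1)
  expect_false(grepl("[GC]", at_only))

  big <- generate_matched_controls(1e6, 0.58, seed = 7)
  at <- mean(strsplit(big, "")[[1]] %in% c("A", "T"))
  expect_lt(abs(at - 0.58), 0.005)
  expect_error(generate_matched_controls(100, 1.2), "at_fraction")
})

test_that("identical sequences give one full-length perfect hit", {
  s <- random_seq(60, 11)
  h <- local_align_all_pairs(c(x = s, y = s), ka, strands = "+")
  expect_equal(nrow(h), 1)
  expect_equal(h$length, 60)
  expect_equal(h$pident, 100)
  expect_equal(h$q_start, 0)
  expect_equal(h$s_end, 60)
})

test_that("planted blocks are recovered on both strands", {
  bg1 <- random_seq(300, 21)
  bg2 <- random_seq(300, 22)
  blk <- random_seq(25, 23)
  a <- paste0(substr(bg1, 1, 100), blk, substr(bg1, 126, 300))
  b <- paste0(substr(bg2, 1, 200), blk, substr(bg2, 226, 300))
  h <- local_align_all_pairs(c(a = a, b = b), ka)
  fwd <- h[h$subject_strand == "+", ]
  expect_gte(nrow(fwd), 1)
  # the reported hit contains the planted coordinates
  expect_true(any(fwd$q_start <= 100 & fwd$q_end >= 125 &
                  fwd$s_start <= 200 & fwd$s_end >= 225))

  b_rc <- paste0(substr(bg2, 1, 200),
                 as.character(Biostrings::reverseComplement(
                   Biostrings::DNAString(blk))),
                 substr(bg2, 226, 300))
  h2 <- local_align_all_pairs(c(a = a, b = b_rc), ka)
  rev <- h2[h2$subject_strand == "-", ]
  expect_gte(nrow(rev), 1)
  expect_true(any(rev$q_start <= 100 & rev$q_end >= 125 &
                  rev$s_start <= 200 & rev$s_end >= 225))
})

test_that("pairs sharing no word-size seed yield no hits, N never seeds", {
  a <- strrep("AC", 50)
  b <- strrep("GT", 50) # shares no 11-mer with a on the forward strand
  h <- local_align_all_pairs(c(a = a, b = b), ka, strands = "+")
  expect_equal(nrow(h), 0)
  # identical sequences fully masked in one copy: no seeds, no hits
  s <- random_seq(80, 31)
  masked <- paste0(substr(s, 1, 10), strrep("N", 60), substr(s, 71, 80))
  h2 <- local_align_all_pairs(c(x = s, y = masked), ka, strands = "+")
  expect_true(all(h2$q_start >= 60 | h2$q_end <= 20))
  # empty sequences are skipped with a warning
  expect_warning(local_align_all_pairs(c(x = s, y = s, z = ""), ka),
                 "empty")
})

test_that("E-values decrease with score and rank hits consistently", {
  bg1 <- random_seq(400, 41)
  bg2 <- random_seq(400, 42)
  blk1 <- random_seq(30, 43)
  blk2 <- random_seq(15, 44)
  a <- paste0(substr(bg1, 1, 50), blk1, substr(bg1, 81, 300), blk2,
              substr(bg1, 316, 400))
  b <- paste0(substr(bg2, 1, 150), blk1, substr(bg2, 181, 350), blk2,
              substr(bg2, 366, 400))
  h <- local_align_all_pairs(c(a = a, b = b), ka, strands = "+")
  expect_gte(nrow(h), 2)
  o_score <- order(-h$score)
  o_e <- order(h$evalue)
  expect_equal(h$score[o_e], h$score[o_score])
  # closed-form E from the reported score
  expect_equal(h$evalue,
               ka$k_const * nchar(a) * nchar(b) * exp(-ka$lambda * h$score))
})

test_that("every maximal shared substring is contained in a reported hit", {
  # oracle equivalence on small inputs: exhaustive diagonal scan vs the
  # seeded aligner, both strands
  set.seed(99)
  seqs <- vapply(1:8, function(i) random_seq(300, 500 + i), "")
  motif <- random_seq(18, 77)
  # plant the motif into three sequences, one of them reverse complement
  seqs[2] <- paste0(substr(seqs[2], 1, 40), motif, substr(seqs[2], 59, 300))
  seqs[5] <- paste0(substr(seqs[5], 1, 211), motif, substr(seqs[5], 230, 300))
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(motif)))
  seqs[7] <- paste0(substr(seqs[7], 1, 100), rc, substr(seqs[7], 119, 300))
  names(seqs) <- paste0("s", 1:8)

  hits <- local_align_all_pairs(seqs, ka, word_size = 11, evalue_max = 10)
  found_planted <- 0
  for (i in 1:7) {
    for (j in (i + 1):8) {
      for (strand in c("+", "-")) {
        subj <- if (strand == "+") seqs[j] else {
          as.character(Biostrings::reverseComplement(
            Biostrings::DNAString(seqs[j])))
        }
        runs <- maximal_shared_runs(seqs[i], subj, 11)
        h <- hits[hits$query_id == names(seqs)[i] &
                  hits$subject_id == names(seqs)[j] &
                  hits$subject_strand == strand, ]
        if (strand == "-" && nrow(h) > 0) {
          # hits report forward-subject coordinates; move to the
          # reverse-complement frame the oracle works in
          sn <- nchar(seqs[j])
          s_start_rev <- sn - h$s_end
          h$s_start <- s_start_rev
        }
        if (nrow(runs) > 0) found_planted <- found_planted + nrow(runs)
        for (k in seq_len(nrow(runs))) {
          contained <- nrow(h) > 0 &&
            any(h$q_start <= runs$q_start[k] & h$q_end >= runs$q_end[k] &
                (h$q_start - h$s_start) == runs$diag[k])
          expect_true(contained, info = sprintf(
            "run %d-%d (%s vs %s, %s) not covered",
            runs$q_start[k], runs$q_end[k], names(seqs)[i], names(seqs)[j],
            strand
          ))
        }
      }
    }
  }
  expect_gte(found_planted, 3) # the planted motifs exercised the check
})

test_that("hit-length statistics respect the closed 12-50 window", {
  h <- data.frame(length = c(12, 50, 51, 11, 20, 20))
  st <- hit_length_stats(h)
  expect_equal(st$total, 4)
  expect_equal(unname(st$histogram["20"]), 2)
  expect_equal(sum(st$histogram), st$total)
  empty <- hit_length_stats(data.frame(length = numeric(0)))
  expect_equal(sum(empty$histogram), 0)
})

test_that("hit-count ANOVA matches the textbook decomposition", {
  # identical groups: F = 0, p = 1
  same <- list(a = c(1, 2, 3), b = c(1, 2, 3), c = c(1, 2, 3))
  res <- compare_hit_counts(same)
  expect_equal(res$F, 0)
  expect_equal(res$p_value, 1)

  # fixed 3x3 table vs hand-computed sums of squares
  tab <- list(g1 = c(1, 2, 3), g2 = c(2, 3, 4), g3 = c(6, 7, 8))
  means <- sapply(tab, mean)
  grand <- mean(unlist(tab))
  ssb <- 3 * sum((means - grand)^2)
  ssw <- sum(sapply(tab, function(x) sum((x - mean(x))^2)))
  f_hand <- (ssb / 2) / (ssw / 6)
  p_hand <- pf(f_hand, 2, 6, lower.tail = FALSE)
  res2 <- compare_hit_counts(tab)
  expect_equal(res2$F, f_hand, tolerance = 1e-12)
  expect_equal(res2$p_value, p_hand, tolerance = 1e-12)

  # permuting bin order leaves F unchanged
  perm <- lapply(tab, function(x) x[c(3, 1, 2)])
  expect_equal(compare_hit_counts(perm)$F, f_hand, tolerance = 1e-12)
  expect_error(compare_hit_counts(tab[1]), "2 groups")
})

test_that("exported hit FASTA slices the query and re-aligns in place", {
  bg1 <- random_seq(200, 61)
  bg2 <- random_seq(200, 62)
  blk <- random_seq(20, 63)
  a <- paste0(substr(bg1, 1, 60), blk, substr(bg1, 81, 200))
  b <- paste0(substr(bg2, 1, 120), blk, substr(bg2, 141, 200))
  seqs <- c(a = a, b = b)
  hits <- local_align_all_pairs(seqs, ka, strands = "+")
  path <- tempfile(fileext = ".fa")
  export_hits_fasta(hits, seqs, path)
  rec <- read_genome_fasta(path)
  expect_equal(length(rec), nrow(hits))
  expect_equal(unname(nchar(rec)), hits$length)
  # the exported subsequence equals the query slice and re-aligning it
  # against its source finds it at the encoded coordinates
  expect_equal(unname(rec[1]),
               substring(a, hits$q_start[1] + 1, hits$q_end[1]))
  re <- local_align_all_pairs(c(hit = unname(rec[1]), src = a), ka,
                              strands = "+")
  expect_true(any(re$s_start <= hits$q_start[1] & re$s_end >= hits$q_end[1]))
  # zero hits -> empty file
  none <- hits[0, ]
  export_hits_fasta(none, seqs, path)
  expect_length(readLines(path), 0)
})
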