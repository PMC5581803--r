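chain_fixture <- function(lines) {
  path <- tempfile(fileext = ".chain")
  writeLines(lines, path)
  path
}

test_that("chain parsing verifies header spans against block sums", {
  # single-block identity chain
  p <- chain_fixture(c("chain 100 chrS 1000 + 0 500 chrT 1000 + 0 500 1",
                       "500", ""))
  ch <- read_chain(p)
  expect_length(ch, 1)
  expect_equal(nrow(ch[[1]]$canon), 1)
  expect_equal(ch[[1]]$canon$s_end, 500)

  # two-block chain with dt = 10, dq = 0 checks out by summation
  p2 <- chain_fixture(c("chain 100 chrS 1000 + 0 210 chrT 1000 + 0 200 1",
                        "100\t10\t0", "100", ""))
  ch2 <- read_chain(p2)
  expect_equal(ch2[[1]]$canon$s_start, c(0, 110))
  expect_equal(ch2[[1]]$canon$t_start, c(0, 100))

  # header claiming a span different from the block sums -> error
  p3 <- chain_fixture(c("chain 100 chrS 1000 + 0 300 chrT 1000 + 0 200 1",
                        "100\t10\t0", "100", ""))
  expect_error(read_chain(p3), "does not match block sums")
  expect_error(read_chain(chain_fixture("chain 1 2 3")), "malformed header")
})

test_that("liftover maps block by block and applies min_match", {
  p <- chain_fixture(c("chain 100 chrS 1000 + 0 210 chrT 1000 + 0 200 1",
                       "100\t10\t0", "100", ""))
  chains <- read_chain(p)
  # identity region maps unchanged
  r <- liftover_interval(list(chrom = "chrS", start = 10, end = 60), chains)
  expect_equal(unname(r$span), c(10, 60))
  expect_equal(r$mapped_fraction, 1.0)

  # [50,150) spans the 10-base gap: 90/100 bases map
  expect_null(liftover_interval(list(chrom = "chrS", start = 50, end = 150),
                                chains, min_match = 0.95))
  r2 <- liftover_interval(list(chrom = "chrS", start = 50, end = 150),
                          chains, min_match = 0.8)
  expect_equal(r2$mapped_fraction, 0.9)
  expect_equal(unname(r2$span), c(50, 140))
  expect_equal(r2$pieces$start, c(50, 100))
  expect_equal(r2$pieces$end, c(100, 140))

  # interval entirely inside the source gap is unmapped
  expect_null(liftover_interval(list(chrom = "chrS", start = 102, end = 108),
                                chains, min_match = 0.1))
  # wrong chromosome is unmapped
  expect_null(liftover_interval(list(chrom = "chrX", start = 0, end = 10),
                                chains))
})

test_that("minus-strand chains flip target coordinates (UCSC convention)", {
  # one 100-base block: source [0,100) aligned to the reverse strand of a
  # 1000-base target starting at strand coordinate 0, i.e. forward
  # [900, 1000), reversed
  p <- chain_fixture(c("chain 50 chrS 500 + 0 100 chrT 1000 - 0 100 7",
                       "100", ""))
  chains <- read_chain(p)
  r <- liftover_interval(list(chrom = "chrS", start = 0, end = 10), chains)
  expect_equal(unname(r$span), c(990, 1000))
  expect_equal(r$strand, "-")
  r2 <- liftover_interval(list(chrom = "chrS", start = 90, end = 100), chains)
  expect_equal(unname(r2$span), c(900, 910))
})

test_that("chain/inverse-chain round trip is the identity on mapped intervals", {
  p <- chain_fixture(c("chain 100 chrS 1000 + 0 430 chrT 900 + 20 480 1",
                       "100\t10\t0", "200\t20\t60", "100", ""))
  chains <- read_chain(p)
  inv <- lapply(chains, invert_chain)
  for (iv in list(c(0, 100), c(110, 310), c(330, 430), c(120, 200))) {
    fw <- liftover_interval(list(chrom = "chrS", start = iv[1], end = iv[2]),
                            chains, min_match = 1.0)
    bk <- liftover_interval(list(chrom = "chrT", start = fw$span[["start"]],
                                 end = fw$span[["end"]]), inv, min_match = 1.0)
    expect_equal(unname(bk$span), iv)
  }
  # also through a minus-strand chain
  pm <- chain_fixture(c("chain 50 chrS 500 + 10 110 chrT 1000 - 0 100 7",
                        "100", ""))
  cm <- read_chain(pm)
  fw <- liftover_interval(list(chrom = "chrS", start = 30, end = 70), cm)
  bk <- liftover_interval(list(chrom = "chrT", start = fw$span[["start"]],
                               end = fw$span[["end"]]),
                          lapply(cm, invert_chain))
  expect_equal(unname(bk$span), c(30, 70))
})

test_that("chain write/read round-trips and agrees with rtracklayer liftOver", {
  genome <- c(chr1 = random_seq(5000, 71))
  edits <- data.frame(
    chrom = "chr1", start = c(1000, 2500, 3600), end = c(1200, 2500, 4000),
    type = c("deletion", "insertion", "inversion"),
    seq = c("", strrep("ACGT", 75), ""), stringsAsFactors = FALSE
  )
  pair <- make_chain_pair(genome, edits)
  path <- tempfile(fileext = ".chain")
  write_chain_file(pair$chains, path)
  back <- read_chain(path)
  expect_length(back, length(pair$chains))
  for (i in seq_along(back)) {
    expect_equal(back[[i]]$canon, pair$chains[[i]]$canon)
    expect_equal(back[[i]]$orient, pair$chains[[i]]$orient)
  }
  # independent oracle: rtracklayer's liftOver on the same chain file
  # (exclude nothing: its default drops "_"-containing scaffold names)
  rt_chain <- rtracklayer::import.chain(path, exclude = "z^")
  gr <- GenomicRanges::GRanges("chr1",
                               IRanges::IRanges(start = c(1, 301, 4501),
                                                width = 200))
  lifted <- rtracklayer::liftOver(gr, rt_chain)
  for (i in seq_along(gr)) {
    ours <- liftover_interval(
      list(chrom = "chr1", start = GenomicRanges::start(gr)[i] - 1,
           end = GenomicRanges::end(gr)[i]),
      pair$chains, min_match = 0.9
    )
    theirs <- range(lifted[[i]])
    expect_equal(unname(ours$span[["start"]]),
                 GenomicRanges::start(theirs) - 1)
    expect_equal(unname(ours$span[["end"]]), GenomicRanges::end(theirs))
  }
})

test_that("make_chain_pair applies edits exactly", {
  genome <- c(c1 = random_seq(2000, 81))
  # zero edits: identity chain, identity liftover
  id <- make_chain_pair(genome, data.frame(
    chrom = character(0), start = numeric(0), end = numeric(0),
    type = character(0), seq = character(0)
  ))
  expect_equal(unname(id$genome_b), unname(genome))
  r <- liftover_interval(list(chrom = "c1", start = 100, end = 300),
                         id$chains)
  expect_equal(unname(r$span), c(100, 300))

  # a 10-bp deletion before a gene shifts lifted coordinates by -10
  del <- make_chain_pair(genome, data.frame(
    chrom = "c1", start = 500, end = 510, type = "deletion", seq = "",
    stringsAsFactors = FALSE
  ))
  r2 <- liftover_interval(list(chrom = "c1", start = 800, end = 900),
                          del$chains)
  expect_equal(unname(r2$span), c(790, 890))
  expect_equal(del$map("c1", 800), 790)
  # inverted segments come back reverse-complemented in genome B
  inv <- make_chain_pair(genome, data.frame(
    chrom = "c1", start = 100, end = 200, type = "inversion", seq = "",
    stringsAsFactors = FALSE
  ))
  expect_equal(
    substring(inv$genome_b[["c1_B"]], 101, 200),
    as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(substring(genome[["c1"]], 101, 200))))
  )
  expect_error(
    make_chain_pair(genome, data.frame(
      chrom = "c1", start = c(100, 150), end = c(200, 250),
      type = "deletion", seq = "", stringsAsFactors = FALSE
    )),
    "overlapping"
  )
})

test_that("conservation percentage merges hit coverage over the query", {
  ka2 <- karlin_altschul_params(k_const = 0.48)
  s <- random_seq(500, 91)
  expect_equal(pairwise_conservation_pct(s, s, ka2), 100)
  t <- random_seq(500, 92)
  expect_equal(pairwise_conservation_pct(s, t, ka2), 0)
  # one 50-nt shared block on a 500-nt gene -> exactly 10%: the flanks are
  # homopolymers of different bases, so extension cannot pick up matches
  blk <- random_seq(50, 93)
  a2 <- paste0(strrep("C", 100), blk, strrep("C", 350))
  b2 <- paste0(strrep("A", 300), blk, strrep("A", 150))
  expect_equal(pairwise_conservation_pct(a2, b2, ka2), 10)
  expect_error(pairwise_conservation_pct("", s, ka2), "empty")
})

test_that("mean conservation score averages covered exonic bases only", {
  g <- gm("g", "chr1", "+", c(0, 10), c(20, 30), biotype = "lncRNA_candidate")
  flat <- data.frame(chrom = "chr1", start = 0, end = 100, score = 0.5)
  expect_equal(mean_conservation_score(g, flat), 0.5)
  split <- data.frame(chrom = "chr1", start = c(0, 20), end = c(10, 30),
                      score = c(1, 0))
  expect_equal(mean_conservation_score(g, split), 0.5)
  # track covering only the intron -> undefined
  intron <- data.frame(chrom = "chr1", start = 12, end = 18, score = 1)
  expect_error(mean_conservation_score(g, intron), "no covered exonic base")
  # partial coverage: only covered bases enter numerator and denominator
  part <- data.frame(chrom = "chr1", start = 0, end = 5, score = 0.8)
  expect_equal(mean_conservation_score(g, part), 0.8)
})
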