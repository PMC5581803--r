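## Shared fixtures. The default synthetic bundle and its pipeline run are
## memoized so several test files can reuse one simulation.

.lnccat_cache <- new.env(parent = emptyenv())

sim_bundle <- function(seed = 11) {
  key <- paste0("sim_", seed)
  if (is.null(.lnccat_cache[[key]])) {
    .lnccat_cache[[key]] <- simulate_dataset(
      synthetic_config(seed = seed),
      out_dir = file.path(tempdir(), paste0("lnccat_sim_", seed))
    )
  }
  .lnccat_cache[[key]]
}

pipeline_result <- function(seed = 11) {
  key <- paste0("pipe_", seed)
  if (is.null(.lnccat_cache[[key]])) {
    .lnccat_cache[[key]] <- run_pipeline(sim_bundle(seed)$files, seed = seed)
  }
  .lnccat_cache[[key]]
}

## Minimal GTF writer for hand-built fixtures (1-based inclusive rows).
write_test_gtf <- function(rows, path = tempfile(fileext = ".gtf")) {
  lines <- vapply(rows, function(r) {
    sprintf('%s\ttest\texon\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s";',
            r$chrom, r$start, r$end, r$strand, r$gene, r$tx)
  }, "")
  writeLines(lines, path)
  path
}

## Quick gene-model constructor for geometry fixtures.
gm <- function(id, chrom, strand, ..., biotype = "coding") {
  ex <- do.call(rbind, lapply(list(...), function(e) {
    data.frame(start = e[1], end = e[2])
  }))
  gene_model(id, chrom, strand, ex, biotype)
}

random_seq <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
}

## Independent brute-force enumeration of all maximal exact shared
## substrings of length >= w between two sequences (forward frames):
## full diagonal scan + run-length encoding, no seeding involved.
maximal_shared_runs <- function(a, b, w) {
  na <- nchar(a); nb <- nchar(b)
  ac <- strsplit(a, "")[[1]]
  bc <- strsplit(b, "")[[1]]
  out <- list()
  for (d in (-(nb - 1)):(na - 1)) {
    i0 <- max(1, 1 + d)
    i1 <- min(na, nb + d)
    if (i1 - i0 + 1 < w) next
    m <- ac[i0:i1] == bc[(i0:i1) - d]
    r <- rle(m)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (k in which(r$values & r$lengths >= w)) {
      out[[length(out) + 1L]] <- data.frame(
        q_start = i0 + starts[k] - 2, # 0-based half-open
        q_end = i0 + ends[k] - 1,
        diag = d
      )
    }
  }
  if (length(out) == 0L) {
    return(data.frame(q_start = numeric(0), q_end = numeric(0), diag = numeric(0)))
  }
  do.call(rbind, out)
}
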