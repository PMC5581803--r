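---
title: "lnccat: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{lnccat: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lnccat)
```

# The problem

Long non-coding RNAs (lncRNAs) assembled from RNA-seq are usually
characterised by a chain of one-off manual steps: merging transcript
exons into composite gene models, removing sub-200-nt and
protein-coding candidates, classifying loci by position relative to
protein-coding genes, summarising expression and differential
expression across cell types, quantifying repeat content, searching the
catalog against itself for short conserved "microdomains", lifting
coordinates onto a second genome to find syntenic loci, and
intersecting promoters with epigenomic peaks and coverage. `lnccat`
packages that chain as tested, composable functions, with a seeded
synthetic generator that emulates every input so the whole analysis can
be exercised end to end without any external data.

Coordinates are 0-based half-open everywhere inside the package (the
BED convention); GTF and RepeatMasker input is converted at the parse
boundary. This removes the most common source of off-by-one drift in
multi-format interval work.

# Catalog construction and positional classification

Composite gene models pool all exons of all transcripts sharing a
`gene_id` and merge overlapping *or book-ended* exons into maximal
disjoint blocks. Book-ended blocks (`[0,100)` + `[100,200)`) describe
one contiguous genomic run, so we merge them; this matters because the
single/multi-exon split is taken on the merged model. Genes with merged
exonic length below 200 nt are removed; a gene of exactly 200 nt is
kept, resolving the usual ">200 nt definition vs <200 nt removal"
ambiguity in favour of retention.

Classification against protein-coding annotation uses a fixed decision
order with a `window` of 5,000 bp by default:

1. a same-strand coding gene overlapping or within the window makes the
   locus `EXCLUDED_SAME_STRAND` (it may be an unannotated extension of
   the coding gene, so exclusion precedes everything else);
2. an opposite-strand coding gene overlapping the lncRNA span makes it
   `AS` (antisense);
3. otherwise the nearest opposite-strand coding gene within the window
   yields `AS_UPSTREAM` or `AS_DOWNSTREAM`;
4. otherwise the locus is a `LINCRNA`.

Two genuinely open choices are made explicit and configurable:

* "within 5 kb" is measured as the gap between gene *spans* (0 when
  spans overlap), with half-open arithmetic
  (`gap = downstream.start − upstream.end`); a gap of exactly 5,000
  counts as within.
* "upstream"/"downstream" are taken relative to the **protein-coding
  gene's** orientation (upstream = beyond its TSS). The opposite
  reading — relative to the lncRNA — is available via
  `upstream_relative_to = "lnc"` in `classify_relative_position()`.

Novelty flags use ≥ 1 bp of same-strand exonic overlap with a reference
lncRNA annotation; coding-potential labels are taken from an external
table (the package deliberately does not re-implement coding-potential
scoring), with absent genes retained and reported.

# Expression summaries

A gene counts as expressed in a cell type if its mean FPKM across that
cell type's replicates exceeds 1.0 *strictly* in either the control or
the stimulated condition; the threshold applies to per-condition means
because replicate handling is otherwise undefined. Differential
expression is intake-only (tables with per-cell-type log2 fold change
and q-value); `de_filter()` applies a strict `q < 0.05`. Cell-type
specificity is summarised as multiplicity counts (genes present in
exactly k of the per-cell-type sets) with percentages of the union.
Display rounding is half-up to integer percent — note `round()` in R
rounds half to even, which changes several of these worked-example
values — and unrounded values are always returned alongside.

Mean expression of a gene set is reported as mean ± SEM (sample
SD/√n) of each gene's *peak condition mean* FPKM. The cis-regulation
analysis pairs each differentially expressed lncRNA with its nearest
protein-coding gene (span gap, ties by smaller start then gene id,
none beyond 1 Mb) and correlates the paired log2 fold changes with
Pearson's r and the standard two-sided t test on n − 2 df.

# Repeat composition and masking

Repeat annotation (RepeatMasker `.out` or BED6 with class/family names)
is mapped to the closed class set SINE/LINE/LTR/DNA/other on the prefix
before `/`. Per-gene fractions are computed over *exonic* bases only —
the catalog sequences are merged exons, not genomic spans. Where
annotations overlap, each base is counted once under a fixed precedence
(SINE > LINE > LTR > DNA > other); the precedence is arbitrary but
must be fixed for the fractions to partition the gene. Catalog-level
profiles are base-weighted across the pooled catalog by default
(`method = "pooled"`); per-gene averaging is available because either
reading of a "percentage of the catalog" is defensible. Before
microdomain searching, repeat bases are hard-masked to `N`
(strand-aware projection into transcript coordinates); masked bases can
never seed an alignment. Soft masking is available as a flag.

# Microdomain discovery

The search for shared 12–50 nt segments is an all-vs-all, both-strand,
*ungapped* seed-and-extend local alignment:

* exact `word_size = 11` seeds (mirroring `blastn -task blastn`),
  scoring match +2 / mismatch −3;
* extension along the seed's diagonal in both directions under an
  X-drop rule (default 20 score units), retaining the locally maximal
  segment — endpoints therefore always land on matches, and seeds
  falling inside an already-reported segment on the same diagonal are
  skipped, so per-diagonal hits are non-overlapping;
* significance by Karlin–Altschul statistics,
  `E = K·m·n·exp(−λS)`, with hits kept at `E ≤ 10`.

λ is the unique positive root of `Σ pᵢpⱼ exp(λ·s(i,j)) = 1`, solved
numerically to `|f| < 1e−10` (for uniform composition with +1/−1
scoring the closed form is λ = ln 3, used as a test oracle). K is
estimated by a seeded Monte-Carlo calibration: random sequence pairs
from the background composition are aligned, locally maximal segments
scoring at least a pivot s₀ are counted, and the expected-count
identity `E[N(S ≥ s₀)] = K·m·n·exp(−λs₀)` is inverted. E-values are
therefore approximate; they are used for thresholding and ranking, both
of which only require monotonicity in the score, and a constant
override (`k_const`) is accepted. Gapped extension is deliberately
out of scope: the targets are short near-exact segments for which an
ungapped model is the appropriate null.

Null comparisons use length-matched i.i.d. random sequences with
`P(A) = P(T) = AT/2` ("matched controls"), plus a protein-coding
sequence set of comparable size. Hit counts are binned per length over
the closed 12–50 nt window and the groups compared by one-way ANOVA on
the per-length-bin counts. Treating bins as observations is one of two
defensible readings of "ANOVA across groups" (the other being
per-sequence counts); it is the package's documented choice. Whether
reciprocal hits should be deduplicated before counting is equally
unstated in typical BLAST-based workflows; the aligner reports each
unordered pair once, so no deduplication is needed.

# Liftover and synteny

UCSC chain files are parsed with full validation (block sums must match
the header spans; the source strand must be `+`). Liftover maps an
interval block by block; minus-strand target coordinates are flipped to
the forward strand per the UCSC convention. A result is reported only
when the mapped-base fraction reaches `min_match`, defaulting to 0.95
(the usual same-species liftOver setting) and meant to be lowered for
cross-species use. Inverting a chain swaps the two genomes, and lifting
a fully mapped interval through a chain and its inverse returns the
original coordinates exactly — a property the tests exercise, along
with agreement with `rtracklayer::liftOver` on identical chain files.

Synteny pairs every source gene whose span lifts at `min_match` with
every target gene overlapping the lifted span by ≥ 1 bp; overlap is
strand-agnostic because orientation is carried by the chain. Pairwise
sequence conservation re-uses the microdomain aligner: retained hit
intervals are merged on the query and the covered percentage is
denominated by the *query* gene length (the denominator is otherwise
undefined; this choice is documented, not inferred). Per-base
conservation scores (PhastCons-style 0–1 tracks) are averaged over
exonic positions, excluding positions absent from the track from both
numerator and denominator.

# Epigenomic overlap

Peak overlap is gene-span vs peak (≥ 1 bp, strand ignored): "percent
genomic overlap" is read as locus overlap, not promoter overlap. TSS
metaprofiles average coverage in `bin_width = 30` bins over
`TSS ± 3,000` bp, the TSS being the span start (`+`) or `span end − 1`
(`−`); minus-strand profiles are reversed so bins always run
upstream→downstream, and windows crossing chromosome ends are
zero-padded to keep the matrix rectangular. bedGraph is the coverage
interchange format; bigWig is out of scope.

# The synthetic test-bed

`simulate_dataset()` emulates every input the pipeline consumes, with
planted ground truth. Genes are laid out in independent *cassettes* on
a fixed grid: each slot holds one protein-coding gene, optionally with
a lncRNA planted in one defined positional geometry against it, or a
lone lncRNA; slots are separated by gene-free margins wider than the
classification window, so every planted class is recoverable by
construction. The default scale — two 1-Mb chromosomes per species, 60
coding genes, 10 lncRNAs per positional class, plus sub-200-nt,
single-exon and coding-potential decoys — runs the full pipeline in
well under a minute and was chosen as the smallest configuration in
which every stage has non-trivial input.

Other planted features, and the real-data features they do *not*
emulate:

* **Expression**: log-normal FPKM around per-gene baselines, planted
  log2 fold changes of magnitude ≥ 2 (a strong but common effect size
  for stimulus-responsive genes), 3 + 3 replicates, four cell types
  with a planted multiplicity pattern (roughly 78/16/4/2% across
  1–4 cell types). The generator derives its own DE table with a
  two-sample t test on log FPKM and Benjamini–Hochberg adjustment —
  a stand-in for count-based DE inference, not a re-implementation of
  it; there is no mean–variance trend, no library-size variation and
  no outlier structure.
* **Cis correlation**: lncRNA fold changes get a random sign and
  magnitude `2 + |N(0, 0.5)|`; the nearest-mRNA partner fold change is
  `ρ·x + √(1−ρ²)·sd(x)·z`, which has Pearson correlation ρ (default
  0.7) with the lncRNA values regardless of their distribution.
* **Sequence**: i.i.d. background at 58% AT; a single shared 20-nt
  motif overwritten into 12 carrier lncRNAs (reverse-complemented on
  minus-strand genes so the spliced transcript carries the motif
  forward). Real lncRNAs share motifs with degeneracy and varying
  copy number; the generator plants one exact copy per carrier.
* **Repeats**: one repeat per retained lncRNA covering ~30% of its
  first exon, cycling through SINE/LINE/LTR/DNA/Simple_repeat families;
  motifs go in the last exon so masking never destroys them.
* **Two genomes**: genome B is genome A with seeded insertions,
  deletions and one inversion per chromosome, placed in gene-free
  margins; the chain is computed exactly from the edit list, and eight
  lncRNAs get syntenic copies (plus decoy B-only genes placed in
  coding-only cassettes so they cannot create unplanned pairs).
* **Epigenome**: active genes (the DE lncRNAs and their partner coding
  genes) get a peak at TSS ± 400 bp and a triangular coverage bump
  (half-width 1 kb, 50-bp resolution); inactive genes get nothing. Real
  coverage has background noise and peak-shape variation.
* **Conservation track**: constant scores per gene category (coding
  exons 0.8, syntenic lncRNA exons 0.6, other lncRNA exons 0.15,
  painted in that order so lncRNA values are exact even under antisense
  overlap), which makes per-gene means exactly recoverable.

Passing tests on this test-bed therefore demonstrate *correctness of
the operations and their composition* — coordinate arithmetic,
classification geometry, statistical plumbing, liftover algebra — not
robustness to the noise structure of real sequencing data.

A single integer seed drives everything; each stage derives an
independent stream from it, so adding a stage never perturbs earlier
outputs, and the emitted bundle is byte-identical across runs with the
same seed.

# Numerical choices and degenerate inputs

* λ root-finding brackets `(1e−12, hi)` with `hi` doubled until the
  defining function is positive; tolerance 1e−14, verified to
  `|f| < 1e−10`. A non-negative expected pairwise score is rejected.
* Monte-Carlo K uses a pivot s₀ chosen so the expected segment count
  per simulated pair is O(1), and a seed word short enough
  (≥ 4) that segments at the pivot score are reliably seeded; the
  estimate is floored at 1e−4.
* Empty sequences are skipped with a warning by the aligner; sequences
  shorter than the word size simply produce no seeds. Zero-variance
  vectors are an error in the correlation; an empty gene set is an
  error in `expression_stats()` and `gene_peak_overlap_pct()`; a score
  track covering no exonic base is an error in
  `mean_conservation_score()`.
* Classification ties (two opposite-strand genes at the same gap) are
  resolved toward upstream; nearest-gene ties break by smaller start,
  then lexicographic id, so results are order-independent.
* Percentages are rounded half away from zero for display; unrounded
  values are always retained and all assertions about totals use the
  unrounded values.

# Problem sizes used by the test suite

The repeated-seed properties run at deliberately small scale: planted
correlation recovery uses 40 seeds × 100 pairs; microdomain power uses
40 seeds × 30 sequences of 400 nt (12 motif carriers); the
aligner-vs-enumeration oracle uses 12 sequences of 400 nt; matched
control composition is checked on one 1-Mb sequence. The end-to-end
pipeline runs once on the default bundle. These sizes keep the suite
fast while leaving each check statistically meaningful; they are the
package's choices, and all of them are driven by a fixed seed.

# Known limitations

* The aligner is pure R and intended for catalog-scale self-comparison
  (hundreds of kilobase-scale sequences), not genome-scale search.
* E-values inherit the Monte-Carlo K's sampling error; they are
  suitable for thresholding at E ≤ 10, not for fine-grained
  significance claims near the threshold.
* Chain parsing requires the source strand to be `+`, as UCSC tools
  emit; chains with reversed source coordinates are rejected rather
  than normalised.
* The DE stand-in in the generator is a t test on log FPKM; its
  q-values behave sensibly on log-normal data but are not a model of
  count noise.
* GTF intake covers the Ensembl/Gencode dialect (exon rows with
  `gene_id`/`transcript_id`); GFF3 is out of scope.
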