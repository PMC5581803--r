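# lnccat — building and characterising lncRNA catalogs

`lnccat` is an R package for researchers who assemble long non-coding
RNA (lncRNA) catalogs from RNA-seq and want the downstream
characterisation — usually a chain of one-off scripts and web tools —
as tested, composable functions:

* **Catalog construction**: merge transcript exons into composite gene
  models (overlapping and book-ended exons unioned into maximal
  disjoint blocks), drop sub-200-nt genes, split single- vs multi-exon
  genes, flag known vs novel against a reference annotation, apply a
  coding-potential intake filter, and extract spliced 5'→3' sequences.
* **Positional classification**: label each lncRNA `AS` (overlapping a
  protein-coding gene on the opposite strand), `AS_UPSTREAM` /
  `AS_DOWNSTREAM` (opposite strand within 5 kb, relative to the coding
  gene's TSS), `LINCRNA` (> 5 kb from any coding gene), or excluded as
  a potential same-strand gene extension.
* **Expression summaries**: expression thresholding (> 1 FPKM on
  condition means), q < 0.05 differential-expression intake,
  cell-type-specificity multiplicities, mean ± SEM expression, and the
  Pearson correlation between each DE lncRNA's log2 fold change and
  that of its nearest mRNA.
* **Repeat composition**: per-gene and per-catalog SINE/LINE/LTR/DNA
  coverage fractions of exonic sequence, and hard-masking ahead of the
  microdomain search.
* **Microdomain discovery**: all-vs-all ungapped seed-and-extend local
  alignment (word size 11, +2/−3, X-drop) with Karlin–Altschul
  E-values, E = K·m·n·exp(−λS), against length- and AT-matched random
  controls and protein-coding sequences; 12–50 nt hit histograms and a
  one-way ANOVA across the groups; FASTA export of hits for external
  motif discovery.
* **Synteny**: UCSC chain parsing with validation, block-by-block
  interval liftover with a mapped-fraction threshold, catalog-vs-catalog
  synteny pairs, pairwise sequence-conservation percentages, and
  PhastCons-style score aggregation over exons.
* **Epigenomic overlap**: percent of gene spans overlapping peak calls,
  and TSS ± 3 kb coverage metaprofiles in 30-bp bins.
* **A synthetic test-bed**: `simulate_dataset()` emits every input the
  pipeline consumes (two genomes, GTFs, FPKM matrix + metadata, DE
  tables, repeat/peak BEDs, coverage and conservation bedGraphs, a
  chain file) with planted ground truth, byte-identically reproducible
  from one seed.

See `vignettes/lnccat-methods.Rmd` for the models, parameters and
design decisions.

## Worked example

```r
library(lnccat)

sim <- simulate_dataset(synthetic_config(seed = 42), out_dir = "demo")
res <- run_pipeline(sim$files, seed = 42)

length(res$models$catalog)      # classified lncRNA catalog size
res$class_distribution          # positional classes of the DE lncRNAs
length(res$de$union)            # lncRNAs DE at q < 0.05
res$correlation                 # cis fold-change correlation
res$hit_stats$lncRNA$total      # 12-50 nt microdomain hits
nrow(res$synteny)               # syntenic pairs recovered
```

Output on this seed:

```
catalog size: 40
  positional_class count      pct pct_rounded
1          LINCRNA     8 22.22222          22
2               AS    10 27.77778          28
3    AS_DOWNSTREAM     8 22.22222          22
4      AS_UPSTREAM    10 27.77778          28
DE lncRNAs (q < 0.05): 36
lncRNA vs nearest-mRNA fold-change correlation: r = 0.483 (n = 36, p = 0.0028)
repeat content of the catalog: 14.5%
12-50 nt hits: lncRNA 126, matched controls 89, coding 358
syntenic pairs recovered: 8
peak overlap: 100% of catalog genes
```

Reading it: the generator planted 10 lncRNAs per positional class (50
in all); 40 survive the length/coding/exclusion filters and every one
is classified into its planted class. 36 of the 40 planted DE genes
pass the generator's own q < 0.05 table on this seed; their fold
changes correlate with the nearest mRNA's (planted ρ = 0.7, attenuated
here by estimation noise at n = 36). The 12 motif-carrying lncRNAs lift
the 12–50 nt hit count above the matched controls, and all 8 planted
syntenic loci are recovered through the chain liftover.

A thin command-line front end with `simulate`, `build`, `classify` and
`run` subcommands is installed at `inst/scripts/lnccat`.

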