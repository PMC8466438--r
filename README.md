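# barcodemito

Tools for the analytic chain of insect DNA-barcoding surveys and
descriptive comparative mitogenomics — the kind of study that asks *which
species are present, are the barcode clusters congruent with taxonomy, and
what do their mitogenomes look like?*  It was built around the workflow
used for olive-feeding lace bugs (Hemiptera: Tingidae) but the statistics
are generic for animal mitochondrial data.

## What it computes

**Barcode side** (aligned COI sequences with species labels):

* dataset filtering: species-level identification, minimum ungapped length
  (default 500 bp), minimum sequences per species (default 3), with a
  per-rule removal report;
* haplotype collapsing (complete deletion of gap/N columns), haplotype
  diversity `H = n(1 − Σp²)/(n − 1)` with Nei's sampling variance,
  nucleotide diversity π with a seeded bootstrap SD, segregating sites S;
* p-distances and Kimura 2-parameter distances
  `d = −½·ln[(1 − 2P − Q)·√(1 − 2Q)]` (pairwise deletion; saturation
  flagged), intra-/interspecific divergence summaries and a conspecificity
  screen (default 3% threshold, 2–3% warning band);
* median-joining haplotype networks (minimum-spanning network plus
  quasi-median Steiner nodes, ε = 0 by default) with GML/DOT export;
* neighbor-joining trees (Saitou–Nei, deterministic tie-breaking),
  column-resampling bootstrap, per-species monophyly verdicts against a
  declared outgroup.

**Mitogenome side** (GenBank flatfiles of annotated circular genomes):

* nucleotide composition with AT skew `(A−T)/(A+T)` and GC skew
  `(G−C)/(G+C)` per feature and aggregate;
* start/stop codon classification under the invertebrate mitochondrial
  code (canonical ATN vs alternative starts; complete TAA/TAG vs
  incomplete TA/T stops);
* relative synonymous codon usage (RSCU);
* gene overlaps and intergenic spacers on the circle, including the
  closure pair across the origin;
* Nei–Gojobori (1986) Ka/Ks with Jukes–Cantor correction, averaged across
  genome pairs per gene;
* tandem repeats in the AT-rich control region by exhaustive motif scan.

A seeded synthetic-data module (`simulate_barcodes()`,
`simulate_mitogenome()`, `derive_mitogenome()`) generates barcode sets
with a planted divergence gap and annotated mitogenomes with the canonical
37-gene arthropod arrangement and fully recorded ground truth, so every
stage is verifiable offline.

## Worked example

```r
library(barcodemito)

# a 3-species barcode set with a planted barcode gap + outgroup
cfg <- barcode_sim_config(n_species = 3, n_per_species = c(8, 6, 5),
                          intra_lambda = c(2, 2, 0), seed = 21,
                          outgroup_div = 120)
sim <- simulate_barcodes(cfg)

res <- run_barcode_report(sim$records, "report", reps = 100, seed = 4,
                          outgroup_species = "Outgroup", min_len = 400)
read.delim("report/diversity_summary.tsv", colClasses = "character")
#>      species n k S      H   H_sd       pi    pi_sd
#> 1 Species_01 8 6 9 0.8929 0.1113 0.004919 0.001282
#> 2 Species_02 6 5 9 0.9333 0.1217 0.005988 0.001902
#> 3 Species_03 5 1 0   n.a.   n.a.     n.a.     n.a.
res$monophyly
#>      species n_tips monophyletic support
#> 1 Species_01      8         TRUE     100
#> 2 Species_02      6         TRUE     100
#> 3 Species_03      5         TRUE     100
```

Per species: `n` sequences collapse to `k` haplotypes with `S` polymorphic
sites; `H`/`pi` are haplotype and nucleotide diversity (± SD).  Species 3
was simulated with zero intraspecific mutation, so it is monomorphic and
the table prints `n.a.`, the convention of standard diversity tables.  On
this planted-gap dataset every species comes back monophyletic with full
bootstrap support — the behaviour expected of a clean barcode dataset.

The directory also gains `pairwise_distances.tsv`, divergence tables, a
`network_<species>.gml` per species, `nj_tree.nwk` and a JSON manifest
recording thresholds and seeds.

For mitogenomes:

```r
sim <- simulate_mitogenome(mito_sim_config(seed = 11))
write_genbank(sim$annotation, "syn.gb")
ann <- read_genbank("syn.gb")
find_tandem_repeats(feature_sequence(ann, "AT-rich"))[, 2:8]
#>   motif_len copies spacer start span  coverage identity
#> 1       170      2      4   427  344 0.4410256        1
```

## Scope

Alignment (MAFFT and friends), NGS assembly/annotation, tRNA secondary
structure, and maximum-likelihood/Bayesian tree inference are upstream or
out of scope; inputs arrive aligned/annotated, and NJ + bootstrap is the
declared distance-based surrogate for clustering checks.  See the methods
vignette (`vignettes/barcodemito-methods.Rmd`) for estimator details and
design rationale.
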