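# alujump

Analysis toolkit for **massively parallel jumping assays (MPJA)** of Alu
retrotransposition: from aligned reads of an error-prone PCR mutant
library to haplotype counts, differential jumping activity, per-variant
and per-window effect estimates, SRP-region enrichment, and edit-distance
comparison against genomic AluS elements.

## Who this is for and what it computes

MPJA experiments measure, for thousands of Alu sequence variants at once,
whether a variant combination (a *haplotype*) jumps better or worse than
the wild-type element. The data are read counts per haplotype in plasmid
libraries (before selection) and jumping libraries (after
retrotransposition and recovery), in replicate. This package implements
the analysis chain a lab running such an assay needs:

1. **Haplotype calling** — reconstruct each read's variant set purely from
   SAM `POS`/`CIGAR`/`MD`/`NM` fields, left-anchor indels, group identical
   haplotypes and count abundance per sample
   (`call_variants()`, `aggregate_haplotypes()`).
2. **QC filters** — aligned length ≥ 200, ≤ 10 nucleotide changes, an
   index-hopping screen, plasmid support > 2 reads, jumping detection
   > 10 reads (`filter_haplotypes()`, `screen_index_hopping()`).
3. **Differential activity** — median-of-ratios size factors and a
   per-haplotype negative-binomial Wald test of jumping vs plasmid
   counts; log2 fold-changes normalized so the wild-type sits at 0;
   classification into high jumpers (log2FC > 2, p < 1e-5), low jumpers
   (log2FC < −2, p < 1e-5, jumping reads present) and non-jumpers
   (zero jumping reads, > 50 plasmid reads, log2FC < −2)
   (`nb_wald_test()`, `classify_jumpers()`).
4. **Variant effects** — the replicate-conditional multiple linear
   regression

   ```
   log2(Jumping_ij + 1) ~ {log2(Plasmid_rep1,j + 1) | i=1; 0 otherwise}
                        + {log2(Plasmid_rep2,j + 1) | i=2; 0 otherwise}
                        + N + intercept
   ```

   with binary variant-membership columns `N`, plus a 5-bp sliding-window
   profile (1-bp step) of regional effects
   (`build_design()`, `fit_variant_model()`, `window_profile()`).
5. **SRP enrichment and logos** — one-sided hypergeometric tests of
   jumper-class variants in the SRP9/14 binding stem-loop intervals with
   Benjamini–Hochberg correction, and position frequency matrices for
   logo rendering (`hypergeom_enrichment()`, `position_frequency_matrix()`).
6. **Genome comparison** — banded Levenshtein distances from jumping
   haplotypes to a genomic AluS set; which elements are fewest edits away
   from a high jumper (`min_distances()`, `nearest_activators()`).

A seeded synthetic-data generator (`sim_config()`, `simulate_mpja()`)
emulates error-prone PCR libraries (1–16 mutations/kb, transition-biased
SNVs plus 1-bp indels, founder-effect and amplification skew, a protected
5′ primer footprint), activity-dependent selection (`q_h ∝ p_h·2^{a_h}`),
negative-binomial counts, ~2.2% index hopping and sub-200-bp fragment
artifacts — so every stage is testable against known ground truth without
any external data.

## Worked example

The `analysis/` directory holds numbered drivers that run the whole study
on two synthetic Alu-like elements (sourcing `analysis/common.R`; outputs
under `results/analysis/`). Running them in order prints, among other
lines:

```
$ Rscript analysis/01_simulate.R
AluSyn1: 800 clones -> 704 distinct haplotypes; 2.92 mutations/clone; 162 with true |activity| > 2

$ Rscript analysis/02_call_haplotypes.R
AluSyn1: 81413 reads -> 1791 haplotype rows
AluSyn1: removed 421 hopped, 667 short, 0 over the edit cap, 11 low-plasmid; 692 retained

$ Rscript analysis/03_differential.R
AluSyn1: 692 haplotypes tested; 79 high, 8 low, 1 non-jumpers; plasmid Spearman 0.92, jumping 0.91

$ Rscript analysis/04_variant_effects.R
AluSyn1: 255 variant columns fitted (0 aliased dropped)
  strongest effects: 186:A>G (+5.11), 22:G>A (+4.83), 30:A>G (+4.08), ...
  286 windows; peak |coefficient| 3.05 at center 168 (SRP regions: [15,55) and [160,200))

$ Rscript analysis/05_enrichment.R
AluSyn2 high     srp_both  k/n = 58/126 vs K/N = 223/770  p = 6.13e-06  p_adj = 7.36e-05

$ Rscript analysis/06_genome_compare.R
AluSyn1: 398 jumping haplotypes vs 100 genomic elements; closest is 4 mismatches away
47 genomic elements within 16 edits of a high jumper
```

Reading these: the mutagenized library carries ~3 mutations per clone;
QC removes hopped reads and truncated fragments while keeping all real
haplotypes; replicates correlate well; the strongest fitted variant
effects and the window-profile peak fall inside the annotated SRP binding
regions (as planted by the simulator's effect model); the high-jumper
variant set is significantly enriched in the SRP intervals; and the
nearest synthetic genomic element is a handful of edits away from an
observed jumping haplotype.

The same machinery is available as a single call:

```r
library(alujump)
manifest <- run_pipeline(list(seed = 11, outdir = "results/pipeline"))
```

which validates the config (unknown keys rejected, all errors collected),
runs simulate → call → differential → effects → enrichment → compare, and
writes TSV/JSON artifacts plus a checksummed manifest; identical seeds
give byte-identical outputs.

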