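---
title: "Models and methods behind the MPJA pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind the MPJA pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The assay and the analysis problem

A massively parallel jumping assay (MPJA) measures the retrotransposition
competence of thousands of Alu sequence variants at once. An error-prone
PCR library of a ~280-300 bp Alu element is cloned into a jumping vector,
transfected, and selected for retrotransposition; sequencing the plasmid
pool ("plasmid" libraries) and the recovered integrated copies ("jumping"
libraries) yields, for every distinct *haplotype* (a particular combination
of nucleotide variants on one element), a pair of count profiles across two
replicates per condition. Haplotypes whose jumping representation rises or
falls relative to their plasmid representation have gained or lost jumping
activity relative to the wild-type element.

`alujump` implements the full computational path: haplotype reconstruction
from alignment records, count aggregation and QC filtering, differential
activity testing, per-variant and per-window effect estimation,
SRP-region enrichment, and edit-distance comparison against a genomic
element collection — together with a synthetic-data generator so that every
stage has a ground truth to be tested against.

# Haplotype reconstruction

Variants are called from SAM alignment fields alone: POS, CIGAR, and the
MD/NM tags are sufficient to reconstruct each read's differences from the
reference without re-alignment. Two independent routes are implemented —
`call_variants()` consumes the MD tag, `call_variants_by_comparison()`
compares the read to the reference base by base along the CIGAR columns —
and the test suite demands exact agreement between them on simulated
libraries, as well as exact round-tripping against the simulator's emitted
records.

Coordinates are 0-based half-open internally; SAM I/O converts to and from
1-based on the boundary. Indels are single-base events and are
**left-anchored** inside homopolymer runs before keying, because MD/CIGAR
placement of an indel within a run is aligner-dependent while haplotype
keys must be stable. A shift never crosses a position edited by another
variant (homopolymer equivalence only holds over unmodified bases), and
multiple deletions sharing a run are packed into its leftmost slots.
Reads that do not span the full reference keep their variant key but gain
an explicit span suffix, so truncated fragments remain distinct rows and
can be removed by the length filter without erasing the full-length
haplotype with the same variants.

## Filters

`filter_haplotypes()` applies the study's QC rules in a fixed order so that
removal reports are reproducible: aligned length >= 200 (sub-200-bp
fragments missing the right arm monomer), edit distance <= 10 (the analysis
targets the minimum number of changes that alter activity), the
index-hopping screen, then count support. The count rule is deliberately
asymmetric: a haplotype must exceed 2 plasmid reads to exist in the
analysis, while exceeding 10 jumping reads only flags it as *detected in
jumping*. A conjunctive reading (requiring both) would contradict the
non-jumper class, which is defined by zero jumping reads; retaining
zero-jumping rows is therefore required. The jumping threshold is applied
to pooled replicates (per-replicate application is a config switch away in
the thresholds block).

The index-hopping screen works at the haplotype level. Hopped reads
surface in a library as haplotypes that belong to a different library:
they align to that library's reference and exactly match a haplotype
natively observed there. A row is removed when it is aligned to a foreign
reference, or when its full sequence collides with another library's
native haplotype (in the latter, unresolvable case both copies are
dropped). This is the detectable signature of hopping given only the
sequencing output; no attempt is made to distinguish hopping from
pre-library cross-contamination, which produces the same signature.

# Differential activity

Normalization uses median-of-ratios size factors (rows containing zeros
excluded from the median), and testing uses a per-haplotype
negative-binomial log-linear model with a single condition coefficient,
`log mu = log s_j + b0 + b1 * jumping_j`, fitted by IRLS with a plug-in
dispersion; `b1/log 2` is the raw log2 fold-change and the Wald p-value is
two-sided normal. This is a deliberate re-implementation of the standard
count-model workflow in simplified form rather than a call into an
existing differential-expression package: the package's guarantees are
phrased as simulation properties (calibration, recovery), not as numerical
parity with any particular implementation, and the acceptance surface
tests exactly those properties.

Dispersion (variance `m + phi m^2`) is estimated per haplotype by method
of moments from within-condition variances, then shrunk toward a
mean-dispersion trend `phi(m) = a0 + a1/m` fitted across haplotypes. Two
numerical choices matter with only two replicates per condition:

* the trend is fitted on **untruncated** moment estimates — clamping the
  1-df noise at zero first would bias the trend upward and make the test
  conservative (the type-I error criterion catches exactly this);
* the shrinkage weight is degrees-of-freedom based,
  `w = df / (df + prior_df)` with `prior_df = 6`, so with `df = 2` the
  trend dominates, as it must when per-row variance estimates carry one
  degree of freedom. The final value is floored at `1e-8`.

Fold-changes are reported raw and WT-normalized
(`log2fc_wt = log2fc_raw - log2fc_raw(reference)`), so the wild-type
haplotype sits at exactly 0 and comparisons are within-library. Rows with
an all-zero condition cannot support the NB fit; they receive a
pseudocount fold-change `log2((mJ+1)/(mP+1))` on normalized means and an
`NA` test. A pseudocount convention is forced by the non-jumper class,
which requires finite negative fold-changes for rows with zero jumping
reads; +1 on normalized counts is the choice here and is configurable in
spirit (the classification rule itself is count-based).

Classes: HIGH (`log2fc_wt > 2`, `p < 1e-5`), LOW (`log2fc_wt < -2`,
`p < 1e-5`, jumping reads present), NON (`log2fc_wt < -2`, zero jumping
reads, plasmid total > 50), REFERENCE, else UNCLASSIFIED. The non-jumper
rule is count-based by default with the p-threshold available as an
option (`require_p_non`), because a Wald p-value for an all-zero group is
convention-dependent rather than informative.

# Variant-level and window-level effects

The per-variant model is an ordinary least-squares regression over rows
stacked by (replicate i, haplotype j):

```
log2(jumping_ij + 1) ~ {log2(plasmid_rep1,j + 1) | i = 1; 0 otherwise}
                     + {log2(plasmid_rep2,j + 1) | i = 2; 0 otherwise}
                     + N + intercept
```

where `N` is the binary haplotype x variant membership matrix. Each
replicate gets its own plasmid covariate so library-representation effects
are absorbed per replicate; the coefficients on `N` columns are per-variant
activity effects in log2 jumping units. Pseudocount 1 is used inside both
log transforms (the model logs raw counts, which requires a convention),
zero-jumping rows are retained, and the intercept is free — no fixed
offset value is imposed. `N` is restricted to variants carried by at least
`min_carriers = 3` haplotypes to stabilize the fit; collinear columns are
dropped and reported as aliased rather than silently absorbed.

The regional profile refits the same model per 5-bp window (1-bp step,
windows entirely within the element; a 280-base element yields 276
windows), replacing `N` with a single indicator "haplotype carries >= 1
variant positioned in the window"; the coefficient is assigned to the
window center. A presence indicator, rather than summing per-variant
columns, keeps the window coefficient interpretable as the typical effect
of hitting the window at all; per-variant columns remain available through
the ordinary variant model. Windows containing no variants are flagged
undefined rather than zero.

# Enrichment and logos

Whether activity-altering variants concentrate in the SRP9/14 binding
stem-loops is tested with a one-sided upper-tail hypergeometric test.
Distinct variants — (position, ref, alt) tuples pooled across haplotypes —
form the universe: a variant carried by many haplotypes counts once, which
matches treating the union of all observed variants as background. Left
and right SRP regions are tested separately and pooled, classes HIGH and
LOW/NON (pooled) are tested against the same background, and
Benjamini-Hochberg adjustment is applied across all class x region tests.

Position frequency matrices for logo rendering tally, per region column,
nucleotide frequencies across a class's reconstructed haplotype sequences
(reference base where no variant; deletions reduce column support;
insertions do not create columns). Columns sum to one over their support.

# Genome comparison

Distances between jumping haplotypes and a genomic AluS-like collection
are unit-cost Levenshtein edit distances: substitutions and single-base
indels each cost one. Plain mismatch counting is undefined across
different lengths, and the haplotypes contain indels, so edit distance is
the primary metric; whether a multi-base indel should count as one event
is moot here because the simulator and caller operate on 1-bp indels. The
scan uses a shrinking band (exact once a current minimum is known) and
ties for the nearest element break to the lexicographically smallest id.
Comparisons are over the annotated core span; polyA tails and flanks are
outside the element model entirely.

# The synthetic-data generator

The generator is the package's ground-truth instrument, and its defaults
are the assay conditions the pipeline targets:

* **Mutagenesis**: i.i.d. per-base mutation probability `mu = 8/1000`
  (the midpoint of the 1-16 mutations/kb range stated for error-prone PCR
  kits, giving roughly 1-6 mutations per ~300 bp element), SNV-dominated
  with `transition_fraction = 0.6` and 7% single-base indels, and a
  protected 5-base 5' prefix mirroring the mutagenesis-primer footprint.
* **Founder skew**: `founder_count = 2` variants drawn once and carried by
  a Bernoulli(0.35) per clone, reproducing the founder-position
  overrepresentation of early-PCR fixation; on top of that, per-clone
  lognormal abundance weights (`abundance_sd = 1`) emulate amplification
  jackpotting, without which replicate rank correlations of a
  singleton-dominated library would be near zero rather than the high
  values real libraries show.
* **Activity**: additive in log2 units, one effect drawn per distinct
  variant, N(0, 2) inside the SRP intervals and N(0, 0.25) outside —
  concentrating activity-altering variants in the SRP stem-loops by
  construction. No epistasis is modeled. `hotspots` (variants with
  elevated carriage probability) and `effect_overrides` (fixed effects by
  position) exist so recovery experiments can plant known causal variants.
* **Selection and counts**: jumping frequencies `q_h` proportional to
  `p_h * 2^(a_h)`, counts NB with variance `m + phi m^2`, `phi = 0.01`,
  depth 1e5 reads per sample, two replicates per condition.
* **Artifacts**: 2.2% index hopping (records swapped between libraries)
  and 1% sub-200-bp truncated fragments with tags rebuilt consistently.

Determinism is strict: every stage derives a child seed from the config
seed, so identical configs give byte-identical outputs regardless of
ambient RNG state.

What the generator does **not** emulate: sequencing base-call errors,
PCR chemistry cycle by cycle, paired-end merging, RNA secondary structure,
position-specific mutability beyond the hotspot mechanism, and epistasis.
Passing tests therefore demonstrate that the analysis recovers truth under
an idealized error-prone-PCR + selection model, not that it is robust to
base-calling noise or alignment ambiguity in real reads.

# Problem sizes and test design

The test and acceptance workloads are sized for a laptop-scale run while
keeping every estimate's sampling error far from its acceptance margin:
1,000-record caller checks, a 5,000-haplotype null at depth 1e5 for
calibration (type-I error in [0.035, 0.065], Kolmogorov-Smirnov distance
< 0.05), 2,000-clone libraries for effect and classification recovery, 20
seeded runs of 1,200 clones for the enrichment reproducibility check, and
100-element genomic sets for the distance stage. The planted-effect
scenario uses 30 causal positions arranged as six 5-bp blocks (three per
SRP arm, effects +2 on the left arm and -2 on the right) among 30 null
hotspots: blocks of window width make "the top windows tile the causal
positions" a well-posed recovery statement, and separating signs by arm
avoids cancellation inside the window indicator.

# Known limitations

* The NB Wald test is a simplified reimplementation: no independent
  filtering, no outlier handling, no multi-factor designs; exact numeric
  parity with established differential-expression packages is not claimed
  (and the classification thresholds make most decisions far from the
  margin where implementations differ).
* With two replicates per condition the per-row dispersion carries 2
  degrees of freedom; everything leans on the trend, so strongly
  mean-dependent dispersion misspecification would propagate into p-values.
* The hop screen cannot distinguish index hopping from pre-library
  cross-contamination, and removes both copies of a genuinely convergent
  cross-library haplotype (vanishingly rare for diverged references).
* Window coefficients are correlated across overlapping windows by
  construction; the profile is a localization instrument, not a set of
  independent tests.
* `align_fragment()` is a small glocal aligner sufficient for full-length
  and truncated fragments of a known element; it is not a read mapper.
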