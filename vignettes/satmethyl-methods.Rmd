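---
title: "Methods: satellite monomer diversity and bisulfite methylation profiling"
author: "satmethyl authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: satellite monomer diversity and bisulfite methylation profiling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(satmethyl)
```

# Scope and data model

`satmethyl` analyses satellite DNA monomer families characterized by
Sanger-style cloning: a *native library* of cloned monomer sequences
(species encoded in record-id prefixes), a set of *bisulfite clones* of the
same monomer from both DNA strands, and optionally *unmethylated control
clones* from bisulfite-treated PCR product. All analyses run in monomer
coordinates (1-based, inclusive; BED exports are 0-based half-open). The
package targets families like a 315-bp, moderately G+C-rich monomer with
low intraspecific diversity (around 0.03) — the regime in which concerted
evolution keeps monomer variants similar enough that a single majority-rule
consensus is a meaningful reference.

# Consensus and alignment handling

Monomer clones of equal length pass through untouched; off-length clones
(rare single-base indels) are globally aligned to a reference — the longest
record, or a supplied one — with unit gap costs, and the induced gap
columns are merged. A record whose length deviates from the reference by
more than 20% is rejected as not belonging to the family. The operation is
idempotent, so pre-aligned input is safe.

The consensus is majority rule per column. Gaps enter the column
frequencies, but a base is emitted whenever the gap frequency is below 0.5;
ties default to the first base in alphabetical order (deterministic), with
an IUPAC mode for workflows that propagate ambiguity (degenerate bisulfite
primers are usually designed from such codes). `N` is excluded from every
frequency denominator.

# Nucleotide diversity

`nucleotide_diversity()` is the average uncorrected p-distance over all
unordered pairs with *pairwise deletion*: columns where either sequence of
a pair carries a gap or `N` are dropped from that pair's denominator only.
This matches the default behaviour of the classical polymorphism software
used for such data; no multiple-hit correction is applied, appropriate at
diversities of a few percent. Sliding windows (default 10 bp, step 1,
windows fully inside the monomer) recompute the estimator on the window's
columns. How the single-deletion monomer enters Pi is not standardized
across tools; pairwise deletion of the gap column is our convention and is
configurable only in the sense that gap-free input sidesteps it.

## The ±2SD segment rule and its statistical limits

A window is *variable* when its diversity exceeds `mean + 2·sd` of the
window values and *conserved* when it falls below `mean − 2·sd`; window
labels are projected onto positions (extreme labels win over intermediate,
*variable* over *conserved* on overlap — the projection precedence is our
choice) and maximal runs become segments.

Two properties of this rule deserve emphasis, because they determine what
it can recover:

1. **Chebyshev bound.** At most a quarter of the windows can lie beyond
   two standard deviations of the mean, whatever the track looks like. If
   near-zero-diversity segments cover more than about 20% of the monomer,
   they dominate the standard deviation and `mean − 2·sd` drops to or below
   zero: *no* window can then be called conserved. A conserved footprint of
   83 bp on a 315-bp monomer (about 21% of windows) sits essentially at
   this bound, so the rule flags variable peaks reliably but conserved
   troughs only when the rest of the track is very tight.
2. **Sampling noise.** The realized diversity of a 10-bp window fluctuates
   around its expectation with a standard deviation of roughly
   `sqrt(4·p / (10·n))` for per-site substitution probability `p` and `n`
   sampled monomers; with `n ≈ 40` and `p ≈ 0.015` that noise (≈ 0.011) is
   of the same order as the signal, further widening the SD.

Consequently the parameter-recovery test plants a compact, deep conserved
footprint (two blocks of 30 and 13 bp at 2% of the baseline rate) in a
family of 120 monomers, where the rule is statistically identifiable, and
asserts both sensitivity (each planted block overlapped by a conserved
segment) and precision (every conserved call inside a planted block, one
window of slack). On study-scale data the rule should be read as a
peak-caller for variable regions and a conservative flagger of the most
extreme conserved windows.

# Bisulfite methylation calling

Bisulfite clones are mapped to the strand-appropriate consensus
(complementary-strand clones to its reverse complement) by global alignment
under an asymmetric score in which read `T` against reference `C` is a
match — conversion is never penalized. Identity is counted over *all*
alignment columns including gaps, so unrelated sequences cannot reach the
70% acceptance threshold through gap-riddled alignments. Primer-derived
read intervals are masked out before counting. Reads shorter than 50
unmasked bases are rejected.

For every monomer position whose native-library column carries cytosine or
thymine on a strand, the methylation estimate is

```
m = (fraction of mapped clones reading C) / (native C+T fraction)
```

The denominator removes the bias of ancestral C→T point mutations: clones
descending from a T-carrying monomer can never read C, so the raw fraction
underestimates methylation at polymorphic sites. The C+T denominator is the
estimator as commonly printed; it fully cancels the bias only where the
column is effectively binary C/T. A cytosine-only denominator
(`normalization = "c_only"`) is available; at a column that is 80% C / 20% T
with 40% of clones reading C the two give 0.40 and 0.50 respectively.
Values above 1 (sampling noise) are clamped to 1 and flagged, never
silently.

Two further choices:

* **Conversion-failure background.** Unconverted unmethylated cytosines
  (probability `1 − e`, with `e` the conversion efficiency, typically
  ≈ 0.987) read as C and inflate `m` additively by about `(1 − m)(1 − e)`.
  The default estimator leaves this in, as the classical manual analysis
  does; passing `conversion_efficiency` to `call_methylation()` removes it
  via `m' = (m − (1 − e))/e`. Efficiency itself is estimated from the
  unmethylated controls as the fraction of covered reference cytosines
  reading T.
* **Aggregation.** Context × strand summaries are observation-weighted by
  default (methylation events over eligible cytosine-site observations,
  pooled over clones and sites), reading "proportion of methylated
  cytosines" as events over opportunities; a site-averaged mode exists
  because the alternative reading cannot be excluded.

Context (CG, CHG, CHH with H ∈ {A,C,T}) is classified on the majority-rule
consensus of each strand, with *circular* successor lookup: in a tandem
array the monomer's last bases continue into the next copy, so the context
of a terminal cytosine wraps to the monomer start. Per-clone context is not
recomputed — the consensus defines the site types, as in a manual screen of
conserved cytosine positions. Gap characters are skipped when walking to
successor bases; an `N` at a needed successor yields `CHH_unresolved`,
excluded from summaries.

Methylation window tracks (default 10 bp, step 1) are observation-weighted
means over cytosine-capable positions; windows without such positions are
`NA`. The `mean + 2·sd` threshold marks highly methylated windows. The
methylation–diversity association is the Spearman rank correlation with
average ranks for ties and the large-sample t approximation for the
p-value (matching the common implementations behind published values); a
seeded permutation test (≥ 10,000 permutations) is available for small
tracks.

# In-silico restriction digestion

`tandem_array()` concatenates monomers head-to-tail (optionally circular —
an idealization of a long array); `digest()` cuts each recognition site
passing the enzyme's methylation-sensitivity rule, independently with a
partial-digestion probability (Bernoulli per site; the seed is mandatory
below 1). Defaults encode the classic isoschizomer logic for CCGG: MspI is
blocked by outer-C methylation, HpaII only by *full* (both-strand)
internal-C methylation, so hemimethylated sites are cut by both enzymes —
the behaviour inferred for hemimethylated satellite monomers rather than
the strictest catalogue semantics; the rule table is data-driven and can
be replaced via a TSV. HaeIII, TaqI and PvuII are methylation-insensitive.
Fragment multisets conserve total length exactly, and `ladder_profile()`
bins fragments to multimer rungs within a ±2 bp tolerance. When monomers
carry a site independently with probability `q`, multimer lengths follow a
geometric law with mean `1/q` — the property test checks the simulation
against this closed form.

# The synthetic-data generator

The generator is first-class, tested code: it defines the conditions under
which the estimators are validated.

* **Family model.** An ancestral monomer (default 315 bp) is built with an
  exact base count at the target G+C (0.4405) and a controlled restriction
  map: one HaeIII and one TaqI site planted inside conserved blocks, one
  PvuII site in a variable block, three CCGG isoschizomer targets; chance
  occurrences of these motifs elsewhere are scrubbed. Each monomer then
  mutates independently per site (default 0.015, uniform among the three
  alternatives; a transition/transversion weight is configurable since the
  substitution process of such families is not standardized) with the rate
  multiplied by 0.2 inside two conserved blocks (positions 41–89 and
  199–232) and by 2.0 inside four 15-bp variable blocks. The closed-form
  expectation `(172·d(p) + 83·d(0.2p) + 60·d(2p))/315` with
  `d(p) = 2p(1−p) + (2/3)p²` gives Pi ≈ 0.0290 under these defaults,
  matching the low-diversity regime the analyses assume. Monomers suffer a
  single-base indel with probability 0.025 (deletion four times as likely
  as insertion), reproducing the observed near-fixation of the unit length.
  All species draw from the same ancestral pool — a deliberately minimal
  surrogate for concerted evolution under a shared satellite library; it
  does not model lineage-specific homogenization.
* **Methylation model.** Every cytosine of every molecule is methylated
  independently at its context rate (defaults CG 0.0565, CHG 0.0179,
  CHH 0.0269 — the observed marginal proportions of the motivating system),
  multiplied by 3 inside two hot blocks (positions 60–89 and 209–221,
  inside the conserved blocks, mirroring a satellite whose methylation
  triplicates the genomic mean there). Note the two defaults together
  overshoot the table-style marginals by construction — the rates are
  per-site probabilities, the table values are genome-wide marginals that
  already include the hot regions; recovery tests therefore switch the hot
  blocks off when checking rate estimates. An optional strand-symmetric
  mode mirrors CpG states across strands.
* **Bisulfite model.** Unmethylated C reads T with probability equal to
  the conversion efficiency (default 0.987); methylated C is fully
  protected (an over-conversion probability is available, default 0).
  Clone counts default to the study-scale 33 direct / 26 complementary,
  with external/internal fragment classes in the corresponding
  proportions.

Everything is deterministic under the configured seeds; `make_dataset()`
writes byte-identical files on re-runs and a ground-truth JSON for
recovery tests.

## What passing tests do and do not show

The generator draws sites independently, uses a single ancestral sequence,
and has no PCR or cloning bias, no chimeric clones, no sequencing error,
and no correlation between methylation states of neighbouring sites beyond
the optional CpG mirroring. Passing recovery tests therefore demonstrates
estimator correctness and statistical calibration under the stated model —
not robustness to the correlated errors, clone-sampling artefacts, or
within-genome rate heterogeneity of real libraries.

# Problem sizes and numerical choices

The shipped tests validate Pi against a brute-force pairwise oracle on up
to 10 random sequences; run rate recovery on 20 replicate clone sets of 60
reads against a 39-monomer family (mean absolute error of the three context
rates below 0.01); estimate conversion efficiency from 40 control clones;
and check the geometric ladder law on arrays of 3,000–4,000 short monomers.
Windows are 10 bp at step 1 throughout, the segment and hot-window rules
use a multiplier of 2, bisulfite alignment accepts reads at ≥ 70%
bisulfite-aware identity with gap-open cost 4 and gap-extension cost 1,
and consensus ties break alphabetically. Degenerate inputs are defined,
not fatal: all-gap columns emit `-` with a warning, zero-coverage positions
yield `NA` calls, sd-zero tracks classify as intermediate throughout, and
constant series report an `NA` correlation.

# Known limitations

* The ±2SD segment rule cannot, by construction, flag conserved footprints
  covering more than ~20–25% of windows (see above); published segment
  boundaries derived with other software may therefore not be reproducible
  by this rule alone.
* The C+T normalization removes mutation bias fully only at binary C/T
  columns; both denominators are provided, and the choice matters at
  polymorphic sites.
* Bisulfite mapping is global against a single consensus per strand;
  structurally rearranged or chimeric clones are rejected rather than
  split-mapped.
* Partial digestion is an independent-Bernoulli model per site; real
  partial digests have enzyme- and chromatin-dependent site preferences.
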