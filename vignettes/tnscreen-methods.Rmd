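---
title: "Calling phage-resistance loci from Tn-Seq selection screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling phage-resistance loci from Tn-Seq selection screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tnscreen)
```

## The experiment this package models

A pooled, high-density transposon mutant library of a bacterium is grown,
split, and either challenged with a lytic phage at high multiplicity of
infection or left untreated. After adsorption, both cultures are plated;
surviving colonies are pooled, and the abundance of every transposon
insertion site is read out by sequencing insertion junctions. Because the
challenge is a *survival selection*, insertions that inactivate a host
factor the phage requires (a surface receptor, its biosynthesis pathway, a
membrane conduit used for genome injection) protect the mutant, and those
genes end up strongly enriched for reads relative to the paired control.
The converse is not informative: any mutant that does not protect is killed,
so depletion is expected genome-wide and is never interpreted.

`tnscreen` covers the analysis from per-site counts to called loci, a
simulator of the whole experiment, profile clustering across many
challenges, and the adsorption/ECOI statistics used to validate hits in
follow-up assays.

## The enrichment procedure

For each challenged replicate and its paired untreated control:

1. **Depth normalization** (`normalize_counts`): challenged site counts are
   multiplied by `control total / challenged total`. This is deliberately
   the simplest possible normalization — by genome-wide totals of the
   *paired* control — rather than median-of-ratios or quantile methods:
   after a strong selection the challenged library composition is
   dominated by true signal, which size-factor methods would partially
   normalize away.
2. **Per-gene log2 fold change** (`gene_log2_fold_change`):
   `log2((x_g + c)/(y_g + c))` on gene totals, pseudocount `c = 1` read
   count (a config knob, echoed into the run metadata). The shared
   pseudocount keeps values finite — most genes have zero challenged
   reads after selection — and makes the transform antisymmetric under
   swapping the challenged and control roles.
3. **Mann–Whitney U test** (`mann_whitney_gene`): challenged vs control
   per-site counts over the union of sites observed in either sample
   within the gene (a site missing from one sample contributes 0 for it).
   The comparison unit is a genuinely open choice — per-gene totals
   across a genome-wide null would be an alternative — and per-site
   counts within the gene were chosen because they test the claim that
   is actually of interest: that reads are elevated across the gene body
   rather than at a single jackpot site. `enrich_pair` exposes the
   per-site unit; the records it returns let a user build any gene-level
   alternative.
4. **Hit calling** (`call_hits`): a gene is a hit iff in **every**
   replicate `log2FC > 2` *and* its challenged unique-insertion count is
   `> 1`. A second, purely visual tier ("strong", `log2FC > 5` in every
   replicate) marks the loci that dominate a heatmap display. The
   "both replicates" scope is applied to *both* criteria (the stricter
   reading of an ambiguous rule; `require_all_replicates = FALSE`
   relaxes it).
5. **Reproducibility and multiplicity**: `replicate_reproducibility` is
   the Pearson correlation of per-gene log2 fold changes between
   replicates over *all* annotated genes (not hits only — correlation
   restricted to called genes would be inflated by construction).
   Benjamini–Hochberg q-values are computed on the per-gene
   `max(p_A, p_B)` — evidence is required in both replicates, so the
   worse replicate is the honest summary — but neither p nor q gates
   hit calling; they are transparency outputs.

### Why unique insertions, and the small-gene flag

A single surviving clone can carry a gene to a large fold change in one
replicate. Requiring more than one distinct insertion site per gene, in
each replicate, demands that *independent* mutants of the same gene
survived — the genetic definition of a reproducible locus. The cost is a
bias against short genes, which offer few insertion positions. Genes
shorter than `small_gene_len` (default 400 bp) that pass the fold-change
criterion in both replicates but fail only the unique-insertion criterion
are therefore emitted with `small_gene_flag = TRUE` in a review list.
They are never auto-promoted: the flag reproduces a manual-curation step,
not a statistical rule.

### Numerical choices

* The exact Mann–Whitney p is defined as
  $P\left(|U - nm/2| \ge |U_{\mathrm{obs}} - nm/2|\right)$ over all
  $\binom{n+m}{n}$ relabelings of the pooled observed values, which
  handles ties exactly and, for tie-free data, coincides with the
  classical doubled one-tail exact p. Enumeration is used when both
  groups have ≤ 8 sites (≤ 12,870 labelings); beyond that the
  tie-corrected normal approximation with a 0.5 continuity correction is
  used, matching `wilcox.test(correct = TRUE)` to ~10 digits on tie-free
  data.
* A gene whose pooled values are all identical (typically all zero in
  both samples) is a degenerate comparison: `p = 1`, flagged.
* Fold changes and U tests are computed on normalized challenged counts;
  unique insertions on raw counts (scaling does not change which sites
  are nonzero, so the two agree by construction).
* Coordinates are 1-based inclusive throughout, matching GFF3; site
  assignment uses closed intervals (both gene ends included), strands
  collapsed (a transposon disrupts either orientation), no terminal
  trimming by default (`trim_frac` exposes the 5–10% edge exclusion some
  Tn-Seq tools apply).

## The simulator

`simulate_experiment` generates: a genome of non-overlapping genes with
Gamma-distributed lengths (mean 1 kb, floor 150 bp, fixed 100 bp
spacers); gene classes (`neutral`, `essential`, `resistance`,
`costly_resistance`, `costly_neutral`) apportioned by largest remainder
with guaranteed representation; a library of `library_size` mutants with
insertion sites uniform outside essential gene bodies (essential voids)
and clonal abundances from a unit-mean exponential scaled by the gene's
relative fitness `w` (fitness-costly classes are depleted during
outgrowth, mimicking loci whose inactivation slows growth yet protects
from phage); two independent challenges of the *same* library — each
mutant survives Bernoulli with probability `s` (resistance classes,
default 0.9) or the escape baseline ε (default 10⁻³, modeling lysogeny
and phenotypic escape) — followed by an abundance-weighted plating
bottleneck (default 20,000 colonies challenged; 100× that for the
untreated arm, mirroring the hundred-fold dilution difference between
plating all survivors versus a 10⁻² dilution of an unkilled culture);
and gamma-multinomial sequencing, with challenged samples at 1% of the
control depth (low-complexity challenged libraries are pooled at 1:100
against controls). Overdispersion multiplies each site's multinomial
rate by a Gamma with shape `dispersion` (default 10, per-site CV ≈ 0.32;
`Inf` recovers the plain multinomial); the per-site-shape
parameterization keeps site detectability independent of how many sites
the library has. All stages draw from per-stage child seeds derived from
one master seed by a fixed counter scheme (`child_seed`), so any stage
can be reproduced in isolation and whole runs are byte-identical for a
fixed seed.

Two genes are deliberately generated short (< 400 bp) — one
resistance-class when present — to exercise the small-gene review path.

Default scale (2,000 genes, 10⁵ mutants, control depth 10⁶) runs the
full simulate → enrich → score cycle in well under a minute on one core;
tests use 150–400 genes and proportionally smaller libraries, which
preserve every qualitative regime.

### What the simulator does and does not emulate

It reproduces the regimes the caller must tolerate: essential voids,
fitness-cost depletion, strong survivor enrichment, asymmetric library
complexity between arms, overdispersed counts, and escape background.
It does *not* model phage population genetics (no host-range mutants),
growth dynamics, sequence-level reads, insertion-site sequence bias, or
within-mutant lineage structure. Passing tests therefore demonstrate
correctness of the statistics and robustness to these regimes — not that
any particular biological screen will reach the same sensitivity.

### A known limitation: clonal escape and all-gene reproducibility

Escape is modeled *per mutant* (one Bernoulli draw per clone), consistent
with survivors being counted as colony units. A consequence at default
scale is that the ~100 escapees per challenge each capture ~1/650 of the
challenged reads; after depth normalization such a gene shows
`log2FC ≈ +2` in the replicate where its escapee arose and ≈ −9 in the
other. These one-replicate "jackpot" genes are exactly what the
dual-replicate, dual-criterion caller is built to reject — and it does:
they produce no false positives. But they dominate the *all-gene*
replicate correlation, which sits near 0.55 at default scale versus
> 0.95 when the escape baseline is zero (both values are computed in the
test suite). Real screens report substantially higher replicate
correlations because escape there acts at the level of the thousands of
cells carrying each insertion, smoothing the background across
replicates; modeling that would require per-cell survival draws, which
conflicts with the colony-unit accounting adopted here. Users comparing
simulated to real reproducibility should restrict the correlation to
escape-free genes or treat the all-gene value as a lower bound.

## Profile clustering

Across a panel of challenges/stress conditions, genes acting in one
pathway show parallel per-condition log2 fold-change profiles.
`correlation_cluster` links two genes when Pearson `r > 0.9` (pairwise
deletion of missing values; pairs with < 3 shared conditions or zero
variance contribute no edge) and reports connected components — the
minimal reading of "similar means correlated above threshold". Connected
components are transitive-closure clusters, so one bridging gene can
merge two tight groups; a complete-linkage alternative
(`method = "complete"`) is provided for users who want every within-
cluster pair above threshold. Labels are deterministic (each cluster is
named by its lexicographically smallest member) and an average-linkage
ordering of `1 − r` is emitted for heatmap layout. Pearson invariance
makes the clustering insensitive to affine rescaling of any profile, so
raw and standardized profiles give identical results.

## Kinetics statistics

* `fraction_unadsorbed`: free titer over mock-infection input at a
  recorded timepoint (pfu/mL over pfu/mL); values > 1 are permitted but
  flagged as counting noise. Fraction adsorbed is the complement.
* `adsorption_rate`: least-squares slope of `ln(free/input)` on time
  (minutes), divided by −B for cell density B (cells/mL), giving the
  classic first-order rate constant k in mL·min⁻¹, with fit R².
  Nonpositive titers cannot enter the log and are excluded with a
  warning. Replicate titers are averaged in pfu space, not log space,
  before fractions are formed.
* `ecoi`: centers-of-infection per input pfu, relative to the wild-type
  reference host (the reference against itself is exactly 1).
* `compare_groups`: two-tailed Welch t test by default (the unequal-
  variance form is the safer default when only "t test" is specified;
  `var_equal = TRUE` gives Student's pooled form), with the star tiers
  `* p<0.05`, `** p<0.005`, `*** p<0.001` — note the unusual middle
  tier — and a degenerate branch for two identical constant groups.
  Tests are run on fractions rather than raw titers, so differences in
  input titer between days do not masquerade as effects.

## Workflow and determinism

`run_config`/`run_pipeline` wrap the whole cycle: configuration is
validated field-by-field before any computation, every stage logs record
counts to stderr, all thresholds and model parameters are echoed into
`run_metadata.txt`, and numeric artifact columns are written with a fixed
format so identical configuration + seed gives byte-identical TSVs. No
stage reads the wall clock or the global RNG state; everything derives
from the master seed. `inst/scripts/tnscreen-cli.R` is a thin shell front
end over the same functions (`simulate`, `enrich`, `cluster`, `score`).
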