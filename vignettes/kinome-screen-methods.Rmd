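---
title: "Methods: host-contrast screen scoring, single-cell stratification and survival statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: host-contrast screen scoring, single-cell stratification and survival statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinscreen)
```

# The experimental design being modeled

A pooled CRISPR knockout library — several hundred genes at four guides
each plus ~100 non-targeting controls (NTCs) — is transduced into tumor
cells at low multiplicity so each clone carries one knockout. The pool
is implanted into two host arms, immune-competent (WT) and
CD8-T-cell-deficient (CD8KO), with enough cells per mouse that each
guide is represented hundreds of times (the *fold representation*,
cells x mice / guides, floored). Tumors are harvested at an early and a
late stage, guides are amplified with per-animal barcodes and
sequenced. A knockout that lets the tumor escape CD8 killing persists in
WT hosts; one that is needed to resist CD8 killing is depleted there
but not in CD8KO hosts. The WT-over-CD8KO contrast therefore isolates
CD8-mediated selection from everything else (engraftment, drift,
growth-rate effects), and the NTC guides provide an in-library null for
what "no selection" looks like after all the shared noise.

# Screen scoring model

**Filter.** A guide's raw count below 40 in a sample is treated as
unmeasured there (`apply_count_filter()`); the stored counts are never
modified. The filter is per guide per sample.

**Normalization.** `normalize_cpm()` maps raw counts to
`raw / sample_total * 1e6 + 1` (counts-per-million with a +1
pseudocount). Sample totals use the full library, including guides the
filter later removes, so filtering cannot change other guides' values.
The pseudocount bounds every value at 1 and makes fold changes always
defined. Per sample, `sum(norm - 1)` is exactly one million — a
conservation identity the tests check at 1e-6 relative tolerance.

**Arm aggregation.** The cross-mouse combination rule is a genuinely
open design choice; this package uses the arithmetic mean of normalized
counts over a group's *passing* samples, and requires a guide to pass
in at least `max(2, ceiling(half the group's samples))` of them to be
usable in that group — fewer passes yield `low_count_excluded` for any
comparison involving the group. The mean-of-arms (rather than
mean-of-per-mouse-fold-changes) reading matches a presentation where
each guide carries a single fold change per contrast; the half rule is
a robustness compromise against calling a guide from one or two mice.

**Fold change and calls.** `fc = mean_WT / mean_CD8KO`. Guides whose
arm means are both below 5 normalized counts are `unanalyzable` (too
close to the pseudocount floor for the ratio to mean anything). The
call rule is anchored on the controls: *enriched* strictly above the
most enriched NTC fold change, *depleted* strictly below the most
depleted one. Strict inequalities make the rule sound by construction —
an NTC can never exceed the extreme of its own set — and send
boundary ties to `neutral`.

**Gene level.** `gene_summary()` counts calls per gene, averages log2
fold changes over usable guides, ranks by that mean (most negative =
rank 1, ties broken by first occurrence for determinism), and tests the
gene's guide log2 fold changes against the NTC guide log2 fold changes
with a two-sided Welch t. No adjustment is applied to the per-gene
p-values' primary column; a Benjamini-Hochberg column (`q_vs_ntc`) is
reported alongside.

**Temporal selection.** `temporal_selection_test()` pools a gene's
guide-level normalized counts over mice within (genotype, stage) and
compares early vs late with an unpaired two-tailed Welch t (Satterthwaite
degrees of freedom), unadjusted, mirroring per-gene figure-level
reporting. Degenerate inputs are handled explicitly: both stages
constant and equal gives t = 0, p = 1; constant but unequal reports the
double-precision floor with a `p_underflow` flag rather than a fake
zero.

# Guide quantification

`quantify_screen()` demultiplexes by exact match of the fixed-length
barcode at a fixed in-read offset, then counts a read for guide *g*
exactly when the 20-mer immediately after the first anchor occurrence
equals *g*'s protospacer. Matching is sequence-only (qualities ignored)
and forward-strand only, since amplicon orientation is fixed by primer
design. Exact matching is the default because no alignment scheme is
canonical for this assay; an optional 1-mismatch mode uses the
per-guide Hamming-1 neighborhood with ambiguous neighbors discarded.
Per sample, assigned + unassigned + skipped reads always equals the
total — a conservation property under test, along with exact
round-tripping of the synthetic FASTQ emitter.

# Synthetic screen generator

`simulate_screen()` draws, in order:

1. **Plasmid abundance**: one lognormal(0, sigma) weight per guide,
   normalized; sigma defaults to 0.5, a typical library skew.
2. **Implantation bottleneck**: per mouse, a multinomial draw of
   `cells_per_mouse` (default 200,000) clones from the plasmid weights.
3. **Selection**: clone weights are multiplied by `exp(s * t)` with `s`
   the per-round log-fitness for that gene in that host arm (0 unless
   planted; always 0 for NTCs) and `t` the stage's elapsed selection
   rounds.
4. **Sequencing**: one multinomial read draw per sample at a
   Poisson-drawn depth (default 4000 reads per guide).

The defaults are the package's fixed study conditions. Two deserve
comment. The stage map defaults to `c(early = 2, late = 4)` *effective
selection rounds*: `t` is deliberately not a cell-division count but
the product of time and per-round selection intensity on the scale
where planted effects `s` are of order 1. With `s = -1`, a clone is
down `exp(-2)` ~ 7-fold at the early stage and `exp(-4)` ~ 55-fold at
the late stage — strong but measurable selection. Mapping stages to
many more rounds at this `s` would push selected clones below the
40-read floor in every sample, leaving nothing for any scoring method
to rank; equivalently one could keep many rounds and shrink `s`, but
anchoring `s = -1` as "strong selection" keeps planted effects
interpretable. The default depth of 4000x per guide (the same order as
the >1000x coverage such screens target) keeps a 55-fold-depleted
guide above the raw-count filter in late samples with margin, so
recovery tests exercise the scoring, not the filter. Arm size defaults
to 6 mice per stage, i.e. about a dozen animals per genotype across
stages, matching the scale of such experiments.

By default there is no overdispersion layer beyond the
bottleneck-then-multinomial chain; mouse-to-mouse variation arises from
independent bottleneck draws. The truth table (per-gene `s_WT`,
`s_CD8KO`) is always returned and never read by analysis code.

What the generator does *not* emulate: tumor microenvironment biology,
immune-cell kinetics, PCR jackpotting, or guide-efficiency variation.
Passing recovery tests therefore show the scoring pipeline is correct
and calibrated under its stated noise model, not that the biology of a
real screen is this clean.

# Single-cell stratification

`annotate_cells()` is a deliberately simple marker-argmax typer (mean
log1p CPM per type's markers; positive maximum wins, ties break in
panel order; all-zero cells are unassigned). Real cohorts are typed
with the source study's full annotation pipeline; here the synthetic
generator's ground-truth labels are the test surface, and the separable
default configuration is recovered at 100%.

`focal_positive_frequency()` computes, per sample, the fraction of
tumor-compartment cells with focal-gene CPM > 0 — detection frequency,
not expression level, which is the more robust quantity under dropout.
`dichotomize_samples()` cuts the cohort at the median frequency;
samples exactly at the median go to "low" (a convention; the tie side
is not canonical), and an all-identical cohort degenerates to all-low
with a warning rather than an arbitrary split.

**Recovery-curve AUC.** For each cell, genes are ranked by descending
expression and the score is the normalized area under the recovery
curve `c(k)` (number of set genes at rank <= k) over the top
`max_rank = ceiling(0.05 * n_genes)` ranks — the standard convention
for this family of rank-based per-cell scores. The normalizer
`sum(min(k, m))` is the maximal area, so scores live in [0, 1], hit 1
exactly when the set occupies the top ranks, and 0 when no set gene
makes the cutoff. Rank ties are broken by a single seeded random
permutation shared across cells; the seed is recorded in the output, a
reproducible answer to an otherwise undocumented tie policy. Because
only ranks enter, any monotone transform of a cell's expression leaves
its score unchanged (a tested invariant).

**Group comparison.** `compare_groups_mw()` uses exact enumeration of
all group assignments when both groups have at most 8 observations
(correct under ties, where the classic null tables are not), and the
tie-corrected normal approximation of U otherwise, without continuity
correction. The exact branch is checked against an independent
enumeration oracle and against `wilcox.test` on tie-free cases.

**Null calibration caveat.** In small gene universes the focal gene
itself competes for top ranks: cells from focal-high samples carry one
extra well-expressed gene, which slightly depresses their signature
scores and inflates the null rejection rate of the downstream
Mann-Whitney (measured ~8% at a 120-gene universe). The effect shrinks
as 1/max_rank; calibration checks therefore run at a 300-gene universe
(12 samples x 40 cells), where the pipeline's null rejection is
consistent with the nominal 5%, and power against a planted coupling of
2 (log-scale program elevation in focal-low samples) exceeds 90% over
200 replicates. Real transcriptomes, with ~20,000 genes, are far past
the regime where this artifact matters.

`welch_de()` contrasts focal-positive vs focal-negative tumor cells per
gene with a vectorized Welch t; raw p is primary and a
Benjamini-Hochberg q is attached. The planted-signal power study in the
tests uses coupling 3 with 100 cells/sample, where >= 90% of program
genes are recovered at q < 0.05 in every seed.

# Survival statistics

`km_fit()` and `logrank()` wrap the survival package's product-limit
and score-test machinery (the standard implementations), fixing the
reporting conventions: events are processed before censorings at tied
times, the median is the smallest time with S(t) <= 0.5 and is an
explicit "undefined" sentinel (NA) when the curve never reaches 0.5 —
the honest report for arms with long-term survivors — and the log-rank
p is two-sided from chi-square with 1 df. Both are tested against
independent hand-computed oracles (explicit product of (1 - d/n);
explicit O-E with hypergeometric variance) and a 1000-replicate
equal-hazard simulation whose rejection rate must sit near 5%.

# Problem sizes and tolerances

The test and acceptance runs use deliberately small instances chosen to
exercise every rule at comfortable margins: 100-gene screens (with the
full 100-NTC complement for envelope calibration, or 20 NTCs for the
recovery study), 20 seeded replicates for recovery and calibration
rates, 300-gene/12-sample/40-cell single-cell cohorts with 200
replicates for null and power rates, and 1000 replicates for log-rank
calibration. Oracle comparisons (Welch, AUC, Mann-Whitney, product
limit) are asserted at 1e-10; the CPM conservation identity at 1e-6
relative; Monte-Carlo rates at bands pre-computed from binomial
sampling noise (e.g. null rejection in [1%, 9%] for 200 replicates at a
nominal 5%).

# Known limitations

- The cross-mouse aggregation rule (mean of normalized counts over
  passing samples) is one defensible reading of an under-specified
  step; per-mouse fold-change medians would be a reasonable alternative
  and would differ in extreme-skew cases.
- The envelope rule conditions on the observed NTC extremes, so its
  false-call rate depends on the NTC count (~2/(n_ntc + 1) for
  exchangeable guides); with few controls it is permissive.
- Strong true depletion interacts with the raw-count filter: a clone
  driven far enough below the sequencing floor becomes
  `low_count_excluded` or `unanalyzable` rather than "very depleted".
  That is faithful to the filter's definition, and it is why the
  generator's default stage/depth operating point keeps planted effects
  measurable.
- The marker-argmax typer ignores doublets, ambient RNA and graded
  identities; the generator plants none of these.
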