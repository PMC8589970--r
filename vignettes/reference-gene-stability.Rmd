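---
title: "Reference-gene stability analysis: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reference-gene stability analysis: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qpcrstab)
```

## The problem

RT-qPCR expression of a target gene is reported relative to one or more
reference ("housekeeping") genes, on the assumption that the references are
expressed at a constant level across all samples and conditions. That
assumption has to be demonstrated, not asserted: a reference that responds
to the treatment silently distorts — and can invert — every downstream fold
change. `qpcrstab` implements the standard validation workflow: several
independent stability statistics computed over a candidate panel, a
consensus ranking, a rule for how many references are needed, and a
validation stage that quantifies what a bad choice would have done.

A second, less widely appreciated issue is assay efficiency. All the
classical stability tools take Cq values at face value, i.e. assume every
assay doubles its product each cycle. Real efficiencies in a typical panel
range roughly 88–108%. The package therefore supports running the whole
analysis twice — on raw and on efficiency-corrected Cq — and comparing the
two rankings position by position.

## Working scale and the efficiency correction

Throughout, Cq is treated as a log2-scale quantity: at 100% efficiency,
`−Cq` equals log2 of the starting template amount up to an additive
constant. All four stability statistics operate on this scale.

For an assay with fractional efficiency `E` (per-cycle gain `1 + E`), a
measured cycle corresponds to `log2(1 + E)` ideal-doubling cycles. The
correction

```
Cq' = Cq * log2(1 + E)
```

maps every assay onto the common ideal scale, so that `2^(−Cq')` tracks the
true relative quantity regardless of the assay's efficiency. It is the
identity at `E = 1`, monotone in `E`, and consistent with the
`2^(−ΔΔCq)` arithmetic used downstream. Commercial packages that offer
"efficiency correction" of Cq do not always document their transform; where
an external tool used a different but equivalent quantity-space rescaling,
rankings are unaffected because all the statistics here depend on Cq only
through per-gene affine-consistent transforms. The formula is a deliberate,
documented package choice (`correct_cq()`), and efficiencies are carried as
fractions internally (percent accepted at file interfaces).

Efficiency itself is estimated from a dilution series by unweighted
ordinary least squares of Cq on log10 relative concentration
(`fit_standard_curve()`), with `E = 10^(−1/slope) − 1`. Unweighted OLS is
the universal thermocycler-software convention; weighting is deliberately
not offered.

## The four stability statistics

**geNorm.** `M_j` is the mean, over all partner genes `k`, of the standard
deviation across samples (n−1 denominator) of the pairwise log2 ratio
`Cq_k − Cq_j`. The procedure then iteratively removes the highest-M gene
and recomputes until two genes remain. Two reporting conventions circulate
for the per-gene M table: the full-panel M values, and each gene's M in the
round it was excluded. `genorm()` reports **both**: `$stability` carries
the full-panel values (used for ranking and consensus), and
`$m_at_exclusion` carries the stepwise trace, in which the final pair share
the SD of their mutual log ratio. Ties at exclusion are resolved by
removing the lexicographically last gene, with a message — ties do occur in
practice (identical printed M values are common at 3-decimal precision) and
a deterministic rule keeps runs reproducible.

The pairwise variation `V_n/n+1` is the SD across samples of
`log2(NF_n / NF_{n+1})`, where `log2 NF_n` is the mean of `−Cq` over the
`n` top-ranked genes; `optimal_reference_count()` returns the smallest `n`
with `V_n/n+1` below the conventional 0.15 cut-off, or the full panel size
with an explicit flag when nothing satisfies it.

**BestKeeper.** Descriptive statistics per gene plus the correlation of
each gene with the BestKeeper index (per-sample geometric mean of Cq over
the panel). The original tool's "SD" is the mean absolute deviation from
the arithmetic mean, not the sample SD; since published tables rarely state
which variant was used, `bestkeeper()` defaults to the MAD convention with
`sd_type = "sd"` available. A zero-variance gene has an undefined
correlation, reported as `NA`, while its SD of 0 is retained.

**NormFinder.** The model-based estimator, in the package's formulation:

1. work on `z = −Cq` centred per sample by the across-gene mean (the
   "global average expression");
2. per gene `i` and group `g`, with `k` genes: the raw variance `s²_ig` of
   `z` is biased by the centring, which leaks a `1/k` share of every gene's
   variance into each value; the corrected estimate is
   `σ̂²_ig = (s²_ig − s̄²_g/(k−1)) · k/(k−2)`, floored at 0 (floors are
   reported, not silent);
3. the intergroup difference `d̂_ig` (group mean of `z` centred over
   groups) is shrunk empirically-Bayes toward 0 by
   `τ²/(τ² + σ̂²_ig/n_g)`, with `τ²` a method-of-moments estimate of the
   between-gene variance of true differences; in fully degenerate data
   (everything zero) the weight is defined as 0;
4. the stability value combines both components,
   `ρ_i = mean_g( |d̃_ig| + sqrt(σ̂²_ig/n_g) )`; with a single group it
   reduces to the intragroup SD.

The additive combination uses the intragroup *standard error*, not the
posterior SD of `d`: the latter vanishes whenever `τ̂² = 0` and would then
rank all genes equally, discarding the intragroup signal.

Grouping is a genuine free parameter: `run_stability()` defaults to the
resistance class for the pooled dataset and to treatment within each
class-specific dataset (the design factors most likely to move expression),
and exposes the choice (`normfinder_grouping`), including a group-free
variant.

**ΔCt.** Each gene's value is the mean over partners of the SD across
samples of the per-sample Cq difference. It shares geNorm's pairwise logic
without the stepwise exclusion, and both are invariant to any per-sample
constant added across genes (a loading effect cancels in differences).

**Consensus.** The comprehensive ranking is the geometric mean of each
gene's ranks across the four methods, with exact ties given average ranks.
This mirrors the popular web consensus tool in spirit; it deliberately does
**not** attempt to emulate that tool's internal re-implementations of the
four methods, whose details are undocumented — published consensus values
are therefore not numerically reproducible from published per-method
tables, and the packaged consensus fixtures are used for order-based
comparisons only.

## Rank-change comparison

`count_rank_changes()` compares two ranking sets of the same method
(typically raw vs efficiency-corrected) position by position: a position
counts as changed when a different gene occupies it. Counts pool over the
three analysis datasets (all / susceptible / resistant), and the percentage
is rounded to the nearest integer. Positional difference — rather than
Kendall or Spearman distance — is the metric that reproduces the published
comparison statistics exactly; note that where two genes are tied in the
underlying values, a printed order swap still counts as a positional
change, which makes the metric conservative for tied tables.

## Normalization and validation

`normalization_factor()` computes per-sample reference quantities
Pfaffl-style, `(1+E)^(Cq̄ − Cq)` with each gene's own efficiency and its
mean Cq as internal anchor, and takes the geometric mean over references.
`relative_expression()` divides the target's analogous quantity by NF and
rescales so the **calibrator condition mean** is exactly 1.0 (the
figure-caption convention; individual calibrator replicates scatter around
1). With all efficiencies set to 1 the pipeline reduces exactly to
`2^(−ΔΔCq)`, which the tests assert to 1e−12.

`condition_summary()` reports mean, sample SD, `SE = SD/√n` and a 95%
confidence interval using the normal approximation by default. At the
usual n = 4 biological replicates a t-based interval is about 60% wider;
the normal variant matches common descriptive-statistics output and the
t variant is available (`ci = "t"`). `normalizer_discordance()` flags
direction flips — one normalizer set calling a condition up-regulated
while the other calls it down-regulated — which is the practically
dangerous failure mode of unstable references.

## The synthetic-data generator

`simulate_cq_dataset()` draws

```
Cq(g, s, rep) = B_g + L_s + delta_g(cond(s)) + eps(g, s) + eta(rep)
```

with `L_s ~ N(0, σ_L²)` shared across genes within a sample,
`eps ~ N(0, τ_g²)`, `eta ~ N(0, σ_tech²)`. Noise is normal on the Cq (log)
scale because expression noise is multiplicative; the loading effect is the
variance component reference-gene normalization exists to remove, and
without it stability analysis is degenerate. Streams are seeded per
(gene, sample) from the master seed, so extending the panel does not
perturb existing genes' draws.

Default design and parameters (chosen once as a realistic herbicide-response
experiment; all configurable):

* design: 2 susceptible + 2 resistant populations × treated/untreated ×
  1 h/24 h × 4 biological replicates = 64 samples, technical triplicates;
* baselines 18.8–28 cycles, matching the spread seen in real panels;
* stability noise `τ` from 0.08 (best candidate) to 0.90 cycles (worst), a
  >10× range so the designed extremes are statistically identifiable;
* loading SD `σ_L = 1.0` cycles, technical SD `σ_tech = 0.15` cycles —
  typical magnitudes for plant tissue extractions and SYBR triplicates;
* mild condition responses on three of the candidates (0.25–0.5 cycles)
  and strong responses on the two validation targets (0.8–1.5 cycles).

The generator's truth (`$truth$reference_order`) ranks genes by the burden
`τ_g + Σ|δ_g|/2` (a shift applied to half the samples contributes about
half its magnitude to observed instability).

What the generator does *not* emulate: Cq censoring at the cycle limit,
missing wells, pipetting outliers, between-run batch effects, or any
fluorescence/melting-curve level phenomena. Passing tests therefore show
that the statistics recover designed stability structure under the model's
own assumptions — not that any particular real panel is stable.

## Numerical and degenerate-input choices

* Sample SD (n−1) throughout geNorm and ΔCt; BestKeeper MAD by default as
  above.
* Technical replicates aggregate by arithmetic mean (median available);
  replicate sets with spread > 0.5 cycles (configurable) are QC-flagged,
  never dropped silently; an empty gene × sample cell is an error naming
  the cell.
* Stability analyses require complete matrices; incomplete panels must be
  resolved explicitly (drop genes or samples) before analysis.
* Cq values are validated to be finite and in (0, 45].
* Negative NormFinder variance estimates floor at 0 and are reported;
  zero-variance genes yield `NA` BestKeeper correlations.
* Exact ranking ties get average ranks for the consensus and keep
  first-occurrence order for display, with the tie groups attached.

## Problem sizes used in the tests

The oracle-equivalence suites run each statistic against an independent
literal-formula transcription on 100 random 4-gene × 6-sample matrices
(agreement to 1e−9). The Monte-Carlo suites use 100 simulated experiments
of the full default design for extreme-gene recovery, and 100 small
5-gene × 8-sample experiments for the pairwise-variation property; these
sizes give the recovery-rate estimates a standard error of ~2–3 percentage
points, adequate for the ≥90%/≥95% thresholds being tested.

## Known limitations

* Published per-method stability *values* are generally not reproducible
  without the underlying raw Cq data; the packaged fixtures carry printed
  values for order-based operations and table reproduction only.
* No confidence intervals on stability values and no significance tests
  between conditions (descriptive statistics only, as is conventional).
* No instrument-file parsing and no fluorescence-curve (LinRegPCR-style)
  efficiency estimation; input is tabular Cq plus assay metadata.
* The consensus is the geometric mean of the four in-package methods'
  ranks; it is not a re-implementation of any specific web tool.
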