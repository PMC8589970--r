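# qpcrstab

Reference-gene (housekeeping-gene) validation for RT-qPCR, with
amplification-efficiency correction.

Relative quantification of a target transcript is only as good as the
internal reference it is normalized against. Before a gene can serve as a
reference its expression must be shown to be stable across the conditions of
the experiment — and that stability assessment itself depends on whether the
quantification cycles (Cq) are first corrected for each assay's
amplification efficiency. `qpcrstab` implements the complete validation
workflow used in plant stress and herbicide-resistance studies (and any
other RT-qPCR design): technical-replicate QC, standard-curve efficiency
estimation, efficiency correction of Cq, four independent stability
statistics, a consensus ranking, the pairwise-variation decision on how many
reference genes are needed, and efficiency-weighted relative quantification
of target genes with best-vs-worst normalizer comparison.

## The statistics

All methods treat Cq as a log2-scale quantity (one cycle = one doubling at
100% efficiency; `-Cq` is log2 expression up to a constant).

- **geNorm M** — for genes *j*, *k* the per-sample log2 expression ratio is
  `A_jk = Cq_k − Cq_j`; `V_jk = SD_samples(A_jk)` and
  `M_j = mean_{k≠j} V_jk`. Lower M = more stable. Stepwise exclusion of the
  highest-M gene yields the ranking; the pairwise variation
  `V_n/n+1 = SD_samples( log2(NF_n / NF_{n+1}) )` between normalization
  factors built from the top *n* and *n+1* genes, compared against the
  conventional 0.15 cut-off, gives the number of references required.
- **BestKeeper** — per-gene descriptive statistics of Cq; "SD" is the mean
  absolute deviation from the arithmetic mean (the original tool's
  convention; sample SD available), plus each gene's Pearson correlation
  with the BestKeeper index (per-sample geometric mean of Cq).
- **NormFinder** — model-based: on sample-centred `−Cq` values, per-group
  intragroup variances are estimated with a bias correction for the shared
  centring term, intergroup differences are shrunk toward zero by their
  sampling variance, and the stability value
  `ρ = mean_groups( |d̃| + √(σ̂²/n) )` combines both components.
- **ΔCt** — mean over partner genes of `SD_samples(Cq_i − Cq_j)`.
- **Consensus** — geometric mean of each gene's (tie-averaged) ranks across
  the four methods.

Efficiency correction rescales raw cycles onto the ideal-doubling scale,
`Cq' = Cq · log2(1 + E)`, with `E = 10^(−1/slope) − 1` estimated from a
dilution-series standard curve. Running the ranking on both scales and
counting, per rank position, how often the occupying gene differs
quantifies how much an uncorrected analysis would mislead gene selection.

Relative expression uses efficiency-weighted (Pfaffl-style) quantities:
`NF` is the geometric mean of the references' `(1+E)^(ΔCq)` relative
quantities, target expression is `(1+E_t)^(ΔCq_t) / NF`, scaled so the
calibrator condition mean is exactly 1.0.

## Worked example

```r
library(qpcrstab)

# a synthetic experiment: 2 susceptible + 2 resistant populations,
# treated/untreated, 1 h / 24 h, 4 bioreps, technical triplicates,
# 11 candidate references of heterogeneous stability + 2 targets
sim <- simulate_cq_dataset(simulation_config(seed = 42))
refs <- sim$truth$config$reference_genes
cq   <- subset_genes(sim$cq, refs)

res <- run_stability(cq, sim$annotations, sim$assays, scale = "both")
res
#> <stability_analysis>
#>   raw consensus (all samples): TBP, GAPC, SPS, ...
#>   efficiency_corrected consensus (all samples): TBP, GAPC, ACT, ...
#>   geNorm: 6/33 positions changed (18%)
#>   BestKeeper: 23/33 positions changed (70%)
#>   NormFinder: 10/33 positions changed (30%)
#>   DeltaCt: 6/33 positions changed (18%)
#>   Consensus: 13/33 positions changed (39%)

head(as.data.frame(res$rankings$efficiency_corrected$all$Consensus), 4)
#>    gene    value rank
#> 1   TBP 1.000000    1
#> 2  GAPC 2.735565    2
#> 3   ACT 3.363586    3
#> 4 CYP28 3.408658    4

round(res$pairwise_variation$efficiency_corrected$all[1:3], 4)
#>   V2/3   V3/4   V4/5
#> 0.0666 0.0488 0.0507
optimal_reference_count(res$pairwise_variation$efficiency_corrected$all)$n
#> [1] 2
```

The consensus picks out the genes simulated with the smallest stability
noise (`TBP`, `GAPC` in the default configuration), the rank-change report
shows how strongly each method reacts to efficiency correction on this
dataset, and `V2/3 < 0.15` says two reference genes suffice — the loading
variation shared by all genes is already captured by the two most stable
candidates.

Target-gene validation against chosen normalizer sets:

```r
agg <- aggregate_technical_replicates(sim$cq)
val <- run_validation(agg, sim$annotations, sim$assays,
                      targets = c("ABCC10", "CYP89A2"),
                      normalizer_sets = list(best  = c("TBP",  "GAPC"),
                                             worst = c("EF1A", "UBQ")),
                      calibrator = list(population_class = "susceptible",
                                        treatment = "untreated",
                                        timepoint = "1h"))
val$targets$CYP89A2$discordance$`best vs worst`
```

Published ranking tables (five methods x three datasets x two scales) and
assay metadata ship as plain-text fixtures:

```r
fx <- load_paper_fixtures()
fixture_ranking(fx, "BestKeeper", "all", "raw")[1:3, ]
efficiency_range(fx$assays)
```

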