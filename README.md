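# prc2suite

Tools for analyzing the interplay between cell proliferation and Polycomb
repressive complex 2 (PRC2) activity in cancer genomics data.

A recurring confound in tumor transcriptomics is that the catalytic PRC2
subunit *EZH2* is itself a proliferation-regulated transcript: its raw
expression tracks how fast tumors divide, so it looks like a marker of poor
prognosis even if the repressive activity it provides is protective.
`prc2suite` implements the analysis toolkit needed to disentangle this:

* **Proliferation-adjusted prognosis.** A proliferation *metagene*
  \(P_s = \mathrm{median}_{g \in G_{prolif}} x_{g,s}\) summarizes each
  sample's proliferative state; the marker is residualized by OLS,
  \(r_s = x_s - (\hat\beta_0 + \hat\beta_1 P_s)\), and both raw and adjusted
  values are evaluated with a from-scratch survival suite: Kaplan–Meier
  product-limit curves, the log-rank test (HR by the O/E method), univariate
  Cox regression (Newton–Raphson on the partial likelihood, Efron or Breslow
  ties), rank-based ROC AUC, and a per-gene copy-number-loss Cox scan with
  Benjamini–Hochberg FDR (default threshold 0.15).
* **H3K27me3 homeostasis kinetics.** The repressive mark is modeled as a
  site-occupancy fraction obeying
  \(dm/dt = \alpha E (1-m) - \delta m - g\ln 2\, m\), where enzyme-dependent
  deposition (\(\alpha E\)) opposes turnover (\(\delta\)) and
  cell-division dilution (\(g \ln 2\)); steady state
  \(m^* = \alpha E/(\alpha E + \delta + g\ln 2)\). A discrete variant halves
  the mark at each division. When enzyme is proportionally coupled to growth
  (\(E = c_1 g\), \(\delta = 0\)), \(m^*\) is growth-independent —
  homeostasis; with fixed or under-coupled enzyme it declines with growth.
* **PRC2 target classification.** Promoter H3K27me3 enrichment from bedGraph
  coverage (fold over background and over knockout), a rank-product
  differential test with permutation pfp, and the responsive / indirect /
  nonresponsive partition, plus early/late timing and rescue calls from
  expression time courses.
* **Single-cell derepression.** Genotype/dye consistency filtering,
  per-genotype detection frequencies, and a variance-ratio concordance
  statistic \(S = 1 - \overline{f_c(1-f_c)} / [\bar f(1-\bar f)(1-1/|G|)]\)
  with a permutation null, separating deterministic ("all or none") from
  stochastic (combinatorial) activation of a gene panel.
* **Synthetic data.** Seeded generators emulate every input — a ~2000-tumor
  cohort with copy-number states and right-censored disease-specific
  survival, growth/enzyme/mark triplets, promoter signal + time courses with
  planted target classes, and a genes × cells single-cell panel — so the
  entire pipeline is testable without controlled-access data.

## Worked example

```r
library(prc2suite)

co  <- generate_cohort(cohort_config(seed = 1))   # 2000 tumors, 150 genes
res <- marker_prognosis(co$expr, co$clinical, "EZH2", co$prolif_genes)
```

The defaults plant the confounded structure: the marker loads on the latent
proliferation factor (which increases hazard) while its
proliferation-independent component is protective. The median-split results:

```
raw:      HR(high vs low) = 1.74, log-rank p = 1.57e-20, AUC = 0.631
adjusted: HR(high vs low) = 0.62, log-rank p = 1.26e-15, AUC = 0.401
```

Raw marker expression predicts *worse* outcome (HR > 1) purely through its
proliferation component; after metagene adjustment the direction inverts
(HR < 1): low marker relative to proliferation is the bad-prognosis state.
Stratifying by the marker's copy-number state shows the same thing
genetically — hemizygous loss is deleterious, gain is protective:

```r
grp <- stratify_by_cnv(co$cnv[co$clinical$sample_id, "EZH2"])
logrank_test(co$clinical$time, co$clinical$event, grp)
#> Log-rank test: 3 groups
#>         observed  expected
#> loss         243 173.06137
#> neutral      814 841.95390
#> gain          53  94.98473
#> chisq = 47.9 on 2 df, p = 3.977e-11
```

The kinetic side of the same biology: with enzyme proportionally coupled to
growth the steady-state mark is constant, while an under-coupled
("knockdown") enzyme loses the mark as growth accelerates:

```r
steady_state_mark(mark_kinetics_params(alpha = 0.01, delta = 0, g = 0.03,
                                       c0 = 0, c1 = 100))
#> [1] 0.5906161   # and identical at any other g

sweep_growth_rates(0.01, 0, c0 = 0.2, c1 = 30, c(0.01, 0.03, 0.05))
#>      g   E    m_star
#> 1 0.01 0.5 0.4190598
#> 2 0.03 1.1 0.3459727
#> 3 0.05 1.7 0.3290915
```

## Command line

Every stage is reachable through `run_pipeline()` or the wrapper script
`inst/cli/prc2suite.R`, with subcommands `simulate-cohort`,
`simulate-growth`, `simulate-targets`, `simulate-cells`, `prognosis`,
`scan`, `homeostasis`, `targets` and `singlecell`; each run writes its
results plus a `provenance.json` (inputs, parameters, seed, version).

```sh
Rscript inst/cli/prc2suite.R simulate-cohort --seed 42 --out cohort/
Rscript inst/cli/prc2suite.R prognosis --expr cohort/expression.tsv \
    --clinical cohort/clinical.tsv --geneset cohort/geneset.txt \
    --cnv cohort/cnv.tsv --marker EZH2 --out results/
```

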