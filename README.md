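# gopredict

How well does transcript expression predict protein expression — and for
which kinds of genes?

In paired bulk transcriptomic (RNA-Seq) / proteomic (LC-MS/MS) data from
adult primate brain, the genome-wide coupling between transcript and
protein log-abundance is notoriously weak: ordinary least squares of
protein on transcript explains only a few percent of the variance. Yet the
coupling is not uniform — categories of genes that share a function or a
cellular location (Gene Ontology terms) can be far more predictive than
the genome-wide baseline. `gopredict` is an R package for researchers who
integrate transcriptomes and proteomes and need to know *when* a
transcript-level result licenses a protein-level conclusion.

## What it computes

For each GO category $c$ with at least 10 complete transcript/protein
pairs, the package fits

$$y_g = \beta_0 + \beta_1 x_g + \varepsilon_g, \qquad g \in c,$$

with $x$ the mean transcript log-expression and $y$ the mean protein
log-expression, and reports $n_c$, $R^2$, the slope $t$-test $p$, and 95%
confidence intervals for slope and intercept. Around that core it
provides:

* **duplicate-category removal** — terms with exactly identical member
  sets keep one representative;
* **a size-matched permutation null** — pseudo-categories of resampled
  observed sizes filled with randomly re-paired transcripts and proteins
  (1000 iterations by default); under independence the null $R^2$ at size
  $n$ is $\mathrm{Beta}(1/2,(n-2)/2)$ with mean $1/(n-1)$, and the
  package's null is validated against that law;
* **distribution diagnostics** per aspect (mean, SD, median, range,
  Shapiro–Wilk, skewness, cumulative curves) and pairwise Mann–Whitney
  comparisons between aspects;
* **covariate screens** — Spearman correlations of category $R^2$ with
  category size (with <20 / ≥20 strata), mean molecular abundance, mean
  gene length, and mean synthesis/degradation rates, plus a four-covariate
  stability multiple regression;
* **cross-condition concordance** — slope-CI overlap, Spearman rank
  concordance of $R^2$, and a scaled rank-change score
  $|\Delta\text{rank}|/n_\text{terms}\times 100$ between species or brain
  regions;
* **a synthetic-data generator** with analytically known ground truth
  (population slope and $R^2$ for every category, including overlapping
  membership), so the entire pipeline is testable without any external
  download.

## A worked example

Simulate a study-shaped dataset (815 gene pairs, 28 overlapping categories
across the three GO aspects, genome-wide population $R^2 = 0.07$) and run
the full analysis:

```r
library(gopredict)
cfg <- synthetic_config(seed = 1)
res <- run_synthetic(cfg, out_dir = "gopredict_demo", n_iterations = 1000)

round(res$overall$r2, 3)
#> [1] 0.085
```

The genome-wide fit explains ~8.5% of protein variance — weak coupling, as
configured (0.07 in population; 815 pairs leave visible sampling error).
Per-aspect descriptive statistics over the per-category $R^2$ values:

```r
print(res$summaries, digits = 2)
#>               aspect n_categories  mean    sd median     min   max shapiro_w shapiro_p skewness
#> 1 biological_process           14 0.188 0.202  0.126 7.1e-05 0.652      0.85     0.020      1.3
#> 2 cellular_component            6 0.028 0.036  0.017 1.3e-04 0.095      0.83     0.102      1.6
#> 3 molecular_function            8 0.250 0.255  0.158 1.5e-02 0.765      0.82     0.046      1.5
```

All three aspects are right-skewed: most categories sit near the weak
median, a minority are far more predictive. The size-matched permutation
null shows what random gene-identity-free pairing produces:

```r
print(res$null_tests, digits = 2)
#>               aspect null_mean null_sd null_median null_skewness   mw_u   mw_p size_rho size_rho_p
#> 1 biological_process     0.058   0.088       0.023           2.9 142911 0.0030    -0.31   1.3e-317
#> 2 cellular_component     0.067   0.094       0.029           2.4  13372 0.2756    -0.25    7.5e-86
#> 3 molecular_function     0.060   0.087       0.025           2.6  53117 0.0012    -0.29   1.6e-155
```

Null $R^2$ is small on average (mean ≈ 0.06, median ≈ 0.02), strongly
right-skewed, and declines with pseudo-category size (negative Spearman
rho) — small random categories produce inflated $R^2$, which is exactly why
the null is size-matched. Observed categories sit significantly above the
null for two aspects (Mann–Whitney $p < 0.01$). Categories exceeding the
null mean by 4 null standard deviations are flagged as genuinely
predictive:

```r
print(res$flagged[, c("term_id", "aspect", "n", "r2", "threshold")], digits = 2)
#>      term_id             aspect  n   r2 threshold
#> 1 GO:0000002 biological_process 11 0.65      0.41
#> 2 GO:0000001 biological_process 10 0.53      0.41
#> 3 GO:0000015 molecular_function 10 0.77      0.41
#> 4 GO:0000016 molecular_function 12 0.50      0.41
```

Because the data are synthetic, `res$recovery` compares every estimate to
its generating truth (the flagged terms are exactly the high-truth
categories), and `res$coupling_recovery` does the same for the covariate
couplings. Real data enter through `read_expression()`,
`read_annotations()` (GAF 2.x or two-column) and `read_covariates()`, and
`run_full()` runs the identical analysis from a `pipeline_config()`.

All tables are written tab-delimited to `out_dir` together with a
`manifest.json` recording the seed, configuration checksum, and row counts
at every filtering step.

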