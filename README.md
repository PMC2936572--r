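# debench — spike-in benchmarks for differential expression pipelines

`debench` builds ground-truth benchmarks for differential gene expression
(DE) analysis and uses them to score any normalization + DE-method
combination. It is aimed at analysts who must choose among preprocessing
and testing pipelines for microarray-like intensity data (bulk or
single-cell expression matrices of non-negative intensities) and want a
quantitative, reproducible basis for the choice.

## The method

Start from a *homogeneous* group of samples — arrays between which no real
biological differences are expected. Sort genes by average expression,
split the samples into equal **control** and **experimental** subgroups,
and inject controlled fold changes into the experimental subgroup: within
every block of 1,000 genes (the top block sub-divided into five 200-gene
blocks), a fraction of genes is multiplied by the fold `Fd` and an equal
fraction divided by it. The injected genes are the *AP* (all-positive)
set, everything else *AN* (all-negative), so any pipeline's selections can
be scored exactly:

    Sensitivity = TP / (TP + FN)
    Specificity = TN / (TN + FP)
    Precision   = TP / (TP + FP)

with Precision preferred over Specificity because AN-genes vastly
outnumber AP-genes. Repeating the split with fresh sample permutations
gives mean ± SD for every metric, overall and within 20 expression-level
blocks along the sorted data.

The package ships the full pipeline:

* **Synthetic cohort generator** — microarray-like matrices with a normal
  background cohort, a lognormal expressed cohort, hypervariable genes and
  per-array linear distortions, so everything is testable without
  downloads (`simulate_matrix()`).
* **Benchmark construction** — `sort_by_mean()`, `split_group()`,
  `inject_changes()`, `make_benchmark()`, `replicate_benchmarks()`.
* **Two-step internal-standard normalization** — per-array iterative
  trimmed-normal background fit, transformation to background-SD units,
  then robust-regression adjustment onto the median profile
  (`two_step_normalize()`); `quantile` and `lowess` comparators and a
  plugin registry for external methods.
* **Associative analysis** — low-variability reference group by F-test,
  Student filter at p < 0.05, associative t-test of each gene's residuals
  against the pooled reference residuals with a Bonferroni-corrected
  threshold, plus fold (`Fa`) and expression-level (`Em`) restrictions
  (`associative_analysis()`); a Welch+BH baseline for comparison.
* **Evaluation** — confusion accounting against the truth, block-wise
  metric profiles, repeat evaluation (`evaluate_repeats()`) and
  replicate-number power analysis (`power_analysis()`).

## Worked example

```r
library(debench)

# a homogeneous 20,000-gene x 20-sample cohort
m <- simulate_homogeneous_group(sim_config(seed = 1))

# benchmark: 2-fold balanced changes in 20% of genes, restrictions
# Fd/Fa/Em = 2/1.5/20, three random-split repeats
ev <- evaluate_repeats(m, injection_design(Fd = 2, fraction = 0.20),
                       normalizer = "two_step", de_method = "associative",
                       restrictions = analysis_restrictions(Fa = 1.5, Em = 20),
                       n_repeats = 3, base_seed = 1)
ev
#> <repeat_evaluation> two_step + associative, 3 repeats
#>   sensitivity 0.995 +/- 0.003   precision 0.997 +/- 0.001

head(ev$blocks[, c("label", "sensitivity_mean", "sensitivity_sd", "precision_mean")], 4)
#>    label sensitivity_mean sensitivity_sd precision_mean
#> 1 95-100        0.9933333    0.005773503      0.9983416
#> 2  90-95        0.9950000    0.005000000      0.9966750
#> 3  85-90        1.0000000    0.000000000      0.9983416
#> 4  80-85        0.9950000    0.005000000      1.0000000
```

The overall line says that, averaged over three random splits, the
two-step + associative chain recovered 99.5% of the injected changes among
the genes within the analysis's expression range, and 99.7% of everything
it selected was a real injected change. The block rows resolve the same
metrics along the expression range ("95-100" is the top 5% of genes by
mean expression). Swapping `normalizer = "lowess"` and an asymmetric
design (`mode = "asymmetric_up"`) reproduces the classic trend-removal
pathology — one-directional changes are partially normalized away and
sensitivity drops.

The same chain is scriptable from a shell:

```sh
Rscript inst/cli/debench.R simulate --n-genes 20000 --n-samples 20 --seed 1 --out matrix.tsv
Rscript inst/cli/debench.R evaluate --matrix matrix.tsv --fd 2 --fraction 0.2 \
    --fa 1.5 --em 20 --repeats 3 --seed 1 --out report.json
```

Subcommands: `simulate`, `inject`, `normalize`, `analyze`, `evaluate`,
`power`, `compare`; each echoes its effective configuration so any run is
reproducible from its log.

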