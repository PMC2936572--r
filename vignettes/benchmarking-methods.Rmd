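---
title: "Constructing and scoring spike-in benchmarks for differential expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constructing and scoring spike-in benchmarks for differential expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The idea

Comparing differential-expression (DE) pipelines is hard because real
experiments come without ground truth. `debench` manufactures that truth
from a *homogeneous* group of arrays: the samples are sorted by average
expression, split into equal "control" and "experimental" subgroups, and
controlled fold changes are multiplied into a known fraction of the
experimental subgroup's genes. Every gene is then either an injected change
(with known direction and fold) or untouched, so any normalization + DE
combination can be scored exactly:

* **Sensitivity** = TP / (TP + FN) — the fraction of injected changes found;
* **Specificity** = TN / (TN + FP);
* **Precision** = TP / (TP + FP) — the fraction of reported changes that are
  real. Precision replaces Specificity as the headline complement of
  Sensitivity because unmodified genes outnumber modified ones several-fold,
  which pins Specificity near 1 regardless of performance.

Because the injection is applied to real (or realistically simulated) raw
intensities, the benchmark inherits the data's full covariance structure —
the property that distinguishes this design from purely model-based
simulation.

# The injection design

Genes are sorted by mean expression and partitioned into consecutive blocks
of `block_size` (default 1000) genes. In the default *balanced* mode,
`fraction/2` of each block's genes are multiplied by the fold `Fd` across
all experimental samples and a disjoint `fraction/2` are divided by `Fd`.
The top block — which spans the widest dynamic range — is sub-partitioned
into blocks of `top_block_split` (default 200) genes treated the same way,
so performance at the highest expression levels is probed in finer detail.
With the default `fraction = 0.20` on 20,000 genes this yields exactly
2,000 up + 2,000 down labels: 100 + 100 per ordinary block and 20 + 20 per
top sub-block.

Placement within a block defaults to `top_of_block` (the highest-mean genes
take the up labels, the next tier the down labels), which is deterministic
and reproducible; a seeded `random` placement is available. An
`asymmetric_up` mode multiplies only — the configuration that famously
breaks rank- and trend-based normalizations — and a `custom` mode takes
separate up/down fractions and folds (e.g. 4-fold up in 10% plus 2-fold
down in another 10%).

Stability is estimated by repeating the whole procedure with fresh random
permutations of the sample order before each split (default 3 repeats) and
reporting mean ± SD of each metric.

# Two-step normalization

The package's house normalization rests on two *internal standards* —
large gene families that behave homogeneously and therefore estimate
technical parameters robustly.

**Step one** fits the background cohort of each array: non-expressed genes
whose intensities form an approximately normal noise distribution. The
published description of the fit is only "a special iteration procedure",
so the implementation is the simplest scheme satisfying the stated
contract: start from the lower half of the sorted intensities, iterate
{estimate mean `Av` and SD; re-admit every value within `Av ± 3·SD`} until
the parameters move by less than 1e-6 relatively (cap 100 iterations). The
raw SD of a ±3-SD-trimmed normal sample underestimates the true SD by the
closed-form factor ≈ 0.98658, which is corrected at every iteration; a
pure normal sample is therefore recovered unbiasedly. Each array is then
transformed `x → (x − Av)/SD`, putting all arrays in *background-SD units*
with the background at mean 0, SD 1. Genes whose mean exceeds 3 (i.e. 3 SD
above background) are called expressed.

**Step two** adjusts the standardized profiles onto a common scale by
robust linear regression against a reference profile. Each array is
regressed (ordinary least squares) on the reference over the current
"equally expressed" set — initialized to all expressed genes — and genes
with residuals beyond 3 residual-SDs are trimmed until membership
stabilizes, the same trimming constant as step one. The fitted line is then
inverted for *all* genes. Two genuinely open choices were resolved as
follows: the reference is the gene-wise **median profile** of the
standardized arrays (symmetric and robust, rather than privileging one
array), and the expressed mask is recomputed on the standardized data
before the fit. Adjusted values may be negative; no flooring is applied,
since the downstream expression restriction handles low values.

Comparators `quantile` (standard rank-mean method, via
`limma::normalizeQuantiles`) and `lowess` (MA-trend removal against the
median profile, span 0.3, pseudo-count 1 for zeros) are built in; any
external method (e.g. VSN) can be attached through `register_normalizer()`.
The lowess span and median-reference design are comparator choices, not
claims about any particular historical pipeline.

# Associative analysis

The house DE method works in background-SD units on the normalized
matrices:

1. **Reference group.** Among expressed genes of the control subgroup, each
   gene's residual variance (deviations from its own control mean) is
   compared by F-ratio against an estimate of the purely technological
   variance; genes below the critical value at `alpha_F` (default 0.05)
   are admitted and their residuals pooled. The technological-variance
   anchor is the median variance of the lowest-variance quartile, divided
   by the matching quantile of the null `chi²(n−1)/(n−1)` distribution so
   that an all-equal-variance null admits ≈ `1 − alpha_F` of genes. The
   anchor choice matters: an uncalibrated low-quartile median is biased low
   and would silently halve the reference group.
2. **Student filter.** Per gene, a classical equal-variance two-sample
   t-test, control vs experimental, at `alpha_student = 0.05`. (Welch is
   reserved for the `ttest_bh` baseline.) Degenerate zero-variance rows
   yield p = 1 for equal means and p = 0 otherwise.
3. **Associative t-test.** The gene's n experimental residuals (deviations
   from the control mean profile) are tested against the N pooled reference
   residuals with the standard pooled-variance two-sample t
   (df = n + N − 2). The threshold is Bonferroni-corrected,
   `alpha_assoc / #genes tested` — the simplest family-wise control that
   makes false positives "improbable".
4. **Restrictions.** A gene is finally selected iff it passes both tests,
   its fold is at least `Fa`, and the larger group mean is at least `Em`.
   Fold is computed as max(mean)/min(mean) with both means floored at 1
   background-SD unit, because ratios with a sub-noise denominator are
   meaningless; `Em` applies to the *larger* group mean so that a change
   collapsing a gene's expression is still assessable. Defaults
   `Fa = 1.5`, `Em = 20` are the benchmark's standard working point for
   `Fd = 2`.

`exclude_hypervariable()` flags genes whose pooled within-group variance
exceeds the technological anchor by more than the F critical value; the
mask can be passed to `associative_analysis()` and the evaluators to drop
such genes from both selection and denominator. On strongly
heteroscedastic data this F-criterion is blunt — absolute variance grows
with expression, so much of the top range is flagged — which is why it is
off by default.

# The evaluation universe

`confusion()` scores the full gene list by default. The evaluation drivers
(`evaluate_repeats()`, `power_analysis()`), however, restrict the universe
to genes meeting the expression restriction (larger group mean ≥ `Em`,
`restrict_to_em = TRUE`). The reasoning: genes below `Em` can never be
selected, whatever the data say — they are out of the analysis's declared
reach, not misses. Scoring them as false negatives would make Sensitivity
an arbitrary function of how much of the array sits near background (half
of it, under the generator's defaults), and would make Sensitivity
*insensitive* to `Em` itself. Under the restricted universe, lowering `Em`
admits noisy near-background genes that the Student filter rightly rejects
and Sensitivity falls — the behaviour this class of benchmark actually
exhibits — while Precision is unaffected by the choice (every selected
gene is above `Em` either way). Set `restrict_to_em = FALSE` for the
whole-array accounting; both the eligible and excluded counts are always
reported.

A selected modified gene with the wrong direction is counted as a miss
*and*, under the default strict convention, as a false positive; a lenient
mode (`direction_strict = FALSE`) is available for direction-blind
external methods.

# The synthetic generator

`simulate_matrix()` emulates a homogeneous single-channel bead-array
cohort: for gene g and array s,

```
value = scale_s · abundance_g · (1 + bio_gs) + offset_s + bg_gs
```

with `abundance = 0` for background genes (their signal is pure
`N(bg_mean, bg_sd)` noise), lognormal abundance for expressed genes,
per-gene multiplicative biological noise, and per-array linear distortions.
Negative draws are clipped at 0, mirroring scanner output; the clipped
fraction is recorded and is ~1e-4 at the defaults.

Defaults, chosen once as a realistic raw-intensity scale: background
`N(100, 15)`; half the genes expressed with `meanlog = log(1000)`,
`sdlog = 1.3` (detected intensities spanning roughly 20–50,000, i.e. a
median ~70 background-SDs); biological CV 0.1; 1% of genes hypervariable
at CV 0.6 (a fraction of *all* genes, drawn from the expressed cohort);
array scale sdlog 0.1 and offset SD 10. The hypervariable tail and the
per-array distortions are the two features deliberately kept, because they
are what normalization and outlier handling exist for.

What the generator does *not* emulate: probe-level effects, spatial
artifacts, saturation, batch structure beyond per-array affine distortion,
and correlated gene modules. Passing benchmarks on synthetic data
therefore demonstrates correctness of the machinery and the qualitative
orderings (fold monotonicity, replicate power, trend-normalization
pathologies), not field performance on any particular platform. One
consequence of the clean noise model is that absolute Sensitivity and
Precision on synthetic benchmarks run higher than on real arrays, whose
heavier outlier structure caps Sensitivity well below 1.

A known, deliberate behaviour: with the hypervariable tail present, an
unmodified exchangeable split still produces a few (typically 2–8)
selections, all from hypervariable genes — they occasionally pass the
Student filter by chance and then sail through the associative test, whose
pooled variance is dominated by the quiet reference pool. This mirrors the
extreme-variability pathology reported for real data; enabling
`exclude_hypervariable()` empties the null selection entirely. The
package keeps exclusion opt-in rather than silently absorbing it into the
default pipeline.

# Numerical choices and degenerate inputs

* Sorting is stable (ties keep input order); all alignment is checked by
  gene-identifier equality, never by position alone.
* Injection uses exact floating multiply/divide; un-injection restores the
  input to ≤ 1 ulp.
* Background fits with fewer than 50 members, zero spread, anti-correlated
  arrays (slope ≤ 0), or fewer than 30 equally expressed genes raise
  errors rather than limping on.
* Matrices are rejected on missing/non-finite values and duplicate
  identifiers; text round trips preserve 12+ significant digits.
* 0/0 metric ratios are reported as `NA`, never 0 or 1.

# Problem sizes

The benchmark's reference configuration is 20,000 genes × 20 arrays with
3 permutation repeats, which the evaluation drivers process in seconds;
the test suite exercises the full configuration for the headline
properties and 2,000–8,000-gene cohorts for module-level checks, sizes
chosen to keep the suite quick while leaving every code path covered.
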