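---
title: "Comparing two Poisson means for RNA-seq differential expression"
author: "poisdeg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing two Poisson means for RNA-seq differential expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poisdeg)
```

## The model

RNA-seq quantifies a gene's expression by the number of short reads mapped
to it. When the replicates are technical (repeated lanes of the same
library), the read count of gene $g$ on lane $j$ of condition $i$ is well
described as an independent Poisson draw,
$X_{ij} \sim \mathrm{Poisson}(\lambda_i)$, with a gene-specific per-lane
rate per condition. Calling a differentially expressed gene (DEG) then
reduces to testing $H_0: \lambda_1 = \lambda_2$ from the two sets of lane
counts. Because all six statistics implemented here depend on the data only
through the condition sums $S_i = \sum_j X_{ij}$ (sufficient statistics for
Poisson rates), genes with low expression — small sums — are exactly the
regime where the tests disagree and where the choice of test matters; for
large rates all six are asymptotically equivalent.

The package does **not** model biological replicates: those introduce
extra-Poisson variance, for which over-dispersed or negative-binomial
models (e.g. edgeR, DESeq2) are the right tool. With technical replicates
and a Poisson likelihood, the estimated standard error used by the
log-fold-change test below would be too small under over-dispersion, and
its type-I error would inflate; that caveat bounds the package's scope.

## The six tests

With $n_1, n_2$ lanes per condition, $\hat\lambda_i = S_i/n_i$ and pooled
rate $\hat\lambda_0 = (S_1+S_2)/(n_1+n_2)$:

* **LRT** (`lrt_test`): the deviance
  $T = 2[S_1\log(\hat\lambda_1/\hat\lambda_0) +
        S_2\log(\hat\lambda_2/\hat\lambda_0)]$,
  asymptotically $\chi^2_1$; upper-tail p-value. (The mean-difference
  terms of the full deviance cancel identically because
  $\hat\lambda_0$ is the pooled average.)
* **Conditional binomial** (`cond_binom_test`): conditional on
  $k = S_1+S_2$, $S_1 \sim \mathrm{Bin}(k, p)$ with
  $p = n_1\lambda_1/(n_1\lambda_1 + n_2\lambda_2)$, so under $H_0$,
  $p_0 = n_1/(n_1+n_2)$ and the p-value is exact — no asymptotics.
* **Wald** (`wald_test`):
  $T = (S_1 - \tfrac{n_1}{n_2}S_2)\big/\sqrt{\tfrac{n_1}{n_2}(S_1+S_2)}$,
  asymptotically standard normal.
* **Wald-Log** (`wald_log_test`): the Wald test after log transformation,
  derived by the delta method:
  $T = \log(\mathrm{FC}) \big/
       \sqrt{(2 + n_1/n_2 + n_2/n_1)/(S_1+S_2)}$
  with $\mathrm{FC} = \hat\lambda_1/\hat\lambda_2$. The denominator is the
  estimated standard error of the log fold change, which ties statistical
  significance directly to the quantity biologists screen on.
* **VST** (`vst_test`): $\sqrt{S + 3/8}$ has approximately constant
  variance $1/4$ for Poisson $S$ (the Anscombe square-root transform), so
  $T = 2[\sqrt{S_1+3/8} - \sqrt{(S_2+3/8)\,n_1/n_2}]\big/\sqrt{1+n_1/n_2}$
  is asymptotically standard normal.
* **Fisher** (`fisher_lane_test`): the exact test on the $2\times 2$ table
  whose rows are $(S_i,\ M_i - S_i)$, with $M_i$ the summed lane totals of
  condition $i$; conditionally on the margins $S_1$ is hypergeometric.

```{r worked}
run_all_tests(20, 5, totals1 = 1e6, totals2 = 1e6)
```

### Two-sidedness and exact-test conventions

All p-values are two-sided: the chi-square upper tail for the LRT,
$2\Phi(-|T|)$ for the three normal statistics, and the
**minimum-likelihood** rule for the two exact tests — the sum of null
probabilities of every outcome no more probable than the observed one.
The minimum-likelihood default makes the conditional and Fisher columns of
the power study coincide (see below); a doubled-smaller-tail rule is
available via `method = "doubled_tail"`. Point probabilities are compared
with a $1 + 10^{-7}$ relative slack so floating-point noise cannot split
exact ties (the same convention as `binom.test` and `fisher.test`, which
the test suite uses as independent oracles).

### Degenerate inputs

Zero condition sums are handled deterministically and conservatively:
whenever a statistic is undefined — $\log(\mathrm{FC})$ with $S_1 = 0$ or
$S_2 = 0$ for Wald-Log, a zero denominator with $S_1+S_2 = 0$ for Wald, or
$k = 0$ for the conditional test — the statistic is `NA`, the p-value is 1
(never reject) and a note is set. At per-lane rates $\lambda \ge 10$ a
zero sum has probability below $5\times 10^{-5}$ per sample, so the
convention cannot visibly move the power estimates; at very small rates it
makes Wald-Log conservative by construction. An optional
`zero_correction = "pseudo"` mode adds half a count to both sums instead,
for users who prefer a finite score to a non-rejection. The VST statistic
needs no convention: its $3/8$ anchor keeps it defined at zero counts.

### The fold-change connection

The Wald-Log denominator generalizes: raising the variance term to the
$1/k$ power (argument `exponent_k`, default 2) interpolates between the
Wald-Log test and, as $k \to \infty$ (denominator $\to 1$), the plain
log-fold-change ranking criterion. For `exponent_k != 2` there is no
reference distribution, so the statistic is returned as a ranking score
with an `NA` p-value. (This exponent is unrelated to the conditioning
total $k = S_1+S_2$; the argument is named `exponent_k` to avoid the
collision.)

## The Monte-Carlo size/power study

`simulate_cell()` draws `runs` datasets from a fully specified design,
applies every requested test to the same draw (common random numbers,
which sharpens between-method comparisons), and counts rejections under
the strict rule $p < \alpha$. Strictness matters with exact tests: at
$\alpha = 10^{-3}$ the event $p = \alpha$ has positive probability, and
the strict rule is what makes the exact tests visibly conservative at
small means. The protocol defaults — $\alpha = 10^{-3}$ (reflecting
many-gene screens, where only stringent p-values survive) and 10,000 runs
per setting — give a Monte-Carlo standard error of at most
$\sqrt{0.25/10^4} = 0.005$ per estimate, reported as `mc_stderr`.

`reference_grid()` holds the benchmark settings: first-condition means 5,
10, 15 and 30 with equal (size) or larger (power) second means — 27
settings for single-lane conditions, 22 for three lanes per condition.
The full double grid at 10,000 runs completes in a few seconds.

```{r power, eval = FALSE}
res <- run_grid(reference_grid(1), runs = 10000, seed = 1)
res
```

Two design choices deserve a note:

* **Seeding.** `run_grid()` derives one deterministic sub-seed per cell by
  mixing the master seed with the cell coordinates, so adding or removing
  grid cells never shifts another cell's random stream and any cell can be
  reproduced in isolation.
* **Fisher lane totals.** The simulation generates gene counts only, so
  the Fisher $2\times 2$ table is built with a large per-lane total
  (default $10^6$, i.e. $10^6 n_i$ per condition — sequencing scale). In
  that large-margin regime the hypergeometric converges to
  $\mathrm{Bin}(k, n_1/(n_1+n_2))$ and the Fisher column reproduces the
  conditional-binomial column, which is exactly how the two exact tests
  behave on real data where a gene is a negligible fraction of a lane's
  reads.

The study's qualitative outcome, asserted cell-wise by the acceptance
tests: Wald-Log is the most powerful method at small means, followed by
the LRT and VST (near-identical), then Wald, with the two exact tests
most conservative — and Wald-Log buys its power with a visibly inflated
type-I error at very small means ($\lambda = 5$, no replicates), becoming
well calibrated for $\lambda \ge 10$.

## The gene-wise pipeline

`test_genes()` applies the vectorised kernels to every gene's condition
sums and reports fold changes (condition 1 over condition 2, with
$|\log_2 \mathrm{FC}|$ alongside), per-method statistics, p-values and
$-\log_{10} p$. Two expression filters mirror standard screening
practice:

* `filter_min_total()` keeps genes with at least `min_total` (default 5)
  reads in *each* condition. The per-condition reading (rather than
  pooled) is deliberate: with five lanes it means an average of one read
  per lane in both samples, and a gene absent from one condition entirely
  is better handled by the tests themselves than silently kept by a
  pooled threshold. A `scope = "pooled"` mode is available.
* `filter_low_expression()` keeps genes whose per-lane average lies in
  the closed interval `[lo, hi]` (default `[1, 10]`) in each condition —
  the low-expression stratum where method choice matters.

DEG counting (`count_degs`) uses raw p-values at fixed cutoffs
($10^{-3}$ down to $10^{-6}$ by default) with the same strict rule as the
simulation; no multiple-testing correction is applied by default because
the screen is calibrated by cutoff, but `adjust = TRUE` adds
Benjamini–Hochberg columns. `global_rescale()` implements global scale
normalization (equalizing lane totals, rounding to keep counts integral
for the exact tests) and is off by default: the Poisson model is stated
on raw counts, and rescaled counts are no longer exactly Poisson.
Per-gene Fisher tables use the column sums of the current matrix by
default (`fisher_totals = "column_sums"`); supplied sequencer totals can
be used instead.

## The synthetic generator

`synth_matrix()` emulates the data-generating process the tests assume:
independent Poisson lane counts with gene-specific base means, a fraction
`deg_fraction` of genes elevated by `fold_change` in one randomly chosen
condition, and ground-truth labels returned alongside. The defaults are
the package's study conditions, chosen once: five lanes per condition
(a typical technical-replicate design), base means uniform on $[1, 10]$
(the low-expression stratum), and 10% true DEGs at fold change 3 — a
moderate effect size, squarely in the range where the tests disagree
rather than all succeeding or all failing.

What the generator deliberately does **not** emulate — and hence what
passing tests on it cannot show: over-dispersion from biological
replication, gene-length effects on counts, correlated genes, and
library-composition artefacts. Results on synthetic matrices validate
the *mechanics* (filters, per-gene testing, counting) and the internal
consistency of the pipeline with the Monte-Carlo engine; they are not
evidence about real tissue comparisons, whose published gene counts
depend on the actual dataset.

## Numerical choices

* Natural logarithms throughout the statistics; $\log_2$ only in
  fold-change reporting, where it is the field's display convention.
* Exact-test enumeration is grouped by the conditioning total, so a
  10,000-run cell costs one enumeration per distinct $k$ rather than per
  run; the hypergeometric support has at most $k+1$ points even with
  $10^6$-read margins, so "exact" never means "slow".
* The LRT statistic is clamped at 0 against floating-point underflow of
  the deviance (it is mathematically non-negative).
* Monte-Carlo standard errors use the binomial plug-in
  $\sqrt{\hat r(1-\hat r)/\mathrm{runs}}$.
* Problem sizes in the test suite: the full 49-setting double grid at
  10,000 runs per cell, plus 10,000-gene null matrices for the
  pipeline/simulator cross-check — the whole suite runs in well under a
  minute.

## Limitations

* Technical replicates only; no over-dispersion, no covariates, no GLM
  layer.
* One-sided variants, mid-p exact tests and continuity corrections are
  out of scope.
* The generalized-exponent statistic (`exponent_k > 2`) is a ranking
  score without a null distribution; treat its ordering, not its scale.
* Published real-data gene tallies are not reproducible without the
  external dataset; the pipeline reproduces the workflow and its
  qualitative method ordering on synthetic data instead.
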