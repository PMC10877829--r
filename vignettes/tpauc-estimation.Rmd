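---
title: "Two-way partial AUC: fast estimation, ground truth, and inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-way partial AUC: fast estimation, ground truth, and inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tpaucfast)
```

## The problem

Diagnostic tests and machine-learning classifiers that output a continuous
score are usually summarised by the area under the ROC curve. In regulated
settings, however, only part of the ROC plane matters: a tuberculosis
screening test, for instance, is required to operate at sensitivity above 90%
*and* specificity above 70% simultaneously. The **two-way partial AUC**
(tpAUC) quantifies exactly that: the area under the ROC curve inside the
upper-left rectangle where sensitivity is at least `b_se` and specificity at
least `b_sp`. Unlike the classical one-way partial AUC, which restricts only
the FPR (or only the TPR) range, the tpAUC constrains both axes at once.

The original nonparametric tpAUC estimator is a *trimmed Mann-Whitney
U-statistic*,

$$\widehat{tpAUC}_o = \frac{1}{n_x n_y} \sum_{i}\sum_{j}
  1\!\!1\{X_i > Y_j,\; X_i \le \hat S_F^{-1}(b_{se}),\;
        Y_j \ge \hat S_G^{-1}(1 - b_{sp})\},$$

where $X$ are positive-class scores, $Y$ negative-class scores, and
$\hat S^{-1}$ empirical survival-function inverses. The double sum costs
$O(n_x n_y)$, which is prohibitive inside bootstrap loops on large samples
(a confidence interval at $n \approx 40{,}000$ with 1,000 resamples is a
multi-day computation).

## The fast estimator

The package's central result is that the tpAUC can be assembled from
quantities every trapezoidal ROC implementation already provides, all of
them $O(n \log n)$. Write $pAUC_{se}$ for the one-way partial area over
sensitivity $\ge b_{se}$ (the region between the ROC curve and the line
FPR = 1) and $pAUC_{sp}$ for the one-way partial area over specificity
$\ge b_{sp}$. Each contains the target rectangle-bounded area plus one
flanking region; the union of the two regions is the full AUC minus the
lower-right rectangle $b_{se} b_{sp}$. Inclusion–exclusion then isolates the
intersection — the tpAUC:

$$\widehat{tpAUC}_p = \widehat{pAUC}_{se} + \widehat{pAUC}_{sp}
  - (\widehat{AUC} - b_{se}\,b_{sp}),$$

valid whenever the ROC curve enters the rectangle at all. Because the ROC is
monotone, that entry condition reduces to a single coordinate lookup: the
specificity attained at the sensitivity bound, $\hat c_{sp}$
(`specificity_at_sensitivity()`), must be at least $b_{sp}$; otherwise the
tpAUC is zero. An algebraically identical *alternative* form computes the
one-way partial area over the specificity band $[b_{sp}, \hat c_{sp}]$ and
subtracts the rectangle of height $b_{se}$ beneath it:

$$\widehat{tpAUC}_a = \widehat{pAUC}_{sp}(b_{sp}, \hat c_{sp})
  - (\hat c_{sp} - b_{sp})\, b_{se}.$$

Both are exposed (`tpauc_proposed()`, `tpauc_alternative()`); the test suite
asserts their numerical identity to 1e-10 over randomized inputs.

```{r hand-example}
s <- score_set(c(3, 1), c(2, 0))   # two positives, two negatives
r <- build_empirical_roc(s)
tpauc_proposed(r, tpauc_bounds(b_se = 0.5, b_sp = 0.4))
tpauc_trimmed_mw(s, tpauc_bounds(0.5, 0.5))
```

## Conventions that matter

A handful of low-level conventions pin down every estimate; they are chosen
once and documented here.

**ROC construction.** One vertex per distinct observed score, with
$FPR(c) = \#\{Y_j > c\}/n_y$ and $TPR(c) = \#\{X_i > c\}/n_x$ (strict
inequality, "positive if score > c"), plus the anchors (0,0) and (1,1).
Orientation is fixed — higher score means positive — with no automatic
direction detection, so identical inputs always give identical curves.
Cross-class ties produce a diagonal segment that the trapezoid rule credits
at half height; the U-statistics instead score ties as zero (strict
$X > Y$). On tie-free data the trapezoidal AUC and the Mann-Whitney AUC are
identical (Bamber's equivalence, asserted to 1e-12 in the tests); on tied
data the two families differ by construction, which is documented rather
than hidden.

**Partial trapezoids.** When a range boundary falls inside a trapezoid the
ROC height at the boundary is obtained by linear interpolation between the
flanking vertices, on either axis. This makes partial areas exactly additive
over adjacent ranges.

**Coordinate lookup.** `specificity_at_sensitivity()` returns the *largest*
specificity at which the curve attains the requested sensitivity: linear
interpolation between flanking vertices, and on a vertical segment (a
sensitivity jump at fixed FPR) the segment's own specificity. This is our
choice where step curves leave the coordinate ambiguous; small-sample
differences against other ROC toolkits can trace to exactly this rule.

**Empirical survival inverses.** $\hat S^{-1}(u)$ is the order statistic at
index $\lfloor (1-u)n \rfloor$ clamped into $[1, n]$. The clamped-floor
reading makes $u = 0$ a vacuous trim, so the two-way trimmed U-statistic at
bounds (0, 0) collapses exactly to the plain Mann-Whitney AUC. The literal
"largest integer strictly smaller" reading would trim one rank even at a
vacuous bound; it is available via `strict = TRUE` for comparison. A 1e-9
epsilon guards the floor against binary floating point (e.g.
`(1 - 0.3) * 10` evaluating a hair below 7).

**Clamping.** The inclusion–exclusion form can return a value a few ulps
outside $[0, (1-b_{se})(1-b_{sp})]$ through cancellation; estimates are
clamped into that interval, with a warning if the excursion exceeds 1e-8.

## Ground truth under the binormal model

For bias studies the package computes exact tpAUC values under the binormal
ROC model, $X \sim N(\mu_x, \sigma_x^2)$, $Y \sim N(\mu_y, \sigma_y^2)$. The
one-way partial area over an FPR band is the integral of the
density-weighted ROC height,

$$pAUC_{fpr}(u_0, u_1) = \frac{1}{\sigma_y}
  \int_{\mu_y - \sigma_y\Phi^{-1}(u_1)}^{\mu_y - \sigma_y\Phi^{-1}(u_0)}
  \Phi\!\left(\frac{\mu_x - z}{\sigma_x}\right)
  \phi\!\left(\frac{\mu_y - z}{\sigma_y}\right) dz,$$

evaluated by adaptive quadrature (absolute tolerance 1e-9; the limits become
infinite half-lines at $u \in \{0, 1\}$ and are handled by the
infinite-interval rule). The flanking rectangle
$[1 - b_{sp} - S_G(S_F^{-1}(b_{se}))]\, b_{se}$ is analytic, and the true
tpAUC is the difference, with the same monotonicity-based zero condition as
the estimators. The tests cross-check the quadrature against closed forms
(full-range AUC $\Phi((\mu_x-\mu_y)/\sqrt{\sigma_x^2+\sigma_y^2})$;
chance-line partial areas $(u_1^2 - u_0^2)/2$) and against Monte-Carlo
estimates of the defining pair probabilities with $10^7$ simulated pairs.

```{r truth}
p <- binormal_params(2, 1.5, 0, 1)
true_tpauc(p, tpauc_bounds(0.6, 0.6))
```

## What the simulations emulate — and what they do not

`sample_binormal()` draws independent Gaussian scores per class: the exact
generative model of the bias study. The two experiment drivers reproduce the
two study designs:

* **Agreement** (`run_agreement_experiment()`): each replicate draws fresh
  model parameters ($\mu_y \sim U(0,2)$, $\mu_x = \mu_y + U(0.1, 1.1)$,
  $\sigma_x, \sigma_y \sim U(0.5, 1.5)$) and fresh bounds
  ($b_{se}, b_{sp} \sim U(0.2, 0.8)$), simulates one dataset, and evaluates
  both estimators. Bounds are redrawn per replicate, not per experiment.
* **Bias** (`run_bias_experiment()`): each run draws parameters
  ($\mu_x \sim U(2,3)$, $\sigma_x \sim U(1,2)$, $\mu_y \sim U(0,1)$,
  $\sigma_y \sim U(1,2)$) and, for each cell of the fixed
  $\{0.2, 0.4, 0.6, 0.8\}^2$ sensitivity/specificity grid, compares the mean
  of `datasets_per_run` estimates against the quadrature truth.

Default experiment sizes are 20 runs with 200 datasets per run and cell; the
reference design of 100 runs with 1,000 datasets is reachable through the
same arguments. These sizes estimate each cell's bias from 4,000 datasets,
ample to rank the two estimators, and keep a full two-sample-size bias study
in the low minutes on one core.

Binormal scores are continuous, so simulated data are tie-free almost
surely, unimodal, and symmetric per class. Real classifier outputs —
probabilities piled up near 0 and 1, heavy ties from discrete features —
violate all three. Passing simulations therefore demonstrate correctness of
the estimators and the claimed convergence/bias patterns under the binormal
model, not distribution-free performance guarantees; the tie conventions
above describe exactly where real tied data will make the trapezoid and
U-statistic families disagree.

## Comparing two classifiers

`bootstrap_delta_ci()` compares two prediction vectors scored on the same
cases. The resampling is paired (each resampled case keeps both predictions
and its label, preserving the correlation between classifiers trained on the
same data) and class-stratified (each resample holds exactly $n_x$ positives
and $n_y$ negatives, so every estimator is defined on every resample); the
literature this follows does not fix the scheme, so this choice is ours. The
bootstrap variance is the population variance of the $B$ resampled
differences, and the interval

$$\widehat{\Delta tpAUC} \pm Z_{1-\alpha/2}
  \sqrt{v^2_{boot}/(n_x + n_y)}$$

is implemented literally, including the division by $n_x + n_y$. That
scaling is coherent only if $v^2_{boot}$ is read as the variance of
$\sqrt{n}\,\widehat{\Delta}$; since the bootstrap variance of
$\widehat{\Delta}$ itself already shrinks with $n$, the literal form yields
very narrow intervals, roughly $\sqrt{n}$ too narrow for nominal coverage.
Fidelity wins by default, and `ci_scaling = "unscaled"` exposes the other
reading ($\pm Z_{1-\alpha/2}\sqrt{v^2_{boot}}$) for users who want
conventional coverage. Replicates run serially; each replicate's resample
derives from a sub-seed indexed by (seed, replicate), so the result is a
deterministic function of the seed.

```{r compare}
set.seed(1)
labels <- rep(c(1, 0), each = 250)
signal <- rnorm(500)
p1 <- signal + 1.2 * labels + rnorm(500, sd = 0.5)
p2 <- signal + 0.7 * labels + rnorm(500, sd = 0.5)
bootstrap_delta_ci(p1, p2, labels, tpauc_bounds(0.4, 0.4),
                   B = 200, seed = 42)
```

## Degenerate inputs and limitations

Single-class inputs raise an error rather than returning `NaN` (every
downstream formula divides by a class size). Bounds must lie strictly below
1, since the rectangle is otherwise empty. Perfectly separated scores attain
the full rectangle area $(1-b_{se})(1-b_{sp})$; completely tied scores give
the chance diagonal, whose tpAUC is zero for any interior bounds (the
diagonal only touches the rectangle corner when $b_{se} + b_{sp} = 1$).

Out of scope by design: smoothed or parametric ROC fits, confidence
intervals for a *single* tpAUC, DeLong-style closed-form variances,
comparisons of more than two classifiers, and fitting binormal parameters to
data. The experiment drivers report machine-independent quantities only —
estimator values, biases and their patterns — never wall-clock comparisons,
which depend on hardware.
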