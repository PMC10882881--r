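---
title: "Calibrating variant-effect predictors for clinical evidence: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibrating variant-effect predictors for clinical evidence: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(predcal)
```

## The problem

A computational variant-effect predictor returns a real-valued score $s(x)$
for each variant $x$. Benchmarking such predictors against labeled truth sets
(clinical databases, deep mutational scans, case/control cohorts) usually
stops at rank-based summaries such as the ROC AUC. For clinical use a harder
question must be answered: *given that a particular variant received score
$s$, what is the probability that it is pathogenic, and how much evidential
weight may a laboratory assign to that prediction under the ACMG/AMP
framework?* predcal implements the chain of estimators that connects raw
(score, label) pairs to that answer: metric suites, a windowed estimator of
the local positive likelihood ratio, evidence-strength score thresholds
under an exponential evidence-combination model, class-prior transfer, and
bootstrap uncertainty.

All operations act on two plain containers: `labeled_scores` (variant id,
score, binary label, with a declared score orientation that is normalized to
higher-is-pathogenic at load time) and `continuous_pairs`
(predicted/observed assay values).

## Metric suites

For continuous targets the package reports $R^2 = 1 - \mathrm{SSE} /
\mathrm{SS_{tot}}$ (scale-sensitive; negative for predictors worse than the
observed mean), RMSE, Pearson $r$, Spearman $\rho$ (Pearson on mid-ranks),
and Kendall's $\tau_b$, the tie-corrected concordance coefficient

$$\tau_b = \frac{\sum_{i<j}\operatorname{sign}(f_i-f_j)\operatorname{sign}(y_i-y_j)}
{\sqrt{\left(\beta(n)-\sum_i \beta(u_i)\right)\left(\beta(n)-\sum_i \beta(v_i)\right)}},
\qquad \beta(k)=\tfrac{k(k-1)}{2},$$

with $u_i$, $v_i$ the tie-group sizes on either side. Ties are ubiquitous in
this domain (discretized predictors, quantized assay read-outs), so $\tau_b$
rather than plain $\tau$ is the default; the two coincide on tie-free data.
$\tau_b$ is computed by merge-sort inversion counting in $O(n \log n)$,
which matters for saturation-mutagenesis-scale inputs (tens of thousands of
variants) where the naive $O(n^2)$ sum and base R's `cor(method =
"kendall")` become impractical; the test suite verifies exact agreement with
both on small instances.

For binary targets the ROC curve places one vertex per distinct score under
the convention "predict pathogenic when $s \ge \tau$"; a tie group therefore
appears as a single vertex and the segment crossing it is a diagonal chord.
This convention is chosen deliberately so that the trapezoidal area under
the curve equals the tie-aware Mann–Whitney statistic
$P(s(X_+) > s(X_-)) + \tfrac12 P(s(X_+) = s(X_-))$ *exactly*, which is how
`auc()` computes it (via mid-ranks). The truncated AUC integrates the ROC
over the clinically relevant low-false-positive strip $\mathrm{FPR} \in [0,
0.2]$, interpolating linearly at the cap (consistent with trapezoidal
integration; the boundary rule is not dictated by the estimator itself), and
normalizes by the cap — the maximum achievable area in the strip — so a
perfect classifier scores 1 and the chance level is $0.1$. The cap, not the
best achievable area for the class mix, is the normalizer; that choice keeps
the quantity a pure rescaling of an integral of the curve. MCC, the four
confusion rates, and the global ratios $\mathrm{LR}^+ =
\mathrm{TPR}/\mathrm{FPR}$, $\mathrm{LR}^- = (1-\mathrm{TPR}) /
(1-\mathrm{FPR})$ and $\mathrm{DOR} = \mathrm{LR}^+/\mathrm{LR}^-$ are
available at any threshold; divisions by zero report `Inf` with a
`degenerate` flag rather than failing, and a degenerate MCC is reported as 0
with a warning so batch reports stay total. DOR has no local analogue (a
local negative likelihood ratio is not definable), so it appears only as a
global, threshold-level quantity.

## The local positive likelihood ratio

The quantity that transfers between populations is the local positive
likelihood ratio

$$\mathrm{lr}^+(s) = \frac{p(s \mid Y=1)}{p(s \mid Y=0)},$$

the ratio of class-conditional score densities (geometrically, the slope of
the ROC curve at $s$). It depends only on the class conditionals, not on the
class mix of the evaluation set, which is what licenses computing it on a
convenience test set and applying it in a population with a very different
prevalence of pathogenic variants.

Estimating $\mathrm{lr}^+$ requires a local posterior estimate. predcal uses
a windowed proportion: at evaluation score $s$, the posterior under the
test-set prior is the fraction of pathogenic items with scores in
$[s-\epsilon, s+\epsilon]$, where $\epsilon$ is 5% of the robust score range
(the 5th–95th percentile interval, so outliers do not inflate windows). For
stability each window must hold at least $\min(\lceil 0.10\,n\rceil, 50)$
items; "at least 10% of the items, capped at 50" is read as a cap on the
requirement, so that large datasets keep genuinely local windows instead of
being forced to 10% of $n$. When the $\epsilon$-window is too sparse it
grows outward by nearest score distance, one whole tie group at a time with
distance ties resolved toward the lower score — admitting whole tie groups
keeps the window a closed score interval and makes membership independent of
item ordering and labels. The windowed posterior $\hat P_D$ is converted to
$\widehat{\mathrm{lr}}^+$ by dividing posterior odds by the test-set prior
odds:

$$\widehat{\mathrm{lr}}^+(s) =
\frac{\hat P_D}{1-\hat P_D}\cdot\frac{1-\alpha_D}{\alpha_D}.$$

The default evaluation grid is the set of distinct observed scores, because
the evidence thresholds of the next section must land on reachable scores; a
uniform grid is available for display. Windows of pure pathogenic items
yield $\widehat{\mathrm{lr}}^+ = \infty$, which is propagated (and flagged)
rather than clipped.

Two display smoothers are provided and never applied silently: isotonic
regression (pool-adjacent-violators on the posterior, appropriate when the
predictor is believed to rank correctly) and a centered moving average; both
keep the raw curve attached. For more stringent threshold setting,
`curve_lower_bound()` substitutes a pointwise bootstrap lower quantile of
the lr$^+$ replicates for the point estimate; it is off by default
everywhere.

## Evidence strengths and score thresholds

The ACMG/AMP guidelines combine qualitative evidence lines (Supporting,
Moderate, Strong, Very Strong) into five pathogenicity classes, with
posterior-probability targets of at least 0.90 for "likely pathogenic" and
0.99 for "pathogenic". The exponential model makes this quantitative: one
Very Strong line carries likelihood ratio $c$, and a combination contributes

$$\mathrm{LR}^+_T = c^{\,n_{su}/8 + n_{mo}/4 + n_{st}/2 + n_{vs}},$$

so one Very Strong equals two Strong, four Moderate, or eight Supporting
lines, and the per-line requirements are $c^{1/8} \le c^{1/4} \le c^{1/2}
\le c$. Posteriors follow the odds-form Bayes relation
$P = \mathrm{LR}^+\alpha / ((\mathrm{LR}^+-1)\alpha + 1)$.

The constant $c$ depends on the class prior $\alpha$: the smaller the
prior, the larger the likelihood ratio needed to reach the same posterior.
The package defaults are the established operating points $c = 351$ at
$\alpha = 0.10$ (diagnostic setting, one or a few candidate genes; 351
rather than 350 to avoid rounding artifacts in the rule-fitting) and
$c = 8511$ at $\alpha = 0.01$ (screening for secondary findings). A
worked-example aside: $c = 350$ gives per-line requirements 2.08, 4.33 and
18.7 after rounding — note that $c^{1/4} = 4.3254$, which some published
tables show truncated as 4.32. `solve_c()` recovers $c$ from any
user-supplied set of combining rules by bisection (each rule demands that
its combined posterior meet its class target); the canonical rule list is
not bundled, so reproducing a specific published $c$ requires supplying the
corresponding rules, including their revisions. For priors of 0.5 and above
the benign-side rule "two Supporting lines assert likely benign" becomes
unsatisfiable under this model and must be dropped from any supplied rule
set.

The score threshold for a level is **not** the first crossing of its
requirement. It is

$$\tau_{su} = \min\{\tau : \forall s \ge \tau,\;
\widehat{\mathrm{lr}}^+(s) \ge c^{1/8}\},$$

a universally quantified condition over the whole upper tail, evaluated on
the discrete grid (where the estimator is defined): an interior dip below
the requirement pushes the threshold above the dip. This guarantees that
*every* score beyond the threshold sustains the claimed evidence level.
Thresholds are non-decreasing in level by construction; unreached levels are
reported as `NA`, which is a legitimate outcome, not an error. Mirrored
benign-direction thresholds (requirements $c^{-1/8}, \dots$) are available
via `direction = "benign"` and disabled by default. For inputs declared
lower-is-positive, thresholds are additionally reported in original score
units (as "score at or below").

## Class-prior transfer

With $\mathrm{lr}^+$, TPR and FPR in hand — all class-prior independent —
the prior-dependent quantities follow at any target prior $\alpha$:

* $\mathrm{PPP}(\tau) = \alpha\,\mathrm{TPR} + (1-\alpha)\,\mathrm{FPR}$,
  the fraction of the target population called at or above $\tau$;
* $\mathrm{PPV}(\tau) = \alpha\,\mathrm{TPR} / \mathrm{PPP}(\tau)$;
* $\rho(s) = \alpha\,\mathrm{lr}^+(s) / (\alpha(\mathrm{lr}^+(s)-1)+1)$,
  the local posterior (local PPV);
* $\mathrm{RR}(s) = \rho(s)/\alpha$, the fold-change in risk relative to
  the population average.

Setting the target prior equal to the observed test prior recovers the
uncorrected empirical quantities exactly (this algebraic identity is
tested to machine precision), and $\mathrm{RR}\cdot\alpha = \rho$ holds by
construction. The test-set prior defaults to the observed positive fraction
and can be overridden when the test set is known to be unrepresentative.
The transfer is valid exactly when the test set and the target population
share class-conditional score distributions and differ only in class mix;
nothing in the data can certify that assumption, so it is stated rather
than checked.

## Uncertainty

Confidence intervals are percentile bootstrap with case resampling (n out
of n), 1000 iterations by default. Percentile intervals are the minimal,
assumption-light choice; bias-corrected accelerated (BCa) intervals are
available by flag, as is stratified (within-class) resampling for severely
imbalanced sets. Binary resamples that lose a class are redrawn and counted;
if the degenerate draws outnumber half of all draws the run aborts with
advice to stratify. P-values against the "random predictor" null (AUC 0.5,
$r = 0$, $\tau = 0$) are computed by label permutation (observed-value
permutation for continuous data), which realizes exactly those nulls, with
the standard $+1$-correction $p = (1 + \#\{T^{null} \ge T\}) /
(B + 1)$. All randomness flows through one seed with a pinned generator
(Mersenne-Twister, inversion normals), and the caller's RNG state is
restored, so reports are reproducible bit for bit.

## The synthetic generators, and what passing them shows

Because real challenge truth sets are access-restricted, validation rests on
generators with analytically known answers:

* **Binormal scores** — class-conditional Gaussians with Bernoulli labels.
  Closed forms: $\mathrm{AUC} = \Phi(\Delta\mu/\sqrt{\sigma_0^2 +
  \sigma_1^2})$; $\mathrm{lr}^+(s) = \varphi_1(s)/\varphi_0(s)$, log-linear
  in $s$ with slope $\Delta\mu/\sigma^2$ when the sigmas are equal. The
  default condition is $\mu_1 - \mu_0 = 1$, unit sigmas, balanced classes —
  an AUC of about 0.76, typical of a moderately informative predictor on a
  balanced benchmark set.
* **Beta mixtures** — for bounded, probability-like scores in $[0,1]$.
* **Bivariate normal pairs** — Pearson correlation $\rho$ by construction,
  Kendall $\tau = (2/\pi)\arcsin\rho$; optional strictly increasing margin
  transforms exercise rank invariance.
* **Quantization** (`generate_tied`) — bin-midpoint coarsening to inject
  ties into any set.

These fixtures exercise estimator correctness, tie handling, prior
transfer, and coverage. They do *not* emulate real predictor pathologies:
heteroscedastic or multimodal score distributions, label noise and database
mislabeling, assay measurement error in the "truth", or training-set
contamination. Passing the closed-form checks therefore certifies the
estimators, not any claim about a particular predictor's real-world
calibration.

## Numerical choices and verification scale

* Windowed posteriors use R's default (type 7) quantiles for the robust
  range; $\epsilon = 0$ (massively tied scores) degrades gracefully to
  exact-score windows plus the count rule.
* `threshold_metrics` uses exact integer confusion counts; MCC's product
  of four sums is computed with square roots interleaved to avoid integer
  overflow at large n.
* Inversion counting accumulates in doubles (pair counts exceed 2^31
  already at n around 66,000).
* Bisection in `solve_c` runs to 1e-6 and the result is also reported as
  the smallest satisfying integer.
* Verification sizes used by the test suite, chosen to bound Monte-Carlo
  error well inside each tolerance: closed-form recovery and prior-transfer
  checks at n = 1e5 (AUC within 0.005 of the closed form; mean relative
  error of windowed lr+ below 5% over the central 90% of scores; the
  sample-mean of the windowed posterior within 0.02 of the test prior);
  tau-b closed form at n = 1e5 within 0.02; bootstrap coverage over 500
  replicate experiments of n = 200 with 300 iterations each, accepting
  92–98% coverage of 95% intervals; oracle equivalence (AUC and tau-b
  against literal brute-force formulas) on 1000 random tied instances at
  1e-12.

## Known limitations

* The windowed lr$^+$ estimator is biased where the curve bends sharply
  within a window (second-order in $\epsilon$) and noisy where the 50-item
  floor binds (score distribution tails); the bootstrap lower bound is the
  provided remedy when conservatism matters.
* Replicate-level assay inputs are not modeled; observed values are taken
  as given (pre-averaged).
* The package quantifies computational evidence only; it does not combine
  multi-source evidence into five-tier clinical classifications of
  individual variants.
* Weighted or grouped correlations, precision-recall analyses, and
  covariate-adjusted odds ratios are out of scope.
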