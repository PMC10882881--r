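# predcal

Calibration and clinical-evidence assessment for variant-effect predictors.

Computational predictors of variant pathogenicity output real-valued scores,
but clinical variant interpretation needs calibrated probabilities and
defensible evidence strengths. Given a table of (variant, score, label)
pairs — or predicted/observed assay values — predcal computes the standard
assessment metrics, estimates the **local positive likelihood ratio**
lr⁺(s) = p(s | pathogenic) / p(s | benign) by adaptive score windowing,
derives **ACMG/AMP evidence-strength score thresholds** (Supporting /
Moderate / Strong / Very Strong) under the exponential
evidence-combination model, transfers prior-dependent quantities (PPV,
posterior probability of pathogenicity, relative risk) to a stated target
class prior, and attaches bootstrap confidence intervals and permutation
p-values throughout. It is aimed at method assessors, tool developers who
want to report calibrated performance, and anyone turning a benchmark set
into clinically interpretable numbers.

## The core model

* Metrics: R², RMSE, Pearson, Spearman, tie-corrected Kendall τ_b
  (O(n log n)); tie-aware Mann–Whitney AUC with exact equality to the
  trapezoidal ROC area; truncated AUC over FPR ∈ [0, 0.2] normalized by the
  cap; MCC, LR⁺, LR⁻, DOR at any threshold.
* Local calibration: the posterior under the test-set prior is estimated as
  the pathogenic fraction in the score window [s − ε, s + ε], with
  ε = 5% of the 5th–95th percentile score range and each window holding at
  least min(⌈0.10 n⌉, 50) items (growing outward by nearest score when
  needed). lr⁺(s) follows by dividing posterior odds by the test-prior odds.
* Evidence model: one Very Strong line carries LR⁺ = c; a combination
  contributes c^(n_su/8 + n_mo/4 + n_st/2 + n_vs); per-level score
  thresholds satisfy τ_level = min{τ : ∀ s ≥ τ, lr⁺(s) ≥ requirement}.
  Defaults c = 351 at prior 0.10 and c = 8511 at prior 0.01; `solve_c()`
  recovers c from a user-supplied rule list.
* Prior transfer: TPR, FPR and lr⁺ are class-prior independent;
  PPP = αTPR + (1−α)FPR, PPV = αTPR/PPP, ρ(s) = αlr⁺/((lr⁺−1)α+1),
  RR = ρ/α are recomputed at the target prior α.

See the methods vignette (`vignettes/predcal-methods.Rmd`) for assumptions,
tie-handling conventions, and design rationale.

## Worked example

A small bundled score set (60 synthetic variants, binormal scores, ~48%
pathogenic) run at the diagnostic operating point (target prior 0.10,
c = 351):

```r
library(predcal)
path <- system.file("extdata", "synthetic_scores.tsv", package = "predcal")
scores <- read_scores(path, id_column = "variant")
cfg <- analysis_config(target_prior = 0.10, evidence_constant = 351, seed = 1)
run_report(scores, cfg)
#> <predcal_report> binary input, n = 60
#>
#> Metrics (with 95% bootstrap CIs, 1000 iterations):
#>         metric estimate ci_low ci_high
#>            auc   0.8788 0.7840  0.9556
#>  truncated_auc   0.5795 0.3681  0.8069
#>
#> Test-set prior alpha_D = 0.4833; target prior alpha = 0.1; c = 351
#>
#> Evidence levels (NA threshold = level not reached):
#>        level lr_requirement threshold    ppp
#>   supporting          2.080    1.3711 0.1201
#>     moderate          4.328    1.9954 0.0310
#>       strong         18.730    2.1682 0.0276
#>  very_strong        351.000    2.1682 0.0276
```

Reading the output: the predictor separates the classes well (AUC 0.88,
but only 0.58 of the achievable area in the clinically relevant low-FPR
strip). Scores at or above 1.37 sustain a local likelihood ratio of at
least 2.08 everywhere and therefore qualify as Supporting evidence; about
12% of variants in a population with 10% pathogenic prevalence would score
that high. Moderate evidence starts at score 2.00, Strong at 2.17. A single
local likelihood ratio converts to a posterior with `posterior_from_lr()`:
for example lr⁺ = 6 at a gene-level prior of 0.21 gives

```r
posterior_from_lr(6, 0.21)
#> [1] 0.6146341
```

— a variant of uncertain significance on its own, which is exactly why
evidence combination matters. `write_report()` serializes the full report
(metrics with CIs, ROC points, calibration curve, evidence table, transfer
table) as JSON; `inst/cli/predcal-report.R` is a command-line wrapper, and
`inst/cli/predcal-simulate.R` generates synthetic sets with analytic truth
sidecars.

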