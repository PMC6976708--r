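# sgmatch

Subject-specific survival gain from propensity-score nearest-neighbour
matching, with censoring-aware response labelling and matched-set variance
estimation — plus the Monte Carlo machinery to compare matching schemes on
synthetic oncology-like cohorts.

## The problem

In observational oncology data, whether an individual patient *responded* to
a treatment is often defined as their overall survival (OS) exceeding what
comparable untreated patients achieved by at least a clinically meaningful
margin of λ months. With a treated patient *i* matched to a set *C(i)* of
control patients by nearest-neighbour (NN) propensity-score (PS) matching
with replacement, the subject-specific survival gain and its variance are

```
SG_i = OS_i^T − Σ_{j ∈ C(i)} w_ij OS_j^C
V_i  = Σ_{j ∈ C(i)} w_ij² · var(OS^C)_{C(i)}        (OS_i^T held fixed)
```

with weights `w_ij = 1/k` (uniform 1:k matching) or
`w_ij ∝ exp(−α |PS_i − PS_j|)` (distance-weighted, α = 5 by default).
Because survival is right-censored, the binary response label
`SG_i ≥ λ` is not always identified: a censored OS is only a lower bound.
The package implements the full decision table — drop censored controls and
renormalise when some remain observed, label `undetermined` when the
comparison is ambiguous (e.g. every control censored and the apparent gain
clears the threshold), commit when the bound forces the answer (e.g. a
censored treated patient whose lower-bound gain already clears λ).

Four matching schemes are provided: one-by-one, 1:k, weighted 1:k, and the
complex bootstrap (b resampled control groups, PS refit and 1:1 matching in
each, matches pooled per treated patient).

To compare these schemes, the package ships a synthetic cohort generator
with known ground truth: 10 standard-normal covariates, logistic treatment
selection on X1–X7, Weibull survival by inverse-probability transform
`OS = (−log u / (λ_w e^LP))^{1/2}` (λ_w = 2·10⁻⁵, shape 2) with linear
predictor on X4–X10, conditional hazard ratio exp(β_treat) = 0.8, and a
shared uniform draw `u` for both treatment arms so that each subject's true
counterfactual gain `SG = OS₁ − OS₀` is known exactly (and `OS₁/OS₀ ≡
0.8^{−1/2}`). Three heterogeneity levels (low/medium/high) scale the
covariate effects from log 1.25 up to log 8, controlling confounding
strength; an intercept calibration targets any treated proportion.

## Worked example

```r
library(sgmatch)

coh <- simulate_cohort(1000, "low", prop_treated = 0.2, p_censor = 0.2, seed = 42)
fit <- sg_match(coh, method = "knn", k = 15, threshold = 3)
summary(fit)
#> Matched survival-gain fit: knn (k = 15, b = 15)
#>   191 treated, 809 controls; threshold 3 months
#>   response labels:
#>     response non_response undetermined
#>           91           82           18
#>   mean STE 30.3, mean STE variance 1013, var(V^s) 902137
#>   per-subject gain quantiles (months):
#>       0%      25%      50%      75%     100%
#> -245.153  -46.689   13.366   84.360  580.416

truth_summary(coh)
#> true ATE: 20.00 months; true variance V: 239.8
```

Reading: of 191 treated patients, 91 are labelled responders (estimated gain
≥ 3 months), 82 non-responders, and 18 (9.4%) hit the label-censoring
problem — their matched comparison is not identified under censoring. The
mean subject-specific gain (30.3 months, over patients with a defined gain)
sits above the cohort's true ATE (20.0 months) by sampling noise and
selection of labelable subjects; the matched-set variance estimator averages
1013 months², against a true gain variance of 240 months² — overestimation
driven by outcome spread within matched sets, exactly the behaviour the
Monte Carlo study quantifies.

The full study is one call (here the reduced 200-iteration profile):

```r
res <- run_grid(n_iterations = 200, base_seed = 1, out_dir = "results")
```

which sweeps treated proportion, censoring rate and k across methods and
heterogeneity levels, writing a tidy CSV and a JSON manifest. A command-line
front end with `simulate | estimate | experiment | report` subcommands lives
at `inst/cli/sgmatch.R`.

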