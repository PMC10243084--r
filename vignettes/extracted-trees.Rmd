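---
title: "Extracted regression trees: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extracted regression trees: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(extree)
```

## The model

`extree` distils a black-box tabular risk scorer into an interpretable
tree in two steps. Step one trains any scorer $f : \mathcal{X} \to [0,1]$
— the package is agnostic about what $f$ is and only relies on the
`risk_scorer()` contract (fixed feature order in, probabilities out).
Step two approximates $f$ by a shallow tree $T$:

1. A $K$-component Gaussian mixture with diagonal covariances,
   $p(x) = \sum_{i=1}^{K} \varphi_i\, N(x;\mu_i,\mathrm{diag}\,\sigma_i^2)$,
   is fitted to the *training* feature matrix by
   expectation–maximisation, giving a generative stand-in $P$ for the
   joint feature distribution.
2. $m$ synthetic inputs $\tilde x \sim P$ are drawn and labelled with the
   scorer's continuous output $\tilde y = f(\tilde x) \in [0,1]$.
3. A CART regression tree is grown on the pairs $(\tilde x, \tilde y)$:
   axis-aligned splits minimising the weighted child sum of squared
   deviations, mean-valued leaves.

The variant that binarizes $\tilde y$ at 0.5 before fitting a
classification tree (Gini splits, positive-fraction leaves) is retained
as the comparison arm, via `extract_tree(mode = "binary")`. The
regression form dominates it for a simple information-theoretic reason:
thresholding collapses the scorer's graded confidence into one bit, so
the surrogate can no longer distinguish a 0.51 from a 0.99, and the tree
inherits that loss. The package's acceptance suite reproduces this
ordering on synthetic cohorts over 20 seeds.

Key assumptions, stated plainly:

* **The mixture is a usable caricature of the feature distribution.**
  Diagonal covariances capture marginal location/spread and, through the
  mixture over components, some gross dependence — but not fine
  correlation structure. Binary and one-hot columns are modelled as
  continuous coordinates and sampled values are *not* rounded before
  scoring; the midpoint split rule puts their tree thresholds at exactly
  0.5, so the rendered tree reads naturally ("emergency admission:
  yes/no"). Scorers that reject non-binary input can opt into
  `round_binaries`-style behaviour via the `clip` argument.
* **The surrogate is only as good as the teacher in the sampled
  region.** Out-of-support samples (e.g. a negative length of stay) are
  passed to the scorer unclipped by default, because the scorer contract
  is defined on the reals and clipping is a modelling choice the user
  should make explicitly (`clip = list(los = c(0, Inf))`).
* **Shallow trees trade fidelity for legibility.** With `max_depth = 4`
  the tree has at most 16 leaves, hence at most 16 distinct risk levels.
  For a truth spread across many additive features this costs real AUC;
  for concentrated ("shallow") truths the surrogate tracks the black box
  closely. Both regimes are exercised in the tests.

## Tunable parameters

| Parameter | Default | Why |
|---|---|---|
| `K` (mixture components) | `select_K()` over 1–10 by BIC; experiments here use K = 3 | BIC = $-2\ell + [(K-1)+2Kd]\log n$; ties to the smaller K. |
| `m` (synthetic pairs) | $10\times$ training rows, capped at 100,000 | "as many as needed"; fidelity is monotone in m, returns diminish past ~10× n. |
| `max_depth` | 4 | a human-readable page-sized tree. |
| `min_leaf` | 50 | leaves estimate means of black-box scores; 50 synthetic samples keep them stable. |
| `min_gain` | 1e-7 | prunes numerically-zero splits only. |
| binarization threshold | 0.5 | the conventional decision cutoff; a score exactly at the threshold maps to the positive class. |
| EM `tol`, `max_iter` | 1e-6 absolute log-likelihood gain, 500 | plateau detection; the trace is recorded and non-decreasing. |
| variance floor | 1e-6 × column variance | prevents degenerate spikes on near-constant (one-hot) coordinates. |
| k-fold `k`, rebalancing | 5, "up" | k unstated in the protocol we follow, 5 is the common default; up-sampling discards no information. |
| MLP `hidden`, `decay`, `maxit` | 4, 0.03, 300 | chosen by a small grid on a held-out synthetic split: up-sampled duplicates overfit badly under weak regularisation. |

## The synthetic cohort generator

Real readmission data are proprietary, so the package ships a generator
whose *stated world* makes every stage testable against a known truth.

* **Schema.** One row per visit: patient/visit ids, admission and
  discharge dates, and an administrative feature roster (age, Charlson
  and van Walraven comorbidity scores, length of stay,
  emergency-admission flag, nursing-home discharge flag, insurance
  class, surgery and ICU flags, transfer and secondary-diagnosis counts,
  specialty, admission month/day-of-week derived from the date, and the
  emergent six-month prior-visit count).
* **Risk link.** Each visit's probability of readmission within 30 days
  is `plogis(intercept + Σ β_j x_j)`, evaluated on that visit's realized
  features (including its actual prior-visit count). Given the draw:
  gap to the next admission is uniform on 1–30 days if "readmitted
  within 30"; otherwise, with a secondary probability calibrated to the
  90-day target, uniform on 31–90; otherwise `91 + Exp(interarrival
  scale)` days (default scale 240). Chains end at the observation-window
  edge or a visit cap. Larger interarrival scales therefore end chains
  sooner and lower realized prevalence — spacing and prevalence are
  linked, as in real cohorts.
* **Calibration.** Default targets are 14.3% (30-day) and 24.4%
  (90-day), the imbalance typical of administrative readmission cohorts.
  A pilot-sample bisection sets the intercept so the *marginal* mean
  risk hits the target; because readmitted patients contribute more
  visits and later visits carry larger prior-visit counts, the realized
  per-visit prevalence overshoots that marginal target by about two
  points, so two stochastic-approximation rounds against small
  internally generated cohorts correct the intercept (and the 31–90-day
  arm) on the realized scale. Residual error is Monte-Carlo noise of the
  check cohorts (≈ ±0.005).
* **Determinism.** Each patient draws from a counter-based sub-stream of
  the master seed, so enlarging a cohort never perturbs the visits of
  patients already generated, and identical configurations reproduce
  identical tables.
* **Two stated mechanisms.** `default_mechanism()` spreads signal across
  ten features with literature-guided coefficients (prior utilisation,
  comorbidity and emergency admission strongest).
  `shallow_mechanism()` concentrates it in three
  (emergency admission 0.8, Charlson 0.6, prior visits 0.6): the regime
  in which a depth-4 surrogate can genuinely match a black box, used by
  the distillation-fidelity experiments.

**What the generator does *not* emulate** — and hence what a green test
does not establish: real joint feature dependence beyond configurable
marginals and the risk link (comorbidity scores here are independent of
age, for instance); disease progression across a patient's visits
(features are re-drawn per visit); seasonal admission patterns; coding
noise and missingness mechanisms; and any non-logistic risk surface.
Tests that pass here show the *pipeline* is correct and the method's
comparative ordering holds under a known truth, not that any particular
hospital's readmission process is captured.

Per-visit versus per-patient rates: outcome labels are per-visit, and
the generator calibrates the per-visit prevalence. A per-patient rate
("share of patients ever readmitted within 30 days") would differ
slightly; the per-visit reading matches how the labels enter the models.

## Evaluation machinery

Metrics are implemented for imbalanced outcomes: midrank (Mann–Whitney)
AUC with average ranks for ties; average precision as the AUPRC
estimator, processing tied scores as blocks — chosen over trapezoidal
interpolation because its no-skill baseline provably equals the positive
prevalence, which the tests exploit; MCC with the zero-denominator
convention; precision/recall/F with zero conventions.

The replication protocol runs R = 50 label-stratified 70–30 splits
(stratification is a deliberate refinement of plain random splitting: it
guarantees positives in every test set so rank metrics are always
defined), rebalances the training side only, and summarises each metric
by mean, sample SD, and a deliberately conservative standard error:
the SD times $\sqrt{(R-1)/\chi^2_{0.05,R-1}}$, the one-sided upper 95%
confidence limit on a normal population SD — 1.2017 at R = 50.
Comparisons against a baseline flag improvements beyond twice (95%) or
three times (99%) the *baseline's* adjusted SE, strictly one-sided. With
a baseline accuracy SD of 0.0093 and AUC SD of 0.0088 these thresholds
round to 0.0224 and 0.0212. Note one printed-precision quirk: an AUPRC
SD of 0.0049 gives 2 × 1.2017 × 0.0049 = 0.0118, not the 0.0116 that
rounding the intermediate adjusted SD (0.0058 → ×2) would suggest; the
implementation always computes from unrounded SDs.

The GMM is refitted inside every replication on that replication's
training split — never on test rows — so no test information leaks into
extraction.

## Numerical choices

* **EM**: responsibilities via log-sum-exp; convergence on absolute
  log-likelihood gain; k-means seeding of component means (random-row
  fallback), column variances as initial spreads, uniform weights. The
  recorded log-likelihood trace is checked non-decreasing to 1e-9 slack
  (pure floating-point noise near the optimum).
* **Splits**: candidate thresholds are midpoints of consecutive distinct
  sorted values (hence exactly 0.5 on 0/1 columns); sums of squares use
  cumulative sums with clamping at zero; ties in gain (to within 1e-9)
  break to the lowest feature index, then the smallest threshold, making
  trees fully deterministic.
* **Boundaries are inclusive**: a 180-day-old prior visit counts; a
  30-day gap is a 30-day readmission; a score exactly at the decision
  threshold predicts positive. The prior-visit count excludes the index
  visit itself (the literal self-counting sum is available via
  `include_self = TRUE`).
* **Censoring**: visits admitted within the outcome window of the
  observation-range end are flagged (their 0 label may be truncation);
  the default keeps them, `drop_censored = TRUE` removes them. Flagging
  keys on the admission date; a long stay near the boundary can still be
  mildly censored, a knowingly accepted approximation.
* **Admission source** is coded as a single emergency-vs-elective
  binary flag, the simplest coding consistent with the roster.
* **Degenerate fidelity**: when tree and scorer predictions are both
  constant, R² is reported as 1 with a `zero_variance` flag rather than
  NaN; AUC-agreement is `NA` when binarized teacher labels are
  single-class.

## Limitations

* The surrogate explains the *black box*, not the world: if the teacher
  encodes a bias, the tree will render it legibly rather than remove it.
* Diagonal mixtures under-represent correlated features; synthetic
  samples can land off the data manifold, where the teacher is
  unconstrained.
* Depth-4 trees cap the number of distinct risk levels at 16; dense
  additive truths lose measurable AUC at that depth (visible in the
  test suite's dense-mechanism runs).
* No cost-complexity pruning, oblique splits, ensembles, or the active
  node-by-node sampling variant of surrogate extraction; extraction here
  is the simpler sample-then-fit form.
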