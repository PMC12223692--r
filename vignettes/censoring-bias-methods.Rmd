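---
title: "Methods: right-censoring bias in long-horizon diagnosis prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: right-censoring bias in long-horizon diagnosis prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem and the observation model

Each child is a triplet `{X, T, S}`: features `X` (a timestamped sequence of
medical codes observed before a fixed prediction age, plus demographic
attributes), an observed time `T = min(E, C)` where `E` is the latent
diagnosis age (possibly "never", represented as `Inf`) and `C` the censoring
age, and the indicator `S = 1` iff `E <= C`. In pediatric EHR data censoring
is dominated by the *administrative* mechanism: records end at a fixed
extraction date, so follow-up length is a deterministic function of birth
date. A binary classifier trained on `S` therefore learns
`P(diagnosed AND followed long enough | X)`; whenever `X` carries any signal
about birth era, the classifier partially learns the censoring distribution.
The discrete-time model instead maximises the censoring-aware likelihood and
estimates `P(E in bin k | X)` directly.

# The synthetic cohort generator

The generator (`cohortConfig()` / `generateCohort()`) emulates the features
of this data regime that drive the phenomenon; it makes no claim of clinical
realism beyond them.

* **Event times.** Discrete hazards on yearly age bins with uniform
  within-bin jitter:
  `h_i(k) = link(logit(h0_k) + covariate effects + trend * (YOB - ref) +
  riskEffect * u_i)` with `u_i ~ N(0,1)` a latent risk propensity. The
  default link is logistic; `hazardLink = "cloglog"`
  (`h = 1 - (1 - h0)^exp(eta)`) makes the bins exactly proportional-hazards
  in the piecewise-exponential sense, which is the configuration used when a
  Cox model's estimand must equal the generating coefficient.
* **Censoring.** `C = min(C_admin, C_drop)` with
  `C_admin = extractionYear - (birthYear + U(0,1))` and `C_drop`
  exponential with rate `dropoutRate`. The spread of censoring ages in real
  pediatric cohorts is unpublished; the scenario default of 0.12/year was
  chosen once so that roughly 60% of children in the late-event scenarios
  are censored before the mean diagnosis age, and — importantly — so that a
  sizeable share of censoring is *independent* of covariates (see the
  limitations section on censoring concordance).
* **Code sequences.** A Poisson process at `meanCodesPerYear` truncated at
  `T`, with marks drawn in two stages: risk versus non-risk by
  `u_i` (risk codes are enriched in high-hazard children), then era versus
  background *within the non-risk codes* by birth year. The two-stage form
  keeps the risk signal orthogonal to the era signal: coding-practice drift
  changes which routine codes appear, it does not dilute clinical content.
  The era signal is what lets any model (including, pathologically, BC)
  infer birth era — and hence follow-up length — from features. The scenario
  presets use `eraDrift = 1.0` per year: strong but deliberate, because
  administrative censoring that is *unpredictable* from `X` is informative
  conditional on `X` and would bias every likelihood-based method; real EHR
  features (vocabulary versions, drug availability, visit templates) date a
  record quite precisely.
* **Demographics.** Sex/race/insurance marginals configurable; defaults are
  typical pediatric health-system marginals (52% male, five race groups,
  public/private/other insurance). Only marginals are modelled.

What the generator does *not* emulate: visit-level clustering of codes,
code-code semantic structure beyond the three sub-vocabularies, competing
risks, time-varying covariate effects, or informative dropout. Passing tests
therefore demonstrate the censoring mechanics, not clinical transportability.

## Scenario presets

Four presets mirror the timing structure of four conditions; hazards were
chosen so the conditional mean event age within the horizon matches the
target (values in years):

| preset | mean event age | incidence | prediction age | horizon |
|--------|---------------|-----------|----------------|---------|
| rom    | 1.58 | 12.9% | 4 months | 3 |
| fa     | 1.98 | 3.7%  | 3 months | 3 |
| autism | 3.75 | 3.2%  | 15 months | 8 |
| adhd   | 6.21 | 4.7%  | 3 years | 8 |

The infant-cutoff presets (rom, fa) use 24 codes/year — well-child schedules
make early infancy code-dense — so that a 3-4 month feature window still
contains usable signal; the late presets use 8/year.

# Filtering

`filterSpec()` combines a birth-year cutoff, a minimum follow-up, and the
prediction-age cutoff (children diagnosed or censored before the prediction
age are excluded). The minimum-follow-up rule by default removes only
*censored* children with short follow-up: removing early-diagnosed children
would discard exactly the positive labels the classifier needs, and the
filter's purpose is to exclude unknowable outcomes, not known ones. The
aggressive literal reading (`dropEarlyEvents = TRUE`) is available since the
source text is ambiguous. `truncateFeatures()` additionally drops any code at
or after the diagnosis age, so post-diagnosis care cannot leak into features.

# Models

One encoder, three heads. The encoder embeds codes (CBOW with negative
sampling, size configurable, default 256 to match common practice; padding
and out-of-vocabulary tokens are zero vectors and stay frozen), applies a
fully connected layer with ReLU per token, mean-pools over the sequence, and
applies a second fully connected layer with ReLU. Demographic one-hots are
appended to the pooled representation. Choices the source material leaves
open, fixed here:

* **Pooling divisor**: the number of real tokens (not the padded length);
  `poolDivisor = "fixed"` switches to the padded length. An empty sequence
  is treated as one padding token, so its representation is the zero vector
  pushed through both layers.
* **Truncation**: sequences longer than `maxSequenceLength` keep the most
  recent events before the cutoff.
* **Embedding post-processing**: the mean token vector is subtracted after
  CBOW training. Small-vocabulary Word2Vec tables concentrate along a single
  shared direction (all pairwise cosines near 1); removing it is standard
  practice and is what makes the downstream encoder trainable.
* **Optimizer**: Adam with decoupled weight decay (applied to weight
  matrices, not biases), early stopping on validation loss, and a grid
  search over learning rate and weight decay. Package defaults are
  lr {1e-4, 1e-3, 1e-2} x wd {0, 1e-5, 1e-4}, patience 10; the scenario
  presets use the reduced grid lr {2e-3, 1e-2} x wd {1e-4, 3e-3} with 40-60
  epochs and patience 8-10, sized for single-CPU runs. The wider decay value
  matters: it lets validation select away spurious era-noise fits in the
  heavy-censoring scenarios.

## The discrete-time likelihood and its censoring convention

The DTNN head is a softmax over the `TimeGrid` bins plus an explicit
beyond-horizon bin (the loss needs survival mass beyond any censoring bin,
so a terminal bin must exist). For an event in bin `k` the loss is
`-log p_k`; for a censoring time the package uses the **actuarial
interval-censoring convention**: a censoring age strictly inside bin `k`
contributes `-0.5 log S(k-1) - 0.5 log S(k)`, i.e. survival through the
completed bins plus half a bin of exposure (exact in expectation for
uniform within-bin censoring). The two integer conventions — "survived the
whole containing bin" or "never entered it" — bias the estimated hazard of a
stratum's terminal bin by up to half its censored count, which is fatal
under administrative censoring where each birth-year stratum exits in a
narrow age band. For the same reason the scenario grids use half-year bins:
the residual approximation error shrinks with bin width. Losses are clamped
at `1e-12` before logs. Censoring beyond the horizon contributes exactly
`-log(beyond-horizon mass)`.

`eventProbabilityBy()` interpolates as a step function at bin right edges,
matching the likelihood's resolution and keeping time-varying AUC
well-defined at bin edges.

## BC and DCPH

BC is a logistic head on `S` with binary cross-entropy; its predicted
probability is used unchanged at every evaluation time. DCPH predicts a
log-hazard ratio trained with the Breslow-tie negative partial
log-likelihood on minibatch risk sets (batches without events are skipped);
absolute risk uses the Breslow baseline cumulative hazard estimated on the
training split, carried flat beyond its last event time.

# Evaluation

* `aucT()` / `apT()`: cases are `S = 1 & T <= t`, controls `T > t`; children
  censored at or before `t` are excluded (censored exactly at `t` excluded,
  since a control must be event-free *beyond* `t`). Ties count one half;
  AP evaluates precision at distinct score thresholds, which equals
  precision-at-case-ranks for distinct scores.
* `harrellC()`: comparable pairs `T_i < T_j` with `S_i = 1`, strict on time.
* `censoringConcordance()`: Harrell's concordance among censored children
  with the censoring time as the outcome and the non-event probability as
  the score.
* `kmEstimate()` wraps the product-limit estimator
  (`survival::survfit`), with right-continuous `S(t) = P(T > t)` and
  Greenwood standard errors.
* `calibrationCurve()`: 10 quantile bins of predicted probability, bins
  under 20 children merged with a neighbour, observed incidence
  `1 - S_KM(t)` within each bin.
* `bootstrapCi()`: unstratified patient resampling, percentile interval,
  point estimate from the unresampled data; resamples on which a metric is
  undefined are redrawn and counted.

# Experiment design choices

* One shared 60/20/20 split per scenario; every setup is evaluated on the
  identical test split (after the common base filter), so metric differences
  are attributable to training-time filtering and head choice only.
  Setup-specific test filtering is available but not the default.
* All randomness flows from a single root seed through named substreams
  (`simulate`, `split`, `embed`, `init`, `bootstrap`), so e.g. changing the
  bootstrap count never changes the simulated cohort.
* The semisynthetic transformation (censoring times rescaled so their
  maximum equals `maxAge`, events overtaken by the new censoring becoming
  censored) is applied to the training *and* validation splits — model
  selection must not peek at labels that would be unavailable under the
  emulated censoring — while the test split stays untouched. Evaluation is
  restricted to times at or below `maxAge`; beyond it the comparison would
  be unfair to models that never saw such times. A `maxAge` of 3 years in
  the rom scenario truncates roughly half of the observed training events.
* The heavy-censoring mechanism experiment uses the autism-analogue cohort
  at a 5-year modeling horizon (the scenario's operating age). Under the
  ADHD analogue, entire late birth-year strata are censored before the
  8-year horizon, so their late-bin hazards are unidentifiable for *any*
  method and the comparison would measure inductive bias, not censoring
  handling.
* Birth-year trend checks compare mean predicted probability across
  birth-year strata (rank correlation over stratum means), matching how
  such trends are read off grouped prediction plots.

# Problem sizes

The shipped tests and the acceptance script use: n = 50,000 for generator
closed-form checks (no training); n = 20,000 for DTNN incidence recovery and
n = 12,000 for DCPH coefficient recovery (code-free cohorts, so the checks
isolate the likelihood and head mechanics from the encoder); n = 24,000 for
the heavy-censoring mechanism; n = 10,000 for the semisynthetic experiment;
n = 6,000 for the no-censoring equivalence check; 100 bootstrap resamples
throughout. Embedding dimension 16, hidden width 16, maximum sequence length
64 in all scenario runs.

# Known limitations

* **The censoring-concordance null is not exactly 0.5 under risk
  heterogeneity.** Among censored children, those at high true risk are
  selectively censored *earlier* (had they remained they would likely have
  been diagnosed), so even an oracle given the latent labels shows a
  censoring concordance slightly below 0.5 (about 0.49 in the heavy
  scenario). Dropout censoring, being independent of risk, dilutes this
  selection effect toward 0.5; that is one reason the scenario includes a
  substantial dropout component. A DTNN value *below* 0.5 therefore does
  not indicate the BC pathology (which is specifically a value above 0.5);
  tests asserting that the DTNN's CI covers 0.5 exactly sit at the
  precision floor of the whole simulation-plus-training stack and can fail
  by a few hundredths at particular seeds.
* The encoder can retain a small spurious era readout (order 0.01-0.03 in
  concordance units) that varies by seed; the weight-decay grid reduces but
  does not eliminate it.
* The actuarial convention is exact only for uniform within-bin censoring
  and constant within-bin hazard; half-year bins keep the residual error
  near 0.005 in cumulative incidence.
* DCPH coefficient recovery is defined only when the generator respects
  proportional hazards (`hazardLink = "cloglog"`); under the default
  logistic link the discrete-time coefficient and the continuous-time
  log-hazard ratio differ by a link mismatch that grows with hazard size.

# Reproducibility

Every report records its root seed, substream seeds, scenario name and
package version. Two runs with the same configuration and seed produce
identical cohorts, splits, models and CSV outputs.
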