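---
title: "Loss-adaptive federated learning on clinical tabular data: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Loss-adaptive federated learning on clinical tabular data: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Intensive-care data sit in silos — different hospitals, different devices —
and usually cannot be pooled centrally. Federated learning sidesteps this by
training models where the data live: a server distributes model weights to
*clients* (data-holding sites), each client runs local gradient descent, and
the server aggregates the returned weights. `loadaboost` is a single-machine
simulator for this setting, built around mortality prediction from binary
drug-exposure indicators: each patient is a row of 0/1 flags over a drug
vocabulary, and the label is in-hospital mortality.

Three protocols are implemented:

* **FedAvg** — every sampled client trains exactly `E` local epochs per
  global round; the server replaces the global weights with the unweighted
  mean of the returned weights.
* **FedAvg with data-sharing** — a remedy for non-IID clients: the server
  holds a small IID pool `G` (a fraction `beta` of the total client
  examples, subsampled from a holdout set) and gives each client a random
  fraction `alpha` of `G` once, at initialization. Clients stay mostly
  decentralized but their local distributions move toward the population.
* **LoAdaBoost** — the loss-adaptive variant this package is named after.
  Each sampled client first trains `ceiling(E/2)` epochs and evaluates its
  training cross-entropy loss `L0`. If `L0` is at or below the *median* of
  the losses reported by the previous round's clients, it stops. Otherwise
  it is retrained in rounds `r = 1, 2, ...` of `max(ceiling(E/2) - r + 1, 1)`
  epochs, stopping as soon as its loss reaches the median or the cumulative
  epoch count hits the budget `floor(3E/2)`. The client reports the
  *pre-retraining* loss `L0` to the server (so next round's median reflects
  comparable half-schedule losses), together with its final weights. The
  median, rather than the mean, makes the criterion robust to a single
  badly-fitted client. Before round 1 the median is initialized to 1.0.

The point of the adaptive schedule is computational: underfitted clients get
more epochs, well-fitted ones fewer, and in expectation a client trains at
most `E` epochs per round — measured here by the *average epochs* metric,
the expected total number of epochs one participating client runs over a
whole federated process (for FedAvg this is exactly `T * E`).

### A deliberate reading of the retraining stop rule

The retraining loop is sometimes written with the stop condition "if the
retrained loss is *above* the median, return", which taken literally would
stop retraining precisely when it has not yet succeeded. This package
implements the intent instead: retraining continues until the loss drops to
the median **or** the `3E/2` budget is exhausted. Relatedly, for odd `E` the
initial half-schedule rounds up (`ceiling(E/2)`), the budget rounds down
(`floor(3E/2)`), and a retraining round that would overshoot the budget is
truncated to the remaining allowance rather than skipped — so the bound
"at least `E/2`, at most `3E/2` epochs" holds exactly for every `E`. The
unit tests check the resulting grant sequence against an independent
epoch-by-epoch replay of the rules for `E = 1, ..., 16`.

## The client model

Every client trains the same multilayer perceptron: inputs are the binary
drug indicators, three rectified-linear hidden layers of 20, 10 and 5 units,
and one sigmoid output unit; biases everywhere. At the default 2,814-drug
input width this is 56,571 trainable parameters. The loss is binary
cross-entropy; optimization is minibatch Adam with the standard defaults
(`eta = 0.001`, `beta1 = 0.9`, `beta2 = 0.999`) and minibatch size
`B = 30`.

Choices the protocol statement leaves open, fixed here as follows:

* **Loss normalization.** The cross-entropy is averaged over examples
  (rather than summed) so client losses are comparable across shard sizes;
  with equal-sized shards — every reference configuration — the two differ
  by a constant factor and induce identical retraining decisions. The sum
  is available via `reduction = "sum"`.
* **Initialization.** Glorot-style uniform from the run seed; all clients
  start round 1 from the same `w_0`, and the initial weights depend only on
  the seed, never on the method — so method comparisons share their starting
  point exactly.
* **Minibatch order** is reshuffled every epoch from a per-(round, client)
  seed. Per-client randomness is derived as `derive_seed(seed, round,
  client_id)`, which makes client updates order-independent ("parallel"
  semantics) and lets a LoAdaBoost round in which nobody retrains reproduce
  a half-epoch FedAvg round bit for bit — a tested identity.
* **Adam state** (first/second moments) is created fresh at every
  `train_local()` call, including each retraining round; only weights are
  carried across rounds, matching the weights-only communication model.
* **Numerical safety.** Predictions are clipped to `[1e-7, 1 - 1e-7]`
  inside the loss so it stays finite at saturated sigmoids; Adam uses the
  matching `1e-7` denominator constant.

## The synthetic cohort generator

The real ICU extracts this simulator emulates are credential-restricted, so
the package ships a generator whose *defaults* mirror the published summary
of a 30,000-patient extract: 2,814 binary drug features, mortality
prevalence 0.30, P(age > 65) = 0.535, P(male) = 0.424. Mortality follows a
sparse logistic model

`logit(p_i) = c + w . x_i + a * age_i + g * gender_i`

with a fraction `effect_sparsity` (default 10%) of drugs carrying
`N(0, effect_scale^2)` log-odds effects and covariate coefficients
`a = 0.9`, `g = 0.3` (older and male patients at higher risk — the sign
structure, not the magnitudes, is what matters downstream). The intercept
`c` is calibrated by bisection on the expected prevalence (the map
`c -> mean(plogis(c + eta))` is monotone, so bisection to `1e-6` is exact
for practical purposes); a target that the saturated linear predictor cannot
reach raises an explicit calibration error. A fraction of drugs (default
20% per covariate) have their prevalence shifted on the logit scale by
`covariate_coupling` for older/male patients, so that sorting by
(AGE_GROUP, GENDER) — the non-IID partitioning — induces genuine covariate
shift in the *features*, not only in the labels.

Partitioning mirrors the reference protocol: IID shards are a random
permutation cut into equal contiguous slices; non-IID shards are equal
slices of the cohort stably sorted by (AGE_GROUP, GENDER), age first. Equal
shard sizes are enforced (an error on non-divisible counts) because every
reference configuration divides exactly. The holdout split is a uniform
sample, which is what makes the shared pool IID.

What the generator does **not** emulate: temporal prescription structure,
dosage, multi-admission patients, drug co-occurrence beyond what the
covariate coupling induces, and any real drug-mortality pharmacology. Tests
passing on synthetic cohorts therefore validate the *mechanics* (protocol
arithmetic, schedules, estimator behaviour under controlled signal), not
clinical performance on real ICU data; the published absolute AUCs on the
restricted databases are out of reach by construction and are not asserted
anywhere.

## The ETL stage

For users holding schema-compatible extracts, `cmd_etl()` reproduces the
preprocessing on CSV tables shaped like ADMISSIONS / PATIENTS /
PRESCRIPTIONS: inner-join admissions and patients on `SUBJECT_ID` into a
personal-information table (`AGE_GROUP` binarized at 65, `GENDER` 0/1,
`MORTALITY` 0/1), select prescriptions whose `ENDDATE - STARTDATE` is
exactly two calendar days (the literal first-48-hours criterion; a
`rule = "within"` switch relaxes this to at most two days, since "first 48
hours" is also readable inclusively), and pivot to a binary subject-by-drug
matrix whose column order is first-appearance order. Decisions taken where
the source schema is ambiguous: age is computed at the *earliest* admission
(`floor((ADMITTIME - DOB) / 365.25)` years); a subject expired on *any*
admission counts as a mortality; the mortality source column is
configurable (default `HOSPITAL_EXPIRE_FLAG`); drug names are matched
exactly, without case folding, to avoid silently merging distinct products.
Subjects with no qualifying prescription keep an all-zero feature row
whenever the caller passes the id universe (as `cmd_etl()` does), matching
the published worked example in which one patient has no exposure among the
listed drugs.

## Evaluation apparatus

* **AUC** is the rank-based (Mann-Whitney) statistic with midrank ties —
  invariant under monotone transforms of the scores, and cross-checked in
  the tests against an independent ROC implementation.
* **Curves** are presented as running maxima (`best_so_far()`), and "AUC at
  convergence" is operationalized as the running maximum at `T_max`,
  matching the monotone presentation the curves use.
* **Cross-validation** is at client level: folds partition *clients*, not
  examples (10 folds of 9 clients at the reference scale). Each fold in
  turn is held out, the method trains on the remaining clients, and the
  held-out fold's pooled examples are scored with the final global model.
  One AUC per repeat is computed from the pooled cross-fold predictions
  (not the mean of per-fold AUCs). Repeats re-randomize the fold assignment
  only; the example-to-client sharding stays fixed, so repeat variance
  reflects fold assignment and training stochasticity. Fold assignment
  depends only on the plan seed and repeat index — two methods evaluated
  under one plan see identical folds, giving a paired design.
* **The paired test** is the exact one-sided Wilcoxon signed-rank test,
  computed by full enumeration of the `2^n` sign assignments (as a rank
  convolution; ties handled by doubled midranks, zeros dropped). With five
  repeats all favouring one method the one-sided p is `1/32 = 0.03125` —
  the smallest value the design can produce, which is why a one-sided exact
  test is the default. A two-sided option exists.

## Problem sizes in the tests and acceptance script

The analytic identities (parameter count, pool/shard arithmetic, schedule
oracle, reduction identity, `T * E`) are checked at the reference scales
they are stated at, which costs nothing. The stochastic properties use
desk-scale cohorts chosen once: the epoch-efficiency property runs 30
clients of 100 patients with 50 drug features over 20 rounds and five
seeds; the data-sharing property runs 90 clients of 100 patients (so the
per-client share keeps the reference geometry `alpha * beta * K = 18%` of a
shard) over 15 rounds and six seeds, on a cohort generated with strong
covariate effects (`a = 2`, `g = 1`) and strong feature coupling
(`covariate_coupling = 2` on 30% of drugs) so the sorted partition is
severely heterogeneous — the regime the data-sharing strategy targets. The
strong-signal CV check uses 8 clients, 4 folds, `effect_scale = 3`, and 30
rounds.

## Known limitations

* Training is plain R matrix algebra on one thread — faithful and
  deterministic, but not fast; the full 2,814-feature, 90-client reference
  runs are hours-scale, which is why tests operate at reduced width.
* The simulator models neither communication failures, stragglers, secure
  aggregation, nor privacy mechanics; "communication cost" exists only in
  the sense that LoAdaBoost additionally transmits one scalar loss per
  client per round.
* With `C = 0` the protocols still train one client per round
  (`m = max(floor(C * K), 1)`), a floor the sampling rule imposes by
  design.
* The generator's covariate coupling is a stylized stand-in for real
  demographic prescribing patterns; its skew is tunable but cannot be
  calibrated against the restricted source databases.
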