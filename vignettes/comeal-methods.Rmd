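---
title: "Cost-sensitive multi-expert active learning: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cost-sensitive multi-expert active learning: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(comeal)
```

## The problem

A wearable activity-recognition model trained for one setting degrades when
the setting changes: a new wearer (*context change*), a new sensor
(*configuration change*), or new activity classes to recognize (*user-need
change*). Collecting a fresh labeled dataset for every change is expensive.
This package implements a cost-sensitive adaptation loop built on two
ideas:

1. **Transfer initialization.** Seed the new learner with the most similar
   labeled data from related source domains (other wearers, other sensor
   locations), matched cluster-to-class by cosine similarity.
2. **Multi-expert active learning.** Query labels only for the most
   informative unlabeled instances, and route each query to the cheapest
   annotator ("expert") that is confident enough. Experts are heterogeneous:
   an (almost) always-correct but expensive *perfect* expert, cheaper
   error-prone *imperfect* experts, and free *on-demand* experts confident
   only on a subset of labels. Newly labeled data is *broadcast* to all
   updatable experts, so cheap experts grow more confident and absorb an
   increasing share of future queries.

## Formal setup

Let $L = \{\ell_1,\dots,\ell_k\}$ be the label set and
$E = \{e_1,\dots,e_p\}$ the expert set. Each expert carries an
*uncertainty score vector* $\vec U = (u_1,\dots,u_k)$ with
$u_i \in [0,100]$ (0 = fully confident on $\ell_i$), and a per-query cost.
Given the unlabeled target pool $X_U$ and labeled pool $X_L$, the system
selects a subset of $X_U$ and one expert per selected instance so that the
total annotation cost $\sum_i \sum_j \beta_i \alpha_{ij} c_{ij}$ is
minimized subject to each selected instance being asked from exactly one
expert ($\sum_j \alpha_{ij} = 1$) and the learner's uncertainty ending
below a threshold $\vec U_{th}$. The joint problem is NP-hard even when the
selected instances are fixed, so the implementation is greedy; an exact
small-instance oracle (`exact_assignment_oracle()`) certifies the greedy on
instances of up to 12 queries by 8 experts, where the per-instance
constraint structure makes the optimum decompose into independent
per-instance cost minima.

### Query strategies

The learner is a probability random forest (10 trees by default, matching
common practice for inertial-sensor recognition). Informativeness of an
unlabeled instance $x$ is measured as

* **entropy**: $-\sum_i P(\ell_i \mid x) \log P(\ell_i \mid x)$ in nats,
  maximized by a uniform posterior;
* **leaf purity**: $1 - \frac{1}{T}\sum_t \mathrm{purity}_t(x)$, where
  $\mathrm{purity}_t(x)$ is the majority-class fraction of the training
  samples in the terminal node of tree $t$ that $x$ falls into — a
  committee-disagreement score obtained from the forest itself;
* **hybrid** (default): the equal-weight mean of the two scores after
  min–max normalization over the query pool. The combination weights are a
  package choice; equal weights keep the two signals symmetric.

Leaf purity is tabulated over the *full* training set at fit time (not only
each tree's bootstrap sample), so scores on well-separated training data
are near 0 but rarely exactly 0. Ties in the top-$K$ selection are broken
by pool insertion order, for determinism.

### Learner uncertainty

The per-label uncertainty of the learner over a pool is
$u_\ell = 100\,(1 - \overline{\max_i P(\ell_i \mid x)})$, averaged over the
pool instances predicted as $\ell$; labels never predicted (including
labels the model has not yet seen) get $u_\ell = 100$. This
confidence-complement form needs no target labels, which is what the
deployment setting requires. It is a package design choice: the framework
only requires *some* per-label uncertainty functional of the model.

### Expert simulation

Experts are simulated the way a study harness would build them from a
labeled corpus, split 50/50 into an *expert initialization* and an
*evaluation* subset (stratified by label, floor rule, seeded shuffle):

* **perfect**: answers with ground truth, flipped to a uniformly random
  wrong label with probability `error_rate` (1–10% is typical); uncertainty
  $100 \times$ `error_rate` on every label; highest cost; never updates.
* **imperfect**: a forest trained on a stratified `data_fraction` (5–10% by
  default) of the initialization split; updatable.
* **on-demand**: a forest trained on all initialization data for its
  *confident labels* plus `n_other = 3` instances per other label; it
  abstains whenever its prediction falls outside the confident set; zero
  cost by default; updatable.

Updatable experts recompute their uncertainty after every collaboration
round as their per-label error rate on the evaluation split
($u_\ell = 100 \times P(\hat y \neq \ell \mid y = \ell)$; labels absent
from their training data are pinned at 100), and their cost as
`base_cost * mean((100 - u)/100)` — cost grows with confidence, so a
well-trained cheap expert is still cheaper than the perfect one by
construction of the base costs.

The default pool gives on-demand experts *overlapping* confident subsets
(about a quarter of the label set each, at least two labels, round-robin
offsets). Overlap lets two on-demand experts corroborate a phase-1
majority; with disjoint singleton scopes, any single non-abstaining expert
would constitute a "majority" of one, which makes phase-1 resolutions only
as reliable as one possibly overconfident annotator.

### The annotation routine

`annotate()` implements greedy two-phase expert selection. Phase 1 queries
every on-demand expert (charged their usually-zero cost); a majority label
among the non-abstaining answers becomes the new semi-label, with working
uncertainty equal to the minimum uncertainty on that label among the
agreeing experts. Phase 2 loops while the working uncertainty exceeds the
threshold for the current semi-label: among perfect/imperfect experts whose
uncertainty on the semi-label is within threshold, the cheapest is asked;
its answer becomes the semi-label and its uncertainty on that answer the
new working uncertainty. Two ambiguities are resolved as follows: the
working uncertainty starts at the sentinel 100 (so phase 2 always engages
when phase 1 produces no majority), and when answers keep revising the
semi-label, after as many iterations as there are experts the cheapest
perfect expert is forced and its answer accepted. If no expert can ever
satisfy the threshold for a label, an escalation error names that label —
a correctly configured pool prevents this via the perfect expert's low
uncertainty.

Thresholds may be given per label or as a scalar; values in $(0, 1]$ are
read as fractions of 100. Uncertainty vectors are percentages throughout,
but reported operating thresholds in this literature are usually fractions
(e.g. 0.2), so both conventions are accepted.

### Transfer initialization

`initialize_learner()` clusters the unlabeled target data with k-means
($k = |L|$, 10 restarts, seeded), computes per-source per-label class
centers (feature means, symmetric with the cluster centers), and assigns
clusters to labels by greedy maximum-weight one-to-one matching on cosine
similarity — one-to-one matching prevents two labels claiming the same
cluster, a case a plain argmax would not resolve. For each label the source
with the most similar class center is selected, and the union of the
per-label source subsets initializes the labeled pool; different labels may
draw from different sources. Whether to weight similarity by cluster size
is an open choice; the implementation does not, keeping the matching purely
geometric.

### Driver variants

`run_driver()` implements the loop with variants: **CAL** (transfer +
collaboration), **CAL\*** (CAL plus a prior-knowledge path that auto-labels
target instances whose prior-model posterior reaches `confidence_floor`,
default 0.9), **NCAL** (no broadcast/uncertainty refresh), **RAL** (random
query selection), and **STL** (a no-query baseline that adds the next most
similar source domain each round). The loop stops when the learner's
uncertainty is within threshold on every label or when a
`budget_fraction` of the initial unlabeled pool has been queried. The
budget cap is a deliberate addition: fixed-budget experiments (the usual
way query-efficiency is reported) set `stop_uth = 0` so runs always use the
full budget, while deployment-style runs leave the stopping threshold tied
to `u_th`.

## The synthetic world generator

All algorithms are exercised on synthetic worlds, so their statistical
assumptions are explicit:

* **Raw streams** (`generate_world()`): each (label, location) has a base
  waveform — a sum of 2–3 sinusoids with label-specific frequencies
  (0.5–3.5 Hz) and amplitudes plus a DC offset, mimicking periodic
  locomotion; each subject applies an affine transform (gain in
  $[1-s, 1+s]$, offset $N(0, s^2)$), emulating inter-subject variation in
  speed and amplitude; Gaussian sensor noise is added on top. Every stream
  contains every label.
* **Feature worlds** (`generate_feature_world()`): a shortcut past the
  signal pipeline — per-class Gaussian clusters with class centers a
  configurable distance apart (exactly `class_sep` when the feature
  dimension allows an orthonormal construction) and per-subject mean shifts
  $N(0, s^2 I)$.

All randomness flows from a single root seed through named substreams
(world / shift / noise / split / experts), so any component can be
regenerated independently and whole experiments are bit-reproducible.

What the generator does *not* emulate: sensor dropout, label noise in the
ground truth, non-stationary activity patterns within a subject,
heavy-tailed noise, and the temporal autocorrelation of real inertial
windows. Passing tests on these worlds show the algorithms implement their
contracts and reproduce the qualitative orderings (informative beats
random querying; collaboration and on-demand experts relieve the expensive
expert; more tolerance means fewer expensive queries) — they do not certify
accuracy levels on any real dataset.

## Scenario harness and experiment sizing

`build_scenario()` constructs the three reconfiguration scenarios on a
feature world. The target domain's instances are split half into the
unlabeled query pool and half into labeled data, the latter split 50/50
into expert initialization and evaluation. Related source domains are
subsampled to `n_source_per_class = 25` labeled instances per class: source
contexts realistically contribute brief labeled calibration sessions while
the target wears the device continuously, and this keeps the query budget
a meaningful share of the total supervision — if transferred source data
dwarfs the query budget, no query strategy could matter either way.

The experiment defaults used by the test-suite and the acceptance script:
4 activity classes, 3 subjects, 6 features, 100 target instances per class,
class separation 3.5 with unit within-class spread, subject shift scale 1.2
(a displacement comparable to the class separation, so transfer
initialization is useful but imperfect), query batches of $K = 10$ at a
15% budget for accuracy comparisons. The collaboration comparison uses a
40% budget and threshold 0.3, because the collaboration gap compounds over
rounds and the threshold must sit above the collaborated experts'
achievable evaluation-error floor for expert feasibility to ever flip.
These problem sizes keep a full 20-seed paired experiment in the
one-minute range on a single core.

## Numerical choices and degenerate inputs

* Windowing uses 0-based offsets and half-open windows; a trailing partial
  window is discarded; a window whose majority label ties is discarded
  (activity-boundary windows carry label noise); window count follows
  $\lfloor (N - W)/S \rfloor + 1$.
* The moving average is centered with edge windows truncated to the
  available samples; width defaults to 5 samples.
* Zero-crossing counts ignore exact zeros, so constant channels score 0.
* Posteriors must sum to 1 within $10^{-6}$; entropy treats
  $0 \log 0 = 0$.
* A single-label training set yields a degenerate learner with one-hot
  posteriors; an empty one is an error.
* Stratified splits use the floor rule per label; a label whose floor is 0
  simply drops out of the sample (and the resulting expert is maximally
  uncertain on it).
* k-means initialization failures for fewer distinct points than clusters
  raise an initialization error rather than silently degrading.

## Known limitations

* Expert uncertainty is recall-based (error among instances *of* a label),
  which cannot detect an expert that over-predicts a label it happens to
  recall well; the overlapping on-demand scopes mitigate this through
  corroborated majorities, but a precision-aware uncertainty would be a
  natural extension.
* The exact assignment oracle certifies the expert-selection step, not the
  joint instance-selection problem, which is NP-hard.
* No cross-device resampling, feature-space mapping between heterogeneous
  sensors, or signal-level fusion across locations.
* Costs are constant per expert per query; batch pricing and annotator
  fatigue are out of scope.

## A worked run

```{r example, eval = FALSE}
scen <- build_scenario(
  "context_change",
  world_config(n_subjects = 3, n_locations = 1,
               subject_shift_scale = 1.2, seed = 11)
)
run <- run_scenario(scen, run_config(variant = "CAL", u_th = 0.2,
                                     budget_fraction = 0.15,
                                     stop_uth = 0, seed = 11))
print(run)
query_counts(run$ledger, "expert_kind")
total_cost(run$ledger)
```
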