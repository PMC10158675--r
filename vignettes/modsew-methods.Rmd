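---
title: "Methods: hourly MODS early warning, ensemble composition, and explanation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hourly MODS early warning, ensemble composition, and explanation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Multiple organ dysfunction syndrome (MODS) — acute, potentially reversible
dysfunction of two or more organ systems — is among the leading causes of
death in critically ill patients, and no specific treatment exists once it is
established. The practical lever is time: an alarm raised hours before the
diagnostic criterion is met lets clinicians intervene while intervention can
still change the trajectory. `modsew` implements a complete hourly
early-warning pipeline for elderly ICU patients: organ scoring and onset
detection, feature extraction with a 12-hour look-ahead label, a
nine-algorithm learner catalog, stacked-ensemble composition searched by
tabular Q-learning, a time-dependent clinical utility metric, Kernel-SHAP
attribution, and rule-screened counterfactual recommendations.

Real critical-care databases of this kind are credential-gated, so the
package ships a synthetic cohort generator with analytically known onsets;
every pipeline stage is exercised and tested against it.

# Organ scoring and onset detection

Each of six organ systems receives an hourly severity sub-score in 0–4 from
the worst value of its governing variable within the hour: minimum GCS
(neurologic), maximum creatinine (renal), maximum bilirubin (hepatic),
minimum oxygenation index PaO2/FiO2 (respiratory), minimum platelets
(hematologic), and — the one composite — the cardiovascular sub-score as the
maximum of the dopamine-, lactate-, and heart-rate-mapped scores. MODS onset
is the first hour at which at least `organs_required` (default 2) organs have
sub-score at or above `dysfunction_threshold` (default 2).

The exact cut-points of the scoring system we mirror are published only in
supplementary material we do not have; the defaults in
`default_score_table()` are Marshall-style placeholder bands, every band is
half-open and closed on the healthy side, and the whole table is a JSON
config (`inst/extdata/score_table_default.json`) so exact cut-points can be
dropped in without code changes. Whether "dysfunction" means sub-score ≥ 2 or
any nonzero score is likewise not fixed in the main text we follow; we default
to ≥ 2 and expose both knobs.

# The synthetic cohort

`simulate_cohort()` draws, per stay: age (uniform over `age_range`, with a
configurable fraction below 65 so cohort filtering is exercised), length of
stay (24 h plus an exponential tail with the configured mean), per-variable
observation times (exponential inter-arrival, mean `sampling_interval`
minutes), baseline values (stationary noise clipped inside each variable's
score-0 band), and per-observation thinning with probability `missing_rate`.
A Bernoulli(`mods_prevalence`) draw decides whether a deterioration episode
is injected: selected organs ramp linearly from healthy values to just below
the dysfunction band before onset, then step into the target band exactly at
the onset hour and plateau. Because baseline noise is clipped to score 0 and
the ramp crosses the dysfunction boundary inside the onset hour's window,
re-scoring the stay recovers the injected onset hour *exactly* — this
round-trip is asserted for every seeded stay.

Default world: 30% prevalence (mid-range of the 11–40% adult ICU incidence
reported in the literature), mean stay 72 h, onsets between hours 30 and 120,
10% missingness, hourly mean sampling. What the generator does *not* emulate:
waveform-level physiology, pharmacology, correlated multi-organ trajectories,
or informative sampling (sicker patients being measured more often). A green
test therefore establishes that the pipeline's mechanics are correct, not
that its learned models would transfer to real patients.

# Entries, features, labels

Stays are filtered (age ≥ 65, first ICU stay, stay longer than 24 h, missing
feature rate below 30%; "missing feature rate" is not defined in our source
and defaults to the fraction of the eight variables never observed during
the stay, with a per-hour alternative available). Observations are aggregated
into hourly windows `(h-1, h]`; empty windows are forward-filled then
back-filled per variable. Organ sub-scores are *recomputed* from the filled
clinical values, never imputed directly. A variable never observed at all
falls back to its healthy reference value so feature vectors stay complete —
cohort filtering bounds how often this can happen.

Each patient-hour becomes one entry with exactly 37 features: mean/max/min of
the eight variables (24), the elapsed ICU hour, six current organ sub-scores,
and six trailing-24-hour maxima of those sub-scores. The label looks 12 hours
ahead: `label(t) = 1` iff an onset exists with `onset <= t + 12`. Post-onset
hours remain positive (this matches the worked examples our label semantics
are anchored to: an entry at hour 60 with onset 72 is positive; an entry at
hour 229 with no onset by 241 is negative); a `truncate_at_onset` switch
drops post-onset entries. Features are z-scored with the *training* split's
mean and standard deviation; zero-variance features are centred only. Splits
are by patient, never by entry.

# Learners

The nine-member catalog (logistic regression, random forest, naive Bayes,
two gradient-boosting variants, kNN, decision tree, AdaBoost, and the
deep-wide network) sits behind one `fit_learner()` / `predict_proba()`
contract. The execution environment provides no tree, boosting, or neural
network packages, so these are implemented in-package: a single weighted CART
regression-tree engine (squared-error impurity, equivalent to Gini on 0/1
targets) backs the tree, forest (bootstrap + `sqrt(p)` feature subsampling),
AdaBoost (discrete, shallow trees, probabilities via the logistic link of the
margin), and both boosting entries (logistic loss with Newton leaf steps; the
two catalog members share the engine with xgboost-like and lightgbm-like
growth defaults — depth 3/rate 0.3 versus depth 6/rate 0.1 with subsampling —
mirroring the two boosted-tree rows of the study design). Hyperparameters are
library-standard defaults, documented as such, since the original study lists
none.

The deep-wide network (DWNN) is dense blocks of affine → batch-normalization
→ ReLU whose outputs are *all* concatenated (optionally with the raw input)
into a single sigmoid unit, so the loss gradient reaches every block directly
regardless of depth; batch normalization stabilizes the deeper blocks.
Training is Adam on class-weighted binary cross-entropy with an internal
early-stopping split; backpropagation (including through batch-norm) is
hand-written and was verified against numerical gradients to ~1e-10 during
development. Class imbalance is handled throughout by inverse-frequency class
weights normalized to preserve the total sample count.

# Stacked-ensemble composition by Q-learning

Two topologies are built in: the two-layer SuperLearner (eight base learners
feeding one meta learner that consumes their predicted probabilities) and the
three-layer SubSuperLearner (two base pairs feeding two first-level metas,
whose outputs join two further base learners as the four inputs of the
terminal meta). With nine slots and nine algorithms the exhaustive search
space is 9^9 = 387,420,489 configurations, which motivates the Q-learning
search (learning rate 0.1, discount 0.85, exploration 0.9 held fixed with an
optional linear decay, 5000 episodes by default).

Two design points deserve explanation:

* **State space.** The state is the slot index alone — exactly the shape of
  the published slot-by-algorithm Q-table — rather than the prefix of choices
  made so far. This is a deliberate simplification: the full-history state
  space would be as large as the search space itself.
* **Backup rule.** With slot-only states, the textbook terminal-reward TD
  update gives every non-terminal row an action-*independent* target
  (`gamma * max` of the next row), so earlier slots can never learn — which
  would contradict the requirement that the per-row argmax readout match
  exhaustive search on small problems. Rewards here are memoized per
  assignment and therefore deterministic, so the package instead applies an
  optimistic backup: `Q(s_i, a_i) <- Q + alpha (gamma^(S-i) r - Q)` only when
  the discounted episode return improves on the current estimate. Each entry
  then converges from below to the best discounted return achievable with
  that slot-action, whose row-wise argmax is the joint optimum's projection.
  Entries stay in [0, 1] for rewards in [0, 1]. The literal TD rule remains
  available (`update = "td"`) for comparison.

Rewards are the validation AUC (Youden index or utility score selectable) of
the assembled candidate on a held-out patient split, evaluated on a
subsampled training pool (the full-scale study subsampled its training
entries the same way). Base models are fitted once per algorithm — out-of-fold
columns for meta training, full-data fits for prediction — so total base fits
are bounded by the catalog size regardless of episode count. Meta learners
default to training on out-of-fold base columns (leak-free); the
refit-and-predict behaviour of the stacking tool the original study used is
available (`stacking = "refit"`) but measurably overfits at desk scale, where
in-sample base columns are far more optimistic than their out-of-sample
counterparts. For the three-layer topology, first-level meta outputs feed the
terminal meta in-sample (single-level out-of-fold; nested cross-validation
was judged not worth its cost here).

# Evaluation

Alongside AUC (rank-based, ties counted one half), accuracy, sensitivity,
specificity and the Youden index, the package implements a time-dependent
utility score: each patient-hour contributes a utility depending on whether
an alarm was raised and where the hour falls relative to onset. An alarm
earns a reward rising linearly from 0 at `onset - 12` to 1 at onset and
falling back to 0 at `onset + 3`; outside that window every alarm costs
-0.05 per hour. Silence during the window accrues a penalty ramping to -2;
silence elsewhere is neutral. These breakpoints mirror the physiological
early-warning utility this score is patterned on, re-centred on the 12-hour
MODS horizon — the exact published shape is in supplementary material we do
not have, so every breakpoint and level is a config field. The total is
normalized as `(U - U_silent) / (U_optimal - U_silent)`, so never alarming
scores 0 and alarming exactly on the reward window of deteriorating patients
scores 1. On a cohort with no deteriorating patients the anchors coincide;
the raw difference is returned instead (an always-alarm policy on such a
cohort scores `hours * u_fp`, negative). Normalization anchors are recomputed
per evaluated cohort, never cached.

# Kernel-SHAP

`explain()` estimates Shapley attributions by kernel-weighted least squares
over feature coalitions, with masked features replaced by values from a
frozen background sample (marginal masking) and the efficiency constraint
`base + sum(phi) = f(x)` eliminated exactly, so local accuracy holds by
construction in both enumeration and sampled modes. When the coalition budget
covers all `2^M - 2` interior coalitions the solution equals the exact
Shapley value; `exact_shapley()` provides the independent `2^M` enumeration
oracle (refusing M > 12) against which the kernel path is tested. The
production concern that re-training an explainer on incoming unlabeled
samples drifts its base value is addressed structurally: `background_snapshot()`
freezes a checksummed background sample, and explaining the same instance
against the same snapshot twice is bit-identical. The stacked ensemble is
explained end-to-end as a single black box through its predict-probability
function.

# Counterfactual recommendations

`generate_counterfactuals()` searches for up to `k` feature vectors that flip
a positive prediction below threshold while keeping immutable features
(by default the elapsed ICU hour) fixed. The stacked ensemble is not
differentiable, so the search is derivative-free, in two phases per
candidate: coordinate perturbations descend on the predicted probability
until it flips, then changed features are greedily restored to their original
values while the prediction stays flipped, minimizing the MAD-scaled L1
proximity. Later candidates down-weight features already used, so
changed-feature sets diversify; set diversity is reported as the determinant
of the kernel `K_ij = 1/(1 + proximity)`. Uniform sampling over admissible
ranges proved almost useless against tree ensembles whose positive
predictions are robust to uncoordinated perturbations — uniform draws land in
"sick" regions of feature space — so the recommended mode sources proposal
values from reference rows the model already predicts negative
(`reference_data =` training entries), analogous to dataset-sourced
counterfactual candidates in the diverse-counterfactual literature.

Plausibility is enforced twice. During search, each proposal is *repaired*:
organ sub-scores are rederived from the candidate's raw aggregates under the
score table, rolling maxima are floored at current scores, and min ≤ mean ≤
max is restored — so emitted candidates are physiologically coherent by
construction. Independently, `rule_screen()` implements the second-round
screening idea as three built-in rules (sub-score/aggregate consistency,
rolling ≥ current, aggregate ordering) plus arbitrary user predicates, for
candidates produced elsewhere. Because counterfactuals ignore the time
dimension, each report carries `act_before_hour` (instance hour + horizon):
the recommendation is only meaningful if acted on before the predicted onset
window closes.

# Numerical and engineering choices

* All randomness flows through explicit seeds; derived stream seeds stay
  within 32-bit range. Identical configs are byte-identical on disk.
* Observation files are written with `%.17g` so read(write(x)) reproduces
  every tuple exactly.
* Hour windows are half-open `(h-1, h]`, 1-based; an observation exactly on
  a boundary belongs to the earlier window's successor.
* Degenerate inputs: single-class labels are errors for class-conditional
  metrics and class weights; empty score sequences, empty cohorts, and
  missing aggregates are errors naming the offending field; an all-NA series
  is left unimputed and flagged.
* Ties: Q-table readout breaks ties at the lowest catalog index; AUC counts
  ties one half; kNN neighbours tie-break on stable order.
* Univariate feature screening (significance-filtered feature tables) is
  descriptive in our source and deliberately not part of the modelling path:
  models always consume all 37 features.

# Known limitations

* The default score-table cut-points and utility breakpoints stand in for
  unavailable supplementary tables; both are config, not constants.
* The synthetic world is easy relative to real ICU data (clean baselines,
  monotone ramps); absolute performance numbers on it say nothing about
  clinical performance.
* The slot-indexed Q-table cannot represent interactions between slot
  choices; it is used because it is the artifact the readout needs, with the
  optimistic backup making its argmax meaningful.
* Desk-scale runs shrink episode counts, boosting rounds, forest sizes and
  network epochs relative to defaults; the defaults keep the full-scale
  values.
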