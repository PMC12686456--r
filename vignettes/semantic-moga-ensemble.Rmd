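---
title: "Multi-objective genetic feature selection with regularized MLP ensembles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-objective genetic feature selection with regularized MLP ensembles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`semogen` implements a two-stage prediction framework for tabular binary
clinical cohorts of the Cleveland heart-disease type: a multi-objective
genetic algorithm (MOGA) selects compact feature subsets under four
competing objectives, and the selected subsets train a small ensemble of
regularized multilayer perceptrons (MLPs) whose outputs are fused by
uniform averaging, fitness-derived weights, or AdaBoost. This vignette is
the package's account of the method: the model, the parameters that
matter, the numerical choices, what the synthetic generator does and does
not emulate, and the known limitations.

## The selection problem

A candidate solution is a binary chromosome $c \in \{0,1\}^d$ over the $d$
base features (13 for the Cleveland schema); bit $j$ includes feature $j$
in the subset $S$. Each subset is scored on four directed objectives:

* **f1 — cross-validated accuracy** (maximize): the pooled
  $(TP+TN)/n$ of a surrogate classifier trained on $S$'s columns over
  stratified CV folds (5 by default, fixed per run so all subsets are
  compared on identical folds).
* **f2 — redundancy** (minimize): the mean absolute pairwise Pearson
  correlation among the selected features,
  $\frac{1}{|S|(|S|-1)}\sum_{i \ne j \in S} |\mathrm{corr}(i,j)|$,
  computed on the original numeric codes (not one-hot expansions), so the
  correlation matrix stays $d \times d$ and a categorical feature
  contributes a single column. Singletons score 0; pairs involving a
  zero-variance column contribute 0.
* **f3 — interpretability** (maximize): the mean of clinician-assigned
  scores in $\{1,2,3\}$. The default map scores age, sex, chol and
  trestbps 3; thal, ca and slope 2; restecg 1; unlisted features default
  to 2. The map is data (`interpretability_map()`, YAML-serializable),
  not code.
* **f4 — G-mean** (maximize): $\sqrt{\text{sensitivity} \times
  \text{specificity}}$ from the same pooled CV predictions as f1. It is 0
  whenever either class is entirely misclassified, which makes it the
  imbalance-sensitive term of the fitness.

Dominance uses the directed comparison (f1 up, f2 down, f3 up, f4 up).
The population is partitioned by fast non-dominated sorting; spread
within a front is preserved by crowding distance (boundary members get
infinite distance, interior members accrue normalized neighbour gaps, and
an objective constant across a front contributes nothing).

### Genetic operators and defaults

| Parameter | Default | Why |
|---|---|---|
| population size | 50 | diversity vs cost on a 13-bit space |
| generations | up to 100 | with stagnation stop below |
| stagnation patience | 10 | stop when the front-1 objective multiset (rounded to 1e-6) is unchanged this many generations |
| crossover | uniform, rate 0.9 | strong mixing on short chromosomes |
| mutation | 0.05 per bit | controlled variation |
| selection | tournament, size 3 | rank, then crowding, then draw order |
| elitism | 2 | see below |
| cardinality cap | 6 | repair, not penalty |

An alternative profile (`moga_config(exp11_profile = TRUE)`: population
100, 200 generations, tournament 2, per-bit mutation $1/13$, top-5%
elitism) matches the configuration used in optimizer benchmarking
studies.

Three choices here were genuinely open and deserve their rationale:

* **Repair, not penalty.** Offspring are repaired into
  $1 \le \mathrm{popcount} \le 6$ (surplus bits cleared uniformly at
  random; an empty chromosome gets one random bit). This keeps all four
  objectives well-defined on every individual; a penalty formulation
  would force arbitrary trade-off weights into a framework whose whole
  point is to avoid them.
* **Elites are per-objective champions** (accuracy first, then G-mean,
  then redundancy, then interpretability), not the top-crowding rank-1
  members. With up to eight boundary members all carrying infinite
  crowding distance, crowding-based elitism can drop the accuracy leader;
  champion-based elitism guarantees the best-f1 individual survives, so
  best-f1 is monotone across generations under memoized fitness.
* **Memoization.** Fitness is cached on the chromosome bits (plus the
  feedback-archive version). With at most 2,379 valid subsets at
  cardinality ≤ 6 over 13 bits, chromosomes recur heavily and the cache
  converts the wrapper search from hours to minutes.

### The fitness surrogate

During evolution f1/f4 are scored by the same MLP architecture as the
final members but on a reduced schedule: 30 epochs, no early stopping.
One adjustment was necessary to make that reduction sound: at the final
members' learning rate (0.001), 30 epochs leave the surrogate far from
convergence and systematically biased toward subsets with wide one-hot
expansions (wider inputs mean wider hidden layers and faster early
learning). The surrogate therefore trains at learning rate 0.01 by
default (`fitness_context(surrogate_lr = )`), which restores
oracle-level subset ranking — verified against a logistic-regression
oracle on planted-signal cohorts. The surrogate is a contract, not a
commitment: anything honoring fit/predict can stand behind f1/f4.

### Semantic feedback

The feedback variant (`feedback_mode = "on"`) closes the loop between
selection and ensemble: every 5 generations the per-objective champions'
out-of-fold probability vectors are archived, and a candidate's f1/f4
are then scored on the uniform fusion of the archived predictions with
the candidate's own. With an empty archive the evaluation reduces
exactly to the feedback-off case. This is one concrete formalization of
ensemble-informed selection; the mechanism is isolated behind
`feedback_mode` so other readings are pluggable.

## The ensemble stage

Four representatives are extracted from the final front — the champion
of each objective, ties broken by crowding distance then lexicographic
bits; a front smaller than four yields repeats. Each champion trains one
MLP on its own columns only.

**Architecture.** Input width $n_{in}$ is the selected subset's width
*after* one-hot expansion of its categoricals (so it can exceed 6); the
hidden layers follow it dynamically as $[2 n_{in}, n_{in}]$ with ReLU,
and a single sigmoid unit outputs $\hat y = \sigma(\omega^T a + b)$.
Training minimizes mean binary cross-entropy plus an L2 penalty
$\lambda \sum \omega^2$ on weights (biases unpenalized, $\lambda =
0.001$) with inverted dropout after each hidden layer, mini-batch Adam
(lr 0.001, $\beta_1 = 0.9$, $\beta_2 = 0.999$, $\epsilon = 10^{-8}$),
batch 16, up to 100 epochs, early stopping on a stratified 20%
validation split with patience 10, and restoration of the best epoch's
parameters. Weights initialize He-normal (scaled by fan-in), biases
zero — an explicit choice so training is bit-reproducible under a seed.
The dropout rate defaults to 0.2; 0.3 appears in some descriptions of
this architecture family and is exposed via `mlp_spec(dropout_rate = )`.
Inverted dropout (scaling at train time) keeps inference mask-free. The
numerical core is compiled (RcppArmadillo) because the wrapper fitness
retrains this network thousands of times per GA run.

**Fusion.** Three fusers share the member pool:

* *uniform*: $\hat y = \frac{1}{K}\sum_k \hat y_k$;
* *weighted*: weights from `moga_weights()` — each champion's objective
  vector is min-max normalized over the champion set (f2 inverted, an
  objective constant across champions contributing a neutral 0.5), the
  champion scalar is the mean of its normalized components, and weights
  are the scalars normalized to sum to 1 (uniform in the fully
  degenerate case);
* *adaboost*: boosting over the fixed member pool. Instance weights
  start at $D_1(i) = 1/N$; each round selects the member minimizing the
  weighted error $\epsilon_t$ of its 0.5-thresholded predictions
  (members reusable across rounds), sets $\alpha_t = \frac{1}{2}
  \ln\frac{1-\epsilon_t}{\epsilon_t}$ ($\epsilon_t$ clipped to
  $[10^{-10}, 1-10^{-10}]$), updates $D_{t+1}(i) \propto D_t(i)
  e^{-\alpha_t y_i h_t(x_i)}$ with labels in $\{-1,+1\}$, and stops
  early once every member errs at $\ge 0.5$. Prediction is
  $\mathrm{sign}\sum_t \alpha_t h_t(x)$ with the documented tie rule
  $\mathrm{sign}(0) \to +1$, and $\sigma(\sum_t \alpha_t h_t(x))$ as the
  probabilistic form. $T$ defaults to 10. The weak-hypothesis definition
  (pool member with minimal weighted error, reusable) is our
  concretization; the source family of methods names the boosted members
  without defining $h_t$.

## Preprocessing

Imputation is mean (or median) substitution for continuous features and
first-encountered-mode for categoricals; min-max scaling maps each
continuous feature's fitting split onto $[0,1]$ (a constant column maps
to 0 — it carries no information and this avoids division by zero), and
values transformed under previously fitted parameters are deliberately
not clipped. One-hot encoding expands categoricals with ≥ 3 levels to
`feature=level` indicators; binary features pass through unchanged
(expanding them would add a perfectly collinear complement). SMOTE
interpolates a minority seed toward one of its $k = 5$ nearest minority
neighbours on the continuous columns and copies the seed's categorical
values (a choice that guarantees valid levels); it is applied inside
training folds only, never to validation or test folds. The UCI
"processed" dialect maps outcome codes > 0 to 1. Stratum-wise
statistical descriptors (mean, SD, min, max, IQR per continuous feature;
own-level frequency per categorical) use linear-interpolation quartiles
(R type 7) and a default stratification of age tertiles crossed with
sex — the stratification is configurable because no single definition is
canonical; descriptor columns are appended to the schema but the
chromosome stays over the 13 base features by default.

## The synthetic cohort generator

`default_cohort_spec()` emulates the shape of the Cleveland data: 303
rows at prevalence 165/303, 5 continuous and 8 categorical/binary
features. Labels are Bernoulli; continuous features are class-conditional
Normal with unit variance and standardized mean shifts of 0.9 (oldpeak),
0.75 (thalach), 0.6 (age), 0.45 (chol) and 0.3 (trestbps); trestbps is
then rebuilt as $0.9 \cdot z_{\text{oldpeak}} + \sqrt{1-0.9^2}\,
\varepsilon$, a planted redundant pair that inherits most of oldpeak's
signal through the correlation. Categorical features are uniform with no
class association by default, so the ground truth for recovery tests is
unambiguous; class-conditional level tilts can be planted explicitly.
Class-conditional sampling (rather than a logistic link) was chosen so
the Bayes-optimal behaviour is analytically controlled in tests.

Perturbations for robustness studies: additive Gaussian noise on a
Bernoulli(fraction) mask over continuous cells with SD equal to
`noise_scale` feature-SDs (the "10/20/30%" of a robustness grid is read
as the *fraction of cells perturbed*, with the magnitude an independent
knob defaulting to 1 SD — both readings are therefore runnable), and
MCAR missingness over all cells (fraction 1 is refused; "randomly
omitting" is read as MCAR, with MAR/MNAR out of scope).

What the generator does *not* emulate: real measurement scales and
units, skewed or heavy-tailed marginals, feature interactions beyond a
single linear correlation, label noise, and structured (MAR/MNAR)
missingness. Tests passing on these cohorts demonstrate that the
machinery recovers known planted structure under controlled conditions —
not that the pipeline attains any particular accuracy on real clinical
data.

## Evaluation toolbox

Confusion-derived metrics return 0 with a degeneracy flag on zero
denominators so batch evaluation never aborts on a degenerate fold; MCC
uses the four-cell correlation form with the same convention. AUC is the
rank-based (Mann–Whitney) estimator with ties counting one half.
Diversity uses Yule's Q on the joint-correctness table, the disagreement
measure $(N_{01}+N_{10})/n$, and Kuncheva's entropy
$\frac{1}{n}\sum_j \min(l_j, L-l_j) / (L - \lceil L/2 \rceil)$. The
ensemble variance index is the mean per-sample population variance of
member probabilities (≤ 0.25 for probabilities), averaged over folds
when used in cross-validation. The robustness index and the ablation
degradation are the same functional, $100 (v_{\text{ref}} - v) /
v_{\text{ref}}$, rounded half-up to two decimals to match tabular
reporting conventions.

## Experiment harnesses and study sizes

`run_variant()` compares the traditional pipeline (accuracy-only GA
feeding a single MLP — the single-objective reading of a selector the
literature leaves unspecified), the cascade (full MOGA, no feedback,
AdaBoost fusion) and the feedback variant, on identical folds and
derived seeds (paired design). `ablation_experiment()` removes one
component at a time: fitness reduced to f1 ("ensemble terms"), weighted
fusion replaced by uniform ("MOGA weighting"), representative extraction
replaced by top-4-by-accuracy ("diversity constraint" — our
concretization of removing a component whose removal mechanism is never
defined). `weighting_comparison()` concretizes "heuristic" weights as
validation-accuracy-proportional. `imbalance_comparison()` runs
accuracy-only, SMOTE-augmented, and four-objective arms; the
accuracy-only reading of the "standard" arm matches the single-objective
baseline the framework is contrasted against.

The bundled studies fix their problem sizes once:
`planted_recovery_study()` runs 10 seeded GA searches at $n = 600$ with
population 36 and up to 50 generations (about a minute per run on one
core); `ensemble_benefit_study()` runs 20 seeds at $n = 300$;
`imbalance_mechanism_study()` runs paired arms at $n = 400$ with a
compact search (population 14, 10 generations) — the contrast between
arms, not the absolute numbers, is the quantity of interest.

## Known limitations

* **Minority recall at strong imbalance is below the detection limit of
  the prescribed architecture.** At prevalence 0.1 the member networks —
  min-max inputs, Adam at 0.001, batch 16, dropout 0.2, ≤ 100 epochs,
  fixed 0.5 threshold — do not push any minority probability across the
  threshold on cohorts of a few hundred rows, so minority recall is 0
  for every subset, the G-mean objective is uniformly 0, and the
  four-objective and accuracy-only arms tie. The imbalance study
  tabulates exactly this. The G-mean mechanism is measurable at
  moderate imbalance (the suite demonstrates f4 separating informative
  from uninformative subsets at prevalence 0.3); at 10:90 one would in
  practice lower the decision threshold, reweight the loss, or extend
  training — all outside the prescribed configuration, so the package
  reports the honest zeros instead.
* Wrapper accuracy at these cohort sizes carries ~1–2% fold noise;
  subsets whose marginal value is below that (a 0.3-SD shift, or the
  second member of a ρ = 0.9 pair) are recovered only inconsistently by
  an argmax over noisy evaluations. This is a property of wrapper
  selection, not of the implementation.
* The GA assumes binary outcomes and tabular features; no multi-class
  targets, longitudinal records, imaging or text.
* Determinism is per-platform: identical seeds reproduce identical runs
  on the same numerical libraries; exact bit-reproducibility across
  BLAS builds is not guaranteed.
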