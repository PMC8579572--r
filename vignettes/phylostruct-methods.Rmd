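---
title: "Resolving host population structure from tree shape: models and methods"
author: "phylostruct"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Resolving host population structure from tree shape: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phylostruct)
```

## The problem

Pathogen phylogenies carry a signature of the host population they spread
through. When a host population is split into sub-populations (demes) with
different transmission intensities that exchange migrants — say a general
population and a high-risk community — the resulting transmission trees are
shaped differently from trees grown in a single homogeneous population.
`phylostruct` turns that observation into a testable, automatable pipeline:
simulate trees under both population types, summarise each tree by eight
topological shape statistics, test whether the statistic distributions
differ, and train classifiers that label a tree as coming from a
*structured* or *non-structured* host population. The intended users are
molecular epidemiologists who already have rooted trees (e.g. bootstrap
replicates of an ML phylogeny) and want a calibrated structured/unstructured
call, and methodologists studying which balance statistics carry the
structure signal.

## The simulation model

### Two-deme birth-death-migration process

A structured population has two demes $S_1$, $S_2$. A lineage in deme $i$
gives birth within its deme at rate $\lambda_i$, dies at rate $\mu_i$, and
migrates to the other deme at rate $\alpha_{ij}$ (all per lineage, per unit
time). With $N_i(t)$ extant lineages, the waiting time to the next event in
deme $i$ is exponential with rate $N_i(t)\,T_i$, where
$T_i = \lambda_i + \mu_i + \alpha_{ij}$ is the deme's per-lineage sub-total
rate. The deme of the next event is selected by comparing a uniform draw
with $T_i / (T_i + T_j)$, and the event type within the selected deme by a
second uniform draw against the cumulative fractions $\lambda_i / T_i$
(birth) and $(\lambda_i + \alpha_{ij})/T_i$ (migration), with death
otherwise. The lineage experiencing the event is uniform among the deme's
extant lineages (lineages are exchangeable).

Two remarks on the deme-selection rule. Weighting demes by $T_i$ alone is
*not* the standard Gillespie composition (which would weight by
$N_i T_i$, the demes' total rates). We implement the sub-total-rate rule as
the default because it is the procedure the pipeline is built to reproduce,
and expose `weighting = "population"` in `select_deme()` /
`sim_bdm_tree()` for the exact Gillespie alternative. Empty demes get zero
weight under either rule, since no event can happen there.

A migration event appears in the tree as a *unifurcating deme-change node*:
the same individual continues on a single descendant edge whose deme label
differs. A structured tree with $n$ tips therefore has at least $n-1$
internal nodes; a non-structured tree has exactly $n-1$.

### Termination, pruning, and the crown convention

Simulations start from a single lineage (in deme 1 by default) and stop
once the configured number of extant lineages is reached. For structured
trees two stopping interpretations are implemented:

* `stop_rule = "joint"` — stop at the first event at which *both* demes
  have reached their per-deme targets (the targets then act as quotas; the
  faster-growing deme overshoots while the slower one catches up);
* `stop_rule = "total"` — stop when the *total* number of extant lineages
  first reaches the sum of the targets, so every structured tree has
  exactly that many tips (550 under the default design), with the per-deme
  split left to the dynamics.

`sim_bdm_tree()` defaults to `"joint"` and records the interpretation in
its `sim_info` attribute. The dataset designs (`baseline_config()` and
friends) default to `"total"`, for three reasons. First, the reference
design reads most naturally as fixed-size trees (350 + 200 tips). Second,
the quota rule couples tree size to the rate parameters: under the default
rates it drifts to roughly 820-tip structured trees, and under the
sensitivity designs — where deme 1 may be subcritical and is only rescued
by immigration from an exploding deme 2 — it requires tens of thousands of
lineages before the quota binds, which is a runaway regime. Third, the
quota rule confounds class and tree size so strongly that the two classes
become almost disjoint in every statistic, which is not the moderate
separation the comparison stage is designed to quantify.

After termination, dead lineages are pruned: dead tips and the internal
nodes left without surviving descendants are removed, bifurcations reduced
to one surviving child are spliced out (their branch lengths merge), and
migration unifurcations are kept. The returned tree is the *crown* tree,
rooted at the first bifurcation with surviving descendants on both sides;
stem nodes above it (including any stem migration nodes) are discarded, so
the root of every returned tree is a bifurcation. Branch lengths are the
accumulated exponential waiting times; every statistic below is purely
topological, so branch lengths never affect downstream results.

If the process dies out before reaching its target the attempt restarts
from scratch, up to `max_retries = 100` times, then errors. Each tree draws
its own seed (dataset seed + replicate index), so any replicate can be
regenerated in isolation and datasets are reproducible end to end.

## R0 parameterisation

The deterministic counterpart of the process is
$$\frac{dS_1}{dt} = (\lambda_1 S_1 + \alpha_{21} S_2) -
  (\mu_1 S_1 + \alpha_{12} S_1), \qquad
\frac{dS_2}{dt} = (\lambda_2 S_2 + \alpha_{12} S_1) -
  (\mu_2 S_2 + \alpha_{21} S_2),$$
with disease-free equilibrium $(0,0)$. Linearising new-infection and
transition terms there gives $F = \mathrm{diag}(\lambda_1, \lambda_2)$ and
$$V = \begin{pmatrix} \alpha_{12}+\mu_1 & -\alpha_{21} \\
                      -\alpha_{12} & \alpha_{21}+\mu_2 \end{pmatrix},$$
and $R_0$ is the dominant eigenvalue of $F V^{-1}$. `r0_general()`
implements the closed form (numerator
$\alpha_{21}\lambda_1 + \alpha_{12}\lambda_2 + \lambda_2\mu_1 +
\lambda_1\mu_2 + \sqrt{\Delta}$ over
$2(\alpha_{21}\mu_1 + (\alpha_{12}+\mu_1)\mu_2)$) and, as an independent
check, the numeric eigenvalue route (`method = "eigen"`); the two agree to
ten significant digits across the test suite's random draws. The
discriminant satisfies
$\Delta = (\lambda_1(\alpha_{21}+\mu_2) - \lambda_2(\alpha_{12}+\mu_1))^2 +
4\lambda_1\lambda_2\alpha_{12}\alpha_{21} \ge 0$, so the closed form is
real for all nonnegative rates.

Simulation designs are parameterised through two *special-case
conventions*, inverted to get birth rates from target $R_0$:

* unstructured: $R_0 = \lambda/\mu$, so $\lambda = R_0\,\mu$;
* structured, per deme: $R_0 = \lambda/(2\alpha + \mu)$, so
  $\lambda = R_0\,(2\alpha + \mu)$ (`r0_structured_deme()`,
  `birth_rate_for_r0()`).

The per-deme convention treats emigration as a removal channel entering
the denominator with weight two, and is deliberately *not* the NGM
eigenvalue of the coupled system: substituting proportional deme rates
($\lambda_2 = k\lambda_1$, $\mu_2 = k\mu_1$, $\alpha_{21} = k\alpha_{12}$)
into the general closed form yields $\lambda_1/\mu_1$, not
$\lambda_1/(2\alpha_{12}+\mu_1)$. We keep both quantities exposed and
clearly named: the per-deme formula is the operational convention that
produces the study's birth rates; the NGM value is the epidemiologically
interpretable threshold quantity, and `sim_bdm_tree()` warns when it is at
or below one.

### Default parameter values

The defaults encode an HIV-like two-risk-group setting: death rate 0.014
per year in the general (low-risk) deme and $3 \times 0.014 = 0.042$ in
the high-risk deme; migration 0.3 (low to high) and 0.2 (high to low);
deme-level $R_0$ 4.99 and 9.09, giving birth rates
$4.99 \times (2\cdot0.3 + 0.014) = 3.0639$ and
$9.09 \times (2\cdot0.2 + 0.042) = 4.0178$; unstructured trees use
$\mu = 0.014$, $R_0 = 4.99$, $\lambda = 0.0699$. Baseline tree sizes are
350 tips (non-structured) and 350 + 200 (structured), with 500 trees per
class.

## Tree-shape statistics

Eight statistics, with three normalisations, summarise each rooted tree
(`tree_shape_stats()`):

| statistic | definition | normalisation |
|---|---|---|
| cherries | internal nodes whose two children are both leaves | $/(n/2)$ |
| Sackin | sum over leaves of root-to-leaf edge counts | $/(0.5\,n(n{+}1)-1)$ |
| Colless | sum over bifurcations of left/right subtended-leaf differences | $/\frac{(n-1)(n-2)}{2}$ |
| total cophenetic | sum over leaf pairs of LCA edge-depth | — |
| ladder length | longest chain of internal nodes with exactly one leaf child, over $n$ | — |
| maximum depth | deepest leaf (edges) | — |
| maximum width | most nodes at any one depth | — |
| width/depth | maximum width over maximum depth | — |

Migration nodes need a convention, and the package pins one that is
internally consistent and reproduced exactly by the shipped worked
example (`example_structured_tree()`, five tips, one migration node):
depth-type statistics (Sackin, maximum depth, maximum width, the LCA
depths inside the total cophenetic index) count migration nodes and their
edges; balance-type statistics (cherries, Colless) treat migration nodes
as transparent pass-throughs; ladder length counts only internal nodes
with exactly one *leaf* child, so a migration node counts only when its
single child is a leaf.

```{r worked-example}
unlist(tree_shape_stats(example_structured_tree()))
```

The total cophenetic index is computed in linear time through the identity
that a pair's LCA depth equals its number of non-root common ancestors,
giving $\sum_{v \ne \mathrm{root}} \binom{\ell(v)}{2}$ with $\ell(v)$ the
leaves under $v$; the tests verify it against an explicit
all-pairs LCA oracle, and the caterpillar/balanced closed forms
($\binom{n}{3}$, $(n-1)(n-2)/2$, normalised Sackin 1, Colless 0) hold
exactly.

## Comparing distributions

For each statistic the structured and non-structured samples are compared
with three two-sample tests (`compare_populations()`,
`comparison_report()`):

* **Kolmogorov-Smirnov** — `stats::ks.test`, sup-distance $D$ between
  empirical CDFs;
* **Cucconi** — the location-scale rank statistic
  $C = (U^2 + V^2 - 2\rho UV) / (2(1-\rho^2))$, where $U$ and $V$
  standardise the sums of squared ranks and squared contrary ranks of one
  sample and $\rho = 2(N^2-4)/((2N+1)(8N+11)) - 1$; asymptotically
  $P(C > c) = e^{-c}$ under the null;
* **Podgor-Gastwirth** — the $F$ statistic of regressing the
  sample-membership indicator on midranks and squared midranks, referred
  to $F(2, N-3)$.

Both rank tests default to a seeded label-permutation p-value
(`B = 9999`), with the asymptotic version available for speed; the
asymptotic mode is what large-scale reports use, since permutation
p-values cannot fall below $1/(B+1)$. Ties — frequent, because the raw
statistics are integers — are handled by midranks. Exact enumeration of
all label permutations on toy samples, and type-I-error calibration at
$\alpha = 0.05$ over 1000 null simulations, back both implementations in
the test suite. Box-plot summaries use the conventional Tukey rule
(outliers beyond 1.5 IQR from the quartiles). No multiple-testing
correction is applied across the eight statistics; the report is meant to
be read per statistic.

## Classification

The feature vector is the three normalised balance statistics plus the
five remaining raw statistics, in a fixed column order
(`feature_columns()`). Five model families are supported: KNN
(`class::knn`), SVMs with linear, polynomial and radial kernels
(`e1071::svm`, cost fixed at 1), and CART decision trees (`rpart`).
Because KNN and SVMs are scale-sensitive, features are standardised to
zero mean and unit variance using training-data statistics only — inside
every tuning fold and every cross-validation fold.

`tune_and_train()` grid-searches by stratified cross-validated accuracy:
$k \in \{3,5,7,9,11\}$ for KNN; degree $\in \{2,3,4\}$ and kernel scale
$\gamma \in \{0.01, 0.1, 1\}$ for the polynomial kernel; $\gamma$ around
the median-pairwise-distance heuristic for the radial kernel; a log grid
of complexity parameters for the decision tree. `kfold_cross_validate()`
(default 10 folds, stratified so each fold preserves the class ratio
within one sample) tunes once on the full data and then reports per-fold
and mean sensitivity, specificity, accuracy and AUC, plus the pooled
confusion matrix. Tuning once rather than nesting the grid search inside
every fold slightly optimistically biases the tuned-parameter choice but
keeps fold metrics honest for fixed hyperparameters; the reported means
are fold averages, not pooled-prediction metrics.

*Structured* is the positive class throughout: sensitivity is the
probability of recognising a structured tree. ROC scores are the signed
SVM decision value (oriented so larger means more structured), the KNN
neighbour vote fraction, and the decision tree's leaf class frequency;
`roc_auc()` integrates by trapezoid, which equals the pairwise
concordance probability (ties half-weighted), an identity the tests
verify by brute force.

## Sensitivity designs

`sensitivity_experiment()` rebuilds the dataset under three perturbations,
each 250 structured + 250 non-structured trees by default, drawn by Latin
hypercube sampling (`lhs::randomLHS`; one sample per equal-probability bin
and dimension): varied tree size (non-structured and deme 1 in (300, 400),
deme 2 in (250, 300)), varied parameters (deme-level $R_0$ in (0.45, 6.34)
for deme 1 and (4.18, 36.75) for deme 2), and both at once. Only the
structured demes' $R_0$ is varied: the intervals describe the two
sub-populations, and an unstructured $R_0$ reaching 0.45 would make a
350-tip tree practically unreachable (a subcritical process with no
immigration to rescue it). Note that under the varied-parameters design a
subcritical deme 1 is sustained by immigration from deme 2 — a regime the
`"total"` stop rule handles gracefully.

## What the generator does and does not emulate

The generator *is* the study conditions: fixed rates derived from
HIV epidemiology in a two-risk-group setting, fixed or interval-drawn tree
sizes, complete sampling of extant lineages at a single time point, and
error-free topologies. Real datasets differ in ways the simulations do not
cover: trees are *estimated* from sequences (reconstruction error,
bootstrap correlation), sampling is incomplete and spread through time,
populations may have more than two demes, and rates vary over time. A
classifier that is near-perfect on the simulated classes therefore
demonstrates that the eight statistics separate the two generating
processes — not that real trees will be classified with the same accuracy.
The package deliberately stops at ingesting user-supplied Newick trees
(`read_newick()`, `classify_trees()`); sequence handling, alignment and
tree inference are out of scope.

## Numerical choices and problem sizes

* Per-tree seeds are dataset seed + replicate index; all stochastic
  stages (simulation, fold assignment, permutation tests, LHS) are
  seeded and reproduce bit-identically.
* Event-loop guard `max_events = 5e6` per attempt; 100 restart attempts
  after extinction.
* The closed-form/eigenvalue $R_0$ agreement is asserted at $10^{-10}$
  relative tolerance.
* Grid ties in tuning resolve to the first grid point (fixed order).
* The test suite runs the baseline design at 250 trees per class and the
  smaller unit fixtures at 40-100 tips; the acceptance script runs the
  full 500 + 500 design. These sizes are the package's chosen desk scale:
  they keep the whole suite under a minute while leaving the Monte-Carlo
  error of the reported quantities well inside the asserted tolerances.

## Known limitations

* Two demes only; no serial sampling; no branch-length-based statistics
  (no gamma statistic or LTT curves), so signal carried purely by
  branch lengths is invisible to the pipeline.
* The sub-total-rate deme selection rule is reproduced as specified; users
  wanting exact Gillespie dynamics should set `weighting = "population"`
  and should expect slightly different deme occupancy dynamics.
* Asymptotic p-values for the Cucconi and Podgor-Gastwirth tests are
  approximations; at the default report sizes (hundreds of trees per
  group) they are accurate, but for small groups the permutation mode is
  preferable.
* The quota (`"joint"`) stop rule can be slow or runaway when one deme is
  strongly subcritical; prefer `"total"` for such designs.
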