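---
title: "Interpreting tree ensembles as regularized decision networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interpreting tree ensembles as regularized decision networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

Tree ensembles (random forests, gradient boosted trees) are the workhorse
predictive models for tabular biological data — microbiome relative
abundances in particular — but a fitted forest of hundreds of trees is
opaque. rulenet interprets a *fitted* ensemble by decomposing it into
decisions, simplifying the decision set, and quantifying how features and
pairs of features contribute to the model's predictions. This vignette is
the package's account of the method: the quantities it computes, the
regularization it applies, the choices made where the design was open, and
what the simulation test bed does and does not demonstrate.

## Decisions and the error function

Let $x = (x^1, \dots, x^p)$ be the features (numeric or categorical) and
$y$ the response, observed on $n$ samples; binary classification is encoded
$y \in \{0, 1\}$ and multi-class problems are reduced one-vs-all. A *rule*
is a conjunction of at most one condition per feature — a half-open
interval $(l, u]$ for numeric features, an admitted level set for
categorical ones. A *decision* $D$ pairs a rule with a constant prediction
$\hat y_D$ on its *support* $S_D$ (the samples satisfying the rule). Every
root-to-leaf path of every tree is one decision; `extract_decisions()`
enumerates them, intersects the path's conditions feature-wise, and
recomputes $\hat y_D$ as the mean response on $S_D$. Recomputing (rather
than trusting leaf values) keeps the original decisions and all modified
decisions below under one estimator. Decisions with empty support, and
conditions admitting a feature's full domain, are dropped.

For a sample subset $S$ and a constant prediction $\hat y$, the error is

$$\alpha(S, \hat y) = \tfrac{1}{|S|} \sum_{i \in S} (y_i - \hat y)^2
\quad \text{(regression)}, \qquad
\alpha(S, \hat y) = \tfrac{1}{|S|} \sum_{i \in S}
\left(1 - \hat y^{\,y_i} (1 - \hat y)^{1 - y_i}\right)
\quad \text{(classification)};$$

for a hard 0/1 prediction the second form is exactly the misclassification
fraction.

## Importance and influence

The *decision importance*
$I_D = \left(1 - \alpha(S_D, \hat y_D) / \alpha(S_D, \bar y)\right) |S_D|$
measures the gain over predicting the global mean $\bar y$, weighted by the
support size; the bracket is $R^2$ (regression) or Cohen's $\kappa$
(classification) on $S_D$, so $I_D$ can be negative. $I_D$ is multiplied by
the decision's *multiplicity* — how many identical rules were collapsed
into it. When the response is constant on $S_D$ the ratio is undefined and
the importance is set to 0.

Removing feature $j$'s condition gives the decision $D_j^{rm}$: its
prediction comes from the *enlarged* support, but its error is evaluated on
the *original* support $S_D$. The decision-wise feature importance is

$$\delta_D^j = \alpha(S_D, \hat y_{D_j^{rm}}) - \alpha(S_D, \hat y_D),$$

which may be negative (a condition can hurt its own decision). The
interaction importance of a pair is
$\delta_D^{j,k} = \sqrt{\delta_D^j \, \delta_D^k}$, with a negative product
truncated to zero before the root — a feature whose removal improves the
decision earns no interaction credit. The square root keeps interaction
importances on the same scale as feature importances.

Each active feature also carries a *direction indicator*
$d_D^j \in \{-1, +1\}$: does the rule admit predominantly large or small
values? The package uses a rank rule — for level-set conditions, $+1$ iff
the mean rank of admitted levels is at least the mean rank of all levels;
for interval conditions, $+1$ iff the mean sample rank of the admitted
region is at least the overall mean rank; ties break to $+1$. This concrete
rule is a design choice of this implementation (the alternatives differ
only on near-symmetric conditions) and is exposed through
`direction_indicator()`.

Influences compare predictions instead of errors:
$\gamma_D^j = d_D^j (\hat y_D - \hat y_{D_j^{rm}})$ and
$\gamma_D^{j,k} = \tfrac{d_D^j + d_D^k}{2} (\hat y_D - \hat y_{D_{j,k}^{rm}})$,
so a positive $\gamma^j$ means large values of $x^j$ push predictions up,
and an opposite-direction pair has zero interaction influence.

Aggregating over the ensemble with $I_D$ as weights:
$F_j = \sum_D \delta_D^j I_D$,
$F_{j,k} = \sum_D \delta_D^{j,k} I_D$,
$\Gamma_j = \sum_{D \in \mathcal D_j} \gamma_D^j I_D \big/
\sum_{D \in \mathcal D_j} I_D$ (likewise $\Gamma_{j,k}$ over the pair's
active set), and
$\eta_{j,k} = \operatorname{sign}\sum_{D} d_D^j d_D^k I_D$ records whether
the two features are predominantly used in the same direction. Features
appearing in no rule get no entry. If an active set's importances sum to
zero the influence is reported as 0. Complement decisions (condition
replaced by its complement within the observed domain) are defined and
exported via `complement_decision()` but enter no aggregate; they are
diagnostic.

## Regularization

**Discretization** (default $K = 2$ levels) bins each numeric feature at
empirical quantiles (`method = "data"`) or at 1-d $k$-means centers of the
model's split thresholds weighted by how often they bound a rule
(`method = "rf-thresholds"`). Each numeric condition is rewritten to the
set of levels in which a *strict majority* of that level's observations
satisfies the original condition; a condition admitting every level is
dropped from its rule, one admitting none kills the decision. Features with
fewer distinct values than $K$ are left unsplit with a warning.

**Pruning** (default tolerance 0.05) iteratively removes, per decision, the
condition with the smallest relative error increase
$(\alpha(S_D, \hat y_{D_j^{rm}}) - \alpha(S_D, \hat y_D)) /
\max(\alpha(S_D, \hat y_D), 10^{-6})$ while that increase stays at or below
the tolerance. Decisions pruned to an empty rule are dropped. After every
decision-wise step identical rules are regrouped, multiplicities summed,
and predictions, supports, and errors recomputed, so total multiplicity
(retained plus dropped) is conserved — a tested invariant.

**Stability selection** draws $B$ resamples of size
$\lceil n/2 \rceil$ with replacement (defaults $B = 10$,
$\pi_{thr} = 0.7$, $\alpha = 1$) and re-runs the *entire decision-wise
regularization inside each resample*: quantile breakpoints are recomputed
from the resample, rules rewritten by the resample's majorities, pruned
against the resample, and regrouped; supports, predictions, errors, and
importances (with the resample mean as reference) follow. Running the
regularization inside the bootstrap is essential: it is what makes a
decision's *presence* across resamples informative, and with it the
selection probabilities. The $q$ most important decisions of each resample
are recorded, where

$$q = \left\lfloor \max\{1, (2\pi_{thr} - 1)\,\alpha\,d\} \right\rfloor$$

and $d$ is the mean number of (regularized, grouped) decisions per
resample; $\alpha$ corresponds to the expected number of false discoveries.
Ties at the $q$ boundary break deterministically by (importance, support
size, rule key). Decisions — identified across resamples by their canonical
rule — in the top $q$ of at least $\pi_{thr} B$ resamples form the stable
ensemble; their metrics are averaged over the resamples where they were
present. Each bootstrap derives its RNG seed as master seed plus index, so
results are independent of execution order and reproducible from a
manifest.

## The network and the summary table

Every rewritten condition is a binary pseudo-feature: a node is a
(feature, admitted level set) pair — `Group=a`, `V3__High`,
`V2__Low_Medium` — carrying $F$ and $\Gamma$ at that granularity. The full
admitted set is the node's identity; levels are not duplicated into
separate nodes, which keeps node metrics well defined. Edges connect pairs
co-active in at least one stable decision with $\delta^{j,k} > 0$ and carry
$F_{j,k}$, $\Gamma_{j,k}$, and $\eta_{j,k}$ (rendered solid for agreeing
directions, dashed otherwise). Exports report importances both raw and
max-normalized to $[0, 1]$ for display. `reduce_network()` prunes the
display to short paths: it returns the subgraph at the smallest
edge-importance threshold such that every connected component of the kept
graph has diameter at most `max_path` (default 3), searching thresholds in
ascending order — a deterministic reading of "remove the least important
edges until paths are short", chosen because the exact reduction algorithm
is not otherwise pinned down. The importance/influence table reports, per
feature, the importance summed over its level sets and, per (feature,
level), the influence, with levels absent from every stable decision
flagged missing (the "white blocks").

## The simulation test bed

`simulate_fsd()` draws twelve independent $N(0.5, 1)$ predictors
$V^1..V^{12}$, a group factor uniform on $\{a, b, c, d\}$, and a binary
response set by ten fixed conjunction rules (`fsd_rules()`): an
exclusive-or pattern of $V^1, V^2$ within group $a$, a single threshold on
$V^3$ in group $b$, same-sign cells of $V^4, V^5$ in group $c$, and
opposite-sign cells of $V^6, V^7$ in group $d$. Cells not covered by a rule
(the mixed-sign cells of group $c$, the same-sign cells of group $d$)
receive a uniformly random sign — any deterministic fill would inject
undocumented signal. Each sign then flips independently with probability
$r$ (default 0.05) and $\{-1, 1\}$ is encoded $\{0, 1\}$. The generator is
bit-for-bit reproducible given a seed, and the flip-noise draw is laid out
so that $r = 1$ exactly inverts the $r = 0$ labels under the same seed.

The matching ground truth (`ground_truth_network()`) has 11 nodes (four
group levels, $V^1..V^7$) and 10 edges (pairs co-occurring in a rule).
Expected node signs derive from the rules: $V^3..V^6$ positive, $V^7$
negative, and $V^1$, $V^2$, and all group levels "depends" (their effect
reverses with context); edge signs are "positive"/"negative" only when
every rule containing the pair predicts the same response.

`evaluate_network()` collapses a predicted network to variable granularity
before matching: level-set nodes of numeric features merge into their
feature, while a level set of an unordered categorical is creditable as any
of its constituent levels (matching the convention that categorical values
are separate entities). Each truth entity is creditable once, most
important predictions first; an optional alias map extends credit to
renamed entities. A prediction whose candidates hit only already-credited
truth entities is a *duplicate identification* — counted neither as a new
true positive nor as a false discovery, which prevents both inflating true
positives and the perverse outcome of a re-identified true signal counting
against precision. Weighted precision weights true and false positives by
their importances. `tpfp_curve()` traces true/false positive counts over
selection-probability thresholds, with a random baseline obtained by
averaging many random rankings of the candidate edges.

What passing the test bed shows — and does not. The generator's features
are independent and Gaussian, groups are balanced, effects are sharp
thresholds, and $p = 13 \ll n$. Real microbiome data are compositional,
sparse, heavy-tailed, high-dimensional, and strongly correlated between
related taxa; recovery there additionally depends on the fitted model's
quality and on feature redundancy (a model may select a sibling taxon of
the true predictor). Passing on the simulation validates the machinery —
formulas, regularization, selection, evaluation — not robustness to those
real-data pathologies.

## Numerical and design notes

- Numeric conditions are half-open, $l < x \le u$: a split sends
  $x \le t$ left. This matches the semantics of `ranger` node tables and of
  threshold rules written with $>/\le$; XGBoost's strict-less splits are
  mapped onto the same convention, which differs only on the boundary set
  (measure zero for continuous features).
- `ranger` conversion was pinned against the learner itself: numeric
  splits send $x \le$ split value left, and partition splits list the
  factor-level indices going *right*; a test compares rule-based per-tree
  predictions with `ranger`'s own.
- Pruning's denominator guard is $\varepsilon = 10^{-6}$; tolerance 0
  removes only conditions with no (or negative) error effect.
- $q$ is computed after rounding away binary-float fuzz, so
  $(2 \cdot 0.7 - 1) \cdot 100$ yields $q = 40$, not 39.
- Degenerate inputs: empty supports are dropped and counted; constant
  responses on a support give importance 0; an empty stable ensemble yields
  an empty (valid) network; constant numeric columns load with a warning.
- The test suite and the acceptance script exercise the method at
  $n = 1000$ with 200–500-tree depth-5 forests fit by `ranger` (the
  package's chosen harness scale for the simulation study: large enough
  for the group-wise rules to be learnable, small enough to iterate on),
  plus 200 randomized mini-ensembles checked against an independent
  brute-force re-implementation of every formula at $10^{-10}$.

## Limitations

Interaction metrics stop at pairs; higher-order structure appears only
indirectly through shared decisions. The method interprets the *model*:
with a poor or biased model, a faithful interpretation inherits the bias,
and correlated features can place importance on surrogates of the true
predictor. Sample weights, missing values, and oblique splits are out of
scope. The stable ensemble's surrogate predictions (`predict()` on a fit)
are a diagnostic, not a replacement for the original model.
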