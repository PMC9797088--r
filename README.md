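# rulenet

Interpretation of fitted tree-ensemble models as regularized decision
networks.

Random forests and gradient boosted trees predict phenotypes from tabular
biological data — microbiome relative abundances, covariates, cell counts —
very well, but a fitted forest of hundreds of trees says little about *how*
features, and interactions between features, drive its predictions. rulenet
takes a fitted ensemble and

1. decomposes it into **decisions** — one conjunction rule per root-to-leaf
   path, paired with a constant prediction on the samples satisfying it;
2. **regularizes** the decision ensemble: numeric features are discretized
   into levels and rules rewritten as level sets, uninformative conditions
   are pruned, duplicate rules are grouped with their multiplicity
   recorded, and only decisions that stay among the most important across
   bootstrap resamples are kept (stability selection);
3. computes **feature and pairwise-interaction importance** (the gain in
   predictive accuracy attributable to a feature within the decisions that
   use it) and **influence** (the direction-signed change in prediction),
   and renders them as an importance/influence table and a **decision
   network** whose nodes are feature levels and whose edges are
   interaction effects.

It is aimed at scientists who already have a well-performing tree-ensemble
model and want a global, statistically regularized picture of the feature
associations inside it.

## The quantities

For a decision $D$ with support $S_D$, prediction $\hat y_D$, and error
function $\alpha$ (mean squared error for regression, mean
misclassification error $\tfrac{1}{|S|}\sum_i 1 - \hat y^{y_i}(1-\hat
y)^{1-y_i}$ for binary classification):

- decision importance
  $I_D = (1 - \alpha(S_D,\hat y_D)/\alpha(S_D,\bar y))\,|S_D| \times$
  multiplicity — $R^2$ or Cohen's $\kappa$ on the support, support-weighted;
- feature importance
  $\delta_D^j = \alpha(S_D, \hat y_{D_j^{rm}}) - \alpha(S_D, \hat y_D)$,
  where $D_j^{rm}$ drops feature $j$'s condition (prediction from the
  enlarged support, error on the original support);
- interaction importance
  $\delta_D^{j,k} = \sqrt{\delta_D^j\,\delta_D^k}$ (zero if the product is
  negative);
- influence $\gamma_D^j = d_D^j(\hat y_D - \hat y_{D_j^{rm}})$ with
  direction indicator $d_D^j = \pm 1$ (rule admits predominantly large or
  small values);
- ensemble aggregates $F_j = \sum_D \delta_D^j I_D$,
  $\Gamma_j = \sum_D \gamma_D^j I_D / \sum_{D \in \mathcal D_j} I_D$
  (likewise for pairs), and
  $\eta_{j,k} = \mathrm{sign}\sum_D d_D^j d_D^k I_D$;
- stability selection keeps decisions in the top
  $q = \lfloor\max\{1, (2\pi_{thr}-1)\,\alpha\,d\}\rfloor$ by importance in
  at least $\pi_{thr} B$ of $B$ bootstrap resamples (defaults
  $\pi_{thr} = 0.7$, $\alpha = 1$, $B = 10$, resamples of size $n/2$), with
  the full decision-wise regularization re-run inside every resample.

See the vignette (`vignettes/decision-networks.Rmd`) for the full method
description and the design choices.

## Worked example

The package ships its own simulation test bed: twelve independent
N(0.5, 1) predictors, a four-level group factor, and a binary phenotype set
by ten fixed group-specific threshold rules, with 5% label noise — so every
true feature association is known.

```r
library(rulenet)
library(ranger)

sim <- simulate_fsd(n = 1000, r = 0.05, seed = 1)
rf  <- ranger(x = sim$data$x, y = factor(sim$data$y), num.trees = 300,
              max.depth = 5, probability = TRUE,
              respect.unordered.factors = "partition", seed = 1)

fit <- rulenet(rf, sim$data, K = 2, B = 10, alpha_reg = 1, seed = 1)
print(fit)
#> rulenet decision-ensemble interpretation
#>   stages: extracted = 7457, grouped = 7455, stable = 43
#>   network: 21 node(s), 53 edge(s)
#>   top features:
#>  entity feature importance   influence n_active
#>   Group   Group 1677.21315 -0.03614816       33
#>      V3      V3 1522.91464  0.18679839       26
#>      V4      V4  419.16006  0.10771793       18
#>      V6      V6  157.85504  0.10843584       10
#>      V2      V2   98.35473  0.07332221       11
```

The 300-tree forest decomposes into 7457 decisions; bootstrap stability
selection keeps 43 of them. The most important stable decision is the
generating rule for group b recovered verbatim — samples in group b with
high V3 are predicted diseased with probability 0.96:

```r
head(as.data.frame(fit$ensemble), 2)
#>                           rule prediction n_support  error importance
#>    Group in {b} & V3 in {High}      0.962      66.2 0.0722       3264
#>  Group in {b,c} & V3 in {High}      0.822     124.7 0.2910       2016
```

Because the generator is known, the recovered network can be scored against
the ground truth (11 true nodes, 10 true interaction edges):

```r
evaluate_network(fit$network, sim$truth)
#> <network_eval>
#>   nodes  TP 11 FP 2 FN 0  precision 0.846 recall 1.000  weighted precision 0.997
#>   edges  TP 10 FP 21 FN 0  precision 0.323 recall 1.000  weighted precision 0.736
```

All 11 true nodes and all 10 true edges are recovered; the extra edges
carry little importance, so 99.7% of the node importance and 73.6% of the
edge importance in the network is attached to true associations.
`plot(fit)` draws the network (node size = importance, color = influence,
dashed edges = opposite-direction pairs), `summary(fit)` prints the stable
decisions and the importance/influence table, and `export_network()`
writes GraphML and TSV files. `run_interpret()` drives the same pipeline
from a YAML/JSON config over a serialized model (XGBoost JSON dump or the
package's per-node CSV) and a feature table, writing a reproducible output
bundle with a manifest.

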