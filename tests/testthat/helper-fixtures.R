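# Fixtures built in code: tiny datasets, hand-written node tables, random
# mini-ensembles, and the forest-fitting harness used by the end-to-end
# checks (model fitting itself is outside the package).

toy_data <- function(n = 40, seed = 1, task = "classification") {
  set.seed(seed)
  x <- data.frame(
    V1 = rnorm(n), V2 = rnorm(n),
    Group = factor(sample(c("a", "b", "c"), n, replace = TRUE)))
  y <- if (task == "classification") {
    as.numeric((x$V1 > 0 & x$Group == "a") | runif(n) < 0.2)
  } else {
    x$V1 + rnorm(n, sd = 0.3)
  }
  rn_data(x, y, task = task)
}

# single numeric stump: V1 <= thr -> leaf 1, else leaf 2
stump_nodes <- function(thr = 0, feature = "V1", tree = 0L) {
  data.frame(
    tree = tree, node = 0:2,
    kind = c("split", "leaf", "leaf"),
    feature = c(feature, NA, NA),
    threshold = c(thr, NA, NA),
    category_set = NA_character_,
    left = c(1L, NA, NA), right = c(2L, NA, NA),
    value = c(NA, 0.2, 0.8),
    stringsAsFactors = FALSE)
}

# depth-2 complete tree on V1 then V2 (7 nodes, 4 leaves)
depth2_nodes <- function() {
  data.frame(
    tree = 0L, node = 0:6,
    kind = c("split", "split", "split", rep("leaf", 4)),
    feature = c("V1", "V2", "V2", rep(NA, 4)),
    threshold = c(0, -1, 1, rep(NA, 4)),
    category_set = NA_character_,
    left = c(1L, 3L, 5L, NA, NA, NA, NA),
    right = c(2L, 4L, 6L, NA, NA, NA, NA),
    value = c(NA, NA, NA, 0.1, 0.4, 0.6, 0.9),
    stringsAsFactors = FALSE)
}

# random conjunction rule over up to `p` numeric features and one factor
random_mini_ensemble <- function(seed, n = 50, p = 3,
                                 task = c("classification", "regression")) {
  task <- match.arg(task)
  set.seed(seed)
  n <- sample(10:n, 1)
  x <- data.frame(matrix(rnorm(n * p), nrow = n))
  names(x) <- paste0("V", seq_len(p))
  x$G <- factor(sample(c("lo", "mid", "hi"), n, replace = TRUE),
                levels = c("lo", "mid", "hi"))
  y <- if (task == "classification") {
    as.numeric(runif(n) < 0.3 + 0.4 * (x$V1 > 0))
  } else {
    x$V1 - 0.5 * x$V2 + rnorm(n, sd = 0.5)
  }
  data <- rn_data(x, y, task = task)
  n_dec <- sample(1:5, 1)
  decisions <- vector("list", n_dec)
  for (i in seq_len(n_dec)) {
    repeat {
      feats <- sample(names(x), sample(1:3, 1))
      conds <- list()
      for (f in feats) {
        conds[[f]] <- if (f == "G") {
          rulenet:::cond_set(sample(levels(x$G), sample(1:2, 1)))
        } else if (runif(1) < 0.5) {
          rulenet:::cond_interval(lower = rnorm(1, sd = 0.7))
        } else {
          rulenet:::cond_interval(upper = rnorm(1, sd = 0.7))
        }
      }
      ev <- evaluate_decision(conds, data)
      if (length(ev$support) > 0) break
    }
    d <- rulenet:::new_decision(conds, ev$prediction, length(ev$support),
                                ev$error,
                                multiplicity = sample(1:3, 1))
    decisions[[i]] <- d
  }
  rulenet:::new_decision_ensemble(decisions, data)
}

# harness forest for end-to-end checks: 'partition' factor splits so group
# levels become true categorical conditions; depth-limited to keep rules at
# the scale of the generating mechanism
fit_forest <- function(data, num_trees = 500, seed = 1, max_depth = 5) {
  ranger::ranger(x = data$x, y = factor(data$y), num.trees = num_trees,
                 max.depth = max_depth, probability = TRUE,
                 respect.unordered.factors = "partition", seed = seed,
                 num.threads = 1)
}
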