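## Rule-based phenotype simulator with a known ground-truth interaction
## network, plus evaluation utilities (precision/recall against the truth,
## TP/FP curves from stability-selection probabilities).

#' The generating rule table of the fully simulated data
#'
#' Ten conjunction rules over a 4-level group factor and seven of twelve
#' independent N(0.5, 1) predictors, each assigning the signed response
#' -1 or 1. Within each group the rules have disjoint supports; group/value
#' combinations not covered by any rule receive a uniformly random sign.
#'
#' @return An object of class `rule_table`: a list of rules, each
#'   `list(group, conditions, response)` with `conditions` a named list of
#'   `c(op, threshold)` entries (`op` is `">"` or `"<="`).
#' @export
fsd_rules <- function() {
  rule <- function(group, conditions, response) {
    list(group = group, conditions = conditions, response = response)
  }
  gt <- function(thr) list(op = ">", threshold = thr)
  le <- function(thr) list(op = "<=", threshold = thr)
  structure(list(
    rule("a", list(V1 = gt(0), V2 = gt(0)), 1),
    rule("a", list(V1 = le(0), V2 = le(0)), 1),
    rule("a", list(V1 = gt(0), V2 = le(0)), -1),
    rule("a", list(V1 = le(0), V2 = gt(0)), -1),
    rule("b", list(V3 = gt(0)), 1),
    rule("b", list(V3 = le(0)), -1),
    rule("c", list(V4 = gt(0), V5 = gt(0)), 1),
    rule("c", list(V4 = le(0), V5 = le(0)), -1),
    rule("d", list(V6 = le(0), V7 = gt(0)), -1),
    rule("d", list(V6 = gt(0), V7 = le(0)), 1)
  ), class = "rule_table")
}

rule_applies <- function(rule, group, x_row) {
  if (group != rule$group) return(FALSE)
  for (f in names(rule$conditions)) {
    cond <- rule$conditions[[f]]
    v <- x_row[[f]]
    ok <- if (cond$op == ">") v > cond$threshold else v <= cond$threshold
    if (!ok) return(FALSE)
  }
  TRUE
}

#' Simulate the fully simulated dataset (FSD)
#'
#' Twelve independent N(0.5, 1) predictors `V1..V12`, a group factor uniform
#' on {a, b, c, d}, and a binary response assigned by [fsd_rules()].
#' Group/value combinations not covered by a rule get a uniformly random
#' sign; every sign is then flipped independently with probability `r`, and
#' the signed response {-1, 1} is encoded as {0, 1}.
#'
#' @param n number of observations.
#' @param r sign-flip noise probability in \[0, 1\].
#' @param seed optional integer seed (bit-for-bit reproducible given a seed).
#' @return `list(data, truth)`: an [rn_data()] classification dataset
#'   (features `Group`, `V1..V12`) and the [ground_truth_network()] of the
#'   generating rules.
#' @export
simulate_fsd <- function(n, r = 0.05, seed = NULL) {
  stopifnot(n >= 1, r >= 0, r <= 1)
  if (!is.null(seed)) set.seed(seed)
  V <- matrix(rnorm(n * 12L, mean = 0.5, sd = 1), nrow = n)
  colnames(V) <- paste0("V", 1:12)
  group <- sample(c("a", "b", "c", "d"), n, replace = TRUE)
  rules <- fsd_rules()
  y_signed <- rep(NA_real_, n)
  for (rl in rules) {
    in_group <- group == rl$group
    m <- in_group
    for (f in names(rl$conditions)) {
      cond <- rl$conditions[[f]]
      m <- m & (if (cond$op == ">") V[, f] > cond$threshold else
        V[, f] <= cond$threshold)
    }
    y_signed[m] <- rl$response
  }
  uncovered <- is.na(y_signed)
  if (any(uncovered)) {
    y_signed[uncovered] <- sample(c(-1, 1), sum(uncovered), replace = TRUE)
  }
  flip <- runif(n) < r
  y_signed[flip] <- -y_signed[flip]
  x <- data.frame(Group = factor(group, levels = c("a", "b", "c", "d")), V)
  data <- rn_data(x, (y_signed + 1) / 2, task = "classification")
  list(data = data, truth = ground_truth_network(rules))
}

#' Ground-truth network of a generating rule table
#'
#' One node per group level and per variable appearing in the rules, one
#' edge per pair co-occurring in a rule. A node's expected influence sign is
#' `"positive"` if in every rule its high side (admitted `>` region, or the
#' complement of an admitted `<=` region) predicts response 1, `"negative"`
#' if it always predicts -1, and `"depends"` otherwise; group-level nodes use
#' the rule responses directly. An edge is `"positive"`/`"negative"` if every
#' rule containing the pair predicts 1 / -1, `"depends"` otherwise.
#'
#' @param rules a [fsd_rules()]-style `rule_table`.
#' @return An object of class `ground_truth_network` with data.frames
#'   `nodes` (id, sign) and `edges` (from, to, sign; `from < to`).
#' @export
ground_truth_network <- function(rules = fsd_rules()) {
  node_contrib <- list()
  edge_resp <- list()
  for (rl in rules) {
    gid <- paste0("Group=", rl$group)
    vars <- names(rl$conditions)
    ids <- c(gid, vars)
    contribs <- c(rl$response, vapply(vars, function(f) {
      d <- if (rl$conditions[[f]]$op == ">") 1 else -1
      d * rl$response
    }, numeric(1L)))
    for (i in seq_along(ids)) {
      node_contrib[[ids[i]]] <- c(node_contrib[[ids[i]]], contribs[i])
    }
    if (length(ids) >= 2L) {
      cmb <- utils::combn(sort(ids), 2L)
      for (q in seq_len(ncol(cmb))) {
        key <- paste(cmb[1L, q], cmb[2L, q], sep = "\r")
        edge_resp[[key]] <- c(edge_resp[[key]], rl$response)
      }
    }
  }
  sign_of <- function(v) {
    if (all(v == 1)) "positive" else if (all(v == -1)) "negative" else
      "depends"
  }
  nodes <- data.frame(id = names(node_contrib),
                      sign = vapply(node_contrib, sign_of, character(1L)),
                      stringsAsFactors = FALSE, row.names = NULL)
  ab <- strsplit(names(edge_resp), "\r", fixed = TRUE)
  edges <- data.frame(from = vapply(ab, `[`, character(1L), 1L),
                      to = vapply(ab, `[`, character(1L), 2L),
                      sign = vapply(edge_resp, sign_of, character(1L)),
                      stringsAsFactors = FALSE, row.names = NULL)
  structure(list(nodes = nodes, edges = edges),
            class = "ground_truth_network")
}

#' @export
print.ground_truth_network <- function(x, ...) {
  cat("<ground_truth_network> ", nrow(x$nodes), " node(s), ",
      nrow(x$edges), " edge(s)\n", sep = "")
  invisible(x)
}

#' Decision ensemble built directly from a generating rule table
#'
#' One decision per rule, evaluated on the data — a perfect predictive model
#' with no learner in the loop, used to test the metric and network pipeline
#' in isolation. Rules with empty support are dropped.
#'
#' @param rules a `rule_table`.
#' @param data an [rn_data()] with a `Group` feature and the rules'
#'   variables.
#' @return A `decision_ensemble`.
#' @export
perfect_ensemble <- function(rules, data) {
  decs <- list()
  for (rl in rules) {
    conds <- list(Group = cond_set(rl$group))
    for (f in names(rl$conditions)) {
      cond <- rl$conditions[[f]]
      conds[[f]] <- if (cond$op == ">") {
        cond_interval(lower = cond$threshold)
      } else {
        cond_interval(upper = cond$threshold)
      }
    }
    ev <- evaluate_decision(conds, data)
    if (length(ev$support) == 0L) next
    decs[[length(decs) + 1L]] <- new_decision(conds, ev$prediction,
                                              length(ev$support), ev$error)
  }
  new_decision_ensemble(decs, data)
}

#' Permute the response, optionally within strata
#'
#' Builds a global-null dataset: `y` is permuted (within the levels of a
#' categorical stratifying feature if given), features are untouched, so any
#' association between features and response is destroyed while the
#' stratum structure of `y` is conserved.
#'
#' @param data an [rn_data()].
#' @param within optional name of a categorical feature to permute within.
#' @param seed optional integer seed.
#' @return A new [rn_data()].
#' @export
permute_response <- function(data, within = NULL, seed = NULL) {
  stopifnot(inherits(data, "rn_data"))
  if (!is.null(seed)) set.seed(seed)
  y <- data$y
  if (is.null(within)) {
    y <- y[sample.int(data$n)]
  } else {
    if (data$feature_kinds[[within]] != "categorical") {
      stop("'within' must name a categorical feature")
    }
    strata <- data$x[[within]]
    for (g in levels(strata)) {
      ix <- which(strata == g)
      y[ix] <- y[ix][sample.int(length(ix))]
    }
  }
  rn_data(data$x, y, task = data$task)
}

## Collapse a decision network to variable granularity: level-set nodes of
## discretized/numeric features merge into one node per feature; nodes of
## unordered categorical features keep their admitted level set
## ("Group=a", "Group=b_c"). Importances are summed, influences
## importance-weighted. Each collapsed node carries its candidate truth
## entities: the feature name for numerics, one "feature=level" entity per
## admitted level for unordered categoricals (the network convention of one
## node per categorical value).
collapse_network <- function(net) {
  empty_nodes <- data.frame(key = character(0), candidates = character(0),
                            importance = numeric(0), influence = numeric(0),
                            stringsAsFactors = FALSE)
  empty_edges <- data.frame(from = character(0), to = character(0),
                            importance = numeric(0), influence = numeric(0),
                            stringsAsFactors = FALSE)
  if (nrow(net$nodes) == 0L) {
    return(list(nodes = empty_nodes, edges = empty_edges))
  }
  key_of <- function(i) {
    nd <- net$nodes[i, ]
    if (is.na(nd$levels) || isTRUE(nd$ordered)) {
      c(nd$feature, nd$feature)
    } else {
      levs <- strsplit(nd$levels, "|", fixed = TRUE)[[1L]]
      c(paste0(nd$feature, "=", paste(levs, collapse = "_")),
        paste(paste0(nd$feature, "=", levs), collapse = "|"))
    }
  }
  kc <- vapply(seq_len(nrow(net$nodes)), key_of, character(2L))
  keys <- kc[1L, ]
  names(keys) <- net$nodes$id
  cand_of <- setNames(kc[2L, ], keys)
  nodes <- data.frame(key = keys, importance = net$nodes$importance,
                      winf = net$nodes$influence *
                        pmax(net$nodes$importance, 0),
                      w = pmax(net$nodes$importance, 0),
                      stringsAsFactors = FALSE)
  agg <- aggregate(cbind(importance, winf, w) ~ key, data = nodes, FUN = sum)
  agg$influence <- ifelse(agg$w > 0, agg$winf / agg$w, 0)
  agg$candidates <- unname(cand_of[agg$key])
  cnodes <- agg[c("key", "candidates", "importance", "influence")]
  if (nrow(net$edges) > 0L) {
    ek_from <- unname(keys[net$edges$from])
    ek_to <- unname(keys[net$edges$to])
    keep <- ek_from != ek_to
    edges <- data.frame(
      from = pmin(ek_from[keep], ek_to[keep]),
      to = pmax(ek_from[keep], ek_to[keep]),
      importance = net$edges$importance[keep],
      winf = net$edges$influence[keep] * pmax(net$edges$importance[keep], 0),
      w = pmax(net$edges$importance[keep], 0), stringsAsFactors = FALSE)
    if (nrow(edges) > 0L) {
      eagg <- aggregate(cbind(importance, winf, w) ~ from + to, data = edges,
                        FUN = sum)
      eagg$influence <- ifelse(eagg$w > 0, eagg$winf / eagg$w, 0)
      cedges <- eagg[c("from", "to", "importance", "influence")]
    } else {
      cedges <- empty_edges
    }
  } else {
    cedges <- empty_edges
  }
  list(nodes = cnodes, edges = cedges, node_candidates = cand_of)
}

## Greedy matching of predictions (each with a candidate entity set) against
## truth entities, most important predictions first; every truth entity is
## creditable once. A prediction whose candidates hit only already-credited
## truth entities is a duplicate identification ("dup"): counted neither as
## a new true positive nor as a false discovery. Returns the status and the
## credited entity (or NA) per prediction.
match_entities <- function(pred_candidates, pred_weights, truth_keys,
                           alias_map = NULL) {
  np <- length(pred_candidates)
  status <- rep("fp", np)
  matched <- rep(NA_character_, np)
  credited <- character(0)
  for (i in order(-pred_weights)) {
    cands <- pred_candidates[[i]]
    if (!is.null(alias_map)) {
      mapped <- alias_map[cands]
      cands <- unique(ifelse(is.na(mapped), cands, mapped))
    }
    hit <- cands[cands %in% setdiff(truth_keys, credited)]
    if (length(hit) > 0L) {
      status[i] <- "tp"
      matched[i] <- hit[1L]
      credited <- c(credited, hit[1L])
    } else if (any(cands %in% truth_keys)) {
      status[i] <- "dup"
      matched[i] <- cands[cands %in% truth_keys][1L]
    }
  }
  list(status = status, is_tp = status == "tp", matched = matched,
       credited = credited)
}

eval_counts <- function(status, weights, n_truth, n_credited) {
  tp <- sum(status == "tp")
  fp <- sum(status == "fp")
  dup <- sum(status == "dup")
  fn <- n_truth - n_credited
  w <- pmax(weights, 0)
  w_tp <- sum(w[status == "tp"])
  w_fp <- sum(w[status == "fp"])
  list(tp = tp, fp = fp, fn = fn, dup = dup,
       precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
       recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       weighted_precision = if (w_tp + w_fp > 0) w_tp / (w_tp + w_fp) else
         NA_real_)
}

#' Evaluate a predicted decision network against a ground truth
#'
#' The predicted network is first collapsed to variable granularity
#' (level-set nodes of a numeric feature merge into one node per feature;
#' level sets of unordered categoricals keep their levels, e.g. `Group=a`).
#' Collapsed entities are matched against the truth's node and edge ids,
#' optionally through an alias map (`c(predicted_name = truth_name)`), with
#' each truth entity creditable once. True and false positives are also
#' weighted by their importances to give the weighted precision.
#'
#' @param predicted a `decision_network`.
#' @param truth a [ground_truth_network()].
#' @param alias_map optional named character vector mapping predicted entity
#'   names onto truth names.
#' @return An object of class `network_eval`: lists `nodes` and `edges`
#'   (tp, fp, fn, precision, recall, weighted_precision) plus detail
#'   data.frames `node_detail` / `edge_detail` (entity, importance,
#'   influence, tp, truth_sign).
#' @export
evaluate_network <- function(predicted, truth, alias_map = NULL) {
  stopifnot(inherits(predicted, "decision_network"),
            inherits(truth, "ground_truth_network"))
  coll <- collapse_network(predicted)
  node_cands <- strsplit(coll$nodes$candidates, "|", fixed = TRUE)
  nm <- match_entities(node_cands, coll$nodes$importance,
                       truth$nodes$id, alias_map)
  node_counts <- eval_counts(nm$status, coll$nodes$importance,
                             nrow(truth$nodes), length(nm$credited))
  ## an edge's candidate pairs cross its endpoints' candidate entities
  cand_by_key <- setNames(node_cands, coll$nodes$key)
  edge_cands <- lapply(seq_len(nrow(coll$edges)), function(i) {
    ca <- cand_by_key[[coll$edges$from[i]]]
    cb <- cand_by_key[[coll$edges$to[i]]]
    pairs <- expand.grid(a = ca, b = cb, stringsAsFactors = FALSE)
    pairs <- pairs[pairs$a != pairs$b, , drop = FALSE]
    if (!is.null(alias_map)) {
      ma <- alias_map[pairs$a]
      mb <- alias_map[pairs$b]
      pairs$a <- ifelse(is.na(ma), pairs$a, ma)
      pairs$b <- ifelse(is.na(mb), pairs$b, mb)
      pairs <- pairs[pairs$a != pairs$b, , drop = FALSE]
    }
    unique(paste(pmin(pairs$a, pairs$b), pmax(pairs$a, pairs$b),
                 sep = "\r"))
  })
  truth_edge_keys <- paste(pmin(truth$edges$from, truth$edges$to),
                           pmax(truth$edges$from, truth$edges$to),
                           sep = "\r")
  em <- match_entities(edge_cands, coll$edges$importance, truth_edge_keys)
  edge_counts <- eval_counts(em$status, coll$edges$importance,
                             nrow(truth$edges), length(em$credited))
  node_detail <- data.frame(
    entity = coll$nodes$key, importance = coll$nodes$importance,
    influence = coll$nodes$influence, tp = nm$is_tp,
    status = nm$status, matched = nm$matched,
    truth_sign = truth$nodes$sign[match(nm$matched, truth$nodes$id)],
    stringsAsFactors = FALSE)
  edge_detail <- data.frame(
    from = coll$edges$from, to = coll$edges$to,
    importance = coll$edges$importance, influence = coll$edges$influence,
    tp = em$is_tp, status = em$status, matched = em$matched,
    truth_sign = truth$edges$sign[match(em$matched, truth_edge_keys)],
    stringsAsFactors = FALSE)
  structure(list(nodes = node_counts, edges = edge_counts,
                 node_detail = node_detail, edge_detail = edge_detail),
            class = "network_eval")
}

#' @export
print.network_eval <- function(x, ...) {
  fmt <- function(s, cnt) {
    cat(sprintf("  %-6s TP %d FP %d FN %d  precision %.3f recall %.3f  weighted precision %.3f\n",
                s, cnt$tp, cnt$fp, cnt$fn, cnt$precision, cnt$recall,
                cnt$weighted_precision))
  }
  cat("<network_eval>\n")
  fmt("nodes", x$nodes)
  fmt("edges", x$edges)
  invisible(x)
}

#' TP/FP curve from stability-selection probabilities
#'
#' For every distinct selection probability (descending), builds the network
#' of all scored candidate decisions at or above that probability, evaluates
#' it against the truth, and records the node and edge TP/FP counts. Both
#' coordinates are nondecreasing along the curve. A random-baseline curve is
#' computed by randomly ranking the full candidate network's edges
#' `n_random` times and averaging the TP count at each rank.
#'
#' @param stable a `stable_ensemble` (from [stability_select()]).
#' @param truth a [ground_truth_network()].
#' @param alias_map optional alias map (see [evaluate_network()]).
#' @param n_random number of random rankings for the baseline.
#' @param seed optional seed for the baseline randomization.
#' @return An object of class `tpfp_curve`: data.frames `curve`
#'   (threshold, node_tp, node_fp, edge_tp, edge_fp) and `baseline`
#'   (n_ranked, edge_tp, edge_fp).
#' @export
tpfp_curve <- function(stable, truth, alias_map = NULL, n_random = 1000L,
                       seed = NULL) {
  stopifnot(inherits(stable, "stable_ensemble"))
  cand <- stable$candidates
  probs <- sort(unique(cand$selection_probability), decreasing = TRUE)
  rows <- list()
  last_net <- NULL
  for (p in probs) {
    sel <- cand$selection_probability >= p
    sub <- new_decision_ensemble(cand$decisions[sel], stable$data)
    met <- cand$metrics[sel]
    agg_ens <- sub
    class(agg_ens) <- c("stable_ensemble", class(agg_ens))
    agg_ens$decision_metrics <- met
    net <- build_network(agg_ens)
    ev <- evaluate_network(net, truth, alias_map)
    rows[[length(rows) + 1L]] <- data.frame(
      threshold = p, node_tp = ev$nodes$tp, node_fp = ev$nodes$fp,
      edge_tp = ev$edges$tp, edge_fp = ev$edges$fp)
    last_net <- net
  }
  curve <- if (length(rows) > 0L) do.call(rbind, rows) else
    data.frame(threshold = numeric(0), node_tp = integer(0),
               node_fp = integer(0), edge_tp = integer(0),
               edge_fp = integer(0))
  ## random baseline over the full candidate network's edges
  baseline <- data.frame(n_ranked = integer(0), edge_tp = numeric(0),
                         edge_fp = numeric(0))
  if (!is.null(last_net) && nrow(last_net$edges) > 0L) {
    ev_full <- evaluate_network(last_net, truth, alias_map)
    labels <- ev_full$edge_detail$tp
    N <- length(labels)
    if (!is.null(seed)) set.seed(seed)
    acc <- numeric(N)
    for (i in seq_len(n_random)) {
      acc <- acc + cumsum(labels[sample.int(N)])
    }
    exp_tp <- acc / n_random
    baseline <- data.frame(n_ranked = seq_len(N), edge_tp = exp_tp,
                           edge_fp = seq_len(N) - exp_tp)
  }
  structure(list(curve = curve, baseline = baseline), class = "tpfp_curve")
}

#' @export
print.tpfp_curve <- function(x, ...) {
  cat("<tpfp_curve> ", nrow(x$curve), " threshold(s)\n", sep = "")
  print(x$curve)
  invisible(x)
}
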