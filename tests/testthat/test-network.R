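mk_levelled_data <- function(n = 200, seed = 31) {
  set.seed(seed)
  x <- data.frame(
    Group = factor(sample(c("a", "b"), n, TRUE)),
    V1 = factor(sample(c("Low", "High"), n, TRUE),
                levels = c("Low", "High"), ordered = TRUE),
    V2 = factor(sample(c("Low", "High"), n, TRUE),
                levels = c("Low", "High"), ordered = TRUE))
  y <- as.numeric(x$Group == "a" & x$V1 == "High")
  y[sample(n, n %/% 10)] <- 1 - y[sample(n, n %/% 10)]
  rn_data(x, y, task = "classification")
}

as_metric_ensemble <- function(decisions, data) {
  ens <- rulenet:::new_decision_ensemble(decisions, data)
  met <- rulenet:::compute_decision_metrics(ens)
  keep <- which(!vapply(met, is.null, logical(1)))
  ens$decisions <- ens$decisions[keep]
  ens$decision_metrics <- met[keep]
  class(ens) <- c("stable_ensemble", class(ens))
  ens
}

test_that("a one-decision ensemble gives two nodes and one edge", {
  d <- mk_levelled_data()
  dec <- local({
    conds <- list(Group = rulenet:::cond_set("a"),
                  V1 = rulenet:::cond_set("High"))
    ev <- evaluate_decision(conds, d)
    dd <- rulenet:::new_decision(conds, ev$prediction, length(ev$support),
                                 ev$error)
    dd
  })
  net <- build_network(as_metric_ensemble(list(dec), d))
  expect_equal(nrow(net$nodes), 2L)
  expect_equal(nrow(net$edges), 1L)
  expect_setequal(net$nodes$id, c("Group=a", "V1__High"))
  expect_true(all(net$nodes$importance_norm >= 0 &
                    net$nodes$importance_norm <= 1))
})

test_that("opposite-direction pairs get zero influence and dashed edges", {
  d <- mk_levelled_data(seed = 32)
  conds <- list(V1 = rulenet:::cond_set("High"),
                V2 = rulenet:::cond_set("Low"))
  ev <- evaluate_decision(conds, d)
  dec <- rulenet:::new_decision(conds, ev$prediction, length(ev$support),
                                ev$error)
  net <- build_network(as_metric_ensemble(list(dec), d))
  if (nrow(net$edges) == 1L) {
    expect_equal(net$edges$influence, 0)
    expect_equal(net$edges$eta, -1)
    expect_equal(net$edges$direction, "dashed")
  } else {
    # the pair had no positive interaction importance on this draw
    expect_equal(nrow(net$edges), 0L)
  }
})

test_that("empty ensembles give empty (but valid) networks", {
  d <- mk_levelled_data(seed = 33)
  net <- build_network(as_metric_ensemble(list(), d))
  expect_equal(nrow(net$nodes), 0L)
  expect_equal(nrow(net$edges), 0L)
  expect_equal(nrow(reduce_network(net)$edges), 0L)
})

fake_network <- function(edges_df, node_ids = NULL) {
  if (is.null(node_ids)) node_ids <- unique(c(edges_df$from, edges_df$to))
  nodes <- data.frame(id = node_ids, feature = node_ids,
                      levels = NA_character_, ordered = NA,
                      importance = 1, influence = 0, n_active = 1,
                      importance_norm = 1, stringsAsFactors = FALSE)
  edges_df$influence <- 0
  edges_df$eta <- 1
  edges_df$direction <- "solid"
  edges_df$importance_norm <- edges_df$importance / max(edges_df$importance)
  structure(list(nodes = nodes, edges = edges_df, provenance = list()),
            class = "decision_network")
}

test_that("network reduction keeps short-diameter graphs intact", {
  star <- fake_network(data.frame(
    from = "hub", to = paste0("x", 1:5), importance = 5:1,
    stringsAsFactors = FALSE))
  red <- reduce_network(star, max_path = 3)
  expect_equal(nrow(red$edges), 5L)
  expect_equal(red$nodes, star$nodes)
})

test_that("network reduction removes weakest edges until paths are short", {
  path5 <- fake_network(data.frame(
    from = paste0("n", 1:5), to = paste0("n", 2:6),
    importance = c(1, 5, 4, 3, 2), stringsAsFactors = FALSE))
  red <- reduce_network(path5, max_path = 3)
  # exhaustive threshold search oracle: the smallest threshold whose
  # subgraph has all components with diameter <= 3 keeps importances >= 3
  expect_setequal(red$edges$importance, c(5, 4, 3))
  expect_true(all(red$edges$importance %in% path5$edges$importance))
  expect_equal(red$nodes, path5$nodes)

  # equal-importance path: only the empty subgraph satisfies the bound
  flat <- fake_network(data.frame(
    from = paste0("n", 1:5), to = paste0("n", 2:6), importance = rep(2, 5),
    stringsAsFactors = FALSE))
  expect_equal(nrow(reduce_network(flat, max_path = 3)$edges), 0L)
  # reduction output is always a subgraph of its input
  expect_true(all(paste(red$edges$from, red$edges$to) %in%
                    paste(path5$edges$from, path5$edges$to)))
})

test_that("networks export and re-import losslessly", {
  d <- mk_levelled_data(seed = 34)
  conds <- list(Group = rulenet:::cond_set("a"),
                V1 = rulenet:::cond_set("High"))
  ev <- evaluate_decision(conds, d)
  dec <- rulenet:::new_decision(conds, ev$prediction, length(ev$support),
                                ev$error)
  net <- build_network(as_metric_ensemble(list(dec), d))
  base <- withr::local_tempfile()
  paths <- export_network(net, base)
  expect_true(all(file.exists(paths)))
  # TSV round trip
  back <- read_network_tsv(paths[["nodes_tsv"]], paths[["edges_tsv"]])
  expect_equal(back$nodes$id, net$nodes$id)
  expect_equal(back$nodes$importance, net$nodes$importance)
  expect_equal(back$edges$importance, net$edges$importance)
  expect_equal(nrow(back$nodes), nrow(net$nodes))
  expect_equal(nrow(back$edges), nrow(net$edges))
  # GraphML round trip through igraph
  g <- igraph::read_graph(paths[["graphml"]], format = "graphml")
  expect_equal(igraph::vcount(g), nrow(net$nodes))
  expect_equal(igraph::ecount(g), nrow(net$edges))
  expect_setequal(igraph::V(g)$name, net$nodes$id)
  expect_equal(sort(igraph::E(g)$importance), sort(net$edges$importance))
})

test_that("network construction is invariant to decision order", {
  skip_if_not_installed("ranger")
  sim <- simulate_fsd(300, r = 0.05, seed = 35)
  pe <- perfect_ensemble(fsd_rules(), sim$data)
  disc <- discretize(sim$data, pe, K = 2)
  ens <- as_metric_ensemble(disc$ensemble$decisions, disc$data)
  net1 <- build_network(ens)
  set.seed(1)
  perm <- sample(length(ens$decisions))
  ens2 <- ens
  ens2$decisions <- ens$decisions[perm]
  ens2$decision_metrics <- ens$decision_metrics[perm]
  net2 <- build_network(ens2)
  o1 <- net1$edges[order(net1$edges$from, net1$edges$to), ]
  o2 <- net2$edges[order(net2$edges$from, net2$edges$to), ]
  row.names(o1) <- row.names(o2) <- NULL
  expect_equal(o2, o1)
})

test_that("the importance/influence table flags unused levels as missing", {
  d <- mk_levelled_data(seed = 36)
  conds <- list(V1 = rulenet:::cond_set("High"))
  ev <- evaluate_decision(conds, d)
  dec <- rulenet:::new_decision(conds, ev$prediction, length(ev$support),
                                ev$error)
  tab <- importance_influence_table(as_metric_ensemble(list(dec), d))
  expect_setequal(tab$level[tab$feature == "V1"], c("Low", "High"))
  low <- tab[tab$feature == "V1" & tab$level == "Low", ]
  high <- tab[tab$feature == "V1" & tab$level == "High", ]
  expect_true(low$missing)
  expect_true(is.na(low$influence))
  expect_false(high$missing)
  # the feature importance is shared across its level rows
  expect_equal(low$importance, high$importance)
})

test_that("table importances agree with feature-level aggregates", {
  sim <- simulate_fsd(400, r = 0.05, seed = 37)
  pe <- perfect_ensemble(fsd_rules(), sim$data)
  disc <- discretize(sim$data, pe, K = 2)
  ens <- as_metric_ensemble(disc$ensemble$decisions, disc$data)
  tab <- importance_influence_table(ens)
  agg <- aggregate_metrics(ens, granularity = "feature")
  for (f in unique(tab$feature)) {
    expect_equal(unique(tab$importance[tab$feature == f]),
                 agg$features$importance[agg$features$entity == f],
                 tolerance = 1e-12)
  }
})
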