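test_that("the simulator is reproducible and follows its generating rules", {
  a <- simulate_fsd(500, r = 0, seed = 50)
  b <- simulate_fsd(500, r = 0, seed = 50)
  expect_identical(a$data$x, b$data$x)
  expect_identical(a$data$y, b$data$y)
  x <- a$data$x
  y <- a$data$y
  # noiseless responses obey the rule table on covered cells
  rb <- x$Group == "b" & x$V3 > 0
  expect_true(all(y[rb] == 1))
  expect_true(all(y[x$Group == "b" & x$V3 <= 0] == 0))
  expect_true(all(y[x$Group == "a" & x$V1 > 0 & x$V2 <= 0] == 0))
  expect_true(all(y[x$Group == "a" & x$V1 > 0 & x$V2 > 0] == 1))
  expect_true(all(y[x$Group == "c" & x$V4 > 0 & x$V5 > 0] == 1))
  expect_true(all(y[x$Group == "d" & x$V6 <= 0 & x$V7 > 0] == 0))
  # feature marginals: 12 N(0.5, 1) predictors, near-uniform groups
  expect_equal(sum(a$data$feature_kinds == "numeric"), 12L)
  expect_equal(mean(as.matrix(x[paste0("V", 1:12)])), 0.5,
               tolerance = 0.05)
  expect_true(all(table(x$Group) > 500 / 4 * 0.6))
})

test_that("r = 1 flips every label produced by the r = 0 run", {
  a <- simulate_fsd(300, r = 0, seed = 51)
  b <- simulate_fsd(300, r = 1, seed = 51)
  expect_identical(a$data$x, b$data$x)
  expect_equal(b$data$y, 1 - a$data$y)
})

test_that("the ground-truth network has 11 nodes and 10 edges with signs", {
  gt <- ground_truth_network(fsd_rules())
  expect_setequal(gt$nodes$id,
                  c(paste0("Group=", c("a", "b", "c", "d")),
                    paste0("V", 1:7)))
  expected_edges <- rbind(
    c("Group=a", "V1"), c("Group=a", "V2"), c("V1", "V2"),
    c("Group=b", "V3"),
    c("Group=c", "V4"), c("Group=c", "V5"), c("V4", "V5"),
    c("Group=d", "V6"), c("Group=d", "V7"), c("V6", "V7"))
  expect_equal(nrow(gt$edges), 10L)
  expect_setequal(paste(gt$edges$from, gt$edges$to),
                  paste(pmin(expected_edges[, 1], expected_edges[, 2]),
                        pmax(expected_edges[, 1], expected_edges[, 2])))
  sign_of <- function(id) gt$nodes$sign[gt$nodes$id == id]
  for (v in paste0("V", 3:6)) expect_equal(sign_of(v), "positive")
  expect_equal(sign_of("V7"), "negative")
  for (v in c("V1", "V2")) expect_equal(sign_of(v), "depends")
  for (g in paste0("Group=", letters[1:4])) {
    expect_equal(sign_of(g), "depends")
  }
})

test_that("a one-rule table yields a two-node positive network", {
  rules <- structure(list(list(group = "g1",
                               conditions = list(X = list(op = ">",
                                                          threshold = 0)),
                               response = 1)), class = "rule_table")
  gt <- ground_truth_network(rules)
  expect_equal(nrow(gt$nodes), 2L)
  expect_equal(nrow(gt$edges), 1L)
  expect_true(all(gt$nodes$sign == "positive"))
  expect_equal(gt$edges$sign, "positive")
})

test_that("the perfect ensemble tracks the generating mechanism", {
  sim <- simulate_fsd(1000, r = 0.05, seed = 52)
  pe <- perfect_ensemble(fsd_rules(), sim$data)
  expect_length(pe$decisions, 10L)
  expect_true(all(vapply(pe$decisions, function(d) d$n_support,
                         numeric(1)) > 0))
  # predictions near the rule's target, within noise
  for (i in seq_along(fsd_rules())) {
    target <- (fsd_rules()[[i]]$response + 1) / 2
    d <- pe$decisions[[i]]
    se <- sqrt(0.05 * 0.95 / d$n_support)
    expect_lte(abs(d$prediction - target), 0.05 + 3 * se)
  }
  # noiseless limit: every decision is pure and importance hits |S_D|
  sim0 <- simulate_fsd(800, r = 0, seed = 53)
  pe0 <- perfect_ensemble(fsd_rules(), sim0$data)
  for (d in pe0$decisions) {
    expect_equal(d$error, 0)
    expect_equal(decision_importance(d, sim0$data), d$n_support)
  }
})

test_that("response permutation conserves balance and honors strata", {
  sim <- simulate_fsd(600, r = 0.05, seed = 54)
  p1 <- permute_response(sim$data, seed = 1)
  expect_equal(sum(p1$y), sum(sim$data$y))
  expect_identical(p1$x, sim$data$x)
  p2 <- permute_response(sim$data, within = "Group", seed = 1)
  for (g in levels(sim$data$x$Group)) {
    ix <- sim$data$x$Group == g
    expect_equal(sum(p2$y[ix]), sum(sim$data$y[ix]))
  }
  p3 <- permute_response(sim$data, within = "Group", seed = 2)
  expect_false(identical(p2$y, p3$y))
  expect_error(permute_response(sim$data, within = "V1"), "categorical")
})

test_that("network evaluation counts TP/FP/FN and weights by importance", {
  gt <- ground_truth_network(fsd_rules())
  fake_net <- function(nodes, edges) {
    structure(list(nodes = nodes, edges = edges, provenance = list()),
              class = "decision_network")
  }
  node_row <- function(id, feature, levels, ordered, imp) {
    data.frame(id = id, feature = feature, levels = levels,
               ordered = ordered, importance = imp, influence = 0.1,
               n_active = 1, importance_norm = 1, stringsAsFactors = FALSE)
  }
  nodes <- rbind(
    node_row("Group=b", "Group", "b", FALSE, 5),
    node_row("V3__High", "V3", "High", TRUE, 4),
    node_row("V9__Low", "V9", "Low", TRUE, 2))
  edges <- data.frame(
    from = c("Group=b", "Group=b"), to = c("V3__High", "V9__Low"),
    importance = c(3, 1), influence = 0, eta = 1, direction = "solid",
    importance_norm = c(1, 1 / 3), stringsAsFactors = FALSE)
  ev <- evaluate_network(fake_net(nodes, edges), gt)
  expect_equal(ev$nodes$tp, 2)
  expect_equal(ev$nodes$fp, 1)
  expect_equal(ev$nodes$fn, 9)
  expect_equal(ev$nodes$precision, 2 / 3)
  expect_equal(ev$nodes$recall, 2 / 11)
  # one TP edge (weight 3) + one FP edge (weight 1)
  expect_equal(ev$edges$tp, 1)
  expect_equal(ev$edges$fp, 1)
  expect_equal(ev$edges$weighted_precision, 0.75)

  # empty prediction: zero recall, undefined precision
  ev0 <- evaluate_network(fake_net(nodes[0, ], edges[0, ]), gt)
  expect_equal(ev0$nodes$recall, 0)
  expect_true(is.na(ev0$nodes$precision))

  # aliasing credits a renamed entity, each truth entity once
  nodes2 <- rbind(node_row("VX__High", "VX", "High", TRUE, 4),
                  node_row("V3__Low", "V3", "Low", TRUE, 3))
  ev2 <- evaluate_network(fake_net(nodes2, edges[0, ]), gt,
                          alias_map = c(VX = "V3"))
  expect_equal(ev2$nodes$tp, 1)
  expect_equal(ev2$nodes$fp, 0)
  expect_equal(ev2$nodes$dup, 1)
})

test_that("multi-level group nodes credit each truth level once", {
  gt <- ground_truth_network(fsd_rules())
  nodes <- data.frame(
    id = c("Group=b_c", "Group=b"), feature = "Group",
    levels = c("b|c", "b"), ordered = FALSE, importance = c(5, 4),
    influence = 0, n_active = 1, importance_norm = 1,
    stringsAsFactors = FALSE)
  net <- structure(list(nodes = nodes,
                        edges = data.frame(from = character(0),
                                           to = character(0),
                                           importance = numeric(0),
                                           influence = numeric(0),
                                           eta = numeric(0),
                                           direction = character(0),
                                           importance_norm = numeric(0))),
                   class = "decision_network")
  ev <- evaluate_network(net, gt)
  # Group={b,c} (higher importance) credits one level; Group=b then credits
  # nothing new: a duplicate identification, not a false discovery
  expect_equal(ev$nodes$tp, 1)
  expect_equal(ev$nodes$dup, 1)
  expect_equal(ev$nodes$fp, 0)
})

test_that("TP/FP curves are monotone with a near-diagonal random baseline", {
  skip_if_not_installed("ranger")
  sim <- simulate_fsd(600, r = 0.05, seed = 55)
  rf <- fit_forest(sim$data, num_trees = 60, seed = 55, max_depth = 4)
  ens <- group_duplicate_rules(extract_decisions(rf, sim$data))
  st <- stability_select(ens, stability_params(B = 8, alpha_reg = 5,
                                               seed = 55),
                         discretize_K = 2)
  curve <- tpfp_curve(st, sim$truth, n_random = 300, seed = 9)
  cc <- curve$curve
  expect_true(all(diff(cc$edge_tp) >= 0))
  expect_true(all(diff(cc$edge_fp) >= 0))
  expect_true(all(diff(cc$node_tp) >= 0))
  expect_true(all(diff(cc$node_fp) >= 0))
  expect_true(all(diff(cc$threshold) <= 0))
  # baseline: expected TP among top m of a random ranking is m * T / N
  bl <- curve$baseline
  if (nrow(bl) > 2) {
    N <- nrow(bl)
    T_true <- bl$edge_tp[N]
    expect_equal(bl$edge_tp, bl$n_ranked * T_true / N,
                 tolerance = 0.25)
    expect_equal(bl$edge_tp + bl$edge_fp, as.numeric(bl$n_ranked))
  }
})
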