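make_decision <- function(conds, data, multiplicity = 1L) {
  ev <- evaluate_decision(conds, data)
  rulenet:::new_decision(conds, ev$prediction, length(ev$support), ev$error,
                         multiplicity = multiplicity)
}

test_that("removed decisions enlarge the support and recompute predictions", {
  d <- toy_data(n = 60, seed = 11)
  dec <- make_decision(list(V1 = rulenet:::cond_interval(lower = 0),
                            Group = rulenet:::cond_set("a")), d)
  rm_v1 <- removed_decision(dec, "V1", d)
  expect_setequal(rm_v1$support, which(d$x$Group == "a"))
  expect_equal(rm_v1$prediction, mean(d$y[d$x$Group == "a"]))
  orig_support <- evaluate_decision(dec, d)$support
  expect_true(all(orig_support %in% rm_v1$support))

  # removing the only condition gives the empty rule: all samples, ybar
  single <- make_decision(list(V1 = rulenet:::cond_interval(lower = 0)), d)
  rm_all <- removed_decision(single, "V1", d)
  expect_equal(rm_all$support, seq_len(d$n))
  expect_equal(rm_all$prediction, mean(d$y))

  # removing a pair
  dec3 <- make_decision(list(V1 = rulenet:::cond_interval(lower = 0),
                             Group = rulenet:::cond_set("a"),
                             V2 = rulenet:::cond_interval(lower = 0)), d)
  rm_pair <- removed_decision(dec3, c("V1", "Group"), d)
  expect_setequal(rm_pair$support, which(d$x$V2 > 0))
  expect_error(removed_decision(dec, "V2", d), "not in rule")
})

test_that("complement decisions take the complementary region", {
  d <- toy_data(n = 60, seed = 12)
  dec <- make_decision(list(V1 = rulenet:::cond_interval(lower = 0),
                            Group = rulenet:::cond_set("a")), d)
  cmp <- complement_decision(dec, "V1", d)
  expect_setequal(cmp$support, which(d$x$V1 <= 0 & d$x$Group == "a"))
  # complement and original partition the removed decision's support
  rm <- removed_decision(dec, "V1", d)
  orig <- evaluate_decision(dec, d)$support
  expect_length(intersect(orig, cmp$support), 0L)
  expect_setequal(union(orig, cmp$support), rm$support)
  # level-set complement within the observed domain
  cmp_g <- complement_decision(dec, "Group", d)
  expect_setequal(cmp_g$conditions$Group$levels, c("b", "c"))
})

test_that("decision importance follows its closed form", {
  d <- toy_data(n = 80, seed = 13)
  dec <- make_decision(list(V1 = rulenet:::cond_interval(lower = 0),
                            Group = rulenet:::cond_set(c("a", "b"))), d)
  S <- evaluate_decision(dec, d)$support
  a_hat <- rulenet:::alpha_error(d$y[S], mean(d$y[S]), d$task)
  a_bar <- rulenet:::alpha_error(d$y[S], mean(d$y), d$task)
  expect_equal(decision_importance(dec, d),
               (1 - a_hat / a_bar) * length(S))
  # linear in multiplicity
  dec3 <- dec
  dec3$multiplicity <- 3L
  expect_equal(decision_importance(dec3, d),
               3 * decision_importance(dec, d))
  # perfect prediction attains the upper bound |S_D|
  dp <- rn_data(data.frame(V1 = c(1, 2, -1, -2, -3, 4)),
                c(1, 1, 0, 0, 0, 1), task = "classification")
  perfect <- make_decision(list(V1 = rulenet:::cond_interval(lower = 0)), dp)
  expect_equal(decision_importance(perfect, dp), 3)
  # constant response on the support: importance defined as 0
  dc <- rn_data(data.frame(V1 = c(1, 2, -1, -2)), c(1, 1, 1, 1),
                task = "classification")
  expect_equal(decision_importance(
    make_decision(list(V1 = rulenet:::cond_interval(lower = 0)), dc), dc), 0)
})

test_that("single-condition decisions satisfy the delta/importance identity", {
  for (seed in 1:5) {
    d <- toy_data(n = 50, seed = seed)
    dec <- make_decision(list(V1 = rulenet:::cond_interval(lower = 0.2)), d,
                         multiplicity = 2L)
    S <- evaluate_decision(dec, d)$support
    a_bar <- rulenet:::alpha_error(d$y[S], mean(d$y), d$task)
    delta <- feature_delta(dec, "V1", d)
    expect_equal(delta * length(S) / a_bar,
                 decision_importance(dec, d) / dec$multiplicity,
                 tolerance = 1e-12)
  }
})

test_that("interaction importance is the square root of the delta product", {
  d <- toy_data(n = 70, seed = 14)
  dec <- make_decision(list(V1 = rulenet:::cond_interval(lower = 0),
                            V2 = rulenet:::cond_interval(upper = 0.5)), d)
  dj <- feature_delta(dec, "V1", d)
  dk <- feature_delta(dec, "V2", d)
  expected <- if (dj * dk < 0) 0 else sqrt(dj * dk)
  expect_equal(interaction_delta(dec, "V1", "V2", d), expected)
  expect_equal(interaction_delta(dec, "V2", "V1", d),
               interaction_delta(dec, "V1", "V2", d))
  expect_gte(interaction_delta(dec, "V1", "V2", d), 0)
  expect_equal(feature_delta(dec, "Group", d), 0)  # inactive feature
})

test_that("direction indicators follow the rank rule", {
  lv2 <- factor(c("Low", "High", "High", "Low"),
                levels = c("Low", "High"), ordered = TRUE)
  lv3 <- factor(c("Low", "Medium", "High", "High"),
                levels = c("Low", "Medium", "High"), ordered = TRUE)
  d <- rn_data(data.frame(A = lv2, B = lv3, V = c(2, -1, 0.5, 3)),
               c(1, 0, 1, 0), task = "classification")
  mk <- function(f, cond) {
    dec <- rulenet:::new_decision(setNames(list(cond), f))
    direction_indicator(dec, f, d)
  }
  expect_equal(mk("A", rulenet:::cond_set("High")), 1)
  expect_equal(mk("A", rulenet:::cond_set("Low")), -1)
  expect_equal(mk("B", rulenet:::cond_set(c("Medium", "High"))), 1)
  expect_equal(mk("B", rulenet:::cond_set(c("Low", "Medium"))), -1)
  # numeric interval: admitted region above/below the mean rank
  expect_equal(mk("V", rulenet:::cond_interval(lower = 1)), 1)
  expect_equal(mk("V", rulenet:::cond_interval(upper = 0)), -1)
})

test_that("influences carry the direction sign and vanish when opposed", {
  d <- toy_data(n = 80, seed = 15)
  dec <- make_decision(list(V1 = rulenet:::cond_interval(lower = 0),
                            V2 = rulenet:::cond_interval(lower = 0)), d)
  g1 <- influence_delta(dec, "V1", d)
  S <- evaluate_decision(dec, d)$support
  rm <- removed_decision(dec, "V1", d)
  d1 <- direction_indicator(dec, "V1", d)
  expect_equal(g1, d1 * (mean(d$y[S]) - rm$prediction))
  # same-direction pair: mean direction 1
  g12 <- influence_delta(dec, c("V1", "V2"), d)
  rm12 <- removed_decision(dec, c("V1", "V2"), d)
  expect_equal(g12, mean(d$y[S]) - rm12$prediction)
  # opposite directions null the pair influence
  dec_op <- make_decision(list(V1 = rulenet:::cond_interval(lower = 0),
                               V2 = rulenet:::cond_interval(upper = 0)), d)
  expect_equal(influence_delta(dec_op, c("V1", "V2"), d), 0)
})

test_that("aggregates match single-decision closed forms and drop inactive features", {
  d <- toy_data(n = 60, seed = 16)
  dec <- make_decision(list(V1 = rulenet:::cond_interval(lower = 0),
                            Group = rulenet:::cond_set("a")), d)
  ens <- rulenet:::new_decision_ensemble(list(dec), d)
  agg <- aggregate_metrics(ens, granularity = "feature")
  I <- decision_importance(dec, d)
  expect_setequal(agg$features$entity, c("V1", "Group"))
  f_v1 <- agg$features[agg$features$entity == "V1", ]
  expect_equal(f_v1$importance, feature_delta(dec, "V1", d) * I)
  expect_equal(f_v1$influence, influence_delta(dec, "V1", d))
  expect_false("V2" %in% agg$features$entity)
  expect_equal(nrow(agg$interactions), 1L)
  expect_equal(agg$interactions$importance,
               interaction_delta(dec, "V1", "Group", d) * I)
})

test_that("metrics agree with the brute-force oracle on random ensembles", {
  for (seed in c(1:10, 101:105)) {
    task <- if (seed %% 2 == 0) "regression" else "classification"
    ens <- random_mini_ensemble(seed, task = task)
    orc <- oracle_aggregate(ens)
    agg <- aggregate_metrics(ens, granularity = "feature")
    for (i in seq_len(nrow(agg$features))) {
      f <- agg$features$entity[i]
      expect_equal(agg$features$importance[i], unname(orc$F_j[[f]]),
                   tolerance = 1e-10, label = paste("F", f, "seed", seed))
      expect_equal(agg$features$influence[i], unname(orc$Gamma_j[[f]]),
                   tolerance = 1e-10, label = paste("Gamma", f, "seed", seed))
    }
    for (i in seq_len(nrow(agg$interactions))) {
      key <- paste(sort(c(agg$interactions$entity_a[i],
                          agg$interactions$entity_b[i])), collapse = "\r")
      expect_equal(agg$interactions$importance[i], unname(orc$F_jk[[key]]),
                   tolerance = 1e-10)
      expect_equal(agg$interactions$influence[i], unname(orc$Gamma_jk[[key]]),
                   tolerance = 1e-10)
      expect_equal(agg$interactions$eta[i], unname(orc$eta[[key]]))
    }
  }
})

test_that("adding a feature that appears in no rule changes no metric", {
  ens <- random_mini_ensemble(42)
  agg1 <- aggregate_metrics(ens, granularity = "feature")
  d2 <- ens$data
  x2 <- d2$x
  set.seed(999)
  x2$EXTRA <- rnorm(nrow(x2))
  ens2 <- ens
  ens2$data <- rn_data(x2, d2$y, task = d2$task)
  agg2 <- aggregate_metrics(ens2, granularity = "feature")
  expect_equal(agg2, agg1)
})
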