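## Main fitting-style entry point: tree ensemble + data in, stable decision
## ensemble with metrics and network out.

#' Interpret a tree-ensemble model as a regularized decision network
#'
#' Runs the full pipeline: extract one decision per root-to-leaf path
#' (predictions recomputed from the data), group duplicates, optionally
#' discretize numeric features into `K` levels and rewrite rules, optionally
#' prune uninformative conditions, select decisions stable across bootstrap
#' resamples, and compute feature/interaction importances and influences and
#' the decision network.
#'
#' @param model a [tree_ensemble()], or a fitted `ranger`/`xgb.Booster`
#'   object (converted via [as_tree_ensemble()]).
#' @param data an [rn_data()] with the training features and response.
#' @param K number of discretization levels (>= 2).
#' @param discretization `"data"` (empirical quantiles) or `"rf-thresholds"`
#'   (k-means on the model's split thresholds).
#' @param discretize_numerics discretize numeric features? (default TRUE)
#' @param prune prune decisions? (default TRUE)
#' @param tolerance pruning tolerance (relative error increase; default
#'   0.05).
#' @param bootstrap run bootstrap stability selection? (default TRUE) When
#'   FALSE the regularized ensemble with full-data metrics is used directly.
#' @param B,pi_thr,alpha_reg,resample_fraction see [stability_params()].
#' @param seed master seed; all stochastic steps derive their seeds from it.
#' @return An object of class `rulenet` with components `ensemble` (the
#'   stable or regularized `decision_ensemble`), `network`
#'   (a [build_network()] result), `feature_metrics` / `interaction_metrics`
#'   (feature-granularity aggregates), `table`
#'   (the [importance_influence_table()]), `map` (discretization map),
#'   `stages` (per-stage decision counts), and the parameters used.
#' @export
rulenet <- function(model, data, K = 2L,
                    discretization = c("data", "rf-thresholds"),
                    discretize_numerics = TRUE, prune = TRUE,
                    tolerance = 0.05, bootstrap = TRUE, B = 10L,
                    pi_thr = 0.7, alpha_reg = 1, resample_fraction = 0.5,
                    seed = NULL) {
  cl <- match.call()
  discretization <- match.arg(discretization)
  sparams <- stability_params(B = B, pi_thr = pi_thr, alpha_reg = alpha_reg,
                              resample_fraction = resample_fraction,
                              seed = seed)
  model <- as_tree_ensemble(model)
  stages <- list()
  ens <- extract_decisions(model, data)
  stages$extracted <- ens$n_extracted
  ens <- group_duplicate_rules(ens)
  stages$grouped <- length(ens$decisions)
  map <- structure(list(), class = "discretization_map")
  work_data <- data
  want_disc <- discretize_numerics && any(data$feature_kinds == "numeric")
  if (bootstrap) {
    ## all decision-wise regularization (discretization, pruning,
    ## regrouping) runs inside each bootstrap resample
    final <- stability_select(ens, sparams, bootstrap_prune = prune,
                              tolerance = tolerance,
                              discretize_K = if (want_disc) K else NULL,
                              discretize_method = discretization)
    map <- final$map
    work_data <- final$data
    stages$stable <- length(final$decisions)
  } else {
    if (want_disc) {
      disc <- discretize(data, ens, K = K, method = discretization)
      ens <- disc$ensemble
      map <- disc$map
      work_data <- disc$data
      stages$discretized <- length(ens$decisions)
    }
    if (prune) {
      ens <- prune_decisions(ens, tolerance = tolerance)
      stages$pruned <- length(ens$decisions)
    }
    met <- compute_decision_metrics(ens)
    keep <- !vapply(met, is.null, logical(1L))
    final <- ens
    final$decisions <- lapply(which(keep), function(i) {
      d <- ens$decisions[[i]]
      d$importance <- met[[i]]$importance
      d
    })
    final$decision_metrics <- met[keep]
    class(final) <- c("stable_ensemble", class(final))
    final$selection_probability <- rep(1, sum(keep))
    final$candidates <- list(decisions = final$decisions,
                             metrics = final$decision_metrics,
                             selection_probability =
                               final$selection_probability)
    final$q <- length(final$decisions)
    final$d <- length(final$decisions)
    final$B <- 0L
    final$params <- sparams
    stages$final <- length(final$decisions)
  }
  fm <- aggregate_metrics(final, granularity = "feature")
  net <- build_network(final, provenance = list(
    params = list(K = K, discretization = discretization,
                  prune = prune, tolerance = tolerance,
                  B = sparams$B, pi_thr = sparams$pi_thr,
                  alpha_reg = sparams$alpha_reg,
                  resample_fraction = sparams$resample_fraction),
    seed = seed,
    model_fingerprint = sprintf("%d trees / %d nodes",
                                length(unique(model$nodes$tree)),
                                nrow(model$nodes))))
  structure(list(call = cl, ensemble = final, network = net,
                 feature_metrics = fm$features,
                 interaction_metrics = fm$interactions,
                 table = importance_influence_table(final),
                 map = map, data = work_data, stages = stages,
                 params = net$provenance$params, seed = seed),
            class = "rulenet")
}

#' @export
print.rulenet <- function(x, ...) {
  cat("rulenet decision-ensemble interpretation\n")
  cat("  stages: ",
      paste(names(x$stages), unlist(x$stages), sep = " = ",
            collapse = ", "), "\n", sep = "")
  cat("  network: ", nrow(x$network$nodes), " node(s), ",
      nrow(x$network$edges), " edge(s)\n", sep = "")
  if (nrow(x$feature_metrics) > 0L) {
    cat("  top features:\n")
    print(head(x$feature_metrics, 5L), row.names = FALSE)
  }
  invisible(x)
}

#' @export
summary.rulenet <- function(object, ...) {
  structure(list(stages = object$stages,
                 features = object$feature_metrics,
                 interactions = object$interaction_metrics,
                 table = object$table,
                 decisions = as.data.frame(object$ensemble),
                 q = object$ensemble$q, d = object$ensemble$d),
            class = "summary.rulenet")
}

#' @export
print.summary.rulenet <- function(x, ...) {
  cat("Stable decisions (", nrow(x$decisions), "; q = ", x$q,
      ", mean ensemble size d = ", round(x$d, 1), "):\n", sep = "")
  print(head(x$decisions[order(-x$decisions$importance), ], 10L),
        row.names = FALSE)
  cat("\nFeature importance and influence:\n")
  print(x$features, row.names = FALSE)
  cat("\nInteraction importance and influence:\n")
  print(head(x$interactions, 10L), row.names = FALSE)
  invisible(x)
}

#' @export
coef.rulenet <- function(object, ...) {
  setNames(object$feature_metrics$importance,
           object$feature_metrics$entity)
}

#' Map new data onto a discretization
#'
#' @param map a `discretization_map`.
#' @param newdata a data.frame.
#' @return The data.frame with mapped columns replaced by ordered factors.
#' @export
apply_discretization <- function(map, newdata) {
  for (f in names(map)) {
    if (!f %in% names(newdata)) next
    if (is.numeric(newdata[[f]])) {
      newdata[[f]] <- cut(newdata[[f]],
                          breaks = c(-Inf, map[[f]]$breakpoints, Inf),
                          labels = map[[f]]$labels, ordered_result = TRUE)
    }
  }
  newdata
}

#' Predict from the stable decision ensemble
#'
#' For each new sample, the prediction is the importance-weighted mean of
#' the predictions of the stable decisions whose rule the sample satisfies;
#' samples covered by no decision get the training response mean. This is a
#' diagnostic surrogate for the interpreted model, not a replacement for it.
#'
#' @param object a `rulenet` fit.
#' @param newdata a data.frame of features (raw scale; discretization is
#'   applied automatically). Defaults to the training features.
#' @param ... unused.
#' @return A numeric vector of predictions.
#' @export
predict.rulenet <- function(object, newdata = NULL, ...) {
  ens <- object$ensemble
  if (is.null(newdata)) {
    x <- object$data$x
  } else {
    x <- apply_discretization(object$map, as.data.frame(newdata))
  }
  n <- nrow(x)
  num <- rep(0, n)
  den <- rep(0, n)
  for (d in ens$decisions) {
    w <- max(d$importance, 0)
    if (is.na(w) || w == 0) next
    m <- rep(TRUE, n)
    for (f in names(d$conditions)) {
      m <- m & cond_mask(d$conditions[[f]], x[[f]])
    }
    num[m] <- num[m] + w * d$prediction
    den[m] <- den[m] + w
  }
  out <- ifelse(den > 0, num / den, ens$global_mean)
  as.numeric(out)
}

#' Plot the decision network
#'
#' A thin display layer over the network exports: node size encodes feature
#' importance, node color influence (blue positive, orange negative), edge
#' width interaction importance, edge type the direction agreement (solid =
#' same direction, dashed = opposite).
#'
#' @param x a `rulenet` fit or a `decision_network`.
#' @param ... passed to `plot.igraph`.
#' @return The igraph object, invisibly.
#' @export
plot.rulenet <- function(x, ...) {
  plot(x$network, ...)
}

#' @rdname plot.rulenet
#' @export
plot.decision_network <- function(x, ...) {
  if (nrow(x$nodes) == 0L) {
    warning("empty network; nothing to plot")
    return(invisible(NULL))
  }
  g <- as_igraph(x)
  infl <- igraph::V(g)$influence
  vcol <- ifelse(infl >= 0, "#4477aa", "#ee7733")
  vsize <- 8 + 22 * igraph::V(g)$importance_norm
  if (igraph::ecount(g) > 0) {
    ew <- 0.5 + 4 * igraph::E(g)$importance_norm
    elty <- ifelse(igraph::E(g)$direction == "solid", 1, 2)
  } else {
    ew <- NULL
    elty <- NULL
  }
  plot(g, vertex.size = vsize, vertex.color = vcol,
       edge.width = ew, edge.lty = elty, ...)
  invisible(g)
}
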