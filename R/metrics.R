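## Decision, feature, and interaction importance and influence.
##
## For a decision D with support S_D and prediction yhat_D, and the error
## function alpha (mean squared error for regression, mean misclassification
## error for binary classification):
##
##   decision importance   I_D     = (1 - alpha(S_D, yhat_D) /
##                                        alpha(S_D, ybar)) * |S_D| * mult
##   feature importance    delta_j = alpha(S_D, yhat_{D_j^rm}) -
##                                   alpha(S_D, yhat_D)
##   interaction           delta_jk = sqrt(delta_j * delta_k)  (0 if the
##                                   product is negative)
##   feature influence     gamma_j  = d_j * (yhat_D - yhat_{D_j^rm})
##   interaction influence gamma_jk = (d_j + d_k)/2 * (yhat_D - yhat_{D_jk^rm})
##
## where D_j^rm removes the condition on feature j (its prediction comes from
## the enlarged support, but its error is evaluated on the ORIGINAL support
## S_D), and d_j in {-1, +1} indicates whether the rule admits predominantly
## large (+1) or small (-1) values of feature j.
##
## Aggregates over the ensemble: F_j = sum delta_j I_D, F_jk = sum delta_jk
## I_D, Gamma_j = sum gamma_j I_D / sum_{active} I_D (analogous for pairs),
## eta_jk = sign(sum_{active} d_j d_k I_D).

#' Decision with one or two features removed from its rule
#'
#' The condition(s) on the given feature(s) are dropped. If the rule becomes
#' empty its support is all samples and its prediction is the sample mean.
#' The prediction is recomputed from the enlarged support; the reported error
#' is that prediction's error on the *original* support (the quantity
#' entering the feature importance).
#'
#' @param decision a decision.
#' @param features one feature name or a pair.
#' @param data an [rn_data()].
#' @return `list(conditions, support, prediction, error_on_original)`.
#' @export
removed_decision <- function(decision, features, data) {
  missing_f <- setdiff(features, names(decision$conditions))
  if (length(missing_f) > 0L) {
    stop("feature(s) not in rule: ", paste(missing_f, collapse = ", "))
  }
  conds <- decision$conditions[setdiff(names(decision$conditions), features)]
  m_orig <- rule_mask(decision$conditions, data)
  m_rm <- rule_mask(conds, data)
  pred <- mean(data$y[m_rm])
  list(conditions = conds, support = which(m_rm), prediction = pred,
       error_on_original = alpha_error(data$y[m_orig], pred, data$task))
}

#' Decision with condition(s) replaced by their complement
#'
#' The admitted interval or level set of the given feature(s) is complemented
#' within the feature's observed domain; prediction and error are recomputed
#' on the complement support.
#'
#' @inheritParams removed_decision
#' @return `list(conditions, support, prediction, error)`; an empty
#'   complement support yields `NA` prediction and error (flagged sentinel).
#' @export
complement_decision <- function(decision, features, data) {
  missing_f <- setdiff(features, names(decision$conditions))
  if (length(missing_f) > 0L) {
    stop("feature(s) not in rule: ", paste(missing_f, collapse = ", "))
  }
  conds <- decision$conditions
  for (f in features) {
    cond <- conds[[f]]
    if (cond$kind == "set") {
      domain <- levels(data$x[[f]])
      admitted <- if (isTRUE(cond$negate)) setdiff(domain, cond$levels) else
        cond$levels
      conds[[f]] <- cond_set(setdiff(domain, admitted))
    } else {
      cond$negate <- !isTRUE(cond$negate)
      conds[[f]] <- cond
    }
  }
  m <- rule_mask(conds, data)
  if (!any(m)) {
    return(list(conditions = conds, support = integer(0),
                prediction = NA_real_, error = NA_real_))
  }
  pred <- mean(data$y[m])
  list(conditions = conds, support = which(m), prediction = pred,
       error = alpha_error(data$y[m], pred, data$task))
}

#' Decision importance
#'
#' `(1 - alpha(S_D, yhat_D)/alpha(S_D, ybar)) * |S_D|`, multiplied by the
#' decision's multiplicity. The bracket is the coefficient of determination
#' (regression) or Cohen's kappa (classification) on the support. When the
#' response is constant on the support (`alpha(S_D, ybar) = 0`) the
#' importance is defined as 0.
#'
#' @param decision a decision.
#' @param data an [rn_data()].
#' @param global_mean the reference prediction `ybar` (defaults to the mean
#'   response of `data`).
#' @return A single number.
#' @export
decision_importance <- function(decision, data, global_mean = mean(data$y)) {
  m <- rule_mask(decision$conditions, data)
  ys <- data$y[m]
  if (length(ys) == 0L) return(NA_real_)
  pred <- mean(ys)
  err <- alpha_error(ys, pred, data$task)
  err0 <- alpha_error(ys, global_mean, data$task)
  if (err0 == 0) return(0)
  (1 - err / err0) * length(ys) * decision$multiplicity
}

#' Decision-wise feature importance
#'
#' `alpha(S_D, yhat_{D_j^rm}) - alpha(S_D, yhat_D)`: how much the error on
#' the decision's own support increases when feature `j` is dropped from the
#' rule. May be negative; zero for inactive features.
#'
#' @param decision a decision.
#' @param feature a feature name active in the rule.
#' @param data an [rn_data()].
#' @return A single number.
#' @export
feature_delta <- function(decision, feature, data) {
  if (!feature %in% names(decision$conditions)) return(0)
  m <- rule_mask(decision$conditions, data)
  ys <- data$y[m]
  pred <- mean(ys)
  rm <- removed_decision(decision, feature, data)
  rm$error_on_original - alpha_error(ys, pred, data$task)
}

#' Decision-wise interaction importance
#'
#' `sqrt(delta_j * delta_k)`, symmetric in `(j, k)`; if the product is
#' negative the interaction importance is 0 (a feature whose removal improves
#' the decision earns no interaction credit).
#'
#' @param decision a decision.
#' @param feature_j,feature_k feature names active in the rule.
#' @param data an [rn_data()].
#' @return A non-negative number.
#' @export
interaction_delta <- function(decision, feature_j, feature_k, data) {
  dj <- feature_delta(decision, feature_j, data)
  dk <- feature_delta(decision, feature_k, data)
  sqrt(max(0, dj * dk))
}

## direction of one condition: +1 if the admitted region lies predominantly
## on the high side of the feature, -1 otherwise (ties break to +1).
## Level-set conditions compare the mean rank of admitted levels to the mean
## rank of all levels; interval conditions compare the mean rank of admitted
## samples to the overall mean rank.
condition_direction <- function(cond, col) {
  if (cond$kind == "set") {
    domain <- levels(col)
    admitted <- if (isTRUE(cond$negate)) setdiff(domain, cond$levels) else
      cond$levels
    if (length(admitted) == 0L) return(1)
    mr <- mean(match(admitted, domain))
    if (mr >= (length(domain) + 1) / 2) 1 else -1
  } else {
    m <- cond_mask(cond, col)
    if (!any(m)) return(1)
    r <- rank(col)
    if (mean(r[m]) >= mean(r)) 1 else -1
  }
}

#' Direction indicator of a feature within a decision
#'
#' +1 when the rule admits predominantly large values of the feature, -1 when
#' it admits predominantly small ones. For level-set conditions the mean rank
#' of admitted levels is compared to the mean rank of all levels; for
#' interval conditions the mean sample rank of the admitted region is
#' compared to the overall mean rank. Ties break to +1.
#'
#' @inheritParams feature_delta
#' @return `+1` or `-1`.
#' @export
direction_indicator <- function(decision, feature, data) {
  if (!feature %in% names(decision$conditions)) {
    stop("feature '", feature, "' not in rule")
  }
  condition_direction(decision$conditions[[feature]], data$x[[feature]])
}

#' Decision-wise feature or interaction influence
#'
#' For one feature: `d_j * (yhat_D - yhat_{D_j^rm})`. For a pair:
#' `(d_j + d_k)/2 * (yhat_D - yhat_{D_jk^rm})`, which is zero when the two
#' directions are opposite.
#'
#' @param decision a decision.
#' @param features one feature name or a pair, active in the rule.
#' @param data an [rn_data()].
#' @return A single number.
#' @export
influence_delta <- function(decision, features, data) {
  m <- rule_mask(decision$conditions, data)
  pred <- mean(data$y[m])
  rm <- removed_decision(decision, features, data)
  d <- vapply(features, function(f) direction_indicator(decision, f, data),
              numeric(1L))
  mean(d) * (pred - rm$prediction)
}

## entity label of a condition at a given granularity. Level sets on ordered
## factors (discretized numerics) render as "V3__Low_Medium"; sets on
## unordered factors as "Group=a"; intervals as the condition string.
entity_label <- function(feature, cond, data, granularity) {
  if (granularity == "feature") return(feature)
  if (cond$kind == "set") {
    domain <- levels(data$x[[feature]])
    admitted <- if (isTRUE(cond$negate)) setdiff(domain, cond$levels) else
      cond$levels
    admitted <- domain[sort(match(admitted, domain))]
    sep <- if (is.ordered(data$x[[feature]])) "__" else "="
    paste0(feature, sep, paste(admitted, collapse = "_"))
  } else {
    cond_string(feature, cond)
  }
}

## Per-decision metrics on the full data or a bootstrap resample.
## `idx` is a resample index vector (with replacement); NULL = full data.
## Returns NULL for a decision with empty support on the resample.
## Uses precomputed full-data masks for speed; masks are subset by `idx`.
decision_metrics_one <- function(decision, cond_masks, y, task, idx = NULL) {
  feats <- names(decision$conditions)
  full_m <- Reduce(`&`, cond_masks, rep(TRUE, length(y)))
  if (!is.null(idx)) {
    yb <- y[idx]
    full_b <- full_m[idx]
  } else {
    yb <- y
    full_b <- full_m
  }
  if (!any(full_b)) return(NULL)
  ys <- yb[full_b]
  ybar <- mean(yb)
  pred <- mean(ys)
  err <- alpha_error(ys, pred, task)
  err0 <- alpha_error(ys, ybar, task)
  imp <- if (err0 == 0) 0 else
    (1 - err / err0) * length(ys) * decision$multiplicity
  k <- length(feats)
  delta <- setNames(numeric(k), feats)
  gamma <- setNames(numeric(k), feats)
  dvec <- decision$direction
  pred_rm <- setNames(numeric(k), feats)
  for (j in seq_len(k)) {
    m_rm <- Reduce(`&`, cond_masks[-j], rep(TRUE, length(y)))
    m_rm_b <- if (is.null(idx)) m_rm else m_rm[idx]
    p_rm <- if (any(m_rm_b)) mean(yb[m_rm_b]) else ybar
    pred_rm[j] <- p_rm
    delta[j] <- alpha_error(ys, p_rm, task) - err
    gamma[j] <- dvec[[feats[j]]] * (pred - p_rm)
  }
  pairs <- NULL
  if (k >= 2L) {
    cmb <- utils::combn(k, 2L)
    np <- ncol(cmb)
    pj <- character(np); pk <- character(np)
    d_jk <- numeric(np); g_jk <- numeric(np); dd <- numeric(np)
    for (q in seq_len(np)) {
      a <- cmb[1L, q]; b <- cmb[2L, q]
      if (k == 2L) {
        m_jk_b <- if (is.null(idx)) rep(TRUE, length(y)) else
          rep(TRUE, length(idx))
        p_jk <- ybar
      } else {
        m_jk <- Reduce(`&`, cond_masks[-c(a, b)], rep(TRUE, length(y)))
        m_jk_b <- if (is.null(idx)) m_jk else m_jk[idx]
        p_jk <- if (any(m_jk_b)) mean(yb[m_jk_b]) else ybar
      }
      pj[q] <- feats[a]; pk[q] <- feats[b]
      d_jk[q] <- sqrt(max(0, delta[a] * delta[b]))
      g_jk[q] <- (dvec[[feats[a]]] + dvec[[feats[b]]]) / 2 * (pred - p_jk)
      dd[q] <- dvec[[feats[a]]] * dvec[[feats[b]]]
    }
    pairs <- data.frame(j = pj, k = pk, delta = d_jk, gamma = g_jk,
                        dd = dd, stringsAsFactors = FALSE)
  }
  list(importance = imp, prediction = pred, error = err,
       n_support = sum(full_b), delta = delta, gamma = gamma,
       pairs = pairs)
}

## precompute per-decision condition masks and direction indicators
ensemble_cache <- function(ensemble) {
  data <- ensemble$data
  lapply(ensemble$decisions, function(d) {
    feats <- names(d$conditions)
    masks <- lapply(feats, function(f) cond_mask(d$conditions[[f]],
                                                 data$x[[f]]))
    names(masks) <- feats
    dir <- vapply(feats, function(f) {
      condition_direction(d$conditions[[f]], data$x[[f]])
    }, numeric(1L))
    list(masks = masks, direction = as.list(dir))
  })
}

## compute per-decision metrics for the whole ensemble (full data or resample)
compute_decision_metrics <- function(ensemble, cache = NULL, idx = NULL) {
  if (is.null(cache)) cache <- ensemble_cache(ensemble)
  y <- ensemble$data$y
  task <- ensemble$task
  lapply(seq_along(ensemble$decisions), function(i) {
    d <- ensemble$decisions[[i]]
    d$direction <- cache[[i]]$direction
    decision_metrics_one(d, cache[[i]]$masks, y, task, idx)
  })
}

#' Aggregate feature and interaction metrics over a decision ensemble
#'
#' Computes every decision's importance, feature deltas, directions, and
#' influences, and aggregates them into feature importances `F_j`,
#' interaction importances `F_jk`, influences `Gamma_j` / `Gamma_jk`, and
#' direction agreements `eta_jk`. Features appearing in no rule get no entry.
#'
#' @param ensemble a `decision_ensemble` (or `stable_ensemble`, whose
#'   bootstrap-averaged decision metrics are then used).
#' @param granularity `"feature"` aggregates per feature name; `"levelset"`
#'   treats each rewritten condition (feature plus admitted level set) as a
#'   binary pseudo-feature, the granularity used by the decision network.
#' @return A list with data.frames `features` (entity, feature, importance,
#'   influence, n_active) and `interactions` (entity_a, entity_b, importance,
#'   influence, eta, any_delta_pos).
#' @export
aggregate_metrics <- function(ensemble,
                              granularity = c("feature", "levelset")) {
  granularity <- match.arg(granularity)
  met <- if (inherits(ensemble, "stable_ensemble")) {
    ensemble$decision_metrics
  } else {
    compute_decision_metrics(ensemble)
  }
  aggregate_from_metrics(ensemble, met, granularity)
}

## an influence is a ratio of importance-weighted sums; when the
## denominator cancels to numerical zero relative to its absolute mass the
## ratio is meaningless and the influence is reported as 0 (the same rule
## the method defines for an exactly-zero denominator)
safe_ratio <- function(num, den, absden) {
  if (absden == 0 || abs(den) <= 1e-9 * absden) 0 else num / den
}

aggregate_from_metrics <- function(ensemble, met, granularity) {
  data <- ensemble$data
  f_imp <- list(); f_inf <- list(); f_den <- list(); f_cnt <- list()
  f_feat <- list(); f_absden <- list()
  e_imp <- list(); e_inf <- list(); e_den <- list(); e_eta <- list()
  e_pos <- list(); e_absden <- list()
  add <- function(env, key, val) {
    env[[key]] <- (if (is.null(env[[key]])) 0 else env[[key]]) + val
    env
  }
  for (i in seq_along(ensemble$decisions)) {
    m <- met[[i]]
    if (is.null(m)) next
    d <- ensemble$decisions[[i]]
    feats <- names(d$conditions)
    ent <- vapply(feats, function(f) {
      entity_label(f, d$conditions[[f]], data, granularity)
    }, character(1L))
    for (j in seq_along(feats)) {
      key <- ent[j]
      f_imp <- add(f_imp, key, m$delta[[feats[j]]] * m$importance)
      f_inf <- add(f_inf, key, m$gamma[[feats[j]]] * m$importance)
      f_den <- add(f_den, key, m$importance)
      f_absden <- add(f_absden, key, abs(m$importance))
      f_cnt <- add(f_cnt, key, 1)
      f_feat[[key]] <- feats[j]
    }
    if (!is.null(m$pairs) && nrow(m$pairs) > 0L) {
      for (q in seq_len(nrow(m$pairs))) {
        ea <- ent[[m$pairs$j[q]]]; eb <- ent[[m$pairs$k[q]]]
        if (ea > eb) { tmp <- ea; ea <- eb; eb <- tmp }
        key <- paste(ea, eb, sep = "\r")
        e_imp <- add(e_imp, key, m$pairs$delta[q] * m$importance)
        e_inf <- add(e_inf, key, m$pairs$gamma[q] * m$importance)
        e_den <- add(e_den, key, m$importance)
        e_absden <- add(e_absden, key, abs(m$importance))
        e_eta <- add(e_eta, key, m$pairs$dd[q] * m$importance)
        e_pos <- add(e_pos, key, as.numeric(m$pairs$delta[q] > 0))
      }
    }
  }
  fkeys <- if (length(f_imp) > 0L) names(f_imp) else character(0)
  features <- data.frame(
    entity = fkeys,
    feature = vapply(fkeys, function(k) f_feat[[k]], character(1L)),
    importance = vapply(fkeys, function(k) f_imp[[k]], numeric(1L)),
    influence = vapply(fkeys, function(k) {
      safe_ratio(f_inf[[k]], f_den[[k]], f_absden[[k]])
    }, numeric(1L)),
    n_active = vapply(fkeys, function(k) f_cnt[[k]], numeric(1L)),
    stringsAsFactors = FALSE, row.names = NULL)
  ekeys <- if (length(e_imp) > 0L) names(e_imp) else character(0)
  ab <- strsplit(ekeys, "\r", fixed = TRUE)
  interactions <- data.frame(
    entity_a = vapply(ab, `[`, character(1L), 1L),
    entity_b = vapply(ab, `[`, character(1L), 2L),
    importance = vapply(ekeys, function(k) e_imp[[k]], numeric(1L)),
    influence = vapply(ekeys, function(k) {
      safe_ratio(e_inf[[k]], e_den[[k]], e_absden[[k]])
    }, numeric(1L)),
    eta = vapply(ekeys, function(k) sign(e_eta[[k]]), numeric(1L)),
    any_delta_pos = vapply(ekeys, function(k) e_pos[[k]] > 0, logical(1L)),
    stringsAsFactors = FALSE, row.names = NULL)
  if (length(fkeys) > 0L) {
    features <- features[order(-features$importance), , drop = FALSE]
    row.names(features) <- NULL
  }
  if (length(ekeys) > 0L) {
    interactions <- interactions[order(-interactions$importance), ,
                                 drop = FALSE]
    row.names(interactions) <- NULL
  }
  list(features = features, interactions = interactions)
}

#' Export feature and interaction metrics as TSV
#'
#' @param metrics result of [aggregate_metrics()].
#' @param feature_path,interaction_path output paths.
#' @return The paths, invisibly.
#' @export
write_metrics <- function(metrics, feature_path, interaction_path) {
  write.table(metrics$features, feature_path, sep = "\t", row.names = FALSE,
              quote = FALSE)
  write.table(metrics$interactions, interaction_path, sep = "\t",
              row.names = FALSE, quote = FALSE)
  invisible(c(feature_path, interaction_path))
}
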