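## Decisions and decision ensembles.
##
## A rule is a conjunction of at most one condition per feature. Numeric
## conditions are half-open intervals `lower < x <= upper`; conditions on
## categorical (or discretized) features admit a non-empty proper subset of
## the observed levels. A condition may be negated (complement decisions).
## A decision pairs a rule with a constant prediction, recomputed as the mean
## response over the samples satisfying the rule.

cond_interval <- function(lower = -Inf, upper = Inf, negate = FALSE) {
  list(kind = "interval", lower = lower, upper = upper, negate = negate)
}

cond_set <- function(levels, negate = FALSE) {
  list(kind = "set", levels = as.character(levels), negate = negate)
}

## logical mask of samples satisfying one condition
cond_mask <- function(cond, col) {
  m <- if (cond$kind == "interval") {
    col > cond$lower & col <= cond$upper
  } else {
    as.character(col) %in% cond$levels
  }
  if (isTRUE(cond$negate)) !m else m
}

## mask of samples satisfying a rule (optionally with features excluded)
rule_mask <- function(conditions, data, exclude = character(0)) {
  keep <- setdiff(names(conditions), exclude)
  m <- rep(TRUE, data$n)
  for (f in keep) m <- m & cond_mask(conditions[[f]], data$x[[f]])
  m
}

cond_string <- function(feature, cond) {
  s <- if (cond$kind == "interval") {
    if (is.finite(cond$lower) && is.finite(cond$upper)) {
      sprintf("%s in (%.6g,%.6g]", feature, cond$lower, cond$upper)
    } else if (is.finite(cond$upper)) {
      sprintf("%s<=%.6g", feature, cond$upper)
    } else {
      sprintf("%s>%.6g", feature, cond$lower)
    }
  } else {
    sprintf("%s in {%s}", feature, paste(cond$levels, collapse = ","))
  }
  if (isTRUE(cond$negate)) paste0("!(", s, ")") else s
}

#' Render a decision's rule as a string
#' @param decision a decision (element of a decision ensemble's `decisions`).
#' @return A single string such as `"Group in {a} & V1>0"`.
#' @export
rule_string <- function(decision) {
  conds <- decision$conditions
  if (length(conds) == 0L) return("<empty rule>")
  paste(mapply(cond_string, names(conds), conds), collapse = " & ")
}

## canonical key used for duplicate grouping and deterministic ordering
rule_key <- function(conditions) {
  if (length(conditions) == 0L) return("<empty>")
  ord <- order(names(conditions))
  parts <- vapply(ord, function(i) {
    cond <- conditions[[i]]
    body <- if (cond$kind == "interval") {
      sprintf("(%.17g,%.17g]", cond$lower, cond$upper)
    } else {
      paste0("{", paste(sort(cond$levels), collapse = "|"), "}")
    }
    paste0(names(conditions)[i], if (isTRUE(cond$negate)) "!" else "=", body)
  }, character(1L))
  paste(parts, collapse = "&")
}

## error function: mean residual sum of squares (regression) or mean
## misclassification error 1 - yhat^y (1-yhat)^(1-y) (binary classification,
## which reduces to mean |y - yhat| for y in {0,1})
alpha_error <- function(y_support, yhat, task) {
  if (length(y_support) == 0L) return(NA_real_)
  if (task == "regression") {
    mean((y_support - yhat)^2)
  } else {
    mean(abs(y_support - yhat))
  }
}

new_decision <- function(conditions, prediction = NA_real_,
                         n_support = NA_integer_, error = NA_real_,
                         multiplicity = 1L) {
  list(conditions = conditions, prediction = prediction,
       n_support = n_support, error = error,
       multiplicity = multiplicity, importance = NA_real_)
}

new_decision_ensemble <- function(decisions, data, dropped_multiplicity = 0L,
                                  n_extracted = NA_integer_) {
  structure(list(decisions = decisions, data = data, task = data$task,
                 global_mean = mean(data$y),
                 dropped_multiplicity = as.integer(dropped_multiplicity),
                 n_extracted = n_extracted),
            class = "decision_ensemble")
}

#' Evaluate a rule on a dataset
#'
#' Computes the support (samples satisfying the rule), the prediction (mean
#' response over the support), and the error of that prediction on the
#' support.
#'
#' @param rule a decision, or a named list of conditions.
#' @param data an [rn_data()].
#' @return `list(support, prediction, error)`; for an empty support the
#'   prediction and error are `NA` (such decisions are dropped upstream).
#' @export
evaluate_decision <- function(rule, data) {
  conds <- if (!is.null(rule$conditions)) rule$conditions else rule
  unknown <- setdiff(names(conds), names(data$x))
  if (length(unknown) > 0L) {
    stop("rule uses feature(s) absent from the data: ",
         paste(unknown, collapse = ", "))
  }
  m <- rule_mask(conds, data)
  support <- which(m)
  if (length(support) == 0L) {
    return(list(support = integer(0), prediction = NA_real_,
                error = NA_real_))
  }
  ys <- data$y[support]
  pred <- mean(ys)
  list(support = support, prediction = pred,
       error = alpha_error(ys, pred, data$task))
}

#' Extract the decision ensemble of a tree-ensemble model
#'
#' One decision per root-to-leaf path. Along each path the split conditions
#' are intersected feature-wise into a single condition per feature;
#' conditions that admit a feature's full domain are dropped. Predictions and
#' errors are recomputed from the data support (not taken from leaf values);
#' decisions with empty support are dropped and counted.
#'
#' @param model a [tree_ensemble()] (or an object convertible via
#'   [as_tree_ensemble()]).
#' @param data an [rn_data()].
#' @return A `decision_ensemble` object.
#' @export
extract_decisions <- function(model, data) {
  model <- as_tree_ensemble(model)
  validate_model_against_data(model, data)
  nodes <- model$nodes
  all_rules <- list()
  for (t in unique(nodes$tree)) {
    nt <- nodes[nodes$tree == t, ]
    idx <- setNames(seq_len(nrow(nt)), nt$node)
    kids <- c(nt$left[nt$kind == "split"], nt$right[nt$kind == "split"])
    root <- setdiff(nt$node, kids)
    stack <- list(list(node = root, conds = list()))
    while (length(stack) > 0L) {
      cur <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      i <- idx[[as.character(cur$node)]]
      if (nt$kind[i] == "leaf") {
        all_rules[[length(all_rules) + 1L]] <- cur$conds
        next
      }
      feat <- nt$feature[i]
      is_cat <- !is.na(nt$category_set[i]) && nzchar(nt$category_set[i])
      old <- cur$conds[[feat]]
      if (is_cat) {
        domain <- levels(data$x[[feat]])
        split_set <- strsplit(nt$category_set[i], "|", fixed = TRUE)[[1L]]
        base <- if (is.null(old)) domain else old$levels
        left_set <- intersect(base, split_set)
        right_set <- setdiff(base, split_set)
        lc <- cur$conds
        lc[[feat]] <- if (setequal(left_set, domain)) NULL else
          cond_set(left_set)
        rc <- cur$conds
        rc[[feat]] <- if (setequal(right_set, domain)) NULL else
          cond_set(right_set)
        if (length(left_set) > 0L) {
          stack[[length(stack) + 1L]] <- list(node = nt$left[i], conds = lc)
        }
        if (length(right_set) > 0L) {
          stack[[length(stack) + 1L]] <- list(node = nt$right[i], conds = rc)
        }
      } else {
        thr <- nt$threshold[i]
        lo <- if (is.null(old)) -Inf else old$lower
        hi <- if (is.null(old)) Inf else old$upper
        l_lo <- lo; l_hi <- min(hi, thr)          # x <= thr
        r_lo <- max(lo, thr); r_hi <- hi          # x > thr
        if (l_lo < l_hi) {
          lc <- cur$conds
          lc[[feat]] <- if (is.infinite(l_lo) && is.infinite(l_hi)) NULL else
            cond_interval(l_lo, l_hi)
          stack[[length(stack) + 1L]] <- list(node = nt$left[i], conds = lc)
        }
        if (r_lo < r_hi) {
          rc <- cur$conds
          rc[[feat]] <- if (is.infinite(r_lo) && is.infinite(r_hi)) NULL else
            cond_interval(r_lo, r_hi)
          stack[[length(stack) + 1L]] <- list(node = nt$right[i], conds = rc)
        }
      }
    }
  }
  n_paths <- length(all_rules)
  keys <- vapply(all_rules, rule_key, character(1L))
  uk <- unique(keys)
  first <- match(uk, keys)
  evals <- lapply(first, function(i) evaluate_decision(all_rules[[i]], data))
  names(evals) <- uk
  decisions <- vector("list", n_paths)
  keep <- logical(n_paths)
  for (i in seq_len(n_paths)) {
    ev <- evals[[keys[i]]]
    if (length(ev$support) == 0L) next
    keep[i] <- TRUE
    decisions[[i]] <- new_decision(all_rules[[i]], ev$prediction,
                                   length(ev$support), ev$error)
  }
  n_empty <- sum(!keep)
  if (n_empty > 0L) {
    message(n_empty, " decision(s) with empty support dropped")
  }
  new_decision_ensemble(decisions[keep], data,
                        dropped_multiplicity = n_empty,
                        n_extracted = n_paths)
}

#' Group decisions with identical rules
#'
#' Decisions whose rules are identical after canonical ordering (features
#' sorted, intervals half-open, level sets sorted) are collapsed into one
#' decision whose multiplicity is the sum of the collapsed multiplicities.
#' The total multiplicity is conserved.
#'
#' @param ensemble a `decision_ensemble`.
#' @return A `decision_ensemble` with unique rules.
#' @export
group_duplicate_rules <- function(ensemble) {
  stopifnot(inherits(ensemble, "decision_ensemble"))
  decs <- ensemble$decisions
  if (length(decs) == 0L) return(ensemble)
  keys <- vapply(decs, function(d) rule_key(d$conditions), character(1L))
  mult <- vapply(decs, function(d) d$multiplicity, numeric(1L))
  uk <- unique(keys)
  first <- match(uk, keys)
  grouped <- lapply(seq_along(uk), function(g) {
    d <- decs[[first[g]]]
    d$multiplicity <- as.integer(sum(mult[keys == uk[g]]))
    d
  })
  out <- ensemble
  out$decisions <- grouped
  out
}

#' @export
print.decision_ensemble <- function(x, ...) {
  m <- vapply(x$decisions, function(d) d$multiplicity, numeric(1L))
  cat("<decision_ensemble> ", length(x$decisions), " decision(s), total ",
      "multiplicity ", sum(m), ", task: ", x$task, ", n = ", x$data$n,
      "\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.decision_ensemble <- function(x, ...) {
  if (length(x$decisions) == 0L) {
    return(data.frame(rule = character(0), prediction = numeric(0),
                      n_support = integer(0), error = numeric(0),
                      multiplicity = integer(0), importance = numeric(0)))
  }
  data.frame(
    rule = vapply(x$decisions, rule_string, character(1L)),
    prediction = vapply(x$decisions, function(d) d$prediction, numeric(1L)),
    n_support = vapply(x$decisions, function(d) d$n_support, numeric(1L)),
    error = vapply(x$decisions, function(d) d$error, numeric(1L)),
    multiplicity = vapply(x$decisions, function(d) d$multiplicity,
                          numeric(1L)),
    importance = vapply(x$decisions, function(d) d$importance, numeric(1L)),
    stringsAsFactors = FALSE)
}

#' Export a decision ensemble as TSV
#'
#' One row per decision: rule string, prediction, support size, error,
#' multiplicity, importance.
#'
#' @param ensemble a `decision_ensemble` (or `stable_ensemble`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_decisions <- function(ensemble, path) {
  write.table(as.data.frame(ensemble), path, sep = "\t", row.names = FALSE,
              quote = FALSE)
  invisible(path)
}
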