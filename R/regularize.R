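## Decision-wise regularization (discretization, pruning) and ensemble-level
## bootstrap stability selection.

level_labels <- function(K) {
  if (K == 2L) c("Low", "High")
  else if (K == 3L) c("Low", "Medium", "High")
  else paste0("L", seq_len(K))
}

#' Discretize numeric features and rewrite the decision ensemble
#'
#' Numeric features are binned into `K` ordered levels, either at empirical
#' quantiles (`method = "data"`) or at breakpoints obtained by clustering the
#' ensemble's split thresholds with 1-d k-means (`method = "rf-thresholds"`,
#' centers weighted by how often each threshold bounds a rule, counting
#' multiplicity). Every numeric condition is rewritten to the set of levels
#' in which a strict majority of that level's observations satisfy the
#' original condition. Conditions admitting all levels are dropped from the
#' rule; decisions whose rewritten condition admits no level are dropped.
#' Duplicates are regrouped and predictions/errors recomputed afterwards.
#'
#' @param data an [rn_data()].
#' @param ensemble the `decision_ensemble` to rewrite.
#' @param K number of levels (>= 2).
#' @param method `"data"` or `"rf-thresholds"`.
#' @return `list(data, map, ensemble)`: the leveled dataset, the
#'   `discretization_map`, and the rewritten ensemble (bound to the new
#'   data).
#' @export
discretize <- function(data, ensemble, K = 2L,
                       method = c("data", "rf-thresholds")) {
  method <- match.arg(method)
  stopifnot(inherits(data, "rn_data"), K >= 2L)
  num_feats <- names(data$feature_kinds)[data$feature_kinds == "numeric"]
  map <- list()
  new_x <- data$x
  for (f in num_feats) {
    col <- data$x[[f]]
    if (length(unique(col)) < K) {
      warning("feature '", f, "': fewer than K = ", K,
              " distinct values; kept unsplit")
      next
    }
    bp <- if (method == "data") {
      unique(as.numeric(quantile(col, probs = seq_len(K - 1L) / K)))
    } else {
      thr <- unlist(lapply(ensemble$decisions, function(d) {
        cond <- d$conditions[[f]]
        if (is.null(cond) || cond$kind != "interval") return(NULL)
        b <- c(cond$lower, cond$upper)
        rep(b[is.finite(b)], d$multiplicity)
      }))
      if (length(unique(thr)) == 0L) {
        unique(as.numeric(quantile(col, probs = seq_len(K - 1L) / K)))
      } else if (length(unique(thr)) <= K - 1L) {
        sort(unique(thr))
      } else {
        sort(as.numeric(kmeans(thr, centers = K - 1L, nstart = 5L)$centers))
      }
    }
    if (length(bp) == 0L) {
      warning("feature '", f, "': no usable breakpoints; kept unsplit")
      next
    }
    labs <- level_labels(length(bp) + 1L)
    map[[f]] <- list(breakpoints = bp, labels = labs, K = length(bp) + 1L,
                     method = method)
    new_x[[f]] <- cut(col, breaks = c(-Inf, bp, Inf), labels = labs,
                      ordered_result = TRUE)
  }
  class(map) <- "discretization_map"
  new_data <- rn_data(new_x, data$y, task = data$task)

  decs <- ensemble$decisions
  dropped <- 0L
  out <- vector("list", length(decs))
  keep <- logical(length(decs))
  for (i in seq_along(decs)) {
    d <- decs[[i]]
    conds <- d$conditions
    ok <- TRUE
    for (f in names(conds)) {
      if (is.null(map[[f]])) next
      cond <- conds[[f]]
      m <- cond_mask(cond, data$x[[f]])
      lev <- new_x[[f]]
      admitted <- character(0)
      for (L in map[[f]]$labels) {
        in_level <- lev == L
        if (sum(m & in_level) > 0.5 * sum(in_level)) {
          admitted <- c(admitted, L)
        }
      }
      if (length(admitted) == 0L) { ok <- FALSE; break }
      if (length(admitted) == map[[f]]$K) {
        conds[[f]] <- NULL
      } else {
        conds[[f]] <- cond_set(admitted)
      }
    }
    if (!ok || length(conds) == 0L) {
      dropped <- dropped + d$multiplicity
      next
    }
    keep[i] <- TRUE
    d$conditions <- conds
    out[[i]] <- d
  }
  new_ens <- new_decision_ensemble(out[keep], new_data,
                                   dropped_multiplicity =
                                     ensemble$dropped_multiplicity + dropped,
                                   n_extracted = ensemble$n_extracted)
  new_ens <- group_duplicate_rules(new_ens)
  new_ens$decisions <- lapply(new_ens$decisions, function(d) {
    ev <- evaluate_decision(d, new_data)
    d$prediction <- ev$prediction
    d$n_support <- length(ev$support)
    d$error <- ev$error
    d
  })
  ## rewritten intersections can be empty even when every condition is not
  empty <- vapply(new_ens$decisions, function(d) d$n_support == 0L,
                  logical(1L))
  if (any(empty)) {
    new_ens$dropped_multiplicity <- new_ens$dropped_multiplicity +
      sum(vapply(new_ens$decisions[empty], function(d) d$multiplicity,
                 numeric(1L)))
    new_ens$decisions <- new_ens$decisions[!empty]
  }
  list(data = new_data, map = map, ensemble = new_ens)
}

#' @export
print.discretization_map <- function(x, ...) {
  cat("<discretization_map> ", length(x), " feature(s)\n", sep = "")
  for (f in names(x)) {
    cat("  ", f, ": ", paste(x[[f]]$labels, collapse = " | "),
        " @ ", paste(signif(x[[f]]$breakpoints, 4), collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

#' Prune uninformative conditions from decisions
#'
#' Iteratively removes, from each decision, the condition whose removal
#' increases the decision's error the least, as long as the relative increase
#' `(alpha(S_D, yhat_rm) - alpha(S_D, yhat_D)) / max(alpha(S_D, yhat_D), 1e-6)`
#' stays at or below `tolerance`. Support, prediction, and error are
#' recomputed after each removal. Decisions pruned down to an empty rule are
#' dropped; duplicates are regrouped afterwards.
#'
#' @param ensemble a `decision_ensemble`.
#' @param tolerance maximum relative error increase (default 0.05).
#' @return A pruned `decision_ensemble`.
#' @export
prune_decisions <- function(ensemble, tolerance = 0.05) {
  stopifnot(inherits(ensemble, "decision_ensemble"), tolerance >= 0)
  data <- ensemble$data
  y <- data$y
  eps <- 1e-6
  dropped <- 0L
  out <- list()
  for (d in ensemble$decisions) {
    conds <- d$conditions
    masks <- lapply(names(conds), function(f) {
      cond_mask(conds[[f]], data$x[[f]])
    })
    if (!any(Reduce(`&`, masks, rep(TRUE, data$n)))) {
      dropped <- dropped + d$multiplicity
      next
    }
    repeat {
      if (length(conds) == 0L) break
      full <- Reduce(`&`, masks, rep(TRUE, data$n))
      ys <- y[full]
      pred <- mean(ys)
      err <- alpha_error(ys, pred, data$task)
      ratios <- vapply(seq_along(conds), function(j) {
        m_rm <- Reduce(`&`, masks[-j], rep(TRUE, data$n))
        p_rm <- mean(y[m_rm])
        (alpha_error(ys, p_rm, data$task) - err) / max(err, eps)
      }, numeric(1L))
      j <- which.min(ratios)
      if (ratios[j] > tolerance) break
      conds <- conds[-j]
      masks <- masks[-j]
    }
    if (length(conds) == 0L) {
      dropped <- dropped + d$multiplicity
      next
    }
    d$conditions <- conds
    out[[length(out) + 1L]] <- d
  }
  new_ens <- new_decision_ensemble(out, data,
                                   dropped_multiplicity =
                                     ensemble$dropped_multiplicity + dropped,
                                   n_extracted = ensemble$n_extracted)
  new_ens <- group_duplicate_rules(new_ens)
  new_ens$decisions <- lapply(new_ens$decisions, function(d) {
    ev <- evaluate_decision(d, data)
    d$prediction <- ev$prediction
    d$n_support <- length(ev$support)
    d$error <- ev$error
    d
  })
  new_ens
}

#' Stability-selection parameters
#'
#' Defaults follow the method's recommendations: `pi_thr = 0.7`,
#' `alpha_reg = 1`, `B = 10` bootstrap resamples of size `n/2` (sub-sampling
#' with replacement). `alpha_reg` corresponds to the expected number of false
#' discoveries.
#'
#' @param B number of bootstrap resamples (>= 1).
#' @param pi_thr selection threshold in (0.5, 1].
#' @param alpha_reg regularization strength (> 0).
#' @param resample_fraction resample size as a fraction of `n`.
#' @param seed optional integer master seed; bootstrap `b` uses `seed + b`.
#' @return An object of class `stability_params`.
#' @export
stability_params <- function(B = 10L, pi_thr = 0.7, alpha_reg = 1,
                             resample_fraction = 0.5, seed = NULL) {
  if (B < 1L) stop("B must be >= 1")
  if (pi_thr <= 0.5 || pi_thr > 1) stop("pi_thr must be in (0.5, 1]")
  if (alpha_reg <= 0) stop("alpha_reg must be > 0")
  if (resample_fraction <= 0 || resample_fraction > 1) {
    stop("resample_fraction must be in (0, 1]")
  }
  structure(list(B = as.integer(B), pi_thr = pi_thr, alpha_reg = alpha_reg,
                 resample_fraction = resample_fraction, seed = seed),
            class = "stability_params")
}

#' Number of top decisions retained per bootstrap
#'
#' `q = floor(max(1, (2 * pi_thr - 1) * alpha_reg * d))`, where `d` is the
#' average number of decisions across the bootstrap resamples.
#'
#' @param pi_thr,alpha_reg see [stability_params()].
#' @param d average decision count.
#' @return An integer.
#' @export
stability_q <- function(pi_thr, alpha_reg, d) {
  ## round away float fuzz ((2*0.7-1)*100 is 39.999... in binary) before
  ## taking the floor
  as.integer(floor(max(1, round((2 * pi_thr - 1) * alpha_reg * d, 9L))))
}

## prune one decision's conditions against a resample; returns the indices
## of the conditions kept (possibly none)
prune_on_sample <- function(masks, y, idx, task, tolerance, eps = 1e-6) {
  keep <- seq_along(masks)
  yb <- if (is.null(idx)) y else y[idx]
  sub <- function(m) if (is.null(idx)) m else m[idx]
  repeat {
    if (length(keep) == 0L) return(keep)
    full <- Reduce(`&`, lapply(masks[keep], sub),
                   rep(TRUE, length(yb)))
    if (!any(full)) return(integer(0))
    ys <- yb[full]
    pred <- mean(ys)
    err <- alpha_error(ys, pred, task)
    ratios <- vapply(seq_along(keep), function(j) {
      m_rm <- Reduce(`&`, lapply(masks[keep[-j]], sub),
                     rep(TRUE, length(yb)))
      p_rm <- if (any(m_rm)) mean(yb[m_rm]) else mean(yb)
      (alpha_error(ys, p_rm, task) - err) / max(err, eps)
    }, numeric(1L))
    j <- which.min(ratios)
    if (length(j) == 0L || ratios[j] > tolerance) return(keep)
    keep <- keep[-j]
  }
}

#' Bootstrap stability selection of decisions
#'
#' For each of `B` resamples (drawn with replacement, size
#' `ceiling(resample_fraction * n)`), the decision-wise regularization and
#' all decision metrics are recomputed on the resample: numeric features are
#' re-discretized from the resample's quantiles and every rule rewritten by
#' the majority rule (when `discretize_K` is given), each decision is pruned
#' against the resample (unless `bootstrap_prune = FALSE`), duplicates are
#' regrouped with their multiplicities summed, and support, prediction,
#' error, and importance are recomputed (the reference mean is the resample
#' mean; decisions with empty resample support are absent). The `q` most
#' important decisions of each resample are recorded, with ties at the
#' boundary broken by (importance, support size, rule key); decisions —
#' identified across resamples by their canonical rule — appearing in the
#' top `q` of at least `pi_thr * B` resamples form the stable ensemble.
#' Each stable decision's metrics (importance, deltas, influences,
#' prediction, error, multiplicity) are averaged over the resamples in which
#' it was present, and feature/interaction metrics are recomputed from those
#' averages.
#'
#' @param ensemble a `decision_ensemble`. With `discretize_K` set this is
#'   the raw (undiscretized) ensemble; otherwise it should already be
#'   decision-wise regularized.
#' @param params a [stability_params()] object.
#' @param bootstrap_prune prune each decision within each resample (the
#'   regularization-inside-the-bootstrap that makes selection probabilities
#'   informative)? Default TRUE.
#' @param tolerance pruning tolerance used within resamples.
#' @param discretize_K if non-NULL, discretize numeric features into this
#'   many levels within each resample (method `"data"` recomputes quantile
#'   breakpoints per resample; `"rf-thresholds"` breakpoints depend only on
#'   the model and are shared). The returned ensemble is bound to the
#'   full-data discretization.
#' @param discretize_method `"data"` or `"rf-thresholds"`.
#' @return A `stable_ensemble`: a `decision_ensemble` whose decisions carry
#'   bootstrap-averaged metrics, plus `selection_probability`, `q`, `d`,
#'   the per-bootstrap top-q sets, all scored candidates (needed for TP/FP
#'   curves), and — when `discretize_K` is used — the full-data
#'   discretization `map`.
#' @export
stability_select <- function(ensemble, params = stability_params(),
                             bootstrap_prune = TRUE, tolerance = 0.05,
                             discretize_K = NULL,
                             discretize_method = c("data", "rf-thresholds")) {
  stopifnot(inherits(ensemble, "decision_ensemble"),
            inherits(params, "stability_params"))
  discretize_method <- match.arg(discretize_method)
  rediscretize <- !is.null(discretize_K)
  data <- ensemble$data
  n <- data$n
  y <- data$y
  task <- ensemble$task
  B <- params$B
  size <- as.integer(ceiling(params$resample_fraction * n))
  raw_decs <- ensemble$decisions
  mult0 <- vapply(raw_decs, function(d) d$multiplicity, numeric(1L))

  ## final binding of the stable ensemble: the full-data discretization
  if (rediscretize) {
    gdisc <- discretize(data, ensemble, K = discretize_K,
                        method = discretize_method)
    out_data <- gdisc$data
    out_map <- gdisc$map
    disc_feats <- names(gdisc$map)
  } else {
    out_data <- data
    out_map <- structure(list(), class = "discretization_map")
    disc_feats <- character(0)
  }

  ## unique conditions across all raw decisions (rewrite/mask cache keys)
  cond_sig <- function(f, cond) {
    if (cond$kind == "interval") {
      sprintf("%s\r(%.17g,%.17g]%s", f, cond$lower, cond$upper,
              if (isTRUE(cond$negate)) "!" else "")
    } else {
      sprintf("%s\r{%s}%s", f, paste(sort(cond$levels), collapse = "|"),
              if (isTRUE(cond$negate)) "!" else "")
    }
  }
  dec_sigs <- lapply(raw_decs, function(d) {
    vapply(names(d$conditions), function(f) cond_sig(f, d$conditions[[f]]),
           character(1L))
  })
  uniq_sigs <- unique(unlist(dec_sigs))
  nu <- length(uniq_sigs)
  uniq_feat <- character(nu)
  uniq_cond <- vector("list", nu)
  dec_cidx <- vector("list", length(raw_decs))
  for (i in seq_along(raw_decs)) {
    ci <- match(dec_sigs[[i]], uniq_sigs)
    dec_cidx[[i]] <- ci
    for (k in seq_along(ci)) {
      if (uniq_feat[ci[k]] == "") {
        uniq_feat[ci[k]] <- names(raw_decs[[i]]$conditions)[k]
        uniq_cond[[ci[k]]] <- raw_decs[[i]]$conditions[[k]]
      }
    }
  }

  idx_list <- lapply(seq_len(B), function(b) {
    if (!is.null(params$seed)) set.seed(as.integer(params$seed) + b)
    sample.int(n, size, replace = TRUE)
  })

  registry <- new.env(hash = TRUE, parent = emptyenv())
  boot <- vector("list", B)
  for (b in seq_len(B)) {
    idx <- idx_list[[b]]
    yb <- y[idx]
    xb <- data$x[idx, , drop = FALSE]

    ## resample discretization of numeric features
    lev_b <- list()
    if (rediscretize) {
      for (f in disc_feats) {
        bp <- if (discretize_method == "data") {
          unique(as.numeric(quantile(xb[[f]],
                                     probs = seq_len(discretize_K - 1L) /
                                       discretize_K)))
        } else {
          out_map[[f]]$breakpoints
        }
        lev_b[[f]] <- cut(xb[[f]], breaks = c(-Inf, bp, Inf),
                          labels = level_labels(length(bp) + 1L),
                          ordered_result = TRUE)
      }
    }

    ## rewrite each unique condition once on the resample:
    ## state 0 = keep (possibly as a level set), 1 = admits every level
    ## (condition dropped from rules), 2 = admits no level (rule dead)
    rw_state <- integer(nu)
    rw_cond <- uniq_cond
    rw_sig <- uniq_sigs
    for (u in seq_len(nu)) {
      f <- uniq_feat[u]
      cond <- uniq_cond[[u]]
      if (!is.null(lev_b[[f]]) && cond$kind == "interval") {
        m <- cond_mask(cond, xb[[f]])
        lv <- lev_b[[f]]
        labs <- levels(lv)
        cnt_all <- tabulate(lv, nbins = length(labs))
        cnt_in <- tabulate(lv[m], nbins = length(labs))
        admitted <- labs[cnt_in > 0.5 * cnt_all]
        if (length(admitted) == 0L) {
          rw_state[u] <- 2L
        } else if (length(admitted) == length(labs)) {
          rw_state[u] <- 1L
        } else {
          rw_cond[[u]] <- cond_set(admitted)
          rw_sig[u] <- cond_sig(f, rw_cond[[u]])
        }
      }
    }

    ## lazily computed resample masks and directions per unique condition
    bmask <- vector("list", nu)
    bdir <- rep(NA_real_, nu)
    get_mask <- function(u) {
      m <- bmask[[u]]
      if (!is.null(m)) return(m)
      f <- uniq_feat[u]
      cond <- rw_cond[[u]]
      col <- if (!is.null(lev_b[[f]]) && cond$kind == "set") lev_b[[f]] else
        xb[[f]]
      m <- cond_mask(cond, col)
      bmask[[u]] <<- m
      m
    }
    get_dir <- function(u) {
      if (!is.na(bdir[u])) return(bdir[u])
      f <- uniq_feat[u]
      cond <- rw_cond[[u]]
      col <- if (!is.null(lev_b[[f]]) && cond$kind == "set") lev_b[[f]] else
        xb[[f]]
      d <- condition_direction(cond, col)
      bdir[u] <<- d
      d
    }

    ## rewrite decisions, group identical rules (hashed accumulation)
    genv <- new.env(hash = TRUE, parent = emptyenv())
    for (i in seq_along(raw_decs)) {
      ci <- dec_cidx[[i]]
      st <- rw_state[ci]
      if (any(st == 2L)) next
      keep <- ci[st == 0L]
      if (length(keep) == 0L) next
      keep <- keep[order(rw_sig[keep])]
      key <- paste(rw_sig[keep], collapse = "&")
      g <- get0(key, envir = genv)
      if (is.null(g)) {
        assign(key, list(cidx = keep, mult = mult0[i]), envir = genv)
      } else {
        g$mult <- g$mult + mult0[i]
        assign(key, g, envir = genv)
      }
    }

    ## prune each grouped rule on the resample, regroup
    fenv <- new.env(hash = TRUE, parent = emptyenv())
    for (key in ls(genv)) {
      g <- get(key, envir = genv)
      masks <- lapply(g$cidx, get_mask)
      kept <- if (bootstrap_prune) {
        prune_on_sample(masks, yb, NULL, task, tolerance)
      } else {
        if (any(Reduce(`&`, masks, rep(TRUE, size)))) seq_along(masks) else
          integer(0)
      }
      if (length(kept) == 0L) next
      cidx2 <- g$cidx[kept]
      key2 <- paste(rw_sig[cidx2], collapse = "&")
      fg <- get0(key2, envir = fenv)
      if (is.null(fg)) {
        assign(key2, list(cidx = cidx2, mult = g$mult), envir = fenv)
      } else {
        fg$mult <- fg$mult + g$mult
        assign(key2, fg, envir = fenv)
      }
    }

    ## score the regularized resample ensemble
    bkeys <- ls(fenv)
    bmet <- vector("list", length(bkeys))
    bmult <- numeric(length(bkeys))
    for (g in seq_along(bkeys)) {
      fg <- get(bkeys[g], envir = fenv)
      feats <- uniq_feat[fg$cidx]
      masks <- lapply(fg$cidx, get_mask)
      names(masks) <- feats
      dirs <- lapply(fg$cidx, get_dir)
      names(dirs) <- feats
      dec <- list(conditions = setNames(rw_cond[fg$cidx], feats),
                  multiplicity = fg$mult, direction = dirs)
      bmet[[g]] <- decision_metrics_one(dec, masks, yb, task, NULL)
      bmult[g] <- fg$mult
      if (is.null(get0(bkeys[g], envir = registry))) {
        assign(bkeys[g], dec$conditions, envir = registry)
      }
    }
    ok <- !vapply(bmet, is.null, logical(1L))
    boot[[b]] <- list(keys = bkeys[ok], metrics = bmet[ok],
                      multiplicity = bmult[ok])
  }

  d_bar <- mean(vapply(boot, function(bb) length(bb$keys), numeric(1L)))
  q <- stability_q(params$pi_thr, params$alpha_reg, d_bar)
  topq <- vector("list", B)
  for (b in seq_len(B)) {
    bb <- boot[[b]]
    if (length(bb$keys) == 0L) { topq[[b]] <- character(0); next }
    impv <- vapply(bb$metrics, `[[`, numeric(1L), "importance")
    supv <- vapply(bb$metrics, `[[`, numeric(1L), "n_support")
    ord <- order(-impv, -supv, bb$keys)
    topq[[b]] <- bb$keys[ord[seq_len(min(q, length(ord)))]]
  }
  all_keys <- unique(unlist(lapply(boot, `[[`, "keys")))
  sel_count <- setNames(numeric(length(all_keys)), all_keys)
  for (b in seq_len(B)) {
    sel_count[topq[[b]]] <- sel_count[topq[[b]]] + 1
  }
  sel_prob <- sel_count / B
  stable_keys <- all_keys[sel_count[all_keys] >= params$pi_thr * B]
  cand_keys <- all_keys[sel_count[all_keys] > 0]

  ## average metrics over the resamples where each candidate was present
  avg_met <- setNames(vector("list", length(cand_keys)), cand_keys)
  avg_mult <- setNames(numeric(length(cand_keys)), cand_keys)
  for (key in cand_keys) {
    mets <- list()
    mults <- numeric(0)
    for (b in seq_len(B)) {
      pos <- match(key, boot[[b]]$keys)
      if (is.na(pos)) next
      mets[[length(mets) + 1L]] <- boot[[b]]$metrics[[pos]]
      mults <- c(mults, boot[[b]]$multiplicity[pos])
    }
    avg_met[[key]] <- average_decision_metrics(mets)
    avg_mult[key] <- mean(mults)
  }

  mk_decision <- function(key) {
    m <- avg_met[[key]]
    d <- new_decision(get(key, envir = registry), m$prediction,
                      m$n_support, m$error,
                      multiplicity = avg_mult[[key]])
    d$importance <- m$importance
    d
  }
  stable_decs <- lapply(stable_keys, mk_decision)
  out <- new_decision_ensemble(stable_decs, out_data,
                               dropped_multiplicity =
                                 ensemble$dropped_multiplicity,
                               n_extracted = ensemble$n_extracted)
  out$selection_probability <- unname(sel_prob[stable_keys])
  out$decision_metrics <- unname(avg_met[stable_keys])
  out$candidates <- list(decisions = lapply(cand_keys, mk_decision),
                         metrics = unname(avg_met[cand_keys]),
                         selection_probability = unname(sel_prob[cand_keys]))
  out$q <- q
  out$d <- d_bar
  out$B <- B
  out$params <- params
  out$map <- out_map
  out$bootstrap_topq <- topq
  class(out) <- c("stable_ensemble", class(out))
  out
}

## elementwise mean of per-bootstrap decision metrics (same decision)
average_decision_metrics <- function(mets) {
  stopifnot(length(mets) > 0L)
  base <- mets[[1L]]
  nm <- length(mets)
  base$importance <- mean(vapply(mets, `[[`, numeric(1L), "importance"))
  base$prediction <- mean(vapply(mets, `[[`, numeric(1L), "prediction"))
  base$error <- mean(vapply(mets, `[[`, numeric(1L), "error"))
  base$n_support <- mean(vapply(mets, `[[`, numeric(1L), "n_support"))
  k <- length(base$delta)
  base$delta <- rowMeans(matrix(unlist(lapply(mets, `[[`, "delta")),
                                nrow = k))
  names(base$delta) <- names(mets[[1L]]$delta)
  base$gamma <- rowMeans(matrix(unlist(lapply(mets, `[[`, "gamma")),
                                nrow = k))
  names(base$gamma) <- names(mets[[1L]]$gamma)
  if (!is.null(base$pairs)) {
    dsum <- Reduce(`+`, lapply(mets, function(m) m$pairs$delta))
    gsum <- Reduce(`+`, lapply(mets, function(m) m$pairs$gamma))
    base$pairs$delta <- dsum / nm
    base$pairs$gamma <- gsum / nm
  }
  base
}

#' @export
print.stable_ensemble <- function(x, ...) {
  cat("<stable_ensemble> ", length(x$decisions), " stable decision(s) (q = ",
      x$q, ", mean ensemble size d = ", round(x$d, 1), ", B = ", x$B,
      ")\n", sep = "")
  invisible(x)
}
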