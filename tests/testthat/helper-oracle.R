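# Straight-line re-implementation of every ensemble metric, independent of
# the package's code paths (no shared helpers, no masks/caching). Used to
# pin the formulas on small random ensembles.

oracle_alpha <- function(y_s, yhat, task) {
  if (task == "regression") {
    sum((y_s - yhat)^2) / length(y_s)
  } else {
    sum(1 - yhat^y_s * (1 - yhat)^(1 - y_s)) / length(y_s)
  }
}

# sample indices satisfying one condition
oracle_cond_idx <- function(cond, col) {
  sat <- if (cond$kind == "interval") {
    which(col > cond$lower & col <= cond$upper)
  } else {
    which(as.character(col) %in% cond$levels)
  }
  if (isTRUE(cond$negate)) setdiff(seq_along(col), sat) else sat
}

oracle_support <- function(conds, x) {
  idx <- seq_len(nrow(x))
  for (f in names(conds)) {
    idx <- intersect(idx, oracle_cond_idx(conds[[f]], x[[f]]))
  }
  idx
}

oracle_direction <- function(cond, col) {
  if (cond$kind == "set") {
    dom <- levels(col)
    adm <- if (isTRUE(cond$negate)) setdiff(dom, cond$levels) else cond$levels
    if (length(adm) == 0) return(1)
    if (mean(match(adm, dom)) >= (length(dom) + 1) / 2) 1 else -1
  } else {
    idx <- oracle_cond_idx(cond, col)
    if (length(idx) == 0) return(1)
    r <- rank(col)
    if (mean(r[idx]) >= mean(r)) 1 else -1
  }
}

# all metrics of one decision, straight from the formulas
oracle_decision_metrics <- function(decision, data) {
  x <- data$x; y <- data$y; task <- data$task
  conds <- decision$conditions
  S <- oracle_support(conds, x)
  if (length(S) == 0) return(NULL)
  ybar <- mean(y)
  yhat <- mean(y[S])
  a_hat <- oracle_alpha(y[S], yhat, task)
  a_bar <- oracle_alpha(y[S], ybar, task)
  I <- if (a_bar == 0) 0 else
    (1 - a_hat / a_bar) * length(S) * decision$multiplicity
  feats <- names(conds)
  delta <- setNames(numeric(length(feats)), feats)
  gamma <- setNames(numeric(length(feats)), feats)
  dirs <- setNames(numeric(length(feats)), feats)
  for (f in feats) {
    S_rm <- oracle_support(conds[setdiff(feats, f)], x)
    yhat_rm <- mean(y[S_rm])
    delta[f] <- oracle_alpha(y[S], yhat_rm, task) - a_hat
    dirs[f] <- oracle_direction(conds[[f]], x[[f]])
    gamma[f] <- dirs[f] * (yhat - yhat_rm)
  }
  pairs <- NULL
  if (length(feats) >= 2) {
    cmb <- combn(feats, 2)
    pairs <- data.frame(j = cmb[1, ], k = cmb[2, ],
                        delta = NA_real_, gamma = NA_real_,
                        stringsAsFactors = FALSE)
    for (q in seq_len(ncol(cmb))) {
      fj <- cmb[1, q]; fk <- cmb[2, q]
      prod <- delta[fj] * delta[fk]
      pairs$delta[q] <- if (prod < 0) 0 else sqrt(prod)
      S_rm2 <- oracle_support(conds[setdiff(feats, c(fj, fk))], x)
      yhat_rm2 <- mean(y[S_rm2])
      pairs$gamma[q] <- (dirs[fj] + dirs[fk]) / 2 * (yhat - yhat_rm2)
    }
  }
  list(importance = I, prediction = yhat, error = a_hat,
       support = S, delta = delta, gamma = gamma, direction = dirs,
       pairs = pairs)
}

# F_j, Gamma_j, F_jk, Gamma_jk, eta_jk summed per feature name
oracle_aggregate <- function(ensemble) {
  per <- lapply(ensemble$decisions, oracle_decision_metrics,
                data = ensemble$data)
  F_j <- list(); G_num <- list(); G_den <- list(); G_absden <- list()
  F_jk <- list(); Gp_num <- list(); Gp_den <- list(); Gp_absden <- list()
  eta_sum <- list()
  acc <- function(lst, key, v) {
    lst[[key]] <- (if (is.null(lst[[key]])) 0 else lst[[key]]) + v
    lst
  }
  for (i in seq_along(per)) {
    m <- per[[i]]
    if (is.null(m)) next
    for (f in names(m$delta)) {
      F_j <- acc(F_j, f, m$delta[f] * m$importance)
      G_num <- acc(G_num, f, m$gamma[f] * m$importance)
      G_den <- acc(G_den, f, m$importance)
      G_absden <- acc(G_absden, f, abs(m$importance))
    }
    if (!is.null(m$pairs)) {
      for (q in seq_len(nrow(m$pairs))) {
        key <- paste(sort(c(m$pairs$j[q], m$pairs$k[q])), collapse = "\r")
        F_jk <- acc(F_jk, key, m$pairs$delta[q] * m$importance)
        Gp_num <- acc(Gp_num, key, m$pairs$gamma[q] * m$importance)
        Gp_den <- acc(Gp_den, key, m$importance)
        Gp_absden <- acc(Gp_absden, key, abs(m$importance))
        eta_sum <- acc(eta_sum, key,
                       m$direction[m$pairs$j[q]] *
                         m$direction[m$pairs$k[q]] * m$importance)
      }
    }
  }
  # a denominator cancelled to numerical zero gives influence 0 (same
  # degenerate-case rule as the implementation, applied independently)
  ratio0 <- function(num, den, absden) {
    if (absden == 0 || abs(den) <= 1e-9 * absden) 0 else num / den
  }
  list(per_decision = per,
       F_j = F_j,
       Gamma_j = lapply(names(G_num), function(f) {
         ratio0(G_num[[f]], G_den[[f]], G_absden[[f]])
       }) |> setNames(names(G_num)),
       F_jk = F_jk,
       Gamma_jk = lapply(names(Gp_num), function(k) {
         ratio0(Gp_num[[k]], Gp_den[[k]], Gp_absden[[k]])
       }) |> setNames(names(Gp_num)),
       eta = lapply(eta_sum, sign))
}
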