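## Decision network: nodes are (feature, level-set) pseudo-features of the
## stable ensemble, edges are pairwise interaction effects. Node/edge sizes
## carry importance, colors influence; an edge is "solid" (eta = +1) when the
## two features are predominantly used in the same direction, "dashed"
## otherwise.

## entity descriptor table for level-set granularity
entity_info <- function(ensemble) {
  data <- ensemble$data
  seen <- list()
  for (d in ensemble$decisions) {
    for (f in names(d$conditions)) {
      cond <- d$conditions[[f]]
      id <- entity_label(f, cond, data, "levelset")
      if (!is.null(seen[[id]])) next
      if (cond$kind == "set") {
        domain <- levels(data$x[[f]])
        admitted <- if (isTRUE(cond$negate)) setdiff(domain, cond$levels) else
          cond$levels
        admitted <- domain[sort(match(admitted, domain))]
        seen[[id]] <- list(feature = f,
                           levels = paste(admitted, collapse = "|"),
                           ordered = is.ordered(data$x[[f]]))
      } else {
        seen[[id]] <- list(feature = f, levels = NA_character_,
                           ordered = NA)
      }
    }
  }
  if (length(seen) == 0L) {
    return(data.frame(id = character(0), feature = character(0),
                      levels = character(0), ordered = logical(0),
                      stringsAsFactors = FALSE))
  }
  data.frame(id = names(seen),
             feature = vapply(seen, `[[`, character(1L), "feature"),
             levels = vapply(seen, `[[`, character(1L), "levels"),
             ordered = vapply(seen, `[[`, logical(1L), "ordered"),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Build the decision network of a decision ensemble
#'
#' Nodes are the (feature, level-set) pseudo-features occurring in the
#' ensemble's rules, attributed with their importance and influence; edges
#' connect pairs co-active in at least one decision with positive
#' decision-wise interaction importance, attributed with interaction
#' importance, influence, and the direction agreement `eta`. Importances are
#' also reported max-normalized to [0, 1] for display.
#'
#' @param ensemble a `stable_ensemble` (bootstrap-averaged metrics) or a
#'   plain `decision_ensemble` (full-data metrics).
#' @param provenance optional list stored on the network (parameters, seed,
#'   model fingerprint).
#' @return An object of class `decision_network` with data.frames `nodes`
#'   and `edges`.
#' @export
build_network <- function(ensemble, provenance = list()) {
  metrics <- aggregate_metrics(ensemble, granularity = "levelset")
  info <- entity_info(ensemble)
  nodes <- metrics$features
  if (nrow(nodes) > 0L) {
    nodes <- merge(nodes, info, by.x = "entity", by.y = "id", sort = FALSE)
    nodes <- nodes[order(-nodes$importance),
                   c("entity", "feature.x", "levels", "ordered", "importance",
                     "influence", "n_active")]
    names(nodes)[names(nodes) == "feature.x"] <- "feature"
    names(nodes)[names(nodes) == "entity"] <- "id"
    mx <- max(nodes$importance)
    nodes$importance_norm <- if (mx > 0) pmax(0, nodes$importance) / mx else 0
    row.names(nodes) <- NULL
  } else {
    nodes <- data.frame(id = character(0), feature = character(0),
                        levels = character(0), ordered = logical(0),
                        importance = numeric(0), influence = numeric(0),
                        n_active = numeric(0), importance_norm = numeric(0),
                        stringsAsFactors = FALSE)
  }
  edges <- metrics$interactions
  edges <- edges[edges$any_delta_pos, , drop = FALSE]
  if (nrow(edges) > 0L) {
    names(edges)[names(edges) == "entity_a"] <- "from"
    names(edges)[names(edges) == "entity_b"] <- "to"
    edges$direction <- ifelse(edges$eta >= 0, "solid", "dashed")
    mx <- max(edges$importance)
    edges$importance_norm <- if (mx > 0) pmax(0, edges$importance) / mx else 0
    edges$any_delta_pos <- NULL
    row.names(edges) <- NULL
  } else {
    edges <- data.frame(from = character(0), to = character(0),
                        importance = numeric(0), influence = numeric(0),
                        eta = numeric(0), direction = character(0),
                        importance_norm = numeric(0), stringsAsFactors = FALSE)
  }
  structure(list(nodes = nodes, edges = edges, provenance = provenance),
            class = "decision_network")
}

#' @export
print.decision_network <- function(x, ...) {
  cat("<decision_network> ", nrow(x$nodes), " node(s), ", nrow(x$edges),
      " edge(s)\n", sep = "")
  invisible(x)
}

#' Convert a decision network to an igraph graph
#' @param net a `decision_network`.
#' @return An undirected igraph graph with node/edge attributes.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "decision_network"))
  igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                vertices = net$nodes)
}

#' Reduce a network to short-path components
#'
#' Removes the lowest-importance edges until every connected component of the
#' retained graph has diameter at most `max_path`. The retained graph is the
#' subgraph at the smallest edge-importance threshold meeting the constraint
#' (thresholds searched in ascending order over the observed importances, so
#' the result is deterministic). Node metrics are unchanged.
#'
#' @param net a `decision_network`.
#' @param max_path maximum within-component path length (default 3).
#' @return A `decision_network` whose edges are a subset of the input's.
#' @export
reduce_network <- function(net, max_path = 3L) {
  stopifnot(inherits(net, "decision_network"), max_path >= 1L)
  if (nrow(net$edges) == 0L) return(net)
  diam_ok <- function(edges) {
    if (nrow(edges) == 0L) return(TRUE)
    g <- igraph::graph_from_data_frame(edges[c("from", "to")],
                                       directed = FALSE)
    dm <- igraph::distances(g)
    dm[is.infinite(dm)] <- 0
    max(dm) <= max_path
  }
  thresholds <- c(-Inf, sort(unique(net$edges$importance)))
  for (t in thresholds) {
    kept <- net$edges[net$edges$importance >= t, , drop = FALSE]
    if (diam_ok(kept)) {
      out <- net
      out$edges <- kept
      row.names(out$edges) <- NULL
      return(out)
    }
  }
  out <- net
  out$edges <- net$edges[0, , drop = FALSE]
  out
}

#' Export a decision network
#'
#' Writes GraphML (via igraph, with importance/influence/direction
#' attributes) and/or paired node and edge TSVs; both re-import losslessly.
#'
#' @param net a `decision_network`.
#' @param path base path; `.graphml`, `_nodes.tsv`, `_edges.tsv` suffixes are
#'   appended.
#' @param formats subset of `c("graphml", "tsv")`.
#' @return Named character vector of the files written, invisibly.
#' @export
export_network <- function(net, path, formats = c("graphml", "tsv")) {
  stopifnot(inherits(net, "decision_network"))
  formats <- match.arg(formats, several.ok = TRUE)
  written <- character(0)
  if ("graphml" %in% formats) {
    f <- paste0(path, ".graphml")
    g <- as_igraph(net)
    igraph::write_graph(g, f, format = "graphml")
    written["graphml"] <- f
  }
  if ("tsv" %in% formats) {
    fn <- paste0(path, "_nodes.tsv")
    fe <- paste0(path, "_edges.tsv")
    write.table(net$nodes, fn, sep = "\t", row.names = FALSE, quote = FALSE)
    write.table(net$edges, fe, sep = "\t", row.names = FALSE, quote = FALSE)
    written["nodes_tsv"] <- fn
    written["edges_tsv"] <- fe
  }
  invisible(written)
}

#' Read a decision network from exported node/edge TSVs
#'
#' @param nodes_path,edges_path paths written by [export_network()].
#' @return A `decision_network`.
#' @export
read_network_tsv <- function(nodes_path, edges_path) {
  nodes <- read.delim(nodes_path, stringsAsFactors = FALSE)
  edges <- read.delim(edges_path, stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges, provenance = list()),
            class = "decision_network")
}

#' Importance/influence summary table
#'
#' One row per (feature, level): the feature's total importance (summed over
#' its level-sets) and the level's influence (importance-weighted mean
#' influence over the decisions whose admitted set contains the level).
#' Levels occurring in no decision are kept with `missing = TRUE` and `NA`
#' influence ("white blocks"). Undiscretized numeric features get a single
#' row with `level = NA`.
#'
#' @param ensemble a `stable_ensemble` or `decision_ensemble`.
#' @return A data.frame with columns feature, level, importance, influence,
#'   missing.
#' @export
importance_influence_table <- function(ensemble) {
  data <- ensemble$data
  met <- if (inherits(ensemble, "stable_ensemble")) {
    ensemble$decision_metrics
  } else {
    compute_decision_metrics(ensemble)
  }
  f_imp <- list()
  lv_num <- list(); lv_den <- list(); lv_absden <- list()
  active_feats <- character(0)
  for (i in seq_along(ensemble$decisions)) {
    m <- met[[i]]
    if (is.null(m)) next
    d <- ensemble$decisions[[i]]
    for (f in names(d$conditions)) {
      cond <- d$conditions[[f]]
      active_feats <- union(active_feats, f)
      f_imp[[f]] <- (if (is.null(f_imp[[f]])) 0 else f_imp[[f]]) +
        m$delta[[f]] * m$importance
      if (cond$kind == "set") {
        domain <- levels(data$x[[f]])
        admitted <- if (isTRUE(cond$negate)) setdiff(domain, cond$levels)
          else cond$levels
        for (L in admitted) {
          key <- paste(f, L, sep = "\r")
          lv_num[[key]] <- (if (is.null(lv_num[[key]])) 0 else
            lv_num[[key]]) + m$gamma[[f]] * m$importance
          lv_den[[key]] <- (if (is.null(lv_den[[key]])) 0 else
            lv_den[[key]]) + m$importance
          lv_absden[[key]] <- (if (is.null(lv_absden[[key]])) 0 else
            lv_absden[[key]]) + abs(m$importance)
        }
      } else {
        key <- paste(f, NA, sep = "\r")
        lv_num[[key]] <- (if (is.null(lv_num[[key]])) 0 else
          lv_num[[key]]) + m$gamma[[f]] * m$importance
        lv_den[[key]] <- (if (is.null(lv_den[[key]])) 0 else
          lv_den[[key]]) + m$importance
        lv_absden[[key]] <- (if (is.null(lv_absden[[key]])) 0 else
          lv_absden[[key]]) + abs(m$importance)
      }
    }
  }
  rows <- list()
  for (f in sort(active_feats)) {
    col <- data$x[[f]]
    levs <- if (is.factor(col)) levels(col) else NA_character_
    for (L in levs) {
      key <- paste(f, L, sep = "\r")
      miss <- is.null(lv_den[[key]])
      infl <- if (miss) NA_real_ else
        safe_ratio(lv_num[[key]], lv_den[[key]], lv_absden[[key]])
      rows[[length(rows) + 1L]] <- data.frame(
        feature = f, level = L, importance = f_imp[[f]], influence = infl,
        missing = miss, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(feature = character(0), level = character(0),
                      importance = numeric(0), influence = numeric(0),
                      missing = logical(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  row.names(out) <- NULL
  out[order(-out$importance, out$feature, out$level), , drop = FALSE]
}
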