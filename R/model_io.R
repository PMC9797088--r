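## Readers and validators for tree-ensemble node tables and feature tables.
##
## Canonical node table (one row per node):
##   tree, node, kind ("split"/"leaf"), feature, threshold, category_set,
##   left, right, value
## Numeric splits send `value <= threshold` to the left child; categorical
## splits send samples whose category is in `category_set` ("|"-joined labels)
## to the left child. Node ids are local to a tree; each tree has one root
## (the node that is no other node's child).

#' Construct a tree-ensemble specification from a node table
#'
#' @param nodes data.frame with columns `tree`, `node`, `kind`, `feature`,
#'   `threshold`, `category_set`, `left`, `right`, `value`.
#' @param task `"classification"` or `"regression"`.
#' @param class_labels optional character vector of class labels.
#' @return An object of class `tree_ensemble`.
#' @export
tree_ensemble <- function(nodes, task = c("classification", "regression"),
                          class_labels = NULL) {
  task <- match.arg(task)
  required <- c("tree", "node", "kind", "feature", "threshold",
                "category_set", "left", "right", "value")
  missing_cols <- setdiff(required, names(nodes))
  if (length(missing_cols) > 0L) {
    stop("node table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  nodes <- nodes[required]
  nodes$tree <- as.integer(nodes$tree)
  nodes$node <- as.integer(nodes$node)
  nodes$kind <- as.character(nodes$kind)
  nodes$feature <- as.character(nodes$feature)
  nodes$threshold <- as.numeric(nodes$threshold)
  nodes$category_set <- as.character(nodes$category_set)
  nodes$left <- as.integer(nodes$left)
  nodes$right <- as.integer(nodes$right)
  nodes$value <- as.numeric(nodes$value)
  obj <- structure(list(nodes = nodes, task = task,
                        class_labels = class_labels),
                   class = "tree_ensemble")
  validate_tree_ensemble(obj)
  obj
}

validate_tree_ensemble <- function(model) {
  nodes <- model$nodes
  if (nrow(nodes) == 0L) stop("tree ensemble has no nodes")
  if (!all(nodes$kind %in% c("split", "leaf"))) {
    bad <- which(!nodes$kind %in% c("split", "leaf"))[1L]
    stop("tree ", nodes$tree[bad], " node ", nodes$node[bad],
         ": unknown node kind '", nodes$kind[bad], "'")
  }
  for (t in unique(nodes$tree)) {
    nt <- nodes[nodes$tree == t, ]
    if (anyDuplicated(nt$node)) {
      stop("tree ", t, ": duplicated node ids")
    }
    splits <- nt[nt$kind == "split", ]
    kids <- c(splits$left, splits$right)
    if (anyNA(kids)) stop("tree ", t, ": split node with missing child id")
    if (!all(kids %in% nt$node)) {
      stop("tree ", t, ": child id(s) ",
           paste(setdiff(kids, nt$node), collapse = ", "), " not present")
    }
    if (anyDuplicated(kids)) {
      stop("tree ", t, ": node referenced as child more than once")
    }
    roots <- setdiff(nt$node, kids)
    if (length(roots) != 1L) {
      stop("tree ", t, ": expected exactly one root, found ", length(roots))
    }
    has_cat <- !is.na(splits$category_set) & nzchar(splits$category_set)
    has_thr <- is.finite(splits$threshold)
    if (any(!has_cat & !has_thr)) {
      bad <- splits$node[which(!has_cat & !has_thr)[1L]]
      stop("tree ", t, " node ", bad,
           ": split carries neither a finite threshold nor a category set")
    }
    if (anyNA(splits$feature) || any(!nzchar(splits$feature))) {
      stop("tree ", t, ": split node without a feature name")
    }
  }
  invisible(model)
}

#' Read a serialized tree-ensemble model
#'
#' Supports XGBoost JSON dumps (`xgb.dump(..., dump_format = "json")`) and the
#' canonical per-node CSV dialect written by [write_node_csv()].
#'
#' @param path path to the model dump.
#' @param dialect `"xgboost-json"` or `"node-csv"`.
#' @param task task of the model; XGBoost dumps do not record it.
#' @return A [tree_ensemble()] object.
#' @export
read_tree_dump <- function(path, dialect = c("xgboost-json", "node-csv"),
                           task = c("classification", "regression")) {
  if (!file.exists(path)) stop("file not found: ", path)
  dialect <- tryCatch(match.arg(dialect),
                      error = function(e) stop("unknown dialect: ",
                                               dialect[1L], call. = FALSE))
  task <- match.arg(task)
  nodes <- switch(dialect,
    "xgboost-json" = parse_xgb_json(path),
    "node-csv" = parse_node_csv(path)
  )
  tree_ensemble(nodes, task = task)
}

parse_xgb_json <- function(path) {
  dump <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                   error = function(e) stop("malformed XGBoost JSON in ",
                                            path, ": ", conditionMessage(e),
                                            call. = FALSE))
  if (length(dump) == 0L) stop("XGBoost dump contains no trees")
  rows <- list()
  walk <- function(node, tree_id) {
    if (is.null(node$nodeid)) {
      stop("tree ", tree_id, ": node without 'nodeid' in XGBoost dump")
    }
    if (!is.null(node$leaf)) {
      rows[[length(rows) + 1L]] <<- data.frame(
        tree = tree_id, node = node$nodeid, kind = "leaf", feature = NA,
        threshold = NA_real_, category_set = NA_character_,
        left = NA_integer_, right = NA_integer_,
        value = as.numeric(node$leaf), stringsAsFactors = FALSE)
    } else {
      if (is.null(node$split) || is.null(node$split_condition)) {
        stop("tree ", tree_id, " node ", node$nodeid,
             ": split without 'split'/'split_condition'")
      }
      rows[[length(rows) + 1L]] <<- data.frame(
        tree = tree_id, node = node$nodeid, kind = "split",
        feature = as.character(node$split),
        threshold = as.numeric(node$split_condition),
        category_set = NA_character_,
        left = as.integer(node$yes), right = as.integer(node$no),
        value = NA_real_, stringsAsFactors = FALSE)
      for (child in node$children) walk(child, tree_id)
    }
  }
  for (i in seq_along(dump)) walk(dump[[i]], i - 1L)
  do.call(rbind, rows)
}

parse_node_csv <- function(path) {
  nodes <- tryCatch(read.csv(path, stringsAsFactors = FALSE,
                             colClasses = c(category_set = "character")),
                    error = function(e) stop("malformed node-csv in ", path,
                                             ": ", conditionMessage(e),
                                             call. = FALSE))
  nodes$category_set[!is.na(nodes$category_set) &
                       !nzchar(nodes$category_set)] <- NA_character_
  if (is.character(nodes$feature)) {
    nodes$feature[!nzchar(nodes$feature)] <- NA_character_
  }
  nodes
}

#' Write a tree ensemble to the canonical node-csv format
#'
#' Floats are formatted with `%.17g` so that a write/read round trip is exact.
#'
#' @param model a [tree_ensemble()] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_node_csv <- function(model, path) {
  stopifnot(inherits(model, "tree_ensemble"))
  nodes <- model$nodes
  out <- data.frame(
    tree = nodes$tree, node = nodes$node, kind = nodes$kind,
    feature = ifelse(is.na(nodes$feature), "", nodes$feature),
    threshold = ifelse(is.na(nodes$threshold), "",
                       sprintf("%.17g", nodes$threshold)),
    category_set = ifelse(is.na(nodes$category_set), "", nodes$category_set),
    left = ifelse(is.na(nodes$left), "", nodes$left),
    right = ifelse(is.na(nodes$right), "", nodes$right),
    value = ifelse(is.na(nodes$value), "", sprintf("%.17g", nodes$value)),
    stringsAsFactors = FALSE)
  write.table(out, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Convert a fitted learner object to a tree ensemble
#'
#' Methods exist for `ranger` (fit with
#' `respect.unordered.factors = "partition"` for true categorical splits) and
#' `xgb.Booster` objects.
#'
#' @param object a fitted model object.
#' @param ... passed to methods.
#' @return A [tree_ensemble()] object.
#' @export
as_tree_ensemble <- function(object, ...) UseMethod("as_tree_ensemble")

#' @rdname as_tree_ensemble
#' @export
as_tree_ensemble.tree_ensemble <- function(object, ...) object

#' @rdname as_tree_ensemble
#' @export
as_tree_ensemble.ranger <- function(object, ...) {
  if (!requireNamespace("ranger", quietly = TRUE)) {
    stop("the 'ranger' package is required to convert ranger models")
  }
  task <- if (object$treetype %in% c("Classification",
                                     "Probability estimation")) {
    "classification"
  } else if (object$treetype == "Regression") {
    "regression"
  } else {
    stop("unsupported ranger tree type: ", object$treetype)
  }
  cov_levels <- object$forest$covariate.levels
  rows <- vector("list", object$num.trees)
  for (t in seq_len(object$num.trees)) {
    ti <- ranger::treeInfo(object, t)
    is_term <- ti$terminal
    value <- rep(NA_real_, nrow(ti))
    if (task == "classification") {
      # probability forests carry per-class columns; plain classification a
      # factor prediction. Either way leaf values are recomputed from data
      # downstream, so any numeric encoding suffices here.
      pcols <- grep("^pred", names(ti), value = TRUE)
      if (length(pcols) > 1L) {
        value[is_term] <- ti[[pcols[length(pcols)]]][is_term]
      } else {
        value[is_term] <- as.numeric(as.factor(ti$prediction))[is_term]
      }
    } else {
      value[is_term] <- as.numeric(ti$prediction)[is_term]
    }
    feat <- as.character(ti$splitvarName)
    threshold <- rep(NA_real_, nrow(ti))
    category_set <- rep(NA_character_, nrow(ti))
    for (i in which(!is_term)) {
      lev <- cov_levels[[feat[i]]]
      if (is.null(lev)) {
        threshold[i] <- as.numeric(ti$splitval[i])
      } else {
        # partition split: listed level indices go right; the left child
        # therefore admits the complement set.
        idx <- as.integer(strsplit(as.character(ti$splitval[i]), ",")[[1L]])
        category_set[i] <- paste(setdiff(lev, lev[idx]), collapse = "|")
      }
    }
    rows[[t]] <- data.frame(
      tree = t - 1L, node = ti$nodeID, kind = ifelse(is_term, "leaf", "split"),
      feature = ifelse(is_term, NA_character_, feat),
      threshold = threshold, category_set = category_set,
      left = ti$leftChild, right = ti$rightChild, value = value,
      stringsAsFactors = FALSE)
  }
  tree_ensemble(do.call(rbind, rows), task = task,
                class_labels = object$forest$levels)
}

#' @rdname as_tree_ensemble
#' @export
as_tree_ensemble.xgb.Booster <- function(object, ...) {
  if (!requireNamespace("xgboost", quietly = TRUE)) {
    stop("the 'xgboost' package is required to convert xgboost models")
  }
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp), add = TRUE)
  writeLines(xgboost::xgb.dump(object, dump_format = "json"), tmp)
  read_tree_dump(tmp, dialect = "xgboost-json", ...)
}

#' Construct a modelling dataset
#'
#' @param x data.frame of features; character columns are converted to
#'   factors, factor columns are kept (categorical), everything else must be
#'   numeric.
#' @param y response; numeric for regression, 0/1 numeric for classification.
#' @param task `"classification"` or `"regression"`.
#' @return An object of class `rn_data`.
#' @export
rn_data <- function(x, y, task = c("classification", "regression")) {
  task <- match.arg(task)
  x <- as.data.frame(x)
  if (nrow(x) < 2L) stop("need at least 2 observations")
  if (ncol(x) < 1L) stop("need at least 1 feature")
  if (length(y) != nrow(x)) stop("length(y) must equal nrow(x)")
  if (anyNA(x)) {
    bad <- which(rowSums(is.na(x)) > 0)
    stop("missing values in feature table, rows: ",
         paste(head(bad, 10L), collapse = ", "))
  }
  if (anyNA(y)) {
    stop("missing values in response, rows: ",
         paste(head(which(is.na(y)), 10L), collapse = ", "))
  }
  for (j in names(x)) {
    if (is.character(x[[j]]) || is.logical(x[[j]])) x[[j]] <- factor(x[[j]])
    if (is.factor(x[[j]])) {
      if (length(unique(as.character(x[[j]]))) < 2L) {
        stop("categorical feature '", j, "' has fewer than 2 observed levels")
      }
      x[[j]] <- droplevels(x[[j]])
    } else if (!is.numeric(x[[j]])) {
      stop("feature '", j, "' is neither numeric nor categorical")
    }
  }
  y <- as.numeric(y)
  if (task == "classification" && !all(y %in% c(0, 1))) {
    stop("classification response must be encoded 0/1")
  }
  kinds <- vapply(x, function(col) {
    if (is.factor(col)) "categorical" else "numeric"
  }, character(1L))
  structure(list(x = x, y = y, task = task, n = nrow(x), p = ncol(x),
                 feature_kinds = kinds),
            class = "rn_data")
}

#' @export
print.rn_data <- function(x, ...) {
  cat("<rn_data> ", x$n, " observations, ", x$p, " features (",
      sum(x$feature_kinds == "numeric"), " numeric, ",
      sum(x$feature_kinds == "categorical"), " categorical), task: ",
      x$task, "\n", sep = "")
  invisible(x)
}

#' Read a delimited feature table with a response column
#'
#' Classification responses are mapped to `{0, 1}` with `positive_class`
#' mapped to 1; a response with more than two classes is reduced one-vs-all
#' (the positive class versus everything else).
#'
#' @param path CSV (`.csv`) or TSV (anything else) file with a header row.
#' @param response_column name of the response column.
#' @param task `"classification"` or `"regression"`.
#' @param positive_class label mapped to 1. Required when the response has
#'   more than two classes; for a two-class response it defaults to the
#'   lexicographically larger label.
#' @return An [rn_data()] object; the positive class is stored in attribute
#'   `"positive_class"`.
#' @export
read_feature_table <- function(path, response_column,
                               task = c("classification", "regression"),
                               positive_class = NULL) {
  task <- match.arg(task)
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    read.csv(path, stringsAsFactors = FALSE)
  } else {
    read.delim(path, stringsAsFactors = FALSE)
  }
  if (!response_column %in% names(tab)) {
    stop("response column '", response_column, "' not found in ", path)
  }
  y_raw <- tab[[response_column]]
  x <- tab[setdiff(names(tab), response_column)]
  if (anyNA(y_raw) || anyNA(x)) {
    bad <- which(is.na(y_raw) | rowSums(is.na(x)) > 0)
    stop("missing values in rows: ", paste(head(bad, 10L), collapse = ", "))
  }
  if (task == "classification") {
    labels <- sort(unique(as.character(y_raw)))
    if (is.null(positive_class)) {
      if (length(labels) > 2L) {
        stop("response has ", length(labels),
             " classes; 'positive_class' is required for one-vs-all reduction")
      }
      positive_class <- labels[length(labels)]
    }
    if (!as.character(positive_class) %in% labels) {
      stop("positive_class '", positive_class,
           "' absent from the response (observed: ",
           paste(labels, collapse = ", "), ")")
    }
    y <- as.numeric(as.character(y_raw) == as.character(positive_class))
  } else {
    y <- as.numeric(y_raw)
  }
  const <- names(x)[vapply(x, function(col) {
    is.numeric(col) && length(unique(col)) == 1L
  }, logical(1L))]
  if (length(const) > 0L) {
    warning("constant numeric column(s): ", paste(const, collapse = ", "))
  }
  out <- rn_data(x, y, task = task)
  attr(out, "positive_class") <- if (task == "classification") {
    as.character(positive_class)
  } else {
    NULL
  }
  out
}

#' Check that a model and a dataset are compatible
#'
#' Every split feature must exist in the data with a compatible kind
#' (numeric thresholds on numeric columns, category sets on categorical
#' columns with known labels), and every threshold must be finite.
#'
#' @param model a [tree_ensemble()].
#' @param data an [rn_data()].
#' @return The validated `list(model = model, data = data)`, invisibly.
#' @export
validate_model_against_data <- function(model, data) {
  stopifnot(inherits(model, "tree_ensemble"), inherits(data, "rn_data"))
  splits <- model$nodes[model$nodes$kind == "split", ]
  unknown <- setdiff(unique(splits$feature), names(data$x))
  if (length(unknown) > 0L) {
    stop("model splits on feature(s) absent from the data: ",
         paste(unknown, collapse = ", "))
  }
  for (i in seq_len(nrow(splits))) {
    feat <- splits$feature[i]
    is_cat_split <- !is.na(splits$category_set[i]) &&
      nzchar(splits$category_set[i])
    if (is_cat_split) {
      if (data$feature_kinds[[feat]] != "categorical") {
        stop("categorical split on numeric column '", feat, "' (tree ",
             splits$tree[i], " node ", splits$node[i], ")")
      }
      labs <- strsplit(splits$category_set[i], "|", fixed = TRUE)[[1L]]
      bad <- setdiff(labs, levels(data$x[[feat]]))
      if (length(bad) > 0L) {
        stop("split on '", feat, "' uses unobserved label(s): ",
             paste(bad, collapse = ", "))
      }
    } else {
      if (data$feature_kinds[[feat]] != "numeric") {
        stop("numeric split on categorical column '", feat, "' (tree ",
             splits$tree[i], " node ", splits$node[i], ")")
      }
      if (!is.finite(splits$threshold[i])) {
        stop("non-finite threshold on '", feat, "' (tree ", splits$tree[i],
             " node ", splits$node[i], ")")
      }
    }
  }
  invisible(list(model = model, data = data))
}

#' @export
print.tree_ensemble <- function(x, ...) {
  nt <- length(unique(x$nodes$tree))
  cat("<tree_ensemble> ", nt, " tree", if (nt != 1L) "s", ", ",
      nrow(x$nodes), " nodes (", sum(x$nodes$kind == "leaf"),
      " leaves), task: ", x$task, "\n", sep = "")
  invisible(x)
}
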