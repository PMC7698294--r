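# CART-style binary recursive partitioning: greedy splits minimizing
# within-leaf SSE (regression) or Gini impurity (classification), with
# deterministic tie-breaks (lowest feature index, then lowest threshold) so
# identical data always yields the identical tree.

node_impurity <- function(y, kind) {
  if (kind == "regression") {
    sum((y - mean(y))^2)
  } else {
    p <- table(y) / length(y)
    length(y) * (1 - sum(p^2))
  }
}

best_split_feature <- function(x, y, min_leaf, kind) {
  o <- order(x)
  xs <- x[o]; ys <- y[o]
  n <- length(y)
  # candidate cut after position i (left = 1..i) where x strictly increases
  cand <- which(diff(xs) > 0)
  cand <- cand[cand >= min_leaf & (n - cand) >= min_leaf]
  if (length(cand) == 0) return(NULL)
  if (kind == "regression") {
    cs <- cumsum(ys); cs2 <- cumsum(ys^2)
    tot <- cs[n]; tot2 <- cs2[n]
    i <- cand
    sseL <- cs2[i] - cs[i]^2 / i
    sseR <- (tot2 - cs2[i]) - (tot - cs[i])^2 / (n - i)
    score <- sseL + sseR
  } else {
    lev <- sort(unique(y))
    gL <- rep(0, length(cand)); gR <- rep(0, length(cand))
    i <- cand
    for (l in lev) {
      cl <- cumsum(ys == l)
      totl <- cl[n]
      gL <- gL + (cl[i])^2 / i
      gR <- gR + (totl - cl[i])^2 / (n - i)
    }
    score <- (i - gL) + ((n - i) - gR)  # n_side * Gini_side summed
  }
  k <- which.min(score)  # ties: smallest index = lowest threshold
  i <- cand[k]
  list(threshold = (xs[i] + xs[i + 1]) / 2, score = score[k])
}

grow_tree <- function(data, y, features, depth, max_depth, min_leaf, kind) {
  pred <- if (kind == "regression") mean(y) else {
    tb <- table(y)
    names(tb)[which.max(tb)]
  }
  purity <- if (kind == "classification") max(table(y)) / length(y) else NA_real_
  leaf <- list(is_leaf = TRUE, prediction = pred, n = length(y),
               purity = purity, impurity = node_impurity(y, kind))
  if (depth >= max_depth || length(y) < 2 * min_leaf ||
      length(unique(y)) == 1) return(leaf)
  best <- NULL
  for (j in seq_along(features)) {
    sp <- best_split_feature(data[[features[j]]], y, min_leaf, kind)
    if (is.null(sp)) next
    # strict improvement keeps earlier feature / lower threshold on ties
    if (is.null(best) || sp$score < best$score - 1e-12) {
      best <- sp; best$var <- features[j]
    }
  }
  if (is.null(best) || best$score >= leaf$impurity - 1e-12) return(leaf)
  go_left <- data[[best$var]] <= best$threshold
  left <- grow_tree(data[go_left, , drop = FALSE], y[go_left], features,
                    depth + 1, max_depth, min_leaf, kind)
  right <- grow_tree(data[!go_left, , drop = FALSE], y[!go_left], features,
                     depth + 1, max_depth, min_leaf, kind)
  list(is_leaf = FALSE, var = best$var, threshold = best$threshold,
       n = length(y), impurity = leaf$impurity, prediction = pred,
       purity = purity, left = left, right = right)
}

tree_depth <- function(node) {
  if (node$is_leaf) 0L else 1L + max(tree_depth(node$left), tree_depth(node$right))
}
tree_leaves <- function(node) {
  if (node$is_leaf) 1L else tree_leaves(node$left) + tree_leaves(node$right)
}

#' Fit a CART regression tree
#'
#' Greedy binary recursive partitioning of a response over design parameters,
#' splitting on the (feature, threshold) pair that minimizes the summed
#' within-child variance; thresholds are midpoints between consecutive
#' observed values.  In-sample R-squared is reported (no validation split is
#' performed — the fit organizes a simulation sweep rather than predicting
#' unseen data).
#'
#' @param data data.frame (e.g. a results table from [run_batch()]).
#' @param target response column name.
#' @param features character vector of predictor columns; defaults to the
#'   table's design-parameter columns (attribute `param_cols`) or all other
#'   numeric columns.
#' @param max_depth,min_leaf stopping rules.
#' @return an object of class `fm_tree` with elements `root`, `kind`,
#'   `features`, `target`, `r_squared`, `depth`, `n_leaves`.
#' @export
fit_regression_tree <- function(data, target, features = NULL,
                                max_depth = 3L, min_leaf = 5L) {
  stopifnot(is.data.frame(data), target %in% names(data))
  y <- data[[target]]
  if (is.null(features)) features <- default_features(data, target)
  if (nrow(data) < 2 * min_leaf)
    stop("need at least 2 * min_leaf rows", call. = FALSE)
  root <- grow_tree(data[, features, drop = FALSE], y, features, 0L,
                    max_depth, min_leaf, "regression")
  pred <- predict_node(root, data)
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst <= 0) 0 else 1 - sum((y - pred)^2) / sst
  structure(list(root = root, kind = "regression", features = features,
                 target = target, r_squared = r2,
                 depth = tree_depth(root), n_leaves = tree_leaves(root)),
            class = "fm_tree")
}

#' Fit a CART classification tree on suitability labels
#'
#' Labels every row of a results table as suitable or not under the given
#' criteria (pore-area window on P5/P95, optional porosity band), then fits
#' a Gini-impurity classification tree on the design parameters.  Training
#' confusion counts are returned; if all rows share one class a root-only
#' tree is returned with a warning.
#'
#' @param results a results table from [run_batch()].
#' @param criteria a [suitability_criteria()].
#' @param max_depth,min_leaf stopping rules.
#' @param features predictor columns (default: design parameters).
#' @return list with `labeled` (results + `suitable` column), `tree`
#'   (an `fm_tree`), and `confusion` (2x2 training counts).
#' @export
label_and_fit_decision_tree <- function(results, criteria = suitability_criteria(),
                                        max_depth = 3L, min_leaf = 5L,
                                        features = NULL) {
  labeled <- label_suitability(results, criteria)
  y <- factor(ifelse(labeled$suitable, "suitable", "unsuitable"),
              levels = c("suitable", "unsuitable"))
  if (is.null(features)) features <- default_features(labeled, "suitable")
  if (length(unique(y)) == 1) {
    warning("all rows are ", as.character(y[1]), "; root-only tree",
            call. = FALSE)
  }
  root <- grow_tree(labeled[, features, drop = FALSE], as.character(y),
                    features, 0L, max_depth, min_leaf, "classification")
  tree <- structure(list(root = root, kind = "classification",
                         features = features, target = "suitable",
                         depth = tree_depth(root), n_leaves = tree_leaves(root)),
                    class = "fm_tree")
  pred <- factor(predict_node(root, labeled), levels = levels(y))
  structure_conf <- table(truth = y, predicted = pred)
  list(labeled = labeled, tree = tree, confusion = structure_conf)
}

default_features <- function(data, target) {
  pc <- attr(data, "param_cols")
  if (!is.null(pc)) return(setdiff(pc, target))
  num <- names(data)[vapply(data, is.numeric, logical(1))]
  metric_cols <- c("surface_porosity", "bulk_porosity", "pore_p5", "pore_p95",
                   "pore_cv", "pore_count", "pore_mean",
                   "fw_min", "fw_max", "fw_mean", "design_id", "replicate",
                   "seed", "suitable")
  setdiff(num, c(target, metric_cols))
}

predict_node <- function(node, data) {
  n <- nrow(data)
  if (node$is_leaf) return(rep(node$prediction, n))
  go_left <- data[[node$var]] <= node$threshold
  out <- rep(node$prediction, n)
  if (any(go_left))
    out[go_left] <- predict_node(node$left, data[go_left, , drop = FALSE])
  if (any(!go_left))
    out[!go_left] <- predict_node(node$right, data[!go_left, , drop = FALSE])
  out
}

#' @param object an `fm_tree`.
#' @param newdata data.frame with the tree's feature columns.
#' @param ... unused.
#' @rdname fit_regression_tree
#' @export
predict.fm_tree <- function(object, newdata, ...) {
  p <- predict_node(object$root, newdata)
  if (object$kind == "regression") as.numeric(p) else p
}

print_node <- function(node, indent = "") {
  if (node$is_leaf) {
    cat(sprintf("%s<leaf> n=%d pred=%s\n", indent, node$n,
                format(node$prediction, digits = 4)))
  } else {
    cat(sprintf("%s%s <= %.4g (n=%d)\n", indent, node$var, node$threshold,
                node$n))
    print_node(node$left, paste0(indent, "  "))
    print_node(node$right, paste0(indent, "  "))
  }
}

#' @export
print.fm_tree <- function(x, ...) {
  cat(sprintf("<fm_tree> %s on %s, depth %d, %d leaves", x$kind, x$target,
              x$depth, x$n_leaves))
  if (!is.null(x$r_squared)) cat(sprintf(", in-sample R^2 = %.3f", x$r_squared))
  cat("\n")
  print_node(x$root)
  invisible(x)
}

node_to_list <- function(node) {
  if (node$is_leaf)
    list(leaf = TRUE, prediction = node$prediction, n = node$n)
  else
    list(leaf = FALSE, var = node$var, threshold = node$threshold, n = node$n,
         left = node_to_list(node$left), right = node_to_list(node$right))
}

#' Export a tree as nested JSON or Graphviz DOT
#'
#' @param tree an `fm_tree`.
#' @param path output file; `.json` or `.dot` chosen by extension.
#' @return `path`, invisibly.
#' @export
export_tree <- function(tree, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::write_json(node_to_list(tree$root), path, auto_unbox = TRUE,
                         digits = NA)
  } else if (ext == "dot") {
    lines <- c("digraph tree {", "  node [shape=box];")
    counter <- new.env(); counter$i <- 0
    emit <- function(node) {
      counter$i <- counter$i + 1
      id <- counter$i
      if (node$is_leaf) {
        lines <<- c(lines, sprintf("  n%d [label=\"n=%d\\npred=%s\"];", id,
                                   node$n, format(node$prediction, digits = 3)))
      } else {
        lines <<- c(lines, sprintf("  n%d [label=\"%s <= %.4g\\nn=%d\"];", id,
                                   node$var, node$threshold, node$n))
        lid <- emit(node$left); rid <- emit(node$right)
        lines <<- c(lines, sprintf("  n%d -> n%d;", id, lid),
                    sprintf("  n%d -> n%d;", id, rid))
      }
      id
    }
    emit(tree$root)
    writeLines(c(lines, "}"), path)
  } else stop("unsupported tree export format: ", ext)
  invisible(path)
}
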