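## CART-style binary trees: Gini splitting for binary classification
## ("class" method) and sum-of-squares splitting for regression ("anova"),
## with weakest-link cost-complexity pruning and seeded cross-validated
## subtree selection. Categorical features are split by ordering their
## levels on the positive-class rate (classification) or mean response
## (regression) and scanning cut points - exact for these two loss
## functions. Ties in split quality are broken by feature name, then by
## the lexicographic left-level set, for cross-platform determinism.

#' Tree-growing parameters
#'
#' @param min_split Minimum node size eligible for splitting (default 20).
#' @param min_bucket Minimum child size (default \code{ceiling(min_split/3)}).
#' @param complexity Minimum impurity-decrease fraction of the root
#'   impurity for a split to be kept (default 0.01).
#' @param max_depth Maximum depth (default 30; root is depth 0).
#' @param n_cv_folds Cross-validation folds used by
#'   \code{\link{prune_tree}} (default 10).
#' @param seed Seed for the fold assignment.
#' @return List of class \code{tree_params}.
#' @export
tree_params <- function(min_split = 20, min_bucket = ceiling(min_split / 3),
                        complexity = 0.01, max_depth = 30, n_cv_folds = 10,
                        seed = 1) {
  stopifnot(min_bucket <= min_split, complexity >= 0, max_depth >= 1,
            n_cv_folds >= 2)
  structure(list(min_split = min_split, min_bucket = min_bucket,
                 complexity = complexity, max_depth = max_depth,
                 n_cv_folds = n_cv_folds, seed = as.integer(seed)),
            class = "tree_params")
}

## ---- impurity helpers -----------------------------------------------------
## classification: n-scaled binary Gini 2*pos*(n-pos)/n
## regression: node SSE

node_impurity <- function(method, n, pos = NULL, s = NULL, ss = NULL) {
  if (method == "class") 2 * pos * (n - pos) / n else ss - s^2 / n
}

prepare_features <- function(features) {
  stopifnot(is.data.frame(features), ncol(features) >= 1, nrow(features) >= 1)
  for (j in names(features)) {
    if (is.character(features[[j]]) || is.logical(features[[j]])) {
      features[[j]] <- factor(features[[j]])
    }
  }
  features
}

## best split of one feature at one node; returns NULL or a candidate list
best_feature_split <- function(x, y, method, min_bucket) {
  n <- length(y)
  if (is.factor(x)) {
    x <- droplevels(x)
    lev <- levels(x)
    if (length(lev) < 2) return(NULL)
    grp_n <- tabulate(x, nbins = length(lev))
    grp_s <- as.numeric(tapply(y, x, sum))
    grp_mean <- grp_s / grp_n
    ord <- order(grp_mean, lev, method = "radix")
    categorical <- TRUE
  } else {
    vals <- sort(unique(x))
    if (length(vals) < 2) return(NULL)
    f <- factor(x, levels = vals)
    grp_n <- tabulate(f, nbins = length(vals))
    grp_s <- as.numeric(tapply(y, f, sum))
    ord <- seq_along(vals)
    lev <- vals
    categorical <- FALSE
  }
  gn <- grp_n[ord]
  gs <- grp_s[ord]
  cn <- cumsum(gn)
  cs <- cumsum(gs)
  k <- length(gn)
  nl <- cn[-k]
  sl <- cs[-k]
  nr <- n - nl
  sr <- sum(gs) - sl
  ok <- nl >= min_bucket & nr >= min_bucket
  if (!any(ok)) return(NULL)
  if (method == "class") {
    child_imp <- 2 * sl * (nl - sl) / nl + 2 * sr * (nr - sr) / nr
    parent <- 2 * sum(gs) * (n - sum(gs)) / n
    gain <- parent - child_imp
  } else {
    gain <- sl^2 / nl + sr^2 / nr - sum(gs)^2 / n
  }
  gain[!ok] <- -Inf
  best <- which.max(gain)
  if (!is.finite(gain[best])) return(NULL)
  if (categorical) {
    left <- sort(as.character(lev[ord][seq_len(best)]))
    right <- sort(as.character(lev[ord][-seq_len(best)]))
    list(gain = gain[best], type = "categorical", left_levels = left,
         right_levels = right, key = paste(left, collapse = "|"),
         majority_left = nl[best] >= nr[best])
  } else {
    thr <- (lev[best] + lev[best + 1]) / 2
    list(gain = gain[best], type = "numeric", threshold = thr,
         key = sprintf("%.12g", thr), majority_left = nl[best] >= nr[best])
  }
}

node_prediction <- function(method, y) {
  if (method == "class") {
    p1 <- mean(y)
    list(class = if (p1 > 0.5) "yes" else "no",
         prob_positive = p1)
  } else {
    list(mean = mean(y))
  }
}

grow_node <- function(features, y, method, params, depth, n_root,
                      root_impurity) {
  n <- length(y)
  if (method == "class") {
    imp <- node_impurity("class", n, pos = sum(y))
    risk <- min(sum(y), n - sum(y))  # misclassification count
  } else {
    imp <- node_impurity("anova", n, s = sum(y), ss = sum(y^2))
    risk <- imp
  }
  node <- list(n = n, n_share = n / n_root, depth = depth, impurity = imp,
               risk = risk, prediction = node_prediction(method, y),
               split = NULL, children = NULL)
  if (n < params$min_split || depth >= params$max_depth || imp <= 0) {
    return(node)
  }
  best <- NULL
  for (j in sort(names(features))) {
    cand <- best_feature_split(features[[j]], y, method, params$min_bucket)
    if (is.null(cand)) next
    cand$feature <- j
    better <- is.null(best) ||
      cand$gain > best$gain + 1e-10 ||
      (abs(cand$gain - best$gain) <= 1e-10 &&
         (cand$feature < best$feature ||
            (cand$feature == best$feature && cand$key < best$key)))
    if (better) best <- cand
  }
  if (is.null(best) || best$gain < params$complexity * root_impurity) {
    return(node)
  }
  go_left <- split_goes_left(best, features[[best$feature]])
  node$split <- best[c("feature", "type",
                       if (best$type == "numeric") "threshold"
                       else c("left_levels", "right_levels"),
                       "majority_left", "gain")]
  node$children <- list(
    left = grow_node(features[go_left, , drop = FALSE], y[go_left], method,
                     params, depth + 1, n_root, root_impurity),
    right = grow_node(features[!go_left, , drop = FALSE], y[!go_left],
                      method, params, depth + 1, n_root, root_impurity))
  node
}

split_goes_left <- function(split, x) {
  if (split$type == "numeric") {
    out <- x < split$threshold
    out[is.na(out)] <- split$majority_left
  } else {
    xc <- as.character(x)
    out <- rep(split$majority_left, length(xc))  # unseen: majority direction
    out[xc %in% split$left_levels] <- TRUE
    out[xc %in% split$right_levels] <- FALSE
  }
  out
}

#' Fit a classification tree
#'
#' Greedy binary CART with Gini impurity decrease for a binary outcome.
#' Growth stops at the minimum split / bucket sizes, maximum depth, or
#' when the best impurity decrease falls below
#' \code{complexity * root impurity}. A constant outcome yields a
#' single-leaf tree.
#'
#' @param features data.frame of categorical/numeric predictors.
#' @param labels Logical (or coercible) binary outcome.
#' @param params A \code{\link{tree_params}}.
#' @return Object of class \code{ethno_tree} (method \code{"class"}).
#' @export
fit_classification_tree <- function(features, labels,
                                    params = tree_params()) {
  features <- prepare_features(features)
  y <- as.numeric(as.logical(labels))
  stopifnot(length(y) == nrow(features), !any(is.na(y)))
  root_imp <- node_impurity("class", length(y), pos = sum(y))
  root <- grow_node(features, y, "class", params, 0, length(y),
                    max(root_imp, .Machine$double.eps))
  structure(list(root = root, method = "class", params = params,
                 feature_names = names(features)),
            class = "ethno_tree")
}

#' Fit a regression tree
#'
#' Greedy binary CART minimizing within-node sum of squares ("anova"
#' method); leaf predictions are node means.
#'
#' @param features data.frame of predictors.
#' @param response Numeric response.
#' @param params A \code{\link{tree_params}}.
#' @return Object of class \code{ethno_tree} (method \code{"anova"}).
#' @export
fit_regression_tree <- function(features, response, params = tree_params()) {
  features <- prepare_features(features)
  y <- as.numeric(response)
  stopifnot(length(y) == nrow(features), !any(is.na(y)))
  root_imp <- node_impurity("anova", length(y), s = sum(y), ss = sum(y^2))
  root <- grow_node(features, y, "anova", params, 0, length(y),
                    max(root_imp, .Machine$double.eps))
  structure(list(root = root, method = "anova", params = params,
                 feature_names = names(features)),
            class = "ethno_tree")
}

## ---- pruning --------------------------------------------------------------

subtree_stats <- function(node) {
  if (is.null(node$children)) {
    return(list(risk = node$risk, leaves = 1))
  }
  l <- subtree_stats(node$children$left)
  r <- subtree_stats(node$children$right)
  list(risk = l$risk + r$risk, leaves = l$leaves + r$leaves)
}

## smallest g(t) = (R(t) - R(T_t)) / (|leaves(T_t)| - 1) over internal nodes
weakest_link <- function(node) {
  if (is.null(node$children)) return(Inf)
  st <- subtree_stats(node)
  g <- (node$risk - st$risk) / (st$leaves - 1)
  min(g, weakest_link(node$children$left), weakest_link(node$children$right))
}

collapse_at <- function(node, alpha) {
  if (is.null(node$children)) return(node)
  node$children$left <- collapse_at(node$children$left, alpha)
  node$children$right <- collapse_at(node$children$right, alpha)
  st <- subtree_stats(node)
  g <- (node$risk - st$risk) / (st$leaves - 1)
  if (g < alpha) {
    node$children <- NULL
    node$split <- NULL
  }
  node
}

prune_at_alpha <- function(tree, alpha) {
  if (alpha <= 0) return(tree)
  repeat {
    g <- weakest_link(tree$root)
    if (g >= alpha || !is.finite(g)) break
    tree$root <- collapse_at(tree$root, alpha)
    if (is.null(tree$root$children)) break
  }
  tree
}

alpha_sequence <- function(tree) {
  alphas <- numeric(0)
  t <- tree
  repeat {
    g <- weakest_link(t$root)
    if (!is.finite(g)) break
    alphas <- c(alphas, max(g, 0))
    t <- prune_at_alpha(t, max(g, 0) + 1e-12)
    if (is.null(t$root$children)) break
  }
  unique(alphas)
}

tree_risk <- function(tree, features, outcome) {
  pred <- predict_tree(tree, features)
  if (tree$method == "class") {
    sum(pred$class != ifelse(as.logical(outcome), "yes", "no"))
  } else {
    sum((as.numeric(outcome) - pred$mean)^2)
  }
}

#' Cost-complexity pruning with cross-validated subtree selection
#'
#' With \code{alpha} supplied, performs weakest-link pruning at that
#' penalty directly (0 leaves the tree unchanged, \code{Inf} collapses it
#' to the root). Otherwise the candidate penalties are the tree's own
#' weakest-link sequence; the subtree minimizing the seeded
#' \code{n_cv_folds}-fold cross-validated risk (misclassification count or
#' test SSE) is returned, ties resolved toward the smaller tree.
#'
#' @param tree A fitted \code{ethno_tree}.
#' @param features,outcome The training data.
#' @param params A \code{\link{tree_params}} (folds and seed).
#' @param alpha Optional fixed complexity penalty.
#' @return The pruned \code{ethno_tree}.
#' @export
prune_tree <- function(tree, features, outcome, params = tree$params,
                       alpha = NULL) {
  stopifnot(inherits(tree, "ethno_tree"))
  features <- prepare_features(features)
  if (!is.null(alpha)) {
    if (is.infinite(alpha)) {
      tree$root$children <- NULL
      tree$root$split <- NULL
      return(tree)
    }
    return(prune_at_alpha(tree, alpha))
  }
  alphas <- alpha_sequence(tree)
  if (length(alphas) == 0) return(tree)
  ## evaluation points: geometric midpoints of consecutive alphas
  pts <- c(0, sqrt(pmax(alphas[-length(alphas)], 1e-12) *
                     alphas[-1]), alphas[length(alphas)] * 2 + 1e-9)
  n <- nrow(features)
  folds <- withr_seed(params$seed,
                      sample(rep_len(seq_len(params$n_cv_folds), n)))
  cv_risk <- numeric(length(pts))
  for (f in seq_len(params$n_cv_folds)) {
    test <- folds == f
    fit_f <- if (tree$method == "class") {
      fit_classification_tree(features[!test, , drop = FALSE],
                              outcome[!test], tree$params)
    } else {
      fit_regression_tree(features[!test, , drop = FALSE],
                          outcome[!test], tree$params)
    }
    for (a in seq_along(pts)) {
      sub <- prune_at_alpha(fit_f, pts[a])
      cv_risk[a] <- cv_risk[a] +
        tree_risk(sub, features[test, , drop = FALSE], outcome[test])
    }
  }
  best <- max(which(cv_risk <= min(cv_risk) + 1e-12))
  prune_at_alpha(tree, pts[best])
}

## ---- prediction and rendering --------------------------------------------

route_row <- function(node, row) {
  while (!is.null(node$children)) {
    x <- row[[node$split$feature]]
    left <- split_goes_left(node$split, x)
    node <- if (left) node$children$left else node$children$right
  }
  node
}

#' Predict from a fitted tree
#'
#' Deterministic routing of each row to its leaf. A category unseen at a
#' split is routed in the majority direction recorded at training and a
#' note attached.
#'
#' @param tree A fitted \code{ethno_tree}.
#' @param rows data.frame with the training feature columns.
#' @return For classification, data.frame with \code{class} and
#'   \code{prob_positive}; for regression, data.frame with \code{mean};
#'   both carry \code{n_share} of the landing leaf.
#' @export
predict_tree <- function(tree, rows) {
  stopifnot(inherits(tree, "ethno_tree"))
  miss <- setdiff(tree$feature_names, names(rows))
  if (length(miss) > 0) {
    stop("rows missing feature column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  leaves <- lapply(seq_len(nrow(rows)), function(i) {
    route_row(tree$root, rows[i, , drop = FALSE])
  })
  if (tree$method == "class") {
    data.frame(
      class = vapply(leaves, function(l) l$prediction$class, character(1)),
      prob_positive = vapply(leaves, function(l) l$prediction$prob_positive,
                             numeric(1)),
      n_share = vapply(leaves, function(l) l$n_share, numeric(1)),
      stringsAsFactors = FALSE)
  } else {
    data.frame(
      mean = vapply(leaves, function(l) l$prediction$mean, numeric(1)),
      n_share = vapply(leaves, function(l) l$n_share, numeric(1)))
  }
}

split_label <- function(split) {
  if (split$type == "numeric") {
    sprintf("%s < %g", split$feature, split$threshold)
  } else {
    sprintf("%s in {%s}", split$feature,
            paste(split$left_levels, collapse = ","))
  }
}

node_label <- function(node, method) {
  if (method == "class") {
    sprintf("pred=%s p(yes)=%.3f n%%=%.1f", node$prediction$class,
            node$prediction$prob_positive, 100 * node$n_share)
  } else {
    sprintf("mean=%.4g n%%=%.1f", node$prediction$mean, 100 * node$n_share)
  }
}

render_node <- function(node, method, indent) {
  pad <- strrep("  ", indent)
  if (is.null(node$children)) {
    return(sprintf("%sleaf: %s", pad, node_label(node, method)))
  }
  c(sprintf("%snode: %s [%s]", pad, node_label(node, method),
            split_label(node$split)),
    render_node(node$children$left, method, indent + 1),
    render_node(node$children$right, method, indent + 1))
}

#' Render a fitted tree as an indented rule listing
#'
#' Each node shows its split rule (internal nodes), prediction (class and
#' positive-class probability, or mean response) and the percentage of
#' training observations it holds.
#'
#' @param tree A fitted \code{ethno_tree}.
#' @return Character vector of lines.
#' @export
tree_to_text <- function(tree) {
  stopifnot(inherits(tree, "ethno_tree"))
  render_node(tree$root, tree$method, 0)
}

#' @export
print.ethno_tree <- function(x, ...) {
  cat(sprintf("%s tree, %d leaves\n",
              if (x$method == "class") "classification" else "regression",
              subtree_stats(x$root)$leaves))
  cat(tree_to_text(x), sep = "\n")
  invisible(x)
}

tree_leaves <- function(node) {
  if (is.null(node$children)) return(list(node))
  c(tree_leaves(node$children$left), tree_leaves(node$children$right))
}
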