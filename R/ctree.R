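#' Parameters for the conditional-inference tree
#'
#' Mirrors the conventional defaults of conditional-inference trees: a
#' split requires the smallest Bonferroni-adjusted covariate association
#' p-value to be at most `alpha` (criterion 1 - alpha = 0.95), nodes with
#' fewer than `minsplit` samples are not split, and both children must
#' hold at least `minbucket` samples.
#'
#' @param alpha Split significance threshold.
#' @param minsplit Minimum node size eligible for splitting.
#' @param minbucket Minimum child size.
#' @param max_depth Maximum depth (Inf = unlimited; root depth 0).
#' @return Object of class `ctree_params`.
#' @export
ctree_params <- function(alpha = 0.05, minsplit = 20, minbucket = 7,
                         max_depth = Inf) {
  stopifnot(alpha > 0, alpha < 1, minbucket >= 1,
            minbucket <= minsplit / 2, max_depth >= 0)
  structure(list(alpha = alpha, minsplit = as.integer(minsplit),
                 minbucket = as.integer(minbucket), max_depth = max_depth),
            class = "ctree_params")
}

# Association p-value between one covariate and the class label.
# Continuous: rank-based two-sample (2 classes) or Kruskal-Wallis (>= 3).
# Binary: exact two-sided Fisher (2 classes) or chi-square (>= 3).
covariate_p_value <- function(x, y, is_binary) {
  if (length(unique(x)) < 2) return(1)
  k <- nlevels(y)
  if (is_binary) {
    tab <- table(factor(x, levels = c(0, 1)), y)
    if (k == 2) {
      stats::fisher.test(tab)$p.value
    } else {
      suppressWarnings(stats::chisq.test(tab)$p.value)
    }
  } else {
    if (k == 2) {
      g <- split(x, y)
      suppressWarnings(stats::wilcox.test(g[[1]], g[[2]], exact = FALSE,
                                          correct = TRUE)$p.value)
    } else {
      suppressWarnings(stats::kruskal.test(x, y)$p.value)
    }
  }
}

# Best cutpoint for covariate x: midpoint between adjacent sorted unique
# values maximizing the chi-square statistic of the left/right-by-class
# table, subject to minbucket on both sides. Returns NULL when no valid
# cut exists. Binary covariates always cut at 0.5.
best_cutpoint <- function(x, y, is_binary, minbucket) {
  n <- length(x)
  if (is_binary) {
    n_left <- sum(x <= 0.5)
    if (n_left < minbucket || n - n_left < minbucket) return(NULL)
    return(0.5)
  }
  ord <- order(x)
  xs <- x[ord]
  ys <- y[ord]
  # candidate boundaries: after the last occurrence of each unique value
  idx <- which(diff(xs) > 0)
  idx <- idx[idx >= minbucket & (n - idx) >= minbucket]
  if (length(idx) == 0) return(NULL)
  classes <- levels(y)
  tot <- as.numeric(table(ys)[classes])
  cum <- sapply(classes, function(cl) cumsum(ys == cl))
  if (is.null(dim(cum))) cum <- matrix(cum, nrow = n)
  stat <- vapply(idx, function(i) {
    left <- cum[i, ]
    right <- tot - left
    nl <- i
    nr <- n - i
    e_left <- tot * nl / n
    e_right <- tot * nr / n
    keep <- tot > 0
    sum((left[keep] - e_left[keep])^2 / e_left[keep]) +
      sum((right[keep] - e_right[keep])^2 / e_right[keep])
  }, numeric(1))
  best <- idx[which.max(stat)]
  (xs[best] + xs[best + 1]) / 2
}

#' Fit a conditional-inference classification tree
#'
#' Recursive partitioning in which each node (1) computes a rank- or
#' exact-test association p-value between every covariate and the class
#' label, (2) Bonferroni-adjusts over covariates, (3) becomes a leaf if the
#' smallest adjusted p exceeds `alpha` or the node is smaller than
#' `minsplit`, and otherwise (4) splits the winning covariate at the
#' cutpoint maximizing the standardized two-sample (chi-square) statistic,
#' subject to `minbucket` on both children. Binary covariates (values in
#' \{0, 1\}) split by level; all variables carry equal weight. The
#' procedure is deterministic.
#'
#' @param features Data frame of covariates only (continuous or 0/1
#'   binary; no missing values).
#' @param labels Class labels (coerced to factor; >= 2 classes for any
#'   split to occur).
#' @param params A [ctree_params()].
#' @return Object of class `shm_ctree`.
#' @export
ctree_fit <- function(features, labels, params = ctree_params()) {
  features <- as.data.frame(features)
  if (anyNA(features) || anyNA(labels)) {
    abort("ctree_fit: missing values are not supported")
  }
  y <- droplevels(as.factor(labels))
  stopifnot(nrow(features) == length(y), nrow(features) >= 1)
  is_binary <- vapply(features, function(col) all(col %in% c(0, 1)),
                      logical(1))
  classes <- levels(y)
  majority <- classes[which.max(table(y))]

  nodes <- list()
  new_node <- function(node) {
    nodes[[length(nodes) + 1]] <<- node
    length(nodes)
  }

  grow <- function(rows, depth, parent_id) {
    yx <- y[rows]
    counts <- as.integer(table(factor(yx, levels = classes)))
    make_leaf <- function(id) {
      nodes[[id]]$is_leaf <<- TRUE
      id
    }
    id <- new_node(list(
      node_id = NA_integer_, parent_id = parent_id, depth = depth,
      n = length(rows), class_counts = counts,
      is_leaf = FALSE, covariate = NA_character_, p_adjusted = NA_real_,
      cutpoint = NA_real_, left_id = NA_integer_, right_id = NA_integer_
    ))
    nodes[[id]]$node_id <<- id

    can_split <- length(rows) >= params$minsplit &&
      length(unique(yx)) >= 2 && depth < params$max_depth
    if (!can_split) return(make_leaf(id))

    p_raw <- vapply(seq_along(features), function(j) {
      covariate_p_value(features[rows, j], droplevels(yx), is_binary[j])
    }, numeric(1))
    p_adj <- pmin(p_raw * ncol(features), 1)
    j_best <- which.min(p_adj)
    if (p_adj[j_best] > params$alpha) return(make_leaf(id))

    cut <- best_cutpoint(features[rows, j_best], droplevels(yx),
                         is_binary[j_best], params$minbucket)
    if (is.null(cut)) return(make_leaf(id))

    go_left <- features[rows, j_best] <= cut
    nodes[[id]]$covariate <<- names(features)[j_best]
    nodes[[id]]$p_adjusted <<- p_adj[j_best]
    nodes[[id]]$cutpoint <<- cut
    left_id <- grow(rows[go_left], depth + 1, id)
    right_id <- grow(rows[!go_left], depth + 1, id)
    nodes[[id]]$left_id <<- left_id
    nodes[[id]]$right_id <<- right_id
    id
  }
  grow(seq_along(y), 0, NA_integer_)

  structure(list(nodes = nodes, classes = classes, majority = majority,
                 params = params, covariates = names(features),
                 n_train = length(y)),
            class = "shm_ctree")
}

leaf_proportions <- function(tree, node) {
  counts <- node$class_counts
  if (sum(counts) == 0) {
    rep(1 / length(counts), length(counts))
  } else {
    counts / sum(counts)
  }
}

leaf_prediction <- function(tree, node) {
  props <- leaf_proportions(tree, node)
  best <- which(props == max(props))
  if (length(best) > 1) {
    # ties broken toward the globally more frequent class
    maj_idx <- match(tree$majority, tree$classes)
    if (maj_idx %in% best) best <- maj_idx else best <- best[1]
  }
  tree$classes[best]
}

#' Predict with a fitted conditional-inference tree
#'
#' Routes each row to its leaf and returns the leaf class proportions (the
#' reported mutability probability) and the majority class, ties broken
#' toward the globally more frequent training class. No surrogate splits:
#' a missing split covariate is an error.
#'
#' @param tree A fitted [ctree_fit()] object.
#' @param features Data frame containing every split covariate.
#' @return Tibble with `.row`, `node_id` (leaf), `predicted`, and one
#'   `prop_<class>` column per class.
#' @export
ctree_predict <- function(tree, features) {
  features <- as.data.frame(features)
  used <- unique(stats::na.omit(vapply(tree$nodes, function(nd) nd$covariate,
                                       character(1))))
  missing <- setdiff(used, names(features))
  if (length(missing) > 0) {
    abort(paste0("ctree_predict: missing covariate(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (length(used) > 0 && anyNA(features[, used, drop = FALSE])) {
    abort("ctree_predict: missing covariate values (no surrogate splits)")
  }
  n <- nrow(features)
  leaf_id <- integer(n)
  for (i in seq_len(n)) {
    id <- 1L
    repeat {
      nd <- tree$nodes[[id]]
      if (nd$is_leaf) break
      id <- if (features[i, nd$covariate] <= nd$cutpoint) {
        nd$left_id
      } else {
        nd$right_id
      }
    }
    leaf_id[i] <- id
  }
  props <- t(vapply(leaf_id, function(id) {
    leaf_proportions(tree, tree$nodes[[id]])
  }, numeric(length(tree$classes))))
  colnames(props) <- paste0("prop_", tree$classes)
  pred <- vapply(leaf_id, function(id) {
    leaf_prediction(tree, tree$nodes[[id]])
  }, character(1))
  dplyr::bind_cols(
    tibble::tibble(.row = seq_len(n), node_id = leaf_id,
                   predicted = factor(pred, levels = tree$classes)),
    tibble::as_tibble(props)
  )
}

#' Structured report of a fitted tree
#'
#' One row per node, ordered by node id: split covariate, adjusted p,
#' cutpoint, children, sample count, per-class counts and the leaf
#' prediction. The report round-trips through [ctree_from_description()].
#'
#' @param tree A fitted [ctree_fit()] object.
#' @return Tibble with one row per node.
#' @export
describe_tree <- function(tree) {
  counts <- t(vapply(tree$nodes, function(nd) as.numeric(nd$class_counts),
                     numeric(length(tree$classes))))
  colnames(counts) <- paste0("n_", tree$classes)
  base <- purrr::map_dfr(tree$nodes, function(nd) {
    tibble::tibble(
      node_id = nd$node_id, parent_id = nd$parent_id, depth = nd$depth,
      is_leaf = nd$is_leaf, covariate = nd$covariate,
      p_adjusted = nd$p_adjusted, cutpoint = nd$cutpoint,
      left_id = nd$left_id, right_id = nd$right_id, n = nd$n,
      predicted = if (nd$is_leaf) leaf_prediction(tree, nd) else NA_character_
    )
  })
  dplyr::bind_cols(base, tibble::as_tibble(counts)) %>%
    dplyr::arrange(.data$node_id)
}

#' Rebuild a tree from its structured report
#'
#' @param description Output of [describe_tree()].
#' @param params Optional [ctree_params()] to attach.
#' @return An `shm_ctree` giving identical predictions to the original.
#' @export
ctree_from_description <- function(description, params = ctree_params()) {
  class_cols <- grep("^n_", names(description), value = TRUE)
  classes <- sub("^n_", "", class_cols)
  root_counts <- as.numeric(description[description$node_id == 1, class_cols])
  majority <- classes[which.max(root_counts)]
  nodes <- lapply(seq_len(nrow(description)), function(i) {
    row <- description[description$node_id == i, ]
    list(node_id = row$node_id, parent_id = row$parent_id,
         depth = row$depth, n = row$n,
         class_counts = as.numeric(row[, class_cols]),
         is_leaf = row$is_leaf, covariate = row$covariate,
         p_adjusted = row$p_adjusted, cutpoint = row$cutpoint,
         left_id = row$left_id, right_id = row$right_id)
  })
  structure(list(nodes = nodes, classes = classes, majority = majority,
                 params = params,
                 covariates = unique(stats::na.omit(description$covariate)),
                 n_train = description$n[description$node_id == 1]),
            class = "shm_ctree")
}

#' Confusion matrix and per-leaf purity
#'
#' @param labels True class labels.
#' @param predictions Prediction tibble from [ctree_predict()] on the same
#'   rows.
#' @return List with `confusion` (tibble `truth`, `predicted`, `count`),
#'   `accuracy`, and `leaves` (tibble `node_id`, `n`, `majority_class`,
#'   `purity`).
#' @export
evaluate_prediction <- function(labels, predictions) {
  stopifnot(length(labels) == nrow(predictions))
  truth <- as.factor(labels)
  confusion <- tibble::tibble(truth = truth,
                              predicted = predictions$predicted) %>%
    dplyr::count(.data$truth, .data$predicted, name = "count")
  leaves <- tibble::tibble(node_id = predictions$node_id, truth = truth) %>%
    dplyr::group_by(.data$node_id) %>%
    dplyr::summarise(
      n = dplyr::n(),
      majority_class = names(which.max(table(.data$truth))),
      purity = max(table(.data$truth)) / dplyr::n(),
      .groups = "drop"
    )
  list(confusion = confusion,
       accuracy = mean(as.character(truth) ==
                         as.character(predictions$predicted)),
       leaves = leaves)
}

#' @export
print.shm_ctree <- function(x, ...) {
  n_leaves <- sum(vapply(x$nodes, `[[`, logical(1), "is_leaf"))
  cat("<shm_ctree> ", length(x$nodes), " node(s), ", n_leaves,
      " leaf/leaves, classes: ", paste(x$classes, collapse = ", "),
      ", n = ", x$n_train, "\n", sep = "")
  invisible(x)
}

#' Tidy a fitted conditional-inference tree
#'
#' @param x A fitted [ctree_fit()] object.
#' @param ... Unused.
#' @return The node-level report of [describe_tree()].
#' @export
tidy.shm_ctree <- function(x, ...) {
  describe_tree(x)
}

#' One-row summary of a fitted conditional-inference tree
#'
#' @param x A fitted [ctree_fit()] object.
#' @param ... Unused.
#' @return Tibble with node/leaf counts, depth, training size and the
#'   split threshold.
#' @export
glance.shm_ctree <- function(x, ...) {
  leaves <- vapply(x$nodes, `[[`, logical(1), "is_leaf")
  depths <- vapply(x$nodes, `[[`, numeric(1), "depth")
  tibble::tibble(
    n_nodes = length(x$nodes),
    n_leaves = sum(leaves),
    depth = max(depths),
    n_train = x$n_train,
    alpha = x$params$alpha
  )
}
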