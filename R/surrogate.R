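# Interpretable surrogate decision tree distilled from the recommendation
# policy: a from-scratch greedy binary CART classifier with an impurity
# stopping rule (leaf when node Gini <= gini_stop), depth cap, and
# deterministic tie-breaking.

#' Gini impurity of a class-count vector
#'
#' `1 - sum((n_c / n)^2)`; 0 for a pure node, `1 - 1/C` for `C` balanced
#' classes.
#'
#' @param class_counts Non-negative integer counts with positive sum.
#' @return Impurity in `[0, 1)`.
#' @export
#' @examples
#' gini_impurity(c(5, 5)) # 0.5
gini_impurity <- function(class_counts) {
  if (any(class_counts < 0) || sum(class_counts) <= 0) {
    stop("Class counts must be non-negative with a positive sum.",
         call. = FALSE)
  }
  p <- class_counts / sum(class_counts)
  1 - sum(p^2)
}

# Best (feature, threshold) split of a node by weighted Gini decrease.
# Thresholds are midpoints between consecutive sorted unique values; ties
# broken by lower feature index, then lower threshold. Returns NULL when no
# split strictly reduces the weighted impurity.
best_gini_split <- function(x, y_int, n_classes, min_leaf) {
  n <- length(y_int)
  parent_counts <- tabulate(y_int, nbins = n_classes)
  parent_gini <- gini_impurity(parent_counts)
  best <- NULL
  for (j in seq_len(ncol(x))) {
    xj <- x[[j]]
    ord <- order(xj)
    xs <- xj[ord]
    ys <- y_int[ord]
    # cumulative class counts after each sorted row
    onehot <- matrix(0L, n, n_classes)
    onehot[cbind(seq_len(n), ys)] <- 1L
    cum <- apply(onehot, 2, cumsum)
    # candidate cuts: between i and i+1 where the value changes
    cuts <- which(diff(xs) > 0)
    cuts <- cuts[cuts >= min_leaf & (n - cuts) >= min_leaf]
    if (length(cuts) == 0) next
    left_n <- cuts
    right_n <- n - cuts
    left_counts <- cum[cuts, , drop = FALSE]
    right_counts <- matrix(parent_counts, length(cuts), n_classes,
                           byrow = TRUE) - left_counts
    gini_l <- 1 - rowSums((left_counts / left_n)^2)
    gini_r <- 1 - rowSums((right_counts / right_n)^2)
    weighted <- (left_n * gini_l + right_n * gini_r) / n
    decrease <- parent_gini - weighted
    k <- which.max(decrease) # first (lowest threshold) among exact ties
    if (decrease[k] > 1e-12 &&
        (is.null(best) || decrease[k] > best$decrease + 1e-12)) {
      best <- list(feature = j,
                   threshold = (xs[cuts[k]] + xs[cuts[k] + 1]) / 2,
                   decrease = decrease[k])
    }
  }
  best
}

#' Fit a surrogate decision tree to the recommendation policy
#'
#' Greedy binary CART classification of the recommended drugs: at each node
#' every (feature, midpoint threshold) candidate is scanned and the split
#' with the largest count-weighted Gini decrease is taken (ties towards the
#' lower feature index, then lower threshold). A node becomes a leaf when
#' its Gini impurity is at or below `gini_stop`, when `max_depth` is
#' reached, or when no split strictly reduces the weighted impurity. Left
#' children take `feature <= threshold`.
#'
#' @param x Feature data frame (numeric columns, no missing values).
#' @param labels Recommended drugs (character or factor over
#'   [drug_classes()], or any label alphabet).
#' @param max_depth Depth cap (root = depth 0); default 10.
#' @param gini_stop Leaf condition on node impurity; default 0.20.
#' @param min_leaf Minimum rows per child; default 1.
#' @return Object of class `pwv_surrogate`: tibble of nodes (`node_id`,
#'   `depth`, `is_leaf`, `split_feature`, `threshold`, `gini`, `n`,
#'   per-class count columns, `majority`, `left_id`, `right_id`) plus the
#'   class levels and settings.
#' @export
fit_surrogate <- function(x, labels, max_depth = 10, gini_stop = 0.20,
                          min_leaf = 1) {
  x <- as.data.frame(x)
  if (nrow(x) != length(labels) || nrow(x) == 0) {
    stop("`x` rows and `labels` must match and be nonempty.", call. = FALSE)
  }
  if (any(!purrr::map_lgl(x, is.numeric)) ||
      any(purrr::map_lgl(x, ~ any(!is.finite(.x))))) {
    stop("Features must be finite numeric columns.", call. = FALSE)
  }
  levels_ <- if (is.factor(labels)) levels(labels) else
    intersect(c(drug_classes(), sort(unique(as.character(labels)))),
              unique(as.character(labels)))
  y_int <- match(as.character(labels), levels_)
  n_classes <- length(levels_)

  nodes <- list()
  next_id <- 1L
  grow <- function(idx, depth) {
    id <- next_id
    next_id <<- next_id + 1L
    counts <- tabulate(y_int[idx], nbins = n_classes)
    g <- gini_impurity(counts)
    majority <- levels_[which.max(counts)]
    node <- list(node_id = id, depth = depth, is_leaf = TRUE,
                 split_feature = NA_character_, threshold = NA_real_,
                 gini = g, n = length(idx), counts = counts,
                 majority = majority, left_id = NA_integer_,
                 right_id = NA_integer_)
    if (g > gini_stop && depth < max_depth && length(idx) >= 2 * min_leaf) {
      split <- best_gini_split(x[idx, , drop = FALSE], y_int[idx],
                               n_classes, min_leaf)
      if (!is.null(split)) {
        node$is_leaf <- FALSE
        node$split_feature <- names(x)[split$feature]
        node$threshold <- split$threshold
        go_left <- x[idx, split$feature] <= split$threshold
        nodes[[id]] <<- node # reserve slot before recursing
        node$left_id <- grow(idx[go_left], depth + 1L)
        node$right_id <- grow(idx[!go_left], depth + 1L)
      }
    }
    nodes[[id]] <<- node
    id
  }
  grow(seq_along(y_int), 0L)

  node_tbl <- dplyr::bind_rows(purrr::map(nodes, function(nd) {
    counts <- stats::setNames(as.list(nd$counts), paste0("n_", levels_))
    dplyr::bind_cols(
      tibble::tibble(node_id = nd$node_id, depth = nd$depth,
                     is_leaf = nd$is_leaf, split_feature = nd$split_feature,
                     threshold = nd$threshold, gini = nd$gini, n = nd$n,
                     majority = nd$majority, left_id = nd$left_id,
                     right_id = nd$right_id),
      tibble::as_tibble(counts)
    )
  }))
  structure(
    list(nodes = node_tbl, levels = levels_, features = names(x),
         max_depth = max_depth, gini_stop = gini_stop, min_leaf = min_leaf),
    class = "pwv_surrogate"
  )
}

#' @export
predict.pwv_surrogate <- function(object, newdata, ...) {
  newdata <- as.data.frame(newdata)
  missing_cols <- setdiff(
    unique(stats::na.omit(object$nodes$split_feature)), names(newdata))
  if (length(missing_cols) > 0) {
    stop("Missing feature column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  nodes <- object$nodes
  out <- character(nrow(newdata))
  route <- function(rows, id) {
    nd <- nodes[nodes$node_id == id, ]
    if (nd$is_leaf) {
      out[rows] <<- nd$majority
      return(invisible())
    }
    left <- newdata[rows, nd$split_feature] <= nd$threshold
    if (any(left)) route(rows[left], nd$left_id)
    if (any(!left)) route(rows[!left], nd$right_id)
  }
  if (nrow(newdata) > 0) route(seq_len(nrow(newdata)), 1L)
  out
}

#' Fidelity of the surrogate to the recommendation policy
#'
#' Fraction of patients for whom the surrogate tree reproduces the
#' recommendation label.
#'
#' @param tree A `pwv_surrogate`.
#' @param x Feature table.
#' @param labels Recommendation labels to imitate.
#' @return A fraction in `[0, 1]`.
#' @export
surrogate_fidelity <- function(tree, x, labels) {
  mean(predict(tree, x) == as.character(labels))
}

#' Render a surrogate tree as indented text
#'
#' Shows, per node, the split rule, impurity, size, class counts, and
#' majority class, truncated to the requested number of levels (deeper
#' subtrees are summarized by their leaf-majority distribution).
#'
#' @param tree A `pwv_surrogate`.
#' @param levels Number of levels to show (root = level 1); default 5.
#' @return Character vector of lines, invisibly; printed as a side effect.
#' @export
render_tree <- function(tree, levels = 5) {
  stopifnot(levels >= 1)
  nodes <- tree$nodes
  lines <- character(0)
  fmt_counts <- function(nd) {
    cc <- unlist(nd[paste0("n_", tree$levels)])
    paste(paste0(tree$levels, ":", cc)[cc > 0], collapse = " ")
  }
  descend <- function(id, depth, prefix) {
    nd <- nodes[nodes$node_id == id, ]
    if (depth >= levels) {
      lines <<- c(lines, sprintf("%s[...] n=%d majority=%s gini=%.3f",
                                 prefix, nd$n, nd$majority, nd$gini))
      return(invisible())
    }
    if (nd$is_leaf) {
      lines <<- c(lines, sprintf("%sleaf: %s (n=%d, gini=%.3f | %s)",
                                 prefix, nd$majority, nd$n, nd$gini,
                                 fmt_counts(nd)))
    } else {
      lines <<- c(lines, sprintf("%s%s <= %.4g (n=%d, gini=%.3f | %s)",
                                 prefix, nd$split_feature, nd$threshold,
                                 nd$n, nd$gini, fmt_counts(nd)))
      descend(nd$left_id, depth + 1, paste0(prefix, "  "))
      descend(nd$right_id, depth + 1, paste0(prefix, "  "))
    }
  }
  descend(1L, 0L, "")
  cat(lines, sep = "\n")
  invisible(lines)
}

#' Export a surrogate tree as a Graphviz DOT description
#'
#' @param tree A `pwv_surrogate`.
#' @return A single DOT-format string.
#' @export
tree_to_dot <- function(tree) {
  nodes <- tree$nodes
  lab <- function(nd) {
    if (nd$is_leaf) {
      sprintf("%s\\nn=%d gini=%.2f", nd$majority, nd$n, nd$gini)
    } else {
      sprintf("%s <= %.4g\\nn=%d gini=%.2f", nd$split_feature,
              nd$threshold, nd$n, nd$gini)
    }
  }
  body <- character(0)
  for (i in seq_len(nrow(nodes))) {
    nd <- nodes[i, ]
    body <- c(body, sprintf("  n%d [label=\"%s\"];", nd$node_id, lab(nd)))
    if (!nd$is_leaf) {
      body <- c(body,
                sprintf("  n%d -> n%d [label=\"yes\"];", nd$node_id, nd$left_id),
                sprintf("  n%d -> n%d [label=\"no\"];", nd$node_id, nd$right_id))
    }
  }
  paste(c("digraph surrogate {", "  node [shape=box];", body, "}"),
        collapse = "\n")
}

#' @export
print.pwv_surrogate <- function(x, ...) {
  cat("<pwv_surrogate> CART policy surrogate:",
      sum(x$nodes$is_leaf), "leaves, depth <=", x$max_depth,
      ", gini_stop =", x$gini_stop, "\n")
  invisible(x)
}
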