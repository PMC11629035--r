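# Shared fixtures: tiny cohorts, lightweight hyperparameters, and an
# independent brute-force CART enumerator used as the surrogate-tree oracle.

quick_hp <- function(n_trees = 60) {
  default_hyperparams(n_trees = n_trees, min_node_size = 2)
}

# Simulation-study settings: lighter forests with wider split subsampling,
# used by the integration and acceptance runs (see the methods vignette).
study_hp <- function(n_trees = 250) {
  default_hyperparams(n_trees = n_trees, mtry_frac = 0.6, min_node_size = 2)
}

# A hand-built miniature cohort with the outcome columns the preprocessing
# expects and a couple of schema covariates.
toy_cohort <- function(drugs, cf_base = NULL, cf_follow = NULL,
                       ba_base = NULL, ba_follow = NULL) {
  n <- length(drugs)
  tibble::tibble(
    patient_id = sprintf("T%03d", seq_len(n)),
    cohort_id = rep(cohort_labels(), length.out = n),
    drug_class = drugs,
    age = seq(50, 70, length.out = n),
    weight_kg = seq(60, 100, length.out = n),
    hba1c = seq(5, 7, length.out = n),
    cfpwv_baseline = cf_base %||% seq(8, 12, length.out = n),
    bapwv_baseline = ba_base %||% seq(12, 16, length.out = n),
    cfpwv_followup = cf_follow %||% seq(7, 11, length.out = n),
    bapwv_followup = ba_follow %||% seq(11, 15, length.out = n),
    followup_years = rep(1.5, n)
  )
}

# A synthetic single-arm dataset with known informative features.
make_arm_dataset <- function(n = 200, p = 8, informative = 2, noise = 0.1,
                             drug = "ACEI", seed = 1, constant_col = FALSE) {
  withr::with_seed(seed, {
    x <- as.data.frame(matrix(rnorm(n * p), n, p))
    names(x) <- paste0("f", seq_len(p))
    if (constant_col) x$f_const <- 1
    beta <- c(seq(2, 0.5, length.out = informative),
              rep(0, ncol(x) - informative))
    y <- as.matrix(x) %*% beta + rnorm(n, 0, noise)
    structure(
      list(drug = drug, x = tibble::as_tibble(x), y = as.numeric(y),
           patient_ids = sprintf("%s%04d", drug, seq_len(n)),
           feature_names = names(x)),
      class = "pwv_arm_dataset"
    )
  })
}

# ---- Independent CART oracle -------------------------------------------
# Naive exhaustive-split CART with the same contract as fit_surrogate():
# scan all features and all midpoints, maximize weighted Gini decrease,
# ties to the lower feature index then lower threshold; leaf when node gini
# <= gini_stop, depth = max_depth, or no strictly improving split. Written
# as plain enumeration (no cumulative-count optimization) so it checks the
# fast implementation independently.
oracle_gini <- function(labels, levels_) {
  p <- table(factor(labels, levels = levels_)) / length(labels)
  1 - sum(p^2)
}

oracle_cart <- function(x, labels, levels_, max_depth = 10,
                        gini_stop = 0.2, min_leaf = 1, depth = 0) {
  g <- oracle_gini(labels, levels_)
  counts <- as.integer(table(factor(labels, levels = levels_)))
  majority <- levels_[which.max(counts)]
  node <- list(depth = depth, gini = g, n = length(labels),
               counts = counts, majority = majority, leaf = TRUE)
  if (g <= gini_stop || depth >= max_depth || length(labels) < 2 * min_leaf) {
    return(node)
  }
  best <- NULL
  for (j in seq_len(ncol(x))) {
    vals <- sort(unique(x[[j]]))
    if (length(vals) < 2) next
    for (t in (utils::head(vals, -1) + utils::tail(vals, -1)) / 2) {
      left <- x[[j]] <= t
      nl <- sum(left); nr <- sum(!left)
      if (nl < min_leaf || nr < min_leaf) next
      w <- (nl * oracle_gini(labels[left], levels_) +
              nr * oracle_gini(labels[!left], levels_)) / length(labels)
      dec <- g - w
      if (dec > 1e-12 && (is.null(best) || dec > best$dec + 1e-12)) {
        best <- list(j = j, t = t, dec = dec)
      }
    }
  }
  if (is.null(best)) return(node)
  node$leaf <- FALSE
  node$split_feature <- names(x)[best$j]
  node$threshold <- best$t
  left <- x[[best$j]] <= best$t
  node$left <- oracle_cart(x[left, , drop = FALSE], labels[left], levels_,
                           max_depth, gini_stop, min_leaf, depth + 1)
  node$right <- oracle_cart(x[!left, , drop = FALSE], labels[!left], levels_,
                            max_depth, gini_stop, min_leaf, depth + 1)
  node
}

# Flatten a pwv_surrogate into the oracle's nested-list shape for
# structural comparison.
surrogate_as_nested <- function(tree, id = 1L) {
  nd <- tree$nodes[tree$nodes$node_id == id, ]
  counts <- as.integer(unlist(nd[paste0("n_", tree$levels)]))
  node <- list(depth = nd$depth, gini = nd$gini, n = nd$n,
               counts = counts, majority = nd$majority, leaf = nd$is_leaf)
  if (!nd$is_leaf) {
    node$leaf <- FALSE
    node$split_feature <- nd$split_feature
    node$threshold <- nd$threshold
    node$left <- surrogate_as_nested(tree, nd$left_id)
    node$right <- surrogate_as_nested(tree, nd$right_id)
  }
  node
}

# Leaf id each row of x lands in, by walking the node table.
route_to_leaf <- function(tree, x) {
  nodes <- tree$nodes
  vapply(seq_len(nrow(x)), function(i) {
    id <- 1L
    repeat {
      nd <- nodes[nodes$node_id == id, ]
      if (nd$is_leaf) return(id)
      id <- if (x[i, nd$split_feature][[1]] <= nd$threshold) {
        nd$left_id
      } else {
        nd$right_id
      }
    }
  }, integer(1))
}

expect_same_tree <- function(fitted, oracle) {
  expect_equal(fitted$leaf, oracle$leaf)
  expect_equal(fitted$n, oracle$n)
  expect_equal(fitted$counts, oracle$counts)
  expect_equal(fitted$gini, oracle$gini, tolerance = 1e-12)
  expect_equal(fitted$majority, oracle$majority)
  if (!oracle$leaf && !fitted$leaf) {
    expect_equal(fitted$split_feature, oracle$split_feature)
    expect_equal(fitted$threshold, oracle$threshold, tolerance = 1e-12)
    expect_same_tree(fitted$left, oracle$left)
    expect_same_tree(fitted$right, oracle$right)
  }
}
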