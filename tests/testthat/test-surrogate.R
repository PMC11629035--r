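test_that("gini impurity matches its closed forms", {
  expect_equal(gini_impurity(c(10, 0, 0, 0, 0, 0)), 0)
  expect_equal(gini_impurity(c(5, 5)), 0.5)
  expect_equal(gini_impurity(rep(1, 6)), 1 - 6 * (1 / 6)^2)
  expect_error(gini_impurity(c(0, 0)), "positive sum")
  expect_error(gini_impurity(c(-1, 2)), "non-negative")
})

test_that("degenerate label sets give a single leaf", {
  x <- tibble::tibble(a = rnorm(10), b = rnorm(10))
  tr <- fit_surrogate(x, rep("ACEI", 10))
  expect_equal(nrow(tr$nodes), 1)
  expect_true(tr$nodes$is_leaf[1])
  expect_equal(tr$nodes$depth[1], 0)
  expect_equal(predict(tr, x), rep("ACEI", 10))
  lines <- render_tree(tr)
  expect_length(lines, 1)
})

test_that("a node at or below the impurity stop is not split", {
  # 90/10 mix: gini = 1 - .81 - .01 = 0.18 <= 0.20, perfectly separable
  x <- tibble::tibble(a = c(rep(0, 9), 1))
  labels <- c(rep("ACEI", 9), "ARB")
  tr <- fit_surrogate(x, labels, gini_stop = 0.20)
  expect_equal(nrow(tr$nodes), 1)
  expect_equal(tr$nodes$gini[1], 0.18, tolerance = 1e-12)
  # with a lower stop the same data is split
  tr2 <- fit_surrogate(x, labels, gini_stop = 0.05)
  expect_equal(nrow(tr2$nodes), 3)
})

test_that("the fitted tree equals the brute-force CART oracle", {
  withr::with_seed(123, {
    for (rep in 1:8) {
      n <- sample(10:30, 1)
      p <- sample(1:3, 1)
      # coarse integer features create plenty of threshold and split ties
      x <- tibble::as_tibble(
        matrix(sample(0:4, n * p, TRUE), n, p,
               dimnames = list(NULL, paste0("v", seq_len(p)))))
      labels <- sample(drug_classes()[1:3], n, TRUE)
      tr <- fit_surrogate(x, labels, max_depth = 10, gini_stop = 0.2)
      oracle <- oracle_cart(x, labels, tr$levels,
                            max_depth = 10, gini_stop = 0.2)
      expect_same_tree(surrogate_as_nested(tr), oracle)
    }
  })
})

test_that("structural invariants hold on a large fitted tree", {
  withr::with_seed(31, {
    x <- tibble::as_tibble(matrix(rnorm(500 * 6), 500, 6,
                                  dimnames = list(NULL, paste0("v", 1:6))))
    labels <- ifelse(x$v1 > 0, "ACEI",
                     ifelse(x$v2 > 0.5, "ARB",
                            sample(drug_classes(), 500, TRUE)))
  })
  tr <- fit_surrogate(x, labels, max_depth = 10, gini_stop = 0.2)
  nodes <- tr$nodes
  count_cols <- paste0("n_", tr$levels)
  for (i in seq_len(nrow(nodes))) {
    nd <- nodes[i, ]
    cc <- as.integer(unlist(nd[count_cols]))
    expect_equal(sum(cc), nd$n)
    expect_equal(gini_impurity(cc), nd$gini, tolerance = 1e-12)
    if (nd$is_leaf) {
      # every leaf satisfies a stopping condition
      expect_true(nd$gini <= 0.2 + 1e-12 || nd$depth == 10 ||
                    nd$n < 2)
    } else {
      l <- nodes[nodes$node_id == nd$left_id, ]
      r <- nodes[nodes$node_id == nd$right_id, ]
      expect_equal(l$n + r$n, nd$n)
      expect_equal(as.integer(unlist(l[count_cols])) +
                     as.integer(unlist(r[count_cols])), cc)
      # children strictly reduce the weighted impurity
      expect_lt((l$n * l$gini + r$n * r$gini) / nd$n, nd$gini)
      expect_lte(max(l$depth, r$depth), 10)
    }
  }
})

test_that("fidelity behaves like an agreement fraction", {
  withr::with_seed(37, {
    x <- tibble::as_tibble(matrix(rnorm(400 * 5), 400, 5,
                                  dimnames = list(NULL, paste0("v", 1:5))))
    labels <- ifelse(x$v1 + 0.5 * x$v2 > 0, "ACEI", "DIU_ARB")
    noisy <- labels
    flip <- sample(400, 60)
    noisy[flip] <- sample(drug_classes(), 60, TRUE)
  })
  # pure separable labels, unlimited impurity drive: exact imitation
  deep <- fit_surrogate(x, labels, max_depth = 10, gini_stop = 0)
  expect_equal(surrogate_fidelity(deep, x, labels), 1)
  # deeper trees imitate at least as well as shallow ones
  d10 <- fit_surrogate(x, noisy, max_depth = 10, gini_stop = 0.05)
  d3 <- fit_surrogate(x, noisy, max_depth = 3, gini_stop = 0.05)
  expect_gte(surrogate_fidelity(d10, x, noisy),
             surrogate_fidelity(d3, x, noisy))
  # label permutation leaves only the majority share learnable
  withr::with_seed(39, perm <- sample(noisy))
  base <- max(table(perm)) / length(perm)
  tr_perm <- fit_surrogate(x, perm, max_depth = 3, gini_stop = 0.2)
  expect_lt(abs(surrogate_fidelity(tr_perm, x, perm) - base), 0.15)
})

test_that("rendering truncates to the requested levels", {
  withr::with_seed(41, {
    x <- tibble::as_tibble(matrix(rnorm(300 * 4), 300, 4,
                                  dimnames = list(NULL, paste0("v", 1:4))))
    labels <- sample(drug_classes(), 300, TRUE)
  })
  tr <- fit_surrogate(x, labels, max_depth = 8, gini_stop = 0.1)
  for (lv in c(1, 3, 5)) {
    lines <- render_tree(tr, levels = lv)
    shown <- sum(!grepl("\\[\\.\\.\\.\\]", lines))
    expect_lte(shown, 2^lv - 1)
  }
  full <- render_tree(tr, levels = max(tr$nodes$depth) + 1)
  expect_equal(length(full), nrow(tr$nodes))
  dot <- tree_to_dot(tr)
  expect_match(dot, "^digraph")
  expect_s3_class(autoplot(tr, levels = 3), "ggplot")
  expect_error(predict(tr, x[, 1:2]), "Missing feature")
  gl <- glance(tr)
  expect_equal(gl$n_nodes, nrow(tidy(tr)))
})
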