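test_that("fitting is seed-reproducible and handles degenerate targets", {
  arm <- make_arm_dataset(n = 120, seed = 2)
  m1 <- fit_arm_model(arm, quick_hp(), seed = 5)
  m2 <- fit_arm_model(arm, quick_hp(), seed = 5)
  newx <- make_arm_dataset(n = 30, seed = 3)$x
  expect_identical(predict(m1, newx), predict(m2, newx))

  flat <- arm
  flat$y <- rep(1.5, length(flat$y))
  expect_warning(mc <- fit_arm_model(flat, quick_hp()), "Constant target")
  expect_equal(predict(mc, newx), rep(1.5, 30))
  expect_error(mdi_importance(mc), "Constant predictor")
})

test_that("predictions demand the training feature columns", {
  arm <- make_arm_dataset(n = 80, seed = 4)
  m <- fit_arm_model(arm, quick_hp())
  expect_error(predict(m, arm$x[, -1]), "missing feature")
})

test_that("impurity importance is normalized and finds the signal", {
  arm <- make_arm_dataset(n = 600, p = 10, informative = 1, noise = 0.05,
                          seed = 6)
  m <- fit_arm_model(arm, quick_hp(n_trees = 150), seed = 6)
  imp <- mdi_importance(m)
  expect_equal(sum(imp), 1, tolerance = 1e-9)
  expect_equal(names(which.max(imp)), "f1")
})

test_that("permutation importance scores unused features exactly zero", {
  arm <- make_arm_dataset(n = 200, p = 5, informative = 2, seed = 8,
                          constant_col = TRUE)
  m <- fit_arm_model(arm, quick_hp(), seed = 8)
  # a constant column is never split on; shuffling it changes nothing
  perm <- permutation_importance(m, arm$x, arm$y, n_repeats = 3, seed = 9)
  expect_identical(perm[["f_const"]], 0)
  expect_equal(names(which.max(perm)), "f1")
  p2 <- permutation_importance(m, arm$x, arm$y, n_repeats = 3, seed = 9)
  expect_identical(perm, p2)
  expect_error(permutation_importance(m, arm$x[1:10, ], arm$y), "differ")
})

test_that("consensus ranking matches an exhaustive sort on a hand table", {
  mdi <- c(a = 0.5, b = 0.3, c = 0.15, d = 0.05)
  perm <- c(a = 0.1, b = 0.4, c = 0.2, d = 0.0)
  tab <- importance_table(mdi, perm)
  # hand-computed mean ranks: a (1+3)/2=2, b (2+1)/2=1.5, c (3+2)/2=2.5, d 4
  expect_equal(tab$feature, c("b", "a", "c", "d"))
  expect_equal(tab$consensus_rank, 1:4)
  expect_equal(select_top_features(tab, k = 2), c("b", "a"))
  expect_equal(select_top_features(tab, k = 10), c("b", "a", "c", "d"))
  expect_equal(select_top_features(tab, k = 1, measure = "mdi"), "a")
  expect_equal(select_top_features(tab, k = 1, measure = "permutation"), "b")
  # vector interface sorts by score with name tie-break
  expect_equal(select_top_features(c(x = 1, y = 2, z = 1), k = 2),
               c("y", "x"))
})

test_that("reduced refits keep only the requested features", {
  arm <- make_arm_dataset(n = 150, p = 6, informative = 2, seed = 10)
  b <- refit_reduced(arm, c("f1", "f2"), quick_hp(), seed = 10)
  expect_s3_class(b, "pwv_arm_bundle")
  expect_equal(b$selected_features, c("f1", "f2"))
  expect_equal(length(predict(b, arm$x)), 150)
  # missing selected column is a contract violation
  expect_error(predict(b, arm$x[, "f1", drop = FALSE]), "f2")
  expect_error(refit_reduced(arm, character(0)), "Empty feature")
  expect_error(refit_reduced(arm, "nope"), "Unknown feature")
  b2 <- refit_reduced(arm, c("f1", "f2"), quick_hp(), seed = 10)
  expect_identical(predict(b, arm$x), predict(b2, arm$x))
})

test_that("counterfactual prediction returns the canonical n x 6 matrix", {
  sim <- generate_cohort(n = 360, seed = 12, noise_sd = 0.1)
  ad <- build_arm_datasets(filter_eligible(sim$cohort, 5))
  fits <- fit_arm_bundles(ad, hyperparams = quick_hp(), k_features = 5,
                          n_repeats = 2, seed = 12)
  X <- sim$cohort[feature_schema()$name]
  preds <- predict_all_arms(fits, X)
  expect_equal(dim(preds), c(360, 6))
  expect_equal(colnames(preds), drug_classes())
  expect_true(all(is.finite(preds)))
  expect_error(predict_all_arms(fits, X[, 1:3]), "missing feature")
})

test_that("the fit-select-refit chain is reproducible under one seed", {
  sim <- generate_cohort(n = 300, seed = 14, noise_sd = 0.1)
  ad <- build_arm_datasets(filter_eligible(sim$cohort, 5))
  f1 <- fit_arm_bundles(ad, hyperparams = quick_hp(), k_features = 4,
                        n_repeats = 2, seed = 3)
  f2 <- fit_arm_bundles(ad, hyperparams = quick_hp(), k_features = 4,
                        n_repeats = 2, seed = 3)
  expect_identical(purrr::map(f1$bundles, "selected_features"),
                   purrr::map(f2$bundles, "selected_features"))
  X <- sim$cohort[feature_schema()$name]
  expect_identical(predict_all_arms(f1, X), predict_all_arms(f2, X))
})

test_that("tidiers expose importance tables and per-arm summaries", {
  sim <- generate_cohort(n = 300, seed = 16, noise_sd = 0.1)
  ad <- build_arm_datasets(filter_eligible(sim$cohort, 5))
  fits <- fit_arm_bundles(ad, hyperparams = quick_hp(), k_features = 4,
                          n_repeats = 2, seed = 16)
  td <- tidy(fits)
  expect_equal(sum(td$selected), 4 * length(fits$bundles))
  expect_true(all(c("mdi_rank", "perm_rank", "consensus_rank") %in% names(td)))
  gl <- glance(fits)
  expect_equal(nrow(gl), length(fits$bundles))
  expect_true(all(gl$n_features == 4))
})
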