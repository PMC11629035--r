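test_that("identical seeds reproduce the cohort field for field", {
  a <- generate_cohort(n = 120, seed = 42)
  b <- generate_cohort(n = 120, seed = 42)
  expect_identical(a$cohort, b$cohort)
  expect_identical(a$truth$effects, b$truth$effects)
  c <- generate_cohort(n = 120, seed = 43)
  expect_false(identical(a$cohort, c$cohort))
})

test_that("arm and cohort proportions track the configured probabilities", {
  sim <- generate_cohort(n = 4000, seed = 5)
  probs <- default_assignment_probs()
  shares <- table(factor(sim$cohort$drug_class, drug_classes())) / 4000
  for (d in drug_classes()) {
    tol <- 4 * sqrt(probs[[d]] * (1 - probs[[d]]) / 4000)
    expect_lt(abs(shares[[d]] - probs[[d]]), tol)
  }
  csh <- table(factor(sim$cohort$cohort_id, cohort_labels())) / 4000
  expect_lt(abs(csh[["EVIDENT"]] - 81 / 194), 4 * sqrt(0.42 * 0.58 / 4000))
  # the printed 194-patient configuration populates all six arms
  small <- generate_cohort(n = 194, seed = 9)
  expect_setequal(unique(small$cohort$drug_class), drug_classes())
})

test_that("noiseless cohorts satisfy followup = baseline - g_d exactly", {
  sim <- generate_cohort(n = 150, noise_sd = 0, seed = 7)
  g <- sim$truth$effects
  idx <- cbind(seq_len(150), match(sim$cohort$drug_class, drug_classes()))
  expect_equal(sim$cohort$cfpwv_baseline - sim$cohort$cfpwv_followup,
               unname(g[idx]), tolerance = 1e-12)
  expect_equal(sim$cohort$bapwv_baseline - sim$cohort$bapwv_followup,
               unname(g[idx]), tolerance = 1e-12)
  # recomputing the effect functions from the truth reproduces the matrix
  g2 <- true_effect_matrix(sim$truth, sim$cohort)
  expect_equal(unname(g2), unname(g), tolerance = 1e-12)
})

test_that("the oracle policy is the brute-force per-patient argmax", {
  sim <- generate_cohort(n = 300, seed = 11)
  g <- sim$truth$effects
  brute <- apply(g, 1, function(row) drug_classes()[which.max(row)])
  expect_equal(sim$truth$oracle_policy$oracle_drug, unname(brute))
  expect_equal(sim$truth$oracle_policy$patient_id, sim$cohort$patient_id)
})

test_that("covariate marginals match the schema within Monte Carlo error", {
  n <- 3000
  sim <- generate_cohort(n = n, seed = 13)
  sch <- feature_schema()
  for (i in seq_len(nrow(sch))) {
    x <- sim$cohort[[sch$name[i]]]
    tol <- if (sch$kind[i] == "binary") {
      4 * sqrt(sch$mean[i] * (1 - sch$mean[i]) / n)
    } else {
      4 * sch$sd[i] / sqrt(n)
    }
    expect_lt(abs(mean(x) - sch$mean[i]), tol, label = sch$name[i])
  }
})

test_that("generator validates its configuration", {
  bad <- default_effect_config()
  bad$ACEI$modifiers <- c("not_a_covariate")
  expect_error(generate_cohort(n = 100, effect_config = bad, seed = 1),
               "unknown covariates")
  expect_error(generate_cohort(n = 5, seed = 1), "too small")
  expect_error(generate_cohort(n = 100, noise_sd = -1, seed = 1), "noise_sd")
})

test_that("baPWV transit-time formula matches hand arithmetic", {
  expect_equal(compute_bapwv(170, 0.08), 14.42, tolerance = 5e-4)
  expect_equal(compute_bapwv(162.5, 0.07), 15.84, tolerance = 5e-4)
  expect_lt(compute_bapwv(170, 1e6), 1e-3) # long transit time -> ~0 velocity
  expect_error(compute_bapwv(170, 0), "positive")
  expect_error(compute_bapwv(90, 0.08), "height")
})

test_that("missingness injection masks covariates at the requested rate", {
  sim <- generate_cohort(n = 1000, seed = 17)
  expect_identical(inject_missingness(sim$cohort, rate = 0), sim$cohort)
  m1 <- inject_missingness(sim$cohort, rate = 0.1, seed = 1)
  m2 <- inject_missingness(sim$cohort, rate = 0.1, seed = 1)
  expect_identical(m1, m2)
  cols <- feature_schema()$name
  frac <- mean(is.na(as.matrix(m1[cols])))
  expect_gt(frac, 0.09)
  expect_lt(frac, 0.11)
  # outcome and identity fields are never masked
  expect_false(anyNA(m1$cfpwv_baseline))
  expect_false(anyNA(m1$bapwv_followup))
  expect_false(anyNA(m1$drug_class))
  expect_error(inject_missingness(sim$cohort, rate = 1), "\\[0, 1\\)")
})

test_that("cohort CSV + truth sidecar round-trips", {
  dir <- withr::local_tempdir()
  sim <- generate_cohort(n = 80, seed = 19)
  write_cohort(sim, file.path(dir, "c"))
  back <- read_cohort(file.path(dir, "c"))
  expect_equal(as.data.frame(back$cohort), as.data.frame(sim$cohort),
               tolerance = 1e-12)
  expect_equal(unname(back$truth$effects), unname(sim$truth$effects),
               tolerance = 1e-12)
  expect_equal(back$truth$oracle_policy, sim$truth$oracle_policy)
})

test_that("EVIDENT covariate shift moves only the external cohort", {
  sim <- generate_cohort(n = 2000, seed = 23, cohort_shift_sd = 0.5)
  ref <- generate_cohort(n = 2000, seed = 23, cohort_shift_sd = 0)
  is_ev <- sim$cohort$cohort_id == "EVIDENT"
  expect_gt(mean(sim$cohort$age[is_ev]) - mean(ref$cohort$age[is_ev]), 2)
  expect_equal(sim$cohort$age[!is_ev], ref$cohort$age[!is_ev])
})
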