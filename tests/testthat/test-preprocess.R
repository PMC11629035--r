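test_that("eligibility filter drops OTHER and undersized arms", {
  cohort <- toy_cohort(c(rep("ACEI", 12), rep("OTHER", 3)))
  kept <- filter_eligible(cohort)
  expect_equal(nrow(kept), 12)
  expect_setequal(unique(kept$drug_class), "ACEI")

  # a group of exactly 10 is retained: the rule is strictly 'fewer than'
  cohort10 <- toy_cohort(c(rep("ARB", 10), rep("BB", 9)))
  kept10 <- filter_eligible(cohort10)
  expect_setequal(unique(kept10$drug_class), "ARB")

  # all arms large enough: only OTHER is removed, order preserved
  drugs <- c(rep(drug_classes(), each = 10), "OTHER")
  cohort_all <- toy_cohort(drugs)
  kept_all <- filter_eligible(cohort_all)
  expect_equal(kept_all$patient_id,
               cohort_all$patient_id[cohort_all$drug_class != "OTHER"])

  expect_error(filter_eligible(toy_cohort(rep("OTHER", 5))), "min_group_size")
})

test_that("median imputation fills gaps and is reusable and idempotent", {
  df <- tibble::tibble(a = c(1, 2, NA, 4), b = c(NA, 1, 1, 0))
  out <- impute_median(df)
  expect_equal(out$data$a, c(1, 2, 2, 4))
  expect_equal(out$medians[["a"]], 2)
  expect_equal(out$data$b[1], 1) # binary: majority value via the median

  clean <- tibble::tibble(a = 1:5 * 1.0)
  expect_identical(impute_median(clean)$data, clean)

  twice <- impute_median(out$data)
  expect_identical(twice$data, out$data)

  # reuse of training medians on held-out rows
  heldout <- tibble::tibble(a = c(NA, 10), b = c(0, NA))
  reused <- impute_median(heldout, medians = out$medians)
  expect_equal(reused$data$a, c(2, 10))

  # medians do not depend on row order
  shuffled <- df[c(3, 1, 4, 2), ]
  expect_equal(impute_median(shuffled)$medians, out$medians)

  expect_error(impute_median(tibble::tibble(a = c(NA_real_, NA_real_))), "a")
  expect_error(impute_median(heldout, medians = c(a = 2)), "b")
})

test_that("PWV standardization uses baseline population moments", {
  cohort <- toy_cohort(rep("ACEI", 3),
                       cf_base = c(8, 10, 12), ba_base = c(8, 10, 12),
                       cf_follow = c(10, 10, 10), ba_follow = c(10, 10, 10))
  std <- standardize_pwv(cohort)
  expect_equal(std$params$cf$mean, 10)
  expect_equal(std$params$cf$sd, 1.632993, tolerance = 1e-6)
  expect_equal(std$scores$cf_baseline_z, c(-1.224745, 0, 1.224745),
               tolerance = 1e-6)
  expect_equal(std$scores$cf_followup_z, c(0, 0, 0))

  # refitting on already-standardized values recovers mean 0, sd 1
  cohort2 <- cohort
  cohort2$cfpwv_baseline <- std$scores$cf_baseline_z
  cohort2$bapwv_baseline <- std$scores$ba_baseline_z
  std2 <- standardize_pwv(cohort2)
  expect_equal(std2$params$cf$mean, 0, tolerance = 1e-12)
  expect_equal(std2$params$cf$sd, 1, tolerance = 1e-12)

  flat <- toy_cohort(rep("ACEI", 3), cf_base = c(9, 9, 9))
  expect_error(standardize_pwv(flat), "Zero variance")
})

test_that("arm datasets partition the eligible patients with the stated target", {
  drugs <- rep(drug_classes(), each = 12)
  cohort <- toy_cohort(drugs)
  ad <- build_arm_datasets(cohort)
  expect_s3_class(ad, "pwv_arm_data")
  sizes <- purrr::map_int(ad$arms, ~ length(.x$y))
  expect_equal(sum(sizes), nrow(cohort))
  ids <- unlist(purrr::map(ad$arms, "patient_ids"))
  expect_setequal(ids, cohort$patient_id)
  expect_equal(anyDuplicated(ids), 0L)
  # every patient sits in the arm of the drug they took
  for (d in names(ad$arms)) {
    expect_setequal(ad$arms[[d]]$patient_ids,
                    cohort$patient_id[cohort$drug_class == d])
  }
})

test_that("the change target averages the two standardized reductions", {
  # construct baselines/followups whose z-changes are 0.8 in both modalities
  cohort <- toy_cohort(rep("ACEI", 3),
                       cf_base = c(8, 10, 12), ba_base = c(8, 10, 12))
  std <- standardize_pwv(cohort)
  sd_cf <- std$params$cf$sd
  sd_ba <- std$params$ba$sd
  cohort$cfpwv_followup <- cohort$cfpwv_baseline - 0.8 * sd_cf
  cohort$bapwv_followup <- cohort$bapwv_baseline - 0.8 * sd_ba
  ad <- build_arm_datasets(cohort)
  expect_equal(ad$arms$ACEI$y, rep(0.8, 3), tolerance = 1e-12)

  ad_cf <- build_arm_datasets(cohort, modality = "cf")
  expect_equal(ad_cf$arms$ACEI$y, rep(0.8, 3), tolerance = 1e-12)
})

test_that("patients missing outcome PWV are dropped, never imputed", {
  cohort <- toy_cohort(rep("ACEI", 12))
  cohort$cfpwv_followup[c(2, 5)] <- NA
  expect_warning(ad <- build_arm_datasets(cohort), "2 patient")
  expect_equal(length(ad$arms$ACEI$y), 10)
  expect_setequal(ad$excluded, cohort$patient_id[c(2, 5)])
})

test_that("unknown drug classes are rejected", {
  cohort <- toy_cohort(c(rep("ACEI", 3), "CCB"))
  expect_error(build_arm_datasets(cohort), "Unknown drug class")
})

test_that("training parameters reapply bit-identically to training rows", {
  sim <- generate_cohort(n = 150, seed = 31)
  cohort <- inject_missingness(sim$cohort, 0.1, seed = 31)
  ad1 <- build_arm_datasets(filter_eligible(cohort, 2))
  ad2 <- build_arm_datasets(filter_eligible(cohort, 2),
                            standardization = ad1$standardization,
                            medians = ad1$medians)
  for (d in names(ad1$arms)) {
    expect_identical(ad1$arms[[d]]$x, ad2$arms[[d]]$x)
    expect_identical(ad1$arms[[d]]$y, ad2$arms[[d]]$y)
  }
})
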