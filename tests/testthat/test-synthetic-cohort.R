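test_that("cohort dimensions, exact label counts and determinism hold", {
  cfg <- cohort_config(seed = 7)          # reference-cohort defaults
  d <- generate_feature_table(cfg)
  expect_equal(dim(d$features), c(51, 854))
  expect_equal(sum(d$labels$complete_response), 14)     # round(14/51 * 51)
  expect_equal(ncol(d$clinical), 12)
  expect_equal(ncol(d$lirads), 19)
  expect_equal(nrow(d$clinical), 51)
  expect_false(anyNA(d$features))

  d2 <- generate_feature_table(cohort_config(seed = 7))
  expect_identical(d$features, d2$features)
  expect_identical(d$labels, d2$labels)
  d3 <- generate_feature_table(cohort_config(seed = 8))
  expect_false(identical(d$features, d3$features))

  # exact positive counts across prevalences
  for (prev in c(14 / 51, 29 / 51, 0.1, 0.5)) {
    dd <- generate_feature_table(cohort_config(n_patients = 40,
                                               n_radiomics = 5,
                                               prevalence = prev, seed = 1))
    expect_equal(sum(dd$labels$complete_response), round(prev * 40))
  }
  expect_error(cohort_config(n_patients = 10, prevalence = 0.01),
               "degenerate")
  expect_error(cohort_config(planted = data.frame(index = c(2, 2),
                                                  delta = c(1, 1))),
               "duplicate")
})

test_that("objective-response configs allocate consistent mRECIST categories", {
  d <- generate_feature_table(cohort_config(prevalence = 29 / 51,
                                            endpoint = "or", seed = 3))
  expect_equal(sum(d$labels$objective_response), 29)
  expect_true(all(d$labels$category[d$labels$objective_response == 1] %in%
                    c("CR", "PR")))
  expect_true(all(d$labels$category[d$labels$objective_response == 0] %in%
                    c("SD", "PD")))
})

test_that("planted effect calibrates to the closed-form Gaussian AUC", {
  # single feature with delta separation: population AUC = Phi(delta/sqrt(2))
  cfg <- cohort_config(n_patients = 5000, n_radiomics = 10, prevalence = 0.3,
                       planted = data.frame(index = 3, delta = 2), seed = 11)
  d <- generate_feature_table(cfg)
  auc <- roc_auc(d$features[, 3], d$labels$complete_response)$auc
  expect_equal(auc, stats::pnorm(2 / sqrt(2)), tolerance = 0.02)
  # unplanted neighbors stay near chance
  auc_noise <- roc_auc(d$features[, 9], d$labels$complete_response)$auc
  expect_lt(abs(auc_noise - 0.5), 0.05)
})

test_that("equicorrelated blocks have the configured correlation structure", {
  d <- generate_feature_table(cohort_config(n_patients = 4000,
                                            n_radiomics = 16,
                                            block_size = 8, rho = 0.6,
                                            prevalence = 0.5, seed = 5))
  cc <- stats::cor(d$features)
  within <- cc[1, 2:8]
  across <- cc[1, 9:16]
  expect_equal(mean(within), 0.6, tolerance = 0.05)
  expect_lt(max(abs(across)), 0.1)
})

test_that("clinical labs match target medians and LI-RADS columns are binary", {
  cfg <- cohort_config(n_patients = 10000, n_radiomics = 2,
                       prevalence = 0.3, seed = 13)
  aux <- generate_clinical_lirads(cfg)
  expect_equal(stats::median(aux$clinical$platelet_count), 115.1,
               tolerance = 0.1)          # 10% relative at n = 1e4
  expect_true(all(aux$clinical$albumin > 0))
  binaries <- vapply(aux$lirads[-1], function(v) all(v %in% 0:1), logical(1))
  expect_true(all(binaries))
  # Bernoulli rates within binomial range of targets
  expect_equal(mean(aux$lirads$nonrim_aphe), 49 / 51, tolerance = 0.02)
  bad <- cohort_config(n_patients = 20, n_radiomics = 2, prevalence = 0.3)
  expect_error(generate_clinical_lirads(bad, lirads_rates = c(x = 1.5)),
               "\\[0, 1\\]")
})

test_that("lesion volumes are deterministic, well-masked and calibrated", {
  vm <- generate_lesion_volume(shape = c(27, 27, 27), spacing = c(1, 1, 1),
                               radius = 10, seed = 3)
  expect_equal(sum(vm$mask), 4 / 3 * pi * 10^3, tolerance = 0.05)
  vm2 <- generate_lesion_volume(shape = c(27, 27, 27), spacing = c(1, 1, 1),
                                radius = 10, seed = 3)
  expect_identical(vm$intensities, vm2$intensities)

  flat <- generate_lesion_volume(shape = c(15, 15, 15), radius = 5,
                                 texture = list(mean = 50, sd = 0, scale = 2),
                                 seed = 1)
  vals <- flat$intensities[flat$mask == 1]
  expect_equal(unname(first_order_features(vals)["variance"]), 0)
  expect_error(generate_lesion_volume(shape = c(10, 10, 10), radius = 20),
               "too large")
})

test_that("cohort CSV round-trip preserves tables", {
  d <- generate_feature_table(cohort_config(n_patients = 12, n_radiomics = 6,
                                            prevalence = 0.25, seed = 2))
  dir <- withr::local_tempdir()
  write_cohort_csv(d, dir)
  expect_true(all(file.exists(file.path(dir, c("features.csv", "clinical.csv",
                                               "lirads.csv", "labels.csv")))))
  back <- read_cohort_csv(dir)
  expect_equal(unname(back$features), unname(d$features), tolerance = 1e-12)
  expect_equal(colnames(back$features), colnames(d$features))
  expect_equal(back$labels$category, d$labels$category)
})

test_that("NIfTI image/mask round-trip preserves the volume", {
  vm <- generate_lesion_volume(shape = c(12, 12, 12), radius = 4, seed = 5)
  dir <- withr::local_tempdir()
  ip <- file.path(dir, "img.nii.gz"); mp <- file.path(dir, "msk.nii.gz")
  write_volume_nifti(vm, ip, mp)
  back <- read_volume_nifti(ip, mp)
  expect_equal(back$intensities, vm$intensities, tolerance = 1e-6)
  expect_equal(back$mask, vm$mask)
  expect_equal(unname(back$spacing), vm$spacing, tolerance = 1e-6)
})
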