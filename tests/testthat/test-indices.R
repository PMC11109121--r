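test_that("growth rate is the relative area increase from day 1", {
  expect_equal(growthRate(100, 300), 2)
  expect_equal(growthRate(150, 150), 0)
  expect_equal(growthRate(200, 100), -0.5)
  expect_error(growthRate(0, 100), "mean_area_day1")
})

test_that("cohort Z-scores use the sample SD and are exact normalisers", {
  expect_equal(zscore(c(0.2, 0.4, 0.6)), c(-1, 0, 1))
  expect_error(zscore(c(5, 5, 5), what = "auc[afatinib]"),
               "zero variance in auc\\[afatinib\\]")
  expect_error(zscore(1), "n >= 2")
  set.seed(2)
  x <- rnorm(25)
  z <- zscore(x)
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sd(z), 1, tolerance = 1e-12)
  zp <- zscore(x, "population")
  expect_equal(sqrt(mean((zp - mean(zp))^2)), 1, tolerance = 1e-12)
})

test_that("CODRP distance from the reference point", {
  expect_equal(codrpDistance(-4.5, -4.5), 0)
  expect_equal(codrpDistance(0, 0), 4.5 * sqrt(2), tolerance = 1e-6)
  expect_equal(codrpDistance(-1.5, 0.5), sqrt(3^2 + 5^2), tolerance = 1e-6)
  expect_error(codrpDistance(NA, 0), "non-finite")
  expect_error(codrpDistance(0, 0, reference_z = 1), "reference_z")
  # strictly increasing in each coordinate above the reference
  z <- seq(-4, 4, by = 0.5)
  expect_true(all(diff(codrpDistance(z, 0)) > 0))
  expect_true(all(diff(codrpDistance(0, z)) > 0))
})

test_that("classification at the cutoff is inclusive-sensitive", {
  expect_identical(classifyCall(-0.5), "sensitive")
  expect_identical(classifyCall(0.3), "resistant")
  expect_identical(classifyCall(-0.17), "sensitive")  # tie rule
  expect_identical(classifyCall(c(-1, 0), cutoff = 0), c("sensitive", "sensitive"))
  expect_error(classifyCall(Inf), "non-finite")
})

test_that("per-drug CODRP indexing matches a monotone map of distances", {
  set.seed(4)
  rec <- data.frame(patient_id = sprintf("P%d", 1:6), drug = "d",
                    auc = runif(6), growth_rate = rnorm(6, 1, 0.4))
  idx <- codrpIndex(rec)
  expect_equal(order(idx$codrp_z), order(idx$codrp_distance))
  expect_equal(idx$codrp_z, zscore(idx$codrp_distance))
  # zero-variance distances propagate as an error
  rec2 <- data.frame(patient_id = c("a", "b"), drug = "d",
                     auc = c(1, 2), growth_rate = c(2, 1))
  expect_error(codrpIndex(rec2), "zero variance in codrp_distance")
  expect_error(codrpIndex(rec[1, ]), ">= 2 patients")
})

test_that("Z-scoring is per drug, never pooled across drugs", {
  set.seed(9)
  one <- data.frame(patient_id = sprintf("P%d", 1:5), drug = "d1",
                    auc = runif(5), growth_rate = rnorm(5, 1, 0.3))
  two <- one
  two$drug <- "d2"
  two$auc <- two$auc + 5          # wildly different scale on the other drug
  idx <- codrpIndex(rbind(one, two))
  expect_equal(idx$codrp_z[idx$drug == "d1"], idx$codrp_z[idx$drug == "d2"],
               tolerance = 1e-12)
})

test_that("cohort row order does not change per-patient indices", {
  set.seed(5)
  rec <- data.frame(patient_id = sprintf("P%d", 1:8), drug = "d",
                    auc = runif(8), growth_rate = rnorm(8, 1, 0.4))
  idx1 <- codrpIndex(rec)
  perm <- sample(8)
  idx2 <- codrpIndex(rec[perm, ])
  m <- match(idx1$patient_id, idx2$patient_id)
  expect_equal(idx1$codrp_z, idx2$codrp_z[m], tolerance = 1e-12)
  expect_identical(idx1$call_codrp, idx2$call_codrp[m])
})

test_that("adding a constant to every AUC changes nothing downstream", {
  set.seed(6)
  rec <- data.frame(patient_id = sprintf("P%d", 1:7), drug = "d",
                    auc = runif(7), growth_rate = rnorm(7, 1, 0.4))
  idx1 <- codrpIndex(rec)
  rec$auc <- rec$auc + 0.3
  idx2 <- codrpIndex(rec)
  expect_equal(idx1$z_auc, idx2$z_auc, tolerance = 1e-12)
  expect_equal(idx1$codrp_z, idx2$codrp_z, tolerance = 1e-12)
  expect_identical(idx1$call_codrp, idx2$call_codrp)
})

test_that("without growth heterogeneity the CODRP index reduces to the AUC index", {
  set.seed(8)
  rec <- data.frame(patient_id = sprintf("P%d", 1:10), drug = "d",
                    auc = runif(10),
                    growth_rate = 0.5 + 1e-9 * rnorm(10))
  expect_warning(idx <- codrpIndex(rec), "reduces to the AUC index")
  expect_equal(idx$codrp_z, idx$z_auc, tolerance = 1e-15)
  expect_identical(idx$call_codrp, idx$call_auc)
})

test_that("computeIndices joins plate-derived AUCs with growth rates", {
  sim <- simulateCohort(simConfig(n_patients = 6, replicate_cv = 0,
                                  growth_auc_corr = 0, seed = 21))
  idx <- computeIndices(sim$plate, sim$growth)
  expect_identical(nrow(idx), 6L)
  expect_true(all(c("z_auc", "z_growth", "codrp_distance", "codrp_z",
                    "call_codrp", "call_auc", "call") %in% names(idx)))
  expect_identical(idx$call, idx$call_codrp)
  idx2 <- computeIndices(sim$plate, sim$growth, mode = "auc_only")
  expect_identical(idx2$call, idx2$call_auc)
  expect_error(computeIndices(sim$plate, sim$growth[-1, ]),
               "lacks growth rates")
})
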