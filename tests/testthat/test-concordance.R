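test_that("packaged afatinib CODRP calls give the published confusion counts", {
  coh <- fixture_cohort()
  sc <- screeningCalls(coh)
  cm <- buildConfusion(sc[sc$mode == "codrp", ], adjudications(coh),
                       "afatinib", mode = "codrp")
  expect_identical(c(cm@tp, cm@fn, cm@tn, cm@fp, cm@excluded),
                   c(6L, 1L, 7L, 0L, 0L))
  expect_equal(sensitivity(cm), 600 / 7, tolerance = 1e-12)
  expect_equal(specificity(cm), 100)
})

test_that("degenerate confusion inputs behave", {
  coh <- fixture_cohort()
  empty <- data.frame(patient_id = character(), call = character())
  cm0 <- buildConfusion(empty, adjudications(coh), "afatinib")
  expect_identical(c(cm0@tp, cm0@fn, cm0@tn, cm0@fp, cm0@excluded),
                   rep(0L, 5))
  expect_error(sensitivity(cm0), "undefined metric")
  expect_error(specificity(cm0), "undefined metric")
  expect_error(accuracy(cm0), "undefined metric")

  one <- data.frame(patient_id = "200", call = "sensitive")
  cm1 <- buildConfusion(one, adjudications(coh), "afatinib")
  expect_identical(c(cm1@tp, cm1@fn, cm1@tn, cm1@fp), c(1L, 0L, 0L, 0L))

  # a call without any clinical adjudication is excluded with a warning
  ghost <- data.frame(patient_id = c("200", "999"),
                      call = c("sensitive", "sensitive"))
  expect_warning(cmg <- buildConfusion(ghost, adjudications(coh), "afatinib"),
                 "no clinical adjudication")
  expect_identical(cmg@excluded, 1L)
})

test_that("not-evaluable patients never enter the denominators", {
  coh <- fixture_cohort()
  sc <- screeningCalls(coh)
  # third-generation screen: clinical lines are osimertinib or lazertinib
  cm <- suppressWarnings(
    buildConfusion(sc[sc$mode == "codrp", ], adjudications(coh),
                   "osimertinib",
                   clinical_drug = c("osimertinib", "lazertinib")))
  expect_identical(cm@tp + cm@fn + cm@tn + cm@fp + cm@excluded, 14L)
  # #263 (NE) plus the eight patients with no third-generation line
  expect_identical(cm@excluded, 9L)
})

test_that("swapping the positive-class convention swaps the two metrics", {
  coh <- fixture_cohort()
  sc <- screeningCalls(coh)[screeningCalls(coh)$mode == "codrp", ]
  adj <- adjudications(coh)
  cm <- buildConfusion(sc, adj, "afatinib")

  flip <- function(x) ifelse(x == "sensitive", "resistant",
                             ifelse(x == "resistant", "sensitive", x))
  sc2 <- sc; sc2$call <- flip(sc2$call)
  adj2 <- adj; adj2$adjudicated <- flip(adj2$adjudicated)
  cm2 <- buildConfusion(sc2, adj2, "afatinib")
  expect_equal(sensitivity(cm2), specificity(cm))
  expect_equal(specificity(cm2), sensitivity(cm))
})

test_that("mode comparison isolates the four AUC-discordant patients", {
  coh <- fixture_cohort()
  cmp <- compareIndices(screeningCalls(coh), adjudications(coh), "afatinib")
  expect_identical(cmp$auc$discordant, c("240", "266", "278", "331"))
  expect_identical(cmp$codrp$discordant, "331")
  expect_equal(cmp$delta$sensitivity_pct, 600 / 7 - 500 / 7,
               tolerance = 1e-12)
  expect_equal(cmp$delta$specificity_pct, 100 - 500 / 7, tolerance = 1e-12)
  # identical calls in both modes leave no delta
  sc <- screeningCalls(coh)
  sc$call[sc$mode == "auc"] <-
    sc$call[sc$mode == "codrp"][match(sc$patient_id[sc$mode == "auc"],
                                      sc$patient_id[sc$mode == "codrp"])]
  cmp0 <- compareIndices(sc[sc$drug == "afatinib", ], adjudications(coh),
                         "afatinib")
  expect_equal(cmp0$delta$sensitivity_pct, 0)
  expect_identical(cmp0$codrp$discordant, cmp0$auc$discordant)
})

test_that("on a simulated cohort CODRP concordance is not below AUC-only", {
  sim <- simulateCohort(simConfig(n_patients = 100, seed = 1))
  idx <- computeIndices(sim$plate, sim$growth)
  m <- merge(idx, sim$truth, by = "patient_id")
  acc_codrp <- mean(m$call_codrp == m$true_class)
  acc_auc <- mean(m$call_auc == m$true_class)
  expect_gte(acc_codrp, acc_auc)
})

test_that("concordance report carries counts, metrics and discordants", {
  coh <- fixture_cohort()
  sc <- screeningCalls(coh)
  rep <- suppressWarnings(
    concordanceReport(sc, adjudications(coh),
                      drug_map = list(afatinib = "afatinib")))
  r <- rep$afatinib$codrp
  expect_identical(r$counts, list(tp = 6L, fn = 1L, tn = 7L, fp = 0L,
                                  excluded = 0L))
  expect_equal(r$sensitivity_pct_reported, 85.7)
  expect_equal(r$specificity_pct_reported, 100)
  expect_identical(r$discordant, "331")
  expect_equal(rep$afatinib$auc$sensitivity_pct, 500 / 7, tolerance = 1e-12)
})
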