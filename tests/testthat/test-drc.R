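test_that("dilution series arithmetic and validation", {
  expect_equal(makeDilutionSeries(50, 3, 7),
               50 / 3^(0:6), tolerance = 1e-12)
  expect_equal(makeDilutionSeries(10, 2, 3), c(10, 5, 2.5))
  expect_error(makeDilutionSeries(50, 3, 1), "n_points")
  expect_error(makeDilutionSeries(50, 1, 7), "fold")
  expect_error(makeDilutionSeries(-1, 3, 7), "top_conc")
})

test_that("viability is normalised to the DMSO control mean", {
  cc <- makeDilutionSeries(10, 2, 3)
  p <- make_profile(cc, list(c(200, 200), c(200), c(200, 200)), c(150, 250))
  expect_equal(unname(normalizeViability(p)), c(1, 1, 1))

  p0 <- make_profile(cc, list(0, 0, 0), c(100, 300))
  expect_equal(unname(normalizeViability(p0)), c(0, 0, 0))

  p2 <- make_profile(cc, list(c(80, 100, 120), c(50), c(10)), 200)
  expect_equal(unname(normalizeViability(p2)), c(0.5, 0.25, 0.05))

  pneg <- make_profile(cc, list(1, 1, 1), c(0, 0))
  expect_error(normalizeViability(pneg), "control error")
})

test_that("4PL fit recovers noiseless generating parameters", {
  cc <- makeDilutionSeries(50, 3, 7)
  for (par in list(c(1, 0, 0.5, 1), c(1, 0.2, 0, 2), c(0.9, 0.1, -0.5, 1.5))) {
    v <- fourPLViability(cc, par[1], par[2], par[3], par[4])
    f <- fitFourPL(cc, v)
    expect_false(f@fallbackUsed)
    expect_true(f@converged)
    expect_equal(c(f@top, f@bottom, f@log10EC50, f@hill), par,
                 tolerance = 1e-6)
  }
})

test_that("noisy 4PL fit stays near the generating midpoint", {
  cc <- makeDilutionSeries(50, 3, 7)
  set.seed(1)
  v <- fourPLViability(cc, 1, 0.2, 0, 2) * (1 + rnorm(7, 0, 0.05))
  f <- fitFourPL(cc, v)
  expect_false(f@fallbackUsed)
  expect_lt(abs(f@log10EC50 - 0), 0.15)
})

test_that("flat or degenerate data fall back to the raw trapezoid", {
  cc <- makeDilutionSeries(50, 3, 7)
  f <- fitFourPL(cc, rep(1, 7))
  expect_true(f@fallbackUsed)
  expect_equal(computeAUC(f, cc, rep(1, 7))$auc, 1.0)
  expect_identical(computeAUC(f, cc, rep(1, 7))$method, "trapezoid_raw")
  # a dose-response that rises with dose is not trusted either
  f2 <- fitFourPL(cc, seq(1, 0.2, length.out = 7))
  expect_true(f2@fallbackUsed)
  expect_error(fitFourPL(c(1, 1), c(0.5, 0.6)), "distinct concentrations")
  expect_error(predictViability(f, cc), "fallback")
})

test_that("normalised AUC spans [0, 1] with the expected anchor values", {
  cc <- makeDilutionSeries(50, 3, 7)
  fb <- fitFourPL(cc, rep(1, 7))  # fallback carrier for raw-curve AUCs
  expect_equal(computeAUC(fb, cc, rep(1, 7))$auc, 1)
  expect_equal(computeAUC(fb, cc, rep(0, 7))$auc, 0)
  # midpoint of a symmetric log grid halves the area
  lmid <- mean(log10(range(cc)))
  f <- fitFourPL(cc, fourPLViability(cc, 1, 0, lmid, 1.3))
  expect_equal(computeAUC(f, cc)$auc, 0.5, tolerance = 1e-6)
  expect_error(computeAUC(f, 50), "distinct concentrations")
})

test_that("quadrature AUC matches a dense trapezoid oracle", {
  cc <- makeDilutionSeries(50, 3, 7)
  set.seed(7)
  for (i in 1:20) {
    f <- methods::new("FourPL", top = runif(1, 0.8, 1.4),
                      bottom = runif(1, 0, 0.4) * 0.5,
                      log10EC50 = runif(1, -1.5, 2),
                      hill = runif(1, 0.5, 5),
                      converged = TRUE, fallbackUsed = FALSE)
    f@bottom <- min(f@bottom, f@top)
    a <- computeAUC(f, cc)$auc
    expect_equal(a, oracle_trapz_auc(f, min(cc), max(cc)), tolerance = 1e-6)
    expect_gte(a, 0); expect_lte(a, 1)
  }
})

test_that("pointwise-larger viability never yields a smaller AUC", {
  cc <- makeDilutionSeries(50, 3, 7)
  fb <- fitFourPL(cc, rep(1, 7))
  set.seed(11)
  for (i in 1:50) {
    y <- runif(7, -0.2, 1.3)
    y2 <- y + runif(7, 0, 0.5)
    expect_gte(computeAUC(fb, cc, y2)$auc, computeAUC(fb, cc, y)$auc)
    a <- computeAUC(fb, cc, y)$auc
    expect_gte(a, 0); expect_lte(a, 1)
  }
})

test_that("replicate order does not affect normalisation or AUC", {
  cc <- makeDilutionSeries(50, 3, 7)
  set.seed(3)
  reps <- lapply(fourPLViability(cc, 1, 0, 0.3, 1.2),
                 function(v) 1e4 * v * (1 + rnorm(3, 0, 0.1)))
  p1 <- make_profile(cc, reps, c(1e4, 1.1e4, 0.9e4))
  p2 <- make_profile(cc, lapply(reps, rev), c(0.9e4, 1.1e4, 1e4))
  expect_equal(normalizeViability(p1), normalizeViability(p2))
})

test_that("a plate table is screened into per-profile AUC rows", {
  cc <- makeDilutionSeries(50, 3, 7)
  sim <- simulateCohort(simConfig(n_patients = 4, replicate_cv = 0,
                                  growth_auc_corr = 0, seed = 5))
  res <- screenAUC(sim$plate)
  expect_identical(nrow(res), 4L)
  expect_true(all(res$auc >= 0 & res$auc <= 1))
  expect_equal(sort(res$patient_id), sort(sim$truth$patient_id))
})
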