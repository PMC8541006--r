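mkTac <- function(times, act, roi = "liver") timeActivityCurve(times, act, roi)

test_that("%ID/g normalisation follows its defining identities", {
  t <- seq(0, 60, 5)
  tc <- mkTac(t, rep(4 / 25, length(t)))          # activity = dose/BW
  expect_equal(normalizeToPidG(tc, dose = 4, bodyWeight = 25)@activities,
               rep(100, length(t)))
  expect_equal(normalizeToPidG(mkTac(t, rep(0, length(t))), 4, 25)@activities,
               rep(0, length(t)))
  a <- runif(length(t))
  one <- normalizeToPidG(mkTac(t, a), dose = 4, bodyWeight = 25)
  two <- normalizeToPidG(mkTac(t, a), dose = 4, bodyWeight = 50)
  expect_equal(two@activities, 2 * one@activities)
  # the per-gram-of-dose convention drops the body-weight factor
  pg <- normalizeToPidG(mkTac(t, a), 4, 25, convention = "per_g")
  expect_equal(pg@activities, 100 * a / 4)
  expect_error(normalizeToPidG(tc, dose = 0, bodyWeight = 25), "dose")
})

test_that("windowed trapezoid integration matches closed forms", {
  expect_equal(integrateWindow(0:10, rep(1, 11), 0, 10), 10)
  expect_equal(integrateWindow(0:10, (0:10) / 10, 0, 10), 5)
  t <- seq(0, 60, 0.1)
  expect_lt(abs(integrateWindow(t, exp(-t), 0, 60) - (1 - exp(-60))), 1e-3)
  # off-grid endpoints are linearly interpolated
  expect_equal(integrateWindow(0:10, (0:10) / 10, 2.5, 7.5),
               (7.5^2 - 2.5^2) / 20)
  expect_error(integrateWindow(0:10, rep(1, 11), -1, 5), "support")
  expect_error(integrateWindow(0:10, rep(1, 11), 5, 11), "support")
})

test_that("pre + post windows add exactly to the full integral", {
  set.seed(4)
  t <- seq(0, 60, 0.5)
  for (i in 1:5) {
    v <- runif(length(t))
    expect_identical(integrateWindow(t, v, 0, 10) + integrateWindow(t, v, 10, 60),
                     integrateWindow(t, v, 0, 60))
  }
})

test_that("uptake metrics: symmetry, zero glycemia, and scale invariance", {
  t <- seq(0, 60, 0.5)
  base <- exp(-t / 30)
  curves <- list(liver = mkTac(t, base, "liver"),
                 visceral_fat = mkTac(t, base, "visceral_fat"),
                 gut = mkTac(t, 2 * base, "gut"))
  up <- computeUptakeMetrics(curves, glycemia = 7)
  expect_equal(up$vf_over_liver, 1)
  expect_equal(up$gut_over_liver, 2)
  expect_equal(up$vf_over_liver * up$liver_over_vf, 1)
  expect_equal(up$gut_over_liver * up$liver_over_gut, 1)
  expect_equal(up$gu_pre_liver, up$ge_pre_liver * 7)

  up0 <- computeUptakeMetrics(curves, glycemia = 0)
  expect_equal(up0$gu_pre_liver, 0)
  expect_true(is.na(up0$vf_over_liver))
  expect_error(computeUptakeMetrics(curves[c("liver", "gut")], 7), "absent")

  # multiplying dose and all activities by one constant leaves %ID/g alone
  sim <- simulateTracerKinetics(kineticParams(), dose = 4)
  sim2 <- simulateTracerKinetics(kineticParams(), dose = 40)
  for (roi in c("liver", "visceral_fat", "gut")) {
    p1 <- normalizeToPidG(tacs(sim)[[roi]], 4, 25)
    p2 <- normalizeToPidG(tacs(sim2)[[roi]], 40, 25)
    expect_equal(p1@activities, p2@activities, tolerance = 1e-12)
  }
})

test_that("systemic metrics follow their definitions", {
  t <- seq(0, 60, 0.5)
  blood <- mkTac(t, rep(2 / 60, length(t)), "blood")  # integral 2 MBq*min/mL
  sm <- computeSystemicMetrics(blood, dose = 10, glycemia = 5,
                               bodyWeight = 25)
  expect_equal(sm$clearance_mL_min, 5)
  expect_equal(sm$egp_umol_min_g, 1)
  expect_equal(sm$blood_fraction_0_10, 10 / 60)

  lateOnly <- mkTac(t, ifelse(t <= 10, 0, 1), "blood")
  expect_equal(computeSystemicMetrics(lateOnly, 10, 5, 25)$blood_fraction_0_10,
               0, tolerance = 1e-6)
  zero <- mkTac(t, rep(0, length(t)), "blood")
  expect_error(computeSystemicMetrics(zero, 10, 5, 25), "clearance undefined")
})

test_that("quantified uptake matches the analytic compartment solution", {
  params <- kineticParams()
  sim <- simulateTracerKinetics(params, dose = 4,
                                volumes = defaultRoiVolumes(25))
  pid <- lapply(tacs(sim), normalizeToPidG, dose = 4, bodyWeight = 25)
  up <- computeUptakeMetrics(pid[c("liver", "visceral_fat", "gut")],
                             glycemia = 7)
  an <- analyticAmounts(params, 4, seq(0, 60, 0.5))
  vols <- defaultRoiVolumes(25)
  for (org in c("liver", "visceral_fat", "gut")) {
    conc <- an[[org]] / vols[[org]] * 100 * 25 / 4
    ref <- (integrateWindow(seq(0, 60, 0.5), conc, 0, 10) +
            integrateWindow(seq(0, 60, 0.5), conc, 10, 60)) * 7
    got <- up[[paste0("gu_pre_", org)]] + up[[paste0("gu_post_", org)]]
    expect_lt(abs(got / ref - 1), 0.005)
  }
})

test_that("the default noise-free cohort keeps blood exposure near 4%", {
  coh <- generateCohort(seed = 2, noiseFree = TRUE, withTaxa = FALSE)
  met <- cohortMetrics(coh)
  expect_lt(abs(mean(met$blood_fraction_0_10) - 0.04), 0.01)
})
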