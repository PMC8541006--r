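test_that("the default design emits 38 subjects in strata 11/8/10/9", {
  coh <- generateCohort(seed = 1, simulateTacs = FALSE, withTaxa = FALSE)
  s <- subjects(coh)
  expect_equal(nrow(s), 38)
  tab <- table(s$age_group, s$maternal_diet)
  expect_equal(tab["weaning", "ND"], 11)
  expect_equal(tab["weaning", "HFD"], 8)
  expect_equal(tab["adult", "ND"], 10)
  expect_equal(tab["adult", "HFD"], 9)
  expect_true(all(s$body_weight_g > 0 & s$injected_dose_MBq > 0))
})

test_that("cohorts are deterministic given the seed, and seeds split stably", {
  a <- generateCohort(seed = 42, simulateTacs = FALSE)
  b <- generateCohort(seed = 42, simulateTacs = FALSE)
  expect_identical(subjects(a), subjects(b))
  expect_identical(kineticRates(a), kineticRates(b))
  expect_identical(histology(a), histology(b))
  expect_identical(abundances(taxa(a)), abundances(taxa(b)))

  # enlarging one stratum must not reshuffle the other subjects' draws
  big <- studyDesign(groupSizes = c(weaning.ND = 11, weaning.HFD = 8,
                                    adult.ND = 10, adult.HFD = 15))
  c2 <- generateCohort(big, seed = 42, simulateTacs = FALSE, withTaxa = FALSE)
  shared <- subjects(a)$subject_id
  expect_identical(subjects(c2)[match(shared, subjects(c2)$subject_id), ],
                   subjects(a)[, names(subjects(c2))])
})

test_that("a planted stratum rate multiplier is recovered from the cohort", {
  # oracle: law of large numbers on the generative model (n = 500/stratum)
  m <- 5
  des <- studyDesign(
    groupSizes = c(weaning.ND = 500, weaning.HFD = 0, adult.ND = 500,
                   adult.HFD = 0),
    rateMultipliers = list(weaning.ND = c(kPV = m), weaning.HFD = c(),
                           adult.ND = c(), adult.HFD = c()))
  coh <- generateCohort(des, seed = 3, simulateTacs = FALSE, withTaxa = FALSE)
  k <- merge(kineticRates(coh), subjects(coh)[c("subject_id", "stratum")])
  ratio <- mean(k$kPV[k$stratum == "weaning.ND"]) /
    mean(k$kPV[k$stratum == "adult.ND"])
  expect_lt(abs(ratio / m - 1), 0.02)
})

test_that("extraction metrics track the generating rates monotonically", {
  # 20-point sweep of the VF extraction rate, noise-free
  kbvs <- seq(2e-4, 4e-3, length.out = 20)
  ge <- vapply(kbvs, function(kbv) {
    sim <- simulateTracerKinetics(kineticParams(kBV = kbv), dose = 4)
    pid <- normalizeToPidG(tacs(sim)$visceral_fat, dose = 4, bodyWeight = 25)
    integrateWindow(pid, t0 = 10, t1 = 60)
  }, numeric(1))
  expect_gt(cor(kbvs, ge, method = "spearman"), 0.99)
})

test_that("weaning strata show higher VF/liver partitioning than adults", {
  coh <- generateCohort(seed = 5, noiseFree = TRUE, withTaxa = FALSE)
  met <- cohortMetrics(coh)
  expect_gt(mean(met$vf_over_liver[met$age_group == "weaning"]),
            mean(met$vf_over_liver[met$age_group == "adult"]))
})

test_that("invalid designs are rejected", {
  expect_error(studyDesign(groupSizes = c(weaning.ND = -1, weaning.HFD = 8,
                                          adult.ND = 10, adult.HFD = 9)),
               "non-negative")
  expect_error(studyDesign(groupSizes = c(a = 1)), "named")
})
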