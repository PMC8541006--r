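test_that("Spearman hits +/-1 on monotone data and handles ties correctly", {
  x <- c(2, 5, 9, 11, 15, 20, 21, 30, 31, 40)
  up <- spearmanTest(x, exp(x / 10))
  expect_equal(up$rho, 1)
  down <- spearmanTest(x, -x^3)
  expect_equal(down$rho, -1)

  # tie-corrected rho: brute-force midrank computation as the oracle
  xt <- c(1, 2, 2, 4); yt <- c(3, 1, 4, 4)
  rx <- c(1, 2.5, 2.5, 4); ry <- c(2, 1, 3.5, 3.5)   # midranks by hand
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  den <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  expect_equal(spearmanTest(xt, yt)$rho, num / den)
})

test_that("small-sample p comes from full permutation enumeration", {
  set.seed(6)
  for (i in 1:5) {
    x <- rnorm(7); y <- rnorm(7)           # no ties: cor.test exact applies
    got <- spearmanTest(x, y)
    ref <- suppressWarnings(cor.test(x, y, method = "spearman", exact = TRUE))
    expect_equal(got$rho, unname(ref$estimate))
    expect_equal(got$p, ref$p.value, tolerance = 1e-12)
  }
  expect_error(spearmanTest(1:3, 1:3), ">= 4")
})

test_that("BH adjustment equals the hand-executed step-up procedure", {
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bhAdjust(0.37), 0.37)
  set.seed(8)
  p <- runif(50)
  q <- bhAdjust(p)
  expect_true(all(q >= p))
  expect_true(all(q <= 1))
  o <- order(p)
  expect_true(all(diff(q[o]) >= -1e-15))   # monotone in rank order
  expect_error(bhAdjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("the metric screen records n, skips sparse pairs, sorts by q", {
  set.seed(12)
  X <- data.frame(m1 = rnorm(12), m2 = rnorm(12))
  Y <- data.frame(t1 = rnorm(12), t2 = rnorm(12))
  Y$t2[1:10] <- NA                         # only 2 complete pairs
  ws <- testthat::capture_warnings(res <- spearmanMatrix(X, Y))
  expect_match(ws, "skipping", all = TRUE)
  expect_length(ws, 2)                     # one per skipped (metric, t2) pair
  expect_equal(nrow(res), 2)
  expect_true(all(res$n == 12))
  expect_true(all(diff(res$q) >= 0))
  expect_equal(res$q, bhAdjust(res$p)[order(bhAdjust(res$p))])
})

test_that("group comparison dispatches Welch t vs ANOVA and handles ties", {
  same <- groupCompare(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)

  gc <- groupCompare(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
  # oracle: Welch statistic and df evaluated from the textbook formulas
  s2 <- var(c(1, 2, 3)) / 3 + var(c(4, 5, 6)) / 3
  tRef <- (mean(c(1, 2, 3)) - mean(c(4, 5, 6))) / sqrt(s2)
  dfRef <- s2^2 / ((var(c(1, 2, 3)) / 3)^2 / 2 + (var(c(4, 5, 6)) / 3)^2 / 2)
  expect_equal(gc$statistic, tRef)
  expect_equal(gc$p, 2 * pt(-abs(tRef), dfRef))
  expect_equal(gc$method, "welch_t")

  three <- groupCompare(rnorm(9), rep(c("a", "b", "c"), each = 3))
  expect_equal(three$method, "anova")
  expect_error(groupCompare(1:3, c("a", "a", "b")), ">= 2 groups")
})

test_that("a planted taxon-metric coupling is ranked first by |rho|", {
  coh <- generateCohort(seed = 17, noiseFree = TRUE, withTaxa = FALSE)
  met <- cohortMetrics(coh)
  vfgu <- met$gu_pre_visceral_fat + met$gu_post_visceral_fat
  firsts <- vapply(1:100, function(i) {
    at <- generateTaxaTable(
      stats::setNames(met$age_group, met$subject_id), nTaxa = 30,
      plantedEffects = NULL, seed = 9000 + i,
      coupling = list(taxon = "taxon_001", covariate = vfgu, strength = 1.5))
    res <- spearmanMatrix(data.frame(vf_gu = vfgu),
                          as.data.frame(t(abundances(at))))
    res$y_name[which.max(abs(res$rho))] == "taxon_001"
  }, logical(1))
  expect_gte(mean(firsts), 0.95)
})

test_that("a fully null screen keeps the q <= 0.05 discovery fraction at bay", {
  fracs <- vapply(1:20, function(i) {
    set.seed(300 + i)
    X <- as.data.frame(matrix(rnorm(38 * 3), 38, 3))
    Y <- as.data.frame(matrix(rnorm(38 * 25), 38, 25))
    mean(spearmanMatrix(X, Y)$q <= 0.05)
  }, numeric(1))
  expect_lte(mean(fracs), 0.05)
})
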