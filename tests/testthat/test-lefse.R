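test_that("total-sum scaling normalises, is idempotent, rejects zero columns", {
  m <- matrix(c(2, 3, 5, 1, 1, 2), 3, 2,
              dimnames = list(paste0("t", 1:3), c("s1", "s2")))
  at <- totalSumNormalize(toyAbundance(m, c("a", "b")))
  expect_equal(abundances(at)[, "s1"], c(t1 = 0.2, t2 = 0.3, t3 = 0.5))
  expect_true(isNormalized(at))
  expect_identical(abundances(totalSumNormalize(at)), abundances(at))

  m0 <- m; m0[, 2] <- 0
  expect_error(totalSumNormalize(toyAbundance(m0, c("a", "b"))), "s2")
})

test_that("screen p on the separated 4+4 case equals the enumeration oracle", {
  x <- c(1, 2, 3, 4, 10, 11, 12, 13)     # complete class separation
  sep <- x / 100
  m <- rbind(sep = sep, const = 0.1, rest = 0.9 - sep)
  colnames(m) <- paste0("s", 1:8)
  at <- toyAbundance(m, rep(c("a", "b"), each = 4), normalized = TRUE)
  scr <- kwScreen(at, alpha = 0.05)

  # oracle: enumerate all C(8,4) labelings of the rank-sum statistic
  ranks <- rank(sep)
  combos <- combn(8, 4)
  W <- apply(combos, 2, function(idx) sum(ranks[idx]))
  obs <- sum(ranks[1:4])
  pExact <- mean(abs(W - mean(W)) >= abs(obs - mean(W)))
  expect_equal(pExact, 2 / 70)
  expect_equal(scr$kw_p[scr$feature_id == "sep"], pExact, tolerance = 1e-12)
  expect_true(scr$pass[scr$feature_id == "sep"])
  expect_equal(scr$kw_p[scr$feature_id == "const"], 1)   # convention
  expect_error(kwScreen(toyAbundance(matrix(1:4, 2, 2), c("a", "b"),
                                     normalized = FALSE)),
               "normalised")
})

test_that("screen validates class structure", {
  m <- matrix(runif(12), 3, 4, dimnames = list(paste0("t", 1:3),
                                               paste0("s", 1:4)))
  at <- totalSumNormalize(toyAbundance(m, c("a", "a", "a", "b")))
  expect_error(kwScreen(at), ">= 2 subjects")
  one <- totalSumNormalize(toyAbundance(m, rep("a", 4)))
  expect_error(kwScreen(one), ">= 2 classes")
})

test_that("discriminant effect size matches an independent LDA-based oracle", {
  skip_if_not_installed("MASS")
  set.seed(21)
  vals <- c(pmax(0.01, rnorm(6, 0.30, 0.02)), pmax(0.01, rnorm(6, 0.03, 0.01)))
  m <- rbind(marker = vals, filler = 1 - vals)
  at <- totalSumNormalize(toyAbundance(m, rep(c("hi", "lo"), each = 6)))
  got <- ldaEffectSize(at, features = "marker")

  # oracle: refit with MASS::lda on the 1e6 scale and recompute the score
  x <- abundances(at)["marker", ] * 1e6
  cls <- factor(rep(c("hi", "lo"), each = 6))
  fit <- MASS::lda(data.frame(x = x), grouping = cls)
  projDiff <- abs(diff(as.numeric(fit$means %*% fit$scaling)))
  rawDiff <- abs(diff(tapply(x, cls, mean)))
  oracle <- log10((projDiff + rawDiff) / 2)
  expect_equal(got$lda_score, unname(oracle), tolerance = 1e-6)
  expect_equal(got$enriched_class, "hi")
})

test_that("degenerate features score below threshold instead of erroring", {
  m <- rbind(same = rep(0.4, 8), rest = rep(0.6, 8))
  at <- toyAbundance(m, rep(c("a", "b"), each = 4), normalized = TRUE)
  eff <- ldaEffectSize(at, features = "same")
  expect_true(is.na(eff$lda_score))
  expect_false(lefseCall(0.01, eff$lda_score))
})

test_that("the biomarker call is strict at the threshold", {
  expect_false(lefseCall(0.01, 3.0, ldaThreshold = 3.0))
  expect_true(lefseCall(0.01, 3.0000001, ldaThreshold = 3.0))
  expect_false(lefseCall(0.2, 5, alpha = 0.05))
})

test_that("scores are invariant to subject order and monotone in effect size", {
  at <- generateTaxaTable(rep(c("a", "b"), each = 8), nTaxa = 15,
                          plantedEffects = list(hit = c(b = 1.5)), seed = 4)
  res <- runLefse(at)
  perm <- sample(ncol(at))
  atP <- abundanceTable(abundances(at)[, perm],
                        classLabels = classLabels(at)[perm],
                        normalized = TRUE)
  resP <- runLefse(atP)
  resP <- resP[match(res$feature_id, resP$feature_id), ]
  expect_equal(res$kw_p, resP$kw_p)
  expect_equal(res$lda_score, resP$lda_score)

  # noise-free 10-point sweep of the planted fold change
  scores <- vapply(seq(0.25, 3, length.out = 10), function(l2) {
    atS <- generateTaxaTable(rep(c("a", "b"), each = 6), nTaxa = 10,
                             plantedEffects = list(hit = c(b = l2)),
                             seed = 8, sdLog = 0)
    ldaEffectSize(atS, features = "hit")$lda_score
  }, numeric(1))
  expect_true(all(diff(scores) >= 0))
})

test_that("a 4-fold planted biomarker is recovered in >= 90% of replicates", {
  hits <- vapply(1:200, function(i) {
    at <- generateTaxaTable(rep(c("a", "b"), each = 10), nTaxa = 20,
                            plantedEffects = list(hit = c(b = 2)),
                            seed = 5000 + i)
    res <- runLefse(at)
    res$called[res$feature_id == "hit"]
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})
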