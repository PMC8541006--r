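## Two-stage LDA effect-size biomarker discovery on compositional abundance
## tables: a nonparametric class screen, then a one-dimensional linear
## discriminant effect size on the 1..1e6 abundance scale, reported as log10
## and called above a strict threshold (default > 3.0).

#' Total-sum scaling
#'
#' Divides every subject column by its sum so relative abundances sum to 1.
#' Idempotent; errors (naming the subject) on an all-zero column.
#'
#' @param table an [AbundanceTable-class].
#' @return The normalised [AbundanceTable-class].
#' @export
totalSumNormalize <- function(table) {
  stopifnot(is(table, "AbundanceTable"))
  m <- abundances(table)
  cs <- colSums(m)
  if (any(cs == 0))
    .stopv("all-zero abundance column for subject(s): ",
           paste(colnames(m)[cs == 0], collapse = ", "))
  abundanceTable(sweep(m, 2, cs, "/"), classLabels = classLabels(table),
                 normalized = TRUE)
}

#' Nonparametric class-difference screen
#'
#' Per-feature nonparametric test of abundance against class.  Two classes
#' without ties use the exact Wilcoxon rank-sum test (exact when both groups
#' have fewer than 50 subjects); ties or more than two classes fall back to
#' the tie-corrected Kruskal--Wallis chi-square approximation.  A feature
#' constant across all subjects returns p = 1 by convention.
#'
#' @param table a normalised [AbundanceTable-class].
#' @param alpha screen level (default 0.05).
#' @return data.frame: \code{feature_id}, \code{kw_p}, \code{pass}.
#' @export
kwScreen <- function(table, alpha = 0.05) {
  stopifnot(is(table, "AbundanceTable"))
  if (!isNormalized(table)) .stopv("table must be total-sum normalised first")
  cls <- factor(classLabels(table))
  if (nlevels(cls) < 2L) .stopv("need >= 2 classes")
  if (any(tabulate(cls) < 2L))
    .stopv("every class needs >= 2 subjects (got: ",
           paste(sprintf("%s=%d", levels(cls), tabulate(cls)), collapse = ", "),
           ")")
  m <- abundances(table)
  p <- apply(m, 1L, function(x) {
    if (max(x) == min(x)) return(1)
    if (nlevels(cls) == 2L && !anyDuplicated(x) &&
        all(tabulate(cls) < 50L)) {
      stats::wilcox.test(x[cls == levels(cls)[1]], x[cls == levels(cls)[2]],
                         exact = TRUE)$p.value
    } else {
      stats::kruskal.test(x, cls)$p.value
    }
  })
  data.frame(feature_id = rownames(m), kw_p = unname(p),
             pass = unname(p) <= alpha, stringsAsFactors = FALSE)
}

# one-dimensional discriminant effect size for one feature (values on the
# 1e6 scale).  Projection scaled to unit pooled within-class variance, as a
# standard LDA fit would; the effect size averages the projected and raw
# class-mean differences.
.ldaEffectOne <- function(x, cls) {
  lev <- levels(cls)
  mk <- vapply(lev, function(l) mean(x[cls == l]), numeric(1))
  enriched <- lev[which.max(mk)]
  if (length(lev) == 2L) {
    g1 <- x[cls == lev[1]]; g2 <- x[cls == lev[2]]
  } else {                       # one-vs-rest on the enriched class
    g1 <- x[cls == enriched]; g2 <- x[cls != enriched]
  }
  rawDiff <- abs(mean(g1) - mean(g2))
  n1 <- length(g1); n2 <- length(g2)
  s2 <- (sum((g1 - mean(g1))^2) + sum((g2 - mean(g2))^2)) / (n1 + n2 - 2)
  projDiff <- if (s2 > 0) rawDiff / sqrt(s2) else rawDiff
  eff <- (projDiff + rawDiff) / 2
  list(score = if (eff > 0) log10(eff) else NA_real_, enriched = enriched)
}

#' Linear-discriminant effect size per feature
#'
#' For each screened feature, relative abundances are rescaled to the
#' 1--1e6 range (multiplied by 1e6), a one-dimensional linear discriminant is
#' fitted (projection scaled to unit pooled within-class variance), and the
#' effect size is the absolute discriminant-projected class-mean difference
#' averaged with the raw class-mean difference; the reported score is its
#' log10.  The class with the larger mean is the enriched class; with more
#' than two classes the enriched class is compared one-vs-rest.  A feature
#' with no class-mean difference gets an NA score ("below threshold"), not an
#' error.  By default the fit is a single deterministic pass; setting
#' \code{nBoot > 1} averages the effect size over seeded 2/3 subsamples per
#' class, reproducing the reference procedure's bootstrap behaviour.
#'
#' @param table a normalised [AbundanceTable-class].
#' @param features feature ids to score (e.g. the screen's passes); default
#'   all features.
#' @param nBoot bootstrap rounds (default 1 = deterministic single fit).
#' @param seed seed for the bootstrap subsampling.
#' @return data.frame: \code{feature_id}, \code{lda_score},
#'   \code{enriched_class}.
#' @export
ldaEffectSize <- function(table, features = NULL, nBoot = 1L, seed = 1L) {
  stopifnot(is(table, "AbundanceTable"))
  if (!isNormalized(table)) .stopv("table must be total-sum normalised first")
  cls <- factor(classLabels(table))
  if (nlevels(cls) < 2L) .stopv("need >= 2 classes")
  m <- abundances(table) * 1e6
  if (is.null(features)) features <- rownames(m)
  bad <- setdiff(features, rownames(m))
  if (length(bad)) .stopv("unknown feature(s): ", paste(bad, collapse = ", "))
  if (length(features) == 0L) .stopv("no features to score")

  scoreOne <- function(fid) {
    x <- m[fid, ]
    if (nBoot <= 1L) return(.ldaEffectOne(x, cls))
    effs <- .withSeed(seed + match(fid, rownames(m)), {
      vapply(seq_len(nBoot), function(b) {
        keep <- unlist(lapply(levels(cls), function(l) {
          idx <- which(cls == l)
          sort(sample(idx, max(2L, ceiling(2 * length(idx) / 3))))
        }))
        r <- .ldaEffectOne(x[keep], droplevels(cls[keep]))
        if (is.na(r$score)) 0 else 10^r$score
      }, numeric(1))
    })
    eff <- mean(effs)
    enriched <- .ldaEffectOne(x, cls)$enriched
    list(score = if (eff > 0) log10(eff) else NA_real_, enriched = enriched)
  }
  res <- lapply(features, scoreOne)
  data.frame(feature_id = features,
             lda_score = vapply(res, `[[`, numeric(1), "score"),
             enriched_class = vapply(res, `[[`, character(1), "enriched"),
             stringsAsFactors = FALSE)
}

#' Biomarker call rule
#'
#' A feature is called when it passes the screen at \code{alpha} and its LDA
#' score strictly exceeds \code{ldaThreshold} (a score exactly at the
#' threshold is not called).
#'
#' @param kwP screen p-value(s).
#' @param ldaScore log10 effect size(s); NA never calls.
#' @param alpha screen level.
#' @param ldaThreshold strict score threshold (default 3.0).
#' @return logical vector.
#' @export
lefseCall <- function(kwP, ldaScore, alpha = 0.05, ldaThreshold = 3.0) {
  kwP <= alpha & !is.na(ldaScore) & ldaScore > ldaThreshold
}

#' Two-stage biomarker discovery
#'
#' Runs the nonparametric screen, scores the survivors with the linear
#' discriminant effect size, and calls biomarkers at \code{lda_score >
#' ldaThreshold}.  \code{strict = TRUE} additionally requires, for more than
#' two classes, that all pairwise rank-sum comparisons between classes agree
#' in direction and reach \code{alpha} (the reference tool's optional
#' consistency substage; off by default).
#'
#' @param table an [AbundanceTable-class]; normalised if not already.
#' @param alpha screen level (default 0.05).
#' @param ldaThreshold strict log10 effect-size threshold (default 3.0).
#' @param strict enable the pairwise consistency substage.
#' @param nBoot,seed passed to [ldaEffectSize()].
#' @return data.frame: \code{feature_id}, \code{kw_p}, \code{lda_score},
#'   \code{enriched_class}, \code{called}, sorted by decreasing score.
#' @examples
#' at <- generateTaxaTable(rep(c("weaning", "adult"), each = 8), nTaxa = 20,
#'                         seed = 3)
#' head(runLefse(at))
#' @export
runLefse <- function(table, alpha = 0.05, ldaThreshold = 3.0, strict = FALSE,
                     nBoot = 1L, seed = 1L) {
  stopifnot(is(table, "AbundanceTable"))
  if (!isNormalized(table)) table <- totalSumNormalize(table)
  scr <- kwScreen(table, alpha = alpha)
  eff <- ldaEffectSize(table, features = scr$feature_id, nBoot = nBoot,
                       seed = seed)
  out <- merge(scr, eff, by = "feature_id", sort = FALSE)
  out$called <- lefseCall(out$kw_p, out$lda_score, alpha, ldaThreshold)
  if (strict) {
    cls <- factor(classLabels(table))
    if (nlevels(cls) > 2L) {
      m <- abundances(table)
      consistent <- vapply(out$feature_id, function(fid) {
        x <- m[fid, ]
        pairs <- utils::combn(levels(cls), 2, simplify = FALSE)
        dir <- sign(vapply(pairs, function(pr)
          mean(x[cls == pr[1]]) - mean(x[cls == pr[2]]), numeric(1)))
        ps <- vapply(pairs, function(pr)
          stats::wilcox.test(x[cls == pr[1]], x[cls == pr[2]],
                             exact = FALSE)$p.value, numeric(1))
        all(ps <= alpha)
      }, logical(1))
      out$called <- out$called & consistent
    }
  }
  out[order(-replace(out$lda_score, is.na(out$lda_score), -Inf)), ,
      drop = FALSE]
}
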