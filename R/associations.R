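## Group comparisons and the Spearman correlation screen linking imaging
## metrics to taxa/pathway abundances, with Benjamini-Hochberg FDR control
## across all pairs of one screen.

.permCache <- new.env(parent = emptyenv())

# all permutations of 1..n (rows), cached; used for exact Spearman p at n < 10
.allPerms <- function(n) {
  key <- as.character(n)
  if (!is.null(.permCache[[key]])) return(.permCache[[key]])
  p <- matrix(1L, 1L, 1L)
  for (m in 2:n) {
    p <- do.call(rbind, lapply(seq_len(m), function(k) {
      q <- p + (p >= k)
      cbind(rep(k, nrow(q)), q)
    }))
  }
  if (n == 1L) p <- matrix(1L, 1L, 1L)
  .permCache[[key]] <- p
  p
}

#' Tie-corrected Spearman correlation with exact small-sample p
#'
#' rho is the Pearson correlation of midranks (the tie-corrected Spearman
#' coefficient).  For n >= 10 the p-value uses the t approximation
#' t = rho sqrt((n-2)/(1-rho^2)) on n-2 degrees of freedom; for n < 10 it is
#' the exact two-sided permutation p over all n! pairings.
#'
#' @param x,y numeric vectors (pairwise-complete observations are used).
#' @return list: \code{rho}, \code{p}, \code{n}.
#' @export
spearmanTest <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4L) .stopv("need >= 4 complete pairs")
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    return(list(rho = NA_real_, p = NA_real_, n = n))
  rho <- stats::cor(rx, ry)
  if (n >= 10L) {
    tstat <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  } else {
    P <- .allPerms(n)
    ryc <- ry - mean(ry); rxc <- rx - mean(rx)
    denom <- sqrt(sum(rxc^2) * sum(ryc^2))
    rhoAll <- as.numeric(matrix(ryc[P], nrow(P), n) %*% rxc) / denom
    p <- mean(abs(rhoAll) >= abs(rho) - 1e-12)
  }
  list(rho = rho, p = min(p, 1), n = n)
}

#' Spearman screen of imaging metrics against feature abundances
#'
#' Computes the tie-corrected Spearman correlation and p-value for every
#' (metric, feature) pair using pairwise-complete observations, then adjusts
#' the whole screen with Benjamini--Hochberg.  Pairs with fewer than 4
#' complete observations are skipped with a warning.
#'
#' @param X data.frame/matrix of metric columns (subjects in rows).
#' @param Y data.frame/matrix of abundance columns (same subjects in rows).
#' @return data.frame sorted by \code{q}: \code{x_name}, \code{y_name},
#'   \code{rho}, \code{p}, \code{q}, \code{n}.
#' @export
spearmanMatrix <- function(X, Y) {
  X <- as.data.frame(X); Y <- as.data.frame(Y)
  if (nrow(X) != nrow(Y))
    .stopv("X and Y must describe the same subjects (row counts differ)")
  rows <- list()
  for (xn in names(X)) for (yn in names(Y)) {
    ok <- stats::complete.cases(X[[xn]], Y[[yn]])
    if (sum(ok) < 4L) {
      warning(sprintf("skipping pair (%s, %s): %d complete pairs",
                      xn, yn, sum(ok)), call. = FALSE)
      next
    }
    r <- spearmanTest(X[[xn]], Y[[yn]])
    rows[[length(rows) + 1L]] <-
      data.frame(x_name = xn, y_name = yn, rho = r$rho, p = r$p, n = r$n,
                 stringsAsFactors = FALSE)
  }
  if (!length(rows)) .stopv("no testable pairs")
  out <- do.call(rbind, rows)
  out$q <- bhAdjust(out$p)
  out <- out[order(out$q, out$p), c("x_name", "y_name", "rho", "p", "q", "n")]
  rownames(out) <- NULL
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up adjusted p-values, capped at 1 and monotone in rank order.
#'
#' @param pValues p-values in [0, 1] (NA passed through).
#' @return Adjusted q-values.
#' @examples
#' bhAdjust(c(0.01, 0.02, 0.03, 0.04))   # all 0.04
#' @export
bhAdjust <- function(pValues) {
  ok <- !is.na(pValues)
  if (any(pValues[ok] < 0 | pValues[ok] > 1))
    .stopv("p-values must lie in [0, 1]")
  stats::p.adjust(pValues, method = "BH")
}

#' Compare a metric between groups
#'
#' Two groups: Welch's (unequal-variance) two-sided t-test.  More than two:
#' one-way analysis of variance.  Groups whose values are identical across
#' the board return statistic 0 and p = 1.
#'
#' @param values per-subject metric.
#' @param groups group labels, same length.
#' @return list: \code{statistic}, \code{p}, \code{method}, and a
#'   data.frame \code{groups} of group mean +/- sem.
#' @export
groupCompare <- function(values, groups) {
  groups <- factor(groups)
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]; groups <- droplevels(groups[ok])
  sizes <- tabulate(groups)
  if (nlevels(groups) < 2L || any(sizes < 2L))
    .stopv("need >= 2 groups with >= 2 subjects each")
  summ <- data.frame(
    group = levels(groups),
    n = sizes,
    mean = as.numeric(tapply(values, groups, mean)),
    sem = as.numeric(tapply(values, groups, stats::sd)) / sqrt(sizes))
  if (nlevels(groups) == 2L) {
    g1 <- values[groups == levels(groups)[1]]
    g2 <- values[groups == levels(groups)[2]]
    if (stats::sd(g1) == 0 && stats::sd(g2) == 0) {
      stat <- if (mean(g1) == mean(g2)) 0 else Inf
      return(list(statistic = stat, p = if (stat == 0) 1 else 0,
                  method = "welch_t", groups = summ))
    }
    tt <- stats::t.test(g1, g2, var.equal = FALSE)
    list(statistic = unname(tt$statistic), p = tt$p.value,
         method = "welch_t", groups = summ)
  } else {
    if (stats::sd(values) == 0)
      return(list(statistic = 0, p = 1, method = "anova", groups = summ))
    fit <- stats::aov(values ~ groups)
    tab <- summary(fit)[[1]]
    list(statistic = tab[["F value"]][1], p = tab[["Pr(>F)"]][1],
         method = "anova", groups = summ)
  }
}

#' Associate imaging metrics with an abundance table
#'
#' Convenience wrapper for the pipeline's association stage: aligns a
#' metrics table (one row per subject) with an [AbundanceTable-class] by
#' subject id and runs [spearmanMatrix()] on the numeric metric columns
#' against all feature abundances.
#'
#' @param metrics data.frame with \code{subject_id} and numeric metric
#'   columns.
#' @param table an [AbundanceTable-class] whose columns are subjects.
#' @param metricCols which metric columns to screen (default: all numeric).
#' @return See [spearmanMatrix()].
#' @export
associateMetricsTaxa <- function(metrics, table, metricCols = NULL) {
  stopifnot(is(table, "AbundanceTable"))
  ids <- intersect(metrics$subject_id, colnames(table))
  if (length(ids) < 4L) .stopv("fewer than 4 subjects shared")
  m <- metrics[match(ids, metrics$subject_id), , drop = FALSE]
  if (is.null(metricCols))
    metricCols <- setdiff(names(m)[vapply(m, is.numeric, logical(1))],
                          "subject_id")
  Y <- t(abundances(table)[, ids, drop = FALSE])
  spearmanMatrix(m[metricCols], as.data.frame(Y))
}
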