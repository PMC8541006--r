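## Kleiner-adapted liver histology grading and the composite
## steatohepatitis (NASH) call: sum of steatosis grade (0-3), lobular
## inflammation grade (0-3) and ballooning (0-1); a sum >= 4 calls NASH.

#' Grade lobular inflammation from foci counts
#'
#' Foci counted at 20x magnification: 0 foci = grade 0, 1 focus = grade 1,
#' two to four foci = grade 2, more than four = grade 3.
#'
#' @param nFoci integer count(s) >= 0.
#' @return Integer grade(s) 0--3.
#' @examples
#' gradeLobularInflammation(c(0, 1, 3, 5))   # 0 1 2 3
#' @export
gradeLobularInflammation <- function(nFoci) {
  if (any(!is.finite(nFoci)) || any(nFoci < 0) || any(nFoci != round(nFoci)))
    .stopv("nFoci must be non-negative integer(s)")
  ifelse(nFoci == 0, 0L, ifelse(nFoci == 1, 1L, ifelse(nFoci <= 4, 2L, 3L)))
}

#' Grade steatosis from the percentage of affected hepatocytes
#'
#' Kleiner cutoffs: below 5\% = grade 0, 5--33\% = grade 1, above 33 up to
#' 66\% = grade 2, above 66\% = grade 3 (boundaries inclusive in the lower
#' grade's upper bound).
#'
#' @param percentAffected percentage(s) in [0, 100].
#' @return Integer grade(s) 0--3.
#' @examples
#' gradeSteatosis(c(4, 5, 33, 50, 66, 100))   # 0 1 1 2 2 3
#' @export
gradeSteatosis <- function(percentAffected) {
  if (any(!is.finite(percentAffected)) || any(percentAffected < 0) ||
      any(percentAffected > 100))
    .stopv("percentAffected must lie in [0, 100]")
  ifelse(percentAffected < 5, 0L,
         ifelse(percentAffected <= 33, 1L,
                ifelse(percentAffected <= 66, 2L, 3L)))
}

#' Composite steatohepatitis score and call
#'
#' Completes a histology record: the sum score is steatosis grade (0--3) +
#' lobular inflammation grade (0--3) + ballooning (0--1), attainable maximum
#' 7, and the categorical steatohepatitis (NASH) call is positive when the
#' sum reaches 4.  Portal inflammation, fibrosis and vessel dilatation are
#' recorded as binary flags but do not enter the composite.
#'
#' @param steatosisGrade integer(s) 0--3.
#' @param lobularGrade integer(s) 0--3.
#' @param ballooning 0 or 1.
#' @return data.frame with the inputs plus \code{sum_score} and \code{nash}.
#' @examples
#' scoreNash(3, 3, 1)   # sum 7, NASH TRUE
#' scoreNash(2, 1, 0)   # sum 3, NASH FALSE
#' @export
scoreNash <- function(steatosisGrade, lobularGrade, ballooning) {
  chk <- function(x, lo, hi, nm) {
    if (any(!is.finite(x)) || any(x < lo) || any(x > hi) ||
        any(x != round(x)))
      .stopv(nm, " must be integer(s) in [", lo, ", ", hi, "]")
  }
  chk(steatosisGrade, 0, 3, "steatosisGrade")
  chk(lobularGrade, 0, 3, "lobularGrade")
  chk(ballooning, 0, 1, "ballooning")
  s <- steatosisGrade + lobularGrade + ballooning
  data.frame(steatosis_grade = as.integer(steatosisGrade),
             lobular_grade = as.integer(lobularGrade),
             ballooning = as.integer(ballooning),
             sum_score = as.integer(s), nash = s >= 4)
}

#' Score a raw histology table
#'
#' Takes raw observations (steatosis percentage -- or separate micro and
#' macro percentages, of which the more severe grade is used -- and lobular
#' foci counts) and returns the completed, graded table with the composite
#' score and NASH call.
#'
#' @param df data.frame with \code{subject_id}, \code{lobular_foci},
#'   \code{ballooning}, and either \code{steatosis_pct} or both
#'   \code{steatosis_micro_pct} and \code{steatosis_macro_pct}; other columns
#'   are carried through.
#' @return The input with \code{steatosis_grade}, \code{lobular_grade},
#'   \code{sum_score} and \code{nash} appended.
#' @export
scoreHistologyTable <- function(df) {
  if (!"lobular_foci" %in% names(df) || !"ballooning" %in% names(df))
    .stopv("histology table needs lobular_foci and ballooning")
  if ("steatosis_pct" %in% names(df)) {
    sg <- gradeSteatosis(df$steatosis_pct)
  } else if (all(c("steatosis_micro_pct", "steatosis_macro_pct") %in%
                 names(df))) {
    sg <- pmax(gradeSteatosis(df$steatosis_micro_pct),
               gradeSteatosis(df$steatosis_macro_pct))
  } else .stopv("histology table needs steatosis_pct (or micro+macro pair)")
  lg <- gradeLobularInflammation(df$lobular_foci)
  sc <- scoreNash(sg, lg, df$ballooning)
  df$steatosis_grade <- sc$steatosis_grade
  df$lobular_grade <- sc$lobular_grade
  df$sum_score <- sc$sum_score
  df$nash <- sc$nash
  df
}
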