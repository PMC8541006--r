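## Quantification of time-activity curves: %ID/g normalisation, windowed
## trapezoid integration, pre-/post-systemic extraction and uptake, organ
## partitioning ratios, systemic clearance and EGP.

#' Normalise a time-activity curve to percent injected dose per gram
#'
#' Two conventions are offered.  The default, \code{"per_g_bw"}, is the
#' SUV-like dimensionless form 100 x concentration x body weight / dose
#' ("per gram of body weight"); \code{"per_g"} is 100 x concentration / dose
#' (units 1/g).  Both are shape-preserving.
#'
#' @param tac a [TimeActivityCurve-class] in MBq/mL.
#' @param dose injected dose, MBq (> 0).
#' @param bodyWeight grams (> 0).
#' @param convention \code{"per_g_bw"} (default) or \code{"per_g"}.
#' @return A [TimeActivityCurve-class] carrying \%ID/g values.
#' @export
normalizeToPidG <- function(tac, dose, bodyWeight,
                            convention = c("per_g_bw", "per_g")) {
  stopifnot(is(tac, "TimeActivityCurve"))
  convention <- match.arg(convention)
  .checkNumber(dose, "dose", positive = TRUE)
  .checkNumber(bodyWeight, "bodyWeight", positive = TRUE)
  fac <- if (convention == "per_g_bw") 100 * bodyWeight / dose else 100 / dose
  timeActivityCurve(tac@times, tac@activities * fac, tac@roi)
}

#' Trapezoid integral of a sampled curve over a window
#'
#' Trapezoid rule on the sample grid; window endpoints that do not fall on
#' the grid are handled by linear interpolation of the curve at \code{t0} and
#' \code{t1}.  No extrapolation: the window must lie within the curve's
#' support.  The rule is additive over adjacent windows sharing a grid point.
#'
#' @param times,values the sampled curve (equal-length; times strictly
#'   increasing), or pass a [TimeActivityCurve-class] as \code{times}.
#' @param t0,t1 window bounds in minutes, \code{t0 < t1}.
#' @return The area (value x min).
#' @examples
#' integrateWindow(0:10, rep(1, 11), 0, 10)   # 10
#' @export
integrateWindow <- function(times, values = NULL, t0, t1) {
  if (is(times, "TimeActivityCurve")) {
    values <- times@activities
    times <- times@times
  }
  if (length(times) != length(values) || length(times) < 2L)
    .stopv("times and values must be equal-length (>= 2)")
  if (any(diff(times) <= 0)) .stopv("times must be strictly increasing")
  if (!(t0 < t1)) .stopv("need t0 < t1")
  if (t0 < min(times) - 1e-9 || t1 > max(times) + 1e-9)
    .stopv(sprintf("window [%g, %g] outside curve support [%g, %g]",
                   t0, t1, min(times), max(times)))
  inner <- times > t0 & times < t1
  tt <- c(t0, times[inner], t1)
  vv <- c(stats::approx(times, values, t0)$y, values[inner],
          stats::approx(times, values, t1)$y)
  sum(diff(tt) * (utils::head(vv, -1) + utils::tail(vv, -1)) / 2)
}

#' Pre-/post-systemic extraction, uptake and partitioning ratios
#'
#' From per-organ \%ID/g curves: glucose fractional extraction integrated over
#' 0--10 min (\code{ge_pre}, reflecting pre-systemic entry) and 10--60 min
#' (\code{ge_post}, post-systemic extraction); glucose uptake \code{gu} =
#' extraction x glycemia; and the organ partitioning ratios on total 0--60 min
#' uptake (visceral fat/liver, gut/liver and their reciprocals).  A ratio is
#' NA when the denominator organ's 0--60 uptake is zero.
#'
#' @param curves named list of \%ID/g [TimeActivityCurve-class] for
#'   \code{liver}, \code{visceral_fat} and \code{gut} (a \code{blood} entry is
#'   ignored here).
#' @param glycemia fasting glycemia, mmol/L (>= 0).
#' @param windows numeric c(pre start, split, end), minutes; default 0/10/60.
#' @return One-row data.frame: \code{ge_pre_<organ>}, \code{ge_post_<organ>},
#'   \code{gu_pre_<organ>}, \code{gu_post_<organ>} and the four ratios.
#' @export
computeUptakeMetrics <- function(curves, glycemia, windows = c(0, 10, 60)) {
  organs <- c("liver", "visceral_fat", "gut")
  missing <- setdiff(organs, names(curves))
  if (length(missing))
    .stopv("absent organ curve(s): ", paste(missing, collapse = ", "))
  .checkNumber(glycemia, "glycemia", nonneg = TRUE)
  stopifnot(length(windows) == 3L, diff(windows) > 0)

  out <- list()
  gu60 <- c()
  for (org in organs) {
    tc <- curves[[org]]
    gePre <- integrateWindow(tc, t0 = windows[1], t1 = windows[2])
    gePost <- integrateWindow(tc, t0 = windows[2], t1 = windows[3])
    out[[paste0("ge_pre_", org)]] <- gePre
    out[[paste0("ge_post_", org)]] <- gePost
    out[[paste0("gu_pre_", org)]] <- gePre * glycemia
    out[[paste0("gu_post_", org)]] <- gePost * glycemia
    gu60[org] <- (gePre + gePost) * glycemia
  }
  rat <- function(num, den) if (gu60[den] == 0) NA_real_ else
    unname(gu60[num] / gu60[den])
  out$vf_over_liver <- rat("visceral_fat", "liver")
  out$gut_over_liver <- rat("gut", "liver")
  out$liver_over_vf <- rat("liver", "visceral_fat")
  out$liver_over_gut <- rat("liver", "gut")
  as.data.frame(out)
}

#' Systemic clearance, endogenous glucose production and blood exposure split
#'
#' Clearance is the ratio of injected dose to the 0--60 min integrated blood
#' activity concentration (mL/min); EGP per gram is clearance x glycemia /
#' body weight (umol/min/g, since mL/min x mmol/L = umol/min); the blood
#' exposure fraction is the share of the 0--60 min blood integral occurring
#' within the first 10 minutes.
#'
#' @param blood blood [TimeActivityCurve-class] (MBq/mL), spanning 0--60 min.
#' @param dose injected dose, MBq (> 0).
#' @param glycemia mmol/L (>= 0).
#' @param bodyWeight grams (> 0).
#' @param windows numeric c(start, split, end), default 0/10/60 min.
#' @return One-row data.frame: \code{clearance_mL_min},
#'   \code{egp_umol_min_g}, \code{blood_fraction_0_10}.
#' @export
computeSystemicMetrics <- function(blood, dose, glycemia, bodyWeight,
                                   windows = c(0, 10, 60)) {
  stopifnot(is(blood, "TimeActivityCurve"))
  .checkNumber(dose, "dose", positive = TRUE)
  .checkNumber(glycemia, "glycemia", nonneg = TRUE)
  .checkNumber(bodyWeight, "bodyWeight", positive = TRUE)
  if (max(blood@times) < windows[3])
    .stopv("blood curve must span [", windows[1], ", ", windows[3], "] min")
  aucAll <- integrateWindow(blood, t0 = windows[1], t1 = windows[3])
  if (aucAll <= 0) .stopv("zero blood integral: clearance undefined")
  aucPre <- integrateWindow(blood, t0 = windows[1], t1 = windows[2])
  clearance <- dose / aucAll
  data.frame(clearance_mL_min = clearance,
             egp_umol_min_g = clearance * glycemia / bodyWeight,
             blood_fraction_0_10 = aucPre / aucAll)
}

#' Per-subject quantification of a cohort
#'
#' Runs the full quantification over a cohort (or over tables read from
#' disk): per organ \%ID/g normalisation, pre-/post-systemic extraction and
#' uptake, partitioning ratios, and systemic metrics; joins CT densities when
#' available.
#'
#' @param cohort a [VisceralCohort-class], or NULL when using \code{subjects}
#'   + \code{tacDir}.
#' @param subjects subject metadata data.frame (default from the cohort).
#' @param tacList named list (by subject) of named TAC lists (default from
#'   the cohort).
#' @param densities optional densities data.frame.
#' @param convention \%ID/g convention, see [normalizeToPidG()].
#' @param windows integration windows c(0, 10, 60) min.
#' @return data.frame, one row per subject.
#' @export
cohortMetrics <- function(cohort = NULL, subjects = NULL, tacList = NULL,
                          densities = NULL,
                          convention = c("per_g_bw", "per_g"),
                          windows = c(0, 10, 60)) {
  convention <- match.arg(convention)
  if (!is.null(cohort)) {
    stopifnot(is(cohort, "VisceralCohort"))
    if (is.null(subjects)) subjects <- subjects(cohort)
    if (is.null(tacList)) tacList <- tacs(cohort)
    if (is.null(densities)) densities <- densities(cohort)
  }
  rows <- lapply(seq_len(nrow(subjects)), function(i) {
    s <- subjects[i, ]
    tl <- tacList[[s$subject_id]]
    if (is.null(tl))
      .stopv("no time-activity curves for subject ", s$subject_id)
    pid <- lapply(tl, normalizeToPidG, dose = s$injected_dose_MBq,
                  bodyWeight = s$body_weight_g, convention = convention)
    up <- computeUptakeMetrics(pid, glycemia = s$glycemia_mmol_L,
                               windows = windows)
    sys <- computeSystemicMetrics(tl$blood, dose = s$injected_dose_MBq,
                                  glycemia = s$glycemia_mmol_L,
                                  bodyWeight = s$body_weight_g,
                                  windows = windows)
    cbind(s[c("subject_id", "age_group", "maternal_diet", "body_weight_g",
              "injected_dose_MBq", "glycemia_mmol_L")], up, sys,
          row.names = NULL)
  })
  out <- do.call(rbind, rows)
  if (!is.null(densities) && nrow(densities))
    out <- merge(out, densities, by = "subject_id", sort = FALSE)
  out
}
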