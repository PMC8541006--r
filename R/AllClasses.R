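#' @importFrom S4Vectors metadata DataFrame
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
NULL

.ROIS <- c("liver", "visceral_fat", "gut", "blood")
.RATE_NAMES <- c("kPA", "kPG", "kPV", "kPL", "kBG", "kBV", "kBL", "kLoss")
.STRATA <- c("weaning.ND", "weaning.HFD", "adult.ND", "adult.HFD")

## ---- KineticParams ---------------------------------------------------------

#' First-order kinetic parameters of the intraperitoneal tracer model
#'
#' Rate constants (1/min) of the linear compartmental model used to simulate
#' intraperitoneally injected FDG.  The peritoneal depot (P) feeds the blood
#' pool (B, absorption \code{kPA}) and delivers tracer pre-systemically to the
#' gut, visceral fat and liver via the mesenteric/portal routes (\code{kPG},
#' \code{kPV}, \code{kPL}).  Blood feeds the same tissues post-systemically
#' (\code{kBG}, \code{kBV}, \code{kBL}) and loses tracer irreversibly at
#' \code{kLoss} (renal excretion).  With \code{trapping = TRUE} (the FDG
#' phosphorylation analogy) tissue compartments are irreversible; otherwise
#' each tissue exchanges back to blood at the same rate constant that fills it.
#'
#' Default values are calibrated so that, on the default 0--60 min grid, the
#' blood pool receives about 4\% of its total 0--60 min exposure within the
#' first 10 minutes while 15--20\% of the injected dose reaches gut plus
#' visceral fat through the pre-systemic routes in the same window.
#'
#' @slot kPA,kPG,kPV,kPL,kBG,kBV,kBL,kLoss non-negative rates, 1/min.
#' @slot trapping logical; irreversible tissue compartments.
#' @seealso [simulateTracerKinetics()]
#' @export
setClass("KineticParams",
  representation(kPA = "numeric", kPG = "numeric", kPV = "numeric",
                 kPL = "numeric", kBG = "numeric", kBV = "numeric",
                 kBL = "numeric", kLoss = "numeric", trapping = "logical"))

setValidity("KineticParams", function(object) {
  r <- kineticRates(object)
  if (any(!is.finite(r))) return("all rates must be finite")
  if (any(r < 0)) return(sprintf("negative rate(s): %s",
                                 paste(names(r)[r < 0], collapse = ", ")))
  if (sum(r[c("kPA", "kPG", "kPV", "kPL")]) <= 0)
    return("at least one peritoneal outflow rate must be positive")
  if (length(object@trapping) != 1L || is.na(object@trapping))
    return("trapping must be TRUE or FALSE")
  TRUE
})

#' Construct kinetic parameters
#'
#' @param kPA peritoneal-to-blood absorption rate (1/min).
#' @param kPG,kPV,kPL pre-systemic delivery rates to gut, visceral fat, liver.
#' @param kBG,kBV,kBL post-systemic (blood-to-tissue) extraction rates.
#' @param kLoss irreversible loss from blood (1/min).
#' @param trapping logical; tissue compartments irreversible (default TRUE).
#' @return A [KineticParams-class] object.
#' @examples
#' kineticParams()                       # calibrated defaults
#' kineticParams(kPV = 0.021)           # elevated visceral-fat delivery
#' @export
kineticParams <- function(kPA = 0.002, kPG = 0.011, kPV = 0.007, kPL = 0.0025,
                          kBG = 6e-4, kBV = 5e-4, kBL = 1.2e-3, kLoss = 7e-4,
                          trapping = TRUE) {
  new("KineticParams", kPA = kPA, kPG = kPG, kPV = kPV, kPL = kPL,
      kBG = kBG, kBV = kBV, kBL = kBL, kLoss = kLoss, trapping = trapping)
}

#' @rdname viscnet-generics
#' @export
setMethod("kineticRates", "KineticParams", function(x, ...) {
  r <- vapply(.RATE_NAMES, function(nm) slot(x, nm), numeric(1))
  names(r) <- .RATE_NAMES
  r
})

setMethod("show", "KineticParams", function(object) {
  r <- kineticRates(object)
  cat("KineticParams (1/min):\n")
  cat(sprintf("  depot:  kPA=%.4g kPG=%.4g kPV=%.4g kPL=%.4g\n",
              r["kPA"], r["kPG"], r["kPV"], r["kPL"]))
  cat(sprintf("  blood:  kBG=%.4g kBV=%.4g kBL=%.4g kLoss=%.4g\n",
              r["kBG"], r["kBV"], r["kBL"], r["kLoss"]))
  cat(sprintf("  trapping: %s\n", object@trapping))
})

## ---- TimeActivityCurve -----------------------------------------------------

#' A sampled time-activity curve for one region of interest
#'
#' Activity concentration (MBq/mL, or \%ID/g after normalisation) against time
#' (minutes) for one ROI.  Times start at 0 and increase strictly.
#'
#' @slot times minutes, strictly increasing from 0.
#' @slot activities non-negative activity concentrations, same length.
#' @slot roi one of \code{"liver"}, \code{"visceral_fat"}, \code{"gut"},
#'   \code{"blood"}.
#' @export
setClass("TimeActivityCurve",
  representation(times = "numeric", activities = "numeric", roi = "character"))

setValidity("TimeActivityCurve", function(object) {
  t <- object@times; a <- object@activities
  if (length(t) != length(a)) return("times and activities differ in length")
  if (length(t) < 2L) return("need at least 2 samples")
  if (t[1] != 0) return("times must start at 0")
  if (any(diff(t) <= 0)) return("times must be strictly increasing")
  if (any(!is.finite(a)) || any(a < 0)) return("activities must be finite and >= 0")
  if (length(object@roi) != 1L || !object@roi %in% .ROIS)
    return(sprintf("roi must be one of: %s", paste(.ROIS, collapse = ", ")))
  TRUE
})

#' Construct a time-activity curve
#'
#' @param times minutes, strictly increasing from 0.
#' @param activities activity concentrations, same length as \code{times}.
#' @param roi ROI label.
#' @return A [TimeActivityCurve-class].
#' @export
timeActivityCurve <- function(times, activities, roi) {
  new("TimeActivityCurve", times = as.numeric(times),
      activities = as.numeric(activities), roi = roi)
}

setMethod("show", "TimeActivityCurve", function(object) {
  cat(sprintf("TimeActivityCurve [%s]: %d samples over %.3g-%.3g min, peak %.4g\n",
              object@roi, length(object@times), min(object@times),
              max(object@times), max(object@activities)))
})

## ---- TracerSimulation ------------------------------------------------------

#' Result of a tracer-kinetics simulation
#'
#' Holds the compartment amounts (MBq) over the time grid, the per-ROI
#' activity-concentration curves (amount divided by ROI volume), and the
#' generating parameters.  Columns of \code{amounts}: \code{P} (peritoneal
#' depot), \code{B} (blood), tissue contents \code{gut}, \code{visceral_fat},
#' \code{liver}, \code{loss}, and the cumulative route integrals
#' \code{gut_pre}, \code{visceral_fat_pre}, \code{liver_pre},
#' \code{gut_post}, \code{visceral_fat_post}, \code{liver_post}.
#'
#' @slot times time grid (min).
#' @slot amounts matrix, time points by compartments (MBq).
#' @slot tacs named list of [TimeActivityCurve-class] (liver, visceral_fat,
#'   gut, blood).
#' @slot params the generating [KineticParams-class].
#' @slot dose injected dose (MBq).
#' @slot volumes named ROI volumes (mL).
#' @export
setClass("TracerSimulation",
  representation(times = "numeric", amounts = "matrix", tacs = "list",
                 params = "KineticParams", dose = "numeric",
                 volumes = "numeric"))

#' @rdname viscnet-generics
#' @export
setMethod("tacs", "TracerSimulation", function(x, ...) x@tacs)

#' @rdname viscnet-generics
#' @export
setMethod("amounts", "TracerSimulation", function(x, ...) x@amounts)

#' Cumulative pre-systemic delivery to gut + visceral fat
#'
#' Amount (MBq) delivered through the peritoneal-to-gut and
#' peritoneal-to-visceral-fat routes up to time \code{tMax}.
#'
#' @param x a [TracerSimulation-class].
#' @param tMax time (min); must lie on the simulation grid.
#' @return Named numeric: per-route amounts and their \code{total}.
#' @export
setMethod("deliveredPreSystemic", "TracerSimulation", function(x, tMax = 10) {
  i <- which(abs(x@times - tMax) < 1e-9)
  if (length(i) != 1L)
    stop("tMax = ", tMax, " is not on the simulation grid")
  g <- x@amounts[i, "gut_pre"]; v <- x@amounts[i, "visceral_fat_pre"]
  l <- x@amounts[i, "liver_pre"]
  c(gut = unname(g), visceral_fat = unname(v), liver = unname(l),
    total = unname(g + v))
})

setMethod("show", "TracerSimulation", function(object) {
  cat(sprintf("TracerSimulation: dose %.3g MBq over %.3g-%.3g min (%d frames)\n",
              object@dose, min(object@times), max(object@times),
              length(object@times)))
  pre <- deliveredPreSystemic(object, max(object@times[object@times <= 10]))
  cat(sprintf("  gut+VF pre-systemic by 10 min: %.1f%% of dose\n",
              100 * pre["total"] / max(object@dose, .Machine$double.eps)))
})

## ---- StudyDesign -----------------------------------------------------------

#' Design of a synthetic cohort
#'
#' Encodes the two-by-two study design (age group at scan: weaning vs adult;
#' maternal diet: ND vs HFD), per-stratum effect multipliers on the kinetic
#' rates, CT-density means, histology severity, and noise levels.  The default
#' design reproduces the study structure: strata of 11 (weaning.ND),
#' 8 (weaning.HFD), 10 (adult.ND) and 9 (adult.HFD) animals, 38 in total;
#' weaning strata have several-fold higher gut/visceral-fat delivery and
#' extraction rates and lower CT densities than adult strata; the weaning.HFD
#' stratum carries an extra multiplier on the visceral-fat rates; the
#' adult.HFD stratum elevated post-systemic hepatic extraction.
#'
#' @slot groupSizes named integer vector over the four strata.
#' @slot rateMultipliers named list per stratum of named multipliers on
#'   kinetic rates.
#' @slot densityMeans named list per stratum: mean HU for liver,
#'   visceral_fat, gut.
#' @slot histologySeverity per-stratum severity in [0, 1] driving the grade
#'   distributions.
#' @slot bodyWeightMean,bodyWeightSD grams, per stratum (named).
#' @slot glycemiaMean,glycemiaSD mmol/L, per stratum (named).
#' @slot triglycerideMean,triglycerideSD mg/dl, per stratum (named).
#' @slot doseMean,doseSD injected dose, MBq.
#' @slot noiseCV multiplicative measurement-noise CV on activities.
#' @slot subjectSDLog log-normal between-subject jitter (sdlog) on rates.
#' @slot histologyFraction fraction of subjects with histology available.
#' @export
setClass("StudyDesign",
  representation(groupSizes = "numeric", rateMultipliers = "list",
                 densityMeans = "list", histologySeverity = "numeric",
                 bodyWeightMean = "numeric", bodyWeightSD = "numeric",
                 glycemiaMean = "numeric", glycemiaSD = "numeric",
                 triglycerideMean = "numeric", triglycerideSD = "numeric",
                 doseMean = "numeric", doseSD = "numeric",
                 noiseCV = "numeric", subjectSDLog = "numeric",
                 histologyFraction = "numeric"))

setValidity("StudyDesign", function(object) {
  gs <- object@groupSizes
  if (!identical(sort(names(gs)), sort(.STRATA)))
    return(sprintf("groupSizes must be named over: %s",
                   paste(.STRATA, collapse = ", ")))
  if (any(!is.finite(gs)) || any(gs < 0) || any(gs != round(gs)))
    return("group sizes must be non-negative integers")
  for (s in .STRATA) {
    m <- object@rateMultipliers[[s]]
    if (!is.null(m) && (any(m < 0) || !all(names(m) %in% .RATE_NAMES)))
      return(sprintf("invalid rate multipliers for stratum %s", s))
  }
  if (object@noiseCV < 0) return("noiseCV must be >= 0")
  if (object@histologyFraction < 0 || object@histologyFraction > 1)
    return("histologyFraction must lie in [0, 1]")
  TRUE
})

#' Construct a study design
#'
#' All arguments default to the study conditions; see [StudyDesign-class].
#' Per-stratum arguments are named vectors/lists over
#' \code{weaning.ND, weaning.HFD, adult.ND, adult.HFD}.
#'
#' @param groupSizes named counts per stratum (default 11/8/10/9).
#' @param rateMultipliers per-stratum multipliers applied to the default
#'   kinetic rates before per-subject jitter.
#' @param densityMeans per-stratum mean CT density (HU) per ROI.
#' @param histologySeverity per-stratum severity in [0, 1].
#' @param bodyWeightMean,bodyWeightSD,glycemiaMean,glycemiaSD
#'   per-stratum means/SDs.
#' @param triglycerideMean,triglycerideSD per-stratum means/SDs (mg/dl).
#' @param doseMean,doseSD injected dose (MBq).
#' @param noiseCV measurement-noise CV (default 0.05).
#' @param subjectSDLog between-subject log-normal jitter on rates.
#' @param histologyFraction fraction of subjects biopsied (default 0.5).
#' @return A [StudyDesign-class].
#' @export
studyDesign <- function(
    groupSizes = c(weaning.ND = 11, weaning.HFD = 8, adult.ND = 10, adult.HFD = 9),
    rateMultipliers = list(
      weaning.ND  = c(),
      weaning.HFD = c(kPG = 1.5, kPV = 3, kBG = 1.5, kBV = 3),
      adult.ND    = c(kPG = 1 / 3, kPV = 1 / 3, kBG = 1 / 3, kBV = 1 / 3),
      adult.HFD   = c(kPG = 1 / 3, kPV = 1 / 3, kBG = 1 / 3, kBV = 1 / 3,
                      kBL = 1.4)),
    densityMeans = list(
      weaning.ND  = c(liver = 35, visceral_fat = -110, gut = 20),
      weaning.HFD = c(liver = 45, visceral_fat = -80, gut = 22),
      adult.ND    = c(liver = 55, visceral_fat = -70, gut = 45),
      adult.HFD   = c(liver = 50, visceral_fat = -75, gut = 43)),
    histologySeverity = c(weaning.ND = 0.15, weaning.HFD = 0.35,
                          adult.ND = 0.55, adult.HFD = 0.80),
    bodyWeightMean = c(weaning.ND = 17, weaning.HFD = 17,
                       adult.ND = 31, adult.HFD = 33),
    bodyWeightSD = c(weaning.ND = 1, weaning.HFD = 1,
                     adult.ND = 2, adult.HFD = 2),
    glycemiaMean = c(weaning.ND = 7.5, weaning.HFD = 7.5,
                     adult.ND = 7.5, adult.HFD = 8.5),
    glycemiaSD = c(weaning.ND = 1, weaning.HFD = 1, adult.ND = 1, adult.HFD = 1),
    triglycerideMean = c(weaning.ND = 80, weaning.HFD = 85,
                         adult.ND = 72, adult.HFD = 102),
    triglycerideSD = c(weaning.ND = 12, weaning.HFD = 12,
                       adult.ND = 10, adult.HFD = 14),
    doseMean = 4, doseSD = 0.4,
    noiseCV = 0.05, subjectSDLog = 0.15, histologyFraction = 0.5) {
  new("StudyDesign", groupSizes = groupSizes,
      rateMultipliers = rateMultipliers, densityMeans = densityMeans,
      histologySeverity = histologySeverity,
      bodyWeightMean = bodyWeightMean, bodyWeightSD = bodyWeightSD,
      glycemiaMean = glycemiaMean, glycemiaSD = glycemiaSD,
      triglycerideMean = triglycerideMean, triglycerideSD = triglycerideSD,
      doseMean = doseMean, doseSD = doseSD, noiseCV = noiseCV,
      subjectSDLog = subjectSDLog, histologyFraction = histologyFraction)
}

setMethod("show", "StudyDesign", function(object) {
  gs <- object@groupSizes[.STRATA]
  cat("StudyDesign:", sum(gs), "subjects (",
      paste(sprintf("%s=%d", .STRATA, gs), collapse = ", "), ")\n")
  cat(sprintf("  noiseCV=%.3g subjectSDLog=%.3g histologyFraction=%.2g\n",
              object@noiseCV, object@subjectSDLog, object@histologyFraction))
})

## ---- AbundanceTable --------------------------------------------------------

#' Taxa/pathway abundance table with class labels
#'
#' A [SummarizedExperiment-class] subclass: one assay \code{"abundance"}
#' (features by subjects, non-negative), a \code{class_label} column in
#' \code{colData}, and a \code{normalized} flag in \code{metadata}.  When
#' normalised (total-sum scaling), every subject column sums to 1.
#'
#' @seealso [abundanceTable()], [totalSumNormalize()], [runLefse()]
#' @export
setClass("AbundanceTable", contains = "SummarizedExperiment")

setValidity("AbundanceTable", function(object) {
  if (!"abundance" %in% SummarizedExperiment::assayNames(object))
    return("assay 'abundance' is required")
  v <- SummarizedExperiment::assay(object, "abundance")
  if (any(!is.finite(v)) || any(v < 0)) return("abundances must be finite and >= 0")
  if (!"class_label" %in% colnames(SummarizedExperiment::colData(object)))
    return("colData must contain class_label")
  norm <- S4Vectors::metadata(object)$normalized
  if (is.null(norm) || !is.logical(norm) || length(norm) != 1L)
    return("metadata$normalized must be a single logical")
  if (isTRUE(norm) && ncol(v) > 0) {
    cs <- colSums(v)
    if (any(abs(cs - 1) > 1e-9))
      return("normalized table has column sums differing from 1")
  }
  TRUE
})

#' Construct an abundance table
#'
#' @param values non-negative matrix, features in rows, subjects in columns.
#' @param classLabels one class label per subject column.
#' @param featureIds,subjectIds optional dimension names (default taken from
#'   \code{values}).
#' @param normalized logical; columns already sum to 1 (total-sum scaled).
#' @return An [AbundanceTable-class].
#' @examples
#' m <- matrix(rpois(12, 20), 3, 4,
#'             dimnames = list(paste0("taxon_", 1:3), paste0("s", 1:4)))
#' at <- abundanceTable(m, classLabels = c("a", "a", "b", "b"))
#' @export
abundanceTable <- function(values, classLabels, featureIds = rownames(values),
                           subjectIds = colnames(values), normalized = FALSE) {
  values <- as.matrix(values)
  if (is.null(featureIds)) featureIds <- sprintf("feature_%d", seq_len(nrow(values)))
  if (is.null(subjectIds)) subjectIds <- sprintf("subject_%d", seq_len(ncol(values)))
  if (length(classLabels) != ncol(values))
    stop("classLabels must have one entry per subject column")
  dimnames(values) <- list(featureIds, subjectIds)
  se <- SummarizedExperiment(
    assays = list(abundance = values),
    colData = S4Vectors::DataFrame(class_label = as.character(classLabels),
                                   row.names = subjectIds))
  S4Vectors::metadata(se)$normalized <- isTRUE(normalized)
  out <- new("AbundanceTable", se)
  validObject(out)
  out
}

#' @rdname viscnet-generics
#' @export
setMethod("classLabels", "AbundanceTable", function(x, ...)
  as.character(SummarizedExperiment::colData(x)$class_label))

#' @rdname viscnet-generics
#' @export
setMethod("isNormalized", "AbundanceTable", function(x)
  isTRUE(S4Vectors::metadata(x)$normalized))

#' Abundance matrix accessor
#' @param x an [AbundanceTable-class].
#' @return The features-by-subjects abundance matrix.
#' @export
abundances <- function(x) SummarizedExperiment::assay(x, "abundance")

setMethod("show", "AbundanceTable", function(object) {
  cat(sprintf("AbundanceTable: %d features x %d subjects (%s), classes: %s\n",
              nrow(object), ncol(object),
              if (isNormalized(object)) "relative" else "raw",
              paste(names(table(classLabels(object))), collapse = ", ")))
})

## ---- VisceralCohort --------------------------------------------------------

#' A simulated (or assembled) imaging + histology + microbiome cohort
#'
#' @slot subjects data.frame of per-subject metadata: subject_id, age_group,
#'   maternal_diet, stratum, body_weight_g, injected_dose_MBq,
#'   glycemia_mmol_L, triglycerides_mg_dl, histology_available.
#' @slot tacs named list (by subject_id) of named lists of
#'   [TimeActivityCurve-class] over the four ROIs.
#' @slot densities data.frame: subject_id plus per-ROI CT density (HU).
#' @slot histology data.frame of raw histology observations for biopsied
#'   subjects.
#' @slot kinetics data.frame of the generating per-subject kinetic rates
#'   (ground truth, for parameter-recovery checks).
#' @slot taxa an [AbundanceTable-class] or NULL.
#' @slot design the generating [StudyDesign-class].
#' @slot seed master seed used.
#' @export
setClass("VisceralCohort",
  representation(subjects = "data.frame", tacs = "list",
                 densities = "data.frame", histology = "data.frame",
                 kinetics = "data.frame", taxa = "ANY",
                 design = "StudyDesign", seed = "numeric"))

setValidity("VisceralCohort", function(object) {
  s <- object@subjects
  need <- c("subject_id", "age_group", "maternal_diet", "body_weight_g",
            "injected_dose_MBq", "glycemia_mmol_L")
  if (!all(need %in% names(s)))
    return(sprintf("subjects lacks column(s): %s",
                   paste(setdiff(need, names(s)), collapse = ", ")))
  if (nrow(s) > 0) {
    if (any(s$body_weight_g <= 0)) return("body weights must be > 0")
    if (any(s$injected_dose_MBq <= 0)) return("injected doses must be > 0")
    if (!all(s$subject_id %in% names(object@tacs) | length(object@tacs) == 0))
      return("tacs must be keyed by subject_id")
  }
  TRUE
})

#' @rdname viscnet-generics
#' @export
setMethod("subjects", "VisceralCohort", function(x, ...) x@subjects)

#' @rdname viscnet-generics
#' @export
setMethod("tacs", "VisceralCohort", function(x, ...) x@tacs)

#' @rdname viscnet-generics
#' @export
setMethod("histology", "VisceralCohort", function(x, ...) x@histology)

#' @rdname viscnet-generics
#' @export
setMethod("densities", "VisceralCohort", function(x, ...) x@densities)

#' @rdname viscnet-generics
#' @export
setMethod("taxa", "VisceralCohort", function(x, ...) x@taxa)

#' @rdname viscnet-generics
#' @export
setMethod("kineticRates", "VisceralCohort", function(x, ...) x@kinetics)

setMethod("show", "VisceralCohort", function(object) {
  s <- object@subjects
  cat(sprintf("VisceralCohort: %d subjects, seed %d\n", nrow(s), object@seed))
  if (nrow(s)) print(table(age_group = s$age_group, maternal_diet = s$maternal_diet))
  if (!is.null(object@taxa))
    cat(sprintf("  taxa: %d features\n", nrow(object@taxa)))
})
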