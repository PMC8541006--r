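## Synthetic cohort generation.  One master seed; per-subject streams are
## derived by counter-based splitting (stratum index * 1000 + within-stratum
## position), so changing one stratum's size never reshuffles another
## subject's draws.

.strataOf <- function(stratum) {
  parts <- strsplit(stratum, ".", fixed = TRUE)[[1]]
  list(age_group = parts[1], maternal_diet = parts[2])
}

.subjectParams <- function(design, stratum, seed) {
  base <- kineticRates(kineticParams())
  mult <- design@rateMultipliers[[stratum]]
  if (length(mult)) base[names(mult)] <- base[names(mult)] * mult
  jit <- if (design@subjectSDLog > 0)
    .withSeed(seed, stats::rlnorm(length(base), 0, design@subjectSDLog))
  else rep(1, length(base))
  rates <- base * jit
  do.call(kineticParams, as.list(rates))
}

.subjectHistology <- function(sev, seed) {
  .withSeed(seed, {
    steat <- min(100, max(0, stats::rnorm(1, 75 * sev, 15)))
    foci <- stats::rpois(1, 6 * sev)
    data.frame(
      steatosis_pct = steat,
      lobular_foci = foci,
      ballooning = stats::rbinom(1, 1, min(1, 0.7 * sev)),
      portal_inflammation = stats::rbinom(1, 1, min(1, 0.5 * sev)),
      fibrosis = stats::rbinom(1, 1, min(1, 0.3 * sev)),
      vessel_dilatation = stats::rbinom(1, 1, 0.2))
  })
}

#' Generate a synthetic cohort
#'
#' Builds a cohort with the study's two-by-two design (default strata
#' 11/8/10/9, 38 animals): per-subject kinetic rates are the calibrated
#' defaults scaled by the stratum multipliers and log-normal between-subject
#' jitter; time-activity curves come from [simulateTracerKinetics()] (with
#' multiplicative measurement noise unless \code{noiseFree}); CT densities are
#' Gaussian per stratum with the liver density linearly depressed by the
#' subject's planted steatosis grade; histology observations are drawn from
#' severity-driven distributions; and, optionally, a taxa abundance table with
#' planted age-group biomarkers is attached.
#'
#' Deterministic given \code{seed}: the same seed reproduces the cohort
#' exactly.
#'
#' @param design a [StudyDesign-class] (default: the study conditions).
#' @param seed master seed.
#' @param noiseFree disable measurement noise on the activity curves.
#' @param simulateTacs set FALSE to skip curve simulation (metadata, rates,
#'   histology and taxa only; faster for design-level checks).
#' @param withTaxa attach a taxa table via [generateTaxaTable()].
#' @param nTaxa number of taxa for the attached table.
#' @return A [VisceralCohort-class].
#' @examples
#' coh <- generateCohort(seed = 1, simulateTacs = FALSE)
#' table(subjects(coh)$age_group, subjects(coh)$maternal_diet)
#' @export
generateCohort <- function(design = studyDesign(), seed = 1L,
                           noiseFree = FALSE, simulateTacs = TRUE,
                           withTaxa = TRUE, nTaxa = 60L) {
  stopifnot(is(design, "StudyDesign"))
  validObject(design)
  seed <- as.integer(seed)

  subj <- list(); tacsL <- list(); dens <- list(); histo <- list(); kin <- list()
  counter <- 0L
  for (si in seq_along(.STRATA)) {
    stratum <- .STRATA[si]
    nS <- design@groupSizes[[stratum]]
    grp <- .strataOf(stratum)
    sev <- design@histologySeverity[[stratum]]
    if (nS == 0) next
    for (k in seq_len(nS)) {
      id <- sprintf("%s_%02d", gsub(".", "_", stratum, fixed = TRUE), k)
      sSeed <- .splitSeed(seed, si * 1000L + k)
      meta <- .withSeed(sSeed, {
        data.frame(
          subject_id = id, age_group = grp$age_group,
          maternal_diet = grp$maternal_diet, stratum = stratum,
          body_weight_g = max(1, stats::rnorm(1, design@bodyWeightMean[[stratum]],
                                              design@bodyWeightSD[[stratum]])),
          injected_dose_MBq = max(0.1, stats::rnorm(1, design@doseMean,
                                                    design@doseSD)),
          glycemia_mmol_L = max(0, stats::rnorm(1, design@glycemiaMean[[stratum]],
                                                design@glycemiaSD[[stratum]])),
          triglycerides_mg_dl = stats::rnorm(1, design@triglycerideMean[[stratum]],
                                             design@triglycerideSD[[stratum]]),
          stringsAsFactors = FALSE)
      })
      # below-range TG readings surface as the assay floor (70 mg/dl)
      if (meta$triglycerides_mg_dl < 70) meta$triglycerides_mg_dl <- 70
      # deterministic within-stratum spread of biopsied subjects
      f <- design@histologyFraction
      meta$histology_available <- floor(k * f) > floor((k - 1) * f)

      params <- .subjectParams(design, stratum, .splitSeed(sSeed, 1L))
      kin[[id]] <- data.frame(subject_id = id, t(kineticRates(params)),
                              stringsAsFactors = FALSE)

      h <- .subjectHistology(sev, .splitSeed(sSeed, 2L))
      if (meta$histology_available)
        histo[[id]] <- cbind(data.frame(subject_id = id), h)

      # CT density: stratum Gaussian; liver HU decreases with steatosis grade
      steatGrade <- gradeSteatosis(h$steatosis_pct)
      dm <- design@densityMeans[[stratum]]
      dens[[id]] <- .withSeed(.splitSeed(sSeed, 3L), data.frame(
        subject_id = id,
        liver_HU = stats::rnorm(1, dm[["liver"]] - 5 * steatGrade, 6),
        visceral_fat_HU = stats::rnorm(1, dm[["visceral_fat"]], 8),
        gut_HU = stats::rnorm(1, dm[["gut"]], 6),
        stringsAsFactors = FALSE))

      if (simulateTacs) {
        sim <- simulateTracerKinetics(
          params, dose = meta$injected_dose_MBq,
          volumes = defaultRoiVolumes(meta$body_weight_g),
          noiseCV = if (noiseFree) 0 else design@noiseCV,
          seed = .splitSeed(sSeed, 4L))
        tacsL[[id]] <- tacs(sim)
      }
      subj[[id]] <- meta
      counter <- counter + 1L
    }
  }
  subjects <- do.call(rbind, subj); rownames(subjects) <- NULL
  densities <- do.call(rbind, dens); rownames(densities) <- NULL
  histology <- if (length(histo)) do.call(rbind, histo) else
    data.frame(subject_id = character(0))
  rownames(histology) <- NULL
  kinetics <- do.call(rbind, kin); rownames(kinetics) <- NULL

  taxaTab <- NULL
  if (withTaxa && nrow(subjects) > 0) {
    taxaTab <- generateTaxaTable(
      classLabels = stats::setNames(subjects$age_group, subjects$subject_id),
      nTaxa = nTaxa, seed = .splitSeed(seed, 999L))
  }
  new("VisceralCohort", subjects = subjects, tacs = tacsL,
      densities = densities, histology = histology, kinetics = kinetics,
      taxa = taxaTab, design = design, seed = as.numeric(seed))
}

#' Write a cohort to the interchange files
#'
#' Writes \code{subjects.csv}, one \code{tac_<subject>.csv} per subject,
#' \code{histology.csv} (biopsied subjects only), \code{densities.csv}, and
#' \code{abundance.tsv} into \code{dir}.
#'
#' @param cohort a [VisceralCohort-class].
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
  stopifnot(is(cohort, "VisceralCohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeSubjectTable(subjects(cohort), file.path(dir, "subjects.csv"))
  for (id in names(tacs(cohort)))
    writeTacTable(tacs(cohort)[[id]], file.path(dir, sprintf("tac_%s.csv", id)))
  if (nrow(histology(cohort)))
    writeHistologyTable(histology(cohort), file.path(dir, "histology.csv"))
  .writeTable(densities(cohort), file.path(dir, "densities.csv"))
  if (!is.null(taxa(cohort)))
    writeAbundanceTable(taxa(cohort), file.path(dir, "abundance.tsv"))
  invisible(dir)
}
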