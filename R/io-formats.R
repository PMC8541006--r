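## Tabular interchange formats.  All tables are UTF-8 with a single header
## row; comma-separated except abundance tables, which are tab-separated by
## community convention.  Missing values are empty cells (read back as NA),
## never zero.  The below-range triglyceride sentinel is the literal "<LOD".

.SUBJECT_COLS <- c("subject_id", "age_group", "maternal_diet", "body_weight_g",
                   "injected_dose_MBq", "glycemia_mmol_L",
                   "triglycerides_mg_dl", "histology_available")
.TAC_COLS <- c("time_min", "roi", "activity_MBq_per_mL")
.HISTO_COLS <- c("subject_id", "steatosis_pct", "lobular_foci", "ballooning",
                 "portal_inflammation", "fibrosis", "vessel_dilatation")

.requireCols <- function(df, cols, what, path) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    .stopv(sprintf("%s '%s' lacks required column(s): %s",
                   what, path, paste(miss, collapse = ", ")))
}

#' Floor below-range triglyceride values
#'
#' Triglyceride readings below the assay's measurable range (recorded with the
#' sentinel \code{"<LOD"}) are set to the lowest accessible value, 70 mg/dl.
#' In-range numeric values pass through unchanged; the operation is
#' idempotent.  Missing values stay missing.
#'
#' @param value numeric or character vector; \code{"<LOD"} marks below-range
#'   readings, empty strings/NA mark missing values.
#' @return Numeric vector in mg/dl.
#' @examples
#' floorTriglycerides(c("<LOD", "120", NA))   # 70 120 NA
#' @export
floorTriglycerides <- function(value) {
  if (is.numeric(value)) {
    out <- as.numeric(value)
  } else {
    ch <- trimws(as.character(value))
    out <- rep(NA_real_, length(ch))
    lod <- !is.na(ch) & ch == "<LOD"
    num <- !is.na(ch) & !lod & nzchar(ch)
    out[lod] <- 70
    parsed <- suppressWarnings(as.numeric(ch[num]))
    if (anyNA(parsed))
      .stopv("non-numeric triglyceride value(s): ",
             paste(ch[num][is.na(parsed)], collapse = ", "))
    out[num] <- parsed
  }
  if (any(!is.na(out) & out < 0))
    .stopv("negative triglyceride value(s)")
  out
}

#' Read a subject metadata table
#'
#' Expects the \code{subjects.csv} layout (columns \code{subject_id},
#' \code{age_group}, \code{maternal_diet}, \code{body_weight_g},
#' \code{injected_dose_MBq}, \code{glycemia_mmol_L},
#' \code{triglycerides_mg_dl}, \code{histology_available}).  Below-range
#' triglycerides (\code{"<LOD"}) are floored to 70 mg/dl; empty cells become
#' NA.  Validation failures name the offending subject and row.
#'
#' @param path CSV file path.
#' @return data.frame, one row per subject.
#' @export
readSubjectTable <- function(path) {
  if (!file.exists(path)) .stopv("subject table not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  .requireCols(df, .SUBJECT_COLS, "subject table", path)
  df <- df[.SUBJECT_COLS]
  num <- function(col) {
    v <- trimws(df[[col]])
    out <- suppressWarnings(as.numeric(ifelse(nzchar(v), v, NA)))
    bad <- nzchar(v) & is.na(out)
    if (any(bad))
      .stopv(sprintf("subject table row %s (%s): cannot parse %s '%s'",
                     paste(which(bad), collapse = ","),
                     paste(df$subject_id[bad], collapse = ","), col,
                     paste(v[bad], collapse = ",")))
    out
  }
  out <- data.frame(
    subject_id = df$subject_id,
    age_group = df$age_group,
    maternal_diet = df$maternal_diet,
    body_weight_g = num("body_weight_g"),
    injected_dose_MBq = num("injected_dose_MBq"),
    glycemia_mmol_L = num("glycemia_mmol_L"),
    triglycerides_mg_dl = floorTriglycerides(df$triglycerides_mg_dl),
    histology_available = toupper(trimws(df$histology_available)) %in%
      c("TRUE", "1", "YES"),
    stringsAsFactors = FALSE)
  badAge <- !out$age_group %in% c("weaning", "adult")
  if (any(badAge))
    .stopv("invalid age_group for subject(s): ",
           paste(out$subject_id[badAge], collapse = ", "))
  badDiet <- !out$maternal_diet %in% c("ND", "HFD")
  if (any(badDiet))
    .stopv("invalid maternal_diet for subject(s): ",
           paste(out$subject_id[badDiet], collapse = ", "))
  badW <- is.na(out$body_weight_g) | out$body_weight_g <= 0
  if (any(badW))
    .stopv("non-positive or missing body_weight_g for subject(s): ",
           paste(out$subject_id[badW], collapse = ", "))
  badD <- is.na(out$injected_dose_MBq) | out$injected_dose_MBq <= 0
  if (any(badD))
    .stopv("non-positive or missing injected_dose_MBq for subject(s): ",
           paste(out$subject_id[badD], collapse = ", "))
  badG <- !is.na(out$glycemia_mmol_L) & out$glycemia_mmol_L < 0
  if (any(badG))
    .stopv("negative glycemia for subject(s): ",
           paste(out$subject_id[badG], collapse = ", "))
  out
}

.writeTable <- function(df, path, sep = ",") {
  numCols <- vapply(df, is.numeric, logical(1))
  out <- df
  for (j in which(numCols)) out[[j]] <- .fmtNum(df[[j]])
  for (j in which(!numCols)) {
    v <- as.character(df[[j]])
    v[is.na(v)] <- ""
    out[[j]] <- v
  }
  utils::write.table(out, path, sep = sep, quote = FALSE, na = "",
                     row.names = FALSE, fileEncoding = "UTF-8", eol = "\n")
  invisible(path)
}

#' Write a subject metadata table
#' @param df data.frame as returned by [readSubjectTable()].
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
writeSubjectTable <- function(df, path) {
  .requireCols(df, .SUBJECT_COLS, "subject table", path)
  .writeTable(df[.SUBJECT_COLS], path)
}

#' Read one subject's time-activity curves
#'
#' Long-format CSV with columns \code{time_min}, \code{roi},
#' \code{activity_MBq_per_mL}; ROIs \code{liver}, \code{visceral_fat},
#' \code{gut}, \code{blood}.
#'
#' @param path CSV path.
#' @return Named list of [TimeActivityCurve-class], one per ROI present.
#' @export
readTacTable <- function(path) {
  if (!file.exists(path)) .stopv("TAC table not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .requireCols(df, .TAC_COLS, "TAC table", path)
  out <- lapply(split(df, df$roi), function(d) {
    d <- d[order(d$time_min), ]
    timeActivityCurve(d$time_min, d$activity_MBq_per_mL, d$roi[1])
  })
  out[intersect(.ROIS, names(out))]
}

#' Write time-activity curves for one subject
#' @param tacList named list of [TimeActivityCurve-class].
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
writeTacTable <- function(tacList, path) {
  df <- do.call(rbind, lapply(tacList, function(tc)
    data.frame(time_min = tc@times, roi = tc@roi,
               activity_MBq_per_mL = tc@activities,
               stringsAsFactors = FALSE)))
  rownames(df) <- NULL
  .writeTable(df, path)
}

#' Read a raw histology observation table
#'
#' Columns: \code{subject_id}, \code{steatosis_pct}, \code{lobular_foci},
#' \code{ballooning}, \code{portal_inflammation}, \code{fibrosis},
#' \code{vessel_dilatation}.
#'
#' @param path CSV path.
#' @return data.frame.
#' @export
readHistologyTable <- function(path) {
  if (!file.exists(path)) .stopv("histology table not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .requireCols(df, .HISTO_COLS, "histology table", path)
  df
}

#' Write a histology table
#' @param df histology data.frame.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
writeHistologyTable <- function(df, path) .writeTable(df, path)

#' Read an abundance table (TSV)
#'
#' Tab-separated, first column \code{feature_id}, one column per subject.
#' Class labels may be supplied directly or joined from a subject table via
#' \code{classColumn}.  The table is flagged as normalised when every column
#' sums to 1 within 1e-6.
#'
#' @param path TSV path.
#' @param classLabels optional vector of class labels, one per subject column
#'   (named by subject or in column order).
#' @param subjectTable optional data.frame with \code{subject_id} to join
#'   labels from.
#' @param classColumn column of \code{subjectTable} holding the class label.
#' @return An [AbundanceTable-class].
#' @export
readAbundanceTable <- function(path, classLabels = NULL, subjectTable = NULL,
                               classColumn = "age_group") {
  if (!file.exists(path)) .stopv("abundance table not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(df)[1] != "feature_id")
    .stopv("abundance table '", path, "' must have first column feature_id")
  m <- as.matrix(df[-1])
  rownames(m) <- df$feature_id
  if (!is.numeric(m)) .stopv("abundance values must be numeric")
  ids <- colnames(m)
  if (is.null(classLabels)) {
    if (!is.null(subjectTable)) {
      idx <- match(ids, subjectTable$subject_id)
      if (anyNA(idx))
        .stopv("subject(s) absent from subject table: ",
               paste(ids[is.na(idx)], collapse = ", "))
      classLabels <- subjectTable[[classColumn]][idx]
    } else classLabels <- rep("unlabelled", length(ids))
  } else if (!is.null(names(classLabels))) {
    classLabels <- classLabels[ids]
  }
  normalized <- ncol(m) > 0 && all(abs(colSums(m) - 1) < 1e-6)
  abundanceTable(m, classLabels = classLabels, normalized = normalized)
}

#' Write an abundance table (TSV)
#' @param x an [AbundanceTable-class].
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
writeAbundanceTable <- function(x, path) {
  m <- abundances(x)
  df <- data.frame(feature_id = rownames(m), as.data.frame(m),
                   check.names = FALSE, stringsAsFactors = FALSE)
  .writeTable(df, path, sep = "\t")
}
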