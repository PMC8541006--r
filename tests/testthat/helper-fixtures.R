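# fixtures built in code: small tables and cohorts shared across tests

writeToySubjects <- function(path = tempfile(fileext = ".csv"),
                             tweak = identity) {
  df <- data.frame(
    subject_id = c("w01", "w02", "a01", "a02"),
    age_group = c("weaning", "weaning", "adult", "adult"),
    maternal_diet = c("ND", "HFD", "ND", "HFD"),
    body_weight_g = c(16.5, 17.2, 30.1, 32.4),
    injected_dose_MBq = c(3.9, 4.1, 4.0, 4.2),
    glycemia_mmol_L = c(7.1, 7.9, 7.4, 8.8),
    triglycerides_mg_dl = c("<LOD", "95.5", "", "120"),
    histology_available = c(TRUE, FALSE, TRUE, TRUE),
    stringsAsFactors = FALSE)
  df <- tweak(df)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

toyAbundance <- function(values, classes, normalized = FALSE) {
  abundanceTable(values, classLabels = classes, normalized = normalized)
}

smallDesign <- function(nPer = 3) {
  studyDesign(groupSizes = c(weaning.ND = nPer, weaning.HFD = nPer,
                             adult.ND = nPer, adult.HFD = nPer))
}

# analytic closed-form amounts for the trapping model (independent of the
# matrix-exponential solver): P = D e^{-Kt}; B from the two-exponential
# convolution; trapped tissue content by direct integration.
analyticAmounts <- function(params, dose, t) {
  r <- kineticRates(params)
  K <- sum(r[c("kPA", "kPG", "kPV", "kPL")])
  kB <- sum(r[c("kBG", "kBV", "kBL", "kLoss")])
  P <- dose * exp(-K * t)
  B <- dose * r[["kPA"]] * (exp(-K * t) - exp(-kB * t)) / (kB - K)
  intP <- dose * (1 - exp(-K * t)) / K
  intB <- dose * r[["kPA"]] / (kB - K) *
    ((1 - exp(-K * t)) / K - (1 - exp(-kB * t)) / kB)
  list(P = P, B = B,
       gut = r[["kPG"]] * intP + r[["kBG"]] * intB,
       visceral_fat = r[["kPV"]] * intP + r[["kBV"]] * intB,
       liver = r[["kPL"]] * intP + r[["kBL"]] * intB,
       loss = r[["kLoss"]] * intB,
       gut_pre = r[["kPG"]] * intP,
       visceral_fat_pre = r[["kPV"]] * intP)
}
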