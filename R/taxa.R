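## Compositional taxa table generator: per-subject log-normal abundances,
## planted class effects on the log scale, then total-sum scaling.

.DEFAULT_PLANTED <- list(
  S24_7         = c(weaning = 2),
  Oscillospira  = c(weaning = 1.5),
  Ruminococcus  = c(weaning = 1),
  Desulfovibrio = c(adult = 2),
  RF39          = c(adult = 1.5),
  Akkermansia   = c(adult = 1.5),
  Lactobacillus = c(adult = 1))

#' Generate a compositional taxa abundance table
#'
#' Draws per-subject taxa abundances from a log-normal scheme: each taxon has
#' a baseline log-abundance (shared across subjects), planted taxa receive the
#' requested expected log2-fold difference between classes before
#' renormalisation, independent log-normal subject noise is added, and every
#' subject column is total-sum scaled to 1.  Optionally one taxon's log
#' abundance can be coupled linearly to a per-subject covariate (e.g. an
#' imaging metric) to plant a taxon--metric association.
#'
#' @param classLabels character vector of class labels, one per subject; if
#'   named, names become subject ids.
#' @param nTaxa total number of taxa (>= number of planted taxa).
#' @param plantedEffects named list: taxon -> named numeric of log2-fold
#'   enrichments per class (the named class's expected log2 abundance exceeds
#'   the other classes' by that amount).  Default: a panel of weaning- and
#'   adult-enriched genera.
#' @param seed seed; the table is deterministic given it.
#' @param sdLog log-scale within-class subject noise SD (default 0.6,
#'   calibrated so a 4-fold planted effect is recoverable at 10 vs 10
#'   subjects; 0 = noise-free).
#' @param coupling optional list \code{list(taxon =, covariate =, strength =)}
#'   adding \code{strength * scale(covariate)} to that taxon's log abundance.
#' @return A normalised [AbundanceTable-class] (columns sum to 1).
#' @examples
#' at <- generateTaxaTable(rep(c("weaning", "adult"), each = 5), nTaxa = 20,
#'                         seed = 7)
#' colSums(abundances(at))
#' @export
generateTaxaTable <- function(classLabels, nTaxa = 60L,
                              plantedEffects = .DEFAULT_PLANTED,
                              seed = 1L, sdLog = 0.6, coupling = NULL) {
  classLabels <- stats::setNames(as.character(classLabels),
                                 names(classLabels))
  nSub <- length(classLabels)
  if (nSub < 1L) .stopv("need at least one subject")
  if (is.null(plantedEffects)) plantedEffects <- list()
  if (nTaxa < length(plantedEffects))
    .stopv("nTaxa must be >= number of planted taxa")
  .checkNumber(sdLog, "sdLog", nonneg = TRUE)

  plantedNames <- names(plantedEffects)
  nNull <- nTaxa - length(plantedNames)
  featureIds <- c(plantedNames,
                  if (nNull > 0) sprintf("taxon_%03d", seq_len(nNull)))
  subjectIds <- if (!is.null(names(classLabels)) &&
                    all(nzchar(names(classLabels)))) names(classLabels)
                else sprintf("subject_%02d", seq_len(nSub))

  if (!is.null(coupling)) {
    if (!all(c("taxon", "covariate", "strength") %in% names(coupling)))
      .stopv("coupling needs elements taxon, covariate, strength")
    if (!coupling$taxon %in% featureIds)
      .stopv("coupling taxon not in the table: ", coupling$taxon)
    if (length(coupling$covariate) != nSub)
      .stopv("coupling covariate must have one value per subject")
  }

  logM <- .withSeed(seed, {
    mu <- stats::rnorm(nTaxa, 0, 1.5)          # baseline log abundances
    eps <- matrix(stats::rnorm(nTaxa * nSub, 0, sdLog), nTaxa, nSub)
    mu + eps
  })
  dimnames(logM) <- list(featureIds, subjectIds)

  for (tx in plantedNames) {
    eff <- plantedEffects[[tx]]
    if (is.null(names(eff)) || !all(names(eff) %in% classLabels))
      .stopv("planted effect for '", tx,
             "' names class(es) absent from classLabels")
    for (cls in names(eff))
      logM[tx, classLabels == cls] <-
        logM[tx, classLabels == cls] + eff[[cls]] * log(2)
  }
  if (!is.null(coupling)) {
    z <- as.numeric(scale(coupling$covariate))
    z[is.na(z)] <- 0
    logM[coupling$taxon, ] <- logM[coupling$taxon, ] + coupling$strength * z
  }
  m <- exp(logM)
  m <- sweep(m, 2, colSums(m), "/")
  abundanceTable(m, classLabels = unname(classLabels),
                 featureIds = featureIds, subjectIds = subjectIds,
                 normalized = TRUE)
}
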