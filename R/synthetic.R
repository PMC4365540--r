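# Synthetic cohort generator. Emulates the statistical structure the
# centering method assumes: latent intrinsic subtypes with block-structured
# expression signatures, clinical ER/TNBC labels statistically associated
# with subtype, Gaussian measurement noise, and an optional per-gene
# cohort-wide technical shift (platform offset between cohorts).

#' Build a synthetic-cohort configuration
#'
#' @param nSamples number of samples.
#' @param subtypeMeans numeric matrix (genes x subtypes) of log-scale signal
#'   means; gene ids as row names, subtype names as column names.
#' @param subtypeProportions per-subtype sampling fractions summing to 1
#'   (default: uniform).
#' @param noiseSd standard deviation of per-cell Gaussian noise (default 1).
#' @param erGivenSubtype per-subtype probability of ER-positivity (default
#'   0.5 everywhere).
#' @param tnbcGivenSubtype per-subtype probability that an ER-negative sample
#'   is triple-negative (default 0: no TNBC labels).
#' @param platformShiftSd standard deviation of the per-gene additive shift
#'   applied to the whole cohort (default 0).
#' @param seed integer seed.
#' @return a [SyntheticCohortConfig].
#' @seealso [defaultBreastConfig()], [generateCohort()]
#' @export
syntheticCohortConfig <- function(nSamples, subtypeMeans,
                                  subtypeProportions = NULL, noiseSd = 1,
                                  erGivenSubtype = NULL,
                                  tnbcGivenSubtype = NULL,
                                  platformShiftSd = 0, seed) {
  k <- ncol(subtypeMeans)
  if (is.null(subtypeProportions)) subtypeProportions <- rep(1 / k, k)
  if (is.null(erGivenSubtype)) erGivenSubtype <- rep(0.5, k)
  if (is.null(tnbcGivenSubtype)) tnbcGivenSubtype <- rep(0, k)
  new("SyntheticCohortConfig",
      nSamples = as.integer(nSamples),
      subtypeNames = colnames(subtypeMeans),
      subtypeProportions = as.numeric(subtypeProportions),
      subtypeMeans = subtypeMeans,
      noiseSd = as.numeric(noiseSd),
      erGivenSubtype = as.numeric(erGivenSubtype),
      tnbcGivenSubtype = as.numeric(tnbcGivenSubtype),
      platformShiftSd = as.numeric(platformShiftSd),
      seed = as.integer(seed))
}

## Fixed constants of the default breast-cancer generator. The block
## amplitude, shared ER-program amplitude, gene-level baseline offsets and
## noise SD were calibrated once so that (i) matched-composition
## classification accuracy lands in 0.9-1.0 and (ii) the composition-skew
## failure of standard centering is exhibited at desk scale; see the methods
## vignette for the rationale.
.BREAST_BLOCK_AMPLITUDE <- 2.0
.BREAST_ER_AMPLITUDE <- 2.0
.BREAST_LUMINAL_CROSS <- 1.0
.BREAST_NOISE_SD <- 0.8
.BREAST_NORMAL_ABUNDANCE <- 5.0
.BREAST_LUMINAL_ABUNDANCE <- -3.0
.BREAST_BASELINE_OFFSETS <- function(nGenes) {
  # Deterministic spread of per-gene overall expression levels (log-scale),
  # cycling over [-6, 6]; gives uncentered profiles gene-level structure so
  # the no-centering arm is meaningfully handicapped.
  rep_len(seq(-6, 6, length.out = 10), nGenes)
}

#' Default synthetic breast-cancer cohort configuration
#'
#' Five intrinsic subtypes over a 50-gene signature: each subtype has a
#' dedicated 8-gene up-regulated block, and a 10-gene ER-program block is
#' shared by the luminal subtypes (up in LumA/LumB, down in Basal-like).
#' ER-positivity is drawn conditional on subtype (LumA 0.95, LumB 0.85,
#' HER2-enriched 0.40, Basal-like 0.05, Normal-like 0.50), so clinical ER
#' status is statistically associated with — but not identical to — the
#' latent subtype, which is what makes composition skew distort standard
#' centering. TNBC labels are drawn for ER-negative samples (Basal-like 0.85,
#' HER2-enriched 0.30, luminal 0.20, Normal-like 0.40).
#'
#' @param nSamples number of samples (at least 50).
#' @param seed integer seed.
#' @param platformShiftSd standard deviation of the cohort-wide per-gene
#'   technical shift (default 0). Use a positive value when generating a
#'   study cohort on a different "platform" than the training cohort.
#' @return a [SyntheticCohortConfig].
#' @examples
#' cfg <- defaultBreastConfig(200, seed = 1)
#' cohort <- generateCohort(cfg)
#' @export
defaultBreastConfig <- function(nSamples, seed, platformShiftSd = 0) {
  if (nSamples < 50L) stop("nSamples must be at least 50 (got ", nSamples, ")")
  subtypes <- CANONICAL_SUBTYPES
  nGenes <- 50L
  blockGenes <- list(
    "Basal-like" = 1:8, "HER2-enriched" = 9:16, "LumA" = 17:24,
    "LumB" = 25:32, "Normal-like" = 33:40
  )
  erGenes <- 41:50
  geneIds <- character(nGenes)
  for (st in subtypes) {
    tag <- c("Basal-like" = "BAS", "HER2-enriched" = "HER", "LumA" = "LUA",
             "LumB" = "LUB", "Normal-like" = "NRM")[[st]]
    geneIds[blockGenes[[st]]] <- sprintf("%s%02d", tag, seq_len(8L))
  }
  geneIds[erGenes] <- sprintf("ERP%02d", seq_len(10L))

  means <- matrix(0, nGenes, length(subtypes),
                  dimnames = list(geneIds, subtypes))
  for (st in subtypes) {
    means[blockGenes[[st]], st] <- .BREAST_BLOCK_AMPLITUDE
  }
  # The two luminal subtypes share most of their expression program: each
  # one's dedicated block is moderately elevated in the other, so they are
  # confusable neighbours (as LumA/LumB are on real data) rather than
  # orthogonal classes.
  means[blockGenes[["LumA"]], "LumB"] <- .BREAST_LUMINAL_CROSS
  means[blockGenes[["LumB"]], "LumA"] <- .BREAST_LUMINAL_CROSS
  means[erGenes, "LumA"] <- .BREAST_ER_AMPLITUDE
  means[erGenes, "LumB"] <- 0.75 * .BREAST_ER_AMPLITUDE
  means[erGenes, "Basal-like"] <- -.BREAST_ER_AMPLITUDE
  means <- means + .BREAST_BASELINE_OFFSETS(nGenes)
  # Normal/stromal program genes are high-abundance in every tumor, so
  # profiles that are NOT gene-centered rank them at the top and default to
  # Normal-like calls — the well-known behaviour of uncentered data under
  # centroid classifiers. Centering (either strategy) removes this offset.
  means[blockGenes[["Normal-like"]], ] <-
    means[blockGenes[["Normal-like"]], ] + .BREAST_NORMAL_ABUNDANCE
  # Luminal differentiation and ER-program genes sit at the low end of the
  # abundance scale, so their subtype contrast is invisible until the
  # per-gene baseline is removed. Both abundance offsets cancel exactly under
  # either centering strategy; they shape only the no-centering behaviour.
  lowAbundance <- c(blockGenes[["LumA"]], blockGenes[["LumB"]], erGenes)
  means[lowAbundance, ] <- means[lowAbundance, ] + .BREAST_LUMINAL_ABUNDANCE

  syntheticCohortConfig(
    nSamples = nSamples,
    subtypeMeans = means,
    subtypeProportions = c("Basal-like" = 0.29, "HER2-enriched" = 0.08,
                           "LumA" = 0.40, "LumB" = 0.16,
                           "Normal-like" = 0.07),
    noiseSd = .BREAST_NOISE_SD,
    erGivenSubtype = c("Basal-like" = 0.05, "HER2-enriched" = 0.40,
                       "LumA" = 0.95, "LumB" = 0.85, "Normal-like" = 0.50),
    tnbcGivenSubtype = c("Basal-like" = 0.85, "HER2-enriched" = 0.30,
                         "LumA" = 0.20, "LumB" = 0.20, "Normal-like" = 0.40),
    platformShiftSd = platformShiftSd,
    seed = seed
  )
}

#' Generate a synthetic cohort
#'
#' Draws each sample's latent subtype from `subtypeProportions`, sets its
#' expression to the subtype's mean profile plus i.i.d. `Normal(0, noiseSd)`
#' noise plus a per-gene `Normal(0, platformShiftSd)` shift drawn once for the
#' whole cohort, and draws ER status conditional on subtype (and TNBC status
#' conditional on ER-negativity). Deterministic given `config@seed`.
#'
#' @param config a [SyntheticCohortConfig].
#' @param samplePrefix prefix of generated sample ids (default `"S"`).
#' @return a [SyntheticCohort].
#' @examples
#' cohort <- generateCohort(defaultBreastConfig(100, seed = 7))
#' @export
generateCohort <- function(config, samplePrefix = "S") {
  stopifnot(is(config, "SyntheticCohortConfig"))
  validObject(config)
  n <- config@nSamples
  genes <- rownames(config@subtypeMeans)
  withSeed(config@seed, {
    subtype <- sample(config@subtypeNames, n, replace = TRUE,
                      prob = config@subtypeProportions)
    shift <- if (config@platformShiftSd > 0) {
      rnorm(length(genes), 0, config@platformShiftSd)
    } else {
      numeric(length(genes))
    }
    expr <- config@subtypeMeans[, subtype, drop = FALSE] +
      matrix(rnorm(length(genes) * n, 0, config@noiseSd), length(genes), n) +
      shift
    pEr <- config@erGivenSubtype[match(subtype, config@subtypeNames)]
    er <- ifelse(rbinom(n, 1L, pEr) == 1L, "positive", "negative")
    pTnbc <- config@tnbcGivenSubtype[match(subtype, config@subtypeNames)]
    tnbc <- ifelse(er == "negative" & rbinom(n, 1L, pTnbc) == 1L,
                   "true", "false")
  })
  ids <- sprintf("%s%04d", samplePrefix, seq_len(n))
  dimnames(expr) <- list(genes, ids)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = expr),
    colData = S4Vectors::DataFrame(er_status = er, tnbc = tnbc,
                                   prototypic_subtype = subtype,
                                   row.names = ids),
    metadata = list(config = config)
  )
  new("SyntheticCohort", se)
}

#' Split a cohort into a training cohort and a skewed study cohort
#'
#' Draws a study cohort of `studySize` samples at the stated ER-positive
#' fraction (integer counts by largest remainder, so a 15% fraction of 75
#' samples yields 11 ER-positive and 64 ER-negative cases), without
#' replacement; the remaining samples form the training cohort. The two are
#' disjoint and together exhaust the input cohort.
#'
#' @param cohort a [SyntheticCohort].
#' @param studyErPositiveFraction fraction of ER-positive samples in the study
#'   cohort, in `[0, 1]`.
#' @param studySize number of study samples.
#' @param seed integer seed.
#' @return list with elements `train` and `study`, both [SyntheticCohort]s.
#' @examples
#' cohort <- generateCohort(defaultBreastConfig(400, seed = 3))
#' split <- splitTrainStudy(cohort, 0.15, 75, seed = 4)
#' @export
splitTrainStudy <- function(cohort, studyErPositiveFraction, studySize,
                            seed) {
  stopifnot(is(cohort, "SyntheticCohort"),
            studyErPositiveFraction >= 0, studyErPositiveFraction <= 1,
            studySize >= 1L, studySize < ncol(cohort))
  clin <- clinicalTable(cohort)
  counts <- apportionCounts(c(studyErPositiveFraction,
                              1 - studyErPositiveFraction), studySize)
  pos <- clin$sample_id[clin$er_status == "positive"]
  neg <- clin$sample_id[clin$er_status == "negative"]
  if (counts[1L] > length(pos) || counts[2L] > length(neg)) {
    stop("cohort cannot supply a ", studySize, "-sample study cohort at ",
         round(100 * studyErPositiveFraction), "% ER-positive (need ",
         counts[1L], "+/", counts[2L], "-, have ", length(pos), "+/",
         length(neg), "-)")
  }
  studyIds <- withSeed(seed, {
    c(if (counts[1L] > 0L) sample(pos, counts[1L]),
      if (counts[2L] > 0L) sample(neg, counts[2L]))
  })
  trainIds <- setdiff(clin$sample_id, studyIds)
  list(train = cohort[, trainIds], study = cohort[, studyIds])
}

#' Write a synthetic cohort's expression and clinical tables to TSV
#'
#' @param cohort a [SyntheticCohort].
#' @param exprPath,clinicalPath output paths.
#' @param comments optional `#`-prefixed provenance lines for both files.
#' @return invisibly, a list of the two paths.
#' @export
writeCohort <- function(cohort, exprPath, clinicalPath,
                        comments = character()) {
  stopifnot(is(cohort, "SyntheticCohort"))
  writeExpression(expressionValues(cohort), exprPath, comments)
  writeClinical(clinicalTable(cohort), clinicalPath, comments)
  invisible(list(expression = exprPath, clinical = clinicalPath))
}
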