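#' @import methods
#' @importFrom stats median quantile cor rnorm rbinom pbinom pchisq sd
#' @importFrom utils read.delim write.table
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
#' @importFrom S4Vectors DataFrame metadata
NULL

#' Per-gene baseline percentile table
#'
#' The central exportable artifact of subgroup-specific gene centering. For
#' each gene of a signature and each clinicopathological subgroup it stores
#' the training-cohort baseline expression \eqn{\mu_{gene}} (median or mean
#' over the *full* training cohort) and the percentile \eqn{Q_{gene}} at which
#' that baseline sits within the subgroup's expression distribution. A study
#' cohort matched to the subgroup is then centered on its own expression value
#' at \eqn{Q_{gene}}, gene by gene.
#'
#' @slot table `data.frame` with columns `gene_id`, `subgroup`, `mu_gene`,
#'   `q_gene`; one row per (gene, subgroup) pair, `q_gene` in `[0, 100]`.
#' @slot baselineMethod `"median"` or `"mean"` — the statistic used for
#'   \eqn{\mu_{gene}}.
#'
#' @seealso [computeSubgroupPercentiles()], [mixturePercentiles()],
#'   [weightedPercentiles()], [subgroupCenter()], [readPercentileTable()].
#' @export
setClass("PercentileTable",
  representation(table = "data.frame", baselineMethod = "character"),
  validity = function(object) {
    tb <- object@table
    need <- c("gene_id", "subgroup", "mu_gene", "q_gene")
    if (!all(need %in% names(tb))) {
      return(paste("table must have columns", paste(need, collapse = ", ")))
    }
    if (nrow(tb) == 0L) return("table has no rows")
    if (any(!is.finite(tb$q_gene)) || any(tb$q_gene < 0) ||
        any(tb$q_gene > 100)) {
      return("q_gene must be finite and within [0, 100]")
    }
    if (any(!is.finite(tb$mu_gene))) return("mu_gene must be finite")
    if (anyDuplicated(paste(tb$gene_id, tb$subgroup, sep = "\r"))) {
      return("each gene must appear exactly once per subgroup")
    }
    for (sg in unique(tb$subgroup)) {
      genes <- sort(tb$gene_id[tb$subgroup == sg])
      if (!identical(genes, sort(unique(tb$gene_id)))) {
        return("every gene must appear once in every subgroup")
      }
    }
    mu <- tapply(tb$mu_gene, tb$gene_id, function(v) diff(range(v)))
    if (any(mu > 0)) {
      return("mu_gene must be identical across subgroups for a given gene")
    }
    if (length(object@baselineMethod) != 1L ||
        !object@baselineMethod %in% c("median", "mean")) {
      return("baselineMethod must be 'median' or 'mean'")
    }
    TRUE
  }
)

#' Subtype centroid matrix
#'
#' Per-subtype reference expression profiles over the signature genes, built
#' from a *centered* training cohort. Each column is the per-gene aggregate
#' (mean or median) of the centered expression of the prototypic samples of
#' one subtype.
#'
#' @slot values numeric matrix, genes x subtypes, with gene row names and
#'   subtype column names; at least two subtypes; finite values.
#'
#' @seealso [trainCentroids()], [classifySamples()], [readCentroids()].
#' @export
setClass("CentroidMatrix",
  representation(values = "matrix"),
  validity = function(object) {
    v <- object@values
    if (!is.numeric(v)) return("values must be numeric")
    if (is.null(rownames(v)) || is.null(colnames(v))) {
      return("values must have gene row names and subtype column names")
    }
    if (ncol(v) < 2L) return("a centroid matrix needs at least 2 subtypes")
    if (anyDuplicated(rownames(v))) return("duplicated gene ids")
    if (anyDuplicated(colnames(v))) return("duplicated subtype names")
    if (any(!is.finite(v))) return("centroid values must be finite")
    TRUE
  }
)

#' Result of a gene-centering operation
#'
#' Holds the centered genes-by-samples matrix together with the per-gene
#' baseline that was subtracted and the name of the centering strategy, so
#' that `centered[g, s] = input[g, s] - baselines[g]` for every non-missing
#' cell.
#'
#' @slot centered numeric matrix (genes x samples), centered expression;
#'   missingness of the input is preserved.
#' @slot baselines named numeric vector of subtracted per-gene baselines.
#' @slot method one of `"standard-median"`, `"standard-mean"`,
#'   `"subgroup-percentile"`, `"none"`.
#'
#' @seealso [standardCenter()], [subgroupCenter()].
#' @export
setClass("CenteringResult",
  representation(centered = "matrix", baselines = "numeric",
                 method = "character"),
  validity = function(object) {
    if (!identical(names(object@baselines), rownames(object@centered))) {
      return("baselines must be named by the centered matrix's genes")
    }
    if (any(!is.finite(object@baselines))) return("baselines must be finite")
    ok <- c("standard-median", "standard-mean", "subgroup-percentile", "none")
    if (length(object@method) != 1L || !object@method %in% ok) {
      return(paste("method must be one of", paste(ok, collapse = ", ")))
    }
    TRUE
  }
)

#' Nearest-centroid subtype assignments
#'
#' Per-sample predicted intrinsic subtype with the full vector of per-subtype
#' correlation scores and the assignment margin (best minus second-best
#' score). Samples whose correlation is undefined (too few non-missing genes,
#' or a zero-variance profile) are flagged `unclassifiable` and carry `NA`
#' scores.
#'
#' @slot sampleIds character vector of sample ids.
#' @slot predicted character vector; a subtype name or `"unclassifiable"`.
#' @slot scores numeric matrix, samples x subtypes, correlations in `[-1, 1]`
#'   (`NA` for unclassifiable samples).
#' @slot margin numeric; best minus second-best score (`NA` if
#'   unclassifiable).
#' @slot flags character; `""`, `"tie"`, or `"unclassifiable:<reason>"`.
#'
#' @seealso [classifySamples()], [confusionSummary()].
#' @export
setClass("SubtypeAssignments",
  representation(sampleIds = "character", predicted = "character",
                 scores = "matrix", margin = "numeric", flags = "character"),
  validity = function(object) {
    n <- length(object@sampleIds)
    if (length(object@predicted) != n || length(object@margin) != n ||
        length(object@flags) != n || nrow(object@scores) != n) {
      return("all per-sample fields must have one entry per sample")
    }
    if (anyDuplicated(object@sampleIds)) return("duplicated sample ids")
    cls <- !startsWith(object@flags, "unclassifiable")
    if (any(object@margin[cls] < -1e-12, na.rm = TRUE)) {
      return("margin must be non-negative")
    }
    TRUE
  }
)

#' Clinicopathological subgroup or mixture specification
#'
#' Describes the training-cohort subgroup whose composition matches the study
#' cohort: one or more named components (predicates over the clinical table)
#' with mixture proportions summing to one. Built-in component names are
#' `"er_positive"`, `"er_negative"`, `"tnbc"`, `"non_tnbc"`, and `"all"`;
#' arbitrary predicates can be supplied as functions of the clinical table
#' returning a logical per sample.
#'
#' @slot componentNames character vector of component labels.
#' @slot proportions numeric mixture proportions in `[0, 1]`, summing to 1.
#' @slot predicates list of `function(clinical) -> logical` selectors.
#'
#' @seealso [subgroupSpec()], [computeSubgroupPercentiles()],
#'   [mixturePercentiles()], [weightedPercentiles()].
#' @export
setClass("SubgroupSpec",
  representation(componentNames = "character", proportions = "numeric",
                 predicates = "list"),
  validity = function(object) {
    k <- length(object@componentNames)
    if (k < 1L) return("at least one component is required")
    if (length(object@proportions) != k || length(object@predicates) != k) {
      return("componentNames, proportions and predicates must align")
    }
    if (any(object@proportions < 0) || any(object@proportions > 1)) {
      return("proportions must lie in [0, 1]")
    }
    if (abs(sum(object@proportions) - 1) > 1e-9) {
      return("proportions must sum to 1 (tolerance 1e-9)")
    }
    if (anyDuplicated(object@componentNames)) {
      return("component names must be unique")
    }
    if (!all(vapply(object@predicates, is.function, logical(1)))) {
      return("predicates must be functions")
    }
    TRUE
  }
)

#' Configuration of a synthetic expression cohort
#'
#' Defines the generative model used by [generateCohort()]: each sample draws
#' a latent intrinsic subtype, its expression is the subtype's mean profile
#' plus i.i.d. Gaussian noise plus a per-gene cohort-wide technical shift, and
#' clinical ER / TNBC labels are drawn conditional on the subtype.
#'
#' @slot nSamples number of samples.
#' @slot subtypeNames subtype labels (columns of `subtypeMeans`).
#' @slot subtypeProportions per-subtype sampling fractions, summing to 1.
#' @slot subtypeMeans numeric matrix genes x subtypes of log-scale signal
#'   means; row names are the gene ids.
#' @slot noiseSd standard deviation of the per-cell Gaussian noise.
#' @slot erGivenSubtype per-subtype probability that a sample is ER-positive.
#' @slot tnbcGivenSubtype per-subtype probability that an ER-negative sample
#'   is triple-negative (ER-positive samples are never TNBC).
#' @slot platformShiftSd standard deviation of the per-gene additive shift
#'   applied to the whole cohort (emulates a platform/technology offset
#'   between cohorts).
#' @slot seed integer seed making the cohort reproducible.
#'
#' @seealso [syntheticCohortConfig()], [defaultBreastConfig()],
#'   [generateCohort()].
#' @export
setClass("SyntheticCohortConfig",
  representation(nSamples = "integer", subtypeNames = "character",
                 subtypeProportions = "numeric", subtypeMeans = "matrix",
                 noiseSd = "numeric", erGivenSubtype = "numeric",
                 tnbcGivenSubtype = "numeric", platformShiftSd = "numeric",
                 seed = "integer"),
  validity = function(object) {
    k <- length(object@subtypeNames)
    if (object@nSamples < 1L) return("nSamples must be positive")
    if (k < 2L) return("at least two subtypes are required")
    if (length(object@subtypeProportions) != k) {
      return("subtypeProportions must have one entry per subtype")
    }
    if (abs(sum(object@subtypeProportions) - 1) > 1e-9) {
      return("subtypeProportions must sum to 1 (tolerance 1e-9)")
    }
    if (any(object@subtypeProportions < 0)) {
      return("subtypeProportions must be non-negative")
    }
    if (!identical(colnames(object@subtypeMeans), object@subtypeNames)) {
      return("subtypeMeans columns must be named by subtypeNames")
    }
    if (is.null(rownames(object@subtypeMeans)) ||
        anyDuplicated(rownames(object@subtypeMeans))) {
      return("subtypeMeans must have unique gene row names")
    }
    if (any(!is.finite(object@subtypeMeans))) {
      return("subtypeMeans must be finite")
    }
    for (nm in c("erGivenSubtype", "tnbcGivenSubtype")) {
      p <- slot(object, nm)
      if (length(p) != k || any(p < 0) || any(p > 1)) {
        return(paste(nm, "must be per-subtype probabilities in [0, 1]"))
      }
    }
    if (object@noiseSd < 0 || object@platformShiftSd < 0) {
      return("noiseSd and platformShiftSd must be non-negative")
    }
    TRUE
  }
)

#' Synthetic cohort container
#'
#' A [SummarizedExperiment::SummarizedExperiment] with one assay `"exprs"`
#' (log-scale expression, genes x samples), clinical labels in `colData`
#' (`er_status`, `tnbc`, `prototypic_subtype`), and the generating
#' [SyntheticCohortConfig] in `metadata(x)$config`.
#'
#' @seealso [generateCohort()], [splitTrainStudy()], [clinicalTable()],
#'   [expressionValues()].
#' @export
setClass("SyntheticCohort", contains = "SummarizedExperiment")
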