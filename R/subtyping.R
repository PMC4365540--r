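# Nearest-centroid subtype classification: centroids are per-gene aggregates
# of centered prototypic samples; a study sample is assigned the subtype whose
# centroid correlates best with its centered expression profile.

#' Train subtype centroids from a centered cohort
#'
#' Builds one reference profile per subtype as the per-gene mean (or median)
#' of the centered expression of that subtype's prototypic samples. The input
#' must already be centered (standard or subgroup-specific); centroids built
#' on uncentered data are not comparable across cohorts.
#'
#' @param trainCentered centered training expression: a [CenteringResult],
#'   numeric matrix, or [SyntheticCohort] (assumed pre-centered).
#' @param clinical clinical table with a `prototypic_subtype` column (defaults
#'   to the cohort's own table when `trainCentered` is a [SyntheticCohort]).
#' @param aggregate `"mean"` (default; prototypic average profiles) or
#'   `"median"`.
#' @return a [CentroidMatrix] with subtypes in canonical order.
#' @examples
#' \dontrun{centroids <- trainCentroids(standardCenter(expr), clinical)}
#' @seealso [classifySamples()]
#' @export
trainCentroids <- function(trainCentered, clinical = NULL,
                           aggregate = c("mean", "median")) {
  aggregate <- match.arg(aggregate)
  if (is.null(clinical)) clinical <- asClinicalTable(trainCentered)
  mat <- asExpressionMatrix(trainCentered)
  validateExpression(mat)
  if (!"prototypic_subtype" %in% names(clinical)) {
    stop("clinical table lacks a 'prototypic_subtype' column")
  }
  lab <- clinical$prototypic_subtype[match(colnames(mat),
                                           clinical$sample_id)]
  unlabeled <- is.na(lab)
  if (any(unlabeled)) {
    warning(sum(unlabeled), " sample(s) without a prototypic subtype were ",
            "excluded from centroid training", call. = FALSE)
    mat <- mat[, !unlabeled, drop = FALSE]
    lab <- lab[!unlabeled]
  }
  counts <- table(lab)
  small <- names(counts)[counts < 2L]
  if (length(small)) {
    stop("subtype(s) with fewer than 2 prototypic samples: ",
         paste(small, collapse = ", "))
  }
  subtypes <- canonicalSubtypeOrder(names(counts))
  agg <- if (aggregate == "mean") {
    function(m) rowMeans(m, na.rm = TRUE)
  } else {
    function(m) apply(m, 1L, median, na.rm = TRUE)
  }
  values <- vapply(subtypes, function(st) {
    agg(mat[, lab == st, drop = FALSE])
  }, numeric(nrow(mat)))
  if (any(!is.finite(values))) {
    stop("centroid has non-finite entries (a gene with all values missing ",
         "within a subtype)")
  }
  dimnames(values) <- list(rownames(mat), subtypes)
  new("CentroidMatrix", values = values)
}

#' Classify samples by highest centroid correlation
#'
#' Assigns each centered study sample to the subtype whose centroid has the
#' highest correlation with the sample's expression profile, computed over the
#' pairwise-complete signature genes. Spearman rank correlation is the default
#' (the PAM50 lineage convention); Pearson is available as a flag. Samples
#' with fewer than `minGenes` non-missing signature genes, or a zero-variance
#' profile, are flagged `unclassifiable` rather than aborting the run. Exact
#' score ties are broken by the canonical subtype order and flagged.
#'
#' @param studyCentered centered study expression: a [CenteringResult],
#'   numeric matrix, or [SyntheticCohort].
#' @param centroids a [CentroidMatrix].
#' @param metric `"spearman"` (default) or `"pearson"`.
#' @param minGenes minimum non-missing signature genes per sample (default
#'   20).
#' @param minCoverage minimum fraction of centroid genes the study matrix must
#'   contain (passed to [alignToSignature()]; default 0.5).
#' @return a [SubtypeAssignments].
#' @seealso [trainCentroids()], [confusionSummary()]
#' @export
classifySamples <- function(studyCentered, centroids,
                            metric = c("spearman", "pearson"),
                            minGenes = 20L, minCoverage = 0.5) {
  metric <- match.arg(metric)
  stopifnot(is(centroids, "CentroidMatrix"))
  mat <- alignToSignature(studyCentered, centroids, minCoverage)
  cv <- centroidValues(centroids)[rownames(mat), , drop = FALSE]
  subtypes <- canonicalSubtypeOrder(colnames(cv))
  cv <- cv[, subtypes, drop = FALSE]
  nSamples <- ncol(mat)
  scores <- matrix(NA_real_, nSamples, length(subtypes),
                   dimnames = list(colnames(mat), subtypes))
  predicted <- character(nSamples)
  margin <- rep(NA_real_, nSamples)
  flags <- character(nSamples)
  for (s in seq_len(nSamples)) {
    x <- mat[, s]
    ok <- !is.na(x)
    if (sum(ok) < minGenes) {
      predicted[s] <- "unclassifiable"
      flags[s] <- sprintf("unclassifiable:only %d non-missing genes (min %d)",
                          sum(ok), minGenes)
      next
    }
    if (sd(x[ok]) == 0) {
      predicted[s] <- "unclassifiable"
      flags[s] <- "unclassifiable:zero-variance profile"
      next
    }
    sc <- suppressWarnings(
      as.numeric(cor(x[ok], cv[ok, , drop = FALSE], method = metric))
    )
    if (all(is.na(sc))) {
      predicted[s] <- "unclassifiable"
      flags[s] <- "unclassifiable:correlation undefined for every centroid"
      next
    }
    scores[s, ] <- sc
    best <- which(sc == max(sc, na.rm = TRUE))
    if (length(best) > 1L) flags[s] <- "tie"
    predicted[s] <- subtypes[best[1L]]
    ord <- sort(sc[!is.na(sc)], decreasing = TRUE)
    margin[s] <- if (length(ord) > 1L) ord[1L] - ord[2L] else 0
  }
  new("SubtypeAssignments", sampleIds = colnames(mat), predicted = predicted,
      scores = scores, margin = margin, flags = flags)
}

#' Write subtype assignments to TSV
#'
#' @param assignments a [SubtypeAssignments].
#' @param path output path.
#' @param comments optional `#`-prefixed provenance lines.
#' @return `path`, invisibly.
#' @export
writeAssignments <- function(assignments, path, comments = character()) {
  stopifnot(is(assignments, "SubtypeAssignments"))
  df <- as.data.frame(assignments)
  for (j in which(vapply(df, is.numeric, logical(1)))) {
    df[[j]] <- .formatNum(df[[j]])
  }
  .writeTsv(df, path, comments)
}
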