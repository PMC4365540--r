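#' Gene identifiers of an object
#'
#' @param x a [PercentileTable], [CentroidMatrix], [CenteringResult], or
#'   [SyntheticCohort].
#' @return character vector of gene ids.
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' Subgroup names stored in a percentile table
#'
#' @param x a [PercentileTable].
#' @return character vector of subgroup names.
#' @export
setGeneric("subgroupNames", function(x) standardGeneric("subgroupNames"))

#' Subtype names of an object
#'
#' @param x a [CentroidMatrix] or [SubtypeAssignments].
#' @return character vector of subtype names.
#' @export
setGeneric("subtypeNames", function(x) standardGeneric("subtypeNames"))

#' Per-gene baseline expression (mu_gene)
#'
#' @param x a [PercentileTable].
#' @return named numeric vector of full-training-cohort baselines.
#' @export
setGeneric("muGene", function(x) standardGeneric("muGene"))

#' Per-gene subgroup percentiles (Q_gene)
#'
#' @param x a [PercentileTable].
#' @param subgroup subgroup name; may be omitted when the table holds a
#'   single subgroup.
#' @return named numeric vector of percentiles in `[0, 100]`.
#' @export
setGeneric("qGene", function(x, subgroup = NULL) standardGeneric("qGene"))

#' Centered expression values
#'
#' @param x a [CenteringResult].
#' @return numeric matrix, genes x samples.
#' @export
setGeneric("centeredValues", function(x) standardGeneric("centeredValues"))

#' Per-gene baselines subtracted by a centering operation
#'
#' @param x a [CenteringResult].
#' @return named numeric vector.
#' @export
setGeneric("baselinesUsed", function(x) standardGeneric("baselinesUsed"))

#' Name of the centering strategy applied
#'
#' @param x a [CenteringResult].
#' @return single character string.
#' @export
setGeneric("centeringMethod", function(x) standardGeneric("centeringMethod"))

#' Centroid values
#'
#' @param x a [CentroidMatrix].
#' @return numeric matrix, genes x subtypes.
#' @export
setGeneric("centroidValues", function(x) standardGeneric("centroidValues"))

#' Predicted subtype per sample
#'
#' @param x a [SubtypeAssignments].
#' @return named character vector (sample id -> subtype or
#'   `"unclassifiable"`).
#' @export
setGeneric("predictedSubtype", function(x) standardGeneric("predictedSubtype"))

#' Per-subtype correlation scores
#'
#' @param x a [SubtypeAssignments].
#' @return numeric matrix, samples x subtypes.
#' @export
setGeneric("assignmentScores", function(x) standardGeneric("assignmentScores"))

#' Clinical annotation table of a cohort
#'
#' @param x a [SyntheticCohort].
#' @return `data.frame` with columns `sample_id`, `er_status`, `tnbc`,
#'   `prototypic_subtype`.
#' @export
setGeneric("clinicalTable", function(x) standardGeneric("clinicalTable"))

#' Expression matrix of a cohort
#'
#' @param x a [SyntheticCohort].
#' @return numeric matrix, genes x samples.
#' @export
setGeneric("expressionValues", function(x) standardGeneric("expressionValues"))


## ---- PercentileTable ----

#' @describeIn PercentileTable gene ids covered by the table.
#' @param x,object a `PercentileTable`.
#' @export
setMethod("geneIds", "PercentileTable", function(x) {
  unique(x@table$gene_id)
})

#' @describeIn PercentileTable subgroups covered by the table.
#' @export
setMethod("subgroupNames", "PercentileTable", function(x) {
  unique(x@table$subgroup)
})

#' @describeIn PercentileTable named vector of per-gene baselines.
#' @export
setMethod("muGene", "PercentileTable", function(x) {
  tb <- x@table[!duplicated(x@table$gene_id), ]
  structure(tb$mu_gene, names = tb$gene_id)
})

#' @describeIn PercentileTable named vector of per-gene percentiles for one
#'   subgroup.
#' @param subgroup subgroup name (optional for single-subgroup tables).
#' @export
setMethod("qGene", "PercentileTable", function(x, subgroup = NULL) {
  sgs <- subgroupNames(x)
  if (is.null(subgroup)) {
    if (length(sgs) > 1L) {
      stop("table holds several subgroups (", paste(sgs, collapse = ", "),
           "); pick one via 'subgroup'")
    }
    subgroup <- sgs
  }
  if (!subgroup %in% sgs) {
    stop("subgroup '", subgroup, "' not present; available: ",
         paste(sgs, collapse = ", "))
  }
  tb <- x@table[x@table$subgroup == subgroup, ]
  structure(tb$q_gene, names = tb$gene_id)
})

#' @describeIn PercentileTable compact display.
#' @export
setMethod("show", "PercentileTable", function(object) {
  cat("PercentileTable:", length(geneIds(object)), "genes x",
      length(subgroupNames(object)), "subgroup(s) [",
      paste(subgroupNames(object), collapse = ", "), "]\n")
  cat("  baseline method:", object@baselineMethod, "\n")
})

#' Coerce a PercentileTable to a data.frame
#'
#' @param x a [PercentileTable].
#' @param ... ignored.
#' @return long-format `data.frame` with columns `gene_id`, `subgroup`,
#'   `mu_gene`, `q_gene`, `baseline_method`.
#' @export
as.data.frame.PercentileTable <- function(x, ...) {
  out <- x@table[, c("gene_id", "subgroup", "mu_gene", "q_gene")]
  out$baseline_method <- x@baselineMethod
  rownames(out) <- NULL
  out
}

## ---- CentroidMatrix ----

#' @describeIn CentroidMatrix gene ids (row names).
#' @param x,object a `CentroidMatrix`.
#' @export
setMethod("geneIds", "CentroidMatrix", function(x) rownames(x@values))

#' @describeIn CentroidMatrix subtype names (column names).
#' @export
setMethod("subtypeNames", "CentroidMatrix", function(x) colnames(x@values))

#' @describeIn CentroidMatrix the genes x subtypes matrix.
#' @export
setMethod("centroidValues", "CentroidMatrix", function(x) x@values)

#' @describeIn CentroidMatrix compact display.
#' @export
setMethod("show", "CentroidMatrix", function(object) {
  cat("CentroidMatrix:", nrow(object@values), "genes x",
      ncol(object@values), "subtypes (",
      paste(colnames(object@values), collapse = ", "), ")\n")
})

## ---- CenteringResult ----

#' @describeIn CenteringResult gene ids of the centered matrix.
#' @param x,object a `CenteringResult`.
#' @export
setMethod("geneIds", "CenteringResult", function(x) rownames(x@centered))

#' @describeIn CenteringResult the centered genes x samples matrix.
#' @export
setMethod("centeredValues", "CenteringResult", function(x) x@centered)

#' @describeIn CenteringResult named vector of subtracted baselines.
#' @export
setMethod("baselinesUsed", "CenteringResult", function(x) x@baselines)

#' @describeIn CenteringResult the centering strategy name.
#' @export
setMethod("centeringMethod", "CenteringResult", function(x) x@method)

#' @describeIn CenteringResult compact display.
#' @export
setMethod("show", "CenteringResult", function(object) {
  cat("CenteringResult (", object@method, "): ", nrow(object@centered),
      " genes x ", ncol(object@centered), " samples\n", sep = "")
})

## ---- SubtypeAssignments ----

#' @describeIn SubtypeAssignments subtype names scored for every sample.
#' @param x,object a `SubtypeAssignments`.
#' @export
setMethod("subtypeNames", "SubtypeAssignments", function(x) {
  colnames(x@scores)
})

#' @describeIn SubtypeAssignments named character vector of predictions.
#' @export
setMethod("predictedSubtype", "SubtypeAssignments", function(x) {
  structure(x@predicted, names = x@sampleIds)
})

#' @describeIn SubtypeAssignments samples x subtypes correlation matrix.
#' @export
setMethod("assignmentScores", "SubtypeAssignments", function(x) x@scores)

#' @describeIn SubtypeAssignments compact display.
#' @export
setMethod("show", "SubtypeAssignments", function(object) {
  tab <- table(factor(object@predicted,
                      levels = canonicalSubtypeOrder(
                        unique(c(colnames(object@scores),
                                 object@predicted)))))
  cat("SubtypeAssignments:", length(object@sampleIds), "samples\n")
  print(tab)
})

#' Coerce subtype assignments to a data.frame
#'
#' @param x a [SubtypeAssignments].
#' @param ... ignored.
#' @return `data.frame` with `sample_id`, `predicted_subtype`, one score
#'   column per subtype, `margin`, and `flags`.
#' @export
as.data.frame.SubtypeAssignments <- function(x, ...) {
  scores <- as.data.frame(x@scores)
  names(scores) <- paste0("score_", colnames(x@scores))
  out <- cbind(
    data.frame(sample_id = x@sampleIds, predicted_subtype = x@predicted,
               stringsAsFactors = FALSE),
    scores,
    data.frame(margin = x@margin, flags = x@flags, stringsAsFactors = FALSE)
  )
  rownames(out) <- NULL
  out
}

## ---- SubgroupSpec ----

#' @describeIn SubgroupSpec compact display.
#' @param object a `SubgroupSpec`.
#' @export
setMethod("show", "SubgroupSpec", function(object) {
  cat("SubgroupSpec:",
      paste(sprintf("%s (%.1f%%)", object@componentNames,
                    100 * object@proportions), collapse = " + "), "\n")
})

## ---- SyntheticCohort ----

#' @describeIn SyntheticCohort clinical labels as a plain `data.frame`.
#' @param x a `SyntheticCohort`.
#' @export
setMethod("clinicalTable", "SyntheticCohort", function(x) {
  cd <- SummarizedExperiment::colData(x)
  data.frame(sample_id = colnames(x),
             er_status = cd$er_status,
             tnbc = cd$tnbc,
             prototypic_subtype = cd$prototypic_subtype,
             stringsAsFactors = FALSE)
})

#' @describeIn SyntheticCohort the `"exprs"` assay (genes x samples).
#' @export
setMethod("expressionValues", "SyntheticCohort", function(x) {
  SummarizedExperiment::assay(x, "exprs")
})

#' @describeIn SyntheticCohort gene ids (assay row names).
#' @export
setMethod("geneIds", "SyntheticCohort", function(x) rownames(x))
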