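# Internal helpers shared across modules.

#' Evaluate an expression under a local, restored RNG state
#'
#' All stochastic operations in the package take an explicit integer seed and
#' run under a locally seeded RNG, so no call disturbs (or depends on) the
#' caller's random state.
#'
#' @param seed single integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
#' @noRd
withSeed <- function(seed, expr) {
  if (length(seed) != 1L || !is.finite(seed)) {
    stop("'seed' must be a single finite integer")
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

## Canonical intrinsic-subtype ordering used for deterministic tie-breaking
## and column ordering wherever these five names occur.
CANONICAL_SUBTYPES <- c("Basal-like", "HER2-enriched", "LumA", "LumB",
                        "Normal-like")

#' Order subtype names canonically
#'
#' The five intrinsic breast-cancer subtypes come first in their fixed
#' canonical order; any other names follow alphabetically.
#' @keywords internal
#' @noRd
canonicalSubtypeOrder <- function(x) {
  known <- CANONICAL_SUBTYPES[CANONICAL_SUBTYPES %in% x]
  c(known, sort(setdiff(x, known)))
}

#' Validate a genes-by-samples expression matrix
#'
#' @param x numeric matrix, rows = genes, columns = samples; dimnames required.
#' @param what label used in error messages.
#' @return `x`, invisibly, after validation.
#' @keywords internal
#' @noRd
validateExpression <- function(x, what = "expression matrix") {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop(what, " must be a numeric matrix (genes x samples)")
  }
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    stop(what, " must have gene row names and sample column names")
  }
  dupg <- unique(rownames(x)[duplicated(rownames(x))])
  if (length(dupg)) {
    stop(what, ": duplicated gene id(s): ", paste(dupg, collapse = ", "))
  }
  dups <- unique(colnames(x)[duplicated(colnames(x))])
  if (length(dups)) {
    stop(what, ": duplicated sample id(s): ", paste(dups, collapse = ", "))
  }
  bad <- is.infinite(x) | is.nan(x)
  if (any(bad)) {
    stop(what, " contains non-finite values; missing data must be NA")
  }
  invisible(x)
}

#' Extract a plain matrix from matrix-like inputs
#'
#' Accepts a numeric matrix, a [CenteringResult], or a [SyntheticCohort] and
#' returns the genes-by-samples matrix.
#' @keywords internal
#' @noRd
asExpressionMatrix <- function(x) {
  if (is(x, "CenteringResult")) return(centeredValues(x))
  if (is(x, "SyntheticCohort")) {
    return(SummarizedExperiment::assay(x, "exprs"))
  }
  x
}

#' Extract a clinical data.frame from clinical-like inputs
#' @keywords internal
#' @noRd
asClinicalTable <- function(x) {
  if (is(x, "SyntheticCohort")) return(clinicalTable(x))
  x
}

## Largest-remainder apportionment: integer counts summing exactly to `total`,
## proportional to `proportions`. Ties on the fractional remainder are broken
## by component order, making the result deterministic.
apportionCounts <- function(proportions, total) {
  raw <- proportions * total
  counts <- floor(raw)
  short <- total - sum(counts)
  if (short > 0) {
    frac <- raw - counts
    take <- order(frac, seq_along(frac), decreasing = c(TRUE, FALSE),
                  method = "radix")[seq_len(short)]
    counts[take] <- counts[take] + 1L
  }
  as.integer(counts)
}
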