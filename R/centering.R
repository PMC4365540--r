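# Gene centering: the standard per-gene median/mean baseline, and the
# subgroup-specific variant that maps the training baseline through a
# clinicopathologically matched subgroup's percentile before looking it up in
# the study cohort. Mixture subgroups are handled either by repeated
# stratified subsampling of the training cohort or by an analytic weighted
# empirical CDF.

## Registry of named clinical predicates a SubgroupSpec can refer to.
## Samples whose relevant label is "unknown" are never selected; callers warn
## when such samples are excluded.
.PREDICATE_REGISTRY <- list(
  all = function(clinical) rep(TRUE, nrow(clinical)),
  er_positive = function(clinical) {
    if (!"er_status" %in% names(clinical)) {
      stop("subgroup 'er_positive' requires an 'er_status' column")
    }
    clinical$er_status == "positive"
  },
  er_negative = function(clinical) {
    if (!"er_status" %in% names(clinical)) {
      stop("subgroup 'er_negative' requires an 'er_status' column")
    }
    clinical$er_status == "negative"
  },
  tnbc = function(clinical) {
    if (!"tnbc" %in% names(clinical)) {
      stop("subgroup 'tnbc' requires a 'tnbc' column")
    }
    clinical$tnbc == "true"
  },
  non_tnbc = function(clinical) {
    if (!"tnbc" %in% names(clinical)) {
      stop("subgroup 'non_tnbc' requires a 'tnbc' column")
    }
    clinical$tnbc == "false"
  }
)

#' Build a subgroup / mixture specification
#'
#' A single subgroup is a one-component spec (`subgroupSpec("er_positive")`);
#' a mixture carries one proportion per component, e.g.
#' `subgroupSpec(c(er_positive = 0.15, er_negative = 0.85))` for a study
#' cohort of 15% ER-positive and 85% ER-negative cases. Components may also be
#' supplied as a named list of predicate functions over the clinical table.
#'
#' @param components either a character vector of registered component names
#'   (`"er_positive"`, `"er_negative"`, `"tnbc"`, `"non_tnbc"`, `"all"`),
#'   optionally named by proportions via `proportions`, or a named numeric
#'   vector mapping component names to proportions, or a named list of
#'   predicate functions.
#' @param proportions numeric mixture proportions (default: equal). Must sum
#'   to 1 within `1e-9`.
#' @return a [SubgroupSpec].
#' @examples
#' subgroupSpec("er_positive")
#' subgroupSpec(c(er_positive = 0.15, er_negative = 0.85))
#' @export
subgroupSpec <- function(components, proportions = NULL) {
  if (is.numeric(components) && !is.null(names(components))) {
    proportions <- unname(components)
    components <- names(components)
  }
  if (is.character(components)) {
    unknown <- setdiff(components, names(.PREDICATE_REGISTRY))
    if (length(unknown)) {
      stop("unknown subgroup component(s): ", paste(unknown, collapse = ", "),
           "; registered: ", paste(names(.PREDICATE_REGISTRY), collapse = ", "))
    }
    preds <- .PREDICATE_REGISTRY[components]
    nms <- components
  } else if (is.list(components)) {
    if (is.null(names(components)) || any(names(components) == "")) {
      stop("predicate components must be named")
    }
    preds <- components
    nms <- names(components)
  } else {
    stop("'components' must be component names or a named list of predicates")
  }
  if (is.null(proportions)) proportions <- rep(1 / length(nms), length(nms))
  new("SubgroupSpec", componentNames = nms, proportions = proportions,
      predicates = unname(preds))
}

#' Select the samples of each subgroup component
#'
#' Evaluates each component predicate on the clinical table and returns the
#' matching sample ids, restricted to samples present in `sampleIds` when
#' given. Overlapping components are an error (mixture components must be
#' disjoint on a given cohort).
#'
#' @param spec a [SubgroupSpec].
#' @param clinical clinical `data.frame`.
#' @param sampleIds optional character vector restricting the universe (e.g.
#'   the columns of an expression matrix).
#' @return named list of character vectors of sample ids, one per component.
#' @export
selectSubgroupSamples <- function(spec, clinical, sampleIds = NULL) {
  stopifnot(is(spec, "SubgroupSpec"))
  validateClinical(clinical)
  if (!is.null(sampleIds)) {
    clinical <- clinical[clinical$sample_id %in% sampleIds, , drop = FALSE]
  }
  sel <- lapply(spec@predicates, function(p) {
    hit <- p(clinical)
    if (!is.logical(hit) || length(hit) != nrow(clinical)) {
      stop("a subgroup predicate must return one logical per clinical row")
    }
    clinical$sample_id[hit & !is.na(hit)]
  })
  names(sel) <- spec@componentNames
  all <- unlist(sel, use.names = FALSE)
  if (anyDuplicated(all)) {
    stop("subgroup components overlap on this cohort (sample(s) ",
         paste(unique(all[duplicated(all)]), collapse = ", "), ")")
  }
  sel
}

#' Per-gene baseline expression of a cohort
#'
#' The expression baseline \eqn{\mu_{gene}}: the per-gene median (the PAM50
#' convention) or mean across the cohort, computed over non-missing values.
#'
#' @param expr numeric matrix (genes x samples), [CenteringResult], or
#'   [SyntheticCohort].
#' @param method `"median"` (default) or `"mean"`.
#' @return named numeric vector, one finite baseline per gene.
#' @examples
#' m <- matrix(c(1, 2, 3, 10), 1, dimnames = list("g", paste0("s", 1:4)))
#' computeBaseline(m, "median")  # 2.5
#' computeBaseline(m, "mean")    # 4
#' @export
computeBaseline <- function(expr, method = c("median", "mean")) {
  method <- match.arg(method)
  mat <- asExpressionMatrix(expr)
  validateExpression(mat)
  stat <- if (method == "median") {
    function(v) median(v, na.rm = TRUE)
  } else {
    function(v) mean(v, na.rm = TRUE)
  }
  out <- apply(mat, 1L, stat)
  bad <- !is.finite(out)
  if (any(bad)) {
    stop("gene(s) with no non-missing values: ",
         paste(rownames(mat)[bad], collapse = ", "))
  }
  out
}

#' Standard gene centering
#'
#' Subtracts each gene's own study-cohort median (or mean) from that gene's
#' expression values — the conventional transformation before centroid-based
#' subtype classification, and the one that fails when the study cohort's
#' clinicopathological composition is skewed.
#'
#' @inheritParams computeBaseline
#' @return a [CenteringResult] with `method = "standard-median"` or
#'   `"standard-mean"`.
#' @examples
#' m <- matrix(c(1, 3, 8), 1, dimnames = list("g", paste0("s", 1:3)))
#' centeredValues(standardCenter(m))  # -2 0 5
#' @seealso [subgroupCenter()]
#' @export
standardCenter <- function(expr, method = c("median", "mean")) {
  method <- match.arg(method)
  mat <- asExpressionMatrix(expr)
  baselines <- computeBaseline(mat, method)
  new("CenteringResult", centered = mat - baselines, baselines = baselines,
      method = paste0("standard-", method))
}

#' Subgroup percentiles of the training baseline
#'
#' For a single clinicopathological subgroup of the training cohort, computes
#' per gene the percentile \eqn{Q_{gene}} at which the *full-cohort* baseline
#' \eqn{\mu_{gene}} sits within the subgroup's expression distribution
#' (midpoint empirical-CDF convention, see [percentileOfValue()]). The
#' baseline is always computed on the full training cohort; only the
#' percentile lookup is subgroup-specific.
#'
#' @param train training-cohort expression (matrix, [CenteringResult], or
#'   [SyntheticCohort]).
#' @param clinical clinical table covering the training samples (defaults to
#'   the cohort's own table when `train` is a [SyntheticCohort]).
#' @param subgroup a single-component [SubgroupSpec] or a registered component
#'   name such as `"er_positive"`.
#' @param baselineMethod `"median"` (default) or `"mean"`.
#' @param minSubgroupSize smallest admissible subgroup (default 10); subgroups
#'   below 30 samples trigger a small-subgroup warning since empirical
#'   percentiles become unstable.
#' @return a [PercentileTable] with one row per gene.
#' @seealso [subgroupCenter()], [mixturePercentiles()],
#'   [weightedPercentiles()]
#' @export
computeSubgroupPercentiles <- function(train, clinical = NULL, subgroup,
                                       baselineMethod = c("median", "mean"),
                                       minSubgroupSize = 10L) {
  baselineMethod <- match.arg(baselineMethod)
  if (is.null(clinical)) clinical <- asClinicalTable(train)
  mat <- asExpressionMatrix(train)
  validateExpression(mat)
  if (is.character(subgroup)) subgroup <- subgroupSpec(subgroup)
  stopifnot(is(subgroup, "SubgroupSpec"))
  if (length(subgroup@componentNames) != 1L) {
    stop("computeSubgroupPercentiles needs a single-component subgroup; ",
         "use mixturePercentiles() or weightedPercentiles() for mixtures")
  }
  sel <- selectSubgroupSamples(subgroup, clinical, colnames(mat))[[1L]]
  if (length(sel) < minSubgroupSize) {
    stop("subgroup '", subgroup@componentNames, "' has ", length(sel),
         " samples; minimum is ", minSubgroupSize)
  }
  if (length(sel) < 30L) {
    warning("subgroup '", subgroup@componentNames, "' has only ", length(sel),
            " samples; empirical percentiles may be unstable", call. = FALSE)
  }
  mu <- computeBaseline(mat, baselineMethod)
  sub <- mat[, sel, drop = FALSE]
  q <- vapply(seq_len(nrow(mat)), function(g) {
    percentileOfValue(sub[g, ], mu[g])
  }, numeric(1))
  new("PercentileTable",
      table = data.frame(gene_id = rownames(mat),
                         subgroup = subgroup@componentNames,
                         mu_gene = unname(mu), q_gene = q,
                         stringsAsFactors = FALSE),
      baselineMethod = baselineMethod)
}

#' Subgroup-specific gene centering
#'
#' Centers a study cohort on the per-gene expression value at the percentile
#' \eqn{Q_{gene}} recorded in a baseline-percentile table: for each gene the
#' baseline subtracted is `quantileAt(study values, q_gene)`, i.e. the study
#' cohort's own value at the percentile where the training baseline sat within
#' the matched training subgroup. With `q_gene = 50` for every gene this
#' reduces exactly to standard median centering.
#'
#' @param study study-cohort expression (matrix, [CenteringResult], or
#'   [SyntheticCohort]).
#' @param table a [PercentileTable].
#' @param subgroup which subgroup of `table` to use (optional when the table
#'   holds a single subgroup).
#' @return a [CenteringResult] with `method = "subgroup-percentile"`, covering
#'   the genes shared between `study` and `table`; study genes absent from the
#'   table are dropped with a warning.
#' @seealso [computeSubgroupPercentiles()], [standardCenter()]
#' @export
subgroupCenter <- function(study, table, subgroup = NULL) {
  stopifnot(is(table, "PercentileTable"))
  mat <- asExpressionMatrix(study)
  validateExpression(mat)
  q <- qGene(table, subgroup)
  shared <- rownames(mat)[rownames(mat) %in% names(q)]
  if (length(shared) == 0L) {
    stop("none of the study genes appear in the percentile table")
  }
  dropped <- setdiff(rownames(mat), shared)
  if (length(dropped)) {
    warning(length(dropped), " study gene(s) absent from the percentile ",
            "table were dropped: ",
            paste(utils::head(dropped, 5L), collapse = ", "),
            if (length(dropped) > 5L) ", ..." else "", call. = FALSE)
  }
  mat <- mat[shared, , drop = FALSE]
  baselines <- vapply(shared, function(g) {
    v <- mat[g, ]
    if (all(is.na(v))) stop("gene '", g, "' has no non-missing study values")
    quantileAt(v, q[[g]])
  }, numeric(1))
  new("CenteringResult", centered = mat - baselines, baselines = baselines,
      method = "subgroup-percentile")
}

#' Mixture percentiles by repeated stratified subsampling
#'
#' For a study cohort that is a stated mixture of clinical subgroups (e.g.
#' 15% ER-positive / 85% ER-negative), draws `nResamples` stratified
#' subsamples of the training cohort at that mixture (without replacement
#' within components, largest-remainder integer counts), computes the per-gene
#' percentile of the full-training-cohort baseline within each pooled draw,
#' and averages the percentiles over draws. Deterministic given `seed`.
#'
#' @param train training-cohort expression.
#' @param clinical clinical table covering the training samples (defaults to
#'   the cohort's own table when `train` is a [SyntheticCohort]).
#' @param mixture a [SubgroupSpec] with one proportion per component.
#' @param subsampleSize samples per draw; default (`NULL`) uses the largest
#'   size every component can supply at its stated proportion, so a
#'   one-component mixture reduces exactly to [computeSubgroupPercentiles()].
#' @param nResamples number of stratified draws (default 200).
#' @param seed integer seed.
#' @param baselineMethod `"median"` (default) or `"mean"`.
#' @return a [PercentileTable] whose subgroup name encodes the mixture, e.g.
#'   `"er_positive:0.15+er_negative:0.85"`.
#' @seealso [weightedPercentiles()] for the analytic (sampling-free) variant.
#' @export
mixturePercentiles <- function(train, clinical = NULL, mixture,
                               subsampleSize = NULL, nResamples = 200L,
                               seed, baselineMethod = c("median", "mean")) {
  baselineMethod <- match.arg(baselineMethod)
  if (is.null(clinical)) clinical <- asClinicalTable(train)
  mat <- asExpressionMatrix(train)
  validateExpression(mat)
  if (is.character(mixture)) mixture <- subgroupSpec(mixture)
  stopifnot(is(mixture, "SubgroupSpec"), nResamples >= 1L)
  sel <- selectSubgroupSamples(mixture, clinical, colnames(mat))
  avail <- lengths(sel)
  props <- mixture@proportions
  keep <- props > 0
  if (any(avail[keep] == 0L)) {
    stop("mixture component(s) with no training samples: ",
         paste(mixture@componentNames[keep & avail == 0L], collapse = ", "))
  }
  if (is.null(subsampleSize)) {
    subsampleSize <- floor(min(avail[keep] / props[keep]))
    repeat {
      counts <- apportionCounts(props, subsampleSize)
      if (all(counts <= avail)) break
      subsampleSize <- subsampleSize - 1L
    }
  } else {
    counts <- apportionCounts(props, subsampleSize)
    short <- counts > avail
    if (any(short)) {
      stop("mixture component(s) cannot supply the required draw: ",
           paste(sprintf("%s (need %d, have %d)",
                         mixture@componentNames[short], counts[short],
                         avail[short]), collapse = ", "))
    }
  }
  mu <- computeBaseline(mat, baselineMethod)
  qsum <- numeric(nrow(mat))
  withSeed(seed, {
    for (r in seq_len(nResamples)) {
      pool <- unlist(lapply(seq_along(sel), function(i) {
        if (counts[i] == 0L) return(character())
        if (counts[i] == avail[i]) return(sel[[i]])
        sample(sel[[i]], counts[i], replace = FALSE)
      }), use.names = FALSE)
      sub <- mat[, pool, drop = FALSE]
      nn <- rowSums(!is.na(sub))
      qsum <- qsum + 100 * (rowSums(sub < mu, na.rm = TRUE) +
                            0.5 * rowSums(sub == mu, na.rm = TRUE)) / nn
    }
  })
  label <- paste(sprintf("%s:%.6g", mixture@componentNames, props),
                 collapse = "+")
  new("PercentileTable",
      table = data.frame(gene_id = rownames(mat), subgroup = label,
                         mu_gene = unname(mu), q_gene = qsum / nResamples,
                         stringsAsFactors = FALSE),
      baselineMethod = baselineMethod)
}

#' Mixture percentiles by sample weighting
#'
#' Analytic alternative to [mixturePercentiles()]: instead of subsampling,
#' every training sample of component *i* (size \eqn{n_i}) receives weight
#' \eqn{p_i / n_i}, and \eqn{Q_{gene}} is the weighted midpoint empirical CDF
#' of the full-cohort baseline \eqn{\mu_{gene}}. When the mixture proportions
#' are proportional to the component sizes this reduces exactly to the
#' unweighted percentile over the pooled components.
#'
#' @inheritParams mixturePercentiles
#' @return a [PercentileTable] (subgroup name encodes the mixture).
#' @export
weightedPercentiles <- function(train, clinical = NULL, mixture,
                                baselineMethod = c("median", "mean")) {
  baselineMethod <- match.arg(baselineMethod)
  if (is.null(clinical)) clinical <- asClinicalTable(train)
  mat <- asExpressionMatrix(train)
  validateExpression(mat)
  if (is.character(mixture)) mixture <- subgroupSpec(mixture)
  stopifnot(is(mixture, "SubgroupSpec"))
  sel <- selectSubgroupSamples(mixture, clinical, colnames(mat))
  props <- mixture@proportions
  empty <- props > 0 & lengths(sel) == 0L
  if (any(empty)) {
    stop("mixture component(s) with no training samples: ",
         paste(mixture@componentNames[empty], collapse = ", "))
  }
  samples <- unlist(sel, use.names = FALSE)
  weights <- unlist(lapply(seq_along(sel), function(i) {
    rep(props[i] / length(sel[[i]]), length(sel[[i]]))
  }), use.names = FALSE)
  mu <- computeBaseline(mat, baselineMethod)
  sub <- mat[, samples, drop = FALSE]
  q <- vapply(seq_len(nrow(sub)), function(g) {
    weightedPercentileOfValue(sub[g, ], weights, mu[g])
  }, numeric(1))
  label <- paste(sprintf("%s:%.6g", mixture@componentNames, props),
                 collapse = "+")
  new("PercentileTable",
      table = data.frame(gene_id = rownames(mat), subgroup = label,
                         mu_gene = unname(mu), q_gene = q,
                         stringsAsFactors = FALSE),
      baselineMethod = baselineMethod)
}
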