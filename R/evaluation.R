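# Evaluation of centering strategies: confusion summaries against prototypic
# labels, paired McNemar comparison of two classifiers, and the ER-composition
# sweep experiment.

#' Confusion summary of subtype assignments
#'
#' Cross-tabulates predicted against true (prototypic) subtypes. Accuracy is
#' the percentage of classified samples whose prediction matches the
#' prototypic label; the error rate is its complement. Unclassifiable samples
#' are excluded from the denominator and counted separately.
#'
#' @param assignments a [SubtypeAssignments].
#' @param truth clinical `data.frame` with `sample_id` and
#'   `prototypic_subtype`, or a [SyntheticCohort].
#' @return object of class `ConfusionSummary`: a list with `subtype_names`,
#'   `counts` (true x predicted), `accuracy`, `error_rate`, `n_evaluated`,
#'   `n_unclassifiable`.
#' @examples
#' \dontrun{confusionSummary(classifySamples(centered, centroids), clinical)}
#' @export
confusionSummary <- function(assignments, truth) {
  stopifnot(is(assignments, "SubtypeAssignments"))
  truth <- asClinicalTable(truth)
  if (!"prototypic_subtype" %in% names(truth)) {
    stop("truth table lacks a 'prototypic_subtype' column")
  }
  pred <- predictedSubtype(assignments)
  unclass <- pred == "unclassifiable"
  pred <- pred[!unclass]
  if (length(pred) == 0L) stop("no classifiable predictions to evaluate")
  lab <- truth$prototypic_subtype[match(names(pred), truth$sample_id)]
  if (any(is.na(lab))) {
    stop("sample(s) without a known true subtype: ",
         paste(utils::head(names(pred)[is.na(lab)], 5L), collapse = ", "))
  }
  levels <- canonicalSubtypeOrder(unique(c(lab, pred,
                                           subtypeNames(assignments))))
  counts <- table(factor(lab, levels), factor(pred, levels),
                  dnn = c("true", "predicted"))
  counts <- unclass(as.matrix(counts))
  accuracy <- sum(diag(counts)) / sum(counts)
  structure(
    list(subtype_names = levels, counts = counts, accuracy = accuracy,
         error_rate = 1 - accuracy, n_evaluated = sum(counts),
         n_unclassifiable = sum(unclass)),
    class = "ConfusionSummary"
  )
}

#' @export
print.ConfusionSummary <- function(x, ...) {
  cat(sprintf("ConfusionSummary: accuracy %.1f%% (error rate %.1f%%) on %d samples",
              100 * x$accuracy, 100 * x$error_rate, x$n_evaluated))
  if (x$n_unclassifiable > 0) {
    cat(sprintf(" (+%d unclassifiable)", x$n_unclassifiable))
  }
  cat("\n")
  print(x$counts)
  invisible(x)
}

#' Paired McNemar comparison of two classifiers
#'
#' Compares two classifiers evaluated on the same samples using only the
#' discordant pairs: `b` = A correct / B wrong, `c` = A wrong / B correct.
#' For few discordant pairs (`b + c < exactThreshold`) the exact two-sided
#' binomial test is used (`p = min(1, 2 * P[X <= min(b, c)])` with
#' `X ~ Binomial(b + c, 1/2)`; `p = 1` when there is no discordance);
#' otherwise the chi-square approximation with continuity correction,
#' `(|b - c| - 1)^2 / (b + c)` on 1 degree of freedom.
#'
#' @param correctA,correctB logical vectors over the same samples: was each
#'   sample classified correctly by method A / method B?
#' @param exactThreshold switch to the chi-square variant when `b + c` reaches
#'   this many discordant pairs (default 25).
#' @return object of class `McNemarResult`: list with `b`, `c`, `statistic`
#'   (`NA` for the exact variant), `p_value`, `variant`.
#' @examples
#' mcnemarTest(c(TRUE, TRUE, FALSE), c(TRUE, FALSE, FALSE))
#' @export
mcnemarTest <- function(correctA, correctB, exactThreshold = 25L) {
  if (length(correctA) != length(correctB)) {
    stop("correctA and correctB must pair the same samples (lengths ",
         length(correctA), " vs ", length(correctB), ")")
  }
  if (any(is.na(correctA)) || any(is.na(correctB))) {
    stop("paired correctness vectors must not contain NA")
  }
  b <- sum(correctA & !correctB)
  c <- sum(!correctA & correctB)
  n <- b + c
  if (n < exactThreshold) {
    p <- if (n == 0L) 1 else min(1, 2 * pbinom(min(b, c), n, 0.5))
    statistic <- NA_real_
    variant <- "exact-binomial"
  } else {
    statistic <- (abs(b - c) - 1)^2 / n
    p <- pchisq(statistic, df = 1L, lower.tail = FALSE)
    variant <- "chi-square-continuity"
  }
  structure(list(b = b, c = c, statistic = statistic, p_value = p,
                 variant = variant),
            class = "McNemarResult")
}

#' @export
print.McNemarResult <- function(x, ...) {
  cat(sprintf("McNemar test (%s): b = %d, c = %d, P = %.4g\n",
              x$variant, x$b, x$c, x$p_value))
  invisible(x)
}

#' ER-composition sweep experiment
#'
#' Reproduces, on any supplied pool, the experiment comparing centering
#' strategies across study-cohort compositions: for each ER-positive
#' proportion on the grid, study cohorts of `cohortSize` samples are drawn
#' (without replacement, per replicate) from the pool at that ER mix, then
#' classified after (i) no centering, (ii) standard median centering, and
#' (iii) subgroup-specific centering with mixture percentiles matched to the
#' drawn mix, and scored against the prototypic labels.
#'
#' @param pool expression pool the study cohorts are drawn from (matrix or
#'   [SyntheticCohort]).
#' @param poolClinical clinical table for the pool (ER status + prototypic
#'   subtypes); defaults to the cohort's own table for a [SyntheticCohort].
#' @param centroids a [CentroidMatrix] (trained on the training cohort).
#' @param train training-cohort expression — the percentile source.
#' @param trainClinical clinical table for the training cohort; defaults to
#'   the cohort's own table for a [SyntheticCohort].
#' @param proportions ER-positive percentages to sweep (default
#'   `seq(0, 100, 10)`).
#' @param cohortSize study-cohort size per draw (default 75).
#' @param nReplicates replicate draws per proportion (default 20).
#' @param seed integer seed governing every draw.
#' @param nResamples stratified resamples inside [mixturePercentiles()]
#'   (default 50).
#' @param subsampleSize subsample size for [mixturePercentiles()] (default
#'   `NULL`: largest feasible).
#' @param metric correlation metric for [classifySamples()].
#' @param baselineMethod baseline statistic (default `"median"`).
#' @return `data.frame` of class `SweepResult` in long format: `proportion`
#'   (percent ER-positive), `strategy` (`none`, `standard`,
#'   `subgroup-specific`), `replicate`, `error_rate`, `n_classified`,
#'   `n_unclassifiable`.
#' @seealso [mixturePercentiles()], [classifySamples()], [confusionSummary()]
#' @export
erProportionSweep <- function(pool, poolClinical = NULL, centroids,
                              train, trainClinical = NULL,
                              proportions = seq(0, 100, by = 10),
                              cohortSize = 75L, nReplicates = 20L, seed,
                              nResamples = 50L, subsampleSize = NULL,
                              metric = c("spearman", "pearson"),
                              baselineMethod = c("median", "mean")) {
  metric <- match.arg(metric)
  baselineMethod <- match.arg(baselineMethod)
  if (is.null(poolClinical)) poolClinical <- asClinicalTable(pool)
  if (is.null(trainClinical)) trainClinical <- asClinicalTable(train)
  poolMat <- asExpressionMatrix(pool)
  trainMat <- asExpressionMatrix(train)
  validateExpression(poolMat)
  stopifnot(all(proportions >= 0), all(proportions <= 100), cohortSize >= 1L,
            nReplicates >= 1L)

  poolClin <- poolClinical[match(colnames(poolMat), poolClinical$sample_id), ]
  erPos <- poolClin$sample_id[poolClin$er_status == "positive"]
  erNeg <- poolClin$sample_id[poolClin$er_status == "negative"]

  rows <- vector("list", length(proportions) * nReplicates * 3L)
  k <- 0L
  withSeed(seed, {
    for (p in proportions) {
      nPos <- apportionCounts(c(p, 100 - p) / 100, cohortSize)[1L]
      nNeg <- cohortSize - nPos
      if (nPos > length(erPos) || nNeg > length(erNeg)) {
        stop("pool cannot supply a ", cohortSize, "-sample cohort at ", p,
             "% ER-positive (need ", nPos, "+/", nNeg,
             "-, have ", length(erPos), "+/", length(erNeg), "-)")
      }
      mixture <- if (p == 0) {
        subgroupSpec("er_negative")
      } else if (p == 100) {
        subgroupSpec("er_positive")
      } else {
        subgroupSpec(c(er_positive = p / 100, er_negative = 1 - p / 100))
      }
      ptab <- mixturePercentiles(trainMat, trainClinical, mixture,
                                 subsampleSize = subsampleSize,
                                 nResamples = nResamples,
                                 seed = sample.int(.Machine$integer.max, 1L),
                                 baselineMethod = baselineMethod)
      for (rep in seq_len(nReplicates)) {
        ids <- c(if (nPos > 0L) sample(erPos, nPos),
                 if (nNeg > 0L) sample(erNeg, nNeg))
        study <- poolMat[, ids, drop = FALSE]
        arms <- list(
          none = study,
          standard = standardCenter(study, baselineMethod),
          `subgroup-specific` = subgroupCenter(study, ptab)
        )
        for (strategy in names(arms)) {
          asg <- classifySamples(arms[[strategy]], centroids, metric)
          cs <- confusionSummary(asg, poolClin)
          k <- k + 1L
          rows[[k]] <- data.frame(
            proportion = p, strategy = strategy, replicate = rep,
            error_rate = cs$error_rate, n_classified = cs$n_evaluated,
            n_unclassifiable = cs$n_unclassifiable,
            stringsAsFactors = FALSE
          )
        }
      }
    }
  })
  out <- do.call(rbind, rows)
  class(out) <- c("SweepResult", class(out))
  out
}

#' Per-(proportion, strategy) mean error rates of a sweep
#'
#' @param sweep a `SweepResult` from [erProportionSweep()].
#' @return `data.frame` with `proportion`, `strategy`, `mean_error_rate`.
#' @export
summarizeSweep <- function(sweep) {
  agg <- stats::aggregate(error_rate ~ proportion + strategy,
                          data = as.data.frame(sweep), FUN = mean)
  names(agg)[names(agg) == "error_rate"] <- "mean_error_rate"
  agg[order(agg$strategy, agg$proportion), , drop = FALSE]
}
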