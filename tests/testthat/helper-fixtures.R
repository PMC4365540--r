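# Shared fixtures and independent oracles used across the suite.

## Random genes-by-samples matrix with dimnames (tie-free w.p. 1).
randomExpr <- function(nGenes, nSamples, seed, sd = 1, mean = 0) {
  set.seed(seed)
  matrix(rnorm(nGenes * nSamples, mean, sd), nGenes, nSamples,
         dimnames = list(sprintf("g%03d", seq_len(nGenes)),
                         sprintf("s%03d", seq_len(nSamples))))
}

## Minimal clinical table.
makeClinical <- function(sampleIds, er = "unknown", tnbc = "unknown",
                         subtype = NA_character_) {
  data.frame(sample_id = sampleIds,
             er_status = rep_len(er, length(sampleIds)),
             tnbc = rep_len(tnbc, length(sampleIds)),
             prototypic_subtype = rep_len(subtype, length(sampleIds)),
             stringsAsFactors = FALSE)
}

## Independent sort-and-count percentile oracle (midpoint convention):
## positional ranks on the sorted vector, averaged over tied positions.
oraclePercentile <- function(v, x) {
  sv <- sort(v)
  n <- length(sv)
  hits <- which(sv == x)
  if (length(hits) > 0L) {
    100 * mean(hits - 0.5) / n
  } else {
    100 * sum(sv < x) / n
  }
}

## Independent piecewise-linear inverse oracle: order statistics pinned at
## percentiles 100 * (i - 0.5) / n, explicit bracketing + interpolation.
oracleQuantile <- function(v, q) {
  sv <- sort(v)
  n <- length(sv)
  p <- 100 * (seq_len(n) - 0.5) / n
  if (q <= p[1L]) return(sv[1L])
  if (q >= p[n]) return(sv[n])
  i <- max(which(p <= q))
  sv[i] + (q - p[i]) / (p[i + 1L] - p[i]) * (sv[i + 1L] - sv[i])
}

## Weighted-CDF oracle by explicit per-sample summation.
oracleWeightedPercentile <- function(v, w, x) {
  num <- 0
  for (i in seq_along(v)) {
    if (v[i] < x) num <- num + w[i]
    if (v[i] == x) num <- num + 0.5 * w[i]
  }
  100 * num / sum(w)
}

## Exact two-sided McNemar oracle: full enumeration of the Binomial(n, 1/2)
## null via choose(), independent of pbinom.
oracleMcnemarExact <- function(b, c) {
  n <- b + c
  if (n == 0L) return(1)
  k <- min(b, c)
  tail <- sum(choose(n, 0:k)) / 2^n
  min(1, 2 * tail)
}

## Direct-formula correlation oracles.
oraclePearson <- function(x, y) {
  n <- length(x)
  num <- sum(x * y) - n * mean(x) * mean(y)
  den <- sqrt((sum(x^2) - n * mean(x)^2) * (sum(y^2) - n * mean(y)^2))
  num / den
}
oracleSpearman <- function(x, y) oraclePearson(rank(x), rank(y))

## All multisets (sorted, with repetition) of size n from alphabet.
allMultisets <- function(alphabet, n) {
  if (n == 1L) return(as.list(alphabet))
  out <- list()
  rec <- function(prefix, startIdx, left) {
    if (left == 0L) {
      out[[length(out) + 1L]] <<- prefix
      return()
    }
    for (i in startIdx:length(alphabet)) {
      rec(c(prefix, alphabet[i]), i, left - 1L)
    }
  }
  rec(numeric(0), 1L, n)
  out
}

## Standard end-to-end setup used by evaluation/acceptance tests: a training
## cohort, a study pool on a shifted platform, and centroids from the
## standard-centered training cohort.
makeHarness <- function(seed, nTrain = 600L, nPool = 300L, shiftSd = 1.5) {
  train <- generateCohort(defaultBreastConfig(nTrain, seed = seed))
  pool <- generateCohort(defaultBreastConfig(nPool, seed = seed + 1L,
                                             platformShiftSd = shiftSd),
                         samplePrefix = "P")
  centroids <- trainCentroids(standardCenter(train), clinicalTable(train))
  list(train = train, pool = pool, centroids = centroids)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
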