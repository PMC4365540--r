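# Confusion summaries, McNemar comparisons, and the composition sweep.

makeAssignments <- function(sampleIds, predicted) {
  subtypes <- c("Basal-like", "HER2-enriched", "LumA", "LumB", "Normal-like")
  scores <- matrix(0, length(sampleIds), length(subtypes),
                   dimnames = list(sampleIds, subtypes))
  for (i in seq_along(sampleIds)) {
    if (predicted[i] != "unclassifiable") scores[i, predicted[i]] <- 1
  }
  new("SubtypeAssignments", sampleIds = sampleIds, predicted = predicted,
      scores = scores,
      margin = ifelse(predicted == "unclassifiable", NA_real_, 1),
      flags = ifelse(predicted == "unclassifiable",
                     "unclassifiable:test", ""))
}

test_that("confusion summary computes accuracy, error rate and conserves counts", {
  ids <- sprintf("S%02d", 1:12)
  truth <- makeClinical(ids, subtype = rep(c("LumA", "LumB", "Basal-like"), 4))
  perfect <- makeAssignments(ids, truth$prototypic_subtype)
  cs <- confusionSummary(perfect, truth)
  expect_equal(cs$accuracy, 1)
  expect_equal(cs$error_rate, 0)
  expect_identical(cs$n_evaluated, 12L)
  expect_equal(sum(cs$counts), 12)

  # printed error rates of a 75-sample cohort: 4 and 25 mismatches
  ids75 <- sprintf("T%02d", 1:75)
  truth75 <- makeClinical(ids75, subtype = "LumA")
  for (nWrong in c(4L, 25L)) {
    pred <- rep("LumA", 75)
    pred[seq_len(nWrong)] <- "LumB"
    cs <- confusionSummary(makeAssignments(ids75, pred), truth75)
    expect_equal(cs$error_rate, nWrong / 75)
    expect_equal(cs$accuracy + cs$error_rate, 1)
  }
  expect_equal(round(100 * 4 / 75, 1), 5.3)
  expect_equal(round(100 * 25 / 75, 1), 33.3)

  # unclassifiable samples excluded from the denominator, counted apart
  pred <- truth$prototypic_subtype
  pred[1:2] <- "unclassifiable"
  cs <- confusionSummary(makeAssignments(ids, pred), truth)
  expect_identical(cs$n_evaluated, 10L)
  expect_identical(cs$n_unclassifiable, 2L)
  expect_equal(cs$accuracy, 1)
})

test_that("mcnemarTest handles the no-discordance and small-sample cases", {
  allTrue <- rep(TRUE, 10)
  res <- mcnemarTest(allTrue, allTrue)
  expect_equal(res$p_value, 1)
  expect_identical(res$b + res$c, 0L)

  # b = 1, c = 6: exact two-sided p = 2 * (C(7,0) + C(7,1)) / 2^7 = 0.125
  a <- c(rep(TRUE, 1), rep(FALSE, 6), rep(TRUE, 3))
  b <- c(rep(FALSE, 1), rep(TRUE, 6), rep(TRUE, 3))
  res <- mcnemarTest(a, b)
  expect_identical(res$variant, "exact-binomial")
  expect_equal(res$p_value, 0.125)

  expect_error(mcnemarTest(c(TRUE, FALSE), TRUE), "pair the same samples")
})

test_that("exact McNemar equals full binomial enumeration for all b + c <= 12", {
  for (b in 0:12) {
    for (c in 0:(12 - b)) {
      got <- mcnemarTest(c(rep(TRUE, b), rep(FALSE, c)),
                         c(rep(FALSE, b), rep(TRUE, c)),
                         exactThreshold = 13L)
      expect_identical(got$variant, "exact-binomial")
      expect_identical(c(got$b, got$c), c(b, c))
      expect_equal(got$p_value, oracleMcnemarExact(b, c), tolerance = 1e-12)
    }
  }
})

test_that("mcnemarTest is symmetric and switches variant at the threshold", {
  set.seed(27)
  a <- runif(60) > 0.4
  b <- runif(60) > 0.4
  r1 <- mcnemarTest(a, b)
  r2 <- mcnemarTest(b, a)
  expect_identical(r1$b, r2$c)
  expect_identical(r1$c, r2$b)
  expect_equal(r1$p_value, r2$p_value)

  # above the threshold the continuity-corrected chi-square applies
  big <- mcnemarTest(c(rep(TRUE, 20), rep(FALSE, 10)),
                     c(rep(FALSE, 20), rep(TRUE, 10)))
  expect_identical(big$variant, "chi-square-continuity")
  expect_equal(big$statistic, (abs(20 - 10) - 1)^2 / 30)
  expect_equal(big$p_value, pchisq(big$statistic, 1, lower.tail = FALSE))
})

test_that("sweep output is complete, deterministic, and error rates are in range", {
  h <- makeHarness(101, nTrain = 300L, nPool = 200L)
  sw <- erProportionSweep(h$pool, centroids = h$centroids, train = h$train,
                          proportions = c(0, 50, 100), cohortSize = 40,
                          nReplicates = 3, seed = 7, nResamples = 10)
  expect_identical(nrow(sw), 3L * 3L * 3L)
  grid <- expand.grid(proportion = c(0, 50, 100),
                      strategy = c("none", "standard", "subgroup-specific"),
                      replicate = 1:3)
  expect_identical(
    nrow(merge(as.data.frame(sw)[, 1:3], grid)), 27L
  )
  expect_true(all(sw$error_rate >= 0 & sw$error_rate <= 1))

  sw2 <- erProportionSweep(h$pool, centroids = h$centroids, train = h$train,
                           proportions = c(0, 50, 100), cohortSize = 40,
                           nReplicates = 3, seed = 7, nResamples = 10)
  expect_identical(as.data.frame(sw), as.data.frame(sw2))

  expect_error(
    erProportionSweep(h$pool, centroids = h$centroids, train = h$train,
                      proportions = 100, cohortSize = 199, nReplicates = 1,
                      seed = 1, nResamples = 5),
    "100% ER-positive"
  )
})
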