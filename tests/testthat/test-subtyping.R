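# Centroid training and nearest-centroid classification.

test_that("trainCentroids reproduces duplicated patterns and hand-computed means", {
  pat <- cbind(A = c(1, -1, 0), B = c(-1, 1, 2))
  rownames(pat) <- c("g1", "g2", "g3")
  m <- pat[, c("A", "A", "A", "B", "B")]
  colnames(m) <- paste0("s", 1:5)
  clin <- makeClinical(colnames(m),
                       subtype = c("LumA", "LumA", "LumA", "LumB", "LumB"))
  cm <- trainCentroids(m, clin, aggregate = "mean")
  expect_equal(centroidValues(cm)[, "LumA"], pat[, "A"])
  expect_equal(centroidValues(cm)[, "LumB"], pat[, "B"])

  # 3 genes x 4 samples, 2 subtypes, means by hand
  m2 <- matrix(c(1, 2, 3, 4,
                 0, 2, 4, 6,
                 5, 5, 1, 1), 3, 4, byrow = TRUE,
               dimnames = list(c("g1", "g2", "g3"), paste0("s", 1:4)))
  clin2 <- makeClinical(colnames(m2), subtype = c("LumA", "LumA", "LumB", "LumB"))
  cm2 <- trainCentroids(m2, clin2)
  expect_equal(unname(centroidValues(cm2)[, "LumA"]), c(1.5, 1, 5))
  expect_equal(unname(centroidValues(cm2)[, "LumB"]), c(3.5, 5, 1))

  clin2$prototypic_subtype[4] <- NA
  expect_warning(expect_error(trainCentroids(m2, clin2), "fewer than 2"),
                 "excluded")
})

test_that("noiseless generator cohorts recover the generator's centered means exactly", {
  cfg <- defaultBreastConfig(100, seed = 21)
  cfg0 <- initialize(cfg, noiseSd = 0)
  cohort <- generateCohort(cfg0)
  centered <- standardCenter(cohort)
  cm <- trainCentroids(centered, clinicalTable(cohort))
  # per-gene medians of the noiseless cohort
  med <- computeBaseline(expressionValues(cohort), "median")
  for (st in subtypeNames(cm)) {
    expect_equal(centroidValues(cm)[, st],
                 cfg0@subtypeMeans[, st] - med, tolerance = 1e-12)
  }
})

test_that("classifySamples assigns a centroid to itself with score 1, its negation to the rival", {
  set.seed(22)
  v <- matrix(rnorm(20), 10, 2,
              dimnames = list(sprintf("g%02d", 1:10), c("LumA", "LumB")))
  cm <- new("CentroidMatrix", values = v)
  study <- cbind(self = v[, "LumA"], anti = -v[, "LumA"])
  for (metric in c("spearman", "pearson")) {
    asg <- classifySamples(study, cm, metric = metric, minGenes = 5)
    expect_identical(unname(predictedSubtype(asg)["self"]), "LumA")
    expect_equal(assignmentScores(asg)["self", "LumA"], 1)
    expect_identical(unname(predictedSubtype(asg)["anti"]), "LumB")
  }
})

test_that("classification argmax matches direct-formula correlation oracles", {
  set.seed(23)
  for (i in 1:10) {
    cm <- new("CentroidMatrix",
              values = matrix(rnorm(30), 10, 3,
                              dimnames = list(sprintf("g%02d", 1:10),
                                              c("Basal-like", "LumA", "LumB"))))
    study <- matrix(rnorm(50), 10, 5,
                    dimnames = list(sprintf("g%02d", 1:10), paste0("s", 1:5)))
    for (metric in c("spearman", "pearson")) {
      oracleFn <- if (metric == "spearman") oracleSpearman else oraclePearson
      asg <- classifySamples(study, cm, metric = metric, minGenes = 5)
      for (s in colnames(study)) {
        sc <- vapply(subtypeNames(cm), function(st) {
          oracleFn(study[, s], centroidValues(cm)[, st])
        }, numeric(1))
        expect_equal(assignmentScores(asg)[s, names(sc)], sc,
                     tolerance = 1e-12)
        expect_identical(unname(predictedSubtype(asg)[s]),
                         names(which.max(sc)))
      }
    }
  }
})

test_that("spearman is invariant to increasing transforms, pearson to positive affine maps", {
  set.seed(24)
  cm <- new("CentroidMatrix",
            values = matrix(rnorm(40), 20, 2,
                            dimnames = list(sprintf("g%02d", 1:20),
                                            c("LumA", "LumB"))))
  study <- matrix(rnorm(60), 20, 3,
                  dimnames = list(sprintf("g%02d", 1:20), paste0("s", 1:3)))
  base <- classifySamples(study, cm, metric = "spearman")
  warped <- apply(study, 2, function(x) exp(x) + x^3)  # strictly increasing
  dimnames(warped) <- dimnames(study)
  expect_identical(predictedSubtype(classifySamples(warped, cm, "spearman")),
                   predictedSubtype(base))
  expect_equal(assignmentScores(classifySamples(warped, cm, "spearman")),
               assignmentScores(base), tolerance = 1e-12)

  basePearson <- classifySamples(study, cm, metric = "pearson")
  affine <- sweep(sweep(study, 2, c(2, 0.5, 10), "*"), 2, c(-1, 3, 7), "+")
  dimnames(affine) <- dimnames(study)
  expect_equal(assignmentScores(classifySamples(affine, cm, "pearson")),
               assignmentScores(basePearson), tolerance = 1e-12)
})

test_that("assignments are deterministic under sample and centroid-column permutations", {
  set.seed(25)
  cm <- new("CentroidMatrix",
            values = matrix(rnorm(100), 20, 5,
                            dimnames = list(sprintf("g%02d", 1:20),
                                            CANONICAL <- c("Basal-like",
                                                           "HER2-enriched",
                                                           "LumA", "LumB",
                                                           "Normal-like"))))
  study <- matrix(rnorm(200), 20, 10,
                  dimnames = list(sprintf("g%02d", 1:20),
                                  sprintf("s%02d", 1:10)))
  a <- predictedSubtype(classifySamples(study, cm))
  b <- predictedSubtype(classifySamples(study[, sample(10)], cm))
  expect_identical(a[names(b)], b)
  cmPerm <- new("CentroidMatrix", values = centroidValues(cm)[, c(3, 1, 5, 2, 4)])
  expect_identical(predictedSubtype(classifySamples(study, cmPerm)), a)
})

test_that("degenerate samples are unclassifiable, not fatal", {
  set.seed(26)
  cm <- new("CentroidMatrix",
            values = matrix(rnorm(60), 30, 2,
                            dimnames = list(sprintf("g%02d", 1:30),
                                            c("LumA", "LumB"))))
  study <- matrix(rnorm(90), 30, 3,
                  dimnames = list(sprintf("g%02d", 1:30),
                                  c("ok", "sparse", "flat")))
  study[11:30, "sparse"] <- NA     # 10 non-missing < minGenes
  study[, "flat"] <- 1             # zero variance
  asg <- classifySamples(study, cm, minGenes = 20)
  pred <- predictedSubtype(asg)
  expect_identical(unname(pred["sparse"]), "unclassifiable")
  expect_identical(unname(pred["flat"]), "unclassifiable")
  expect_true(pred["ok"] %in% c("LumA", "LumB"))
  expect_match(asg@flags[2], "non-missing")
  expect_match(asg@flags[3], "zero-variance")
})
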