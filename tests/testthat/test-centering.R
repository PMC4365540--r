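# Standard and subgroup-specific centering, mixture and weighted percentiles.

test_that("computeBaseline returns the per-gene statistic over non-missing values", {
  m <- matrix(c(1, 2, 3, 1, 2, 3, 10, NA), 2, 4, byrow = TRUE,
              dimnames = list(c("g1", "g2"), paste0("s", 1:4)))
  expect_equal(computeBaseline(m, "median"),
               c(g1 = median(c(1, 2, 3, 1)), g2 = median(c(2, 3, 10))))
  expect_equal(computeBaseline(m, "mean")[["g2"]], mean(c(2, 3, 10)))
  m[2, ] <- NA
  expect_error(computeBaseline(m), "g2")
})

test_that("standardCenter subtracts the study cohort's own baseline", {
  m <- matrix(c(5, 5, 5, 1, 3, 8), 2, 3, byrow = TRUE,
              dimnames = list(c("const", "g"), paste0("s", 1:3)))
  res <- standardCenter(m, "median")
  expect_equal(unname(centeredValues(res)["const", ]), c(0, 0, 0))
  expect_equal(unname(centeredValues(res)["g", ]), c(-2, 0, 5))
  expect_equal(baselinesUsed(res), c(const = 5, g = 3))
  expect_identical(centeringMethod(res), "standard-median")
  # the defining identity: centered = input - baseline
  expect_equal(centeredValues(res), m - baselinesUsed(res))
})

test_that("computeSubgroupPercentiles puts the full-cohort baseline at the stated subgroup percentile", {
  # whole cohort as the subgroup, tie-free values -> every gene at its own
  # median, i.e. q = 50 exactly (odd and even cohort sizes)
  for (n in c(11, 12)) {
    m <- randomExpr(20, n, seed = n)
    clin <- makeClinical(colnames(m), er = "positive")
    pt <- suppressWarnings(
      computeSubgroupPercentiles(m, clin, "all", minSubgroupSize = 5)
    )
    expect_equal(unname(qGene(pt)), rep(50, 20))
    expect_equal(muGene(pt), computeBaseline(m, "median"))
  }

  # toy example: gene (1..6), subgroup = samples 4-6; mu = 3.5 sits below
  # every subgroup value -> percentile 0
  m <- matrix(1:6, 1, dimnames = list("g", paste0("s", 1:6)))
  clin <- makeClinical(colnames(m),
                       er = c(rep("negative", 3), rep("positive", 3)))
  expect_warning(
    pt <- computeSubgroupPercentiles(m, clin, "er_positive",
                                     minSubgroupSize = 2),
    "unstable"
  )
  expect_equal(unname(qGene(pt)), 0)
  expect_equal(unname(muGene(pt)), 3.5)

  expect_error(
    suppressWarnings(
      computeSubgroupPercentiles(m, clin, "er_positive", minSubgroupSize = 5)
    ),
    "minimum is 5"
  )
})

test_that("subgroupCenter at q = 50 reduces to standard median centering", {
  study <- randomExpr(30, 17, seed = 5)
  pt <- new("PercentileTable",
            table = data.frame(gene_id = rownames(study), subgroup = "all",
                               mu_gene = 0, q_gene = 50,
                               stringsAsFactors = FALSE),
            baselineMethod = "median")
  sub <- subgroupCenter(study, pt)
  std <- standardCenter(study, "median")
  expect_equal(centeredValues(sub), centeredValues(std), tolerance = 1e-12)
})

test_that("full reduction: percentiles from the whole training cohort reproduce standard centering on any study cohort", {
  train <- randomExpr(40, 30, seed = 6)
  clinTrain <- makeClinical(colnames(train), er = "positive")
  pt <- computeSubgroupPercentiles(train, clinTrain, "all")
  study <- randomExpr(40, 23, seed = 7)
  expect_equal(centeredValues(subgroupCenter(study, pt)),
               centeredValues(standardCenter(study, "median")),
               tolerance = 1e-9)
})

test_that("subgroupCenter is equivariant to per-gene shifts of the study cohort", {
  study <- randomExpr(25, 19, seed = 8)
  clin <- makeClinical(colnames(study), er = "positive")
  pt <- suppressWarnings(computeSubgroupPercentiles(study, clin, "all"))
  set.seed(9)
  shifts <- rnorm(25, sd = 4)
  shifted <- study + shifts
  expect_equal(centeredValues(subgroupCenter(shifted, pt)),
               centeredValues(subgroupCenter(study, pt)),
               tolerance = 1e-9)
})

test_that("subgroupCenter drops unknown genes with a warning, errors when none overlap", {
  study <- randomExpr(10, 8, seed = 10)
  pt <- new("PercentileTable",
            table = data.frame(gene_id = rownames(study)[1:6],
                               subgroup = "all", mu_gene = 0, q_gene = 50,
                               stringsAsFactors = FALSE),
            baselineMethod = "median")
  expect_warning(res <- subgroupCenter(study, pt), "dropped")
  expect_identical(nrow(centeredValues(res)), 6L)

  other <- randomExpr(4, 8, seed = 11)
  rownames(other) <- paste0("x", 1:4)
  expect_error(suppressWarnings(subgroupCenter(other, pt)), "none of the")
})

test_that("mixturePercentiles with one full component equals computeSubgroupPercentiles", {
  m <- randomExpr(15, 40, seed = 12)
  clin <- makeClinical(colnames(m),
                       er = c(rep("positive", 25), rep("negative", 15)))
  direct <- suppressWarnings(computeSubgroupPercentiles(m, clin, "er_positive"))
  viaMix <- mixturePercentiles(m, clin, subgroupSpec("er_positive"),
                               nResamples = 5, seed = 1)
  expect_equal(unname(qGene(viaMix)), unname(qGene(direct)))
})

test_that("mixturePercentiles is deterministic given seed", {
  m <- randomExpr(15, 60, seed = 13)
  clin <- makeClinical(colnames(m),
                       er = c(rep("positive", 30), rep("negative", 30)))
  mix <- subgroupSpec(c(er_positive = 0.3, er_negative = 0.7))
  a <- mixturePercentiles(m, clin, mix, subsampleSize = 40, nResamples = 20,
                          seed = 99)
  b <- mixturePercentiles(m, clin, mix, subsampleSize = 40, nResamples = 20,
                          seed = 99)
  expect_identical(as.data.frame(a), as.data.frame(b))
  c <- mixturePercentiles(m, clin, mix, subsampleSize = 40, nResamples = 20,
                          seed = 100)
  expect_false(identical(qGene(a), qGene(c)))

  expect_error(
    mixturePercentiles(m, clin, mix, subsampleSize = 200, nResamples = 2,
                       seed = 1),
    "cannot supply"
  )
})

test_that("weightedPercentiles matches the explicit-summation oracle", {
  set.seed(14)
  for (i in 1:10) {
    nPos <- sample(5:12, 1)
    nNeg <- sample(5:12, 1)
    m <- randomExpr(8, nPos + nNeg, seed = 14 + i)
    clin <- makeClinical(colnames(m),
                         er = c(rep("positive", nPos), rep("negative", nNeg)))
    pPos <- runif(1, 0.1, 0.9)
    mix <- subgroupSpec(c(er_positive = pPos, er_negative = 1 - pPos))
    pt <- weightedPercentiles(m, clin, mix)
    mu <- computeBaseline(m, "median")
    w <- c(rep(pPos / nPos, nPos), rep((1 - pPos) / nNeg, nNeg))
    for (g in rownames(m)) {
      expect_equal(qGene(pt)[[g]], oracleWeightedPercentile(m[g, ], w, mu[[g]]),
                   tolerance = 1e-12)
    }
  }
})

test_that("weighted percentiles with proportions matching component sizes reduce to pooled percentiles", {
  m <- randomExpr(12, 40, seed = 30)
  clin <- makeClinical(colnames(m),
                       er = c(rep("positive", 10), rep("negative", 30)))
  mix <- subgroupSpec(c(er_positive = 0.25, er_negative = 0.75))
  pooled <- computeSubgroupPercentiles(m, clin, "all")
  expect_equal(unname(qGene(weightedPercentiles(m, clin, mix))),
               unname(qGene(pooled)), tolerance = 1e-12)
})

test_that("mixture resampling converges to the weighted analytic percentiles", {
  m <- randomExpr(20, 120, seed = 31)
  clin <- makeClinical(colnames(m),
                       er = c(rep("positive", 60), rep("negative", 60)))
  mix <- subgroupSpec(c(er_positive = 0.15, er_negative = 0.85))
  wq <- qGene(weightedPercentiles(m, clin, mix))
  mq <- qGene(mixturePercentiles(m, clin, mix, nResamples = 400, seed = 5))
  expect_lt(max(abs(wq - mq[names(wq)])), 1)
})

test_that("subgroup spec validates proportions and disjointness", {
  expect_error(subgroupSpec(c(er_positive = 0.4, er_negative = 0.4)),
               "sum to 1")
  expect_error(subgroupSpec("nope"), "unknown subgroup component")
  clin <- makeClinical(c("S1", "S2"), er = "positive", tnbc = "true")
  spec <- subgroupSpec(c(er_positive = 0.5, tnbc = 0.5))
  expect_error(suppressWarnings(selectSubgroupSamples(spec, clin)), "overlap")
})
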