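test_that("chi-square independence matches the direct formula", {
  # perfectly balanced table: no association
  flat <- chiSquareIndependence(matrix(10, 2, 2))
  expect_equal(flat@statistic, 0)
  expect_equal(cramersV(flat), 0)

  set.seed(1)
  tab <- matrix(rpois(10, 40) + 1, 5, 2)
  res <- chiSquareIndependence(tab)
  # textbook sum((O - E)^2 / E) with marginal-product expected counts
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  expect_equal(res@statistic, sum((tab - E)^2 / E), tolerance = 1e-9)
  expect_equal(res@df, 4L)
  expect_equal(res@pValue, pchisq(res@statistic, 4, lower.tail = FALSE))
  expect_equal(cramersV(res),
               sqrt(res@statistic / (sum(tab) * 1)), tolerance = 1e-12)
  expect_gte(cramersV(res), 0)
  expect_lte(cramersV(res), 1)

  bad <- matrix(c(0, 0, 5, 5), 2, 2, byrow = TRUE,
                dimnames = list(c("empty", "full"), NULL))
  expect_error(chiSquareIndependence(bad), "empty")
  expect_error(chiSquareIndependence(matrix(c(1, 2), 1)), "2 x 2")
})

test_that("group comparison is a Welch t-test with antisymmetry", {
  cat <- data.frame(substance = letters[1:6],
                    is_psychedelic = rep(c(TRUE, FALSE), each = 3))
  props <- data.frame(substance = letters[1:6],
                      proportion = c(0.1, 0.2, 0.3, 0.1, 0.2, 0.3))
  res <- compareGroupProportions(props, cat)
  expect_equal(res$t, 0)
  expect_equal(res$p, 1)
  # swapping the groups negates t
  cat2 <- cat; cat2$is_psychedelic <- !cat$is_psychedelic
  props$proportion <- c(0.3, 0.35, 0.4, 0.05, 0.1, 0.12)
  expect_equal(compareGroupProportions(props, cat)$t,
               -compareGroupProportions(props, cat2)$t)
  # matches stats::t.test directly
  direct <- t.test(props$proportion[1:3], props$proportion[4:6])
  expect_equal(compareGroupProportions(props, cat)$t,
               unname(direct$statistic))
  expect_error(
    compareGroupProportions(props[1:3, ], cat),
    "at least 2 substances")
})

test_that("psychedelic-vs-other comparison has power at the design effect", {
  # substance-level proportions from generated corpora, 100 replicates
  rejections <- 0L
  for (r in 1:100) {
    cfg <- generatorConfig(nSubstances = 8, reportsPerSubstance = 10,
                           sentencesPerReport = 20, seed = 3000 + r)
    syn <- generateCorpus(cfg)
    gt <- syn$groundTruth
    props <- aggregate(is_visual ~ substance, gt, mean)
    names(props)[2] <- "proportion"
    p <- compareGroupProportions(props, syn$catalogue)$p
    rejections <- rejections + (p < 0.05)
  }
  expect_gte(rejections, 90)
})

test_that("the dispersion statistic T matches its definition", {
  # one seed, two substances: the single pairwise difference
  expect_equal(tStatistic(matrix(c(0.2, 0.4), 1)), 0.2)
  # identical substance profiles: T = 0
  expect_equal(tStatistic(matrix(0.3, 4, 5)), 0)
  # one seed, three substances: mean of {0.1, 0.3, 0.2}
  expect_equal(tStatistic(matrix(c(0.1, 0.2, 0.4), 1)), 0.2)
  expect_error(tStatistic(matrix(1, 3, 1)), "at least 2 substances")

  set.seed(4)
  for (i in 1:25) {
    V <- matrix(runif(5 * 6), 5, 6)
    expect_equal(tStatistic(V), naiveT(V), tolerance = 1e-12)
  }
  # invariance to row and column permutation; linear scaling
  V <- matrix(runif(4 * 5), 4, 5)
  expect_equal(tStatistic(V[sample(4), sample(5)]), tStatistic(V),
               tolerance = 1e-12)
  expect_equal(tStatistic(0.37 * V), 0.37 * tStatistic(V),
               tolerance = 1e-12)
})

test_that("the permutation test shuffles labels and reports the plain p", {
  set.seed(6)
  mem <- matrix(runif(60 * 4) < 0.4, 60, 4,
                dimnames = list(NULL, paste("seed", 1:4)))
  labs <- rep(c("A", "B", "C"), each = 20)
  res <- permutationTest(mem, labs, nPermutations = 99, seed = 11)
  expect_s4_class(res, "PermutationResult")
  expect_length(nullDistribution(res), 99)
  # the p-value is exactly the plain proportion of permuted T >= observed
  expect_equal(pValue(res),
               mean(nullDistribution(res) >= observedT(res)))
  # the observed statistic agrees with the standalone computation
  V <- proportionMatrix(mem, labs)
  expect_equal(observedT(res), tStatistic(V), tolerance = 1e-12)
  # reproducible given the seed; smoothed estimator offsets by 1/(n+1)
  res2 <- permutationTest(mem, labs, nPermutations = 99, seed = 11)
  expect_identical(nullDistribution(res), nullDistribution(res2))
  sm <- permutationTest(mem, labs, nPermutations = 99, seed = 11,
                        smoothed = TRUE)
  expect_equal(pValue(sm),
               (sum(nullDistribution(res) >= observedT(res)) + 1) / 100)
  expect_error(permutationTest(mem, rep("A", 60), nPermutations = 9),
               "degenerate")
})

test_that("strong substance effects give extreme permutation p-values", {
  rejections <- 0L
  for (r in 1:20) {
    theta <- diag(4) * 0.8 + 0.05
    cfg <- generatorConfig(nSubstances = 4, reportsPerSubstance = 8,
                           sentencesPerReport = 12, visualPropensity = 0.5,
                           nCategories = 4, categoryMixture = theta,
                           seed = 4000 + r)
    syn <- generateCorpus(cfg)
    gt <- syn$groundTruth[syn$groundTruth$is_visual, ]
    mem <- outer(gt$category, sort(unique(syn$seeds$category)), `==`)
    colnames(mem) <- sort(unique(syn$seeds$category))
    p <- pValue(permutationTest(mem, gt$substance, nPermutations = 400,
                                seed = r))
    rejections <- rejections + (p < 0.005)
  }
  expect_gte(rejections, 19)
})

test_that("clustermap ordering reproduces forced merges and the oracle", {
  # two identical rows merge first at height zero
  V <- rbind(c(0.1, 0.9, 0.3), c(0.1, 0.9, 0.3), c(0.8, 0.2, 0.7))
  cm <- clustermapOrder(V)
  expect_equal(cm$rowDendrogram$height[1], 0)
  expect_setequal(cm$rowDendrogram$merge[1, ], c(-1, -2))
  # three 1-D points {0, 0.1, 1}: the close pair merges before joining 1
  V2 <- cbind(c(0, 0.1, 1), c(0, 0.1, 1))
  cm2 <- clustermapOrder(V2)
  expect_setequal(cm2$rowDendrogram$merge[1, ], c(-1, -2))
  # merge heights match a naive agglomerative reference
  set.seed(9)
  for (i in 1:10) {
    M <- matrix(runif(36), 6, 6)
    cm3 <- clustermapOrder(M, linkage = "average")
    expect_equal(sort(cm3$rowDendrogram$height),
                 sort(naiveAverageLinkageHeights(M)), tolerance = 1e-9)
    expect_equal(sort(cm3$colDendrogram$height),
                 sort(naiveAverageLinkageHeights(t(M))), tolerance = 1e-9)
  }
  # constant matrix: valid output, arbitrary order
  cmc <- clustermapOrder(matrix(0.5, 3, 3))
  expect_setequal(cmc$rowOrder, 1:3)
  expect_error(clustermapOrder(matrix(1, 1, 5)), "at least 2")
})
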