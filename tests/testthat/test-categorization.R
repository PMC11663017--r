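make_seedset <- function(vectors, categories = NULL) {
  texts <- paste0("seed ", seq_len(ncol(vectors)))
  colnames(vectors) <- texts
  new("SeedSet",
      info = data.frame(category = categories %||% rep("c", ncol(vectors)),
                        text = texts, stringsAsFactors = FALSE),
      vectors = vectors)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("seed membership follows the inclusive distance rule", {
  set.seed(1)
  S <- l2Normalize(matrix(rnorm(8 * 5), 8))
  seeds <- make_seedset(S)
  # a sentence identical to a seed vector is a member of that seed
  mem <- scoreMembership(t(S[, 2, drop = FALSE]), seeds, threshold = 0.55)
  expect_true(mem[1, 2])
  # a tiny threshold with distinct vectors yields no memberships
  X <- t(l2Normalize(matrix(rnorm(8 * 10), 8)))
  expect_false(any(scoreMembership(X, seeds, threshold = 1e-6)))
  expect_error(scoreMembership(matrix(0, 2, 4), seeds), "dimension mismatch")
})

test_that("membership matches a brute-force double loop", {
  set.seed(2)
  S <- l2Normalize(matrix(rnorm(6 * 5), 6))
  X <- t(l2Normalize(matrix(rnorm(6 * 100), 6)))
  seeds <- make_seedset(S)
  mem <- scoreMembership(X, seeds, threshold = 0.9)
  expect_identical(unname(unclass(mem))[, ], naiveMembership(X, S, 0.9))
  expect_gt(sum(mem), 0)
})

test_that("V(s, d) is the within-threshold proportion per substance", {
  mem <- matrix(FALSE, 6, 2, dimnames = list(NULL, c("seed a", "seed b")))
  mem[1, 1] <- TRUE              # 1 of A's 4 sentences matches seed a
  mem[5:6, 2] <- TRUE            # both of B's sentences match seed b
  subs <- c("A", "A", "A", "A", "B", "B")
  V <- proportionMatrix(mem, subs)
  expect_equal(vMatrix(V)["seed a", "A"], 0.25)
  expect_equal(vMatrix(V)["seed b", "B"], 1)
  expect_equal(unname(substanceCounts(V)), c(4, 2))
  # ordering invariance
  perm <- sample(6)
  V2 <- proportionMatrix(mem[perm, ], subs[perm])
  expect_equal(vMatrix(V2), vMatrix(V))
  # dropping a substance leaves the other column untouched
  V3 <- proportionMatrix(mem[1:4, , drop = FALSE], subs[1:4])
  expect_equal(vMatrix(V3)[, "A"], vMatrix(V)[, "A"])
  # zero-visual substances are dropped with a warning
  expect_warning(
    V4 <- proportionMatrix(mem, factor(subs, levels = c("A", "B", "C"))),
    "zero visual")
  expect_setequal(substanceNames(V4), c("A", "B"))
})

test_that("well-separated seeds give exclusive membership on synthetic data", {
  # pairwise anchor separation 1.2 > 2 * 0.55, small noise
  q <- quickSyn(nSubstances = 3, reportsPerSubstance = 10,
                sentencesPerReport = 10, visualPropensity = 1,
                nCategories = 4, anchorMinSeparation = 1.2,
                noiseSd = 0.08, seed = 15)
  seeds <- embedSeeds(q$syn$seeds, q$syn$backend)
  mem <- scoreMembership(q$embedded, seeds, threshold = 0.55)
  expect_true(all(rowSums(mem) <= 1))
  # and every sentence lands in its own category's seed
  expect_equal(mean(rowSums(mem) == 1), 1)
})

test_that("V recovers the generator's category mixtures", {
  q <- quickSyn(nSubstances = 4, reportsPerSubstance = 30,
                sentencesPerReport = 20, visualPropensity = 0.5,
                nCategories = 5, seed = 25)
  vis <- q$embedded[, q$truth$is_visual]
  seeds <- embedSeeds(q$syn$seeds, q$syn$backend)
  V <- categorizeVisualSentences(vis, seeds, threshold = 0.55)
  theta <- t(q$syn$theta)[, substanceNames(V), drop = FALSE]
  n_d <- substanceCounts(V)[colnames(theta)]
  se <- sqrt(theta * (1 - theta) / rep(n_d, each = nrow(theta)))
  expect_true(all(abs(vMatrix(V) - theta) <= 3 * se + 1e-9))
  # row metadata carries seed categories
  expect_identical(seedInfo(V)$category, q$syn$seeds$category)
})

test_that("UMAP projection returns a reproducible 2-D layout that keeps clusters", {
  set.seed(5)
  centers <- l2Normalize(matrix(rnorm(16 * 2), 16))
  X <- rbind(t(l2Normalize(centers[, 1] + matrix(rnorm(16 * 40, 0, 0.05), 16))),
             t(l2Normalize(centers[, 2] + matrix(rnorm(16 * 40, 0, 0.05), 16))))
  co <- projectUMAP(X, nNeighbors = 10, seed = 17)
  expect_equal(dim(co), c(80L, 2L))
  co2 <- projectUMAP(X, nNeighbors = 10, seed = 17)
  expect_equal(co, co2)
  grp <- rep(1:2, each = 40)
  D <- as.matrix(dist(co))
  within <- mean(D[outer(grp, grp, `==`) & upper.tri(D)])
  between <- mean(D[outer(grp, grp, `!=`)])
  expect_lt(within, between)
  expect_error(projectUMAP(X[1:5, ]), "too few points")
})

test_that("proportion matrices serialise with their counts sidecar", {
  q <- quickSyn(nSubstances = 3, reportsPerSubstance = 10,
                sentencesPerReport = 10, visualPropensity = 0.6, seed = 35)
  vis <- q$embedded[, q$truth$is_visual]
  seeds <- embedSeeds(q$syn$seeds, q$syn$backend)
  V <- categorizeVisualSentences(vis, seeds)
  path <- withr::local_tempfile(fileext = ".tsv")
  writeProportionMatrixTSV(V, path)
  back <- utils::read.delim(path, check.names = FALSE)
  expect_equal(as.matrix(back[, substanceNames(V)]), vMatrix(V),
               ignore_attr = TRUE)
  counts <- utils::read.delim(paste0(path, ".counts.tsv"))
  expect_equal(counts$n_visual, unname(substanceCounts(V)))
})
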