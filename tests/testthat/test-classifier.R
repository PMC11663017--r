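test_that("training-sentence sampling is uniform, exact, and reproducible", {
  q <- quickSyn(nSubstances = 4, reportsPerSubstance = 10,
                sentencesPerReport = 10, seed = 31, embed = FALSE)
  st <- sentenceTable(q$corpus)
  all_of_it <- sampleTrainingSentences(q$corpus, nrow(st), seed = 1)
  expect_setequal(all_of_it$sentence_id, st$sentence_id)
  expect_identical(sampleTrainingSentences(q$corpus, 50, seed = 7),
                   sampleTrainingSentences(q$corpus, 50, seed = 7))
  expect_error(sampleTrainingSentences(q$corpus, nrow(st) + 1, seed = 1),
               "cannot sample")
  # large samples approach the per-substance corpus fractions
  s <- sampleTrainingSentences(q$corpus, 300, seed = 3)
  frac <- table(s$substance) / 300
  expect_true(all(abs(frac - 0.25) < 0.08))
})

test_that("the offline rule labeller is pure and matches its contract", {
  lab <- ruleLabeler()
  expect_identical(lab("I saw geometric patterns."), 1L)
  expect_identical(lab("Would I repeat the experience?"), 0L)
  expect_identical(lab("We made dinner and went home early"), 0L)
  expect_identical(lab("I saw geometric patterns."),
                   lab("I saw geometric patterns."))
  q <- quickSyn(nSubstances = 2, reportsPerSubstance = 5,
                sentencesPerReport = 10, seed = 41, embed = FALSE)
  auto <- autoLabel(q$corpus)
  expect_true(all(auto$label %in% c(0L, 1L)))
  expect_true(all(auto$provenance == "automated"))
  # the templated synthetic corpus is labelled exactly by the rules
  expect_equal(auto$label, as.integer(q$truth$is_visual))
  # non-binary labellers are rejected with the offending sentence
  expect_error(autoLabel(sentenceTable(q$corpus),
                         labeler = function(x) rep(2L, length(x))),
               "non-binary")
})

test_that("the correction ledger reproduces the reference class counts", {
  # 10,000 automated labels, 1,231 positive; the review flips 244 positives
  samples <- data.frame(sentence_id = sprintf("s%05d", 1:10000),
                        label = rep(c(1L, 0L), c(1231, 8769)),
                        provenance = "automated",
                        stringsAsFactors = FALSE)
  ledger <- data.frame(sentence_id = sprintf("s%05d", 1:244),
                       old_label = 1L, new_label = 0L,
                       reviewer = "manual")
  fixed <- applyCorrections(samples, ledger)
  counts <- attr(fixed, "class_counts")
  expect_equal(unname(counts["1"]), 987L)
  expect_equal(unname(counts["0"]), 9013L)
  expect_true(all(fixed$provenance[1:244] == "corrected"))
  expect_true(all(fixed$original_label[1:244] == 1L))
  # idempotence
  twice <- applyCorrections(fixed, ledger)
  expect_identical(twice$label, fixed$label)
  expect_identical(twice$original_label, fixed$original_label)
  # empty ledger leaves labels untouched; unknown ids are an error
  expect_identical(applyCorrections(samples, ledger[0, ])$label,
                   samples$label)
  expect_error(applyCorrections(samples,
                                data.frame(sentence_id = "nope",
                                           old_label = 1L, new_label = 0L)),
               "unknown sentence_id")
})

test_that("training separates separable classes and fails gracefully", {
  q <- quickSyn(nSubstances = 2, reportsPerSubstance = 20,
                sentencesPerReport = 15, visualPropensity = 0.4, seed = 51)
  y <- as.integer(q$truth$is_visual)
  model <- trainClassifier(q$embedded, y, seed = 8)
  expect_gte(trainingReport(model)$accuracy, 0.99)
  # undersampling touches the training split only: balanced training count,
  # untouched 20% test split
  n <- length(y)
  expect_equal(trainingReport(model)$n_test, n - floor(0.8 * n))
  expect_true(trainingReport(model)$n_train %% 2 == 0)
  expect_lte(trainingReport(model)$n_train, 2 * sum(y))
  # single-class input is rejected
  expect_error(trainClassifier(q$embedded, rep(1L, n), seed = 1),
               "both classes")
})

test_that("random labels give chance-level held-out accuracy", {
  set.seed(60)
  X <- matrix(rnorm(2000 * 16), 2000, 16)
  y <- rep(c(0L, 1L), 1000)
  model <- trainClassifier(X, y, seed = 61)
  expect_gt(trainingReport(model)$accuracy, 0.45)
  expect_lt(trainingReport(model)$accuracy, 0.55)
})

test_that("the fitted boundary is stable under dataset duplication", {
  set.seed(70)
  X <- rbind(matrix(rnorm(200 * 8, mean = 1), 200, 8),
             matrix(rnorm(200 * 8, mean = -1), 200, 8))
  y <- rep(c(1L, 0L), each = 200)
  m1 <- trainClassifier(X, y, seed = 3, lambda = 0.01)
  m2 <- trainClassifier(rbind(X, X), c(y, y), seed = 3, lambda = 0.01)
  w1 <- m1@weights / sqrt(sum(m1@weights^2))
  w2 <- m2@weights / sqrt(sum(m2@weights^2))
  expect_gt(sum(w1 * w2), 0.995)
})

test_that("probability predictions follow the logistic form exactly", {
  flat <- new("VisualSentenceClassifier", weights = rep(0, 4), intercept = 0,
              threshold = 0.75, dimension = 4L, trainingReport = list())
  X <- matrix(rnorm(40), 10, 4)
  expect_equal(predictProbability(flat, X), rep(0.5, 10))
  set.seed(80)
  w <- rnorm(4); b <- 0.3
  model <- new("VisualSentenceClassifier", weights = w, intercept = b,
               threshold = 0.75, dimension = 4L, trainingReport = list())
  # independent hand-rolled sigmoid
  manual <- 1 / (1 + exp(-(X %*% w + b)))
  expect_equal(predictProbability(model, X), as.numeric(manual),
               tolerance = 1e-12)
  # sigmoid symmetry: complement model negates weights and intercept
  comp <- new("VisualSentenceClassifier", weights = -w, intercept = -b,
              threshold = 0.75, dimension = 4L, trainingReport = list())
  expect_equal(predictProbability(model, X) + predictProbability(comp, X),
               rep(1, 10), tolerance = 1e-12)
  expect_error(predictProbability(model, matrix(0, 2, 5)),
               "dimension mismatch")
})

test_that("extraction uses an inclusive threshold and recovers propensities", {
  # three sentences engineered to score 0.74, 0.75, 0.76 under w = (2, 0)
  target <- c(0.74, 0.75, 0.76)
  be <- functionBackend("angles", 2, function(texts) {
    p <- target[match(texts, c("a", "b", "c"))]
    cosv <- stats::qlogis(p) / 2
    rbind(cosv, sqrt(1 - cosv^2))
  })
  sent <- data.frame(sentence_id = c("s1", "s2", "s3"), report_id = "r",
                     substance = "A", text = c("a", "b", "c"))
  ec <- embedCorpus(sent, be)
  model <- new("VisualSentenceClassifier", weights = c(2, 0), intercept = 0,
               threshold = 0.75, dimension = 2L, trainingReport = list())
  ex <- extractVisualSentences(ec, model)
  expect_equal(ex$probabilities, c(s1 = 0.74, s2 = 0.75, s3 = 0.76),
               tolerance = 1e-12)
  expect_equal(ncol(ex$visual), 2L)          # 0.75 is included
  ex0 <- extractVisualSentences(ec, model, threshold = 0)
  expect_equal(ncol(ex0$visual), 3L)
  expect_equal(ex0$proportions$proportion, 1)

  # per-substance proportions recover the generator propensities
  q <- quickSyn(nSubstances = 4, reportsPerSubstance = 25,
                sentencesPerReport = 20, seed = 91)
  y <- as.integer(q$truth$is_visual)
  model2 <- trainClassifier(q$embedded, y, seed = 92)
  exq <- extractVisualSentences(q$embedded, model2)
  p_true <- q$syn$p[exq$proportions$substance]
  se <- sqrt(p_true * (1 - p_true) / exq$proportions$n_sentences)
  expect_true(all(abs(exq$proportions$proportion - p_true) <= 3 * se))
})

test_that("probability histograms normalise to unit maximum", {
  set.seed(100)
  p <- runif(500)
  subs <- rep(c("A", "B"), c(300, 200))
  h <- probabilityHistograms(p, subs, breaks = seq(0, 1, 0.1))
  expect_equal(rowSums(h$counts), c(A = 300, B = 200))
  expect_equal(unname(apply(h$relFrequency, 1, max)), c(1, 1))
  expect_equal(sum(h$pooled$counts), 500)
  # single-substance corpus: substance histogram equals the pooled curve
  h1 <- probabilityHistograms(p[1:300], rep("A", 300),
                              breaks = seq(0, 1, 0.1))
  expect_equal(unname(h1$counts[1, ]), h1$pooled$counts)
  expect_equal(unname(h1$relFrequency[1, ]), h1$pooled$relFrequency)
})
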