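#' @include AllClasses.R AllGenerics.R embedding.R synthetic.R
NULL

#' Sample sentences for labelling
#'
#' Uniform sampling without replacement from the corpus sentence table (the
#' study design sampled 10,000 sentences this way), reproducible given the
#' seed.
#'
#' @param corpus a [ReportCorpus-class] (or a sentence data.frame).
#' @param n number of sentences to draw.
#' @param seed integer seed.
#' @return a sentence data.frame with `n` rows, order permuted.
#' @export
sampleTrainingSentences <- function(corpus, n, seed) {
  sent <- if (is(corpus, "ReportCorpus")) sentenceTable(corpus) else corpus
  if (n > nrow(sent))
    stop("cannot sample ", n, " sentences from a corpus of ", nrow(sent))
  .withSeed(seed, {
    idx <- sample.int(nrow(sent), n)
    out <- sent[idx, , drop = FALSE]
    rownames(out) <- NULL
    out
  })
}

#' Offline rule-based visual-effect labeller
#'
#' A transparent keyword/pattern labeller returning 1 for sentences that
#' explicitly describe visual effects and 0 otherwise. It is the packaged
#' default for [autoLabel()], so the pipeline runs without any language-model
#' service; an LLM labeller can be plugged in as any function mapping a
#' character vector to 0/1 labels.
#'
#' @param patterns character vector of case-insensitive regular expressions;
#'   a sentence matching any of them is labelled 1.
#' @return a vectorised labelling function, `character -> integer {0, 1}`.
#' @examples
#' lab <- ruleLabeler()
#' lab(c("I saw geometric patterns.", "Would I repeat the experience?"))
#' @export
ruleLabeler <- function(patterns = c("\\bI saw\\b", "\\bsee(ing)?\\b.*\\b(colou?rs|patterns|trails)\\b",
                                     "\\bvisuals?\\b", "\\bvision\\b",
                                     "\\bvisual(ly)?\\b", "colou?rs?\\b",
                                     "patterns?\\b", "kaleidoscop",
                                     "fractal", "hallucinat",
                                     "\\btracers?\\b", "geometr",
                                     "\\bmorphing\\b", "\\bbreathing walls\\b")) {
  force(patterns)
  rx <- paste0("(", paste(patterns, collapse = ")|("), ")")
  function(texts) as.integer(grepl(rx, texts, ignore.case = TRUE,
                                   perl = TRUE))
}

#' Automatically label sentences as visual effect or not
#'
#' Applies a labelling backend to each sentence and records the provenance
#' as `"automated"`. The labeller may be the packaged [ruleLabeler()] or any
#' function from character vectors to `{0, 1}`; anything else it returns is
#' an error naming the offending sentence. Labelling is pure: the same
#' sentence always receives the same label.
#'
#' @param sentences sentence data.frame (columns `sentence_id`, `text`) or a
#'   [ReportCorpus-class].
#' @param labeler labelling function; default [ruleLabeler()].
#' @return data.frame `sentence_id`, `label`, `provenance`.
#' @export
autoLabel <- function(sentences, labeler = ruleLabeler()) {
  sent <- if (is(sentences, "ReportCorpus")) sentenceTable(sentences)
          else sentences
  labels <- labeler(as.character(sent$text))
  bad <- which(!(labels %in% c(0L, 1L)))
  if (length(bad))
    stop("labeler returned a non-binary label for sentence '",
         sent$sentence_id[bad[1]], "': ", labels[bad[1]])
  data.frame(sentence_id = sent$sentence_id,
             label = as.integer(labels),
             provenance = "automated",
             stringsAsFactors = FALSE)
}

#' Apply a manual-correction ledger to a labelled set
#'
#' The study design manually reviewed all automatically labelled positive
#' sentences and recorded label changes in a ledger. Applying the ledger sets
#' each referenced sentence's label to `new_label`, marks its provenance as
#' `"corrected"`, and preserves the original label in `original_label`.
#' Application is idempotent.
#'
#' @param samples data.frame with `sentence_id`, `label`, `provenance`.
#' @param ledger data.frame with `sentence_id`, `old_label`, `new_label`
#'   (and optionally `reviewer`).
#' @return the updated labelled set, with attribute `class_counts` giving
#'   the final per-class counts.
#' @export
applyCorrections <- function(samples, ledger) {
  stopifnot(all(c("sentence_id", "label") %in% names(samples)))
  if (nrow(ledger)) {
    stopifnot(all(c("sentence_id", "new_label") %in% names(ledger)))
    unknown <- setdiff(ledger$sentence_id, samples$sentence_id)
    if (length(unknown))
      stop("ledger references unknown sentence_id(s): ",
           paste(utils::head(unknown, 5L), collapse = ", "))
    if (!"original_label" %in% names(samples))
      samples$original_label <- samples$label
    idx <- match(ledger$sentence_id, samples$sentence_id)
    samples$label[idx] <- as.integer(ledger$new_label)
    samples$provenance[idx] <- "corrected"
  }
  counts <- table(factor(samples$label, levels = c(0L, 1L)))
  attr(samples, "class_counts") <- stats::setNames(as.integer(counts),
                                                   names(counts))
  samples
}

## ---------------------------------------------------------------------------
## Training and prediction
## ---------------------------------------------------------------------------

.asSentenceMatrix <- function(x) {
  if (is(x, "EmbeddedCorpus")) t(embeddingMatrix(x))
  else if (is.matrix(x)) x
  else stop("x must be an EmbeddedCorpus or a sentences-by-dimensions matrix")
}

#' Train the visual-effect sentence classifier
#'
#' Random train/test split (default 80/20); within the training split only,
#' the majority class is randomly undersampled to the minority count; a
#' logistic model with an L2 penalty is then fitted on the embedding vectors
#' by penalised maximum likelihood. Held-out accuracy is the fraction of
#' test-split labels matching predictions thresholded at 0.5, on the
#' untouched (natural-balance) test split. The default penalty corresponds
#' to an L2 strength of 1 on the summed-loss scale (`lambda = 1/n_train`).
#'
#' @param x an [EmbeddedCorpus-class] or numeric matrix, sentences x
#'   dimensions.
#' @param labels binary vector (0/1), one per sentence.
#' @param split training fraction, default 0.8.
#' @param seed integer seed governing the split and the undersampling.
#' @param lambda optional ridge penalty passed to the optimiser; default
#'   `1 / n_train`.
#' @param threshold extraction probability threshold stored on the model
#'   (default 0.75); training diagnostics always use 0.5.
#' @return a [VisualSentenceClassifier-class].
#' @export
trainClassifier <- function(x, labels, split = 0.8, seed = 1L,
                            lambda = NULL, threshold = 0.75) {
  X <- .asSentenceMatrix(x)
  y <- as.integer(labels)
  stopifnot(length(y) == nrow(X), all(y %in% c(0L, 1L)))
  if (length(unique(y)) < 2L)
    stop("both classes must be present in the labelled set")
  n <- nrow(X)
  .withSeed(seed, {
    idx <- sample.int(n)
    n_train <- floor(split * n)
    tr <- idx[seq_len(n_train)]
    te <- idx[-seq_len(n_train)]
    if (length(unique(y[tr])) < 2L || length(te) == 0L)
      stop("a class is absent from the training split; ",
           "use a different seed or a larger sample")
    # undersample the majority class, training split only
    pos <- tr[y[tr] == 1L]
    neg <- tr[y[tr] == 0L]
    m <- min(length(pos), length(neg))
    tr_bal <- c(if (length(pos) > m) sample(pos, m) else pos,
                if (length(neg) > m) sample(neg, m) else neg)
    lam <- if (is.null(lambda)) 1 / length(tr_bal) else lambda
    fit <- glmnet::glmnet(X[tr_bal, , drop = FALSE], y[tr_bal],
                          family = "binomial", alpha = 0, lambda = lam,
                          standardize = FALSE, thresh = 1e-10,
                          maxit = 1e6)
    beta <- as.numeric(fit$beta[, 1])
    b0 <- as.numeric(fit$a0[1])
    p_test <- stats::plogis(drop(X[te, , drop = FALSE] %*% beta) + b0)
    acc <- mean((p_test >= 0.5) == (y[te] == 1L))
    new("VisualSentenceClassifier",
        weights = beta, intercept = b0,
        threshold = threshold, dimension = ncol(X),
        trainingReport = list(accuracy = acc, split_seed = as.integer(seed),
                              n_train = length(tr_bal),
                              n_test = length(te), lambda = lam))
  })
}

#' @rdname predictProbability
#' @export
setMethod("predictProbability",
          signature(model = "VisualSentenceClassifier", x = "matrix"),
          function(model, x) {
  if (ncol(x) != model@dimension)
    stop("dimension mismatch: model expects ", model@dimension,
         ", got ", ncol(x))
  as.numeric(stats::plogis(drop(x %*% model@weights) + model@intercept))
})

#' @rdname predictProbability
#' @export
setMethod("predictProbability",
          signature(model = "VisualSentenceClassifier", x = "EmbeddedCorpus"),
          function(model, x) {
  p <- predictProbability(model, t(embeddingMatrix(x)))
  stats::setNames(p, colnames(x))
})

#' Extract visual-effect sentences from an embedded corpus
#'
#' Keeps every sentence whose predicted probability is at least the
#' threshold (inclusive comparison, default the model's 0.75) and reports
#' per-substance visual-sentence proportions (visual count over total
#' sentence count for the substance) and the whole-corpus proportion.
#'
#' @param ecorpus an [EmbeddedCorpus-class] covering the full corpus.
#' @param model a [VisualSentenceClassifier-class].
#' @param threshold probability threshold; default `model`'s stored value.
#' @return list with `visual` (the retained [EmbeddedCorpus-class] subset),
#'   `probabilities` (all sentences), `proportions` (data.frame `substance`,
#'   `n_sentences`, `n_visual`, `proportion`), and `overall`.
#' @export
extractVisualSentences <- function(ecorpus, model, threshold = NULL) {
  stopifnot(is(ecorpus, "EmbeddedCorpus"),
            is(model, "VisualSentenceClassifier"))
  if (is.null(threshold)) threshold <- model@threshold
  p <- predictProbability(model, ecorpus)
  keep <- p >= threshold
  sub <- SummarizedExperiment::colData(ecorpus)$substance
  totals <- table(sub)
  vis <- table(factor(sub[keep], levels = names(totals)))
  props <- data.frame(substance = names(totals),
                      n_sentences = as.integer(totals),
                      n_visual = as.integer(vis),
                      proportion = as.numeric(vis) / as.numeric(totals),
                      stringsAsFactors = FALSE)
  rownames(props) <- NULL
  list(visual = ecorpus[, keep],
       probabilities = p,
       proportions = props,
       overall = mean(keep),
       threshold = threshold)
}

#' Prediction-probability histograms per substance
#'
#' Relative-frequency histograms of classifier probabilities, one per
#' substance, each rescaled so its maximum bin height is 1 (substances have
#' very different sentence counts, so unit-maximum scaling makes shapes
#' comparable), plus the pooled distribution over all sentences.
#'
#' @param probabilities numeric vector of probabilities in `[0, 1]`.
#' @param substances substance label per probability.
#' @param breaks histogram break points spanning `[0, 1]`.
#' @return list with `breaks`, `mids`, `counts` (substances x bins), the
#'   unit-maximum `relFrequency` matrix, and `pooled` (counts and unit-max
#'   relative frequencies over all sentences).
#' @export
probabilityHistograms <- function(probabilities, substances,
                                  breaks = seq(0, 1, by = 0.05)) {
  stopifnot(length(probabilities) == length(substances),
            all(probabilities >= 0 & probabilities <= 1))
  bins <- cut(probabilities, breaks, include.lowest = TRUE)
  counts <- table(substances, bins)
  counts <- matrix(as.integer(counts), nrow(counts), ncol(counts),
                   dimnames = dimnames(counts))
  rel <- counts / pmax(apply(counts, 1L, max), 1L)
  pooled <- as.integer(table(bins))
  list(breaks = breaks,
       mids = (breaks[-1] + breaks[-length(breaks)]) / 2,
       counts = counts,
       relFrequency = rel,
       pooled = list(counts = pooled,
                     relFrequency = pooled / max(pooled, 1L)))
}
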