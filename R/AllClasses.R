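#' @import methods
#' @importFrom S4Vectors DataFrame metadata
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
NULL

## ---------------------------------------------------------------------------
## Report corpus
## ---------------------------------------------------------------------------

#' ReportCorpus: a segmented narrative-report corpus
#'
#' Holds single-substance narrative reports after markup removal and sentence
#' segmentation, together with the substance catalogue in force for the
#' corpus. Constructed by [buildCorpus()]; rarely instantiated directly.
#'
#' @slot reports data.frame with columns `report_id`, `substance`,
#'   `n_sentences`; one row per retained report, `report_id` unique.
#' @slot sentences data.frame with columns `sentence_id`, `report_id`,
#'   `substance`, `text`; one row per segmented sentence, in corpus order.
#' @slot catalogue data.frame with columns `substance`, `drug_class`,
#'   `is_psychedelic`; every substance in the corpus has an entry.
#'
#' @seealso [buildCorpus()], [summarizeCorpus()]
#' @export
setClass("ReportCorpus",
         representation(reports = "data.frame",
                        sentences = "data.frame",
                        catalogue = "data.frame"))

setValidity("ReportCorpus", function(object) {
  msg <- character()
  need_r <- c("report_id", "substance", "n_sentences")
  need_s <- c("sentence_id", "report_id", "substance", "text")
  need_c <- c("substance", "drug_class", "is_psychedelic")
  if (!all(need_r %in% names(object@reports)))
    msg <- c(msg, "reports must have columns report_id, substance, n_sentences")
  if (!all(need_s %in% names(object@sentences)))
    msg <- c(msg, "sentences must have columns sentence_id, report_id, substance, text")
  if (!all(need_c %in% names(object@catalogue)))
    msg <- c(msg, "catalogue must have columns substance, drug_class, is_psychedelic")
  if (length(msg))
    return(msg)
  if (anyDuplicated(object@reports$report_id))
    msg <- c(msg, "report_id must be unique within a corpus")
  if (anyDuplicated(object@sentences$sentence_id))
    msg <- c(msg, "sentence_id must be unique within a corpus")
  if (nrow(object@sentences) &&
      any(!nzchar(trimws(object@sentences$text))))
    msg <- c(msg, "segmented sentences must be non-empty after trimming")
  missing <- setdiff(unique(object@sentences$substance),
                     object@catalogue$substance)
  if (length(missing))
    msg <- c(msg, paste0("substances missing from catalogue: ",
                         paste(missing, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Embedding backends
## ---------------------------------------------------------------------------

#' EmbeddingBackend: contract for sentence-embedding services
#'
#' Virtual base class. A backend declares a `name` and an output `dimension`
#' and implements [embedText()]. Backends must be deterministic (same string,
#' same vector) and dimension-consistent. Two concrete backends ship with the
#' package: [functionBackend()], wrapping any R function, and
#' [syntheticBackend()], which places tagged synthetic sentences near known
#' anchor directions on the unit sphere. A live embedding service (such as a
#' commercial 1,536-dimensional sentence-embedding model) can be adapted by
#' wrapping its client in [functionBackend()]; no such adapter is exercised by
#' the package tests.
#'
#' @slot name character backend identifier (used as the cache key prefix).
#' @slot dimension integer embedding dimension.
#' @aliases EmbeddingBackend
#' @export
setClass("EmbeddingBackend",
         representation("VIRTUAL",
                        name = "character",
                        dimension = "integer"))

#' @rdname functionBackend
#' @export
setClass("FunctionBackend",
         contains = "EmbeddingBackend",
         representation(fun = "function"))

#' @rdname syntheticBackend
#' @export
setClass("SyntheticBackend",
         contains = "EmbeddingBackend",
         representation(anchors = "matrix",
                        background = "matrix",
                        noiseSd = "numeric",
                        seed = "integer"))

setValidity("SyntheticBackend", function(object) {
  msg <- character()
  if (nrow(object@anchors) != object@dimension ||
      nrow(object@background) != object@dimension)
    msg <- c(msg, "anchor matrices must have `dimension` rows")
  if (is.null(colnames(object@anchors)) || anyDuplicated(colnames(object@anchors)))
    msg <- c(msg, "category anchors must have unique column names (tokens)")
  if (ncol(object@background) < 1L)
    msg <- c(msg, "at least one background anchor is required")
  if (object@noiseSd < 0)
    msg <- c(msg, "noiseSd must be nonnegative")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Embedded corpus
## ---------------------------------------------------------------------------

#' EmbeddedCorpus: sentences with their embedding vectors
#'
#' A \linkS4class{SummarizedExperiment} whose single assay, `"embedding"`,
#' stores one L2-normalised embedding vector per sentence (rows = embedding
#' dimensions, columns = sentences). `colData` carries the sentence metadata
#' (`sentence_id`, `report_id`, `substance`, `text`) and `metadata()` records
#' the backend name and dimension. Column subsetting keeps metadata aligned
#' with vectors, so the visual-effect subset produced by
#' [extractVisualSentences()] is again an `EmbeddedCorpus`.
#'
#' @seealso [embedCorpus()]
#' @export
setClass("EmbeddedCorpus", contains = "SummarizedExperiment")

setValidity("EmbeddedCorpus", function(object) {
  msg <- character()
  if (!"embedding" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "an assay named 'embedding' is required")
  need <- c("sentence_id", "report_id", "substance", "text")
  if (!all(need %in% colnames(SummarizedExperiment::colData(object))))
    msg <- c(msg, "colData must have sentence_id, report_id, substance, text")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Seed catalogue
## ---------------------------------------------------------------------------

#' SeedSet: embedded seed-sentence catalogue
#'
#' Seed sentences are prototypical visual-effect descriptions; each defines a
#' semantic region as the ball of a given embedding radius around its vector.
#' Categories (Pattern, Movement, Color, ...) are metadata used for labelling
#' and colouring; all scoring is per individual seed sentence.
#'
#' @slot info data.frame with columns `category`, `text`, one row per seed.
#' @slot vectors numeric matrix, embedding dimension x number of seeds,
#'   produced by the same backend (and normalisation) as the corpus.
#' @seealso [embedSeeds()], [seedCatalogue()]
#' @export
setClass("SeedSet",
         representation(info = "data.frame", vectors = "matrix"))

setValidity("SeedSet", function(object) {
  msg <- character()
  if (!all(c("category", "text") %in% names(object@info)))
    msg <- c(msg, "info must have columns category, text")
  if (ncol(object@vectors) != nrow(object@info))
    msg <- c(msg, "one vector column per seed sentence is required")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Classifier
## ---------------------------------------------------------------------------

#' VisualSentenceClassifier: binary linear model over embedding vectors
#'
#' A logistic model `p = sigmoid(w . v + b)` trained on labelled embedding
#' vectors with an L2 penalty. `threshold` is the probability above which
#' (inclusively) a sentence counts as a visual-effect sentence at extraction
#' time; training diagnostics use a 0.5 decision threshold.
#'
#' @slot weights numeric weight vector, one per embedding dimension.
#' @slot intercept numeric scalar.
#' @slot threshold extraction probability threshold in `[0, 1]` (default 0.75).
#' @slot dimension integer embedding dimension the model expects.
#' @slot trainingReport list with elements `accuracy`, `split_seed`,
#'   `n_train`, `n_test`, `lambda`.
#' @seealso [trainClassifier()], [predictProbability()],
#'   [extractVisualSentences()]
#' @export
setClass("VisualSentenceClassifier",
         representation(weights = "numeric",
                        intercept = "numeric",
                        threshold = "numeric",
                        dimension = "integer",
                        trainingReport = "list"))

setValidity("VisualSentenceClassifier", function(object) {
  msg <- character()
  if (length(object@weights) != object@dimension)
    msg <- c(msg, "weights length must equal dimension")
  if (length(object@threshold) != 1L ||
      object@threshold < 0 || object@threshold > 1)
    msg <- c(msg, "threshold must be a single probability in [0, 1]")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Proportion matrix
## ---------------------------------------------------------------------------

#' ProportionMatrix: seed-by-substance membership proportions V(s, d)
#'
#' `V(s, d)` is the proportion of substance `d`'s visual-effect sentences
#' whose embedding vectors lie within the distance threshold of seed sentence
#' `s`. Rows are seed sentences, columns substances. Membership is not
#' exclusive, so columns need not sum to one.
#'
#' @slot values numeric matrix in `[0, 1]`, seeds x substances; dimnames are
#'   seed texts and substance names.
#' @slot seedInfo data.frame with `category`, `text` for each row.
#' @slot counts named numeric vector of per-substance visual-sentence totals
#'   (the denominators of each column).
#' @seealso [proportionMatrix()], [tStatistic()], [clustermapOrder()]
#' @export
setClass("ProportionMatrix",
         representation(values = "matrix",
                        seedInfo = "data.frame",
                        counts = "numeric"))

setValidity("ProportionMatrix", function(object) {
  msg <- character()
  v <- object@values
  if (length(v) && (min(v) < 0 || max(v) > 1))
    msg <- c(msg, "all V(s, d) must lie in [0, 1]")
  if (ncol(v) != length(object@counts))
    msg <- c(msg, "one count per substance column is required")
  if (!is.null(colnames(v)) && !identical(colnames(v), names(object@counts)))
    msg <- c(msg, "count names must match substance column names")
  if (nrow(v) != nrow(object@seedInfo))
    msg <- c(msg, "one seedInfo row per matrix row is required")
  if (length(v)) {
    prods <- sweep(v, 2L, object@counts, `*`)
    if (max(abs(prods - round(prods))) > 0.5)
      msg <- c(msg, "V(s, d) * count(d) must be within 0.5 of an integer")
  }
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Inferential results
## ---------------------------------------------------------------------------

#' ContingencyResult: chi-square independence test with Cramer's V
#'
#' @slot statistic Pearson chi-square statistic.
#' @slot df degrees of freedom, `(r - 1)(c - 1)`.
#' @slot n total count in the table.
#' @slot cramersV effect size `sqrt(chi2 / (n * min(r - 1, c - 1)))`.
#' @slot pValue upper-tail chi-square p-value.
#' @seealso [chiSquareIndependence()]
#' @export
setClass("ContingencyResult",
         representation(statistic = "numeric",
                        df = "integer",
                        n = "numeric",
                        cramersV = "numeric",
                        pValue = "numeric"))

#' PermutationResult: observed T, its permutation null and p-value
#'
#' @slot observedT dispersion statistic on the observed labels.
#' @slot nullT permuted statistics, one per shuffle.
#' @slot pValue proportion of permuted T greater than or equal to observed T
#'   (or the smoothed `(b + 1)/(n + 1)` variant if requested).
#' @slot nPermutations number of label shuffles.
#' @slot seed RNG seed used for the shuffles.
#' @seealso [permutationTest()], [tStatistic()]
#' @export
setClass("PermutationResult",
         representation(observedT = "numeric",
                        nullT = "numeric",
                        pValue = "numeric",
                        nPermutations = "integer",
                        seed = "integer"))

setValidity("PermutationResult", function(object) {
  if (length(object@nullT) != object@nPermutations)
    return("nullT must hold one value per permutation")
  TRUE
})
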