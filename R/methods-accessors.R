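#' @include AllClasses.R AllGenerics.R
NULL

#' Accessors for psyvis classes
#'
#' Small accessor generics so user code never touches slots directly:
#' `reportTable()` / `sentenceTable()` / `catalogue()` / `substanceNames()`
#' for [ReportCorpus-class]; `embeddingMatrix()` / `sentenceData()` for
#' [EmbeddedCorpus-class]; `seedInfo()` / `seedVectors()` for
#' [SeedSet-class]; `vMatrix()` / `substanceCounts()` for
#' [ProportionMatrix-class]; `observedT()` / `nullDistribution()` /
#' `pValue()` for [PermutationResult-class]; `cramersV()` / `pValue()` for
#' [ContingencyResult-class]; `backendName()` / `backendDimension()` for
#' backends; `trainingReport()` for the classifier.
#'
#' @param x an object of the documented class.
#' @param ... passed on; `cramersV()` can also be called directly with the
#'   chi-square ingredients, see [cramersVFromChisq()].
#' @return the underlying component, as a plain data.frame, matrix or vector.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setMethod("reportTable", "ReportCorpus", function(x) x@reports)

#' @rdname accessors
#' @export
setMethod("sentenceTable", "ReportCorpus", function(x) x@sentences)

#' @rdname accessors
#' @export
setMethod("catalogue", "ReportCorpus", function(x) x@catalogue)

#' @rdname accessors
#' @export
setMethod("substanceNames", "ReportCorpus",
          function(x) sort(unique(x@reports$substance)))

#' @rdname accessors
#' @export
setMethod("backendName", "EmbeddingBackend", function(x) x@name)

#' @rdname accessors
#' @export
setMethod("backendDimension", "EmbeddingBackend", function(x) x@dimension)

#' @rdname accessors
#' @export
setMethod("embeddingMatrix", "EmbeddedCorpus",
          function(x) SummarizedExperiment::assay(x, "embedding"))

#' @rdname accessors
#' @export
setMethod("sentenceData", "EmbeddedCorpus", function(x) {
  as.data.frame(SummarizedExperiment::colData(x))
})

#' @rdname accessors
#' @export
setMethod("substanceNames", "EmbeddedCorpus",
          function(x) sort(unique(SummarizedExperiment::colData(x)$substance)))

#' @rdname accessors
#' @export
setMethod("seedInfo", "SeedSet", function(x) x@info)

#' @rdname accessors
#' @export
setMethod("seedVectors", "SeedSet", function(x) x@vectors)

#' @rdname accessors
#' @export
setMethod("vMatrix", "ProportionMatrix", function(x) x@values)

#' @rdname accessors
#' @export
setMethod("seedInfo", "ProportionMatrix", function(x) x@seedInfo)

#' @rdname accessors
#' @export
setMethod("substanceCounts", "ProportionMatrix", function(x) x@counts)

#' @rdname accessors
#' @export
setMethod("substanceNames", "ProportionMatrix", function(x) colnames(x@values))

#' @rdname accessors
#' @export
setMethod("observedT", "PermutationResult", function(x) x@observedT)

#' @rdname accessors
#' @export
setMethod("nullDistribution", "PermutationResult", function(x) x@nullT)

#' @rdname accessors
#' @export
setMethod("pValue", "PermutationResult", function(x) x@pValue)

#' @rdname accessors
#' @export
setMethod("pValue", "ContingencyResult", function(x) x@pValue)

#' @rdname accessors
#' @export
setMethod("cramersV", "ContingencyResult", function(x, ...) x@cramersV)

#' @rdname accessors
#' @export
setMethod("trainingReport", "VisualSentenceClassifier",
          function(x) x@trainingReport)

## ---------------------------------------------------------------------------
## show methods
## ---------------------------------------------------------------------------

setMethod("show", "ReportCorpus", function(object) {
  cat("ReportCorpus with", nrow(object@reports), "reports,",
      nrow(object@sentences), "sentences,",
      length(unique(object@reports$substance)), "substances\n")
})

setMethod("show", "EmbeddedCorpus", function(object) {
  cat("EmbeddedCorpus:", ncol(object), "sentences x",
      nrow(object), "embedding dimensions (backend: ",
      S4Vectors::metadata(object)$backend, ")\n", sep = " ")
})

setMethod("show", "SyntheticBackend", function(object) {
  cat("SyntheticBackend '", object@name, "': dim ", object@dimension,
      ", ", ncol(object@anchors), " category anchors, ",
      ncol(object@background), " background anchors, noise sd ",
      object@noiseSd, "\n", sep = "")
})

setMethod("show", "FunctionBackend", function(object) {
  cat("FunctionBackend '", object@name, "': dim ", object@dimension,
      "\n", sep = "")
})

setMethod("show", "SeedSet", function(object) {
  cat("SeedSet with", nrow(object@info), "seed sentences in",
      length(unique(object@info$category)), "categories; embedding dim",
      nrow(object@vectors), "\n")
})

setMethod("show", "VisualSentenceClassifier", function(object) {
  tr <- object@trainingReport
  cat("VisualSentenceClassifier: dim ", object@dimension,
      ", extraction threshold ", object@threshold, sep = "")
  if (!is.null(tr$accuracy))
    cat(", held-out accuracy ", sprintf("%.3f", tr$accuracy), sep = "")
  cat("\n")
})

setMethod("show", "ProportionMatrix", function(object) {
  cat("ProportionMatrix V(s, d):", nrow(object@values), "seed sentences x",
      ncol(object@values), "substances\n")
})

setMethod("show", "ContingencyResult", function(object) {
  cat(sprintf("Chi-square independence: X2(%d, N = %s) = %.4g, p = %.3g, Cramer's V = %.3f\n",
              object@df, format(object@n, big.mark = ","),
              object@statistic, object@pValue, object@cramersV))
})

setMethod("show", "PermutationResult", function(object) {
  cat(sprintf("Permutation test: observed T = %.6g, p = %.4g (%d permutations, seed %d)\n",
              object@observedT, object@pValue,
              object@nPermutations, object@seed))
})
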