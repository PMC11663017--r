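#' @include AllClasses.R
NULL

#' Embed a character vector of texts with a backend
#'
#' Every [EmbeddingBackend-class] implements this generic. The contract is
#' deterministic: the same input string always yields the same vector, and all
#' outputs share the backend's declared dimension. Columns of the returned
#' matrix correspond to the input texts, rows to embedding dimensions.
#'
#' @param backend an [EmbeddingBackend-class] object.
#' @param texts character vector of sentences to embed.
#' @return numeric matrix of size `backendDimension(backend)` x `length(texts)`.
#' @export
setGeneric("embedText", function(backend, texts) standardGeneric("embedText"))

#' @rdname accessors
#' @export
setGeneric("backendName", function(x) standardGeneric("backendName"))

#' @rdname accessors
#' @export
setGeneric("backendDimension", function(x) standardGeneric("backendDimension"))

#' @rdname accessors
#' @export
setGeneric("reportTable", function(x) standardGeneric("reportTable"))

#' @rdname accessors
#' @export
setGeneric("sentenceTable", function(x) standardGeneric("sentenceTable"))

#' @rdname accessors
#' @export
setGeneric("catalogue", function(x) standardGeneric("catalogue"))

#' @rdname accessors
#' @export
setGeneric("substanceNames", function(x) standardGeneric("substanceNames"))

#' @rdname accessors
#' @export
setGeneric("embeddingMatrix", function(x) standardGeneric("embeddingMatrix"))

#' @rdname accessors
#' @export
setGeneric("sentenceData", function(x) standardGeneric("sentenceData"))

#' @rdname accessors
#' @export
setGeneric("seedInfo", function(x) standardGeneric("seedInfo"))

#' @rdname accessors
#' @export
setGeneric("seedVectors", function(x) standardGeneric("seedVectors"))

#' @rdname accessors
#' @export
setGeneric("vMatrix", function(x) standardGeneric("vMatrix"))

#' @rdname accessors
#' @export
setGeneric("substanceCounts", function(x) standardGeneric("substanceCounts"))

#' @rdname accessors
#' @export
setGeneric("observedT", function(x) standardGeneric("observedT"))

#' @rdname accessors
#' @export
setGeneric("nullDistribution", function(x) standardGeneric("nullDistribution"))

#' @rdname accessors
#' @export
setGeneric("pValue", function(x) standardGeneric("pValue"))

#' @rdname accessors
#' @export
setGeneric("cramersV", function(x, ...) standardGeneric("cramersV"))

#' @rdname accessors
#' @export
setGeneric("trainingReport", function(x) standardGeneric("trainingReport"))

#' Predict visual-effect probabilities for embedded sentences
#'
#' Applies the logistic model `p = sigmoid(w . v + b)` to each embedding
#' vector. Probabilities are monotone in the linear score and lie in `[0, 1]`.
#'
#' @param model a [VisualSentenceClassifier-class].
#' @param x an [EmbeddedCorpus-class], or a numeric matrix with one row per
#'   sentence and one column per embedding dimension.
#' @return numeric vector of probabilities, one per sentence.
#' @export
setGeneric("predictProbability",
           function(model, x) standardGeneric("predictProbability"))
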