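#' @include AllClasses.R AllGenerics.R
NULL

## deterministic 31-ary polynomial string hash mod a Mersenne prime; used to
## key synthetic-backend noise to the sentence text
.HASH_P <- 2147483647
.hashEnv <- new.env(parent = emptyenv())
.hashEnv$pows <- 1

.hashPows <- function(n) {
  pows <- .hashEnv$pows
  while (length(pows) < n)
    pows[length(pows) + 1L] <- (pows[length(pows)] * 31) %% .HASH_P
  .hashEnv$pows <- pows
  pows[seq_len(n)]
}

.textHash <- function(texts) {
  vapply(texts, function(txt) {
    v <- utf8ToInt(txt)
    if (!length(v)) return(0)
    sum((v %% .HASH_P) * .hashPows(length(v)) %% .HASH_P) %% .HASH_P
  }, numeric(1), USE.NAMES = FALSE)
}

#' L2-normalise embedding vectors
#'
#' Vectors are normalised to unit Euclidean norm on ingestion regardless of
#' backend, so that the Euclidean distance threshold used for categorisation
#' is equivalent to a cosine-similarity threshold (a radius `r` on the unit
#' sphere corresponds to cosine similarity `1 - r^2/2`). Normalisation is
#' idempotent.
#'
#' @param x numeric vector, or matrix with one vector per column.
#' @return object of the same shape with unit-norm columns.
#' @export
l2Normalize <- function(x) {
  if (is.matrix(x)) {
    nrm <- sqrt(colSums(x^2))
    if (any(nrm == 0)) stop("cannot normalise a zero vector")
    sweep(x, 2L, nrm, `/`)
  } else {
    nrm <- sqrt(sum(x^2))
    if (nrm == 0) stop("cannot normalise a zero vector")
    x / nrm
  }
}

#' Euclidean distance between two embedding vectors
#'
#' Semantic similarity of two sentences corresponds to a small Euclidean
#' distance between their embedding vectors. The distance is symmetric,
#' nonnegative, and zero exactly for identical vectors.
#'
#' @param a,b numeric vectors of equal length.
#' @return nonnegative scalar.
#' @export
semanticDistance <- function(a, b) {
  if (length(a) != length(b))
    stop("dimension mismatch: ", length(a), " vs ", length(b))
  sqrt(sum((a - b)^2))
}

## squared Euclidean distances between columns of X (d x n) and S (d x k)
.crossDist2 <- function(X, S) {
  if (nrow(X) != nrow(S))
    stop("dimension mismatch: ", nrow(X), " vs ", nrow(S))
  d2 <- outer(colSums(X^2), colSums(S^2), `+`) - 2 * crossprod(X, S)
  d2[d2 < 0] <- 0
  d2
}

## ---------------------------------------------------------------------------
## Backends
## ---------------------------------------------------------------------------

#' Wrap an arbitrary embedding function as a backend
#'
#' `fun` receives a character vector and must return a numeric matrix with
#' `dimension` rows and one column per input text. This is the adapter point
#' for any external embedding service.
#'
#' @param name backend identifier (cache key prefix).
#' @param dimension embedding dimension.
#' @param fun embedding function.
#' @return a `FunctionBackend`.
#' @export
functionBackend <- function(name, dimension, fun) {
  new("FunctionBackend", name = name, dimension = as.integer(dimension),
      fun = fun)
}

#' @export
#' @describeIn functionBackend calls `fun` and validates its output shape.
setMethod("embedText", "FunctionBackend", function(backend, texts) {
  out <- backend@fun(texts)
  if (!is.matrix(out) || nrow(out) != backend@dimension ||
      ncol(out) != length(texts))
    stop("backend '", backend@name, "' returned a ",
         paste(dim(out), collapse = "x"),
         " result; expected ", backend@dimension, "x", length(texts))
  out
})

#' Deterministic synthetic embedding backend
#'
#' A test stand-in for a sentence-embedding service. A sentence containing a
#' category token (matching `viscat[a-z]+`) embeds as
#' `normalize(anchor + eps)`, where the anchor is the unit vector registered
#' for that token and `eps` is Gaussian noise whose RMS norm is `noiseSd`
#' (per-coordinate sd `noiseSd/sqrt(dim)`, so thresholds are
#' dimension-independent). The noise is keyed to the backend seed and a hash
#' of the sentence text, so the same string always maps to the same vector. A
#' sentence containing a background token (`bgtok[a-z]+`) embeds near that
#' background anchor; a sentence with no token embeds near a background
#' anchor chosen by text hash.
#'
#' @param anchors unit-vector matrix (dim x categories) with token column
#'   names, e.g. from [generateAnchors()].
#' @param background unit-vector matrix (dim x k) of background anchors with
#'   token column names.
#' @param noiseSd RMS norm of the perturbation (0 maps tokens exactly to
#'   their anchors).
#' @param seed integer backend seed.
#' @param name backend identifier.
#' @return a `SyntheticBackend`.
#' @export
syntheticBackend <- function(anchors, background, noiseSd = 0.1, seed = 1L,
                             name = "synthetic") {
  if (!is.matrix(anchors) || !is.matrix(background))
    stop("anchors and background must be matrices with one vector per column")
  if (nrow(anchors) != nrow(background))
    stop("unknown dimension: anchors and background disagree")
  new("SyntheticBackend", name = name, dimension = nrow(anchors),
      anchors = anchors, background = background,
      noiseSd = noiseSd, seed = as.integer(seed))
}

#' @export
#' @describeIn syntheticBackend deterministic tag-to-anchor embedding.
setMethod("embedText", "SyntheticBackend", function(backend, texts) {
  dim <- backend@dimension
  sdc <- if (backend@noiseSd > 0) backend@noiseSd / sqrt(dim) else 0
  hashes <- .textHash(texts)
  cat_tok <- regmatches(texts, regexpr("viscat[a-z]+", texts))
  has_cat <- grepl("viscat[a-z]+", texts)
  bg_tok <- regmatches(texts, regexpr("bgtok[a-z]+", texts))
  has_bg <- grepl("bgtok[a-z]+", texts)

  out <- matrix(0, dim, length(texts))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed))
      assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)

  ci <- bi <- 1L
  for (j in seq_along(texts)) {
    if (has_cat[j]) {
      tok <- cat_tok[ci]; ci <- ci + 1L
      if (!tok %in% colnames(backend@anchors))
        stop("missing anchor for category token '", tok, "'")
      anchor <- backend@anchors[, tok]
    } else if (has_bg[j]) {
      tok <- bg_tok[bi]; bi <- bi + 1L
      if (!tok %in% colnames(backend@background))
        stop("missing anchor for background token '", tok, "'")
      anchor <- backend@background[, tok]
    } else {
      anchor <- backend@background[, (hashes[j] %% ncol(backend@background)) + 1L]
    }
    if (sdc > 0) {
      set.seed((backend@seed * 1000003 + hashes[j]) %% .HASH_P)
      v <- anchor + stats::rnorm(dim, 0, sdc)
    } else {
      v <- anchor
    }
    out[, j] <- v / sqrt(sum(v^2))
  }
  out
})

## ---------------------------------------------------------------------------
## Cache
## ---------------------------------------------------------------------------

#' In-memory embedding cache
#'
#' Keyed by (backend name, exact sentence text), honouring the backend
#' determinism contract: once a sentence has been embedded it is never sent
#' to the backend again. [saveEmbeddingCache()] / [loadEmbeddingCache()]
#' persist a cache as JSON-lines records `{backend, text, vector}`.
#'
#' @return an empty `EmbeddingCache`.
#' @export
embeddingCache <- function() {
  structure(new.env(parent = emptyenv()), class = "EmbeddingCache")
}

.cacheKey <- function(backend_name, text) paste0(backend_name, "\r", text)

#' @rdname embeddingCache
#' @param cache an `EmbeddingCache`.
#' @param path file path for the JSON-lines store.
#' @export
saveEmbeddingCache <- function(cache, path) {
  keys <- ls(cache, sorted = TRUE)
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  for (k in keys) {
    parts <- strsplit(k, "\r", fixed = TRUE)[[1]]
    writeLines(jsonlite::toJSON(
      list(backend = parts[1], text = paste(parts[-1], collapse = "\r"),
           vector = get(k, envir = cache)),
      auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}

#' @rdname embeddingCache
#' @export
loadEmbeddingCache <- function(path) {
  cache <- embeddingCache()
  for (line in readLines(path, warn = FALSE, encoding = "UTF-8")) {
    if (!nzchar(trimws(line))) next
    rec <- jsonlite::fromJSON(line)
    assign(.cacheKey(rec$backend, rec$text), as.numeric(rec$vector),
           envir = cache)
  }
  cache
}

## ---------------------------------------------------------------------------
## Corpus embedding
## ---------------------------------------------------------------------------

#' Embed every sentence of a corpus
#'
#' Maps each sentence to exactly one embedding vector through the backend,
#' consulting the cache first (cached sentences are not re-embedded). All
#' vectors are L2-normalised on ingestion. Non-finite backend output is an
#' error naming the offending sentence; partial results are never silently
#' dropped.
#'
#' @param corpus a [ReportCorpus-class], or a data.frame with columns
#'   `sentence_id`, `report_id`, `substance`, `text`.
#' @param backend an [EmbeddingBackend-class].
#' @param cache optional [embeddingCache()]; filled in place.
#' @return an [EmbeddedCorpus-class].
#' @export
embedCorpus <- function(corpus, backend, cache = NULL) {
  sent <- if (is(corpus, "ReportCorpus")) sentenceTable(corpus) else corpus
  stopifnot(all(c("sentence_id", "report_id", "substance", "text") %in%
                  names(sent)))
  texts <- as.character(sent$text)
  bname <- backendName(backend)
  dim <- backendDimension(backend)

  uniq <- unique(texts)
  if (!is.null(cache)) {
    keys <- .cacheKey(bname, uniq)
    cached <- vapply(keys, exists, logical(1), envir = cache,
                     inherits = FALSE)
    todo <- uniq[!cached]
  } else {
    todo <- uniq
  }

  emb <- new.env(parent = emptyenv())
  if (length(todo)) {
    m <- embedText(backend, todo)
    bad <- which(!apply(m, 2L, function(v) all(is.finite(v))))
    if (length(bad))
      stop("backend '", bname, "' returned non-finite vectors for: ",
           paste(utils::head(todo[bad], 5L), collapse = " | "))
    for (j in seq_along(todo)) {
      v <- m[, j]
      assign(todo[j], v, envir = emb)
      if (!is.null(cache))
        assign(.cacheKey(bname, todo[j]), v, envir = cache)
    }
  }
  getvec <- function(txt) {
    if (exists(txt, envir = emb, inherits = FALSE))
      get(txt, envir = emb)
    else
      get(.cacheKey(bname, txt), envir = cache, inherits = FALSE)
  }
  mat <- vapply(texts, getvec, numeric(dim), USE.NAMES = FALSE)
  if (!is.matrix(mat)) mat <- matrix(mat, nrow = dim)
  mat <- l2Normalize(mat)
  colnames(mat) <- sent$sentence_id
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(embedding = mat),
    colData = S4Vectors::DataFrame(sent, row.names = sent$sentence_id))
  out <- new("EmbeddedCorpus", se)
  S4Vectors::metadata(out) <- list(backend = bname, dimension = dim)
  out
}
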