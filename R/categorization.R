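#' @include AllClasses.R AllGenerics.R embedding.R classifier.R
NULL

#' Read a seed-sentence catalogue
#'
#' A TSV with columns `category` and `text`, one row per seed sentence.
#'
#' @param path file path.
#' @return data.frame with columns `category`, `text`.
#' @export
readSeedCatalogue <- function(path) {
  seeds <- utils::read.delim(path, stringsAsFactors = FALSE,
                             check.names = FALSE)
  stopifnot(all(c("category", "text") %in% names(seeds)))
  seeds
}

#' Packaged seed-sentence catalogue for visual-effect categorisation
#'
#' The 41 prototypical visual-effect sentences used for categorisation,
#' grouped into eight categories (Pattern, Movement, Color, Entities, Global
#' visual alterations, Distortion, Affect, Other). Each seed defines a
#' semantic region of visual-effect space; a report sentence is an instance
#' of that region when its embedding vector lies within the distance
#' threshold of the seed's vector.
#'
#' @return data.frame with columns `category`, `text`.
#' @export
seedCatalogue <- function() {
  readSeedCatalogue(system.file("extdata", "seed_sentences.tsv",
                                package = "psyvis", mustWork = TRUE))
}

#' Embed a seed catalogue with the corpus backend
#'
#' Seed vectors must come from the same backend, and receive the same L2
#' normalisation, as the corpus sentences, so that distances are comparable.
#'
#' @param seeds data.frame with `category`, `text` (e.g. [seedCatalogue()]).
#' @param backend the [EmbeddingBackend-class] used for the corpus.
#' @param cache optional [embeddingCache()].
#' @return a [SeedSet-class].
#' @export
embedSeeds <- function(seeds, backend, cache = NULL) {
  stopifnot(all(c("category", "text") %in% names(seeds)))
  sent <- data.frame(sentence_id = paste0("seed", seq_len(nrow(seeds))),
                     report_id = "seeds", substance = "seeds",
                     text = seeds$text, stringsAsFactors = FALSE)
  emb <- embedCorpus(sent, backend, cache = cache)
  vec <- embeddingMatrix(emb)
  colnames(vec) <- seeds$text
  new("SeedSet", info = as.data.frame(seeds[, c("category", "text")]),
      vectors = vec)
}

#' Score sentence membership against seed sentences
#'
#' Sentence `i` is a member of seed `s` when the Euclidean distance between
#' their embedding vectors is at most `threshold` (inclusive; default 0.55
#' on unit-normalised vectors). Membership is not exclusive: a sentence may
#' match several seeds, or none.
#'
#' @param x an [EmbeddedCorpus-class] (typically the visual-effect subset)
#'   or a sentences-by-dimensions matrix.
#' @param seeds a [SeedSet-class].
#' @param threshold distance threshold, `> 0`.
#' @return logical matrix, sentences x seeds, with seed texts as column
#'   names; attribute `threshold` records the radius used.
#' @export
scoreMembership <- function(x, seeds, threshold = 0.55) {
  stopifnot(is(seeds, "SeedSet"), threshold > 0)
  X <- .asSentenceMatrix(x)
  S <- seedVectors(seeds)
  if (ncol(X) != nrow(S))
    stop("dimension mismatch: sentences have ", ncol(X),
         " dimensions, seeds have ", nrow(S))
  d2 <- .crossDist2(t(X), S)
  mem <- d2 <= threshold^2
  dimnames(mem) <- list(rownames(X), colnames(S))
  attr(mem, "threshold") <- threshold
  mem
}

#' Build the seed-by-substance proportion matrix V(s, d)
#'
#' `V(s, d)` is the number of substance `d`'s visual-effect sentences within
#' the distance threshold of seed `s`, divided by the total number of visual
#' effect sentences for `d`. Substances with zero visual sentences have an
#' undefined proportion and are dropped from the matrix with a warning.
#'
#' @param membership logical sentences-by-seeds matrix from
#'   [scoreMembership()].
#' @param substances substance label per sentence (row of `membership`).
#' @param seeds optional [SeedSet-class] supplying seed categories for the
#'   row metadata.
#' @return a [ProportionMatrix-class].
#' @export
proportionMatrix <- function(membership, substances, seeds = NULL) {
  stopifnot(is.matrix(membership),
            length(substances) == nrow(membership))
  substances <- as.factor(substances)
  empty <- setdiff(levels(substances), unique(as.character(substances)))
  if (length(empty))
    warning("substance(s) with zero visual sentences dropped from V: ",
            paste(empty, collapse = ", "))
  substances <- droplevels(substances)
  if (nlevels(substances) == 0L)
    stop("no visual sentences to categorise")
  counts <- rowsum(membership + 0L, substances)        # substances x seeds
  totals <- as.integer(table(substances))[match(rownames(counts),
                                                levels(substances))]
  V <- t(counts / totals)                              # seeds x substances
  info <- if (!is.null(seeds)) {
    stopifnot(identical(seedInfo(seeds)$text, colnames(membership)))
    seedInfo(seeds)
  } else {
    data.frame(category = NA_character_,
               text = colnames(membership) %||%
                 paste0("seed", seq_len(ncol(membership))),
               stringsAsFactors = FALSE)
  }
  rownames(V) <- info$text
  new("ProportionMatrix", values = V, seedInfo = info,
      counts = stats::setNames(as.numeric(totals), colnames(V)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Categorise the visual-effect subset of a corpus
#'
#' Convenience wrapper chaining [scoreMembership()] and
#' [proportionMatrix()].
#'
#' @param visual an [EmbeddedCorpus-class] of visual-effect sentences.
#' @param seeds a [SeedSet-class].
#' @param threshold distance threshold (default 0.55).
#' @return a [ProportionMatrix-class].
#' @export
categorizeVisualSentences <- function(visual, seeds, threshold = 0.55) {
  mem <- scoreMembership(visual, seeds, threshold)
  proportionMatrix(mem, SummarizedExperiment::colData(visual)$substance,
                   seeds = seeds)
}

#' Write a proportion matrix (and its counts sidecar) as TSV
#'
#' @param pm a [ProportionMatrix-class].
#' @param path output TSV (seeds as rows, substances as columns); the
#'   per-substance visual-sentence totals go to `<path>.counts.tsv`.
#' @export
writeProportionMatrixTSV <- function(pm, path) {
  v <- vMatrix(pm)
  out <- data.frame(category = seedInfo(pm)$category,
                    seed = rownames(v), v, check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  counts <- data.frame(substance = names(substanceCounts(pm)),
                       n_visual = as.integer(substanceCounts(pm)))
  utils::write.table(counts, paste0(path, ".counts.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Two-dimensional UMAP projection for inspection
#'
#' Projects embedding vectors to 2-D with uniform manifold approximation and
#' projection, delegated to the established `umap-learn` implementation
#' through a `python` subprocess. The projection is for visual inspection of
#' the semantic space only; all quantitative analysis in this package runs
#' in the full-dimensional embedding space.
#'
#' @param x an [EmbeddedCorpus-class] or sentences-by-dimensions matrix with
#'   at least a few dozen rows.
#' @param nNeighbors UMAP `n_neighbors` (local neighbourhood size).
#' @param minDist UMAP `min_dist`.
#' @param seed integer `random_state` for a reproducible layout.
#' @param python python executable with `umap-learn` and `numpy` available.
#' @return numeric matrix, points x 2.
#' @export
projectUMAP <- function(x, nNeighbors = 15, minDist = 0.1, seed = 42L,
                        python = "python") {
  X <- .asSentenceMatrix(x)
  if (nrow(X) < 20L)
    stop("too few points for a UMAP projection (need at least 20, got ",
         nrow(X), ")")
  script <- system.file("python", "umap_project.py", package = "psyvis",
                        mustWork = TRUE)
  inp <- tempfile(fileext = ".tsv")
  outp <- tempfile(fileext = ".tsv")
  on.exit(unlink(c(inp, outp)), add = TRUE)
  utils::write.table(X, inp, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  res <- system2(python, c(script, inp, outp, nNeighbors, minDist,
                           as.integer(seed)),
                 stdout = TRUE, stderr = TRUE)
  status <- attr(res, "status")
  if (!is.null(status) && status != 0)
    stop("UMAP subprocess failed:\n", paste(res, collapse = "\n"))
  coords <- as.matrix(utils::read.table(outp, sep = "\t"))
  dimnames(coords) <- list(rownames(X), c("umap1", "umap2"))
  coords
}
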