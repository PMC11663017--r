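# Independent oracles and small fixtures used across the suite.

# Brute-force double loop over unordered substance pairs; deliberately naive
# and independent of the package's sorted-sum implementation.
naiveT <- function(V) {
  S <- nrow(V); D <- ncol(V)
  total <- 0
  for (s in seq_len(S)) {
    inner <- 0
    for (d1 in seq_len(D - 1))
      for (d2 in (d1 + 1):D)
        inner <- inner + abs(V[s, d1] - V[s, d2])
    total <- total + 2 * inner / (D * (D - 1))
  }
  total / S
}

# Naive agglomerative average-linkage clustering of the rows of X under
# Euclidean distance; returns merge heights in merge order.
naiveAverageLinkageHeights <- function(X) {
  D <- as.matrix(stats::dist(X))
  clusters <- as.list(seq_len(nrow(X)))
  heights <- numeric(0)
  while (length(clusters) > 1L) {
    best <- c(NA, NA); bestd <- Inf
    for (i in seq_len(length(clusters) - 1L))
      for (j in (i + 1L):length(clusters)) {
        d <- mean(D[clusters[[i]], clusters[[j]]])
        if (d < bestd) { bestd <- d; best <- c(i, j) }
      }
    heights <- c(heights, bestd)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  heights
}

# Brute-force seed membership: explicit per-pair Euclidean distances.
naiveMembership <- function(X, S, threshold) {
  out <- matrix(FALSE, nrow(X), ncol(S))
  for (i in seq_len(nrow(X)))
    for (j in seq_len(ncol(S)))
      out[i, j] <- sqrt(sum((X[i, ] - S[, j])^2)) <= threshold
  out
}

# Small synthetic corpus with its built corpus, ground-truth labels aligned
# to the corpus sentence table, and embedded corpus.
quickSyn <- function(..., embed = TRUE) {
  syn <- generateCorpus(generatorConfig(...))
  corpus <- buildCorpus(syn$reports, syn$catalogue, minReports = 1)
  st <- sentenceTable(corpus)
  m <- match(st$text, syn$groundTruth$text)
  stopifnot(!anyNA(m))
  list(syn = syn, corpus = corpus,
       truth = syn$groundTruth[m, , drop = FALSE],
       embedded = if (embed) embedCorpus(corpus, syn$backend) else NULL)
}

# An embedding backend that counts how many texts it is asked to embed.
countingBackend <- function(dim = 6L) {
  calls <- new.env(parent = emptyenv())
  calls$n <- 0L
  backend <- functionBackend("counting", dim, function(texts) {
    calls$n <- calls$n + length(texts)
    vapply(texts, function(t) {
      v <- (sum(utf8ToInt(t)) %% 89 + 1) * seq_len(dim)
      v / sqrt(sum(v^2))
    }, numeric(dim))
  })
  list(backend = backend, calls = calls)
}

# Random text fuzzer for the sentence splitter.
fuzzString <- function(maxlen = 60L) {
  alphabet <- c(letters[1:6], " ", " ", ".", ".", "0", "5", "9", ",")
  paste(sample(alphabet, sample.int(maxlen, 1L), replace = TRUE),
        collapse = "")
}
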