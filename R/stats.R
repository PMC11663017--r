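#' @include AllClasses.R AllGenerics.R categorization.R
NULL

#' Cramer's V from chi-square ingredients
#'
#' `V = sqrt(chi2 / (n * min(r - 1, c - 1)))` for a contingency table with
#' `r` rows, `c` columns and total count `n`; `V` lies in `[0, 1]` and is
#' zero exactly when the chi-square statistic is zero.
#'
#' @param chi2 Pearson chi-square statistic.
#' @param n total table count.
#' @param r,c table dimensions (default 2 x 2, where the denominator is
#'   simply `n`).
#' @return Cramer's V.
#' @examples
#' cramersVFromChisq(72912, 2246254)   # ~0.180
#' @export
cramersVFromChisq <- function(chi2, n, r = 2L, c = 2L) {
  stopifnot(chi2 >= 0, n > 0, r >= 2L, c >= 2L)
  sqrt(chi2 / (n * min(r - 1L, c - 1L)))
}

#' Pearson chi-square test of independence with Cramer's V
#'
#' Expected counts come from the table marginals; the p-value from the
#' chi-square distribution with `(r - 1)(c - 1)` degrees of freedom. In this
#' package the canonical use is the substance-by-classification table (rows
#' = substances, columns = visual / not visual at the extraction threshold).
#'
#' @param tab matrix of nonnegative counts, at least 2 x 2.
#' @return a [ContingencyResult-class].
#' @export
chiSquareIndependence <- function(tab) {
  tab <- as.matrix(tab)
  if (nrow(tab) < 2L || ncol(tab) < 2L)
    stop("need at least a 2 x 2 table")
  if (any(tab < 0) || any(tab != round(tab)))
    stop("counts must be nonnegative integers")
  zr <- which(rowSums(tab) == 0)
  if (length(zr))
    stop("zero marginal for row ",
         paste(rownames(tab)[zr] %||% zr, collapse = ", "))
  zc <- which(colSums(tab) == 0)
  if (length(zc))
    stop("zero marginal for column ",
         paste(colnames(tab)[zc] %||% zc, collapse = ", "))
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  n <- sum(tab)
  new("ContingencyResult",
      statistic = as.numeric(ct$statistic),
      df = as.integer(ct$parameter),
      n = n,
      cramersV = cramersVFromChisq(as.numeric(ct$statistic), n,
                                   nrow(tab), ncol(tab)),
      pValue = as.numeric(ct$p.value))
}

#' Compare visual-effect proportions between psychedelic and other substances
#'
#' Welch two-sample t-test on unweighted substance-level visual-effect
#' proportions, psychedelic versus non-psychedelic, with group membership
#' taken from the catalogue's `is_psychedelic` flag.
#'
#' @param proportions data.frame with columns `substance` and `proportion`
#'   (e.g. the `proportions` element of [extractVisualSentences()]).
#' @param catalogue data.frame with `substance` and `is_psychedelic`.
#' @return list with `t` (psychedelic minus non-psychedelic orientation),
#'   `df`, `p`, and the two group means.
#' @export
compareGroupProportions <- function(proportions, catalogue) {
  stopifnot(all(c("substance", "proportion") %in% names(proportions)))
  idx <- match(proportions$substance, catalogue$substance)
  if (anyNA(idx))
    stop("substance(s) missing from catalogue: ",
         paste(proportions$substance[is.na(idx)], collapse = ", "))
  psy <- catalogue$is_psychedelic[idx]
  a <- proportions$proportion[psy]
  b <- proportions$proportion[!psy]
  if (length(a) < 2L || length(b) < 2L)
    stop("each group needs at least 2 substances (got ", length(a),
         " psychedelic, ", length(b), " other)")
  tt <- stats::t.test(a, b, var.equal = FALSE)
  list(t = as.numeric(tt$statistic), df = as.numeric(tt$parameter),
       p = as.numeric(tt$p.value),
       mean_psychedelic = mean(a), mean_other = mean(b))
}

## mean absolute pairwise difference of a numeric vector, via the sorted-sum
## identity sum_{i<j} |x_i - x_j| = sum_k x_(k) (2k - n - 1)
.meanAbsPairDiff <- function(x) {
  n <- length(x)
  x <- sort(x)
  2 * sum(x * (2 * seq_len(n) - n - 1)) / (n * (n - 1))
}

#' Inter-substance dispersion statistic T
#'
#' For each seed sentence `s`, the mean absolute difference of `V(s, d)`
#' over all unordered pairs of substances quantifies how much substances
#' disagree in their association with that seed; `T` is the mean of these
#' per-seed dispersions:
#' `T = (1/|S|) * sum_s (2 / (|D| (|D| - 1))) * sum_{d1 < d2} |V(s, d1) - V(s, d2)|`.
#' `T` is zero exactly when all substances share identical seed profiles,
#' and scales linearly with the matrix entries.
#'
#' @param V a [ProportionMatrix-class], or a numeric matrix with seeds as
#'   rows and substances as columns.
#' @return nonnegative scalar.
#' @examples
#' tStatistic(matrix(c(0.2, 0.4), 1))   # single pair: 0.2
#' @export
tStatistic <- function(V) {
  v <- if (is(V, "ProportionMatrix")) vMatrix(V) else as.matrix(V)
  if (ncol(v) < 2L)
    stop("T requires at least 2 substances")
  mean(apply(v, 1L, .meanAbsPairDiff))
}

#' Permutation test for inter-substance variation in seed profiles
#'
#' Shuffles substance labels uniformly across the visual-effect sentences
#' (group sizes preserved), rebuilds `V(s, d)` and recomputes [tStatistic()]
#' for each shuffle, giving the null distribution of `T` under no
#' association between substance and visual-effect profile. The p-value is
#' the plain proportion of permuted `T` values greater than or equal to the
#' observed one (the `(b + 1)/(n + 1)` estimator is available via
#' `smoothed = TRUE`).
#'
#' @param x logical sentences-by-seeds membership matrix from
#'   [scoreMembership()], or an [EmbeddedCorpus-class] of visual-effect
#'   sentences (then `seeds` must be given and membership is computed at
#'   `threshold`).
#' @param substances substance label per sentence; defaults to the corpus
#'   `substance` column when `x` is an [EmbeddedCorpus-class].
#' @param seeds a [SeedSet-class], required when `x` is a corpus.
#' @param threshold membership distance threshold (default 0.55).
#' @param nPermutations number of label shuffles (reference procedure:
#'   10,000).
#' @param seed integer RNG seed.
#' @param smoothed use the `(b + 1)/(n + 1)` p-value estimator.
#' @return a [PermutationResult-class].
#' @export
permutationTest <- function(x, substances = NULL, seeds = NULL,
                            threshold = 0.55, nPermutations = 10000L,
                            seed = 1L, smoothed = FALSE) {
  if (is(x, "EmbeddedCorpus")) {
    if (is.null(seeds))
      stop("seeds are required to categorise an embedded corpus")
    if (is.null(substances))
      substances <- SummarizedExperiment::colData(x)$substance
    M <- scoreMembership(x, seeds, threshold) + 0L
  } else {
    stopifnot(is.matrix(x))
    if (is.null(substances))
      stop("substance labels are required with a membership matrix")
    M <- x + 0L
  }
  stopifnot(nPermutations >= 1L)
  labels <- droplevels(as.factor(substances))
  if (nlevels(labels) < 2L)
    stop("degenerate input: at least 2 substances are required")
  n <- nrow(M)
  totals <- as.integer(table(labels))
  tstat_of <- function(lab) {
    counts <- rowsum(M, lab)                  # substances x seeds
    mean(apply(counts / totals, 2L, .meanAbsPairDiff))
  }
  obs <- tstat_of(labels)
  nullT <- .withSeed(seed, {
    vapply(seq_len(nPermutations), function(b)
      tstat_of(labels[sample.int(n)]), numeric(1))
  })
  p <- if (smoothed) (sum(nullT >= obs) + 1) / (nPermutations + 1)
       else mean(nullT >= obs)
  new("PermutationResult", observedT = obs, nullT = as.numeric(nullT),
      pValue = p, nPermutations = as.integer(nPermutations),
      seed = as.integer(seed))
}

#' Hierarchical clustering orders for a clustermap of V(s, d)
#'
#' Agglomerative hierarchical clustering of the seed rows (on their
#' substance-profile vectors) and of the substance columns (on their
#' seed-profile vectors), with dissimilarity defined as the Euclidean
#' distance between proportion vectors. Returns the leaf orders and merge
#' trees needed to render a clustermap. On a constant matrix every
#' dissimilarity is zero and the returned order is valid but arbitrary.
#'
#' @param V a [ProportionMatrix-class] or seeds-by-substances matrix with at
#'   least 2 rows and columns.
#' @param linkage one of `"average"` (default), `"single"`, `"complete"`,
#'   `"ward"`.
#' @return list with `rowOrder`, `colOrder` (leaf index orders) and
#'   `rowDendrogram`, `colDendrogram` (`hclust` merge trees).
#' @export
clustermapOrder <- function(V, linkage = c("average", "single", "complete",
                                           "ward")) {
  linkage <- match.arg(linkage)
  method <- if (linkage == "ward") "ward.D2" else linkage
  v <- if (is(V, "ProportionMatrix")) vMatrix(V) else as.matrix(V)
  if (nrow(v) < 2L || ncol(v) < 2L)
    stop("need at least 2 rows and 2 columns")
  rowH <- stats::hclust(stats::dist(v), method = method)
  colH <- stats::hclust(stats::dist(t(v)), method = method)
  list(rowOrder = rowH$order, colOrder = colH$order,
       rowDendrogram = rowH, colDendrogram = colH, linkage = linkage)
}
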