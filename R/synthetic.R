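#' @include AllClasses.R AllGenerics.R embedding.R
NULL

## evaluate expr under a fixed seed without disturbing the caller's RNG
.withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  expr
}

## digit-free word for index i (1-based), from a fixed syllabary
.syllWord <- function(i) {
  syl <- c("ba", "de", "ki", "lo", "mu", "na", "po", "ra", "su", "ti")
  vapply(i, function(k) {
    k <- k - 1L
    w <- syl[k %% 10L + 1L]
    while (k >= 10L) {
      k <- k %/% 10L
      w <- paste0(syl[k %% 10L + 1L], w)
    }
    w
  }, character(1))
}

.categoryTokens <- function(n) paste0("viscat", .syllWord(seq_len(n)))
.backgroundTokens <- function(n) paste0("bgtok", .syllWord(seq_len(n)))

#' Configuration for the synthetic corpus generator
#'
#' Collects the ground-truth parameters of a simulated report corpus:
#' substances and their psychedelic flags, report and sentence counts, the
#' per-substance probability that a sentence describes a visual effect
#' (`visualPropensity`), per-substance mixtures over visual-effect categories
#' (`categoryMixture`), and the embedding geometry (anchor separation and
#' noise). Defaults emulate the structure of the real corpus at desk scale:
#' sentences per report follow a discretised log-normal with median about 40
#' and mean about 50 (matching the right-skew of the published summary
#' table), psychedelic substances have a markedly higher visual propensity
#' (0.15 vs 0.04) in line with the reported corpus-wide visual-sentence
#' fraction of a few percent, and anchors are separated by more than twice
#' the categorisation distance threshold so that ground-truth membership is
#' unambiguous.
#'
#' @param nSubstances number of substances.
#' @param psychedelic logical flags, one per substance (default: first half).
#' @param reportsPerSubstance reports drawn for every substance.
#' @param sentencesPerReport `NULL` for the log-normal model, or a fixed
#'   integer count per report.
#' @param sentencesMeanlog,sentencesSdlog log-normal parameters for sentences
#'   per report (used when `sentencesPerReport` is `NULL`).
#' @param visualPropensity numeric vector `p_d` in `[0, 1]`, one per
#'   substance; `NULL` for the psychedelic/comparison defaults.
#' @param nCategories number of visual-effect categories.
#' @param categoryMixture matrix `theta` (substances x categories), rows
#'   summing to 1; `NULL` to draw each row from a flat Dirichlet under
#'   `seed`.
#' @param embeddingDim embedding dimension (64 by default; the analysis
#'   depends only on distances, not on the reference dimension).
#' @param anchorMinSeparation minimum pairwise Euclidean distance between
#'   category anchors; keep above twice the categorisation threshold for
#'   exclusive-membership fixtures.
#' @param noiseSd RMS norm of the embedding perturbation.
#' @param nBackground number of background (non-visual) anchors.
#' @param distanceThreshold categorisation radius the fixture should respect;
#'   background anchors are placed further than
#'   `distanceThreshold + 3 * noiseSd` from every category anchor.
#' @param seed integer root seed; everything is reproducible given it.
#' @return a validated `GeneratorConfig` list.
#' @seealso [generateCorpus()], [nullCorpus()]
#' @export
generatorConfig <- function(nSubstances = 8L,
                            psychedelic = NULL,
                            reportsPerSubstance = 50L,
                            sentencesPerReport = NULL,
                            sentencesMeanlog = log(40),
                            sentencesSdlog = 0.67,
                            visualPropensity = NULL,
                            nCategories = 6L,
                            categoryMixture = NULL,
                            embeddingDim = 64L,
                            anchorMinSeparation = 1.2,
                            noiseSd = 0.1,
                            nBackground = 5L,
                            distanceThreshold = 0.55,
                            seed = 1L) {
  nSubstances <- as.integer(nSubstances)
  if (is.null(psychedelic))
    psychedelic <- seq_len(nSubstances) <= ceiling(nSubstances / 2)
  if (length(psychedelic) != nSubstances)
    stop("psychedelic flags must have one entry per substance")
  if (is.null(visualPropensity))
    visualPropensity <- ifelse(psychedelic, 0.15, 0.04)
  if (length(visualPropensity) == 1L)
    visualPropensity <- rep(visualPropensity, nSubstances)
  if (length(visualPropensity) != nSubstances ||
      any(visualPropensity < 0 | visualPropensity > 1))
    stop("visualPropensity must be per-substance probabilities in [0, 1]")
  if (!is.null(categoryMixture)) {
    categoryMixture <- as.matrix(categoryMixture)
    if (nrow(categoryMixture) != nSubstances ||
        ncol(categoryMixture) != nCategories)
      stop("categoryMixture must be nSubstances x nCategories")
    if (any(categoryMixture < 0) ||
        max(abs(rowSums(categoryMixture) - 1)) > 1e-12)
      stop("categoryMixture rows must be nonnegative and sum to 1")
  }
  if (anchorMinSeparation <= 0 || noiseSd < 0)
    stop("anchorMinSeparation must be positive and noiseSd nonnegative")
  structure(list(nSubstances = nSubstances,
                 psychedelic = as.logical(psychedelic),
                 reportsPerSubstance = as.integer(reportsPerSubstance),
                 sentencesPerReport = sentencesPerReport,
                 sentencesMeanlog = sentencesMeanlog,
                 sentencesSdlog = sentencesSdlog,
                 visualPropensity = visualPropensity,
                 nCategories = as.integer(nCategories),
                 categoryMixture = categoryMixture,
                 embeddingDim = as.integer(embeddingDim),
                 anchorMinSeparation = anchorMinSeparation,
                 noiseSd = noiseSd,
                 nBackground = as.integer(nBackground),
                 distanceThreshold = distanceThreshold,
                 seed = as.integer(seed)),
            class = "GeneratorConfig")
}

#' Sample well-separated unit anchor vectors
#'
#' Rejection-samples unit vectors until all pairwise Euclidean distances are
#' at least `minSeparation`. In moderate dimension random unit vectors are
#' nearly orthogonal (pairwise distance about `sqrt(2)`), so separations up
#' to about 1.4 are cheap; tighter packings than the dimension allows fail
#' after `maxAttempts` with advice to lower the separation or raise the
#' dimension.
#'
#' @param n number of anchors.
#' @param dim embedding dimension.
#' @param minSeparation minimum pairwise Euclidean distance.
#' @param seed integer seed (deterministic output).
#' @param maxAttempts rejection-sampling budget.
#' @return `dim` x `n` matrix of unit columns.
#' @export
generateAnchors <- function(n, dim, minSeparation, seed = 1L,
                            maxAttempts = 10000L) {
  .withSeed(seed, {
    out <- matrix(0, dim, 0)
    attempts <- 0L
    while (ncol(out) < n) {
      attempts <- attempts + 1L
      if (attempts > maxAttempts)
        stop("could not place ", n, " anchors at separation ",
             minSeparation, " in dimension ", dim, " after ", maxAttempts,
             " attempts; lower minSeparation or raise dim")
      v <- stats::rnorm(dim)
      v <- v / sqrt(sum(v^2))
      if (ncol(out) == 0 ||
          all(sqrt(colSums((out - v)^2)) >= minSeparation))
        out <- cbind(out, v)
    }
    dimnames(out) <- NULL
    out
  })
}

## background anchors kept clear of all category anchors
.backgroundAnchors <- function(n, dim, categoryAnchors, minDist,
                               maxAttempts = 10000L) {
  out <- matrix(0, dim, 0)
  attempts <- 0L
  while (ncol(out) < n) {
    attempts <- attempts + 1L
    if (attempts > maxAttempts)
      stop("could not place background anchors clear of category anchors")
    v <- stats::rnorm(dim)
    v <- v / sqrt(sum(v^2))
    if (all(sqrt(colSums((categoryAnchors - v)^2)) > minDist))
      out <- cbind(out, v)
  }
  out
}

#' Generate a synthetic report corpus with known ground truth
#'
#' For each substance, draws reports and per-report sentence counts; each
#' sentence is a visual-effect sentence with probability `p_d`; visual
#' sentences draw a category from `theta_d` and carry a category token that
#' the bundled [syntheticBackend()] maps near that category's anchor;
#' non-visual sentences carry a background token. Sentence text is templated
#' ("I saw ... shapes ...") so the offline rule labeller and the synthetic
#' backend agree with the ground truth; every sentence gets a unique nonce
#' word so texts (and hence embedding noise draws) are distinct. Report text
#' joins sentences with ". " and a terminal period, so corpus segmentation
#' reproduces the generated sentences exactly.
#'
#' @param config a [generatorConfig()].
#' @return a `SyntheticCorpus` list with elements `reports` (data.frame for
#'   [buildCorpus()]), `groundTruth` (per-sentence `report_id`, `position`,
#'   `text`, `is_visual`, `category`), `backend` (a [syntheticBackend()]),
#'   `catalogue`, `seeds` (a seed-sentence data.frame, one per category),
#'   `p` and `theta` (the true parameters), `categories`, and `config`.
#' @export
generateCorpus <- function(config) {
  stopifnot(inherits(config, "GeneratorConfig"))
  .withSeed(config$seed, {
    K <- config$nCategories
    dim <- config$embeddingDim
    cat_tokens <- .categoryTokens(K)
    cat_names <- paste0("cat_", .syllWord(seq_len(K)))
    bg_tokens <- .backgroundTokens(config$nBackground)

    anchors <- generateAnchors(K, dim, config$anchorMinSeparation,
                               seed = config$seed * 7L + 3L)
    colnames(anchors) <- cat_tokens
    bg <- .backgroundAnchors(config$nBackground, dim, anchors,
                             minDist = config$distanceThreshold +
                               3 * config$noiseSd + 0.05)
    colnames(bg) <- bg_tokens

    theta <- config$categoryMixture
    if (is.null(theta)) {
      theta <- matrix(stats::rgamma(config$nSubstances * K, 1),
                      config$nSubstances, K)
      theta <- theta / rowSums(theta)
    }
    substances <- sprintf("S%02d", seq_len(config$nSubstances))
    rownames(theta) <- substances
    colnames(theta) <- cat_names
    p <- stats::setNames(config$visualPropensity, substances)

    nonce <- 0L
    rep_rows <- vector("list", config$nSubstances)
    gt_rows <- vector("list", config$nSubstances)
    for (d in seq_len(config$nSubstances)) {
      nr <- config$reportsPerSubstance
      nsent <- if (is.null(config$sentencesPerReport)) {
        pmax(1L, as.integer(round(stats::rlnorm(nr, config$sentencesMeanlog,
                                                config$sentencesSdlog))))
      } else rep(as.integer(config$sentencesPerReport), nr)
      N <- sum(nsent)
      rid <- sprintf("%s_r%s", substances[d], .syllWord(seq_len(nr)))
      sent_rep <- rep(seq_len(nr), nsent)
      is_vis <- stats::runif(N) < p[d]
      cat_idx <- rep(NA_integer_, N)
      nv <- sum(is_vis)
      if (nv > 0)
        cat_idx[is_vis] <- sample.int(K, nv, replace = TRUE,
                                      prob = theta[d, ])
      bg_idx <- sample.int(config$nBackground, N, replace = TRUE)
      words <- .syllWord(nonce + seq_len(N))
      nonce <- nonce + N
      text <- ifelse(is_vis,
                     paste0("I saw ", cat_tokens[pmax(cat_idx, 1L)],
                            " shapes drifting near the zon", words,
                            " corner"),
                     paste0("We sat by the ", bg_tokens[bg_idx],
                            " stove and talked about the zon", words,
                            " recipe"))
      report_text <- vapply(split(text, sent_rep), function(ss)
        paste0(paste(ss, collapse = ". "), "."), character(1))
      rep_rows[[d]] <- data.frame(report_id = rid,
                                  substance = substances[d],
                                  text = as.character(report_text),
                                  stringsAsFactors = FALSE)
      gt_rows[[d]] <- data.frame(
        report_id = rid[sent_rep],
        position = unlist(lapply(nsent, seq_len), use.names = FALSE),
        text = text,
        substance = substances[d],
        is_visual = is_vis,
        category = ifelse(is_vis, cat_names[cat_idx], NA_character_),
        stringsAsFactors = FALSE)
    }

    backend <- syntheticBackend(anchors, bg, noiseSd = config$noiseSd,
                                seed = config$seed)
    catalogue <- data.frame(
      substance = substances,
      drug_class = ifelse(config$psychedelic, "psychedelic", "comparison"),
      is_psychedelic = config$psychedelic,
      stringsAsFactors = FALSE)
    seeds <- data.frame(category = cat_names,
                        text = paste0("I saw ", cat_tokens, " shapes"),
                        stringsAsFactors = FALSE)
    structure(list(reports = do.call(rbind, rep_rows),
                   groundTruth = do.call(rbind, gt_rows),
                   backend = backend,
                   catalogue = catalogue,
                   seeds = seeds,
                   p = p,
                   theta = theta,
                   categories = data.frame(category = cat_names,
                                           token = cat_tokens,
                                           stringsAsFactors = FALSE),
                   substances = substances,
                   config = config),
              class = "SyntheticCorpus")
  })
}

#' @export
print.SyntheticCorpus <- function(x, ...) {
  cat("SyntheticCorpus:", length(x$substances), "substances,",
      nrow(x$reports), "reports,", nrow(x$groundTruth), "sentences (",
      sum(x$groundTruth$is_visual), "visual )\n")
  invisible(x)
}

#' Generate an exchangeable null corpus
#'
#' All substances share one visual propensity and one category mixture, so
#' substance labels are exchangeable by construction; the permutation test
#' should then reject at its nominal rate. The shared values are the first
#' entry/row of the configured parameters (or, when the mixture is
#' unspecified, one flat-Dirichlet row drawn under the config seed).
#'
#' @param config a [generatorConfig()].
#' @param p optional shared visual propensity overriding the config.
#' @return a `SyntheticCorpus`, see [generateCorpus()].
#' @export
nullCorpus <- function(config, p = NULL) {
  stopifnot(inherits(config, "GeneratorConfig"))
  shared_p <- if (!is.null(p)) p else config$visualPropensity[1]
  theta <- config$categoryMixture
  shared_theta <- if (!is.null(theta)) theta[1, ] else .withSeed(
    config$seed * 11L + 5L, {
      w <- stats::rgamma(config$nCategories, 1)
      w / sum(w)
    })
  config$visualPropensity <- rep(shared_p, config$nSubstances)
  config$categoryMixture <- matrix(shared_theta, config$nSubstances,
                                   config$nCategories, byrow = TRUE)
  generateCorpus(config)
}
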