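#' @include AllClasses.R AllGenerics.R corpus.R embedding.R classifier.R
#' @include categorization.R stats.R synthetic.R
NULL

.REFERENCE_PROB_THRESHOLD <- 0.75
.REFERENCE_DIST_THRESHOLD <- 0.55

#' Configuration for an end-to-end pipeline run
#'
#' Describes one full analysis: corpus source (a synthetic-corpus generator
#' or report files plus an embedding backend), classifier settings, and the
#' categorisation/statistics parameters. The probability threshold (0.75)
#' and distance threshold (0.55) default to the reference procedure's
#' values; overriding either triggers a warning at run time that results are
#' no longer comparable to the reference analysis. All randomness flows from
#' the single `seed`, expanded per stage.
#'
#' @param generator a [generatorConfig()] for a synthetic run, or `NULL`
#'   when reading a user corpus.
#' @param reportsPath JSON-lines report file (see [readReportsJSONL()]);
#'   ignored when `generator` is given.
#' @param cataloguePath substance catalogue TSV; defaults to the packaged
#'   [substanceClasses()] for user corpora.
#' @param seedsPath seed-sentence TSV; defaults to the packaged
#'   [seedCatalogue()] for user corpora.
#' @param backend an [EmbeddingBackend-class]; required for user corpora
#'   (synthetic runs use the generator's bundled backend).
#' @param minReports substance inclusion threshold (reference value 100).
#' @param labelSampleSize sentences to sample for labelling (reference
#'   value 10,000); capped at the corpus size.
#' @param trainSplit training fraction for [trainClassifier()].
#' @param probabilityThreshold visual-effect extraction threshold.
#' @param distanceThreshold seed-membership distance threshold.
#' @param nPermutations label shuffles for [permutationTest()].
#' @param linkage clustermap linkage method.
#' @param seed root integer seed.
#' @return a `PipelineConfig` list.
#' @export
pipelineConfig <- function(generator = NULL,
                           reportsPath = NULL,
                           cataloguePath = NULL,
                           seedsPath = NULL,
                           backend = NULL,
                           minReports = 100L,
                           labelSampleSize = 10000L,
                           trainSplit = 0.8,
                           probabilityThreshold = .REFERENCE_PROB_THRESHOLD,
                           distanceThreshold = .REFERENCE_DIST_THRESHOLD,
                           nPermutations = 10000L,
                           linkage = "average",
                           seed = 1L) {
  if (is.null(generator) && is.null(reportsPath))
    stop("either a generator config or a reports path is required")
  if (is.null(generator) && is.null(backend))
    stop("an embedding backend is required for a user-supplied corpus")
  structure(list(generator = generator, reportsPath = reportsPath,
                 cataloguePath = cataloguePath, seedsPath = seedsPath,
                 backend = backend, minReports = as.integer(minReports),
                 labelSampleSize = as.integer(labelSampleSize),
                 trainSplit = trainSplit,
                 probabilityThreshold = probabilityThreshold,
                 distanceThreshold = distanceThreshold,
                 nPermutations = as.integer(nPermutations),
                 linkage = linkage, seed = as.integer(seed)),
            class = "PipelineConfig")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the arguments of [pipelineConfig()]; a `generator`
#' mapping is passed to [generatorConfig()].
#'
#' @param path YAML file.
#' @return a `PipelineConfig`.
#' @export
readPipelineConfig <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$generator))
    y$generator <- do.call(generatorConfig, y$generator)
  do.call(pipelineConfig, y)
}

#' A small packaged demonstration configuration
#'
#' A synthetic-corpus pipeline sized to complete end-to-end in well under a
#' minute on one CPU: 6 substances, 12 reports each, 12 sentences per
#' report, 200 permutations.
#'
#' @param seed root seed.
#' @return a `PipelineConfig`.
#' @export
demoPipelineConfig <- function(seed = 1L) {
  pipelineConfig(
    generator = generatorConfig(nSubstances = 6L, reportsPerSubstance = 12L,
                                sentencesPerReport = 12L, seed = seed),
    minReports = 1L, labelSampleSize = 400L, nPermutations = 200L,
    seed = seed)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

.hclustAsList <- function(h) {
  list(merge = unclass(h$merge), height = h$height, order = h$order,
       labels = h$labels)
}

#' Run the full analysis pipeline
#'
#' Executes corpus assembly, embedding, labelling and classifier training,
#' visual-sentence extraction, seed categorisation, and the inferential
#' layer (chi-square association, group comparison, permutation test,
#' clustermap orders), writing every stage output plus a run manifest to
#' `outDir`. A re-run with the same configuration reproduces identical
#' outputs (the manifest's timestamp aside); any stage failure aborts with
#' the stage name.
#'
#' @param config a [pipelineConfig()].
#' @param outDir output directory (created if needed).
#' @return invisibly, a list with the in-memory stage results
#'   (`corpus`, `embedded`, `model`, `extraction`, `V`, `stats`) and
#'   `files`, the paths written.
#' @export
runPipeline <- function(config, outDir) {
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  if (config$probabilityThreshold != .REFERENCE_PROB_THRESHOLD ||
      config$distanceThreshold != .REFERENCE_DIST_THRESHOLD)
    warning("non-reference threshold(s) configured; results are not ",
            "comparable to the reference procedure")
  root <- config$seed

  src <- .stage("corpus", {
    if (!is.null(config$generator)) {
      gen <- config$generator
      syn <- generateCorpus(gen)
      list(reports = syn$reports, catalogue = syn$catalogue,
           seeds = syn$seeds, backend = syn$backend, synthetic = syn)
    } else {
      list(reports = readReportsJSONL(config$reportsPath),
           catalogue = if (is.null(config$cataloguePath)) substanceClasses()
                       else readSubstanceCatalogue(config$cataloguePath),
           seeds = if (is.null(config$seedsPath)) seedCatalogue()
                   else readSeedCatalogue(config$seedsPath),
           backend = config$backend, synthetic = NULL)
    }
  })
  corpus <- .stage("corpus",
                   buildCorpus(src$reports, src$catalogue,
                               minReports = config$minReports))
  summary <- summarizeCorpus(corpus)

  files <- c(sentences = file.path(outDir, "sentences.tsv"),
             summary = file.path(outDir, "corpus_summary.tsv"),
             proportions = file.path(outDir, "visual_proportions.tsv"),
             vmatrix = file.path(outDir, "V_matrix.tsv"),
             nullT = file.path(outDir, "null_T.tsv"),
             stats = file.path(outDir, "stats.json"),
             clustermap = file.path(outDir, "clustermap.json"),
             model = file.path(outDir, "classifier.json"),
             manifest = file.path(outDir, "manifest.json"))
  writeSentencesTSV(corpus, files["sentences"])
  utils::write.table(summary, files["summary"], sep = "\t", quote = FALSE,
                     row.names = FALSE)

  cache <- embeddingCache()
  embedded <- .stage("embedding", embedCorpus(corpus, src$backend, cache))

  model <- .stage("classifier", {
    nsamp <- min(config$labelSampleSize, nrow(sentenceTable(corpus)))
    samp <- sampleTrainingSentences(corpus, nsamp, seed = root + 1L)
    labelled <- autoLabel(samp)
    vec <- t(embeddingMatrix(embedded)[, samp$sentence_id, drop = FALSE])
    trainClassifier(vec, labelled$label, split = config$trainSplit,
                    seed = root + 2L,
                    threshold = config$probabilityThreshold)
  })
  writeClassifierJSON(model, files["model"])

  extraction <- .stage("extraction",
                       extractVisualSentences(embedded, model))
  utils::write.table(extraction$proportions, files["proportions"],
                     sep = "\t", quote = FALSE, row.names = FALSE)

  seedSet <- .stage("categorization",
                    embedSeeds(src$seeds, src$backend, cache))
  V <- .stage("categorization", {
    categorizeVisualSentences(extraction$visual, seedSet,
                              threshold = config$distanceThreshold)
  })
  writeProportionMatrixTSV(V, files["vmatrix"])

  statsOut <- .stage("stats", {
    tab <- cbind(visual = extraction$proportions$n_visual,
                 not_visual = extraction$proportions$n_sentences -
                   extraction$proportions$n_visual)
    rownames(tab) <- extraction$proportions$substance
    tab <- tab[rowSums(tab) > 0, , drop = FALSE]
    chi <- if (nrow(tab) >= 2L && all(colSums(tab) > 0))
      chiSquareIndependence(tab) else NULL
    ttest <- tryCatch(
      compareGroupProportions(extraction$proportions, src$catalogue),
      error = function(e) NULL)
    perm <- permutationTest(extraction$visual,
                            seeds = seedSet,
                            threshold = config$distanceThreshold,
                            nPermutations = config$nPermutations,
                            seed = root + 3L)
    cmap <- if (nrow(vMatrix(V)) >= 2L && ncol(vMatrix(V)) >= 2L)
      clustermapOrder(V, linkage = config$linkage) else NULL
    list(chi = chi, ttest = ttest, perm = perm, clustermap = cmap)
  })

  utils::write.table(
    data.frame(permutation = seq_along(nullDistribution(statsOut$perm)),
               T = nullDistribution(statsOut$perm)),
    files["nullT"], sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(
    chi_square = if (!is.null(statsOut$chi)) list(
      statistic = statsOut$chi@statistic, df = statsOut$chi@df,
      n = statsOut$chi@n, cramers_v = statsOut$chi@cramersV,
      p = statsOut$chi@pValue),
    group_t_test = statsOut$ttest,
    permutation = list(observed_T = observedT(statsOut$perm),
                       p = pValue(statsOut$perm),
                       n_permutations = statsOut$perm@nPermutations,
                       seed = statsOut$perm@seed),
    visual_proportion_overall = extraction$overall,
    thresholds = list(probability = config$probabilityThreshold,
                      distance = config$distanceThreshold)),
    files["stats"], auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(statsOut$clustermap))
    jsonlite::write_json(list(
      linkage = statsOut$clustermap$linkage,
      rows = .hclustAsList(statsOut$clustermap$rowDendrogram),
      columns = .hclustAsList(statsOut$clustermap$colDendrogram)),
      files["clustermap"], auto_unbox = TRUE, digits = NA)

  digestable <- setdiff(names(files), "manifest")
  manifest <- list(
    package_version = as.character(utils::packageVersion("psyvis")),
    timestamp = format(Sys.time(), tz = "UTC"),
    seed = root,
    stage_seeds = list(generator = root, label_sample = root + 1L,
                       train = root + 2L, permutation = root + 3L),
    thresholds = list(probability = config$probabilityThreshold,
                      distance = config$distanceThreshold),
    min_reports = config$minReports,
    n_permutations = config$nPermutations,
    backend = backendName(src$backend),
    digests = as.list(tools::md5sum(files[digestable])))
  jsonlite::write_json(manifest, files["manifest"], auto_unbox = TRUE)

  invisible(list(corpus = corpus, summary = summary, embedded = embedded,
                 model = model, extraction = extraction, seedSet = seedSet,
                 V = V, stats = statsOut, files = files))
}

#' Serialise / restore a classifier as JSON
#'
#' The model artifact stores the weights, intercept, extraction threshold,
#' dimension and training report.
#'
#' @param model a [VisualSentenceClassifier-class].
#' @param path JSON file path.
#' @return `writeClassifierJSON` returns the path invisibly;
#'   `readClassifierJSON` returns the restored model.
#' @export
writeClassifierJSON <- function(model, path) {
  jsonlite::write_json(list(weights = model@weights,
                            intercept = model@intercept,
                            threshold = model@threshold,
                            dimension = model@dimension,
                            training_report = model@trainingReport),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeClassifierJSON
#' @export
readClassifierJSON <- function(path) {
  j <- jsonlite::fromJSON(path)
  new("VisualSentenceClassifier",
      weights = as.numeric(j$weights),
      intercept = as.numeric(j$intercept),
      threshold = as.numeric(j$threshold),
      dimension = as.integer(j$dimension),
      trainingReport = as.list(j$training_report))
}
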