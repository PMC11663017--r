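#' @include AllClasses.R AllGenerics.R
NULL

#' Remove markup from report text
#'
#' Narrative reports are archived with presentation markup (HTML-style tags,
#' entity references). This strips the tags, decodes entities, and preserves
#' the visible text in order, using a reference HTML parser. Empty input
#' yields empty output.
#'
#' @param raw_text character vector, possibly containing markup.
#' @return character vector of the same length, markup-free.
#' @examples
#' stripMarkup("<p>I saw colors.</p>")
#' stripMarkup("A &amp; B")
#' @export
stripMarkup <- function(raw_text) {
  vapply(raw_text, function(txt) {
    if (is.na(txt) || !nzchar(txt)) return("")
    if (!grepl("[<&]", txt)) return(txt)
    doc <- xml2::read_html(paste0("<html><body>", txt, "</body></html>"))
    xml2::xml_text(doc)
  }, character(1), USE.NAMES = FALSE)
}

#' Split markup-free text into sentences at period characters
#'
#' Segmentation splits at `.` with two exceptions: a period with a numeral
#' character immediately on both sides is a decimal point, not a boundary
#' ("2.5 grams"); and any period belonging to a run of two or more
#' consecutive periods is an ellipsis and is retained inside the current
#' segment ("it went on... forever"). Split periods are dropped; segments are
#' whitespace-trimmed and empty segments removed, so the result never
#' contains an empty string. By default only `.` terminates sentences;
#' additional terminator characters (for example `?` and `!`) can be opted in
#' via `extraTerminators`.
#'
#' @param text a single markup-free character string.
#' @param extraTerminators character vector of extra single characters that
#'   also end a sentence (no decimal/ellipsis exceptions apply to them);
#'   empty by default.
#' @return character vector of sentences, in order.
#' @examples
#' splitSentences("I took 2.5 grams. It hit fast.")
#' splitSentences("It went on... forever. Then stopped.")
#' @export
splitSentences <- function(text, extraTerminators = character(0)) {
  stopifnot(is.character(text), length(text) == 1L)
  if (is.na(text) || !nzchar(text)) return(character(0))
  ch <- strsplit(text, "", fixed = TRUE)[[1]]
  n <- length(ch)
  digit <- ch %in% as.character(0:9)
  is_dot <- ch == "."
  split_at <- ch %in% extraTerminators
  for (i in which(is_dot)) {
    if ((i > 1L && is_dot[i - 1L]) || (i < n && is_dot[i + 1L])) next
    if (i > 1L && i < n && digit[i - 1L] && digit[i + 1L]) next
    split_at[i] <- TRUE
  }
  grp <- cumsum(c(0L, split_at[-n]))
  keep <- !split_at
  if (!any(keep)) return(character(0))
  segs <- vapply(split(ch[keep], grp[keep]), paste, character(1),
                 collapse = "")
  segs <- trimws(segs)
  unname(segs[nzchar(segs)])
}

.substanceLabels <- function(substance) {
  if (is.list(substance)) {
    lapply(substance, function(s) {
      s <- trimws(as.character(unlist(s)))
      s[nzchar(s)]
    })
  } else {
    lapply(strsplit(as.character(substance), ";", fixed = TRUE),
           function(s) {
             s <- trimws(s)
             s[nzchar(s) & !is.na(s)]
           })
  }
}

#' Assemble a segmented corpus from raw reports
#'
#' Applies the preprocessing rules of the study design: reports associated
#' with more than one substance (or none) are excluded; markup is stripped;
#' text is segmented with [splitSentences()]; each sentence receives a
#' sentence identifier alongside its report identifier and substance label;
#' and only substances with at least `minReports` retained reports are kept
#' (default 100 distinct reports).
#'
#' @param reports data.frame with columns `report_id`, `substance`
#'   (a character vector, a `;`-separated string for multi-substance reports,
#'   or a list column of label vectors) and `text`.
#' @param catalogue data.frame with columns `substance`, `drug_class`,
#'   `is_psychedelic`; every retained substance must have an entry.
#' @param minReports minimum number of single-substance reports a substance
#'   needs to stay in the corpus.
#' @param extraTerminators passed to [splitSentences()].
#' @return a [ReportCorpus-class].
#' @examples
#' reps <- data.frame(report_id = c("r1", "r2"),
#'                    substance = c("LSD", "LSD"),
#'                    text = c("I saw colors. Walls moved.", "It was calm."))
#' cat <- data.frame(substance = "LSD", drug_class = "lysergamide",
#'                   is_psychedelic = TRUE)
#' buildCorpus(reps, cat, minReports = 1)
#' @export
buildCorpus <- function(reports, catalogue, minReports = 100,
                        extraTerminators = character(0)) {
  stopifnot(is.data.frame(reports),
            all(c("report_id", "substance", "text") %in% names(reports)),
            is.data.frame(catalogue))
  labels <- .substanceLabels(reports$substance)
  single <- lengths(labels) == 1L
  reports <- reports[single, , drop = FALSE]
  substance <- vapply(labels[single], `[`, character(1), 1L)

  unknown <- setdiff(unique(substance), catalogue$substance)
  if (length(unknown))
    stop("substance(s) missing from catalogue: ",
         paste(unknown, collapse = ", "))

  counts <- table(substance)
  keep_sub <- names(counts)[counts >= minReports]
  keep <- substance %in% keep_sub
  reports <- reports[keep, , drop = FALSE]
  substance <- substance[keep]

  clean <- stripMarkup(as.character(reports$text))
  segs <- lapply(clean, splitSentences, extraTerminators = extraTerminators)
  nseg <- lengths(segs)

  rep_tab <- data.frame(report_id = as.character(reports$report_id),
                        substance = substance,
                        n_sentences = nseg,
                        stringsAsFactors = FALSE)
  sent_tab <- data.frame(
    sentence_id = unlist(mapply(function(id, k) {
      if (k == 0L) character(0) else paste0(id, ".s", seq_len(k))
    }, rep_tab$report_id, nseg, SIMPLIFY = FALSE), use.names = FALSE),
    report_id = rep(rep_tab$report_id, nseg),
    substance = rep(substance, nseg),
    text = unlist(segs, use.names = FALSE),
    stringsAsFactors = FALSE)
  if (nrow(sent_tab) == 0L)
    sent_tab <- data.frame(sentence_id = character(0),
                           report_id = character(0),
                           substance = character(0),
                           text = character(0))
  cat_keep <- catalogue[, c("substance", "drug_class", "is_psychedelic")]
  new("ReportCorpus", reports = rep_tab, sentences = sent_tab,
      catalogue = as.data.frame(cat_keep))
}

#' Summarise a corpus at the substance level
#'
#' One row per substance with the number of reports and the mean, standard
#' deviation, minimum, median and maximum of sentences per report, sorted by
#' report count. The median number of reports per substance (a headline
#' dataset descriptor) is attached as attribute `median_reports`. A substance
#' with a single report gets a standard deviation of 0.
#'
#' @param corpus a [ReportCorpus-class].
#' @return data.frame with columns `substance`, `n_reports`,
#'   `mean_sentences`, `sd_sentences`, `min_sentences`, `median_sentences`,
#'   `max_sentences`, plus attribute `median_reports`.
#' @export
summarizeCorpus <- function(corpus) {
  stopifnot(is(corpus, "ReportCorpus"))
  reps <- reportTable(corpus)
  by_sub <- split(reps$n_sentences, reps$substance)
  out <- data.frame(
    substance = names(by_sub),
    n_reports = vapply(by_sub, length, integer(1)),
    mean_sentences = vapply(by_sub, mean, numeric(1)),
    sd_sentences = vapply(by_sub, function(x)
      if (length(x) < 2L) 0 else stats::sd(x), numeric(1)),
    min_sentences = vapply(by_sub, min, numeric(1)),
    median_sentences = vapply(by_sub, stats::median, numeric(1)),
    max_sentences = vapply(by_sub, max, numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  out <- out[order(-out$n_reports, out$substance), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "median_reports") <- stats::median(out$n_reports)
  out
}

## ---------------------------------------------------------------------------
## I/O and packaged fixtures
## ---------------------------------------------------------------------------

#' Read reports from JSON-lines
#'
#' One JSON object per line with fields `report_id`, `substance` (string or
#' array of strings) and `text`.
#'
#' @param path file path.
#' @return data.frame with a list column `substance`, ready for
#'   [buildCorpus()].
#' @export
readReportsJSONL <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  recs <- lapply(lines, jsonlite::fromJSON)
  data.frame(
    report_id = vapply(recs, function(r) as.character(r$report_id),
                       character(1)),
    substance = I(lapply(recs, function(r) as.character(r$substance))),
    text = vapply(recs, function(r) as.character(r$text), character(1)),
    stringsAsFactors = FALSE)
}

#' Read reports listed in a manifest of plain-text files
#'
#' @param manifest path to a TSV with columns `report_id`, `substance`,
#'   `path`; `path` entries are resolved relative to `dir` when given.
#' @param dir optional base directory for the `path` column.
#' @return data.frame ready for [buildCorpus()].
#' @export
readReportsManifest <- function(manifest, dir = dirname(manifest)) {
  man <- utils::read.delim(manifest, stringsAsFactors = FALSE)
  stopifnot(all(c("report_id", "substance", "path") %in% names(man)))
  txt <- vapply(man$path, function(p) {
    fp <- if (file.exists(p)) p else file.path(dir, p)
    paste(readLines(fp, warn = FALSE, encoding = "UTF-8"), collapse = "\n")
  }, character(1), USE.NAMES = FALSE)
  data.frame(report_id = as.character(man$report_id),
             substance = as.character(man$substance),
             text = txt, stringsAsFactors = FALSE)
}

#' Write the sentence table of a corpus as TSV
#'
#' @param corpus a [ReportCorpus-class].
#' @param path output file.
#' @export
writeSentencesTSV <- function(corpus, path) {
  utils::write.table(sentenceTable(corpus), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a substance catalogue TSV
#'
#' Expected columns: `substance`, `drug_class`, `is_psychedelic`.
#'
#' @param path file path.
#' @return data.frame.
#' @export
readSubstanceCatalogue <- function(path) {
  cat <- utils::read.delim(path, stringsAsFactors = FALSE,
                           check.names = FALSE)
  stopifnot(all(c("substance", "drug_class", "is_psychedelic") %in%
                  names(cat)))
  cat$is_psychedelic <- as.logical(cat$is_psychedelic)
  cat
}

#' Packaged substance catalogue (constructed class designations)
#'
#' The 103 substance names of the published corpus summary, with drug-class
#' designations and psychedelic flags constructed from substance chemistry:
#' exactly 30 substances are flagged psychedelic, following the rule that a
#' psychedelic belongs to (or contains compounds of) the tryptamine,
#' phenethylamine or lysergamide classes. The per-substance class assignments
#' are a synthetic reconstruction (the source database's own designations are
#' not redistributable), suitable for examples and pipeline demonstrations.
#'
#' @return data.frame with columns `substance`, `drug_class`,
#'   `is_psychedelic`.
#' @export
substanceClasses <- function() {
  readSubstanceCatalogue(system.file("extdata",
                                     "substance_classes_synthetic.tsv",
                                     package = "psyvis", mustWork = TRUE))
}

#' Packaged corpus summary table
#'
#' The published substance-level summary of the narrative report corpus:
#' number of reports and sentences-per-report statistics for each of the 103
#' substances. Useful as a reference input, for example to compute the median
#' number of reports per substance.
#'
#' @return data.frame with columns `substance`, `n_reports`,
#'   `mean_sentences`, `sd_sentences`, `min_sentences`, `median_sentences`,
#'   `max_sentences`.
#' @export
corpusSummaryTable <- function() {
  utils::read.delim(system.file("extdata", "corpus_summary.tsv",
                                package = "psyvis", mustWork = TRUE),
                    stringsAsFactors = FALSE, check.names = FALSE)
}
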