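test_that("markup stripping removes tags, decodes entities, keeps plain text", {
  expect_identical(stripMarkup("<p>I saw colors.</p>"), "I saw colors.")
  expect_identical(stripMarkup("plain text"), "plain text")
  expect_identical(stripMarkup("A &amp; B"), "A & B")
  expect_identical(stripMarkup(""), "")
  expect_identical(
    stripMarkup("<div><b>bold</b> and <i>italic</i> order</div>"),
    "bold and italic order")
})

test_that("sentence splitting honours the decimal and ellipsis exceptions", {
  expect_identical(splitSentences("I took 2.5 grams. It hit fast."),
                   c("I took 2.5 grams", "It hit fast"))
  expect_identical(splitSentences("It went on... forever. Then stopped."),
                   c("It went on... forever", "Then stopped"))
  expect_identical(splitSentences("One. Two. Three."),
                   c("One", "Two", "Three"))
  expect_identical(splitSentences(""), character(0))
  # decimal exception needs a numeral on BOTH sides
  expect_identical(splitSentences("I took 5. grams went down."),
                   c("I took 5", "grams went down"))
  # '?' and '!' split only when opted in
  expect_identical(splitSentences("Really? Yes."), c("Really? Yes"))
  expect_identical(splitSentences("Really? Yes.", extraTerminators = c("?", "!")),
                   c("Really", "Yes"))
})

test_that("splitting never yields empty strings and preserves characters", {
  set.seed(42)
  for (i in 1:1000) {
    x <- fuzzString()
    segs <- splitSentences(x)
    expect_false(any(segs == ""))
    # rejoining preserves every non-period, non-whitespace character in order
    expect_identical(gsub("[ .]", "", paste(segs, collapse = "")),
                     gsub("[ .]", "", x))
  }
})

test_that("corpus assembly applies the exclusion and inclusion rules", {
  mk <- function(sub, n, multi = FALSE) {
    data.frame(report_id = paste0(sub, seq_len(n)),
               substance = if (multi) paste0(sub, ";other") else sub,
               text = "I saw colors. It was calm.",
               stringsAsFactors = FALSE)
  }
  cat <- data.frame(substance = c("A", "B", "C", "other"),
                    drug_class = "x", is_psychedelic = FALSE)
  reps <- rbind(mk("A", 120), mk("B", 99), mk("C", 150))
  corpus <- buildCorpus(reps, cat, minReports = 100)
  expect_setequal(substanceNames(corpus), c("A", "C"))

  # a multi-substance report never enters the corpus
  reps2 <- rbind(mk("A", 120), mk("A", 1, multi = TRUE))
  corpus2 <- buildCorpus(reps2, cat, minReports = 100)
  expect_equal(nrow(reportTable(corpus2)), 120)

  # unknown substances are an error naming the substance
  bad <- mk("Zeta", 5)
  expect_error(buildCorpus(bad, cat, minReports = 1), "Zeta")
})

test_that("corpus segmentation matches the generator ground truth", {
  q <- quickSyn(nSubstances = 3, reportsPerSubstance = 8, seed = 11,
                embed = FALSE)
  reps <- reportTable(q$corpus)
  # per-substance report counts match the configuration
  expect_true(all(table(reps$substance) == 8))
  # sentence counts equal the sum of per-report segment counts
  expect_equal(nrow(sentenceTable(q$corpus)), sum(reps$n_sentences))
  # and equal the generator's sentence-level ground truth
  gt_counts <- table(q$syn$groundTruth$report_id)
  expect_equal(unname(reps$n_sentences),
               as.integer(gt_counts[reps$report_id]))
})

test_that("substance-level summaries report the five order statistics", {
  reps <- data.frame(
    report_id = c("a1", "a2", "a3", "b1"),
    substance = c("A", "A", "A", "B"),
    text = c("One. Two.", "One. Two. Three. Four.",
             "One. Two. Three. Four. Five. Six.", "Solo."),
    stringsAsFactors = FALSE)
  cat <- data.frame(substance = c("A", "B"), drug_class = "x",
                    is_psychedelic = FALSE)
  s <- summarizeCorpus(buildCorpus(reps, cat, minReports = 1))
  a <- s[s$substance == "A", ]
  expect_equal(a$mean_sentences, 4)
  expect_equal(a$median_sentences, 4)
  expect_equal(a$min_sentences, 2)
  expect_equal(a$max_sentences, 6)
  # degenerate single-report substance: sd reported as 0
  expect_equal(s$sd_sentences[s$substance == "B"], 0)
  expect_equal(attr(s, "median_reports"), 2)
})

test_that("JSON-lines report files round-trip into a corpus", {
  path <- withr::local_tempfile(fileext = ".jsonl")
  writeLines(c(
    '{"report_id":"r1","substance":"A","text":"<p>I saw colors.</p> Nice."}',
    '{"report_id":"r2","substance":["A","B"],"text":"Two labels."}',
    '{"report_id":"r3","substance":"A","text":"Calm. Quiet."}'), path)
  reps <- readReportsJSONL(path)
  expect_equal(nrow(reps), 3)
  cat <- data.frame(substance = c("A", "B"), drug_class = "x",
                    is_psychedelic = FALSE)
  corpus <- buildCorpus(reps, cat, minReports = 1)
  # the two-label report is excluded; markup stripped before segmentation
  expect_equal(nrow(reportTable(corpus)), 2)
  expect_identical(sentenceTable(corpus)$text[1:2],
                   c("I saw colors", "Nice"))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeSentencesTSV(corpus, tsv)
  expect_equal(nrow(utils::read.delim(tsv)), 4)
})

test_that("packaged catalogues are consistent", {
  classes <- substanceClasses()
  summary <- corpusSummaryTable()
  expect_equal(nrow(classes), 103)
  expect_equal(sum(classes$is_psychedelic), 30)
  expect_setequal(classes$substance, summary$substance)
})
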