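test_that("lemmatization normalizes spelling and inflection without stemming", {
  ann <- annotate_sentence("Patients were randomised")
  expect_true("randomize" %in% ann$lemmas)
  expect_true("be" %in% ann$lemmas)

  # lemmatization, not stemming: derivational forms stay distinct
  expect_equal(lemmatize_token("randomized"), "randomize")
  expect_equal(lemmatize_token("randomization"), "randomization")
  expect_equal(lemmatize_token("randomisation"), "randomization")
  expect_equal(lemmatize_token("hospitalisation"), "hospitalization")
  expect_equal(lemmatize_token("criteria"), "criterion")
  expect_equal(lemmatize_token("analysed"), "analyze")
  expect_equal(lemmatize_token("generated"), "generate")
  expect_equal(lemmatize_token("stratified"), "stratify")

  expect_error(annotate_sentence(""), "empty")
})

test_that("token spans are within-sentence, aligned and increasing", {
  ann <- annotate_sentence("Randomisation was stratified by centre (blocks of 4).")
  expect_equal(length(ann$lemmas), nrow(ann$tokens))
  expect_equal(length(ann$pos), nrow(ann$tokens))
  expect_true(all(ann$tokens$start < ann$tokens$end))
  expect_true(all(diff(ann$tokens$start) > 0))
  expect_true(all(ann$tokens$end <= nchar(ann$sentence)))
  expect_identical(
    substring(ann$sentence, ann$tokens$start + 1L, ann$tokens$end),
    ann$tokens$surface)
})

test_that("entity tagging finds registry ids, ratios, CIs, orgs and locations", {
  e1 <- tag_entities(annotate_sentence(
    "The trial was registered with ClinicalTrials.gov, NCT01148849."))
  expect_true(any(e1$kind == "REGISTRY_ID" & e1$normalized == "NCT01148849"))

  e2 <- tag_entities(annotate_sentence(
    "Patients were randomly assigned in a 1 : 1 ratio."))
  expect_true(any(e2$kind == "ALLOCATION_RATIO" & e2$normalized == "1:1"))

  e3 <- tag_entities(annotate_sentence(
    "The mean difference was 4 points (95% CI, 2 to 7)."))
  expect_true("CONFIDENCE_INTERVAL" %in% e3$kind)

  e4 <- tag_entities(annotate_sentence(
    "The World Health Organization office in New York approved the protocol."))
  expect_true(any(e4$kind == "ORG" & e4$normalized == "World Health Organization"))
  expect_true(any(e4$kind == "LOCATION" & e4$normalized == "New York"))

  e5 <- tag_entities(annotate_sentence(
    "Recruitment ran between March 2014 and June 2016 with P = 0.03."))
  expect_true("DATE_RANGE" %in% e5$kind)
  expect_true("P_VALUE" %in% e5$kind)
})

test_that("entity spans lie inside the sentence and re-match their pattern", {
  sentences <- c(
    "Registered as ISRCTN12345678 and EudraCT 2014-001234-56.",
    "Allocation used a 2:1 ratio with 95% confidence interval reporting.",
    "Enrolment between January 2010 and May 2012 in Canada (NCT00000001).")
  for (s in sentences) {
    ann <- annotate_sentence(s)
    ents <- tag_entities(ann)
    expect_gt(nrow(ents), 0)
    expect_true(all(ents$start >= 0 & ents$end <= nchar(s)))
    expect_true(all(nchar(ents$normalized) > 0))
    # within one kind, mentions never overlap
    for (k in unique(ents$kind)) {
      ek <- ents[ents$kind == k, ]
      if (nrow(ek) > 1) expect_true(all(ek$start[-1] >= ek$end[-nrow(ek)]))
    }
  }
})

test_that("cue matching agrees with a brute-force scan on generated sentences", {
  cues <- load_cue_patterns()
  patterns <- cues[cues$kind %in% c("lemma", "regex"),
                   c("cue_id", "kind", "pattern")]
  # lemma phrases with ';' are conjunctions at detector level; for the raw
  # matcher each phrase is matched independently
  patterns$pattern <- vapply(strsplit(patterns$pattern, ";"),
                             function(x) x[[1]], "")
  set.seed(42)
  n_checked <- 0L
  for (seed in sample.int(5000, 8)) {
    ms <- build_manuscript(realize_manuscript(sample_manuscript_plan(seed))$text)
    for (sec in ms$sections) {
      for (i in seq_len(nrow(sec$sentences))) {
        ann <- annotate_sentence(sec$sentences[i, ])
        hits <- match_cues(ann, patterns)
        expect_identical(nrow(hits), brute_force_cue_hits(ann, patterns))
        n_checked <- n_checked + 1L
      }
    }
  }
  expect_gt(n_checked, 200L)
})

test_that("all cue hits are reported, including overlaps, and bad regexes are named", {
  ann <- annotate_sentence("The sample size was calculated to provide 90% power.")
  pats <- data.frame(cue_id = c("size", "power", "size-again"),
                     kind = c("lemma", "lemma", "regex"),
                     pattern = c("sample size", "power", "(?i)sample size"),
                     stringsAsFactors = FALSE)
  hits <- match_cues(ann, pats)
  expect_equal(nrow(hits), 3L)
  expect_setequal(hits$cue_id, c("size", "power", "size-again"))

  bad <- data.frame(cue_id = "broken", kind = "regex", pattern = "([",
                    stringsAsFactors = FALSE)
  expect_error(match_cues(ann, bad), "broken")
})
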