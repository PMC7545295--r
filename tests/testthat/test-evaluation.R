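mk_match <- function(item_id, status, matched = NULL, code = NULL) {
  consortcheck:::new_item_match(item_id, status, matched,
                                notification_code = code, message = "")
}
sent <- function(section, index, text = "s") {
  data.frame(section_label = section, index = index, text = text,
             stringsAsFactors = FALSE)
}
truth <- function(present, section = character(0), index = integer(0)) {
  list(present = present,
       sentences = data.frame(section_label = section, index = index,
                              stringsAsFactors = FALSE))
}

test_that("correctness covers the full outcome table", {
  # extracted sentence agrees with truth
  expect_true(score_item_on_article(
    mk_match("19", "found", sent("RESULTS", 4L)), truth(TRUE, "RESULTS", 4L)))
  # notification with a correctly located sentence counts as a detection
  expect_true(score_item_on_article(
    mk_match("14a", "notification", sent("METHODS", 2L), "WRONG_SECTION"),
    truth(TRUE, "METHODS", 2L)))
  # null finding on a truly absent item
  expect_true(score_item_on_article(
    mk_match("19", "not_found"), truth(FALSE)))
  # extraction of the wrong sentence
  expect_false(score_item_on_article(
    mk_match("19", "found", sent("RESULTS", 1L)), truth(TRUE, "RESULTS", 4L)))
  # miss of a present item
  expect_false(score_item_on_article(
    mk_match("19", "not_found"), truth(TRUE, "RESULTS", 4L)))
  # spurious extraction on an absent item
  expect_false(score_item_on_article(
    mk_match("19", "found", sent("RESULTS", 1L)), truth(FALSE)))
  # items outside the accuracy set are not scoreable
  expect_error(score_item_on_article(
    mk_match("13a", "found", sent("RESULTS", 0L)), truth(TRUE, "RESULTS", 0L)),
    "excluded")
})

test_that("per-item accuracy is exact division with a degenerate-input error", {
  scores <- data.frame(
    article_id = rep(sprintf("a%d", 1:10), times = 2),
    item_id = rep(c("4a", "19"), each = 10),
    correct = c(rep(TRUE, 9), FALSE, rep(TRUE, 10)),
    stringsAsFactors = FALSE)
  tab <- per_item_accuracy(scores)
  expect_equal(tab$accuracy[tab$item_id == "4a"], 0.9)
  expect_equal(tab$accuracy[tab$item_id == "19"], 1.0)
  expect_error(per_item_accuracy(scores[0, ]))
})

test_that("accuracy banding puts the 0.90 boundary in the middle band", {
  tab <- data.frame(item_id = c("a", "b", "c", "d", "e"),
                    accuracy = c(0.79, 0.80, 0.85, 0.90, 0.91))
  bands <- bin_accuracies(tab)
  expect_equal(unname(bands["LT80"]), 1L)
  expect_equal(unname(bands["B80_90"]), 3L)
  expect_equal(unname(bands["GT90"]), 1L)
  expect_equal(sum(bands), nrow(tab))
})

test_that("triage partitions sentences and matches a hand-enumerated case", {
  # three articles; item 19 truth in a1 and a2 only, item 4a truth in all
  reg_item <- function(id, status, matched = NULL) mk_match(id, status, matched)
  empty_matches <- function() {
    ms <- lapply(load_registry()$item_id, function(id) {
      st <- if (id %in% c("2a", "22", "17b")) "not_implemented" else "not_found"
      mk_match(id, st)
    })
    names(ms) <- load_registry()$item_id
    ms
  }
  mk_report <- function(id, overrides) {
    ms <- empty_matches()
    for (k in names(overrides)) ms[[k]] <- overrides[[k]]
    structure(list(id = id, matches = ms, warnings = character(0)),
              class = "consort_report")
  }
  reports <- list(
    # a1: 19 correct, 4a correct -> 2 positives
    mk_report("a1", list("19" = reg_item("19", "found", sent("RESULTS", 0L)),
                         "4a" = reg_item("4a", "found", sent("METHODS", 1L)))),
    # a2: 19 extracts the wrong sentence (negative) and misses truth
    # (undetected); 4a correct
    mk_report("a2", list("19" = reg_item("19", "found", sent("RESULTS", 5L)),
                         "4a" = reg_item("4a", "found", sent("METHODS", 1L)))),
    # a3: 4a truth missed entirely -> undetected
    mk_report("a3", list()))
  truths <- list(
    list(article_id = "a1", items = list(
      "19" = truth(TRUE, "RESULTS", 0L), "4a" = truth(TRUE, "METHODS", 1L))),
    list(article_id = "a2", items = list(
      "19" = truth(TRUE, "RESULTS", 0L), "4a" = truth(TRUE, "METHODS", 1L))),
    list(article_id = "a3", items = list("4a" = truth(TRUE, "METHODS", 0L))))

  tri <- triage_sentences(reports, truths)
  # hand enumeration: positives = a1x2 + a2(4a) = 3; negatives = a2(19 wrong
  # sentence) = 1; undetected = a2(19 truth) + a3(4a truth) = 2
  expect_equal(tri$positive, 3L)
  expect_equal(tri$negative, 1L)
  expect_equal(tri$undetected, 2L)
  expect_equal(tri$proportion_bad, 3 / 6)

  # invariant to article order
  tri_rev <- triage_sentences(rev(reports), rev(truths))
  expect_equal(tri_rev, tri)

  # misaligned corpora are rejected
  expect_error(triage_sentences(reports[1:2], truths), "aligned")
})

test_that("perfect and null detectors hit the triage extremes", {
  corpus <- withr::local_tempdir()
  generate_corpus(4, seed = 12, outdir = corpus)
  truths <- read_ground_truth(file.path(corpus, "truth.json"))
  reports <- check_corpus(corpus)
  tri <- triage_sentences(reports, truths)
  expect_equal(tri$negative + tri$undetected, 0L)
  expect_equal(tri$proportion_bad, 0)

  # a detector that extracts nothing leaves every truth sentence undetected
  null_reports <- lapply(reports, function(r) {
    r$matches <- lapply(r$matches, function(m) {
      if (m$status %in% c("found", "notification")) mk_match(m$item_id, "not_found")
      else m
    })
    r
  })
  tri0 <- triage_sentences(null_reports, truths)
  expect_equal(tri0$positive, 0L)
  expect_equal(tri0$proportion_bad, 1)
})

test_that("accuracy equals a brute-force recount on a generated corpus", {
  corpus <- withr::local_tempdir()
  generate_corpus(6, seed = 33, outdir = corpus)
  truths <- read_ground_truth(file.path(corpus, "truth.json"))
  reports <- check_corpus(corpus)
  tab <- per_item_accuracy(evaluate_corpus(reports, truths))
  oracle <- brute_force_accuracy(reports, truths)
  expect_equal(stats::setNames(tab$accuracy, tab$item_id), oracle[tab$item_id])
})

test_that("ground truth files round-trip", {
  corpus <- withr::local_tempdir()
  generate_corpus(2, seed = 5, outdir = corpus)
  path <- file.path(corpus, "truth.json")
  truths <- read_ground_truth(path)
  path2 <- file.path(corpus, "truth2.json")
  write_ground_truth(truths, path2)
  expect_identical(read_ground_truth(path2), truths)
})
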