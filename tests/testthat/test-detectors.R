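test_that("a randomised-trial title is matched to item 1a", {
  ms <- build_manuscript(MINI_MANUSCRIPT)
  m <- detect_item(ms, "1a")
  expect_equal(m$status, "found")
  expect_equal(m$matched$section_label, "TITLE")
  expect_match(m$matched$text, "Randomised Controlled Trial")

  ms2 <- build_manuscript(sub("^.*Randomised Controlled Trial",
                              "Long-Term Outcomes of Epralastat Therapy",
                              MINI_MANUSCRIPT))
  expect_equal(detect_item(ms2, "1a")$status, "not_found")
})

test_that("a trial-design sentence without a ratio raises MISSING_ALLOCATION_RATIO", {
  txt <- paste(
    "A Randomized Trial of PMR versus SCS",
    "", "Methods",
    "Patients were randomly assigned to PMR or SCS in this parallel-group trial.",
    sep = "\n")
  m <- detect_item(build_manuscript(txt), "3a")
  expect_equal(m$status, "notification")
  expect_equal(m$notification_code, "MISSING_ALLOCATION_RATIO")
  expect_gt(nrow(m$matched), 0)

  # with the ratio stated, the same sentence is a plain find
  m2 <- detect_item(build_manuscript(sub("parallel-group trial",
                                         "parallel-group trial with a 1:1 ratio",
                                         txt)), "3a")
  expect_equal(m2$status, "found")
})

test_that("flow numbers confined to a figure caption raise CHECK_FIGURE_OR_TABLE", {
  real <- spirit_like_fixture()
  rep <- run_checklist(build_manuscript(real$text))
  for (id in c("13a", "13b")) {
    expect_equal(rep$matches[[id]]$status, "notification")
    expect_equal(rep$matches[[id]]$notification_code, "CHECK_FIGURE_OR_TABLE")
    expect_match(rep$matches[[id]]$message, "Figure 1")
  }
  # the analysed-denominator sentence is in the body, so 16 is a plain find
  expect_equal(rep$matches[["16"]]$status, "found")
})

test_that("the case-study-style fixture yields exactly three notifications", {
  real <- spirit_like_fixture()
  rep <- run_checklist(build_manuscript(real$text))
  notif <- names(Filter(function(m) m$status == "notification", rep$matches))
  expect_setequal(notif, c("3a", "13a", "13b"))
  expect_equal(rep$matches[["3a"]]$notification_code, "MISSING_ALLOCATION_RATIO")
})

test_that("evidence found only outside the expected section raises WRONG_SECTION", {
  # a recruitment-dates sentence (Results-expected 14a) placed in Methods
  real <- realize_manuscript(make_controlled_plan(303, misplace = "14a"))
  rep <- run_checklist(build_manuscript(real$text))
  m <- rep$matches[["14a"]]
  expect_equal(m$status, "notification")
  expect_equal(m$notification_code, "WRONG_SECTION")
  expect_match(m$message, "Results")
  expect_false("RESULTS" %in% m$matched$section_label)

  # correctly placed evidence passes the placement check unchanged
  m_ok <- rep$matches[["4a"]]
  expect_equal(m_ok$status, "found")

  # placement assessment never touches title-scope items
  m1a <- assess_section_placement(rep$matches[["1a"]], "1a")
  expect_equal(m1a$status, rep$matches[["1a"]]$status)
})

test_that("every report has 37 matches with the registry status partition", {
  rep <- run_checklist(build_manuscript(MINI_MANUSCRIPT))
  expect_length(rep$matches, 37L)
  expect_setequal(names(rep$matches), load_registry()$item_id)
  statuses <- vapply(rep$matches, `[[`, "", "status")
  expect_equal(sum(statuses == "not_implemented"), 3L)
  expect_setequal(names(statuses)[statuses == "not_implemented"],
                  c("2a", "22", "17b"))
  expect_equal(sum(table(statuses)), 37L)

  # matched sentences are recoverable from the manuscript by coordinates
  ms <- build_manuscript(MINI_MANUSCRIPT)
  for (m in rep$matches) {
    if (!nrow(m$matched)) next
    for (j in seq_len(nrow(m$matched))) {
      sec_lab <- m$matched$section_label[j]
      if (sec_lab == "TITLE") {
        expect_equal(m$matched$text[j], ms$title)
      } else {
        sec <- Filter(function(s) s$label == sec_lab, ms$sections)[[1]]
        expect_equal(sec$sentences$text[sec$sentences$index ==
                                          m$matched$index[j]],
                     m$matched$text[j])
      }
    }
  }
})

test_that("an empty manuscript yields only null findings", {
  rep <- run_checklist(build_manuscript(""))
  statuses <- vapply(rep$matches, `[[`, "", "status")
  expect_equal(sum(statuses == "not_implemented"), 3L)
  expect_equal(sum(statuses == "not_found"), 34L)
})

test_that("detection is deterministic and local to sentences", {
  real <- realize_manuscript(sample_manuscript_plan(77))
  ms <- build_manuscript(real$text)
  r1 <- run_checklist(ms)
  r2 <- run_checklist(ms)
  expect_identical(r1$matches, r2$matches)

  # deleting an unmatched (distractor) sentence never flips found -> not_found
  matched_texts <- unlist(lapply(r1$matches, function(m) m$matched$text))
  meth <- Filter(function(s) s$label == "METHODS", ms$sections)[[1]]
  unmatched <- setdiff(meth$sentences$text, matched_texts)
  expect_gt(length(unmatched), 0)
  pruned_text <- sub(unmatched[1], "", real$text, fixed = TRUE)
  r3 <- run_checklist(build_manuscript(pruned_text))
  found_before <- names(Filter(function(m) m$status == "found", r1$matches))
  for (id in found_before) {
    expect_true(r3$matches[[id]]$status %in% c("found", "notification"),
                label = paste("item", id, "still detected after pruning"))
  }
})

test_that("reference lists do not trigger detectors", {
  txt <- paste(
    "A Study Title Without the Key Phrase",
    "", "Methods", "The visits took place monthly.",
    "", "References",
    "1. Someone A. A randomised trial of everything: sample size and power. Lancet. 2001;357:1-8.",
    sep = "\n")
  rep <- run_checklist(build_manuscript(txt))
  expect_equal(rep$matches[["1a"]]$status, "not_found")
  expect_equal(rep$matches[["7a"]]$status, "not_found")
})
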