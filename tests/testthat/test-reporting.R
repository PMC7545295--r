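test_that("JSON serialization round-trips reports exactly", {
  set.seed(7)
  for (seed in sample.int(5000, 6)) {
    rep <- run_checklist(
      build_manuscript(realize_manuscript(sample_manuscript_plan(seed))$text),
      id = paste0("doc_", seed))
    rep2 <- parse_json_report(to_json_report(rep))
    expect_identical(rep2$id, rep$id)
    expect_identical(rep2$warnings, rep$warnings)
    expect_identical(rep2$matches, rep$matches)
  }
})

test_that("JSON carries notification codes and section names", {
  real <- realize_manuscript(make_controlled_plan(909, misplace = "14a"))
  rep <- run_checklist(build_manuscript(real$text))
  j <- to_json_report(rep)
  parsed <- jsonlite::fromJSON(j, simplifyVector = FALSE)
  m14a <- parsed$matches[["14a"]]
  expect_equal(m14a$status, "notification")
  expect_equal(m14a$notification_code, "WRONG_SECTION")
  expect_match(m14a$message, "Results")          # expected section
  expect_match(m14a$message, "Introduction")     # section where it was found
})

test_that("checklist documents carry one row per item in CONSORT order", {
  rep <- run_checklist(build_manuscript(MINI_MANUSCRIPT), id = "mini")
  md <- withr::local_tempfile(fileext = ".md")
  render_checklist_doc(rep, md, "markdown")
  lines <- readLines(md)
  rows <- grep("^\\| [0-9]", lines, value = TRUE)
  expect_length(rows, 37L)
  expect_match(rows[1], "^\\| 1a \\|")
  expect_match(rows[grep("^\\| 1a", rows)], "Randomised Controlled Trial")
  expect_match(rows[grep("^\\| 2a", rows)], "Not implemented")
  expect_match(rows[grep("^\\| 19", rows)], "RESULTS")
})

test_that("markdown and docx renderings agree cell for cell", {
  rep <- run_checklist(build_manuscript(MINI_MANUSCRIPT), id = "mini")
  docx <- withr::local_tempfile(fileext = ".docx")
  render_checklist_doc(rep, docx, "docx")
  # the docx is a standard zip container with the wordprocessing part
  expect_setequal(utils::unzip(docx, list = TRUE)$Name,
                  c("[Content_Types].xml", "_rels/.rels", "word/document.xml"))
  xf <- utils::unzip(docx, "word/document.xml", exdir = withr::local_tempdir())
  xml <- readChar(xf, file.size(xf))
  for (r in consortcheck:::checklist_rows(rep)) {
    cell <- consortcheck:::xml_escape(r$reported)
    expect_true(grepl(cell, xml, fixed = TRUE),
                label = paste("docx carries cell for item", r$item_id))
  }
})

test_that("notifications document lists each notification or an empty marker", {
  real <- spirit_like_fixture()
  rep <- run_checklist(build_manuscript(real$text))
  md <- withr::local_tempfile(fileext = ".md")
  render_notifications(rep, md, "markdown")
  entries <- grep("^- ", readLines(md), value = TRUE)
  expect_length(entries, 3L)
  expect_true(any(grepl("MISSING_ALLOCATION_RATIO", entries)))

  quiet <- run_checklist(build_manuscript(""))
  quiet$matches <- lapply(quiet$matches, function(m) m)  # no notifications
  md2 <- withr::local_tempfile(fileext = ".md")
  render_notifications(quiet, md2, "markdown")
  expect_true(any(grepl("No notifications", readLines(md2))))
})

test_that("check_document writes the full artifact set atomically", {
  real <- realize_manuscript(sample_manuscript_plan(404))
  input <- file.path(withr::local_tempdir(), "paper.txt")
  writeLines(real$text, input)
  rep <- check_document(input, quiet = TRUE)
  files <- attr(rep, "files")
  expect_setequal(basename(files),
                  c("paper.consort.md", "paper.notifications.md",
                    "paper.report.json"))
  expect_true(all(file.exists(files)))
  # JSON on disk parses back to the in-memory report
  rep2 <- parse_json_report(files[grepl("report.json", files)])
  expect_identical(rep2$matches, rep$matches)

  expect_error(check_document(file.path(tempdir(), "absent.txt")), "not found")
})
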