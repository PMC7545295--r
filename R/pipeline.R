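# Orchestration: ingest -> detect -> report for one document or a corpus
# directory, with atomic output writes (temp file then rename).

ingest_document <- function(input) {
  if (!file.exists(input)) stop("input not found: ", input, call. = FALSE)
  raw <- if (grepl("\\.pdf$", input, ignore.case = TRUE)) {
    extract_pdf_text(input)
  } else {
    parse_plaintext(paste(readLines(input, encoding = "UTF-8", warn = FALSE),
                          collapse = "\n"))
  }
  segment_sections(raw)
}

move_into_place <- function(tmp, dest) {
  if (!file.rename(tmp, dest)) {  # rename can fail across filesystems
    file.copy(tmp, dest, overwrite = TRUE)
    unlink(tmp)
  }
  dest
}

#' Check one manuscript end to end
#'
#' Runs the four-step pipeline — text extraction, section/sentence
#' segmentation, per-item detection, report generation — and writes the
#' requested artifacts next to each other in `outdir`:
#' `<stem>.consort.<ext>`, `<stem>.notifications.<ext>`, and
#' `<stem>.report.json`. Output files are written to a temporary path and
#' moved into place, so failures never leave partial files.
#'
#' @param input Path to a `.txt` manuscript (plain-text dialect) or a
#'   text-layer `.pdf`.
#' @param outdir Output directory (default: directory of `input`).
#' @param format `"markdown"` or `"docx"` for the two documents.
#' @param json Also write the JSON report (default `TRUE`).
#' @param quiet Suppress the per-step log lines.
#' @return The `consort_report`, invisibly, with an attribute `files`
#'   naming the written artifacts.
#' @export
check_document <- function(input, outdir = dirname(input),
                           format = c("markdown", "docx"), json = TRUE,
                           quiet = FALSE) {
  format <- match.arg(format)
  say <- function(...) if (!quiet) message(sprintf(...))
  ms <- ingest_document(input)
  n_sent <- sum(vapply(ms$sections, function(s) nrow(s$sentences), 0L))
  say("ingest: %d section(s), %d sentence(s), %d caption(s)",
      length(ms$sections), n_sent, length(ms$captions))
  report <- run_checklist(ms, id = basename(input))
  statuses <- vapply(report$matches, `[[`, "", "status")
  say("detect: %d found, %d notification(s), %d not found, %d not implemented",
      sum(statuses == "found"), sum(statuses == "notification"),
      sum(statuses == "not_found"), sum(statuses == "not_implemented"))

  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  stem <- sub("\\.[^.]+$", "", basename(input))
  ext <- if (format == "docx") "docx" else "md"
  files <- character(0)
  write_atomic <- function(dest, writer) {
    tmp <- tempfile(tmpdir = outdir)
    writer(tmp)
    move_into_place(tmp, dest)
    dest
  }
  files <- c(files, write_atomic(
    file.path(outdir, sprintf("%s.consort.%s", stem, ext)),
    function(f) render_checklist_doc(report, f, format)))
  files <- c(files, write_atomic(
    file.path(outdir, sprintf("%s.notifications.%s", stem, ext)),
    function(f) render_notifications(report, f, format)))
  if (json) {
    files <- c(files, write_atomic(
      file.path(outdir, sprintf("%s.report.json", stem)),
      function(f) to_json_report(report, f)))
  }
  say("report: wrote %s", paste(basename(files), collapse = ", "))
  attr(report, "files") <- files
  invisible(report)
}

#' Run the checker over a generated corpus directory
#'
#' Reads every `doc_*.txt` in `dir` (as written by [generate_corpus()]),
#' runs the full checklist on each, and returns the reports with ids
#' matching the corpus ground truth.
#'
#' @param dir Corpus directory.
#' @return List of `consort_report`.
#' @export
check_corpus <- function(dir) {
  files <- sort(list.files(dir, pattern = "^doc_.*\\.txt$", full.names = TRUE))
  if (!length(files)) stop("no doc_*.txt files in ", dir, call. = FALSE)
  lapply(files, function(f) {
    ms <- ingest_document(f)
    run_checklist(ms, id = sub("\\.txt$", "", basename(f)))
  })
}

#' Evaluate a corpus directory against its ground truth
#'
#' Convenience wrapper: runs [check_corpus()], scores it with
#' [evaluate_corpus()], and returns the per-item accuracy table, band
#' counts, and triage result.
#'
#' @param dir Corpus directory containing `doc_*.txt` and `truth.json`.
#' @param truth_file Override path to the ground-truth JSON.
#' @param split Restrict to documents of this split (requires
#'   `manifest.json`); `NULL` uses all documents.
#' @return List with `accuracy` (data frame), `bands` (named counts),
#'   `triage` (list), `scores` (per article-item data frame).
#' @export
evaluate_corpus_dir <- function(dir, truth_file = file.path(dir, "truth.json"),
                                split = NULL) {
  truths <- read_ground_truth(truth_file)
  reports <- check_corpus(dir)
  if (!is.null(split)) {
    manifest <- jsonlite::fromJSON(file.path(dir, "manifest.json"),
                                   simplifyVector = FALSE)
    keep <- vapply(Filter(function(d) d$split == split, manifest$documents),
                   `[[`, "", "id")
    reports <- Filter(function(r) r$id %in% keep, reports)
    truths <- Filter(function(tr) tr$article_id %in% keep, truths)
  }
  scores <- evaluate_corpus(reports, truths)
  acc <- per_item_accuracy(scores)
  list(accuracy = acc, bands = bin_accuracies(acc),
       triage = triage_sentences(reports, truths), scores = scores)
}
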