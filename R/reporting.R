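# Report serialization and document rendering. The JSON report is the
# lossless machine-readable artifact; the checklist and notifications
# documents are row-model renderings shared between markdown and docx so
# that cell text is format-independent.

REPORT_SCHEMA_VERSION <- "1.0"

#' Serialize a checklist report to JSON
#'
#' Lossless: [parse_json_report()] reconstructs an identical report
#' (`parse(serialize(x))` equals `x`).
#'
#' @param report A `consort_report` from [run_checklist()].
#' @param path Optional file path; when given the JSON is written there.
#' @return JSON text (a character scalar), invisibly when `path` is given.
#' @export
to_json_report <- function(report, path = NULL) {
  stopifnot(inherits(report, "consort_report"))
  body <- list(
    schema_version = REPORT_SCHEMA_VERSION,
    id = report$id,
    warnings = as.list(report$warnings),
    matches = lapply(report$matches, function(m) {
      list(item_id = m$item_id,
           status = m$status,
           matched = lapply(seq_len(nrow(m$matched)), function(i) {
             list(section_label = m$matched$section_label[i],
                  index = m$matched$index[i],
                  text = m$matched$text[i])
           }),
           notification_code = if (is.null(m$notification_code)) NULL else m$notification_code,
           message = m$message)
    }))
  json <- jsonlite::toJSON(body, auto_unbox = TRUE, null = "null", pretty = TRUE)
  if (!is.null(path)) {
    writeLines(json, path, useBytes = TRUE)
    return(invisible(as.character(json)))
  }
  as.character(json)
}

#' @rdname to_json_report
#' @param json JSON text or a path to a JSON report file.
#' @export
parse_json_report <- function(json) {
  if (length(json) == 1L && !grepl("^\\s*\\{", json) && file.exists(json)) {
    json <- paste(readLines(json, encoding = "UTF-8"), collapse = "\n")
  }
  x <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  matches <- lapply(x$matches, function(m) {
    md <- if (length(m$matched)) {
      data.frame(
        section_label = vapply(m$matched, `[[`, "", "section_label"),
        index = vapply(m$matched, function(e) as.integer(e$index), 0L),
        text = vapply(m$matched, `[[`, "", "text"),
        stringsAsFactors = FALSE)
    } else {
      data.frame(section_label = character(0), index = integer(0),
                 text = character(0), stringsAsFactors = FALSE)
    }
    new_item_match(m$item_id, m$status, md,
                   notification_code = m$notification_code,
                   message = m$message)
  })
  names(matches) <- vapply(x$matches, `[[`, "", "item_id")
  structure(list(id = x$id,
                 matches = matches,
                 warnings = as.character(unlist(x$warnings))),
            class = "consort_report")
}

truncate_excerpt <- function(text, width = 300L) {
  ifelse(nchar(text) > width, paste0(substr(text, 1L, width - 1L), "…"), text)
}

# shared row model: one row per checklist item, format-independent cell text
checklist_rows <- function(report) {
  reg <- load_registry()
  rows <- lapply(seq_len(nrow(reg)), function(i) {
    item <- reg[i, , drop = FALSE]
    m <- report$matches[[item$item_id]]
    loc <- switch(m$status,
      not_implemented = "Not implemented",
      not_found = "Not found",
      notification = if (nrow(m$matched)) {
        sprintf("%s: %s [%s]", m$matched$section_label[1],
                truncate_excerpt(m$matched$text[1]), m$message)
      } else sprintf("[%s]", m$message),
      found = sprintf("%s: %s", m$matched$section_label[1],
                      truncate_excerpt(m$matched$text[1])))
    list(item_id = item$item_id, prompt = item$prompt, reported = loc,
         status = m$status)
  })
  rows
}

#' Render the filled CONSORT checklist as a document
#'
#' One row per checklist item in CONSORT numbering order; found rows cite
#' the section and the first matched sentence (truncated at 300
#' characters), notification rows carry the notification message, and
#' unimplemented items read "Not implemented". Markdown and docx renderings
#' of the same report contain identical cell texts.
#'
#' @param report A `consort_report`.
#' @param path Output file path.
#' @param format `"markdown"` or `"docx"`.
#' @return `path`, invisibly.
#' @export
render_checklist_doc <- function(report, path, format = c("markdown", "docx")) {
  stopifnot(inherits(report, "consort_report"))
  format <- match.arg(format)
  rows <- checklist_rows(report)
  if (format == "markdown") {
    esc <- function(s) gsub("|", "\\|", gsub("\n", " ", s), fixed = TRUE)
    lines <- c("# CONSORT 2010 checklist",
               "",
               sprintf("Manuscript: %s", if (nzchar(report$id)) report$id else "(unnamed)"),
               "",
               "| Item | Checklist description | Reported |",
               "| --- | --- | --- |",
               vapply(rows, function(r) {
                 sprintf("| %s | %s | %s |", r$item_id, esc(r$prompt), esc(r$reported))
               }, ""))
    writeLines(lines, path, useBytes = TRUE)
  } else {
    cells <- lapply(rows, function(r) c(r$item_id, r$prompt, r$reported))
    write_docx_table(path, title = "CONSORT 2010 checklist",
                     header = c("Item", "Checklist description", "Reported"),
                     rows = cells)
  }
  invisible(path)
}

#' Render the notifications summary document
#'
#' One entry per notification-status item, in checklist order; a report
#' without notifications yields a document stating "No notifications".
#'
#' @param report A `consort_report`.
#' @param path Output file path.
#' @param format `"markdown"` or `"docx"`.
#' @return `path`, invisibly.
#' @export
render_notifications <- function(report, path, format = c("markdown", "docx")) {
  stopifnot(inherits(report, "consort_report"))
  format <- match.arg(format)
  notif <- Filter(function(m) m$status == "notification", report$matches)
  entries <- vapply(notif, function(m) {
    sprintf("Item %s (%s): %s", m$item_id, m$notification_code, m$message)
  }, "")
  if (format == "markdown") {
    lines <- c("# Notifications", "",
               sprintf("Manuscript: %s", if (nzchar(report$id)) report$id else "(unnamed)"),
               "")
    lines <- c(lines, if (length(entries)) paste0("- ", entries) else "No notifications.")
    writeLines(lines, path, useBytes = TRUE)
  } else {
    paras <- if (length(entries)) entries else "No notifications."
    write_docx_paragraphs(path, title = "Notifications", paragraphs = paras)
  }
  invisible(path)
}
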