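# Canonical section labels used throughout the package.
CANONICAL_SECTIONS <- c("ABSTRACT", "INTRODUCTION", "METHODS", "RESULTS",
                        "DISCUSSION", "OTHER_INFO", "REFERENCES", "UNLABELED")

# Heading synonym lexicon: canonical label -> printed headings (case-insensitive).
SECTION_SYNONYMS <- list(
  ABSTRACT     = c("Abstract", "Summary"),
  INTRODUCTION = c("Introduction", "Background"),
  METHODS      = c("Methods", "Method", "Patients and Methods",
                   "Materials and Methods", "Subjects and Methods",
                   "Methods and Materials", "Design and Methods"),
  RESULTS      = c("Results", "Findings"),
  DISCUSSION   = c("Discussion", "Comment", "Comments"),
  OTHER_INFO   = c("Acknowledgments", "Acknowledgements", "Funding",
                   "Trial Registration", "Other Information",
                   "Declarations", "Conflicts of Interest"),
  REFERENCES   = c("References", "Bibliography", "Literature Cited")
)

# Abbreviations after which a period never ends a sentence.
PROTECTED_ABBREV <- c("e.g", "i.e", "vs", "Dr", "Mr", "Mrs", "Ms", "Prof",
                      "et al", "al", "Fig", "Figs", "No", "Nos", "approx",
                      "ca", "cf", "St")

normalize_text <- function(text) {
  text <- stringi::stri_trans_nfc(enc2utf8(text))
  text <- gsub("\r\n?", "\n", text)
  # drop raw control characters other than newline/tab
  gsub("[\\x01-\\x08\\x0B\\x0C\\x0E-\\x1F\\x7F]", "", text, perl = TRUE)
}

#' Parse a plain-text manuscript into a raw document
#'
#' Accepts the package's plain-text manuscript dialect: an optional
#' `TITLE:` line (otherwise the first non-empty line is the title), section
#' headings on their own line (matched case-insensitively against a synonym
#' lexicon, e.g. "Patients and Methods" maps to METHODS), and
#' `Figure N.` / `Table N.` caption lines. Line endings are normalized to
#' `"\n"` and the text to Unicode NFC.
#'
#' @param text Character scalar (may be empty).
#' @return A `consort_rawdoc`: list with `pages` (character vector),
#'   `source_kind` (`"text"`), and `warnings`.
#' @export
parse_plaintext <- function(text) {
  stopifnot(is.character(text), length(text) == 1L, !is.na(text))
  text <- normalize_text(text)
  pages <- if (nzchar(text)) text else character(0)
  structure(list(pages = pages, source_kind = "text", warnings = character(0)),
            class = "consort_rawdoc")
}

match_heading <- function(line) {
  line <- trimws(sub(":\\s*$", "", trimws(line)))
  if (!nzchar(line) || nchar(line) > 60) return(NA_character_)
  for (canon in names(SECTION_SYNONYMS)) {
    if (tolower(line) %in% tolower(SECTION_SYNONYMS[[canon]])) return(canon)
  }
  NA_character_
}

is_caption_line <- function(line) {
  grepl("^\\s*(Figure|Fig\\.?|Table)\\s+[A-Za-z0-9]+[.:]", line)
}

parse_caption <- function(line) {
  m <- regmatches(line, regexec(
    "^\\s*(Figure|Fig\\.?|Table)\\s+([A-Za-z0-9]+)[.:]\\s*(.*)$", line))[[1]]
  kind <- if (grepl("^Table$", m[2])) "table" else "figure"
  list(kind = kind, label = m[3], text = m[4])
}

#' Segment a raw document into a structured manuscript
#'
#' Splits page text into the title, canonical IMRaD sections, and
#' figure/table captions, then breaks each section body into sentences with
#' exact character offsets. Text appearing after the abstract but before the
#' first recognized heading is labeled INTRODUCTION. If no heading is
#' recognized at all, the whole body becomes one UNLABELED section and a
#' warning is recorded (not an error).
#'
#' @param raw A `consort_rawdoc` from [parse_plaintext()] or
#'   [extract_pdf_text()].
#' @return A `consort_manuscript`: list with `title`, `sections` (each a list
#'   with `label`, `raw_heading`, `body`, `sentences`), `captions`, and
#'   `warnings`.
#' @export
segment_sections <- function(raw) {
  stopifnot(inherits(raw, "consort_rawdoc"))
  warnings <- raw$warnings
  text <- paste(raw$pages, collapse = "\n")
  lines <- if (nzchar(text)) strsplit(text, "\n", fixed = TRUE)[[1]] else character(0)

  title <- ""
  captions <- list()
  any_heading <- any(!is.na(vapply(lines, match_heading, "")))
  # title: explicit marker wins, else the first non-empty line; when the
  # document has recognizable headings (so nothing can be swallowed), a
  # title wrapped over several physical lines (as after PDF extraction) is
  # merged up to the first blank line, heading, or caption
  title_idx <- integer(0)
  for (i in seq_along(lines)) {
    if (grepl("^TITLE:", lines[i])) {
      title <- trimws(sub("^TITLE:\\s*", "", lines[i]))
      title_idx <- i
      break
    }
    if (nzchar(trimws(lines[i]))) {
      if (is.na(match_heading(lines[i]))) {
        title <- trimws(lines[i])
        title_idx <- i
        if (any_heading) {
          j <- i + 1L
          while (j <= length(lines) && nzchar(trimws(lines[j])) &&
                 is.na(match_heading(lines[j])) && !is_caption_line(lines[j]) &&
                 length(title_idx) < 6L) {
            title <- paste(title, trimws(lines[j]))
            title_idx <- c(title_idx, j)
            j <- j + 1L
          }
        }
      }
      break
    }
  }

  current <- NULL        # canonical label of open section
  current_head <- ""
  buf <- character(0)
  sections <- list()
  seen_any_heading <- FALSE

  flush_section <- function(sections, label, heading, buf) {
    body_lines <- buf[cumsum(nzchar(trimws(buf))) > 0]  # drop leading blanks
    while (length(body_lines) && !nzchar(trimws(body_lines[length(body_lines)]))) {
      body_lines <- body_lines[-length(body_lines)]
    }
    body <- paste(body_lines, collapse = "\n")
    if (!nzchar(body) && !nzchar(heading)) return(sections)
    sections[[length(sections) + 1L]] <- list(
      label = label, raw_heading = heading, body = body)
    sections
  }

  for (i in seq_along(lines)) {
    if (i %in% title_idx) next
    line <- lines[i]
    h <- match_heading(line)
    if (!is.na(h)) {
      if (!is.null(current) || length(buf)) {
        label <- if (is.null(current)) {
          if (seen_any_heading) "INTRODUCTION" else "UNLABELED"
        } else current
        sections <- flush_section(sections, label, current_head, buf)
      }
      current <- h
      current_head <- trimws(line)
      buf <- character(0)
      seen_any_heading <- TRUE
    } else if (is_caption_line(line)) {
      captions[[length(captions) + 1L]] <- parse_caption(line)
    } else {
      buf <- c(buf, line)
    }
  }
  if (!is.null(current) || length(buf)) {
    label <- if (is.null(current)) "UNLABELED" else current
    sections <- flush_section(sections, label, current_head, buf)
  }

  # text before the first heading (after an abstract-less title) -> INTRODUCTION
  if (length(sections)) {
    labs <- vapply(sections, `[[`, "", "label")
    if (labs[1] == "UNLABELED" && seen_any_heading) {
      sections[[1]]$label <- "INTRODUCTION"
      labs[1] <- "INTRODUCTION"
    }
    if (all(labs == "UNLABELED")) {
      warnings <- c(warnings, "no recognizable section headings; document kept as a single UNLABELED section")
    }
  } else if (nzchar(title) || length(lines)) {
    warnings <- c(warnings, "document has no section content")
  }

  sections <- lapply(sections, function(s) {
    s$sentences <- split_sentences(s$body, s$label)
    s
  })

  structure(list(title = title, sections = sections, captions = captions,
                 warnings = warnings),
            class = "consort_manuscript")
}

#' Split a section body into sentences with exact offsets
#'
#' Sentence boundaries are placed after `.`, `?` or `!` followed by
#' whitespace and an uppercase letter, digit or opening bracket. A boundary
#' is suppressed when the period belongs to a protected abbreviation
#' ("e.g.", "vs.", "Dr.", "et al.", "Fig.", "No.", ...), after a single
#' initial, or inside an unbalanced parenthetical span. Offsets are 0-based,
#' half-open; `substr(body, start + 1, end)` recovers each sentence, and the
#' spans plus inter-sentence whitespace reassemble the body exactly.
#'
#' @param body Section body text (may contain newlines, treated as spaces).
#' @param section_label Canonical label recorded on each sentence.
#' @return Data frame with columns `text`, `section_label`, `index`,
#'   `start`, `end`; zero rows for an empty body.
#' @export
split_sentences <- function(body, section_label = "UNLABELED") {
  empty <- data.frame(text = character(0), section_label = character(0),
                      index = integer(0), start = integer(0), end = integer(0),
                      stringsAsFactors = FALSE)
  if (is.null(body) || !nzchar(body)) return(empty)

  chars <- strsplit(body, "", fixed = TRUE)[[1]]
  n <- length(chars)
  depth <- 0L
  ends <- integer(0)   # candidate boundary: index of terminal punctuation (1-based)
  for (i in seq_len(n)) {
    ch <- chars[i]
    if (ch %in% c("(", "[")) depth <- depth + 1L
    else if (ch %in% c(")", "]")) depth <- max(0L, depth - 1L)
    if (!(ch %in% c(".", "?", "!")) || depth > 0L) next
    # need whitespace then uppercase/digit/open-bracket (or end of text)
    j <- i + 1L
    if (j <= n && !grepl("[ \t\n]", chars[j])) next
    while (j <= n && grepl("[ \t\n]", chars[j])) j <- j + 1L
    if (j <= n && !grepl('[A-Z0-9("“\\[]', chars[j])) next
    if (ch == ".") {
      prefix <- substr(body, max(1L, i - 12L), i - 1L)
      abbrev_hit <- any(vapply(PROTECTED_ABBREV, function(a) {
        grepl(paste0("(^|[^A-Za-z])", gsub("\\.", "\\\\.", a), "$"), prefix)
      }, logical(1)))
      if (abbrev_hit) next
      if (grepl("(^|[^A-Za-z])[A-Z]$", prefix)) next  # single initial "J."
    }
    ends <- c(ends, i)
  }
  if (!length(ends) || ends[length(ends)] < n) {
    # trailing text without terminal punctuation forms the last sentence
    last_non_ws <- max(which(!grepl("[ \t\n]", chars)), 0L)
    if (last_non_ws > if (length(ends)) ends[length(ends)] else 0L) {
      ends <- c(ends, last_non_ws)
    }
  }

  starts <- integer(0); stops <- integer(0)
  pos <- 1L
  for (e in ends) {
    s <- pos
    while (s <= e && grepl("[ \t\n]", chars[s])) s <- s + 1L
    if (s <= e) { starts <- c(starts, s); stops <- c(stops, e) }
    pos <- e + 1L
  }
  if (!length(starts)) return(empty)
  texts <- substring(body, starts, stops)
  data.frame(text = texts, section_label = section_label,
             index = seq_along(texts) - 1L,
             start = starts - 1L, end = stops,
             stringsAsFactors = FALSE)
}

#' Flatten a manuscript back to the plain-text dialect
#'
#' Inverse-ish of [segment_sections()]: emits the title, each section under
#' its printed heading, and caption lines. Used for idempotence checks and
#' for rendering generated manuscripts.
#' @param ms A `consort_manuscript`.
#' @return Character scalar.
#' @export
flatten_manuscript <- function(ms) {
  stopifnot(inherits(ms, "consort_manuscript"))
  parts <- character(0)
  if (nzchar(ms$title)) parts <- c(parts, ms$title, "")
  for (s in ms$sections) {
    head <- if (nzchar(s$raw_heading)) s$raw_heading else tools::toTitleCase(tolower(s$label))
    parts <- c(parts, head, "", s$body, "")
  }
  for (cp in ms$captions) {
    lab <- if (cp$kind == "table") "Table" else "Figure"
    parts <- c(parts, paste0(lab, " ", cp$label, ". ", cp$text), "")
  }
  paste(parts, collapse = "\n")
}
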