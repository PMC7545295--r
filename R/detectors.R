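# Per-item detection engine. Each checklist item is screened by rule rows
# from inst/extdata/cue_patterns.tsv; a sentence triggers a row when the
# row's cue (lemma phrase(s), regex, or entity kind) is present, any required
# entity kind co-occurs in the same sentence, and any word-sense gate lemma
# is present. Sections ABSTRACT and REFERENCES are excluded from body
# detection (title/abstract-scope items have their own routes; reference
# lists would spuriously trigger keyword cues).

BODY_DETECTION_SECTIONS <- c("INTRODUCTION", "METHODS", "RESULTS",
                             "DISCUSSION", "OTHER_INFO", "UNLABELED")
CAPTION_FLOW_RE <- "(?i)(flow|consort|enrol)"

#' Load the packaged cue-pattern table
#'
#' One row per detection rule; a checklist item is detected in a sentence
#' when any of its rows triggers. Columns: `item_id`, `cue_id`, `kind`
#' (`lemma` = semicolon-separated lemma phrases that must all occur,
#' `regex` = case-insensitive pattern over the sentence text, `entity` =
#' entity kind), `pattern`, `entity` (pipe-separated kinds, any of which
#' must co-occur), `gate` (semicolon-separated lemmas, any of which must be
#' present), `sections` (restrict to these canonical sections), and
#' `min_sentences` (distinct matching sentences required; 2 for the
#' structured-abstract item 1b).
#'
#' @param path Optional override path to a cue table in the same format.
#' @return Data frame of rules.
#' @export
load_cue_patterns <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(.consort_cache$cues)) return(.consort_cache$cues)
    path <- .extdata("cue_patterns.tsv")
    cache <- TRUE
  } else cache <- FALSE
  cues <- utils::read.delim(path, stringsAsFactors = FALSE, quote = "",
                            colClasses = "character")
  cues$min_sentences <- as.integer(cues$min_sentences)
  if (cache) .consort_cache$cues <- cues
  cues
}

# annotate every sentence of a manuscript once; returns a list (per section)
# of lists (per sentence) with $ann and $ents
annotate_manuscript <- function(ms) {
  lapply(ms$sections, function(s) {
    lapply(seq_len(nrow(s$sentences)), function(i) {
      ann <- annotate_sentence(s$sentences[i, ])
      list(ann = ann, ents = tag_entities(ann))
    })
  })
}

# does this annotated sentence (+entities) trigger this rule row?
rule_triggers <- function(row, ann, ents) {
  hit <- switch(row$kind,
    lemma = {
      phrases <- strsplit(row$pattern, ";", fixed = TRUE)[[1]]
      all(vapply(phrases, function(p) has_phrase(ann, trimws(p)), logical(1)))
    },
    regex = grepl(row$pattern, ann$sentence, perl = TRUE),
    entity = row$pattern %in% ents$kind,
    stop("unknown cue kind: ", row$kind, call. = FALSE))
  if (!hit) return(FALSE)
  if (nzchar(row$entity)) {
    kinds <- strsplit(row$entity, "|", fixed = TRUE)[[1]]
    if (!any(kinds %in% ents$kind)) return(FALSE)
  }
  if (nzchar(row$gate)) {
    gates <- strsplit(row$gate, ";", fixed = TRUE)[[1]]
    if (!has_lemma(ann, gates)) return(FALSE)
  }
  TRUE
}

new_item_match <- function(item_id, status, matched = NULL,
                           notification_code = NULL, message = "") {
  if (is.null(matched)) {
    matched <- data.frame(section_label = character(0), index = integer(0),
                          text = character(0), stringsAsFactors = FALSE)
  }
  structure(list(item_id = item_id, status = status, matched = matched,
                 notification_code = notification_code, message = message),
            class = "consort_item_match")
}

#' Detect evidence for one checklist item in a manuscript
#'
#' Applies the item's cue rules to the manuscript. Not-implemented items
#' (2a, 22, 17b) short-circuit. Title-scope item 1a inspects only the
#' title; abstract-scope item 1b requires at least two labeled subsection
#' sentences in the abstract. Participant-flow items (13a, 13b, 16) that
#' find no body evidence but find a flow-diagram-like figure/table caption
#' return a CHECK_FIGURE_OR_TABLE notification. Item 3a with a trial-design
#' sentence but no allocation-ratio entity in any matched sentence returns
#' a MISSING_ALLOCATION_RATIO notification. Matched sentences are reported
#' in document order.
#'
#' @param manuscript A `consort_manuscript`.
#' @param item One registry row (see [lookup_item()]) or an item id.
#' @param cues Cue table (defaults to the packaged one).
#' @param .ann Pre-computed annotations from an internal cache (used by
#'   [run_checklist()]); leave `NULL` to annotate on the fly.
#' @return A `consort_item_match`: `item_id`, `status` (one of `found`,
#'   `not_found`, `notification`, `not_implemented`), `matched` (data frame
#'   `section_label`/`index`/`text`), `notification_code`, `message`.
#' @export
detect_item <- function(manuscript, item, cues = load_cue_patterns(), .ann = NULL) {
  stopifnot(inherits(manuscript, "consort_manuscript"))
  if (is.character(item)) item <- lookup_item(item)
  item_id <- item$item_id

  if (item$status == "not_implemented") {
    return(new_item_match(item_id, "not_implemented",
                          message = sprintf("Item %s is not implemented.", item_id)))
  }
  rules <- cues[cues$item_id == item_id, , drop = FALSE]
  if (!nrow(rules)) {
    return(new_item_match(item_id, "not_found",
                          message = sprintf("No detection rules for item %s.", item_id)))
  }

  if (item$scope == "TITLE") {
    title <- manuscript$title
    if (nzchar(title)) {
      ann <- annotate_sentence(title)
      ents <- tag_entities(ann)
      for (i in seq_len(nrow(rules))) {
        if (rule_triggers(rules[i, ], ann, ents)) {
          matched <- data.frame(section_label = "TITLE", index = 0L,
                                text = title, stringsAsFactors = FALSE)
          return(new_item_match(item_id, "found", matched,
                                message = "Identified as a randomized trial in the title."))
        }
      }
    }
    return(new_item_match(item_id, "not_found",
                          message = "Title does not identify the study as a randomized trial."))
  }

  if (is.null(.ann)) .ann <- annotate_manuscript(manuscript)

  scan_sections <- if (item$scope == "ABSTRACT") "ABSTRACT" else BODY_DETECTION_SECTIONS
  matched <- list()
  for (si in seq_along(manuscript$sections)) {
    sec <- manuscript$sections[[si]]
    if (!sec$label %in% scan_sections) next
    applicable <- rules[vapply(rules$sections, function(ss) {
      !nzchar(ss) || sec$label %in% trimws(strsplit(ss, ",")[[1]])
    }, logical(1)), , drop = FALSE]
    if (!nrow(applicable)) next
    for (k in seq_len(nrow(sec$sentences))) {
      a <- .ann[[si]][[k]]
      for (ri in seq_len(nrow(applicable))) {
        if (rule_triggers(applicable[ri, ], a$ann, a$ents)) {
          matched[[length(matched) + 1L]] <- data.frame(
            section_label = sec$label, index = sec$sentences$index[k],
            text = sec$sentences$text[k], stringsAsFactors = FALSE)
          break
        }
      }
    }
  }
  matched_df <- if (length(matched)) do.call(rbind, matched) else NULL
  n_hits <- if (is.null(matched_df)) 0L else nrow(matched_df)
  need <- max(rules$min_sentences, 1L)

  if (n_hits >= need) {
    # item 3a sub-requirement: a design sentence must state the allocation ratio
    if (item_id == "3a") {
      has_ratio <- any(vapply(seq_len(n_hits), function(j) {
        ann <- annotate_sentence(matched_df$text[j])
        "ALLOCATION_RATIO" %in% tag_entities(ann)$kind
      }, logical(1)))
      if (!has_ratio) {
        return(new_item_match(item_id, "notification", matched_df,
                              notification_code = "MISSING_ALLOCATION_RATIO",
                              message = paste("A trial-design sentence was found,",
                                              "but the allocation ratio is not stated.")))
      }
    }
    return(new_item_match(item_id, "found", matched_df,
                          message = sprintf("Evidence found in %s.",
                                            paste(unique(matched_df$section_label),
                                                  collapse = ", "))))
  }

  if (item$figure_check) {
    for (cp in manuscript$captions) {
      if (grepl(CAPTION_FLOW_RE, cp$text, perl = TRUE)) {
        lab <- paste(if (cp$kind == "table") "Table" else "Figure", cp$label)
        return(new_item_match(item_id, "notification",
                              notification_code = "CHECK_FIGURE_OR_TABLE",
                              message = sprintf(
                                "Please check whether %s contains the information for item %s.",
                                lab, item_id)))
      }
    }
  }
  new_item_match(item_id, "not_found",
                 message = sprintf("No relevant information identified for item %s.",
                                   item_id))
}

#' Check that found evidence sits in the CONSORT-expected section
#'
#' For a `found` match of a body-scope item, compares the sections of the
#' matched sentences with the item's expected sections from the registry.
#' If no matched sentence lies in an expected section, the match becomes a
#' WRONG_SECTION notification whose message names both the section where
#' the evidence was found and the section the CONSORT checklist expects.
#' Title/abstract-scope items and items with at least one correctly placed
#' sentence are returned unchanged.
#'
#' @param match A `consort_item_match`.
#' @param item The corresponding registry row.
#' @return A (possibly updated) `consort_item_match`.
#' @export
assess_section_placement <- function(match, item) {
  stopifnot(inherits(match, "consort_item_match"))
  if (is.character(item)) item <- lookup_item(item)
  if (match$status != "found") return(match)
  if (item$scope != "BODY") return(match)
  expected <- item_expected_sections(item)
  if (!length(expected)) return(match)
  found_in <- unique(match$matched$section_label)
  if (any(found_in %in% expected)) return(match)
  match$status <- "notification"
  match$notification_code <- "WRONG_SECTION"
  match$message <- sprintf(
    "Item %s should be present in the %s section of the article instead of the current %s section.",
    match$item_id,
    paste(pretty_section(expected), collapse = " or "),
    paste(pretty_section(found_in), collapse = " and "))
  match
}

pretty_section <- function(labels) {
  nice <- c(ABSTRACT = "Abstract", INTRODUCTION = "Introduction",
            METHODS = "Methods", RESULTS = "Results",
            DISCUSSION = "Discussion", OTHER_INFO = "Other information",
            REFERENCES = "References", UNLABELED = "Unlabeled",
            TITLE = "Title")
  out <- nice[labels]
  out[is.na(out)] <- labels[is.na(out)]
  unname(out)
}

#' Run the full CONSORT checklist over a manuscript
#'
#' Applies [detect_item()] and [assess_section_placement()] for all 37
#' registry items. Deterministic: identical input yields an identical
#' report.
#'
#' @param manuscript A `consort_manuscript`.
#' @param cues Cue table override (defaults to the packaged rules).
#' @param id Manuscript identifier recorded in the report.
#' @return A `consort_report`: list with `id`, `matches` (named list of 37
#'   `consort_item_match`, keyed and ordered by item id), and `warnings`
#'   carried over from ingestion.
#' @export
run_checklist <- function(manuscript, cues = load_cue_patterns(), id = "") {
  stopifnot(inherits(manuscript, "consort_manuscript"))
  reg <- load_registry()
  ann <- annotate_manuscript(manuscript)
  matches <- vector("list", nrow(reg))
  names(matches) <- reg$item_id
  for (i in seq_len(nrow(reg))) {
    item <- reg[i, , drop = FALSE]
    m <- detect_item(manuscript, item, cues = cues, .ann = ann)
    m <- assess_section_placement(m, item)
    matches[[i]] <- m
  }
  structure(list(id = id, matches = matches, warnings = manuscript$warnings),
            class = "consort_report")
}

#' @export
print.consort_report <- function(x, ...) {
  statuses <- vapply(x$matches, `[[`, "", "status")
  cat("CONSORT checklist report", if (nzchar(x$id)) paste0("for '", x$id, "'"), "\n")
  tab <- table(factor(statuses, levels = c("found", "notification",
                                           "not_found", "not_implemented")))
  for (s in names(tab)) cat(sprintf("  %-16s %d\n", s, tab[[s]]))
  notif <- names(statuses)[statuses == "notification"]
  for (id in notif) cat("  note [", id, "]: ", x$matches[[id]]$message, "\n", sep = "")
  invisible(x)
}
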