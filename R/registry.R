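# cache for packaged resources (registry, cue table, gazetteers, lemma lexicon)
.consort_cache <- new.env(parent = emptyenv())

.extdata <- function(file) {
  path <- system.file("extdata", file, package = "consortcheck")
  if (identical(path, "") || !file.exists(path)) {
    stop("packaged resource not found: inst/extdata/", file, call. = FALSE)
  }
  path
}

#' Load the CONSORT 2010 checklist registry
#'
#' Reads the packaged registry of the 37 CONSORT 2010 checklist sub-items.
#' Each item carries its identifier (`"1a"` ... `"25"`), the checklist prompt,
#' the scope it is evaluated against (`TITLE`, `ABSTRACT`, or `BODY`), the
#' canonical manuscript sections where the CONSORT checklist expects the item
#' to be reported, an implementation status (`detectable` or
#' `not_implemented`; items 2a, 22 and 17b are not implemented), whether the
#' item participates in accuracy scoring (items 2a, 22, 17b, 10, 13a, 13b and
#' 16 are excluded, leaving 30 scored items), and whether the item is a
#' participant-flow item whose evidence is often confined to a figure or
#' table (13a, 13b, 16).
#'
#' @return A data frame with 37 rows and columns `item_id`, `scope`,
#'   `expected_sections` (comma-separated canonical labels, `""` for
#'   title/abstract scope), `status`, `in_accuracy`, `figure_check`,
#'   `prompt`. Loading is idempotent; the result is cached.
#' @export
#' @examples
#' reg <- load_registry()
#' nrow(reg)                                   # 37
#' sum(reg$status == "not_implemented")        # 3
#' sum(reg$in_accuracy)                        # 30
load_registry <- function() {
  if (!is.null(.consort_cache$registry)) return(.consort_cache$registry)
  path <- .extdata("checklist_items.tsv")
  reg <- utils::read.delim(path, stringsAsFactors = FALSE, quote = "",
                           colClasses = "character")
  needed <- c("item_id", "scope", "expected_sections", "status",
              "in_accuracy", "figure_check", "prompt")
  if (!all(needed %in% names(reg))) {
    stop("checklist registry resource is corrupted (missing columns): ",
         path, call. = FALSE)
  }
  reg$in_accuracy <- reg$in_accuracy == "TRUE"
  reg$figure_check <- reg$figure_check == "TRUE"
  if (nrow(reg) != 37L || anyDuplicated(reg$item_id)) {
    stop("checklist registry resource is corrupted (expected 37 unique items): ",
         path, call. = FALSE)
  }
  .consort_cache$registry <- reg
  reg
}

#' Look up a single checklist item by id
#'
#' @param item_id Checklist sub-item code, e.g. `"1a"`, `"9"`, `"13b"`.
#' @return One-row data frame (a single `ChecklistItem` record).
#' @export
lookup_item <- function(item_id) {
  reg <- load_registry()
  i <- match(item_id, reg$item_id)
  if (is.na(i)) {
    stop("unknown CONSORT item id: '", item_id, "'", call. = FALSE)
  }
  reg[i, , drop = FALSE]
}

# expected sections for an item as a character vector (possibly empty)
item_expected_sections <- function(item) {
  s <- item$expected_sections
  if (is.na(s) || !nzchar(s)) return(character(0))
  trimws(strsplit(s, ",", fixed = TRUE)[[1]])
}
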