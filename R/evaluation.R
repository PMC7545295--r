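# Performance machinery: per-article-item correctness, per-item accuracy
# across a corpus, accuracy banding, and the positive/negative/undetected
# sentence triage used during detector training. Sentence identity is exact
# (section label, sentence index) equality throughout — the synthetic truth
# is exact, and fuzzy matching would mask offset bugs.

#' Score one item match against ground truth for one article
#'
#' An assessment is correct when the checker either (1) extracts a relevant
#' sentence — status `found` or `notification` with at least one matched
#' sentence identical, by (section, index), to a truth sentence — or (2)
#' reports a null finding (`not_found`) for an article that truly does not
#' contain the item. Every other combination is incorrect. Only items in
#' the accuracy set may be scored.
#'
#' @param match A `consort_item_match`.
#' @param truth_entry List with `present` (logical) and `sentences` (data
#'   frame with `section_label`, `index`; zero rows when absent).
#' @return Logical scalar.
#' @export
score_item_on_article <- function(match, truth_entry) {
  stopifnot(inherits(match, "consort_item_match"))
  item <- lookup_item(match$item_id)
  if (!item$in_accuracy) {
    stop("item ", match$item_id, " is excluded from accuracy scoring",
         call. = FALSE)
  }
  present <- isTRUE(truth_entry$present)
  ts <- truth_entry$sentences
  if (match$status %in% c("found", "notification") && nrow(match$matched)) {
    if (!present || is.null(ts) || !nrow(ts)) return(FALSE)
    truth_keys <- paste(ts$section_label, ts$index)
    match_keys <- paste(match$matched$section_label, match$matched$index)
    return(any(match_keys %in% truth_keys))
  }
  if (match$status == "not_found") return(!present)
  # notification without any matched sentence cannot be verified against truth
  FALSE
}

truth_entry_for <- function(truth, item_id) {
  e <- truth$items[[item_id]]
  if (is.null(e)) {
    e <- list(present = FALSE,
              sentences = data.frame(section_label = character(0),
                                     index = integer(0)))
  }
  e
}

#' Score every in-accuracy item of every article in a corpus
#'
#' @param reports List of `consort_report` (one per article; `id` fields
#'   must match the truth article ids).
#' @param truths List of ground-truth records as read by
#'   [read_ground_truth()].
#' @return Data frame with columns `article_id`, `item_id`, `correct`.
#' @export
evaluate_corpus <- function(reports, truths) {
  rep_ids <- vapply(reports, `[[`, "", "id")
  truth_ids <- vapply(truths, `[[`, "", "article_id")
  if (!setequal(rep_ids, truth_ids) || length(rep_ids) != length(truth_ids)) {
    stop("report and ground-truth corpora are not aligned by article id",
         call. = FALSE)
  }
  truths <- truths[match(rep_ids, truth_ids)]
  reg <- load_registry()
  scored_items <- reg$item_id[reg$in_accuracy]
  out <- list()
  for (i in seq_along(reports)) {
    for (item_id in scored_items) {
      ok <- score_item_on_article(reports[[i]]$matches[[item_id]],
                                  truth_entry_for(truths[[i]], item_id))
      out[[length(out) + 1L]] <- data.frame(article_id = rep_ids[i],
                                            item_id = item_id, correct = ok,
                                            stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

band_of <- function(acc) {
  ifelse(acc < 0.80, "LT80", ifelse(acc <= 0.90, "B80_90", "GT90"))
}

#' Per-item accuracy across a corpus
#'
#' Accuracy for each item is the number of articles correctly assessed
#' divided by the total number of articles (exact rational division).
#' Restricted to the 30 items in the accuracy set.
#'
#' @param scores Data frame from [evaluate_corpus()].
#' @return Data frame with `item_id`, `n_articles`, `n_correct`,
#'   `accuracy`, `band` (`LT80` for accuracy below 0.80, `B80_90` for 0.80
#'   up to and including 0.90, `GT90` above 0.90).
#' @export
per_item_accuracy <- function(scores) {
  stopifnot(is.data.frame(scores), nrow(scores) > 0L)
  n_articles <- length(unique(scores$article_id))
  if (n_articles < 1L) stop("accuracy requires at least one article", call. = FALSE)
  agg <- stats::aggregate(correct ~ item_id, data = scores, FUN = sum)
  cnt <- stats::aggregate(correct ~ item_id, data = scores, FUN = length)
  tab <- data.frame(item_id = agg$item_id,
                    n_articles = cnt$correct,
                    n_correct = agg$correct,
                    stringsAsFactors = FALSE)
  tab$accuracy <- tab$n_correct / tab$n_articles
  tab$band <- band_of(tab$accuracy)
  reg <- load_registry()
  tab[order(match(tab$item_id, reg$item_id)), , drop = FALSE]
}

#' Count items per accuracy band
#'
#' Bands follow the reporting convention: below 80%, 80% to 90%
#' (inclusive at both ends; "more than 90%" is strict), and above 90%.
#'
#' @param table Data frame from [per_item_accuracy()].
#' @return Named integer vector with elements `LT80`, `B80_90`, `GT90`.
#' @export
bin_accuracies <- function(table) {
  stopifnot(is.data.frame(table), "accuracy" %in% names(table))
  counts <- table(factor(band_of(table$accuracy),
                         levels = c("LT80", "B80_90", "GT90")))
  out <- as.integer(counts)
  names(out) <- names(counts)
  out
}

#' Triage extracted sentences into positive / negative / undetected
#'
#' Over all in-accuracy items of all articles, each extracted sentence
#' (matched by a `found` or `notification` item) is positive when it is a
#' truth sentence for that item and negative otherwise; each truth sentence
#' the checker did not extract is undetected. The three groups partition
#' the (article, item, sentence) universe. `proportion_bad` is
#' (negative + undetected) / (positive + negative + undetected), the
#' quantity driven below 10% during detector training.
#'
#' @param reports List of `consort_report`.
#' @param truths Aligned list of ground-truth records.
#' @return List with `positive`, `negative`, `undetected`,
#'   `proportion_bad`.
#' @export
triage_sentences <- function(reports, truths) {
  rep_ids <- vapply(reports, `[[`, "", "id")
  truth_ids <- vapply(truths, `[[`, "", "article_id")
  if (!setequal(rep_ids, truth_ids) || length(rep_ids) != length(truth_ids)) {
    stop("report and ground-truth corpora are not aligned by article id",
         call. = FALSE)
  }
  truths <- truths[match(rep_ids, truth_ids)]
  reg <- load_registry()
  scored_items <- reg$item_id[reg$in_accuracy]
  extracted <- character(0)
  truth_keys <- character(0)
  for (i in seq_along(reports)) {
    for (item_id in scored_items) {
      m <- reports[[i]]$matches[[item_id]]
      if (m$status %in% c("found", "notification") && nrow(m$matched)) {
        extracted <- c(extracted, paste(rep_ids[i], item_id,
                                        m$matched$section_label,
                                        m$matched$index, sep = "\r"))
      }
      te <- truth_entry_for(truths[[i]], item_id)
      if (isTRUE(te$present) && nrow(te$sentences)) {
        truth_keys <- c(truth_keys, paste(rep_ids[i], item_id,
                                          te$sentences$section_label,
                                          te$sentences$index, sep = "\r"))
      }
    }
  }
  extracted <- unique(extracted)
  truth_keys <- unique(truth_keys)
  positive <- sum(extracted %in% truth_keys)
  negative <- length(extracted) - positive
  undetected <- sum(!truth_keys %in% extracted)
  total <- positive + negative + undetected
  list(positive = positive, negative = negative, undetected = undetected,
       proportion_bad = if (total) (negative + undetected) / total else 0)
}

# ---- ground-truth file format --------------------------------------------

#' Read / write corpus ground truth
#'
#' Ground truth for a corpus is one JSON file: an array of article records,
#' each with `article_id` and `items` mapping item ids to `present` plus
#' the exact `(section_label, index)` coordinates of the truth sentences.
#'
#' @param truths List of ground-truth records.
#' @param path File path.
#' @return For `read_ground_truth`, the list of records.
#' @export
write_ground_truth <- function(truths, path) {
  body <- lapply(truths, function(tr) {
    list(article_id = tr$article_id,
         items = lapply(tr$items, function(e) {
           list(present = isTRUE(e$present),
                sentences = lapply(seq_len(nrow(e$sentences)), function(i) {
                  list(section_label = e$sentences$section_label[i],
                       index = e$sentences$index[i])
                }))
         }))
  })
  writeLines(jsonlite::toJSON(body, auto_unbox = TRUE, pretty = TRUE),
             path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  x <- jsonlite::fromJSON(paste(readLines(path, encoding = "UTF-8"),
                                collapse = "\n"), simplifyVector = FALSE)
  lapply(x, function(tr) {
    items <- lapply(tr$items, function(e) {
      sents <- if (length(e$sentences)) {
        data.frame(
          section_label = vapply(e$sentences, `[[`, "", "section_label"),
          index = vapply(e$sentences, function(s) as.integer(s$index), 0L),
          stringsAsFactors = FALSE)
      } else {
        data.frame(section_label = character(0), index = integer(0),
                   stringsAsFactors = FALSE)
      }
      list(present = isTRUE(e$present), sentences = sents)
    })
    list(article_id = tr$article_id, items = items)
  })
}
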