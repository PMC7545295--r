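# Seeded synthetic-corpus generator. A manuscript plan (drawn from a seed
# and a probability config) fully determines one document; realization
# writes the plain-text dialect and exact ground truth whose sentence
# coordinates are obtained by running the package's own sentence splitter
# over the generated section bodies.

NOT_IMPLEMENTED_ITEMS <- c("2a", "22", "17b")
FIGURE_ONLY_ITEMS <- c("13a", "13b", "16")
# items whose detectors are section-filtered or caption-driven are never
# misplaced by the generator (their evidence placement is part of the rule)
MISPLACE_INELIGIBLE <- c("1a", "1b", "12b", "18", FIGURE_ONLY_ITEMS,
                         NOT_IMPLEMENTED_ITEMS)
BODY_PLAN_SECTIONS <- c("INTRODUCTION", "METHODS", "RESULTS", "DISCUSSION",
                        "OTHER_INFO")

#' Generator configuration
#'
#' Defaults describe a realistic reporting landscape: most items are
#' reported (each present with probability 0.9), occasionally in the wrong
#' section (probability 0.05 among eligible items), participant-flow
#' numbers are confined to the flow-diagram caption in 30% of manuscripts,
#' a trial-design sentence omits the allocation ratio a quarter of the
#' time, and every section carries 2-3 near-miss distractor sentences.
#'
#' @param include_prob Probability an item is reported.
#' @param misplace_prob Probability a reported, eligible item lands in a
#'   non-expected section.
#' @param figure_only_prob Probability the flow items (13a/13b/16) appear
#'   only in the figure caption.
#' @param noratio_prob Probability a reported trial-design sentence (3a)
#'   omits the allocation ratio.
#' @param distractor_range Integer range of distractors per section.
#' @return Named list of settings.
#' @export
synth_config <- function(include_prob = 0.9, misplace_prob = 0.05,
                         figure_only_prob = 0.3, noratio_prob = 0.25,
                         distractor_range = 2:3) {
  probs <- c(include_prob, misplace_prob, figure_only_prob, noratio_prob)
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  list(include_prob = include_prob, misplace_prob = misplace_prob,
       figure_only_prob = figure_only_prob, noratio_prob = noratio_prob,
       distractor_range = distractor_range)
}

#' Sample a manuscript plan
#'
#' Deterministic given `seed`: which items the manuscript reports, which
#' template variant realizes each, whether an item is misplaced into a
#' non-expected section, whether the flow items are figure-only, and the
#' drawn parameter set (drug, condition, counts, dates, registry id, ...).
#' Not-implemented items (2a, 22, 17b) are never planned as truth-bearing.
#'
#' @param seed Integer seed.
#' @param config From [synth_config()].
#' @return A `consort_plan` list.
#' @export
sample_manuscript_plan <- function(seed, config = synth_config()) {
  set.seed(seed)
  reg <- load_registry()
  detectable <- setdiff(reg$item_id, NOT_IMPLEMENTED_ITEMS)

  include <- stats::setNames(stats::runif(length(detectable)) < config$include_prob,
                             detectable)
  params <- sample_params()

  variant <- stats::setNames(integer(length(detectable)), detectable)
  placement <- stats::setNames(rep(NA_character_, length(detectable)), detectable)
  misplace <- stats::setNames(rep(FALSE, length(detectable)), detectable)
  figure_only <- stats::setNames(rep(FALSE, length(detectable)), detectable)

  for (id in detectable) {
    if (!include[[id]]) next
    spec <- ITEM_TEMPLATES[[id]]
    nv <- if (!is.null(spec)) length(spec$variants) else 1L
    variant[[id]] <- sample.int(nv, 1L)
    if (!is.null(spec)) placement[[id]] <- spec$section
    if (id %in% FIGURE_ONLY_ITEMS && stats::runif(1) < config$figure_only_prob) {
      figure_only[[id]] <- TRUE
    }
    if (!(id %in% MISPLACE_INELIGIBLE) && stats::runif(1) < config$misplace_prob) {
      misplace[[id]] <- TRUE
      placement[[id]] <- sample(setdiff(BODY_PLAN_SECTIONS, spec$section), 1L)
    }
  }
  ratio_omitted <- isTRUE(include[["3a"]]) && stats::runif(1) < config$noratio_prob

  distractors <- lapply(DISTRACTORS, function(bank) {
    k <- min(sample(config$distractor_range, 1L), length(bank))
    sort(sample.int(length(bank), k))
  })

  structure(list(seed = seed, include = include, variant = variant,
                 placement = placement, misplace = misplace,
                 figure_only = figure_only, ratio_omitted = ratio_omitted,
                 distractors = distractors, params = params),
            class = "consort_plan")
}

item_sentence <- function(plan, id) {
  spec <- ITEM_TEMPLATES[[id]]
  if (id == "3a" && plan$ratio_omitted) return(tpl(spec$noratio, plan$params))
  tpl(spec$variants[plan$variant[[id]]], plan$params)
}

#' Realize a manuscript plan as text plus exact ground truth
#'
#' Builds the plain-text manuscript (title, structured or unstructured
#' abstract, IMRaD sections with item sentences and distractors interleaved
#' at seeded positions, figure/table caption lines, a references section),
#' then re-parses each section body with [split_sentences()] so the ground
#' truth records the exact (section, sentence index) coordinates the
#' ingestion pipeline will see.
#'
#' @param plan A `consort_plan`.
#' @return List with `text` (the manuscript), `truth` (a ground-truth
#'   record as used by [evaluate_corpus()]), and `plan`.
#' @export
realize_manuscript <- function(plan) {
  stopifnot(inherits(plan, "consort_plan"))
  set.seed(plan$seed + 31L)  # layout randomness separated from plan draws
  p <- plan$params
  inc <- function(id) isTRUE(plan$include[[id]])

  truth_items <- list()
  mark <- function(id, section, index) {
    e <- truth_items[[id]]
    if (is.null(e)) {
      e <- list(present = TRUE,
                sentences = data.frame(section_label = character(0),
                                       index = integer(0),
                                       stringsAsFactors = FALSE))
    }
    e$sentences <- rbind(e$sentences,
                         data.frame(section_label = section, index = index,
                                    stringsAsFactors = FALSE))
    truth_items[[id]] <<- e
  }

  title <- tpl(sample(if (inc("1a")) TITLES_RANDOMIZED else TITLES_PLAIN, 1L), p)
  if (inc("1a")) mark("1a", "TITLE", 0L)

  abstract <- vapply(if (inc("1b")) ABSTRACT_STRUCTURED else ABSTRACT_PLAIN,
                     tpl, "", p = p, USE.NAMES = FALSE)
  if (inc("1b")) for (i in seq_along(abstract)) mark("1b", "ABSTRACT", i - 1L)

  # collect body sentences per section: item sentences in registry order,
  # then distractors spliced in at seeded positions
  reg <- load_registry()
  section_items <- stats::setNames(vector("list", length(BODY_PLAN_SECTIONS)),
                                   BODY_PLAN_SECTIONS)
  for (id in reg$item_id) {
    if (id %in% c("1a", "1b", NOT_IMPLEMENTED_ITEMS)) next
    if (!inc(id)) next
    if (id %in% FIGURE_ONLY_ITEMS && isTRUE(plan$figure_only[[id]])) next
    sec <- plan$placement[[id]]
    section_items[[sec]] <- c(section_items[[sec]],
                              stats::setNames(item_sentence(plan, id), id))
  }

  section_bodies <- list()
  for (sec in BODY_PLAN_SECTIONS) {
    items <- section_items[[sec]]
    dstr <- vapply(DISTRACTORS[[sec]][plan$distractors[[sec]]], tpl, "",
                   p = p, USE.NAMES = FALSE)
    texts <- if (length(items)) unname(items) else character(0)
    tags <- names(items)
    for (d in dstr) {
      pos <- sample.int(length(texts) + 1L, 1L)
      texts <- append(texts, d, after = pos - 1L)
      tags <- append(tags, NA_character_, after = pos - 1L)
    }
    if (!length(texts)) next
    body <- paste(texts, collapse = " ")
    sents <- split_sentences(body, sec)
    if (nrow(sents) != length(texts) || !all(sents$text == texts)) {
      stop("template realization produced unexpected sentence boundaries in ",
           sec, " (seed ", plan$seed, ")", call. = FALSE)
    }
    for (k in seq_along(tags)) {
      if (!is.na(tags[k])) mark(tags[k], sec, k - 1L)
    }
    section_bodies[[sec]] <- body
  }

  # absent items recorded explicitly so truth files are self-contained
  for (id in setdiff(reg$item_id, names(truth_items))) {
    truth_items[[id]] <- list(
      present = FALSE,
      sentences = data.frame(section_label = character(0), index = integer(0),
                             stringsAsFactors = FALSE))
  }

  heading_for <- c(INTRODUCTION = "Introduction", METHODS = "Methods",
                   RESULTS = "Results", DISCUSSION = "Discussion",
                   OTHER_INFO = "Acknowledgments")
  lines <- c(title, "", "Abstract", paste(abstract, collapse = " "), "")
  for (sec in BODY_PLAN_SECTIONS) {
    if (is.null(section_bodies[[sec]])) next
    lines <- c(lines, heading_for[[sec]], section_bodies[[sec]], "")
    if (sec == "RESULTS") {
      lines <- c(lines, paste0("Figure 1. ", FIGURE1_CAPTION),
                 paste0("Table 1. ", TABLE1_CAPTION), "")
    }
  }
  lines <- c(lines, "References", REFERENCES_BANK, "")

  list(text = paste(lines, collapse = "\n"),
       truth = list(article_id = sprintf("doc_%d", plan$seed),
                    items = truth_items),
       plan = plan)
}

#' Generate a seeded corpus of synthetic manuscripts with ground truth
#'
#' Writes `doc_###.txt` files (optionally also simple text-layer PDFs), a
#' single `truth.json` ground-truth file, and a `manifest.json` describing
#' the split assignment. Per-document seeds are drawn from the master seed,
#' so the same call yields byte-identical corpora.
#'
#' @param n Number of documents.
#' @param seed Master seed.
#' @param outdir Output directory (created if needed).
#' @param split_sizes Named integer vector summing to `n` (e.g.
#'   `c(training = 111, testing = 25, validation = 22)`); default puts all
#'   documents in one "training" split.
#' @param pdf Also render each document as a PDF.
#' @param config Generator configuration from [synth_config()].
#' @return The manifest (list), invisibly.
#' @export
generate_corpus <- function(n, seed, outdir, split_sizes = NULL, pdf = FALSE,
                            config = synth_config()) {
  stopifnot(n >= 1)
  if (is.null(split_sizes)) split_sizes <- c(training = n)
  if (is.null(names(split_sizes))) {
    names(split_sizes) <- c("training", "testing", "validation",
                            paste0("split", seq_along(split_sizes)))[seq_along(split_sizes)]
  }
  if (sum(split_sizes) != n) {
    stop("split sizes must sum to n (", n, ")", call. = FALSE)
  }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  doc_seeds <- sample.int(.Machine$integer.max - 1L, n)
  split_label <- rep(names(split_sizes), times = split_sizes)

  docs <- vector("list", n)
  truths <- vector("list", n)
  for (i in seq_len(n)) {
    plan <- sample_manuscript_plan(doc_seeds[i], config)
    real <- realize_manuscript(plan)
    id <- sprintf("doc_%03d", i)
    real$truth$article_id <- id
    file <- file.path(outdir, paste0(id, ".txt"))
    writeLines(real$text, file, useBytes = TRUE)
    if (pdf) write_manuscript_pdf(real$text, file.path(outdir, paste0(id, ".pdf")))
    truths[[i]] <- real$truth
    docs[[i]] <- list(id = id, file = basename(file), split = split_label[i],
                      plan_seed = doc_seeds[i],
                      digest = sprintf("%d:%d", nchar(real$text),
                                       sum(utf8ToInt(real$text)) %% 1000000L))
  }
  write_ground_truth(truths, file.path(outdir, "truth.json"))
  manifest <- list(n_documents = n, master_seed = seed,
                   splits = as.list(split_sizes), documents = docs)
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE),
             file.path(outdir, "manifest.json"), useBytes = TRUE)
  invisible(manifest)
}
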