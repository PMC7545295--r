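# Shared fixtures and independent oracles used across test files.

# parse the plain-text dialect straight to a manuscript
build_manuscript <- function(text) segment_sections(parse_plaintext(text))

# a small hand-written manuscript exercising several detectors at once
MINI_MANUSCRIPT <- paste(
  "Effect of Epralastat Compared With Placebo in Chronic Migraine: A Randomised Controlled Trial",
  "",
  "Abstract",
  "Background: Chronic migraine is disabling. Methods: Adults were randomly assigned to epralastat or placebo. Results: Epralastat reduced monthly attacks. Conclusions: Epralastat was effective.",
  "",
  "Introduction",
  "The objective of this trial was to determine whether epralastat reduces attack frequency.",
  "",
  "Methods",
  "The study was designed as a parallel-group, double-blind trial in which participants were allocated in a 1:1 ratio.",
  "Patients were eligible if they were aged 18 to 65 years.",
  "Participants, investigators, and outcome assessors were blinded to treatment assignment throughout the trial.",
  "",
  "Results",
  "Serious adverse events occurred in 4 patients in the epralastat group and 6 patients in the control group.",
  "",
  "Figure 1. Enrolment, randomisation, and follow-up of the participants in the trial flow diagram.",
  "",
  "Discussion",
  "This trial has several limitations, including imprecision.",
  "",
  "Acknowledgments",
  "This trial was funded by the Medical Research Council.",
  sep = "\n")

# plan builder with deterministic overrides: everything included, placed in
# its home section, with optional figure-only / ratio-omitted behavior
make_controlled_plan <- function(seed = 101, figure_only = character(0),
                                 exclude = character(0), ratio_omitted = FALSE,
                                 misplace = character(0)) {
  plan <- sample_manuscript_plan(seed)
  for (id in names(plan$include)) {
    plan$include[[id]] <- !(id %in% exclude)
    plan$misplace[[id]] <- FALSE
    plan$figure_only[[id]] <- FALSE
    if (plan$include[[id]]) {
      spec <- consortcheck:::ITEM_TEMPLATES[[id]]
      if (!is.null(spec)) plan$placement[[id]] <- spec$section
      if (plan$variant[[id]] == 0L) plan$variant[[id]] <- 1L
    }
  }
  for (id in figure_only) plan$figure_only[[id]] <- TRUE
  for (id in misplace) {
    plan$misplace[[id]] <- TRUE
    home <- consortcheck:::ITEM_TEMPLATES[[id]]$section
    plan$placement[[id]] <- setdiff(c("INTRODUCTION", "METHODS", "RESULTS",
                                      "DISCUSSION", "OTHER_INFO"), home)[1]
  }
  plan$ratio_omitted <- ratio_omitted
  plan
}

# fixture mirroring the comparing-two-therapies case study: trial-design
# sentence without an allocation ratio, participant-flow numbers confined to
# the flow-diagram figure caption
spirit_like_fixture <- function(seed = 202) {
  plan <- make_controlled_plan(seed, figure_only = c("13a", "13b"),
                               ratio_omitted = TRUE)
  realize_manuscript(plan)
}

# ---- independent oracles --------------------------------------------------

# O(n*m) brute-force cue matcher over every lemma window / regex scan
brute_force_cue_hits <- function(annotated, patterns) {
  hits <- 0L
  lem <- annotated$lemmas
  for (i in seq_len(nrow(patterns))) {
    p <- patterns[i, ]
    if (p$kind == "regex") {
      m <- gregexpr(p$pattern, annotated$sentence, perl = TRUE)[[1]]
      if (m[1] != -1) hits <- hits + length(m)
    } else {
      want <- strsplit(trimws(p$pattern), "\\s+")[[1]]
      k <- length(want)
      if (k > length(lem)) next
      for (s in seq_len(length(lem) - k + 1L)) {
        window <- lem[s:(s + k - 1L)]
        if (identical(window, want)) hits <- hits + 1L
      }
    }
  }
  hits
}

# naive recount of per-item accuracy from reports + truths, independent of
# evaluate_corpus / per_item_accuracy internals
brute_force_accuracy <- function(reports, truths) {
  reg <- load_registry()
  ids <- reg$item_id[reg$in_accuracy]
  truth_by_id <- stats::setNames(truths, vapply(truths, `[[`, "", "article_id"))
  out <- numeric(0)
  for (item in ids) {
    n_ok <- 0L
    for (r in reports) {
      tr <- truth_by_id[[r$id]]
      e <- tr$items[[item]]
      present <- !is.null(e) && isTRUE(e$present)
      m <- r$matches[[item]]
      ok <- FALSE
      if (m$status %in% c("found", "notification") && nrow(m$matched) > 0) {
        if (present) {
          for (j in seq_len(nrow(m$matched))) {
            for (k in seq_len(nrow(e$sentences))) {
              if (m$matched$section_label[j] == e$sentences$section_label[k] &&
                  m$matched$index[j] == e$sentences$index[k]) ok <- TRUE
            }
          }
        }
      } else if (m$status == "not_found" && !present) ok <- TRUE
      n_ok <- n_ok + ok
    }
    out[item] <- n_ok / length(reports)
  }
  out
}
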