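test_that("plans and documents are deterministic given a seed", {
  p1 <- sample_manuscript_plan(7)
  p2 <- sample_manuscript_plan(7)
  expect_identical(p1, p2)
  expect_identical(realize_manuscript(p1)$text, realize_manuscript(p2)$text)

  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  generate_corpus(3, seed = 9, outdir = d1)
  generate_corpus(3, seed = 9, outdir = d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = paste("file", f, "byte-identical across runs"))
  }
})

test_that("configuration probabilities are validated and respected at the extremes", {
  expect_error(synth_config(include_prob = 1.2), "\\[0, 1\\]")
  expect_error(synth_config(misplace_prob = -0.1), "\\[0, 1\\]")

  none <- sample_manuscript_plan(3, synth_config(include_prob = 0))
  expect_false(any(none$include))
  all_in <- sample_manuscript_plan(3, synth_config(include_prob = 1))
  expect_true(all(all_in$include))
})

test_that("per-item inclusion frequency tracks the configured probability", {
  cfg <- synth_config(include_prob = 0.9)
  n <- 300
  inc <- vapply(seq_len(n), function(s) {
    sample_manuscript_plan(s, cfg)$include
  }, logical(34))
  freq <- rowMeans(inc)
  se <- sqrt(0.9 * 0.1 / n)
  expect_true(all(abs(freq - 0.9) <= 3 * se),
              label = "all per-item inclusion frequencies within 3 SE of 0.9")
})

test_that("plans determine truth: presence and exact coordinates", {
  for (seed in c(21, 22, 23)) {
    plan <- sample_manuscript_plan(seed)
    real <- realize_manuscript(plan)
    reg <- load_registry()
    # plan -> truth fidelity for scored items
    for (id in reg$item_id[reg$in_accuracy]) {
      if (id %in% c("1a", "1b")) next
      expect_identical(isTRUE(real$truth$items[[id]]$present),
                       isTRUE(plan$include[[id]]),
                       label = paste("plan/truth agree for", id, "seed", seed))
    }
    # truth coordinates are valid after re-ingesting the document
    ms <- build_manuscript(real$text)
    for (id in names(real$truth$items)) {
      e <- real$truth$items[[id]]
      if (!isTRUE(e$present)) next
      for (k in seq_len(nrow(e$sentences))) {
        lab <- e$sentences$section_label[k]
        idx <- e$sentences$index[k]
        if (lab == "TITLE") {
          expect_true(nzchar(ms$title))
        } else {
          sec <- Filter(function(s) s$label == lab, ms$sections)
          expect_length(sec, 1L)
          expect_true(idx %in% sec[[1]]$sentences$index,
                      label = paste("coordinate", lab, idx, "for", id))
        }
      }
    }
  }
})

test_that("figure-only flow items leave the body and land in the caption", {
  real <- realize_manuscript(make_controlled_plan(77, figure_only = c("13a", "13b")))
  expect_false(isTRUE(real$truth$items[["13a"]]$present))
  expect_false(grepl("randomly assigned to receive", real$text))
  ms <- build_manuscript(real$text)
  expect_true(any(vapply(ms$captions, function(cp) {
    grepl("randomisation", cp$text)
  }, logical(1))))
})

test_that("corpus generation writes the requested split structure", {
  dir <- withr::local_tempdir()
  man <- generate_corpus(6, seed = 4, outdir = dir,
                         split_sizes = c(training = 3, testing = 2,
                                         validation = 1))
  expect_equal(man$n_documents, 6)
  splits <- vapply(man$documents, `[[`, "", "split")
  counts <- table(splits)
  expect_equal(as.integer(counts[c("training", "testing", "validation")]),
               c(3L, 2L, 1L))
  expect_length(list.files(dir, pattern = "^doc_.*\\.txt$"), 6L)
  expect_true(file.exists(file.path(dir, "truth.json")))
  expect_true(file.exists(file.path(dir, "manifest.json")))

  expect_error(generate_corpus(5, seed = 1, outdir = dir,
                               split_sizes = c(training = 3)), "sum to n")
})

test_that("not-implemented items are never truth-bearing", {
  for (seed in c(31, 32)) {
    real <- realize_manuscript(sample_manuscript_plan(seed))
    for (id in c("2a", "22", "17b")) {
      expect_false(isTRUE(real$truth$items[[id]]$present))
    }
  }
})
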