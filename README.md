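# consortcheck

Rule-based screening of randomized-clinical-trial manuscripts against the
CONSORT 2010 reporting checklist.

The CONSORT 2010 statement lists 37 sub-items an RCT report should contain
(randomized-trial identification in the title, eligibility criteria, sample
size determination, allocation concealment, blinding, participant flow,
harms, registration, funding, ...). `consortcheck` reads a manuscript —
plain text in a simple markup dialect, or a text-layer PDF — segments it
into IMRaD sections and sentences, and screens every sentence against
per-item lexical rules: lemma-level cue phrases, pattern/gazetteer entity
tagging (trial registry ids such as `NCT01148849`, allocation ratios such
as `1:1`, confidence intervals, organizations, locations), and
same-sentence co-occurrence constraints. The result is a filled checklist
plus *notifications* for findings that need human eyes:

* `MISSING_ALLOCATION_RATIO` — a trial-design sentence (item 3a) that never
  states the allocation ratio;
* `WRONG_SECTION` — evidence found only outside the section the checklist
  expects;
* `CHECK_FIGURE_OR_TABLE` — participant-flow items (13a/13b/16) whose
  numbers seem to live only in a flow-diagram figure.

Items 2a, 22 and 17b are too subjective for lexical rules and are carried
as *not implemented*; of the remaining 34 items, 30 participate in accuracy
scoring (item 10 and the figure-prone 13a/13b/16 are excluded).

For each scored item, **accuracy** over a corpus is the fraction of
articles assessed correctly, where correct means: the checker extracts a
truly relevant sentence (exact section + sentence-index agreement with the
ground truth), or reports a null finding for an article that truly lacks
the item. During rule development, extracted and missed sentences are
triaged into *positive / negative / undetected* groups and the rules are
refined until `(negative + undetected) / total < 10%` on a training split.

Because published trial PDFs cannot be redistributed, the package ships a
seeded synthetic-manuscript generator with exact ground truth (template
sentences per item, near-miss distractors, optional misplacement, flow
numbers confined to a figure caption) so the whole training/validation
design runs self-contained.

## Worked example

```r
library(consortcheck)

# generate one synthetic RCT manuscript (or point `check_document` at
# your own .txt / text-layer .pdf)
real <- realize_manuscript(sample_manuscript_plan(seed = 5))
path <- file.path(tempdir(), "trial_report.txt")
writeLines(real$text, path)

report <- check_document(path, quiet = TRUE)
print(report)
#> CONSORT checklist report for 'trial_report.txt'
#>   found            26
#>   notification     4
#>   not_found        4
#>   not_implemented  3
#>   note [3a]: A trial-design sentence was found, but the allocation ratio is not stated.
#>   note [12a]: Item 12a should be present in the Methods section of the article instead of the current Other information section.
#>   note [13b]: Please check whether Figure 1 contains the information for item 13b.
#>   note [14b]: Item 14b should be present in the Results section of the article instead of the current Other information section.
```

Reading the output: 26 checklist items were matched to sentences, 4 need
attention (this generated manuscript omits the allocation ratio from its
design sentence, reports two items in the wrong section, and confines the
losses-after-randomization numbers to the flow-diagram caption), 4 are
genuinely absent from the document, and 3 are never assessed by the tool.
`check_document()` also wrote `trial_report.consort.md` (the filled 37-row
checklist), `trial_report.notifications.md`, and `trial_report.report.json`
(lossless machine-readable report) next to the input.

Corpus-level evaluation:

```r
dir <- tempfile()
generate_corpus(22, seed = 1, outdir = dir, split_sizes = c(validation = 22))
ev <- evaluate_corpus_dir(dir)
ev$bands        # items per accuracy band (<80%, 80-90%, >90%)
ev$triage       # positive / negative / undetected sentence counts
```

A command-line front end wraps the same functions:

```sh
CLI=$(Rscript -e 'cat(system.file("exec", "consort-check", package = "consortcheck"))')
Rscript "$CLI" run paper.pdf --format md
Rscript "$CLI" synth --n 158 --seed 0 --splits 111,25,22 --outdir corpus/
Rscript "$CLI" evaluate --corpus corpus/ --split validation
```

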