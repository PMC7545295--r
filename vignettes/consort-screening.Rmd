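---
title: "Rule-based CONSORT screening: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rule-based CONSORT screening: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(consortcheck)
```

## The problem

The CONSORT 2010 statement enumerates 37 sub-items of information a
randomized-clinical-trial (RCT) report should contain — from identification
as a randomized trial in the title (item 1a) down to funding sources (item
25). Checking a manuscript against the list by hand is slow and error-prone;
`consortcheck` automates a first screening pass. It reads a manuscript,
locates candidate evidence sentences for each sub-item with deterministic
lexical rules, and emits a filled checklist plus a list of *notifications* —
findings that need human attention because the evidence is incomplete
(a trial-design sentence without an allocation ratio), misplaced (reported
in a section other than the one the checklist expects), or possibly
embedded in a figure or table (participant-flow counts that live only in a
flow diagram).

The tool is a screening aid, not a referee: item 2a (background/rationale)
and item 22 (interpretation) are too subjective for lexical rules and item
17b is only a recommendation, so these three are carried as
*not implemented*. Item 10 (who generated/enrolled/assigned) is detected on
a best-effort basis but excluded from accuracy scoring, as are the three
figure-prone flow items 13a, 13b and 16, leaving 30 scored items.

## Pipeline

Processing runs in four steps:

1. **Text acquisition.** Input is either the plain-text manuscript dialect
   (title line, labeled section headings, `Figure N.` / `Table N.` caption
   lines) or a text-layer PDF. The PDF adapter is intentionally minimal: a
   paired writer/extractor for uncompressed single-font PDFs, which the
   synthetic-corpus generator uses to render fixtures so that extraction
   error is measurable as a text diff. Two-column pages are linearized
   column-major; end-of-line hyphenation is repaired only when the break is
   mid-token (lowercase on both sides). Encrypted or image-only PDFs fail
   fast — OCR is out of scope.
2. **Segmentation.** Headings are canonicalized against a synonym lexicon
   ("Patients and Methods" → METHODS, "Comment" → DISCUSSION,
   "Acknowledgments"/"Funding"/"Trial Registration" → OTHER_INFO); captions
   are diverted to a separate caption list; reference lists are segmented
   but excluded from detection, because citation titles otherwise trigger
   keyword cues spuriously. Sentence boundaries are placed at `.?!` +
   whitespace + uppercase/digit, suppressed after protected abbreviations
   ("e.g.", "vs.", "Dr.", "et al.", "Fig.", "No.") and inside parenthetical
   spans. Character offsets are 0-based and half-open, and reassembling the
   sentence spans plus the whitespace between them must reproduce each
   section body byte for byte — this invariant is tested on every fixture.
3. **Detection.** Each sentence is tokenized, lemmatized and entity-tagged
   once, then screened against per-item rules (next section).
4. **Reporting.** The filled checklist and the notifications summary are
   rendered as markdown or docx from one shared row model (identical cell
   text in both formats), and the whole report serializes losslessly to
   JSON.

## Linguistic primitives

The lemmatizer is a small rule system: an exception lexicon for irregular
forms (`was → be`, `criteria → criterion`, `withdrew → withdraw`),
British→American normalization at the lemma level (`randomise → randomize`,
`hospitalisation → hospitalization`, `centre → center`), and regular
inflection stripping with final-e restoration driven by a verb lexicon
(`generated → generate`). It is lemmatization, not stemming: derivational
forms stay distinct (`randomized → randomize` but
`randomization → randomization`), which lets a cue distinguish "was
randomized" from "the randomization list". The suffix rules are deliberately
narrow; words outside the trial-reporting vocabulary may lemmatize
imperfectly (e.g. `exercise`), which is harmless because no cue uses them.

Entity tagging is pattern- and gazetteer-based, deterministic, and
longest-match non-overlapping within each kind:

* trial registry identifiers — `NCT` + 8 digits, `ISRCTN` + 8 digits,
  `EudraCT dddd-dddddd-dd`, `ACTRN` + 14 digits, `ChiCTR`, `UMIN` + 9
  digits;
* allocation ratios (`1:1`, `2 : 1`, `1:1:1`), confidence intervals
  (`95% CI, 2 to 7`, `95% confidence interval`), percentages, bare counts,
  month-year date ranges, and P values;
* organizations and locations from packaged gazetteers (funders, agencies
  and sponsors; countries, US states, major cities) plus a capitalization
  heuristic for multi-word names ending in an institutional head noun.

A pluggable statistical NER could replace the gazetteers behind the same
`tag_entities()` surface; the packaged version needs no model download and
is fully reproducible.

## Per-item detection rules

No public rule set exists for this task, so the per-item cue table
(`inst/extdata/cue_patterns.tsv`) is the package's central design artifact
and its main tuning surface. A rule row fires on a sentence when its cue
(a contiguous lemma phrase, a case-insensitive regex, or an entity kind) is
present, any required entity kind co-occurs *in the same sentence* (the
relationship-extraction constraint — e.g. item 4b needs a setting lemma
*and* a location/organization mention; item 7a needs "sample size" or
"power" *and* a count or percentage), and any word-sense gate lemma is
present (e.g. "blind" counts for item 11a only near a role word such as
participant, investigator or assessor; "block" counts for 8b only near a
randomization lemma). All matching sentences are kept, in document order.

Three notification conditions sit on top of found/not-found:

* **MISSING_ALLOCATION_RATIO** — item 3a found a trial-design sentence but
  no allocation-ratio entity occurs in any matched sentence;
* **CHECK_FIGURE_OR_TABLE** — a flow item (13a/13b/16) found no body
  evidence but a figure/table caption looks like a flow diagram
  (flow/CONSORT/enrolment vocabulary);
* **WRONG_SECTION** — a found item none of whose matched sentences lies in
  the checklist-expected section; the message names both the found and the
  expected section. Finding beats the notification: one correctly placed
  sentence suffices.

Most detectors search every body section, so misplaced evidence is still
found and then flagged by the placement check. Two items are
section-filtered instead: 12b (additional analyses, METHODS) and 18 (other
analyses performed, RESULTS) share so much vocabulary ("subgroup",
"adjusted", "analyses") that without the filter each would fire on the
other's sentences. This is a deliberate trade: those two items give up
wrong-section detection in exchange for precision.

## Evaluation machinery

Correctness of one item on one article follows the two-clause definition:
the checker either extracts a relevant sentence, or reports a null finding
for an article that truly lacks the item. Sentence identity is exact
(section label, sentence index) equality — the synthetic ground truth is
exact, and fuzzy overlap would mask offset bugs. A notification whose
matched sentence is correctly located counts as a correct extraction, since
a human is being pointed at the right place. Per-item accuracy is the
number of correctly assessed articles divided by all articles; items are
banded below 80%, 80–90%, and above 90%, with both boundaries assigned to
the middle band ("more than 90%" is read strictly).

Sentence triage partitions, over the 30 scored items, the union of
extracted and truth sentences into *positive* (extracted and true),
*negative* (extracted but not true) and *undetected* (true but missed);
`proportion_bad = (negative + undetected) / total` is the training-time
criterion driven below 10%. Restricting the universe to scored items keeps
caption-only notifications (which reference no sentence) out of a
sentence-level metric.

## The synthetic corpus

There is no redistributable corpus of annotated RCT manuscripts, so the
package ships a seeded generator whose output *is* the test bed. A plan
(drawn from a seed) decides per item: reported or omitted (default
inclusion probability 0.9 — high-impact-journal RCT reports carry most
items), misplaced into a non-expected section (probability 0.05),
figure-only for the flow items (probability 0.3 — flow numbers very often
live only in the CONSORT diagram), and an allocation-ratio-free design
sentence for 3a a quarter of the time. Every section also receives 2–3
near-miss distractors ("patients were assigned a study identification
number" — assignment vocabulary with no randomization semantics), which
operationalize the negative triage group; templates are parameterized from
seeded pools (drug names, conditions, counts, dates, registry ids) so no
two fixtures are textually identical and detectors cannot latch onto
literal strings. Items that are misplaced by the plan are drawn only from
those whose detectors search all sections, so placement noise tests the
wrong-section machinery rather than silently deleting evidence; the
realization step re-runs the package's own sentence splitter to record
exact truth coordinates, and a round-trip test verifies them after full
re-ingestion.

The experiment sizes mirror a 158-article study design: a training split
of 111 documents for rule refinement, a testing split of 25, and a
validation split of 22 for the headline per-item accuracy count. These are
the sizes the test suite and `scripts/acceptance.R` use.

What the generator does *not* emulate bounds what passing tests show: real
journal typography (running headers, references interleaved with text,
tables with numeric bodies), genuinely ambiguous clinical prose, reporting
styles outside the template vocabulary, and OCR noise. Accuracy on the
synthetic validation split demonstrates that the pipeline is internally
consistent and that the rules express the intended semantics — not that
the same rules reach the same accuracy on arbitrary published PDFs.

## Numerical and degenerate-input choices

* Offsets 0-based half-open everywhere; `substr(body, start + 1, end)`
  recovers a sentence.
* Empty input is legal at every level: an empty document yields 34
  null findings and 3 not-implemented rows, never an error.
* A manuscript without recognizable headings becomes one UNLABELED section
  plus a warning; detection still runs over it.
* Ties between multiple matching sentences are not broken — all matches are
  kept; the first (document order) is the one cited in the rendered
  checklist, truncated at 300 characters.
* The docx renderer writes a stored (uncompressed) ZIP container in pure R
  with its own CRC-32; markdown is the primary format and both renderings
  share one row model.

## Limitations

The rule vocabulary was refined against the synthetic training split until
the triage criterion was met, which is the method's own training procedure
but also means the rules and templates co-evolved; applying the tool to
real manuscripts will surface vocabulary the cue table lacks (the table is
a data file precisely so it can be extended without code changes). Items
2a, 22 and 17b remain out of scope by design, and item 9 (allocation
concealment) has the least distinctive vocabulary of the scored items —
its rule is kept deliberately high-recall.
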