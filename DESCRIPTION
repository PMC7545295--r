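Package: consortcheck
Title: Rule-Based CONSORT 2010 Compliance Screening for Randomized Trial Manuscripts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reads a randomized-clinical-trial manuscript (plain text or a
    simple text-layer PDF), segments it into canonical IMRaD sections and
    sentences, and screens it against the 37 sub-items of the CONSORT 2010
    reporting checklist using deterministic lexical rules: lemma-level cue
    matching, pattern/gazetteer entity tagging (trial registry identifiers,
    allocation ratios, confidence intervals, organizations, locations), and
    same-sentence co-occurrence constraints. Produces a filled checklist and
    a notifications summary (wrong section, missing allocation ratio,
    information possibly confined to a figure or table) as markdown, docx and
    JSON. Ships a seeded synthetic manuscript generator with exact ground
    truth plus an evaluation harness (per-item accuracy, accuracy banding,
    and positive/negative/undetected sentence triage) so detector
    performance can be measured end to end without any external corpus.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stringi,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
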