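# Shared lexical primitives: tokenizer, rule lemmatizer with British/American
# normalization, coarse POS tags, pattern/gazetteer entity tagging, and
# lemma-sequence cue matching. Everything here is deterministic.

# irregular forms and spelling variants the suffix rules cannot derive
LEMMA_EXCEPTIONS <- c(
  was = "be", were = "be", is = "be", are = "be", been = "be", being = "be",
  am = "be", has = "have", had = "have", having = "have", does = "do",
  did = "do", done = "do", went = "go", gone = "go", underwent = "undergo",
  undergone = "undergo", took = "take", taken = "take", gave = "give",
  given = "give", chose = "choose", chosen = "choose", lost = "lose",
  withdrew = "withdraw", withdrawn = "withdraw", met = "meet",
  men = "man", women = "woman", children = "child", criteria = "criterion",
  data = "data", analyses = "analysis", analysed = "analyze",
  analyse = "analyze", analysing = "analyze", emphasise = "emphasize",
  centre = "center", centres = "center", centred = "center",
  programme = "program", programmes = "program",
  generalisability = "generalizability", generalizability = "generalizability",
  enrolled = "enroll", enrolling = "enroll", enrolment = "enrollment",
  enrol = "enroll", labelled = "label", labelling = "label",
  stopped = "stop", stopping = "stop", planned = "plan", planning = "plan",
  occurred = "occur", saw = "see", seen = "see", found = "find", led = "lead",
  better = "good", best = "good", worse = "bad", worst = "bad"
)

# verbs whose -ed/-ing forms restore a final "e"
E_FINAL_VERBS <- c(
  "allocate", "administrate", "assume", "balance", "base", "calculate",
  "change", "compare", "complete", "conceive", "continue", "declare",
  "describe", "determine", "dose", "estimate", "evaluate", "examine",
  "exclude", "generate", "include", "indicate", "measure", "minimize",
  "note", "observe", "operate", "participate", "permute", "provide",
  "randomize", "receive", "reduce", "require", "schedule", "state",
  "stratify", "terminate", "use", "value", "analyze", "organize",
  "standardize", "hospitalize", "summarize", "tabulate", "write", "define",
  "time", "place", "square", "give", "make", "take", "combine", "decline"
)

VERB_LEXICON <- unique(c(E_FINAL_VERBS, c(
  "be", "have", "do", "go", "assign", "assess", "blind", "mask", "conceal",
  "enroll", "recruit", "treat", "report", "perform", "conduct", "collect",
  "record", "register", "fund", "support", "follow", "withdraw",
  "discontinue", "stop", "end", "amend", "adjust", "occur", "remain",
  "show", "find", "detect", "test", "review", "monitor", "approve",
  "obtain", "consent", "screen", "see", "meet", "lose", "undergo", "plan")))

ADJ_LEXICON <- c(
  "primary", "secondary", "random", "double-blind", "single-blind",
  "open-label", "parallel", "factorial", "multicenter", "placebo-controlled",
  "eligible", "adverse", "serious", "statistical", "clinical", "baseline",
  "identical", "interim", "two-sided", "one-sided", "exploratory",
  "prespecified", "pre-specified", "ancillary", "opaque", "sealed",
  "computer-generated", "intention-to-treat", "per-protocol")

#' Tokenize, lemmatize and POS-tag a sentence
#'
#' Tokens are maximal runs of letters (hyphen/apostrophe-joined compounds
#' stay single tokens, e.g. "double-blind"), numbers, or single punctuation
#' characters. Lemmas are lowercase canonical forms: irregular forms come
#' from a small exception lexicon, British spellings are normalized to
#' American at the lemma level (randomise -> randomize, hospitalisation ->
#' hospitalization, centre -> center), and regular inflections (-s, -es,
#' -ies, -ed, -ing) are stripped with consonant-doubling and final-e
#' restoration. Derivational suffixes are kept (lemmatization, not
#' stemming: "randomized" -> "randomize" but "randomization" ->
#' "randomization"). POS tags are coarse lexicon-based guesses
#' (NOUN/VERB/ADJ/NUM/OTHER); detectors rely on lemmas and entities, not on
#' tag subtleties.
#'
#' @param sentence Either a one-row sentence data frame (from
#'   [split_sentences()]) or a character scalar.
#' @return A `consort_annotated` list: `sentence` (text), `tokens` (data
#'   frame surface/start/end, 0-based half-open offsets within the
#'   sentence), `lemmas`, `pos`.
#' @export
annotate_sentence <- function(sentence) {
  text <- if (is.data.frame(sentence)) sentence$text[1] else sentence
  stopifnot(is.character(text), length(text) == 1L)
  if (!nzchar(text)) stop("cannot annotate an empty sentence", call. = FALSE)

  m <- gregexpr("[A-Za-z]+(?:['-][A-Za-z]+)*|[0-9]+(?:[.,][0-9]+)*|[^A-Za-z0-9 \t\n]",
                text, perl = TRUE)[[1]]
  if (m[1] == -1) {
    tokens <- data.frame(surface = character(0), start = integer(0),
                         end = integer(0), stringsAsFactors = FALSE)
  } else {
    len <- attr(m, "match.length")
    tokens <- data.frame(surface = substring(text, m, m + len - 1L),
                         start = as.integer(m - 1L),
                         end = as.integer(m + len - 1L),
                         stringsAsFactors = FALSE)
  }
  lemmas <- vapply(tokens$surface, lemmatize_token, "", USE.NAMES = FALSE)
  pos <- mapply(function(surface, lemma) {
    if (grepl("^[0-9]", surface)) "NUM"
    else if (!grepl("^[A-Za-z]", surface)) "OTHER"
    else if (lemma %in% VERB_LEXICON) "VERB"
    else if (lemma %in% ADJ_LEXICON) "ADJ"
    else "NOUN"
  }, tokens$surface, lemmas, USE.NAMES = FALSE)

  structure(list(sentence = text, tokens = tokens,
                 lemmas = lemmas, pos = pos),
            class = "consort_annotated")
}

#' @rdname annotate_sentence
#' @param token A single token (character scalar).
#' @export
lemmatize_token <- function(token) {
  w <- tolower(token)
  if (!grepl("^[a-z]", w)) return(w)
  hit <- LEMMA_EXCEPTIONS[w]
  if (!is.na(hit)) return(unname(hit))
  # British -is- suffixes -> -iz- (randomise(d), minimisation, organising)
  w <- sub("isation(s?)$", "ization\\1", w)
  w <- sub("is(e|ed|es|ing)$", "iz\\1", w)

  strip_e_restore <- function(stem) {
    if (paste0(stem, "e") %in% E_FINAL_VERBS) return(paste0(stem, "e"))
    # consonant doubling: stopped -> stop (handled by exceptions for common ones)
    if (grepl("([b-df-hj-np-tv-z])\\1$", stem)) {
      undoubled <- sub("(.)\\1$", "\\1", stem)
      if (!undoubled %in% c("ro", "fu")) return(stem)  # keep e.g. "enroll"
    }
    stem
  }
  if (grepl("ies$", w) && nchar(w) > 4) return(sub("ies$", "y", w))
  if (grepl("ied$", w) && nchar(w) > 4) return(sub("ied$", "y", w))
  if (grepl("ing$", w) && nchar(w) > 5) return(strip_e_restore(sub("ing$", "", w)))
  if (grepl("ed$", w) && nchar(w) > 4) return(strip_e_restore(sub("ed$", "", w)))
  if (grepl("(sses|ches|shes|xes|zes)$", w)) return(sub("es$", "", w))
  if (grepl("s$", w) && !grepl("(ss|us|is)$", w) && nchar(w) > 3) {
    return(sub("s$", "", w))
  }
  w
}

# ---- entity tagging -------------------------------------------------------

MONTHS_RE <- "(January|February|March|April|May|June|July|August|September|October|November|December)"

ENTITY_PATTERNS <- list(
  REGISTRY_ID = paste0(
    "NCT[0-9]{8}|ISRCTN[0-9]{8}|EudraCT[ -]?[0-9]{4}-[0-9]{6}-[0-9]{2}|",
    "ACTRN[0-9]{14}|ChiCTR-?[A-Za-z0-9-]{4,}|UMIN[0-9]{9}"),
  ALLOCATION_RATIO = "[0-9]{1,2}\\s*:\\s*[0-9]{1,2}(\\s*:\\s*[0-9]{1,2})?",
  CONFIDENCE_INTERVAL = paste0(
    "[0-9]{2}(\\.[0-9]+)?%\\s*(CI|confidence interval)",
    "(\\s*[,:]?\\s*-?[0-9.]+\\s*(to|–|-|,)\\s*-?[0-9.]+)?"),
  P_VALUE = "\\bP\\s*[<>=]\\s*\\.?[0-9]+(\\.[0-9]+)?",
  PERCENTAGE = "-?[0-9]+(\\.[0-9]+)?%",
  DATE_RANGE = paste0(MONTHS_RE, "\\s+[0-9]{4}\\s+(to|and|through|until|–|-)\\s+",
                      "(", MONTHS_RE, "\\s+)?[0-9]{4}"),
  COUNT = "(?<![0-9.:])[0-9]{1,6}(?![0-9.:%])"
)

load_gazetteer <- function(which = c("organizations", "locations")) {
  which <- match.arg(which)
  key <- paste0("gaz_", which)
  if (!is.null(.consort_cache[[key]])) return(.consort_cache[[key]])
  lines <- readLines(.extdata(paste0("gazetteer_", which, ".txt")), encoding = "UTF-8")
  lines <- trimws(lines[!grepl("^\\s*(#|$)", lines)])
  .consort_cache[[key]] <- lines
  lines
}

# one longest-first alternation regex per gazetteer, cached
gazetteer_pattern <- function(which) {
  key <- paste0("gazpat_", which)
  if (!is.null(.consort_cache[[key]])) return(.consort_cache[[key]])
  entries <- load_gazetteer(which)
  entries <- entries[order(-nchar(entries))]
  esc <- gsub("([.|()\\^{}+$*?\\[\\]\\\\-])", "\\\\\\1", entries)
  pat <- paste0("(?<![A-Za-z])(", paste(esc, collapse = "|"), ")(?![A-Za-z])")
  .consort_cache[[key]] <- pat
  pat
}

regex_matches <- function(text, pattern, perl = TRUE) {
  m <- gregexpr(pattern, text, perl = perl)[[1]]
  if (m[1] == -1) return(NULL)
  len <- attr(m, "match.length")
  data.frame(start = as.integer(m - 1L), end = as.integer(m + len - 1L),
             text = substring(text, m, m + len - 1L), stringsAsFactors = FALSE)
}

# longest-match, non-overlapping selection within one entity kind
drop_overlaps <- function(df) {
  if (is.null(df) || !nrow(df)) return(df)
  df <- df[order(df$start, -(df$end - df$start)), , drop = FALSE]
  keep <- logical(nrow(df)); last_end <- -1L
  for (i in seq_len(nrow(df))) {
    if (df$start[i] >= last_end) { keep[i] <- TRUE; last_end <- df$end[i] }
  }
  df[keep, , drop = FALSE]
}

#' Tag entity mentions in an annotated sentence
#'
#' Pattern-driven kinds (trial registry identifiers, allocation ratios,
#' confidence intervals, percentages, counts, date ranges, P values) are
#' matched by regular expressions, greedily and longest-match,
#' non-overlapping within each kind. Organizations and locations come from
#' packaged gazetteers plus a capitalization heuristic for multi-word
#' proper names ending in an institutional head noun (University, Institute,
#' Hospital, ...).
#'
#' @param annotated A `consort_annotated` from [annotate_sentence()].
#' @return Data frame with columns `kind`, `start`, `end` (0-based,
#'   half-open offsets into the sentence), `normalized`.
#' @export
tag_entities <- function(annotated) {
  stopifnot(inherits(annotated, "consort_annotated"))
  text <- annotated$sentence
  out <- list()
  for (kind in names(ENTITY_PATTERNS)) {
    df <- drop_overlaps(regex_matches(text, ENTITY_PATTERNS[[kind]]))
    if (is.null(df) || !nrow(df)) next
    norm <- switch(kind,
      ALLOCATION_RATIO = gsub("\\s", "", df$text),
      REGISTRY_ID = gsub("\\s", "", df$text),
      df$text)
    out[[kind]] <- data.frame(kind = kind, start = df$start, end = df$end,
                              normalized = norm, stringsAsFactors = FALSE)
  }
  # gazetteer ORG / LOCATION (each gazetteer compiled to one alternation)
  for (spec in list(c("organizations", "ORG"), c("locations", "LOCATION"))) {
    hits <- regex_matches(text, gazetteer_pattern(spec[1]))
    # capitalization heuristic for organizations
    if (spec[2] == "ORG") {
      df <- regex_matches(text, paste0(
        "((?!The )[A-Z][a-z]+ )+?(University|Institute|Hospital|Foundation|Council|",
        "Center|Centre|Ministry|Organization|Organisation|Society|Agency|College)\\b"))
      if (!is.null(df)) hits <- rbind(hits, df)
    }
    hits <- drop_overlaps(hits)
    if (!is.null(hits) && nrow(hits)) {
      out[[spec[2]]] <- data.frame(kind = spec[2], start = hits$start,
                                   end = hits$end, normalized = hits$text,
                                   stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(kind = character(0), start = integer(0),
                      end = integer(0), normalized = character(0),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$start, res$kind), , drop = FALSE]
}

# ---- cue matching ---------------------------------------------------------

#' Match cue patterns against an annotated sentence
#'
#' A cue pattern is either a lemma sequence (space-separated lemmas that
#' must occur contiguously in the sentence's lemma stream) or a regular
#' expression evaluated case-insensitively over the sentence text. All
#' patterns are evaluated and every hit is returned (overlaps are not
#' suppressed).
#'
#' @param annotated A `consort_annotated`.
#' @param patterns Data frame with columns `cue_id`, `kind` (`"lemma"` or
#'   `"regex"`), `pattern`, and optionally `weight`.
#' @return Data frame of hits: `cue_id`, `start`, `end` (0-based character
#'   offsets into the sentence).
#' @export
match_cues <- function(annotated, patterns) {
  stopifnot(inherits(annotated, "consort_annotated"), is.data.frame(patterns))
  hits <- list()
  for (i in seq_len(nrow(patterns))) {
    p <- patterns[i, ]
    if (identical(p$kind, "regex")) {
      bad <- function(e) {
        stop("malformed regex in cue pattern '", p$cue_id, "': ",
             conditionMessage(e), call. = FALSE)
      }
      ok <- tryCatch(regex_matches(annotated$sentence, p$pattern),
                     error = bad, warning = bad)
      if (!is.null(ok) && nrow(ok)) {
        hits[[length(hits) + 1L]] <- data.frame(
          cue_id = p$cue_id, start = ok$start, end = ok$end,
          stringsAsFactors = FALSE)
      }
    } else {
      seq_lemmas <- strsplit(trimws(p$pattern), "\\s+")[[1]]
      pos <- match_lemma_sequence(annotated, seq_lemmas)
      if (length(pos)) {
        toks <- annotated$tokens
        hits[[length(hits) + 1L]] <- data.frame(
          cue_id = p$cue_id,
          start = toks$start[pos],
          end = toks$end[pos + length(seq_lemmas) - 1L],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(hits)) {
    return(data.frame(cue_id = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, hits)
}

# starting token positions where the lemma sequence matches contiguously
match_lemma_sequence <- function(annotated, seq_lemmas) {
  lem <- annotated$lemmas
  k <- length(seq_lemmas)
  if (!k || length(lem) < k) return(integer(0))
  out <- integer(0)
  for (s in seq_len(length(lem) - k + 1L)) {
    if (all(lem[s:(s + k - 1L)] == seq_lemmas)) out <- c(out, s)
  }
  out
}

# convenience: does the sentence contain this lemma (or any of these)?
has_lemma <- function(annotated, lemmas) any(annotated$lemmas %in% lemmas)
has_phrase <- function(annotated, phrase) {
  length(match_lemma_sequence(annotated, strsplit(phrase, "\\s+")[[1]])) > 0L
}
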