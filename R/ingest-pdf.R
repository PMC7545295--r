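# Minimal PDF adapter.
#
# The checking pipeline operates on the plain-text manuscript dialect; PDF
# support is an adapter in front of it. The writer emits a small, valid,
# uncompressed PDF (Helvetica, one text-showing operation per line) in one- or
# two-column layout; the extractor reads any PDF whose content streams are
# unencrypted and uncompressed, recovers positioned text lines, linearizes
# two-column pages column-major (left column top-to-bottom, then right), and
# repairs end-of-line hyphenation. Encrypted or image-only PDFs (no text
# operators) fail fast; OCR is out of scope.

PDF_PAGE_W <- 612; PDF_PAGE_H <- 792   # US letter, points
PDF_MARGIN <- 54; PDF_LEADING <- 13; PDF_FONTSIZE <- 10

pdf_escape <- function(s) {
  s <- gsub("\\", "\\\\", s, fixed = TRUE)
  s <- gsub("(", "\\(", s, fixed = TRUE)
  gsub(")", "\\)", s, fixed = TRUE)
}

pdf_unescape <- function(s) {
  s <- gsub("\\(", "(", s, fixed = TRUE)
  s <- gsub("\\)", ")", s, fixed = TRUE)
  gsub("\\\\", "\\", s, fixed = TRUE)
}

# wrap text to a column width measured in characters (Helvetica ~0.5em/char)
wrap_line <- function(line, width_chars) {
  if (!nzchar(trimws(line))) return("")
  out <- character(0)
  words <- strsplit(line, " +")[[1]]
  cur <- ""
  for (w in words) {
    cand <- if (nzchar(cur)) paste(cur, w) else w
    if (nchar(cand) <= width_chars || !nzchar(cur)) cur <- cand
    else { out <- c(out, cur); cur <- w }
  }
  c(out, cur)
}

#' Render plain text as a simple text-layer PDF
#'
#' Writes an uncompressed single-font PDF whose text layer reproduces
#' `text` line for line (after word-wrapping to the column width). Used by
#' the synthetic corpus generator so that PDF extraction error is
#' measurable as a text diff against the known source.
#'
#' @param text Character scalar; `""` yields a zero-page PDF.
#' @param path Output file path.
#' @param columns 1 (default) or 2; with 2, lines fill the left column of a
#'   page top-to-bottom, then the right column.
#' @return `path`, invisibly.
#' @export
write_manuscript_pdf <- function(text, path, columns = 1L) {
  stopifnot(is.character(text), length(text) == 1L, columns %in% c(1L, 2L))
  text <- normalize_text(text)
  usable_h <- PDF_PAGE_H - 2 * PDF_MARGIN
  lines_per_col <- floor(usable_h / PDF_LEADING)
  col_w <- if (columns == 2L) (PDF_PAGE_W - 3 * PDF_MARGIN) / 2 else PDF_PAGE_W - 2 * PDF_MARGIN
  width_chars <- floor(col_w / (PDF_FONTSIZE * 0.5))

  lines <- if (nzchar(text)) {
    unlist(lapply(strsplit(text, "\n", fixed = TRUE)[[1]], wrap_line, width_chars))
  } else character(0)

  per_page <- lines_per_col * columns
  n_pages <- if (length(lines)) ceiling(length(lines) / per_page) else 0L

  objs <- list()  # body of each numbered object, in object-number order
  # 1: catalog, 2: pages, 3: font; pages start at 4 (content streams follow)
  page_obj_ids <- if (n_pages) 3L + seq_len(n_pages) else integer(0)
  content_obj_ids <- page_obj_ids + n_pages
  kids <- paste(sprintf("%d 0 R", page_obj_ids), collapse = " ")
  objs[[1]] <- "<< /Type /Catalog /Pages 2 0 R >>"
  objs[[2]] <- sprintf("<< /Type /Pages /Kids [%s] /Count %d >>", kids, n_pages)
  objs[[3]] <- "<< /Type /Font /Subtype /Type1 /BaseFont /Helvetica >>"

  for (p in seq_len(n_pages)) {
    page_lines <- lines[((p - 1L) * per_page + 1L):min(p * per_page, length(lines))]
    ops <- c("BT", sprintf("/F1 %d Tf", PDF_FONTSIZE))
    for (k in seq_along(page_lines)) {
      col <- if (columns == 2L) ((k - 1L) %/% lines_per_col) else 0L
      row <- (k - 1L) %% lines_per_col
      x <- PDF_MARGIN + col * (col_w + PDF_MARGIN)
      y <- PDF_PAGE_H - PDF_MARGIN - row * PDF_LEADING
      if (nzchar(page_lines[k])) {
        ops <- c(ops, sprintf("1 0 0 1 %.1f %.1f Tm (%s) Tj",
                              x, y, pdf_escape(page_lines[k])))
      }
    }
    ops <- c(ops, "ET")
    stream <- paste(ops, collapse = "\n")
    objs[[page_obj_ids[p]]] <- sprintf(
      "<< /Type /Page /Parent 2 0 R /MediaBox [0 0 %d %d] /Resources << /Font << /F1 3 0 R >> >> /Contents %d 0 R >>",
      PDF_PAGE_W, PDF_PAGE_H, content_obj_ids[p])
    objs[[content_obj_ids[p]]] <- sprintf(
      "<< /Length %d >>\nstream\n%s\nendstream", nchar(stream, "bytes"), stream)
  }

  con <- file(path, "wb")
  on.exit(close(con))
  put <- function(s) writeBin(charToRaw(s), con)
  offsets <- integer(length(objs))
  put("%PDF-1.4\n")
  pos <- nchar("%PDF-1.4\n", "bytes")
  for (i in seq_along(objs)) {
    offsets[i] <- pos
    chunk <- sprintf("%d 0 obj\n%s\nendobj\n", i, objs[[i]])
    put(chunk)
    pos <- pos + nchar(chunk, "bytes")
  }
  xref_pos <- pos
  xref <- c(sprintf("xref\n0 %d", length(objs) + 1L),
            "0000000000 65535 f ",
            sprintf("%010d 00000 n ", offsets))
  put(paste0(paste(xref, collapse = "\n"), "\n"))
  put(sprintf("trailer\n<< /Size %d /Root 1 0 R >>\nstartxref\n%d\n%%%%EOF\n",
              length(objs) + 1L, xref_pos))
  invisible(path)
}

# de-hyphenate line breaks: join "frag-" + "ment" only when the break is
# mid-token (lowercase letter on both sides of the hyphen)
repair_hyphenation <- function(lines) {
  i <- 1L
  while (i < length(lines)) {
    if (grepl("[a-z]-$", lines[i]) && grepl("^[a-z]", lines[i + 1L])) {
      lines[i] <- paste0(sub("-$", "", lines[i]), lines[i + 1L])
      lines <- lines[-(i + 1L)]
    } else i <- i + 1L
  }
  lines
}

#' Extract the text layer from a PDF
#'
#' Reads an unencrypted PDF with uncompressed content streams, collects
#' positioned text-showing operations, orders them top-to-bottom within
#' columns and left column before right (column-major linearization), and
#' repairs end-of-line hyphenation. Compressed-stream PDFs are reported as
#' having no readable text layer; OCR of image-only PDFs is out of scope.
#'
#' @param pdf_path Path to a PDF file.
#' @return A `consort_rawdoc` with one element of `pages` per PDF page.
#' @export
extract_pdf_text <- function(pdf_path) {
  if (!file.exists(pdf_path)) stop("file not found: ", pdf_path, call. = FALSE)
  raw <- readBin(pdf_path, "raw", file.size(pdf_path))
  txt <- rawToChar(raw[raw != as.raw(0)])
  Encoding(txt) <- "latin1"
  if (!startsWith(txt, "%PDF")) {
    stop("not a PDF file (missing %PDF header): ", pdf_path, call. = FALSE)
  }
  if (grepl("/Encrypt", txt, fixed = TRUE)) {
    stop("PDF is encrypted; cannot extract text: ", pdf_path, call. = FALSE)
  }

  # page objects in document order give us the page partition
  n_pages <- length(gregexpr("/Type\\s*/Page[^s]", txt, perl = TRUE)[[1]])
  if (attr(gregexpr("/Type\\s*/Page[^s]", txt, perl = TRUE)[[1]], "match.length")[1] == -1) n_pages <- 0L

  # collect text ops per content stream
  streams <- regmatches(txt, gregexpr("stream\r?\n.*?endstream", txt))[[1]]
  has_tj <- any(grepl("\\bTj\\b|\\bTJ\\b", streams))
  if (length(streams) && !has_tj || (!length(streams) && n_pages > 0L)) {
    stop("PDF has no readable text layer (image-only or compressed streams); ",
         "OCR is out of scope: ", pdf_path, call. = FALSE)
  }

  pages <- character(0)
  for (st in streams) {
    ops <- regmatches(st, gregexpr(
      "1 0 0 1 ([0-9.]+) ([0-9.]+) Tm \\(((?:[^()\\\\]|\\\\.)*)\\) Tj",
      st, perl = TRUE))[[1]]
    if (!length(ops)) { if (grepl("BT", st)) pages <- c(pages, ""); next }
    m <- regmatches(ops, regexec(
      "1 0 0 1 ([0-9.]+) ([0-9.]+) Tm \\(((?:[^()\\\\]|\\\\.)*)\\) Tj", ops, perl = TRUE))
    x <- vapply(m, function(g) as.numeric(g[2]), 0)
    y <- vapply(m, function(g) as.numeric(g[3]), 0)
    s <- vapply(m, function(g) pdf_unescape(g[4]), "")
    # column-major: cluster x into columns, read each top-to-bottom
    xs <- sort(unique(round(x)))
    col_of <- vapply(round(x), function(v) which.min(abs(xs - v)), 0L)
    # merge x clusters closer than 20pt
    col_id <- cumsum(c(TRUE, diff(xs) > 20))
    col_of <- col_id[col_of]
    ord <- order(col_of, -y)
    lines <- repair_hyphenation(s[ord])
    pages <- c(pages, paste(lines, collapse = "\n"))
  }

  structure(list(pages = pages, source_kind = "pdf", warnings = character(0)),
            class = "consort_rawdoc")
}
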