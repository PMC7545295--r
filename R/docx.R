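# Minimal OOXML (docx) writer. A docx file is a ZIP container of XML parts;
# entries are written with the "stored" (uncompressed) method so the
# container can be produced in pure R. Readable by Word, LibreOffice and
# unzip alike.

crc32_table <- local({
  tab <- NULL
  function() {
    if (!is.null(tab)) return(tab)
    t <- integer(256)
    for (n in 0:255) {
      c <- n
      for (k in 1:8) {
        c <- if (bitwAnd(c, 1L) != 0L) {
          bitwXor(bitwAnd(bitwShiftR(c, 1), 0x7FFFFFFF), -306674912L)  # 0xEDB88320
        } else bitwAnd(bitwShiftR(c, 1), 0x7FFFFFFF)
      }
      t[n + 1L] <- c
    }
    tab <<- t
    t
  }
})

crc32 <- function(bytes) {
  tab <- crc32_table()
  crc <- -1L  # 0xFFFFFFFF
  for (b in as.integer(bytes)) {
    idx <- bitwAnd(bitwXor(crc, b), 255L)
    crc <- bitwXor(bitwAnd(bitwShiftR(crc, 8), 0x00FFFFFF), tab[idx + 1L])
  }
  bitwXor(crc, -1L)
}

int_to_raw <- function(x, n) {
  # little-endian unsigned; x may be a (signed) 32-bit integer
  out <- raw(n)
  v <- as.double(x)
  if (v < 0) v <- v + 2^32
  for (i in seq_len(n)) {
    out[i] <- as.raw(v %% 256)
    v <- v %/% 256
  }
  out
}

# write a stored-method ZIP archive; entries = named list of raw vectors
write_stored_zip <- function(path, entries) {
  con <- file(path, "wb")
  on.exit(close(con))
  offsets <- integer(length(entries))
  crcs <- numeric(length(entries))
  pos <- 0L
  dostime <- int_to_raw(0L, 2); dosdate <- int_to_raw(33L, 2)  # fixed epoch-ish stamp
  for (i in seq_along(entries)) {
    name <- charToRaw(names(entries)[i])
    data <- entries[[i]]
    crcs[i] <- crc32(data)
    offsets[i] <- pos
    header <- c(charToRaw("PK\x03\x04"), int_to_raw(20L, 2), int_to_raw(0L, 2),
                int_to_raw(0L, 2), dostime, dosdate, int_to_raw(crcs[i], 4),
                int_to_raw(length(data), 4), int_to_raw(length(data), 4),
                int_to_raw(length(name), 2), int_to_raw(0L, 2), name)
    writeBin(header, con)
    writeBin(data, con)
    pos <- pos + length(header) + length(data)
  }
  cd_start <- pos
  for (i in seq_along(entries)) {
    name <- charToRaw(names(entries)[i])
    data <- entries[[i]]
    cd <- c(charToRaw("PK\x01\x02"), int_to_raw(20L, 2), int_to_raw(20L, 2),
            int_to_raw(0L, 2), int_to_raw(0L, 2), dostime, dosdate,
            int_to_raw(crcs[i], 4), int_to_raw(length(data), 4),
            int_to_raw(length(data), 4), int_to_raw(length(name), 2),
            int_to_raw(0L, 2), int_to_raw(0L, 2), int_to_raw(0L, 2),
            int_to_raw(0L, 2), int_to_raw(0L, 4), int_to_raw(offsets[i], 4),
            name)
    writeBin(cd, con)
    pos <- pos + length(cd)
  }
  eocd <- c(charToRaw("PK\x05\x06"), int_to_raw(0L, 2), int_to_raw(0L, 2),
            int_to_raw(length(entries), 2), int_to_raw(length(entries), 2),
            int_to_raw(pos - cd_start, 4), int_to_raw(cd_start, 4),
            int_to_raw(0L, 2))
  writeBin(eocd, con)
  invisible(path)
}

xml_escape <- function(s) {
  s <- gsub("&", "&amp;", s, fixed = TRUE)
  s <- gsub("<", "&lt;", s, fixed = TRUE)
  s <- gsub(">", "&gt;", s, fixed = TRUE)
  gsub('"', "&quot;", s, fixed = TRUE)
}

docx_parts <- function(document_xml) {
  list(
    "[Content_Types].xml" = charToRaw(paste0(
      '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
      '<Types xmlns="http://schemas.openxmlformats.org/package/2006/content-types">',
      '<Default Extension="rels" ContentType="application/vnd.openxmlformats-package.relationships+xml"/>',
      '<Default Extension="xml" ContentType="application/xml"/>',
      '<Override PartName="/word/document.xml" ContentType="application/vnd.openxmlformats-officedocument.wordprocessingml.document.main+xml"/>',
      '</Types>')),
    "_rels/.rels" = charToRaw(paste0(
      '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
      '<Relationships xmlns="http://schemas.openxmlformats.org/package/2006/relationships">',
      '<Relationship Id="rId1" Type="http://schemas.openxmlformats.org/officeDocument/2006/relationships/officeDocument" Target="word/document.xml"/>',
      '</Relationships>')),
    "word/document.xml" = charToRaw(document_xml)
  )
}

docx_par <- function(text, bold = FALSE) {
  rpr <- if (bold) "<w:rPr><w:b/></w:rPr>" else ""
  sprintf('<w:p><w:r>%s<w:t xml:space="preserve">%s</w:t></w:r></w:p>',
          rpr, xml_escape(text))
}

docx_document <- function(body_xml) {
  paste0('<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
         '<w:document xmlns:w="http://schemas.openxmlformats.org/wordprocessingml/2006/main">',
         "<w:body>", body_xml, "</w:body></w:document>")
}

write_docx_table <- function(path, title, header, rows) {
  cell <- function(text, bold = FALSE) {
    sprintf("<w:tc><w:tcPr><w:tcW w:w='3000' w:type='dxa'/></w:tcPr>%s</w:tc>",
            docx_par(text, bold))
  }
  tr <- function(cells, bold = FALSE) {
    paste0("<w:tr>", paste(vapply(cells, cell, "", bold = bold), collapse = ""),
           "</w:tr>")
  }
  tbl <- paste0(
    "<w:tbl><w:tblPr><w:tblBorders>",
    paste(sprintf("<w:%s w:val='single' w:sz='4' w:space='0' w:color='auto'/>",
                  c("top", "left", "bottom", "right", "insideH", "insideV")),
          collapse = ""),
    "</w:tblBorders></w:tblPr>",
    tr(as.list(header), bold = TRUE),
    paste(vapply(rows, function(r) tr(as.list(r)), ""), collapse = ""),
    "</w:tbl>")
  body <- paste0(docx_par(title, bold = TRUE), tbl)
  write_stored_zip(path, docx_parts(docx_document(body)))
}

write_docx_paragraphs <- function(path, title, paragraphs) {
  body <- paste0(docx_par(title, bold = TRUE),
                 paste(vapply(paragraphs, docx_par, ""), collapse = ""))
  write_stored_zip(path, docx_parts(docx_document(body)))
}
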