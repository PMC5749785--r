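#' Read a character matrix (NEXUS, TSV or relaxed PHYLIP)
#'
#' Format is sniffed: a `#NEXUS` header starts a NEXUS standard/DNA matrix
#' (the `MATRIX` block of a `DATA` or `CHARACTERS` block); a first line of
#' two integers starts relaxed PHYLIP (`name sequence`); anything else is
#' read as TSV with a `taxon` column followed by one column per character
#' (or a single `chars` column holding the concatenated row string).
#'
#' @param path Input file.
#' @return A [char_matrix()].
#' @export
read_char_matrix <- function(path) {
  lines <- readLines(path, warn = FALSE)
  .assert(length(lines) > 0L, "empty matrix file", "plastodecay_parse_error")
  first <- trimws(lines[1L])
  if (toupper(first) == "#NEXUS") return(.read_nexus_matrix(lines))
  if (grepl("^\\s*\\d+\\s+\\d+\\s*$", first)) {
    body <- lines[-1L]
    body <- body[nzchar(trimws(body))]
    parts <- strsplit(trimws(body), "\\s+")
    taxa <- vapply(parts, `[`, "", 1L)
    seqs <- vapply(parts, function(p) paste(p[-1L], collapse = ""), "")
    mat <- do.call(rbind, strsplit(toupper(seqs), "", fixed = TRUE))
    rownames(mat) <- taxa
    return(char_matrix(mat))
  }
  d <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE)
  .assert("taxon" %in% names(d), "TSV matrix needs a 'taxon' column",
          "plastodecay_parse_error")
  taxa <- d$taxon
  d$taxon <- NULL
  mat <- if (ncol(d) == 1L && all(nchar(d[[1L]]) > 1L)) {
    do.call(rbind, strsplit(d[[1L]], "", fixed = TRUE))
  } else as.matrix(d)
  rownames(mat) <- taxa
  colnames(mat) <- NULL
  char_matrix(mat)
}

.read_nexus_matrix <- function(lines) {
  up <- toupper(lines)
  mstart <- grep("^\\s*MATRIX\\s*$", up)
  .assert(length(mstart) >= 1L, "NEXUS file has no MATRIX block",
          "plastodecay_parse_error")
  mstart <- mstart[1L]
  rows <- list()
  for (i in (mstart + 1L):length(lines)) {
    txt <- trimws(lines[i])
    if (txt == ";" || grepl(";\\s*$", txt)) {
      txt <- sub(";\\s*$", "", txt)
      if (nzchar(txt)) {
        p <- strsplit(txt, "\\s+")[[1L]]
        rows[[p[1L]]] <- paste0(if (is.null(rows[[p[1L]]])) "" else
          rows[[p[1L]]], paste(p[-1L], collapse = ""))
      }
      break
    }
    if (!nzchar(txt) || startsWith(txt, "[")) next
    p <- strsplit(txt, "\\s+")[[1L]]
    rows[[p[1L]]] <- paste0(if (is.null(rows[[p[1L]]])) "" else rows[[p[1L]]],
                            paste(p[-1L], collapse = ""))
  }
  .assert(length(rows) >= 2L, "NEXUS matrix has fewer than 2 taxa",
          "plastodecay_parse_error")
  mat <- do.call(rbind, strsplit(toupper(unlist(rows)), "", fixed = TRUE))
  rownames(mat) <- names(rows)
  char_matrix(mat)
}
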