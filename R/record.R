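#' Plastome record container
#'
#' Internal coordinates are 0-based half-open on the linearized circular
#' sequence; file I/O converts to each format's native convention.
#'
#' @param id Identifier.
#' @param seq Nucleotide string (A/C/G/T/N; uppercased on input).
#' @param regions `data.frame` with columns `region` (LSC/IRa/SSC/IRb),
#'   `start`, `end`, or `NULL` when unknown.
#' @param genes Annotation `data.frame` with columns `name`, `type` (CDS,
#'   tRNA, rRNA, intron, pseudogene, other), `strand`, `region`, `part`,
#'   `start`, `end`.
#' @return An object of class `plastome_record`.
#' @export
plastome_record <- function(id, seq, regions = NULL, genes = NULL) {
  seq <- toupper(seq)
  bad <- setdiff(unique(.chars(seq)), c(.DNA, "N"))
  .assert(length(bad) == 0L,
          sprintf("sequence contains unsupported characters: %s",
                  paste(bad, collapse = ",")), "plastodecay_parse_error")
  n <- nchar(seq)
  if (!is.null(genes) && nrow(genes) > 0L) {
    .assert(all(genes$start >= 0L & genes$end <= n & genes$start < genes$end),
            "annotation coordinates exceed sequence length",
            "plastodecay_bounds_error")
  }
  structure(list(id = id, seq = seq, regions = regions, genes = genes,
                 length = n),
            class = "plastome_record")
}

#' @export
print.plastome_record <- function(x, ...) {
  cat(sprintf("<plastome_record> %s: %d bp, %d annotations\n", x$id, x$length,
              if (is.null(x$genes)) 0L else nrow(x$genes)))
  if (!is.null(x$regions)) {
    with(x$regions, cat(paste(sprintf("  %s: %d..%d (%d bp)", region, start,
                                      end, end - start), collapse = "\n"), "\n"))
  }
  invisible(x)
}

#' Extract a region's sequence from a record
#' @param record A `plastome_record` with regions.
#' @param region One of `"LSC"`, `"IRa"`, `"SSC"`, `"IRb"`.
#' @return Nucleotide string.
#' @export
region_seq <- function(record, region) {
  .assert(!is.null(record$regions), "record has no region boundaries",
          "plastodecay_invalid_argument")
  r <- record$regions[record$regions$region == region, ]
  .assert(nrow(r) == 1L, sprintf("unknown region %s", region),
          "plastodecay_invalid_argument")
  substr(record$seq, r$start + 1L, r$end)
}

#' Extract a gene's coding-strand sequence (introns spliced out)
#' @param record A `plastome_record`.
#' @param gene Gene name; IR-duplicated genes return the first copy.
#' @return Nucleotide string on the coding strand.
#' @export
gene_seq <- function(record, gene) {
  d <- record$genes[record$genes$name == gene &
                      !(record$genes$type %in% "intron"), , drop = FALSE]
  .assert(nrow(d) > 0L, sprintf("gene %s not annotated", gene),
          "plastodecay_missing_gene")
  rg <- d$region[1L]
  if (!is.na(rg)) d <- d[d$region == rg, , drop = FALSE]
  d <- d[order(d$start), , drop = FALSE]
  s <- paste(substring(record$seq, d$start + 1L, d$end), collapse = "")
  if (d$strand[1L] == "-") .revcomp(s) else s
}

# Replace record$seq[start, end) by `replacement`, shifting all downstream
# annotation and region coordinates. Assumes the interval lies inside a single
# annotated feature (or intergenic) and a single region.
.splice <- function(record, start, end, replacement = "") {
  delta <- nchar(replacement) - (end - start)
  record$seq <- paste0(substr(record$seq, 1L, start),
                       replacement,
                       substr(record$seq, end + 1L, record$length))
  shift <- function(x, lo) ifelse(x >= lo, x + delta, x)
  if (!is.null(record$genes) && nrow(record$genes) > 0L) {
    g <- record$genes
    g$start <- shift(g$start, end)
    g$end <- shift(g$end, start + 1L)  # features ending at/after the cut shrink
    keep <- g$end > g$start
    record$genes <- g[keep, , drop = FALSE]
  }
  if (!is.null(record$regions)) {
    r <- record$regions
    r$start <- shift(r$start, end)
    r$end <- shift(r$end, start + 1L)
    record$regions <- r
  }
  record$length <- nchar(record$seq)
  record
}
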