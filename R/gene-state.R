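#' Locate a reference gene in a query plastome
#'
#' Finds maximal local alignments between the query genome (both strands) and
#' a reference CDS with at least `min_identity` nucleotide identity and
#' `min_len` aligned bases. Hits are found by repeated best local alignment
#' (Smith-Waterman via [Biostrings::pairwiseAlignment()], match +2,
#' mismatch -3, gap open 5, gap extend 2) with the found region masked out
#' between rounds; they are reported sorted by query position.
#'
#' @param query A `plastome_record` or nucleotide string.
#' @param reference_gene Coding-strand reference CDS (>= 25 bp).
#' @param min_len Minimum hit length (default 25 bp).
#' @param min_identity Minimum hit identity (default 0.70).
#' @param min_score Significance floor on the local alignment score (default
#'   40, i.e. 20 matched bases): under Karlin-Altschul statistics for this
#'   scoring scheme a score of 40 has expect << 1e-3 against a plastome-sized
#'   query, so chance alignments that happen to exceed 25 bp at 70% identity
#'   are excluded.
#' @param max_hits Per-strand cap on reported hits.
#' @return `data.frame` with 0-based half-open `qstart`, `qend` (query),
#'   `rstart`, `rend` (reference), `strand`, `identity`, `indel` (net
#'   query-minus-reference aligned length), `score`.
#' @export
locate_gene <- function(query, reference_gene, min_len = 25L,
                        min_identity = 0.70, min_score = 40, max_hits = 10L) {
  qseq <- if (inherits(query, "plastome_record")) query$seq else toupper(query)
  .assert(nchar(reference_gene) >= 25L, "reference gene must be >= 25 bp",
          "plastodecay_invalid_argument")
  ref <- Biostrings::DNAString(toupper(reference_gene))
  submat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3,
                                                     baseOnly = FALSE)
  submat["N", ] <- -1000; submat[, "N"] <- -1000   # masked bases never align
  scan_strand <- function(sq, strand) {
    n <- nchar(sq)
    hits <- list()
    cur <- sq
    for (round in seq_len(max_hits)) {
      aln <- Biostrings::pairwiseAlignment(
        Biostrings::DNAString(cur), ref, type = "local",
        substitutionMatrix = submat, gapOpening = 5, gapExtension = 2)
      w <- Biostrings::nchar(aln)
      # successive best scores are non-increasing, so stop at the floor
      if (Biostrings::score(aln) < min_score) break
      pid <- Biostrings::pid(aln) / 100
      qr <- as.data.frame(Biostrings::pattern(aln)@range)
      rr <- as.data.frame(Biostrings::subject(aln)@range)
      if (pid >= min_identity && (qr$end - qr$start + 1L) >= min_len) {
        qs <- qr$start - 1L; qe <- qr$end
        if (strand == "-") { tmp <- qs; qs <- n - qe; qe <- n - tmp }
        hits[[length(hits) + 1L]] <- data.frame(
          qstart = qs, qend = qe, rstart = rr$start - 1L, rend = rr$end,
          strand = strand, identity = pid,
          indel = (qr$end - qr$start) - (rr$end - rr$start),
          score = Biostrings::score(aln))
      }
      cur <- paste0(substr(cur, 1L, qr$start - 1L),
                    strrep("N", qr$end - qr$start + 1L),
                    substr(cur, qr$end + 1L, nchar(cur)))
    }
    hits
  }
  out <- c(scan_strand(qseq, "+"), scan_strand(.revcomp(qseq), "-"))
  if (length(out) == 0L) {
    return(data.frame(qstart = integer(0), qend = integer(0),
                      rstart = integer(0), rend = integer(0),
                      strand = character(0), identity = numeric(0),
                      indel = integer(0), score = numeric(0)))
  }
  out <- do.call(rbind, out)
  out <- out[order(out$qstart), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify the degradation state of a gene
#'
#' Against a reference CDS: `deleted` when no hit of at least 25 bp exists;
#' otherwise coverage is the union of reference intervals hit divided by the
#' reference length. `fragment` when coverage <= the pseudogene coverage
#' floor (default 0.20, the ">20% of the coding region" rule); `complete`
#' when coverage >= 0.95 and the reconstructed reading frame has a start
#' codon, a terminal stop, no internal stop and no frameshift; every other
#' disrupted locus is a `pseudogene`, with the lesions (`no_start`,
#' `no_stop`, `internal_stop`, `frameshift`) reported as evidence.
#'
#' @param hits Hit table from [locate_gene()] for this reference.
#' @param reference_gene The reference CDS used.
#' @param query The query `plastome_record` or sequence (for frame
#'   reconstruction).
#' @param pseudo_floor Coverage floor separating fragment from pseudogene.
#' @param complete_floor Coverage floor for a complete call.
#' @return A `gene_state_call`: list with `state`, `coverage`, `lesions`,
#'   `hits`.
#' @export
classify_gene_state <- function(hits, reference_gene, query = NULL,
                                pseudo_floor = 0.20, complete_floor = 0.95) {
  ref <- toupper(reference_gene)
  rlen <- nchar(ref)
  call <- function(state, coverage, lesions = character(0))
    structure(list(state = state, coverage = coverage, lesions = lesions,
                   hits = hits), class = "gene_state_call")
  if (nrow(hits) == 0L) return(call("deleted", 0))
  # greedy selection by score: drop hits whose reference interval is already
  # (mostly) covered by a stronger hit, so weak redundant alignments cannot
  # inject phantom lesions
  hits <- hits[order(-hits$score), , drop = FALSE]
  keep <- logical(nrow(hits))
  for (i in seq_len(nrow(hits))) {
    ov <- FALSE
    for (j in which(keep)) {
      inter <- min(hits$rend[i], hits$rend[j]) -
        max(hits$rstart[i], hits$rstart[j])
      if (inter > 5L) { ov <- TRUE; break }
    }
    keep[i] <- !ov
  }
  hits <- hits[keep, , drop = FALSE]
  hits <- hits[order(hits$qstart), , drop = FALSE]
  # contradictory strands on overlapping query intervals are ambiguous
  if (length(unique(hits$strand)) > 1L) {
    pl <- hits[hits$strand == "+", ]; mi <- hits[hits$strand == "-", ]
    for (i in seq_len(nrow(pl))) for (j in seq_len(nrow(mi))) {
      if (pl$qstart[i] < mi$qend[j] && mi$qstart[j] < pl$qend[i]) {
        stop(errorCondition(
          "overlapping hits on contradictory strands",
          class = c("plastodecay_ambiguous_locus", "error", "condition")))
      }
    }
  }
  coverage <- .union_len(hits$rstart, hits$rend) / rlen
  if (coverage <= pseudo_floor) return(call("fragment", coverage))
  # reconstruct the coding sequence from the dominant strand's hits
  strand <- names(sort(table(hits$strand), decreasing = TRUE))[1L]
  h <- hits[hits$strand == strand, , drop = FALSE]
  h <- h[order(h$rstart), , drop = FALSE]
  qseq <- if (inherits(query, "plastome_record")) query$seq else
    if (is.null(query)) NULL else toupper(query)
  lesions <- character(0)
  if (min(h$rstart) > 0L) lesions <- c(lesions, "no_start")
  if (max(h$rend) < rlen) lesions <- c(lesions, "no_stop")
  if (sum(h$indel) %% 3L != 0L ||
      (nrow(h) > 1L && any((h$rstart[-1L] - h$rend[-nrow(h)]) %% 3L != 0L))) {
    lesions <- c(lesions, "frameshift")
  }
  if (!is.null(qseq)) {
    segs <- vapply(seq_len(nrow(h)), function(i) {
      s <- substr(qseq, h$qstart[i] + 1L, h$qend[i])
      if (strand == "-") .revcomp(s) else s
    }, character(1L))
    rec <- paste(segs, collapse = "")
    if (h$rstart[1L] == 0L && substr(rec, 1L, 3L) != "ATG") {
      lesions <- c(lesions, "no_start")
    }
    L <- nchar(rec)
    if (h$rend[nrow(h)] == rlen &&
        !(substr(rec, L - 2L, L) %in% .STOPS)) {
      lesions <- c(lesions, "no_stop")
    }
    if (!("frameshift" %in% lesions) && L >= 6L) {
      Lc <- (L %/% 3L) * 3L
      cod <- substring(rec, seq(1L, Lc - 3L, 3L), seq(3L, Lc - 3L, 3L))
      if (any(cod %in% .STOPS)) lesions <- c(lesions, "internal_stop")
    }
  }
  lesions <- unique(lesions)
  if (coverage >= complete_floor && length(lesions) == 0L) {
    call("complete", coverage)
  } else {
    call("pseudogene", coverage, lesions)
  }
}

#' @export
print.gene_state_call <- function(x, ...) {
  cat(sprintf("<gene_state_call> %s (coverage %.2f%s)\n", x$state,
              x$coverage,
              if (length(x$lesions)) paste0("; lesions: ",
                                            paste(x$lesions, collapse = ","))
              else ""))
  invisible(x)
}

#' Classify all reference genes of a query plastome
#'
#' @param query A `plastome_record` or sequence.
#' @param refs Named character vector of reference CDS (e.g.
#'   [reference_genes()]).
#' @param ... Passed to [locate_gene()] / [classify_gene_state()].
#' @return `data.frame` with one row per gene: `gene`, `state`, `coverage`,
#'   `lesions` (comma-collapsed).
#' @export
classify_genes <- function(query, refs, ...) {
  rows <- lapply(names(refs), function(g) {
    hits <- locate_gene(query, refs[[g]])
    cl <- classify_gene_state(hits, refs[[g]], query, ...)
    data.frame(gene = g, state = cl$state, coverage = cl$coverage,
               lesions = paste(cl$lesions, collapse = ","))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Encode the 22-character ndh matrix
#'
#' Characters 1-11 code each ndh gene (A..K order) absent (0) / present (1);
#' characters 12-22 code pseudogenized (0), decayed/fragmented (1) or
#' complete (2), with `-` (inapplicable) when the gene is deleted.
#' State mapping: complete -> (1,2), pseudogene -> (1,0), fragment -> (1,1),
#' deleted -> (0,-).
#'
#' @param calls Named list (by taxon) of data.frames with columns `gene` and
#'   `state` covering all 11 ndh genes (e.g. from [classify_genes()]).
#' @return An `ndh_matrix`: character matrix, taxa x 22.
#' @export
encode_ndh_matrix <- function(calls) {
  genes <- ndh_genes()
  rows <- lapply(names(calls), function(tx) {
    d <- calls[[tx]]
    st <- d$state[match(genes, d$gene)]
    .assert(!anyNA(st), sprintf("taxon %s lacks a call for some ndh gene", tx),
            "plastodecay_incomplete_input")
    pres <- ifelse(st == "deleted", "0", "1")
    deg <- c(complete = "2", pseudogene = "0", fragment = "1",
             deleted = "-")[st]
    c(pres, unname(deg))
  })
  mat <- do.call(rbind, rows)
  rownames(mat) <- names(calls)
  colnames(mat) <- c(paste0("pres_", genes), paste0("deg_", genes))
  structure(mat, class = c("ndh_matrix", class(mat)))
}

#' Decode an ndh matrix back to states
#' @param mat An `ndh_matrix` from [encode_ndh_matrix()].
#' @return Named list (by taxon) of data.frames with `gene` and `state`.
#' @export
decode_ndh_matrix <- function(mat) {
  genes <- ndh_genes()
  out <- lapply(rownames(mat), function(tx) {
    pres <- mat[tx, 1:11]; deg <- mat[tx, 12:22]
    .assert(all((pres == "0") == (deg == "-")),
            "matrix inconsistent: character i+11 must be '-' iff character i is 0",
            "plastodecay_invalid_argument")
    st <- ifelse(pres == "0", "deleted",
                 c(`0` = "pseudogene", `1` = "fragment", `2` = "complete")[deg])
    data.frame(gene = genes, state = unname(st))
  })
  stats::setNames(out, rownames(mat))
}

#' Write an ndh matrix as NEXUS (and/or TSV)
#'
#' NEXUS uses `MISSING=? GAP=- SYMBOLS="012"`; the TSV keeps one column per
#' character.
#'
#' @param mat An `ndh_matrix`.
#' @param nexus,tsv Output paths (either may be `NULL`).
#' @return Invisibly, the paths written.
#' @export
write_ndh_matrix <- function(mat, nexus = NULL, tsv = NULL) {
  if (!is.null(nexus)) {
    rowstr <- apply(unclass(mat), 1L, paste, collapse = "")
    lines <- c("#NEXUS", "BEGIN DATA;",
               sprintf("  DIMENSIONS NTAX=%d NCHAR=%d;", nrow(mat), ncol(mat)),
               "  FORMAT DATATYPE=STANDARD MISSING=? GAP=- SYMBOLS=\"012\";",
               "  MATRIX",
               sprintf("    %-24s %s", rownames(mat), rowstr),
               "  ;", "END;")
    writeLines(lines, nexus)
  }
  if (!is.null(tsv)) {
    utils::write.table(cbind(taxon = rownames(mat), as.data.frame(unclass(mat))),
                       tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(c(nexus = nexus, tsv = tsv))
}
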