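#' Aligned matrix container
#'
#' Rows are taxa, columns aligned characters over `A/C/G/T/N/-`. Named
#' partitions are sets of column indices; they need not be disjoint (a gene
#' partition can sit inside the LSC partition).
#'
#' @param mat Character matrix (single characters) with taxa as rownames, or
#'   a character vector of equal-length sequences named by taxon.
#' @param partitions Named list of integer column index vectors.
#' @return An object of class `aligned_matrix`.
#' @export
aligned_matrix <- function(mat, partitions = list()) {
  if (is.character(mat) && is.null(dim(mat))) {
    .assert(length(unique(nchar(mat))) == 1L, "rows have unequal lengths",
            "plastodecay_invalid_argument")
    nms <- names(mat)
    mat <- do.call(rbind, strsplit(toupper(mat), "", fixed = TRUE))
    rownames(mat) <- nms
  }
  .assert(is.matrix(mat) && is.character(mat), "mat must be a character matrix",
          "plastodecay_invalid_argument")
  .assert(!is.null(rownames(mat)), "taxa must be given as rownames",
          "plastodecay_invalid_argument")
  bad <- setdiff(unique(as.vector(mat)), c(.DNA, "N", "-"))
  .assert(length(bad) == 0L,
          sprintf("unsupported alignment characters: %s",
                  paste(bad, collapse = ",")), "plastodecay_invalid_argument")
  for (p in partitions) {
    .assert(all(p >= 1L & p <= ncol(mat)), "partition indices out of range",
            "plastodecay_invalid_argument")
  }
  structure(list(taxa = rownames(mat), mat = mat, partitions = partitions),
            class = "aligned_matrix")
}

#' @export
print.aligned_matrix <- function(x, ...) {
  cat(sprintf("<aligned_matrix> %d taxa x %d columns, %d partitions\n",
              nrow(x$mat), ncol(x$mat), length(x$partitions)))
  invisible(x)
}

#' Read a multi-FASTA alignment
#' @param path Multi-FASTA file of equal-length sequences.
#' @param partitions Optional RAxML-style partition file (see
#'   [read_partitions()]).
#' @return An [aligned_matrix()].
#' @export
read_alignment <- function(path, partitions = NULL) {
  x <- Biostrings::readDNAStringSet(path)
  seqs <- stats::setNames(as.character(x), sub("\\s.*$", "", names(x)))
  pp <- if (is.null(partitions)) list() else read_partitions(partitions)
  aligned_matrix(seqs, partitions = pp)
}

#' Read a RAxML-style partition file
#'
#' Lines of the form `name = 1-100, 200-300` with 1-based inclusive column
#' ranges (an optional `DNA,` model prefix is tolerated).
#'
#' @param path Partition file path.
#' @return Named list of integer column index vectors.
#' @export
read_partitions <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    ln <- sub("^[A-Za-z]+\\s*,\\s*", "", ln)
    kv <- strsplit(ln, "=", fixed = TRUE)[[1L]]
    .assert(length(kv) == 2L, sprintf("unparseable partition line: %s", ln),
            "plastodecay_parse_error")
    nm <- trimws(kv[1L])
    idx <- integer(0)
    for (rg in strsplit(trimws(kv[2L]), ",")[[1L]]) {
      m <- regmatches(rg, regexec("^\\s*(\\d+)\\s*-\\s*(\\d+)\\s*$", rg))[[1L]]
      if (length(m) == 3L) idx <- c(idx, seq.int(as.integer(m[2L]),
                                                 as.integer(m[3L])))
      else idx <- c(idx, as.integer(trimws(rg)))
    }
    out[[nm]] <- idx
  }
  out
}

#' Pairwise p-distance
#'
#' Proportion of differing sites over compared sites; compared sites are
#' columns where both rows hold one of A/C/G/T (pairwise deletion of gaps and
#' N). Returns `NA` when no sites can be compared.
#'
#' @param a,b Equal-length character vectors (or strings) of aligned bases.
#' @return Fraction in `[0, 1]`, or `NA` if undefined.
#' @export
p_distance <- function(a, b) {
  if (is.character(a) && length(a) == 1L) a <- .chars(toupper(a))
  if (is.character(b) && length(b) == 1L) b <- .chars(toupper(b))
  .assert(length(a) == length(b), "rows have different lengths",
          "plastodecay_invalid_argument")
  ok <- a %in% .DNA & b %in% .DNA
  if (!any(ok)) return(NA_real_)
  sum(a[ok] != b[ok]) / sum(ok)
}

#' Classify alignment columns
#'
#' A column is `variable` when at least two distinct states among A/C/G/T
#' occur, and `parsimony-informative` when at least two states each occur in
#' at least two taxa. Gaps and N never count as states.
#'
#' @param x An [aligned_matrix()] or character matrix.
#' @return Character vector per column: `"constant"`,
#'   `"variable-uninformative"` or `"parsimony-informative"`.
#' @export
site_classes <- function(x) {
  mat <- if (inherits(x, "aligned_matrix")) x$mat else x
  apply(mat, 2L, function(col) {
    tb <- table(col[col %in% .DNA])
    if (length(tb) < 2L) "constant"
    else if (sum(tb >= 2L) >= 2L) "parsimony-informative"
    else "variable-uninformative"
  })
}

#' Per-partition alignment statistics
#'
#' For each named partition: alignment length, variable site count and
#' percentage, parsimony-informative count (PIC) and percentage, mean pairwise
#' p-distance (unweighted over all taxon pairs, pairwise deletion), and GC
#' percentage. An empty partition is reported with zero length and flagged.
#'
#' @param x An [aligned_matrix()].
#' @param partitions Named list of column index vectors (defaults to the
#'   matrix's own partitions; when absent, one partition spanning all
#'   columns).
#' @return `data.frame` of class `partition_stats`.
#' @export
partition_stats <- function(x, partitions = NULL) {
  .assert(inherits(x, "aligned_matrix"), "x must be an aligned_matrix",
          "plastodecay_invalid_argument")
  if (is.null(partitions)) partitions <- x$partitions
  if (length(partitions) == 0L) partitions <- list(all = seq_len(ncol(x$mat)))
  cls <- site_classes(x)
  rows <- lapply(names(partitions), function(nm) {
    idx <- partitions[[nm]]
    if (length(idx) == 0L) {
      return(data.frame(name = nm, length = 0L, variable = 0L,
                        variable_pct = NA_real_, pic = 0L, pic_pct = NA_real_,
                        mean_p_distance = NA_real_, gc_pct = NA_real_,
                        empty = TRUE))
    }
    sub <- x$mat[, idx, drop = FALSE]
    nv <- sum(cls[idx] != "constant")
    np <- sum(cls[idx] == "parsimony-informative")
    pairs <- utils::combn(nrow(sub), 2L)
    pd <- apply(pairs, 2L, function(ij) p_distance(sub[ij[1L], ], sub[ij[2L], ]))
    ch <- as.vector(sub)
    acgt <- sum(ch %in% .DNA)
    data.frame(name = nm, length = length(idx), variable = nv,
               variable_pct = 100 * nv / length(idx), pic = np,
               pic_pct = 100 * np / length(idx),
               mean_p_distance = mean(pd, na.rm = TRUE),
               gc_pct = if (acgt > 0L)
                 100 * sum(ch %in% c("G", "C")) / acgt else NA_real_,
               empty = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("partition_stats", "data.frame")
  out
}

#' Spearman rank correlation with t-approximation p-value
#'
#' Average ranks for ties; two-sided p-value from the asymptotic
#' t-distribution approximation.
#'
#' @param x,y Equal-length numeric vectors (n >= 5).
#' @return List with `rho` and `p_value` (both `NA` when a ranking has zero
#'   variance).
#' @export
spearman_rho <- function(x, y) {
  .assert(length(x) == length(y) && length(x) >= 5L,
          "x and y must have equal length >= 5",
          "plastodecay_invalid_argument")
  if (stats::sd(rank(x)) == 0 || stats::sd(rank(y)) == 0) {
    return(list(rho = NA_real_, p_value = NA_real_))
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = FALSE))
  list(rho = unname(ct$estimate), p_value = ct$p.value)
}

#' Rank divergence hotspots
#'
#' Regions sorted by parsimony-informative site count (descending), ties
#' broken by mean p-distance (descending), then by name (ascending).
#'
#' @param stats A [partition_stats()] table.
#' @param k Number of top regions to return (>= 1; capped at the region
#'   count).
#' @return The top-`k` rows in rank order.
#' @export
rank_hotspots <- function(stats, k = 10L) {
  .assert(k >= 1L, "k must be >= 1", "plastodecay_invalid_argument")
  o <- order(-stats$pic,
             -ifelse(is.na(stats$mean_p_distance), -Inf, stats$mean_p_distance),
             stats$name)
  out <- stats[o, , drop = FALSE][seq_len(min(k, nrow(stats))), , drop = FALSE]
  rownames(out) <- NULL
  out
}
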