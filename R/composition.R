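#' Detect the quadripartite structure of a circular plastome
#'
#' Finds the maximal pair of disjoint intervals whose sequences are reverse
#' complements of each other (allowing a small mismatch fraction), each at
#' least `min_ir` bp: the inverted repeats. The larger of the two inter-IR
#' segments is labelled LSC, the smaller SSC, and the linearization is rotated
#' so the LSC starts at position 0 (ties between equal-length segments are
#' broken by the lexicographically smaller segment becoming the LSC).
#' Detection is seed-and-extend on exact `k`-mers shared between the doubled
#' sequence and its reverse complement, so it is invariant to rotation of the
#' circular input.
#'
#' @param seq Nucleotide string (or `plastome_record`).
#' @param min_ir Minimum IR length in bp (default 1000).
#' @param max_mismatch_frac Mismatch fraction tolerated while extending
#'   (default 0.01).
#' @param k Exact seed length (default 25).
#' @return An object of class `quadripartite`: list with `found`, and when
#'   found `regions` (LSC/IRa/SSC/IRb, 0-based half-open on the rotated
#'   linearization), `offset` (rotation applied), `sequence` (rotated), and
#'   `ir_length`.
#' @export
detect_quadripartite <- function(seq, min_ir = 1000L, max_mismatch_frac = 0.01,
                                 k = 25L) {
  if (inherits(seq, "plastome_record")) seq <- seq$seq
  seq <- toupper(seq)
  n <- nchar(seq)
  .assert(n >= 4L * min_ir, "sequence shorter than 4 x min_ir",
          "plastodecay_invalid_argument")
  s2 <- paste0(seq, seq)
  n2 <- 2L * n
  cs <- .chars(s2)
  comp <- .comp_chars(cs)
  rc2 <- .revcomp(s2)
  kmA <- substring(s2, seq_len(n2 - k + 1L), seq_len(n2 - k + 1L) + k - 1L)
  kmB <- substring(rc2, seq_len(n2 - k + 1L), seq_len(n2 - k + 1L) + k - 1L)
  common <- intersect(kmA, kmB)
  common <- common[!grepl("N", common, fixed = TRUE)]
  if (length(common) == 0L) {
    return(structure(list(found = FALSE), class = "quadripartite"))
  }
  posA <- split(seq_along(kmA), kmA)[common]
  posB <- split(seq_along(kmB), kmB)[common]
  cands <- integer(0)   # anti-diagonal c = i + j + k - 1, with i from B pos
  seed_u <- list()
  for (idx in seq_along(common)) {
    for (j in posA[[idx]]) for (p in posB[[idx]]) {
      i <- n2 - p - k + 2L
      cc <- i + j + k - 1L
      key <- as.character(cc)
      cands <- union(cands, cc)
      seed_u[[key]] <- c(seed_u[[key]], j, i)
    }
    if (length(cands) > 2000L) break
  }
  best <- NULL
  for (cc in cands) {
    umin <- max(1L, cc - n2); umax <- min(floor((cc - 1L) / 2), n2)
    if (umax - umin + 1L < min_ir) next
    us <- seq.int(umin, umax)
    mm <- cs[us] != comp[cc - us]
    su <- seed_u[[as.character(cc)]]
    su <- sort(unique(su[su >= umin & su <= umax]))
    if (length(su) == 0L) next
    # an anti-diagonal can carry several distinct seed clusters (the doubled
    # sequence makes IR images recur); extend each cluster separately
    cl_id <- cumsum(c(1L, diff(su) > 8L * k))
    for (cl in split(su, cl_id)) {
      a <- min(cl); b <- min(max(cl) + k - 1L, umax)
      a <- a - umin + 1L; b <- b - umin + 1L   # index into mm
      # shrink to a clean seed core, then X-drop extension (match +1,
      # mismatch -3): trims at the score maximum, so exact planted IRs
      # recover exact boundaries while isolated mismatches are tolerated
      while (a <= b && mm[a]) a <- a + 1L
      while (b >= a && mm[b]) b <- b - 1L
      if (b < a) next
      xdrop <- 12L
      sc <- 0L; bestsc <- 0L; bestpos <- a
      p <- a - 1L
      while (p >= 1L) {
        sc <- sc + if (mm[p]) -3L else 1L
        if (sc > bestsc) { bestsc <- sc; bestpos <- p }
        if (sc < bestsc - xdrop) break
        p <- p - 1L
      }
      a <- bestpos
      sc <- 0L; bestsc <- 0L; bestpos <- b
      p <- b + 1L
      while (p <= length(mm)) {
        sc <- sc + if (mm[p]) -3L else 1L
        if (sc > bestsc) { bestsc <- sc; bestpos <- p }
        if (sc < bestsc - xdrop) break
        p <- p + 1L
      }
      b <- bestpos
      len <- b - a + 1L
      if (len < min_ir || len > n %/% 2L) next
      if (sum(mm[a:b]) > max_mismatch_frac * len) next
      ua <- a + umin - 1L; ub <- b + umin - 1L
      i1 <- (ua - 1L) %% n; i2 <- (cc - ub - 1L) %% n
      gap1 <- (i2 - (i1 + len)) %% n
      gap2 <- (i1 - (i2 + len)) %% n
      if (gap1 + gap2 != n - 2L * len) next   # arms overlap on the circle
      if (is.null(best) || len > best$len) {
        best <- list(len = len, i1 = i1, i2 = i2, gap1 = gap1, gap2 = gap2)
      }
    }
  }
  if (is.null(best)) {
    return(structure(list(found = FALSE), class = "quadripartite"))
  }
  L <- best$len
  seg_at <- function(start, glen)
    if (glen == 0L) "" else substr(s2, start %% n + 1L, start %% n + glen)
  segA <- seg_at(best$i1 + L, best$gap1)  # between arm1-end and arm2-start
  segB <- seg_at(best$i2 + L, best$gap2)
  lsc_is_A <- if (best$gap1 != best$gap2) best$gap1 > best$gap2 else segA <= segB
  if (lsc_is_A) {
    off <- (best$i1 + L) %% n; gL <- best$gap1; gS <- best$gap2
  } else {
    off <- (best$i2 + L) %% n; gL <- best$gap2; gS <- best$gap1
  }
  rotated <- paste0(substr(seq, off + 1L, n), substr(seq, 1L, off))
  regions <- data.frame(
    region = c("LSC", "IRa", "SSC", "IRb"),
    start = c(0L, gL, gL + L, gL + L + gS),
    end = c(gL, gL + L, gL + L + gS, gL + 2L * L + gS))
  structure(list(found = TRUE, regions = regions, offset = off,
                 sequence = rotated, ir_length = L),
            class = "quadripartite")
}

#' @export
print.quadripartite <- function(x, ...) {
  if (!x$found) cat("<quadripartite> no inverted-repeat pair found",
                    "(single-copy genome)\n")
  else {
    cat(sprintf("<quadripartite> IR length %d, rotation offset %d\n",
                x$ir_length, x$offset))
    print(x$regions)
  }
  invisible(x)
}

#' GC content of a sequence, in percent
#'
#' `100 (G+C) / (A+C+G+T)`, ignoring N, reported to one decimal.
#'
#' @param seq Nucleotide string or `plastome_record`.
#' @return Percentage, rounded to one decimal place.
#' @export
gc_content <- function(seq) {
  if (inherits(seq, "plastome_record")) seq <- seq$seq
  .assert(is.character(seq) && length(seq) == 1L && nchar(seq) > 0L,
          "empty sequence", "plastodecay_invalid_argument")
  ch <- .chars(toupper(seq))
  acgt <- sum(ch %in% .DNA)
  .assert(acgt > 0L, "sequence has no A/C/G/T", "plastodecay_invalid_argument")
  round(100 * sum(ch %in% c("G", "C")) / acgt, 1L)
}

#' Codon usage of a set of coding sequences
#'
#' Counts over the 64 codons, relative frequencies, and amino-acid totals
#' aggregated under the bacterial/plastid genetic code (translation table 11).
#' A CDS whose length is not a multiple of 3 has its incomplete terminal codon
#' trimmed (reported in `trimmed`).
#'
#' @param cds_set Character vector of coding sequences.
#' @return List with `counts` (named length-64 integer), `freq` (sums to 1),
#'   `aa` (totals per amino acid, `*` = stop), `n_codons`, `trimmed`.
#' @export
codon_usage <- function(cds_set) {
  .assert(length(cds_set) > 0L && any(nchar(cds_set) >= 3L),
          "empty CDS set", "plastodecay_invalid_argument")
  codons64 <- sort(apply(expand.grid(.DNA, .DNA, .DNA)[, 3:1], 1L, paste,
                         collapse = ""))
  counts <- stats::setNames(integer(64L), codons64)
  trimmed <- integer(0)
  for (i in seq_along(cds_set)) {
    s <- toupper(cds_set[[i]])
    extra <- nchar(s) %% 3L
    if (extra != 0L) {
      trimmed <- c(trimmed, i)
      s <- substr(s, 1L, nchar(s) - extra)
    }
    cod <- substring(s, seq(1L, nchar(s), 3L), seq(3L, nchar(s), 3L))
    cod <- cod[cod %in% codons64]   # codons containing N are skipped
    tb <- table(cod)
    counts[names(tb)] <- counts[names(tb)] + as.integer(tb)
  }
  n <- sum(counts)
  .assert(n > 0L, "no complete codons in CDS set",
          "plastodecay_invalid_argument")
  code <- Biostrings::getGeneticCode("11")
  aa <- tapply(counts, code[names(counts)], sum)
  list(counts = counts, freq = counts / n, aa = c(aa), n_codons = n,
       trimmed = trimmed)
}
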