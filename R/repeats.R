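#' Find microsatellites (SSRs)
#'
#' Reports maximal, non-extendable perfect tandem runs whose unit size is
#' 1-6 bp and whose full copy number meets the per-unit-size minimum
#' (MISA-style thresholds: mono >= 10, di >= 6, tri/tetra/penta/hexa >= 5 by
#' default). Runs whose unit is itself periodic are reported at the smallest
#' period; a run entirely contained in a kept run of smaller period is
#' dropped.
#'
#' @param seq Nucleotide string or `plastome_record`.
#' @param thresholds Integer vector of minimum copy counts for unit sizes
#'   1..6.
#' @return `data.frame` with `kind` (`tandem`), `unit`, `copies`, `start`,
#'   `end` (0-based half-open, covering the full copies), `length`.
#' @export
find_ssrs <- function(seq, thresholds = c(10L, 6L, 5L, 5L, 5L, 5L)) {
  if (inherits(seq, "plastome_record")) seq <- seq$seq
  .assert(length(thresholds) == 6L, "thresholds must cover unit sizes 1-6",
          "plastodecay_invalid_argument")
  cs <- .chars(toupper(seq))
  n <- length(cs)
  out <- list()
  for (p in 1:6) {
    if (n < p * 2L) next
    eq <- cs[seq_len(n - p)] == cs[(p + 1L):n]
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (i in which(r$values & r$lengths >= p * (thresholds[p] - 1L))) {
      run_start <- starts[i]                  # 1-based
      total <- r$lengths[i] + p               # perfect tandem region length
      copies <- total %/% p
      if (copies < thresholds[p]) next
      unit <- paste(cs[run_start:(run_start + p - 1L)], collapse = "")
      if (!.is_primitive_unit(unit)) next
      out[[length(out) + 1L]] <- data.frame(
        kind = "tandem", unit = unit, copies = copies,
        start = run_start - 1L, end = run_start - 1L + copies * p,
        length = copies * p, period = p)
    }
  }
  if (length(out) == 0L) {
    return(data.frame(kind = character(0), unit = character(0),
                      copies = integer(0), start = integer(0),
                      end = integer(0), length = integer(0)))
  }
  d <- do.call(rbind, out)
  d <- d[order(d$period, d$start), , drop = FALSE]
  keep <- rep(TRUE, nrow(d))
  for (i in seq_len(nrow(d))) {
    if (!keep[i]) next
    for (j in seq_len(nrow(d))) {
      if (i == j || !keep[j]) next
      if (d$period[j] > d$period[i] &&
          d$start[j] >= d$start[i] && d$end[j] <= d$end[i]) keep[j] <- FALSE
    }
  }
  d <- d[keep, , drop = FALSE]
  d <- d[order(d$start), , drop = FALSE]
  d$period <- NULL
  rownames(d) <- NULL
  d
}

# Maximal <=k-mismatch windows along one mismatch vector (sentinel method):
# windows bounded by the (k+1)-th mismatch on each side, or the range ends.
# Only windows of at least min_len positions are materialized.
.max_windows <- function(mm, k, min_len = 1L) {
  P <- c(0L, which(mm), length(mm) + 1L)
  nm <- length(P) - 2L
  if (nm <= k) {
    a <- 1L; b <- length(mm)
    if (b - a + 1L < min_len) return(NULL)
    return(cbind(a = a, b = b, mmc = nm))
  }
  t <- 0:(nm - k)
  a <- P[t + 1L] + 1L
  b <- P[t + k + 2L] - 1L
  len_ok <- b - a + 1L >= min_len
  if (!any(len_ok)) return(NULL)
  a <- a[len_ok]; b <- b[len_ok]
  cs <- cumsum(mm)
  mmc <- cs[b] - ifelse(a > 1L, cs[a - 1L], 0L)
  cbind(a = a, b = b, mmc = mmc)
}

#' Find long direct and palindromic repeats
#'
#' REPuter-style search: pairs of intervals of at least `min_len` bp where
#' the second copy matches the first (direct) or its reverse complement
#' (palindromic) with at most `max_mismatch` mismatches (Hamming) and
#' identity >= `min_identity`; both filters must hold. Only maximal
#' (non-extendable) pairs are reported: each window is bounded by the
#' (`max_mismatch`+1)-th mismatch or the sequence end on either side.
#' Self-pairing is excluded. Candidate diagonals come from exact seed
#' matches, which cannot miss any qualifying window (a window of `min_len`
#' with `max_mismatch` mismatches always contains an exact run of the seed
#' length).
#'
#' @param seq Nucleotide string or `plastome_record`.
#' @param min_len Minimum arm length (>= 8; default 30).
#' @param max_mismatch Maximum Hamming mismatches (default 3, REPuter `-h 3`).
#' @param min_identity Minimum identity (default 0.90).
#' @param max_reports Cap on reported pairs, best-scoring first (default
#'   10000).
#' @param ir_flag_len Palindromic hits at least this long are flagged
#'   `is_ir_pair` (the full IRa/IRb pair trivially matches as one giant
#'   palindrome; default 1000).
#' @return `data.frame` with `kind` (`direct`/`palindromic`), 0-based
#'   half-open `start1`, `end1`, `start2`, `end2`, `length`, `mismatches`,
#'   `identity`, `is_ir_pair`.
#' @export
find_long_repeats <- function(seq, min_len = 30L, max_mismatch = 3L,
                              min_identity = 0.90, max_reports = 10000L,
                              ir_flag_len = 1000L) {
  if (inherits(seq, "plastome_record")) seq <- seq$seq
  .assert(min_len >= 8L, "min_len must be >= 8", "plastodecay_invalid_argument")
  cs <- .chars(toupper(seq))
  comp <- .comp_chars(cs)
  n <- length(cs)
  q <- max(4L, as.integer(ceiling((min_len - max_mismatch) /
                                    (max_mismatch + 1L))))
  q <- min(q, as.integer(min_len))
  km <- substring(seq, seq_len(n - q + 1L), seq_len(n - q + 1L) + q - 1L)
  pos_by_km <- split(seq_len(n - q + 1L), km)
  res <- list()
  emit <- function(kind, s1, e1, s2, e2, mmc, diag) {
    len <- e1 - s1
    if (len < min_len) return()
    if (1 - mmc / len < min_identity) return()
    if (s1 == s2) return()
    key <- paste(kind, s1, e1, s2, e2)
    if (!is.null(res[[key]])) return()
    res[[key]] <<- data.frame(kind = kind, start1 = s1, end1 = e1,
                              start2 = s2, end2 = e2, length = len,
                              mismatches = mmc, identity = 1 - mmc / len,
                              diag = diag)
  }
  # direct repeats: diagonals d = j - i > 0 holding >= 2 seed occurrences
  diags <- integer(0)
  for (pp in pos_by_km) {
    if (length(pp) < 2L) next
    dd <- as.vector(outer(pp, pp, "-"))
    diags <- c(diags, dd[dd > 0L])
  }
  for (d in sort(unique(diags))) {
    lim <- n - d
    if (lim < min_len) next
    mm <- cs[seq_len(lim)] != cs[(d + 1L):n]
    w <- .max_windows(mm, max_mismatch, min_len)
    for (i in seq_len(NROW(w))) {
      emit("direct", w[i, "a"] - 1L, w[i, "b"], w[i, "a"] - 1L + d,
           w[i, "b"] + d, w[i, "mmc"], d)
    }
  }
  # palindromic repeats: anti-diagonals c = u + v where S[u] == comp(S[v])
  rcseq <- .revcomp(seq)
  kmr <- substring(rcseq, seq_len(n - q + 1L), seq_len(n - q + 1L) + q - 1L)
  cands <- integer(0)
  common <- intersect(names(pos_by_km), unique(kmr))
  if (length(common) > 0L) {
    pos_r <- split(seq_len(n - q + 1L), kmr)[common]
    for (idx in seq_along(common)) {
      for (j in pos_by_km[[common[idx]]]) for (p in pos_r[[idx]]) {
        i <- n - p - q + 2L      # S[j..] == revcomp of S[i..]
        cands <- c(cands, i + j + q - 1L)
      }
    }
  }
  for (cc in sort(unique(cands))) {
    umin <- max(1L, cc - n)
    umax <- floor((cc - 1L) / 2)    # u < v: arms must not cross the center
    if (umax - umin + 1L < min_len) next
    us <- seq.int(umin, umax)
    mm <- cs[us] != comp[cc - us]
    w <- .max_windows(mm, max_mismatch, min_len)
    for (i in seq_len(NROW(w))) {
      a <- us[w[i, "a"]]; b <- us[w[i, "b"]]
      emit("palindromic", a - 1L, b, cc - b - 1L, cc - a, w[i, "mmc"], cc)
    }
  }
  if (length(res) == 0L) {
    return(data.frame(kind = character(0), start1 = integer(0),
                      end1 = integer(0), start2 = integer(0),
                      end2 = integer(0), length = integer(0),
                      mismatches = integer(0), identity = numeric(0),
                      is_ir_pair = logical(0)))
  }
  d <- do.call(rbind, res)
  # several shift-variant maximal windows can share one underlying repeat;
  # collapse overlapping windows on the same (anti-)diagonal to the
  # best-scoring representative
  d$score <- d$length - 4L * d$mismatches
  d <- d[order(d$kind, d$diag, d$start1), , drop = FALSE]
  grp <- integer(nrow(d)); g <- 0L; prev_end <- -1L; prev_key <- ""
  for (i in seq_len(nrow(d))) {
    key <- paste(d$kind[i], d$diag[i])
    if (key != prev_key || d$start1[i] >= prev_end) {
      g <- g + 1L; prev_end <- d$end1[i]
    } else prev_end <- max(prev_end, d$end1[i])
    grp[i] <- g; prev_key <- key
  }
  d <- do.call(rbind, lapply(split(d, grp), function(x)
    x[order(-x$score, x$start1), , drop = FALSE][1L, , drop = FALSE]))
  d$diag <- NULL; d$score <- NULL
  d$is_ir_pair <- d$kind == "palindromic" & d$length >= ir_flag_len
  d <- d[order(-(2L * d$length - 5L * d$mismatches), d$start1), , drop = FALSE]
  d <- d[seq_len(min(nrow(d), max_reports)), , drop = FALSE]
  d <- d[order(d$start1, d$start2), , drop = FALSE]
  rownames(d) <- NULL
  d
}

#' Annotate repeats with their genomic context
#'
#' Labels each hit by the feature class with the largest overlap among CDS,
#' intron, tRNA, rRNA and pseudogene; positions covered by no feature are
#' intergenic, and ties go to intergenic. Nearest flanking gene names are
#' recorded for locus matching across species.
#'
#' @param hits Repeat table from [find_ssrs()] / [find_long_repeats()].
#' @param record A `plastome_record` with annotations.
#' @return `hits` with `context` (and `context2` for pairs), `flank_up`,
#'   `flank_down` columns filled.
#' @export
annotate_repeat_context <- function(hits, record) {
  ann <- record$genes
  ctx_of <- function(s, e) {
    if (is.na(s)) return(NA_character_)
    best <- "intergenic"
    if (!is.null(ann) && nrow(ann) > 0L) {
      per_class <- vapply(split(seq_len(nrow(ann)), ann$type), function(ii) {
        ss <- pmax(ann$start[ii], s); ee <- pmin(ann$end[ii], e)
        ok <- ee > ss
        if (!any(ok)) 0 else as.numeric(.union_len(ss[ok], ee[ok]))
      }, numeric(1L))
      covered <- {
        ss <- pmax(ann$start, s); ee <- pmin(ann$end, e)
        ok <- ee > ss
        if (!any(ok)) 0L else .union_len(ss[ok], ee[ok])
      }
      inter <- (e - s) - covered
      per_class <- per_class[per_class > 0L]
      if (length(per_class) > 0L) {
        mx <- max(per_class)
        if (mx > inter) {
          cand <- names(per_class)[per_class == mx]
          best <- sort(cand)[1L]
        }
      }
    }
    best
  }
  flanks <- function(s, e) {
    if (is.null(ann) || nrow(ann) == 0L || is.na(s)) {
      return(c(NA_character_, NA_character_))
    }
    g <- ann[!(ann$type %in% "intron"), , drop = FALSE]
    up <- g[g$start <= s, , drop = FALSE]
    dn <- g[g$end >= e, , drop = FALSE]
    c(if (nrow(up)) up$name[which.max(up$start)] else ".",
      if (nrow(dn)) dn$name[which.min(dn$end)] else ".")
  }
  s1 <- if ("start" %in% names(hits)) hits$start else hits$start1
  e1 <- if ("end" %in% names(hits)) hits$end else hits$end1
  hits$context <- mapply(ctx_of, s1, e1)
  if ("start2" %in% names(hits)) {
    hits$context2 <- mapply(ctx_of, hits$start2, hits$end2)
  }
  fl <- t(mapply(flanks, s1, e1))
  hits$flank_up <- fl[, 1L]
  hits$flank_down <- fl[, 2L]
  hits
}

#' Repeat loci shared by all species
#'
#' Loci are matched by (flanking gene context, kind, unit) rather than by
#' absolute coordinates, so coordinate drift between genomes does not matter.
#'
#' @param hit_sets Named list (>= 2 species) of annotated hit tables (from
#'   [annotate_repeat_context()]).
#' @return The hits of the first species whose locus key occurs in every
#'   species, with a `locus` key column.
#' @export
shared_repeats <- function(hit_sets) {
  .assert(length(hit_sets) >= 2L, "need at least two species",
          "plastodecay_invalid_argument")
  key_of <- function(h) {
    if (nrow(h) == 0L) return(character(0))
    unit <- if ("unit" %in% names(h)) h$unit else rep(".", nrow(h))
    paste(h$kind, unit, h$context, h$flank_up, h$flank_down, sep = "|")
  }
  keys <- lapply(hit_sets, key_of)
  shared <- Reduce(intersect, keys)
  first <- hit_sets[[1L]]
  out <- first[keys[[1L]] %in% shared, , drop = FALSE]
  out$locus <- keys[[1L]][keys[[1L]] %in% shared]
  out <- out[!duplicated(out$locus), , drop = FALSE]
  rownames(out) <- NULL
  out
}
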