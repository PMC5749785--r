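# Independent oracles used across the suite. Each reimplements the checked
# quantity by brute force (exhaustive enumeration or naive dynamic
# programming) without touching the implementation's code paths.

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")

revcomp_chr <- function(s)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))

# ---- Fitch length by exhaustive internal-state assignment -------------------

# Minimum mutation count for one character by enumerating every assignment of
# states to internal nodes (and to tips with ?/-), counting per-edge changes.
oracle_fitch_char <- function(tree, states) {
  ntip <- length(tree$tip.label)
  alph <- sort(unique(states[!(states %in% c("?", "-"))]))
  k <- length(alph)
  if (k <= 1L) return(0L)
  internals <- (ntip + 1L):(ntip + tree$Nnode)
  amb_tips <- which(states %in% c("?", "-"))
  vars <- c(internals, amb_tips)
  A <- as.matrix(expand.grid(rep(list(seq_len(k)), length(vars))))
  node_state <- function(v) {
    if (v %in% vars) A[, match(v, vars)]
    else rep(match(states[v], alph), nrow(A))
  }
  total <- numeric(nrow(A))
  for (e in seq_len(nrow(tree$edge))) {
    total <- total + (node_state(tree$edge[e, 1L]) !=
                        node_state(tree$edge[e, 2L]))
  }
  min(total)
}

oracle_fitch <- function(tree, mat) {
  sum(vapply(seq_len(ncol(mat)), function(j)
    oracle_fitch_char(tree, mat[match(tree$tip.label, rownames(mat)), j]),
    numeric(1L)))
}

# ---- ACCTRAN by enumeration -------------------------------------------------

# All minimal reconstructions of one character on a rooted binary tree;
# returns the minimum step count and, among minimal ones, the minimum total
# depth of change edges (root-proximity objective).
oracle_acctran_char <- function(rt, states) {
  ntip <- length(rt$tip.label)
  alph <- sort(unique(states[!(states %in% c("?", "-"))]))
  k <- length(alph)
  if (k <= 1L) return(list(steps = 0L, depthsum = 0L))
  root <- ntip + 1L
  nn <- ntip + rt$Nnode
  depth <- integer(nn)
  ed <- rt$edge
  for (i in seq_len(nrow(ed))) depth[ed[i, 2L]] <- NA
  # compute depths via repeated passes (edges not guaranteed ordered)
  depth <- rep(NA_integer_, nn); depth[root] <- 0L
  repeat {
    done <- TRUE
    for (i in seq_len(nrow(ed))) {
      if (is.na(depth[ed[i, 2L]]) && !is.na(depth[ed[i, 1L]])) {
        depth[ed[i, 2L]] <- depth[ed[i, 1L]] + 1L
        done <- FALSE
      }
    }
    if (done) break
  }
  internals <- (ntip + 1L):nn
  amb_tips <- which(states %in% c("?", "-"))
  vars <- c(internals, amb_tips)
  A <- as.matrix(expand.grid(rep(list(seq_len(k)), length(vars))))
  node_state <- function(v) {
    if (v %in% vars) A[, match(v, vars)]
    else rep(match(states[v], alph), nrow(A))
  }
  steps <- numeric(nrow(A)); dsum <- numeric(nrow(A))
  for (i in seq_len(nrow(ed))) {
    chg <- node_state(ed[i, 1L]) != node_state(ed[i, 2L])
    steps <- steps + chg
    dsum <- dsum + chg * depth[ed[i, 2L]]
  }
  mn <- min(steps)
  list(steps = mn, depthsum = min(dsum[steps == mn]))
}

# ---- local alignment: affine-gap Smith-Waterman -----------------------------

# Best local alignment between q and r; gap of length L costs open + ext*L
# (Biostrings semantics). Returns score and 0-based half-open intervals.
oracle_sw <- function(q, r, match = 2, mismatch = -3, open = 5, ext = 2) {
  qc <- strsplit(q, "")[[1L]]; rc <- strsplit(r, "")[[1L]]
  n <- length(qc); m <- length(rc)
  NEG <- -1e9
  M <- matrix(0, n + 1L, m + 1L)
  Ix <- matrix(NEG, n + 1L, m + 1L)   # gap in r (consuming q)
  Iy <- matrix(NEG, n + 1L, m + 1L)   # gap in q (consuming r)
  best <- 0; bi <- 0L; bj <- 0L
  for (i in 2L:(n + 1L)) {
    for (j in 2L:(m + 1L)) {
      s <- if (qc[i - 1L] == rc[j - 1L]) match else mismatch
      M[i, j] <- max(0, M[i - 1L, j - 1L], Ix[i - 1L, j - 1L],
                     Iy[i - 1L, j - 1L]) + s
      Ix[i, j] <- max(M[i - 1L, j] - open - ext, Ix[i - 1L, j] - ext)
      Iy[i, j] <- max(M[i, j - 1L] - open - ext, Iy[i, j - 1L] - ext)
      if (M[i, j] > best) { best <- M[i, j]; bi <- i; bj <- j }
    }
  }
  if (best <= 0) return(NULL)
  # traceback from (bi, bj) through the three matrices
  i <- bi; j <- bj; state <- "M"
  repeat {
    if (state == "M") {
      prev <- max(0, M[i - 1L, j - 1L], Ix[i - 1L, j - 1L], Iy[i - 1L, j - 1L])
      i <- i - 1L; j <- j - 1L
      if (prev == 0) break
      state <- if (prev == M[i, j]) "M" else if (prev == Ix[i, j]) "Ix" else "Iy"
    } else if (state == "Ix") {
      from_m <- M[i - 1L, j] - open - ext
      state <- if (Ix[i, j] == from_m) "M" else "Ix"
      i <- i - 1L
    } else {
      from_m <- M[i, j - 1L] - open - ext
      state <- if (Iy[i, j] == from_m) "M" else "Iy"
      j <- j - 1L
    }
  }
  # i/j are the 1-based positions of the first aligned pair; report 0-based
  # half-open intervals
  list(score = best, qstart = i - 1L, qend = bi - 1L,
       rstart = j - 1L, rend = bj - 1L)
}

# ---- SSRs by brute-force triple enumeration ---------------------------------

oracle_ssrs <- function(seq, thresholds = c(10L, 6L, 5L, 5L, 5L, 5L)) {
  cs <- strsplit(toupper(seq), "")[[1L]]
  n <- length(cs)
  is_primitive <- function(u) {
    p <- nchar(u)
    if (p == 1L) return(TRUE)
    for (d in seq_len(p - 1L)) {
      if (p %% d == 0L && strrep(substr(u, 1L, d), p / d) == u) return(FALSE)
    }
    TRUE
  }
  runs <- list()
  for (p in 1:6) for (i in seq_len(n)) {
    # maximal run starting at i: not extendable left by one character
    if (i > 1L && i - 1L + p <= n && cs[i - 1L] == cs[i - 1L + p]) next
    j <- i
    while (j + p <= n && cs[j + p] == cs[j]) j <- j + 1L
    total <- j + p - i
    copies <- total %/% p
    if (copies < thresholds[p]) next
    unit <- paste(cs[i:(i + p - 1L)], collapse = "")
    if (!is_primitive(unit)) next
    runs[[length(runs) + 1L]] <- data.frame(
      unit = unit, copies = copies, start = i - 1L,
      end = i - 1L + copies * p, period = p)
  }
  if (length(runs) == 0L) {
    return(data.frame(unit = character(0), copies = integer(0),
                      start = integer(0), end = integer(0)))
  }
  d <- unique(do.call(rbind, runs))
  keep <- rep(TRUE, nrow(d))
  for (i in seq_len(nrow(d))) for (j in seq_len(nrow(d))) {
    if (i != j && keep[i] && d$period[j] > d$period[i] &&
        d$start[j] >= d$start[i] && d$end[j] <= d$end[i]) keep[j] <- FALSE
  }
  d <- d[keep, c("unit", "copies", "start", "end")]
  d <- d[order(d$start), , drop = FALSE]
  rownames(d) <- NULL
  d
}

# ---- long repeats by all-diagonal enumeration -------------------------------

# Same window semantics as the implementation (maximal <=k-mismatch windows,
# length and identity filters, per-diagonal collapse to the best-scoring
# window of each overlap group) but scanning every diagonal without seeds.
oracle_long_repeats <- function(seq, min_len = 30L, max_mismatch = 3L,
                                min_identity = 0.90) {
  cs <- strsplit(toupper(seq), "")[[1L]]
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")[cs]
  n <- length(cs)
  k <- max_mismatch
  windows_of <- function(mm) {
    P <- c(0L, which(mm), length(mm) + 1L)
    nm <- length(P) - 2L
    if (nm <= k) {
      if (length(mm) < min_len) return(NULL)
      return(cbind(a = 1L, b = length(mm), mmc = nm))
    }
    t <- 0:(nm - k)
    a <- P[t + 1L] + 1L; b <- P[t + k + 2L] - 1L
    ok <- b - a + 1L >= min_len
    if (!any(ok)) return(NULL)
    a <- a[ok]; b <- b[ok]
    cseq <- cumsum(mm)
    cbind(a = a, b = b, mmc = cseq[b] - ifelse(a > 1L, cseq[a - 1L], 0L))
  }
  collapse <- function(d) {
    if (nrow(d) == 0L) return(d)
    d$score <- d$length - 4L * d$mismatches
    d <- d[order(d$start1), , drop = FALSE]
    groups <- list(); cur <- d[1L, , drop = FALSE]; cur_end <- d$end1[1L]
    for (i in seq_len(nrow(d))[-1L]) {
      if (d$start1[i] < cur_end) {
        cur <- rbind(cur, d[i, ]); cur_end <- max(cur_end, d$end1[i])
      } else {
        groups[[length(groups) + 1L]] <- cur
        cur <- d[i, , drop = FALSE]; cur_end <- d$end1[i]
      }
    }
    groups[[length(groups) + 1L]] <- cur
    out <- do.call(rbind, lapply(groups, function(g)
      g[order(-g$score, g$start1), , drop = FALSE][1L, , drop = FALSE]))
    out$score <- NULL
    out
  }
  res <- list()
  for (d in seq_len(n - min_len)) {
    lim <- n - d
    if (lim < min_len) next
    mm <- cs[seq_len(lim)] != cs[(d + 1L):n]
    w <- windows_of(mm)
    if (is.null(w)) next
    hits <- data.frame(kind = "direct", start1 = w[, "a"] - 1L, end1 = w[, "b"],
                       start2 = w[, "a"] - 1L + d, end2 = w[, "b"] + d,
                       length = w[, "b"] - w[, "a"] + 1L,
                       mismatches = w[, "mmc"])
    hits <- hits[1 - hits$mismatches / hits$length >= min_identity, ,
                 drop = FALSE]
    if (nrow(hits)) res[[length(res) + 1L]] <- collapse(hits)
  }
  for (cc in 3:(2L * n - 1L)) {
    umin <- max(1L, cc - n); umax <- floor((cc - 1L) / 2)
    if (umax - umin + 1L < min_len) next
    us <- seq.int(umin, umax)
    mm <- cs[us] != comp[cc - us]
    w <- windows_of(mm)
    if (is.null(w)) next
    a <- us[w[, "a"]]; b <- us[w[, "b"]]
    hits <- data.frame(kind = "palindromic", start1 = a - 1L, end1 = b,
                       start2 = cc - b - 1L, end2 = cc - a,
                       length = b - a + 1L, mismatches = w[, "mmc"])
    hits <- hits[1 - hits$mismatches / hits$length >= min_identity &
                   hits$start1 != hits$start2, , drop = FALSE]
    if (nrow(hits)) res[[length(res) + 1L]] <- collapse(hits)
  }
  if (length(res) == 0L) {
    return(data.frame(kind = character(0), start1 = integer(0),
                      end1 = integer(0), start2 = integer(0),
                      end2 = integer(0)))
  }
  out <- do.call(rbind, res)
  out <- out[order(out$start1, out$start2), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# ---- bipartitions (independent of the consensus implementation) -------------

oracle_splits <- function(tree) {
  labs_all <- sort(tree$tip.label)
  ref <- labs_all[1L]
  tr <- ape::root(tree, outgroup = ref, resolve.root = TRUE)
  pp <- ape::prop.part(tr)
  labs <- attr(pp, "labels")
  out <- character(0)
  for (ii in pp) {
    s <- labs[ii]
    if (ref %in% s) s <- setdiff(labs, s)
    if (length(s) >= 2L && length(s) <= length(labs) - 2L) {
      out <- c(out, paste(sort(s), collapse = ","))
    }
  }
  sort(unique(out))
}

repeat_key <- function(d) {
  if (nrow(d) == 0L) return(character(0))
  sort(paste(d$kind, d$start1, d$end1, d$start2, d$end2))
}
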