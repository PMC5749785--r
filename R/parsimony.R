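#' Character matrix for parsimony analysis
#'
#' Taxa by characters, each entry a single state symbol (nucleotides or
#' numbered states 0-9), `?` for missing or `-` for inapplicable/gap. Both
#' `?` and `-` are treated as fully ambiguous (the full state set of the
#' column) in all parsimony passes, PAUP's standard treatment.
#'
#' @param x Character matrix with taxa as rownames (or an
#'   [aligned_matrix()], in which case `N` maps to `?`).
#' @return An object of class `char_matrix`.
#' @export
char_matrix <- function(x) {
  if (inherits(x, "aligned_matrix")) {
    m <- x$mat
    m[m == "N"] <- "?"
    x <- m
  }
  if (inherits(x, "ndh_matrix")) x <- unclass(x)
  .assert(is.matrix(x) && is.character(x) && !is.null(rownames(x)),
          "x must be a character matrix with taxa rownames",
          "plastodecay_invalid_argument")
  .assert(!anyDuplicated(rownames(x)), "duplicate taxon names",
          "plastodecay_invalid_argument")
  structure(list(taxa = rownames(x), mat = x), class = "char_matrix")
}

#' @export
print.char_matrix <- function(x, ...) {
  cat(sprintf("<char_matrix> %d taxa x %d characters\n", nrow(x$mat),
              ncol(x$mat)))
  invisible(x)
}

# Per-column state alphabets and tip bitmasks. `?` and `-` get the full mask.
.col_masks <- function(cm) {
  mat <- cm$mat
  nc <- ncol(mat)
  alph <- vector("list", nc)
  masks <- matrix(0L, nrow(mat), nc, dimnames = list(rownames(mat), NULL))
  for (j in seq_len(nc)) {
    col <- mat[, j]
    st <- sort(unique(col[!(col %in% c("?", "-"))]))
    alph[[j]] <- st
    if (length(st) == 0L) { masks[, j] <- 1L; next }
    full <- bitwShiftL(1L, length(st)) - 1L
    mk <- bitwShiftL(1L, match(col, st) - 1L)
    mk[is.na(mk)] <- full
    masks[, j] <- mk
  }
  list(alphabets = alph, masks = masks)
}

.rooted_binary <- function(tree) {
  tr <- tree
  if (!ape::is.rooted(tr)) {
    tr <- ape::root(tr, outgroup = tr$tip.label[1L], resolve.root = TRUE)
  }
  .assert(ape::is.binary(tr), "tree must be binary",
          "plastodecay_invalid_argument")
  tr
}

# Per-character Fitch step counts on a binary tree; vectorized over columns.
.fitch_steps <- function(tree, cm, masks = NULL) {
  if (is.null(masks)) masks <- .col_masks(cm)$masks
  .assert(setequal(tree$tip.label, rownames(masks)),
          "tree leaves and matrix taxa differ", "plastodecay_invalid_argument")
  tr <- .rooted_binary(tree)
  tr <- stats::reorder(tr, "postorder")
  ntip <- length(tr$tip.label)
  nn <- ntip + tr$Nnode
  nc <- ncol(masks)
  nm <- matrix(0L, nn, nc)
  nm[seq_len(ntip), ] <- masks[match(tr$tip.label, rownames(masks)), ,
                               drop = FALSE]
  steps <- integer(nc)
  seen <- logical(nn)
  ed <- tr$edge
  for (i in seq_len(nrow(ed))) {
    p <- ed[i, 1L]; ch <- ed[i, 2L]
    cmk <- nm[ch, ]
    if (!seen[p]) { nm[p, ] <- cmk; seen[p] <- TRUE }
    else {
      inter <- bitwAnd(nm[p, ], cmk)
      z <- inter == 0L
      if (any(z)) {
        steps[z] <- steps[z] + 1L
        inter[z] <- bitwOr(nm[p, ], cmk)[z]
      }
      nm[p, ] <- inter
    }
  }
  steps
}

#' Fitch parsimony length of a tree
#'
#' Sum over characters of the minimum mutation count (unordered states, unit
#' costs), with `?` and `-` at the tips treated as the full state set. The
#' result is independent of rooting.
#'
#' @param tree An [ape::phylo] tree (binary; rooted or unrooted).
#' @param cm A [char_matrix()] whose taxa match the tree's leaves.
#' @return Integer number of steps.
#' @export
fitch_length <- function(tree, cm) {
  sum(.fitch_steps(tree, cm))
}

# ---- canonical bipartitions ------------------------------------------------

# Nontrivial bipartitions of an (un)rooted tree, each normalized to the side
# not containing the alphabetically first taxon, as sorted comma strings.
.bipartitions <- function(tree) {
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

.topo_key <- function(tree) paste(.bipartitions(tree), collapse = ";")

# Compress columns to unique site patterns with weights, dropping columns
# that are free on every tree (some state shared by all tips). Lengths are
# unchanged; searches only get faster.
.compress_patterns <- function(masks) {
  keep <- apply(masks, 2L, function(col) Reduce(bitwAnd, col) == 0L)
  masks <- masks[, keep, drop = FALSE]
  if (ncol(masks) == 0L) {
    return(list(masks = masks, weights = numeric(0)))
  }
  key <- apply(masks, 2L, paste, collapse = ",")
  first <- !duplicated(key)
  w <- as.vector(table(factor(key, levels = key[first])))
  list(masks = masks[, first, drop = FALSE], weights = w)
}

# ---- light edge-list trees for search --------------------------------------
# Tips carry ids 1..N (taxon index); internal nodes get ids > N as created.

.lt_initial <- function(t1, t2, t3, next_id) {
  list(edges = rbind(c(next_id, t1), c(next_id, t2), c(next_id, t3)),
       next_id = next_id + 1L)
}

.lt_insert <- function(lt, edge_row, tip) {
  m <- lt$edges[edge_row, ]
  w <- lt$next_id
  edges <- rbind(lt$edges[-edge_row, , drop = FALSE],
                 c(m[1L], w), c(w, m[2L]), c(w, tip))
  list(edges = edges, next_id = w + 1L)
}

# Weighted Fitch length for a light tree over the columns of `masks`
# (rows = taxon ids).
.lt_fitch <- function(lt, masks, n_all, w = NULL) {
  if (is.null(w)) w <- rep(1, ncol(masks))
  ed <- lt$edges
  nodes <- sort(unique(as.vector(ed)))
  adj <- vector("list", max(nodes))
  for (i in seq_len(nrow(ed))) {
    a <- ed[i, 1L]; b <- ed[i, 2L]
    adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
  }
  root <- nodes[nodes <= n_all][1L]   # any tip as root
  nc <- ncol(masks)
  # iterative postorder
  parent <- integer(max(nodes)); order_ <- integer(0)
  stack <- root; parent[root] <- 0L
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    order_ <- c(order_, v)
    for (u in adj[[v]]) if (u != parent[v]) { parent[u] <- v; stack <- c(stack, u) }
  }
  steps <- integer(nc)
  nm <- matrix(0L, max(nodes), nc)
  tips_here <- nodes[nodes <= n_all]
  nm[tips_here, ] <- masks[tips_here, , drop = FALSE]
  seen <- logical(max(nodes))
  for (v in rev(order_)) {
    if (v == root) next
    p <- parent[v]
    if (p == root) { steps <- steps + as.integer(bitwAnd(nm[v, ], nm[root, ]) == 0L); next }
    if (!seen[p]) { nm[p, ] <- nm[v, ]; seen[p] <- TRUE }
    else {
      inter <- bitwAnd(nm[p, ], nm[v, ])
      z <- inter == 0L
      if (any(z)) {
        steps[z] <- steps[z] + 1L
        inter[z] <- bitwOr(nm[p, ], nm[v, ])[z]
      }
      nm[p, ] <- inter
    }
  }
  sum(steps * w)
}

.lt_to_phylo <- function(lt, taxa) {
  ed <- lt$edges
  n_all <- length(taxa)
  adj <- list()
  for (i in seq_len(nrow(ed))) {
    a <- as.character(ed[i, 1L]); b <- as.character(ed[i, 2L])
    adj[[a]] <- c(adj[[a]], ed[i, 2L]); adj[[b]] <- c(adj[[b]], ed[i, 1L])
  }
  tips <- sort(unique(as.vector(ed)))
  tips <- tips[tips <= n_all]
  start <- tips[1L]
  nwk <- function(v, par) {
    kids <- setdiff(adj[[as.character(v)]], par)
    if (length(kids) == 0L) return(taxa[v])
    paste0("(", paste(vapply(kids, nwk, "", par = v), collapse = ","), ")")
  }
  hub <- adj[[as.character(start)]][1L]
  kids <- setdiff(adj[[as.character(hub)]], start)
  txt <- paste0("(", taxa[start], ",",
                paste(vapply(kids, nwk, "", par = hub), collapse = ","), ");")
  ape::read.tree(text = txt)
}

# Max-mini-style addition order: start from the most distant pair (Hamming on
# shared non-missing characters), then farthest-point insertion. Exactness of
# branch-and-bound does not depend on this; it only tightens early bounds.
.addition_order <- function(cm) {
  mat <- cm$mat
  n <- nrow(mat)
  dd <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    ok <- !(mat[i, ] %in% c("?", "-")) & !(mat[j, ] %in% c("?", "-"))
    dd[i, j] <- dd[j, i] <- sum(mat[i, ok] != mat[j, ok])
  }
  pick <- which(dd == max(dd), arr.ind = TRUE)
  pick <- pick[pick[, 1L] != pick[, 2L], , drop = FALSE]
  ord <- if (nrow(pick) == 0L) 1:2 else sort(as.integer(pick[1L, ]))
  while (length(ord) < n) {
    rest <- setdiff(seq_len(n), ord)
    mind <- vapply(rest, function(r) min(dd[r, ord]), numeric(1L))
    ord <- c(ord, rest[which.max(mind)])
  }
  ord
}

#' Maximum-parsimony tree search
#'
#' Three methods: `exhaustive` enumerates every unrooted topology (n <= 9);
#' `branch_and_bound` (n <= 16) is exact, pruning partial trees whose Fitch
#' length already exceeds the best complete tree (initial bound from a
#' stepwise-addition tree); `heuristic` runs random-addition replicates
#' followed by subtree-pruning-regrafting (SPR) hill climbing. All distinct
#' minimal topologies found are returned (duplicates removed by canonical
#' bipartition-set hashing); the exact methods guarantee the global optimum
#' and the complete optimal set.
#'
#' @param cm A [char_matrix()] (>= 4 taxa).
#' @param method `"branch_and_bound"` (default), `"exhaustive"` or
#'   `"heuristic"`.
#' @param seed Integer seed (heuristic random addition).
#' @param n_starts Random-addition replicates for the heuristic.
#' @return A `search_result`: list with `length`, `trees` (multiPhylo of all
#'   minimal topologies), `method`, `ci`, `ri`.
#' @export
search_mp <- function(cm, method = c("branch_and_bound", "exhaustive",
                                     "heuristic"),
                      seed = 1L, n_starts = 10L) {
  method <- match.arg(method)
  taxa <- cm$taxa
  n <- length(taxa)
  .assert(n >= 4L, "need at least 4 taxa", "plastodecay_invalid_argument")
  msk <- .col_masks(cm)$masks
  cp <- .compress_patterns(msk)
  cmsk <- cp$masks; w <- cp$weights
  if (method == "exhaustive") {
    .assert(n <= 9L, "exhaustive enumeration supports at most 9 taxa",
            "plastodecay_invalid_argument")
    trees <- phangorn::allTrees(n, rooted = FALSE, tip.label = taxa)
    # score via the light edge-list Fitch: every enumerated tree shares the
    # same tip numbering, so the mask rows can be aligned once
    msk_ord <- cmsk[match(trees[[1L]]$tip.label, rownames(cmsk)), ,
                    drop = FALSE]
    lens <- if (ncol(cmsk) == 0L) rep(0, length(trees)) else
      vapply(trees, function(tr)
        .lt_fitch(list(edges = tr$edge, next_id = n + tr$Nnode + 1L),
                  msk_ord, n, w), numeric(1L))
    best <- min(lens)
    mp <- trees[lens == best]
  } else if (method == "branch_and_bound") {
    .assert(n <= 16L,
            "branch_and_bound supports at most 16 taxa; use method='heuristic'",
            "plastodecay_invalid_argument")
    ord <- .addition_order(cm)
    greedy <- .greedy_addition(ord, cmsk, n, w)
    bound <- .lt_fitch(greedy, cmsk, n, w)
    env <- new.env()
    env$best <- bound
    env$found <- list()
    recurse <- function(lt, k) {
      len <- .lt_fitch(lt, cmsk, n, w)
      if (len > env$best) return()
      if (k > n) {
        if (len < env$best) { env$best <- len; env$found <- list(lt) }
        else env$found[[length(env$found) + 1L]] <- lt
        return()
      }
      for (e in seq_len(nrow(lt$edges))) {
        recurse(.lt_insert(lt, e, ord[k]), k + 1L)
      }
    }
    lt0 <- .lt_initial(ord[1L], ord[2L], ord[3L], n + 1L)
    recurse(lt0, 4L)
    best <- env$best
    mp <- lapply(env$found, .lt_to_phylo, taxa = taxa)
  } else {
    res <- .with_stream(seed, "search_mp_heuristic", {
      out <- list()
      for (r in seq_len(n_starts)) {
        ord <- if (r == 1L) .addition_order(cm) else sample.int(n)
        lt <- .greedy_addition(ord, cmsk, n, w)
        lt <- .spr_hillclimb(lt, cmsk, n, w)
        out[[r]] <- lt
      }
      out
    })
    lens <- vapply(res, .lt_fitch, numeric(1L), masks = cmsk, n_all = n, w = w)
    best <- min(lens)
    mp <- lapply(res[lens == best], .lt_to_phylo, taxa = taxa)
  }
  keys <- vapply(mp, .topo_key, character(1L))
  mp <- mp[!duplicated(keys)]
  class(mp) <- "multiPhylo"
  ciri <- ci_ri(cm, mp[[1L]])
  structure(list(length = as.integer(best), trees = mp, method = method,
                 ci = ciri$ci, ri = ciri$ri),
            class = "search_result")
}

#' @export
print.search_result <- function(x, ...) {
  cat(sprintf(
    "<search_result> %d most parsimonious tree(s), %d steps (CI %.3f, RI %s), method %s\n",
    length(x$trees), x$length, x$ci,
    if (is.na(x$ri)) "NA" else sprintf("%.3f", x$ri), x$method))
  invisible(x)
}

.greedy_addition <- function(ord, masks, n_all, w = NULL) {
  lt <- .lt_initial(ord[1L], ord[2L], ord[3L], n_all + 1L)
  for (k in seq_along(ord)[-(1:3)]) {
    cand <- lapply(seq_len(nrow(lt$edges)), function(e)
      .lt_insert(lt, e, ord[k]))
    lens <- vapply(cand, .lt_fitch, numeric(1L), masks = masks,
                   n_all = n_all, w = w)
    lt <- cand[[which.min(lens)]]
  }
  lt
}

.spr_hillclimb <- function(lt, masks, n_all, w = NULL) {
  cur_len <- .lt_fitch(lt, masks, n_all, w)
  repeat {
    improved <- FALSE
    for (e in seq_len(nrow(lt$edges))) {
      moves <- .spr_moves(lt, e, n_all)
      if (length(moves) == 0L) next
      lens <- vapply(moves, .lt_fitch, numeric(1L), masks = masks,
                     n_all = n_all, w = w)
      if (min(lens) < cur_len) {
        lt <- moves[[which.min(lens)]]
        cur_len <- min(lens)
        improved <- TRUE
        break
      }
    }
    if (!improved) break
  }
  lt
}

# All SPR rearrangements pruning the subtree below edge `e` (on the child
# side) and reattaching it on every edge of the remaining tree.
.spr_moves <- function(lt, e, n_all) {
  ed <- lt$edges
  u <- ed[e, 1L]; v <- ed[e, 2L]
  # nodes on v's side (excluding the edge)
  adj <- list()
  for (i in seq_len(nrow(ed))) {
    a <- as.character(ed[i, 1L]); b <- as.character(ed[i, 2L])
    adj[[a]] <- c(adj[[a]], ed[i, 2L]); adj[[b]] <- c(adj[[b]], ed[i, 1L])
  }
  side <- v; stack <- v
  while (length(stack)) {
    x <- stack[length(stack)]; stack <- stack[-length(stack)]
    for (y in adj[[as.character(x)]]) {
      if (y != u && !(y %in% side)) { side <- c(side, y); stack <- c(stack, y) }
    }
  }
  rest_rows <- !(ed[, 1L] %in% side & ed[, 2L] %in% side)
  rest_rows[e] <- FALSE
  rest <- ed[rest_rows, , drop = FALSE]
  # suppress u (now degree 2 in rest)
  nb <- c(rest[rest[, 1L] == u, 2L], rest[rest[, 2L] == u, 1L])
  if (length(nb) != 2L) return(list())   # u was the hub of a 3-leaf rest
  rest <- rest[rest[, 1L] != u & rest[, 2L] != u, , drop = FALSE]
  rest <- rbind(rest, nb)
  sub <- ed[ed[, 1L] %in% side & ed[, 2L] %in% side, , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(rest))) {
    a <- rest[i, 1L]; b <- rest[i, 2L]
    if (a == nb[1L] && b == nb[2L] && nrow(rest) > 1L) {
      # reattaching on the merged edge restores the original tree; keep it
      # only as identity move (skip)
      next
    }
    w <- lt$next_id
    edges <- rbind(rest[-i, , drop = FALSE], c(a, w), c(w, b), c(w, v), sub)
    out[[length(out) + 1L]] <- list(edges = edges, next_id = w + 1L)
  }
  out
}

#' Strict consensus of a set of trees
#'
#' Retains exactly the bipartitions present in every input tree (possibly
#' multifurcating).
#'
#' @param trees A `multiPhylo` or list of [ape::phylo] trees with identical
#'   leaf sets.
#' @return A [ape::phylo] tree.
#' @export
strict_consensus <- function(trees) {
  if (inherits(trees, "phylo")) return(trees)
  .assert(length(trees) >= 1L, "empty tree set", "plastodecay_invalid_argument")
  ls1 <- sort(trees[[1L]]$tip.label)
  for (tr in trees) {
    .assert(identical(sort(tr$tip.label), ls1), "trees have different leaf sets",
            "plastodecay_invalid_argument")
  }
  if (length(trees) == 1L) return(trees[[1L]])
  class(trees) <- "multiPhylo"
  ape::consensus(trees, p = 1, rooted = FALSE)
}

#' Consistency and retention indices
#'
#' Per character: `m` = observed states among non-missing tips minus 1;
#' `s` = Fitch steps on the tree; `g` = maximum steps on any tree =
#' non-missing tip count minus the count of the most frequent state.
#' `CI = sum(m)/sum(s)` (1 when `sum(s)` is 0) and
#' `RI = (sum(g)-sum(s))/(sum(g)-sum(m))` (`NA` when `sum(g) = sum(m)`).
#' By default all characters are included (PAUP's headline CI);
#' `informative_only = TRUE` restricts to parsimony-informative characters.
#'
#' @param cm A [char_matrix()].
#' @param tree A binary [ape::phylo] tree over the same taxa.
#' @param informative_only Restrict to parsimony-informative characters.
#' @return List with `ci` and `ri`.
#' @export
ci_ri <- function(cm, tree, informative_only = FALSE) {
  mat <- cm$mat
  s <- .fitch_steps(tree, cm)
  m <- integer(ncol(mat)); g <- integer(ncol(mat)); informative <- logical(ncol(mat))
  for (j in seq_len(ncol(mat))) {
    col <- mat[, j]
    obs <- col[!(col %in% c("?", "-"))]
    tb <- table(obs)
    m[j] <- max(0L, length(tb) - 1L)
    g[j] <- if (length(tb) > 0L) length(obs) - max(tb) else 0L
    informative[j] <- sum(tb >= 2L) >= 2L
  }
  if (informative_only) { s <- s[informative]; m <- m[informative]; g <- g[informative] }
  ci <- if (sum(s) == 0L) 1.0 else sum(m) / sum(s)
  ri <- if (sum(g) == sum(m)) NA_real_ else (sum(g) - sum(s)) / (sum(g) - sum(m))
  list(ci = ci, ri = ri)
}

#' Nonparametric bootstrap support
#'
#' Resamples characters with replacement to the original count, repeats the
#' parsimony search, and reports for each bipartition the percentage of
#' replicates whose strict consensus of most parsimonious trees contains it.
#'
#' @param cm A [char_matrix()].
#' @param n_reps Number of pseudoreplicates (>= 1).
#' @param method Search method per replicate (see [search_mp()]).
#' @param seed Integer seed.
#' @return `data.frame` with `split` (comma-joined taxa of the smaller side,
#'   normalized) and `support` (percent).
#' @export
bootstrap_support <- function(cm, n_reps = 100L, method = "branch_and_bound",
                              seed = 1L) {
  .assert(n_reps >= 1L, "n_reps must be >= 1", "plastodecay_invalid_argument")
  nc <- ncol(cm$mat)
  tally <- new.env()
  .with_stream(seed, "bootstrap_support", {
    for (r in seq_len(n_reps)) {
      idx <- sample.int(nc, nc, replace = TRUE)
      sub <- char_matrix(cm$mat[, idx, drop = FALSE])
      sr <- search_mp(sub, method = method, seed = seed + r)
      cons <- strict_consensus(sr$trees)
      for (sp in .bipartitions(cons)) {
        tally[[sp]] <- (if (is.null(tally[[sp]])) 0L else tally[[sp]]) + 1L
      }
    }
  })
  sps <- ls(tally)
  out <- data.frame(split = sps,
                    support = vapply(sps, function(s) 100 * tally[[s]] / n_reps,
                                     numeric(1L)))
  out <- out[order(-out$support, out$split), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' ACCTRAN character-change mapping
#'
#' Roots the tree on a named outgroup and reconstructs ancestral states per
#' character under accelerated transformation: among all minimal-change
#' (Fitch-optimal) reconstructions, the one placing changes as close to the
#' root as possible (preferring early gains plus reversals over parallel
#' gains). Implemented as a Sankoff pass minimizing the pair
#' (changes, sum of change-edge depths) lexicographically; ties in the
#' traceback prefer the parent's state, then the lowest state symbol.
#'
#' @param tree An [ape::phylo] tree containing `outgroup`.
#' @param cm A [char_matrix()].
#' @param outgroup Taxon name used to root the tree.
#' @return `data.frame` with one row per change: `char`, `node` (child
#'   endpoint of the branch: tip label or internal node id), `from`, `to`,
#'   `depth` (edges from root). The attribute `per_char_changes` holds the
#'   mapped change count per character (equal to the Fitch length).
#' @export
acctran_map <- function(tree, cm, outgroup) {
  .assert(outgroup %in% tree$tip.label, "outgroup not among leaves",
          "plastodecay_invalid_argument")
  rt <- ape::root(ape::unroot(tree), outgroup = outgroup, resolve.root = TRUE)
  .assert(ape::is.binary(rt), "tree must be binary after rooting",
          "plastodecay_invalid_argument")
  rt <- stats::reorder(rt, "postorder")
  ntip <- length(rt$tip.label)
  root <- ntip + 1L
  nn <- ntip + rt$Nnode
  # depths
  depth <- integer(nn); depth[root] <- 0L
  ed <- rt$edge
  for (i in rev(seq_len(nrow(ed)))) depth[ed[i, 2L]] <- depth[ed[i, 1L]] + 1L
  kids <- split(ed[, 2L], ed[, 1L])
  cmk <- .col_masks(cm)
  mat <- cm$mat
  taxa_ord <- match(rt$tip.label, rownames(mat))
  changes <- list()
  per_char <- integer(ncol(mat))
  BIG <- 1e9
  for (j in seq_len(ncol(mat))) {
    st <- cmk$alphabets[[j]]
    k <- length(st)
    if (k <= 1L) next
    steps_c <- matrix(BIG, nn, k)
    depth_c <- matrix(BIG, nn, k)
    for (t in seq_len(ntip)) {
      val <- mat[taxa_ord[t], j]
      if (val %in% c("?", "-")) { steps_c[t, ] <- 0; depth_c[t, ] <- 0 }
      else { steps_c[t, match(val, st)] <- 0; depth_c[t, match(val, st)] <- 0 }
    }
    # postorder combine
    po_nodes <- unique(ed[, 1L])      # postorder: parents appear after children
    for (p in po_nodes) {
      sc <- numeric(k); dc <- numeric(k)
      for (chv in kids[[as.character(p)]]) {
        bs <- numeric(k); bd <- numeric(k)
        for (s in seq_len(k)) {
          cand_s <- steps_c[chv, ] + (seq_len(k) != s)
          cand_d <- depth_c[chv, ] + (seq_len(k) != s) * depth[chv]
          o <- order(cand_s, cand_d)[1L]
          bs[s] <- cand_s[o]; bd[s] <- cand_d[o]
        }
        sc <- sc + bs; dc <- dc + bd
      }
      steps_c[p, ] <- sc; depth_c[p, ] <- dc
    }
    # root assignment and preorder traceback
    final <- integer(nn)
    o <- order(steps_c[root, ], depth_c[root, ])[1L]
    final[root] <- o
    per_char[j] <- as.integer(steps_c[root, o])
    pre <- rev(po_nodes)
    for (p in pre) {
      fs <- final[p]
      for (chv in kids[[as.character(p)]]) {
        cand_s <- steps_c[chv, ] + (seq_len(k) != fs)
        cand_d <- depth_c[chv, ] + (seq_len(k) != fs) * depth[chv]
        ok <- which(cand_s == min(cand_s) &
                      cand_d == min(cand_d[cand_s == min(cand_s)]))
        t <- if (fs %in% ok) fs else ok[1L]
        final[chv] <- t
        if (t != fs) {
          lab <- if (chv <= ntip) rt$tip.label[chv] else
            sprintf("node%d", chv)
          changes[[length(changes) + 1L]] <- data.frame(
            char = j, node = lab, from = st[fs], to = st[t],
            depth = depth[chv])
        }
      }
    }
  }
  out <- if (length(changes)) do.call(rbind, changes) else
    data.frame(char = integer(0), node = character(0), from = character(0),
               to = character(0), depth = integer(0))
  attr(out, "per_char_changes") <- per_char
  out
}
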