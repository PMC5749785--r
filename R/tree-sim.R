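#' Generate a random binary tree with known seed
#'
#' Draws a random unrooted binary topology with strictly positive branch
#' lengths. The same `(n_taxa, seed)` pair always yields the same tree, so
#' simulated datasets are reproducible fixtures.
#'
#' @param n_taxa Number of leaves (>= 3).
#' @param seed Integer seed; every operation in the simulator draws from its
#'   own stream derived from `(seed, operation name)`.
#' @param labels Optional character vector of leaf labels
#'   (default `t01, t02, ...`).
#' @return An [ape::phylo] tree with `n_taxa` leaves and positive branch
#'   lengths.
#' @export
generate_tree <- function(n_taxa, seed = 1L, labels = NULL) {
  .assert(is.numeric(n_taxa) && length(n_taxa) == 1L && n_taxa >= 3,
          "n_taxa must be a single integer >= 3", "plastodecay_invalid_argument")
  n_taxa <- as.integer(n_taxa)
  if (is.null(labels)) labels <- sprintf("t%02d", seq_len(n_taxa))
  .assert(length(labels) == n_taxa && !anyDuplicated(labels),
          "labels must be n_taxa unique strings", "plastodecay_invalid_argument")
  .with_stream(seed, "generate_tree", {
    if (n_taxa == 3L) {
      tr <- ape::read.tree(text = "(a:1,b:1,c:1);")
      tr$edge.length <- stats::runif(3L, 0.1, 1)
      tr$tip.label <- labels
      tr
    } else {
      tr <- ape::rtree(n_taxa, rooted = FALSE, tip.label = labels)
      tr$edge.length <- pmax(tr$edge.length, 1e-3)
      tr
    }
  })
}

#' Evolve an alignment along a tree under Jukes-Cantor
#'
#' Simulates nucleotide substitution (no indels) along `tree`: every leaf
#' sequence has exactly `root_length` columns, so the result is an alignment
#' by construction. Per-branch substitution follows the Jukes-Cantor model:
#' the probability that a site differs from its parent after an expected
#' `d = rate * branch length` substitutions/site is `3/4 (1 - exp(-4 d / 3))`.
#'
#' @param tree A binary [ape::phylo] tree with branch lengths.
#' @param root_length Number of sites (>= 1); ignored when `root_seq` given.
#' @param rate Rate multiplier applied to branch lengths
#'   (expected substitutions/site per unit branch length); must be >= 0.
#' @param seed Integer seed.
#' @param root_seq Optional root sequence (string over A/C/G/T); when supplied
#'   its length defines the alignment length.
#' @param partitions Optional named list of column index vectors attached to
#'   the result.
#' @param rates Optional numeric vector of per-column rate multipliers
#'   (recycled), enabling per-partition rate contrasts.
#' @return An [aligned_matrix] with one row per leaf.
#' @export
evolve_alignment <- function(tree, root_length = 1000L, rate = 0.05, seed = 1L,
                             root_seq = NULL, partitions = list(),
                             rates = NULL) {
  .assert(inherits(tree, "phylo"), "tree must be a phylo object",
          "plastodecay_invalid_argument")
  .assert(is.numeric(rate) && length(rate) == 1L && rate >= 0,
          "rate must be a single non-negative number",
          "plastodecay_invalid_argument")
  if (is.null(root_seq)) {
    .assert(root_length >= 1, "root_length must be >= 1",
            "plastodecay_invalid_argument")
  } else {
    root_length <- nchar(root_seq)
  }
  L <- as.integer(root_length)
  site_rate <- if (is.null(rates)) rep(1, L) else rep_len(rates, L)

  tr <- tree
  if (!ape::is.rooted(tr)) {
    tr <- ape::root(tr, outgroup = tr$tip.label[1L], resolve.root = TRUE)
  }
  tr <- stats::reorder(tr, "cladewise")
  ntip <- length(tr$tip.label)
  nnode <- tr$Nnode
  root <- ntip + 1L

  .with_stream(seed, "evolve_alignment", {
    seqs <- vector("list", ntip + nnode)
    seqs[[root]] <- if (is.null(root_seq)) {
      sample.int(4L, L, replace = TRUE)
    } else {
      m <- match(.chars(toupper(root_seq)), .DNA)
      .assert(!anyNA(m), "root_seq must contain only A/C/G/T",
              "plastodecay_invalid_argument")
      m
    }
    for (i in seq_len(nrow(tr$edge))) {
      par <- tr$edge[i, 1L]; chi <- tr$edge[i, 2L]
      d <- rate * tr$edge.length[i] * site_rate
      p_same <- 0.25 + 0.75 * exp(-4 * d / 3)
      x <- seqs[[par]]
      chg <- stats::runif(L) > p_same
      if (any(chg)) {
        off <- sample.int(3L, sum(chg), replace = TRUE)
        x[chg] <- (x[chg] - 1L + off) %% 4L + 1L
      }
      seqs[[chi]] <- x
    }
    mat <- do.call(rbind, lapply(seq_len(ntip), function(i) .DNA[seqs[[i]]]))
    rownames(mat) <- tr$tip.label
    aligned_matrix(mat, partitions = partitions)
  })
}
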