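test_that("fitch_length matches hand-checkable examples", {
  cm <- char_matrix(matrix(c("0", "0", "1", "1"), 4, 1,
                           dimnames = list(c("A", "B", "C", "D"), NULL)))
  t1 <- ape::read.tree(text = "((A,B),(C,D));")
  t2 <- ape::read.tree(text = "((A,C),(B,D));")
  expect_equal(fitch_length(t1, cm), 1L)
  expect_equal(fitch_length(t2, cm), 2L)

  # constant character: zero steps on any tree
  cc <- char_matrix(matrix("A", 4, 3, dimnames = list(c("A", "B", "C", "D"),
                                                      NULL)))
  expect_equal(fitch_length(t1, cc), 0L)

  expect_error(fitch_length(t1, char_matrix(matrix("0", 3, 1,
                            dimnames = list(c("A", "B", "X"), NULL)))),
               class = "plastodecay_invalid_argument")
})

test_that("fitch_length is invariant to rooting and taxon order", {
  set.seed(71)
  for (r in 1:10) {
    n <- sample(5:8, 1)
    tr <- ape::rtree(n, rooted = FALSE)
    m <- matrix(sample(c("A", "C", "G", "T", "?", "-"), n * 10, TRUE,
                       prob = c(.23, .23, .23, .23, .04, .04)), n, 10,
                dimnames = list(tr$tip.label, NULL))
    cm <- char_matrix(m)
    L <- fitch_length(tr, cm)
    for (og in sample(tr$tip.label, 2)) {
      expect_equal(fitch_length(ape::root(tr, og, resolve.root = TRUE), cm), L)
    }
    perm <- char_matrix(m[sample(n), , drop = FALSE])
    expect_equal(fitch_length(tr, perm), L)
  }
})

test_that("fitch_length equals the exhaustive assignment oracle", {
  set.seed(72)
  for (r in 1:25) {
    n <- sample(4:7, 1)
    tr <- ape::rtree(n, rooted = FALSE)
    m <- matrix(sample(c("0", "1", "2", "?"), n * 6, TRUE,
                       prob = c(.35, .35, .2, .1)), n, 6,
                dimnames = list(tr$tip.label, NULL))
    expect_equal(fitch_length(tr, char_matrix(m)), oracle_fitch(tr, m),
                 info = paste("replicate", r))
  }
})

test_that("search_mp on 4 taxa examines the 3 topologies", {
  m <- matrix(c("0", "0", "1", "1",
                "0", "1", "0", "1",
                "0", "1", "1", "0"), 4, 3,
              dimnames = list(c("A", "B", "C", "D"), NULL))
  cm <- char_matrix(m)
  sr <- search_mp(cm, method = "exhaustive")
  all3 <- phangorn::allTrees(4, rooted = FALSE, tip.label = c("A", "B", "C",
                                                              "D"))
  lens <- vapply(all3, fitch_length, integer(1L), cm = cm)
  expect_equal(sr$length, min(lens))
  expect_equal(length(sr$trees), sum(lens == min(lens)))
})

test_that("branch-and-bound equals exhaustive enumeration", {
  set.seed(73)
  for (r in 1:8) {
    m <- matrix(sample(c("0", "1"), 6 * 12, TRUE), 6, 12,
                dimnames = list(paste0("t", 1:6), NULL))
    cm <- char_matrix(m)
    ex <- search_mp(cm, "exhaustive")
    bb <- search_mp(cm, "branch_and_bound")
    expect_equal(bb$length, ex$length)
    expect_setequal(vapply(bb$trees, plastodecay:::.topo_key, ""),
                    vapply(ex$trees, plastodecay:::.topo_key, ""))
  }
})

test_that("heuristic search reaches the exact optimum on small matrices", {
  set.seed(74)
  for (r in 1:4) {
    m <- matrix(sample(c("0", "1", "2"), 7 * 15, TRUE), 7, 15,
                dimnames = list(paste0("t", 1:7), NULL))
    cm <- char_matrix(m)
    ex <- search_mp(cm, "exhaustive")
    he <- search_mp(cm, "heuristic", seed = r, n_starts = 8)
    expect_equal(he$length, ex$length)
  }
})

test_that("matrices evolved on a known tree recover that topology", {
  # low-homoplasy regime: every branch carries signal (>= 0.3 expected
  # substitutions/site at rate 0.2 it is ~6% per branch), 250 characters
  hits <- 0L
  for (r in 1:50) {
    tr <- generate_tree(8, seed = 700 + r)
    tr$edge.length <- pmax(tr$edge.length, 0.3)
    am <- evolve_alignment(tr, 250, rate = 0.2, seed = 700 + r)
    sr <- search_mp(char_matrix(am), method = "branch_and_bound")
    if (length(sr$trees) == 1L &&
        plastodecay:::.topo_key(sr$trees[[1]]) ==
        plastodecay:::.topo_key(tr)) hits <- hits + 1L
  }
  expect_gte(hits, 48L)   # >= 95% of 50 replicates
})

test_that("strict_consensus keeps exactly the shared bipartitions", {
  t1 <- ape::read.tree(text = "((t1,t2),(t3,(t4,t5)));")
  t2 <- ape::read.tree(text = "((t1,t2),(t4,(t3,t5)));")
  cons <- strict_consensus(c(t1, t2))
  expect_identical(oracle_splits(cons),
                   intersect(oracle_splits(t1), oracle_splits(t2)))

  # single tree: itself
  expect_identical(oracle_splits(strict_consensus(list(t1))),
                   oracle_splits(t1))

  # no shared internal bipartition: star tree
  s1 <- ape::read.tree(text = "((t1,t2),(t3,t4),t5);")
  s2 <- ape::read.tree(text = "((t1,t3),(t2,t4),t5);")
  s3 <- ape::read.tree(text = "((t1,t4),(t2,t3),t5);")
  star <- strict_consensus(c(s1, s2, s3))
  expect_length(oracle_splits(star), 0L)

  # randomized: consensus bipartitions equal the intersection
  set.seed(75)
  for (r in 1:5) {
    trees <- lapply(1:3, function(i) ape::rtree(7, rooted = FALSE))
    for (i in 2:3) trees[[i]]$tip.label <- trees[[1]]$tip.label
    cons <- strict_consensus(trees)
    expect_identical(oracle_splits(cons),
                     Reduce(intersect, lapply(trees, oracle_splits)))
  }

  t3 <- ape::read.tree(text = "((x1,t2),(t3,(t4,t5)));")
  expect_error(strict_consensus(c(t1, t3)),
               class = "plastodecay_invalid_argument")
})

test_that("ci_ri matches hand-enumerated cases and bounds", {
  # every character fits the tree: CI = RI = 1
  tr <- ape::read.tree(text = "((t1,t2),(t6,((t3,t4),t5)));")
  m <- matrix(c("0", "0", "1", "1", "1", "0"), 6, 1,
              dimnames = list(paste0("t", 1:6), NULL))
  expect_equal(ci_ri(char_matrix(m), tr), list(ci = 1, ri = 1))

  # one binary character with two independent origins: m=1, s=2, g=3
  m2 <- matrix(c("1", "1", "0", "0", "1", "0"), 6, 1,
               dimnames = list(paste0("t", 1:6), NULL))
  tr2 <- ape::read.tree(text = "((t1,t2),((t3,t4),(t5,t6)));")
  expect_equal(fitch_length(tr2, char_matrix(m2)), 2L)
  res <- ci_ri(char_matrix(m2), tr2)
  expect_equal(res$ci, 0.5)
  expect_equal(res$ri, 0.5)

  # bounds on random matrices; CI = 1 implies RI = 1
  set.seed(76)
  for (r in 1:10) {
    mm <- matrix(sample(c("0", "1", "?"), 6 * 8, TRUE,
                        prob = c(.45, .45, .1)), 6, 8,
                 dimnames = list(paste0("t", 1:6), NULL))
    rr <- ci_ri(char_matrix(mm), tr2)
    expect_gt(rr$ci, 0); expect_lte(rr$ci, 1)
    if (!is.na(rr$ri)) { expect_gte(rr$ri, 0); expect_lte(rr$ri, 1) }
    if (isTRUE(all.equal(rr$ci, 1)) && !is.na(rr$ri)) expect_equal(rr$ri, 1)
  }
})

test_that("acctran_map places changes root-proximally", {
  tr <- ape::read.tree(text = "((t1,t2),(t6,((t3,t4),t5)));")
  # constant character: no changes anywhere
  mc <- matrix("0", 6, 1, dimnames = list(paste0("t", 1:6), NULL))
  expect_equal(nrow(acctran_map(tr, char_matrix(mc), "t1")), 0L)

  # character derived in one clade: a single change on the stem
  m <- matrix(c("0", "0", "1", "1", "0", "0"), 6, 1,
              dimnames = list(paste0("t", 1:6), NULL))
  ch <- acctran_map(tr, char_matrix(m), "t1")
  expect_equal(nrow(ch), 1L)
  expect_equal(attr(ch, "per_char_changes")[1],
               fitch_length(tr, char_matrix(m)))

  # ambiguous case: ACCTRAN prefers early gain + reversal over two gains
  trx <- ape::read.tree(text = "(((((A,B),C),D),E),OG);")
  mx <- matrix(c("1", "1", "0", "1", "0", "0"), 6, 1,
               dimnames = list(c("A", "B", "C", "D", "E", "OG"), NULL))
  chx <- acctran_map(trx, char_matrix(mx), "OG")
  expect_equal(nrow(chx), 2L)
  expect_true("C" %in% chx$node)              # reversal on the C branch
  expect_identical(sort(chx$from), c("0", "1"))

  expect_error(acctran_map(tr, char_matrix(m), "nope"),
               class = "plastodecay_invalid_argument")
})

test_that("acctran_map agrees with the enumeration oracle", {
  set.seed(77)
  for (r in 1:15) {
    n <- sample(6:7, 1)
    tr <- ape::rtree(n, rooted = FALSE)
    og <- tr$tip.label[1]
    m <- matrix(sample(c("0", "1", "2"), n * 5, TRUE), n, 5,
                dimnames = list(tr$tip.label, NULL))
    cm <- char_matrix(m)
    ch <- acctran_map(tr, cm, og)
    per <- attr(ch, "per_char_changes")
    rt <- ape::root(ape::unroot(tr), outgroup = og, resolve.root = TRUE)
    fs <- plastodecay:::.fitch_steps(tr, cm)
    for (j in 1:5) {
      o <- oracle_acctran_char(rt, m[match(rt$tip.label, rownames(m)), j])
      expect_equal(per[j], o$steps, info = paste(r, j))
      expect_equal(per[j], fs[j], info = paste(r, j))
      dsum <- sum(ch$depth[ch$char == j])
      expect_equal(dsum, o$depthsum, info = paste(r, j))
    }
  }
})

test_that("bootstrap_support behaves on degenerate matrices", {
  # 50 identical characters all supporting one split: support 100
  m <- matrix(rep(c("0", "0", "1", "1", "0", "0"), 50), 6, 50,
              dimnames = list(paste0("t", 1:6), NULL))
  bs <- bootstrap_support(char_matrix(m), n_reps = 20, seed = 1)
  expect_true("t3,t4" %in% bs$split)
  expect_equal(bs$support[bs$split == "t3,t4"], 100)

  # all-constant matrix: no support above star resolution
  mc <- matrix("0", 6, 30, dimnames = list(paste0("t", 1:6), NULL))
  bsc <- bootstrap_support(char_matrix(mc), n_reps = 5, seed = 1)
  expect_equal(nrow(bsc), 0L)

  # two seeds at moderate depth agree within binomial error
  set.seed(78)
  mm <- matrix(sample(c("0", "1"), 6 * 30, TRUE), 6, 30,
               dimnames = list(paste0("t", 1:6), NULL))
  b1 <- bootstrap_support(char_matrix(mm), n_reps = 150, seed = 1)
  b2 <- bootstrap_support(char_matrix(mm), n_reps = 150, seed = 2)
  shared <- intersect(b1$split, b2$split)
  for (s in shared) {
    expect_lte(abs(b1$support[b1$split == s] - b2$support[b2$split == s]), 15)
  }
})

test_that("character matrices parse from NEXUS, PHYLIP and TSV", {
  nex <- withr::local_tempfile(fileext = ".nex")
  writeLines(c("#NEXUS", "BEGIN DATA;", "  DIMENSIONS NTAX=3 NCHAR=4;",
               "  FORMAT DATATYPE=STANDARD MISSING=? GAP=- SYMBOLS=\"012\";",
               "  MATRIX", "    tA 0101", "    tB 01?1", "    tC 1-01",
               "  ;", "END;"), nex)
  cm <- read_char_matrix(nex)
  expect_equal(dim(cm$mat), c(3L, 4L))
  expect_identical(unname(cm$mat["tB", 3]), "?")
  expect_identical(unname(cm$mat["tC", 2]), "-")

  phy <- withr::local_tempfile(fileext = ".phy")
  writeLines(c("3 4", "tA ACGT", "tB AC-T", "tC A?GT"), phy)
  cp <- read_char_matrix(phy)
  expect_identical(unname(cp$mat["tB", 3]), "-")

  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("taxon\tc1\tc2", "tA\t0\t1", "tB\t1\t?"), tsv)
  ct <- read_char_matrix(tsv)
  expect_equal(dim(ct$mat), c(2L, 2L))
  expect_identical(unname(ct$mat["tB", 2]), "?")
})
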