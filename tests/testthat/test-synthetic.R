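test_that("generate_tree returns labelled binary trees deterministically", {
  expect_error(generate_tree(2), class = "plastodecay_invalid_argument")

  tr3 <- generate_tree(3, seed = 1)
  expect_s3_class(tr3, "phylo")
  expect_equal(length(tr3$tip.label), 3L)

  t1 <- generate_tree(5, seed = 1)
  t2 <- generate_tree(5, seed = 1)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  expect_false(identical(ape::write.tree(t1),
                         ape::write.tree(generate_tree(5, seed = 2))))

  labs <- c("alpha", "beta", "gamma", "delta", "eps", "zeta")
  t6 <- generate_tree(6, seed = 2, labels = labs)
  expect_setequal(t6$tip.label, labs)
  expect_true(all(t6$edge.length > 0))
})

test_that("evolve_alignment is deterministic and respects rate 0", {
  tr <- generate_tree(5, seed = 3)
  expect_error(evolve_alignment(tr, 100, rate = -1),
               class = "plastodecay_invalid_argument")

  am0 <- evolve_alignment(tr, 80, rate = 0, seed = 4)
  expect_true(all(apply(am0$mat, 2, function(col) length(unique(col)) == 1L)))

  a1 <- evolve_alignment(tr, 200, rate = 0.1, seed = 5)
  a2 <- evolve_alignment(tr, 200, rate = 0.1, seed = 5)
  expect_identical(a1$mat, a2$mat)
  expect_equal(dim(a1$mat), c(5L, 200L))

  rooted <- evolve_alignment(tr, 50, rate = 0.05, seed = 6,
                             root_seq = strrep("ACGT", 25))
  expect_equal(ncol(rooted$mat), 100L)
})

test_that("evolve_alignment preserves base composition (Jukes-Cantor)", {
  tr <- generate_tree(4, seed = 7)
  counts <- c(A = 0, C = 0, G = 0, T = 0)
  for (s in 1:20) {
    am <- evolve_alignment(tr, 400, rate = 0.2, seed = s)
    tb <- table(factor(am$mat, levels = c("A", "C", "G", "T")))
    counts <- counts + as.vector(tb)
  }
  p <- stats::chisq.test(counts, p = rep(0.25, 4))$p.value
  expect_gt(p, 0.01)
})

test_that("build_plastome obeys region arithmetic and plants intact genes", {
  bp <- plastome_blueprint(lsc = 8000, ir = 2500, ssc = 1000, seed = 11)
  out <- build_plastome(bp)
  rec <- out$record

  expect_equal(rec$length, 8000 + 1000 + 2 * 2500)
  expect_identical(region_seq(rec, "IRb"), revcomp_chr(region_seq(rec, "IRa")))

  for (g in c("ndhA", "ndhF", "matK", "atpF", "rbcL")) {
    s <- gene_seq(rec, g)
    expect_identical(substr(s, 1, 3), "ATG")
    expect_true(substr(s, nchar(s) - 2, nchar(s)) %in% c("TAA", "TAG", "TGA"))
    cod <- substring(s, seq(1, nchar(s) - 3, 3), seq(3, nchar(s) - 3, 3))
    expect_false(any(cod %in% c("TAA", "TAG", "TGA")))
  }

  # a 100-codon roster gene spans 300 bp
  gA <- rec$genes[rec$genes$name == "ndhA", ]
  expect_equal(gA$end - gA$start, 300L)

  # planted repeats are present verbatim
  rt <- out$truth$repeats
  ssr <- rt[rt$kind == "ssr" & rt$unit == "A", ][1, ]
  expect_identical(substr(rec$seq, ssr$start1 + 1, ssr$end1),
                   strrep("A", ssr$end1 - ssr$start1))
  dr <- rt[rt$kind == "direct", ][1, ]
  expect_identical(substr(rec$seq, dr$start1 + 1, dr$end1),
                   substr(rec$seq, dr$start2 + 1, dr$end2))

  # identical seed => identical genome
  expect_identical(build_plastome(bp)$record$seq, rec$seq)

  # detect_quadripartite round-trips the blueprint boundaries exactly
  q <- detect_quadripartite(rec$seq, min_ir = 1000)
  expect_true(q$found)
  expect_equal(q$regions$end - q$regions$start, c(8000L, 2500L, 1000L, 2500L))
  expect_equal(q$offset, 0L)
})

test_that("blueprints that cannot fit their roster are rejected", {
  expect_error(plastome_blueprint(lsc = 500, ir = 2500, ssc = 1000, seed = 1),
               class = "plastodecay_invalid_blueprint")
})

test_that("apply_degradation applies each lesion recipe as stated", {
  out <- build_plastome(default_blueprint("desk", seed = 12))
  rec <- out$record

  expect_error(
    apply_degradation(rec, degradation_scenario("nope", "deleted")),
    class = "plastodecay_missing_gene")

  glen <- function(r, g) {
    d <- r$genes[r$genes$name == g, ]
    if (nrow(d) == 0) 0L else max(d$end) - min(d$start)
  }

  # deleted: sequence absent, genome shrinks by the gene length
  L <- glen(rec, "ndhA")
  dg <- apply_degradation(rec, degradation_scenario("ndhA", "deleted"),
                          out$truth)
  expect_equal(dg$record$length, rec$length - L)
  expect_false("ndhA" %in% dg$record$genes$name)
  expect_equal(dg$truth$genes$state[dg$truth$genes$gene == "ndhA"], "deleted")

  # pseudogene via start ablation: length unchanged, first codon != ATG
  dg2 <- apply_degradation(rec, degradation_scenario("ndhB", "pseudogene",
                                                     "start_loss"))
  expect_equal(dg2$record$length, rec$length)
  s <- gene_seq(dg2$record, "ndhB")
  expect_false(substr(s, 1, 3) == "ATG")

  # fragment: 30 bp remnant
  dg3 <- apply_degradation(rec, degradation_scenario("ndhC", "fragment"))
  expect_equal(glen(dg3$record, "ndhC"), 30L)

  # frameshift: one base shorter, same annotation span
  dg4 <- apply_degradation(rec, degradation_scenario("ndhD", "pseudogene",
                                                     "frameshift"))
  expect_equal(dg4$record$length, rec$length - 1L)

  # downstream annotations shift consistently and IRs stay mirrored
  expect_identical(region_seq(dg$record, "IRb"),
                   revcomp_chr(region_seq(dg$record, "IRa")))
  for (g in setdiff(unique(rec$genes$name), "ndhA")) {
    expect_identical(gene_seq(dg$record, g), gene_seq(rec, g))
  }
})

test_that("truth manifests round-trip through TSV", {
  out <- build_plastome(default_blueprint("desk", seed = 13))
  dg <- apply_degradation(out$record,
                          degradation_scenario(c("ndhA", "ndhB"),
                                               c("deleted", "fragment")),
                          out$truth)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_truth_manifest(dg$truth, path, taxon = "tx")
  back <- read_truth_manifest(path)
  expect_identical(back$gene, dg$truth$genes$gene)
  expect_identical(back$true_state, dg$truth$genes$state)
  expect_identical(back$start, dg$truth$genes$start)
  expect_identical(back$end, dg$truth$genes$end)
})
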