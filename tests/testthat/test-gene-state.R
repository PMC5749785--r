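make_orf <- function(codons, seed) {
  set.seed(seed)
  body <- setdiff(apply(expand.grid(c("A", "C", "G", "T"),
                                    c("A", "C", "G", "T"),
                                    c("A", "C", "G", "T")), 1, paste,
                        collapse = ""), c("TAA", "TAG", "TGA"))
  paste0("ATG", paste(sample(body, codons - 2, TRUE), collapse = ""), "TAA")
}

test_that("locate_gene finds planted genes and respects its floors", {
  set.seed(41)
  ref <- make_orf(80, 41)
  query <- paste0(rand_dna(500), ref, rand_dna(400))

  h <- locate_gene(query, ref)
  expect_equal(nrow(h), 1L)
  expect_equal(h$qstart, 500L)
  expect_equal(h$qend, 500L + nchar(ref))
  expect_equal(h$rstart, 0L)
  expect_equal(h$rend, nchar(ref))
  expect_equal(h$identity, 1)
  expect_equal(h$strand, "+")

  # reverse-complement placement is found on the minus strand
  qrc <- paste0(rand_dna(300), revcomp_chr(ref), rand_dna(300))
  hrc <- locate_gene(qrc, ref)
  expect_equal(hrc$strand, "-")
  expect_equal(hrc$qstart, 300L)

  # a query with no 25 bp stretch of the reference yields nothing
  expect_equal(nrow(locate_gene(rand_dna(600), ref)), 0L)

  expect_error(locate_gene(query, "ATGTAA"),
               class = "plastodecay_invalid_argument")
})

test_that("locate_gene agrees with an exhaustive Smith-Waterman oracle", {
  set.seed(42)
  for (case in 1:20) {
    ref <- make_orf(sample(20:40, 1), 100 + case)
    copy <- ref
    # plant a mutated copy: substitutions, and sometimes a 1 bp deletion
    nsub <- sample(0:3, 1)
    if (nsub > 0) {
      pos <- sample(nchar(copy), nsub)
      for (p in pos) {
        substr(copy, p, p) <- sample(setdiff(c("A", "C", "G", "T"),
                                             substr(copy, p, p)), 1)
      }
    }
    if (case %% 4 == 0) {
      cut <- sample(10:(nchar(copy) - 10), 1)
      copy <- paste0(substr(copy, 1, cut - 1),
                     substr(copy, cut + 1, nchar(copy)))
    }
    query <- paste0(rand_dna(60), copy, rand_dna(60))
    h <- locate_gene(query, ref)
    o <- oracle_sw(query, ref)
    expect_false(is.null(o))
    top <- h[which.max(h$score), ]
    expect_equal(top$score, o$score, info = paste("case", case))
    expect_equal(top$qstart, o$qstart, info = paste("case", case))
    expect_equal(top$qend, o$qend, info = paste("case", case))
    expect_equal(top$rstart, o$rstart, info = paste("case", case))
    expect_equal(top$rend, o$rend, info = paste("case", case))
  }
})

test_that("classify_gene_state implements the four-state rules", {
  set.seed(43)
  ref <- make_orf(90, 43)
  flank <- function(x) paste0(rand_dna(400), x, rand_dna(400))
  classify <- function(q) {
    classify_gene_state(locate_gene(q, ref), ref, q)
  }

  # intact planted gene -> complete
  expect_equal(classify(flank(ref))$state, "complete")

  # start-codon ablation (ATG -> TTG), full length -> pseudogene, no_start
  ps <- ref; substr(ps, 1, 3) <- "TTG"
  cl <- classify(flank(ps))
  expect_equal(cl$state, "pseudogene")
  expect_true("no_start" %in% cl$lesions)

  # lost stop -> pseudogene, no_stop
  ns <- ref; substr(ns, nchar(ns) - 2, nchar(ns)) <- "CAA"
  cl <- classify(flank(ns))
  expect_equal(cl$state, "pseudogene")
  expect_true("no_stop" %in% cl$lesions)

  # internal stop -> pseudogene, internal_stop
  is_ <- ref; substr(is_, 121, 123) <- "TAA"
  cl <- classify(flank(is_))
  expect_equal(cl$state, "pseudogene")
  expect_true("internal_stop" %in% cl$lesions)

  # 1 bp frameshift -> pseudogene, frameshift
  fs <- paste0(substr(ref, 1, 100), substr(ref, 102, nchar(ref)))
  cl <- classify(flank(fs))
  expect_equal(cl$state, "pseudogene")
  expect_true("frameshift" %in% cl$lesions)

  # truncation to 30 bp -> fragment
  cl <- classify(flank(substr(ref, 1, 30)))
  expect_equal(cl$state, "fragment")
  expect_lte(cl$coverage, 0.20)

  # full excision -> deleted
  cl30 <- classify_gene_state(locate_gene(rand_dna(800), ref), ref)
  expect_equal(cl30$state, "deleted")
})

test_that("fragment calls flip to deleted below the 25 bp floor, never back", {
  set.seed(44)
  ref <- make_orf(90, 44)
  # guard the remnant with bases complementary to the reference continuation
  # so alignment slop cannot extend the remnant past the floor by chance
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  guarded <- function(keep) {
    cont <- strsplit(substr(ref, keep + 1, keep + 20), "")[[1]]
    paste0(rand_dna(300), substr(ref, 1, keep),
           paste(comp[cont], collapse = ""), rand_dna(280))
  }
  for (keep in c(40L, 30L, 26L)) {
    q <- guarded(keep)
    st <- classify_gene_state(locate_gene(q, ref), ref, q)$state
    expect_equal(st, "fragment", info = paste("keep", keep))
  }
  for (keep in c(24L, 15L)) {
    q <- guarded(keep)
    st <- classify_gene_state(locate_gene(q, ref), ref, q)$state
    expect_equal(st, "deleted", info = paste("keep", keep))
  }
})

test_that("degradation round-trip recovers planted states", {
  out <- build_plastome(default_blueprint("desk", seed = 45))
  refs <- reference_genes(out$truth)[ndh_genes()]
  for (s in 1:5) {
    sc <- random_scenario(seed = 500 + s)
    dg <- apply_degradation(out$record, sc, out$truth)
    calls <- classify_genes(dg$record, refs)
    expect_identical(calls$state[match(sc$gene, calls$gene)], sc$state,
                     info = paste("scenario seed", 500 + s))
  }
})

test_that("ndh matrix encoding follows the 22-character scheme", {
  genes <- ndh_genes()
  all_complete <- data.frame(gene = genes, state = "complete")
  m <- encode_ndh_matrix(list(tx = all_complete))
  expect_identical(paste(m["tx", ], collapse = ""),
                   paste0(strrep("1", 11), strrep("2", 11)))

  st <- rep("complete", 11)
  st[1] <- "deleted"; st[2] <- "pseudogene"; st[3] <- "fragment"
  m2 <- encode_ndh_matrix(list(tx = data.frame(gene = genes, state = st)))
  expect_identical(unname(m2["tx", 1]), "0")
  expect_identical(unname(m2["tx", 12]), "-")
  expect_identical(unname(m2["tx", c(2, 13)]), c("1", "0"))
  expect_identical(unname(m2["tx", c(3, 14)]), c("1", "1"))

  # round trip
  dec <- decode_ndh_matrix(m2)
  expect_identical(dec$tx$state, st)

  # consistency invariant holds for random state vectors
  set.seed(46)
  for (r in 1:20) {
    sr <- sample(c("complete", "pseudogene", "fragment", "deleted"), 11, TRUE)
    mr <- encode_ndh_matrix(list(a = data.frame(gene = genes, state = sr)))
    expect_identical(unname(mr[1, 1:11] == "0"), unname(mr[1, 12:22] == "-"))
    expect_identical(decode_ndh_matrix(mr)$a$state, sr)
  }

  expect_error(encode_ndh_matrix(list(tx = all_complete[-1, ])),
               class = "plastodecay_incomplete_input")
})

test_that("ndh matrices write to NEXUS and TSV", {
  genes <- ndh_genes()
  m <- encode_ndh_matrix(list(
    a = data.frame(gene = genes, state = "complete"),
    b = data.frame(gene = genes,
                   state = c("deleted", rep("pseudogene", 10)))))
  nex <- withr::local_tempfile(fileext = ".nex")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_ndh_matrix(m, nexus = nex, tsv = tsv)
  lines <- readLines(nex)
  expect_identical(lines[1], "#NEXUS")
  expect_true(any(grepl("NTAX=2 NCHAR=22", lines)))
  back <- read_char_matrix(nex)
  expect_identical(unname(back$mat), unname(unclass(m)))
  d <- utils::read.table(tsv, sep = "\t", header = TRUE,
                         colClasses = "character")
  expect_equal(nrow(d), 2L)
})
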