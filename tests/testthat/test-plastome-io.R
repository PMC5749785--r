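test_that("GFF3 coordinates convert to the 0-based half-open convention", {
  seq <- rand_dna(1000)
  fa <- withr::local_tempfile(fileext = ".fa")
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(">chr", seq), fa)
  writeLines(c("##gff-version 3",
               "chr\tx\tCDS\t1\t300\t.\t+\t.\tID=g1;Name=geneA"), gff)
  rec <- read_plastome(fa, gff)
  expect_equal(rec$genes$start, 0L)
  expect_equal(rec$genes$end, 300L)

  bad <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr\tx\tCDS\t1\t3000\t.\t+\t.\tID=g1;Name=geneA"), bad)
  expect_error(read_plastome(fa, bad), class = "plastodecay_bounds_error")
})

test_that("write -> read round-trips a plastome record", {
  out <- build_plastome(default_blueprint("desk", seed = 21))
  rec <- out$record
  fa <- withr::local_tempfile(fileext = ".fa")
  gff <- withr::local_tempfile(fileext = ".gff3")
  write_plastome(rec, fa, gff)
  back <- read_plastome(fa, gff)
  expect_identical(back$seq, rec$seq)
  expect_identical(back$regions$start, rec$regions$start)
  expect_identical(back$regions$end, rec$regions$end)
  expect_setequal(back$genes$name, rec$genes$name)
  ord <- order(back$genes$start, back$genes$name)
  ord0 <- order(rec$genes$start, rec$genes$name)
  expect_identical(back$genes$start[ord], rec$genes$start[ord0])
  expect_identical(back$genes$strand[ord], rec$genes$strand[ord0])

  # idempotence: a second round-trip is byte-stable
  fa2 <- withr::local_tempfile(fileext = ".fa")
  gff2 <- withr::local_tempfile(fileext = ".gff3")
  write_plastome(back, fa2, gff2)
  expect_identical(readLines(fa2), readLines(fa))
})

test_that("ambiguity codes other than N are rejected", {
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">chr", "ACGTRYACGT"), fa)
  expect_error(read_plastome(fa), class = "plastodecay_parse_error")
  expect_silent(plastome_record("x", "ACGTNNACGT"))
})

test_that("a minimal GenBank flat file parses", {
  gb <- withr::local_tempfile(fileext = ".gb")
  seq <- paste0("ATG", strrep("AAC", 20), "TAA")   # 66 bp CDS at 11..76
  full <- paste0(rand_dna(10), seq, rand_dna(24))
  # ORIGIN block formatting: 60 bases per line
  chunks <- substring(full, seq(1, nchar(full), 60),
                      pmin(seq(1, nchar(full), 60) + 59, nchar(full)))
  writeLines(c(
    "LOCUS       TESTPLAST 100 bp DNA circular PLN 01-JAN-2018",
    "DEFINITION  synthetic test record.",
    "FEATURES             Location/Qualifiers",
    "     source          1..100",
    "     CDS             11..76",
    "                     /gene=\"ndhZ\"",
    "     tRNA            complement(80..95)",
    "                     /gene=\"trnX\"",
    "ORIGIN",
    paste0("        1 ", tolower(chunks[1])),
    paste0("       61 ", tolower(chunks[2])),
    "//"), gb)
  rec <- read_plastome(gb, format = "genbank")
  expect_equal(rec$length, 100L)
  expect_identical(toupper(rec$seq), toupper(full))
  cds <- rec$genes[rec$genes$name == "ndhZ", ]
  expect_equal(cds$start, 10L)
  expect_equal(cds$end, 76L)
  expect_identical(gene_seq(rec, "ndhZ"), seq)
  expect_equal(rec$genes$strand[rec$genes$name == "trnX"], "-")
})

test_that("coordinate conversions are mutually inverse on random intervals", {
  set.seed(31)
  start1 <- sample.int(5000, 1000, replace = TRUE)
  end1 <- start1 + sample.int(300, 1000, replace = TRUE)
  # internal: (start1 - 1, end1); back: (start0 + 1, end0)
  start0 <- start1 - 1L; end0 <- end1
  expect_identical(start0 + 1L, start1)
  expect_identical(end0, end1)
  expect_identical(end0 - start0, end1 - start1 + 1L)
})

test_that("minus-strand genes come back on the coding strand", {
  out <- build_plastome(default_blueprint("desk", seed = 22))
  rec <- out$record
  minus <- rec$genes[rec$genes$strand == "-" & rec$genes$type == "CDS" &
                       rec$genes$region == "LSC", ][1, ]
  s <- gene_seq(rec, minus$name)
  expect_identical(substr(s, 1, 3), "ATG")
  expect_identical(revcomp_chr(revcomp_chr(s)), s)
})

test_that("detect_quadripartite is rotation-invariant and honest about absence", {
  out <- build_plastome(plastome_blueprint(8000, 2500, 1000, seed = 23))
  seq <- out$record$seq
  q0 <- detect_quadripartite(seq, min_ir = 1000)
  set.seed(24)
  for (off in sample(nchar(seq) - 1, 3)) {
    rot <- paste0(substr(seq, off + 1, nchar(seq)), substr(seq, 1, off))
    q <- detect_quadripartite(rot, min_ir = 1000)
    expect_true(q$found)
    expect_equal(q$regions$end - q$regions$start,
                 q0$regions$end - q0$regions$start)
  }

  set.seed(25)
  rnd <- rand_dna(10000)
  expect_false(detect_quadripartite(rnd, min_ir = 1000)$found)
  expect_error(detect_quadripartite(rnd, min_ir = 5000),
               class = "plastodecay_invalid_argument")
})

test_that("gc_content and codon_usage match their definitions", {
  expect_equal(gc_content("ATGC"), 50.0)
  expect_equal(gc_content("GGCC"), 100.0)
  expect_equal(gc_content("ATGCNNNN"), 50.0)   # N ignored
  expect_error(gc_content(""), class = "plastodecay_invalid_argument")

  cu <- codon_usage("ATGTTGTAA")
  expect_equal(unname(cu$counts[c("ATG", "TTG", "TAA")]), c(1L, 1L, 1L))
  expect_equal(unname(cu$aa["L"]), 1)          # TTG is Leucine in table 11
  expect_equal(sum(cu$freq), 1, tolerance = 1e-12)

  # additivity / concatenation invariance
  one <- codon_usage("ATGTAA")
  two <- codon_usage(c("ATGTAA", "ATGTAA"))
  expect_identical(two$counts, one$counts * 2L)

  # incomplete terminal codon is trimmed and reported
  tr <- codon_usage("ATGTAACC")
  expect_equal(tr$trimmed, 1L)
  expect_equal(tr$n_codons, 2L)
  expect_error(codon_usage(character(0)),
               class = "plastodecay_invalid_argument")
})
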