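#' Blueprint for a synthetic quadripartite plastome
#'
#' A blueprint states the region lengths (LSC, IR, SSC), the gene roster and a
#' plan of repeats to plant. [build_plastome()] turns it into a concrete
#' genome with a truth manifest. The built genome is
#' `LSC | IRa | SSC | IRb` with IRb the exact reverse complement of IRa, total
#' length `LSC + SSC + 2 IR`.
#'
#' @param lsc,ir,ssc Region lengths in bp.
#' @param genes Gene roster `data.frame` with columns `gene`, `type`
#'   (`CDS`/`tRNA`/`rRNA`), `region` (`LSC`/`SSC`/`IR`), `strand` (`+`/`-`),
#'   `codons` (CDS length in codons, incl. start and stop), `len_bp`
#'   (non-CDS length), `intron_len` (0 for none; an intron splits the CDS in
#'   two parts).
#' @param repeats Repeat plan `data.frame` with columns `kind`
#'   (`ssr`/`direct`/`palindromic`), `unit` (SSR motif), `copies` (SSR copy
#'   number), `len` (arm length for long repeats) and `region`.
#' @param seed Integer seed controlling all random background sequence.
#' @return An object of class `plastome_blueprint`.
#' @export
plastome_blueprint <- function(lsc, ir, ssc, genes = default_gene_roster(),
                               repeats = default_repeat_plan(), seed = 1L) {
  .assert(all(c(lsc, ir, ssc) >= 100), "region lengths must be >= 100 bp",
          "plastodecay_invalid_blueprint")
  .assert(all(genes$region %in% c("LSC", "SSC", "IR")),
          "gene region must be LSC, SSC or IR", "plastodecay_invalid_blueprint")
  .assert(!anyDuplicated(genes$gene), "duplicate gene names in roster",
          "plastodecay_invalid_blueprint")
  bp <- structure(list(lsc = as.integer(lsc), ir = as.integer(ir),
                       ssc = as.integer(ssc), genes = genes,
                       repeats = repeats, seed = as.integer(seed)),
                  class = "plastome_blueprint")
  # genes + repeats must fit their region with minimal spacers
  for (rg in c("LSC", "SSC", "IR")) {
    glen <- sum(.element_len(genes[genes$region == rg, , drop = FALSE]))
    rlen <- sum(.repeat_len(repeats[repeats$region == rg, , drop = FALSE]))
    need <- glen + rlen +
      30L * (sum(genes$region == rg) + sum(repeats$region == rg) + 1L)
    cap <- c(LSC = bp$lsc, SSC = bp$ssc, IR = bp$ir)[[rg]]
    .assert(need <= cap,
            sprintf("region %s too small for its roster (%d bp needed, %d available)",
                    rg, need, cap), "plastodecay_invalid_blueprint")
  }
  bp
}

.element_len <- function(genes) {
  if (nrow(genes) == 0L) return(integer(0))
  ifelse(genes$type == "CDS", genes$codons * 3L + genes$intron_len,
         genes$len_bp)
}

.repeat_len <- function(repeats) {
  if (nrow(repeats) == 0L) return(integer(0))
  ifelse(repeats$kind == "ssr", nchar(repeats$unit) * repeats$copies,
         2L * repeats$len + 40L)
}

#' Default desk-scale gene roster
#'
#' Eleven intronless ndh genes (A-K), a handful of photosynthesis/housekeeping
#' genes, one intron-containing gene (atpF), a tRNA, and an rRNA placed in the
#' IR. ndhF sits in the SSC as in real plastomes.
#'
#' @return A roster `data.frame` for [plastome_blueprint()].
#' @export
default_gene_roster <- function() {
  g <- function(gene, type, region, strand, codons = NA_integer_,
                len_bp = NA_integer_, intron_len = 0L)
    data.frame(gene = gene, type = type, region = region, strand = strand,
               codons = codons, len_bp = len_bp, intron_len = intron_len)
  rbind(
    g("psbA", "CDS", "LSC", "+", 110L),
    g("matK", "CDS", "LSC", "-", 100L),
    g("atpF", "CDS", "LSC", "+", 80L, intron_len = 150L),
    g("rbcL", "CDS", "LSC", "+", 110L),
    g("ndhA", "CDS", "LSC", "+", 100L),
    g("ndhB", "CDS", "LSC", "-", 100L),
    g("ndhC", "CDS", "LSC", "+", 80L),
    g("ndhD", "CDS", "LSC", "+", 95L),
    g("ndhE", "CDS", "LSC", "-", 80L),
    g("ndhG", "CDS", "LSC", "+", 85L),
    g("ndhH", "CDS", "LSC", "+", 95L),
    g("ndhI", "CDS", "LSC", "-", 80L),
    g("ndhJ", "CDS", "LSC", "+", 80L),
    g("ndhK", "CDS", "LSC", "+", 85L),
    g("trnH", "tRNA", "LSC", "+", len_bp = 74L),
    g("ndhF", "CDS", "SSC", "-", 90L),
    g("rrn16", "rRNA", "IR", "+", len_bp = 500L)
  )
}

#' Default repeat plan
#' @return A repeat-plan `data.frame` for [plastome_blueprint()].
#' @export
default_repeat_plan <- function() {
  rbind(
    data.frame(kind = "ssr", unit = "A", copies = 12L, len = NA_integer_,
               region = "LSC"),
    data.frame(kind = "ssr", unit = "AT", copies = 7L, len = NA_integer_,
               region = "LSC"),
    data.frame(kind = "direct", unit = NA_character_, copies = NA_integer_,
               len = 40L, region = "LSC"),
    data.frame(kind = "palindromic", unit = NA_character_, copies = NA_integer_,
               len = 35L, region = "SSC")
  )
}

#' Desk-scale (~14 kb) and paper-scale (~140 kb) blueprint presets
#'
#' The desk-scale preset is one tenth of a typical ~140 kb plastome so full
#' pipelines run in seconds; the paper-scale preset matches real genome sizes
#' for stress tests.
#'
#' @param scale `"desk"` or `"paper"`.
#' @param seed Integer seed.
#' @return A [plastome_blueprint()].
#' @export
default_blueprint <- function(scale = c("desk", "paper"), seed = 1L) {
  scale <- match.arg(scale)
  if (scale == "desk") {
    plastome_blueprint(lsc = 8000L, ir = 2500L, ssc = 1000L, seed = seed)
  } else {
    plastome_blueprint(lsc = 80000L, ir = 25000L, ssc = 10000L, seed = seed)
  }
}

.make_orf <- function(codons) {
  body <- setdiff(apply(expand.grid(.DNA, .DNA, .DNA), 1L, paste, collapse = ""),
                  .STOPS)
  paste0("ATG", paste(sample(body, codons - 2L, replace = TRUE), collapse = ""),
         "TAA")
}

#' Build a plastome from a blueprint
#'
#' Lays out each region as alternating random spacers and elements (genes in
#' roster order, then planted repeats), appends `IRb = revcomp(IRa)`, and
#' records every planted feature in a truth manifest. Every CDS has an intact
#' reading frame (ATG start, no internal stop, TAA stop) at its recorded
#' coordinates; genes placed in the IR are annotated in both copies.
#'
#' @param blueprint A [plastome_blueprint()].
#' @param id Genome identifier.
#' @return A list with `record` (a `plastome_record`: `id`, `seq`, `regions`,
#'   `genes`; coordinates 0-based half-open) and `truth` (gene states,
#'   repeat coordinates, blueprint, seed).
#' @export
build_plastome <- function(blueprint, id = "synthetic") {
  .assert(inherits(blueprint, "plastome_blueprint"),
          "blueprint must be a plastome_blueprint",
          "plastodecay_invalid_blueprint")
  bp <- blueprint
  .with_stream(bp$seed, "build_plastome", {
    region_seqs <- list(); ann <- list(); rep_truth <- list()
    gene_seqs <- list()
    for (rg in c("LSC", "IR", "SSC")) {
      cap <- c(LSC = bp$lsc, IR = bp$ir, SSC = bp$ssc)[[rg]]
      gsub_ <- bp$genes[bp$genes$region == rg, , drop = FALSE]
      rsub <- bp$repeats[bp$repeats$region == rg, , drop = FALSE]
      parts <- character(0); pos <- 0L
      n_el <- nrow(gsub_) + nrow(rsub)
      free <- cap - sum(.element_len(gsub_)) - sum(.repeat_len(rsub))
      sp_len <- if (n_el > 0L) {
        w <- stats::runif(n_el + 1L, 0.5, 1.5)
        s <- floor(free * w / sum(w))
        s[1L] <- s[1L] + (free - sum(s)); s
      } else free
      add <- function(s) { parts[[length(parts) + 1L]] <<- s; pos <<- pos + nchar(s) }
      for (i in seq_len(nrow(gsub_))) {
        add(.random_dna(sp_len[i]))
        gi <- gsub_[i, ]
        if (gi$type == "CDS") {
          cds <- .make_orf(gi$codons)
          gene_seqs[[gi$gene]] <- cds
          if (gi$intron_len > 0L) {
            half <- (gi$codons %/% 2L) * 3L
            intr <- .random_dna(gi$intron_len)
            el <- paste0(substr(cds, 1L, half), intr,
                         substr(cds, half + 1L, nchar(cds)))
            if (gi$strand == "-") el <- .revcomp(el)
            s0 <- pos
            if (gi$strand == "+") {
              ann[[length(ann) + 1L]] <- data.frame(
                name = gi$gene, type = c("CDS", "intron", "CDS"),
                strand = gi$strand, region = rg, part = c(1L, NA, 2L),
                start = s0 + c(0L, half, half + gi$intron_len),
                end = s0 + c(half, half + gi$intron_len, nchar(el)))
            } else {
              ann[[length(ann) + 1L]] <- data.frame(
                name = gi$gene, type = c("CDS", "intron", "CDS"),
                strand = gi$strand, region = rg, part = c(2L, NA, 1L),
                start = s0 + c(0L, nchar(cds) - half,
                               nchar(cds) - half + gi$intron_len),
                end = s0 + c(nchar(cds) - half,
                             nchar(cds) - half + gi$intron_len, nchar(el)))
            }
            add(el)
          } else {
            el <- if (gi$strand == "-") .revcomp(cds) else cds
            ann[[length(ann) + 1L]] <- data.frame(
              name = gi$gene, type = "CDS", strand = gi$strand, region = rg,
              part = 1L, start = pos, end = pos + nchar(el))
            add(el)
          }
        } else {
          el <- .random_dna(gi$len_bp)
          gene_seqs[[gi$gene]] <- el
          ann[[length(ann) + 1L]] <- data.frame(
            name = gi$gene, type = gi$type, strand = gi$strand, region = rg,
            part = 1L, start = pos, end = pos + nchar(el))
          if (gi$strand == "-") el <- .revcomp(el)
          add(el)
        }
      }
      for (i in seq_len(nrow(rsub))) {
        add(.random_dna(sp_len[nrow(gsub_) + i]))
        ri <- rsub[i, ]
        if (ri$kind == "ssr") {
          s0 <- pos
          add(strrep(ri$unit, ri$copies))
          rep_truth[[length(rep_truth) + 1L]] <- data.frame(
            kind = "ssr", unit = ri$unit, copies = ri$copies,
            len = nchar(ri$unit) * ri$copies, region = rg,
            start1 = s0, end1 = pos, start2 = NA_integer_, end2 = NA_integer_)
        } else {
          # planted arm avoids internal SSRs so planted-recovery is unambiguous
          arm <- .random_dna(ri$len)
          s1 <- pos; add(arm)
          add(.random_dna(40L))
          s2 <- pos
          add(if (ri$kind == "direct") arm else .revcomp(arm))
          rep_truth[[length(rep_truth) + 1L]] <- data.frame(
            kind = ri$kind, unit = NA_character_, copies = NA_integer_,
            len = ri$len, region = rg,
            start1 = s1, end1 = s1 + ri$len, start2 = s2, end2 = s2 + ri$len)
        }
      }
      add(.random_dna(cap - pos))
      region_seqs[[rg]] <- paste(parts, collapse = "")
    }
    # guard bases: make the IR junctions non-extendable so the planted IR
    # boundaries are unambiguous (an A at both ends of a single-copy region
    # can never pair with its own complement across the junction)
    for (rg in c("LSC", "SSC")) {
      s <- region_seqs[[rg]]
      substr(s, 1L, 1L) <- "A"
      substr(s, nchar(s), nchar(s)) <- "A"
      region_seqs[[rg]] <- s
    }
    ira <- region_seqs$IR
    regions <- data.frame(
      region = c("LSC", "IRa", "SSC", "IRb"),
      start = c(0L, bp$lsc, bp$lsc + bp$ir, bp$lsc + bp$ir + bp$ssc),
      end = c(bp$lsc, bp$lsc + bp$ir, bp$lsc + bp$ir + bp$ssc,
              bp$lsc + 2L * bp$ir + bp$ssc))
    genome <- paste0(region_seqs$LSC, ira, region_seqs$SSC, .revcomp(ira))
    anns <- do.call(rbind, ann)
    offs <- c(LSC = 0L, IR = bp$lsc, SSC = bp$lsc + bp$ir)
    anns$start <- anns$start + offs[anns$region]
    anns$end <- anns$end + offs[anns$region]
    anns$region[anns$region == "IR"] <- "IRa"
    # mirror IRa annotations into IRb
    ira_ann <- anns[anns$region == "IRa", , drop = FALSE]
    if (nrow(ira_ann) > 0L) {
      irb0 <- bp$lsc + bp$ir + bp$ssc
      mirr <- ira_ann
      mirr$region <- "IRb"
      mirr$strand <- ifelse(ira_ann$strand == "+", "-", "+")
      mirr$start <- irb0 + (bp$lsc + bp$ir - ira_ann$end)
      mirr$end <- irb0 + (bp$lsc + bp$ir - ira_ann$start)
      anns <- rbind(anns, mirr)
    }
    anns <- anns[order(anns$start), , drop = FALSE]
    rownames(anns) <- NULL
    rec <- plastome_record(id = id, seq = genome, regions = regions,
                           genes = anns)
    gt <- anns[!(anns$type %in% "intron") & anns$region != "IRb", , drop = FALSE]
    gt <- do.call(rbind, lapply(split(gt, gt$name), function(d) data.frame(
      gene = d$name[1L], state = "complete", lesion = NA_character_,
      start = min(d$start), end = max(d$end), strand = d$strand[1L],
      region = d$region[1L])))
    rownames(gt) <- NULL
    truth <- list(genes = gt[order(gt$start), , drop = FALSE],
                  repeats = if (length(rep_truth)) {
                    rt <- do.call(rbind, rep_truth)
                    roffs <- c(LSC = 0L, IRa = bp$lsc, IR = bp$lsc,
                               SSC = bp$lsc + bp$ir)
                    rt$start1 <- rt$start1 + roffs[rt$region]
                    rt$end1 <- rt$end1 + roffs[rt$region]
                    rt$start2 <- rt$start2 + roffs[rt$region]
                    rt$end2 <- rt$end2 + roffs[rt$region]
                    rt
                  } else NULL,
                  gene_seqs = gene_seqs, blueprint = bp, seed = bp$seed)
    list(record = rec, truth = truth)
  })
}

#' Reference CDS set of a built plastome
#'
#' @param truth The truth manifest from [build_plastome()].
#' @return Named character vector of coding-strand gene sequences.
#' @export
reference_genes <- function(truth) {
  unlist(truth$gene_seqs)
}
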