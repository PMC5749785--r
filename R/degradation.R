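#' Degradation scenario
#'
#' States a target degradation state per gene plus the lesion recipe used to
#' reach it. Recipes: `start_loss` (ATG -> ATA), `premature_stop` (mid-gene
#' codon -> TAA), `frameshift` (1-bp deletion mid-gene), `stop_loss`
#' (TAA -> CAA) for pseudogenes; `truncate` (keep the first `fragment_bp` of
#' the CDS, default 30 bp, strictly above the 25 bp detection floor) for
#' fragments; `excise` (full deletion) for deleted genes.
#'
#' @param gene Character vector of gene names.
#' @param state Target states in `complete`, `pseudogene`, `fragment`,
#'   `deleted`.
#' @param lesion Recipe per gene; `NA` picks the canonical recipe for the
#'   state (`start_loss` for pseudogene, `truncate` for fragment, `excise`
#'   for deleted).
#' @param fragment_bp Remnant length for `truncate` (>= 25).
#' @return A `degradation_scenario` data.frame.
#' @export
degradation_scenario <- function(gene, state,
                                 lesion = NA_character_, fragment_bp = 30L) {
  .assert(all(state %in% c("complete", "pseudogene", "fragment", "deleted")),
          "unknown target state", "plastodecay_invalid_argument")
  .assert(fragment_bp >= 25L, "fragment remnant must keep >= 25 bp",
          "plastodecay_invalid_argument")
  lesion <- rep_len(lesion, length(gene))
  default <- c(complete = NA_character_, pseudogene = "start_loss",
               fragment = "truncate", deleted = "excise")
  lesion <- ifelse(is.na(lesion), default[state], lesion)
  ok <- (state == "complete" & is.na(lesion)) |
    (state == "pseudogene" &
       lesion %in% c("start_loss", "premature_stop", "frameshift", "stop_loss")) |
    (state == "fragment" & lesion == "truncate") |
    (state == "deleted" & lesion == "excise")
  .assert(all(ok), "lesion recipe inconsistent with target state",
          "plastodecay_invalid_argument")
  structure(data.frame(gene = gene, state = state, lesion = lesion,
                       fragment_bp = as.integer(fragment_bp)),
            class = c("degradation_scenario", "data.frame"))
}

#' Draw a random degradation scenario for the ndh genes
#'
#' State frequencies default to roughly the mix seen across terrestrial
#' Lentibulariaceae plastomes: many intact or pseudogenized copies, fewer
#' fragments and deletions.
#'
#' @param genes Gene names (default the 11 ndh genes).
#' @param seed Integer seed.
#' @param probs State probabilities for
#'   (complete, pseudogene, fragment, deleted).
#' @return A [degradation_scenario()].
#' @export
random_scenario <- function(genes = ndh_genes(), seed = 1L,
                            probs = c(0.35, 0.3, 0.2, 0.15)) {
  .with_stream(seed, "random_scenario", {
    st <- sample(c("complete", "pseudogene", "fragment", "deleted"),
                 length(genes), replace = TRUE, prob = probs)
    les <- rep(NA_character_, length(genes))
    ps <- st == "pseudogene"
    les[ps] <- sample(c("start_loss", "premature_stop", "frameshift",
                        "stop_loss"), sum(ps), replace = TRUE)
    degradation_scenario(genes, st, les)
  })
}

#' The eleven plastid ndh genes, in fixed matrix order
#' @return Character vector `ndhA` .. `ndhK`.
#' @export
ndh_genes <- function() paste0("ndh", c(LETTERS[1:11]))

#' Apply a degradation scenario to a plastome
#'
#' Lesions are applied on the coding strand and spliced back; coordinates of
#' all downstream annotations and region boundaries shift consistently after
#' excisions. Genes inside the IR cannot be degraded (that would break the
#' IRb = revcomp(IRa) invariant); single-copy genes only.
#'
#' @param record A `plastome_record`.
#' @param scenario A [degradation_scenario()].
#' @param truth Optional truth manifest to update (from [build_plastome()]).
#' @return List with the degraded `record` and updated `truth` (gene states
#'   and remnant coordinates).
#' @export
apply_degradation <- function(record, scenario, truth = NULL) {
  .assert(inherits(record, "plastome_record"), "record must be a plastome_record",
          "plastodecay_invalid_argument")
  for (i in seq_len(nrow(scenario))) {
    gn <- scenario$gene[i]
    hit <- record$genes[record$genes$name == gn &
                          !(record$genes$type %in% "intron"), , drop = FALSE]
    .assert(nrow(hit) > 0L, sprintf("gene %s not present in plastome", gn),
            "plastodecay_missing_gene")
    .assert(!any(hit$region %in% c("IRa", "IRb")),
            sprintf("gene %s lies in the IR and cannot be degraded", gn),
            "plastodecay_invalid_argument")
    .assert(all(hit$part == 1L),
            sprintf("gene %s has introns; degradation supports intronless CDS", gn),
            "plastodecay_invalid_argument")
  }
  # apply right-to-left so earlier coordinates stay valid
  ord <- order(vapply(scenario$gene, function(gn)
    min(record$genes$start[record$genes$name == gn]), integer(1L)),
    decreasing = TRUE)
  for (i in ord) {
    gn <- scenario$gene[i]; st <- scenario$state[i]; le <- scenario$lesion[i]
    if (st == "complete") next
    row <- which(record$genes$name == gn)
    s <- record$genes$start[row]; e <- record$genes$end[row]
    strand <- record$genes$strand[row]
    cds <- substring(record$seq, s + 1L, e)
    if (strand == "-") cds <- .revcomp(cds)
    L <- nchar(cds)
    new <- switch(le,
      start_loss = paste0("ATA", substr(cds, 4L, L)),
      stop_loss = paste0(substr(cds, 1L, L - 3L), "CAA"),
      premature_stop = {
        mid <- (L %/% 6L) * 3L  # a codon one third of the way in
        paste0(substr(cds, 1L, mid), "TAA", substr(cds, mid + 4L, L))
      },
      frameshift = {
        mid <- L %/% 2L
        paste0(substr(cds, 1L, mid - 1L), substr(cds, mid + 1L, L))
      },
      truncate = substr(cds, 1L, scenario$fragment_bp[i]),
      excise = "")
    if (strand == "-") new <- .revcomp(new)
    record <- .splice(record, s, e, new)
    if (st %in% c("pseudogene", "fragment")) {
      record$genes$type[record$genes$name == gn] <- "pseudogene"
    }
    if (!is.null(truth)) {
      j <- truth$genes$gene == gn
      truth$genes$state[j] <- st
      truth$genes$lesion[j] <- le
      rowg <- which(record$genes$name == gn)
      if (length(rowg) == 1L) {
        truth$genes$start[j] <- record$genes$start[rowg]
        truth$genes$end[j] <- record$genes$end[rowg]
      } else {
        truth$genes$start[j] <- NA_integer_
        truth$genes$end[j] <- NA_integer_
      }
    }
  }
  # shifts move upstream truth coordinates too; refresh from annotations
  if (!is.null(truth)) {
    for (j in seq_len(nrow(truth$genes))) {
      gn <- truth$genes$gene[j]
      d <- record$genes[record$genes$name == gn &
                          !(record$genes$type %in% "intron") &
                          !(record$genes$region %in% "IRb"), , drop = FALSE]
      if (nrow(d) > 0L) {
        truth$genes$start[j] <- min(d$start)
        truth$genes$end[j] <- max(d$end)
      }
    }
  }
  list(record = record, truth = truth)
}

#' Repair reading frames broken by simulated substitutions
#'
#' Neutral simulation can by chance ablate a start/stop codon or create an
#' internal stop; real coding genes are under purifying selection. This pass
#' restores ATG starts, terminal stops and removes in-frame stops for every
#' annotated intact CDS, emulating that selection so planted degradation
#' states stay unambiguous.
#'
#' @param record A `plastome_record` whose CDS annotations are intact genes.
#' @return The repaired record.
#' @export
repair_orfs <- function(record) {
  cds <- record$genes[record$genes$type == "CDS" & record$genes$part == 1L &
                        !(record$genes$region %in% "IRb"), , drop = FALSE]
  for (nm in unique(cds$name)) {
    d <- cds[cds$name == nm, , drop = FALSE]
    if (nrow(d) > 1L) next  # intron-containing genes left as-is
    s <- d$start; e <- d$end; strand <- d$strand
    seqg <- substring(record$seq, s + 1L, e)
    if (strand == "-") seqg <- .revcomp(seqg)
    L <- nchar(seqg)
    if (L %% 3L != 0L) next
    substr(seqg, 1L, 3L) <- "ATG"
    substr(seqg, L - 2L, L) <- "TAA"
    cod <- substring(seqg, seq(1L, L - 3L, 3L), seq(3L, L - 3L, 3L))
    bad <- which(cod %in% .STOPS)
    for (b in bad) substr(seqg, 3L * b - 1L, 3L * b - 1L) <- "C"
    if (strand == "-") seqg <- .revcomp(seqg)
    record$seq <- paste0(substr(record$seq, 1L, s), seqg,
                         substr(record$seq, e + 1L, record$length))
  }
  record
}
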