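#' Write a plastome record as FASTA + GFF3
#'
#' Coordinates are converted from the internal 0-based half-open convention to
#' GFF3's 1-based inclusive one. Region boundaries are emitted as `region`
#' features named LSC/IRa/SSC/IRb so a round-trip restores them.
#'
#' @param record A `plastome_record`.
#' @param fasta,gff3 Output paths.
#' @return Invisibly, the paths written.
#' @export
write_plastome <- function(record, fasta, gff3 = NULL) {
  x <- Biostrings::DNAStringSet(record$seq)
  names(x) <- record$id
  Biostrings::writeXStringSet(x, fasta)
  if (!is.null(gff3)) {
    lines <- "##gff-version 3"
    emit <- function(type, start0, end0, strand, attrs)
      sprintf("%s\tplastodecay\t%s\t%d\t%d\t.\t%s\t.\t%s",
              record$id, type, start0 + 1L, end0, strand, attrs)
    if (!is.null(record$regions)) {
      r <- record$regions
      lines <- c(lines, emit("region", r$start, r$end, "+",
                             sprintf("ID=region-%s;Name=%s", r$region, r$region)))
    }
    if (!is.null(record$genes) && nrow(record$genes) > 0L) {
      g <- record$genes
      type_map <- c(CDS = "CDS", tRNA = "tRNA", rRNA = "rRNA",
                    intron = "intron", pseudogene = "pseudogene",
                    other = "biological_region")
      lines <- c(lines, emit(type_map[g$type], g$start, g$end, g$strand,
                             sprintf("ID=%s-%s-%d;Name=%s;region_tag=%s;part=%s",
                                     g$name, g$region, seq_len(nrow(g)), g$name,
                                     g$region, ifelse(is.na(g$part), ".",
                                                      g$part))))
    }
    writeLines(lines, gff3)
  }
  invisible(c(fasta = fasta, gff3 = gff3))
}

#' Read a plastome from FASTA + GFF3 or a GenBank flat file
#'
#' @param path FASTA path (with `annotations`) or GenBank flat-file path.
#' @param annotations GFF3 path accompanying `path` when
#'   `format = "fasta+gff3"`.
#' @param format `"fasta+gff3"` or `"genbank"`.
#' @return A `plastome_record`; coordinates converted to the internal 0-based
#'   half-open convention, multi-part features preserved as ordered parts.
#' @export
read_plastome <- function(path, annotations = NULL,
                          format = c("fasta+gff3", "genbank")) {
  format <- match.arg(format)
  if (format == "genbank") return(.read_genbank(path))
  x <- Biostrings::readDNAStringSet(path)
  .assert(length(x) >= 1L, "empty FASTA", "plastodecay_parse_error")
  id <- sub("\\s.*$", "", names(x)[1L])
  seq <- as.character(x[[1L]])
  bad <- setdiff(unique(.chars(toupper(seq))), c(.DNA, "N"))
  .assert(length(bad) == 0L,
          sprintf("ambiguity codes other than N are not supported: %s",
                  paste(bad, collapse = ",")), "plastodecay_parse_error")
  regions <- NULL; genes <- NULL
  if (!is.null(annotations)) {
    gr <- rtracklayer::import(annotations, format = "gff3")
    d <- as.data.frame(gr)
    n <- nchar(seq)
    .assert(all(d$end <= n & d$start >= 1L),
            "GFF3 coordinates exceed sequence length", "plastodecay_bounds_error")
    is_region <- as.character(d$type) == "region" &
      d$Name %in% c("LSC", "IRa", "SSC", "IRb")
    if (any(is_region)) {
      r <- d[is_region, ]
      regions <- data.frame(region = as.character(r$Name),
                            start = r$start - 1L, end = r$end)
      regions <- regions[match(c("LSC", "IRa", "SSC", "IRb"), regions$region), ]
      rownames(regions) <- NULL
    }
    gd <- d[!is_region, , drop = FALSE]
    if (nrow(gd) > 0L) {
      type_back <- c(CDS = "CDS", tRNA = "tRNA", rRNA = "rRNA",
                     intron = "intron", pseudogene = "pseudogene",
                     biological_region = "other", gene = "CDS")
      part <- if ("part" %in% names(gd)) suppressWarnings(
        as.integer(as.character(gd$part))) else rep(NA_integer_, nrow(gd))
      region_tag <- if ("region_tag" %in% names(gd))
        as.character(gd$region_tag) else rep(NA_character_, nrow(gd))
      genes <- data.frame(
        name = as.character(gd$Name), type = unname(type_back[as.character(gd$type)]),
        strand = as.character(gd$strand), region = region_tag,
        part = part, start = gd$start - 1L, end = gd$end)
      genes <- genes[order(genes$start), , drop = FALSE]
      rownames(genes) <- NULL
    }
  }
  plastome_record(id = id, seq = seq, regions = regions, genes = genes)
}

# Minimal GenBank flat-file reader: LOCUS id, gene/CDS/tRNA/rRNA features with
# `a..b`, `complement(...)` and `join(...)` locations plus /gene qualifiers,
# and the ORIGIN sequence block. Enough for plastome annotation exchange; not
# a general-purpose parser.
.read_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  .assert(length(lines) > 0L && grepl("^LOCUS", lines[1L]),
          sprintf("%s: not a GenBank flat file (no LOCUS line)", path),
          "plastodecay_parse_error")
  id <- strsplit(trimws(sub("^LOCUS\\s+", "", lines[1L])), "\\s+")[[1L]][1L]
  ori <- grep("^ORIGIN", lines)
  .assert(length(ori) == 1L, "GenBank file has no ORIGIN block",
          "plastodecay_parse_error")
  seq_lines <- lines[(ori + 1L):length(lines)]
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  seq <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  feat_start <- grep("^FEATURES", lines)
  .assert(length(feat_start) == 1L, "GenBank file has no FEATURES block",
          "plastodecay_parse_error")
  block <- lines[(feat_start + 1L):(ori - 1L)]
  feats <- list(); cur <- NULL
  for (ln in block) {
    if (grepl("^ {5}\\S", ln)) {
      if (!is.null(cur)) feats[[length(feats) + 1L]] <- cur
      key <- sub("^ {5}(\\S+).*$", "\\1", ln)
      loc <- trimws(sub("^ {5}\\S+\\s+", "", ln))
      cur <- list(key = key, loc = loc, quals = character(0))
    } else if (!is.null(cur)) {
      txt <- trimws(ln)
      if (startsWith(txt, "/")) cur$quals <- c(cur$quals, txt)
      else if (!grepl("^/", txt) && !grepl("\"", txt) &&
               grepl("^[0-9.,()<>a-z]+$", txt)) cur$loc <- paste0(cur$loc, txt)
    }
  }
  if (!is.null(cur)) feats[[length(feats) + 1L]] <- cur
  rows <- list()
  for (f in feats) {
    if (!(f$key %in% c("CDS", "tRNA", "rRNA", "gene"))) next
    loc <- gsub("[<>]", "", f$loc)
    strand <- "+"
    if (grepl("^complement\\(", loc)) {
      strand <- "-"
      loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
    }
    loc <- sub("^join\\((.*)\\)$", "\\1", loc)
    parts <- strsplit(loc, ",")[[1L]]
    m <- regmatches(parts, regexec("^(\\d+)\\.\\.(\\d+)$", parts))
    .assert(all(lengths(m) == 3L),
            sprintf("unparseable GenBank location: %s", f$loc),
            "plastodecay_parse_error")
    gq <- grep("^/gene=", f$quals, value = TRUE)
    name <- if (length(gq)) gsub("\"", "", sub("^/gene=", "", gq[1L])) else f$key
    for (k in seq_along(m)) {
      rows[[length(rows) + 1L]] <- data.frame(
        name = name, type = if (f$key == "gene") "other" else f$key,
        strand = strand, region = NA_character_,
        part = if (length(m) > 1L) k else 1L,
        start = as.integer(m[[k]][2L]) - 1L, end = as.integer(m[[k]][3L]))
    }
  }
  genes <- if (length(rows)) {
    g <- do.call(rbind, rows)
    g <- g[g$type != "other" | !(g$name %in% g$name[g$type != "other"]), ,
           drop = FALSE]
    g[order(g$start), , drop = FALSE]
  } else NULL
  if (!is.null(genes)) rownames(genes) <- NULL
  plastome_record(id = id, seq = seq, genes = genes)
}

#' Write the truth manifest of a synthetic plastome as TSV
#'
#' Columns `taxon, gene, true_state, lesion, start, end, strand` with 1-based
#' inclusive coordinates to match GFF3. [read_truth_manifest()] restores the
#' internal representation losslessly.
#'
#' @param truth Truth manifest (from [build_plastome()] /
#'   [apply_degradation()]).
#' @param path Output TSV path.
#' @param taxon Taxon label stored in the first column.
#' @return Invisibly, `path`.
#' @export
write_truth_manifest <- function(truth, path, taxon = "synthetic") {
  g <- truth$genes
  out <- data.frame(taxon = taxon, gene = g$gene, true_state = g$state,
                    lesion = ifelse(is.na(g$lesion), ".", g$lesion),
                    start = ifelse(is.na(g$start), NA_integer_, g$start + 1L),
                    end = g$end, strand = g$strand)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a truth manifest TSV
#' @param path TSV written by [write_truth_manifest()].
#' @return `data.frame` with internal 0-based half-open coordinates.
#' @export
read_truth_manifest <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
  d$lesion[d$lesion == "."] <- NA_character_
  d$start <- d$start - 1L
  d
}
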