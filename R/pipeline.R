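#' Build a pipeline run configuration
#'
#' All thresholds default to the values used throughout the package: fragment
#' detection floor 25 bp, pseudogene coverage floor 0.20, long-repeat minimum
#' 30 bp at >= 90% identity with <= 3 mismatches, MISA-style SSR copy minima,
#' IR detection floor 1000 bp.
#'
#' @param mode `"synthetic"` (simulate then analyse) or `"empirical"`
#'   (analyse supplied files).
#' @param n_taxa Number of simulated taxa (synthetic mode).
#' @param seed Integer seed recorded in the manifest and driving every stage.
#' @param scale Blueprint preset, `"desk"` (~14 kb) or `"paper"` (~140 kb).
#' @param rate Substitutions/site per unit branch length for the simulated
#'   alignment.
#' @param scenarios `"random"` or a named list (taxon ->
#'   [degradation_scenario()]).
#' @param outgroup Taxon used to root for ACCTRAN (default: first taxon).
#' @param search_method [search_mp()] method.
#' @param bootstrap Bootstrap pseudoreplicates (0 = skip).
#' @param do_repeats Scan repeats per taxon (slowest stage).
#' @param inputs Empirical mode: `data.frame(taxon, fasta, gff3)`.
#' @param refs Empirical mode: path to a reference CDS FASTA (one record per
#'   gene).
#' @param alignment,partitions Empirical mode: optional alignment FASTA and
#'   partition file for divergence statistics.
#' @param thresholds Named list overriding individual thresholds.
#' @return A `run_config` list.
#' @export
run_config <- function(mode = c("synthetic", "empirical"), n_taxa = 6L,
                       seed = 1L, scale = "desk", rate = 0.02,
                       scenarios = "random", outgroup = NULL,
                       search_method = "branch_and_bound", bootstrap = 0L,
                       do_repeats = TRUE, inputs = NULL, refs = NULL,
                       alignment = NULL, partitions = NULL,
                       thresholds = list()) {
  mode <- match.arg(mode)
  th <- list(fragment_floor = 25L, pseudo_floor = 0.20, complete_floor = 0.95,
             repeat_min_len = 30L, repeat_identity = 0.90, max_mismatch = 3L,
             ssr_thresholds = c(10L, 6L, 5L, 5L, 5L, 5L), min_ir = 1000L)
  th[names(thresholds)] <- thresholds
  .assert(all(vapply(th[c("fragment_floor", "pseudo_floor", "complete_floor",
                          "repeat_min_len", "repeat_identity", "max_mismatch",
                          "min_ir")], function(v) is.numeric(v) && v > 0,
                     logical(1L))),
          "all thresholds must be positive", "plastodecay_invalid_argument")
  structure(list(mode = mode, n_taxa = as.integer(n_taxa),
                 seed = as.integer(seed), scale = scale, rate = rate,
                 scenarios = scenarios, outgroup = outgroup,
                 search_method = search_method,
                 bootstrap = as.integer(bootstrap), do_repeats = do_repeats,
                 inputs = inputs, refs = refs, alignment = alignment,
                 partitions = partitions, thresholds = th),
            class = "run_config")
}

#' Write / read a run configuration as JSON
#' @param config A [run_config()].
#' @param path JSON path.
#' @return `write_run_config` returns `path` invisibly; `read_run_config`
#'   returns the restored `run_config`.
#' @export
write_run_config <- function(config, path) {
  x <- unclass(config)
  x$inputs <- if (is.null(x$inputs)) NULL else as.list(x$inputs)
  jsonlite::write_json(x, path, auto_unbox = TRUE, null = "null", digits = NA)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, x[!vapply(x, is.null, logical(1L))])
}

.stage <- function(quiet, name, expr) {
  t0 <- Sys.time()
  if (!quiet) message(sprintf("[plastodecay] %s ...", name))
  res <- tryCatch(expr, error = function(e) {
    stop(errorCondition(
      sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
      class = c("plastodecay_stage_error", "error", "condition")))
  })
  if (!quiet) message(sprintf("[plastodecay] %s done (%.1f s)", name,
                              as.numeric(Sys.time() - t0, units = "secs")))
  res
}

#' Run the end-to-end pipeline
#'
#' Synthetic mode: simulate a tree and quadripartite plastomes, evolve them
#' under Jukes-Cantor, apply per-taxon degradation scenarios, then classify
#' gene states, encode the 22-character ndh matrix, run the parsimony search
#' with strict consensus and ACCTRAN tracing, compute partition divergence
#' statistics and hotspot ranking, scan repeats, and write a reproducibility
#' manifest. Outputs land under
#' `<outdir>/{genomes,calls,matrix,trees,divergence,repeats,manifest}` as
#' TSV/FASTA/GFF3/Newick/JSON; re-running the same config reproduces
#' byte-identical TSV/JSON outputs.
#'
#' @param config A [run_config()].
#' @param outdir Output directory (created).
#' @param quiet Suppress stage logging.
#' @return Invisibly, a list with the main in-memory results (`tree`,
#'   `truths`, `calls`, `ndh`, `search`, `consensus`, `acctran`, `stats`,
#'   `hotspots`, `repeats`, `manifest`).
#' @export
run_pipeline <- function(config, outdir, quiet = FALSE) {
  .assert(inherits(config, "run_config"), "config must be a run_config",
          "plastodecay_invalid_argument")
  if (config$mode == "empirical") {
    .assert(!is.null(config$inputs) && nrow(config$inputs) > 0L &&
              all(file.exists(config$inputs$fasta)),
            "empirical mode requires existing input files",
            "plastodecay_invalid_argument")
    .assert(!is.null(config$refs) && file.exists(config$refs),
            "empirical mode requires a reference CDS FASTA",
            "plastodecay_invalid_argument")
  }
  dirs <- file.path(outdir, c("genomes", "calls", "matrix", "trees",
                              "divergence", "repeats", "manifest"))
  for (d in dirs) dir.create(d, recursive = TRUE, showWarnings = FALSE)
  th <- config$thresholds
  seed <- config$seed

  if (config$mode == "synthetic") {
    tree <- .stage(quiet, "simulate: tree",
                   generate_tree(config$n_taxa, seed))
    base <- .stage(quiet, "simulate: base plastome",
                   build_plastome(default_blueprint(config$scale, seed)))
    refs <- reference_genes(base$truth)
    aln <- .stage(quiet, "simulate: evolve genomes",
                  evolve_alignment(tree, rate = config$rate, seed = seed,
                                   root_seq = base$record$seq))
    taxa <- tree$tip.label
    sim <- .stage(quiet, "simulate: degrade + write genomes", {
      recs <- list(); truths <- list()
      for (i in seq_along(taxa)) {
        tx <- taxa[i]
        rec <- plastome_record(tx, paste(aln$mat[tx, ], collapse = ""),
                               regions = base$record$regions,
                               genes = base$record$genes)
        rec <- repair_orfs(rec)
        scen <- if (identical(config$scenarios, "random")) {
          random_scenario(seed = seed * 1000L + i)
        } else config$scenarios[[tx]]
        truth <- base$truth
        dg <- apply_degradation(rec, scen, truth)
        recs[[tx]] <- dg$record
        truths[[tx]] <- dg$truth
        write_plastome(dg$record, file.path(dirs[1L], paste0(tx, ".fasta")),
                       file.path(dirs[1L], paste0(tx, ".gff3")))
        write_truth_manifest(dg$truth, file.path(dirs[1L],
                                                 paste0(tx, ".truth.tsv")),
                             taxon = tx)
      }
      list(recs = recs, truths = truths)
    })
    recs <- sim$recs; truths <- sim$truths
    ape::write.tree(tree, file.path(dirs[4L], "true_tree.nwk"))
  } else {
    tree <- NULL; truths <- NULL
    refs_set <- Biostrings::readDNAStringSet(config$refs)
    refs <- stats::setNames(as.character(refs_set),
                            sub("\\s.*$", "", names(refs_set)))
    recs <- list()
    for (i in seq_len(nrow(config$inputs))) {
      tx <- config$inputs$taxon[i]
      gff <- if ("gff3" %in% names(config$inputs)) config$inputs$gff3[i]
      else NULL
      recs[[tx]] <- read_plastome(config$inputs$fasta[i], gff)
    }
    taxa <- names(recs)
  }

  ndh_refs <- refs[intersect(ndh_genes(), names(refs))]
  calls <- .stage(quiet, "classify gene states", {
    out <- list()
    for (tx in taxa) {
      cl <- classify_genes(recs[[tx]], ndh_refs,
                           pseudo_floor = th$pseudo_floor,
                           complete_floor = th$complete_floor)
      utils::write.table(cbind(taxon = tx, cl),
                         file.path(dirs[2L], paste0(tx, ".calls.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      out[[tx]] <- cl
    }
    out
  })

  ndh <- .stage(quiet, "encode ndh matrix", {
    m <- encode_ndh_matrix(calls)
    write_ndh_matrix(m, nexus = file.path(dirs[3L], "ndh_matrix.nex"),
                     tsv = file.path(dirs[3L], "ndh_matrix.tsv"))
    m
  })

  outgroup <- if (is.null(config$outgroup)) taxa[1L] else config$outgroup
  cm <- char_matrix(ndh)
  search <- NULL; cons <- NULL; acct <- NULL; boot <- NULL
  if (length(taxa) >= 4L) {
    search <- .stage(quiet, "parsimony search",
                     search_mp(cm, method = config$search_method, seed = seed))
    cons <- strict_consensus(search$trees)
    acct <- .stage(quiet, "ACCTRAN tracing",
                   acctran_map(search$trees[[1L]], cm, outgroup = outgroup))
    if (config$bootstrap > 0L) {
      boot <- .stage(quiet, "bootstrap",
                     bootstrap_support(cm, n_reps = config$bootstrap,
                                       method = config$search_method,
                                       seed = seed))
      utils::write.table(boot, file.path(dirs[4L], "bootstrap.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    .stage(quiet, "write trees", {
      ape::write.tree(search$trees, file.path(dirs[4L], "mp_trees.nwk"))
      ape::write.tree(cons, file.path(dirs[4L], "strict_consensus.nwk"))
      utils::write.table(acct, file.path(dirs[4L], "acctran_changes.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      jsonlite::write_json(
        list(length = search$length, n_mp_trees = length(search$trees),
             ci = search$ci, ri = search$ri, method = search$method),
        file.path(dirs[4L], "search_summary.json"), auto_unbox = TRUE,
        digits = NA)
    })
  } else if (!quiet) {
    message("[plastodecay] fewer than 4 taxa: parsimony stages skipped")
  }

  stats <- NULL; hotspots <- NULL
  aln_obj <- if (config$mode == "synthetic") {
    aln$partitions <- .blueprint_partitions(base$record)
    aln
  } else if (!is.null(config$alignment)) {
    read_alignment(config$alignment, config$partitions)
  } else NULL
  if (!is.null(aln_obj)) {
    stats <- .stage(quiet, "divergence statistics", partition_stats(aln_obj))
    hotspots <- rank_hotspots(stats, 10L)
    utils::write.table(stats, file.path(dirs[5L], "partition_stats.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(hotspots, file.path(dirs[5L], "hotspots.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  repeats <- NULL
  if (isTRUE(config$do_repeats)) {
    repeats <- .stage(quiet, "repeat scan", {
      out <- list()
      for (tx in taxa) {
        ss <- find_ssrs(recs[[tx]], thresholds = th$ssr_thresholds)
        lr <- find_long_repeats(recs[[tx]], min_len = th$repeat_min_len,
                                max_mismatch = th$max_mismatch,
                                min_identity = th$repeat_identity,
                                ir_flag_len = th$min_ir)
        ss <- annotate_repeat_context(ss, recs[[tx]])
        lr <- annotate_repeat_context(lr, recs[[tx]])
        utils::write.table(ss, file.path(dirs[6L], paste0(tx, ".ssrs.tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        utils::write.table(lr, file.path(dirs[6L], paste0(tx, ".long.tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        out[[tx]] <- list(ssrs = ss, long = lr)
      }
      summ <- do.call(rbind, lapply(taxa, function(tx) {
        lr <- out[[tx]]$long
        lr <- lr[!lr$is_ir_pair, , drop = FALSE]
        data.frame(taxon = tx, tandem = nrow(out[[tx]]$ssrs),
                   direct = sum(lr$kind == "direct"),
                   palindromic = sum(lr$kind == "palindromic"))
      }))
      utils::write.table(summ, file.path(dirs[6L], "summary.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      if (length(taxa) >= 2L) {
        sh <- shared_repeats(lapply(out, `[[`, "ssrs"))
        utils::write.table(sh, file.path(dirs[6L], "shared.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      }
      out
    })
  }

  manifest <- .stage(quiet, "manifest", {
    files <- sort(list.files(outdir, recursive = TRUE, full.names = TRUE))
    files <- files[!grepl("manifest", files)]
    mf <- list(
      package = "plastodecay",
      version = as.character(utils::packageVersion("plastodecay")),
      mode = config$mode, seed = seed, n_taxa = config$n_taxa,
      scale = config$scale, rate = config$rate,
      search_method = config$search_method, outgroup = outgroup,
      thresholds = th,
      checksums = as.list(stats::setNames(unname(tools::md5sum(files)),
                                          sub(paste0("^", outdir, "/?"), "",
                                              files))))
    jsonlite::write_json(mf, file.path(dirs[7L], "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    mf
  })

  invisible(list(tree = tree, truths = truths, calls = calls, ndh = ndh,
                 search = search, consensus = cons, acctran = acct,
                 bootstrap = boot, stats = stats, hotspots = hotspots,
                 repeats = repeats, manifest = manifest))
}

# Column partitions of the base genome: regions, each gene, the ndh set, and
# intergenic positions (1-based columns of the unaligned simulated matrix).
.blueprint_partitions <- function(record) {
  p <- list()
  for (i in seq_len(nrow(record$regions))) {
    r <- record$regions[i, ]
    p[[r$region]] <- seq.int(r$start + 1L, r$end)
  }
  g <- record$genes
  covered <- integer(0)
  for (nm in unique(g$name)) {
    d <- g[g$name == nm & !(g$type %in% "intron") & g$region != "IRb", ,
           drop = FALSE]
    if (nrow(d) == 0L) next
    idx <- unlist(lapply(seq_len(nrow(d)), function(i)
      seq.int(d$start[i] + 1L, d$end[i])))
    p[[nm]] <- idx
  }
  all_gene <- unlist(lapply(seq_len(nrow(g)), function(i)
    seq.int(g$start[i] + 1L, g$end[i])))
  p[["genes"]] <- sort(unique(all_gene))
  p[["intergenic"]] <- setdiff(seq_len(record$length), p[["genes"]])
  nd <- intersect(names(p), ndh_genes())
  if (length(nd)) p[["ndh"]] <- sort(unique(unlist(p[nd])))
  p
}
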