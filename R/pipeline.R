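## End-to-end orchestration: simulate -> bubbles -> allele matrix ->
## phylogeny / consensus / enrichment / consequence / QC, with one global
## seed fanned out deterministically to every stage and a JSON report.

#' Default pipeline configuration
#'
#' A compact run: the default [sim_config()] study (5 assemblies, 2
#' chromosomes of 5 Mb, ~300 SVs), 5 consensus replicates at 10% noise and
#' 200 permutation replicates for the depletion test.
#'
#' @param seed global seed; every stage seed derives from it
#' @param ... overrides for any configuration entry (`sim` entries may be
#'   given as a named list under `sim`)
#' @return list of class `run_config`
#' @export
run_config <- function(seed = 1, ...) {
  cfg <- list(
    seed = seed,
    sim = list(),
    n_replicates = 5L,
    noise = 0.1,
    n_perms = 200L,
    pairing = "bubble",
    breakpoint_tolerance = 100,
    length_ratio_min = 0.9,
    outgroups = c("G", "N"),
    ingroup = c("O", "P", "B")
  )
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad)) {
    stop("invalid config key(s): ", paste(bad, collapse = ", "),
         "; valid keys: ", paste(names(cfg), collapse = ", "))
  }
  cfg[names(dots)] <- dots
  structure(cfg, class = "run_config")
}

#' Read a pipeline configuration from YAML
#' @param path YAML file; keys as in [run_config()]
#' @return a `run_config`
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  y <- yaml::read_yaml(path)
  do.call(run_config, y)
}

#' Run the full analysis pipeline on a simulated pangenome
#'
#' Simulates a planted-truth pangenome, writes its tracks, re-reads the
#' graph and walks from disk, and runs every analysis stage: bubble
#' detection and summary, allele matrix with completeness filtering,
#' discordance + UPGMA dendrogram + topology classification, UpSet
#' intersection sets, SV calling with carriers, consensus scoring of noisy
#' replicates against the truth catalogue, CDS-overlap depletion testing,
#' and per-assembly QC summaries. Writes a JSON report, the dendrogram
#' Newick and intermediate TSVs into `outdir`.
#'
#' @param config a [run_config()], a YAML path, or NULL for defaults
#' @param outdir output directory (default a fresh temporary directory)
#' @return the report, invisibly (list, also serialised to
#'   `<outdir>/report.json`)
#' @export
run_pipeline <- function(config = NULL, outdir = tempfile("pansv_run_")) {
  if (is.null(config)) config <- run_config()
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(outdir, "run.log")
  logf <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    cat(msg, "\n", sep = "", file = log_path, append = TRUE)
    message(msg)
  }
  logf("pansv %s | global seed %s",
       as.character(utils::packageVersion("pansv")), config$seed)

  sim_args <- config$sim
  sim_args$seed <- derive_seed(config$seed, 1L)
  scfg <- do.call(sim_config, sim_args)
  simdir <- file.path(outdir, "simulated")
  truth <- simulate_pangenome(scfg, outdir = simdir)
  logf("simulated %d SVs on %d chromosomes", nrow(truth$sv), scfg$n_chroms)

  graph <- read_rgfa(file.path(simdir, "graph.gfa"))
  walks <- lapply(scfg$leaves, function(leaf) {
    read_walks(file.path(simdir, "walks", paste0(leaf, ".bed")),
               assembly = leaf)
  })
  names(walks) <- scfg$leaves

  bubbles <- detect_superbubbles(graph)
  bsum <- summarize_bubbles(bubbles, graph)
  logf("detected %d bubbles (%d large)", bsum$n_bubbles, bsum$n_large)

  mat <- build_allele_matrix(bubbles, walks)
  fc <- filter_complete(mat)
  write_allele_matrix(fc$matrix, file.path(outdir, "matrix.tsv"))

  disc <- pairwise_discordance(fc$matrix)
  tree <- upgma(disc)
  newick <- dendrogram_newick(tree)
  writeLines(newick, file.path(outdir, "dendrogram.nwk"))
  topo <- classify_topology(tree, outgroups = config$outgroups,
                            ingroup = config$ingroup)
  planted_topo <- classify_topology(
    upgma(ape::cophenetic.phylo(truth$tree)[scfg$leaves, scfg$leaves]),
    outgroups = config$outgroups, ingroup = config$ingroup)
  logf("dendrogram topology %s (planted %s)", topo, planted_topo)

  upset <- intersection_sets(fc$matrix)
  utils::write.table(upset, file.path(outdir, "upset.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  svs <- call_svs(bubbles, fc$matrix)
  utils::write.table(svs, file.path(outdir, "svs.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  mc <- match_config(config$breakpoint_tolerance, config$length_ratio_min)
  reps <- emit_replicates(truth, config$n_replicates, config$noise,
                          seed = derive_seed(config$seed, 2L))
  truth_cat <- truth$sv[radix_order(truth$sv$chrom, truth$sv$start), ]
  agreements <- lapply(reps, function(r) score_agreement(r, truth_cat, mc))
  f1s <- vapply(agreements, `[[`, numeric(1), "f1")
  logf("consensus vs truth at noise %.2f: mean F1 %.1f", config$noise,
       mean(f1s))

  enr <- cds_overlap_test(bubbles, truth$gene_track, truth$chrom_sizes,
                          n_replicates = config$n_perms,
                          seed = derive_seed(config$seed, 3L),
                          pairing = config$pairing)
  logf("CDS depletion: %d bubble-gene overlaps, one-sided p %.3g",
       enr$observed$total, enr$test$p_one_sided)

  coding <- coding_consequences_table(svs, truth$gene_track)
  utils::write.table(coding, file.path(outdir, "consequences.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  qc <- lapply(scfg$leaves, function(leaf) {
    qc_summary(truth$contigs[[leaf]], truth$phase_blocks[[leaf]],
               truth$error_bases[[leaf]], truth$total_bases,
               truth$repeat_tracks[[leaf]], truth$gap_tracks[[leaf]],
               truth$depth_tracks[[leaf]], truth$chrom_sizes)
  })
  names(qc) <- scfg$leaves

  report <- list(
    seed = config$seed,
    n_planted_svs = nrow(truth$sv),
    bubble_summary = unclass(bsum),
    n_sites_removed = fc$n_removed,
    dendrogram = newick,
    topology = topo,
    planted_topology = planted_topo,
    upset = upset,
    consensus = list(noise = config$noise,
                     n_replicates = config$n_replicates,
                     mean_f1 = mean(f1s),
                     mean_precision = mean(vapply(agreements, `[[`,
                                                  numeric(1), "precision")),
                     mean_recall = mean(vapply(agreements, `[[`,
                                               numeric(1), "recall"))),
    depletion = list(observed_total = enr$observed$total,
                     n_genes_hit = length(enr$observed$genes_hit),
                     W = enr$test$W,
                     p_one_sided = enr$test$p_one_sided,
                     p_empirical = enr$test$p_empirical,
                     pairing = enr$test$pairing,
                     n_perms = config$n_perms),
    qc = lapply(qc, function(x) {
      unclass(x)[c("ng50", "pg50", "qv", "n_contigs", "n_end_to_end",
                   "n_gaps", "n_dropout_regions")]
    })
  )
  jsonlite::write_json(report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  logf("report written to %s", file.path(outdir, "report.json"))
  invisible(report)
}

#' Coding consequences for a table of SVs against a gene track
#'
#' Runs [coding_consequence()] for every SV/gene pair whose intervals
#' overlap (genes taken from `CDS`-classed rows grouped by name).
#'
#' @param svs data.frame of SV records
#' @param features feature track with CDS rows
#' @return data.frame with one row per overlapping SV/gene pair: SV
#'   coordinates, gene id, consequence kind and amino-acid change
#' @export
coding_consequences_table <- function(svs, features) {
  cds <- features[features$class == "CDS", , drop = FALSE]
  out <- list()
  for (gid in unique(cds$name)) {
    gc <- cds[cds$name == gid, , drop = FALSE]
    gm <- suppressWarnings(
      gene_model(gid, gc$chrom[1L], "+", gc[, c("start", "end")]))
    hit <- which(svs$chrom == gm$chrom & svs$start < gm$span[2] &
                   svs$end > gm$span[1])
    for (i in hit) {
      cq <- coding_consequence(svs[i, ], gm)
      out[[length(out) + 1L]] <- data.frame(
        chrom = svs$chrom[i], start = svs$start[i], end = svs$end[i],
        svtype = svs$svtype[i], gene = gid, kind = cq$kind,
        aa_change = cq$aa_change)
    }
  }
  if (!length(out)) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), svtype = character(),
                      gene = character(), kind = character(),
                      aa_change = integer()))
  }
  do.call(rbind, out)
}
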