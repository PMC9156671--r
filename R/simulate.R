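## Planted-truth pangenome simulator. Emulates iterative assembly-to-graph
## construction: a linear rank-0 backbone per chromosome is split at the
## breakpoints of SVs planted on the branches of a known tree, and alternate
## allele nodes are attached. Every downstream module can be validated
## against the planted catalogue, carrier sets and tree.

#' Simulation configuration
#'
#' Defaults describe a compact five-assembly study: two 5 Mb chromosomes, an
#' outgroup-heavy ultrametric tree (gaur-like `G` far out, indicine-like `N`
#' next, three close taurine-like leaves `O`, `P`, `B`), and an SV rate
#' giving roughly 300 planted SVs (insertions, deletions and VNTR
#' expansions, minimum 50 bp — the divergence threshold below which
#' sequences do not form new graph nodes).
#'
#' @param n_chroms number of chromosomes
#' @param chrom_length chromosome length in bp
#' @param leaves assembly labels (tip labels of `tree`)
#' @param tree rooted Newick string with branch lengths (divergence units)
#' @param sv_rate SV events per bp per unit branch length
#' @param sv_len_min minimum SV length in bp (>= 50)
#' @param sv_len_mean mean SV length in bp (geometric law shifted to the
#'   minimum; matches the heavy right tail of pangenome bubbles)
#' @param vntr_fraction probability an event is a tandem-motif expansion
#' @param n_genes genes placed independently of SVs
#' @param cds_per_gene CDS intervals per gene (150 bp each, so the total CDS
#'   length is always a multiple of 3)
#' @param p_satellite probability a chromosome's proximal satellite block
#'   meets the 50 kb end-to-end threshold
#' @param p_telomere probability the distal telomere block meets 500 bp
#' @param depth_mean mean fold-coverage of the depth tracks
#' @param depth_window depth window size in bp
#' @param n_cnv planted copy-number-variable regions (depth signal)
#' @param cnv_max_copies maximum additional copies per CNV
#' @param gap_rate mean assembly gaps per chromosome
#' @param seed integer seed
#' @return list of class `sim_config`
#' @export
sim_config <- function(n_chroms = 2L,
                       chrom_length = 5e6,
                       leaves = c("O", "B", "P", "N", "G"),
                       tree = "((((P:0.1,B:0.1):0.15,O:0.25):0.35,N:0.6):0.4,G:1.0);",
                       sv_rate = 1e-5,
                       sv_len_min = 50L,
                       sv_len_mean = 500,
                       vntr_fraction = 0.3,
                       n_genes = 60L,
                       cds_per_gene = 4L,
                       p_satellite = 0.75,
                       p_telomere = 0.6,
                       depth_mean = 20,
                       depth_window = 1e4,
                       n_cnv = 2L,
                       cnv_max_copies = 4L,
                       gap_rate = 1.5,
                       seed = 1L) {
  stopifnot(n_chroms >= 1, chrom_length > 1e4, sv_rate >= 0,
            sv_len_min >= 50, sv_len_mean > sv_len_min,
            vntr_fraction >= 0, vntr_fraction <= 1,
            n_genes >= 0, cds_per_gene >= 1,
            p_satellite >= 0, p_satellite <= 1,
            p_telomere >= 0, p_telomere <= 1,
            depth_mean > 0, depth_window >= 1000, n_cnv >= 0,
            cnv_max_copies >= 1, gap_rate >= 0,
            length(leaves) >= 2, !anyDuplicated(leaves))
  phy <- ape::read.tree(text = tree)
  if (is.null(phy) || !setequal(phy$tip.label, leaves)) {
    stop("tree tip labels must equal the leaf labels")
  }
  if (is.null(phy$edge.length)) stop("tree must carry branch lengths")
  structure(list(n_chroms = as.integer(n_chroms),
                 chrom_length = chrom_length, leaves = leaves, tree = tree,
                 sv_rate = sv_rate, sv_len_min = as.integer(sv_len_min),
                 sv_len_mean = sv_len_mean, vntr_fraction = vntr_fraction,
                 n_genes = as.integer(n_genes),
                 cds_per_gene = as.integer(cds_per_gene),
                 p_satellite = p_satellite, p_telomere = p_telomere,
                 depth_mean = depth_mean, depth_window = depth_window,
                 n_cnv = as.integer(n_cnv),
                 cnv_max_copies = as.integer(cnv_max_copies),
                 gap_rate = gap_rate, seed = as.integer(seed)),
            class = "sim_config")
}

## Tip labels below the child node of every edge of a rooted phylo tree.
edge_clades <- function(phy) {
  ntip <- length(phy$tip.label)
  lapply(seq_len(nrow(phy$edge)), function(i) {
    node <- phy$edge[i, 2L]
    if (node <= ntip) return(phy$tip.label[node])
    desc <- node
    tips <- character()
    while (length(desc)) {
      kids <- phy$edge[phy$edge[, 1L] %in% desc, 2L]
      tips <- c(tips, phy$tip.label[kids[kids <= ntip]])
      desc <- kids[kids > ntip]
    }
    sort(tips)
  })
}

## Sample non-overlapping (start, len) placements on chromosomes, keeping a
## `gap` bp margin between intervals and from the ends.
place_intervals <- function(lens, chroms, chrom_sizes, gap = 50,
                            margin = 200, max_tries = 200L) {
  placed <- lapply(names(chrom_sizes), function(x) {
    base::matrix(numeric(0), ncol = 2)
  })
  names(placed) <- names(chrom_sizes)
  start <- integer(length(lens))
  for (k in order(-lens)) {   # place the big ones first
    chrom <- chroms[k]
    C <- chrom_sizes[[chrom]]
    lo <- margin
    hi <- C - margin - lens[k]
    if (hi <= lo) stop("SV placement failure: interval longer than chromosome; lower sv_rate or sv_len_mean")
    ok <- FALSE
    occ <- placed[[chrom]]
    for (try in seq_len(max_tries)) {
      s <- floor(stats::runif(1, lo, hi))
      if (nrow(occ) == 0L ||
          all(s + lens[k] + gap <= occ[, 1L] | s >= occ[, 2L] + gap)) {
        ok <- TRUE
        break
      }
    }
    if (!ok) stop("SV placement failure after bounded retries (overcrowded chromosome); lower sv_rate")
    placed[[chrom]] <- rbind(occ, c(s, s + lens[k]))
    start[k] <- as.integer(s)
  }
  start
}

## Draw the planted SV catalogue on the tree (no placement yet).
draw_sv_events <- function(config, phy) {
  clades <- edge_clades(phy)
  genome <- config$n_chroms * config$chrom_length
  geo_p <- 1 / (config$sv_len_mean - config$sv_len_min + 1)
  motifs3 <- seq(6L, 90L, by = 3L)
  motifs_n3 <- setdiff(6:90, motifs3)
  counts <- stats::rpois(nrow(phy$edge),
                         config$sv_rate * phy$edge.length * genome)
  n <- sum(counts)
  if (n == 0L) {
    return(data.frame(branch = integer(), ref_len = integer(),
                      alt_len = integer(), sv_class = character(),
                      motif_len = integer(), extra_copies = integer(),
                      carriers = character()))
  }
  branch <- rep(seq_len(nrow(phy$edge)), counts)
  L <- config$sv_len_min + stats::rgeom(n, geo_p)
  cls <- ifelse(stats::runif(n) < config$vntr_fraction, "VNTR",
                ifelse(stats::runif(n) < 0.5, "DEL", "INS"))
  motif <- ifelse(stats::runif(n) < 0.5,
                  sample(motifs3, n, replace = TRUE),
                  sample(motifs_n3, n, replace = TRUE))
  motif[cls != "VNTR"] <- NA_integer_
  copies <- pmax(ceiling(config$sv_len_min / motif), round(L / motif))
  anchor <- sample(1:49, n, replace = TRUE)
  ref_len <- ifelse(cls == "DEL", L,
                    ifelse(cls == "INS", anchor, motif))
  alt_len <- ifelse(cls == "DEL", 0L,
                    ifelse(cls == "INS", anchor + L, motif * (copies + 1L)))
  data.frame(branch = branch, ref_len = as.integer(ref_len),
             alt_len = as.integer(alt_len), sv_class = cls,
             motif_len = as.integer(motif), extra_copies = as.integer(copies),
             carriers = vapply(clades[branch], paste, "", collapse = ","))
}

sv_type_rule <- function(ref_len, alt_len, min_len = 50) {
  ifelse(ref_len < min_len & alt_len >= min_len, "INS",
         ifelse(alt_len < min_len & ref_len >= min_len, "DEL", "COMPLEX"))
}

## Build the planted graph and per-leaf walks for one SV catalogue.
## sv must have chrom, start, end, ref_len, alt_len, carriers; intervals
## non-overlapping per chromosome and clear of chromosome ends.
build_planted_graph <- function(sv, chrom_sizes, leaves) {
  sv <- sv[radix_order(sv$chrom, sv$start), , drop = FALSE]
  rownames(sv) <- NULL
  sv$source <- rep(NA_character_, nrow(sv))
  sv$sink <- rep(NA_character_, nrow(sv))
  sv$ref_path <- rep(NA_character_, nrow(sv))
  sv$alt_path <- rep(NA_character_, nrow(sv))
  counter <- 0L
  seg_parts <- list()
  link_parts <- list()
  for (chrom in names(chrom_sizes)) {
    C <- chrom_sizes[[chrom]]
    rows <- which(sv$chrom == chrom)
    bp <- sort(unique(c(0, C, sv$start[rows], sv$end[rows])))
    nseg <- length(bp) - 1L
    ids <- sprintf("s%05d", counter + seq_len(nseg))
    counter <- counter + nseg
    seg_parts[[length(seg_parts) + 1L]] <- data.frame(
      id = ids, length = as.integer(diff(bp)), sequence = NA_character_,
      sn = chrom, so = as.integer(bp[-length(bp)]), sr = 0L)
    if (nseg > 1L) {
      link_parts[[length(link_parts) + 1L]] <- data.frame(
        from = ids[-nseg], from_orient = "+", to = ids[-1L], to_orient = "+")
    }
    if (!length(rows)) next
    i_mid <- match(sv$start[rows], bp)
    i_snk <- match(sv$end[rows], bp)
    if (any(i_mid == 1L)) stop("SV at chromosome start cannot be anchored")
    src <- ids[i_mid - 1L]
    mid <- ids[i_mid]
    snk <- ids[i_snk]
    has_alt <- sv$alt_len[rows] > 0L
    alt <- rep(NA_character_, length(rows))
    if (any(has_alt)) {
      alt[has_alt] <- sprintf("s%05d", counter + seq_len(sum(has_alt)))
      counter <- counter + sum(has_alt)
      first_carrier <- sub(",.*$", "", sv$carriers[rows][has_alt])
      seg_parts[[length(seg_parts) + 1L]] <- data.frame(
        id = alt[has_alt], length = as.integer(sv$alt_len[rows][has_alt]),
        sequence = NA_character_, sn = first_carrier, so = 0L, sr = 1L)
      link_parts[[length(link_parts) + 1L]] <- data.frame(
        from = c(src[has_alt], alt[has_alt]), from_orient = "+",
        to = c(alt[has_alt], snk[has_alt]), to_orient = "+")
    }
    if (any(!has_alt)) {
      link_parts[[length(link_parts) + 1L]] <- data.frame(
        from = src[!has_alt], from_orient = "+", to = snk[!has_alt],
        to_orient = "+")
    }
    sv$source[rows] <- src
    sv$sink[rows] <- snk
    sv$ref_path[rows] <- sprintf(">%s>%s>%s", src, mid, snk)
    sv$alt_path[rows] <- ifelse(has_alt, sprintf(">%s>%s>%s", src, alt, snk),
                                sprintf(">%s>%s", src, snk))
  }
  graph <- pangenome_graph(do.call(rbind, seg_parts),
                           if (length(link_parts)) do.call(rbind, link_parts)
                           else data.frame(from = character(),
                                           from_orient = character(),
                                           to = character(),
                                           to_orient = character()))
  carr <- strsplit(sv$carriers, ",", fixed = TRUE)
  walks <- lapply(leaves, function(leaf) {
    is_carrier <- vapply(carr, function(cs) leaf %in% cs, TRUE)
    data.frame(assembly = rep(leaf, nrow(sv)), chrom = sv$chrom,
               start = as.integer(sv$start), end = as.integer(sv$end),
               source = sv$source, sink = sv$sink,
               path = as.character(ifelse(is_carrier, sv$alt_path,
                                          sv$ref_path)))
  })
  names(walks) <- leaves
  list(graph = graph, walks = walks, sv = sv)
}

#' Simulate a planted-truth pangenome
#'
#' Draws SV events along the branches of the configured tree (Poisson per
#' branch at `sv_rate` events per bp per unit branch length), places them
#' without overlap on the backbone chromosomes, and builds the corresponding
#' pangenome graph, per-assembly haplotype walks, gene and repeat annotation,
#' windowed depth tracks with planted CNV signal, and assembly length
#' tables. The carrier set of every SV is exactly the clade below its
#' branch. Fully deterministic given the config seed.
#'
#' @param config a [sim_config()]
#' @param outdir optional directory; when given, all tracks are written with
#'   [write_pangenome()]
#' @return object of class `synthetic_truth` with elements `config`, `tree`
#'   (ape phylo), `chrom_sizes`, `sv` (planted catalogue with carriers),
#'   `graph`, `walks`, `gene_track`, `repeat_tracks`, `gap_tracks`,
#'   `depth_tracks`, `cnv`, `contigs`, `phase_blocks`, `error_bases`,
#'   `total_bases`
#' @export
simulate_pangenome <- function(config, outdir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  phy <- ape::read.tree(text = config$tree)
  chrom_sizes <- stats::setNames(rep(config$chrom_length, config$n_chroms),
                                 sprintf("chr%d", seq_len(config$n_chroms)))
  truth <- with_seed(config$seed, {
    sv <- draw_sv_events(config, phy)
    if (nrow(sv)) {
      sv$chrom <- sample(names(chrom_sizes), nrow(sv), replace = TRUE)
      sv$start <- place_intervals(sv$ref_len, sv$chrom, chrom_sizes)
      sv$end <- sv$start + sv$ref_len
      sv$svtype <- sv_type_rule(sv$ref_len, sv$alt_len)
      sv <- sv[radix_order(sv$chrom, sv$start), , drop = FALSE]
      sv$id <- sprintf("sv%04d", seq_len(nrow(sv)))
      rownames(sv) <- NULL
    } else {
      sv$chrom <- character(); sv$start <- integer(); sv$end <- integer()
      sv$svtype <- character(); sv$id <- character()
    }
    built <- build_planted_graph(sv, chrom_sizes, config$leaves)

    ## genes: fixed-size CDS blocks so total CDS is always in frame
    gene_rows <- list()
    if (config$n_genes > 0L) {
      cds_len <- 150L
      intron <- 350L
      span <- config$cds_per_gene * cds_len +
        (config$cds_per_gene - 1L) * intron
      gchrom <- sample(names(chrom_sizes), config$n_genes, replace = TRUE)
      gstart <- place_intervals(rep(span, config$n_genes), gchrom,
                                chrom_sizes, gap = 100)
      for (g in seq_len(config$n_genes)) {
        gid <- sprintf("g%03d", g)
        gene_rows[[length(gene_rows) + 1L]] <- data.frame(
          chrom = gchrom[g], start = gstart[g], end = gstart[g] + span,
          name = gid, class = "gene")
        for (x in seq_len(config$cds_per_gene)) {
          s <- gstart[g] + (x - 1L) * (cds_len + intron)
          gene_rows[[length(gene_rows) + 1L]] <- data.frame(
            chrom = gchrom[g], start = s, end = s + cds_len,
            name = gid, class = "CDS")
        }
      }
    }
    gene_track <- if (length(gene_rows)) {
      gt <- do.call(rbind, gene_rows)
      gt[radix_order(gt$chrom, gt$start), , drop = FALSE]
    } else {
      data.frame(chrom = character(), start = integer(), end = integer(),
                 name = character(), class = character())
    }

    ## per-assembly repeat completeness, gaps, contigs and phase blocks
    repeat_tracks <- list()
    gap_tracks <- list()
    contigs <- list()
    phase_blocks <- list()
    for (leaf in config$leaves) {
      rr <- list()
      gg <- list()
      cl <- numeric(0)
      bl <- numeric(0)
      for (chrom in names(chrom_sizes)) {
        C <- chrom_sizes[[chrom]]
        sat <- if (stats::runif(1) < config$p_satellite) {
          stats::runif(1, 5e4, 1.5e5)
        } else stats::runif(1, 0, 5e4)
        tel <- if (stats::runif(1) < config$p_telomere) {
          stats::runif(1, 500, 3000)
        } else stats::runif(1, 0, 500)
        sat <- floor(sat); tel <- floor(tel)
        if (sat >= 1) {
          rr[[length(rr) + 1L]] <- data.frame(
            chrom = chrom, start = 0L, end = as.integer(sat),
            name = "centromeric_satellite", class = "satellite")
        }
        if (tel >= 1) {
          rr[[length(rr) + 1L]] <- data.frame(
            chrom = chrom, start = as.integer(C - tel), end = as.integer(C),
            name = "telomeric_repeat", class = "telomere")
        }
        ngap <- stats::rpois(1L, config$gap_rate)
        gpos <- sort(floor(stats::runif(ngap, 0.1 * C, 0.9 * C)))
        if (ngap > 0L) {
          gg[[length(gg) + 1L]] <- data.frame(
            chrom = chrom, start = as.integer(gpos),
            end = as.integer(gpos + 100), name = "gap", class = "gap")
        }
        bounds <- c(0, as.numeric(rbind(gpos, gpos + 100)), C)
        ctg <- bounds[seq(2, length(bounds), by = 2)] -
          bounds[seq(1, length(bounds), by = 2)]
        cl <- c(cl, ctg)
        for (len in ctg) {  # phase blocks refine contigs
          nb <- stats::rpois(1L, 1)
          if (nb == 0L || len < 1e4) {
            bl <- c(bl, len)
          } else {
            cuts <- sort(stats::runif(nb, 0, len))
            bl <- c(bl, diff(c(0, cuts, len)))
          }
        }
      }
      repeat_tracks[[leaf]] <- if (length(rr)) do.call(rbind, rr) else
        data.frame(chrom = character(), start = integer(), end = integer(),
                   name = character(), class = character())
      gap_tracks[[leaf]] <- if (length(gg)) do.call(rbind, gg) else
        data.frame(chrom = character(), start = integer(), end = integer(),
                   name = character(), class = character())
      contigs[[leaf]] <- cl
      phase_blocks[[leaf]] <- bl
    }

    ## planted CNV regions: depth scaled by (1 + additional copies)
    w <- config$depth_window
    cnv <- data.frame(chrom = character(), start = integer(),
                      end = integer(), extra_copies = integer(),
                      carriers = character())
    if (config$n_cnv > 0L) {
      clades <- edge_clades(phy)
      for (k in seq_len(config$n_cnv)) {
        for (try in 1:100) {
          chrom <- sample(names(chrom_sizes), 1L)
          nwin <- sample(3:6, 1L)
          s <- w * sample.int(floor(chrom_sizes[[chrom]] / w) - nwin - 2L, 1L)
          if (!nrow(cnv) || all(cnv$chrom != chrom |
                                  s + nwin * w <= cnv$start - w |
                                  s >= cnv$end + w)) break
        }
        e <- sample.int(length(clades), 1L)
        cnv <- rbind(cnv, data.frame(
          chrom = chrom, start = as.integer(s),
          end = as.integer(s + nwin * w),
          extra_copies = sample.int(config$cnv_max_copies, 1L),
          carriers = paste(clades[[e]], collapse = ",")))
      }
    }

    depth_tracks <- list()
    for (leaf in config$leaves) {
      dd <- list()
      for (chrom in names(chrom_sizes)) {
        starts <- seq(0, chrom_sizes[[chrom]] - w, by = w)
        depth <- pmax(0, stats::rnorm(length(starts), config$depth_mean,
                                      0.08 * config$depth_mean))
        if (nrow(cnv)) {
          for (k in seq_len(nrow(cnv))) {
            carr <- strsplit(cnv$carriers[k], ",", fixed = TRUE)[[1]]
            if (cnv$chrom[k] == chrom && leaf %in% carr) {
              hit <- starts >= cnv$start[k] & starts + w <= cnv$end[k]
              depth[hit] <- depth[hit] * (1 + cnv$extra_copies[k])
            }
          }
        }
        dd[[length(dd) + 1L]] <- data.frame(
          chrom = chrom, window_start = as.integer(starts),
          window_size = as.integer(w), mean_depth = depth)
      }
      depth_tracks[[leaf]] <- do.call(rbind, dd)
    }

    total_bases <- sum(chrom_sizes)
    qv_true <- stats::runif(length(config$leaves), 40, 50)
    error_bases <- stats::setNames(
      round(total_bases * 10^(-qv_true / 10)), config$leaves)

    structure(list(config = config, tree = phy, chrom_sizes = chrom_sizes,
                   sv = built$sv, graph = built$graph, walks = built$walks,
                   gene_track = gene_track, repeat_tracks = repeat_tracks,
                   gap_tracks = gap_tracks, depth_tracks = depth_tracks,
                   cnv = cnv, contigs = contigs, phase_blocks = phase_blocks,
                   error_bases = error_bases, total_bases = total_bases),
              class = "synthetic_truth")
  })
  if (!is.null(outdir)) write_pangenome(truth, outdir)
  truth
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf("synthetic_truth: %d leaves, %d chrom x %.3g bp, %d planted SVs (%s)\n",
              length(x$config$leaves), x$config$n_chroms,
              x$config$chrom_length, nrow(x$sv),
              paste(sprintf("%s=%d", names(table(x$sv$sv_class)),
                            table(x$sv$sv_class)), collapse = ", ")))
  invisible(x)
}

#' Planted allele matrix of a synthetic truth
#'
#' The matrix downstream modules should reconstruct exactly at noise 0:
#' allele 1 at carried SVs, 0 elsewhere, no MISSING entries.
#' @param truth a `synthetic_truth`
#' @return an `allele_matrix`
#' @export
truth_allele_matrix <- function(truth) {
  sv <- truth$sv
  leaves <- truth$config$leaves
  keys <- site_key(sv$chrom, sv$start, sv$end)
  entries <- base::matrix(0L, nrow(sv), length(leaves),
                          dimnames = list(keys, leaves))
  carr <- strsplit(sv$carriers, ",", fixed = TRUE)
  for (i in seq_len(nrow(sv))) entries[i, carr[[i]]] <- 1L
  ## reference path = walk of any non-carrier, alternate = walk of a carrier
  wpaths <- lapply(truth$walks, function(w) {
    stats::setNames(w$path, site_key(w$chrom, w$start, w$end))
  })
  allele_paths <- lapply(seq_len(nrow(sv)), function(i) {
    non_carrier <- setdiff(leaves, carr[[i]])[1L]
    ref <- unname(wpaths[[non_carrier]][keys[i]])
    alt <- if (length(carr[[i]]) && nzchar(carr[[i]][1L])) {
      unname(wpaths[[carr[[i]][1L]]][keys[i]])
    } else NULL
    c(ref, alt)
  })
  structure(list(
    sites = data.frame(chrom = sv$chrom, start = sv$start, end = sv$end,
                       key = keys),
    assemblies = leaves,
    entries = entries,
    allele_paths = allele_paths
  ), class = "allele_matrix")
}

#' Write all tracks of a synthetic truth to a directory
#'
#' Emits the rGFA graph, per-assembly walk BEDs, feature BEDs, depth TSVs,
#' length tables, the truth catalogue and the tree (Newick). Output is
#' byte-deterministic for a given truth object.
#'
#' @param truth a `synthetic_truth`
#' @param outdir output directory (created if needed)
#' @return `outdir`, invisibly
#' @export
write_pangenome <- function(truth, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  for (d in c("walks", "repeats", "gaps", "depth", "contigs", "blocks")) {
    dir.create(file.path(outdir, d), showWarnings = FALSE)
  }
  write_rgfa(truth$graph, file.path(outdir, "graph.gfa"))
  for (leaf in truth$config$leaves) {
    write_walks(truth$walks[[leaf]], file.path(outdir, "walks",
                                               paste0(leaf, ".bed")))
    write_features(truth$repeat_tracks[[leaf]],
                   file.path(outdir, "repeats", paste0(leaf, ".bed")))
    write_features(truth$gap_tracks[[leaf]],
                   file.path(outdir, "gaps", paste0(leaf, ".bed")))
    write_depth(truth$depth_tracks[[leaf]],
                file.path(outdir, "depth", paste0(leaf, ".tsv")))
    writeLines(sprintf("contig_%04d\t%d", seq_along(truth$contigs[[leaf]]),
                       as.integer(truth$contigs[[leaf]])),
               file.path(outdir, "contigs", paste0(leaf, ".tsv")))
    writeLines(sprintf("block_%04d\t%d",
                       seq_along(truth$phase_blocks[[leaf]]),
                       as.integer(truth$phase_blocks[[leaf]])),
               file.path(outdir, "blocks", paste0(leaf, ".tsv")))
  }
  write_features(truth$gene_track, file.path(outdir, "genes.bed"))
  utils::write.table(truth$sv, file.path(outdir, "truth_svs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(truth$cnv, file.path(outdir, "truth_cnv.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(sprintf("%s\t%d", names(truth$chrom_sizes),
                     as.integer(truth$chrom_sizes)),
             file.path(outdir, "chrom_sizes.tsv"))
  writeLines(sprintf("%s\t%d", names(truth$error_bases),
                     as.integer(truth$error_bases)),
             file.path(outdir, "error_bases.tsv"))
  ape::write.tree(truth$tree, file.path(outdir, "tree.nwk"))
  cfg <- truth$config
  class(cfg) <- NULL
  yaml::write_yaml(cfg, file.path(outdir, "config.yaml"))
  invisible(outdir)
}

#' Emit perturbed replicate SV catalogues
#'
#' Emulates the order sensitivity of iterative pangenome construction: each
#' replicate independently perturbs every planted SV with probability
#' `noise`; a perturbed SV is either dropped (missed bubble) or split into
#' two smaller flanking events (shattered bubble), with equal probability.
#' Split pieces have roughly half the original length, so they fail the
#' default consensus length-ratio criterion against the truth record.
#'
#' @param truth a `synthetic_truth`
#' @param n_replicates number of replicate catalogues
#' @param noise per-SV perturbation probability in `[0, 1)`
#' @param seed integer seed
#' @param outdir optional directory; when given, each replicate's rebuilt
#'   graph and walk files are written under `replicate_<r>/`
#' @return list of SV catalogues (data.frames sorted by chrom, start), with
#'   attribute `perturbed` giving the per-replicate perturbed fraction
#' @export
emit_replicates <- function(truth, n_replicates, noise, seed = 1,
                            outdir = NULL) {
  stopifnot(inherits(truth, "synthetic_truth"), noise >= 0, noise < 1,
            n_replicates >= 1)
  sv <- truth$sv
  out <- vector("list", n_replicates)
  perturbed <- numeric(n_replicates)
  for (r in seq_len(n_replicates)) {
    rep_sv <- with_seed(derive_seed(seed, r), {
      u <- stats::runif(nrow(sv))
      mode <- ifelse(u >= noise, "keep",
                     ifelse(stats::runif(nrow(sv)) < 0.5, "drop", "split"))
      rows <- list()
      for (i in seq_len(nrow(sv))) {
        if (mode[i] == "drop") next
        if (mode[i] == "keep") {
          rows[[length(rows) + 1L]] <- sv[i, ]
          next
        }
        rows_i <- split_sv(sv[i, ])
        for (p in rows_i) rows[[length(rows) + 1L]] <- p
      }
      perturbed[r] <- mean(mode != "keep")
      if (!length(rows)) {
        sv[0, ]
      } else {
        x <- do.call(rbind, rows)
        x$svtype <- sv_type_rule(x$ref_len, x$alt_len)
        x <- x[radix_order(x$chrom, x$start), , drop = FALSE]
        rownames(x) <- NULL
        x
      }
    })
    out[[r]] <- rep_sv
    if (!is.null(outdir)) {
      built <- build_planted_graph(rep_sv, truth$chrom_sizes,
                                   truth$config$leaves)
      rdir <- file.path(outdir, sprintf("replicate_%d", r))
      dir.create(file.path(rdir, "walks"), recursive = TRUE,
                 showWarnings = FALSE)
      write_rgfa(built$graph, file.path(rdir, "graph.gfa"))
      for (leaf in truth$config$leaves) {
        write_walks(built$walks[[leaf]],
                    file.path(rdir, "walks", paste0(leaf, ".bed")))
      }
    }
  }
  attr(out, "perturbed") <- perturbed
  out
}

## Split one SV record into two flanking half-length events (10 bp apart so
## the rebuilt graph keeps them as separate bubbles). Returns a list of
## records; falls back to dropping when the SV is too small to split.
split_sv <- function(rec) {
  if (rec$alt_len > rec$ref_len) {      # insertion-like: halve the insert
    ins <- rec$alt_len - rec$ref_len
    h <- floor(ins / 2)
    if (h < 1L || rec$ref_len < 1L) return(list())
    a <- rec; a$alt_len <- as.integer(a$ref_len + h)
    b <- rec
    b$start <- as.integer(rec$end + 10L)
    b$end <- as.integer(b$start + 10L)
    b$ref_len <- 10L
    b$alt_len <- as.integer(10L + (ins - h))
    list(a, b)
  } else {                               # deletion-like: halve the interval
    L <- rec$ref_len
    if (L < 30L) return(list())
    h <- floor((L - 10L) / 2)
    a <- rec; a$end <- as.integer(a$start + h); a$ref_len <- as.integer(h)
    b <- rec; b$start <- as.integer(a$end + 10L)
    b$ref_len <- as.integer(rec$end - b$start)
    list(a, b)
  }
}
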