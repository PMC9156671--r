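## Assembly completeness and correctness summaries: NG50/PG50, Phred-scaled
## base error (QV), terminal repeat completeness, end-to-end chromosome
## calls, and coverage-dropout counting.

#' NG50 contig length
#'
#' Smallest contig length L such that contigs of length >= L together cover
#' at least half of the expected genome size. Returns 0 with a warning when
#' the assembly sums to less than half the expected size.
#'
#' @param lengths numeric vector of contig lengths (bp)
#' @param genome_size expected genome size G (bp)
#' @return NG50 in bp
#' @export
ng50 <- function(lengths, genome_size) {
  stopifnot(length(lengths) >= 1L, all(lengths > 0), genome_size > 0)
  s <- sort(lengths, decreasing = TRUE)
  cum <- cumsum(s)
  hit <- which(cum >= genome_size / 2)
  if (!length(hit)) {
    warning("assembly covers less than half the expected genome size")
    return(0)
  }
  s[hit[1L]]
}

#' PG50: NG50 over haplotype-phased block lengths
#'
#' Identical computation to [ng50()] applied to phase-block lengths; since
#' blocks refine contigs, PG50 never exceeds NG50.
#' @param block_lengths numeric vector of phase-block lengths (bp)
#' @inheritParams ng50
#' @return PG50 in bp
#' @export
pg50 <- function(block_lengths, genome_size) ng50(block_lengths, genome_size)

#' Phred-scaled base quality (QV)
#'
#' `-10 * log10(error_bases / total_bases)`; zero observed errors are capped
#' at QV 99 (attribute `capped`).
#' @param error_bases estimated erroneous bases
#' @param total_bases assembly bases assessed
#' @return QV value; attribute `capped` is TRUE when errors were zero
#' @export
qv <- function(error_bases, total_bases) {
  stopifnot(total_bases > 0, error_bases >= 0)
  if (error_bases > total_bases) stop("more error bases than total bases")
  if (error_bases == 0) {
    return(structure(99, capped = TRUE))
  }
  structure(-10 * log10(error_bases / total_bases), capped = FALSE)
}

#' Repeat bases within a terminal window of a chromosome
#'
#' Total bp of intervals of one repeat class clipped to the first
#' (`proximal`) or last (`distal`) `window` bp of the chromosome. Intervals
#' straddling the window boundary contribute only their inside portion.
#'
#' @param repeats feature track data.frame
#' @param chrom chromosome label
#' @param chrom_length chromosome length (bp)
#' @param window terminal window size in bp (default 10 kb, the convention
#'   for telomere accounting)
#' @param end `"proximal"` or `"distal"`
#' @param class repeat class to count (default `"telomere"`)
#' @return bp count
#' @export
telomere_bases <- function(repeats, chrom, chrom_length, window = 1e4,
                           end = c("distal", "proximal"),
                           class = "telomere") {
  end <- match.arg(end)
  r <- repeats[repeats$chrom == chrom & repeats$class == class, , drop = FALSE]
  if (nrow(r) == 0L) return(0)
  if (end == "proximal") {
    lo <- 0; hi <- min(window, chrom_length)
  } else {
    lo <- max(0, chrom_length - window); hi <- chrom_length
  }
  sum(clip_bp(r$start, r$end, lo, hi))
}

#' End-to-end chromosome report
#'
#' A chromosome is called end-to-end when it has at least `sat_min` bp of
#' centromeric satellite at the proximal end (within the first `sat_window`
#' bp; bovine-style acrocentric chromosomes put the centromere there) and at
#' least `tel_min` bp of telomeric repeat within the distal `tel_window` bp.
#' Both thresholds are inclusive ("at least").
#'
#' @param repeats feature track with `satellite` and `telomere` classed rows
#' @param gaps feature track of assembly gaps (class `gap`), may be empty
#' @param chrom_sizes named numeric vector of chromosome lengths
#' @param sat_min proximal satellite threshold in bp (default 50 kb)
#' @param tel_min distal telomere threshold in bp (default 500)
#' @param sat_window proximal window for satellite counting (default 5 Mb)
#' @param tel_window distal window for telomere counting (default 10 kb)
#' @return data.frame with one row per chromosome: `chrom`,
#'   `proximal_satellite_bp`, `distal_telomere_bp`, `n_gaps`, `end_to_end`
#' @export
end_to_end_report <- function(repeats, gaps, chrom_sizes, sat_min = 5e4,
                              tel_min = 500, sat_window = 5e6,
                              tel_window = 1e4) {
  chroms <- names(chrom_sizes)
  rows <- lapply(chroms, function(chrom) {
    sat <- telomere_bases(repeats, chrom, chrom_sizes[[chrom]],
                          window = sat_window, end = "proximal",
                          class = "satellite")
    tel <- telomere_bases(repeats, chrom, chrom_sizes[[chrom]],
                          window = tel_window, end = "distal",
                          class = "telomere")
    ng <- if (is.null(gaps) || nrow(gaps) == 0L) 0L else {
      sum(gaps$chrom == chrom & gaps$class == "gap")
    }
    data.frame(chrom = chrom, proximal_satellite_bp = sat,
               distal_telomere_bp = tel, n_gaps = ng,
               end_to_end = sat >= sat_min && tel >= tel_min)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Count coverage-dropout regions
#'
#' A dropout region is a maximal run of consecutive depth windows whose mean
#' depth is below `threshold` fold-coverage; each run counts once however
#' many windows it spans. Runs never extend across chromosomes.
#'
#' @param depth depth track data.frame
#' @param threshold fold-coverage threshold (default 1.0, i.e. near-total
#'   dropout)
#' @return integer count of dropout regions; attribute `per_chrom` holds the
#'   per-chromosome counts
#' @export
dropout_regions <- function(depth, threshold = 1.0) {
  validate_depth(depth)
  if (nrow(depth) == 0L) return(structure(0L, per_chrom = integer()))
  per <- vapply(split(depth, depth$chrom), function(d) {
    d <- d[order(d$window_start), , drop = FALSE]
    r <- rle(d$mean_depth < threshold)
    sum(r$values)
  }, 1L)
  structure(sum(per), per_chrom = per)
}

#' Assembly QC summary
#'
#' Bundles the per-assembly completeness metrics: NG50, PG50, QV,
#' end-to-end chromosome count and coverage-dropout count.
#'
#' @param contig_lengths numeric vector of contig lengths
#' @param block_lengths numeric vector of phase-block lengths
#' @param error_bases estimated erroneous bases
#' @param total_bases total assembly bases
#' @param repeats,gaps feature tracks (see [end_to_end_report()])
#' @param depth depth track
#' @param chrom_sizes named numeric vector of chromosome lengths
#' @param genome_size expected genome size (defaults to `sum(chrom_sizes)`)
#' @return list of class `qc_summary`
#' @export
qc_summary <- function(contig_lengths, block_lengths, error_bases,
                       total_bases, repeats, gaps, depth, chrom_sizes,
                       genome_size = sum(chrom_sizes)) {
  ete <- end_to_end_report(repeats, gaps, chrom_sizes)
  structure(list(
    ng50 = ng50(contig_lengths, genome_size),
    pg50 = pg50(block_lengths, genome_size),
    qv = as.numeric(qv(error_bases, total_bases)),
    n_contigs = length(contig_lengths),
    n_end_to_end = sum(ete$end_to_end),
    n_gaps = sum(ete$n_gaps),
    n_dropout_regions = as.integer(dropout_regions(depth)),
    per_chrom = ete
  ), class = "qc_summary")
}

#' @export
print.qc_summary <- function(x, ...) {
  cat(sprintf(paste0("qc_summary: NG50 %.3g bp, PG50 %.3g bp, QV %.1f, ",
                     "%d contigs, %d/%d end-to-end, %d gaps, %d dropout regions\n"),
              x$ng50, x$pg50, x$qv, x$n_contigs, x$n_end_to_end,
              nrow(x$per_chrom), x$n_gaps, x$n_dropout_regions))
  invisible(x)
}
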