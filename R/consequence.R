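## Coding consequences of SVs: in-frame vs frameshift calls, VNTR protein
## extensions, and depth-based copy-number estimation.

#' Construct a gene model
#'
#' @param id gene identifier
#' @param chrom chromosome label
#' @param strand `"+"` or `"-"`
#' @param cds data.frame of CDS intervals (`start`, `end`, 0-based half-open)
#' @return list of class `gene_model`; warns (and proceeds) if the total CDS
#'   length is not divisible by 3
#' @export
gene_model <- function(id, chrom, strand = "+", cds) {
  stopifnot(is.data.frame(cds), all(c("start", "end") %in% names(cds)),
            nrow(cds) >= 1L, all(cds$end > cds$start),
            strand %in% c("+", "-"))
  cds <- cds[order(cds$start), c("start", "end"), drop = FALSE]
  total <- sum(cds$end - cds$start)
  if (total %% 3L != 0L) {
    warning("gene ", id, ": total CDS length ", total,
            " not divisible by 3; annotation may be truncated")
  }
  structure(list(id = id, chrom = chrom, strand = strand, cds = cds,
                 span = c(min(cds$start), max(cds$end))),
            class = "gene_model")
}

new_consequence <- function(kind, aa_change, genes, coding_bp_change = 0,
                            flag = "") {
  structure(list(kind = kind, aa_change = aa_change, genes = genes,
                 coding_bp_change = coding_bp_change, flag = flag),
            class = "consequence")
}

#' @export
print.consequence <- function(x, ...) {
  cat(sprintf("consequence: %s (aa change %+d, coding bp %+d) [%s]%s\n",
              x$kind, x$aa_change, x$coding_bp_change,
              paste(x$genes, collapse = ","),
              if (nzchar(x$flag)) paste0(" flag=", x$flag) else ""))
  invisible(x)
}

#' Coding consequence of an SV against a gene model
#'
#' Only the portion of the SV that overlaps coding sequence counts towards
#' the coding base-pair change: a deletion removes the CDS-overlapped bases
#' of its reference interval, while an insertion (net gain) deposits its
#' gained bases at a point, so the full gain counts whenever the SV interval
#' touches CDS. A net coding change divisible by 3 is in-frame (amino-acid
#' change = change / 3, negative for deletions); otherwise the variant is a
#' frameshift. A deletion-like SV whose interval contains the gene's whole
#' span is reported as `GENE_SPANNING_DEL`; an SV with no CDS overlap is
#' `NON_CODING`. The amino-acid magnitude is strand-independent.
#'
#' @param sv one SV record (list or single-row data.frame with `chrom`,
#'   `start`, `end`, `ref_len`, `alt_len`)
#' @param gene a [gene_model()] on the same chromosome
#' @return a `consequence` object
#' @export
coding_consequence <- function(sv, gene) {
  stopifnot(inherits(gene, "gene_model"))
  sv <- as.list(sv)
  if (!identical(as.character(sv$chrom), as.character(gene$chrom))) {
    stop("sv and gene are on different chromosomes")
  }
  deletion_like <- sv$alt_len < sv$ref_len
  if (deletion_like && sv$start <= gene$span[1] && sv$end >= gene$span[2]) {
    return(new_consequence("GENE_SPANNING_DEL", 0L, gene$id,
                           -sum(gene$cds$end - gene$cds$start)))
  }
  ov <- sum(clip_bp(gene$cds$start, gene$cds$end, sv$start, sv$end))
  if (ov == 0) return(new_consequence("NON_CODING", 0L, character()))
  change <- if (sv$alt_len >= sv$ref_len) sv$alt_len - sv$ref_len else -ov
  if (change == 0) return(new_consequence("NON_CODING", 0L, gene$id))
  if (change %% 3L != 0L) {
    return(new_consequence("FRAMESHIFT", 0L, gene$id, change))
  }
  kind <- if (change > 0) "IN_FRAME_INS" else "IN_FRAME_DEL"
  new_consequence(kind, as.integer(change / 3L), gene$id, change)
}

#' Protein consequence of a tandem-repeat copy-number change
#'
#' A gain (or loss, negative count) of `extra_copies` copies of a
#' `motif_len`-bp repeat motif inside coding sequence extends (shortens) the
#' protein by `extra_copies * motif_len / 3` residues when the motif length
#' is divisible by 3; otherwise the expansion shifts the reading frame.
#'
#' @param motif_len repeat motif length in bp (> 0)
#' @param extra_copies integer copy-number change (negative = contraction)
#' @param gene optional gene id to report
#' @return a `consequence` object (`VNTR_EXTENSION`, `FRAMESHIFT`, or
#'   `NON_CODING` for zero copies)
#' @export
vntr_extension <- function(motif_len, extra_copies, gene = character()) {
  stopifnot(motif_len > 0, extra_copies == round(extra_copies))
  extra_copies <- as.integer(extra_copies)
  if (extra_copies == 0L) return(new_consequence("NON_CODING", 0L, gene))
  bp <- extra_copies * as.integer(motif_len)
  if (motif_len %% 3 != 0) {
    return(new_consequence("FRAMESHIFT", 0L, gene, bp, flag = "vntr"))
  }
  new_consequence("VNTR_EXTENSION", as.integer(bp / 3L), gene, bp)
}

#' Additional copy number from windowed read depth
#'
#' Estimates the number of additional copies of a region as
#' `round(mean depth over the region / baseline) - 1`, floored at 0, with
#' half-integer ratios rounded away from zero. The raw depth ratio is
#' reported alongside because long-read platforms routinely disagree by one
#' copy. The estimate is invariant to scaling depth and baseline together.
#'
#' @param depth depth track data.frame (`chrom`, `window_start`,
#'   `window_size`, `mean_depth`)
#' @param chrom chromosome of the region
#' @param start,end region interval (0-based half-open); must contain at
#'   least one full depth window
#' @param baseline baseline fold-coverage; `NULL` (default) uses the median
#'   depth of same-chromosome windows outside the region
#' @return list of class `copy_number_estimate`: `additional_copies`,
#'   `ratio`, `baseline`, `n_windows`
#' @export
copy_number_from_depth <- function(depth, chrom, start, end, baseline = NULL) {
  validate_depth(depth)
  w <- depth$window_size[1L]
  inside <- depth$chrom == chrom & depth$window_start >= start &
    depth$window_start + w <= end
  if (!any(inside)) {
    stop("region contains no full depth window; use a smaller window size")
  }
  if (is.null(baseline)) {
    outside <- depth$chrom == chrom & !inside
    if (!any(outside)) stop("no windows outside the region to set a baseline")
    baseline <- stats::median(depth$mean_depth[outside])
  }
  if (baseline <= 0) stop("baseline depth must be positive")
  ratio <- mean(depth$mean_depth[inside]) / baseline
  structure(list(additional_copies = max(0L, as.integer(round_away(ratio)) - 1L),
                 ratio = ratio, baseline = baseline,
                 n_windows = sum(inside)),
            class = "copy_number_estimate")
}

#' @export
print.copy_number_estimate <- function(x, ...) {
  cat(sprintf("copy_number: +%d additional copies (depth ratio %.2f over baseline %.2f, %d windows)\n",
              x$additional_copies, x$ratio, x$baseline, x$n_windows))
  invisible(x)
}
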