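## Cross-pangenome SV consensus: greedy one-to-one matching of SV sets,
## precision/recall/F1 scoring, and shared-fraction tables over many sets.

#' Matching configuration for SV-set comparison
#'
#' Two records match iff they are on the same chromosome, have the same
#' `svtype`, their starts differ by at most `breakpoint_tolerance` bp and the
#' ratio of their lengths (shorter over longer, length = max(ref_len,
#' alt_len)) is at least `length_ratio_min`. These defaults follow common
#' SV-benchmarking practice and are echoed into every report.
#'
#' @param breakpoint_tolerance bp (default 100)
#' @param length_ratio_min fraction in (0, 1] (default 0.9)
#' @return list of class `match_config`
#' @export
match_config <- function(breakpoint_tolerance = 100, length_ratio_min = 0.9) {
  stopifnot(breakpoint_tolerance >= 0,
            length_ratio_min > 0, length_ratio_min <= 1)
  structure(list(breakpoint_tolerance = breakpoint_tolerance,
                 length_ratio_min = length_ratio_min),
            class = "match_config")
}

sv_length <- function(x) pmax(x$ref_len, x$alt_len)

check_sorted <- function(x, what) {
  if (nrow(x) > 1L) {
    o <- radix_order(x$chrom, x$start)
    if (!identical(o, seq_len(nrow(x)))) {
      stop(what, " records must be sorted by (chrom, start)")
    }
  }
  invisible(x)
}

#' Greedy one-to-one matching between two SV sets
#'
#' Test records are scanned left to right; each is matched to the compatible
#' (see [match_config()]) unmatched truth record with the nearest start,
#' earliest on ties. Each record is matched at most once. Greedy matching is
#' deterministic; its cardinality is near-optimal in practice (checked
#' against maximum bipartite matching in the test-suite).
#'
#' @param test,truth data.frames of SV records (`chrom`, `start`, `end`,
#'   `ref_len`, `alt_len`, `svtype`), each sorted by (chrom, start)
#' @param config a [match_config()]
#' @return data.frame with columns `test_idx`, `truth_idx`
#' @export
match_sv_sets <- function(test, truth, config = match_config()) {
  check_sorted(test, "test")
  check_sorted(truth, "truth")
  tol <- config$breakpoint_tolerance
  rmin <- config$length_ratio_min
  len_test <- sv_length(test)
  len_truth <- sv_length(truth)
  used <- rep(FALSE, nrow(truth))
  m_test <- integer(0)
  m_truth <- integer(0)
  for (i in seq_len(nrow(test))) {
    cand <- which(!used & truth$chrom == test$chrom[i] &
                    truth$svtype == test$svtype[i] &
                    abs(truth$start - test$start[i]) <= tol)
    if (!length(cand)) next
    ratio <- pmin(len_test[i], len_truth[cand]) /
      pmax(len_test[i], len_truth[cand])
    ratio[pmax(len_test[i], len_truth[cand]) == 0] <- 1
    cand <- cand[ratio >= rmin]
    if (!length(cand)) next
    j <- cand[which.min(abs(truth$start[cand] - test$start[i]))]
    used[j] <- TRUE
    m_test <- c(m_test, i)
    m_truth <- c(m_truth, j)
  }
  data.frame(test_idx = m_test, truth_idx = m_truth)
}

#' Precision/recall/F1 agreement between an SV set and a truth set
#'
#' @inheritParams match_sv_sets
#' @return list of class `agreement_report`: `n_truth`, `n_test`,
#'   `n_matched`, `precision`, `recall`, `f1` (percentages; empty test set
#'   gives 0 by convention) and the matching `config`
#' @export
score_agreement <- function(test, truth, config = match_config()) {
  if (nrow(truth) == 0L) stop("empty truth set: recall undefined")
  m <- match_sv_sets(test, truth, config)
  n_matched <- nrow(m)
  precision <- if (nrow(test) > 0L) 100 * n_matched / nrow(test) else 0
  recall <- 100 * n_matched / nrow(truth)
  f1 <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  structure(list(n_truth = nrow(truth), n_test = nrow(test),
                 n_matched = n_matched, precision = precision,
                 recall = recall, f1 = f1, config = config),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf(paste0("agreement: %d/%d test, %d/%d truth matched; ",
                     "P %.1f%% R %.1f%% F1 %.1f%% ",
                     "(tol %g bp, length ratio >= %g)\n"),
              x$n_matched, x$n_test, x$n_matched, x$n_truth,
              x$precision, x$recall, x$f1,
              x$config$breakpoint_tolerance, x$config$length_ratio_min))
  invisible(x)
}

#' Shared-fraction table across several SV sets
#'
#' Records from all sets are clustered into sites by single linkage over
#' pairwise cross-set matches (union-find via graph components), then each
#' site is classified by which labels contain it. When `groups` is given
#' (label -> group, e.g. sequencing platform), per-site group presence is
#' reported as well.
#'
#' @param sv_sets named list (label -> sorted SV data.frame)
#' @param groups optional named character vector mapping labels to groups
#' @param config a [match_config()]
#' @return list of class `shared_fractions`: `sites` (one row per site with
#'   logical presence columns per label), `subsets` (counts and fractions per
#'   label subset), `common_to_all` fraction, `unique_fractions` per label,
#'   and `group_subsets` when groups are supplied
#' @export
shared_fractions <- function(sv_sets, groups = NULL, config = match_config()) {
  stopifnot(is.list(sv_sets), length(sv_sets) >= 2L, !is.null(names(sv_sets)))
  labs <- names(sv_sets)
  counts <- vapply(sv_sets, nrow, 1L)
  offsets <- cumsum(c(0L, counts[-length(counts)]))
  names(offsets) <- labs
  n_total <- sum(counts)
  edges <- list()
  for (i in seq_len(length(labs) - 1L)) {
    for (j in (i + 1L):length(labs)) {
      m <- match_sv_sets(sv_sets[[i]], sv_sets[[j]], config)
      if (nrow(m)) {
        edges[[length(edges) + 1L]] <-
          cbind(offsets[i] + m$test_idx, offsets[j] + m$truth_idx)
      }
    }
  }
  g <- igraph::make_empty_graph(n = n_total, directed = FALSE)
  if (length(edges)) {
    g <- igraph::add_edges(g, t(do.call(rbind, edges)))
  }
  comp <- igraph::components(g)$membership
  rec_label <- rep(labs, counts)
  pres <- vapply(labs, function(l) {
    tabulate(comp[rec_label == l], nbins = max(comp)) > 0L
  }, logical(max(comp)))
  if (is.null(dim(pres))) pres <- base::matrix(pres, nrow = 1L,
                                               dimnames = list(NULL, labs))
  n_sites <- nrow(pres)
  subset_key <- apply(pres, 1L, function(r) paste(labs[r], collapse = "+"))
  tab <- table(subset_key)
  subsets <- data.frame(subset = names(tab), count = as.integer(tab))
  subsets$fraction <- subsets$count / n_sites
  subsets <- subsets[radix_order(-subsets$count, subsets$subset), , drop = FALSE]
  rownames(subsets) <- NULL
  unique_fractions <- vapply(labs, function(l) {
    sum(pres[, l] & rowSums(pres) == 1L) / n_sites
  }, numeric(1))
  out <- list(sites = as.data.frame(pres),
              subsets = subsets,
              n_sites = n_sites,
              common_to_all = sum(rowSums(pres) == length(labs)) / n_sites,
              unique_fractions = unique_fractions,
              config = config)
  if (!is.null(groups)) {
    stopifnot(all(labs %in% names(groups)))
    gl <- unique(groups[labs])
    gpres <- vapply(gl, function(gr) {
      rowSums(pres[, labs[groups[labs] == gr], drop = FALSE]) > 0L
    }, logical(n_sites))
    if (is.null(dim(gpres))) gpres <- base::matrix(gpres, nrow = 1L,
                                                   dimnames = list(NULL, gl))
    gkey <- apply(gpres, 1L, function(r) paste(gl[r], collapse = "+"))
    gtab <- table(gkey)
    out$group_subsets <- data.frame(subset = names(gtab),
                                    count = as.integer(gtab),
                                    fraction = as.integer(gtab) / n_sites)
  }
  structure(out, class = "shared_fractions")
}

#' @export
print.shared_fractions <- function(x, ...) {
  cat(sprintf("shared_fractions: %d sites, %.1f%% common to all\n",
              x$n_sites, 100 * x$common_to_all))
  print(utils::head(x$subsets, 10L))
  invisible(x)
}
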