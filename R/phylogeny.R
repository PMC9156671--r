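## SV-based phylogeny: pairwise mutually-exclusive-bubble counts, UPGMA
## dendrograms with deterministic tie-breaking, taurine-style topology
## classification, and UpSet intersection sets.

#' Pairwise discordance (mutually exclusive bubbles)
#'
#' For every pair of assemblies, counts the bubbles at which both walks are
#' present but take different paths. Sites MISSING in either member of a pair
#' are skipped for that pair (pairwise-complete), so partially phased
#' assemblies still contribute.
#'
#' @param matrix an `allele_matrix`
#' @param restrict_chrom optional chromosome label to restrict to
#' @return object of class `discordance_matrix`: `labels`, `D` (symmetric
#'   count matrix, zero diagonal), `n_sites_used` (jointly non-missing sites
#'   per pair)
#' @export
pairwise_discordance <- function(matrix, restrict_chrom = NULL) {
  stopifnot(inherits(matrix, "allele_matrix"))
  ent <- matrix$entries
  if (nrow(ent) == 0L) stop("empty allele matrix")
  if (!is.null(restrict_chrom)) {
    if (!restrict_chrom %in% matrix$sites$chrom) {
      stop("unknown chromosome: ", restrict_chrom)
    }
    ent <- ent[matrix$sites$chrom == restrict_chrom, , drop = FALSE]
  }
  labs <- matrix$assemblies
  k <- length(labs)
  D <- base::matrix(0L, k, k, dimnames = list(labs, labs))
  n_used <- base::matrix(nrow(ent), k, k, dimnames = list(labs, labs))
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      ok <- !is.na(ent[, i]) & !is.na(ent[, j])
      d <- sum(ent[ok, i] != ent[ok, j])
      D[i, j] <- D[j, i] <- d
      n_used[i, j] <- n_used[j, i] <- sum(ok)
    }
  }
  diag(n_used) <- rowSums(!is.na(ent))[seq_len(k)]
  structure(list(labels = labs, D = D, n_sites_used = n_used),
            class = "discordance_matrix")
}

#' @export
print.discordance_matrix <- function(x, ...) {
  cat("discordance_matrix over", length(x$labels), "assemblies:\n")
  print(x$D)
  invisible(x)
}

#' UPGMA dendrogram from a distance or discordance matrix
#'
#' Average-linkage agglomeration: at each step the two clusters with the
#' smallest mean pairwise distance (over all cross pairs of leaves, computed
#' from the original matrix) are merged at height equal to half that mean
#' distance, so an ultrametric input is recovered exactly. Ties are broken
#' deterministically by the lexicographically smallest member label of the
#' candidate pair.
#'
#' @param dist a `discordance_matrix` or a symmetric numeric matrix with
#'   dimnames
#' @param normalize divide counts by the per-pair number of jointly
#'   non-missing sites before clustering (discordance input only)
#' @return object of class `sv_dendrogram`: `labels`, `merge` (hclust-style
#'   merge matrix), `height` (UPGMA heights, half the mean inter-cluster
#'   distance), `members` (leaf sets per merge)
#' @export
upgma <- function(dist, normalize = FALSE) {
  if (inherits(dist, "discordance_matrix")) {
    D <- dist$D
    if (normalize) {
      n <- dist$n_sites_used
      n[n == 0L] <- NA
      D <- D / n
      diag(D) <- 0
    }
  } else {
    D <- as.matrix(dist)
    if (normalize) stop("normalize applies to discordance_matrix input only")
  }
  if (is.null(dimnames(D)[[1]])) {
    dimnames(D) <- list(paste0("L", seq_len(nrow(D))),
                        paste0("L", seq_len(nrow(D))))
  }
  if (nrow(D) != ncol(D) || !isTRUE(all.equal(D, t(D), check.attributes = FALSE))) {
    stop("distance matrix must be symmetric")
  }
  labs <- dimnames(D)[[1]]
  k <- length(labs)
  if (k < 2L) stop("need at least 2 labels")
  ## active clusters: integer code (negative leaf / positive merge), members
  active <- lapply(seq_len(k), function(i) list(code = -i, members = labs[i]))
  merge <- base::matrix(0L, k - 1L, 2L)
  height <- numeric(k - 1L)
  members <- vector("list", k - 1L)
  avg_dist <- function(a, b) mean(D[a$members, b$members])
  for (step in seq_len(k - 1L)) {
    best <- NULL
    best_d <- Inf
    best_key <- NULL
    m <- length(active)
    for (i in seq_len(m - 1L)) {
      for (j in (i + 1L):m) {
        d <- avg_dist(active[[i]], active[[j]])
        key <- sort(c(min(active[[i]]$members), min(active[[j]]$members)))
        newer <- !is.null(best) &&
          (key[1] < best_key[1] || (key[1] == best_key[1] && key[2] < best_key[2]))
        if (d < best_d - 1e-12 || (abs(d - best_d) <= 1e-12 && newer)) {
          best <- c(i, j)
          best_d <- d
          best_key <- key
        }
      }
    }
    i <- best[1]; j <- best[2]
    merge[step, ] <- c(active[[i]]$code, active[[j]]$code)
    height[step] <- best_d / 2
    members[[step]] <- sort(c(active[[i]]$members, active[[j]]$members))
    merged <- list(code = step, members = members[[step]])
    active <- c(active[-c(i, j)], list(merged))
  }
  structure(list(labels = labs, merge = merge, height = height,
                 members = members), class = "sv_dendrogram")
}

#' @export
print.sv_dendrogram <- function(x, ...) {
  cat("sv_dendrogram:", dendrogram_newick(x), "\n")
  invisible(x)
}

cluster_height <- function(tree, code) if (code < 0L) 0 else tree$height[code]
cluster_members <- function(tree, code) {
  if (code < 0L) tree$labels[-code] else tree$members[[code]]
}

#' Newick string for an UPGMA dendrogram
#'
#' Branch lengths are height differences, so leaf-to-root path length equals
#' the root height (ultrametric).
#' @param tree an `sv_dendrogram`
#' @param digits significant digits for branch lengths
#' @return character Newick string (semicolon-terminated)
#' @export
dendrogram_newick <- function(tree, digits = 6) {
  rec <- function(code, parent_h) {
    h <- cluster_height(tree, code)
    bl <- sprintf("%.*g", digits, parent_h - h)
    if (code < 0L) return(paste0(tree$labels[-code], ":", bl))
    kids <- tree$merge[code, ]
    paste0("(", rec(kids[1], h), ",", rec(kids[2], h), "):", bl)
  }
  root <- nrow(tree$merge)
  h <- tree$height[root]
  kids <- tree$merge[root, ]
  paste0("(", rec(kids[1], h), ",", rec(kids[2], h), ");")
}

#' Convert an UPGMA dendrogram to an ape phylo tree
#' @param tree an `sv_dendrogram`
#' @return an [ape::read.tree()] phylo object
#' @export
dendrogram_phylo <- function(tree) {
  ape::read.tree(text = dendrogram_newick(tree))
}

#' Classify the branching arrangement of a 5-taxon SV dendrogram
#'
#' For a dendrogram over two ordered outgroups (default gaur `G`, then
#' Nellore `N`) and a three-member ingroup (taurine `O`, `P`, `B`): if the
#' root splits off the first outgroup alone, the next split the second
#' outgroup alone, the classification is the ingroup label that splits first
#' from the remaining pair (`O_OUT`, `P_OUT` or `B_OUT`); any violation of
#' the outgroup order returns `OTHER`.
#'
#' @param tree an `sv_dendrogram` over exactly the five labels
#' @param outgroups ordered outgroup labels, outermost first
#' @param ingroup ingroup labels
#' @return one of `"O_OUT"`, `"P_OUT"`, `"B_OUT"` (generally
#'   `paste0(label, "_OUT")`) or `"OTHER"`
#' @export
classify_topology <- function(tree, outgroups = c("G", "N"),
                              ingroup = c("O", "P", "B")) {
  stopifnot(inherits(tree, "sv_dendrogram"))
  expected <- c(outgroups, ingroup)
  if (!setequal(tree$labels, expected) || length(tree$labels) != length(expected)) {
    stop("tree labels do not match outgroups + ingroup")
  }
  ## walk down from the root, peeling one outgroup per level
  code <- nrow(tree$merge)
  for (og in outgroups) {
    kids <- tree$merge[code, ]
    km <- lapply(kids, cluster_members, tree = tree)
    hit <- vapply(km, function(m) identical(m, og), TRUE)
    if (!any(hit)) return("OTHER")
    code <- kids[!hit]
    if (code < 0L) return("OTHER")
  }
  ## code now roots the ingroup trio
  kids <- tree$merge[code, ]
  km <- lapply(kids, cluster_members, tree = tree)
  single <- vapply(km, length, 1L) == 1L
  if (sum(single) != 1L) return("OTHER")
  out <- km[single][[1]]
  if (!out %in% ingroup) return("OTHER")
  paste0(out, "_OUT")
}

#' UpSet intersection sets of non-reference bubble carriers
#'
#' Each bubble with at least one non-reference carrier contributes one count
#' to the subset of assemblies that carry a non-reference allele there;
#' bubbles where every assembly took the reference path contribute nothing.
#' Requires a complete matrix (run [filter_complete()] first).
#'
#' @param matrix a complete `allele_matrix`
#' @return data.frame with `subset` (assembly labels joined by `+`, in matrix
#'   column order) and `count`; attribute `n_nonref` holds the total
#' @export
intersection_sets <- function(matrix) {
  stopifnot(inherits(matrix, "allele_matrix"))
  ent <- matrix$entries
  if (anyNA(ent)) {
    stop("matrix has MISSING entries; run filter_complete() first")
  }
  labs <- matrix$assemblies
  keys <- apply(ent, 1L, function(r) paste(labs[r > 0L], collapse = "+"))
  keys <- keys[keys != ""]
  tab <- table(keys)
  out <- data.frame(subset = names(tab), count = as.integer(tab))
  out <- out[radix_order(-out$count, out$subset), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_nonref") <- sum(out$count)
  out
}
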