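## Retrace per-assembly haplotype walks through bubbles into a
## bubble x assembly allele matrix.

#' Build the bubble-by-assembly allele matrix
#'
#' Walk records are matched to bubbles by their (chrom, ref_start, ref_end)
#' site key. The allele index of an entry is the position of the walk's path
#' among the distinct paths observed at that bubble; the graph's reference
#' path is always allele 0, whether or not any assembly took it. Absent or
#' `"."` walks give MISSING (NA) entries. Walk records whose site matches no
#' bubble are ignored with a warning count; multiple records for one site and
#' assembly are ambiguous and treated as MISSING with a warning.
#'
#' @param bubbles list of bubbles from [detect_superbubbles()]
#' @param walks named list (assembly label -> data.frame) of walk records as
#'   returned by [read_walks()]
#' @return object of class `allele_matrix`: `sites` (data.frame with `chrom`,
#'   `start`, `end`, `key`), `assemblies`, `entries` (integer matrix of
#'   0-based allele indices, NA = MISSING), `allele_paths` (list of path
#'   strings per site, element 1 = reference)
#' @export
build_allele_matrix <- function(bubbles, walks) {
  stopifnot(is.list(walks), length(walks) >= 1L, !is.null(names(walks)))
  iv <- bubble_intervals(bubbles)
  keys <- site_key(iv$chrom, iv$start, iv$end)
  if (anyDuplicated(keys)) stop("duplicate bubble site keys")
  assemblies <- names(walks)
  ns <- length(keys)
  entries <- matrix(NA_integer_, nrow = ns, ncol = length(assemblies),
                    dimnames = list(keys, assemblies))
  allele_paths <- lapply(bubbles, function(b) {
    if (b$no_ref) character() else b$allele_paths[b$ref_allele]
  })
  src <- iv$source
  snk <- iv$sink
  n_unmatched <- 0L
  n_ambiguous <- 0L
  for (a in seq_along(assemblies)) {
    w <- walks[[a]]
    if (nrow(w) == 0L) next
    wkey <- site_key(w$chrom, w$start, w$end)
    row <- match(wkey, keys)
    n_unmatched <- n_unmatched + sum(is.na(row))
    w <- w[!is.na(row), , drop = FALSE]
    row <- row[!is.na(row)]
    dup_sites <- unique(row[duplicated(row)])
    if (length(dup_sites)) {
      n_ambiguous <- n_ambiguous + length(dup_sites)
      keep <- !(row %in% dup_sites)
      w <- w[keep, , drop = FALSE]
      row <- row[keep]
    }
    for (k in seq_along(row)) {
      p <- w$path[k]
      if (is.na(p)) next
      i <- row[k]
      steps <- parse_path(p)
      if (nrow(steps) < 2L || steps$seg[1L] != src[i] ||
          steps$seg[nrow(steps)] != snk[i]) {
        stop("walk path endpoints do not match bubble source/sink: ",
             assemblies[a], " ", keys[i], " path ", p)
      }
      j <- match(p, allele_paths[[i]])
      if (is.na(j)) {
        allele_paths[[i]] <- c(allele_paths[[i]], p)
        j <- length(allele_paths[[i]])
      }
      entries[i, a] <- j - 1L
    }
  }
  if (n_unmatched > 0L) {
    warning(n_unmatched, " walk record(s) matched no bubble and were ignored")
  }
  if (n_ambiguous > 0L) {
    warning(n_ambiguous, " ambiguous site/assembly pair(s) treated as MISSING")
  }
  structure(list(
    sites = data.frame(chrom = iv$chrom, start = iv$start, end = iv$end,
                       key = keys),
    assemblies = assemblies,
    entries = entries,
    allele_paths = allele_paths
  ), class = "allele_matrix")
}

#' @export
print.allele_matrix <- function(x, ...) {
  cat(sprintf("allele_matrix: %d sites x %d assemblies (%d MISSING entries)\n",
              nrow(x$entries), ncol(x$entries), sum(is.na(x$entries))))
  invisible(x)
}

#' Drop sites with incomplete haplotype information
#'
#' Removes every matrix row (bubble) where at least one assembly's walk is
#' MISSING, keeping only bubbles with complete haplotype path information
#' across all assemblies. Idempotent.
#'
#' @param matrix an `allele_matrix`
#' @return list with `matrix` (filtered) and `n_removed`
#' @export
filter_complete <- function(matrix) {
  stopifnot(inherits(matrix, "allele_matrix"))
  bad <- rowSums(is.na(matrix$entries)) > 0L
  out <- matrix
  out$sites <- matrix$sites[!bad, , drop = FALSE]
  out$entries <- matrix$entries[!bad, , drop = FALSE]
  out$allele_paths <- matrix$allele_paths[!bad]
  list(matrix = out, n_removed = sum(bad))
}

#' Write an allele matrix as TSV
#'
#' One row per site: the site key then one 0-based allele-index column per
#' assembly, `"."` for MISSING.
#' @param matrix an `allele_matrix`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_allele_matrix <- function(matrix, path) {
  ent <- matrix$entries
  body <- apply(ent, 1L, function(r) {
    paste(ifelse(is.na(r), ".", as.character(r)), collapse = "\t")
  })
  header <- paste(c("site", matrix$assemblies), collapse = "\t")
  writeLines(c(header, paste(rownames(ent), body, sep = "\t")), path)
  invisible(path)
}
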