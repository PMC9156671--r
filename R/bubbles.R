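## Superbubble detection on the oriented-copy digraph of a pangenome graph,
## bubble summarisation, and SV typing of bubble alleles.

## Build the oriented digraph: each segment contributes a "+" and "-" copy;
## every link (a,ao)->(b,bo) induces the reverse-complement edge
## (b,!bo)->(a,!ao). Returns adjacency/parent lists over integer node ids.
oriented_digraph <- function(graph) {
  s <- graph$segments
  l <- graph$links
  nodes <- c(node_label(s$id, "+"), node_label(s$id, "-"))
  idx <- stats::setNames(seq_along(nodes), nodes)
  from <- c(node_label(l$from, l$from_orient),
            node_label(l$to, flip_orient(l$to_orient)))
  to <- c(node_label(l$to, l$to_orient),
          node_label(l$from, flip_orient(l$from_orient)))
  e <- unique(data.frame(from = idx[from], to = idx[to]))
  out <- vector("list", length(nodes))
  inn <- vector("list", length(nodes))
  if (nrow(e)) {
    sp <- split(e$to, e$from)
    out[as.integer(names(sp))] <- sp
    sp <- split(e$from, e$to)
    inn[as.integer(names(sp))] <- sp
  }
  list(nodes = nodes, idx = idx, out = out, inn = inn,
       seg = rep(s$id, 2L), orient = rep(c("+", "-"), each = nrow(s)),
       length = rep(s$length, 2L), sr = rep(s$sr, 2L))
}

## Minimal superbubble search from source node `s` (integer id) by frontier
## expansion: nodes are visited only once all their parents are visited, so
## the interior is topologically ordered and acyclic by construction. Returns
## list(sink, interior) or NULL when no superbubble starts at `s`.
find_superbubble_from <- function(dg, s) {
  n_out <- dg$out
  n_in <- dg$inn
  stack <- c(s)
  visited <- integer(0)
  seen <- integer(0)
  while (length(stack)) {
    v <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    visited <- c(visited, v)
    seen <- setdiff(seen, v)
    kids <- n_out[[v]]
    if (is.null(kids) || length(kids) == 0L) return(NULL)  # tip
    for (u in kids) {
      if (u == s) return(NULL)  # cycle through the source
      if (!(u %in% seen) && !(u %in% visited)) seen <- c(seen, u)
      if (all(n_in[[u]] %in% c(visited, s)) && !(u %in% visited) &&
          !(u %in% stack)) {
        stack <- c(stack, u)
      }
    }
    if (length(stack) == 1L && length(seen) == 1L && stack[1L] == seen[1L]) {
      t <- stack[1L]
      if (t %in% n_out[[t]]) return(NULL)
      if (s %in% n_out[[t]]) return(NULL)  # would re-enter the source
      interior <- setdiff(visited, s)
      return(list(sink = t, interior = interior))
    }
  }
  NULL
}

## Enumerate all source->sink paths inside the (acyclic) bubble subgraph.
## Returns a list of integer node vectors including the endpoints.
enumerate_allele_paths <- function(dg, s, t, interior, max_paths = 4096L) {
  allowed <- c(s, interior, t)
  paths <- list()
  walk <- function(v, acc) {
    if (length(paths) >= max_paths) stop("too many allele paths in one bubble")
    if (v == t) {
      paths[[length(paths) + 1L]] <<- c(acc, v)
      return(invisible(NULL))
    }
    for (u in dg$out[[v]]) {
      if (u %in% allowed && !(u %in% acc)) walk(u, c(acc, v))
    }
    invisible(NULL)
  }
  walk(s, integer(0))
  paths
}

#' Detect minimal superbubbles anchored on the reference backbone
#'
#' Enumerates minimal superbubbles of the oriented-copy digraph whose source
#' and sink are forward-oriented rank-0 (reference backbone) segments and
#' which contain at least two distinct source-to-sink paths (i.e. represent a
#' variant site). A superbubble is a single-entry single-exit subgraph in
#' which every path from the entry reaches the exit and interior nodes are
#' reachable only between them; minimality takes the nearest valid exit per
#' entry. Nested bubbles are suppressed: only outermost sites are reported,
#' so interiors of reported bubbles are disjoint.
#'
#' @param graph a [pangenome_graph()]
#' @return list of `bubble` objects sorted by (chrom, ref_start); each has
#'   fields `chrom`, `ref_start`, `ref_end` (backbone projection of the
#'   interior), `source`, `sink`, `alleles` (list of oriented step
#'   data.frames), `allele_paths` (path strings), `allele_lengths` (interior
#'   bp per allele), `interior` (segment ids), `ref_allele` (index of the
#'   reference path or NA), `no_ref` flag
#' @export
detect_superbubbles <- function(graph) {
  validate_graph(graph)
  s <- graph$segments
  if (!any(s$sr == 0L, na.rm = TRUE)) stop("no reference backbone")
  dg <- oriented_digraph(graph)
  n <- nrow(s)
  seg_row <- stats::setNames(seq_len(n), s$id)
  is_src_candidate <- function(v) {
    dg$orient[v] == "+" && !is.na(dg$sr[v]) && dg$sr[v] == 0L &&
      length(dg$out[[v]]) >= 1L
  }
  found <- list()
  for (v in seq_len(n)) {  # "+" copies occupy 1..n
    if (!is_src_candidate(v)) next
    sb <- find_superbubble_from(dg, v)
    if (is.null(sb)) next
    t <- sb$sink
    if (dg$orient[t] != "+" || is.na(dg$sr[t]) || dg$sr[t] != 0L) next
    paths <- enumerate_allele_paths(dg, v, t, sb$interior)
    if (length(paths) < 2L) next
    found[[length(found) + 1L]] <- list(src = v, snk = t,
                                        interior = sb$interior, paths = paths)
  }
  if (!length(found)) return(list())
  bubbles <- lapply(found, function(b) {
    src_seg <- s[seg_row[dg$seg[b$src]], ]
    snk_seg <- s[seg_row[dg$seg[b$snk]], ]
    interior_lengths <- vapply(b$paths, function(p) {
      inner <- p[-c(1L, length(p))]
      if (length(inner)) sum(dg$length[inner]) else 0L
    }, numeric(1))
    strs <- vapply(b$paths, function(p) {
      path_string(dg$seg[p], dg$orient[p])
    }, "")
    ## reference allele: interior entirely forward rank-0, or the direct edge
    is_ref <- vapply(b$paths, function(p) {
      inner <- p[-c(1L, length(p))]
      if (!length(inner)) return(src_seg$so + src_seg$length == snk_seg$so)
      all(dg$orient[inner] == "+") && all(dg$sr[inner] == 0L, na.rm = TRUE) &&
        !anyNA(dg$sr[inner])
    }, TRUE)
    ord <- radix_order(!is_ref, strs)
    no_ref <- !any(is_ref)
    structure(list(
      chrom = src_seg$sn,
      ref_start = src_seg$so + src_seg$length,
      ref_end = snk_seg$so,
      source = src_seg$id,
      sink = snk_seg$id,
      alleles = lapply(b$paths[ord], function(p) {
        data.frame(seg = dg$seg[p], orient = dg$orient[p])
      }),
      allele_paths = strs[ord],
      allele_lengths = interior_lengths[ord],
      interior = unique(dg$seg[b$interior]),
      ref_allele = if (no_ref) NA_integer_ else 1L,
      no_ref = no_ref,
      span_start = src_seg$so,
      span_end = snk_seg$so + snk_seg$length
    ), class = "bubble")
  })
  ## outermost filter: drop bubbles whose backbone span is strictly contained
  ## in another bubble's span on the same chromosome
  chroms <- vapply(bubbles, `[[`, "", "chrom")
  sp_s <- vapply(bubbles, `[[`, numeric(1), "span_start")
  sp_e <- vapply(bubbles, `[[`, numeric(1), "span_end")
  keep <- rep(TRUE, length(bubbles))
  for (i in seq_along(bubbles)) {
    contained <- which(chroms == chroms[i] & seq_along(bubbles) != i &
                         sp_s <= sp_s[i] & sp_e >= sp_e[i] &
                         (sp_s < sp_s[i] | sp_e > sp_e[i]))
    if (length(contained)) keep[i] <- FALSE
  }
  bubbles <- bubbles[keep]
  ord <- radix_order(vapply(bubbles, `[[`, "", "chrom"),
                     vapply(bubbles, `[[`, numeric(1), "ref_start"))
  bubbles[ord]
}

#' @export
print.bubble <- function(x, ...) {
  cat(sprintf("bubble %s:%d-%d [%s..%s] %d allele(s), max interior %d bp%s\n",
              x$chrom, x$ref_start, x$ref_end, x$source, x$sink,
              length(x$alleles), max(x$allele_lengths),
              if (x$no_ref) " (no-ref)" else ""))
  invisible(x)
}

#' Bubble intervals as a data.frame
#'
#' Convenience projection of a bubble list to (chrom, start, end, source,
#' sink, n_alleles, max_len), the BED dialect used on disk.
#' @param bubbles list of bubbles from [detect_superbubbles()]
#' @return data.frame
#' @export
bubble_intervals <- function(bubbles) {
  if (!length(bubbles)) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), source = character(),
                      sink = character(), n_alleles = integer(),
                      max_len = numeric()))
  }
  data.frame(
    chrom = vapply(bubbles, `[[`, "", "chrom"),
    start = vapply(bubbles, function(b) as.integer(b$ref_start), 1L),
    end = vapply(bubbles, function(b) as.integer(b$ref_end), 1L),
    source = vapply(bubbles, `[[`, "", "source"),
    sink = vapply(bubbles, `[[`, "", "sink"),
    n_alleles = vapply(bubbles, function(b) length(b$alleles), 1L),
    max_len = vapply(bubbles, function(b) max(b$allele_lengths), numeric(1))
  )
}

#' Summarize a bubble set
#'
#' @param bubbles list of bubbles from [detect_superbubbles()]
#' @param graph the graph they were detected on
#' @param large_threshold bubbles whose largest allele exceeds this many bp
#'   count as large (default 1000)
#' @return list with `n_bubbles`, `n_large`, `mean_bubble_size` (mean over
#'   bubbles of the maximum allele length), `nonref_bases`, `nonref_nodes`
#' @export
summarize_bubbles <- function(bubbles, graph, large_threshold = 1000) {
  s <- graph$segments
  max_len <- vapply(bubbles, function(b) max(b$allele_lengths), numeric(1))
  structure(list(
    n_bubbles = length(bubbles),
    n_large = sum(max_len > large_threshold),
    mean_bubble_size = if (length(bubbles)) mean(max_len) else 0,
    nonref_bases = sum(s$length[s$sr > 0L], na.rm = TRUE),
    nonref_nodes = sum(s$sr > 0L, na.rm = TRUE)
  ), class = "bubble_summary")
}

#' @export
print.bubble_summary <- function(x, ...) {
  cat(sprintf(paste0("bubbles: %d (%d large), mean size %.1f bp; ",
                     "non-reference: %d bp across %d nodes\n"),
              x$n_bubbles, x$n_large, x$mean_bubble_size,
              x$nonref_bases, x$nonref_nodes))
  invisible(x)
}

#' Type the non-reference alleles of a bubble as SVs
#'
#' Each non-reference allele yields one SV record typed by the 50 bp
#' divergence threshold: INS when the reference allele is short (< 50 bp) and
#' the alternate long (>= 50 bp), DEL in the mirrored case, COMPLEX
#' otherwise. Bubbles without a reference allele are typed COMPLEX and
#' flagged `no-ref`. Carriers are filled in later from the allele matrix.
#'
#' @param bubble a `bubble`
#' @param min_len SV length threshold in bp (default 50)
#' @return data.frame of SV records: `chrom`, `start`, `end`, `ref_len`,
#'   `alt_len`, `svtype`, `allele` (index into the bubble's allele list),
#'   `flag`
#' @export
classify_sv <- function(bubble, min_len = 50) {
  stopifnot(length(bubble$alleles) >= 2L)
  if (bubble$no_ref) {
    alt_idx <- seq_along(bubble$alleles)
    return(data.frame(chrom = bubble$chrom,
                      start = as.integer(bubble$ref_start),
                      end = as.integer(bubble$ref_end),
                      ref_len = as.integer(bubble$ref_end - bubble$ref_start),
                      alt_len = as.integer(bubble$allele_lengths[alt_idx]),
                      svtype = "COMPLEX", allele = alt_idx, flag = "no-ref"))
  }
  ref_len <- bubble$ref_end - bubble$ref_start
  alt_idx <- setdiff(seq_along(bubble$alleles), bubble$ref_allele)
  alt_len <- bubble$allele_lengths[alt_idx]
  svtype <- ifelse(ref_len < min_len & alt_len >= min_len, "INS",
                   ifelse(alt_len < min_len & ref_len >= min_len, "DEL",
                          "COMPLEX"))
  data.frame(chrom = bubble$chrom, start = as.integer(bubble$ref_start),
             end = as.integer(bubble$ref_end),
             ref_len = as.integer(ref_len), alt_len = as.integer(alt_len),
             svtype = svtype, allele = alt_idx, flag = "")
}

#' Call an SV catalogue with carriers from bubbles and an allele matrix
#'
#' Combines [classify_sv()] on every bubble with carrier sets read off the
#' allele matrix: the carriers of an SV are the assemblies whose walk took
#' the corresponding non-reference allele.
#'
#' @param bubbles list of bubbles
#' @param matrix an `allele_matrix` built on the same bubbles
#' @return data.frame of SV records with a `carriers` column
#'   (comma-separated assembly labels), sorted by (chrom, start)
#' @export
call_svs <- function(bubbles, matrix) {
  recs <- list()
  keys <- matrix$sites$key
  for (b in bubbles) {
    cs <- classify_sv(b)
    row <- match(site_key(b$chrom, b$ref_start, b$ref_end), keys)
    cs$carriers <- ""
    if (!is.na(row)) {
      ent <- matrix$entries[row, ]
      paths <- matrix$allele_paths[[row]]
      for (k in seq_len(nrow(cs))) {
        ap <- b$allele_paths[cs$allele[k]]
        j <- match(ap, paths)
        if (!is.na(j)) {
          cs$carriers[k] <- paste(matrix$assemblies[!is.na(ent) & ent == j - 1L],
                                  collapse = ",")
        }
      }
    }
    recs[[length(recs) + 1L]] <- cs
  }
  out <- do.call(rbind, recs)
  out[radix_order(out$chrom, out$start, out$alt_len), , drop = FALSE]
}
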