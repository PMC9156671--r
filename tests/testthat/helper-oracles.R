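## Independent brute-force oracles and random-input generators shared by the
## test files. These deliberately re-derive results by enumeration rather
## than calling the package's own algorithms.

## ---- random graphs for the superbubble oracle ----

## Random small pangenome graph: a rank-0 backbone chain plus extra rank-1
## nodes wired with random (sometimes reverse-oriented, sometimes cyclic)
## links. Produces diamonds, nested bubbles, tips and dead ends.
random_test_graph <- function(n_max = 12L) {
  nb <- sample(2:5, 1L)
  n_extra <- sample(0:(n_max - nb), 1L)
  lens <- sample(50:500, nb + n_extra, replace = TRUE)
  ids <- sprintf("s%02d", seq_len(nb + n_extra))
  so <- cumsum(c(0L, lens[seq_len(nb - 1L)]))
  segments <- data.frame(
    id = ids, length = lens, sequence = NA_character_,
    sn = c(rep("chr1", nb), rep("alt", n_extra)),
    so = c(so, rep(0L, n_extra)),
    sr = c(rep(0L, nb), rep(1L, n_extra)))
  links <- data.frame(from = ids[seq_len(nb - 1L)], from_orient = "+",
                      to = ids[1L + seq_len(nb - 1L)], to_orient = "+")
  if (n_extra > 0L) {
    for (k in seq_len(n_extra)) {
      e <- ids[nb + k]
      a <- sample(ids[-match(e, ids)], 1L)
      b <- sample(ids[-match(e, ids)], 1L)
      links <- rbind(links,
                     data.frame(from = a, from_orient = "+", to = e,
                                to_orient = "+"),
                     data.frame(from = e, from_orient = "+", to = b,
                                to_orient = "+"))
    }
  }
  for (k in seq_len(sample(0:3, 1L))) {
    links <- rbind(links, data.frame(
      from = sample(ids, 1L),
      from_orient = sample(c("+", "-"), 1L, prob = c(0.9, 0.1)),
      to = sample(ids, 1L),
      to_orient = sample(c("+", "-"), 1L, prob = c(0.9, 0.1))))
  }
  pangenome_graph(segments, unique(links), validate = FALSE)
}

## ---- exhaustive superbubble oracle ----

## Oriented digraph built independently of the package internals: node
## labels "id+"/"id-", edge list with reverse-complement mirror edges.
oracle_digraph <- function(graph) {
  s <- graph$segments
  l <- graph$links
  flip <- function(o) ifelse(o == "+", "-", "+")
  edges <- unique(rbind(
    data.frame(from = paste0(l$from, l$from_orient),
               to = paste0(l$to, l$to_orient)),
    data.frame(from = paste0(l$to, flip(l$to_orient)),
               to = paste0(l$from, flip(l$from_orient)))))
  nodes <- c(paste0(s$id, "+"), paste0(s$id, "-"))
  list(nodes = nodes, edges = edges,
       out = function(v) edges$to[edges$from == v],
       inn = function(v) edges$from[edges$to == v])
}

## Nodes reachable from `from` without passing through `block`
## (the blocked node itself is included when reached, not expanded).
oracle_reach <- function(dg, from, block, reverse = FALSE) {
  step <- if (reverse) dg$inn else dg$out
  seen <- character()
  frontier <- from
  while (length(frontier)) {
    v <- frontier[1L]
    frontier <- frontier[-1L]
    if (v %in% seen) next
    seen <- c(seen, v)
    if (v != from && v == block) next
    frontier <- c(frontier, step(v))
  }
  seen
}

## All simple directed paths from s to t restricted to `allowed` nodes,
## by exhaustive enumeration.
oracle_paths <- function(dg, s, t, allowed) {
  paths <- list()
  walk <- function(v, acc) {
    if (v == t) {
      paths[[length(paths) + 1L]] <<- c(acc, v)
      return(invisible(NULL))
    }
    for (u in dg$out(v)) {
      if (u %in% allowed && !(u %in% acc)) walk(u, c(acc, v))
    }
  }
  walk(s, character())
  paths
}

oracle_acyclic <- function(dg, nodes) {
  ## Kahn's algorithm on the induced subgraph
  e <- dg$edges[dg$edges$from %in% nodes & dg$edges$to %in% nodes, ]
  indeg <- table(factor(e$to, levels = nodes))
  active <- nodes
  repeat {
    zero <- active[indeg[active] == 0L]
    if (!length(zero)) break
    active <- setdiff(active, zero)
    drop <- e$from %in% zero
    for (v in e$to[drop]) indeg[v] <- indeg[v] - 1L
    e <- e[!drop, ]
  }
  length(active) == 0L
}

## Tests the superbubble conditions for the ordered node pair (s, t):
## forward/backward reachability sets agree, the induced subgraph is
## acyclic, and s/t are not mutually re-entrant.
oracle_is_superbubble <- function(dg, s, t) {
  if (s == t) return(NULL)
  fwd <- oracle_reach(dg, s, t)
  if (!(t %in% fwd)) return(NULL)
  bwd <- oracle_reach(dg, t, s, reverse = TRUE)
  if (!setequal(fwd, bwd)) return(NULL)
  if (s %in% dg$out(t)) return(NULL)
  if (!oracle_acyclic(dg, fwd)) return(NULL)
  fwd
}

## Full oracle: for every rank-0 forward source, take the valid sink with
## the smallest superbubble (node count, ties by node label); keep bubbles
## with >= 2 distinct allele paths; drop bubbles strictly contained in
## another's backbone span; sort by (chrom, ref_start). Returns a data.frame
## of (source, sink, n_alleles) plus the sorted allele path strings.
oracle_superbubbles <- function(graph) {
  s <- graph$segments
  dg <- oracle_digraph(graph)
  r0 <- s$id[s$sr == 0L]
  sources <- paste0(r0, "+")
  found <- list()
  for (src in sources) {
    best <- NULL
    for (t in dg$nodes) {
      u <- oracle_is_superbubble(dg, src, t)
      if (is.null(u)) next
      if (is.null(best) || length(u) < length(best$u) ||
          (length(u) == length(best$u) && t < best$t)) {
        best <- list(t = t, u = u)
      }
    }
    if (is.null(best)) next
    t <- best$t
    tseg <- sub("[+-]$", "", t)
    if (!grepl("\\+$", t) || !(tseg %in% r0)) next
    paths <- oracle_paths(dg, src, t, best$u)
    if (length(paths) < 2L) next
    sseg <- sub("[+-]$", "", src)
    strs <- vapply(paths, function(p) {
      paste0(ifelse(grepl("\\+$", p), ">", "<"), sub("[+-]$", "", p),
             collapse = "")
    }, "")
    found[[length(found) + 1L]] <- list(
      source = sseg, sink = tseg,
      chrom = s$sn[s$id == sseg],
      span_start = s$so[s$id == sseg],
      span_end = s$so[s$id == tseg] + s$length[s$id == tseg],
      ref_start = s$so[s$id == sseg] + s$length[s$id == sseg],
      alleles = sort(strs))
  }
  if (!length(found)) {
    return(data.frame(source = character(), sink = character(),
                      chrom = character(), ref_start = numeric(),
                      alleles = character()))
  }
  keep <- rep(TRUE, length(found))
  for (i in seq_along(found)) {
    for (j in seq_along(found)) {
      if (i == j) next
      if (found[[j]]$chrom == found[[i]]$chrom &&
          found[[j]]$span_start <= found[[i]]$span_start &&
          found[[j]]$span_end >= found[[i]]$span_end &&
          (found[[j]]$span_start < found[[i]]$span_start ||
             found[[j]]$span_end > found[[i]]$span_end)) {
        keep[i] <- FALSE
      }
    }
  }
  found <- found[keep]
  out <- data.frame(
    source = vapply(found, `[[`, "", "source"),
    sink = vapply(found, `[[`, "", "sink"),
    chrom = vapply(found, `[[`, "", "chrom"),
    ref_start = vapply(found, `[[`, numeric(1), "ref_start"),
    alleles = vapply(found, function(b) paste(b$alleles, collapse = "|"), ""))
  out[order(out$chrom, out$ref_start, method = "radix"), , drop = FALSE]
}

## Summary of detector output in the oracle's comparable form.
detector_summary <- function(bubbles) {
  if (!length(bubbles)) {
    return(data.frame(source = character(), sink = character(),
                      chrom = character(), ref_start = numeric(),
                      alleles = character()))
  }
  data.frame(
    source = vapply(bubbles, `[[`, "", "source"),
    sink = vapply(bubbles, `[[`, "", "sink"),
    chrom = vapply(bubbles, `[[`, "", "chrom"),
    ref_start = vapply(bubbles, function(b) as.numeric(b$ref_start),
                       numeric(1)),
    alleles = vapply(bubbles, function(b) {
      paste(sort(b$allele_paths), collapse = "|")
    }, ""))
}

## ---- misc brute-force oracles ----

## Triple-loop discordance
brute_discordance <- function(ent) {
  k <- ncol(ent)
  D <- matrix(0L, k, k, dimnames = dimnames(ent)[c(2, 2)])
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (i == j) next
      for (r in seq_len(nrow(ent))) {
        if (!is.na(ent[r, i]) && !is.na(ent[r, j]) &&
            ent[r, i] != ent[r, j]) {
          D[i, j] <- D[i, j] + 1L
        }
      }
    }
  }
  D
}

## Maximum bipartite matching cardinality between two SV sets under the
## same compatibility predicate as match_sv_sets, via igraph.
brute_max_matching <- function(test, truth, config) {
  lt <- pmax(test$ref_len, test$alt_len)
  lr <- pmax(truth$ref_len, truth$alt_len)
  compat <- list()
  for (i in seq_len(nrow(test))) {
    for (j in seq_len(nrow(truth))) {
      ratio <- min(lt[i], lr[j]) / max(lt[i], lr[j])
      if (max(lt[i], lr[j]) == 0) ratio <- 1
      if (test$chrom[i] == truth$chrom[j] &&
          test$svtype[i] == truth$svtype[j] &&
          abs(test$start[i] - truth$start[j]) <= config$breakpoint_tolerance &&
          ratio >= config$length_ratio_min) {
        compat[[length(compat) + 1L]] <- c(i, nrow(test) + j)
      }
    }
  }
  if (!length(compat)) return(0L)
  g <- igraph::make_empty_graph(nrow(test) + nrow(truth), directed = FALSE)
  g <- igraph::add_edges(g, t(do.call(rbind, compat)))
  igraph::V(g)$type <- c(rep(FALSE, nrow(test)), rep(TRUE, nrow(truth)))
  igraph::max_bipartite_match(g)$matching_size
}

## Random sorted SV catalogue on one chromosome.
random_sv_set <- function(n, chrom_len = 1e5) {
  start <- sort(sample.int(chrom_len - 2000L, n))
  type <- sample(c("INS", "DEL"), n, replace = TRUE)
  len <- sample(50:1500, n, replace = TRUE)
  data.frame(chrom = "chr1", start = start,
             end = start + ifelse(type == "DEL", len, 10L),
             ref_len = ifelse(type == "DEL", len, 10L),
             alt_len = ifelse(type == "DEL", 0L, len), svtype = type)
}
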