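## Readers and writers for every on-disk format the pipeline touches.
## One documented dialect per format; all coordinates 0-based half-open
## internally. GFF3 (1-based closed) is converted on read.

#' Construct a pangenome graph object
#'
#' A reference-backed pangenome graph in the rGFA sense: segments carry an
#' origin sample (`sn`), origin offset (`so`) and rank (`sr`; 0 = reference
#' backbone), and links are oriented segment adjacencies. Rank-0 segments of
#' one chromosome must tile it contiguously.
#'
#' @param segments data.frame with columns `id`, `length`, `sequence`
#'   (NA allowed), `sn`, `so`, `sr`
#' @param links data.frame with columns `from`, `from_orient`, `to`,
#'   `to_orient`
#' @param validate check invariants (default TRUE)
#' @return object of class `pangenome_graph`
#' @export
pangenome_graph <- function(segments, links, validate = TRUE) {
  segments <- as.data.frame(segments)
  links <- as.data.frame(links)
  need_s <- c("id", "length", "sequence", "sn", "so", "sr")
  need_l <- c("from", "from_orient", "to", "to_orient")
  if (nrow(segments) == 0L) {
    segments <- data.frame(id = character(), length = integer(),
                           sequence = character(), sn = character(),
                           so = integer(), sr = integer())
  }
  if (nrow(links) == 0L) {
    links <- data.frame(from = character(), from_orient = character(),
                        to = character(), to_orient = character())
  }
  stopifnot(all(need_s %in% names(segments)), all(need_l %in% names(links)))
  g <- structure(list(segments = segments[need_s], links = links[need_l]),
                 class = "pangenome_graph")
  if (validate) validate_graph(g)
  g
}

#' Validate pangenome graph invariants
#'
#' Checks segment-id uniqueness, link endpoints, sequence/length agreement
#' and contiguous tiling of each chromosome by its rank-0 segments.
#' @param graph a `pangenome_graph`
#' @return the graph, invisibly; errors on violation
#' @export
validate_graph <- function(graph) {
  s <- graph$segments
  l <- graph$links
  if (anyDuplicated(s$id)) {
    stop("duplicate segment id(s): ",
         paste(unique(s$id[duplicated(s$id)]), collapse = ", "))
  }
  bad <- setdiff(c(l$from, l$to), s$id)
  if (length(bad)) stop("link endpoint names unknown segment(s): ",
                        paste(unique(bad), collapse = ", "))
  if (!all(l$from_orient %in% c("+", "-")) || !all(l$to_orient %in% c("+", "-"))) {
    stop("link orientations must be '+' or '-'")
  }
  has_seq <- !is.na(s$sequence) & s$sequence != "*"
  if (any(has_seq & nchar(s$sequence) != s$length)) {
    stop("segment sequence length disagrees with length field")
  }
  r0 <- s[!is.na(s$sr) & s$sr == 0L, , drop = FALSE]
  for (chrom in unique(r0$sn)) {
    cc <- r0[r0$sn == chrom, , drop = FALSE]
    cc <- cc[order(cc$so), , drop = FALSE]
    if (nrow(cc) > 1L) {
      expected <- cc$so[-nrow(cc)] + cc$length[-nrow(cc)]
      if (!all(cc$so[-1L] == expected)) {
        stop("rank-0 segments do not tile chromosome ", chrom, " contiguously")
      }
    }
  }
  invisible(graph)
}

#' @export
print.pangenome_graph <- function(x, ...) {
  s <- x$segments
  cat(sprintf("pangenome_graph: %d segments (%d rank-0), %d links, %d bp non-reference\n",
              nrow(s), sum(s$sr == 0L, na.rm = TRUE), nrow(x$links),
              sum(s$length[s$sr > 0L], na.rm = TRUE)))
  invisible(x)
}

## Parse one "TAG:TYPE:value" vector into a named character vector.
parse_gfa_tags <- function(fields) {
  if (length(fields) == 0L) return(character())
  m <- regmatches(fields, regexec("^([A-Za-z][A-Za-z0-9]):([AifZHB]):(.*)$", fields))
  bad <- vapply(m, length, 1L) != 4L
  if (any(bad)) stop("malformed GFA tag: ", fields[bad][1L])
  stats::setNames(vapply(m, `[`, "", 4L), vapply(m, `[`, "", 2L))
}

#' Read an rGFA/GFA1 pangenome graph
#'
#' Accepts GFA1 `S` and `L` records; `S` records may carry rGFA `SN`/`SO`/`SR`
#' tags and `LN` when the sequence is `*`. Segments lacking an `SR` tag
#' default to rank 1 (non-reference) with a warning. Header (`H`) and comment
#' lines are ignored.
#'
#' @param path file path
#' @return a [pangenome_graph()]
#' @export
read_rgfa <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  keep <- !grepl("^\\s*$", lines) & !startsWith(lines, "#")
  idx <- which(keep)
  seg_rows <- list()
  link_rows <- list()
  missing_sr <- 0L
  for (i in idx) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    rec <- f[1]
    if (rec == "H") next
    if (rec == "S") {
      if (length(f) < 3L) stop("malformed S record at line ", i)
      tags <- parse_gfa_tags(f[-(1:3)])
      seq <- f[3]
      len <- if (seq != "*") nchar(seq) else if ("LN" %in% names(tags)) {
        as.integer(tags[["LN"]])
      } else stop("S record without sequence or LN tag at line ", i)
      if (!is.na(seq) && seq != "*" && "LN" %in% names(tags) &&
          as.integer(tags[["LN"]]) != len) {
        stop("LN tag disagrees with sequence length at line ", i)
      }
      sr <- if ("SR" %in% names(tags)) as.integer(tags[["SR"]]) else {
        missing_sr <- missing_sr + 1L
        1L
      }
      seg_rows[[length(seg_rows) + 1L]] <- data.frame(
        id = f[2], length = len,
        sequence = if (seq == "*") NA_character_ else seq,
        sn = if ("SN" %in% names(tags)) tags[["SN"]] else NA_character_,
        so = if ("SO" %in% names(tags)) as.integer(tags[["SO"]]) else NA_integer_,
        sr = sr)
    } else if (rec == "L") {
      if (length(f) < 5L) stop("malformed L record at line ", i)
      link_rows[[length(link_rows) + 1L]] <- data.frame(
        from = f[2], from_orient = f[3], to = f[4], to_orient = f[5])
    } else {
      stop("unsupported record type '", rec, "' at line ", i)
    }
  }
  if (missing_sr > 0L) {
    warning(missing_sr, " segment(s) lack an SR tag; defaulting to rank 1")
  }
  segments <- if (length(seg_rows)) do.call(rbind, seg_rows) else
    data.frame(id = character(), length = integer(), sequence = character(),
               sn = character(), so = integer(), sr = integer())
  links <- if (length(link_rows)) do.call(rbind, link_rows) else
    data.frame(from = character(), from_orient = character(),
               to = character(), to_orient = character())
  links <- unique(links)
  pangenome_graph(segments, links)
}

#' Write a pangenome graph as rGFA
#'
#' Deterministic record order: segments sorted by id, links lexicographically.
#' `SN`/`SO`/`SR` tags are emitted whenever present so that
#' `read_rgfa(write_rgfa(g))` round-trips exactly.
#'
#' @param graph a [pangenome_graph()]
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_rgfa <- function(graph, path) {
  validate_graph(graph)
  s <- graph$segments
  l <- graph$links
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("H\tVN:Z:1.0", con)
  if (nrow(s)) {
    s <- s[radix_order(s$id), , drop = FALSE]
    lines <- sprintf("S\t%s\t%s\tLN:i:%d", s$id,
                     ifelse(is.na(s$sequence), "*", s$sequence), s$length)
    lines <- paste0(lines,
                    ifelse(is.na(s$sn), "", sprintf("\tSN:Z:%s", s$sn)),
                    ifelse(is.na(s$so), "", sprintf("\tSO:i:%d", s$so)),
                    ifelse(is.na(s$sr), "", sprintf("\tSR:i:%d", s$sr)))
    writeLines(lines, con)
  }
  if (nrow(l)) {
    l <- l[radix_order(l$from, l$from_orient, l$to, l$to_orient), , drop = FALSE]
    writeLines(sprintf("L\t%s\t%s\t%s\t%s\t0M",
                       l$from, l$from_orient, l$to, l$to_orient), con)
  }
  invisible(path)
}

#' Read per-assembly haplotype walks
#'
#' Tab-separated bubble-call dialect: `chrom`, `start`, `end` (0-based
#' half-open on the backbone), `source`, `sink` segment ids, and a
#' `>`/`<`-prefixed path string (`"."` = missing walk). With
#' `permissive = TRUE` extra trailing columns (as real bubble callers append)
#' are ignored.
#'
#' @param path file path
#' @param assembly assembly label; defaults to the file name without extension
#' @param permissive ignore extra trailing columns
#' @return data.frame of walk records with columns `assembly`, `chrom`,
#'   `start`, `end`, `source`, `sink`, `path` (NA = missing)
#' @export
read_walks <- function(path, assembly = NULL,
                       permissive = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(assembly)) {
    assembly <- sub("\\.[^.]*$", "", basename(path))
  }
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*$", lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) {
    return(data.frame(assembly = character(), chrom = character(),
                      start = integer(), end = integer(), source = character(),
                      sink = character(), path = character()))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- vapply(parts, length, 1L)
  if (permissive) {
    if (any(nf < 6L)) stop("line ", which(nf < 6L)[1L], ": expected >= 6 columns")
    parts <- lapply(parts, `[`, 1:6)
  } else if (any(nf != 6L)) {
    stop("line ", which(nf != 6L)[1L], ": expected 6 columns, found ",
         nf[nf != 6L][1L])
  }
  m <- do.call(rbind, parts)
  out <- data.frame(assembly = assembly, chrom = m[, 1],
                    start = as.integer(m[, 2]), end = as.integer(m[, 3]),
                    source = m[, 4], sink = m[, 5],
                    path = ifelse(m[, 6] == ".", NA_character_, m[, 6]))
  if (anyNA(out$start) || anyNA(out$end)) stop("non-numeric coordinates")
  bad <- which(out$end <= out$start)
  if (length(bad)) stop("line ", bad[1L], ": end <= start")
  ok_path <- is.na(out$path) | grepl("^([><][^><]+)+$", out$path)
  if (!all(ok_path)) stop("line ", which(!ok_path)[1L], ": malformed path string")
  out
}

#' Write haplotype walks in the 6-column bubble-call dialect
#' @param walks data.frame as returned by [read_walks()]
#' @param path output file
#' @return `path`, invisibly
#' @export
write_walks <- function(walks, path) {
  p <- ifelse(is.na(walks$path), ".", walks$path)
  writeLines(sprintf("%s\t%d\t%d\t%s\t%s\t%s", walks$chrom,
                     as.integer(walks$start), as.integer(walks$end),
                     walks$source, walks$sink, p), path)
  invisible(path)
}

FEATURE_CLASSES <- c("CDS", "gene", "satellite", "telomere", "gap", "other")

#' Read a feature track (BED or GFF3)
#'
#' BED uses a 5-column dialect (`chrom`, `start`, `end`, `name`, `class`) in
#' 0-based half-open coordinates. GFF3 (1-based closed) is imported through
#' rtracklayer and converted; the GFF3 `type` becomes the class and the first
#' available attribute of `gene_id`, `Name`, `ID` becomes the name. Classes
#' outside CDS, gene, satellite, telomere, gap are mapped to `"other"`.
#'
#' @param path file path
#' @param format `"BED"` or `"GFF3"`
#' @return data.frame feature track sorted by (chrom, start) with columns
#'   `chrom`, `start`, `end`, `name`, `class`
#' @export
read_features <- function(path, format = c("BED", "GFF3")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "BED") {
    x <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("chrom", "start", "end", "name", "class"),
                           colClasses = c("character", "integer", "integer",
                                          "character", "character"))
  } else {
    gr <- rtracklayer::import(path, format = "gff3")
    mc <- as.data.frame(gr)
    name <- rep(NA_character_, nrow(mc))
    for (col in c("gene_id", "Name", "ID")) {
      if (col %in% names(mc)) {
        take <- is.na(name) & !is.na(mc[[col]])
        name[take] <- as.character(mc[[col]][take])
      }
    }
    x <- data.frame(chrom = as.character(mc$seqnames),
                    start = mc$start - 1L,   # 1-based closed -> 0-based half-open
                    end = mc$end,
                    name = name,
                    class = as.character(mc$type))
  }
  if (any(x$start < 0L | x$end < 0L)) stop("negative coordinates in ", path)
  if (any(x$end <= x$start)) stop("empty or inverted interval in ", path)
  x$class[!(x$class %in% FEATURE_CLASSES)] <- "other"
  x[radix_order(x$chrom, x$start), , drop = FALSE]
}

#' Write a feature track in the 5-column BED dialect
#' @param track feature track data.frame
#' @param path output file
#' @return `path`, invisibly
#' @export
write_features <- function(track, path) {
  writeLines(sprintf("%s\t%d\t%d\t%s\t%s", track$chrom,
                     as.integer(track$start), as.integer(track$end),
                     track$name, track$class), path)
  invisible(path)
}

#' Read a windowed depth table
#'
#' TSV with columns `chrom`, `window_start`, `window_size`, `mean_depth`.
#' Windows must be non-overlapping with one fixed size per track.
#' @param path file path
#' @return data.frame depth track
#' @export
read_depth <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  x <- utils::read.table(path, sep = "\t", header = FALSE,
                         col.names = c("chrom", "window_start", "window_size",
                                       "mean_depth"),
                         colClasses = c("character", "integer", "integer",
                                        "numeric"))
  validate_depth(x)
  x
}

validate_depth <- function(x) {
  if (nrow(x) == 0L) return(invisible(x))
  if (length(unique(x$window_size)) != 1L) stop("depth windows must have one fixed size")
  if (any(x$mean_depth < 0)) stop("negative mean depth")
  sp <- split(x$window_start, x$chrom)
  w <- x$window_size[1L]
  for (st in sp) {
    st <- sort(st)
    if (length(st) > 1L && any(diff(st) < w)) stop("overlapping depth windows")
  }
  invisible(x)
}

#' Write a windowed depth table
#' @param depth depth track data.frame
#' @param path output file
#' @return `path`, invisibly
#' @export
write_depth <- function(depth, path) {
  writeLines(sprintf("%s\t%d\t%d\t%.6g", depth$chrom,
                     as.integer(depth$window_start),
                     as.integer(depth$window_size), depth$mean_depth), path)
  invisible(path)
}

#' Read a two-column (name, length) table
#'
#' Used for chromosome sizes, contig lengths and phase-block lengths.
#' @param path file path
#' @return data.frame with columns `name`, `length`
#' @export
read_lengths <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  x <- utils::read.table(path, sep = "\t", header = FALSE,
                         col.names = c("name", "length"),
                         colClasses = c("character", "numeric"))
  if (any(x$length <= 0)) stop("non-positive length in ", path)
  x
}
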