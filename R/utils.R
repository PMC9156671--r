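#' @keywords internal
"_PACKAGE"

## Shared helpers: coordinate conventions, path strings, seeds.
## All interval containers in this package are 0-based half-open (BED
## convention); GFF3 import is the only place a coordinate shift happens.

#' Round half away from zero
#'
#' Depth ratios are rounded to the nearest integer with ties away from zero
#' (base [round()] rounds half to even, which would bias copy-number calls
#' at exact half-integer ratios).
#' @param x numeric vector
#' @return integer-valued numeric vector
#' @keywords internal
round_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Derive a module seed from a global seed
#'
#' Counter-based fan-out so every pipeline stage gets an independent but
#' reproducible stream. Result is kept below 2^31 - 1.
#' @param seed integer global seed
#' @param index integer counter (>= 1)
#' @return integer seed
#' @export
derive_seed <- function(seed, index) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.numeric(index))
  as.integer((abs(seed) * 1103L + 12289L * index) %% (.Machine$integer.max - 1L))
}

## Evaluate `expr` with a locally seeded RNG, restoring the caller's stream.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Parse an oriented path string
#'
#' Path strings follow the `>`/`<` dialect (`">s1>s2<s3"`): each step is an
#' orientation character followed by a segment id.
#' @param x character scalar path string
#' @return data.frame with columns `seg` and `orient` (`"+"` or `"-"`)
#' @export
parse_path <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  if (is.na(x) || x == "" || x == ".") {
    return(data.frame(seg = character(), orient = character()))
  }
  if (!grepl("^([><][^><]+)+$", x)) {
    stop("malformed path string: ", x)
  }
  steps <- regmatches(x, gregexpr("[><][^><]+", x))[[1]]
  data.frame(
    seg = substring(steps, 2L),
    orient = ifelse(substring(steps, 1L, 1L) == ">", "+", "-")
  )
}

#' Build a path string from segments and orientations
#' @param seg character vector of segment ids
#' @param orient character vector of `"+"`/`"-"`
#' @return character scalar
#' @export
path_string <- function(seg, orient = rep("+", length(seg))) {
  stopifnot(length(seg) == length(orient), all(orient %in% c("+", "-")))
  if (length(seg) == 0L) return(".")
  paste0(ifelse(orient == "+", ">", "<"), seg, collapse = "")
}

## Oriented node labels used by the bubble detector ("s1+", "s1-").
node_label <- function(seg, orient) paste0(seg, orient)
flip_orient <- function(o) ifelse(o == "+", "-", "+")

## Stable, locale-independent ordering for character keys.
radix_order <- function(...) order(..., method = "radix")

## Internal interval helper: total bp of [s1,e1) clipped to [s2,e2).
clip_bp <- function(start, end, lo, hi) {
  pmax(0, pmin(end, hi) - pmax(start, lo))
}

site_key <- function(chrom, start, end) sprintf("%s:%d-%d", chrom, start, end)
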