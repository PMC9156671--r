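chain_graph <- function() {
  pangenome_graph(
    data.frame(id = c("s1", "s2", "s3"), length = c(100L, 50L, 80L),
               sequence = NA_character_, sn = "chr1",
               so = c(0L, 100L, 150L), sr = 0L),
    data.frame(from = c("s1", "s2"), from_orient = "+",
               to = c("s2", "s3"), to_orient = "+"))
}

diamond_graph <- function() {
  pangenome_graph(
    data.frame(id = c("s1", "s2", "s3", "s4"),
               length = c(100L, 60L, 200L, 80L),
               sequence = NA_character_,
               sn = c("chr1", "chr1", "B", "chr1"),
               so = c(0L, 100L, 0L, 160L),
               sr = c(0L, 0L, 1L, 0L)),
    data.frame(from = c("s1", "s1", "s2", "s3"), from_orient = "+",
               to = c("s2", "s3", "s4", "s4"), to_orient = "+"))
}

test_that("a linear reference chain has no bubbles", {
  expect_equal(detect_superbubbles(chain_graph()), list())
})

test_that("a diamond yields one two-allele bubble with backbone endpoints", {
  bub <- detect_superbubbles(diamond_graph())
  expect_length(bub, 1L)
  b <- bub[[1]]
  expect_equal(b$source, "s1")
  expect_equal(b$sink, "s4")
  expect_length(b$alleles, 2L)
  expect_equal(b$ref_allele, 1L)
  expect_equal(b$allele_paths[1], ">s1>s2>s4")
  expect_equal(b$ref_start, 100)
  expect_equal(b$ref_end, 160)
  expect_equal(sort(b$allele_lengths), c(60, 200))
  expect_false(b$no_ref)
})

test_that("a graph without rank-0 segments is rejected", {
  g <- pangenome_graph(
    data.frame(id = "x1", length = 10L, sequence = NA_character_,
               sn = "a", so = 0L, sr = 1L),
    data.frame(from = character(), from_orient = character(),
               to = character(), to_orient = character()))
  expect_error(detect_superbubbles(g), "no reference backbone")
})

test_that("detector matches the exhaustive-path oracle on random graphs", {
  set.seed(20240917)
  for (k in 1:120) {
    g <- random_test_graph()
    det <- detector_summary(detect_superbubbles(g))
    ora <- oracle_superbubbles(g)
    rownames(det) <- rownames(ora) <- NULL
    expect_equal(det, ora, ignore_attr = TRUE)
  }
})

test_that("reported bubble intervals are disjoint per chromosome", {
  truth <- simulate_pangenome(sim_config(seed = 5, n_chroms = 1L,
                                         chrom_length = 3e5, sv_rate = 4e-5,
                                         n_genes = 5L))
  iv <- bubble_intervals(detect_superbubbles(truth$graph))
  for (chrom in unique(iv$chrom)) {
    x <- iv[iv$chrom == chrom, ]
    x <- x[order(x$start), ]
    if (nrow(x) > 1L) expect_true(all(x$start[-1L] >= x$end[-nrow(x)]))
  }
})

test_that("noise-free simulator output reproduces the planted catalogue exactly", {
  for (seed in c(2, 9, 13)) {
    truth <- simulate_pangenome(sim_config(seed = seed, n_chroms = 1L,
                                           chrom_length = 3e5,
                                           sv_rate = 4e-5, n_genes = 5L))
    bub <- detect_superbubbles(truth$graph)
    expect_equal(length(bub), nrow(truth$sv))
    mat <- build_allele_matrix(bub, truth$walks)
    svs <- call_svs(bub, mat)
    planted <- truth$sv[order(truth$sv$chrom, truth$sv$start), ]
    expect_equal(svs$chrom, planted$chrom)
    expect_equal(svs$start, planted$start)
    expect_equal(svs$end, planted$end)
    expect_equal(svs$ref_len, planted$ref_len)
    expect_equal(svs$alt_len, planted$alt_len)
    expect_equal(svs$svtype, planted$svtype)
    got_carr <- lapply(strsplit(svs$carriers, ","), sort)
    want_carr <- lapply(strsplit(planted$carriers, ","), sort)
    expect_equal(got_carr, want_carr)
  }
})

test_that("bubble summaries count large bubbles and non-reference content", {
  expect_equal(summarize_bubbles(list(), chain_graph())$n_bubbles, 0L)
  expect_equal(summarize_bubbles(list(), chain_graph())$mean_bubble_size, 0)

  g <- diamond_graph()
  g$segments$length[3] <- 1200L
  bub <- detect_superbubbles(g)
  s <- summarize_bubbles(bub, g)
  expect_equal(s$n_bubbles, 1L)
  expect_equal(s$n_large, 1L)
  expect_equal(s$mean_bubble_size, 1200)
  expect_equal(s$nonref_bases, 1200)
  expect_equal(s$nonref_nodes, 1L)

  ## threshold is strictly greater than 1 kb
  g$segments$length[3] <- 1000L
  s <- summarize_bubbles(detect_superbubbles(g), g)
  expect_equal(s$n_large, 0L)
})

test_that("summary of simulator output matches the truth catalogue aggregates", {
  for (seed in 1:5) {
    truth <- simulate_pangenome(sim_config(seed = seed, n_chroms = 1L,
                                           chrom_length = 3e5,
                                           sv_rate = 4e-5, n_genes = 5L))
    bub <- detect_superbubbles(truth$graph)
    s <- summarize_bubbles(bub, truth$graph)
    max_len <- pmax(truth$sv$ref_len, truth$sv$alt_len)
    expect_equal(s$n_bubbles, nrow(truth$sv))
    expect_equal(s$n_large, sum(max_len > 1000))
    expect_equal(s$mean_bubble_size, mean(max_len))
    expect_equal(s$nonref_bases, sum(truth$sv$alt_len[truth$sv$alt_len > 0]))
  }
})

test_that("SV typing follows the 50 bp length asymmetry rule", {
  mk <- function(ref_len, alt_len) {
    structure(list(chrom = "chr1", ref_start = 1000,
                   ref_end = 1000 + ref_len,
                   source = "s1", sink = "s3",
                   alleles = list(1, 2),
                   allele_paths = c(">s1>s2>s3", ">s1>sX>s3"),
                   allele_lengths = c(ref_len, alt_len),
                   interior = c("s2", "sX"), ref_allele = 1L,
                   no_ref = FALSE), class = "bubble")
  }
  ins <- classify_sv(mk(0, 725))
  expect_equal(ins$svtype, "INS")
  expect_equal(ins$alt_len, 725L)
  del <- classify_sv(mk(17017, 0))
  expect_equal(del$svtype, "DEL")
  expect_equal(del$ref_len, 17017L)
  expect_equal(classify_sv(mk(100, 120))$svtype, "COMPLEX")
  ## boundary: 49/50
  expect_equal(classify_sv(mk(49, 50))$svtype, "INS")
  expect_equal(classify_sv(mk(50, 49))$svtype, "DEL")
  expect_equal(classify_sv(mk(49, 49))$svtype, "COMPLEX")

  noref <- mk(60, 80)
  noref$no_ref <- TRUE
  noref$ref_allele <- NA_integer_
  cs <- classify_sv(noref)
  expect_true(all(cs$svtype == "COMPLEX"))
  expect_true(all(cs$flag == "no-ref"))
})
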