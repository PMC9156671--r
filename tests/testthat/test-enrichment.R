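cds_track <- function(starts, ends, gene = sprintf("g%02d", seq_along(starts)),
                      chrom = "chr1") {
  data.frame(chrom = chrom, start = starts, end = ends, name = gene,
             class = "CDS")
}

test_that("half-open interval intersection counts overlap bases and genes", {
  bub <- data.frame(chrom = "chr1", start = 100L, end = 200L)
  ov <- intersect_bubbles_cds(bub, cds_track(150, 160, "g1"))
  expect_equal(ov$total, 1L)
  expect_equal(ov$pairs$bp, 10L)
  expect_equal(ov$genes_hit, "g1")
  expect_equal(ov$per_bubble_bp, 10)

  ## touching intervals do not overlap under half-open coordinates
  ov2 <- intersect_bubbles_cds(bub, cds_track(200, 210))
  expect_equal(ov2$total, 0L)
  expect_equal(length(ov2$genes_hit), 0L)

  expect_error(
    intersect_bubbles_cds(bub, cds_track(10, 20), chrom_lengths = c(chr2 = 100)),
    "missing from length table")
})

test_that("intersection matches an all-pairs oracle on random interval sets", {
  set.seed(55)
  for (k in 1:30) {
    nb <- sample(10:60, 1)
    nc <- sample(5:40, 1)
    bs <- sample.int(1e4, nb)
    bub <- data.frame(chrom = sample(c("chr1", "chr2"), nb, replace = TRUE),
                      start = bs, end = bs + sample(10:500, nb, replace = TRUE))
    cs <- sample.int(1e4, nc)
    cds <- data.frame(chrom = sample(c("chr1", "chr2"), nc, replace = TRUE),
                      start = cs, end = cs + sample(10:300, nc, replace = TRUE),
                      name = sprintf("g%02d", sample(10, nc, replace = TRUE)),
                      class = "CDS")
    ov <- intersect_bubbles_cds(bub, cds)
    brute <- 0L
    brute_genes <- character()
    for (i in seq_len(nb)) {
      hit_genes <- character()
      for (j in seq_len(nc)) {
        bp <- min(bub$end[i], cds$end[j]) - max(bub$start[i], cds$start[j])
        if (bub$chrom[i] == cds$chrom[j] && bp > 0) {
          hit_genes <- union(hit_genes, cds$name[j])
        }
      }
      brute <- brute + length(hit_genes)
      brute_genes <- union(brute_genes, hit_genes)
    }
    expect_equal(ov$total, brute)
    expect_setequal(ov$genes_hit, brute_genes)
    expect_true(all(ov$pairs$bp > 0))
    expect_equal(ov$total, sum(ov$per_chrom$count))
  }
})

test_that("permutation keeps chromosome and length and is seed-deterministic", {
  set.seed(21)
  bs <- sort(sample.int(5e4, 40))
  bub <- data.frame(chrom = sample(c("chr1", "chr2"), 40, replace = TRUE),
                    start = bs, end = bs + sample(50:2000, 40, replace = TRUE))
  sizes <- c(chr1 = 1e5, chr2 = 8e4)
  p1 <- permute_bubbles(bub, sizes, seed = 3)
  p2 <- permute_bubbles(bub, sizes, seed = 3)
  expect_identical(p1, p2)
  expect_equal(p1$chrom, bub$chrom)
  for (chrom in c("chr1", "chr2")) {
    expect_setequal(
      (p1$end - p1$start)[p1$chrom == chrom],
      (bub$end - bub$start)[bub$chrom == chrom])
  }
  expect_true(all(p1$start >= 0 & p1$end <= sizes[p1$chrom]))

  ## degenerate placement: length C-1 forces 1-based start 1 (0-based 0)
  tight <- data.frame(chrom = "chr1", start = 5L, end = 103L)
  p <- permute_bubbles(tight, c(chr1 = 99), seed = 1)
  expect_equal(p$start, 0L)
  expect_error(permute_bubbles(tight, c(chr1 = 98)), "longer than")
})

test_that("permuted starts are uniform on the admissible interval", {
  bub <- data.frame(chrom = "chr1", start = 0L, end = 1000L)
  sizes <- c(chr1 = 21000)
  draws <- pansv:::with_seed(777, {
    vapply(1:10000, function(i) permute_bubbles(bub, sizes)$start, 1L)
  })
  ## admissible starts are 0..20000; chi-square over 20 equal bins
  obs <- table(cut(draws, breaks = seq(0, 20000, length.out = 21),
                   include.lowest = TRUE))
  expect_gt(stats::chisq.test(obs)$p.value, 0.001)
})

test_that("signed-rank depletion test reproduces exact small-sample p-values", {
  obs <- structure(list(per_bubble_bp = c(0, 0, 0, 0, 0, 0),
                        per_chrom = data.frame(chrom = "chr1", count = 0L),
                        total = 0L, n_bubbles = 6L),
                   class = "overlap_result")
  null <- structure(list(n_replicates = 64L,
                         totals = rep(5L, 64L),
                         per_chrom = matrix(5L, 1, 64,
                                            dimnames = list("chr1", NULL)),
                         per_bubble_first = c(3, 8, 2, 5, 1, 4),
                         seed = 1L),
                    class = "permutation_null")
  ## six all-negative differences: exact one-sided p = 1/2^6
  t1 <- depletion_test(obs, null, pairing = "bubble")
  expect_equal(t1$W, 0)
  expect_equal(t1$p_one_sided, 1 / 64, tolerance = 1e-12)
  expect_equal(t1$n_pairs, 6L)
  expect_equal(t1$p_empirical, 1 / 65, tolerance = 1e-12)

  ## observed equal to every replicate -> all differences zero -> p = 1
  obs2 <- obs
  obs2$per_bubble_bp <- null$per_bubble_first
  obs2$total <- 5L
  expect_warning(t2 <- depletion_test(obs2, null, pairing = "bubble"),
                 "zero")
  expect_equal(t2$p_one_sided, 1)

  expect_warning(t3 <- depletion_test(obs2, null, pairing = "replicate"),
                 "zero")
  expect_equal(t3$p_one_sided, 1)
  expect_error(depletion_test(obs, structure(list(n_replicates = 5L),
                                             class = "permutation_null")),
               "at least 10")
})

test_that("the full overlap test pipeline is reproducible and coherent", {
  set.seed(10)
  bs <- sort(sample.int(9e4, 50))
  bub <- data.frame(chrom = "chr1", start = bs,
                    end = bs + sample(50:800, 50, replace = TRUE))
  cds <- cds_track(seq(1000, 90000, by = 3000),
                   seq(1000, 90000, by = 3000) + 400)
  sizes <- c(chr1 = 1e5)
  r1 <- cds_overlap_test(bub, cds, sizes, n_replicates = 50, seed = 4)
  r2 <- cds_overlap_test(bub, cds, sizes, n_replicates = 50, seed = 4)
  expect_identical(r1$null$totals, r2$null$totals)
  expect_identical(r1$test$p_one_sided, r2$test$p_one_sided)
  expect_gt(r1$test$p_one_sided, 0)
  expect_lte(r1$test$p_one_sided, 1)
  expect_equal(r1$observed$total,
               intersect_bubbles_cds(bub, cds)$total)
})

test_that("genes planted to avoid bubbles give strong depletion evidence", {
  set.seed(12)
  bs <- seq(2000, 90000, by = 4000)
  bub <- data.frame(chrom = "chr1", start = bs, end = bs + 1500L)
  ## CDS placed only in the complement of bubbles
  cds <- cds_track(bs + 2000L, bs + 2000L + 900L)
  sizes <- c(chr1 = 1e5)
  r <- cds_overlap_test(bub, cds, sizes, n_replicates = 200, seed = 8)
  expect_equal(r$observed$total, 0L)
  expect_lt(r$test$p_one_sided, 0.01)
  expect_lt(r$test$p_empirical, 0.05)
})
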