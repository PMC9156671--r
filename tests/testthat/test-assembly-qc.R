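test_that("NG50 follows the expected-genome-size definition", {
  expect_equal(ng50(100, 100), 100)
  expect_equal(ng50(c(50, 40, 30), 100), 50)   # cumulative 50 >= 50
  expect_equal(ng50(c(40, 40, 30), 100), 40)
  expect_warning(res <- ng50(c(30, 19), 100), "half")
  expect_equal(res, 0)
  ## invariance under permutation, monotone in any single length
  set.seed(2)
  for (k in 1:20) {
    lens <- sample(1:500, 12)
    G <- 2000
    expect_equal(ng50(sample(lens), G), ng50(lens, G))
    i <- sample(12, 1)
    lens2 <- lens
    lens2[i] <- lens2[i] + sample(1:100, 1)
    expect_gte(ng50(lens2, G), ng50(lens, G))
  }
})

test_that("NG50 equals a brute-force scan on random inputs", {
  set.seed(8)
  for (k in 1:50) {
    lens <- sample(1:1000, sample(3:15, 1), replace = TRUE)
    G <- sum(lens) * runif(1, 0.5, 1.5)
    ## the crossing contig: the largest candidate length L whose
    ## at-least-L contigs still cover half the genome
    brute <- 0
    for (L in sort(unique(lens))) {
      if (sum(lens[lens >= L]) >= G / 2) brute <- L
    }
    got <- suppressWarnings(ng50(lens, G))
    expect_equal(got, brute)
  }
})

test_that("PG50 is NG50 on phase blocks and refinement never increases it", {
  lens <- c(500, 400, 300)
  expect_equal(pg50(lens, 1000), ng50(lens, 1000))
  set.seed(5)
  for (k in 1:20) {
    lens <- sample(50:1000, 8)
    G <- sum(lens)
    blocks <- unlist(lapply(lens, function(L) {
      h <- sample.int(L - 1, 1)
      c(h, L - h)
    }))
    expect_lte(pg50(blocks, G), ng50(lens, G))
    expect_equal(pg50(blocks, G), suppressWarnings(ng50(blocks, G)))
  }
})

test_that("QV is the Phred-scaled error rate with a cap at zero errors", {
  expect_equal(as.numeric(qv(10, 1e6)), 50)
  expect_equal(as.numeric(qv(1, 1e5)), 50)
  z <- qv(0, 1e6)
  expect_equal(as.numeric(z), 99)
  expect_true(attr(z, "capped"))
  expect_error(qv(10, 5), "more error")
  ## inverse round-trip
  set.seed(3)
  for (rate in 10^runif(20, -8, -2)) {
    total <- 1e9
    q <- as.numeric(qv(rate * total, total))
    expect_equal(10^(-q / 10), rate, tolerance = 1e-12)
  }
})

test_that("terminal repeat bases are clipped to the window", {
  rep_track <- function(start, end, class = "telomere") {
    data.frame(chrom = "chr1", start = start, end = end, name = "r",
               class = class)
  }
  C <- 1e6
  ## fully inside the distal 10 kb
  expect_equal(telomere_bases(rep_track(C - 5000, C - 4880), "chr1", C), 120)
  ## 15 kb from the end: outside
  expect_equal(telomere_bases(rep_track(C - 15000, C - 14000), "chr1", C), 0)
  ## straddling the boundary: per-base brute force
  set.seed(9)
  for (k in 1:20) {
    s <- C - sample(8000:12000, 1)
    e <- s + sample(500:4000, 1)
    got <- telomere_bases(rep_track(s, e), "chr1", C)
    brute <- sum(seq(s, e - 1) >= C - 1e4 & seq(s, e - 1) < C)
    expect_equal(got, brute)
  }
  ## proximal window and class filter
  expect_equal(telomere_bases(rep_track(1000, 3000, "satellite"), "chr1", C,
                              window = 5e6, end = "proximal",
                              class = "satellite"), 2000)
  expect_equal(telomere_bases(rep_track(1000, 3000, "satellite"), "chr1", C,
                              end = "distal"), 0)
})

test_that("end-to-end calls use inclusive 50 kb / 500 bp thresholds", {
  mk <- function(sat_bp, tel_bp) {
    C <- 1e6
    rep <- rbind(
      data.frame(chrom = "chr1", start = 0L, end = sat_bp, name = "s",
                 class = "satellite"),
      data.frame(chrom = "chr1", start = C - tel_bp, end = C, name = "t",
                 class = "telomere"))
    rep <- rep[rep$end > rep$start, ]
    end_to_end_report(rep, NULL, c(chr1 = C))
  }
  expect_true(mk(60000, 600)$end_to_end)
  expect_true(mk(50000, 500)$end_to_end)     # "at least" is inclusive
  expect_false(mk(49999, 500)$end_to_end)
  expect_false(mk(50000, 499)$end_to_end)
  r <- mk(60000, 600)
  expect_equal(r$proximal_satellite_bp, 60000)
  expect_equal(r$distal_telomere_bp, 600)
})

test_that("end-to-end counts track the configured completeness probabilities", {
  counts <- 0
  n_seeds <- 40
  cfg0 <- NULL
  for (seed in 1:n_seeds) {
    cfg <- sim_config(seed = seed, n_chroms = 4L, chrom_length = 1e6,
                      sv_rate = 1e-6, n_genes = 2L,
                      p_satellite = 0.7, p_telomere = 0.5)
    cfg0 <- cfg
    truth <- simulate_pangenome(cfg)
    rep1 <- truth$repeat_tracks[[cfg$leaves[1]]]
    gap1 <- truth$gap_tracks[[cfg$leaves[1]]]
    counts <- counts + sum(end_to_end_report(rep1, gap1,
                                             truth$chrom_sizes)$end_to_end)
  }
  expected <- cfg0$p_satellite * cfg0$p_telomere * cfg0$n_chroms
  se <- sqrt(cfg0$n_chroms * 0.35 * 0.65 / n_seeds)
  expect_lt(abs(counts / n_seeds - expected), 3 * se)
})

test_that("dropout regions merge consecutive low-coverage windows", {
  d <- data.frame(chrom = "chr1", window_start = seq(0L, 9e4L, by = 1e4L),
                  window_size = 10000L, mean_depth = 20)
  expect_equal(as.integer(dropout_regions(d)), 0L)
  d$mean_depth[c(3, 4, 5, 8)] <- 0.2
  expect_equal(as.integer(dropout_regions(d)), 2L)
  ## threshold is strict: exactly 1.0 is not a dropout at threshold 1
  d$mean_depth[8] <- 1.0
  expect_equal(as.integer(dropout_regions(d)), 1L)

  ## brute-force scan oracle on random multi-chromosome tracks
  set.seed(14)
  for (k in 1:30) {
    dd <- do.call(rbind, lapply(c("chr1", "chr2"), function(ch) {
      data.frame(chrom = ch, window_start = seq(0L, 19e4L, by = 1e4L),
                 window_size = 10000L,
                 mean_depth = sample(c(0.1, 0.5, 2, 20), 20, replace = TRUE))
    }))
    brute <- 0L
    for (ch in c("chr1", "chr2")) {
      low <- dd$mean_depth[dd$chrom == ch] < 1
      for (i in seq_along(low)) {
        if (low[i] && (i == 1 || !low[i - 1])) brute <- brute + 1L
      }
    }
    expect_equal(as.integer(dropout_regions(dd)), brute)
  }
})

test_that("dropout counts do not increase with sequencing depth", {
  n_drop <- vapply(c(2, 5, 20), function(depth_mean) {
    truth <- simulate_pangenome(
      sim_config(seed = 11, n_chroms = 1L, chrom_length = 1e6,
                 sv_rate = 1e-6, n_genes = 2L, depth_mean = depth_mean))
    as.integer(dropout_regions(truth$depth_tracks[[1]]))
  }, 1L)
  expect_true(all(diff(n_drop) <= 0))
})

test_that("qc_summary bundles the per-assembly metrics coherently", {
  truth <- simulate_pangenome(sim_config(seed = 2, n_chroms = 2L,
                                         chrom_length = 1e6, sv_rate = 1e-6,
                                         n_genes = 2L))
  leaf <- truth$config$leaves[1]
  s <- qc_summary(truth$contigs[[leaf]], truth$phase_blocks[[leaf]],
                  truth$error_bases[[leaf]], truth$total_bases,
                  truth$repeat_tracks[[leaf]], truth$gap_tracks[[leaf]],
                  truth$depth_tracks[[leaf]], truth$chrom_sizes)
  expect_lte(s$pg50, s$ng50)
  expect_gt(s$qv, 30)
  expect_equal(nrow(s$per_chrom), 2L)
  expect_equal(s$n_gaps, sum(vapply(truth$gap_tracks[[leaf]]$class == "gap",
                                    isTRUE, TRUE)))
})
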