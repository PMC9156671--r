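random_matrix_fixture <- function(n_assemblies = 5L, n_sites = 200L,
                                  missing = 0.1) {
  ent <- matrix(sample(0:2, n_assemblies * n_sites, replace = TRUE,
                       prob = c(0.6, 0.3, 0.1)),
                n_sites, n_assemblies,
                dimnames = list(NULL, LETTERS[seq_len(n_assemblies)]))
  ent[matrix(runif(length(ent)) < missing, n_sites)] <- NA_integer_
  keys <- sprintf("chr%d:%d-%d", rep(1:2, length.out = n_sites),
                  seq_len(n_sites) * 100L, seq_len(n_sites) * 100L + 50L)
  rownames(ent) <- keys
  structure(list(
    sites = data.frame(chrom = rep(c("chr1", "chr2"),
                                   length.out = n_sites),
                       start = seq_len(n_sites) * 100L,
                       end = seq_len(n_sites) * 100L + 50L, key = keys),
    assemblies = colnames(ent), entries = ent,
    allele_paths = replicate(n_sites, character(), simplify = FALSE)
  ), class = "allele_matrix")
}

test_that("pairwise discordance counts mutually exclusive bubbles", {
  m <- random_matrix_fixture(3, 10, missing = 0)
  m$entries[] <- 0L
  m$entries[, 1] <- 0L
  expect_true(all(pairwise_discordance(m)$D == 0))  # identical columns

  m$entries[1, 1] <- 1L                              # one discordant site
  D <- pairwise_discordance(m)$D
  expect_equal(D["A", "B"], 1L)
  expect_equal(D["A", "C"], 1L)
  expect_equal(D["B", "C"], 0L)
})

test_that("discordance equals the triple-loop oracle on random matrices", {
  set.seed(31)
  for (k in 1:10) {
    m <- random_matrix_fixture()
    got <- pairwise_discordance(m)
    expect_equal(unname(got$D), unname(brute_discordance(m$entries)))
    expect_true(isSymmetric(got$D))
    expect_true(all(diag(got$D) == 0))
    expect_true(all(got$D <= got$n_sites_used))
  }
})

test_that("chromosome restriction subsets sites and rejects unknown labels", {
  set.seed(5)
  m <- random_matrix_fixture()
  d1 <- pairwise_discordance(m, restrict_chrom = "chr1")
  d2 <- pairwise_discordance(m, restrict_chrom = "chr2")
  dall <- pairwise_discordance(m)
  expect_equal(d1$D + d2$D, dall$D)
  expect_error(pairwise_discordance(m, restrict_chrom = "chrX"), "unknown")
})

test_that("UPGMA reproduces closed-form and hand-computed merge sequences", {
  ## two leaves at distance 10 merge at height 5
  D <- matrix(c(0, 10, 10, 0), 2, dimnames = list(c("A", "B"), c("A", "B")))
  t2 <- upgma(D)
  expect_equal(t2$height, 5)

  ## four leaves: d(AB)=2, d(AC)=d(BC)=8, d(*D)=12
  D4 <- matrix(c(0, 2, 8, 12,
                 2, 0, 8, 12,
                 8, 8, 0, 12,
                 12, 12, 12, 0), 4, byrow = TRUE,
               dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  t4 <- upgma(D4)
  expect_equal(t4$height, c(1, 4, 6))
  expect_equal(t4$members, list(c("A", "B"), c("A", "B", "C"),
                                c("A", "B", "C", "D")))
  expect_error(upgma(matrix(c(0, 1, 2, 0), 2)), "symmetric")
})

test_that("UPGMA recovers ultrametric distances exactly", {
  set.seed(12)
  for (k in 1:10) {
    n <- sample(4:8, 1)
    phy <- ape::rcoal(n, tip.label = paste0("t", 1:n))
    D <- ape::cophenetic.phylo(phy)
    tree <- upgma(D)
    ## cophenetic distances of the dendrogram must equal the input
    got <- matrix(0, n, n, dimnames = dimnames(D))
    for (s in seq_along(tree$members)) {
      mem <- tree$members[[s]]
      kids <- tree$merge[s, ]
      a <- if (kids[1] < 0) tree$labels[-kids[1]] else tree$members[[kids[1]]]
      b <- setdiff(mem, a)
      got[a, b] <- got[b, a] <- 2 * tree$height[s]
    }
    expect_equal(got[rownames(D), colnames(D)], D, tolerance = 1e-10)
  }
})

test_that("UPGMA agrees with average-linkage hclust on tie-free matrices", {
  set.seed(8)
  for (k in 1:10) {
    n <- sample(4:8, 1)
    x <- matrix(rnorm(n * 3), n)
    rownames(x) <- paste0("t", 1:n)
    D <- as.matrix(dist(x))
    hc <- stats::hclust(stats::as.dist(D), method = "average")
    tree <- upgma(D)
    expect_equal(sort(2 * tree$height), sort(hc$height), tolerance = 1e-10)
    ## every merged cluster must appear in the hclust cut at the same height
    my_parts <- lapply(tree$members, paste, collapse = "+")
    for (s in seq_len(n - 1L)) {
      cl <- stats::cutree(hc, h = hc$height[s] + 1e-9)
      hc_parts <- vapply(split(names(cl), cl), function(g) {
        paste(sort(g), collapse = "+")
      }, "")
      expect_true(my_parts[[s]] %in% hc_parts)
    }
  }
})

test_that("taurine-style topology classification matches the stated rule", {
  D <- function(newick) {
    upgma(ape::cophenetic.phylo(ape::read.tree(text = newick)))
  }
  expect_equal(classify_topology(
    D("(G:4,(N:3,(O:2,(P:1,B:1):1):1):1);")), "O_OUT")
  expect_equal(classify_topology(
    D("(G:4,(N:3,(P:2,(O:1,B:1):1):1):1);")), "P_OUT")
  expect_equal(classify_topology(
    D("(G:4,(N:3,(B:2,(O:1,P:1):1):1):1);")), "B_OUT")
  ## N outermost violates the outgroup order
  expect_equal(classify_topology(
    D("(N:4,(G:3,(O:2,(P:1,B:1):1):1):1);")), "OTHER")
  ## outgroups merged together first
  expect_equal(classify_topology(
    D("((G:1,N:1):3,(O:2,(P:1,B:1):1):2);")), "OTHER")
  expect_error(classify_topology(D("(X:4,(N:3,(O:2,(P:1,B:1):1):1):1);")),
               "labels")
})

test_that("classification agrees with a clade-membership check on all 105 topologies", {
  labs <- c("G", "N", "O", "P", "B")
  trees <- phangorn::allTrees(5, rooted = TRUE, tip.label = labs)
  expect_equal(length(trees), 105L)
  has_clade <- function(phy, tips) {
    pp <- ape::prop.part(phy)
    any(vapply(pp, function(p) setequal(phy$tip.label[p], tips), TRUE))
  }
  for (phy in trees) {
    ## ultrametric distances: d(i,j) = 2 * (size of smallest clade holding
    ## both - 1), so every topology maps to a distinct ultrametric matrix
    clades <- c(lapply(ape::prop.part(phy), function(p) phy$tip.label[p]),
                list(labs))
    Dm <- matrix(0, 5, 5, dimnames = list(labs, labs))
    for (i in 1:4) {
      for (j in (i + 1):5) {
        sizes <- vapply(clades, function(cl) {
          if (all(c(labs[i], labs[j]) %in% cl)) length(cl) else NA_integer_
        }, 1L)
        Dm[i, j] <- Dm[j, i] <- 2 * (min(sizes, na.rm = TRUE) - 1)
      }
    }
    got <- classify_topology(upgma(Dm))
    ## brute-force expectation from clade membership
    expected <- "OTHER"
    if (has_clade(phy, c("N", "O", "P", "B")) &&
        has_clade(phy, c("O", "P", "B"))) {
      for (x in c("O", "P", "B")) {
        if (has_clade(phy, setdiff(c("O", "P", "B"), x))) {
          expected <- paste0(x, "_OUT")
        }
      }
    }
    expect_equal(got, expected)
  }
})

test_that("intersection sets tally non-reference carrier subsets", {
  m <- random_matrix_fixture(4, 6, missing = 0)
  m$assemblies <- c("O", "B", "P", "N")
  colnames(m$entries) <- m$assemblies
  m$entries[] <- 0L
  m$entries[1, ] <- 1L                 # all four carry
  m$entries[2, c(1, 3)] <- 1L          # O and P
  m$entries[3, 2] <- 2L                # B alone, different allele index
  ## row 4-6 all reference -> contribute nothing
  sets <- intersection_sets(m)
  expect_equal(attr(sets, "n_nonref"), 3L)
  expect_setequal(sets$subset, c("O+B+P+N", "O+P", "B"))
  expect_true(all(sets$count == 1L))

  m$entries[4, 1] <- NA_integer_
  expect_error(intersection_sets(m), "filter_complete")
})

test_that("intersection counts equal a brute-force subset tally", {
  set.seed(41)
  for (k in 1:10) {
    m <- random_matrix_fixture(4, 100, missing = 0)
    sets <- intersection_sets(m)
    brute <- table(apply(m$entries, 1, function(r) {
      paste(m$assemblies[r > 0], collapse = "+")
    }))
    brute <- brute[names(brute) != ""]
    expect_equal(sum(sets$count), sum(brute))
    for (s in sets$subset) {
      expect_equal(sets$count[sets$subset == s], unname(as.integer(brute[s])))
    }
  }
})

test_that("discordance decomposes over intersection sets on biallelic matrices", {
  set.seed(17)
  m <- random_matrix_fixture(4, 150, missing = 0)
  m$entries[m$entries > 1L] <- 1L
  D <- pairwise_discordance(m)$D
  sets <- intersection_sets(m)
  labs <- m$assemblies
  for (i in 1:3) {
    for (j in (i + 1):4) {
      in_set <- function(s, lab) lab %in% strsplit(s, "+", fixed = TRUE)[[1]]
      disc <- sum(sets$count[vapply(sets$subset, function(s) {
        xor(in_set(s, labs[i]), in_set(s, labs[j]))
      }, TRUE)])
      expect_equal(unname(D[i, j]), disc)
    }
  }
})

test_that("dendrograms serialise to valid ultrametric Newick", {
  D4 <- matrix(c(0, 2, 8, 12,
                 2, 0, 8, 12,
                 8, 8, 0, 12,
                 12, 12, 12, 0), 4, byrow = TRUE,
               dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  tree <- upgma(D4)
  phy <- dendrogram_phylo(tree)
  expect_s3_class(phy, "phylo")
  expect_true(ape::is.ultrametric(phy))
  expect_equal(max(ape::node.depth.edgelength(phy)), 6)
})
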