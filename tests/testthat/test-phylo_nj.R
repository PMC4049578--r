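test_that("variance-scaled trait distance matches its definition", {
  g <- data.frame(group = c("A", "B", "C"),
                  TC = c(10, 12, 14), TSN = c(600, 600, 600))
  expect_error(trait_distance(g), "zero standard deviation")
  g$TSN <- c(600, 650, 700)
  D <- trait_distance(g)
  sig_tc <- sqrt(mean((g$TC - mean(g$TC))^2))
  sig_tsn <- sqrt(mean((g$TSN - mean(g$TSN))^2))
  expect_equal(D["A", "B"],
               (10 - 12)^2 / sig_tc^2 + (600 - 650)^2 / sig_tsn^2)
  expect_equal(diag(D), setNames(rep(0, 3), g$group))

  # brute-force double loop on a random 6-group table
  set.seed(61)
  g6 <- data.frame(group = paste0("g", 1:6), TC = runif(6, 1, 6),
                   TSN = runif(6, 500, 700))
  D6 <- trait_distance(g6)
  s_tc <- sqrt(mean((g6$TC - mean(g6$TC))^2))
  s_tsn <- sqrt(mean((g6$TSN - mean(g6$TSN))^2))
  for (i in 1:6) for (j in 1:6)
    expect_equal(D6[i, j], (g6$TC[i] - g6$TC[j])^2 / s_tc^2 +
                   (g6$TSN[i] - g6$TSN[j])^2 / s_tsn^2)
  expect_equal(D6, t(D6))
  # sample-sd variant rescales every entry by (n-1)/n
  Ds <- trait_distance(g6, sd_type = "sample")
  expect_equal(unclass(Ds), unclass(D6) * 5 / 6, ignore_attr = TRUE)
})

test_that("three-taxon tree uses the closed-form branch lengths", {
  D <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- neighbor_joining(D)
  expect_equal(tr$newick, "(a:1,b:2,c:3);")
})

test_that("NJ recovers topology and branch lengths on additive matrices", {
  skip_if_not_installed("ape")
  for (s in 1:50) {
    n <- sample(4:8, 1)
    ra <- random_additive(n, seed = 7000 + s)
    est <- ape::read.tree(text = neighbor_joining(ra$D)$newick)
    expect_equal(topo_dist(est, ra$tree), 0)
    Dhat <- as.matrix(stats::cophenetic(est))[rownames(ra$D),
                                              colnames(ra$D)]
    expect_lt(max(abs(Dhat - ra$D)), 1e-9)
  }
})

test_that("NJ agrees with the reference implementation on noisy matrices", {
  skip_if_not_installed("ape")
  set.seed(71)
  for (s in 1:10) {
    ra <- random_additive(6, seed = 300 + s)
    D <- ra$D + matrix(runif(36, 0, 0.05), 6)  # mild symmetric noise
    D <- (D + t(D)) / 2; diag(D) <- 0
    mine <- ape::read.tree(text = neighbor_joining(D)$newick)
    ref <- ape::nj(D)
    expect_equal(topo_dist(mine, ape::unroot(ref)), 0)
  }
})

test_that("NJ matches exhaustive minimum evolution on ultrametric 5-taxon data", {
  skip_if_not_installed("ape")
  skip_if_not_installed("phangorn")
  for (s in 1:8) {
    set.seed(800 + s)
    h <- stats::hclust(stats::dist(matrix(rnorm(10), 5)), method = "average")
    D <- as.matrix(stats::cophenetic(h))
    dimnames(D) <- list(paste0("t", 1:5), paste0("t", 1:5))
    nj_tr <- ape::read.tree(text = neighbor_joining(D)$newick)
    me_tr <- me_best_topology(D)
    expect_equal(topo_dist(nj_tr, me_tr), 0)
  }
})

test_that("leaf order does not change the tree", {
  skip_if_not_installed("ape")
  ra <- random_additive(7, seed = 99)
  perm <- sample(7)
  t1 <- ape::read.tree(text = neighbor_joining(ra$D)$newick)
  t2 <- ape::read.tree(
    text = neighbor_joining(ra$D[perm, perm])$newick)
  expect_equal(topo_dist(t1, t2), 0)
  expect_lt(max(abs(as.matrix(stats::cophenetic(t1))[rownames(ra$D),
                                                     rownames(ra$D)] -
                  as.matrix(stats::cophenetic(t2))[rownames(ra$D),
                                                   rownames(ra$D)])),
            1e-9)
})

test_that("invalid distance matrices are refused", {
  D <- matrix(c(0, 1, 1, 0), 2)
  expect_error(neighbor_joining(D), "at least 3")
  D3 <- matrix(c(0, 1, 2, 1, 0, NA, 2, NA, 0), 3)
  expect_error(neighbor_joining(D3), "finite")
  D4 <- matrix(c(0, 1, 2, 5, 0, 3, 2, 3, 0), 3)
  expect_error(neighbor_joining(D4), "symmetric")
})

test_that("deuterostome groups form a clan on a gradient cohort", {
  skip_if_not_installed("ape")
  co <- small_cohort(seed = 17, n_species = 2, len_scale = 0.5)
  comp <- composition_table(co$records, protein_sets("set5"))
  g <- group_mean_composition(comp)
  # trait distances are not additive, so clamped branches are expected
  tr <- suppressWarnings(neighbor_joining(trait_distance(g)))
  ph <- ape::root(ape::read.tree(text = tr$newick), outgroup = "Porifera",
                  resolve.root = TRUE)
  deut <- co$metadata$group[co$metadata$clade == "deuterostome"]
  expect_true(ape::is.monophyletic(ph, deut))
})

test_that("outgroup rooting and writers produce parseable output", {
  skip_if_not_installed("ape")
  ra <- random_additive(5, seed = 123)
  tr <- neighbor_joining(ra$D)
  rooted <- root_tree(tr, rownames(ra$D)[1])
  expect_s3_class(ape::read.tree(text = rooted$newick), "phylo")
  f <- withr::local_tempfile(fileext = ".nwk")
  write_newick(tr, f)
  expect_s3_class(ape::read.tree(f), "phylo")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_distance(ra$D, f2)
  back <- utils::read.delim(f2)
  expect_equal(as.matrix(back[, -1]),
               matrix(ra$D, 5, dimnames = list(NULL, colnames(ra$D))),
               tolerance = 1e-8)
})
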