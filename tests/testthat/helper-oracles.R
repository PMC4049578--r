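# Independent oracles and small fixture builders shared across test files.

# direct-convolution smoother: plain double loop, kept deliberately naive
brute_smooth <- function(x, iters) {
  for (k in seq_len(iters)) {
    y <- numeric(length(x))
    for (i in seq_along(x)) {
      w <- max(1, i - 1):min(length(x), i + 1)
      acc <- 0  # plain double accumulation, left to right
      for (j in w) acc <- acc + x[j]
      y[i] <- acc / length(w)
    }
    x <- y
  }
  x
}

# textbook product-moment formula, no calls into stats::cor
pearson_manual <- function(x, y) {
  n <- length(x)
  num <- n * sum(x * y) - sum(x) * sum(y)
  den <- sqrt(n * sum(x^2) - sum(x)^2) * sqrt(n * sum(y^2) - sum(y)^2)
  num / den
}

mk_rec <- function(species, group, gene, seq) {
  data.frame(species_id = species, group = group, gene = gene,
             sequence = seq, stringsAsFactors = FALSE)
}

# a tiny all-constant scale makes hand computation trivial
flat_scale <- function(value = 1) {
  structure(stats::setNames(rep(value, 20), mmpevol:::AA_CANONICAL),
            class = "hydropathy_scale")
}

small_cohort <- function(seed = 11, groups = NULL, n_species = 3,
                         len_scale = 0.3, ...) {
  spec <- default_cohort_spec(n_species = n_species,
                              gene_length_scale = len_scale,
                              seed = seed, ...)
  if (!is.null(groups))
    spec$groups <- spec$groups[spec$groups$group %in% groups, ]
  simulate_cohort(spec)
}

fixture_dir <- function() {
  system.file("extdata", "fixture_cohort", package = "mmpevol",
              mustWork = TRUE)
}

# OLS branch lengths of a fixed topology against a distance matrix
ols_branch_lengths <- function(tree, D) {
  tips <- tree$tip.label
  pairs <- utils::combn(length(tips), 2)
  d <- D[cbind(tips[pairs[1, ]], tips[pairs[2, ]])]
  X <- matrix(0, ncol(pairs), nrow(tree$edge))
  for (e in seq_len(nrow(tree$edge))) {
    child <- tree$edge[e, 2]
    below <- if (child <= length(tips)) tips[child] else
      tips[unlist(phangorn::Descendants(tree, child, "tips"))]
    ina <- tips[pairs[1, ]] %in% below
    inb <- tips[pairs[2, ]] %in% below
    X[xor(ina, inb), e] <- 1
  }
  stats::lm.fit(X, d)$coefficients
}

# exhaustive minimum-evolution search over all unrooted topologies
me_best_topology <- function(D) {
  labs <- rownames(D)
  trees <- phangorn::allTrees(length(labs), rooted = FALSE,
                              tip.label = labs)
  bestlen <- Inf; best <- NULL
  for (i in seq_along(trees)) {     # [[ ]] restores compressed tip labels
    tr <- trees[[i]]
    b <- ols_branch_lengths(tr, D)
    tl <- sum(b)
    if (tl < bestlen - 1e-12) { bestlen <- tl; best <- tr }
  }
  best
}

# unrooted Robinson-Foulds distance as a bare number
topo_dist <- function(a, b) as.numeric(ape::dist.topo(a, b))

# random tree-metric (additive) distance matrix plus its generating tree
random_additive <- function(n, seed) {
  set.seed(seed)
  tr <- ape::unroot(ape::rtree(n))
  tr$edge.length <- stats::runif(nrow(tr$edge), 0.1, 2)
  D <- as.matrix(stats::cophenetic(tr))
  list(tree = tr, D = D[tr$tip.label, tr$tip.label])
}
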