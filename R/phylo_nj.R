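#' Variance-scaled composition distance between animal groups
#'
#' The pairwise distance between groups i and j is the sum over the chosen
#' variables of (v_i - v_j)^2 / sigma_v^2, where sigma_v is the standard
#' deviation of v across the groups being compared -- so each variable
#' enters on a comparable, dimensionless footing.  Defaults follow the
#' composition-space tree: variables TC and TSN on the 5-protein set.
#'
#' @param group_comp Group-level table from [group_mean_composition()]
#'   (or any data.frame with a `group` column and the variable columns).
#' @param variables Character vector of variable columns (default
#'   `c("TC", "TSN")`).
#' @param protein_set Protein set to select when `group_comp` carries a
#'   `protein_set` column (default `"set5"`).
#' @param sd_type `"population"` (divide by n; default) or `"sample"`.
#' @return Symmetric numeric matrix with zero diagonal, group names as
#'   dimnames, and the sigmas as attribute `sigmas`.
#' @export
trait_distance <- function(group_comp, variables = c("TC", "TSN"),
                           protein_set = "set5",
                           sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  d <- group_comp
  if (!is.null(d$protein_set)) d <- d[d$protein_set == protein_set, ]
  if (nrow(d) < 3L) stop("need at least 3 groups")
  miss <- setdiff(variables, names(d))
  if (length(miss))
    stop("variable(s) not in table: ", paste(miss, collapse = ", "))
  n <- nrow(d)
  D <- matrix(0, n, n, dimnames = list(d$group, d$group))
  sigmas <- numeric(0)
  for (v in variables) {
    x <- as.numeric(d[[v]])
    sig <- if (sd_type == "population")
      sqrt(mean((x - mean(x))^2)) else stats::sd(x)
    if (sig == 0) stop("zero standard deviation for variable ", v)
    sigmas[v] <- sig
    D <- D + outer(x, x, `-`)^2 / sig^2
  }
  attr(D, "sigmas") <- sigmas
  D
}

# lowest-index (i, j), i < j, minimising Q -- deterministic tie-break
min_pair <- function(Q) {
  n <- nrow(Q)
  best <- c(NA_integer_, NA_integer_); bestv <- Inf
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    better <- !is.finite(bestv) ||
      Q[i, j] < bestv - 1e-12 * max(1, abs(bestv))
    if (better) { bestv <- Q[i, j]; best <- c(i, j) }
  }
  best
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard agglomeration: at each step the pair minimising
#' Q(i, j) = (n - 2) D(i, j) - r_i - r_j (r = row sums) is joined, branch
#' lengths follow the usual two-point formulas, and distances to the new
#' node are D(u, k) = (D(i, k) + D(j, k) - D(i, j)) / 2; three remaining
#' nodes are resolved by the closed-form three-point formulas.  Ties in Q
#' are broken toward the lowest index pair, so the result is deterministic.
#' Negative branch lengths are clamped to zero with a warning.  On an
#' additive (tree-metric) matrix the generating topology and branch
#' lengths are recovered exactly.
#'
#' @param D Symmetric numeric matrix, zero diagonal, n >= 3; dimnames
#'   supply the leaf labels.
#' @return List of class `trait_tree`: `newick` (unrooted tree string),
#'   `labels`, `D`.
#' @export
neighbor_joining <- function(D) {
  D <- as.matrix(D)
  n <- nrow(D)
  if (n < 3L) stop("need at least 3 leaves")
  if (anyNA(D) || any(!is.finite(D))) stop("distances must be finite")
  if (any(D < 0)) stop("distances must be non-negative")
  if (max(abs(D - t(D))) > 1e-12 * max(1, max(abs(D))))
    stop("distance matrix must be symmetric")
  labels <- rownames(D) %||% paste0("t", seq_len(n))
  diag(D) <- 0

  frag <- labels   # newick fragment per active node
  clamped <- FALSE
  brlen <- function(l) { if (l < 0) { clamped <<- TRUE; l <- 0 }; l }

  while (nrow(D) > 3L) {
    m <- nrow(D)
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, `+`)
    diag(Q) <- Inf
    ij <- min_pair(Q)
    i <- ij[1L]; j <- ij[2L]
    li <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    lj <- D[i, j] - li
    li <- brlen(li); lj <- brlen(lj)
    newfrag <- sprintf("(%s:%.12g,%s:%.12g)", frag[i], li, frag[j], lj)
    dk <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], dk[keep]),
                c(dk[keep], 0))
    frag <- c(frag[keep], newfrag)
    dimnames(D2) <- list(seq_len(m - 1L), seq_len(m - 1L))
    D <- D2
  }

  la <- brlen((D[1, 2] + D[1, 3] - D[2, 3]) / 2)
  lb <- brlen((D[1, 2] + D[2, 3] - D[1, 3]) / 2)
  lc <- brlen((D[1, 3] + D[2, 3] - D[1, 2]) / 2)
  newick <- sprintf("(%s:%.12g,%s:%.12g,%s:%.12g);",
                    frag[1], la, frag[2], lb, frag[3], lc)
  if (clamped)
    warning("negative branch length(s) clamped to 0")
  structure(list(newick = newick, labels = labels, D = NULL),
            class = "trait_tree")
}

#' @export
print.trait_tree <- function(x, ...) {
  cat("unrooted neighbor-joining tree,", length(x$labels), "leaves\n")
  cat(x$newick, "\n")
  invisible(x)
}

#' Write a tree to a newick file
#'
#' @param tree A `trait_tree`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  writeLines(tree$newick, path)
  invisible(path)
}

#' Root a trait tree at an outgroup leaf
#'
#' The neighbor-joining tree is unrooted; for display it can be rooted at a
#' designated outgroup (e.g. Porifera).  Requires the `ape` package.
#'
#' @param tree A `trait_tree`.
#' @param outgroup Leaf label to root at.
#' @return A `trait_tree` whose newick string is rooted.
#' @export
root_tree <- function(tree, outgroup) {
  if (!requireNamespace("ape", quietly = TRUE))
    stop("rooting requires the 'ape' package")
  if (!outgroup %in% tree$labels) stop("unknown outgroup: ", outgroup)
  ph <- ape::read.tree(text = tree$newick)
  ph <- ape::root(ph, outgroup = outgroup, resolve.root = TRUE)
  structure(list(newick = ape::write.tree(ph), labels = tree$labels,
                 D = tree$D),
            class = "trait_tree")
}

#' Write a distance matrix as TSV or PHYLIP square format
#'
#' @param D Symmetric distance matrix.
#' @param path Output path.
#' @param format `"tsv"` (header row + row names) or `"phylip"`.
#' @return `path`, invisibly.
#' @export
write_distance <- function(D, path, format = c("tsv", "phylip")) {
  format <- match.arg(format)
  if (format == "tsv") {
    df <- data.frame(group = rownames(D), D, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    con <- file(path, "w"); on.exit(close(con))
    writeLines(sprintf("%5d", nrow(D)), con)
    for (i in seq_len(nrow(D)))
      writeLines(paste(formatC(rownames(D)[i], width = -10),
                       paste(sprintf("%.6f", D[i, ]), collapse = " ")),
                 con)
  }
  invisible(path)
}
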