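#' Mass-specific basal metabolic rate
#'
#' Within an animal group the allometric law BMR = C * M^alpha holds; the
#' BMR per unit body mass is then msBMR = C * M^-(1-alpha).  Units are those
#' of the source BMR data and are treated as relative: only logarithms of
#' these quantities enter correlations.
#'
#' @param C Allometric constant (> 0).
#' @param alpha Allometric exponent in (0, 1].
#' @param M Mean body mass of the group, grams (> 0).
#' @return msBMR (vectorised over the inputs).
#' @export
#' @examples
#' msbmr(C = 1, alpha = 0.75, M = 16)  # 16^-0.25 = 0.5
msbmr <- function(C, alpha, M) {
  check_allometry(C, alpha, M)
  C * M^(-(1 - alpha))
}

#' Basal metabolic rate per unit mitochondrion
#'
#' The mitochondrial density of a cell falls with body mass, so the BMR per
#' unit mitochondrion falls more slowly with M than msBMR does.  This is
#' expressed as mtBMR = C * M^-(1-alpha)/F with a scaling-adjustment
#' parameter F >= 1: F = 1 recovers msBMR, and F = Inf removes the mass
#' dependence entirely so that mtBMR = C.  (The mt-density proportionality
#' constant is fixed at 1, which is what makes F = 1 coincide with msBMR.)
#'
#' @inheritParams msbmr
#' @param F_adj Scaling-adjustment parameter, >= 1; `Inf` is legal.
#' @return mtBMR (vectorised).
#' @export
#' @examples
#' mtbmr(C = 2, alpha = 0.75, M = 1e4, F_adj = 3)
#' mtbmr(C = 0.37, alpha = 0.7, M = 100, F_adj = Inf)  # = C
mtbmr <- function(C, alpha, M, F_adj) {
  check_allometry(C, alpha, M)
  if (any(F_adj < 1)) stop("F must be >= 1")
  # power form keeps F = 1 bitwise equal to msbmr and F = Inf equal to C
  # (the exponent (1 - alpha)/Inf is exactly zero)
  C * M^(-(1 - alpha) / F_adj)
}

#' Natural log of mtBMR
#'
#' ln(mtBMR) = ln C - (1 - alpha) * ln M / F exactly; this closed log form
#' is used for all correlations (it is overflow-safe and handles F = Inf
#' without a limit computation).
#'
#' @inheritParams mtbmr
#' @return ln(mtBMR), vectorised.
#' @export
ln_mtbmr <- function(C, alpha, M, F_adj) {
  check_allometry(C, alpha, M)
  if (any(F_adj < 1)) stop("F must be >= 1")
  log(C) - (1 - alpha) * log(M) / F_adj  # finite/Inf == 0, so F = Inf drops the mass term
}

check_allometry <- function(C, alpha, M) {
  if (any(M <= 0)) stop("body mass M must be > 0")
  if (any(C <= 0)) stop("allometric constant C must be > 0")
  if (any(alpha <= 0 | alpha > 1))
    stop("allometric exponent alpha must lie in (0, 1]")
  invisible(TRUE)
}

#' Default F grid for the sweep
#'
#' @return Numeric vector from 1 to `Inf`.
#' @export
default_f_grid <- function() {
  c(1, 1.25, 1.5, 2, 2.5, 3, 4, 5, 7.5, 10, 20, 50, 100, Inf)
}

#' Sweep F and locate the strongest STC--ln(mtBMR) correlation
#'
#' For each F on the grid, computes ln(mtBMR) for every group from its
#' allometric parameters and correlates it with the group's Ser+Thr
#' percentage; reports the full R^2 curve and the F maximising it.  Ties are
#' broken toward larger F (F = Inf, i.e. mtBMR = C, wins a perfect tie).
#'
#' @param metadata `group_metadata` data.frame (columns `group`, `M`, `C`,
#'   `alpha`).
#' @param stc Named numeric vector of STC (percent) per group; names must
#'   match `metadata$group`.
#' @param grid F values to evaluate (default [default_f_grid()]).
#' @return List of class `f_sweep` with `grid`, `r2` (NA where a variable
#'   is degenerate), `best_F`, `best_r2`, `n`, and `mtbmr_best` (named
#'   per-group mtBMR at `best_F`).
#' @export
f_sweep <- function(metadata, stc, grid = default_f_grid()) {
  groups <- intersect(metadata$group, names(stc))
  if (length(groups) < 3L)
    stop("need at least 3 groups with both STC and metadata")
  md <- metadata[match(groups, metadata$group), ]
  y <- as.numeric(stc[groups])
  if (length(grid) < 1L) stop("empty F grid")
  r2 <- vapply(grid, function(f) {
    x <- ln_mtbmr(md$C, md$alpha, md$M, f)
    if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
    stats::cor(x, y)^2
  }, numeric(1))
  ord <- order(grid)
  grid <- grid[ord]; r2 <- r2[ord]
  if (all(is.na(r2))) stop("R^2 undefined on the whole grid (zero variance)")
  best_idx <- max(which(r2 == max(r2, na.rm = TRUE)))  # ties -> larger F
  best_F <- grid[best_idx]
  structure(list(grid = grid, r2 = r2, best_F = best_F,
                 best_r2 = r2[best_idx], n = length(groups),
                 mtbmr_best = stats::setNames(
                   mtbmr(md$C, md$alpha, md$M, best_F), groups)),
            class = "f_sweep")
}

#' @export
print.f_sweep <- function(x, ...) {
  cat(sprintf("F sweep over %d values, n = %d groups\n",
              length(x$grid), x$n))
  cat(sprintf("  best F = %s with R^2 = %.4f\n",
              format(x$best_F), x$best_r2))
  invisible(x)
}
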