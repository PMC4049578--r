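#' Squared Pearson correlation with sign of association
#'
#' The correlation battery reports R^2 together with the sign (P/N) of the
#' underlying correlation, following the convention of the composition
#' tables.
#'
#' @param x,y Numeric vectors of equal length >= 3, finite.
#' @return List `r2`, `sign` (`"P"` or `"N"`; `"0"` for exactly zero
#'   correlation), `n`.
#' @export
#' @examples
#' pearson_r2(1:10, 2 * (1:10) + 1)  # r2 = 1, sign "P"
pearson_r2 <- function(x, y) {
  stopifnot(length(x) == length(y))
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L) stop("need at least 3 finite point pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance: correlation undefined")
  r <- stats::cor(x, y)
  list(r2 = r^2, sign = if (r > 0) "P" else if (r < 0) "N" else "0",
       n = length(x))
}

#' Ordinary least-squares line fit
#'
#' @param x,y Numeric vectors, n >= 3 (n = 2 returns the interpolating
#'   line).
#' @param subset Optional logical/integer subset of points (e.g. the
#'   deuterostome groups) applied to both vectors.
#' @return List of class `mmp_fit`: `model = "linear"`, `slope`,
#'   `intercept`, `r2`, `n`.
#' @export
fit_linear <- function(x, y, subset = NULL) {
  if (!is.null(subset)) { x <- x[subset]; y <- y[subset] }
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 2L) stop("need at least 2 points")
  if (stats::sd(x) == 0) stop("zero variance in x: line undefined")
  fit <- stats::lm(y ~ x)
  sstot <- sum((y - mean(y))^2)
  r2 <- if (sstot == 0) 1 else 1 - sum(stats::resid(fit)^2) / sstot
  structure(list(model = "linear",
                 slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 r2 = r2, n = length(x)),
            class = "mmp_fit")
}

#' Power-law fit y = a * x^b
#'
#' Fitted two ways: nonlinear least squares on the original scale
#' (Levenberg--Marquardt, initialised from the log--log OLS solution) as the
#' headline result, and the log--log OLS fit itself, reported alongside.
#' On noise-free power-law data the two coincide.  The nonlinear R^2 is
#' 1 - SSres/SStot on the original scale and may be negative for a poor
#' model (flagged, not hidden).
#'
#' @param x,y Strictly positive numeric vectors, n >= 3.
#' @return List of class `mmp_fit`: `model = "power"`, `a`, `b`, `r2`,
#'   `loglog` (list `a`, `b`, `r2` of the log--log fit), `converged`, `n`.
#' @export
#' @examples
#' x <- seq(0.5, 0.9, length.out = 8)
#' f <- fit_power(x, 0.429 * x^-4.2045)
#' c(f$a, f$b)
fit_power <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L) stop("need at least 3 points")
  if (any(x <= 0) || any(y <= 0))
    stop("power-law fit requires strictly positive x and y")
  ll <- stats::lm(log(y) ~ log(x))
  a0 <- exp(unname(stats::coef(ll)[1L])); b0 <- unname(stats::coef(ll)[2L])
  ll_sstot <- sum((log(y) - mean(log(y)))^2)
  ll_r2 <- if (ll_sstot == 0) 1 else
    1 - sum(stats::resid(ll)^2) / ll_sstot
  loglog <- list(a = a0, b = b0, r2 = ll_r2)
  nl <- tryCatch(
    suppressWarnings(
      minpack.lm::nlsLM(y ~ a * x^b, start = list(a = a0, b = b0),
                        control = minpack.lm::nls.lm.control(maxiter = 200))),
    error = function(e) NULL)
  if (is.null(nl)) {
    warning("nonlinear power fit did not converge; log-log fit reported")
    return(structure(list(model = "power", a = a0, b = b0,
                          r2 = loglog$r2, loglog = loglog,
                          converged = FALSE, n = length(x)),
                     class = "mmp_fit"))
  }
  cf <- stats::coef(nl)
  resid <- y - cf[["a"]] * x^cf[["b"]]
  sstot <- sum((y - mean(y))^2)
  r2 <- if (sstot == 0) 1 else 1 - sum(resid^2) / sstot
  structure(list(model = "power", a = cf[["a"]], b = cf[["b"]], r2 = r2,
                 loglog = loglog, converged = TRUE, n = length(x)),
            class = "mmp_fit")
}

#' @export
print.mmp_fit <- function(x, ...) {
  if (x$model == "linear")
    cat(sprintf("linear fit: y = %.4g * x + %.4g (R^2 = %.4f, n = %d)\n",
                x$slope, x$intercept, x$r2, x$n))
  else
    cat(sprintf("power fit: y = %.4g * x^%.4g (R^2 = %.4f, n = %d)\n",
                x$a, x$b, x$r2, x$n))
  invisible(x)
}

#' Two-predictor linear model of ln(mtBMR)
#'
#' Fits y ~ x1 + x2 by OLS (typically ln(mtBMR) on STC and HYD).  By
#' nesting, its R^2 is at least that of either single-predictor fit.
#'
#' @param y Response vector.
#' @param x1,x2 Predictor vectors.
#' @return List: `coefficients` (intercept, b1, b2), `r2`, `n`,
#'   `collinear` (TRUE when x1 and x2 are linearly dependent; the fit is
#'   then reported with the aliased coefficient as NA).
#' @export
multi_linear <- function(y, x1, x2) {
  keep <- is.finite(y) & is.finite(x1) & is.finite(x2)
  y <- y[keep]; x1 <- x1[keep]; x2 <- x2[keep]
  if (length(y) < 4L) stop("need at least 4 points for two predictors")
  fit <- stats::lm(y ~ x1 + x2)
  cf <- stats::coef(fit)
  sstot <- sum((y - mean(y))^2)
  r2 <- if (sstot == 0) 1 else 1 - sum(stats::resid(fit)^2) / sstot
  list(coefficients = cf, r2 = r2, n = length(y),
       collinear = anyNA(cf))
}

#' Per-protein correlation table (HYD--TC and TC--CC)
#'
#' For each of the 13 genes, correlates HYD with TC and TC with CC across
#' the analysis units (group means by default; species-level points when
#' `level = "species"`), each gene analysed as its own single-gene protein
#' set.
#'
#' @param records `mmp_fasta` or records data.frame.
#' @param scale,iterations Passed to the profiling step.
#' @param level `"group"` (default) or `"species"`.
#' @return Data.frame: `gene`, `HYD_TC_r2`, `HYD_TC_sign`, `TC_CC_r2`,
#'   `TC_CC_sign`, `n`, ordered by decreasing `HYD_TC_r2`.
#' @export
build_table1 <- function(records, scale = hydropathy_scale(),
                         iterations = 10L,
                         level = c("group", "species")) {
  level <- match.arg(level)
  if (inherits(records, "mmp_fasta")) records <- records$records
  sets <- stats::setNames(lapply(mmp_genes(), identity), mmp_genes())
  comp <- composition_table(records, sets, scale, iterations)
  if (level == "group") comp <- group_mean_composition(comp)
  rows <- lapply(mmp_genes(), function(g) {
    d <- comp[comp$protein_set == g, ]
    ht <- pearson_r2(d$HYD, d$TC)
    tc <- pearson_r2(d$TC, d$CC)
    data.frame(gene = g, HYD_TC_r2 = ht$r2, HYD_TC_sign = ht$sign,
               TC_CC_r2 = tc$r2, TC_CC_sign = tc$sign, n = ht$n)
  })
  out <- do.call(rbind, rows)
  out[order(-out$HYD_TC_r2), ]
}

table2_rows <- function() {
  c("TC-HYD", "TC-CC", "HYD-CC", "HYD-STC", "STC-CC",
    "TSN-TC", "TSN-HYD",
    "STC-ln(mtBMR)", "TC-ln(mtBMR)", "HYD-ln(mtBMR)", "CC-ln(mtBMR)",
    "STC-ln(msBMR)", "STC-ln(MLS)", "CC-ln(MLS)", "STC-ln(mtBMR*MLS)")
}

#' Variable-pair correlation table over the nested protein sets
#'
#' Builds the full correlation battery over group-mean points: the
#' composition pairs (TC-HYD, TC-CC, HYD-CC, HYD-STC, STC-CC), the TSN
#' pairs (TSN-TC, TSN-HYD; computed with the deuterostome groups excluded,
#' where the TSN gradients are monotone), and the metabolic/lifespan rows
#' (STC/TC/HYD/CC vs ln(mtBMR) at the sweep's best F, STC vs ln(msBMR),
#' STC/CC vs ln(MLS), and STC vs ln(mtBMR * MLS), the log of the lifetime
#' energy turned over per mitochondrion, computed as
#' ln(mtBMR) + ln(MLS)).  One column per protein set plus the arithmetic
#' row mean.
#'
#' @param group_comp Group-level table from [group_mean_composition()].
#' @param metadata `group_metadata` data.frame.
#' @param F_adj F value used for the mtBMR rows (e.g. `sweep$best_F`);
#'   default `Inf`.
#' @param sets Protein-set names to use as columns (default the five nested
#'   sets).
#' @return List of class `mmp_table2`: `r2` (matrix rows x sets plus
#'   `mean` column), `sign` (character matrix), `n` (integer matrix),
#'   `F_adj`.
#' @export
build_table2 <- function(group_comp, metadata, F_adj = Inf,
                         sets = c("set3", "set4", "set5", "set6", "set7")) {
  rows <- table2_rows()
  r2 <- matrix(NA_real_, length(rows), length(sets),
               dimnames = list(rows, sets))
  sgn <- matrix(NA_character_, length(rows), length(sets),
                dimnames = list(rows, sets))
  nmat <- matrix(NA_integer_, length(rows), length(sets),
                 dimnames = list(rows, sets))
  for (sn in sets) {
    d <- group_comp[group_comp$protein_set == sn, ]
    md <- metadata[match(d$group, metadata$group), ]
    keepmd <- !is.na(md$group)
    lnmt <- ln_mtbmr(md$C[keepmd], md$alpha[keepmd], md$M[keepmd], F_adj)
    lnms <- log(msbmr(md$C[keepmd], md$alpha[keepmd], md$M[keepmd]))
    lnmls <- log(md$MLS[keepmd])
    dm <- d[keepmd, ]
    non_deut <- md$clade[keepmd] != "deuterostome"
    vals <- list(
      "TC-HYD" = list(dm$TC, dm$HYD),
      "TC-CC" = list(dm$TC, dm$CC),
      "HYD-CC" = list(dm$HYD, dm$CC),
      "HYD-STC" = list(dm$HYD, dm$STC),
      "STC-CC" = list(dm$STC, dm$CC),
      "TSN-TC" = list(dm$TSN[non_deut], dm$TC[non_deut]),
      "TSN-HYD" = list(dm$TSN[non_deut], dm$HYD[non_deut]),
      "STC-ln(mtBMR)" = list(dm$STC, lnmt),
      "TC-ln(mtBMR)" = list(dm$TC, lnmt),
      "HYD-ln(mtBMR)" = list(dm$HYD, lnmt),
      "CC-ln(mtBMR)" = list(dm$CC, lnmt),
      "STC-ln(msBMR)" = list(dm$STC, lnms),
      "STC-ln(MLS)" = list(dm$STC, lnmls),
      "CC-ln(MLS)" = list(dm$CC, lnmls),
      "STC-ln(mtBMR*MLS)" = list(dm$STC, lnmt + lnmls))
    for (rn in rows) {
      p <- tryCatch(pearson_r2(vals[[rn]][[1]], vals[[rn]][[2]]),
                    error = function(e) NULL)
      if (!is.null(p)) {
        r2[rn, sn] <- p$r2; sgn[rn, sn] <- p$sign; nmat[rn, sn] <- p$n
      }
    }
  }
  r2 <- cbind(r2, mean = rowMeans(r2, na.rm = TRUE))
  structure(list(r2 = r2, sign = sgn, n = nmat, F_adj = F_adj),
            class = "mmp_table2")
}

#' @export
print.mmp_table2 <- function(x, digits = 4, ...) {
  cat(sprintf("variable-pair correlations (R^2), mtBMR at F = %s\n",
              format(x$F_adj)))
  m <- round(x$r2, digits)
  sgncol <- x$sign[, 1]
  print(data.frame(sign = sgncol, m[, , drop = FALSE],
                   check.names = FALSE))
  invisible(x)
}
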