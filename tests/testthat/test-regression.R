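test_that("squared Pearson correlation matches the textbook formula", {
  x <- 1:10
  expect_equal(pearson_r2(x, 2 * x + 1), list(r2 = 1, sign = "P", n = 10L))
  expect_equal(pearson_r2(x, -x)$sign, "N")
  set.seed(21)
  for (i in 1:20) {
    a <- rnorm(20); b <- rnorm(20) + 0.3 * a
    expect_equal(pearson_r2(a, b)$r2, pearson_manual(a, b)^2,
                 tolerance = 1e-12)
  }
  expect_error(pearson_r2(x, rep(1, 10)), "zero variance")
  expect_error(pearson_r2(1:2, 2:3), "at least 3")
})

test_that("linear fits recover generating lines exactly", {
  hyd <- seq(0.45, 0.62, length.out = 9)
  f1 <- fit_linear(hyd, -65.66 * hyd + 41.75)
  expect_equal(f1$slope, -65.66, tolerance = 1e-9)
  expect_equal(f1$intercept, 41.75, tolerance = 1e-9)
  expect_equal(f1$r2, 1, tolerance = 1e-12)

  f2 <- fit_linear(hyd, -18.32 * hyd + 14.92)
  expect_equal(f2$slope, -18.32, tolerance = 1e-9)
  expect_equal(f2$intercept, 14.92, tolerance = 1e-9)

  # two distinct points: the interpolating line
  f3 <- fit_linear(c(1, 3), c(2, 8))
  expect_equal(f3$slope, 3)
  expect_equal(f3$intercept, -1)

  expect_error(fit_linear(rep(2, 5), 1:5), "zero variance in x")
})

test_that("subset fits partition the points", {
  x <- 1:10; y <- x + rnorm(10)
  deut <- c(rep(TRUE, 4), rep(FALSE, 6))
  fa <- fit_linear(x, y, deut); fb <- fit_linear(x, y, !deut)
  expect_equal(fa$n + fb$n, 10L)
})

test_that("power fit recovers generating coefficients on clean data", {
  x <- seq(0.45, 0.62, length.out = 10)
  f <- fit_power(x, 0.429 * x^-4.2045)
  expect_equal(f$a, 0.429, tolerance = 1e-6)
  expect_equal(f$b, -4.2045, tolerance = 1e-6)
  expect_equal(f$r2, 1, tolerance = 1e-9)
  expect_true(f$converged)
  # log-log route agrees in the noise-free limit
  expect_equal(f$loglog$a, 0.429, tolerance = 1e-9)
  expect_equal(f$loglog$b, -4.2045, tolerance = 1e-9)

  # constant y: zero residuals leave the gradient singular, so the fit may
  # legitimately come back via the signalled log-log fallback
  fc <- suppressWarnings(fit_power(x, rep(3.3, 10)))
  expect_equal(fc$b, 0, tolerance = 1e-6)
  expect_equal(fc$a, 3.3, tolerance = 1e-6)

  expect_error(fit_power(c(-1, 1, 2), c(1, 2, 3)), "positive")
})

test_that("R^2 is invariant under affine transforms of either variable", {
  set.seed(31)
  x <- runif(15); y <- 2 * x + rnorm(15, sd = 0.2)
  r0 <- pearson_r2(x, y)$r2
  expect_equal(pearson_r2(3 * x - 1, y)$r2, r0)
  expect_equal(pearson_r2(x, -0.5 * y + 4)$r2, r0)
})

test_that("two-predictor fit nests the single-predictor fits", {
  set.seed(41)
  for (i in 1:25) {
    x1 <- rnorm(12); x2 <- rnorm(12)
    y <- 1 + 0.8 * x1 - 0.5 * x2 + rnorm(12)
    m <- multi_linear(y, x1, x2)
    expect_gte(m$r2 + 1e-12, pearson_r2(x1, y)$r2)
    expect_gte(m$r2 + 1e-12, pearson_r2(x2, y)$r2)
  }
  y <- 2 + 3 * rnorm(10); x1 <- rnorm(10); x2 <- rnorm(10)
  exact <- 1 - 2 * x1 + 4 * x2
  expect_equal(multi_linear(exact, x1, x2)$r2, 1, tolerance = 1e-12)
  # pure-noise second predictor adds (almost) nothing
  m2 <- multi_linear(0.9 * x1, x1, x2)
  expect_equal(m2$r2, 1, tolerance = 1e-9)
  mc <- multi_linear(rnorm(10), x1, 2 * x1)
  expect_true(mc$collinear)
})

test_that("per-gene correlation table ranks a constructed signal", {
  co <- small_cohort(seed = 13, n_species = 6, len_scale = 0.8)
  t1 <- build_table1(co$records)
  expect_setequal(t1$gene, mmp_genes())
  # the generator ties TC to HYD in every gene; in the long subunits the
  # pooled site counts give the correlation real statistical power, while
  # the shortest genes (ATP8, ND4L, ...) stay noisy at this cohort size
  long <- c("ND4", "ND5", "ND2", "CO1", "CYTB")
  expect_true(all(t1$HYD_TC_sign[t1$gene %in% long] == "N"))
  expect_true(all(t1$HYD_TC_r2[t1$gene %in% long] > 0.5))
  expect_gt(median(t1$HYD_TC_r2), 0.3)
  expect_equal(t1$n, rep(13L, 13L))
})

test_that("variable-pair table fills every row with its n and sign", {
  co <- small_cohort(seed = 14, n_species = 6, len_scale = 0.8)
  comp <- composition_table(co$records, protein_sets())
  g <- group_mean_composition(comp)
  t2 <- build_table2(g, co$metadata, F_adj = Inf)
  expect_equal(dim(t2$r2), c(15L, 6L))
  expect_true(all(t2$r2[, "mean"] ==
                    rowMeans(t2$r2[, 1:5, drop = FALSE], na.rm = TRUE)))
  expect_true(all(t2$r2[is.finite(t2$r2)] >= 0 &
                    t2$r2[is.finite(t2$r2)] <= 1))
  # strong designed TC-HYD dependence, negative
  expect_true(all(t2$r2["TC-HYD", 1:5] > 0.8))
  expect_true(all(t2$sign["TC-HYD", ] == "N"))
  # composition rows use all 13 groups; TSN rows exclude the 5 deuterostomes
  expect_true(all(t2$n["TC-HYD", ] == 13L))
  expect_true(all(t2$n["TSN-TC", ] == 8L))
  # the lifetime-energy row is the elementwise product inside the log
  md <- co$metadata
  expect_equal(ln_mtbmr(md$C, md$alpha, md$M, 2) + log(md$MLS),
               log(mtbmr(md$C, md$alpha, md$M, 2) * md$MLS))
})

test_that("independent variables give near-zero table cells", {
  set.seed(55)
  r2s <- replicate(20, {
    x <- rnorm(13); y <- rnorm(13)
    pearson_r2(x, y)$r2
  })
  expect_lt(median(r2s), 0.2)
})
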