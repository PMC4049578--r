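test_that("identical spec and seed give byte-identical cohorts", {
  spec <- default_cohort_spec(n_species = 2, gene_length_scale = 0.2,
                              seed = 99)
  spec$groups <- spec$groups[1:3, ]
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_cohort(simulate_cohort(spec), d1)
  write_cohort(simulate_cohort(spec), d2)
  for (f in c("cohort.faa", "metadata.tsv", "truth.json"))
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = f)
  # and a different seed changes the sequences
  spec$seed <- 100L
  write_cohort(simulate_cohort(spec), d2)
  expect_false(identical(unname(tools::md5sum(file.path(d1, "cohort.faa"))),
                         unname(tools::md5sum(file.path(d2, "cohort.faa")))))
})

test_that("realized compositions hit the targets within sampling error", {
  spec <- default_cohort_spec(n_species = 1, noise_sd = 0, noise_hyd = 0,
                              seed = 12)
  spec$groups <- spec$groups[spec$groups$group %in%
                               c("Aves", "Platyhelminthes"), ]
  co <- simulate_cohort(spec)
  comp <- composition_table(co$records, protein_sets("all13"))
  for (i in seq_len(nrow(comp))) {
    g <- spec$groups[spec$groups$group == comp$group[i], ]
    n_sites <- comp$TSN[i]   # ~3400 sites per species over all 13 genes
    for (v in c("TC", "SC", "CC")) {
      p <- g[[paste0("target_", v)]] / 100
      bound <- 100 * 4 * sqrt(p * (1 - p) / n_sites)  # ~99.99% interval
      expect_lt(abs(comp[[v]][i] - 100 * p), bound)
    }
    # smoothing preserves the mean score, so HYD over the (nearly
    # all-positive) domain sits close to the target mean hydropathy
    expect_lt(abs(comp$HYD[i] - g$target_HYD), 0.05)
  }
})

test_that("single-species groups pass through aggregation unchanged", {
  spec <- default_cohort_spec(n_species = 1, noise_sd = 0,
                              gene_length_scale = 0.3, seed = 5)
  spec$groups <- spec$groups[1:3, ]
  co <- simulate_cohort(spec)
  comp <- composition_table(co$records, protein_sets("set3"))
  g <- group_mean_composition(comp)
  expect_equal(sort(g$TC), sort(comp$TC))
})

test_that("infeasible composition targets are refused", {
  spec <- default_cohort_spec(seed = 1)
  spec$groups$target_TC[1] <- 60
  spec$groups$target_SC[1] <- 50
  expect_error(simulate_cohort(spec), "infeasible")
})

test_that("the truth record regenerates the cohort bit-for-bit", {
  spec <- default_cohort_spec(n_species = 2, gene_length_scale = 0.2,
                              seed = 31)
  spec$groups <- spec$groups[c(1, 9, 13), ]
  co <- simulate_cohort(spec)
  co2 <- simulate_cohort(co$truth$spec)
  expect_identical(co$records, co2$records)
})

test_that("block-structured sampling keeps compositions but shapes domains", {
  spec <- default_cohort_spec(n_species = 1, noise_sd = 0, noise_hyd = 0,
                              block_structure = TRUE, seed = 8)
  spec$groups <- spec$groups[spec$groups$group == "Fishes", ]
  co <- simulate_cohort(spec)
  comp <- composition_table(co$records, protein_sets("all13"))
  g <- spec$groups[1, ]
  expect_lt(abs(comp$TC - g$target_TC), 1.2)
  # segments create genuine sub-maximal hydrophobic domains
  prof <- profile_protein(co$records$sequence[1], iterations = 10)
  expect_true(any(prof$mask) && !all(prof$mask))
})

test_that("allometric simulation embeds the declared affine link", {
  sim <- simulate_allometry(F_true = 3, slope = 1.2, noise_sd = 0,
                            seed = 44)
  lnmt <- ln_mtbmr(sim$metadata$C, sim$metadata$alpha, sim$metadata$M, 3)
  fit <- fit_linear(lnmt, unname(sim$stc))
  expect_equal(fit$slope, 1.2, tolerance = 1e-9)
  expect_equal(fit$intercept, sim$truth$intercept, tolerance = 1e-9)
  expect_warning(simulate_allometry(mass_decades = 2, seed = 1),
                 "orders of magnitude")
  expect_error(simulate_allometry(n_groups = 3), "at least 5")
})
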