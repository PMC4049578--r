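#' Default pipeline configuration
#'
#' @param fasta,metadata Input paths.
#' @param out_dir Output directory.
#' @param ... Overrides of the defaults (see Details).
#' @details Configurable keys: `scale` (scale name or file), `iterations`
#'   (smoothing passes, default 10), `domain` (`full_sequence` /
#'   `hydrophobic_mask`), `sets` (protein-set names), `sweep_set` (set whose
#'   STC drives the F sweep, default `set3`), `f_grid`, `table2_sets`,
#'   `fit_set` (set used for the TC--HYD and TSN fits, default `set5`),
#'   `tree_set`, `tree_variables`, `tree_sd_type`, `level` (`group` /
#'   `species` regression points), `min_species`.
#' @return Named list of class `mmp_config`.
#' @export
pipeline_config <- function(fasta, metadata, out_dir, ...) {
  cfg <- list(
    fasta = fasta, metadata = metadata, out_dir = out_dir,
    scale = "cowan_whittaker", iterations = 10L,
    domain = "full_sequence",
    sets = c("set3", "set4", "set5", "set6", "set7", "all13"),
    sweep_set = "set3", f_grid = default_f_grid(),
    table2_sets = c("set3", "set4", "set5", "set6", "set7"),
    fit_set = "set5",
    tree_set = "set5", tree_variables = c("TC", "TSN"),
    tree_sd_type = "population",
    level = "group", min_species = 1L)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  class(cfg) <- c("mmp_config", "list")
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' Flat keys mirroring [pipeline_config()]; `fasta`, `metadata` and
#' `out_dir` are required.
#'
#' @param path YAML file.
#' @return `mmp_config`.
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  need <- c("fasta", "metadata", "out_dir")
  miss <- setdiff(need, names(y))
  if (length(miss))
    stop("config is missing key(s): ", paste(miss, collapse = ", "))
  if (!is.null(y$f_grid))
    y$f_grid <- vapply(y$f_grid,
                       function(v) if (identical(v, "Inf")) Inf
                       else as.numeric(v), numeric(1))
  do.call(pipeline_config, y)
}

write_tsv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) sprintf("%.10g", x))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  path
}

#' Run the full comparative pipeline
#'
#' Reads sequences and metadata, validates them, computes species- and
#' group-level composition tables over the configured protein sets, the
#' per-protein correlation table, the F sweep, the variable-pair
#' correlation table at the sweep's best F, the TC--HYD power/linear fits
#' with the deuterostome split, the TSN regressions, and the
#' neighbor-joining tree, writing every result plus a run manifest (config,
#' package version, input checksums) into `out_dir`.  The pipeline is
#' deterministic: rerunning the same config on the same inputs reproduces
#' every output byte-for-byte.
#'
#' @param config An `mmp_config` (or path to a YAML config).
#' @return Invisible list with the in-memory results (`validation`,
#'   `composition`, `group_composition`, `table1`, `sweep`, `table2`,
#'   `fits`, `tree`, `out_dir`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_config(config)
  cfg <- config
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  scale <- hydropathy_scale(cfg$scale)
  sets <- protein_sets(cfg$sets)

  fa <- read_mmp_fasta(cfg$fasta)
  md <- read_group_metadata(cfg$metadata)
  write_tsv(fa$rejects, file.path(cfg$out_dir, "rejects.tsv"))
  val <- validate_dataset(fa, md, sets, cfg$min_species)
  jsonlite::write_json(unclass(val), file.path(cfg$out_dir,
                                               "validation.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  comp <- composition_table(fa, sets, scale, cfg$iterations, cfg$domain)
  gcomp <- group_mean_composition(comp)
  write_tsv(comp, file.path(cfg$out_dir, "composition_species.tsv"))
  write_tsv(gcomp, file.path(cfg$out_dir, "composition_groups.tsv"))

  tab1 <- build_table1(fa, scale, cfg$iterations, cfg$level)
  write_tsv(tab1, file.path(cfg$out_dir, "table1.tsv"))

  gsweep <- gcomp[gcomp$protein_set == cfg$sweep_set, ]
  sweep <- f_sweep(md, stats::setNames(gsweep$STC, gsweep$group),
                   cfg$f_grid)
  write_tsv(data.frame(F = sweep$grid, r2 = sweep$r2, n = sweep$n),
            file.path(cfg$out_dir, "fsweep.tsv"))
  write_tsv(data.frame(group = names(sweep$mtbmr_best),
                       mtbmr = unname(sweep$mtbmr_best)),
            file.path(cfg$out_dir, "mtbmr_bestF.tsv"))

  tab2 <- build_table2(gcomp, md, sweep$best_F, cfg$table2_sets)
  t2 <- data.frame(pair = rownames(tab2$r2), sign = tab2$sign[, 1],
                   tab2$r2, check.names = FALSE)
  write_tsv(t2, file.path(cfg$out_dir, "table2.tsv"))

  dfit <- gcomp[gcomp$protein_set == cfg$fit_set, ]
  clade <- md$clade[match(dfit$group, md$group)]
  deut <- clade == "deuterostome"
  # a fit on too few groups is reported as its error, not fatal
  safely <- function(expr) tryCatch(unclass(expr), error = function(e)
    list(error = conditionMessage(e)))
  fits <- list(
    tc_hyd_power = safely(fit_power(dfit$HYD, dfit$TC)),
    tc_hyd_linear_deuterostome =
      safely(fit_linear(dfit$HYD, dfit$TC, deut)),
    tc_hyd_linear_other = safely(fit_linear(dfit$HYD, dfit$TC, !deut)),
    tsn_tc_other = safely(fit_linear(dfit$TSN, dfit$TC, !deut)),
    tsn_hyd_other = safely(fit_linear(dfit$TSN, dfit$HYD, !deut)),
    tsn_tc_deuterostome = safely(fit_linear(dfit$TSN, dfit$TC, deut)),
    tsn_hyd_deuterostome = safely(fit_linear(dfit$TSN, dfit$HYD, deut)))
  mdx <- md[match(dfit$group, md$group), ]
  fits$stc_hyd_multi <- safely(multi_linear(
    ln_mtbmr(mdx$C, mdx$alpha, mdx$M, sweep$best_F), dfit$STC, dfit$HYD))
  jsonlite::write_json(fits, file.path(cfg$out_dir, "fits.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  D <- trait_distance(gcomp, cfg$tree_variables, cfg$tree_set,
                      cfg$tree_sd_type)
  tree <- neighbor_joining(D)
  write_distance(D, file.path(cfg$out_dir, "trait_distance.tsv"))
  write_newick(tree, file.path(cfg$out_dir, "tree.nwk"))

  manifest <- list(
    config = lapply(unclass(cfg), function(v)
      if (is.numeric(v)) ifelse(is.infinite(v), "Inf", v) else v),
    package_version = as.character(utils::packageVersion("mmpevol")),
    inputs = list(fasta_md5 = unname(tools::md5sum(cfg$fasta)),
                  metadata_md5 = unname(tools::md5sum(cfg$metadata))))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(validation = val, composition = comp,
                 group_composition = gcomp, table1 = tab1, sweep = sweep,
                 table2 = tab2, fits = fits, tree = tree,
                 out_dir = cfg$out_dir))
}
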