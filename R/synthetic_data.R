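#' Default cohort specification
#'
#' Thirteen animal groups (Porifera, Cnidaria, six protostome groups, and
#' the deuterostome series Echinodermata--Fishes--Amphibia--Eutheria--Aves)
#' with group target compositions lying on the inverse TC--HYD power curve
#' TC = a * HYD^b, Ser tied to Thr (SC = 0.8 TC), a weak opposing Cys trend,
#' gene lengths proportional to the human reference lengths with a
#' group-specific total-site-number factor, and allometric metadata with
#' log-spaced body masses.  All values are the generator's fixed study
#' conditions; the `truth` element of [simulate_cohort()] records them.
#'
#' @param n_species Species per group (default 20).
#' @param gene_length_scale Multiplier on the reference gene lengths
#'   (default 1; lower it for fast toy cohorts).
#' @param power_a,power_b Coefficients of the TC--HYD power relation
#'   (defaults 0.429 and -4.2045).
#' @param noise_sd Per-species Gaussian jitter on the composition targets,
#'   percentage points (default 0.35).
#' @param noise_hyd Per-species jitter on the target mean hydropathy,
#'   score units (default 0.015).
#' @param block_structure Use the two-state (hydrophobic/polar segment)
#'   sampler instead of iid residue sampling (default FALSE).
#' @param seed Master seed (mandatory for [simulate_cohort()]).
#' @return List of class `cohort_spec`.
#' @export
default_cohort_spec <- function(n_species = 20L, gene_length_scale = 1,
                                power_a = 0.429, power_b = -4.2045,
                                noise_sd = 0.35, noise_hyd = 0.015,
                                block_structure = FALSE, seed = 1L) {
  groups <- data.frame(
    group = c("Porifera", "Cnidaria", "Mollusca", "Crustacea", "Hexapoda",
              "Chelicerata", "Nematoda", "Platyhelminthes",
              "Echinodermata", "Fishes", "Amphibia", "Eutheria", "Aves"),
    clade = c("basal", "basal", rep("protostome", 6),
              rep("deuterostome", 5)),
    target_HYD = c(0.730, 0.720, 0.690, 0.700, 0.705, 0.710, 0.745, 0.750,
                   0.665, 0.645, 0.620, 0.585, 0.580),
    tsn_factor = c(0.97, 0.95, 0.92, 0.90, 0.89, 0.88, 0.85, 0.84,
                   0.96, 1.00, 0.99, 0.97, 0.93),
    M = c(1, 5, 10, 5, 0.05, 0.5, 0.001, 0.01, 50, 500, 30, 5000, 300),
    C = c(0.3, 0.4, 0.5, 0.6, 0.8, 0.6, 0.3, 0.25, 0.5, 1.0, 1.2, 3.5,
          4.5),
    alpha = c(0.75, 0.76, 0.74, 0.73, 0.75, 0.74, 0.72, 0.70, 0.75, 0.79,
              0.77, 0.71, 0.67),
    MLS = c(20, 10, 8, 5, 1.5, 4, 1, 2, 15, 15, 12, 25, 18),
    stringsAsFactors = FALSE)
  groups$target_TC <- power_a * groups$target_HYD^power_b
  groups$target_SC <- 0.8 * groups$target_TC
  groups$target_CC <- pmax(0.2, 1.4 - 0.08 * groups$target_TC)
  structure(list(groups = groups, n_species = as.integer(n_species),
                 gene_length_scale = gene_length_scale,
                 power_a = power_a, power_b = power_b,
                 noise_sd = noise_sd, noise_hyd = noise_hyd,
                 block_structure = block_structure, seed = as.integer(seed)),
            class = "cohort_spec")
}

# residue pools used by the generator: strongly hydrophobic vs the polar
# remainder (S, T, C handled explicitly by the targets)
POOL_HYDRO <- c("I", "L", "V", "F", "M", "W")
POOL_POLAR <- c("G", "A", "P", "Y", "H", "N", "Q", "D", "E", "K", "R")

# per-residue sampling probabilities hitting the composition and
# mean-hydropathy targets in expectation
residue_probs <- function(tc, sc, cc, mu, scale) {
  p_fix <- c(T = tc, S = sc, C = cc) / 100
  if (sum(p_fix) >= 1)
    stop("infeasible targets: T/S/C percentages sum to >= 100")
  rest <- 1 - sum(p_fix)
  mean_hp <- mean(scale[POOL_HYDRO]); mean_po <- mean(scale[POOL_POLAR])
  contrib <- sum(p_fix * scale[c("T", "S", "C")])
  h <- (mu - contrib - rest * mean_po) / (mean_hp - mean_po)
  if (h < 0 || h > rest) {
    warning("target mean hydropathy clipped to the feasible range")
    h <- min(max(h, 0), rest)
  }
  probs <- c(p_fix,
             stats::setNames(rep(h / length(POOL_HYDRO),
                                 length(POOL_HYDRO)), POOL_HYDRO),
             stats::setNames(rep((rest - h) / length(POOL_POLAR),
                                 length(POOL_POLAR)), POOL_POLAR))
  probs[AA_CANONICAL]
}

sample_sequence_iid <- function(len, probs) {
  paste(sample(names(probs), len, replace = TRUE, prob = probs),
        collapse = "")
}

# two-state segment sampler: hydrophobic runs (mean length 15) alternate
# with polar runs; stationary hydrophobic occupancy matches the iid target,
# so expected compositions are unchanged but the smoothed profile acquires
# genuine positive/negative domains
sample_sequence_blocks <- function(len, probs, mean_h_run = 15) {
  h <- sum(probs[POOL_HYDRO])
  if (h <= 0 || h >= 1) return(sample_sequence_iid(len, probs))
  mean_p_run <- mean_h_run * (1 - h) / h
  em_h <- probs[POOL_HYDRO] / h
  em_p <- probs[setdiff(names(probs), POOL_HYDRO)] / (1 - h)
  out <- character(0); state_h <- stats::runif(1) < h
  while (length(out) < len) {
    run <- 1L + stats::rgeom(1, 1 / (if (state_h) mean_h_run else mean_p_run))
    em <- if (state_h) em_h else em_p
    out <- c(out, sample(names(em), run, replace = TRUE, prob = em))
    state_h <- !state_h
  }
  paste(out[seq_len(len)], collapse = "")
}

#' Reference gene lengths used by the generator
#'
#' @return Named integer vector over the 13 canonical genes (human
#'   reference mitochondrial annotation).
#' @export
reference_gene_lengths <- function() {
  tab <- utils::read.delim(
    system.file("extdata", "human_mmp_lengths.tsv", package = "mmpevol",
                mustWork = TRUE), comment.char = "#")
  stats::setNames(as.integer(tab$length), tab$gene)
}

#' Simulate a sequence cohort with known composition structure
#'
#' Sequences are drawn residue-by-residue from per-species multinomial
#' frequencies tuned so that expected Thr/Ser/Cys percentages and the
#' expected mean hydropathy score hit the (jittered) group targets; gene
#' lengths follow the human reference lengths scaled by the group's
#' total-site-number factor.  Identical spec + seed gives an identical
#' cohort.
#'
#' @param spec A [default_cohort_spec()] (possibly modified).
#' @return List of class `mmp_cohort`: `records` (species x gene
#'   data.frame as in [read_mmp_fasta()]), `metadata` (`group_metadata`),
#'   `truth` (every generator parameter, including the per-species
#'   realised targets).
#' @export
simulate_cohort <- function(spec = default_cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (is.null(spec$seed)) stop("spec$seed is mandatory")
  scale <- hydropathy_scale()
  base_len <- reference_gene_lengths()
  genes <- names(base_len)
  rec <- vector("list", 0L)
  species_truth <- vector("list", 0L)
  for (gi in seq_len(nrow(spec$groups))) {
    g <- spec$groups[gi, ]
    set.seed((as.numeric(spec$seed) * 1000003 + gi * 7919) %% 2147483647)
    lens <- stats::setNames(
      pmax(30L, as.integer(round(base_len * g$tsn_factor *
                                   spec$gene_length_scale))),
      genes)
    for (si in seq_len(spec$n_species)) {
      tc <- max(0.05, g$target_TC + stats::rnorm(1, 0, spec$noise_sd))
      sc <- max(0.05, g$target_SC + stats::rnorm(1, 0, spec$noise_sd))
      cc <- max(0.05, g$target_CC + stats::rnorm(1, 0, spec$noise_sd / 2))
      mu <- g$target_HYD + stats::rnorm(1, 0, spec$noise_hyd)
      probs <- residue_probs(tc, sc, cc, mu, scale)
      sp <- sprintf("%s_sp%02d", g$group, si)
      for (gn in genes) {
        seqstr <- if (spec$block_structure)
          sample_sequence_blocks(lens[[gn]], probs)
        else sample_sequence_iid(lens[[gn]], probs)
        rec[[length(rec) + 1L]] <- data.frame(
          species_id = sp, group = g$group, gene = gn, sequence = seqstr,
          stringsAsFactors = FALSE)
      }
      species_truth[[length(species_truth) + 1L]] <- data.frame(
        species_id = sp, group = g$group, target_TC = tc, target_SC = sc,
        target_CC = cc, target_HYD = mu)
    }
  }
  records <- do.call(rbind, rec)
  metadata <- spec$groups[c("group", "clade", "M", "C", "alpha", "MLS")]
  class(metadata) <- c("group_metadata", "data.frame")
  truth <- list(spec = spec,
                species_targets = do.call(rbind, species_truth))
  structure(list(records = records, metadata = metadata, truth = truth),
            class = "mmp_cohort")
}

#' Write a simulated cohort to disk
#'
#' Emits `cohort.faa` (FASTA in the package's header dialect),
#' `metadata.tsv`, and `truth.json` holding every generator parameter (the
#' spec plus the per-species realised targets), from which the cohort can
#' be regenerated bit-for-bit.
#'
#' @param cohort An `mmp_cohort` from [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_mmp_fasta(cohort$records, file.path(dir, "cohort.faa"))
  utils::write.table(cohort$metadata, file.path(dir, "metadata.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(spec = unclass(cohort$truth$spec),
         species_targets = cohort$truth$species_targets),
    file.path(dir, "truth.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Simulate group metadata with a known STC--ln(mtBMR) link
#'
#' Builds an allometric metadata table whose group STC values are exactly
#' affine in ln(mtBMR) at a chosen true F, plus Gaussian noise.  Group
#' allometric constants C and exponents alpha vary across groups (C
#' log-normal, alpha uniform); without that variation every F would fit a
#' mass-gradient cohort equally well and the sweep could not identify
#' F_true.
#'
#' @param n_groups Number of groups (>= 5).
#' @param F_true The generating F (`Inf` allowed).
#' @param slope,intercept Affine link STC = intercept + slope * ln(mtBMR);
#'   intercept defaults to a value keeping STC in a realistic 2--10 range.
#' @param noise_sd Gaussian noise on STC, percentage points (default 0:
#'   exact construction).
#' @param mass_decades Total span of log10 body mass (default 6; a warning
#'   is issued below 3).
#' @param seed Seed for the random draws.
#' @return List: `metadata` (`group_metadata`), `stc` (named vector),
#'   `truth` (generator parameters).
#' @export
simulate_allometry <- function(n_groups = 13L, F_true = Inf, slope = 1.2,
                               intercept = NULL, noise_sd = 0,
                               mass_decades = 6, seed = 1L) {
  if (n_groups < 5L) stop("need at least 5 groups")
  if (mass_decades < 3)
    warning("mass range spans < 3 orders of magnitude; F is weakly identified")
  set.seed(seed %% 2147483647L)
  M <- 10^seq(-mass_decades / 2, mass_decades / 2,
              length.out = n_groups)
  C <- exp(stats::rnorm(n_groups, log(0.5), 0.6))
  alpha <- stats::runif(n_groups, 0.66, 0.80)
  MLS <- exp(stats::rnorm(n_groups, log(8), 0.7))
  groups <- sprintf("G%02d", seq_len(n_groups))
  lnmt <- ln_mtbmr(C, alpha, M, F_true)
  if (is.null(intercept)) intercept <- 6 - slope * mean(lnmt)
  stc <- intercept + slope * lnmt + stats::rnorm(n_groups, 0, noise_sd)
  md <- data.frame(group = groups,
                   clade = rep(c("protostome", "deuterostome", "basal"),
                               length.out = n_groups),
                   M = M, C = C, alpha = alpha, MLS = MLS,
                   stringsAsFactors = FALSE)
  class(md) <- c("group_metadata", "data.frame")
  list(metadata = md, stc = stats::setNames(stc, groups),
       truth = list(F_true = F_true, slope = slope, intercept = intercept,
                    noise_sd = noise_sd, seed = seed))
}
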