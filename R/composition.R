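#' Count canonical residues in a set of sequences
#'
#' Ambiguity codes are excluded from both numerator and denominator of any
#' percentage downstream.
#'
#' @param sequences Character vector of amino-acid strings.
#' @return Named integer vector of counts over the 20 canonical residues.
#' @keywords internal
count_residues <- function(sequences) {
  aa <- Biostrings::AAStringSet(toupper(sequences))
  m <- Biostrings::letterFrequency(aa, letters = AA_CANONICAL)
  stats::setNames(as.integer(colSums(m)), AA_CANONICAL)
}

#' Percentage of a residue subset, pooled over sequences
#'
#' 100 x (sites carrying a residue of `residues`) / (all canonical sites),
#' pooled by concatenation over the supplied sequences (one species x one
#' protein set, typically).  With `domain = "hydrophobic_mask"` only sites
#' inside the hydrophobic domain (smoothed score S(n) > 0) enter numerator
#' and denominator; profiles must then be supplied.
#'
#' @param sequences Character vector of sequences to pool.
#' @param residues Residue subset, e.g. `c("S", "T")`.
#' @param domain `"full_sequence"` (default) or `"hydrophobic_mask"`.
#' @param profiles List of [profile_protein()] results parallel to
#'   `sequences` (required for the mask domain).
#' @return Percentage in \[0, 100\].
#' @export
#' @examples
#' residue_percent("STAA", "T")          # 25
#' residue_percent(c("ST", "AA"), c("S", "T"))  # 50
residue_percent <- function(sequences, residues,
                            domain = c("full_sequence", "hydrophobic_mask"),
                            profiles = NULL) {
  domain <- match.arg(domain)
  residues <- toupper(residues)
  stopifnot(all(residues %in% AA_CANONICAL))
  if (domain == "full_sequence") {
    cnt <- count_residues(sequences)
    denom <- sum(cnt)
    if (denom == 0L) stop("no canonical residues to count")
    return(100 * sum(cnt[residues]) / denom)
  }
  if (is.null(profiles) || length(profiles) != length(sequences))
    stop("hydrophobic_mask domain requires one profile per sequence")
  num <- 0L; denom <- 0L
  for (i in seq_along(sequences)) {
    p <- profiles[[i]]
    res <- strsplit(toupper(sequences[i]), "")[[1]][p$positions]
    inmask <- res[p$mask]
    denom <- denom + length(inmask)
    num <- num + sum(inmask %in% residues)
  }
  if (denom == 0L) stop("empty hydrophobic domain across pooled sequences")
  100 * num / denom
}

#' Total site number of a protein set
#'
#' TSN is the pooled count of canonical amino-acid sites over the genes of a
#' protein set for one species (ambiguity codes do not count as sites).
#'
#' @param records Data.frame of records for one species (`gene`,
#'   `sequence`).
#' @param genes Character vector of canonical gene symbols making up the
#'   set.
#' @return Integer site count.
#' @export
tsn <- function(records, genes) {
  miss <- setdiff(genes, records$gene)
  if (length(miss))
    stop("missing gene(s) for TSN: ", paste(miss, collapse = ", "))
  seqs <- records$sequence[match(genes, records$gene)]
  sum(count_residues(seqs))
}

#' Species-level composition table
#'
#' For every species x protein set, computes the pooled Thr percentage (TC),
#' Ser percentage (SC), Ser+Thr percentage (STC), Cys percentage (CC), the
#' total site number (TSN) and the pooled hydrophobicity HYD (mean smoothed
#' score over sites with S(n) > 0, pooled across the set's genes).  Species
#' lacking any gene of a set are dropped from that set's rows (and reported
#' via the `dropped` attribute).
#'
#' @param records `mmp_fasta` object or its `records` data.frame.
#' @param sets Named list of protein sets (default [protein_sets()]).
#' @param scale Hydrophobicity scale for HYD.
#' @param iterations Smoothing passes for the profiles.
#' @param domain Composition domain: percentages over the full sequence
#'   (default) or restricted to the hydrophobic mask.
#' @return Data.frame with columns `species_id`, `group`, `protein_set`,
#'   `domain`, `TC`, `SC`, `STC`, `CC`, `TSN`, `HYD`.
#' @export
composition_table <- function(records, sets = protein_sets(),
                              scale = hydropathy_scale(),
                              iterations = 10L,
                              domain = c("full_sequence",
                                         "hydrophobic_mask")) {
  domain <- match.arg(domain)
  if (inherits(records, "mmp_fasta")) records <- records$records

  # one profile per record, reused by every set
  profiles <- lapply(records$sequence, profile_protein, scale = scale,
                     iterations = iterations)

  sp_group <- unique(records[c("species_id", "group")])
  rows <- vector("list", 0L); dropped <- vector("list", 0L)
  for (k in seq_len(nrow(sp_group))) {
    sp <- sp_group$species_id[k]
    idx_sp <- which(records$species_id == sp)
    have <- records$gene[idx_sp]
    for (sn in names(sets)) {
      genes <- sets[[sn]]
      if (!all(genes %in% have)) {
        dropped[[length(dropped) + 1L]] <-
          data.frame(species_id = sp, protein_set = sn)
        next
      }
      idx <- idx_sp[match(genes, have)]
      seqs <- records$sequence[idx]
      prof <- profiles[idx]
      pooled_s <- unlist(lapply(prof, `[[`, "smoothed"), use.names = FALSE)
      hyd <- if (any(pooled_s > 0)) mean(pooled_s[pooled_s > 0]) else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        species_id = sp, group = sp_group$group[k], protein_set = sn,
        domain = domain,
        TC = residue_percent(seqs, "T", domain, prof),
        SC = residue_percent(seqs, "S", domain, prof),
        STC = residue_percent(seqs, c("S", "T"), domain, prof),
        CC = residue_percent(seqs, "C", domain, prof),
        TSN = tsn(records[idx, ], genes),
        HYD = hyd,
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(species_id = character(), group = character(),
               protein_set = character(), domain = character(),
               TC = numeric(), SC = numeric(), STC = numeric(),
               CC = numeric(), TSN = integer(), HYD = numeric())
  attr(out, "dropped") <- if (length(dropped)) do.call(rbind, dropped) else
    data.frame(species_id = character(), protein_set = character())
  out
}

#' Aggregate a species-level composition table to group means
#'
#' Unweighted arithmetic mean of each variable over the species of a group;
#' per-group standard deviation and species count are reported alongside.
#'
#' @param comp Species-level table from [composition_table()].
#' @return Data.frame with columns `group`, `protein_set`, `domain`, `n`,
#'   the per-variable means (`TC`, `SC`, `STC`, `CC`, `TSN`, `HYD`) and
#'   their standard deviations (`TC_sd`, ...).
#' @export
group_mean_composition <- function(comp) {
  vars <- c("TC", "SC", "STC", "CC", "TSN", "HYD")
  key <- interaction(comp$group, comp$protein_set, comp$domain, drop = TRUE)
  pieces <- lapply(split(comp, key), function(d) {
    out <- data.frame(group = d$group[1], protein_set = d$protein_set[1],
                      domain = d$domain[1], n = nrow(d))
    for (v in vars) {
      out[[v]] <- mean(d[[v]])
      out[[paste0(v, "_sd")]] <- if (nrow(d) > 1) stats::sd(d[[v]]) else 0
    }
    out
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out[order(out$protein_set, out$group), ]
}
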