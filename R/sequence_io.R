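#' Gene-symbol synonym table
#'
#' Cross-taxon database annotations name the same mitochondrial gene in many
#' ways (COX1/COI/MT-CO1, CYB/COB/MT-CYB, NAD4/NADH4, ...).  The synonym
#' table shipped with the package maps those spellings onto the canonical
#' 13-symbol vocabulary of [mmp_genes()].
#'
#' @param path Optional path to an alternative two-column TSV
#'   (`synonym`, `canonical`); defaults to the shipped table.
#' @return Named character vector mapping upper-cased synonyms to canonical
#'   symbols.
#' @export
gene_synonyms <- function(path = NULL) {
  path <- path %||% system.file("extdata", "gene_synonyms.tsv",
                                package = "mmpevol", mustWork = TRUE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           comment.char = "#")
  bad <- setdiff(unique(tab$canonical), mmp_genes())
  if (length(bad))
    stop("synonym table maps onto non-canonical symbol(s): ",
         paste(bad, collapse = ", "))
  stats::setNames(tab$canonical, toupper(tab$synonym))
}

#' Normalize gene names to the canonical 13-symbol vocabulary
#'
#' @param gene Character vector of gene names as found in sequence headers.
#' @param synonyms Synonym map as returned by [gene_synonyms()].
#' @return Character vector of canonical symbols, `NA` where no synonym is
#'   known.
#' @export
#' @examples
#' normalize_gene(c("COX1", "MT-ND4", "cytb", "nonsense"))
normalize_gene <- function(gene, synonyms = gene_synonyms()) {
  out <- unname(synonyms[toupper(trimws(gene))])
  out
}

#' Read a protein FASTA of mtDNA-encoded membrane proteins
#'
#' Headers are expected to encode `species_id|group|gene` (the shipped
#' dialect) or to match a caller-supplied regular expression with three
#' capture groups in that order.  Gene names are normalized via the synonym
#' table; records whose header cannot be parsed, whose gene is unknown, or
#' whose sequence contains letters outside the canonical alphabet plus
#' tolerated ambiguity codes (X, B, Z, U) are collected into a reject report
#' rather than silently dropped.
#'
#' @param path Path to a protein FASTA file.
#' @param header_regex Optional regex with three capture groups
#'   (species, group, gene); when `NULL` the `|`-delimited dialect is used.
#' @param synonyms Synonym map, see [gene_synonyms()].
#' @return A list of class `mmp_fasta` with elements `records` (data.frame:
#'   `species_id`, `group`, `gene`, `sequence`) and `rejects` (data.frame:
#'   `header`, `reason`).
#' @export
read_mmp_fasta <- function(path, header_regex = NULL,
                           synonyms = gene_synonyms()) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  aa <- Biostrings::readAAStringSet(path)
  if (length(aa) == 0L) stop("empty FASTA file: ", path)
  headers <- names(aa)
  seqs <- toupper(as.character(aa))

  if (is.null(header_regex)) {
    parts <- strsplit(headers, "|", fixed = TRUE)
    fields <- lapply(parts, function(p) if (length(p) == 3L) trimws(p) else NULL)
  } else {
    m <- regmatches(headers, regexec(header_regex, headers))
    fields <- lapply(m, function(p) if (length(p) == 4L) trimws(p[-1L]) else NULL)
  }

  rec <- list(); rej <- list()
  for (i in seq_along(headers)) {
    f <- fields[[i]]
    if (is.null(f) || any(!nzchar(f))) {
      rej[[length(rej) + 1L]] <- c(headers[i], "unparseable header")
      next
    }
    gene <- normalize_gene(f[3L], synonyms)
    if (is.na(gene)) {
      rej[[length(rej) + 1L]] <- c(headers[i],
                                   paste0("unknown gene synonym: ", f[3L]))
      next
    }
    s <- seqs[i]
    letters_used <- unique(strsplit(s, "")[[1]])
    alien <- setdiff(letters_used, c(AA_CANONICAL, AA_AMBIGUOUS, "*"))
    if (nchar(s) == 0L) {
      rej[[length(rej) + 1L]] <- c(headers[i], "empty sequence")
      next
    }
    if (length(alien)) {
      rej[[length(rej) + 1L]] <- c(headers[i],
        paste0("invalid residue code(s): ", paste(alien, collapse = "")))
      next
    }
    s <- gsub("*", "", s, fixed = TRUE)  # trailing stop codons
    rec[[length(rec) + 1L]] <- data.frame(
      species_id = f[1L], group = f[2L], gene = gene, sequence = s,
      stringsAsFactors = FALSE)
  }

  records <- if (length(rec)) {
    r <- do.call(rbind, rec); rownames(r) <- NULL; r
  } else
    data.frame(species_id = character(), group = character(),
               gene = character(), sequence = character())
  rejects <- if (length(rej))
    data.frame(header = vapply(rej, `[`, "", 1L),
               reason = vapply(rej, `[`, "", 2L), stringsAsFactors = FALSE)
  else data.frame(header = character(), reason = character())

  dup <- duplicated(records[c("species_id", "gene")])
  if (any(dup)) {
    d <- records[dup, ]
    rejects <- rbind(rejects, data.frame(
      header = paste(d$species_id, d$group, d$gene, sep = "|"),
      reason = "duplicate (species, gene) record"))
    records <- records[!dup, ]
  }

  structure(list(records = records, rejects = rejects), class = "mmp_fasta")
}

#' Write protein records back to FASTA
#'
#' Emits the package's `species_id|group|gene` header dialect, so
#' `read_mmp_fasta(write_mmp_fasta(x))` round-trips canonicalized records.
#'
#' @param records Data.frame with columns `species_id`, `group`, `gene`,
#'   `sequence` (e.g. the `records` element of an `mmp_fasta`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mmp_fasta <- function(records, path) {
  if (inherits(records, "mmp_fasta")) records <- records$records
  aa <- Biostrings::AAStringSet(records$sequence)
  names(aa) <- paste(records$species_id, records$group, records$gene,
                     sep = "|")
  Biostrings::writeXStringSet(aa, path, width = 70L)
  invisible(path)
}

#' Read the per-group metadata table
#'
#' One row per animal group: clade label (`deuterostome`, `protostome` or
#' `basal`), mean body mass M in grams, the allometric constant C and
#' exponent alpha of BMR = C * M^alpha fitted within the group, and the
#' group-mean maximum lifespan MLS in years.  Masses and lifespans are group
#' means over the individual species.
#'
#' @param path Path to a TSV with columns `group`, `clade`, `M`, `C`,
#'   `alpha`, `MLS`.
#' @return Data.frame of class `group_metadata`.
#' @export
read_group_metadata <- function(path) {
  if (!file.exists(path)) stop("metadata file not found: ", path)
  md <- utils::read.delim(path, stringsAsFactors = FALSE,
                          comment.char = "#")
  needed <- c("group", "clade", "M", "C", "alpha", "MLS")
  miss <- setdiff(needed, names(md))
  if (length(miss))
    stop("metadata is missing column(s): ", paste(miss, collapse = ", "))
  md <- md[needed]
  if (anyDuplicated(md$group))
    stop("duplicate group row(s): ",
         paste(unique(md$group[duplicated(md$group)]), collapse = ", "))
  bad_clade <- setdiff(unique(md$clade),
                       c("deuterostome", "protostome", "basal"))
  if (length(bad_clade))
    stop("unknown clade label(s): ", paste(bad_clade, collapse = ", "))
  if (any(md$M <= 0)) stop("body mass M must be > 0")
  if (any(md$C <= 0)) stop("allometric constant C must be > 0")
  if (any(md$alpha <= 0 | md$alpha > 1))
    stop("allometric exponent alpha must lie in (0, 1]")
  if (any(md$MLS <= 0)) stop("maximum lifespan MLS must be > 0")
  class(md) <- c("group_metadata", "data.frame")
  md
}

#' Cross-check sequence records against metadata and protein sets
#'
#' Reports, without failing: groups present in the FASTA but absent from the
#' metadata (and vice versa), species missing genes of each requested
#' protein set, and groups with fewer species than `min_species`.
#'
#' @param records `mmp_fasta` object or its `records` data.frame.
#' @param metadata `group_metadata` data.frame.
#' @param sets Named list of protein sets (default: all of [protein_sets()]).
#' @param min_species Minimum species count per group worth flagging
#'   (default 1).
#' @return A list of class `mmp_validation` with elements
#'   `groups_without_metadata`, `metadata_without_sequences`,
#'   `missing_genes` (data.frame `species_id`, `set`, `gene`),
#'   `small_groups` (data.frame `group`, `n_species`) and `ok` (logical:
#'   no issue found).
#' @export
validate_dataset <- function(records, metadata, sets = protein_sets(),
                             min_species = 1L) {
  if (inherits(records, "mmp_fasta")) records <- records$records
  fasta_groups <- unique(records$group)
  meta_groups <- unique(metadata$group)

  by_species <- split(records$gene, records$species_id)
  mg <- list()
  for (sp in names(by_species)) {
    have <- by_species[[sp]]
    for (sn in names(sets)) {
      lack <- setdiff(sets[[sn]], have)
      if (length(lack))
        mg[[length(mg) + 1L]] <- data.frame(species_id = sp, set = sn,
                                            gene = lack)
    }
  }
  missing_genes <- if (length(mg)) do.call(rbind, mg) else
    data.frame(species_id = character(), set = character(),
               gene = character())

  nsp <- tapply(records$species_id, records$group,
                function(x) length(unique(x)))
  small <- data.frame(group = names(nsp), n_species = as.integer(nsp))
  small <- small[small$n_species < min_species, , drop = FALSE]

  out <- list(
    groups_without_metadata = setdiff(fasta_groups, meta_groups),
    metadata_without_sequences = setdiff(meta_groups, fasta_groups),
    missing_genes = missing_genes,
    small_groups = small)
  out$ok <- length(out$groups_without_metadata) == 0L &&
    nrow(missing_genes) == 0L && nrow(small) == 0L
  class(out) <- "mmp_validation"
  out
}

#' @export
print.mmp_validation <- function(x, ...) {
  cat("Dataset validation:", if (x$ok) "OK" else "issues found", "\n")
  if (length(x$groups_without_metadata))
    cat(" groups without metadata:",
        paste(x$groups_without_metadata, collapse = ", "), "\n")
  if (length(x$metadata_without_sequences))
    cat(" metadata rows without sequences:",
        paste(x$metadata_without_sequences, collapse = ", "), "\n")
  if (nrow(x$missing_genes))
    cat(" species x set combinations with missing genes:",
        nrow(x$missing_genes), "\n")
  if (nrow(x$small_groups))
    cat(" under-sized groups:",
        paste(x$small_groups$group, collapse = ", "), "\n")
  invisible(x)
}
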