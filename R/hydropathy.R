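#' Load a hydrophobicity scale
#'
#' Scales are two-column TSV files (`residue`, `score`) covering the 20
#' canonical residues.  The package ships the Cowan--Whittaker pH 7.5 scale
#' (the default used throughout) and the Kyte--Doolittle scale for
#' cross-checks.  Ambiguity codes have no scale value; sites carrying them
#' are excluded from profiling (see [raw_profile()]).
#'
#' @param name `"cowan_whittaker"` or `"kyte_doolittle"`, or the path of a
#'   scale TSV.
#' @return Named numeric vector of length 20, class `hydropathy_scale`.
#' @export
#' @examples
#' sc <- hydropathy_scale()
#' sc[["W"]]
hydropathy_scale <- function(name = "cowan_whittaker") {
  path <- switch(name,
    cowan_whittaker = system.file("extdata", "scales",
      "cowan_whittaker_ph7.5.tsv", package = "mmpevol", mustWork = TRUE),
    kyte_doolittle = system.file("extdata", "scales",
      "kyte_doolittle.tsv", package = "mmpevol", mustWork = TRUE),
    name)
  if (!file.exists(path)) stop("no such scale: ", name)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  sc <- stats::setNames(as.numeric(tab$score), toupper(tab$residue))
  miss <- setdiff(AA_CANONICAL, names(sc))
  if (length(miss))
    stop("scale does not cover residue(s): ", paste(miss, collapse = ", "))
  structure(sc[AA_CANONICAL], class = "hydropathy_scale",
            scale_name = if (file.exists(name)) basename(name) else name)
}

#' Per-site hydrophobicity scores of one protein
#'
#' Looks up each residue in the scale.  Sites carrying ambiguity codes
#' (X, B, Z, U) have no defined score; they are dropped from the scored
#' profile (their flanking scored sites become neighbours for smoothing)
#' and reported through the `excluded` mask.
#'
#' @param sequence Amino-acid string (or a one-row record data.frame with a
#'   `sequence` column).
#' @param scale A [hydropathy_scale()].
#' @return List with `scores` (numeric, one per scored site), `positions`
#'   (1-based positions of the scored sites in the input sequence) and
#'   `excluded` (logical per input site).
#' @export
raw_profile <- function(sequence, scale = hydropathy_scale()) {
  if (is.data.frame(sequence)) sequence <- sequence$sequence[[1]]
  stopifnot(is.character(sequence), length(sequence) == 1L)
  res <- strsplit(toupper(sequence), "")[[1]]
  if (length(res) == 0L) stop("empty sequence")
  known <- res %in% names(scale)
  alien <- setdiff(res[!known], AA_AMBIGUOUS)
  if (length(alien))
    stop("residue code(s) with no scale value and not an ambiguity code: ",
         paste(unique(alien), collapse = ""))
  if (!any(known)) stop("sequence has no canonical residues to score")
  list(scores = unname(scale[res[known]]),
       positions = which(known),
       excluded = !known)
}

# one pass of the three-site moving average with truncated terminal windows
smooth_pass <- function(x) {
  L <- length(x)
  if (L <= 1L) return(x)
  if (L == 2L) return(rep(mean(x), 2L))
  left <- c(0, x[-L]); right <- c(x[-1L], 0)
  n <- c(2L, rep(3L, L - 2L), 2L)
  (left + x + right) / n
}

#' Iterated three-site moving average
#'
#' Each pass replaces every site score by the mean of the window
#' \{n-1, n, n+1\}; terminal sites average the two available values.  The
#' smoothed profile S(n) is obtained by repeating the pass a fixed number of
#' times (default 10 elsewhere in the package), or until convergence when
#' `tol` is given.  Repeated passes provably flatten any profile toward a
#' constant, so the iteration count is a real parameter and is reported
#' back by [profile_protein()].
#'
#' @param raw Numeric vector of per-site scores.
#' @param iterations Non-negative integer; 0 returns `raw` unchanged.
#' @param tol Optional convergence threshold: stop early once the largest
#'   per-site change of a pass falls below `tol`.
#' @return Numeric vector S(n) of the same length, with attribute
#'   `iterations_used`.
#' @export
#' @examples
#' smooth_profile(c(0, 3, 0, 3, 0), 1)  # 1.5 1 2 1 1.5
smooth_profile <- function(raw, iterations, tol = NULL) {
  stopifnot(is.numeric(raw), length(raw) >= 1L)
  if (length(iterations) != 1L || is.na(iterations) || iterations < 0)
    stop("iterations must be a non-negative integer")
  iterations <- as.integer(iterations)
  s <- as.numeric(raw)
  used <- 0L
  while (used < iterations) {
    s_new <- smooth_pass(s)
    used <- used + 1L
    if (!is.null(tol) && max(abs(s_new - s)) < tol) { s <- s_new; break }
    s <- s_new
  }
  attr(s, "iterations_used") <- used
  s
}

#' Scalar hydrophobicity HYD of a smoothed profile
#'
#' HYD is the mean of S(n) over the hydrophobic domain, i.e. over sites with
#' S(n) strictly greater than zero.  When several proteins are pooled (the
#' per-species, per-protein-set HYD), their positive-domain sites are
#' concatenated before averaging, so long proteins weigh more -- consistent
#' with the pooled site counts used for composition percentages.
#'
#' @param smoothed Numeric vector S(n), or a list of such vectors to pool.
#' @return The scalar HYD.  If no site has S(n) > 0 an error of class
#'   `mmp_no_hydrophobic_domain` is signalled (a profile with HYD exactly 0
#'   is a different, legal outcome).
#' @export
hyd_value <- function(smoothed) {
  if (is.list(smoothed)) smoothed <- unlist(smoothed, use.names = FALSE)
  pos <- smoothed[smoothed > 0]
  if (length(pos) == 0L)
    stop(structure(class = c("mmp_no_hydrophobic_domain", "error",
                             "condition"),
                   list(message = "no hydrophobic domain: no site with S(n) > 0",
                        call = sys.call(-1))))
  mean(pos)
}

#' Full hydropathy profile of one protein record
#'
#' Combines [raw_profile()], [smooth_profile()] and [hyd_value()].
#'
#' @inheritParams raw_profile
#' @inheritParams smooth_profile
#' @return List of class `hydropathy_profile`: `raw`, `smoothed`, `mask`
#'   (S(n) > 0), `positions`, `excluded`, `HYD` (`NA` if the mask is empty),
#'   `iterations_used`.
#' @export
profile_protein <- function(sequence, scale = hydropathy_scale(),
                            iterations = 10L, tol = NULL) {
  rp <- raw_profile(sequence, scale)
  s <- smooth_profile(rp$scores, iterations, tol)
  mask <- s > 0
  hyd <- if (any(mask)) mean(s[mask]) else NA_real_
  structure(list(raw = rp$scores, smoothed = as.numeric(s), mask = mask,
                 positions = rp$positions, excluded = rp$excluded,
                 HYD = hyd,
                 iterations_used = attr(s, "iterations_used")),
            class = "hydropathy_profile")
}

#' @export
print.hydropathy_profile <- function(x, ...) {
  cat(sprintf(
    "hydropathy profile: %d scored sites (%d excluded), %d smoothing pass(es)\n",
    length(x$raw), sum(x$excluded), x$iterations_used))
  cat(sprintf("  hydrophobic domain: %d sites, HYD = %s\n",
              sum(x$mask),
              if (is.na(x$HYD)) "undefined" else format(x$HYD, digits = 4)))
  invisible(x)
}

#' Write a per-site profile dump
#'
#' @param profile A `hydropathy_profile`.
#' @param sequence The sequence the profile was computed from.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, sequence, path) {
  res <- strsplit(toupper(sequence), "")[[1]]
  df <- data.frame(position = profile$positions,
                   residue = res[profile$positions],
                   raw = profile$raw,
                   smoothed = profile$smoothed,
                   hydrophobic = profile$mask)
  utils::write.table(format(df, digits = 10), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
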