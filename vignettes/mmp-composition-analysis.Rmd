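---
title: "Hydropathy, Ser/Thr composition and metabolic scaling of mitochondrial membrane proteins"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hydropathy, Ser/Thr composition and metabolic scaling of mitochondrial membrane proteins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mmpevol)
```

## The scientific question

The 13 proteins encoded on animal mtDNA are membrane subunits of the
respiratory chain.  Their amino-acid composition is overwhelmingly
non-polar, but the *degree* of hydrophobicity varies across animal groups,
and so — inversely — does the content of the moderately polar residues Ser
and Thr, which can form interhelical hydrogen-bond networks.  This package
measures both quantities per species and per group, relates them to basal
metabolic rate expressed per unit mitochondrion, and summarises the
between-group structure as a composition-space tree.  The five large
proton-pumping subunits (ND4, ND5, ND2, CO1, CO3) are where the inverse
relation is strongest, which is why the nested protein sets are built
around them.

## Hydropathy profiling

Each canonical residue receives a score from a hydrophobicity scale.  The
default is the Cowan–Whittaker pH 7.5 scale, shipped as an editable TSV
(`inst/extdata/scales/`); the Kyte–Doolittle scale is included for
cross-checks, and any two-column file can be substituted.  Scales live in
data rather than code so a transcription can be audited and corrected
without touching logic.

The per-site profile is smoothed by repeating a three-site moving average:
site *n* is replaced by the mean of sites *n−1, n, n+1*, terminal sites by
the mean of the two available values.  Choices made here:

* **Iteration count.** Repetition "until smooth" has to mean a finite
  number of passes: each pass is a strict contraction toward a constant
  profile (the variance of S never increases, and the contraction rate of
  the slowest mode scales like 1/length²).  The default is **10 passes**,
  exposed as `iterations` and echoed back as `iterations_used`; an optional
  convergence mode (`tol`) stops when the largest per-site change of a pass
  falls below the threshold.
* **Termini.** Windows truncate rather than pad; padding would invent
  boundary scores.
* **Hydrophobic domain.** The mask is *strictly* S(n) > 0, and
  HYD is the mean of S(n) over masked sites.  When a protein set is pooled,
  masked sites are concatenated across proteins before averaging, so long
  subunits carry proportionally more weight — consistent with the pooled
  site counts used for percentages.  A profile with an empty mask signals a
  distinct "no hydrophobic domain" condition rather than returning 0,
  because HYD = 0 and "no positive domain" are different statements.
* **Ambiguity codes.** X/B/Z/U have no scale value.  Those sites are
  excluded from scoring and from every composition denominator, and the
  smoothing window simply bridges them (the flanking scored sites become
  neighbours).  The alternative — inventing a scale value — would bias HYD
  in a direction that depends on the invented number.

This smoothed-mask definition of the hydrophobic domain deliberately
replaces external transmembrane-topology predictors; helix-level spatial
analysis is out of scope.

## Composition statistics

TC, SC, STC and CC are percentages of pooled canonical sites for one
species × protein set; TSN is the pooled site count.  Percentages can be
computed over the full sequence (default) or restricted to the hydrophobic
mask (`domain = "hydrophobic_mask"`); both are exposed because the
composition denominator used with a masked analysis is a genuine
ambiguity, and reporting the domain label with every row keeps the choice
visible.  Species lacking a gene of a set are dropped from that set's
statistics (and logged): pooling an incomplete denominator would bias the
percentages.  Group values are unweighted means over species, with the
standard deviation and n reported alongside.

## Allometry and the F sweep

Within a group, BMR = C·M^α, so msBMR = C·M^−(1−α).  Dividing by the
mass-dependence of mitochondrial density gives the per-mitochondrion rate,
parameterised as

$$\mathrm{mtBMR} = C \cdot M^{-(1-\alpha)/F}, \qquad F \ge 1 .$$

F = 1 is msBMR; F = ∞ removes the mass term, leaving mtBMR = C.  The
mt-density proportionality constant is fixed at 1 (that is what makes
F = 1 coincide with msBMR), and the underlying density exponent is not a
separate runtime parameter — it is absorbed into F.  All correlations use
the exact log form ln(mtBMR) = ln C − (1−α)·ln M / F, which is
overflow-safe and handles F = ∞ without limits.  Body mass M and maximum
lifespan MLS are group means over species, in grams and years; C is in the
(relative) units of the source BMR data, which cancel in correlations.

`f_sweep()` evaluates the squared Pearson correlation between group STC
and ln(mtBMR) on a grid of F values (default 1, 1.25, 1.5, 2, 2.5, 3, 4,
5, 7.5, 10, 20, 50, 100, ∞ — F = 3 is kept on the grid as the preset used
in earlier vertebrate work) and reports the full curve plus the argmax,
ties broken toward larger F.  Identifiability caveat: the mass term scales
as 1/F, so adjacent grid values above ~20 differ by only a few percent of
the mass term and cannot be distinguished on noisy data; the reported R²
curve makes this flatness visible rather than hiding it.

## Regression battery

* Correlations are reported as R² plus the sign (P/N) of the raw
  correlation, with n for every cell.  No multiple-testing correction is
  applied; the tables are descriptive.
* Group-mean points are the default regression input; species-level raw
  mode is a flag.
* The TC–HYD power law y = a·x^b is fitted two ways: nonlinear least
  squares on the original scale (Levenberg–Marquardt, started from the
  log–log OLS solution — on noise-free power data the two coincide) as the
  headline, with the log–log fit reported alongside, since either
  convention is defensible and they differ under noise.
* TSN rows of the pair-correlation table are computed with the
  deuterostome groups excluded, where the TSN gradients are monotone; the
  deuterostome lineage runs the other way and is fitted separately
  (`fit_linear(..., subset = )`).
* ln(mtBMR·MLS) is computed as ln(mtBMR) + ln(MLS).
* The table's final column is the plain arithmetic row mean.

## The composition-space tree

The distance between groups i and j is
D(i,j) = ΔTC²/σ²_TC + ΔTSN²/σ²_TSN over the 5-protein set, each variable
scaled by its **population** (divide-by-n) standard deviation across the
included groups — the n groups are the complete population being compared,
not a sample; the sample-sd variant is a flag and only rescales every
entry by (n−1)/n, leaving the tree unchanged.  Neighbor joining is
implemented in the package (Q-matrix agglomeration, standard branch-length
formulas, three-point closed form at the end).  Ties in Q are broken
toward the lowest index pair so results are deterministic; negative branch
lengths — expected, since trait distances are not additive — are clamped
to zero with a warning.  The tree is emitted unrooted; an outgroup-rooting
helper (e.g. at Porifera) is provided for display.

## The synthetic cohort

The generator emulates the statistical structure the analysis consumes,
and no more:

* 13 groups (two basal, six protostome, five deuterostome) × 20 species ×
  13 genes by default; gene lengths are the human reference lengths scaled
  by a per-group TSN factor (0.84–1.00), giving the ~20% between-group TSN
  spread the analysis expects, with deuterostome TSN high and the
  flatworm/nematode end low.
* Group mean hydropathy targets run from 0.75 (Platyhelminthes) down to
  0.58 (Aves) so that the Aves/Eutheria mean sits ≈22% below the
  Nematoda/Platyhelminthes mean; TC targets follow the inverse power curve
  TC = 0.429·HYD^−4.2045, Ser is tied to Thr (SC = 0.8·TC), and CC runs
  weakly opposite to TC.  Per-species targets jitter around the group
  targets (σ = 0.35 percentage points; 0.015 score units for hydropathy).
* Sequences are drawn site-iid from a per-group multinomial: Thr/Ser/Cys
  probabilities equal their targets, and the remainder is split between a
  strongly hydrophobic pool (I, L, V, F, M, W) and a polar pool so the
  expected mean score hits the hydropathy target — a residue-level
  multinomial is the minimal sufficient generator for an analysis that
  only consumes compositions and windowed means.  An optional two-state
  block sampler alternates hydrophobic and polar runs (mean hydrophobic
  run 15 sites, stationary occupancy preserved) when genuinely
  sub-maximal hydrophobic domains are wanted.
* One master seed; per-group streams are derived deterministically, and
  the emitted ground-truth JSON regenerates the cohort bit-for-bit.

What the generator does **not** emulate: phylogenetic autocorrelation
within groups (species are exchangeable), helix architecture, and any
direct mechanistic link between the metadata's allometric parameters and
the sequence targets.  Passing recovery tests therefore demonstrates that
the pipeline measures what the generator encodes — not that real MMP data
satisfy the model.

One measurable consequence of the iid design: because HYD averages only
the *positive* part of the smoothed profile, low-hydropathy groups are
pulled slightly upward (the selection effect grows as the mean approaches
0), compressing the realized HYD range and steepening the recovered
power-law exponent by roughly 5–10% relative to the generating −4.2045.
The end-to-end recovery checks account for this by comparing against the
fitted standard error rather than expecting exactness.

`simulate_allometry()` builds metadata whose STC is affine in ln(mtBMR)
at a chosen true F.  Group C (log-normal, sd 0.6 on the log scale) and α
(uniform on 0.66–0.80) vary across groups deliberately: with shared C and
α, STC generated at any F is affine in ln M and every F fits perfectly,
so the sweep could identify nothing.  Masses are log-spaced over six
decades.

## Problem sizes and numerical checks

The test suite exercises: the smoother against an independently coded
direct convolution (≥100 random profiles, lengths 1–60, 0–6 passes,
bitwise agreement), affine equivariance and variance monotonicity;
composition closure (20 single-residue percentages sum to 100 within
1e−9), STC = TC + SC exactly, and strict TSN nesting across the 3→7 sets;
the allometric identities at F = 1 and F = ∞ to machine precision (the
power-form implementation makes them bitwise); noise-free recovery of the
power and linear generator coefficients to 1e−6 or better; neighbor
joining on 50 random additive matrices (n ≤ 8: topology and path lengths
to 1e−9), against the reference NJ implementation on perturbed matrices,
and against an exhaustive minimum-evolution search on ultrametric 5-taxon
instances; and byte-identical reruns of the full pipeline on the shipped
fixture cohort.  Unit-test cohorts use 2–8 species per group with gene
lengths scaled to 0.2–0.8 of the reference to keep the designed signal
detectable at small n while the suite stays fast; the acceptance script
runs the full 13 × 20 cohort at reference lengths.

## Known limitations

* The F grid's upper region is nearly degenerate (see above): under noise,
  the argmax among {20, 50, 100, ∞} is close to arbitrary even when the
  curve's rise toward large F is unambiguous.
* Percentages and HYD treat sites as exchangeable within a protein;
  positional information is used only through the smoothing window.
* The composition distance uses two variables (TC, TSN) by default; it is
  a phenetic summary, not a substitution model, and branch lengths have no
  time interpretation.
* Metadata rows (C, α, M, MLS) must be supplied for every group entering
  the metabolic correlations; groups without metadata are simply absent
  from those rows (the validator reports them).
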