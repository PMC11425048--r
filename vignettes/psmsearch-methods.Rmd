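---
title: "Full-database peptide-spectrum matching with an inverted spectrum index"
author: "psmsearch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Full-database peptide-spectrum matching with an inverted spectrum index}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psmsearch)
```

## The problem

Bottom-up proteomics identifies peptides by matching MS2 fragment spectra
from data-dependent acquisition (DDA) against the theoretical b/y fragment
ions of in-silico digested protein sequences. Conventional engines keep the
problem tractable by restricting the precursor mass error (ppm-scale narrow
search, or a few hundred Da in open search) and by capping the number of
variable modifications per peptide, typically at three. Both restrictions
cost interpretive power: a peptide whose precursor mass is shifted by an
unanticipated modification, or that carries many modification sites, is
invisible.

`psmsearch` implements the opposite trade. Every candidate peptide form is
matched against **every** spectrum — no precursor tolerance at all (the
mass difference Δm is merely reported, over a window of −6000 to 4500 Da by
default) — and up to 20 variable modification sites per peptide are
enumerated in full (2^20 ≈ 10^6 forms; beyond 20 sites the enumeration is
truncated to at most 3 simultaneous modifications, Σ~i≤3~ C(n, i) forms).
Two design choices make this affordable:

1. **The inverted index is built over the experimental spectra, not the
   theoretical fragments.** Each spectrum keeps its K most intense peaks
   (K = 150 by default), their m/z values are discretized to integer bins
   of calibrated width w (`floor((mz − offset)/w)`, half-open intervals),
   and the index maps each occupied bin to the postings list of
   (spectrum id, binned intensity). Memory is therefore proportional to
   the number of spectra — a few hundred bytes per spectrum — and
   completely independent of the candidate space, which can grow to
   billions of forms without touching the index.
2. **Theoretical fragments are generated at run time and discarded.** The
   candidate stream digests the FASTA (trypsin, C-terminal of K/R except
   before P, up to 2 missed cleavages, 7–50 residues by default), appends
   reversed decoys, and lazily walks each peptide's modification-site
   subsets (by increasing subset size, lexicographic within a size). For
   each form, only the integer bins of its b/y ions (charges 1+, and 2+
   against precursors of charge ≥ 2) are queried; nothing per-candidate is
   stored beyond the running best matches.

## Scoring

For each candidate × spectrum pair reached through the index the engine
accumulates the matched b- and y-ion counts (N~b~, N~y~) and matched binned
intensities (ΣI~b~, ΣI~y~). Pairs with fewer than `min_matched = 4` matched
ions are dropped before scoring. Survivors receive two complementary
scores:

* **Hyperscore** (X!Tandem lineage):
  `H = ln(Nb! · Ny! · max(ΣIb, 1) · max(ΣIy, 1))`, computed as a sum of
  log-terms; the `max(·, 1)` guard keeps H finite and makes the no-match
  score exactly 0.
* **Fast cross-correlation** (SEQUEST/Comet lineage): bin intensities are
  square-rooted, normalized to a maximum of 50 within 10 equal m/z windows,
  and background-subtracted as
  `y′[b] = y[b] − (1/151) Σ~τ=−75..75~ y[b+τ]`; the score X is the raw dot
  product of y′ with the unit theoretical-ion vector. The processed
  spectrum is held sparsely (occupied bins plus prefix sums), so evaluating
  y′ at a queried bin is two binary searches rather than a dense vector.

Two best-PSM streams are maintained simultaneously, under the same total
order (max H, then max X, then lexicographically smallest peptide key, then
target before decoy):

* the **rank-1 stream** — the best candidate per spectrum, the search
  output proper;
* the **per-peptide stream** — the best spectrum per candidate form. This
  is the granularity the validation stage consumes: a decoy peptide that
  never wins a spectrum outright still contributes its best match, which is
  what makes a full negative class available even on runs where rank-1
  decoy wins are rare.

The C++ core accumulates every reduction (mass sums, intensity sums, xcorr
dot products) in extended precision matching R's `sum()`/`cumsum()`
accumulators, so the indexed search and the pure-R all-pairs reference
matcher (`search_all_naive()`) agree bit for bit; that equivalence is
asserted over randomized instances in the test suite.

## Bin-width calibration

The bin width is the coupling constant between instrument accuracy and
index granularity. `optimal_bin_width()` scores a grid of candidate widths
by the total squared error of the binned representation. Two regimes exist:

* Without external truth, the only measurable error is the offset of each
  observed peak from its bin center; this discretization error shrinks
  monotonically as bins shrink, so the grid minimum sits at the smallest
  width — useful as a sanity check, not for calibration.
* With reference m/z values (calibrant ions, or the generator's truth), a
  peak whose observed and true m/z share a bin contributes the quantization
  error `(ref − bin_center)²`, while a peak whose measurement noise pushed
  it across a bin boundary is a *lost match* and contributes its raw
  instrument error `(ref − obs)²`. Match loss dominates at small widths,
  quantization at large widths, so the curve falls and then rises with a
  single interior minimum near twice the instrument σ, and the minimum
  value is on the order of the instrument variance.

The default grid is log-spaced (25 points over 0.005–0.1 Da). A linear grid
with 0.001 Da steps was tried first and rejected: neighboring widths then
differ by less than the sampling jitter of the empirical curve, which
manufactures spurious local minima even with 2·10^5 calibration peaks. The
default engine width of 0.02 Da corresponds to the calibrated optimum for a
fragment σ of 0.005–0.01 Da.

## The learned validation stage

Per run — never transferred across runs, since score and RT distributions
are instrument- and gradient-specific — two small networks are trained from
scratch, deterministically given the run seed:

* **Retention-time regressor.** Peptides are encoded as 63 features: 20
  whole-sequence residue counts, 20 counts of the first two residues, 20
  of the last two, the C-terminal residue index, the length, and the
  neutral mass (composition counts ignore modifications; only the mass
  feature moves). The network has four parallel branches — dense stacks of
  depth 1, 2 and 3 (64 ReLU units, dropout 0.2) plus a linear shortcut —
  concatenated and reduced 256 → 64 → 1, trained with Adam on min-max
  scaled RT with a 90/10 split and early stopping. Below 200 confident
  peptides the model falls back to a linear fit on the same features
  (which is rank-deficient by construction — the counts sum to the length
  — and harmlessly so); below 20 peptides RT prediction is disabled and
  the downstream RT-error feature is zeroed.
* **PSM discriminant.** A three-layer classifier (32-16-1, ReLU, dropout
  0.2, weighted cross-entropy) over 16 features: H, X, log1p(N~b~),
  log1p(N~y~), matched-intensity fraction, length, ln M, charge one-hot
  (1–4+), Δm, |Δm|, number of variable modifications, missed cleavages,
  and the RT error (observed − predicted, seconds). Positives are the
  target precursors (best PSM per modified peptide and charge) of the
  rank-1 stream at a 1% hyperscore-ranked target-decoy q-value; negatives
  are the best PSMs of **all** decoy peptides, weighted by
  n~pos~/n~neg~ to balance the classes. The discriminant score d is the
  pre-sigmoid logit.

All rank-1 PSMs are rescored with d and q-values are computed at the PSM,
peptide (best d per modified peptide) and protein (best d per accession,
decoy accessions competing) levels: records sorted by d descending,
`FDR(i) = #decoys / max(1, #targets)` among the top i, q = running minimum
from the bottom, ties evaluated at complete tie groups so the arbitrary
order within a tie cannot change the estimate. The reports keep target
records at q ≤ 0.01; a protein supported only by shared peptides is kept
but flagged `shared_only`. The simple decoy ratio is the default; a `+1`
numerator correction and picked-protein pairing are available as flags.

## The synthetic-data generator

The generator exists so that every stage is testable against known truth
without external downloads. A run consists of uniform-composition random
proteins (100–400 aa), and MS2 spectra of which a configurable fraction
(default 80%) carry signal: a tryptic peptide drawn from the proteome, its
variable modification sites switched on with occupancy 0.2, the full b/y
ladder (1+, plus 2+ for precursors of charge ≥ 2, drawn 2+/3+ with
probability 0.7/0.3) with Gaussian m/z error (σ = 0.005 Da), log-normal
intensities (meanlog 0, sdlog 0.5), Poisson(30) uniform background peaks,
a precursor mass error of σ = 0.002 Da, and a retention time following an
additive per-residue model (coefficients drawn once per run, uniform
60–420 s per residue) plus N(0, 30 s) noise. The remaining spectra are
background peaks only. Output is byte-stable MGF plus a ground-truth table
covering every spectrum.

What the generator deliberately does **not** emulate: chromatographic peak
shapes, isotope envelopes, co-fragmentation chimeras, intensity structure
along the ion series, and real unidentified spectra (which in practice are
fragment-rich, not sparse background). Consequently, passing the synthetic
end-to-end tests demonstrates the correctness of the machinery — indexing,
enumeration, scoring, training, FDR bookkeeping — not the engine's
sensitivity on real instrument data, where score distributions are far
less separable.

## Numerical and design choices

* Monoisotopic residue masses throughout; proton 1.007276466 Da, water
  18.0105646 Da.
* Bin mapping is floor-based with half-open intervals; boundary values
  belong to the upper bin.
* Within-spectrum bin collisions merge by intensity summation, preserving
  total matched intensity; one canonical binning routine is shared by the
  index builder, the xcorr preprocessor and the reference matcher so all
  paths agree exactly.
* The best-PSM total order ends in "target before decoy", making the
  reduction deterministic and order-independent; exact score ties are
  resolved by the lexicographic peptide key first.
* When several variable-modification specs target one residue, each
  position is eligible for at most one spec (first in configuration
  order, with a warning), so the streamed form count always equals the
  closed-form count.
* A sequence occurring in both target and decoy space (palindromic
  peptides) is kept once as a target, flagged `shared`, and excluded from
  discriminant negatives.
* Networks are trained in plain R matrix arithmetic (Adam, inverted
  dropout); all randomness — initialization, shuffling, dropout masks —
  flows from the run seed, so identical data and seed reproduce identical
  weights.

## Problem sizes used in the shipped checks

The test suite and the acceptance script run the whole engine at desk
scale: the default synthetic condition (200 proteins, 1000 spectra, 80%
signal — about 2 × 10^4 peptides and 7 × 10^4 candidate forms per run, of
which the per-peptide stream retains what matches), 20 replicate seeds for
the empirical-FDR average, 20 randomized index-vs-reference instances of
up to 100 spectra × 1000 forms, an RT recovery study of 2000 peptides, and
a calibration study of 2 × 10^4 peaks. These sizes were chosen as the
smallest at which the measured quantities are stable, and they keep a full
run in the tens of seconds on one core.

## Known limitations

* Only trypsin and full cleavage specificity; no a/c/x/z or neutral-loss
  ions; no isotope-error candidate expansion; no PTM-site localization
  scoring; no protein-inference parsimony beyond the shared-only flag.
* Expectation-value calibration of the hyperscore is deliberately absent:
  validation relies on the learned discriminant and target-decoy
  q-values.
* The per-peptide stream holds one record per matched candidate form; for
  databases of tens of millions of forms this table, not the index, is
  the memory ceiling.
* Missing precursor charge is assumed 2+ (with a warning); no multiple
  charge hypotheses are scored per spectrum.
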