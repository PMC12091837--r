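---
title: "Distance-controlled splits for TCR-peptide binding benchmarks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Distance-controlled splits for TCR-peptide binding benchmarks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tcrsplit)
library(dplyr)
```

## Why split by distance?

Machine-learning predictors of TCR-peptide binding are trained on tables
of (peptide, CDR3-beta) pairs with a binary binding label. How such a
table is split into train/validation/test sets largely determines what
the test AUROC means:

* **Random Split (RS)** — records are permuted and cut at the ratio
  boundaries. The same peptide typically appears on both sides of the
  cut, so a model that merely memorises per-peptide label statistics
  scores far above chance. RS estimates in-distribution performance and
  systematically overstates generalization to new peptides.
* **Hard Split (HS)** — whole peptides are assigned to exactly one set,
  so test peptides are never seen during training. This is the toughest
  conventional setting, but it says nothing about *how far* the test
  peptides are from the training ones.
* **Distance Split (DS)** — like HS, but the peptides eligible for test
  and validation are restricted to a percentile band of an aggregated
  peptide-peptide distance, so the typical train-to-test distance is
  under experimental control. Sweeping the band turns "out of
  distribution" from a binary property into a dial.

`tcrsplit` implements all three splitters over three peptide distance
metrics, a synthetic data generator that reproduces the statistical
shape these methods face in practice, and a small benchmarking harness
with reference predictors that make the split-dependent effects visible
without training any deep model.

## Distance metrics

Given unique peptides $p_1, \dots, p_n$, `peptide_distances()` builds a
symmetric $n \times n$ matrix with zero diagonal under one of:

* **Levenshtein** — unit-cost edit distance between sequences.
* **BLOSUM** — let $S(a,b)$ be the optimal Needleman-Wunsch global
  alignment score under BLOSUM62 with affine gaps. The package converts
  this similarity into the score-difference pseudo-distance
  $$d(a,b) = S(a,a) + S(b,b) - 2\,S(a,b),$$
  clamped at zero. This guarantees $d(a,a) = 0$ and symmetry, which a
  raw alignment score does not.
* **RMSD** — residues of the two peptides are paired via the match
  columns of their optimal global sequence alignment (same parameters as
  the BLOSUM metric), the paired C-alpha coordinates are superposed with
  the Kabsch algorithm (proper rotations only), and up to five
  outlier-rejection cycles remove pairs deviating by more than 2.0 A
  before re-superposing — the behaviour of PyMOL's `align`, which is the
  de-facto standard for this computation. Only C-alpha atoms are used:
  side-chain placement in predicted peptide structures is unreliable and
  would inflate an all-atom RMSD.

### Alignment conventions

The gap model is affine with `gap_open = -10` and `gap_extend = -1`; a
gap of length $L$ scores `gap_open + (L - 1) * gap_extend`. These are the
most widely used protein-alignment defaults (EMBOSS `needle` uses the
same pair). The dynamic program is the package's own Gotoh kernel in
C++, with a fixed traceback preference (diagonal, then gap in the second
sequence, then gap in the first) so the residue pairing is
deterministic; its scores are verified in the test suite against both
exhaustive enumeration of all alignments on short sequences and an
independent alignment engine.

Two degenerate cases need pinning. First, for a rare, very dissimilar
pair of peptides the *optimal* global alignment is completely gapped and
leaves nothing to superpose; `ca_rmsd()` then falls back to the best
ungapped offset pairing (maximum substitution score over an overlap of
at least three residues, first optimum on ties), so every matrix entry
stays finite. The exported `pair_ca_atoms()` keeps the strict contract
and raises a no-overlap error instead. Second, fewer than three paired
atoms leave the rotation underdetermined; this is always an error, as is
a (nearly) collinear point set in `kabsch_superpose()`.

## The Distance Split

For a chosen metric, `aggregate_distances()` reduces each matrix row to
a single number per peptide — the median distance to all other peptides
by default (the mean and the minimum are selectable; the minimum gives
the most stringent notion of novelty, since a peptide is only "far" if
*no* training peptide is close). `split_distance()` then:

1. converts the percentile band $(b_l, b_u)$ into realized distance
   bounds $(d_l, d_u)$ by linear interpolation between closest ranks
   (`quantile(type = 7)`; the interpolation rule is pinned because it
   affects reproducibility at small $n$);
2. filters to *eligible* peptides: aggregated distance inside
   $[d_l, d_u]$ and record count inside `[min_count, max_count]`;
3. repeatedly draws an eligible peptide uniformly at random and moves
   **all** of its records to the test set, until the test budget
   (`ratio * n_records`, 5% by default) is reached; then fills the
   validation set the same way from the remaining eligible peptides;
   everything else trains.

Peptide atomicity beats budget exactness: the last drawn peptide may
overshoot its budget and is kept whole. With heavy-tailed per-peptide
counts this overshoot is the dominant deviation from the nominal
90-5-5 ratios, which is why Monte-Carlo checks of the realized
fractions are run at sizes where no single peptide exceeds the stated
tolerance. If the eligible pool empties before a budget is met the
splitter raises an infeasibility error naming the shortfall — it never
silently relaxes the band, because a silently widened band would change
the meaning of the reported train-test distance. Test peptides are drawn
before validation peptides; the order matters when the pool is shallow
and is fixed for reproducibility.

The count limits (defaults 5 and 5000) bound how much a single very
rare or very frequent peptide can dominate the held-out sets. They are
calibrated to datasets with on the order of $10^2$ records per peptide;
for the ~8 records per peptide of the desk-scale synthetic fixtures the
equivalent floor is proportionally lower (the acceptance script uses 2).

Negatives follow their peptide: a shuffled negative whose peptide is
drawn into the test set moves with it. CDR3-beta sequences may still be
shared across splits — both baselines in the literature constrain
peptides only, and the package follows that definition.

## Shuffled negatives

`generate_negatives()` augments a table of binding records with
non-binding ones by sampling (peptide, CDR3-beta) combinations that are
absent from the positives, under the standard assumption that a random
pairing is very unlikely to bind. Combinations are rejection-sampled
and, if necessary, completed by exhaustive enumeration of the remaining
non-positive combinations, so the draw is exact and terminates. The
number of negatives is an explicit argument defaulting to the number of
positives (a balanced set); no published count is hard-coded. Duplicate
(peptide, CDR3-beta, label) rows are collapsed on ingest so a repeated
row can never leak across splits.

## The synthetic generator

`fixture_spec()` describes datasets with the statistical structure the
splitters face in practice; every stage of the package is testable
against it without downloading anything.

* **Peptides**: uniform-random sequences of length 8-11 over the 20
  standard amino acids (the typical length range of MHC class I
  epitopes).
* **Counts**: per-peptide record counts drawn as $\lceil 1/U \rceil$, a
  discrete Pareto with tail index 1, truncated at 500. This reproduces
  the "median 2, mean much larger" skew of real interaction databases,
  where a handful of immunodominant epitopes hold most records.
* **CDR3-beta**: random strings of length 10-16 flanked by the canonical
  `C`...`F`, drawn from a pool of at least 600 (so the pool always
  exceeds the maximum per-peptide count and sampling without replacement
  is feasible).
* **Labels**: either fair coins (`random`, for calibration checks) or
  `peptide_keyed`: each peptide receives a latent binding propensity
  drawn uniformly from $[0.1, 0.9]$ and labels are Bernoulli draws from
  it. The range excludes 0 and 1 so per-split AUROC stays defined. This
  creates exactly the peptide-memorisable signal that separates RS from
  HS.
* **Structures**: an ideal backbone curve per peptide — an alpha-helix
  with 100 degrees of turn and 1.5 A rise per residue at radius 2.3 A
  (consecutive C-alpha spacing 3.83 A), or an extended zigzag — plus
  isotropic Gaussian jitter of `jitter_sd` (default 0.3 A) on every
  coordinate. Draws are retried (up to 20 times) until all consecutive
  C-alpha spacings stay inside the physical 2.0-4.5 A window; 0.3 A is
  the default because it keeps that invariant satisfiable with
  overwhelming probability while still producing a usable spread of
  pairwise RMSD values (~0.3-0.9 A, matching the scale reported for
  predicted epitope structures).

Because the jitter is independent of the sequence, structure distances
carry no sequence signal by construction: the rank correlation between
the RMSD and BLOSUM matrices on fixtures is near zero, while Levenshtein
and BLOSUM correlate positively (both are functions of the sequences).
This reproduces, at the level of direction, the correlation structure
reported for real epitope data — and it is also the generator's main
departure from reality, where sequence and structure are of course
coupled. Passing tests therefore demonstrate that the *splitting
machinery* behaves as specified, not that any biological conclusion
transfers.

## The benchmark harness

`run_benchmark()` executes a split plan (RS, HS, and DS per band and
metric) across a list of seeds — five by default, matching the common
repetition protocol — and reports, per split: the pooled test AUROC of a
reference predictor and the median train-to-test peptide distance.
AUROC is the Mann-Whitney statistic (ties count half); pooled rather
than macro-averaged over peptides, which is the simpler and more common
choice. Summaries are the per-split mean with a normal-approximation
95% confidence interval over seeds ($\pm 1.96\,s/\sqrt{k}$), and the
Spearman rank correlation between band index and AUROC across the DS
runs (exact p-value for at most ten untied points, asymptotic
otherwise; undefined — reported as `NA` — when the AUROC is constant
across runs).

Two reference predictors ship with the package. The
`memorization_predictor()` scores a test pair by the empirical positive
rate of its peptide in training and falls back to 0.5 for unseen
peptides; it is deliberately the *simplest* model that exploits RS
leakage, and on any peptide-disjoint split its AUROC is exactly 0.5 by
construction — a built-in negative control. The `random_predictor()`
scores uniformly at random and should be calibrated at 0.5 everywhere.
Deep models are out of scope by design; the harness exposes a
`predictor` factory argument (`function(train) function(newdata)
scores`) so external models can be plugged in unchanged.

## Problem sizes and numerical choices

The test-suite and acceptance-script study conditions are: fixtures of
200 peptides (about 1,500 records) for band-monotonicity, RS-vs-HS and
calibration checks; 100 seeded split runs spread over 50-500 peptides
for the partition invariants; 800 peptides for the Monte-Carlo check of
realized split fractions, the size at which single-peptide overshoot
granularity drops below the 2-point tolerance; 1,000 random pairs for
the edit-distance oracle and every pair of sequences up to length 3
over a 4-letter sub-alphabet for exhaustive alignment enumeration.
Jitter-monotonicity is checked over `jitter_sd` in {0.05, 0.15, 0.3},
the range compatible with the C-alpha spacing invariant.

Symmetry and zero-diagonal assertions on distance matrices use a 1e-9
relative tolerance; rigid-motion invariance of the RMSD is asserted at
1e-6 A; the Kabsch result is compared with a grid-plus-refinement
rotation search at 1e-4 A. Medians of an even number of values average
the two central values (R's default). All randomness flows through
explicit integer seeds (`withr::with_seed`), so every split, fixture
and benchmark is reproducible from its manifest.

## Known limitations

* Synthetic structures are idealised backbones, not folded peptides;
  only inter-structure distance *relationships* are meaningful.
* The RMSD is not length-normalised; comparisons between peptides of
  very different lengths rest on the aligned subset only.
* The band mechanism controls the *aggregated* distance of held-out
  peptides, not the minimum pairwise distance: with the default median
  aggregator some test peptides may still have close training
  neighbours. Use `aggregator = "min"` for the stringent variant.
* Highly clustered peptide sets can concentrate a band on a local
  cluster; the count limits mitigate but do not remove this.
* MHC information is carried through but not used for stratification;
  class II data and cross-dataset protocols are out of scope.
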