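---
title: "cppscreen: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{cppscreen: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its science: the data model, the
descriptor set, the regression and design machinery, the synthetic-data
generator, and the decisions taken where the design was genuinely open. It
states no empirical result that the test suite or the acceptance script
does not itself compute.

## Setting

A bacterial CPP screen measures, for each peptide in a library of short
(5–24 residue) sequences, a penetration efficiency — intracellular
fluorescence of a dye-labelled peptide after treatment and washing, in
arbitrary units — and a cytotoxicity readout — the maximum OD600 of a
treated culture as a percentage of the untreated control. The modeling
task is to regress log10 efficiency on sequence-derived descriptors, so
that new efficient peptides can be designed in silico; the analytics task
is to describe what distinguishes efficient from inefficient and toxic
from safe peptides.

## Peptide data model

Sequences use the 20 canonical one-letter codes; letter case encodes
chirality (uppercase = L, lowercase = D), matching the convention screen
tables use for the occasional all-D entry. Chirality is carried through
validation, I/O and filtering, but **not** through descriptors: hydropathy
and scale tables are defined for L-residues, and a D-residue's side-chain
chemistry is that of its parent amino acid, so descriptor computations
case-fold. FASTA reading is implemented in the package (not via a
sequence-container library) specifically because standard readers
upper-case input, which would silently erase chirality.

Screening tables are comma-delimited UTF-8 with columns
`id, sequence, intensity_au, max_od_pct, source`; empty cells or `.` are
missing values and never coerced to zero, and negative measurements are
rejected at parse time. The library-inclusion filter keeps peptides of
5–24 residues, all-L unless the id is whitelisted, and linear chemistry;
linearity is a metadata flag because it is not derivable from sequence
text. Rejections report the *first* failed criterion, in the fixed order
length, chirality, linearity.

## Descriptors (505 dimensions)

The feature vector concatenates:

1. **Amino-acid composition** (20): residue fractions, summing to 1.
2. **Dipeptide composition** (400): ordered adjacent-pair fractions over
   `length − 1`; all-zero for single-residue peptides (a documented
   degenerate case, not an error).
3. **Scale averages** (85): the arithmetic mean over residues of each scale
   in a vendored per-residue battery. Mean aggregation keeps features
   length-independent and is the standard convention for such batteries.

The 20 + 400 + 85 = 505 layout fixes the battery size at 85. Which 85
published indices a given historical analysis used is generally not
recoverable, and the canonical index database cannot be redistributed
here, so the packaged battery
(`inst/extdata/aaindex85_synthetic.tsv`) is an explicit stand-in: 17
anchor scales transcribed from standard references (Kyte–Doolittle and
other hydrophobicity scales, Hopp–Woods hydrophilicity, Grantham polarity,
bulkiness, residue mass and volume, helix/sheet/turn propensities, free
amino-acid pI, net-charge and aromatic/aliphatic indicators, TOP-IDP
disorder propensity) plus 68 synthetic composite scales generated once as
seeded linear blends of the standardized anchors with noise, labelled
`SYNTxxxx` and frozen in the fixture. The composites span the same
chemical families (charge, hydropathy, polarity, volume, structure
propensity, flexibility) and give the battery the collinearity structure a
real index subset has. Any file in the same tab-delimited format can be
swapped in via `load_aaindex(path)`.

### Transform

Compositions contain zeros and scale averages can be negative, so a plain
logarithm is undefined; features are mapped by the signed log
`sl(x) = sign(x)·ln(1 + |x|)` — monotone, defined everywhere, linear near
zero — then z-scored per feature (constant features are centered and given
scale 1, so they transform to exactly zero). Min–max normalization is
available as an option (`normalization = "minmax"`); z-scoring is the
default because Pearson ranking is scale-invariant and z-scores keep
forest split values interpretable. The regression target is
`log10(intensity_au)`: the efficient/inefficient cutoff of 2.5 lies inside
log10 of the screen intensity range (log10 13 ≈ 1.11 to
log10 4043 ≈ 3.61), so base 10 is the only base on which that cutoff is
meaningful. Fitted transform parameters are stored and re-applied
deterministically to new data.

### Physicochemistry

Net charge at pH is the Henderson–Hasselbalch sum over ionizable groups
(side chains of D, E, C, Y, H, K, R and both termini, each counted once):
`+Σ_basic 1/(1+10^(pH−pKa)) − Σ_acidic 1/(1+10^(pKa−pH))`. The default
pKa set is EMBOSS's (vendored in `inst/extdata/pka_emboss.tsv`,
swappable); fluorophore labels and their linkage chemistry are ignored.
The isoelectric point is found by bisection on [0, 14] to 1e-4 pH units —
net charge is strictly decreasing in pH, positive at pH 0 and negative at
pH 14, so the crossing exists and is unique; tests verify agreement with a
dense-grid search to 1e-3. GRAVY is the mean Kyte–Doolittle hydropathy.
The disorder score is explicitly a proxy: the mean TOP-IDP
disorder-propensity value rescaled to [0, 1]. Predictor-based disorder
scores (energy-estimation algorithms served over the web) are out of
scope; the proxy is used only for descriptive analytics, never as a model
feature beyond its presence in the battery.

## Modeling

**Feature selection.** Features are ranked by `|r|`, the absolute Pearson
correlation with log10 efficiency; constant features get `r = 0`; ties
break by canonical feature order, so rankings are deterministic.
`selection_mode` controls *where* ranking happens during
cross-validation:

- `"nested"` (default): ranking is recomputed inside each training fold.
  No information from a fold's test rows can reach its feature list — a
  property the test suite verifies by injecting a feature that is perfect
  only on test rows and confirming it is never selected.
- `"global"`: ranking happens once on the full data before folds are
  formed, the minimal reading of the original workflow this package
  re-implements. This leaks the test rows' correlations into selection and
  typically flatters CV metrics; it exists for comparability and is
  clearly flagged.

**Regressor.** No random-forest implementation is available in the target
environment, so the package ships its own: bagged CART regression trees
(variance-reduction splits, unrestricted depth, terminal nodes of at least
`nodesize = 5`, `mtry = n_features/3` candidate features per split,
500 trees), compiled via Rcpp. All randomness is drawn from R's RNG, so a
`model_config(seed = )` fully determines the forest; predictions are
averages of training targets and hence provably bounded by the
training-target range. These hyperparameters follow common
regression-forest defaults; the original analysis used a GUI tool whose
internal defaults are unpublished.

**Cross-validation.** Rows are shuffled once with the given seed and dealt
into k = 10 near-equal folds. Metrics are computed on pooled out-of-fold
predictions: `R² = 1 − SS_res/SS_tot` (coefficient of determination, not
squared Pearson, not per-fold averaging — pooling is the choice that keeps
`R² ≤ 0` meaningful for null data), RMSE in log10 units, and binary
accuracy obtained by thresholding the out-of-fold *regression* predictions
at 2.5 — "changing the model to binary classification" is read as
re-scoring, not retraining a classifier. The top-n sweep runs the grid
50, 100, …, 500 with a shared fold assignment (so differences are due to n
alone) and picks the highest R², ties to the smaller n.

**Persistence.** A model bundle (forest, transform parameters, selected
features, config, version) serializes to a single JSON archive. Doubles
are written as `%.17g` strings because 17 significant decimal digits
round-trip IEEE doubles exactly; a reloaded bundle reproduces predictions
bit-for-bit, and the suite asserts `identical()`.

## Design generation

Candidate pools mix, 50/50 by default, (a) random peptides of 10–20
residues with uniform residue usage, and (b) recombinants of the screen
library: single-point crossover at a shared random cut, or tandem fusion
truncated at the tail to 24 residues, chosen 50/50 per candidate.
Candidates outside 10–24 residues are rejected at source; duplicates
against both the pool and the library are dropped and regenerated up to a
retry cap (a partial pool with a warning if exhausted — relevant only for
tiny libraries). "Recombination" is operationalized as these two operators
because they are the simplest constructions whose products inherit library
composition; the screens this emulates do not document their construction.
Scoring featurizes each candidate, applies the stored transform, restricts
to the bundle's features and averages the forest; the top k (default 9,
the size of a typical designed panel) are returned with ties broken
lexicographically so output is deterministic. A 200,000-candidate default
pool scores in minutes on one CPU; tests and examples use smaller pools
and say so.

## Screen analytics

Toxicity classes: cytotoxic iff max-OD < 50% (boundary safe). Efficiency
classes: efficient iff log10 intensity ≥ 2.5 (boundary efficient). Both
boundary decisions are arbitrary-but-fixed and tested. Property
comparisons take the top and bottom 15 peptides by *raw* intensity (log
transforms do not change ranks) and apply Welch's unequal-variance
two-sided t-test — the conservative choice when the variant of "t test" is
unspecified — with no multiple-testing correction across the four
properties (raw p-values are reported, as screen reports conventionally
do). `correlate()` returns Pearson r, the exact t-distribution two-sided
p, and the least-squares line; zero-variance input is flagged degenerate
rather than raised, because screens legitimately produce constant columns.

## Synthetic screens: the stated world

`simulate_screen()` generates the world the pipeline assumes, not a fit to
any particular dataset:

- 98 peptides of 5–24 residues; each peptide draws a cationic bias
  `w ~ U(0, 0.6)` and each residue is K/R with probability w, otherwise
  uniform — yielding the charge spread real CPP libraries have.
- True log10 intensity
  `= 1.8 + 0.22·net_charge − 0.25·GRAVY + N(0, 0.35)`, exponentiated and
  clipped to [13, 4043] A.U. Effect directions (charge up, hydrophobicity
  down) are the screen finding the model must recover; magnitudes were
  fixed once so that a 98-row screen yields strong single-feature
  correlations and are not revisited per test.
- Toxicity is drawn independently of intensity — mirroring the empirical
  absence of a permeability–toxicity correlation — with exactly
  `round(98 · 10/98) = 10` peptides cytotoxic (uniform max-OD on
  [14, 50)) and the rest truncated-normal on [50, 107] around 90%. The
  exact count (rather than an i.i.d. Bernoulli draw) is a deliberate
  choice so the stand-in screen reproduces a fixed cytotoxic count
  deterministically.

`recover_parameters()` runs the whole pipeline on a simulated screen and
compares CV R² to the noise ceiling `1 − σ²/var(y)`; at defaults the
pipeline recovers ≥ 70% of the ceiling, at σ = 0 it exceeds R² = 0.8, and
permuted targets drive R² to or below zero.

**What a green test does and does not establish.** The generator's signal
is a two-term linear function of sequence, so it validates the plumbing —
featurization, transform, selection, honest cross-validation, design
scoring — and the direction of the recovered chemistry. It does not
emulate real screens' epistasis, measurement heteroscedasticity, library
phylogeny (many real entries are variants of one transduction domain), or
assay-specific artifacts. Two visible consequences, recorded rather than
tuned away: the stand-in's top single-feature `|r|` runs ≈ 0.8, above the
≈ 0.63 a real screen prints, and its sweep optimum is typically n = 50
(the signal is low-dimensional), not the n = 250 a real screen selects.
Reproducing printed screen metrics requires the real measured table, which
is not redistributable with this package; given such a table in the
documented CSV schema, `selection_mode = "global"` reproduces the printed
workflow exactly.

## Numerical choices

- pI bisection tolerance 1e-4 pH; charge-at-pI residual asserted < 1e-3.
- Oracle agreement (Pearson, RMSE, Welch t, top-k scoring) asserted to
  1e-12; composition identities to 1e-9.
- Ties: feature ranking by canonical column order; design ranking by
  lexicographic sequence order (radix/C locale, platform-stable); sweep by
  smaller n.
- Degenerate inputs: length-1 peptides (zero dipeptide block), constant
  features (r = 0, transform to zero), zero-variance correlation inputs
  (flagged), empty candidate pools (error).
- All seeds are explicit function arguments; per-fold forest seeds derive
  as `seed + fold` so folds are independent but reproducible.

## Limitations

- The 85-scale battery is a documented stand-in, not the historical index
  subset; absolute feature identities (beyond family) are not comparable
  across implementations.
- The disorder proxy is a composition average and cannot reproduce
  context-dependent disorder predictions.
- Net charge and pI ignore the fluorophore label, cysteine oxidation and
  position-specific pKa shifts.
- The designer optimizes predicted penetration only; toxicity-aware
  multi-objective design is out of scope.
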