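---
title: "maldiscreen: methods, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{maldiscreen: methods, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(maldiscreen)
```

## The analysis

`maldiscreen` implements a fingertip-smear screening analysis for breast
cancer: sweat proteins deposited by a fingertip are digested in situ with
trypsin, the resulting peptides are profiled by MALDI-TOF MS, and the
spectra are classified into benign, early or metastatic classes. The
package covers the computational half of that workflow — in silico
digestion and peptide-mass-fingerprint (PMF) matching, spectral
preprocessing, featurization, classification and evaluation — plus a
synthetic cohort generator that stands in for the patient data, so the
whole chain runs and is tested offline.

## In silico digestion and PMF matching

Panel proteins are concatenated into one *master sequence* with the
22-residue spacer `RQQQQQQQQQQQQQQQQQQQQR` between consecutive proteins.
The spacer's R termini guarantee that tryptic cleavage isolates each
protein, so a single digestion covers the panel. Digestion uses the
standard trypsin rule (cleave after K or R, suppressed when the next
residue is P — the convention of mMass-style PMF tools), up to 2 missed
cleavages, and expands each peptide into all methionine-oxidation variants
(+15.994915 Da each). Masses are monoisotopic [M+H]+:
sum of residue masses + 18.010565 (water) + 1.007276 (proton). Only charge
+1 is computed.

Spacer-derived peptides are generated but flagged
(`spacer` column) and excluded from matching by default: the spacer exists
only to separate proteins, and flagging rather than dropping preserves
auditability. Whether the original analysis removed them explicitly is not
documented; excluding them by default is the conservative choice and can
be overridden (`include_spacer = TRUE`).

Matching is ppm-based throughout, because the acceptance thresholds of the
original protocol are expressed in ppm: a 30 ppm initial screen
(`match_peaks`), a 10 ppm acceptance against centroided peaks
(`refine_matches`), and a 10 ppm blank screen against control digests
(`screen_blanks`). A peak may match several isobaric peptides; all matches
are kept and sorted by |ppm| — the analysis reports putative
identifications, not unique assignments. Relative intensities are
normalised per replicate by the trypsin autolysis peak at m/z 842.5094.
The shipped exclusion list (CHCA matrix clusters/adducts and porcine
trypsin autolysis peaks) is an editable config: the original protocol
removes these *classes* of ions but prints no list, so the file states our
concrete choice.

Recomputing the ppm errors of the published fingermark identifications
from the standard residue-mass table reproduces the printed values of the
worked-example rows exactly to 1 dp, and all 32 pairs fall within 10 ppm;
a few other rows differ by 0.1–0.5 ppm, consistent with the original
tool's slightly different mass table. We deliberately do not tune the
constants to force agreement.

## Spectral preprocessing

The chain mirrors a vendor-style workflow with these defaults
(`prep_params()`):

| parameter | default | unit | note |
|---|---|---|---|
| SG half-width | 3 | points | window 2·3+1 = 7 |
| SG cycles | 2 | — | applied twice |
| SG polynomial order | 2 | — | vendor order unspecified; quadratic preserves peak area |
| intensity threshold | 700 | a.u. | surrogate for S/N < 3 exclusion; sub-threshold maxima recorded as 0 |
| centroid top % | 80 | % | centroid from points ≥ 20 % of apex |
| min width at half height | 5 | grid points | vendor dialogs use channels |
| deisotope window | 700–2000 | Da | charge 1 only |
| isotope spacing | 1.00235 | Da | averagine spacing at +1 |
| isotope tolerance | 0.01 | Da | chain length ≤ 4 |
| contaminant tolerance | 10 | ppm | exclusion-list removal |

Two conventions deserve flagging because the vendor semantics are not
published. "Centroid top % at 80" is read as *the centroid is computed
from the points whose intensity lies within the top 80 % of the apex
height* (i.e. ≥ 20 % of apex); "minimum peak width at half height of 5" is
read in grid points. Both are documented conventions, not inferences from
the protocol text.

Degenerate inputs: profiles shorter than the SG window are an error;
sub-threshold maxima are carried as intensity-0 rows in exports and
treated as absent by featurization; centroid positions that collide after
3-dp rounding keep the maximum intensity.

## Featurization

Cross-sample variation in m/z positions reported to 3 dp makes the pooled
peak matrix highly sparse, so per-sample positions are rounded to 1 dp,
collisions within a sample resolved by the maximum intensity, and missing
positions zero-padded, yielding a dense samples × m/z matrix. Rounding is
half-away-from-zero (banker's rounding would shift boundary positions) and
column keys are stored as scaled integers (m/z × 10) to avoid
floating-point key inequality across samples. The counts of distinct
pre-rounding (3 dp) and post-rounding (1 dp) positions are first-class
outputs (`n_sparse_positions`, `n_dense_positions`);
`featurize_peaklist_dir()` applies the same logic to a directory of
exported text peak lists, e.g. the deposited archive of the original
study. No normalization or transformation is applied at this stage: the
learners consume raw collapsed intensities.

## The four classifiers

All four are implemented from scratch with fixed hyperparameters; given
the small cohort, hyperparameter tuning is deliberately out of scope.

* **KNN**: k = 3, Euclidean distance, exhaustive linear search. Vote ties
  (possible 1-1-1 with three classes) are broken by the class of the
  nearest neighbour among the tied classes; distance ties by training-row
  order. Both rules are deterministic and distance-respecting.
* **Decision tree**: binary threshold splits on single features chosen by
  maximal Shannon information gain; growth stops at pure nodes or ≤ 2
  objects; pessimistic post-pruning uses the C4.5 binomial upper confidence
  bound at confidence factor 0.25 ("confidence factor" and "objects per
  node" are C4.5 vocabulary). Leaf ties predict the lowest class index.
* **SVM**: soft margin C = 3.5 trained by SMO (deterministic second-choice
  heuristic, KKT tolerance 10⁻³), polynomial kernel. The kernel degree is
  not published; the default is degree 1 with `gamma = 1`, `coef0 = 1`,
  exposed in the spec. Multiclass is one-vs-one majority vote, ties broken
  by aggregate decision margin then class order. "Simple logistic" is
  implemented as post-hoc logistic calibration of decision values; it
  affects scores only, never argmax predictions.
* **MLP**: one hidden layer of 150 logistic units, softmax output,
  cross-entropy loss, per-sample SGD with learning rate 0.001 and momentum
  0.9, weights initialised uniformly in [−0.05, 0.05] from the seed,
  sample order reshuffled per epoch, up to 500 epochs with stop when the
  mean epoch loss changes by < 10⁻⁶. Loss, activation and epoch count are
  not published; these are documented substitutes.

One design decision required deviating from a first-pass reading that the
MLP, like the other learners, should consume raw intensities with no
internal scaling. With the fixed init range (±0.05) and learning rate
(0.001), raw a.u.-scale intensities (thousands) saturate every logistic
hidden unit at initialisation; the derivative term a(1−a) underflows to
exactly zero, so the hidden layer receives no gradient and the network
cannot train — we measured a ≈ 45 % ceiling even for a full multinomial
fit on the frozen hidden features. The MLP therefore min–max normalises
its inputs to [0, 1] *inside* the learner (ranges learnt on the training
fold, reapplied at prediction), which is the behaviour of the classic
toolkit whose hyperparameter vocabulary these settings echo. The
normalisation is explicit, part of the model spec (`normalize`), and can
be switched off. KNN, tree and SVM consume strictly raw intensities.

## Donor-grouped evaluation

The cohort has 15 donors × 9 spectra; replicate spectra of one donor are
not independent, so fold assignment is at the donor level: within each
class donors are shuffled (seeded) and dealt round-robin across the 10
folds with the deal pointer carried across classes. This satisfies
stratification with a max–min donor count per class across folds of ≤ 1,
and with 15 donors in 10 folds gives 5 folds of 2 donors and 5 of 1. The
exact allocation of the original analysis is unpublished; this scheme is
our choice. Donor leakage (a donor present on both sides of a split) is
asserted on every run and is an error, not a warning.

Instead of averaging per-fold accuracies, held-out predictions from the 10
disjoint test folds are pooled into a single out-of-sample confusion
matrix — every sample counted exactly once — and the categorical accuracy
is its trace over its total, reported to 1 dp in percent. A record-wise
(non-grouped) CV (`plan_record_folds` / `run_record_cv`) is provided only
to quantify the optimism of ignoring donor structure; on cohorts with
donor effects and zero class effects it scores above the grouped protocol,
which is the motivation for grouping.

For visualisation, 2-D PCA scores are computed by SVD of the
column-centred matrix with signs fixed so each component's
largest-magnitude loading is positive; three scaling strategies (none,
per-column standardisation, per-column min–max) are available prior to
reduction, and constant columns map to zero. UMAP is not re-implemented:
dimensionality-reduction internals are outside the package's scope, and
PCA covers the tested surface.

## What the synthetic generator emulates — and what it does not

`simulate_cohort()` reproduces the statistical *structure* the analysis
assumes: the 3 × 5 × 3 × 3 design (135 spectra), acquisition range m/z
600–2800, marker peptides with class-dependent log2 intensity shifts,
shared keratin-like background peptides, CHCA and trypsin contaminant
peaks, sub-threshold noise peaks, and — critically for featurization —
Gaussian m/z jitter (sd 0.003 Da) on positions reported to 3 dp, which
makes the pooled 3-dp matrix sparse while 1-dp rounding collapses each
truth peak back to essentially one column. Intensities are lognormal
around class- and donor-adjusted means (strictly positive and
heavy-tailed, like MS intensities); the donor effect is one multiplicative
factor shared by all 9 spectra of a donor, which is what makes grouped CV
strictly harder than record-wise CV. `render_profile()` additionally
renders truth peaks as Gaussians with +1/+2 isotope satellites (+1.00235
and +2.00470 Da, decreasing areas) on a fixed grid for testing the
preprocessing chain end to end.

The study publishes no effect sizes or intensity distributions, so the
default panel (a versioned YAML config, `default_panel()`) states
modelling assumptions: dermcidin and zinc-α2-glycoprotein peptides rise
with disease progression, calmodulin-like protein 3 falls, background
keratins carry no signal; donor sd 0.75 log2, replicate sd 0.35 log2.
These values were chosen once as a plausible biomarker-panel
parameterisation and are not calibrated against the patient data.

The generator does **not** model instrument physics (laser power, TOF
calibration drift, detector saturation), chromatographic retention-time
selection, vendor raw formats, peak-shape asymmetry, chemical baseline, or
correlated contaminant/suppression structure. Consequently, passing tests
demonstrate that the *pipeline logic* is correct and that the evaluation
protocol behaves as designed under known ground truth; they do not
demonstrate that the published patient-data accuracies (62.2–97.8 %) are
reproducible — those depend on unpublished fold allocations and training
seeds and on the real spectra, and are reproduction targets only with the
deposited archive.

## Problem sizes and seeds used by the tests

The test-suite simulations are sized for completeness rather than scale:
digestion equivalence uses random sequences up to 60 residues against a
brute-force enumerator; KNN is checked against a naive oracle on 200
query rows; MLP gradients against central finite differences (relative
tolerance 10⁻⁴); effect monotonicity over 100 small simulated cohorts; the
grouped-vs-record-wise gap over 20 seeds; and the end-to-end MLP check
uses one full 135-spectrum cohort with doubled marker effects (pooled
grouped-CV accuracy ≥ 0.9 at fixed seeds). The chance-level check
averages grouped-CV accuracy over 5 null cohorts (all class effects zero)
and expects it within 1/3 ± 0.15 — the wide band reflects that with 15
donors the effective number of independent units is 15, not 135.

## Known limitations

* Centroid and width conventions follow documented assumptions where
  vendor semantics are unpublished (see above).
* The SVM's polynomial degree, the MLP's loss/activation/epoch regime and
  the fold allocation are stated substitutes for unpublished details.
* Matching reports all isobaric candidates without protein-level
  inference, MS/MS scoring or FDR control — as in the original protocol.
* The deposited archive's sparse/dense position counts (30,764 / 5,940)
  can be reproduced with `featurize_peaklist_dir()` only after downloading
  the archive; the package ships no patient data.
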