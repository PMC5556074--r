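---
title: "Methods: interface hot-spot classification with hotspotr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: interface hot-spot classification with hotspotr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hotspotr)
```

## The problem

When a residue at a protein–protein interface is mutated to alanine, the
change in binding free energy (ddG, kcal/mol) measures how much that
residue contributes to the interaction. Residues with ddG >= 2.0
kcal/mol are *hot-spots* (HS); the rest are *null-spots* (NS). Because
experimental alanine scanning is slow and expensive, hotspotr predicts
the label from the complex's structure and sequence: it extracts
features for every interfacial residue of a two-partner complex and
classifies them with a stacked ensemble trained on labelled
alanine-scanning data. The labelling boundary is inclusive
(`label_from_ddg(2.0)` is `"HS"`).

## Interface definition and structural features

A residue is *interfacial* when it loses solvent accessible surface
area (SASA) upon complexation: monomer SASA − complex SASA > 0 (with a
1e-6 Å² numerical tolerance). This burial-based definition is symmetric
in the two partners and requires two SASA evaluations — the whole
complex and each isolated chain group.

SASA is computed with the Shrake–Rupley method: each atom is inflated
by the probe radius (1.4 Å, water) and sampled with a deterministic
golden-section spiral point set (960 points per atom by default); a
point is accessible when it clears every neighbouring inflated sphere.
Van der Waals radii are a Bondi-style element table
(`vdw_radii()`); unknown elements fall back to carbon. Structures are
accepted with or without hydrogens, and all features are computed on
the atoms present — note that contact counts at 2.5 Å are sensitive to
whether protons are present, so training and prediction structures
should be protonated consistently.

Twelve SASA descriptors per residue span the absolute / relative /
ratio families: complex, monomer and delta SASA; the same three divided
by the residue type's theoretical Gly-X-Gly maximum
(`max_sasa_reference()`, so "relative" values can slightly exceed 1);
side-chain complex/monomer/delta SASA (side chain = all atoms except
N, CA, C, O/OXT and backbone hydrogens); the fraction buried
(delta/monomer, defined as 0 when the monomer value is 0); and the
residue's complex and monomer SASA relative to the mean over residues
of the same type in the same state. The set is assembled in
`sasa_feature_vector()` and both reference tables are replaceable
arguments.

Contacts are intermolecular atom pairs within 2.5 Å and 4.0 Å,
counted per residue against the opposite chain group. Hydrophobic
contacts are carbon–carbon intermolecular pairs within 4.5 Å between
residues of the apolar set {ALA, VAL, LEU, ILE, MET, PHE, TRP, PRO} —
the most common operationalization of a "hydrophobic interaction"
count. The interface composition (20 counts of interfacial residues by
type) is a complex-level feature attached identically to every residue
row.

## Sequence descriptors

Protein-level descriptors are computed per chain group (chains
concatenated in author order) and attached to each residue of that
group:

* **AAC** — the fraction of each amino-acid type.
* **PAAC** (pseudo amino-acid composition, order `lambda`, weight `w`)
  — the 20 composition terms plus `lambda` sequence-order correlation
  factors built from standardized hydrophobicity, hydrophilicity and
  side-chain-mass scales (population-SD standardization over the 20
  types); entry j averages the mean squared property difference of
  residues j apart, and the full vector is normalized to sum to 1.
* **APAAC** (amphiphilic PAAC) — separate hydrophobicity and
  hydrophilicity channels whose order-j terms are mean *products* of
  the standardized properties, giving `2*lambda` terms. A
  consequence worth knowing: for a homopolymer the APAAC correlation
  terms equal the squared standardized property of that residue, not
  zero (only PAAC's difference-based terms vanish).
* **Scale covariances** — each residue is projected onto `k`
  per-residue-type scales (default: the first 5 principal components of
  the BLOSUM62 substitution matrix, sign-fixed for determinism), each
  component is centered along the sequence, and all auto- and
  cross-covariances up to `lag` (default 7) are returned (`k^2 * lag`
  values). Fingerprinting or proteochemometric scale matrices plug in
  through the `scales` argument with the same contract.
* **PSSM** — 20 log-odds scores plus 20 weighted observed percentages
  at the residue's own position, read from an externally produced
  ASCII profile (`read_pssm()`). Profile generation depends on the
  search tool and database, so it is deliberately outside the package;
  when a chain has no profile the 40 features are imputed as 0 and
  flagged (`pssm_imputed`). Profiles declared to come from fewer than
  10 homologs are rejected.

Defaults `lambda = 30`, `w = 0.05` follow the conventional PAAC
parameterization; both require the chain-group sequence to be longer
than `lambda`, so short synthetic fixtures use smaller orders.

## Preprocessing and the six variants

Features are z-scored with the *training* mean and sample standard
deviation (n−1); test data always reuses training statistics.
Zero-variance training columns are dropped and recorded. PCA (when
used) is fitted on the scaled training matrix and retains the smallest
d with cumulative variance ratio >= 0.95. Class imbalance (~24% HS) is
addressed by up-sampling the minority class with replacement to the
majority size (every majority row kept exactly once) or down-sampling
every class to the minority size without replacement. Composition
order is always scale → [PCA] → [resample], giving the six variants
Scaled, ScaledUp, ScaledDown, PCA, PCAUp, PCADown.

Two choices the data sources leave open are made here: observations
with missing values are dropped at assembly (logged), and the
stratified 70/30 split rounds per-class training sizes to nearest,
which reproduces the canonical 374/160 partition of 127 HS + 407 NS.
A genuinely ambiguous corner: with per-class rounding, half-cases
(e.g. two classes of 5 at fraction 0.5) cannot produce an odd total;
R's round-half-to-even applies.

## Benchmarking and classifier clustering

Candidate classifiers are described by binary capability tags
(a 51-algorithm × 55-tag table ships as editable CSV). Algorithms are
clustered on the Jaccard distance d = 1 − |a∩b|/|a∪b| with complete
linkage, cut at k = 5. Determinism is enforced by lexicographic
pre-ordering; an all-zero tag pair is defined to have distance 0 (with
a warning). Because many tag vectors are sparse, several merges occur
at distance 1 and the five clusters are less balanced than an
idealized taxonomy; the tag table is data, so a richer annotation
changes the clustering without code changes.

The registry implements a representative subset spanning all five
families (random forests, boosted trees, plain and penalized logistic
regression, kernel SVMs, discriminant/distance/Bayes models; 13
models), each behind a uniform fit/predict-probability interface.
"pda" is a ridge-shrunk Gaussian discriminant (pooled covariance +
lambda I) implemented in-package.

`benchmark_models()` runs repeated stratified k-fold cross-validation
(default 10×10) per model × variant and averages AUROC, Accuracy, TPR,
TNR, PPV, NPV, FDR, FNR, F1 and MCC across folds. Resampling happens
*inside* each training fold, never before fold assignment — resampling
first would copy minority rows across folds and leak. Models that fail
on every fold are reported as non-converged; degenerate fold metrics
(zero denominators) are NaN and excluded from the averages rather than
aborting the run. Per-cluster champions maximize AUROC + TPR + TNR
(configurable), ties breaking lexicographically.

Cluster-performance differences are tested by one-way MANOVA on the
per-algorithm metric vectors: between- and within-scatter matrices H
and E, eigenvalues of H·E⁻¹, Pillai trace V = sum(lambda/(1+lambda))
with the standard F approximation. (Some texts print a
tr((I+A)⁻¹)-style expression for this statistic; the standard Pillai
trace is implemented and is what `stats::manova` reports, which the
test suite uses as an independent cross-check.)

## The stacked ensemble

The final classifier stacks champion bases — by default rf, svmPoly
and pda — under a logistic meta-model
logit(pi) = b0 + sum(b_j X_j), where X_j are the bases' *binary*
classifications (a switch allows probabilities). Meta inputs are
out-of-fold: the training data is split into stratified folds (5 by
default), each base is refitted without the held-out fold
(up-sampling applied inside the retained folds only) and classifies
the held-out rows. Fitting the meta-model on in-sample base outputs
would let it learn the bases' overfit; cross-fitting prevents that at
the cost of a small divergence from any protocol that stacks
in-sample outputs — training-set metrics are accordingly more
conservative here.

Bidirectional stepwise selection then reduces the meta-model: the
variable with the largest Wald p-value above alpha (default 0.05) is
removed, removed variables are reconsidered for re-entry, and ties
resolve lexicographically. If every variable is removed the
intercept-only model is kept and flagged. If the meta-likelihood is
degenerate (glm reports separation or fails to converge), the
coefficients fall back to a ridge-penalized logistic fit and stepwise
is skipped, flagged `penalized` — Wald statistics are meaningless in
that regime. The fallback triggers only on glm's own degeneracy
signals; large-but-identified coefficients are left to the Wald
machinery, which handles them conservatively.

One degenerate regime deserves a warning label: when the base votes
are (near-)perfect — as on strongly separable synthetic data — the
meta-likelihood sits at the boundary. Either glm reports separation
(penalized fallback, stepwise skipped) or, under quasi-separation,
every Wald statistic deflates (the Hauck–Donner effect) and stepwise
can discard *all* bases, leaving the flagged intercept-only model.
Both outcomes are flagged on the returned object rather than silently
repaired; they do not arise at realistic accuracy levels, which is
where a Wald-based stepwise is meaningful.

Prediction applies the stored scaler (and PCA basis), collects base
votes, and calls HS when pi >= threshold (0.5 by default, boundary
inclusive). Model archives embed the preprocessing state and a schema
version; prediction fails with an explicit listing of missing/extra
feature names when the schema does not match.

## What the synthetic generators emulate

`make_synthetic_complex()` builds two extended poly-residue chains
with a controllable contact patch — enough geometry to exercise
parsing, SASA burial, interface detection and contact counting, with
the generator recording its own brute-force contact oracle. It does
not emulate real protein packing, secondary structure or side-chain
chemistry beyond C-beta.

`make_synthetic_table()` draws labels at the study's ~24% HS imbalance
and Gaussian features with a class-mean shift on a subset of columns;
`make_synthetic_dataset1()` fixes the exact published composition
(534 observations, 53 complexes, 127/407 labels via the ddG rule, 881
feature columns). These tables exercise every preprocessing,
benchmarking and stacking code path, but their Gaussian class
structure is *more* separable than real alanine-scanning data — with
the default 40 informative columns shifted by 1.2 SD, retrained
test metrics sit near 1.0 rather than at published levels. Passing
tests on them demonstrates correct mechanics and honest resampling,
not real-data accuracy.

The pipeline acceptance check uses n = 534, 40 features of which 10
carry a 1.2 SD shift, 20 seeds: large enough for stable stepwise
behaviour, small enough to run in minutes on one CPU.

## Numerical choices and limitations

* SASA quadrature: 960 deterministic spiral points (cross-checked
  against a 10× finer self-oracle within 2%); rigid-body invariance
  holds to quadrature noise (~2%), contacts exactly.
* Alternate locations: highest occupancy wins, first on ties; common
  modified residues (MSE, SEP, ...) map to their parent; other
  non-standard residues are dropped with a warning.
* All seeded operations save and restore the caller's RNG state;
  end-to-end runs are bitwise reproducible under one master seed.
* Zero-denominator metrics are NaN with the computation continuing —
  degenerate folds must not abort a 100-fold benchmark.
* Known limitations: no mmCIF, no assembly generation, no internal
  protonation or structure repair; PSSM profiles must be produced
  externally; the tag table is a curated annotation, and clusterings
  under other annotations will differ; only a representative subset of
  the full published algorithm zoo is implemented.
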