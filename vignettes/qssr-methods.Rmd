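---
title: "Methods: structure-selectivity modeling with qssr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: structure-selectivity modeling with qssr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qssr)
```

## The problem this package addresses

Proline-catalyzed aldol reactions can be steered by *secondary-sphere
modification*: arylboronic acids bind proline reversibly and reshape the
catalyst's microenvironment without covalent synthesis. Crossing a set of
such modifiers with a set of solvents produces a selectivity landscape —
diastereomeric ratios (dr) and enantiomeric ratios (er) that vary with both
factors. The mechanistic question is *which structural configuration of the
modifier* (the free boronic acid, its H-bond or π complex with the
aldehyde, or its proline or enamine adduct) best explains the observed
selectivity in each solvent.

`qssr` turns that question into a reproducible computation:

1. parametrize each hypothesized configuration as a library of 3D
   structures, one per modifier;
2. extract steric and stereoelectronic descriptors from each library;
3. transform the experimental outcomes to modelable responses,
   `log(dr)` and ΔΔG‡;
4. exhaustively fit small multivariate linear models and rank them by
   leave-one-out Q²;
5. compare, per solvent, the best model each configuration library can
   offer.

The configuration whose descriptors support the most predictive model is
the one the data favor as the selectivity-determining species.

## Responses

Diastereoselectivity is modeled as `log10(dr_anti / dr_syn)`. The dr is
always stored as a labeled anti/syn pair, never a bare ratio, because
experimental reports mix "3:1 anti" and "1:2 syn" notations and a bare
ratio silently corrupts the sign. Base 10 is the package default (the
field's convention when a base is unstated); natural log is available via
the `base` argument.

Enantioselectivity is converted to an activation free-energy difference,

ΔΔG‡ = −RT ln(er_major / er_minor),

with R = 1.9872×10⁻³ kcal mol⁻¹ K⁻¹ and T defaulting to 298.15 K
(reactions at ambient temperature; T is exposed in
`campaign_settings()` because it is a physical parameter, not a constant
of the method). Under this sign convention a selective reaction has a
negative ΔΔG‡, and `ddg_from_er(a, b) = -ddg_from_er(b, a)` exactly.

Duplicate runs are averaged on the *transformed* scale before modeling.
Averaging after the log/exponential transform keeps the additive-Gaussian
noise assumption of the linear model on the response actually being fit;
averaging raw ratios would make replicate noise multiplicative and skewed.

## Descriptors

Per structure the package computes:

* **Sterimol L, B1, B5** — Verloop's substituent steric parameters along an
  attachment axis, vdW radii included. The default radius set is Bondi
  (1964) with the common boron extension; it is pluggable. No +0.40 Å
  correction is applied to L (that correction reproduced CPK-model
  measurements; modern implementations report the bare
  projection-plus-radius extent).
* **Distances, bond lengths, dihedrals** — Euclidean Å; dihedrals signed,
  IUPAC convention, range (−180°, 180°].
* **Atomic charges and charge differences** — read from annotation tables
  (e.g. NBO charges from a DFT run); never computed internally.
* **Point-charge dipole and its frame components** — μ = Σᵢ qᵢ(rᵢ − o)
  about the aryl-ring centroid, projected on the ring frame. Units e·Å
  (× 4.80320 for Debye). This is an approximation: a DFT dipole includes
  the full electron density, a point-charge dipole only its atomic
  condensation. Since charges are this package's only electronic input,
  the charge-derived dipole is the implemented definition, documented as
  such.
* **Stretching frequencies** — pass-through columns from the annotation
  table (cm⁻¹); vibrational analysis is out of scope.

### The ring frame

Dipole components are reported in the frame of the boronic acid's aromatic
ring: centroid = unweighted mean of six ring atoms, normal = least-squares
plane normal, axis 1 = centroid → ipso carbon (the ring atom bonded to
boron, by convention the *first* listed ring atom), axis 2 = the in-plane
ortho/meta direction completing a right-handed frame. Because the sign of a
best-fit normal is arbitrary, the frame fixes it by requiring the second
listed ring atom to lie on the positive axis-2 side; this makes the whole
frame equivariant under rigid motions, which the tests verify on random
rotations. Coplanarity is enforced with a 0.3 Å tolerance — optimized
aromatic rings deviate far less, and the slack tolerates idealized or
force-field geometries. Non-aromatic modifiers have no canonical ring, so
the ring atom list is always user-supplied.

### Numerical choices in Sterimol

The substituent is identified by cutting the attachment bond in a bond
graph perceived from covalent radii (bonded if d < 1.3 × sum of Cordero
radii) — necessary because XYZ carries no bonds. Cutting a ring bond does
not disconnect the graph and is reported as an error rather than guessed
around. B1 is computed by an angular scan of the support function of the
projected atom disks, default step 0.25° (hard cap 0.5°), rather than
analytic vertex enumeration: the scan is simple, and its agreement with a
0.01° reference scan is part of the acceptance suite (within 0.01 Å on
random substituents).

## The regression engine

Descriptors are z-scored (sample sd, n−1) before fitting; normalized
coefficients are comparable across descriptors, and `raw_equation()` maps
any fit back to raw units exactly (predictions agree to 1e−8 by
construction, asserted in tests). Constant columns cannot be z-scored and
are reported as errors, not dropped silently.

OLS fits include an intercept. Rank deficiency is declared when the
reciprocal condition number of the design matrix falls below 1e−10.

Model quality is judged by cross-validated Q² = 1 − PRESS/TSS. Two
decisions deserve emphasis:

* **TSS is taken about the full-sample mean** in all Q² variants. This is
  the common chemometric choice; a fold-training-mean variant changes Q²
  slightly but not the subset ranking (PRESS is the only subset-dependent
  term).
* **Q²(LOO) is the selection criterion, not R²**: R² always improves with
  added terms, while Q² penalizes fits that do not predict held-out
  observations, so ranking by Q² suppresses overfit models. For OLS the
  LOO residual obeys e₍₋ᵢ₎ = eᵢ/(1 − hᵢᵢ), hence PRESS ≥ RSS and
  Q²(LOO) ≤ R² for every fit — the suite treats any violation as a broken
  implementation. `q2_loo()` defaults to the n explicit refits as the
  reference path; the hat-matrix identity is the fast path used inside the
  search, and the two are asserted equal to 1e−8.

Repeated k-fold Q² (3-fold and 5-fold, 500 iterations by default) is
reported for selected models: per iteration the data are partitioned into
folds of sizes differing by at most one, out-of-fold residuals are pooled
into PRESS, and the mean and sd over iterations are returned. All
partitions flow from one seed, so reports are exactly reproducible. With
k = n the partition is deterministic singletons and the estimate equals
Q²(LOO), a consistency relation the tests exercise.

The subset search is exhaustive over all 1- to `max_terms`-descriptor
subsets (default 3: the model size used throughout this workflow), with a
collinearity pre-filter: two descriptors with pairwise |r| ≥ 0.8 are never
co-selected — standard hygiene in descriptor regression, where near-copies
of one descriptor would otherwise split credit unstably. Ranking is by
Q²(LOO) descending with deterministic tie-breaks (fewer terms, then higher
R², then lexicographic labels). Repeated k-fold CV is evaluated for the
top `kfold_top` models (default 1) rather than all ~1350 candidates: the
ranking never uses it, and computing 1000 CV iterations per candidate
would multiply runtime by three orders of magnitude for numbers nobody
reads. `q2_kfold()` is exported for any fit on demand.

## The campaign comparison

`run_campaign()` executes the search for every (solvent, response,
configuration) cell and ranks configurations per solvent by their best
Q²(LOO). Three policies keep the comparison honest:

* A response whose per-solvent spread is below a floor (default sd < 0.1,
  in log(dr) units or kcal/mol) is *skipped with a flag*, never fit: a
  flat response supports no structure-selectivity conclusion, and a model
  fit to noise would rank configurations randomly. ΔΔG‡ is modeled only in
  solvents where er actually varies, via the same floor.
* A library whose descriptor assembly fails is marked failed-with-reason
  and the campaign continues; cells are independent, and dropping one
  library never changes another's best model (tested).
* Configurations whose best Q² differ by less than a tolerance (default
  0.05) are flagged as near-ties: several hypothesized structures then
  explain the data about equally well and the ranking should not be
  over-read. The tolerance is a reporting threshold, not a statistical
  test; the default is our choice.

## The synthetic-data module

The generators replace the two inputs the pipeline cannot produce for
itself — DFT-derived descriptor tables and the wet-lab outcome table:

* `gen_matrix()` draws modifier × descriptor matrices from an
  equicorrelated Gaussian (single knob ρ). The default ρ = 0 gives
  independent candidates, the cleanest setting for testing whether
  Q²-ranking recovers a planted subset; raising ρ is how the tests stress
  the collinearity filter (at ρ high enough, sample correlations at n = 15
  cross the 0.8 cut and the filter, by design, forbids co-selection —
  including, occasionally, of the planted pair, which is a property of the
  filter rather than of the ranking).
* `gen_response()` plants y = Σ βⱼxⱼ + ε with defaults n = 15 compounds,
  20 candidates, subset {x3, x7, x9}, β = (2, −1, 0.5), and noise sd
  equal to 5% of the noiseless response range (an absolute sd can be given
  instead). Ground truth travels with the response.
* `gen_toy_structures()` builds idealized planar para/meta-substituted
  phenylboronic acids from standard bond lengths (C–C 1.39, C–H 1.09,
  C–B 1.56, B–O 1.36, O–H 0.96 Å; substituent fragments H, F, Cl, Br, Me,
  OH, CN, CF3, NO2, OMe). They are *not* optimized geometries: they exist
  so ring frames, bond perception and Sterimol can be exercised end to end
  without quantum chemistry, with a fixed atom layout (`ring_atoms = 1:6`,
  ipso first).
* `gen_outcomes()` back-transforms planted log(dr) values to labeled
  anti/syn pairs (10^y : 1), redraws replicate noise per duplicate, tiles
  the requested design exactly, and emits er columns (50:50 unless a ΔΔG‡
  response is planted for that solvent).

What passing tests on these data show — and what they do not: the
generators emulate the *statistical* structure the workflow assumes (a
sparse linear response in a modest candidate pool, replicate noise on the
transformed scale, one generating configuration per solvent). They do not
emulate DFT-quality geometries, realistic descriptor covariance beyond a
single ρ, heteroscedastic measurement error, or a background reaction that
erases structure-selectivity correlation (the methanol situation in the
motivating campaign). Green synthetic tests certify the machinery, not any
chemical conclusion about real systems.

## Problem sizes and determinism

The shipped test and acceptance runs use the study's natural sizes:
15 modifiers, 20 candidate descriptors, 3-term models, 100-seed recovery
and configuration-identification experiments, and 500-iteration repeated
CV for reported models. Every stochastic step (matrix draws, response
noise, fold partitions, per-solvent generating configurations) is driven
by explicit integer seeds, and reports carry their seed, so any table in
any output can be regenerated exactly.

## Known limitations

* Dipoles are point-charge approximations (see above).
* The descriptor inventory is fixed to the kinds listed; no buried
  volume, surface areas, or conformer ensembles.
* The search is exhaustive, which is exact but quadratic-to-cubic in the
  candidate count at `max_terms = 3`; pools much beyond ~60 descriptors
  deserve a pre-screen.
* `subset_search` requires complete matrices; missing cells are an
  assembly error by design, not imputed.
* With n = 15 and a weak third term, Q²(LOO) ranking has a genuine
  false-selection rate at high noise; the acceptance experiments quantify
  it (the 100-seed recovery rate at the default noise level) rather than
  hide it.
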