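---
title: "Quantifying KIR2D docking geometry atop HLA-C: methods and conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying KIR2D docking geometry atop HLA-C: methods and conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Inhibitory natural-killer-cell receptors KIR2DL2 and KIR2DL3 are allelic
two-domain (D1 + D2) immunoglobulin-like receptors that bind the C1 group
of HLA-C allotypes. Crystal structures of their ternary complexes with
peptide-HLA-C show that even closely related receptors, binding the same
ligand with an essentially identical set of contact residues, can sit on
the platform in measurably different orientations. `kirdock` turns that
qualitative observation into reproducible numbers: for any pair of
two-domain receptor complexes it reports per-complex hinge (elbow) angles,
per-domain twist differences, centre-of-mass shifts along the
peptide-binding groove, superposition r.m.s.d. values, interface contact
footprints and buried surface area; alongside it implements the binding
statistics that usually accompany such structures (bead-fluorescence and
tetramer normalizations, steady-state KD fits, and adaptive FDR testing
over a peptide panel).

## Geometry: model and conventions

**Domain frames.** Each domain is represented by the principal-axis frame
of its C-alpha cloud: centroid plus orthonormal axes `e1` (long axis,
largest covariance eigenvalue), `e2` (middle) and `e3 = e1 x e2` (short).
Eigen-decomposition uses the symmetric solver; if either consecutive
eigenvalue ratio is below 1.01 the cloud is effectively degenerate and the
frame is refused rather than silently ill-conditioned. Two sign rules make
frames reproducible:

* `e1` points from the centroid of the first 10% of residues (in residue
  order) toward the centroid of the last 10% — i.e. roughly N-to-C along
  the domain.
* `e2` points into the hemisphere of an "up" reference. Within a complex,
  up is the unit vector from the platform C-alpha centroid to the receptor
  C-alpha centroid. This intrinsic choice (rather than a laboratory +z)
  makes every reported quantity exactly invariant under rigid motion of
  the input coordinates, which the test suite checks.

**Hinge.** The hinge (elbow) angle of a receptor is the angle between the
D1 and D2 `e1` axes, computed per complex from the C-alpha atoms of the
domain ranges (defaults: D1 = residues 1-102, D2 = 108-200, with 103-107
as the interdomain linker; all configurable).

**Twist.** Rotations are compared after aligning both complexes on the HLA
platform — a Kabsch least-squares superposition over paired platform
C-alpha atoms (default residues 1-180 of the heavy chain; beta-2
microglobulin and the peptide are deliberately excluded from the
alignment). Pairing is by author residue number only, so allotypes that
differ in sequence or in modelled residue ranges pair correctly. The
Kabsch implementation applies the determinant correction, so a reflection
can never be returned, even for degenerate (planar) inputs.

The rotation `R` carrying the reference domain onto the aligned comparison
domain is then factored exactly as `R = swing %*% twist`, where `twist` is
a rotation about the reference domain's `e3` axis and `swing` is a
rotation about an axis perpendicular to it (quaternion projection method).
The signed twist angle is the reported per-domain twist difference; its
magnitude is what one compares with published figures, and the sign is
retained in machine output (swapping reference and comparison negates it).
This operationalizes "rotation of the domain about its short axis,
perpendicular to the axis that defines the hinge" in a way that is fully
testable by construction: rotating a domain rigidly by a known angle about
its own `e3` must be recovered exactly, and is.

**Centre-of-mass shift.** After platform alignment, the displacement of a
domain's C-alpha centroid is projected onto the groove axis — the unit
vector from the reference peptide's first-position C-alpha to its
last-position C-alpha — so positive values mean "toward the peptide
C-terminus".

**Why these conventions can differ from any particular published number.**
Axis-sign rules, the exact platform range, and the choice of asymmetric-
unit copy are rarely stated alongside printed hinge/twist values, and
copy-to-copy coordinate differences alone reach ~0.4 A. Angles computed
here should therefore be compared with published values at a tolerance of
a few degrees (r.m.s.d. within ~0.15 A, buried areas within ~10%), which
is also how the package's own documentation quotes them. The conventions
block of every `geometry_comparison` records all choices applied.

## Interface: contacts and buried surface

Contacts use a heavy-atom distance criterion, cutoff 4.0 A by default (the
conventional crystallographic contact distance; configurable), one record
per residue pair with the minimum distance and the atom pair achieving it.
Footprints classify each contact into one receptor region — the D1 A-B
(14-22), C-C' (41-47) and E-F (67-74) loops, the interdomain loop
(103-107), the D2 B-C (132-135) and F-F' (181-187) loops, or `D1:other` /
`D2:other` — and one target element: the alpha1 (50-84) or alpha2
(138-180) helix, a peptide position `P1..Pn`, or `other`. The loop
boundaries beyond the two the literature states explicitly (B-C and F-F')
were chosen to contain every loop residue named in published contact
descriptions (Lys44/Phe45 in C-C'; Met70/Gln71/Asp72 in E-F;
Leu104/Tyr105/Glu106 in the interdomain loop); all are configurable per
model.

Solvent-accessible surface area is computed by the Shrake-Rupley method
with a deterministic golden-spiral point set (no RNG; 960 points per atom
by default, probe 1.4 A) over a fixed, documented van der Waals radii set
(C 1.70, N 1.55, O 1.52, S 1.80 A). Hydrogens are dropped at parse time
(the relevant crystal structures, at 2.5-3.1 A, contain none) and waters
and other heteroatoms are excluded from all geometry and surface
computations. Buried surface area is the both-sides convention,
`SASA(receptor) + SASA(ligand) - SASA(complex)`, with beta-2 microglobulin
included on the ligand side by default (it is part of the ternary-complex
surface; a flag excludes it). Single-sphere and two-sphere closed forms
bound the quadrature error at 960 points below 1%; because the point grid
is fixed in the laboratory frame, surface areas are invariant under rigid
motion only to within that quadrature error.

## Binding statistics

* **Bead normalization**: `(S#N - SNC) - (BG#N - BGNC)` per bead, i.e. the
  sample channel minus its negative-control bead, background-corrected by
  the same contrast in the isotype-control channel. Negative specific
  signals are retained and flagged, never clamped. Panels are summarised
  as percent-of-maximum within each experiment, then averaged across
  experiments; tetramer staining is divided by FLAG-positive staining
  (transfection-efficiency control) and normalized to wild type.
* **Steady-state KD**: nonlinear least squares on
  `Req(C) = Rmax * C / (KD + C)` (Levenberg-Marquardt, positive-bounded),
  initialized at `Rmax0 = max(Req)` and `KD0` = concentration at half-max.
  The KD standard deviation comes from the fit covariance; the convergence
  flag is honest — an all-zero series reports failure rather than a
  number, and concentration series truncated far below KD yield inflated
  SD, which a test documents.
* **Panel testing**: unpaired two-sample t-tests from summary statistics,
  pooled-variance by default (with n = 2 per group this reproduces the one
  published p-value that recomputes cleanly from the printed summary
  statistics, 0.0107 for the P8G peptide; the printed wild-type p-value
  does not recompute under either the pooled or the Welch flavour and is
  therefore not asserted numerically), Welch by flag. Multiplicity is
  handled by the adaptive two-stage step-up FDR procedure: stage one is a
  Benjamini-Hochberg step-up at `Q/(1+Q)` whose rejection count estimates
  the number of true nulls `m0 = m - r1`; stage two is a step-up at
  `Q * m / m0`. Q-values are the smallest Q at which a test is a
  discovery, found by bisection (the procedure is monotone in Q, which a
  property test verifies); they agree with a brute-force implementation on
  all small p-sets and reproduce the published "no discoveries at Q = 1%"
  outcome on the peptide panel, both from the printed p-values and from
  p-values recomputed from the printed means and SDs.

## The synthetic-data generator

Real deposited coordinates cannot accompany a lightweight package, so
every pipeline stage is exercised on ground-truthed synthetic complexes:
a 180-residue platform body whose long axis defines the groove, a
9-residue peptide along the groove just above the platform surface, a
small body standing in for beta-2 microglobulin, and a two-domain receptor
(102 + 93 residues plus a 5-residue linker) whose long axes meet at
exactly the requested hinge angle, elbow over the peptide C-terminal half
— the canonical KIR2D docking arrangement. Perturbations rotate each
domain rigidly about its own `e3`, translate the receptor along the
groove, and add isotropic Gaussian coordinate noise; all truth values are
recorded in a manifest.

Design choices worth knowing:

* Bodies are sampled uniformly in an ellipsoid and then exactly whitened
  and rescaled so the *sample* covariance equals the target diagonal. The
  construction axes therefore coincide with the sample principal axes, and
  zero-noise recovery tolerances (0.5 degrees across the hinge 60-90 x
  twist 0-15 grid) measure the estimator, not Monte-Carlo sampling error.
  In practice zero-noise recovery is exact to floating-point precision.
* Each domain's middle axis is constructed as the projection of the
  platform normal onto the plane perpendicular to the long axis, which
  keeps the `e2` sign rule stable under the supported perturbations.
* Residues carry a C-alpha plus a dummy C-beta placed 1.53 A outward from
  the body centroid, so heavy-atom contact and buried-surface computations
  have protruding atoms to work with; surface-area correctness itself is
  tested on explicit small atom sets against closed forms.
* Twisting a domain about `e3` legitimately changes the elbow angle, so
  the hinge "truth" for a perturbed pair is its zero-noise value, not the
  pre-perturbation hinge.
* The noise model is isotropic Gaussian per atom — the simplest model
  under which angle-recovery tolerances can be stated (with 0.3 A noise,
  hinge and twist stay within 2 degrees of truth in at least 95 of 100
  seeds). Real coordinate error is anisotropic and correlated along the
  chain; the generator makes no attempt at bond geometry, rotamers or
  sequence realism. Passing these tests therefore demonstrates the
  correctness of the estimators under the stated error model, not
  crystallographic accuracy on real data.
* Generators are pure functions of `(parameters, seed)`; a single integer
  seed expands to independent substreams per body as
  `(seed * 1000 + k) mod (2^31 - 1)`.

## Problem sizes and determinism

The shipped analyses use 976-atom synthetic complexes, 960-point surface
quadrature (480 where only differences of totals matter), 100-seed noise
and KD sweeps, and a 10,000-replicate null simulation for FDR control —
sizes chosen so the whole grid runs end-to-end in about a minute on one
CPU while leaving Monte-Carlo error well below every stated tolerance.
All stochastic steps take explicit seeds and restore the caller's RNG
state.

## Known limitations

* Hinge/twist conventions are one defensible operationalization; numbers
  from other programs can differ by a few degrees without either being
  wrong. Compare magnitudes and orderings, and read the conventions block.
* Contact tables reproduce presence/absence of key contacts, not the
  row-level output of any particular legacy program whose cutoff and
  criteria are unstated.
* Whether published buried-surface totals are per-side or summed over both
  sides is often unstated; this package reports the both-sides total (and
  each side separately).
* No symmetry-mate generation or assembly building: analyses use one
  explicitly configured asymmetric-unit copy.
* Kinetic (on/off-rate) SPR analysis, flow-cytometry file parsing and
  donor-level nonparametric statistics are out of scope.
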