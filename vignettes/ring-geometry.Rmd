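---
title: "Geometry of helicase rings bound to single-stranded DNA: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Geometry of helicase rings bound to single-stranded DNA: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ringgeom)
```

## The problem

Replicative helicases of the MCM family are ring-shaped hexamers. Crystal
structures of the N-terminal domain tier (MCM_N) of archaeal MCMs show a
six-membered ring whose central channel holds single-stranded DNA in an
unusual pose: the ssDNA circles the interior of the ring roughly
perpendicular to the channel axis, engaging the OB-fold ("C") subdomain of
a subset of subunits. Several quantitative claims follow from such a model:
how far the ring deviates from ideal sixfold symmetry, how wide the channel
is at each height, which subunit interfaces are close enough to bind DNA,
which angular direction the 5′→3′ order takes, and how strongly the protein
binds DNA in solution. `ringgeom` implements each of those measurements as a
composable, tidy function, together with synthetic generators that produce
assemblies with exactly known ground truth so every stage can be validated
without any crystallographic input.

All coordinates are in ångströms; author residue numbering is authoritative
throughout, because published per-residue claims (probe residues, subdomain
ranges) are stated in author numbering.

## Deviation from cyclic symmetry

An n-membered ring with chains $c_1 \dots c_n$ (in ring order) is exactly
$C_n$ symmetric iff some rigid rotation maps each subunit onto its
neighbor. The statistic here makes that operational: take the superposition
atoms (by default the Cα of a user-chosen subdomain range) of all chains
concatenated in ring order, and superpose them — one single global
least-squares fit — onto the same coordinates with the chain labels rotated
one step ($c_2 \dots c_n c_1$). The fitted RMSD is zero iff the ring is
exactly $C_n$, and grows smoothly with any deviation. We use one global
fit of the concatenated point set rather than averaging per-chain fits,
because the statistic is a property of the whole ring, and only the global
fit vanishes exactly at perfect symmetry.

The rigid-body kernel is the standard SVD (Kabsch) solution with the
determinant correction so reflections are never returned; protein chains
are chiral and an improper "superposition" would be meaningless. Nearly
collinear point sets are rejected rather than solved, because the
symmetry statistic must not depend on an ill-conditioned fit.

The fitted rotation of a near-symmetric ring approximates the ring's
$360/n$° symmetry operation, so its invariant line is the channel
(pseudo-symmetry) axis. We read the axis direction off the rotation matrix
(the eigenvector with eigenvalue +1, with the sign fixed from the
antisymmetric part) and anchor the axis at the point of the invariant line
nearest the subdomain centroid, solving $(I-R)\,p = t_\perp$ by
pseudoinverse. A second, independent axis construction — the
smallest-variance principal direction of the Cα cloud, i.e. the normal of
the ring plane — is provided as `fit_axis(..., method = "inertia")`; on
mildly perturbed synthetic rings the two agree within a couple of degrees,
which is one of the package's cross-method tests.

Which residue range constitutes the superposition subdomain is user
configuration (`ring_definition(chains, subdomain)`). Published MCM
analyses use the OB-fold subdomain; the exact boundaries are
structure-specific and are deliberately not defaulted. When a residue in
the range is unmodeled in some chains, the row-correspondence is restored
by dropping that residue number from *every* chain (intersection rule),
with a warning; this can perturb the statistic in the third decimal
relative to other conventions, which is why reported values carry that
caveat.

## Channel radius profile

The published visualization of channel width is a cylindrical merge: many
copies of the hexamer rotated about the channel axis, surfaced, and
clipped. The displayed quantity, though, is simply how closely the protein
approaches the channel center at each height. `radial_profile()` computes
that directly: atoms are binned by axial coordinate (default bin width
1 Å — finer than subdomain extent, coarser than coordinate noise), and
each bin reports the minimum distance to the axis over its atoms. Because
radial distance is invariant under rotation about the axis, the minimum
over any set of rotated copies equals the minimum over the original atoms;
the explicit 72-copy (5° increment) rotational merge is retained in the
test suite as an oracle and agrees to 1e-9. Atoms are treated as points;
an optional uniform `probe_radius` can be subtracted when an excluded-
volume reading is wanted. `clearance_vs_reference()` compares each bin
against a straight reference cylinder (default 20 Å diameter, the envelope
of B-form duplex DNA) with an inclusive boundary: a bin whose minimum
radius equals the reference radius is counted passable, matching the
"would fit" reading. `narrowest_point()` breaks ties toward the smallest
axial coordinate so repeated calls are deterministic.

No molecular surfaces are computed: the package reports atom-center
geometry, not solvent-excluded surfaces, and this is a deliberate scope
decision, not an approximation of one.

## Interface engagement classification

DNA occupancy at a subunit interface correlates with how closely the two
subunits approach: the probe metric is the distance between one marker atom
on subunit $i$ (for PfMCM, residue 201 Cα) and a partner atom on its
counterclockwise neighbor (residue 127 Cα). Interfaces with probe distance
below `tau_engaged` (default 7.5 Å) are classed `engaged`, above
`tau_disengaged` (default 8.4 Å) `disengaged`, and `intermediate` between.
The published statements use strict inequalities ("less than", "exceeds"),
so a distance exactly at either threshold falls in the intermediate class.
Both residues and thresholds are configuration (`probe_spec()`), because
the residue numbers are specific to one protein and the metric generalizes.

The "counterclockwise neighbor" is resolved through the ring order of
`ring_definition()` together with the axis `c_face_sign` convention; the
classification output lists the resolved pairing (`chain_i`, `chain_j`) so
the orientation can be verified at a glance. `engagement_vs_dna()` joins
the classes with an observed per-subunit DNA occupancy table and counts
concordant and discordant interfaces; intermediate interfaces are excluded
from the concordance counts by default since the model makes no prediction
between the thresholds (they can be included with
`count_intermediate = TRUE`).

## Geometry of the bound ssDNA

A nucleic-acid path is the 5′→3′-ordered list of nucleotides of the DNA
chains, each represented by one reference point: the C1′ atom, which is
present in every modeled nucleotide and central to it, with the phosphate
P as fallback. Ascending author residue number is taken as 5′→3′.

*Polarity.* The reference points are projected into the plane normal to the
channel axis, and the signed angular increments between consecutive
nucleotides are summed. Each increment is wrapped to (−180°, 180°], so a
single step is never ambiguous — consecutive modeled nucleotides sweep far
less than 180° in any physical geometry. The sign is taken about the
direction pointing at the viewer; positive net sweep is counterclockwise on
the viewer's page. Which physical face the viewer occupies is the
`c_face_sign`/`view_from` convention: for an N-domain-only model the
C-terminal (ATPase) face cannot be inferred from the coordinates, so it is
explicit user input, and outputs echo the convention to prevent sign
confusion. Reversing the nucleotide order flips the sense and negates the
sweep; a closed sampled circle sweeps ±360° within 1° at any sampling
density of at least 8 points (both property-tested).

*Planarity.* A total-least-squares plane (smallest principal direction of
the centered reference points) is fitted, and the acute angle between its
normal and the axis is reported: 0° means the DNA lies in a plane exactly
perpendicular to the channel. Collinear paths are rejected as degenerate.

*Stretches.* Maximal runs of consecutively numbered nucleotides within a
chain, reported sorted descending. Two chains are never merged into one
stretch even if their numbering continues, since per-hexamer stretch counts
are defined on modeled chains.

*Subunit assignment.* Each nucleotide is assigned to the protein chain with
the most heavy-atom contacts within a cutoff (default 4.5 Å, a standard
heavy-atom contact distance); ties go to the chain earlier in ring order
and contact-free nucleotides stay unassigned. On the synthetic fixtures the
per-subunit counts are stable to cutoff changes of ±0.25 Å — documented as
a test, not as a guarantee for arbitrary structures. The full-occupancy
capacity of a ring is then simply `ring_size * per_subunit_increment`
(24 for a hexamer binding four nucleotides per subunit).

## EMSA Hill fits

Band intensities from a mobility-shift titration, normalized by the
no-protein lane, follow the paired isotherm

$$\frac{I_{free}}{I_0} = \frac{K_{half}^h}{K_{half}^h + c^h},\qquad
  \frac{I_{bound}}{I_0} = \frac{c^h}{K_{half}^h + c^h},$$

with $c$ the protein concentration, $K_{half}$ the half-binding
concentration and $h$ the Hill coefficient. `fit_titration()` minimizes the
joint sum of squares over both band residuals simultaneously, weighting the
two equally (nothing in the data dictates otherwise), using
Levenberg–Marquardt with box bounds. Initialization is deliberately dumb
and robust: $K_{half}$ starts at the concentration whose free fraction is
nearest 0.5 and $h$ at 1. $h$ is bounded to (0.1, 10]: a nine-point ladder
cannot constrain steeper exponents, and unbounded fits on sparse ladders
diverge. Series with fewer than three distinct positive concentrations, or
with no binding transition in range (all-bound/all-free), are refused
rather than fitted. Both input dialects — precomputed fractions and raw
two-band intensities with a zero-concentration lane — are accepted.

Binding-defect sizes are reported as $K_{half}$ ratios
(`fold_change(mutant, wildtype)`). Published fold-change statements for
this family of measurements do not come with Hill coefficients, so the
ratio-of-$K_{half}$ reading is the one implemented and documented.

Simulation checks (run by the test suite and the acceptance script):
noiseless titrations generated at the nine-point wild-type ladder
(1.4–54 µM) are recovered to better than 1e-4 relative error over a
3×3 grid of true parameters ($K_{half} \in \{1, 5, 20\}$ µM,
$h \in \{0.8, 1, 2\}$); with 2% Gaussian band noise, the median recovered
$K_{half}$ over 200 seeded replicates stays within 5% of truth.

## The synthetic generators

`make_ring()` places $n$ copies of a fixed 30-point monomer template at
equal angles about +z at the ring radius (default 20 Å, the scale of an
MCM N-tier ring). The template is a closed-form, chiral, non-planar
pseudo-fold computed from the point index — no randomness — so fixture
values are stable across platforms and sessions. Perturbations are applied
per subunit in the subunit's local frame (radial, tangential, axial shifts
and a twist), either as explicit per-subunit values or as i.i.d. Gaussian
sigmas under a mandatory seed. Zero perturbation yields an exactly $C_n$
assembly, and the construction axis, ring definition and resolved
perturbations ride along as ground-truth attributes, so every downstream
statistic has an analytically known expected value in the zero-noise case.

`make_dna()` lays nucleotide reference points on a circular or helical
path; the sign of the angular step fully determines handedness, the rise
sets planarity, and omitted positions create numbering gaps with known
stretch structure. `simulate_titration()` evaluates the Hill model and
adds truncated-Gaussian noise on the fraction scale (fractions clipped to
[0, 1]); no error model is prescribed by the data, so a simple one was
chosen once.

What the generators do **not** emulate: real side-chain packing, B-factors
and coordinate error models, partially occupied conformers, or the
sequence-dependent pucker of real DNA. Passing tests on synthetic rings
therefore validate the geometry and statistics of the implementation, not
the crystallographic realism of any particular model; conclusions about a
real structure always require running the same functions on that
structure's coordinate file.

## Numerical choices and degenerate inputs

- Superposition tolerates any non-collinear input of ≥ 3 points; the
  rank test uses the second singular value relative to the first at 1e-8.
- Axis directions are normalized to unit length; the fitted axis sign is
  made deterministic by keeping the direction in the +z hemisphere (ties
  broken toward +x, then +y).
- Altloc reduction keeps the highest-occupancy conformer, ties resolved to
  altloc "A" then alphabetically; insertion-coded residues order after
  their base number and are excluded from residue-range selections, which
  match on plain author numbers.
- Interface classes at exactly a threshold are intermediate (strict
  inequalities); note this makes boundary classes knife-edge under
  floating-point perturbation, which is inherent to any strict rule.
- Profile bins with no atoms carry `NA` radius and are excluded from
  narrowest-point detection; `narrowest_point` ties break toward smaller z.

## Problem sizes used by the checks

The test suite and `scripts/acceptance.R` run entirely on synthetic data at
these sizes, chosen to exercise every code path at desk scale: 6 × 30-point
rings for symmetry statistics (20 perturbed replicates against the
brute-force axis/angle oracle), 200 random ≤ 10-point sets against the
quaternion superposition oracle, 72–200-atom clouds for channel profiles,
12–13-nucleotide synthetic DNA paths, and 200 seeded replicates for the
noisy Hill-fit study. Checks against published per-structure numbers
require the deposited coordinate files, which are not redistributed with
the package; `tests/testthat/test-acceptance.R` documents the options
(`ringgeom.structure_ssdna`, `ringgeom.structure_apo`,
`ringgeom.c_subdomain`) through which local copies are supplied.

## Known limitations

- mmCIF support is limited to the coordinate (`atom_site`) dialect the
  bio3d reader understands.
- The channel profile is atom-center geometry; no solvent-excluded surface
  is computed, and `probe_radius` is a uniform offset, not per-element
  radii.
- The symmetry statistic depends (in the third decimal) on the
  residue-intersection convention when chains are unevenly modeled.
- `fold_change` compares point estimates; no confidence intervals are
  propagated from the titration fits.
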