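---
title: "Descriptor extraction for radiometal-chelator complexes: models and methods"
author: "radchel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Descriptor extraction for radiometal-chelator complexes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radchel)
```

## Scope and scientific setting

Radiometal-chelator complexes - a radioactive metal ion (Ga³⁺, Cu²⁺, Ac³⁺,
...) held by a polydentate ligand through O/N donor atoms - are the working
parts of radiopharmaceuticals. Screening candidate complexes computationally
rests on a compact set of descriptors: electronic ones that proxy chemical
stability, and structural/solvation ones that summarise how the complex
behaves in water. `radchel` implements the descriptor-extraction and
force-field-derivation computations of such a screening pipeline as tested,
reusable R code. It deliberately does **not** run any electronic-structure
or molecular-dynamics engine: quantum-chemistry outputs (orbital spectra,
total energies, Hessians, optimized geometries) and MD trajectories are
*inputs*, and a synthetic-data generator produces physically structured
stand-ins with known ground truth so that every extractor can be validated
at desk scale.

## Electronic descriptors

**Frontier gap.** For a closed-shell complex the gap is
$E_\mathrm{LUMO} - E_\mathrm{HOMO}$; for open-shell species the highest
occupied level across both spin channels (the SOMO) takes the HOMO's place,
and the LUMO is by default the lowest unoccupied level across both channels
(`frontier_gap(lumo_across_channels = FALSE)` restricts it to the SOMO's
channel). A gap below zero is reported with a flag, never clamped. The
conventional stability classification places a complex above or below a
4 eV line; `classify_stability()` uses a *strict* inequality, so a gap of
exactly 4 eV is "not above" - the line itself is a boundary, not a member.

**Delta-SCF block.** From total energies of the $N$, $N{+}1$ and $N{-}1$
electron systems at fixed geometry:
$\mathrm{IE}_v = E_{N-1} - E_N$, $\mathrm{EA}_v = E_N - E_{N+1}$, the
fundamental gap $E_\mathrm{gap} = \mathrm{IE}_v - \mathrm{EA}_v =
E_{N+1} + E_{N-1} - 2E_N$, hardness $\eta = E_\mathrm{gap}/2$ and softness
$S = 1/(2\eta)$. The softness definition is the standard conceptual-DFT
reciprocal form; the product $\eta S = 1/2$ is asserted in the tests as an
identity. A zero gap leaves $S$ as a flagged missing value. Because these
are small differences of ~10³ eV totals, "exact" identities hold to about
$10^{-12}$ *relative to the total energies*, and the tests bound them that
way rather than relative to the near-cancelling gap.

**QM/MM benchmark MAE.** `bond_length_mae()` identifies coordination bonds
as metal-X pairs (X in {O, N} by default) within 3.0 Å in the reference
structure - the typical upper end of M-O/M-N coordination distances - and
reports the mean absolute deviation of those bond lengths in a comparison
structure with identical atom ordering. Both the donor set and the cutoff
are arguments.

## Morphology descriptors

The gyration tensor
$S = \sum_i w_i\, (r_i-\bar r)(r_i-\bar r)^\top / \sum_i w_i$
with eigenvalues $\lambda_1 \le \lambda_2 \le \lambda_3$ yields
$R_g^2 = \sum_k \lambda_k$, asphericity $b = \lambda_3 -
(\lambda_1+\lambda_2)/2$, acylindricity $c = \lambda_2 - \lambda_1$ and the
relative shape anisotropy $\kappa^2 = (b^2 + \tfrac34 c^2)/R_g^4 \in [0,1]$
($0$ for cubic/tetrahedral symmetry, $1$ for collinear configurations).
Weighting is by atomic mass by default, matching the common
trajectory-analysis convention; `mass_weighted = FALSE` gives the uniform
variant. The implementation is checked against a brute-force double-sum
assembly of the tensor on random clouds to $10^{-10}$.

**Minimal projection area (MPA).** Atoms are projected as disks of their
van der Waals radii onto the three planes perpendicular to the principal
inertia axes; the MPA is the smallest union-of-disks area. The embedded
radius table is the Bondi set, extended with values in the 2.0-2.5 Å range
for heavy metals without a Bondi entry (see `R/elements.R`). The union area
is measured by 2-D grid occupancy at 0.05 Å resolution (configurable)
rather than exact power-diagram integration; the accuracy gate is analytic
closure (single disk $\pi r^2$ and the two-circle lens formula within
0.5%) plus a grid-halving convergence check (<0.2% change). The grid origin
is snapped to multiples of the resolution so any single disk's cells are a
subset of the union's cells, making the "union is at least the largest
disk" bound hold on the grid exactly. Only the three principal-axis
projections are evaluated - the geometric definition - not an orientation
optimisation over the sphere. With degenerate inertia moments the
eigenvector basis is whatever the deterministic symmetric eigensolver
returns; the projected area over a degenerate subspace can depend on that
basis at the grid-tolerance level (a known limitation). Per-frame values
along a trajectory are averaged; regenerating independent conformers per
frame would be an alternative reading of "conformer averaging", not
implemented.

## Trajectory descriptors

**Solvation shells.** A water belongs to the first shell of a frame when
its oxygen's minimum distance to *any* solute atom is at most $r_1$, and to
the second shell in $(r_1, r_2]$; the defaults $r_1 = 3.4$ Å, $r_2 = 5.0$ Å
are the de-facto water-shell conventions of trajectory post-processing
tools (`metal_only = TRUE` gives a metal-centric variant). Frames are
assumed pre-imaged; there is no minimum-image handling.

**Hydrogen bonds.** Geometric criteria: donor-acceptor heavy-atom distance
$\le 3.0$ Å and donor-H-acceptor angle $\ge 135°$, both configurable -
again the standard post-processing convention, since no single criterion is
canonical. Donors are N/O/F atoms with a bonded hydrogen (water O-H pairs
are inferred from atom roles when the bond list does not cover them);
acceptors are all N/O/F. Occupancy is reported per donor-H-acceptor triple,
plus per-frame counts split into intra-solute and solute-water bonds; a
"percentage of H-bonds" with an unstated denominator is deliberately not
reported.

**RMSF.** Frames are superposed onto the running mean structure by a Kabsch
fit on the solute (two refinement passes), then
$\mathrm{RMSF}_i = \sqrt{\langle |r_i - \langle r_i\rangle|^2\rangle}$.
For isotropic per-atom jitter of width $\sigma$ the sampling law is
$\mathrm{RMSF} \to \sqrt{3}\sigma$; the fit removes six rigid-body degrees
of freedom, biasing the mean by a factor $\approx\sqrt{1 - 6/(3N)}$, which
is why the validation uses a 60-atom solute (bias <2%) rather than a tiny
one.

**Conformational clustering.** Pairwise Kabsch RMSD on the solute selection
feeds hierarchical agglomerative clustering (`stats::hclust`);
average linkage is the default, with single/complete available, since the
tool family that popularised trajectory clustering defaults to average.
The requested cluster count defaults to 10 (the "ten most populated
clusters" reporting convention) but is capped by the number of *distinct*
frames, so duplicated frames are never split to pad the count. Clusters are
relabelled by population; each representative is the medoid (minimum summed
intra-cluster RMSD, ties to the lowest frame index). The matrix is the
dominant memory cost, so a `stride` argument keeps at most ~2000 frames in
it for long trajectories; whether striding distorts populations depends on
the trajectory's mixing, which is the user's call, not an assumption.

## Seminario force constants

From the Cartesian Hessian (read as packed lower-triangular
Hartree/Bohr² text and converted once to kcal mol⁻¹ Å⁻² via
627.5095/0.529177² = 2240.87), the bond constant between atoms $i,j$ is
$k = \sum_m \lambda_m |\hat v_m \cdot \hat u_{ij}|$ over the eigenpairs of
the negated interatomic $3\times3$ block, averaged between the $ij$ and
$ji$ blocks. Negative block eigenvalues (numerical noise at minima)
participate through the $|\cdot|$ projection weight as in the original
scheme - no clipping. Note that for a symmetric full Hessian the $ji$ block
is the transpose of the $ij$ block; when bending terms make that block
non-normal, its right eigenvectors differ between the two, the two
estimates differ at the percent level, and only their average is reported.

The angle constant for A-B-C combines per-arm stiffnesses projected onto
the in-plane perpendiculars as
$1/k_\theta = 1/(R_{AB}^2 k_{PA}) + 1/(R_{CB}^2 k_{PC})$.
Two measured regimes, both asserted in the test suite against analytic
Hessians built by `make_harmonic_hessian()`:

* **Isolated bend** (angle term only): each projected arm stiffness
  reflects the one shared angle spring, the compliance sum double-counts
  it, and the recovered constant is $k_\theta (1-\cos\theta)/2$ - exactly
  half at 90°. `coupling_correction = TRUE` doubles the series result and
  recovers the exact constant at the right-angle geometry (the canonical
  octahedral L-M-L arrangement the generator emits).
* **Full bonded Hessian** (bond springs on the arms, the realistic case):
  eigenvector mixing inside the off-diagonal blocks restores most of the
  loss and the *plain* series lands within a few percent of $k_\theta$
  (measured +3.2% on the bonded right-angle triatomic;
  `analysis/03_forcefield_constants.R` tabulates both regimes across
  angles).

The plain series is therefore the default - it is the original projection
scheme and the right choice on real Hessians - and the correction is a
flag for isolated-bend constructions. `write_frcmod_fragment()` emits the
BOND/ANGLE sections in fixed-decimal frcmod layout (2-decimal constants,
3-decimal equilibria); dihedrals, Lennard-Jones and charges are out of
scope, as are the charge-fitting and topology-assembly stages around the
Seminario step.

## The synthetic-data generator

Every input format has a generator with exact, seeded ground truth:

* `make_structure()`: shapes with documented exact symmetries (cube -
  equal gyration eigenvalues; rod - $\kappa^2 = 1$; ring, Fibonacci
  sphere shell, seeded random cloud), optional metal at the centroid.
* `make_trajectory()`: conformer mixtures with **stratified**
  largest-remainder counts (a 0.7/0.3 split of 1000 frames is exactly
  700/300 - population ground truth is exact at any $n$, unlike i.i.d.
  draws), isotropic Gaussian jitter, optional random rigid motions, labels
  kept as an attribute.
* `make_solvated_frame()`: exact shell occupancies with min-distance bands
  sampled uniformly, a 2.4 Å water-water exclusion, rigid 3-site waters
  (O-H 0.96 Å, 104.5°). This is placement geometry only - no physical
  water model is claimed.
* `make_orbital_ladder()`: closed- or open-shell ladders whose frontier
  gap is exact by construction.
* `make_harmonic_hessian()`: analytic second derivatives of
  $\sum \tfrac12 k (d-d_0)^2 + \sum \tfrac12 k_\theta (\theta-\theta_0)^2$
  at equilibrium - exactly symmetric, translationally invariant (atom-block
  row sums vanish), with every force constant known.

What the generator does *not* emulate: anharmonicity, correlated solvent
structure, realistic water dynamics, conformational kinetics, finite
electronic-structure accuracy. Passing the suite therefore demonstrates
that the extractors measure what they claim on data whose answer is known;
it does not certify accuracy of any upstream engine on real complexes.

## Problem sizes and numerical choices

The shipped analyses and checks use desk-scale sizes chosen to make every
law they test measurable with comfortable margin: 8-60 atom solutes,
50-5000 frame trajectories, 200-frame two-basin mixtures, 6-compound
dataset trees. Tolerances follow the quantity: exact-symmetry descriptors
to $10^{-9}$-$10^{-12}$, oracle agreement to $10^{-10}$, grid-based areas
to 0.5% at 0.05 Å with a <0.2% halving gate, sampling laws to 5%.
Tie-breaks are deterministic throughout (lowest index); degenerate inputs
(coincident atoms, zero gaps, single frames, all-occupied spectra) return
flagged values or typed errors, never silent numbers. File parsing is
strict: a malformed line names its line number, and no reader truncates
silently.

## Dataset layout and provenance

`run_dataset()` walks a `CYC|ACYC / family / compound` tree, mirrors the
14-family classification (6 cyclic: DOTA, NOTA, TETA, SAR, CBTETA,
MACROPA; 8 acyclic: DTPA, DEDPA, DFO, EDTA, ATSM, HBED, NEUNPAA, DPAA),
computes whatever each compound's files support, and writes one merged CSV
(QM columns first, then MD), with per-family means/SDs and per-class
percentages above the 4 eV line. Unknown families pass through with a
warning. Records are assembled in sorted order, so output is independent
of directory traversal order, and re-running a compound with unchanged
inputs is bit-stable. The orbital-energy text layout is this package's own
simple convention (`occupation energy` per line, `alpha`/`beta` section
headers); externally deposited spectra should be adapted to it at read
time - the reader is the single documented adapter point.
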