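---
title: "Computing 3D molecular descriptors from MD trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Computing 3D molecular descriptors from MD trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## What the package computes and why

Quantitative structure–property relationship (QSPR) models regress
material or molecular properties on *molecular descriptors* — numeric
summaries of molecular structure.  Most descriptor software starts from a
single static structure (a SMILES string or one 3D conformer).  Molecular
dynamics (MD) simulations instead provide many molecules over many time
frames, and the conformational fluctuation itself carries information:
descriptors such as the radius of gyration, folding profiles or surface
areas of a flexible chain only make sense as per-frame quantities.

`trajdescr` closes this gap for LAMMPS users.  It reads the static system
definition (a data file, atom style `"full"`, which carries masses,
partial charges and bonds) and a text dump trajectory, reconstructs every
molecule's continuous geometry under periodic boundary conditions, and
evaluates six families of 3D descriptors per molecule per frame, writing
one CSV table per molecule (`molecule_<molID>.csv`).  The system density
is reported per frame alongside, since in "real" units it follows
directly from the total mass and the box volume
(\(\rho = 1.66054\,\sum_i m_i / V\) g/cm³ with \(V\) in Å³).

```{r, eval = FALSE}
library(trajdescr)
run_descriptors("system.data", "system.lammpstrj", "descriptors",
                sets = 1:6)
```

## From files to per-molecule geometries

The data-file parser locates sections (`Masses`, `Atoms`, `Bonds`,
optionally `Angles`, `Dihedrals`, `Impropers`) by name, in any order, and
skips `Coeff` sections; the dump reader binds columns by the names in
each frame's `ITEM: ATOMS` header, never by position.  Scaled dump
coordinates (`xs ys zs`) are rejected rather than silently converted.
Angles and dihedrals are parsed when present but nothing downstream needs
them: every descriptor here is a function of the bond graph, the partial
charges, the masses and the per-frame coordinates.

Elements are inferred from the per-type masses: an exact united-atom mass
(CH, CH₂, CH₃, CH₄ at 13.019, 14.027, 15.035, 16.043 g/mol, within
0.005) is matched first, then any element whose standard atomic weight
lies within 0.5 g/mol, then a united-atom entry within 0.5 g/mol.  The
exact-first rule matters because CH₂ (14.027) and nitrogen (14.007)
differ by only 0.02 g/mol; testing the united-atom table at tight
tolerance first keeps both usable.  United-atom pseudo-elements inherit
carbon's van der Waals radius, volume and electronic properties but keep
their own mass, which is the simplest defensible treatment of united-atom
force fields such as TraPPE-UA.  All atomic properties (Bondi radii,
volumes as \((4/3)\pi r^3\), Pauling electronegativities, static dipole
polarizabilities, NIST first ionization potentials, electron affinities)
are hard-coded in `property_table()` and exported as
`inst/extdata/atomic_properties.csv`, so results are reproducible across
installations.  Descriptor weights other than charge are scaled relative
to carbon (\(w_i = p_i / p_C\)); partial charges are used raw, in e.

When the dump carries wrapped coordinates, each molecule is rebuilt by a
breadth-first traversal of its bond graph from the lowest atom id,
placing every newly reached atom at the minimum-image position relative
to its placed neighbour (displacement components folded into
\([-L/2, L/2)\)).  This is exact up to a whole-molecule lattice
translation, which no descriptor can see.  The construction assumes an
orthogonal box; triclinic tilt factors are rejected.  A reconstructed
bond reaching 45% of the shortest box side is refused
(`BondLongerThanHalfBox`) rather than guessed: at half the box the
minimum image and its periodic alias become indistinguishable, and a
silently mis-unwrapped bond would corrupt every downstream number.  The
45% margin is a deliberate safety band below the exact L/2 ambiguity
point; real bonded pairs are 1–2 Å in boxes ≥ 10 Å, far below it.

## The six descriptor families

**Set 1 — 3D topology/connectivity (22 columns).**  Classic topological
indices evaluated on the *geometric* distance matrix so they respond to
conformation: 3D Wiener (\(\sum_{i<j} r_{ij}\)), 3D Harary
(\(\sum 1/r_{ij}\)), average geometric distance, a Balaban-type index
over distance-matrix row sums, eccentricity statistics (radius, diameter,
mean, Petitjean shape), and Randić-type connectivity indices of order
0–2 scaled by the mean bond length.  All eleven repeat on the
hydrogen-suppressed graph (`_hs` suffix), the usual convention for
topological indices; on hydrogen-free (e.g. united-atom) molecules the
two halves coincide, and suppressing hydrogens is the only place where
atoms are ever dropped — every other family always uses all atoms.

**Set 2 — geometric (37 columns).**  Dipole moment about the centre of
mass (4.8032 D per e·Å), principal moments of inertia with ratios and
shape factor, the mass-weighted gyration tensor set (Rg, asphericity,
acylindricity, relative shape anisotropy κ²), gravitation indices over
all pairs and bonded pairs, van der Waals volume (union of spheres on a
0.2 Å voxel grid), shadow indices (projection areas onto the principal
planes on a 0.1 Å grid, plus rectangle-normalised fractions), the plane
of best fit score, and chain measures: span, geometric diameter, and —
along one shortest path realising the topological diameter (ties broken
by the lexicographically smallest atom-id sequence) — end-to-end distance
\(R_{ee}\), contour length \(L\), Kuhn length \(l_k = R_{ee}^2/L\), and
folding profiles \(\phi_k\) (k = 1..10), the mean straightness ratio of
k-bond windows along the backbone.  Acylindricity follows the standard
Theodorou–Suter definition \(c = \lambda_2 - \lambda_1\) (ascending
eigenvalues), so a planar square scores 1 and a rod scores 0.  The plane
of best fit is the plane through the centroid minimising the *mean
absolute* atom distance; because the least-squares normal is arbitrary
for isotropic geometries (a regular tetrahedron), the orientation is
found by a deterministic spherical grid (512 directions plus the three
principal axes) refined by local optimisation, rather than taken from an
eigenvector.

**Set 3 — GETAWAY (311 columns).**  The molecular influence matrix
\(H = M(M^\top M)^{+}M^\top\) of the centred coordinates is an orthogonal
projector; its diagonal (the leverages \(h_i\)) measures each atom's
influence on the geometry and its trace equals the geometry's rank.
Seven scalars summarise the leverage distribution (ITH, ISH, HIC, HGM —
100× the leverage geometric mean —, RARS, RCON, REIG), and for each of
eight weighting schemes (unit plus the seven atomic properties) the
package reports lag-indexed sums over pairs at topological distance k:
\(H_k\) and \(HATS_k\) for k = 0..8, \(R_k\) and \(R^{max}_k\) for
k = 1..8 from \(R_{ij} = \sqrt{h_i h_j}/r_{ij}\), each with its total.
The positive-element filter applies to \(H_k\) only, following the
original formulation.  Reference descriptor catalogues enumerate larger
GETAWAY families by adding further matrix variants; this package declares
the 311-descriptor enumeration above as its stable contract.

**Set 4 — CPSA (30 columns).**  A Shrake–Rupley solvent-accessible
surface area engine with a deterministic golden-spiral point set (960
points per atom, probe 1.4 Å — the water convention; both configurable)
feeds the 30 charged-partial-surface-area descriptors: PPSA/PNSA/DPSA
1–3, fractional and surface-weighted variants, relative charges and
charged surfaces, and the polar/apolar split with atoms of |q| ≥ 0.2 e
counted as polar.  A charge threshold generalises the heteroatom rules of
the CPSA literature to arbitrary force-field typing.  A test point lying
exactly on another sphere's boundary counts as accessible (strict
interiority), so two coincident spheres each keep their full area — the
rule is arbitrary at a measure-zero set but must be fixed for
determinism.  Empty charge classes yield zeros, never division errors.

**Set 5 — WHIM (112 columns).**  For seven weighting schemes (unit,
mass, |charge|, van der Waals volume, electronegativity, polarizability,
ionization potential — 16 × 7 = 112) the weighted covariance of the
coordinates is diagonalised: eigenvalues L1–L3, shape proportions
Th1–Th2, symmetries G1–G3 (fraction of atoms with a same-element mirror
counterpart across each principal plane: counterpart window 0.5 Å,
self-window 0.25 Å), densities E1–E3, and the global T, A, V, K
(acentric factor), G.  Eigenvector signs are fixed by making each
vector's largest-magnitude component positive, preventing score-sign
nondeterminism; electron affinity is excluded from WHIM (it remains in
the autocorrelations), the minimal scheme set consistent with 112
columns.  A molecule whose charges are all zero falls back to unit
weights for the charge scheme and the block is flagged
(`charge_fallback` attribute).

**Set 6 — RDF / 3D-MoRSE / autocorrelations (1110 columns).**
Property-weighted radial distribution values
\(R_w(r_k)=\sum_{i<j} w_i w_j e^{-\beta(r_k-r_{ij})^2}\) with
\(\beta = 100\) Å⁻² at \(r_k = 0.5,\dots,15\) Å; 3D-MoRSE scattering sums
\(\sum w_i w_j \,\mathrm{sinc}(s\,r_{ij})\) at \(s = 0..29\) Å⁻¹; and
Moreau–Broto, Moran and Geary spatial autocorrelations of the seven
atomic properties on 1 Å distance bins \([k, k+1)\), k = 0..29.  These
grids are the established conventions for the families and give exactly
240 + 240 + 3 × 210 columns.  Empty bins and zero-variance property
vectors yield exact zeros for Moran/Geary.

## Engine contracts

Work is partitioned into (molecule, frame) units and distributed with
fork-based parallelism; results are reassembled in deterministic order
and numbers printed with shortest round-trip decimal formatting, so
output bytes are identical for any worker count and across reruns.
`molecule_<molID>.csv` files are written via a temp-file-and-rename so a
crash never leaves a truncated table, and a `manifest.json` records
inputs, configuration and a hash of the descriptor catalogue.  Frame
selection (e.g. discarding equilibration) is the user's job; a `stride`
option thins frames as a convenience.  Descriptor averaging over frames
or molecules is deliberately left downstream.

## The synthetic fixture generator

Because the package's correctness claims rest on known ground truth,
the fixture module is first-class code: molecule templates (all-atom
methane with C–H = 1.09 Å and charges −0.4/+0.1 e; united-atom zig-zag
alkanes at 1.54 Å / 114°; seeded freely jointed random-walk chains;
planar rings), replicated on a grid in an orthogonal periodic box, with a
seeded rigid motion per molecule per frame, written out as a data
file/dump pair together with the exact unwrapped coordinates.  Wrapped
variants fold the same coordinates into the box, so the unwrapping path
can be checked against truth bit by bit.  The generator emulates file
structure, periodic wrapping, composition and seeded conformational
variety — it does *not* emulate force-field energetics, excluded volume
or equilibrated ensembles.  Passing tests therefore establish parsing,
reconstruction and descriptor mathematics, not the physical realism of
any particular trajectory.

## Numerical choices and test scale

Grid spacings (0.2 Å volume, 0.1 Å shadow) balance the 2% accuracy
asserted in the tests against cost; SASA uses 960 deterministic sphere
points (doubling them moves a 20-atom chain's total area by < 0.5%).
Leverage equivalence classes for ITH use a 1e-6 gap tolerance; covariance
eigenvalues are clipped at zero; degenerate denominators (single atoms,
zero radius, zero variance, empty charge classes) return 0 by contract
rather than NaN.  The test suite exercises molecules of 2–20 atoms and
runs brute-force double-loop oracles (written independently of the
implementation) for every family at 1e-9–1e-12 tolerances, with
grid-based quantities compared at 2%; these sizes keep the full suite
under a couple of minutes on one core while covering every code path the
descriptors have.

## Known limitations

Orthogonal boxes only for wrapped input; no reactive (bond-less) force
fields; no binary dumps; no implicit-hydrogen reconstruction for
united-atom models (hydrogen handling is suppression-only, in set 1);
descriptors are per-molecule, so nothing spans periodic images or
molecule pairs; "real" units are assumed throughout and only density
would be affected by a different unit system.
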