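---
title: "Computing solvent accessible surface areas: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Computing solvent accessible surface areas: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sasar)
```

## The model

The solvent accessible surface of a molecule is defined by a spherical
probe of radius $r_p$ rolling over the molecule's van der Waals spheres:
the surface traced by the probe *center* is the SASA. Equivalently, it is
the union of spheres of radius $R_i = r_i + r_p$ around the atom centers
$x_i$, with each atom's contribution the part of its extended sphere not
contained in any other extended sphere. The model's assumptions are the
usual ones: atoms are hard spheres with fixed radii, hydrogens are normally
absorbed into heavy-atom group radii, and a single static conformation is
evaluated.

`sasar` computes per-atom areas with either of the two classical
discretizations.

**Lee & Richards slicing.** Atom $i$'s extended sphere is cut into
`n_slices` slabs of thickness $\Delta z = 2R_i/n$. Each atom is sliced
individually, so small atoms automatically get thinner slabs. At the slab
midpoint $z$, the sphere's cross-section is a circle of radius
$\rho_i = \sqrt{R_i^2 - (z - z_i)^2}$; every neighbor whose extended
sphere reaches the plane cuts a circle of radius $\rho_j$ at in-plane
distance $\delta$, occluding an angular interval of half-width
$\arccos\!\big((\delta^2 + \rho_i^2 - \rho_j^2)/(2\delta\rho_i)\big)$
centered on the direction to the neighbor. The intervals are normalized to
$[0, 2\pi)$ (splitting wrap-arounds), sorted and merged; if the exposed
fraction is $f$, the slab contributes $f \cdot 2\pi R_i \Delta z$ — the
Archimedes hat-box area of the strip, which is why an isolated sphere is
*exact at any slice count* (the strips telescope to $4\pi R_i^2$).

**Shrake & Rupley test points.** `n_points` near-uniform points are placed
on each extended sphere and the accessible fraction estimated by counting
points strictly outside all neighboring extended spheres:
$A_i = (\text{accessible}/n)\,4\pi R_i^2$. The points come from the
Fibonacci (golden-angle) spiral: point $k$ of $n$ sits at height
$z_k = 1 - (2k+1)/n$ and azimuth $k\pi(3-\sqrt 5)$. The lattice is
deterministic, so results are exactly reproducible, and its
nearest-neighbor spacing stays within a factor two of the uniform ideal
$\sqrt{4\pi/n}$ (property-tested for $n$ = 100, 500, 2000).

**Neighbor search.** Contacts ($\lVert x_i - x_j\rVert < r_i + r_j + 2r_p$,
strictly) are found with a cell list: atoms are hashed into a cubic grid of
side $2(r_{\max} + r_p)$, so all neighbors of an atom lie in its own or the
26 adjacent cells. Construction touches each atom once and queries are
$O(1)$ for bounded density, making the whole calculation linear in atom
count. The per-atom loop is trivially parallelizable; because accumulation
order is fixed (ascending atom, slice and point indices), any partition of
the loop gives bit-identical results, which is why the `n_workers`
parameter can never change an output value.

## Parameters

| parameter | default | unit | notes |
|---|---|---|---|
| `algorithm` | `lee_richards` | — | S&R available as alternative |
| `probe_radius` | 1.4 | Å | water-sized probe, the field's convention |
| `n_slices` | 20 | slices/atom | L&R resolution; 1000 serves as reference grade |
| `n_points` | 100 | points/atom | S&R resolution; low counts suit quick scans |
| `n_workers` | 2 | — | bookkeeping only; never affects values |

The S&R default of 100 points reflects the two engines' complementary
cost profiles: at low resolution S&R is the cheaper way to get a rough
area, while at and beyond roughly 20 slices / 1000 points L&R gives more
accuracy per unit work, so the package's default engine is L&R at 20
slices. Accuracy is measured as $\varepsilon = |A - A_\mathrm{ref}|/N$
(Å² per atom, $N$ atoms), with $A_\mathrm{ref}$ from L&R at 1000 slices
(`error_per_atom()`); the test suite verifies that the mean $\varepsilon$
over seeded packings decreases monotonically over 10, 20, 50, 100 slices
and that the two engines' high-resolution results (1000 slices vs 5000
points) agree to better than 0.05 Å²/atom — two independent
discretizations converging on the same number is the strongest correctness
check available short of closed forms.

## Radius assignment

`assign_radii()` resolves each atom by case-insensitive (residue, atom)
lookup in a classifier. The builtin ProtOr set covers the 20 standard amino
acids plus Sec, Pyl and MSE, the standard nucleotides (A, C, G, U, T and
DA, DC, DG, DT, with `*`-primed legacy atom names normalized to `'`), the
acetyl and NH2 capping groups, and water. Group radii: tetrahedral carbon
1.88 Å, aromatic C–H 1.76, bare trigonal carbon 1.61, nitrogen 1.64,
carbonyl/carboxylate oxygen 1.42, hydroxyl oxygen 1.46, sulfur 1.77;
phosphorus and selenium, absent from the original group set, are assigned
1.8 and 1.9 Å. Carbon-centered classes count as apolar, N/O/S/P/Se-centered
as polar — the NACCESS-tradition split behind the log's Apolar/Polar lines;
users can override any of it via `parse_classifier_config()` (the shipped
`protor.config` and `naccess.config` in `inst/extdata` document the
format).

Unmatched atoms fall back to the element's van der Waals radius
(main-group table: H 1.10, C 1.70, N 1.55, O 1.52, P 1.80, S 1.80,
Se 1.90, …), apolar for carbon and polar otherwise, with a warning per
distinct fallback; atoms whose element is unknown raise an error by
default (silent guessing corrupts totals) or are dropped under
`unknown = "skip"`. Nucleotide oxygen classes are not part of the original
protein-focused group set; the package assigns them by hydrogen-count
analogy (ester and carbonyl O 1.42, the ribose 2'-OH 1.46, sugar carbons
1.88, aromatic base C–H 1.76, junction and carbonyl carbons 1.61), a
documented package decision.

## Numerical choices and edge cases

- **Strict inequalities at tangency.** Tangent spheres are not neighbors
  and a test point exactly on a neighbor's surface is accessible: a tangent
  sphere occludes a measure-zero set, so this convention loses nothing and
  makes the two engines and the neighbor search mutually consistent.
- **Slab midpoint evaluation.** Slice circles are evaluated at slab
  centers (midpoint rule, second-order accurate); the midpoint never
  coincides with a pole, so $\rho_i > 0$ always.
- **Arc clamping.** The $\arccos$ argument is clamped to $[-1, 1]$;
  a neighbor circle that swallows the slice circle
  ($\delta + \rho_i \le \rho_j$) buries the whole slab, one entirely
  inside it ($\delta + \rho_j \le \rho_i$) does not touch the boundary.
- **Coincident centers.** The atom with the smaller extended sphere is
  fully buried; on an exact tie the higher-index atom is buried — a
  deterministic tie-break so duplicated atoms never double-count surface.
- **Translation invariance.** Both engines work in atom-local frames:
  only center *differences* and radii enter. A rigid translation that is
  exact in floating point therefore changes nothing, bit for bit (the test
  suite checks this with dyadic coordinates, where translated positions
  are exactly representable); rotations change results only through the
  discretization, by under 1% at 20 slices or 1000 points.
- **Parsing.** Fixed-column PDB parsing keeps the first MODEL and the
  first alternate-location conformer (blank or `A`) — the conventional
  single-conformer choice, which the file format itself does not dictate —
  and detects hydrogens from the element columns, falling back to a
  digit-stripped first-character heuristic for legacy files.

## What the synthetic fixtures do and do not show

The test surface is built entirely from generated inputs: seeded uniform
sphere packings (`random_packing()`; 200 spheres of radius 1.5–2.0 Å in a
30 Å box give a realistic mixture of fully buried and nearly fully exposed
atoms), toy PDB text (`toy_pdb()`, `poly_ala_pdb()`), and the two-sphere
closed form (`two_sphere_analytic()`, itself verified against Monte-Carlo
surface integration at 3σ over 50 random configurations). These exercise
the geometry, the parser contracts, the classifier paths and the
aggregation identities. They do not exercise crystallographic pathologies
(chain breaks, nonstandard residues beyond the covered set, occupancy
disorder beyond two-state altlocs) or the absolute radii conventions of
other programs: totals on real structures depend on the radius set, so
cross-program comparisons must hold the parameterization fixed. Problem
sizes in the default test run (packings up to 200 atoms, 20 packings at
reference resolution, 1000 neighbor-equivalence instances) were chosen to
probe each scaling regime of the cell list while keeping a full run in the
low minutes.

## Known limitations

- Areas are approximations; exact analytic SASA and gradients are out of
  scope, as is the second (test-point) lattice of the double cubic lattice
  method.
- The slice placement of other L&R implementations is not replicated, so
  agreement with them is close but not bitwise at equal resolution.
- No mmCIF input, symmetry expansion, or relative (Gly-X-Gly normalized)
  accessibilities.
- The selection grammar is the documented subset (`resn`, `resi`, `chain`,
  `name`, `symbol` with boolean operators, `+` lists and `resi` ranges),
  not the full Pymol language.
- Computation is serial; `n_workers` is recorded for log compatibility and
  the per-atom loop is partition-safe by construction, but no threads are
  spawned.
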