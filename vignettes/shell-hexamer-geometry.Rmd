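---
title: "Methods: interface burial, symmetry and nanotube geometry of shell-protein hexamers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: interface burial, symmetry and nanotube geometry of shell-protein hexamers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hexshell)
```

## The scientific problem

Bacterial microcompartment (BMC) shells are tiled by hexameric proteins.
PduA, a major shell hexamer of the 1,2-propanediol-utilisation
metabolosome, tiles a hexagonal lattice with adjacent hexamers 67.2 Å
apart, buries only a narrow edge (~1,200 Å² per hexamer–hexamer
interface against a subunit surface of ~20,400 Å²), and, when
overproduced on its own, rolls up into cytoplasmic nanotubes roughly
20 nm across.  Which residues hold the tiling together, how a flat
hexagonal sheet can close into a tube, and how mutation breaks the
hexamer's 6-fold symmetry and its pore geometry are all questions that
reduce to well-defined geometry and surface-area computations.  This
package implements those computations and a synthetic structure
generator so that every one of them is testable without any external
coordinate files.

## Solvent-accessible surface area

`compute_sasa()` is a Shrake–Rupley implementation.  Each atom carries
a van der Waals radius from a bundled table (C 1.70, N 1.55, O 1.52,
S 1.80, default 1.70 Å; override per call or through a key–value config
file).  Sample points are placed on the probe-expanded sphere
(radius + probe, probe default 1.4 Å) with a deterministic generalized
spiral (golden-angle) point set, so results are bit-reproducible at a
fixed point count — there is no Monte-Carlo jitter between runs.  A
point is occluded if it falls strictly inside any other probe-expanded
sphere; the atom's accessible area is the free fraction times
4π(r + p)².  Areas are therefore reported at the probe-expanded
surface, under which an isolated carbon atom has area
4π(1.7 + 1.4)² ≈ 120.8 Å².

Numerical choices:

* `n_points = 960` by default.  Doubling it changes reported areas by
  well under 1% (asserted in the test suite); 60 is the enforced floor.
* Exactly coincident atoms of equal radius would see each other's
  surface as exactly tangent; a guard band plus a symmetric tie rule
  collapses such a group to one representative and splits its area
  equally.
* Hydrogens are not special-cased (deposited shell-protein structures
  lack them); HETATM records are kept on reading but excluded from
  protein SASA unless requested.
* The hot loop is in C++; an independent brute-force Monte-Carlo
  surface integration (random points, direct occlusion test) lives in
  the test helpers and agrees within 2% on random clusters.

## Burial accounting and hot spots

`delta_asa()` computes, per residue, ASA(unit alone) − ASA(unit in
assembly).  The default assembly context for a tiling hexamer is the
central hexamer plus all six in-plane neighbours
(`hexamer_context(..., "sheet")`): each edge residue touches exactly
one neighbour, so per-residue values are robust to the choice, but the
sheet matches the bringing-together procedure the analysis emulates; a
`"pair"` context is selectable.  Small negative differences (point
sampling) are floored at zero and counted in an attribute.

`buried_surface_area()` uses the two-sided convention
BSA = ASA(A) + ASA(B) − ASA(A∪B), i.e. burial summed over both
partners — the convention under which four subunits (two per hexamer)
together bury the quoted interface area.  It is exactly symmetric in
its arguments because the identical point sets are used either way.
The sum of one unit's per-residue ΔASA equals that unit's one-sided
burial exactly; the two one-sided burials differ slightly (fractions of
a percent) because the spiral point set is not symmetric under the
interface inversion, which is one reason the two-sided BSA is the
reported interface quantity.

`rank_interface_hotspots()` sorts residues by ΔASA (ties broken by
residue number) and annotates each with its *dyad distance*: the
distance between the residue's side-chain terminal atom (LYS→NZ,
ARG→CZ, VAL→CB, ASP→CG, …; side-chain centroid as fallback) and its
image under the 2-fold that relates adjacent hexamers.  A large burial
close to the dyad marks the substitution most disruptive to tiling when
replaced by a like-charged residue, because the introduced charge meets
its own symmetry mate; this is the geometric logic behind ranking a
dyad-contact lysine as the most sensitive position and a mid-edge
valine as the least.

## Cyclic symmetry

`fit_symmetry_axis()` minimises the mean squared distance between the
model and itself rotated by 360°/n with chains cyclically permuted.
The rotation angle is held fixed at 360°/n; the axis direction (two
parameters) and the centre (two parameters, in the plane normal to the
axis) are optimised by Nelder–Mead from a Kabsch-superposition
initialiser, with the minimum taken over the n cyclic chain pairings so
the rotational direction of the chain labels does not matter.  Only
cyclic pairings are considered — hexamer chains must be in rotational
order, which symmetry-expanded structures and the generator guarantee.

The reported `deviation_rmsd` is the superposition RMSD divided by √2.
The raw RMSD compares two copies that each carry the full atomic
displacement, so for i.i.d. Gaussian noise of σ per coordinate its
expectation is σ√6; the per-copy convention (σ√3) estimates the mean
atomic departure from the ideal symmetric reference, which is the
quantity one wants to quote as "how far from 6-fold symmetric is this
hexamer".  Under this convention a σ = 0.5 Å perturbation scores
≈ 0.87 Å, and the score is invariant under rigid motion and exactly
zero for the generated ideal hexamer.

## The synthetic hexamer

`make_ideal_hexamer()` emits a coarse-grained pseudo-atom wedge disc,
not an all-atom protein: subunit fold detail is irrelevant to every
computation above, which depend only on the disc geometry, the marker
positions and the vdW radii.  Design of the default spec:

* **Hexagon circumradius 35 Å** (disc ~70 Å across): frozen so that
  edge-to-edge tiling at the native 67.2 Å centre spacing leaves the
  flat edge surfaces ~6.6 Å apart (atom centres) — in probe-bridged
  contact for burial, far from the clash threshold.
* **Thickness 20 Å**: a generic single-BMC-domain disc height; the
  sources do not state one, so it is config-exposed, not asserted.
* **Bevel 30°** (15° per face): the wedge taper that lets adjacent
  hexamers bend out of plane by up to the bevel angle without
  interpenetrating — the geometric property that makes a 12-per-turn
  ring (30° tilt) possible with no hexamer distortion.
* **Concave/convex faces**: a 4 Å spherical-cap offset makes the two
  faces inequivalent; the flatter (dimpled) +z face is designated
  concave and is oriented outward in tube models.
* **Markers** carry real residue numbers and names so selection logic
  is identical for synthetic and deposited structures: 22 (ASP,
  dyad-acidic), 26 (LYS CE/NZ, dyad-contact), 40 (SER N, pore loop on a
  4.5 Å circle), 51 (VAL CB, mid-edge), 79 (ARG NE/CZ/NH1/NH2,
  protruding arm).  The dyad-contact NZ atoms interdigitate across the
  interface mid-line in an antiparallel pair (2.7 Å apart in the flat
  sheet), which is what keeps them in contact when the interface bends
  by 30–40° in tubes; the arms protrude past the hexagon outline and
  meet in threes around the lattice holes, dominating the marker ΔASA
  ranking.  These positions were tuned once against the tiling
  constraints and then frozen.

What the generator does **not** emulate: real side-chain packing and
hydrogen-bond chemistry, sequence-dependent interface energetics,
crystallographic waters and ions, and the absolute ΔASA magnitudes of
an all-atom interface (the synthetic marker burials are
order-of-magnitude, not quantitative, matches).  Passing tests on
synthetic hexamers therefore validate the *computations* — area
bookkeeping, symmetry scoring, construction geometry — not the
biological numbers of any particular protein; those are recovered by
running the same functions on deposited coordinates
(`read_structure()` accepts any PDB file, e.g. the native shell-protein
hexamer, expanded to its lattice neighbours with
`expand_neighbors()`).

`perturb_hexamer()` adds i.i.d. Gaussian coordinate noise as the model
of symmetry breaking; `sample_diameters()` draws TEM-like measurement
sets reported in the conventional "m ± s (n measurements)" style; and
`make_alignment_fixture()` writes aligned-FASTA fixtures with chosen
conserved columns.  All generators take explicit seeds, are
byte-deterministic, and restore the caller's RNG state.

## Sheets, strips and tubes

`build_sheet()` places copies on the hexagonal lattice (row offset
spacing/2, row separation spacing·√3/2), giving exact
nearest-neighbour spacing.  `tiling_dimensionality()` classifies a set
of centres as 0 (point), 1 (strip) or 2 (sheet) from the rank of the
nearest-neighbour difference vectors; the neighbour shell is 5% above
the minimum spacing, comfortably separating neighbour classes whose
spacings differ by ~1% in real strip- versus sheet-forming crystals,
and the rank tolerance is 10⁻⁶ of the leading singular value.

Ring tubes (`build_ring_tube()`): N hexamers per ring on the circle of
radius s/(2·sin(180°/N)) — so in-ring neighbour chords equal the
spacing exactly — with every 6-fold axis radial, concave face outward.
Successive rings are offset by half an azimuthal step and spacing·√3/2
axially, making intra- and inter-ring packing equivalent.  The
half-step interdigitation is also why N must be even: an odd ring
cannot close with alternating vertices.  Closed forms: interior angle
(N−2)·180/N, tilt 360/N (150°/30° at N = 12).

Helical tubes (`build_helical_tube()`): the same sheet rolled the
other way, with hexamer edges approximately parallel to the tube axis.
The builder wraps the sheet *isometrically* about the cylinder whose
circumference is the wrap vector W = n·a₁ − m·a₂ (a₁ strand step, a₂
row step, m strands): travelling n hexamers along a strand comes back
around the tube m rows up, which is precisely the m-start
identification.  An isometric wrap is the only construction that
preserves every in-sheet contact — holding the azimuthal step at
exactly 360/n while accumulating rise along the strand shears the
lattice, compressing inter-strand rows by ~7% into steric clashes (or,
with relaxed rows, stretching them out of contact), as is easily shown
analytically and was confirmed numerically during design.  Bending
only shortens centre distances by the arc-to-chord correction
(~1–2 Å), so contacts tighten slightly and never break.

Descriptors: the nominal pitch (default m·s·√3/2, i.e. close-packed
rows; override honoured verbatim, e.g. 138 Å) and nominal rise
pitch/n are reported alongside the *measured* per-turn count and rise
of the realised wrap, which differ by a few percent because an
inextensible sheet cannot satisfy both nominal values at once.  With
the close-packed default the 10-per-turn two-start wrap has a
centreline diameter of ≈ 19.6 nm — consistent with tube diameters
measured by TEM — while a relaxed 138 Å pitch widens the rows to 69 Å
and keeps only the in-strand contacts; both variants build without
clashes.  Diameters are always reported under three conventions
(centreline, outer = centreline + thickness, lumen = centreline −
thickness) and none is silently equated with a TEM wall-to-wall
measurement: for the 12-ring the centreline diameter is ≈ 26 nm, and
which convention a stained-section measurement corresponds to is not
derivable from geometry alone.

`clash_check()` reports inter-copy atom pairs closer than 0.6·(rᵢ+rⱼ);
`contact_preservation()` derives hexamer adjacency from copy centres
(within 1.25× the minimum centre distance) and scores the fraction of
adjacent pairs whose marker residues (default 26) approach within 6 Å.

## Pore geometry and hydrogen bonds

`pore_profile()` samples along the fitted 6-fold axis; the radius at an
axial point is the smallest clearance min(‖xᵢ − p(z)‖ − rᵢ) over atoms,
floored at zero.  This 3-D clearance reduces to (radial distance −
radius) for atoms in the sampling plane and is well defined between
atom layers, which a plane-restricted definition is not.  The three
cross separations pair the designated pore-loop atom (default:
main-chain N of residue 40) of chain k with chain k+3 — the opposite
subunit under rotational chain ordering, a documented input
requirement.  For a strict C6 hexamer all three are equal; their spread
(anisotropy) is the pore-level signature of broken symmetry, and
`symmetry_report()` flags it above 0.5 Å.  `probe_fit()` marks each
axial sample against a probe radius (a glycerol-sized probe is ~2.6 Å)
and reports whether a continuous passing corridor spans the profile.

`detect_hbonds()` uses heavy-atom criteria only, since deposited
structures lack hydrogens: donor/acceptor N/O pairs within 3.5 Å
(standard heavy-atom cutoff; configurable), excluding intra-residue
pairs, pairs at covalent range (< 2.0 Å) and backbone pairs of
sequence-adjacent residues.  With `require_geometry` the
antecedent–donor–acceptor angle must be ≥ 90°, the antecedent being the
donor's nearest covalent-range neighbour in its own residue; atoms
without one (coarse models) skip the test.  Where both partners could
donate, N is preferred over O, then the lower serial — a deterministic
convention, stated rather than inferred.  Bonds are classified
intra-subunit / intra-hexamer / inter-hexamer from the chain and copy
relationship, and `compare_interfaces()` diffs two inventories keyed by
(donor residue, acceptor residue, class).

## Conservation mapping

`column_conservation()` maps 1-based ungapped reference positions
through the reference's gaps to alignment columns and scores consensus
identity: the share of non-gap letters equal to the column mode, ties
broken alphabetically, gaps excluded from numerator and denominator.
This matches the all-identical ("asterisk") level of conservation
annotation; similarity classes are out of scope by design.  Input goes
through `Biostrings` (Clustal and aligned-FASTA dialects).

## Structure I/O conventions

Fixed-column PDB with CRYST1 support; the fractional→Cartesian
convention places **a** along x and **b** in the xy-plane.  Chain
identifiers use the single-character alphabet (A–Z, a–z, 0–9) up to 62
chains; larger assemblies (a three-ring tube has 216 chains) switch to
a deterministic two-character scheme (AA, AB, …) occupying columns
21–22, which the package's reader parses back — standard files leave
column 21 blank, so reading ordinary PDB files is unaffected.  Highest
occupancy wins among alternate locations (ties: first in file).
Models beyond 99,999 atoms are refused with advice to split the
output.  mmCIF and full space-group operator expansion are non-goals;
only explicit translations/rotations are applied.

## Problem sizes and determinism

The shipped tests and the acceptance script use the sizes a desk-scale
analysis needs: 3×3 sheets, three-ring (36-hexamer, ~20,000
pseudo-atom) ring tubes, two-turn two-start helices, 960-point SASA,
25-seed perturbation panels.  Everything except the explicitly seeded
generators is deterministic; every report embeds a provenance block
(package version, parameters).

## Known limitations

* Synthetic marker burials are qualitative; quantitative interface
  areas require all-atom input structures supplied by the user.
* Symmetry fitting requires chains in rotational order and equal atom
  counts; it does not search non-cyclic chain correspondences or detect
  the symmetry order automatically.
* The helix reports both nominal and measured descriptors precisely
  because the nominal triple (per-turn count, pitch, diameter) of a
  rolled sheet is over-determined; users should quote the measured
  values for a built model.
* Hydrogen-bond detection is geometric and hydrogen-free; it cannot
  distinguish donor from acceptor chemistry beyond the stated
  heuristic.
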