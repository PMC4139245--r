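# hexshell

Geometry and interface analysis for bacterial microcompartment (BMC)
shell-protein hexamers: how they tile sheets, why mutations at the
hexamer–hexamer interface break the tiling, and how a hexagonal sheet
rolls into a nanotube.

## The problem and the math

BMC shells (e.g. the Pdu metabolosome, whose major facet protein is the
hexamer PduA) are tiled by flat six-fold-symmetric discs ~70 Å across
that meet edge-to-edge at a 67.2 Å centre spacing.  The package
implements the quantitative toolkit for studying such lattices:

* **Interface burial.**  Shrake–Rupley solvent-accessible surface area
  (deterministic spiral point set, probe 1.4 Å), per-residue burial on
  assembly ΔASA(res) = ASA(res | alone) − ASA(res | in sheet), and the
  two-sided buried surface area BSA = ASA(A) + ASA(B) − ASA(A∪B).
  Interface hot spots are ranked by ΔASA and annotated with their
  distance to the inter-hexamer 2-fold (dyad): a large burial close to
  the dyad marks the residue whose like-charge substitution is
  predicted most disruptive to tiling.
* **Symmetry.**  A C_n axis fit minimising the RMSD between the model
  and itself rotated by 360°/n (chains cyclically permuted), reported
  per copy: 0 for a strict hexamer, growing with perturbation — the
  score that separates a native six-fold hexamer from a
  symmetry-broken mutant.
* **Tiling and tubes.**  Hexagonal sheet construction; classification
  of centre sets as 0/1/2-dimensional tilings (point / strip / sheet);
  ring-stack nanotubes with N hexamers per turn — interior angle
  (N−2)·180/N, inter-hexamer tilt 360/N, centreline radius
  s/(2 sin(180°/N)), N even forced by vertex interdigitation — and
  multi-start helical wraps built by isometric rolling of the sheet.
  Built models are validated by steric clash checks and by the fraction
  of adjacent hexamer pairs that keep their marker-residue contact.
* **Pore and contacts.**  Pore-radius profiles along the symmetry axis,
  opposite-subunit cross separations (whose inequality diagnoses a
  symmetry-broken pore), probe-fit tests, geometric hydrogen-bond
  inventories and native-vs-mutant interface diffs.
* **Conservation.**  Alignment column conservation (consensus identity)
  mapped to reference residue numbering.
* **Synthetic data.**  A coarse-grained wedge-bevelled C6 hexamer with
  labelled marker residues (22/26/40/51/79), symmetry perturbation,
  TEM-like diameter samples and alignment fixtures — so the complete
  pipeline runs and is tested without any downloads.  Crystal-cell
  arithmetic (CRYST1 I/O, |u**a**+v**b**+w**c**| lattice translations)
  connects the same functions to deposited structures.

## Worked example

```r
library(hexshell)

hx <- make_ideal_hexamer()          # strict C6, 570 pseudo-atoms
symmetry_deviation(hx, 6)
#> [1] 6.607483e-15

# burial upon sheet formation: the protruding arm dominates
sheet <- hexamer_context(hx, spacing = 67.2, context = "sheet")
dyad  <- interface_dyad(c(0, 0, 0), c(67.2, 0, 0))
head(rank_interface_hotspots(hx, sheet, dyad), 3)
#>   residue resno resid delta_asa dyad_distance
#> 1  ARG-79    79   ARG 80.687782     33.438301
#> 2  LYS-26    26   LYS 57.071645      2.720294
#> 3 GLY-181   181   GLY  9.183006     30.712750

# ring nanotube: 12 hexamers per turn -> 150 deg interior, 30 deg tilt
ring_geometry(12, spacing = 67.2)
#> <tube_geometry> n=12: interior 150.0 deg, tilt 30.0 deg, R 129.8 A
#>   diameter (nm): centerline 26.0 | outer 28.0 | lumen 24.0

tube <- build_ring_tube(hx, tube_spec("ring", 12, n_turns_or_rings = 3))
nrow(clash_check(tube)); contact_preservation(tube)
#> [1] 0
#> [1] 1

# TEM-style measurement emulation
format_measurement(sample_diameters(20.4, 1.1, 20, seed = 1))
#> [1] "20.6 ± 1.0 nm (20 measurements)"
```

The first lines say the generated hexamer is six-fold symmetric to
machine precision; the hot-spot table says the arm residue (79) buries
the most surface on tiling while the dyad-contact residue (26), second
by burial, sits essentially on the two-fold axis (2.7 Å from its own
image) — the geometric reason an aspartate there is maximally
disruptive; the remaining entries (generic edge pseudo-atoms such as
GLY-181, and the mid-edge marker VAL-51 further down) bury far less.  The tube
block confirms the 150°/30° ring geometry and that a three-ring,
72-subunit-per-turn model builds without clashes while keeping every
inter-hexamer marker contact.

A thin command-line wrapper ships in `inst/scripts/hexshell`
(subcommands `interface-report`, `build-models`, `symmetry`,
`simulate`, `conservation`; exit codes 0/2/3 for success / validation
error / input error).

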