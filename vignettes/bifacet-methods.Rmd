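---
title: "Designing bifaceted pseudo-dihedral protein nanomaterials with bifacet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing bifaceted pseudo-dihedral protein nanomaterials with bifacet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bifacet)
```

## The design problem

Most designed protein nanoparticles carry strict point-group symmetry: every
subunit sees the same environment, so the particle surface is isotropic and
no face can be addressed independently. A bifaceted (Janus-like) particle
breaks this: its two faces are chemically distinct and can carry different
functional cargo. One route to such materials starts from a pseudosymmetric
heterotrimer — three chains with an identical backbone fold arranged with
three-fold symmetry but carrying three different sequences (an "ABC"
trimer). Five such trimers close into a 15-subunit ring (a "crown") through
a previously designed A–B interface, leaving the C subunits' terminal
helices free. Docking two crowns against each other along their shared
five-fold axis produces a 30-subunit assembly with dihedral D~5~ symmetry
held together by a new C–C interface; *asymmetrizing* that interface into a
C–D pair turns the material into a pseudo-D~5~ (ABC)~5~–(ABD)~5~ particle
whose two rings assemble only when mixed, making all six subunit identities
uniquely addressable.

`bifacet` implements the computational side of this workflow with
machine-checkable geometry:

1. generate idealized pseudosymmetric building blocks (`block_recipe()`,
   `make_pseudo_heterotrimer()`, `make_crown()`);
2. enumerate and score axial docks of two rings (`dock_grid()`,
   `score_docks()`, `rank_docks()`, `realize_dock()`);
3. identify the dihedral interface positions and emit biased or multistate
   sequence-design specifications for an external neural design tool
   (`find_interface_pairs()`, `make_bias_spec()`, `emit_multistate_spec()`,
   `enumerate_design_jobs()`);
4. filter candidate designs on structure-prediction confidence metrics with
   negative-design rules (`filter_batch()`, `evaluate_extension_design()`);
5. define extended, rotated or terminus-reoriented target architectures for
   an external backbone-diffusion tool (`make_extension_target()`,
   `emit_contig_spec()`, `make_adjacency_target()`);
6. quantify bead colocalization from centroid tables
   (`colocalization()`, `batch_colocalization()`).

Heavy machine-learning inference — sequence design, structure prediction,
backbone diffusion — is deliberately out of scope. The package *emits the
input specifications* those tools consume and *consumes the metric tables*
they produce.

## Coordinate model and conventions

Structures are tidy tibbles with one row per atom (`chain`, `role`, `resi`,
`aa`, `atom`, `element`, `x`, `y`, `z`, `helix`) and the principal symmetry
axis fixed to +z through the origin. Coordinates are in Angstrom, residue
indices 1-based, ranges inclusive on both ends. All geometry is
backbone-level: scoring, superposition and symmetry checks use CA atoms
only, which matches the resolution at which such assemblies are normally
validated (backbone-level map comparisons; side chains are typically not
resolved).

Rigid transforms are proper rotations plus translations; superposition uses
the closed-form Kabsch/SVD solution with reflections rejected by forcing
the determinant to +1, and refuses degenerate (collinear, fewer than three
point) inputs because the rotation is then underdetermined. PDB I/O is
delegated to `bio3d`; entity roles ride in the segid columns and helix
annotations in `HELIX` records so files round-trip.

The dihedral partner operation is fixed as: flip 180° about the x axis,
rotate `phi` about z, translate `z_offset` along z. Equivalent
parameterizations exist (any in-plane flip axis works); fixing one makes
poses comparable across runs. Because the rings are five-fold symmetric,
`phi` is only meaningful modulo 72° and grids are validated to the
canonical `[0, 72)` range. The operation is an involution — applying it
twice is the identity — which the test suite exploits as a symmetry oracle.

## The synthetic building blocks

No external dataset is required: all tests and the acceptance workflow run
on generated fixtures. A subunit is a "blade" of antiparallel ideal helices
(1.5 Å rise and 100° twist per residue, 2.3 Å radius — giving the canonical
3.8 Å CA–CA spacing) stacked outward along a radial direction and joined by
short loops. Three blades related by exact 120° rotations about z, carrying
distinct seeded random sequences, form the pseudosymmetric heterotrimer;
the default subunit has six helices of twelve residues.

Placing that trimer on the crown ring required one genuine design decision.
If the trimer's three-fold axis coincides with the ring's five-fold axis,
the fifteen chains form a single C~15~ rotational orbit: every inter-trimer
role pair is then geometrically equivalent, and no choice of contact cutoff
can isolate an A–B ring interface or a C-only dihedral interface. Real
crowns do not have this degeneracy because their trimers sit *off* the ring
axis with tilted local symmetry axes. `make_crown()` therefore tilts the
trimer's three-fold axis (40° about y by default, lifting the C blade
towards the dihedral interface) and translates it to `ring_radius` (50 Å)
before the five-fold expansion. With the default blade azimuth (10°), the
generated crown realizes the intended contact topology: adjacent trimers
touch only through an A–B contact (5.1 Å minimum CA–CA distance, all other
inter-trimer pairs beyond 10 Å), a dihedral partner touches only through
the C subunits, and the fixture is clash-free (minimum inter-trimer
distance well above the 2.5 Å floor the generator enforces). These
parameters were chosen once, by requiring the generator to reproduce the
stated architecture, and are validated by the test suite.

What the fixtures do *not* emulate: real packing density, loop geometry,
side chains, sequence–structure consistency, or the actual fold of any
deposited crown. Passing tests therefore demonstrate that the *operations*
(symmetry algebra, dock enumeration and counting, selection bookkeeping,
filtering logic) are correct, not that any particular real protein would
assemble.

```{r crown}
crown <- make_crown(block_recipe(seed = 7))
length(chain_ids(crown))
verify_symmetry(crown, 5, tol = 1e-6)
```

## Dock scoring

The published workflow scored axial docks with a motif-hash interface
score internal to a docking program that is not reimplemented here. The
package substitutes a documented, fully testable score:

\[
\mathrm{score} = n_\mathrm{contacts} - w \cdot n_\mathrm{clashes}
\]

with contacts counted as CA pairs between the two rings' *C-role* chains
within 8 Å (the designable interface; the A–B ring interface already
exists), clashes as CA pairs between *any* chains closer than 3.5 Å, and
`w = 10`. This preserves the contract — rank docks by interface quality,
reject clashing docks — while remaining verifiable against a brute-force
all-pairs oracle, which the tests do on crowns of ≤ 600 CA atoms. Ties are
broken deterministically (fewer clashes, more contacts, smaller |z|,
smaller phi) so rankings are invariant to input order. Truncating the C
subunits by one to four whole helices before docking reproduces the
diversity-generating preprocessing step; both rings of a dihedral pair
share the truncation level.

The default search grid (phi step 2°, z step 2 Å over 50–90 Å in the
acceptance workflow) is an artifact choice: the source procedure does not
state its resolution, and the fixture geometry is smooth enough that finer
grids change nothing but runtime.

## Asymmetric interface design specifications

Interface positions are collected at the position level (any cross-ring CA
within 8 Å) and each C-side position is paired with the D-side position
onto which it maps under the assembly's own two-fold (taken from the dock
pose, or estimated numerically by minimizing the re-paired rmsd over the
flip azimuth). On exact two-fold fixtures the pairing rmsd is numerically
zero.

Three biasing schemes asymmetrize the interface, built from fixed
amino-acid categories — small (S, T, N, Q, V, I, L), bulky (F, Y, W),
negative (D, E), positive (R, H, K; histidine counted positive, no pH
model): `charges` favours positive letters on one side and negative on the
other, `clashes` small versus bulky, `charges-clashes` positive-and-bulky
versus negative-and-small. Both sides receive *positive* additive-logit
biases (`+level` for each favoured letter at each interface position);
levels are 0.1, 0.2, 0.69, 1.1 and 3.9. The conventional fold labels read
0.69 as two-fold and 1.1 as three-fold likelihood increases, consistent
with natural logarithms; 3.9 is labelled four-fold even though
exp(3.9) ≈ 49. The package emits 3.9 as listed and surfaces the
inconsistency through `bias_fold_label()` rather than silently
"correcting" a value that was used as printed. Whether biases applied to
all interface positions or a curated subset is not specified; the default
is all positions within the cutoff.

The job manifest enumerates the full factorial: 3 schemes × 5 levels × 7
temperatures (0.1–1.0) plus 7 unbiased jobs, 100 sequences each. The
multistate specification encodes one on-target C–D state and two off-target
states (C–C and D–D, each side paired with its own two-fold image) weighted
by β ∈ {−1, −0.5, −0.25}; the on-target weight of +1 is a package
convention, since only the off-target β values are prescribed.

## Negative-design filtering

Filtering consumes metric tables (design id, interface label, CA rmsd to
the design model, mean pAE interaction, pLDDT) and applies, with *strict*
inequalities exactly as printed:

* on-target pass: rmsd < 2.0 Å, mean pAE interaction < 10, pLDDT > 90;
* off-target rejection: discard if either off-target prediction has
  rmsd < 2.0 Å, pAE < 10 **and** pLDDT > 95;
* specificity gap: the off-target minus on-target pAE difference must
  exceed 10.

The gap criterion's phrasing ("between the C–D and either C–C or D–D")
admits two readings; the package defaults to requiring the gap against
*both* off-targets — the stricter reading, consistent with the
negative-design goal — and exposes `gap_mode = "any"` for the alternative.
Boundary values fail (a design at exactly 2.0 Å rmsd does not pass), which
the tests pin against an independently coded truth-table oracle. pLDDT
tables on a 0–1 scale are auto-detected and rescaled with a warning.
Extension designs use the separate rule pLDDT > 90 and rmsd to the diffused
backbone < 1.5 Å.

```{r filter}
evaluate_design(
  metric_record("d1", "CD", rmsd = 1.0, pae_interaction = 5,  plddt = 95),
  metric_record("d1", "CC", rmsd = 5.0, pae_interaction = 25, plddt = 70),
  metric_record("d1", "DD", rmsd = 6.0, pae_interaction = 28, plddt = 60))
```

## Architecture editing

Extension targets cut the loop preceding the last two helices of each C
subunit on the (ABC) face — the cut point is the loop midpoint, recorded so
numbering is reproducible — and move everything on that face except the
interface fragments rigidly along the five-fold axis: 25, 50, 75 or 100 Å,
plus one 50 Å target rotated 25°. The rotation is applied about the global
z axis before the translation; the two commute for a rotation about the
translation axis, but the order is fixed and documented. The C–D interface
atoms are bit-identical before and after, the moved selection is rigid to
1e-8 Å, and the five moved C subunits stay five-fold symmetric — all
properties the test suite asserts.

Insert-length ranges for the de novo connection are a total lookup over the
five preset targets (50–150, 100–250, 150–350, 250–400 residues for 25, 50,
75, 100 Å; 150–350 for the rotated target, implemented as its own entry
rather than an alias of the 75 Å row) and anything else requires an
explicit range. The reduced diffusion input takes the four body helices
nearest the opened gap plus the two fixed interface helices — the source
procedure does not say *which* four helices, and proximity to the rebuilt
region is the defensible reading.

Terminus reorientation targets are expressed as block-adjacency problems:
a permuted helix order with one inserted helix, a symmetric binary
adjacency matrix (geometric contact map at 10 Å for existing helices,
requested contacts for the new one), and the list of deleted loops. A loop
survives reordering only if its two helices remain consecutive *in the same
orientation*; reversing the first three helices therefore deletes three
loops, matching the described edit. The default new-helix placeholder is 14
residues.

## Colocalization statistic

Two centroid populations interact when their centroid-to-centroid distance
is strictly below 7.5 µm (roughly twice a particle radius); matching is
"any neighbour within threshold" with no one-to-one assignment, mirroring
the quantification that measures each particle against all particles of
the opposite colour. Per-field results are pooled by summed counts; because
"percentage across 25 fields" is ambiguous between pooled and averaged,
`batch_colocalization()` reports both.

## Numerical choices and problem sizes

* Transform orthonormality and inversion are enforced to 1e-8; symmetry
  closure on generated fixtures is asserted at 1e-6 Å.
* Chain correspondence under a symmetry operation uses greedy
  nearest-centroid matching; tests validate it against exhaustive
  permutation search on assemblies of up to six chains.
* Dock scoring factors the axial translation out of the pair distances, so
  z-scans reuse one in-plane distance matrix per rotation; results are
  identical to the naive O(N²) computation, which remains the test oracle.
* The test suite and the acceptance workflow run on the default crown
  (1,305 CA atoms) and a reduced three-helix crown (540 CA atoms) with a
  756-pose dock grid — sizes chosen so the whole suite completes in about a
  minute on one core while still exercising every operation at full
  fidelity.

## Limitations

The package reasons about idealized CA-level geometry only: no energetics,
no side chains, no sequence–structure feedback. The dock score is a
contact/clash proxy, not a physical interface energy, so absolute score
values are not comparable across different building blocks. The synthetic
crown is a geometric stand-in whose contact topology — not whose
coordinates — matches the target architecture. And the emitted bias,
multistate, contig and adjacency specifications are only as good as the
external tools that consume them; nothing here predicts whether a designed
sequence will actually assemble.
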