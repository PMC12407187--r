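# bifacet

Design toolkit for **bifaceted (Janus-like) protein nanomaterials with
pseudo-dihedral symmetry**, aimed at protein designers who build
self-assembling materials by dock-and-design.

Most designed nanoparticles have strict point-group symmetry, so their
surfaces are isotropic and no face can be functionalized independently. A
bifaceted particle instead has two chemically distinct, independently
addressable faces. One route starts from a *pseudosymmetric heterotrimer* —
three chains with identical backbones arranged with 3-fold symmetry but
three distinct sequences ("ABC") — five of which close into a 15-subunit
ring (a *crown*) through an existing A–B interface. Docking two crowns
against each other along the shared 5-fold axis gives a 30-subunit
assembly with dihedral D₅ symmetry:

- the dock samples only the axial degrees of freedom, a rotation φ
  (canonical in [0°, 72°)) and a translation *z* along the symmetry axis,
  optionally truncating the C subunits by 1–4 terminal helices, and ranks
  poses by `score = n_contacts − w · n_clashes` over CA atoms (contacts
  restricted to the designable C subunits);
- *asymmetrizing* the resulting C–C interface into a C–D pair — by biasing
  an external sequence-design network with per-position additive logits
  (schemes `charges`, `clashes`, `charges-clashes` at levels 0.1–3.9), or
  by explicit multistate design with off-target states weighted
  β ∈ {−1, −0.5, −0.25} — yields a pseudo-D₅ (ABC)₅–(ABD)₅ particle whose
  rings only assemble when mixed, making all six subunits uniquely
  addressable;
- candidate designs are filtered on structure-prediction confidence:
  on-target rmsd < 2.0 Å, mean pAE interaction < 10, pLDDT > 90; off-target
  (C–C, D–D) predictions rejected at rmsd < 2.0 Å, pAE < 10, pLDDT > 95;
  and a pAE-interaction gap > 10 between off- and on-target (all
  inequalities strict);
- particle size and shape are tuned by cutting the loop before the last
  two helices of C and translating the rest of the (ABC)₅ face 25–100 Å
  along the axis (one target also rotated 25°), emitting contig
  specifications with preset insert ranges for a backbone-diffusion tool;
  termini are reoriented via block-adjacency targets;
- bead colocalization by functionalized particles is quantified by
  centroid-to-centroid matching at a strict 7.5 µm threshold.

The neural networks themselves (sequence design, structure prediction,
backbone diffusion) are interfaced through files, not re-implemented. A
synthetic generator produces idealized pseudosymmetric heterotrimers and
crowns, so every operation is exercised end-to-end without external data.

## Worked example

```r
library(bifacet)

crown_abc <- make_crown(block_recipe(seed = 7))
crown_abc
#> <bifacet_structure: 15 chains, 1305 residues, 1305 atoms>

# axial dock search: rotation x translation along the five-fold axis
grid  <- dock_grid(phi_values = seq(0, 70, by = 2),
                   z_values   = seq(50, 90, by = 2))
poses <- score_docks(crown_abc, enumerate_docks(crown_abc, grid))
rank_docks(poses, top_k = 3, clash_free = TRUE)
#>   phi z_offset truncation n_contacts n_clashes score
#> 1   4       60          0        975         0   975
#> 2   4       62          0        725         0   725
#> 3  16       54          0        655         0   655

# bifaceted assembly: second ring shares A/B, carries a new C-face sequence
crown_abd <- with_role_sequence(crown_abc, "C", seed = 99)
assembly  <- build_bifaceted(crown_abc, crown_abd,
                             rank_docks(poses, 1, clash_free = TRUE))
addressable_roles(assembly)
#>    face role  n_chains
#> 1     1 A            5
#> 2     1 B            5
#> 3     1 C            5
#> 4     2 A            5
#> 5     2 B            5
#> 6     2 D            5

verify_symmetry(assembly, 5, tol = 0.5, phi = 4, z_offset = 60)
#>   cyclic_closure_rmsd dihedral_backbone_rmsd n_chains is_pseudo
#> 1            9.95e-15               9.40e-15       30 TRUE
```

The top dock places the two rings at φ = 4°, z = 60 Å with 975 C–C CA
contacts and no clashes; the realized 30-chain assembly closes its 5-fold
and dihedral symmetry to machine precision at backbone level while the C
and D sequences differ — the definition of a pseudo-D₅ bifaceted particle,
hence `is_pseudo = TRUE`.

```r
pairs <- find_interface_pairs(assembly)   # 210 positions, pairing rmsd ~6e-7 A
jobs  <- enumerate_design_jobs(pairs)     # 105 biased + 7 unbiased jobs,
                                          # 100 sequences each
spec  <- make_bias_spec(pairs, "charges", level = 0.69)  # +0.69 for R/H/K
                                          # on side C, D/E on side D
```

Each interface position maps onto its dihedral two-fold image to
sub-Angstrom precision, and the emitted job manifest covers the full
scheme x level x temperature factorial an external design tool would
consume.

A thin command-line wrapper over these functions ships in
`inst/cli/bifacet.R` (`crown`, `dock`, `filter`, `coloc`, `validate`
subcommands).

## Package layout

- `R/structure.R`, `R/io.R`, `R/transforms.R` — tidy atom-table structure
  model, PDB/mmCIF I/O (via bio3d), rigid transforms and Kabsch
  superposition
- `R/symmetry.R` — cyclic expansion, dihedral partner, symmetry
  verification
- `R/synthetic.R` — idealized heterotrimer/crown generator, helix
  segmentation, truncation, chain concatenation
- `R/dock.R` — axial dock enumeration, scoring, ranking, realization
- `R/interface.R` — interface pairing, bias/multistate specification
  emission, design-job manifests
- `R/design_filter.R` — negative-design metric filtering
- `R/architecture.R` — extension and terminus-reorientation targets,
  contig/adjacency emission, diffusion job manifests
- `R/assembly.R` — bifaceted assembly composition, interface-class
  analysis, reports
- `R/coloc.R` — bead colocalization statistic
- `vignettes/bifacet-methods.Rmd` — the model, conventions, design
  decisions and limitations in full
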