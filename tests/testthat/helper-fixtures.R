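# Shared fixtures, built once per test run. Geometry depends only on the
# recipe's geometric parameters, so a fixed reference pose is valid for all
# seeds of the same recipe shape.

REC <- block_recipe(seed = 7)
TRI <- make_pseudo_heterotrimer(REC)
CROWN <- make_crown(REC)

SMALL_REC <- block_recipe(n_helices_per_subunit = 3, helix_length = 10,
                          seed = 11)
SMALL_CROWN <- make_crown(SMALL_REC)

# Clash-free reference pose for the default crown geometry (top-ranked
# clash-free dock of the default-recipe crown; the C blades of the two
# rings interdigitate and all cross-ring contacts are C-C).
REF_POSE <- tibble::tibble(phi = 4, z_offset = 60, truncation = 0L)

# Bifaceted fixture: the partner ring shares A/B sequences and carries a
# reseeded C-subunit sequence, as when deriving an (ABD) ring from (ABC).
ASM <- build_bifaceted(CROWN, with_role_sequence(CROWN, "C", seed = 99),
                       REF_POSE)

# A single-chain 6-helix fixture with annotations (the C subunit).
C_CHAIN <- get_chain(TRI, "C")

# Brute-force O(N^2) contact/clash counts used as the docking oracle.
brute_counts <- function(ring, phi, z_offset, truncation = 0,
                         contact_cutoff = 8, clash_cutoff = 3.5) {
  ring <- truncate_c_subunit(ring, truncation)
  ca <- ring[ring$atom == "CA", ]
  xyz <- cbind(ca$x, ca$y, ca$z)
  partner <- apply_transform(xyz, dihedral_transform(phi, z_offset))
  n <- nrow(xyz)
  contacts <- 0L; clashes <- 0L
  is_c <- ca$role == "C"
  for (i in seq_len(n)) {
    d <- sqrt(colSums((t(partner) - xyz[i, ])^2))
    clashes <- clashes + sum(d < clash_cutoff)
    if (is_c[i]) contacts <- contacts + sum(d[is_c] <= contact_cutoff)
  }
  list(contacts = as.integer(contacts), clashes = as.integer(clashes))
}

# Random proper rotation built from elementary rotations.
random_transform <- function() {
  transform_compose(
    translation(stats::runif(3, -20, 20)),
    transform_compose(rot_z(stats::runif(1, 0, 360)),
                      transform_compose(rot_y(stats::runif(1, 0, 360)),
                                        rot_x(stats::runif(1, 0, 360)))))
}
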