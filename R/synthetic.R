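#' Idealized alpha-helix parameters
#'
#' Geometry of the CA trace of an idealized alpha helix: 1.5 Angstrom rise
#' per residue, 100 degrees of twist per residue and a 2.3 Angstrom helical
#' radius, which together give the canonical ~3.8 Angstrom consecutive CA-CA
#' distance and ~5.4 Angstrom i to i+3 distance.
#'
#' @param rise_per_residue Angstrom per residue along the helix axis.
#' @param twist_per_residue Degrees per residue.
#' @param radius Helix radius, Angstrom.
#' @export
helix_params <- function(rise_per_residue = 1.5, twist_per_residue = 100,
                         radius = 2.3) {
  if (rise_per_residue <= 0 || twist_per_residue <= 0 || radius <= 0) {
    abort("helix parameters must all be positive")
  }
  structure(list(rise_per_residue = rise_per_residue,
                 twist_per_residue = twist_per_residue,
                 radius = radius), class = "helix_params")
}

#' Recipe for synthetic pseudosymmetric building blocks
#'
#' Controls the idealized heterotrimer and crown fixtures. The geometric
#' defaults place a three-bladed heterotrimer on a ring such that, after
#' five-fold expansion, adjacent trimers touch through an A-B interface and
#' a dihedral partner ring touches only through the C subunits; they were
#' chosen once for the default blade geometry and are validated by the
#' package tests.
#'
#' @param n_helices_per_subunit Helix count per subunit, >= 2 (default 6).
#' @param helix_length Residues per helix, >= 7 (default 12).
#' @param ring_radius Distance from the five-fold axis to each trimer
#'   centroid in the crown, Angstrom.
#' @param seed Integer seed controlling the deterministic subunit sequences.
#' @param helix_spacing Spacing between adjacent helix axes within a
#'   subunit, Angstrom.
#' @param r_start Distance from the trimer three-fold axis to the first
#'   helix of each subunit, Angstrom.
#' @param blade_phase Azimuth of the C subunit's outward direction, degrees.
#' @param tilt Tilt of the trimer three-fold axis applied when placing
#'   trimers on the crown ring, degrees; lifts the C subunit towards the
#'   dihedral interface.
#' @param loop_length Residues per connecting loop.
#' @param params [helix_params()] for the CA trace.
#' @export
block_recipe <- function(n_helices_per_subunit = 6, helix_length = 12,
                         ring_radius = 50, seed = 1,
                         helix_spacing = 7.5, r_start = 5,
                         blade_phase = 10, tilt = 40, loop_length = 3,
                         params = helix_params()) {
  if (n_helices_per_subunit < 2) abort("n_helices_per_subunit must be >= 2")
  if (helix_length < 7) abort("helix_length must be >= 7")
  structure(list(n_helices_per_subunit = as.integer(n_helices_per_subunit),
                 helix_length = as.integer(helix_length),
                 ring_radius = ring_radius, seed = as.integer(seed),
                 helix_spacing = helix_spacing, r_start = r_start,
                 blade_phase = blade_phase, tilt = tilt,
                 loop_length = as.integer(loop_length), params = params),
            class = "block_recipe")
}

#' Generate an ideal alpha-helix CA trace
#'
#' Builds a single-chain structure whose CA atoms lie on a regular helix
#' with the stated rise, twist and radius, with the helix axis along +z
#' starting at the origin.
#'
#' @param n_res Number of residues, >= 4.
#' @param params A [helix_params()].
#' @param chain Chain identifier.
#' @param aa One-letter code used for every residue.
#' @return A single-chain structure with `helix_ranges` `(1, n_res)`.
#' @examples
#' hx <- make_ideal_helix(10)
#' diff(range(hx$z))  # 9 intervals x 1.5 A rise
#' @export
make_ideal_helix <- function(n_res, params = helix_params(), chain = "A",
                             aa = "A") {
  if (n_res < 4) abort("an ideal helix needs at least 4 residues")
  k <- seq_len(n_res) - 1
  ang <- deg2rad(k * params$twist_per_residue)
  new_structure(tibble(
    chain = chain, role = "other", resi = seq_len(n_res), aa = aa,
    atom = "CA", element = "C",
    x = params$radius * cos(ang),
    y = params$radius * sin(ang),
    z = k * params$rise_per_residue,
    helix = 1L
  ))
}

# CA trace of one subunit "blade": n_helices antiparallel vertical helices
# whose axes sit along a radial line at azimuth `direction`, joined by short
# loops. Helix 1 is innermost; the chain C terminus ends on the outermost
# helix, pointing away from the three-fold axis.
blade_chain <- function(recipe, direction, chain = "A", role = "other",
                        seq_letters = NULL) {
  p <- recipe$params
  nh <- recipe$n_helices_per_subunit
  hl <- recipe$helix_length
  ll <- recipe$loop_length
  u <- c(cos(deg2rad(direction)), sin(deg2rad(direction)), 0)
  pieces <- list()
  for (j in seq_len(nh)) {
    axis_xy <- (recipe$r_start + (j - 1) * recipe$helix_spacing) * u[1:2]
    k <- seq_len(hl) - 1
    ang <- deg2rad(k * p$twist_per_residue)
    zz <- k * p$rise_per_residue
    if (j %% 2 == 0) zz <- rev(zz)  # antiparallel packing
    pieces[[length(pieces) + 1]] <- tibble(
      x = axis_xy[1] + p$radius * cos(ang),
      y = axis_xy[2] + p$radius * sin(ang),
      z = zz, helix = as.integer(j))
    if (j < nh) {
      a <- c(axis_xy[1] + p$radius * cos(ang[hl]),
             axis_xy[2] + p$radius * sin(ang[hl]), zz[hl])
      nxt_xy <- (recipe$r_start + j * recipe$helix_spacing) * u[1:2]
      b <- c(nxt_xy[1] + p$radius, nxt_xy[2], if (j %% 2 == 0) 0 else (hl - 1) * p$rise_per_residue)
      fr <- seq_len(ll) / (ll + 1)
      pieces[[length(pieces) + 1]] <- tibble(
        x = a[1] + fr * (b[1] - a[1]),
        y = a[2] + fr * (b[2] - a[2]),
        z = a[3] + fr * (b[3] - a[3]) + 1.0,  # bulge keeps loops off-helix
        helix = NA_integer_)
    }
  }
  atoms <- bind_rows(pieces)
  n <- nrow(atoms)
  if (is.null(seq_letters)) seq_letters <- rep("A", n)
  new_structure(tibble(
    chain = chain, role = role, resi = seq_len(n), aa = seq_letters,
    atom = "CA", element = "C",
    x = atoms$x, y = atoms$y, z = atoms$z, helix = atoms$helix))
}

# Deterministic random sequence for one subunit.
random_sequence <- function(n, seed) {
  withr::with_seed(seed, sample(canonical_aa(), n, replace = TRUE))
}

#' Generate an idealized pseudosymmetric heterotrimer
#'
#' Three subunits (entity roles A, B, C) with identical backbones related by
#' 120-degree rotations about z, carrying distinct deterministic sequences
#' drawn from a seeded stream. Each subunit is a "blade" of antiparallel
#' helices extending radially from the three-fold axis; the C subunit's
#' outermost (C-terminal) helix points away from the axis, leaving it free
#' for the design of an additional interface.
#'
#' @param recipe A [block_recipe()].
#' @return A 3-chain structure with chains `A`, `B`, `C` and matching roles.
#' @export
make_pseudo_heterotrimer <- function(recipe = block_recipe()) {
  if (!inherits(recipe, "block_recipe")) abort("`recipe` must be a block_recipe")
  base <- blade_chain(recipe, direction = recipe$blade_phase)
  n <- nrow(base)
  seqs <- list(
    A = random_sequence(n, recipe$seed * 1000L + 1L),
    B = random_sequence(n, recipe$seed * 1000L + 2L),
    C = random_sequence(n, recipe$seed * 1000L + 3L))
  # guard against (astronomically unlikely) sequence collisions
  if (anyDuplicated(map_chr(seqs, paste, collapse = "")) > 0) {
    seqs$B[1] <- setdiff(canonical_aa(), seqs$B[1])[1]
  }
  mk <- function(role, ang) {
    ch <- apply_transform(base, rot_z(ang))
    ch$chain <- role
    ch$role <- role
    ch$aa <- seqs[[role]]
    ch
  }
  # role C points along blade_phase (radially outward once on the ring)
  out <- bind_structures(list(mk("A", 120), mk("B", 240), mk("C", 0)))
  validate_structure(out)
  out
}

#' Generate a crown: a five-fold ring of pseudosymmetric heterotrimers
#'
#' Places the heterotrimer of [make_pseudo_heterotrimer()] on a ring of
#' radius `ring_radius` (tilting its three-fold axis by `tilt` degrees so
#' that the C subunits face the dihedral interface) and expands it with
#' five-fold cyclic symmetry about +z, yielding a 15-chain ring-like
#' substructure. The fixture is verified clash-free: no CA-CA pair between
#' different trimers may be closer than 2.5 Angstrom.
#'
#' @param recipe A [block_recipe()].
#' @return A 15-chain structure; the `copy` column holds the trimer index.
#' @examples
#' crown <- make_crown(block_recipe(seed = 7))
#' length(chain_ids(crown))
#' @export
make_crown <- function(recipe = block_recipe()) {
  tri <- make_pseudo_heterotrimer(recipe)
  placed <- apply_transform(tri, crown_placement(recipe))
  crown <- expand_cyclic(placed, cyclic_spec(5))
  dmin <- min_intertrimer_distance(crown)
  if (dmin < 2.5) {
    abort(sprintf(paste0("crown generation produced inter-trimer clashes ",
                         "(min CA-CA %.2f A); increase ring_radius"), dmin))
  }
  crown
}

# Rigid placement of the heterotrimer onto the crown ring: tilt the
# three-fold axis about y (lifting the C blade, which points along +x),
# then translate out to the ring radius.
crown_placement <- function(recipe) {
  transform_compose(translation(c(recipe$ring_radius, 0, 0)),
                    rot_y(-recipe$tilt))
}

# Minimum CA-CA distance between chains belonging to different trimer
# copies (requires the `copy` column from expand_cyclic).
min_intertrimer_distance <- function(crown) {
  ca <- crown[crown$atom == "CA", ]
  xyz <- cbind(ca$x, ca$y, ca$z)
  d2 <- cross_dist2(xyz, xyz)
  same <- outer(ca$copy, ca$copy, `==`)
  d2[same] <- Inf
  sqrt(min(d2))
}

#' Assign helix intervals to a chain
#'
#' Returns annotated helix intervals when the chain carries them; otherwise
#' assigns helices geometrically as maximal runs of at least 6 residues in
#' which the CA(i) to CA(i+3) distance lies in the 4.5 to 6.5 Angstrom
#' window (which accepts the ideal alpha helix at ~5.4 Angstrom and rejects
#' extended chain at ~11.4 Angstrom). Loops are the complement.
#'
#' @param chain A single-chain structure.
#' @param window i,i+3 distance acceptance window, Angstrom.
#' @param min_run Minimum helix length, residues.
#' @return Tibble of `(helix, start, end)` intervals (possibly empty).
#' @export
segment_helices <- function(chain, window = c(4.5, 6.5), min_run = 6) {
  if (length(chain_ids(chain)) != 1) abort("segment_helices expects one chain")
  ca <- chain[chain$atom == "CA", ]
  if (nrow(ca) < 7) abort("chain must have at least 7 residues")
  ann <- chain_helix_ranges(chain)
  if (nrow(ann) > 0) return(ann)
  xyz <- cbind(ca$x, ca$y, ca$z)
  n <- nrow(xyz)
  d13 <- sqrt(rowSums((xyz[seq_len(n - 3), , drop = FALSE] -
                         xyz[4:n, , drop = FALSE])^2))
  helical <- d13 >= window[1] & d13 <= window[2]
  # residue i is helical if it participates in any accepted i,i+3 window
  res_flag <- rep(FALSE, n)
  for (i in which(helical)) res_flag[i:(i + 3)] <- TRUE
  r <- rle(res_flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values & r$lengths >= min_run
  tibble(helix = seq_len(sum(keep)),
         start = ca$resi[starts[keep]],
         end = ca$resi[ends[keep]])
}

#' Truncate the C subunit by whole helices
#'
#' Removes the last `n_helices` helix intervals of every C-role chain,
#' together with any trailing loop residues after the new last helix, so a
#' helix terminus is always the new C terminus. Other chains are untouched;
#' `n_helices = 0` is the identity.
#'
#' @param s A structure containing at least one C-role chain.
#' @param n_helices Number of terminal helices to remove.
#' @return The truncated structure.
#' @export
truncate_c_subunit <- function(s, n_helices) {
  n_helices <- as.integer(n_helices)
  if (n_helices < 0) abort("n_helices must be >= 0")
  if (n_helices == 0) return(s)
  c_chains <- unique(s$chain[s$role == "C"])
  if (length(c_chains) == 0) abort("structure has no C-role chain")
  keep <- rep(TRUE, nrow(s))
  for (ch in c_chains) {
    rows <- s[s$chain == ch, ]
    hr <- chain_helix_ranges(rows)
    if (nrow(hr) == 0) hr <- segment_helices(get_chain(s, ch))
    if (n_helices >= nrow(hr)) {
      abort(sprintf("cannot truncate %d helices: chain %s has only %d",
                    n_helices, ch, nrow(hr)))
    }
    last_end <- hr$end[nrow(hr) - n_helices]
    keep[s$chain == ch & s$resi > last_end] <- FALSE
  }
  out <- s[keep, ]
  class(out) <- class(s)
  out
}

#' Enumerate C-subunit truncation variants
#'
#' Returns the structures truncated by 1 to `max_truncation` helices; the
#' full-length input is handled separately by the caller.
#'
#' @param s A structure with a C-role chain.
#' @param max_truncation Maximum number of helices to remove (default 4).
#' @return A list of `max_truncation` structures.
#' @export
enumerate_truncation_variants <- function(s, max_truncation = 4) {
  if (max_truncation < 1) abort("max_truncation must be >= 1")
  map(seq_len(max_truncation), function(k) truncate_c_subunit(s, k))
}

#' Concatenate all chains into a single chain
#'
#' Joins the chains in the given order into one chain with residues
#' renumbered 1..N contiguously and coordinates unchanged, mirroring the
#' single-chain input preparation required by symmetric docking programs.
#'
#' @param s A structure.
#' @param order Character vector covering every chain id exactly once.
#' @param chain_id Identifier of the resulting chain.
#' @return A list with `structure` (single chain) and `mapping`, a tibble of
#'   `(chain, resi, new_resi)` recovering the original chain boundaries.
#' @export
concatenate_chains <- function(s, order = chain_ids(s), chain_id = "A") {
  if (!setequal(order, chain_ids(s)) || anyDuplicated(order) > 0 ||
      length(order) != length(chain_ids(s))) {
    abort("`order` must cover all chains exactly once")
  }
  parts <- map(order, function(ch) s[s$chain == ch, ])
  out <- bind_rows(parts)
  ca_mask <- out$atom == "CA"
  key <- paste(out$chain, out$resi)
  first_key <- key[!duplicated(key)]
  new_resi <- match(key, first_key)
  mapping <- tibble(chain = out$chain[!duplicated(key)],
                    resi = out$resi[!duplicated(key)],
                    new_resi = seq_along(first_key))
  out$resi <- as.integer(new_resi)
  # renumber helix annotations sequentially across the concatenated chain
  hkey <- ifelse(is.na(out$helix), NA, paste(out$chain, out$helix))
  out$helix <- as.integer(match(hkey, unique(hkey[!is.na(hkey)])))
  out$chain <- chain_id
  out$role <- "other"
  class(out) <- c("bifacet_structure", class(tibble()))
  list(structure = out, mapping = mapping)
}

#' Re-draw the sequences of one entity role
#'
#' Replaces the amino-acid sequences of every chain with the given role by a
#' fresh deterministic draw, leaving the backbone untouched. Used to derive
#' the second building block of a bifaceted pair: the (ABD) ring shares the
#' A and B sequences of the (ABC) ring but carries a new sequence on the
#' subunit facing the dihedral interface.
#'
#' @param s A structure.
#' @param role Entity role whose sequences are replaced (default `"C"`).
#' @param seed Integer seed for the new sequence.
#' @return The structure with replaced sequences.
#' @export
with_role_sequence <- function(s, role = "C", seed) {
  chains <- unique(s$chain[s$role == role])
  if (length(chains) == 0) abort(paste0("no chains with role ", role))
  for (ch in chains) {
    sel <- s$chain == ch
    n_res <- length(unique(s$resi[sel]))
    new_seq <- random_sequence(n_res, seed)
    s$aa[sel] <- new_seq[match(s$resi[sel], unique(s$resi[sel]))]
  }
  s
}

# Squared cross-distances between two coordinate matrices (n x 3, m x 3).
cross_dist2 <- function(a, b) {
  an <- rowSums(a^2); bn <- rowSums(b^2)
  d2 <- outer(an, bn, `+`) - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  d2
}
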