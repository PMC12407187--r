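#' Dock sampling grid
#'
#' The axial dock search samples a rotation `phi` about the shared symmetry
#' axis, a translation `z` along it, and a C-subunit truncation level.
#' `phi` is canonical in `[0, 360 / n)` degrees (72 degrees for n = 5),
#' since larger values are symmetry-equivalent.
#'
#' @param phi_values Degrees, each in `[0, 360 / n)`.
#' @param z_values Angstrom.
#' @param truncation_levels Helix counts removed from the C subunits.
#' @param n Cyclic order of the rings (default 5).
#' @export
dock_grid <- function(phi_values, z_values, truncation_levels = 0L, n = 5) {
  if (length(phi_values) == 0 || length(z_values) == 0 ||
      length(truncation_levels) == 0) {
    abort("dock grid lists must be nonempty")
  }
  lim <- 360 / n
  if (any(phi_values < 0 | phi_values >= lim)) {
    abort(sprintf("phi values must lie in [0, %g) for n = %d", lim, n))
  }
  structure(list(phi_values = phi_values, z_values = z_values,
                 truncation_levels = as.integer(truncation_levels), n = n),
            class = "dock_grid")
}

#' Scoring parameters for axial docks
#'
#' The dock score is a documented contact-minus-clash substitute for
#' motif-hash interface scoring: `score = n_contacts - clash_weight *
#' n_clashes`, where contacts are CA pairs between the designable C-role
#' chains of the two rings within `contact_cutoff` and clashes are CA pairs
#' between any chains closer than `clash_cutoff`.
#'
#' @param contact_cutoff Angstrom (default 8).
#' @param clash_cutoff Angstrom (default 3.5); must be below the contact
#'   cutoff.
#' @param clash_weight Positive penalty weight (default 10).
#' @export
score_params <- function(contact_cutoff = 8, clash_cutoff = 3.5,
                         clash_weight = 10) {
  if (!(clash_cutoff < contact_cutoff)) {
    abort("clash_cutoff must be smaller than contact_cutoff")
  }
  if (clash_weight <= 0) abort("clash_weight must be positive")
  structure(list(contact_cutoff = contact_cutoff,
                 clash_cutoff = clash_cutoff,
                 clash_weight = clash_weight), class = "score_params")
}

#' Enumerate dock poses over a grid
#'
#' One pose per `(phi, z, truncation)` triple, unscored. Use
#' [score_docks()] to fill in contact and clash counts.
#'
#' @param ring A ring structure aligned on +z.
#' @param grid A [dock_grid()].
#' @return A `dock_poses` tibble with columns `phi`, `z_offset`,
#'   `truncation`, `n_contacts`, `n_clashes`, `score`.
#' @export
enumerate_docks <- function(ring, grid) {
  if (!inherits(grid, "dock_grid")) abort("`grid` must be a dock_grid")
  poses <- tidyr::expand_grid(truncation = grid$truncation_levels,
                              z_offset = grid$z_values,
                              phi = grid$phi_values)
  poses <- poses[, c("phi", "z_offset", "truncation")]
  poses$n_contacts <- NA_integer_
  poses$n_clashes <- NA_integer_
  poses$score <- NA_real_
  class(poses) <- c("dock_poses", class(poses))
  poses
}

#' Score dock poses
#'
#' For each pose the opposing ring is built with [dihedral_partner()] from
#' the ring truncated at the pose's level (both copies of a dihedral pair
#' share the truncation). `n_contacts` counts inter-ring CA pairs within
#' the contact cutoff restricted to C-role chains (the designable
#' interface); `n_clashes` counts inter-ring CA pairs over all chains
#' closer than the clash cutoff.
#'
#' @param ring A ring structure aligned on +z.
#' @param poses A `dock_poses` tibble from [enumerate_docks()], or a
#'   one-row pose specification.
#' @param params A [score_params()].
#' @return The poses tibble with counts and scores filled in.
#' @export
score_docks <- function(ring, poses, params = score_params()) {
  cc2 <- params$contact_cutoff^2
  cl2 <- params$clash_cutoff^2
  for (t_lev in unique(poses$truncation)) {
    trunc <- truncate_c_subunit(ring, t_lev)
    ca <- trunc[trunc$atom == "CA", ]
    xyz <- cbind(ca$x, ca$y, ca$z)
    is_c <- ca$role == "C"
    rows <- which(poses$truncation == t_lev)
    for (phi in unique(poses$phi[rows])) {
      # factor the z translation out: with partner p = flip + rot(phi) at
      # z = 0, the pair distance at offset z is dxy^2 + (zi + zj - z)^2,
      # so only pairs with dxy within the contact cutoff can ever count
      p0 <- apply_transform(xyz, dihedral_transform(phi, 0))
      dxy2 <- cross_dist2(cbind(xyz[, 1:2], 0), cbind(p0[, 1:2], 0))
      keep <- dxy2 <= cc2
      kd <- dxy2[keep]
      kw <- outer(xyz[, 3], -p0[, 3], `+`)[keep]
      kc <- outer(is_c, is_c, `&`)[keep]
      for (i in rows[poses$phi[rows] == phi]) {
        d2 <- kd + (kw - poses$z_offset[i])^2
        nc <- sum(kc & d2 <= cc2)
        ncl <- sum(d2 < cl2)
        poses$n_contacts[i] <- as.integer(nc)
        poses$n_clashes[i] <- as.integer(ncl)
        poses$score[i] <- nc - params$clash_weight * ncl
      }
    }
  }
  poses
}

#' @rdname score_docks
#' @param phi,z_offset,truncation Pose coordinates for scoring a single
#'   pose without building a grid.
#' @export
score_pose <- function(ring, phi, z_offset, truncation = 0,
                       params = score_params()) {
  poses <- tibble(phi = phi, z_offset = z_offset,
                  truncation = as.integer(truncation),
                  n_contacts = NA_integer_, n_clashes = NA_integer_,
                  score = NA_real_)
  class(poses) <- c("dock_poses", class(poses))
  score_docks(ring, poses, params)
}

#' Rank scored dock poses
#'
#' Descending by score, with ties broken by fewer clashes, more contacts,
#' smaller `|z_offset|`, then smaller `phi`; the ordering is invariant to
#' the input permutation.
#'
#' @param poses Scored `dock_poses`.
#' @param top_k Number of poses to keep.
#' @param clash_free Drop poses with any clash before ranking?
#' @export
rank_docks <- function(poses, top_k = nrow(poses), clash_free = FALSE) {
  if (any(is.na(poses$score))) {
    abort("all poses must be scored before ranking")
  }
  if (clash_free) poses <- poses[poses$n_clashes == 0, ]
  out <- poses |>
    arrange(desc(.data$score), .data$n_clashes, desc(.data$n_contacts),
            abs(.data$z_offset), .data$phi)
  head(out, top_k)
}

#' Realize a dock as a two-ring assembly
#'
#' Truncates both rings at the pose's truncation level, places the second
#' ring with [dihedral_partner()], relabels the opposing ring's C-role
#' chains to role D (unless `relabel_role = FALSE`, e.g. for a
#' single-component dihedral assembly), and deterministically relabels
#' chain identifiers to avoid collisions. The result carries a `face`
#' column (1 = first ring, 2 = partner) and the pose and its two-fold
#' transform as attributes.
#'
#' @param ring_c,ring_d Ring structures aligned on +z.
#' @param pose A one-row scored pose (or a list with `phi`, `z_offset`,
#'   `truncation`).
#' @param relabel_role Relabel the partner's C chains to role D?
#' @return The composed assembly structure.
#' @export
realize_dock <- function(ring_c, ring_d, pose, relabel_role = TRUE) {
  phi <- pose$phi[1]; zoff <- pose$z_offset[1]
  t_lev <- as.integer(pose$truncation[1] %||% 0L)
  a <- truncate_c_subunit(ring_c, t_lev)
  b <- truncate_c_subunit(ring_d, t_lev)
  b <- dihedral_partner(b, phi, zoff)
  if (relabel_role) b$role[b$role == "C"] <- "D"
  b <- relabel_chains(b, avoid = chain_ids(a))
  a$face <- 1L
  b$face <- 2L
  out <- bind_structures(list(a, b))
  validate_structure(out)
  attr(out, "pose") <- tibble(phi = phi, z_offset = zoff, truncation = t_lev)
  attr(out, "two_fold") <- dihedral_transform(phi, zoff)
  out
}
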