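#' Cyclic symmetry specification
#'
#' @param order_n Cyclic order, an integer >= 2 (the crown architecture uses
#'   n = 5). The symmetry axis is fixed to +z.
#' @export
cyclic_spec <- function(order_n) {
  order_n <- as.integer(order_n)
  if (is.na(order_n) || order_n < 2) {
    abort("cyclic order must be an integer >= 2")
  }
  structure(list(order_n = order_n, axis = c(0, 0, 1)), class = "cyclic_spec")
}

as_cyclic_spec <- function(spec) {
  if (inherits(spec, "cyclic_spec")) spec else cyclic_spec(spec)
}

#' Expand an asymmetric unit into a cyclic ring
#'
#' Produces `order_n` copies of the input, copy k rotated by `k * 360 / n`
#' degrees about the +z axis. Chains are deterministically relabeled from the
#' single-character PDB pool and a `copy` column (1-based copy index) is
#' added, so higher-level code can track which symmetry copy each chain
#' belongs to.
#'
#' @param asu A structure positioned with the intended symmetry axis on +z.
#' @param spec A [cyclic_spec()] or a bare integer order.
#' @return A structure with `order_n` times the input chain count.
#' @examples
#' tri <- make_pseudo_heterotrimer(block_recipe(seed = 1))
#' ring <- expand_cyclic(tri, 5)
#' length(chain_ids(ring))
#' @export
expand_cyclic <- function(asu, spec) {
  spec <- as_cyclic_spec(spec)
  n <- spec$order_n
  n_out <- length(chain_ids(asu)) * n
  if (n_out > 62) {
    abort("expansion would exceed the 62 chain-ID pool")
  }
  copies <- map(seq_len(n), function(k) {
    s <- apply_transform(asu, rot_z((k - 1) * 360 / n))
    s$copy <- k
    s
  })
  out <- bind_structures(copies)
  # relabel: copy 1 keeps chain order, subsequent copies continue the pool
  old <- paste(rep(seq_len(n), each = length(chain_ids(asu))),
               rep(chain_ids(asu), n))
  key <- paste(out$copy, out$chain)
  out$chain <- chain_id_pool()[match(key, old)]
  validate_structure(out)
  out
}

#' Opposing ring of a dihedral pair
#'
#' Returns the input ring flipped by a 180-degree rotation about the x axis,
#' then rotated by `phi` about z and translated by `z_offset` along z. This
#' is the standard parameterization of the second ring of a dihedral
#' assembly; the original ring is not modified. The dihedral flip axis is
#' fixed to x, with `phi` absorbing the rotational freedom.
#'
#' @param ring A structure aligned on +z.
#' @param phi Rotation about z, degrees.
#' @param z_offset Translation along z, Angstrom.
#' @return The transformed partner structure.
#' @export
dihedral_partner <- function(ring, phi = 0, z_offset = 0) {
  apply_transform(ring, dihedral_transform(phi, z_offset))
}

#' @rdname dihedral_partner
#' @export
dihedral_transform <- function(phi = 0, z_offset = 0) {
  transform_compose(translation(c(0, 0, z_offset)),
                    transform_compose(rot_z(phi), rot_x(180)))
}

# Greedy nearest-centroid chain pairing between a transformed structure and
# the original. Returns tibble(from, to) of chain ids. Chains of unequal
# length pair at infinite cost.
pair_chains_greedy <- function(moved, original) {
  cent <- function(s) {
    ca <- s[s$atom == "CA", ]
    ca |>
      group_by(chain = .data$chain) |>
      summarise(x = mean(.data$x), y = mean(.data$y), z = mean(.data$z),
                n = dplyr::n(), .groups = "drop")
  }
  a <- cent(moved); b <- cent(original)
  d <- as.matrix(stats::dist(rbind(as.matrix(a[, c("x", "y", "z")]),
                                   as.matrix(b[, c("x", "y", "z")]))))
  d <- d[seq_len(nrow(a)), nrow(a) + seq_len(nrow(b)), drop = FALSE]
  d[outer(a$n, b$n, `!=`)] <- Inf
  pairs <- tibble(from = character(), to = character())
  for (i in seq_len(min(nrow(a), nrow(b)))) {
    ix <- arrayInd(which.min(d), dim(d))
    if (!is.finite(d[ix[1], ix[2]])) break
    pairs <- bind_rows(pairs, tibble(from = a$chain[ix[1]], to = b$chain[ix[2]]))
    d[ix[1], ] <- Inf
    d[, ix[2]] <- Inf
  }
  pairs
}

# CA rmsd between a transformed structure and the original under greedy chain
# re-pairing. Returns Inf when pairing is incomplete.
repaired_rmsd <- function(moved, original, return_pairs = FALSE) {
  pairs <- pair_chains_greedy(moved, original)
  if (nrow(pairs) < length(chain_ids(original))) {
    return(if (return_pairs) list(rmsd = Inf, pairs = pairs) else Inf)
  }
  sq <- 0; n <- 0
  for (i in seq_len(nrow(pairs))) {
    ma <- ca_coords(get_chain(moved, pairs$from[i]))
    mb <- ca_coords(get_chain(original, pairs$to[i]))
    sq <- sq + sum((ma - mb)^2)
    n <- n + nrow(ma)
  }
  val <- sqrt(sq / n)
  if (return_pairs) list(rmsd = val, pairs = pairs) else val
}

#' Verify cyclic and dihedral backbone symmetry
#'
#' Measures how well a structure closes under its stated cyclic symmetry and
#' under a dihedral two-fold flip, and flags pseudosymmetry (backbone-level
#' closure with sequence-level asymmetry).
#'
#' `cyclic_closure_rmsd` is the CA rmsd between the structure and its copy
#' rotated by `360 / order_n` degrees about z, under greedy nearest-centroid
#' chain re-pairing. `dihedral_backbone_rmsd` is the analogous rmsd for a
#' two-fold flip about an in-plane axis; the flip's z placement is estimated
#' from the coordinates and its azimuth is optimized numerically (or taken
#' from `phi`/`z_offset` when supplied, e.g. from a dock pose). `is_pseudo`
#' is `TRUE` when the backbone closes within `tol` but paired chains carry
#' different sequences.
#'
#' @param s A structure.
#' @param spec A [cyclic_spec()] or integer order.
#' @param tol Closure tolerance in Angstrom.
#' @param phi,z_offset Optional known dihedral parameters.
#' @return A one-row tibble: `cyclic_closure_rmsd`, `dihedral_backbone_rmsd`,
#'   `n_chains`, `is_pseudo`.
#' @export
verify_symmetry <- function(s, spec, tol = 0.5, phi = NULL, z_offset = NULL) {
  spec <- as_cyclic_spec(spec)
  n <- spec$order_n
  ids <- chain_ids(s)
  if (length(ids) %% n != 0) {
    abort(sprintf("chain count (%d) not divisible by cyclic order (%d)",
                  length(ids), n))
  }
  cyc <- repaired_rmsd(apply_transform(s, rot_z(360 / n)), s,
                       return_pairs = TRUE)

  dihedral_at <- function(psi, zoff) {
    repaired_rmsd(apply_transform(s, dihedral_transform(psi, zoff)), s)
  }
  if (!is.null(phi) || !is.null(z_offset)) {
    psi_best <- phi %||% 0
    z_best <- z_offset %||% 0
  } else {
    z_best <- 2 * mean(s$z[s$atom == "CA"])
    grid <- seq(0, 360 - 1e-9, by = 360 / (8 * n))
    vals <- map_dbl(grid, dihedral_at, zoff = z_best)
    g0 <- grid[which.min(vals)]
    opt <- optimize(dihedral_at, interval = c(g0 - 360 / (8 * n), g0 + 360 / (8 * n)),
                    zoff = z_best, tol = 1e-6)
    psi_best <- opt$minimum
  }
  dres <- repaired_rmsd(apply_transform(s, dihedral_transform(psi_best, z_best)),
                        s, return_pairs = TRUE)

  seqs <- setNames(map_chr(ids, chain_sequence, s = s), ids)
  pairs_differ <- function(pairs) {
    if (nrow(pairs) == 0) return(FALSE)
    any(seqs[pairs$from] != seqs[pairs$to])
  }
  is_pseudo <-
    (is.finite(dres$rmsd) && dres$rmsd <= tol && pairs_differ(dres$pairs)) ||
    (is.finite(cyc$rmsd) && cyc$rmsd <= tol && pairs_differ(cyc$pairs))

  tibble(
    cyclic_closure_rmsd = cyc$rmsd,
    dihedral_backbone_rmsd = dres$rmsd,
    n_chains = length(ids),
    is_pseudo = is_pseudo
  )
}
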