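#' Tidy structural model
#'
#' A structure is a tibble with one row per atom and columns `chain`
#' (single-character identifier), `role` (entity role: `"A"`, `"B"`, `"C"`,
#' `"D"` or `"other"`), `resi` (1-based residue index within the chain, author
#' numbering), `aa` (one-letter amino-acid code or `"X"`), `atom` (atom label,
#' e.g. `"CA"`), `element`, the coordinates `x`, `y`, `z` in Angstrom, and
#' `helix` (integer helix identifier within the chain, `NA` for loop
#' residues). Extra columns (e.g. `trimer`, `face`) are carried along
#' untouched by all geometric operations. The principal symmetry axis is by
#' convention the +z axis through the origin.
#'
#' @param atoms A data frame with at least the columns listed above.
#' @return A `bifacet_structure` tibble.
#' @examples
#' hx <- make_ideal_helix(10)
#' is_structure(hx)
#' @export
new_structure <- function(atoms) {
  atoms <- as_tibble(atoms)
  required <- c("chain", "role", "resi", "aa", "atom", "element",
                "x", "y", "z", "helix")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols) > 0) {
    abort(paste0("structure is missing columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  atoms$resi <- as.integer(atoms$resi)
  atoms$helix <- as.integer(atoms$helix)
  s <- structure(atoms, class = c("bifacet_structure", class(tibble())))
  validate_structure(s)
  s
}

#' @rdname new_structure
#' @param x Object to test.
#' @export
is_structure <- function(x) inherits(x, "bifacet_structure")

#' Validate structure invariants
#'
#' Checks that residue indices are strictly increasing within each chain,
#' that every residue carries a CA atom, that amino-acid codes are canonical
#' (or `"X"`), that coordinates are finite and that helix annotations form
#' disjoint ordered intervals within residue bounds.
#'
#' @param s A structure.
#' @return `s`, invisibly, if valid; otherwise an error is raised.
#' @export
validate_structure <- function(s) {
  if (nrow(s) == 0) abort("structure has no atoms")
  if (!all(is.finite(s$x) & is.finite(s$y) & is.finite(s$z))) {
    abort("structure has non-finite coordinates")
  }
  bad_aa <- setdiff(unique(s$aa), c(canonical_aa(), "X"))
  if (length(bad_aa) > 0) {
    abort(paste0("invalid amino-acid codes: ", paste(bad_aa, collapse = ", ")))
  }
  bad_role <- setdiff(unique(s$role), c("A", "B", "C", "D", "other"))
  if (length(bad_role) > 0) {
    abort(paste0("invalid entity roles: ", paste(bad_role, collapse = ", ")))
  }
  for (ch in unique(s$chain)) {
    rows <- s[s$chain == ch, ]
    resi <- unique(rows$resi)
    if (is.unsorted(resi, strictly = TRUE)) {
      abort(paste0("residue indices not strictly increasing in chain ", ch))
    }
    no_ca <- setdiff(resi, rows$resi[rows$atom == "CA"])
    if (length(no_ca) > 0) {
      abort(paste0("chain ", ch, " residues without CA atom: ",
                   paste(no_ca, collapse = ", ")))
    }
    hr <- chain_helix_ranges(rows)
    if (nrow(hr) > 1) {
      if (any(hr$start[-1] <= hr$end[-nrow(hr)])) {
        abort(paste0("helix ranges overlap or are out of order in chain ", ch))
      }
    }
  }
  invisible(s)
}

#' Chain identifiers of a structure
#' @param s A structure.
#' @return Character vector of chain ids, in order of first appearance.
#' @export
chain_ids <- function(s) unique(s$chain)

#' Extract one chain as a structure
#' @param s A structure.
#' @param chain Chain identifier.
#' @export
get_chain <- function(s, chain) {
  if (!chain %in% s$chain) abort(paste0("no chain ", chain, " in structure"))
  out <- s[s$chain == chain, ]
  class(out) <- class(s)
  out
}

#' CA coordinates as a numeric matrix
#'
#' @param s A structure.
#' @return An n x 3 matrix of CA positions (Angstrom), one row per residue in
#'   chain order.
#' @export
ca_coords <- function(s) {
  ca <- s[s$atom == "CA", ]
  m <- cbind(ca$x, ca$y, ca$z)
  colnames(m) <- c("x", "y", "z")
  m
}

#' One-letter sequence of a chain
#' @param s A structure.
#' @param chain Chain identifier.
#' @return A single string.
#' @export
chain_sequence <- function(s, chain) {
  rows <- s[s$chain == chain & s$atom == "CA", ]
  paste(rows$aa, collapse = "")
}

# Helix ranges for a set of rows belonging to one chain, from the helix
# annotation column. Returns tibble(helix, start, end) with inclusive bounds.
chain_helix_ranges <- function(rows) {
  ca <- rows[rows$atom == "CA" & !is.na(rows$helix), ]
  if (nrow(ca) == 0) {
    return(tibble(helix = integer(), start = integer(), end = integer()))
  }
  ca |>
    group_by(helix = .data$helix) |>
    summarise(start = min(.data$resi), end = max(.data$resi),
              .groups = "drop") |>
    arrange(.data$start)
}

#' Helix intervals of a chain
#'
#' Returns the annotated helix intervals of a chain as a tibble with columns
#' `helix`, `start`, `end` (residue indices, inclusive). Returns zero rows if
#' the chain carries no annotation; see [segment_helices()] for geometric
#' assignment.
#'
#' @param s A structure.
#' @param chain Chain identifier; may be omitted for single-chain structures.
#' @export
helix_ranges <- function(s, chain = NULL) {
  if (is.null(chain)) {
    ids <- chain_ids(s)
    if (length(ids) != 1) abort("specify `chain` for multi-chain structures")
    chain <- ids
  }
  chain_helix_ranges(s[s$chain == chain, ])
}

#' Relabel chains deterministically
#'
#' Assigns fresh single-character chain identifiers from the 62-character PDB
#' pool in order of first appearance, optionally skipping identifiers already
#' in use elsewhere.
#'
#' @param s A structure.
#' @param avoid Character vector of identifiers that must not be used.
#' @return The relabeled structure.
#' @export
relabel_chains <- function(s, avoid = character()) {
  pool <- setdiff(chain_id_pool(), avoid)
  old <- chain_ids(s)
  if (length(old) > length(pool)) {
    abort(paste0("chain-ID capacity exceeded: need ", length(old),
                 " identifiers but only ", length(pool), " are available"))
  }
  map <- setNames(pool[seq_along(old)], old)
  s$chain <- unname(map[s$chain])
  s
}

#' @export
print.bifacet_structure <- function(x, ...) {
  n_ch <- length(chain_ids(x))
  n_res <- nrow(x[x$atom == "CA", ])
  cat(sprintf("<bifacet_structure: %d chain%s, %d residues, %d atoms>\n",
              n_ch, if (n_ch == 1) "" else "s", n_res, nrow(x)))
  NextMethod()
}

# Bind structures (e.g. symmetry copies) preserving the structure class.
bind_structures <- function(...) {
  out <- bind_rows(...)
  class(out) <- c("bifacet_structure", class(tibble()))
  out
}
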