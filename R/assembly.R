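#' Build a bifaceted two-ring assembly
#'
#' Composes a 30-chain bifaceted model from two 15-chain crowns and a dock
#' pose: the second ring is placed as the dihedral partner and its C-role
#' chains become role D, yielding the (ABC)5-(ABD)5 architecture in which
#' all six face/role combinations are independently addressable.
#'
#' @param ring_abc,ring_abd 15-chain crown structures with roles A, B, C.
#' @param pose A scored dock pose (one row).
#' @return A `bifacet_assembly` structure (30 chains, `face` column,
#'   pose and two-fold transform attributes).
#' @export
build_bifaceted <- function(ring_abc, ring_abd, pose) {
  for (ring in list(ring_abc, ring_abd)) {
    if (length(chain_ids(ring)) != 15) {
      abort("each ring must be a 15-chain crown")
    }
    if (!all(c("A", "B", "C") %in% ring$role)) {
      abort("rings must carry entity roles A, B and C")
    }
  }
  out <- realize_dock(ring_abc, ring_abd, pose, relabel_role = TRUE)
  class(out) <- c("bifacet_assembly", class(out))
  attr(out, "component_rings") <- c("ABC5", "ABD5")
  out
}

#' Addressable face/role combinations of an assembly
#'
#' @param a A `bifacet_assembly` (or any structure with `face` and `role`
#'   columns).
#' @return A tibble of distinct `(face, role)` pairs with chain counts; a
#'   full bifaceted model reports six rows.
#' @export
addressable_roles <- function(a) {
  if (!"face" %in% names(a)) abort("assembly lacks a `face` column")
  a[a$atom == "CA", ] |>
    distinct(.data$face, .data$role, .data$chain) |>
    group_by(.data$face, .data$role) |>
    summarise(n_chains = dplyr::n(), .groups = "drop") |>
    arrange(.data$face, .data$role)
}

#' Enumerate designed interface classes
#'
#' Finds every pair of entity roles in contact across distinct trimers,
#' classifies each contact as `cyclic` (between trimers of the same ring)
#' or `dihedral` (across the two rings), and marks a class `asymmetric`
#' when the two partners differ in role or sequence. Contacts within one
#' trimer are inherited from the building block rather than designed; they
#' are reported with relation `intra_trimer` and `designed = FALSE`.
#'
#' @param a An assembly carrying `face`, `copy` and role labels.
#' @param contact_cutoff CA-CA contact threshold, Angstrom (default 8).
#' @return A tibble of interface classes, deduplicated by
#'   `(role_pair, relation)`: columns `role_a`, `role_b`, `relation`,
#'   `symmetry`, `designed`, `min_distance`.
#' @export
count_designed_interface_classes <- function(a, contact_cutoff = 8) {
  if (!all(c("face", "copy") %in% names(a))) {
    abort("assembly must carry `face` and `copy` columns")
  }
  if (any(a$role == "other")) {
    abort("all chains must carry entity role labels")
  }
  ca <- a[a$atom == "CA", ]
  ids <- unique(ca$chain)
  info <- ca |>
    distinct(.data$chain, .data$role, .data$face, .data$copy)
  seqs <- setNames(map_chr(ids, chain_sequence, s = a), ids)
  xyz_by <- map(ids, function(ch) {
    m <- ca[ca$chain == ch, ]
    cbind(m$x, m$y, m$z)
  })
  names(xyz_by) <- ids
  classes <- list()
  for (i in seq_along(ids)) for (j in seq_len(i - 1)) {
    ci <- info[info$chain == ids[i], ]; cj <- info[info$chain == ids[j], ]
    dmin <- sqrt(min(cross_dist2(xyz_by[[ids[i]]], xyz_by[[ids[j]]])))
    if (dmin > contact_cutoff) next
    relation <- if (ci$face != cj$face) "dihedral"
      else if (ci$copy != cj$copy) "cyclic"
      else "intra_trimer"
    sym <- if (ci$role == cj$role && seqs[ids[i]] == seqs[ids[j]])
      "symmetric" else "asymmetric"
    classes[[length(classes) + 1]] <- tibble(
      role_a = min(ci$role, cj$role), role_b = max(ci$role, cj$role),
      relation = relation, symmetry = sym, min_distance = dmin)
  }
  if (length(classes) == 0) {
    return(tibble(role_a = character(), role_b = character(),
                  relation = character(), symmetry = character(),
                  designed = logical(), min_distance = double()))
  }
  bind_rows(classes) |>
    group_by(.data$role_a, .data$role_b, .data$relation, .data$symmetry) |>
    summarise(min_distance = min(.data$min_distance), .groups = "drop") |>
    mutate(designed = .data$relation != "intra_trimer") |>
    arrange(desc(.data$designed), .data$relation, .data$role_a) |>
    select("role_a", "role_b", "relation", "symmetry", "designed",
           "min_distance")
}

#' Structured assembly report
#'
#' Chain and residue counts per face and role, symmetry closure, interface
#' classes and the dock parameters, as a serializable list.
#'
#' @param a A `bifacet_assembly` or crown structure.
#' @param contact_cutoff Contact threshold for interface classes.
#' @param tol Symmetry closure tolerance passed to [verify_symmetry()].
#' @return An `assembly_report` list.
#' @export
assembly_report <- function(a, contact_cutoff = 8, tol = 0.5) {
  pose <- attr(a, "pose")
  roles <- if ("face" %in% names(a)) addressable_roles(a) else
    a[a$atom == "CA", ] |>
      distinct(.data$role, .data$chain) |>
      group_by(.data$role) |>
      summarise(n_chains = dplyr::n(), .groups = "drop")
  res_counts <- a[a$atom == "CA", ] |>
    group_by(.data$chain) |>
    summarise(n_res = dplyr::n(), .groups = "drop")
  sym <- verify_symmetry(a, 5, tol = tol,
                         phi = pose$phi[1] %||% NULL,
                         z_offset = pose$z_offset[1] %||% NULL)
  classes <- if (all(c("face", "copy") %in% names(a)))
    count_designed_interface_classes(a, contact_cutoff) else NULL
  rep <- list(n_chains = length(chain_ids(a)),
              roles = roles,
              residue_counts = res_counts,
              symmetry = sym,
              interface_classes = classes,
              pose = pose)
  class(rep) <- "assembly_report"
  rep
}

#' @rdname assembly_report
#' @param rep An `assembly_report`.
#' @param path JSON output path.
#' @export
write_assembly_report <- function(rep, path) {
  jsonlite::write_json(unclass(rep), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", null = "null")
  invisible(path)
}

#' @rdname assembly_report
#' @export
read_assembly_report <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  rep <- list(n_chains = raw$n_chains,
              roles = as_tibble(raw$roles),
              residue_counts = as_tibble(raw$residue_counts),
              symmetry = as_tibble(raw$symmetry),
              interface_classes = if (!is.null(raw$interface_classes))
                as_tibble(raw$interface_classes) else NULL,
              pose = if (!is.null(raw$pose)) as_tibble(raw$pose) else NULL)
  class(rep) <- "assembly_report"
  rep
}

#' @export
print.assembly_report <- function(x, ...) {
  cat(sprintf("<assembly_report: %d chains>\n", x$n_chains))
  print(x$roles)
  print(x$symmetry)
  if (!is.null(x$interface_classes)) print(x$interface_classes)
  invisible(x)
}
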