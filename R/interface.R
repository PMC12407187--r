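#' Amino-acid categories used for interface biasing
#'
#' The fixed category sets used by the negative-design biasing schemes:
#' small (S, T, N, Q, V, I, L), bulky (F, Y, W), negatively charged (D, E)
#' and positively charged (R, H, K; histidine is treated as positively
#' charged, with no pH modeling).
#'
#' @return A named list of character vectors; the sets are pairwise
#'   disjoint.
#' @export
amino_categories <- function() {
  list(small = c("S", "T", "N", "Q", "V", "I", "L"),
       bulky = c("F", "Y", "W"),
       negative = c("D", "E"),
       positive = c("R", "H", "K"))
}

#' Allowed bias levels and their fold labels
#'
#' The additive-logit bias levels offered to the external sequence-design
#' tool are 0.1, 0.2, 0.69, 1.1 and 3.9. The conventional labels read 0.69
#' as a two-fold and 1.1 as a three-fold likelihood increase (consistent
#' with natural logarithms, exp(0.69) ~ 2 and exp(1.1) ~ 3); 3.9 is
#' labelled four-fold even though exp(3.9) is about 49 — the value is
#' emitted as listed, and `bias_fold_label()` surfaces the inconsistency in
#' its `log_consistent` column rather than silently correcting it.
#'
#' @export
bias_levels <- function() c(0.1, 0.2, 0.69, 1.1, 3.9)

#' @rdname bias_levels
#' @param level A bias level.
#' @return A one-row tibble: `level`, `fold_label` (NA for unlabelled
#'   levels), `log_consistent`.
#' @export
bias_fold_label <- function(level) {
  folds <- c(`0.69` = 2, `1.1` = 3, `3.9` = 4)
  lbl <- unname(folds[as.character(level)])
  tibble(level = level,
         fold_label = lbl,
         log_consistent = ifelse(is.na(lbl), NA,
                                 abs(exp(level) - lbl) / lbl <= 0.02))
}

#' Identify paired interface positions across the dihedral two-fold
#'
#' Collects every C-role and D-role position with a cross-interface CA
#' within `cutoff`, then pairs each C-side position with the D-side
#' position onto which it maps under the assembly's dihedral two-fold (the
#' nearest image after applying the flip), recording the overall pairing
#' rmsd. Interface membership is position-level: a position may contact
#' several partners but appears in at most one pair.
#'
#' @param assembly An assembly from [realize_dock()] (or any structure with
#'   C- and D-role chains; the two-fold transform is taken from the
#'   `two_fold` attribute when present and estimated numerically
#'   otherwise).
#' @param cutoff Contact cutoff in Angstrom (default 8).
#' @return An `interface_pairs` tibble with columns `chain_c`, `resi_c`,
#'   `chain_d`, `resi_d`, `distance` (displacement of the mapped image from
#'   its partner) and attributes `pairing_rmsd` and `cutoff`. Empty (with a
#'   warning) if no contacts lie within the cutoff.
#' @export
find_interface_pairs <- function(assembly, cutoff = 8) {
  ca <- assembly[assembly$atom == "CA", ]
  cc <- ca[ca$role == "C", ]
  dd <- ca[ca$role == "D", ]
  if (nrow(cc) == 0 || nrow(dd) == 0) {
    abort("assembly must contain both C-role and D-role chains")
  }
  cxyz <- cbind(cc$x, cc$y, cc$z)
  dxyz <- cbind(dd$x, dd$y, dd$z)
  d2 <- cross_dist2(cxyz, dxyz)
  c_int <- which(apply(d2, 1, min) <= cutoff^2)
  d_int <- which(apply(d2, 2, min) <= cutoff^2)
  empty <- tibble(chain_c = character(), resi_c = integer(),
                  chain_d = character(), resi_d = integer(),
                  distance = double())
  if (length(c_int) == 0) {
    warn("no cross-interface contacts within cutoff; returning empty map")
    return(structure(empty, class = c("interface_pairs", class(empty)),
                     pairing_rmsd = NA_real_, cutoff = cutoff))
  }
  m <- attr(assembly, "two_fold") %||% estimate_two_fold(assembly)
  mapped <- apply_transform(cxyz[c_int, , drop = FALSE], m)
  md <- cross_dist2(mapped, dxyz[d_int, , drop = FALSE])
  # greedy unique assignment by increasing displacement
  pairs <- empty
  while (nrow(md) > 0 && ncol(md) > 0 && is.finite(min(md))) {
    ix <- arrayInd(which.min(md), dim(md))
    i <- c_int[ix[1]]; j <- d_int[ix[2]]
    pairs <- bind_rows(pairs, tibble(
      chain_c = cc$chain[i], resi_c = cc$resi[i],
      chain_d = dd$chain[j], resi_d = dd$resi[j],
      distance = sqrt(md[ix[1], ix[2]])))
    md[ix[1], ] <- Inf
    md[, ix[2]] <- Inf
  }
  pairs <- arrange(pairs, .data$chain_c, .data$resi_c)
  structure(pairs, class = c("interface_pairs", class(empty)),
            pairing_rmsd = sqrt(mean(pairs$distance^2)), cutoff = cutoff)
}

# Estimate the dihedral two-fold of an assembly lacking a stored pose:
# z placement from the CA centroid, azimuth by numeric minimization of the
# re-paired rmsd.
estimate_two_fold <- function(assembly) {
  zc <- 2 * mean(assembly$z[assembly$atom == "CA"])
  obj <- function(psi) {
    repaired_rmsd(apply_transform(assembly, dihedral_transform(psi, zc)),
                  assembly)
  }
  grid <- seq(0, 360 - 1e-9, by = 5)
  vals <- map_dbl(grid, obj)
  g0 <- grid[which.min(vals)]
  opt <- optimize(obj, interval = c(g0 - 5, g0 + 5), tol = 1e-8)
  dihedral_transform(opt$minimum, zc)
}

#' Build biased sequence-design specifications for the two interface sides
#'
#' Emits one per-position additive-logit bias specification per interface
#' side. The `charges` scheme favours positively charged residues (R, H, K)
#' on the first side and negatively charged (D, E) on the other; `clashes`
#' favours small residues on the first side and bulky on the other;
#' `charges-clashes` favours positive-and-bulky versus
#' negative-and-small. Every interface position on a side receives `+level`
#' for each favoured letter; no negative biases are emitted (both sides are
#' biased positively).
#'
#' @param pairs An [find_interface_pairs()] map.
#' @param scheme One of `"charges"`, `"clashes"`, `"charges-clashes"`.
#' @param level One of [bias_levels()].
#' @param side_assignment `"C_first"` (default) applies the scheme's first
#'   category set to the C side; `"D_first"` swaps the two sides.
#' @return A named list of two `bias_spec` tibbles (`C` and `D`), each with
#'   columns `chain`, `resi`, `aa`, `bias` and attributes `scheme`,
#'   `level`, `side`.
#' @export
make_bias_spec <- function(pairs, scheme = c("charges", "clashes",
                                             "charges-clashes"),
                           level, side_assignment = c("C_first", "D_first")) {
  scheme <- match.arg(scheme)
  side_assignment <- match.arg(side_assignment)
  if (!level %in% bias_levels()) {
    abort(paste0("level must be one of ",
                 paste(bias_levels(), collapse = ", ")))
  }
  cats <- amino_categories()
  sets <- switch(scheme,
    "charges" = list(first = cats$positive, second = cats$negative),
    "clashes" = list(first = cats$small, second = cats$bulky),
    "charges-clashes" = list(first = c(cats$positive, cats$bulky),
                             second = c(cats$negative, cats$small)))
  if (side_assignment == "D_first") sets <- list(first = sets$second,
                                                 second = sets$first)
  side_spec <- function(chain_col, resi_col, letters, side) {
    pos <- distinct(tibble(chain = pairs[[chain_col]],
                           resi = pairs[[resi_col]]))
    spec <- tidyr::expand_grid(pos, aa = letters)
    spec$bias <- rep(level, nrow(spec))
    structure(spec, class = c("bias_spec", class(tibble())),
              scheme = scheme, level = level, side = side)
  }
  list(C = side_spec("chain_c", "resi_c", sets$first, "C"),
       D = side_spec("chain_d", "resi_d", sets$second, "D"))
}

#' Write / read a bias specification
#'
#' Serializes a bias spec in the external design tool's per-residue bias
#' dictionary dialect: a JSON object keyed by chain, then by residue index,
#' holding a 20-letter vector of additive logits (zero for unbiased
#' letters).
#'
#' @param spec A `bias_spec` tibble (one side) from [make_bias_spec()].
#' @param path Output JSON path.
#' @export
write_bias_spec <- function(spec, path) {
  out <- list()
  for (ch in unique(spec$chain)) {
    rows <- spec[spec$chain == ch, ]
    per_res <- list()
    for (r in unique(rows$resi)) {
      v <- setNames(rep(0, 20), canonical_aa())
      sel <- rows[rows$resi == r, ]
      v[sel$aa] <- sel$bias
      per_res[[as.character(r)]] <- v
    }
    out[[ch]] <- per_res
  }
  jsonlite::write_json(out, path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_bias_spec
#' @export
read_bias_spec <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  rows <- list()
  for (ch in names(raw)) {
    for (r in names(raw[[ch]])) {
      # vectors are stored in canonical letter order (names are not
      # preserved by the array serialization)
      v <- setNames(unlist(raw[[ch]][[r]]), canonical_aa())
      nz <- v[v != 0]
      if (length(nz) > 0) {
        rows[[length(rows) + 1]] <- tibble(chain = ch, resi = as.integer(r),
                                           aa = names(nz), bias = unname(nz))
      }
    }
  }
  out <- if (length(rows) > 0) bind_rows(rows) else
    tibble(chain = character(), resi = integer(), aa = character(),
           bias = double())
  structure(out, class = c("bias_spec", class(tibble())))
}

#' Enumerate biased and unbiased sequence-design jobs
#'
#' Builds the job manifest for asymmetric interface design: one job per
#' (scheme, level, temperature) combination plus one unbiased job per
#' temperature, each requesting `n_seq` sequences. With the default three
#' schemes, five levels and seven temperatures this is 105 biased plus 7
#' unbiased jobs. When `dir` is given the per-job bias specifications are
#' written there and their paths recorded.
#'
#' @param pairs An interface pair map.
#' @param schemes Biasing schemes to enumerate.
#' @param levels Bias levels to enumerate.
#' @param temperatures Sampling temperatures.
#' @param n_seq Sequences requested per job (default 100).
#' @param dir Optional output directory for spec files.
#' @return A `design_jobs` tibble.
#' @export
enumerate_design_jobs <- function(pairs,
                                  schemes = c("charges", "clashes",
                                              "charges-clashes"),
                                  levels = bias_levels(),
                                  temperatures = c(0.1, 0.2, 0.4, 0.5,
                                                   0.6, 0.8, 1.0),
                                  n_seq = 100, dir = NULL) {
  biased <- tidyr::expand_grid(scheme = schemes, level = levels,
                               temperature = temperatures)
  unbiased <- tibble(scheme = "unbiased", level = NA_real_,
                     temperature = temperatures)
  jobs <- bind_rows(biased, unbiased)
  jobs$n_seq <- as.integer(n_seq)
  jobs$job_id <- sprintf("job_%03d", seq_len(nrow(jobs)))
  jobs$spec_path_c <- NA_character_
  jobs$spec_path_d <- NA_character_
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    for (i in which(jobs$scheme != "unbiased")) {
      spec <- make_bias_spec(pairs, jobs$scheme[i], jobs$level[i])
      base <- file.path(dir, paste0(jobs$job_id[i]))
      write_bias_spec(spec$C, paste0(base, "_C.json"))
      write_bias_spec(spec$D, paste0(base, "_D.json"))
      jobs$spec_path_c[i] <- paste0(base, "_C.json")
      jobs$spec_path_d[i] <- paste0(base, "_D.json")
    }
  }
  jobs <- jobs[, c("job_id", "scheme", "level", "temperature", "n_seq",
                   "spec_path_c", "spec_path_d")]
  class(jobs) <- c("design_jobs", class(jobs))
  jobs
}

#' @rdname enumerate_design_jobs
#' @param jobs A `design_jobs` tibble.
#' @param path Manifest TSV path.
#' @export
write_job_manifest <- function(jobs, path) {
  readr::write_tsv(as_tibble(jobs), path)
  invisible(path)
}

#' @rdname enumerate_design_jobs
#' @export
read_job_manifest <- function(path) {
  jobs <- readr::read_tsv(path, show_col_types = FALSE,
                          col_types = readr::cols(
                            job_id = "c", scheme = "c", level = "d",
                            temperature = "d", n_seq = "i",
                            spec_path_c = "c", spec_path_d = "c"))
  class(jobs) <- c("design_jobs", class(jobs))
  jobs
}

#' Emit a multistate sequence-design specification
#'
#' Defines the explicit negative-design problem: one on-target state (the
#' C-D interface, weight +1) and two off-target states (the hypothetical
#' C-C and D-D homodimeric interfaces, each weighted `beta < 0`). The
#' off-target state geometries pair each side with its own two-fold image.
#'
#' @param assembly An assembly with C- and D-role chains.
#' @param pairs The interface pair map.
#' @param beta Off-target state weight; one of -1, -0.5, -0.25 (any
#'   negative value is accepted with a warning).
#' @param path Optional JSON output path.
#' @return A `multistate_spec` list (invisibly writes `path` if given).
#' @export
emit_multistate_spec <- function(assembly, pairs, beta, path = NULL) {
  if (beta >= 0) abort("beta must be negative")
  if (!beta %in% c(-1, -0.5, -0.25)) {
    warn("beta is outside the standard set (-1, -0.5, -0.25)")
  }
  c_pos <- distinct(tibble(chain = pairs$chain_c, resi = pairs$resi_c))
  d_pos <- distinct(tibble(chain = pairs$chain_d, resi = pairs$resi_d))
  spec <- list(
    beta = beta,
    states = list(
      list(name = "CD", kind = "on_target", weight = 1,
           side_a = c_pos, side_b = d_pos),
      list(name = "CC", kind = "off_target", weight = beta,
           side_a = c_pos, side_b = c_pos),
      list(name = "DD", kind = "off_target", weight = beta,
           side_a = d_pos, side_b = d_pos)))
  class(spec) <- "multistate_spec"
  if (!is.null(path)) {
    jsonlite::write_json(unclass(spec), path, auto_unbox = TRUE, digits = NA,
                         dataframe = "columns")
  }
  invisible(spec)
}

#' @rdname emit_multistate_spec
#' @export
read_multistate_spec <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  side_tbl <- function(side) {
    tibble(chain = unlist(side$chain), resi = as.integer(unlist(side$resi)))
  }
  spec <- list(beta = raw$beta,
               states = purrr::map(raw$states, function(st) {
                 list(name = st$name, kind = st$kind, weight = st$weight,
                      side_a = side_tbl(st$side_a),
                      side_b = side_tbl(st$side_b))
               }))
  class(spec) <- "multistate_spec"
  spec
}

#' Extract the terminal helical fragment of a chain
#'
#' Returns the sub-chain from the start of the n-th-from-last helix through
#' the C terminus, renumbered from 1, with helix annotations carried over.
#' This is the fragment submitted to structure prediction when validating
#' interface designs (five C-terminal helices by default).
#'
#' @param chain A single-chain structure with helix annotations.
#' @param n_helices Number of terminal helices to keep (default 5).
#' @return A single-chain structure.
#' @export
extract_terminal_fragment <- function(chain, n_helices = 5) {
  if (length(chain_ids(chain)) != 1) {
    abort("extract_terminal_fragment expects a single chain")
  }
  hr <- chain_helix_ranges(chain)
  if (nrow(hr) == 0) hr <- segment_helices(chain)
  if (nrow(hr) < n_helices) {
    abort(sprintf("chain has %d helices but %d were requested",
                  nrow(hr), n_helices))
  }
  start <- hr$start[nrow(hr) - n_helices + 1]
  out <- chain[chain$resi >= start, ]
  out$resi <- out$resi - start + 1L
  out$helix <- out$helix - min(out$helix, na.rm = TRUE) + 1L
  class(out) <- class(chain)
  out
}
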