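#' Cut the loop preceding the last two helices of a C subunit
#'
#' Severs the loop before the last two helices so the interface-forming
#' C-terminal helices can stay fixed while the rest of the subunit is
#' moved. The cut point is the midpoint residue of the severed loop, so
#' downstream numbering is reproducible.
#'
#' @param c_chain A single-chain structure with at least 3 helices and a
#'   loop before the last two.
#' @return A list with `body` and `interface_fragment` (tibbles of
#'   `(chain, resi)` selections partitioning the chain) and `cut_point`.
#' @export
cut_terminal_loop <- function(c_chain) {
  if (length(chain_ids(c_chain)) != 1) {
    abort("cut_terminal_loop expects a single chain")
  }
  hr <- chain_helix_ranges(c_chain)
  if (nrow(hr) == 0) hr <- segment_helices(c_chain)
  if (nrow(hr) < 3) abort("chain must have at least 3 helices")
  h_before <- hr[nrow(hr) - 2, ]
  h_first_kept <- hr[nrow(hr) - 1, ]
  if (h_first_kept$start - h_before$end <= 1) {
    abort("no loop between the last two helices and the preceding helix")
  }
  loop <- seq(h_before$end + 1, h_first_kept$start - 1)
  cut_point <- loop[floor((length(loop) + 1) / 2)]
  resi <- unique(c_chain$resi[c_chain$atom == "CA"])
  ch <- chain_ids(c_chain)
  list(body = tibble(chain = ch, resi = resi[resi <= cut_point]),
       interface_fragment = tibble(chain = ch, resi = resi[resi > cut_point]),
       cut_point = cut_point)
}

#' Define an extended (or rotated) target architecture
#'
#' Builds a target for de novo subunit extension: everything on the first
#' (ABC) face except the interface fragments of its C subunits (their last
#' two helices plus anything C-terminal) is rotated by `rho` about the
#' five-fold axis and translated `d` Angstrom along it, leaving the
#' designed asymmetric C-D interface bit-identical. The rotation is applied
#' about the global z axis before the translation (the two commute for a
#' rotation about the translation axis).
#'
#' @param assembly A realized two-ring assembly with a `face` column.
#' @param d Translation along z, Angstrom; the preset architectures use
#'   25, 50, 75 and 100 (0 is allowed as an explicit identity override).
#' @param rho Rotation about z, degrees (0 or 25 in the presets).
#' @return A list with `target` (an `extension_target`) and `structure`
#'   (the transformed assembly).
#' @export
make_extension_target <- function(assembly, d, rho = 0) {
  if (d < 0) abort("extension distance d must be >= 0")
  if (!"face" %in% names(assembly)) {
    abort("assembly must carry a `face` column (see realize_dock)")
  }
  c_chains <- unique(assembly$chain[assembly$role == "C" &
                                      assembly$face == 1])
  if (length(c_chains) == 0) abort("no C-role chains on face 1")
  cuts <- map(c_chains, function(ch) cut_terminal_loop(get_chain(assembly, ch)))
  names(cuts) <- c_chains
  frag_key <- bind_rows(map(cuts, "interface_fragment"))
  is_frag <- paste(assembly$chain, assembly$resi) %in%
    paste(frag_key$chain, frag_key$resi)
  moved <- assembly$face == 1 & !is_frag
  tf <- transform_compose(translation(c(0, 0, d)), rot_z(rho))
  xyz <- cbind(assembly$x, assembly$y, assembly$z)
  xyz[moved, ] <- apply_transform(xyz[moved, , drop = FALSE], tf)
  out <- assembly
  out$x <- xyz[, 1]; out$y <- xyz[, 2]; out$z <- xyz[, 3]
  target <- structure(list(
    distance_d = d, rotation_rho = rho,
    cut_points = map_int(cuts, function(x) as.integer(x$cut_point)),
    moved_selection = distinct(tibble(chain = assembly$chain[moved],
                                      resi = assembly$resi[moved])),
    transform = tf), class = "extension_target")
  list(target = target, structure = out)
}

# Insert-length lookup for the preset extension architectures.
extension_insert_table <- function() {
  tibble(d = c(25, 50, 75, 100, 50),
         rho = c(0, 0, 0, 0, 25),
         min_res = c(50, 100, 150, 250, 150),
         max_res = c(150, 250, 350, 400, 350))
}

#' Emit the contig specification for an extension target
#'
#' Looks up the insert-length range for the target's `(d, rho)`
#' architecture: 50-150, 100-250, 150-350 and 250-400 residues for 25, 50,
#' 75 and 100 Angstrom extensions, and 150-350 for the 50 Angstrom + 25
#' degree rotated target. Targets outside the preset table require an
#' explicit `insert_range`. The reduced diffusion input comprises the last
#' four helices of the translated body portion of the C subunit (the four
#' nearest the opened gap) plus the two fixed interface helices.
#'
#' @param target An `extension_target`.
#' @param assembly The assembly the target was made from (used to resolve
#'   helix annotations for the reduced input selection).
#' @param insert_range Optional explicit `(min, max)` insert length.
#' @return A `contig_spec` list: `fixed_segments`, `insert_length_range`,
#'   `reduced_input_selection` and a contig string per C subunit.
#' @export
emit_contig_spec <- function(target, assembly = NULL, insert_range = NULL) {
  if (!inherits(target, "extension_target")) {
    abort("`target` must be an extension_target")
  }
  if (is.null(insert_range)) {
    tab <- extension_insert_table()
    hit <- tab[tab$d == target$distance_d & tab$rho == target$rotation_rho, ]
    if (nrow(hit) == 0) {
      abort(sprintf(paste0("no preset insert range for d = %g, rho = %g; ",
                           "supply `insert_range` explicitly"),
                    target$distance_d, target$rotation_rho))
    }
    insert_range <- c(hit$min_res[1], hit$max_res[1])
  }
  if (insert_range[1] > insert_range[2]) {
    abort("insert range minimum exceeds maximum")
  }
  c_chains <- names(target$cut_points)
  fixed <- list(); reduced <- list(); contig <- character()
  for (ch in c_chains) {
    cut <- target$cut_points[[ch]]
    if (!is.null(assembly)) {
      hr <- chain_helix_ranges(assembly[assembly$chain == ch, ])
      body_h <- hr[hr$end <= cut, ]
      iface_h <- hr[hr$start > cut, ]
      last4 <- tail(body_h, 4)
      reduced[[ch]] <- tibble(chain = ch,
                              start = c(last4$start, iface_h$start),
                              end = c(last4$end, iface_h$end),
                              part = c(rep("body", nrow(last4)),
                                       rep("interface", nrow(iface_h))))
    }
    res <- if (!is.null(assembly)) {
      sort(unique(assembly$resi[assembly$chain == ch]))
    } else NULL
    last_res <- if (is.null(res)) NA_integer_ else max(res)
    fixed[[ch]] <- tibble(chain = ch,
                          start = c(1L, cut + 1L),
                          end = c(cut, last_res))
    contig <- c(contig, sprintf("%s1-%d/%d-%d/%s%d-%s", ch, cut,
                                insert_range[1], insert_range[2],
                                ch, cut + 1,
                                ifelse(is.na(last_res), "end", last_res)))
  }
  structure(list(fixed_segments = bind_rows(fixed),
                 insert_length_range = insert_range,
                 reduced_input_selection = if (length(reduced) > 0)
                   bind_rows(reduced) else NULL,
                 contig_strings = contig),
            class = "contig_spec")
}

#' Define a terminus-reorientation target with block adjacency
#'
#' Builds the specification used to reorient chain termini: a permuted
#' helix order with one optional inserted helix, a symmetric binary
#' adjacency matrix over helices stating which must pack together, and the
#' loops deleted by the reordering. When no explicit contacts are given the
#' adjacency of the existing helices is their geometric contact map
#' (minimum CA-CA distance below `contact_cutoff`).
#'
#' @param chain A single-chain structure with helix annotations.
#' @param new_order Permutation of the helix indices `1..H`, optionally
#'   including the value `H + 1` for one inserted helix.
#' @param new_helix_length Length of the inserted helix, residues.
#' @param contacts List of 2-element helix-index vectors that must be in
#'   contact (used for the inserted helix; self-contacts are rejected).
#' @param contact_cutoff Geometric contact threshold, Angstrom.
#' @return An `adjacency_target` list: `helix_order`, `new_helix_length`,
#'   `adjacency` (binary symmetric matrix), `deleted_loops`.
#' @export
make_adjacency_target <- function(chain, new_order = NULL,
                                  new_helix_length = 14, contacts = NULL,
                                  contact_cutoff = 10) {
  hr <- chain_helix_ranges(chain)
  if (nrow(hr) == 0) hr <- segment_helices(chain)
  h <- nrow(hr)
  if (h < 2) abort("chain must have at least 2 helices")
  if (is.null(new_order)) new_order <- seq_len(h)
  has_new <- (h + 1) %in% new_order
  if (!setequal(setdiff(new_order, h + 1), seq_len(h)) ||
      anyDuplicated(new_order) > 0) {
    abort("new_order must be a permutation of 1..H, optionally with H + 1")
  }
  n_tot <- h + as.integer(has_new)
  adj <- matrix(0L, n_tot, n_tot)
  # geometric contact map over the existing helices
  ca <- chain[chain$atom == "CA", ]
  for (i in seq_len(h - 1)) for (j in seq(i + 1, h)) {
    a <- ca[ca$resi >= hr$start[i] & ca$resi <= hr$end[i], ]
    b <- ca[ca$resi >= hr$start[j] & ca$resi <= hr$end[j], ]
    dmin <- sqrt(min(cross_dist2(cbind(a$x, a$y, a$z),
                                 cbind(b$x, b$y, b$z))))
    if (dmin < contact_cutoff) adj[i, j] <- adj[j, i] <- 1L
  }
  for (p in contacts %||% list()) {
    if (length(p) != 2) abort("contacts must be 2-element index pairs")
    if (p[1] == p[2]) abort("a helix cannot be required to contact itself")
    if (any(p > n_tot) || any(p < 1)) abort("contact index out of range")
    adj[p[1], p[2]] <- adj[p[2], p[1]] <- 1L
  }
  # the loop after helix i survives only when helix i+1 still directly
  # follows it in the new order (a reversed pair needs a rebuilt loop)
  ord_pos <- match(seq_len(h), new_order)
  deleted <- purrr::map_dfr(seq_len(h - 1), function(i) {
    still_adjacent <- ord_pos[i + 1] == ord_pos[i] + 1
    if (still_adjacent) return(NULL)
    tibble(after_helix = i, start = hr$end[i] + 1L,
           end = hr$start[i + 1] - 1L)
  })
  structure(list(helix_order = new_order,
                 new_helix_length = as.integer(new_helix_length),
                 adjacency = adj,
                 deleted_loops = deleted),
            class = "adjacency_target")
}

#' Emit backbone-diffusion job manifests
#'
#' One manifest entry per target, carrying the target type, its defining
#' parameters, the requested backbone count (100 by default) and, when
#' `dir` is given, the paths of the written input coordinate and
#' specification files.
#'
#' @param targets An `extension_target`/`adjacency_target` or list of them.
#' @param n_backbones Backbones requested per job.
#' @param dir Optional output directory for spec files.
#' @param structures Optional list of structures (parallel to `targets`)
#'   written as input coordinate files.
#' @return A `diffusion_jobs` tibble.
#' @export
emit_diffusion_job <- function(targets, n_backbones = 100, dir = NULL,
                               structures = NULL) {
  if (inherits(targets, c("extension_target", "adjacency_target"))) {
    targets <- list(targets)
  }
  jobs <- purrr::imap_dfr(targets, function(tg, i) {
    if (inherits(tg, "extension_target")) {
      tibble(job_id = sprintf("diff_%03d", i), target_type = "extension",
             d = tg$distance_d, rho = tg$rotation_rho,
             new_helix_length = NA_integer_,
             n_backbones = as.integer(n_backbones))
    } else {
      tibble(job_id = sprintf("diff_%03d", i), target_type = "adjacency",
             d = NA_real_, rho = NA_real_,
             new_helix_length = tg$new_helix_length,
             n_backbones = as.integer(n_backbones))
    }
  })
  jobs$input_path <- NA_character_
  jobs$spec_path <- NA_character_
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    for (i in seq_along(targets)) {
      spec_path <- file.path(dir, paste0(jobs$job_id[i], "_spec.json"))
      tg <- targets[[i]]
      payload <- if (inherits(tg, "extension_target")) {
        list(type = "extension", d = tg$distance_d, rho = tg$rotation_rho,
             cut_points = as.list(tg$cut_points))
      } else {
        list(type = "adjacency", helix_order = tg$helix_order,
             new_helix_length = tg$new_helix_length,
             adjacency = tg$adjacency)
      }
      jsonlite::write_json(payload, spec_path, auto_unbox = TRUE, digits = NA)
      jobs$spec_path[i] <- spec_path
      if (!is.null(structures) && !is.null(structures[[i]])) {
        pdb_path <- file.path(dir, paste0(jobs$job_id[i], "_input.pdb"))
        write_structure(structures[[i]], pdb_path)
        jobs$input_path[i] <- pdb_path
      }
    }
  }
  class(jobs) <- c("diffusion_jobs", class(jobs))
  jobs
}

#' @rdname emit_diffusion_job
#' @param jobs A `diffusion_jobs` tibble.
#' @param path Manifest TSV path.
#' @export
write_diffusion_manifest <- function(jobs, path) {
  readr::write_tsv(as_tibble(jobs), path)
  invisible(path)
}

#' @rdname emit_diffusion_job
#' @export
read_diffusion_manifest <- function(path) {
  jobs <- readr::read_tsv(path, show_col_types = FALSE,
                          col_types = readr::cols(
                            job_id = "c", target_type = "c", d = "d",
                            rho = "d", new_helix_length = "i",
                            n_backbones = "i", input_path = "c",
                            spec_path = "c"))
  class(jobs) <- c("diffusion_jobs", class(jobs))
  jobs
}

#' Write an adjacency matrix file
#'
#' Whitespace-delimited 0/1 matrix with a helix-index header row, the
#' format consumed by block-adjacency backbone generation.
#'
#' @param target An `adjacency_target`.
#' @param path Output path.
#' @export
write_adjacency_matrix <- function(target, path) {
  m <- target$adjacency
  lines <- c(paste(seq_len(ncol(m)), collapse = " "),
             apply(m, 1, paste, collapse = " "))
  writeLines(lines, path)
  invisible(path)
}
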