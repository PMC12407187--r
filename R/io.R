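#' Read a macromolecular coordinate file
#'
#' Parses a PDB (or mmCIF) file into a [new_structure()] tibble. All chains
#' and atoms present in the file are represented; residue indices are taken
#' from author numbering. Entity roles are recovered from the PDB `segid`
#' field when it is one of `A`, `B`, `C`, `D` (the convention used by
#' [write_structure()]); otherwise the role is `"other"`. Helix annotations
#' are recovered from `HELIX` records when present.
#'
#' @param path File path.
#' @param format `"pdb"` or `"mmcif"`.
#' @return A `bifacet_structure`.
#' @export
read_structure <- function(path, format = c("pdb", "mmcif")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  pdb <- tryCatch(
    if (format == "pdb") bio3d::read.pdb(path, verbose = FALSE)
    else bio3d::read.cif(path, verbose = FALSE),
    error = function(e) abort(paste0("could not parse ", format, " file ",
                                     path, ": ", conditionMessage(e))))
  at <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0) abort(paste0("no ATOM records in ", path))
  aa1 <- suppressWarnings(bio3d::aa321(at$resid))
  aa1[is.na(aa1) | !aa1 %in% canonical_aa()] <- "X"
  role <- ifelse(!is.na(at$segid) & at$segid %in% c("A", "B", "C", "D"),
                 at$segid, "other")
  chain <- ifelse(is.na(at$chain) | at$chain == "", "A", at$chain)
  s <- tibble(
    chain = chain,
    role = role,
    resi = as.integer(at$resno),
    aa = aa1,
    atom = at$elety,
    element = ifelse(is.na(at$elesy) | at$elesy == "",
                     substr(at$elety, 1, 1), at$elesy),
    x = at$x, y = at$y, z = at$z,
    helix = NA_integer_
  )
  # recover helix annotations from HELIX records, numbering per chain
  hx <- pdb$helix
  if (!is.null(hx) && length(hx$start) > 0) {
    htab <- tibble(chain = hx$chain,
                   start = as.integer(hx$start),
                   end = as.integer(hx$end)) |>
      arrange(.data$chain, .data$start) |>
      group_by(.data$chain) |>
      mutate(helix_id = row_number()) |>
      ungroup()
    for (i in seq_len(nrow(htab))) {
      sel <- s$chain == htab$chain[i] &
        s$resi >= htab$start[i] & s$resi <= htab$end[i]
      s$helix[sel] <- htab$helix_id[i]
    }
  }
  # CA completeness check with an informative listing
  miss <- s |>
    group_by(.data$chain, .data$resi) |>
    summarise(has_ca = any(.data$atom == "CA"), .groups = "drop") |>
    filter(!.data$has_ca)
  if (nrow(miss) > 0) {
    abort(paste0("residues without CA atom: ",
                 paste(paste0(miss$chain, ":", miss$resi), collapse = ", ")))
  }
  new_structure(s)
}

#' Write a structure to a coordinate file
#'
#' Emits strict-columnar PDB `ATOM` records (single model, no altlocs).
#' Entity roles are stored in the `segid` field and `HELIX` records are
#' written for annotated helices, so files round-trip through
#' [read_structure()]. Writing requires at most 62 chains (the
#' single-character PDB chain-ID space); larger assemblies raise a capacity
#' error.
#'
#' @param s A structure.
#' @param path Output file path.
#' @param format Only `"pdb"` is supported for writing.
#' @return `path`, invisibly.
#' @export
write_structure <- function(s, path, format = c("pdb", "mmcif")) {
  format <- match.arg(format)
  if (format == "mmcif") {
    abort("mmCIF writing is not supported; use format = \"pdb\"")
  }
  if (!is_structure(s)) abort("`s` must be a bifacet_structure")
  if (nrow(s) == 0) abort("cannot write an empty structure")
  ids <- s$chain[!duplicated(s$chain)]
  # duplicate chain ids = id re-appearing after another chain intervened
  runs <- rle(s$chain)$values
  if (anyDuplicated(runs) > 0) {
    abort("duplicate chain identifiers; relabel before writing")
  }
  if (length(ids) > 62) {
    abort("more than 62 chains cannot be written in the strict PDB dialect")
  }
  if (any(nchar(ids) != 1)) abort("PDB chain identifiers must be single characters")
  validate_structure(s)
  aa3 <- bio3d::aa123(s$aa)
  aa3[s$aa == "X"] <- "UNK"
  bio3d::write.pdb(
    file = path,
    xyz = as.numeric(t(cbind(s$x, s$y, s$z))),
    resno = s$resi,
    resid = aa3,
    chain = s$chain,
    elety = s$atom,
    eleno = seq_len(nrow(s)),
    segid = s$role,
    elesy = s$element,
    o = rep(1, nrow(s)), b = rep(0, nrow(s))
  )
  # bio3d leaves the segid columns (73-76) blank: inject the entity role
  # there so it round-trips
  lines <- readLines(path)
  atom_ix <- grep("^ATOM", lines)
  seg <- sprintf("%-4s", s$role)
  for (k in seq_along(atom_ix)) {
    ln <- lines[atom_ix[k]]
    if (nchar(ln) < 76) ln <- formatC(ln, width = -76)
    substr(ln, 73, 76) <- seg[k]
    lines[atom_ix[k]] <- ln
  }
  writeLines(lines, path)

  # prepend HELIX records (bio3d does not emit secondary structure)
  hx <- purrr::map_dfr(chain_ids(s), function(ch) {
    hr <- helix_ranges(s, ch)
    if (nrow(hr) == 0) return(NULL)
    hr$chain <- ch
    hr
  })
  if (nrow(hx) > 0) {
    recs <- sprintf(
      "HELIX  %3d %3s ALA %s %4d  ALA %s %4d  1%36d",
      seq_len(nrow(hx)), sprintf("H%02d", seq_len(nrow(hx)) %% 100),
      hx$chain, hx$start, hx$chain, hx$end,
      hx$end - hx$start + 1)
    body <- readLines(path)
    writeLines(c(recs, body), path)
  }
  invisible(path)
}
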