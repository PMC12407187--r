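#' Negative-design filter thresholds
#'
#' Thresholds of the decision procedure applied to structure-prediction
#' confidence metrics. A design passes when its on-target (C-D) prediction
#' is confident (rmsd below `on_rmsd_max`, mean pAE interaction below
#' `on_pae_max`, pLDDT above `on_plddt_min`), neither off-target (C-C or
#' D-D) prediction is confident (all three of its conditions met
#' simultaneously), and the pAE-interaction gap between off- and on-target
#' exceeds `pae_gap_min`. All comparisons are strict, so boundary values
#' fail.
#'
#' @param on_rmsd_max,on_pae_max,on_plddt_min On-target thresholds
#'   (2.0 Angstrom, 10, 90).
#' @param off_rmsd_max,off_pae_max,off_plddt_min Off-target-rejection
#'   thresholds (2.0 Angstrom, 10, 95).
#' @param pae_gap_min Required mean-pAE-interaction gap (10).
#' @export
filter_thresholds <- function(on_rmsd_max = 2.0, on_pae_max = 10,
                              on_plddt_min = 90, off_rmsd_max = 2.0,
                              off_pae_max = 10, off_plddt_min = 95,
                              pae_gap_min = 10) {
  th <- list(on_rmsd_max = on_rmsd_max, on_pae_max = on_pae_max,
             on_plddt_min = on_plddt_min, off_rmsd_max = off_rmsd_max,
             off_pae_max = off_pae_max, off_plddt_min = off_plddt_min,
             pae_gap_min = pae_gap_min)
  if (any(unlist(th) <= 0)) abort("all thresholds must be positive")
  structure(th, class = "filter_thresholds")
}

#' Construct a metric record
#'
#' One structure-prediction confidence record for a design/interface pair:
#' CA rmsd to the design model (Angstrom), mean predicted aligned error for
#' the interchain interactions (0-30 scale) and pLDDT (0-100 scale).
#'
#' @param design_id Design identifier.
#' @param interface One of `"CD"`, `"CC"`, `"DD"`.
#' @param rmsd,pae_interaction,plddt Metric values.
#' @export
metric_record <- function(design_id, interface, rmsd, pae_interaction,
                          plddt) {
  if (!interface %in% c("CD", "CC", "DD")) {
    abort("interface must be one of CD, CC, DD")
  }
  if (rmsd < 0 || pae_interaction < 0 || plddt < 0 || plddt > 100) {
    abort("metric values out of range")
  }
  tibble(design_id = design_id, interface = interface, rmsd = rmsd,
         pae_interaction = pae_interaction, plddt = plddt)
}

#' Evaluate one design against the negative-design filter
#'
#' @param cd,cc,dd Metric records (one-row data frames from
#'   [metric_record()] or equivalent) for the on-target C-D and off-target
#'   C-C and D-D interfaces of the same design.
#' @param thresholds A [filter_thresholds()].
#' @param gap_mode `"both"` (default) requires the pAE gap against both
#'   off-targets; `"any"` accepts a gap against either.
#' @return A one-row `filter_verdict` tibble with `design_id`, `passed`,
#'   and `reasons` (list-column of rule identifiers, empty iff passed).
#' @examples
#' v <- evaluate_design(
#'   metric_record("d1", "CD", 1.0, 5, 95),
#'   metric_record("d1", "CC", 5.0, 25, 70),
#'   metric_record("d1", "DD", 6.0, 28, 60))
#' v$passed
#' @export
evaluate_design <- function(cd, cc, dd, thresholds = filter_thresholds(),
                            gap_mode = c("both", "any")) {
  gap_mode <- match.arg(gap_mode)
  if (length(unique(c(cd$design_id, cc$design_id, dd$design_id))) != 1) {
    abort("metric records belong to different designs")
  }
  if (cd$interface != "CD" || cc$interface != "CC" || dd$interface != "DD") {
    abort("metric records are mislabeled; expected CD, CC, DD")
  }
  th <- thresholds
  reasons <- character()
  on_ok <- cd$rmsd < th$on_rmsd_max &&
    cd$pae_interaction < th$on_pae_max &&
    cd$plddt > th$on_plddt_min
  if (!on_ok) reasons <- c(reasons, "on_target_fail")
  off_predicted <- function(r) {
    r$rmsd < th$off_rmsd_max && r$pae_interaction < th$off_pae_max &&
      r$plddt > th$off_plddt_min
  }
  if (off_predicted(cc)) reasons <- c(reasons, "off_target_CC_predicted")
  if (off_predicted(dd)) reasons <- c(reasons, "off_target_DD_predicted")
  gap_cc <- cc$pae_interaction - cd$pae_interaction > th$pae_gap_min
  gap_dd <- dd$pae_interaction - cd$pae_interaction > th$pae_gap_min
  gap_ok <- if (gap_mode == "both") gap_cc && gap_dd else gap_cc || gap_dd
  if (!gap_ok) reasons <- c(reasons, "gap_fail")
  out <- tibble(design_id = cd$design_id,
                passed = length(reasons) == 0,
                reasons = list(reasons))
  class(out) <- c("filter_verdict", class(out))
  out
}

#' Filter a batch of designs
#'
#' Applies [evaluate_design()] to every design in a long metric table with
#' columns `design_id`, `interface`, `rmsd`, `pae_interaction`, `plddt`.
#' Designs with missing or duplicated interface rows receive a per-design
#' error entry rather than aborting the batch. pLDDT tables on the 0-1
#' scale are auto-detected (every value at most 1) and rescaled to 0-100
#' with a warning.
#'
#' @param records Long metric tibble (or data frame).
#' @inheritParams evaluate_design
#' @return A `filter_verdicts` tibble ordered by `design_id`, with columns
#'   `design_id`, `passed`, `reasons`, `error`; use [glance()] for the
#'   summary counts.
#' @export
filter_batch <- function(records, thresholds = filter_thresholds(),
                         gap_mode = c("both", "any")) {
  gap_mode <- match.arg(gap_mode)
  records <- as_tibble(records)
  needed <- c("design_id", "interface", "rmsd", "pae_interaction", "plddt")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols) > 0) {
    abort(paste0("metric table is missing columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (nrow(records) > 0 && all(records$plddt <= 1)) {
    warn("pLDDT values look 0-1 scaled; rescaling to 0-100")
    records$plddt <- records$plddt * 100
  }
  ids <- sort(unique(records$design_id))
  if (length(ids) == 0) {
    out <- tibble(design_id = character(), passed = logical(),
                  reasons = list(), error = character())
    class(out) <- c("filter_verdicts", class(out))
    return(out)
  }
  out <- purrr::map_dfr(ids, function(id) {
    rows <- records[records$design_id == id, ]
    counts <- table(factor(rows$interface, levels = c("CD", "CC", "DD")))
    if (any(counts != 1)) {
      bad <- names(counts)[counts != 1]
      return(tibble(design_id = id, passed = NA,
                    reasons = list(character()),
                    error = paste0("expected one row per interface; bad: ",
                                   paste(bad, collapse = ", "))))
    }
    v <- evaluate_design(rows[rows$interface == "CD", ],
                         rows[rows$interface == "CC", ],
                         rows[rows$interface == "DD", ],
                         thresholds, gap_mode)
    v$error <- NA_character_
    v
  })
  class(out) <- c("filter_verdicts", class(out))
  out
}

#' @importFrom generics glance
#' @export
generics::glance

#' Summarize batch filter verdicts
#'
#' @param x A `filter_verdicts` tibble.
#' @param ... Unused.
#' @return A one-row tibble with the number of designs, passes, errors and
#'   per-reason failure counts.
#' @export
glance.filter_verdicts <- function(x, ...) {
  reason_names <- c("on_target_fail", "off_target_CC_predicted",
                    "off_target_DD_predicted", "gap_fail")
  counts <- map_int(reason_names,
                    function(r) sum(map_lgl(x$reasons, function(v) r %in% v)))
  out <- tibble(n_designs = nrow(x),
                n_passed = sum(x$passed, na.rm = TRUE),
                n_errors = sum(is.na(x$passed)))
  out[reason_names] <- as.list(counts)
  out
}

#' Evaluate an extension design against the structure-prediction filter
#'
#' Pass requires pLDDT strictly above `plddt_min` and rmsd to the diffused
#' backbone strictly below `rmsd_max` (defaults 90 and 1.5 Angstrom).
#'
#' @param plddt pLDDT value(s), 0-100 scale.
#' @param rmsd_to_diffused rmsd value(s), Angstrom.
#' @param plddt_min,rmsd_max Thresholds.
#' @return Logical vector.
#' @export
evaluate_extension_design <- function(plddt, rmsd_to_diffused,
                                      plddt_min = 90, rmsd_max = 1.5) {
  if (any(!is.finite(plddt)) || any(!is.finite(rmsd_to_diffused))) {
    abort("metrics must be finite")
  }
  plddt > plddt_min & rmsd_to_diffused < rmsd_max
}

#' Read / write metric tables and verdicts
#'
#' Metric tables are CSV or TSV files with columns `design_id`,
#' `interface`, `rmsd`, `pae_interaction`, `plddt`.
#'
#' @param path File path (delimiter inferred from the extension).
#' @export
read_metric_table <- function(path) {
  fn <- if (grepl("\\.csv$", path)) readr::read_csv else readr::read_tsv
  fn(path, show_col_types = FALSE)
}

#' @rdname read_metric_table
#' @param verdicts A `filter_verdicts` tibble.
#' @export
write_verdicts <- function(verdicts, path) {
  out <- as_tibble(verdicts)
  out$reasons <- map_chr(out$reasons, paste, collapse = ";")
  readr::write_tsv(out, path)
  invisible(path)
}
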