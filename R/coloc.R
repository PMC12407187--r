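#' Particle colocalization statistic
#'
#' Centroid-to-centroid matching between two labeled particle populations:
#' a reference particle counts as interacting when any opposite-channel
#' centroid lies strictly closer than `threshold` (7.5 micrometres by
#' default, roughly twice a particle radius). No one-to-one assignment is
#' enforced. The percentage is `100 * n_interacting_ref / n_ref` (0 when
#' the reference channel is empty).
#'
#' @param ref,other Data frames (or matrices) of particle centroids with
#'   columns `x` and `y` in micrometres; may be empty.
#' @param threshold Interaction distance, micrometres; must be positive.
#' @return A one-row `coloc_result` tibble: `n_ref`, `n_other`,
#'   `n_interacting_ref`, `percent_ref`, `threshold`.
#' @examples
#' colocalization(data.frame(x = 0, y = 0), data.frame(x = 7.4, y = 0))
#' @export
colocalization <- function(ref, other, threshold = 7.5) {
  if (threshold <= 0) abort("threshold must be positive")
  ref <- as_centroids(ref)
  other <- as_centroids(other)
  n_int <- if (nrow(ref) == 0 || nrow(other) == 0) 0L else {
    d2 <- cross_dist2(cbind(ref$x, ref$y, 0), cbind(other$x, other$y, 0))
    as.integer(sum(apply(d2, 1, min) < threshold^2))
  }
  out <- tibble(n_ref = nrow(ref), n_other = nrow(other),
                n_interacting_ref = n_int,
                percent_ref = if (nrow(ref) == 0) 0 else
                  100 * n_int / nrow(ref),
                threshold = threshold)
  class(out) <- c("coloc_result", class(out))
  out
}

as_centroids <- function(p) {
  if (is.matrix(p)) p <- as_tibble(p, .name_repair = "minimal")
  p <- as_tibble(p)
  if (nrow(p) == 0) return(tibble(x = double(), y = double()))
  if (!all(c("x", "y") %in% names(p))) {
    if (ncol(p) >= 2) names(p)[1:2] <- c("x", "y")
    else abort("centroid tables need columns x and y")
  }
  if (!all(is.finite(p$x) & is.finite(p$y))) {
    abort("centroid coordinates must be finite")
  }
  p[, c("x", "y")]
}

#' Colocalization across multiple fields of view
#'
#' Evaluates the colocalization statistic per imaging field and pools the
#' counts. The pooled percentage is computed from summed counts (interacting
#' and total particles added across fields), not as the mean of per-field
#' percentages; both summaries are reported since the two differ when field
#' sizes vary.
#'
#' @param fields Nonempty list of `list(ref = , other = )` centroid-table
#'   pairs.
#' @param threshold Interaction distance, micrometres.
#' @return A list with `per_field` (tibble with one row per field) and
#'   `pooled` (one-row tibble with summed counts, `percent_pooled` and
#'   `percent_mean_of_fields`).
#' @export
batch_colocalization <- function(fields, threshold = 7.5) {
  if (length(fields) == 0) abort("`fields` must be a nonempty list")
  per_field <- purrr::imap_dfr(fields, function(f, i) {
    r <- colocalization(f$ref, f$other, threshold)
    r$field <- i
    r
  })
  pooled <- tibble(
    n_fields = nrow(per_field),
    n_ref = sum(per_field$n_ref),
    n_interacting_ref = sum(per_field$n_interacting_ref),
    percent_pooled = if (sum(per_field$n_ref) == 0) 0 else
      100 * sum(per_field$n_interacting_ref) / sum(per_field$n_ref),
    percent_mean_of_fields = mean(per_field$percent_ref),
    threshold = threshold)
  list(per_field = per_field, pooled = pooled)
}

#' Read a centroid table
#'
#' CSV with columns `x_um`, `y_um` (or `x`, `y`), one row per particle.
#'
#' @param path File path.
#' @export
read_centroids <- function(path) {
  p <- readr::read_csv(path, show_col_types = FALSE)
  names(p) <- sub("_um$", "", names(p))
  as_centroids(p)
}
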