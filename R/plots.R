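#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_tile coord_equal
#'   facet_wrap labs scale_colour_brewer theme_minimal
NULL

#' Plot a structure projection
#'
#' CA-trace scatter of a structure projected onto a coordinate plane,
#' coloured by entity role.
#'
#' @param object A `bifacet_structure`.
#' @param plane `"xz"` (default, side view along the symmetry axis) or
#'   `"xy"` (top view).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bifacet_structure <- function(object, plane = c("xz", "xy"), ...) {
  plane <- match.arg(plane)
  ca <- as_tibble(object[object$atom == "CA", ])
  h <- if (plane == "xz") "x" else "x"
  v <- if (plane == "xz") "z" else "y"
  ggplot(ca, aes(x = .data[[h]], y = .data[[v]], colour = .data$role)) +
    geom_point(size = 0.6) +
    coord_equal() +
    labs(x = paste0(h, " (Å)"), y = paste0(v, " (Å)"),
         colour = "role") +
    theme_minimal()
}

#' Plot a dock score landscape
#'
#' Score as a function of the axial rotation and translation, one facet
#' per truncation level.
#'
#' @param object Scored `dock_poses`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dock_poses <- function(object, ...) {
  ggplot(as_tibble(object),
         aes(x = .data$phi, y = .data$z_offset, fill = .data$score)) +
    geom_tile() +
    facet_wrap(~truncation, labeller = ggplot2::label_both) +
    labs(x = "phi (deg)", y = "z offset (Å)", fill = "score") +
    theme_minimal()
}

#' @rdname autoplot.dock_poses
#' @param poses Scored `dock_poses`.
#' @export
plot_dock_landscape <- function(poses) autoplot.dock_poses(poses)

#' Plot two particle populations and their interactions
#'
#' @param ref,other Centroid tables (micrometres).
#' @param threshold Interaction distance, micrometres.
#' @return A ggplot object.
#' @export
plot_colocalization <- function(ref, other, threshold = 7.5) {
  ref <- as_centroids(ref); other <- as_centroids(other)
  d2 <- if (nrow(ref) > 0 && nrow(other) > 0)
    cross_dist2(cbind(ref$x, ref$y, 0), cbind(other$x, other$y, 0))
  else matrix(Inf, nrow(ref), nrow(other))
  pts <- bind_rows(
    mutate(ref, channel = "reference",
           interacting = if (nrow(other) > 0)
             apply(d2, 1, min) < threshold^2 else FALSE),
    mutate(other, channel = "other",
           interacting = if (nrow(ref) > 0)
             apply(d2, 2, min) < threshold^2 else FALSE))
  ggplot(pts, aes(x = .data$x, y = .data$y, colour = .data$channel,
                  shape = .data$interacting)) +
    geom_point(size = 2) +
    coord_equal() +
    labs(x = "x (µm)", y = "y (µm)") +
    theme_minimal()
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' Tidy an assembly report
#'
#' @param x An `assembly_report`.
#' @param ... Unused.
#' @return A tibble of face/role chain counts joined with the symmetry
#'   summary columns.
#' @export
tidy.assembly_report <- function(x, ...) {
  roles <- x$roles
  roles$n_chains_total <- x$n_chains
  roles$cyclic_closure_rmsd <- x$symmetry$cyclic_closure_rmsd
  roles$is_pseudo <- x$symmetry$is_pseudo
  roles
}
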