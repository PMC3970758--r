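#' Construct a channel axis
#'
#' A channel axis is a unit direction, a point on the axis, and a sign
#' convention declaring which direction along the axis points toward the
#' C-terminal (ATPase) face of the ring. The convention cannot be inferred
#' from an N-domain-only model and is therefore user input; all
#' clockwise/counterclockwise statements are resolved through it.
#'
#' @param direction Length-3 direction vector (normalized internally).
#' @param point Length-3 point on the axis (angstroms).
#' @param c_face_sign +1 if `direction` points toward the C-terminal face,
#'   -1 if it points away.
#' @return A list of class `rg_axis`.
#' @export
channel_axis <- function(direction, point = c(0, 0, 0), c_face_sign = 1) {
  direction <- as.numeric(direction)
  nrm <- sqrt(sum(direction^2))
  if (!is.finite(nrm) || nrm < 1e-12) {
    rlang::abort("axis direction must be a nonzero vector", class = "rg_type_error")
  }
  if (!c_face_sign %in% c(-1, 1)) {
    rlang::abort("c_face_sign must be +1 or -1", class = "rg_type_error")
  }
  structure(
    list(
      direction = direction / nrm,
      point = as.numeric(point),
      c_face_sign = c_face_sign
    ),
    class = "rg_axis"
  )
}

#' Fit the channel axis of a ring
#'
#' Two constructions are provided. `"permutation_rotation"` takes the
#' rotation fitted by the cyclic-permutation superposition
#' ([permutation_rmsd()]) and uses its invariant line: for a near-C_n ring
#' this is the pseudo-symmetry axis. `"inertia"` takes the principal
#' direction of smallest variance of the selected atom cloud through its
#' centroid: for a flat ring the cloud spreads in the ring plane, so the
#' smallest-variance direction is the ring normal. Both agree to a degree
#' or so on near-symmetric rings.
#'
#' @inheritParams permutation_rmsd
#' @param method `"permutation_rotation"` (default) or `"inertia"`.
#' @param c_face_sign Declares which fitted direction points toward the
#'   C-terminal face. The fitted direction is flipped, if needed, so that
#'   the *returned* direction times `c_face_sign` points at that face while
#'   keeping the returned direction within 90 degrees of the +z axis (a
#'   deterministic sign tie-break).
#' @return An `rg_axis`.
#' @export
fit_axis <- function(assembly, ring,
                     method = c("permutation_rotation", "inertia"),
                     atom_name = "CA", c_face_sign = 1) {
  method <- match.arg(method)
  if (method == "permutation_rotation") {
    sym <- permutation_rmsd(assembly, ring,
      atom_name = atom_name,
      c_face_sign = c_face_sign
    )
    ax <- sym$axis
  } else {
    coords <- do.call(rbind, select_coords(assembly, ring, atom_name)$coords)
    centroid <- colMeans(coords)
    c0 <- sweep(coords, 2, centroid)
    sv <- svd(c0, nu = 0)
    if (sv$d[2] / max(sv$d[1], 1e-12) < 1e-8) {
      rlang::abort("degenerate atom cloud: no defined plane", class = "rg_degeneracy_error")
    }
    ax <- channel_axis(sv$v[, 3], centroid, c_face_sign = c_face_sign)
  }
  # deterministic sign: keep direction in the +z hemisphere (z tie -> +x, +y)
  d <- ax$direction
  key <- c(d[3], d[1], d[2])
  first <- which(abs(key) > 1e-9)[1]
  if (!is.na(first) && key[first] < 0) d <- -d
  channel_axis(d, ax$point, c_face_sign = c_face_sign)
}

# axial coordinate and radial distance of points relative to an axis
axis_cylindrical <- function(points, axis) {
  p0 <- sweep(as_points(points), 2, axis$point)
  zc <- as.numeric(p0 %*% axis$direction)
  perp <- p0 - outer(zc, axis$direction)
  list(z = zc, r = sqrt(rowSums(perp^2)))
}

#' Minimum channel radius along the axis
#'
#' Slices the structure into bins along the channel axis and reports, per
#' bin, the minimum distance from the axis over the selected atoms — i.e.
#' how closely the protein approaches the channel center at each axial
#' position. This equals the profile of a full 360-degree cylindrical merge
#' of the structure about the axis, computed directly: radial distance is
#' invariant under rotation about the axis, so the minimum over any set of
#' rotated copies equals the minimum over the original atoms.
#'
#' @param assembly An `rg_assembly` (or any data frame of atoms).
#' @param axis An `rg_axis`.
#' @param selection Optional predicate taking the atom tibble and returning
#'   a logical vector (e.g. `~ .x$atom == "CA"`); default keeps all atoms.
#' @param bin_width Bin width along the axis in angstroms (default 1.0,
#'   finer than subdomain extent, coarser than coordinate noise).
#' @param probe_radius Optional uniform radius subtracted from each
#'   distance (point atoms by default).
#' @return A tibble of class `rg_radial_profile` with columns `z` (bin
#'   center, angstroms), `min_radius` (NA for empty bins) and `n_atoms`;
#'   attributes `bin_width` and `selection_label`.
#' @export
radial_profile <- function(assembly, axis, selection = NULL, bin_width = 1.0,
                           probe_radius = 0) {
  atoms <- tibble::as_tibble(assembly)
  label <- "all atoms"
  if (!is.null(selection)) {
    keep <- rlang::as_function(selection)(atoms)
    atoms <- atoms[keep, , drop = FALSE]
    label <- "custom selection"
  }
  if (nrow(atoms) == 0) {
    rlang::abort("empty atom selection", class = "rg_selection_error")
  }
  if (bin_width <= 0) {
    rlang::abort("bin_width must be positive", class = "rg_type_error")
  }
  cyl <- axis_cylindrical(atoms[, c("x", "y", "z")], axis)
  lo <- floor(min(cyl$z) / bin_width) * bin_width
  hi <- ceiling(max(cyl$z) / bin_width) * bin_width
  if (hi <= lo) hi <- lo + bin_width
  edges <- seq(lo, hi, by = bin_width)
  idx <- findInterval(cyl$z, edges, rightmost.closed = TRUE)
  prof <- tibble::tibble(
    bin = seq_len(length(edges) - 1),
    z = (edges[-length(edges)] + edges[-1]) / 2
  ) |>
    dplyr::left_join(
      tibble::tibble(bin = idx, r = pmax(cyl$r - probe_radius, 0)) |>
        dplyr::group_by(.data$bin) |>
        dplyr::summarise(min_radius = min(.data$r), n_atoms = dplyr::n()),
      by = "bin"
    ) |>
    dplyr::mutate(n_atoms = dplyr::coalesce(.data$n_atoms, 0L)) |>
    dplyr::select("z", "min_radius", "n_atoms")
  attr(prof, "bin_width") <- bin_width
  attr(prof, "selection_label") <- label
  class(prof) <- unique(c("rg_radial_profile", class(prof)))
  prof
}

#' Narrowest point of a channel profile
#'
#' @param profile An `rg_radial_profile`.
#' @return A one-row tibble (`z`, `min_radius`); ties broken toward the
#'   smallest z.
#' @export
narrowest_point <- function(profile) {
  occ <- profile[!is.na(profile$min_radius), ]
  if (nrow(occ) == 0) {
    rlang::abort("all profile bins are empty", class = "rg_selection_error")
  }
  occ <- occ[order(occ$min_radius, occ$z), ]
  tibble::tibble(z = occ$z[1], min_radius = occ$min_radius[1])
}

#' Which profile bins pass a reference cylinder
#'
#' Marks each occupied bin passable if its minimum radius is at least the
#' reference radius — i.e. a straight cylinder of the given diameter (20 A
#' by default, the envelope of B-form duplex DNA) would fit at that axial
#' position.
#'
#' @param profile An `rg_radial_profile`.
#' @param reference_diameter Cylinder diameter in angstroms (default 20).
#' @return The profile with a logical `passable` column (NA for empty
#'   bins); the boundary case `min_radius == diameter/2` is passable.
#' @export
clearance_vs_reference <- function(profile, reference_diameter = 20) {
  dplyr::mutate(tibble::as_tibble(profile),
    passable = .data$min_radius >= reference_diameter / 2
  )
}

#' Plot a channel radius profile
#'
#' @param object An `rg_radial_profile`.
#' @param reference_diameter Optional reference cylinder diameter to draw
#'   as a horizontal line at its radius.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot rg_radial_profile
#' @export
autoplot.rg_radial_profile <- function(object, reference_diameter = NULL, ...) {
  p <- ggplot2::ggplot(
    object[!is.na(object$min_radius), ],
    ggplot2::aes(x = .data$z, y = .data$min_radius)
  ) +
    ggplot2::geom_step() +
    ggplot2::labs(
      x = "position along channel axis (Å)",
      y = "minimum radius (Å)",
      title = "Channel radius profile"
    )
  if (!is.null(reference_diameter)) {
    p <- p + ggplot2::geom_hline(
      yintercept = reference_diameter / 2,
      linetype = "dashed"
    )
  }
  p
}
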