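wrap_angle <- function(a) {
  # wrap to (-180, 180]
  w <- ((a + 180) %% 360) - 180
  ifelse(w == -180, 180, w)
}

#' Angular polarity of a nucleic-acid path around the channel
#'
#' Projects the nucleotide reference points onto the plane normal to the
#' channel axis and accumulates the signed angular increment between
#' consecutive nucleotides (each wrapped to (-180, 180] degrees so a single
#' step is never ambiguous). The sign is taken about the direction pointing
#' at the viewer: positive net sweep is counterclockwise on the viewer's
#' page, negative is clockwise. `view_from = "c_face"` places the viewer on
#' the C-terminal face as declared by the axis `c_face_sign`; `"n_face"` is
#' the opposite side and flips the sense.
#'
#' @param path An `rg_na_path` (>= 3 nucleotides).
#' @param axis An `rg_axis`.
#' @param view_from `"c_face"` (default) or `"n_face"`.
#' @return A tibble of class `rg_polarity` with columns `sense`
#'   (`"clockwise"`/`"counterclockwise"`), `net_sweep` (signed degrees on
#'   the viewer's page), `n_nucleotides`, `view`.
#' @export
polarity <- function(path, axis, view_from = c("c_face", "n_face")) {
  view_from <- match.arg(view_from)
  pts <- as_points(path[, c("x", "y", "z")])
  if (nrow(pts) < 3) {
    rlang::abort("need >= 3 nucleotides for polarity", class = "rg_type_error")
  }
  viewer <- axis$direction * axis$c_face_sign
  if (view_from == "n_face") viewer <- -viewer
  cyl <- axis_cylindrical(pts, axis)
  if (any(cyl$r <= 0.1)) {
    rlang::abort("nucleotide reference point lies on the channel axis",
      class = "rg_degeneracy_error"
    )
  }
  # right-handed in-plane basis about the viewer direction
  ref <- if (abs(viewer[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- ref - sum(ref * viewer) * viewer
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- cross3(viewer, e1)
  p0 <- sweep(pts, 2, axis$point)
  ang <- atan2(p0 %*% e2, p0 %*% e1) * 180 / pi
  sweep_deg <- sum(wrap_angle(diff(as.numeric(ang))))
  out <- tibble::tibble(
    sense = if (sweep_deg < 0) "clockwise" else "counterclockwise",
    net_sweep = sweep_deg,
    n_nucleotides = nrow(pts),
    view = view_from
  )
  class(out) <- unique(c("rg_polarity", class(out)))
  out
}

cross3 <- function(a, b) {
  c(
    a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1]
  )
}

#' Tilt of the nucleic-acid plane relative to the channel axis
#'
#' Fits a total-least-squares plane through the nucleotide reference points
#' (smallest principal direction of the centered cloud) and returns the
#' acute angle between the plane normal and the axis direction. Zero means
#' the DNA circles the ring in a plane exactly perpendicular to the
#' channel.
#'
#' @inheritParams polarity
#' @return Angle in degrees, in [0, 90].
#' @export
planarity <- function(path, axis) {
  pts <- as_points(path[, c("x", "y", "z")])
  if (nrow(pts) < 3) {
    rlang::abort("need >= 3 points to fit a plane", class = "rg_type_error")
  }
  p0 <- sweep(pts, 2, colMeans(pts))
  sv <- svd(p0, nu = 0)
  if (sv$d[2] / max(sv$d[1], 1e-12) < 1e-8) {
    rlang::abort("collinear points: plane undefined", class = "rg_degeneracy_error")
  }
  normal <- sv$v[, 3]
  cosang <- abs(sum(normal * axis$direction))
  acos(pmin(1, cosang)) * 180 / pi
}

#' Contiguous nucleotide stretches
#'
#' Maximal runs of consecutively numbered nucleotides within each chain of
#' the path(s); two chains never merge into one stretch. Lengths are
#' reported sorted descending.
#'
#' @param paths An `rg_na_path`, or a list of them (e.g. one per hexamer).
#' @return Integer vector of stretch lengths (sorted descending) for a
#'   single path; a list of such vectors for a list input.
#' @export
segment_stretches <- function(paths) {
  if (is.data.frame(paths)) {
    return(stretches_one(paths))
  }
  lapply(paths, stretches_one)
}

stretches_one <- function(path) {
  runs <- unlist(lapply(split(path$resno, path$chain), function(r) {
    r <- sort(r)
    rle(cumsum(c(1L, diff(r) != 1L)))$lengths
  }), use.names = FALSE)
  sort(as.integer(runs), decreasing = TRUE)
}

#' Assign nucleotides to ring subunits by atomic contacts
#'
#' Each nucleotide is assigned to the protein chain with the most heavy-atom
#' contacts within `contact_cutoff` of any of the nucleotide's heavy atoms;
#' ties go to the chain earlier in ring order, and nucleotides with no
#' contacts stay unassigned.
#'
#' @param assembly An `rg_assembly` holding both the ring and the DNA.
#' @param ring An `rg_ring`.
#' @param paths An `rg_na_path` (nucleotides to assign).
#' @param contact_cutoff Heavy-atom distance cutoff in angstroms
#'   (default 4.5).
#' @return A list with `assignments` (tibble: `chain`, `resno`, `base`,
#'   `assigned_chain`, `n_contacts`) and `per_subunit` (tibble:
#'   `assigned_chain`, `n_nucleotides`, over all ring chains).
#' @export
assign_nucleotides <- function(assembly, ring, paths, contact_cutoff = 4.5) {
  assembly <- as_assembly(assembly)
  ring <- as_ring(ring, assembly)
  prot <- assembly |>
    dplyr::filter(
      .data$chain %in% ring$chains, .data$polymer == "protein",
      .data$elem != "H"
    )
  prot_xyz <- as.matrix(prot[, c("x", "y", "z")])
  na_atoms <- na_path_atoms(assembly, paths)
  key <- paste(paths$chain, paths$resno)
  assigned <- character(length(key))
  ncontacts <- integer(length(key))
  for (k in seq_along(key)) {
    nt <- na_atoms[paste(na_atoms$chain, na_atoms$resno) == key[k], ]
    if (nrow(nt) == 0) {
      # fall back to the reference point when only that is modeled
      nt <- paths[k, , drop = FALSE]
    }
    nt_xyz <- as.matrix(nt[, c("x", "y", "z")])
    d2 <- outer(rowSums(nt_xyz^2), rowSums(prot_xyz^2), "+") -
      2 * nt_xyz %*% t(prot_xyz)
    contact <- colSums(d2 <= contact_cutoff^2) > 0
    counts <- vapply(
      ring$chains,
      function(ch) sum(contact[prot$chain == ch]),
      integer(1)
    )
    if (all(counts == 0)) {
      assigned[k] <- NA_character_
      ncontacts[k] <- 0L
    } else {
      assigned[k] <- ring$chains[which.max(counts)] # which.max: first max = tie rule
      ncontacts[k] <- max(counts)
    }
  }
  assignments <- tibble::tibble(
    chain = paths$chain, resno = paths$resno, base = paths$base,
    assigned_chain = assigned, n_contacts = ncontacts
  )
  per_subunit <- tibble::tibble(assigned_chain = ring$chains) |>
    dplyr::left_join(
      dplyr::count(
        assignments[!is.na(assignments$assigned_chain), ],
        .data$assigned_chain,
        name = "n_nucleotides"
      ),
      by = "assigned_chain"
    ) |>
    dplyr::mutate(n_nucleotides = dplyr::coalesce(.data$n_nucleotides, 0L))
  list(assignments = assignments, per_subunit = per_subunit)
}

#' Full-occupancy nucleotide capacity of a ring
#'
#' With a fixed binding increment per subunit, a ring of n subunits can
#' hold n times that increment when every subunit engages the DNA
#' simultaneously (6 x 4 = 24 for an MCM hexamer).
#'
#' @param ring_size Number of subunits (positive integer).
#' @param per_subunit_increment Nucleotides bound per subunit (positive
#'   integer).
#' @return Integer capacity.
#' @export
full_occupancy_capacity <- function(ring_size, per_subunit_increment) {
  rs <- as.integer(ring_size)
  inc <- as.integer(per_subunit_increment)
  if (is.na(rs) || is.na(inc) || rs <= 0 || inc <= 0) {
    rlang::abort("ring_size and per_subunit_increment must be positive integers",
      class = "rg_type_error"
    )
  }
  rs * inc
}
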