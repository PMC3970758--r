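#' Deviation of a ring from n-fold cyclic symmetry
#'
#' The symmetry statistic for an n-subunit ring: the subdomain coordinates
#' of all chains in ring order are concatenated and superposed, in a single
#' global least-squares fit, onto the same coordinates with the chain list
#' cyclically rotated by `step` (chains ABCDEF onto BCDEFA for a hexamer).
#' The resulting RMSD is zero if and only if the ring is exactly C_n
#' symmetric about some axis, and grows with any deviation from cyclic
#' symmetry. The rotation fitted by the superposition approximates the
#' ring's 360/n degree symmetry operation, so its axis is the channel
#' (pseudo-symmetry) axis.
#'
#' @param assembly An `rg_assembly`.
#' @param ring An `rg_ring` from [ring_definition()].
#' @param step Cyclic permutation step (default 1); must not be 0 mod n.
#' @param atom_name Atom used for the fit (default `"CA"`).
#' @param c_face_sign +1 or -1: which direction along the fitted axis points
#'   toward the C-terminal (ATPase) face; fixes viewing conventions
#'   downstream.
#' @return A list of class `rg_symmetry_report`: `permutation_rmsd`
#'   (angstroms), `per_subunit` (tibble of per-chain RMSD after the global
#'   fit), `rotation_angle` (degrees), `axis` (an `rg_axis`), `n`, `step`,
#'   and the fitted `superposition`.
#' @export
permutation_rmsd <- function(assembly, ring, step = 1L, atom_name = "CA",
                             c_face_sign = 1) {
  ring <- as_ring(ring, as_assembly(assembly))
  n <- length(ring$chains)
  step <- as.integer(step)
  if (step %% n == 0) {
    rlang::abort("permutation step must not be 0 mod n", class = "rg_type_error")
  }
  sel <- select_coords(assembly, ring, atom_name)
  coords <- sel$coords
  perm <- ((seq_len(n) - 1 + step) %% n) + 1
  moving <- do.call(rbind, coords)
  target <- do.call(rbind, coords[perm])
  fit <- superpose(moving, target)
  moved <- apply_transform(moving, fit$rotation, fit$translation)
  m <- nrow(coords[[1]])
  per_chain <- vapply(seq_len(n), function(i) {
    idx <- ((i - 1) * m + 1):(i * m)
    rmsd_fixed(moved[idx, , drop = FALSE], target[idx, , drop = FALSE])
  }, numeric(1))
  aa <- rotation_axis_angle(fit$rotation)
  centroid <- colMeans(moving)
  point <- rotation_axis_point(fit$rotation, fit$translation, near = centroid)
  axis <- channel_axis(aa$axis, point, c_face_sign = c_face_sign)
  structure(
    list(
      permutation_rmsd = fit$rmsd,
      per_subunit = tibble::tibble(chain = ring$chains, rmsd = per_chain),
      rotation_angle = aa$angle_deg,
      axis = axis,
      n = n, step = step,
      label = ring$label,
      superposition = fit
    ),
    class = "rg_symmetry_report"
  )
}

#' @export
print.rg_symmetry_report <- function(x, ...) {
  cat(sprintf(
    "C%d-symmetry deviation [%s]: permutation RMSD %.3f A (rotation %.2f deg)\n",
    x$n, x$label, x$permutation_rmsd, x$rotation_angle
  ))
  print(x$per_subunit)
  invisible(x)
}

#' Tidy a symmetry report
#'
#' @param x An `rg_symmetry_report`.
#' @param ... Unused.
#' @return One row per subunit with the global statistic repeated.
#' @method tidy rg_symmetry_report
#' @export
tidy.rg_symmetry_report <- function(x, ...) {
  dplyr::mutate(x$per_subunit,
    permutation_rmsd = x$permutation_rmsd,
    rotation_angle = x$rotation_angle,
    label = x$label
  )
}

#' Pairwise subunit-to-subunit RMSD matrix
#'
#' Each subunit's subdomain coordinates are individually superposed onto
#' every other subunit's; the (i, j) entry is that fitted RMSD. The matrix
#' is symmetric with a zero diagonal and diagnoses conformational spread
#' among monomers independently of their placement in the ring.
#'
#' @inheritParams permutation_rmsd
#' @return A tibble in long form (`chain_i`, `chain_j`, `rmsd`) with an
#'   n x n `"matrix"` attribute.
#' @export
subunit_pairwise_rmsd_matrix <- function(assembly, ring, atom_name = "CA") {
  ring <- as_ring(ring, as_assembly(assembly))
  coords <- select_coords(assembly, ring, atom_name)$coords
  n <- length(coords)
  m <- matrix(0, n, n, dimnames = list(ring$chains, ring$chains))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      r <- superpose(coords[[i]], coords[[j]])$rmsd
      m[i, j] <- r
      m[j, i] <- r
    }
  }
  out <- tibble::as_tibble(as.data.frame.table(m, stringsAsFactors = FALSE)) |>
    rlang::set_names(c("chain_i", "chain_j", "rmsd"))
  attr(out, "matrix") <- m
  out
}
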