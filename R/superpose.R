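#' Optimal rigid-body superposition of paired point sets
#'
#' Least-squares superposition (Kabsch, via SVD of the covariance matrix)
#' of `moving` onto `target` over all proper rotations and translations.
#' Reflections are excluded: the returned rotation always has determinant
#' +1, preserving chirality.
#'
#' The fitted transform maps a point row-vector `p` to
#' `p %*% t(rotation) + translation`.
#'
#' @param moving,target Numeric n x 3 matrices (or data frames with
#'   `x`, `y`, `z`) of paired points, n >= 3.
#' @return A list of class `rg_superposition` with elements `rotation`
#'   (3 x 3, det +1), `translation` (length 3), and `rmsd` (angstroms,
#'   root-mean-square residual after fitting).
#' @examples
#' a <- matrix(rnorm(30), ncol = 3)
#' superpose(a, a)$rmsd # 0
#' @export
superpose <- function(moving, target) {
  a <- as_points(moving)
  b <- as_points(target)
  if (nrow(a) != nrow(b)) {
    rlang::abort("point sets differ in length", class = "rg_type_error")
  }
  if (nrow(a) < 3) {
    rlang::abort("need >= 3 points to superpose", class = "rg_type_error")
  }
  ca <- colMeans(a)
  cb <- colMeans(b)
  a0 <- sweep(a, 2, ca)
  b0 <- sweep(b, 2, cb)
  # both sets nearly collinear -> rotation about the line is undetermined
  if (rank2_deficient(a0) && rank2_deficient(b0)) {
    rlang::abort("degenerate (near-collinear) point configuration",
      class = "rg_degeneracy_error"
    )
  }
  h <- crossprod(a0, b0) # 3x3 covariance
  sv <- svd(h)
  d <- sign(det(sv$v %*% t(sv$u)))
  r <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  t_vec <- as.numeric(cb - r %*% ca)
  resid <- b - (a %*% t(r) + matrix(t_vec, nrow(a), 3, byrow = TRUE))
  structure(
    list(
      rotation = r,
      translation = t_vec,
      rmsd = sqrt(mean(rowSums(resid^2)))
    ),
    class = "rg_superposition"
  )
}

#' RMSD between paired point sets without refitting
#'
#' Plain root-mean-square deviation over the pairing as given; no rotation
#' or translation is applied. Used for per-subunit deviations after a
#' single global fit.
#'
#' @inheritParams superpose
#' @param a,b Paired point sets of equal length.
#' @return RMSD in angstroms.
#' @export
rmsd_fixed <- function(a, b) {
  a <- as_points(a)
  b <- as_points(b)
  if (nrow(a) != nrow(b)) {
    rlang::abort("point sets differ in length", class = "rg_type_error")
  }
  sqrt(mean(rowSums((a - b)^2)))
}

as_points <- function(p) {
  if (is.data.frame(p)) p <- as.matrix(p[, c("x", "y", "z")])
  p <- as.matrix(p)
  storage.mode(p) <- "double"
  if (ncol(p) != 3) rlang::abort("points must be n x 3", class = "rg_type_error")
  if (!all(is.finite(p))) rlang::abort("non-finite coordinates", class = "rg_type_error")
  p
}

# TRUE when the centered cloud has (numerically) rank < 2
rank2_deficient <- function(p0, tol = 1e-8) {
  s <- svd(p0, nu = 0, nv = 0)$d
  scale <- max(s[1], 1)
  s[2] / scale < tol
}

apply_transform <- function(p, rotation, translation) {
  as_points(p) %*% t(rotation) + matrix(translation, nrow(p), 3, byrow = TRUE)
}

# axis (unit), angle (deg, in [0, 180]) of a proper rotation matrix
rotation_axis_angle <- function(r) {
  tr <- sum(diag(r))
  ang <- acos(pmin(1, pmax(-1, (tr - 1) / 2)))
  # antisymmetric part gives sin(angle) * axis
  v <- c(r[3, 2] - r[2, 3], r[1, 3] - r[3, 1], r[2, 1] - r[1, 2]) / 2
  if (sqrt(sum(v^2)) > 1e-12) {
    axis <- v / sqrt(sum(v^2))
  } else {
    # angle ~ 0 or ~ 180: eigenvector of eigenvalue +1
    e <- eigen(r)
    i <- which.min(abs(e$values - 1))
    axis <- Re(e$vectors[, i])
    axis <- axis / sqrt(sum(axis^2))
  }
  list(axis = axis, angle_deg = ang * 180 / pi)
}

# a point on the invariant line of the screw transform (R, t): solve
# (I - R) p = t_perp, the component of t perpendicular to the axis
rotation_axis_point <- function(rotation, translation, near = c(0, 0, 0)) {
  aa <- rotation_axis_angle(rotation)
  u <- aa$axis
  t_perp <- translation - sum(translation * u) * u
  m <- diag(3) - rotation
  p0 <- tryCatch(
    as.numeric(MASS_ginv(m) %*% t_perp),
    error = function(e) rep(0, 3)
  )
  # project the reference point onto the line p0 + s * u
  p0 + sum((near - p0) * u) * u
}

# minimal Moore-Penrose pseudoinverse (avoids a MASS dependency)
MASS_ginv <- function(m, tol = 1e-10) {
  sv <- svd(m)
  pos <- sv$d > tol * max(sv$d, 1)
  if (!any(pos)) {
    return(matrix(0, ncol(m), nrow(m)))
  }
  sv$v[, pos, drop = FALSE] %*%
    (t(sv$u[, pos, drop = FALSE]) / sv$d[pos])
}
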