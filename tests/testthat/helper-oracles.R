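# Independent oracles used to cross-check the geometry kernels. These stay
# deliberately naive and share no code with the package internals.

# Horn's closed-form quaternion superposition (proper rotations only).
# Returns the minimal RMSD of moving onto target.
quaternion_rmsd <- function(moving, target) {
  a0 <- sweep(moving, 2, colMeans(moving))
  b0 <- sweep(target, 2, colMeans(target))
  m <- crossprod(a0, b0)
  sxx <- m[1, 1]; sxy <- m[1, 2]; sxz <- m[1, 3]
  syx <- m[2, 1]; syy <- m[2, 2]; syz <- m[2, 3]
  szx <- m[3, 1]; szy <- m[3, 2]; szz <- m[3, 3]
  k <- matrix(c(
    sxx + syy + szz, syz - szy,        szx - sxz,        sxy - syx,
    syz - szy,       sxx - syy - szz,  sxy + syx,        szx + sxz,
    szx - sxz,       sxy + syx,       -sxx + syy - szz,  syz + szy,
    sxy - syx,       szx + sxz,        syz + szy,       -sxx - syy + szz
  ), 4, 4, byrow = TRUE)
  lambda <- max(eigen(k, symmetric = TRUE, only.values = TRUE)$values)
  ss <- sum(a0^2) + sum(b0^2) - 2 * lambda
  sqrt(max(0, ss) / nrow(moving))
}

rodrigues <- function(u, angle) {
  u <- u / sqrt(sum(u^2))
  kx <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(angle) * kx + (1 - cos(angle)) * (kx %*% kx)
}

# RMSD for a fixed rotation with the (closed-form) optimal translation.
rmsd_given_rotation <- function(a0, b0, r) {
  resid <- b0 - a0 %*% t(r)
  sqrt(mean(rowSums(resid^2)))
}

# Brute-force superposition: coarse-to-fine grid over the rotation axis
# (parametrized as a tilt (a, b) of the +z axis, u ~ (a, b, 1)) and the
# rotation angle omega; translation optimal per rotation. Suited to
# ring-permutation fits, whose optimal axis is within ~30 degrees of the
# construction axis; refines the rmsd to ~1e-4 A.
grid_search_rmsd <- function(moving, target, levels = 7, tilt_max = 0.7) {
  a0 <- sweep(moving, 2, colMeans(moving))
  b0 <- sweep(target, 2, colMeans(target))
  eval_at <- function(a, b, om) {
    rmsd_given_rotation(a0, b0, rodrigues(c(a, b, 1), om))
  }
  best <- c(a = 0, b = 0, om = 0)
  best_val <- Inf
  widths <- c(a = tilt_max, b = tilt_max, om = pi)
  grid_n <- c(13, 13, 25)
  for (lev in seq_len(levels)) {
    as <- seq(best["a"] - widths["a"], best["a"] + widths["a"], length.out = grid_n[1])
    bs <- seq(best["b"] - widths["b"], best["b"] + widths["b"], length.out = grid_n[2])
    oms <- seq(best["om"] - widths["om"], best["om"] + widths["om"], length.out = grid_n[3])
    for (a in as) for (b in bs) for (om in oms) {
      v <- eval_at(a, b, om)
      if (v < best_val) {
        best_val <- v
        best <- c(a = a, b = b, om = om)
      }
    }
    widths <- widths * (2.5 / (grid_n - 1))
    grid_n <- c(9, 9, 9)
  }
  best_val
}

# Dense 1-D grid search for planar problems: rotation about the given
# normal in fixed angular steps, centroids aligned.
planar_grid_rmsd <- function(moving, target, normal, step_deg = 0.01) {
  a0 <- sweep(moving, 2, colMeans(moving))
  b0 <- sweep(target, 2, colMeans(target))
  angles <- seq(-180, 180, by = step_deg) * pi / 180
  min(vapply(
    angles,
    function(om) rmsd_given_rotation(a0, b0, rodrigues(normal, om)),
    numeric(1)
  ))
}

# Explicit rotational merge: n_copies of the atoms rotated about the axis
# in equal increments, profile of the union. The channel module computes
# this without materializing the copies.
rotational_merge_profile <- function(assembly, axis, bin_width = 1, n_copies = 72) {
  pts <- as.matrix(assembly[, c("x", "y", "z")])
  p0 <- sweep(pts, 2, axis$point)
  copies <- lapply(seq_len(n_copies) - 1, function(k) {
    r <- rodrigues(axis$direction, 2 * pi * k / n_copies)
    sweep(p0 %*% t(r), 2, axis$point, "+")
  })
  merged <- do.call(rbind, copies)
  df <- tibble::tibble(
    chain = "X", resno = seq_len(nrow(merged)), resname = "GLY", atom = "CA",
    x = merged[, 1], y = merged[, 2], z = merged[, 3]
  )
  radial_profile(df, axis, bin_width = bin_width)
}

# Total-least-squares plane by brute force: coarse-to-fine search over
# normal directions minimizing the sum of squared point-plane distances.
grid_plane_angle <- function(points, axis, levels = 6) {
  p0 <- sweep(points, 2, colMeans(points))
  obj <- function(th, ph) {
    n <- c(sin(th) * cos(ph), sin(th) * sin(ph), cos(th))
    sum((p0 %*% n)^2)
  }
  best <- c(th = pi / 2, ph = 0)
  best_val <- Inf
  widths <- c(th = pi / 2, ph = pi)
  grid_n <- c(31, 61)
  for (lev in seq_len(levels)) {
    ths <- seq(best["th"] - widths["th"], best["th"] + widths["th"], length.out = grid_n[1])
    phs <- seq(best["ph"] - widths["ph"], best["ph"] + widths["ph"], length.out = grid_n[2])
    for (th in ths) for (ph in phs) {
      v <- obj(th, ph)
      if (v < best_val) {
        best_val <- v
        best <- c(th = th, ph = ph)
      }
    }
    widths <- widths * (2.5 / (grid_n - 1))
    grid_n <- c(9, 9)
  }
  n <- c(
    sin(best["th"]) * cos(best["ph"]),
    sin(best["th"]) * sin(best["ph"]),
    cos(best["th"])
  )
  acos(min(1, abs(sum(n * axis$direction)))) * 180 / pi
}

# Random proper rotation + translation (for invariance property tests).
random_rigid_transform <- function() {
  u <- stats::rnorm(3)
  r <- rodrigues(u / sqrt(sum(u^2)), stats::runif(1, 0, 2 * pi))
  list(rotation = r, translation = stats::rnorm(3, 0, 20))
}

transform_assembly <- function(assembly, rt) {
  xyz <- as.matrix(assembly[, c("x", "y", "z")]) %*% t(rt$rotation)
  xyz <- sweep(xyz, 2, rt$translation, "+")
  assembly$x <- xyz[, 1]
  assembly$y <- xyz[, 2]
  assembly$z <- xyz[, 3]
  assembly
}
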