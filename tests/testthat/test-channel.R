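test_that("both axis methods recover the construction axis of a C6 ring", {
  ring <- make_ring(synthetic_ring_spec(n_subunits = 6))
  rd <- attr(ring, "ring")
  for (m in c("permutation_rotation", "inertia")) {
    ax <- fit_axis(ring, rd, method = m)
    expect_equal(abs(ax$direction[3]), 1, tolerance = 1e-6)
    expect_equal(ax$point[1:2], c(0, 0), tolerance = 1e-6)
  }
})

test_that("the fitted axis is equivariant under rigid rotation of the assembly", {
  ring <- make_ring(synthetic_ring_spec(n_subunits = 6))
  rd <- attr(ring, "ring")
  old <- fit_axis(ring, rd)
  set.seed(3)
  rt <- random_rigid_transform()
  moved <- as_assembly(transform_assembly(ring, rt))
  new <- fit_axis(moved, rd)
  expected <- as.numeric(rt$rotation %*% old$direction)
  # the sign tie-break may flip the direction; compare up to sign
  expect_equal(abs(sum(new$direction * expected)), 1, tolerance = 1e-6)
})

test_that("permutation and inertia axes agree on mildly perturbed rings", {
  set.seed(47)
  for (i in 1:5) {
    spec <- synthetic_ring_spec(
      perturbation = c(radial_shift = 0.5, axial_shift = 0.5),
      seed = sample.int(1e6, 1)
    )
    ring <- make_ring(spec)
    rd <- attr(ring, "ring")
    a1 <- fit_axis(ring, rd, method = "permutation_rotation")$direction
    a2 <- fit_axis(ring, rd, method = "inertia")$direction
    ang <- acos(min(1, abs(sum(a1 * a2)))) * 180 / pi
    expect_lt(ang, 2)
  }
})

test_that("a ring of atoms at constant radius reports that radius in every occupied bin", {
  n <- 60
  phi <- 2 * pi * seq_len(n) / n
  atoms <- tibble::tibble(
    chain = "A", resno = seq_len(n), resname = "GLY", atom = "CA",
    x = 20 * cos(phi), y = 20 * sin(phi), z = runif(n, -3, 3)
  )
  prof <- radial_profile(atoms, channel_axis(c(0, 0, 1)))
  occ <- prof[prof$n_atoms > 0, ]
  expect_true(all(abs(occ$min_radius - 20) < 1e-9))
})

test_that("a bin with several atoms reports the smallest radius", {
  atoms <- tibble::tibble(
    chain = "A", resno = 1:2, resname = "GLY", atom = "CA",
    x = c(5, 10), y = 0, z = c(0.2, 0.3)
  )
  prof <- radial_profile(atoms, channel_axis(c(0, 0, 1)))
  expect_equal(prof$min_radius[prof$n_atoms == 2], 5)
})

test_that("the profile equals the explicit 72-copy rotational-merge oracle", {
  set.seed(59)
  cloud <- tibble::tibble(
    chain = "A", resno = 1:150, resname = "GLY", atom = "CA",
    x = rnorm(150, sd = 12), y = rnorm(150, sd = 12), z = rnorm(150, sd = 8)
  )
  ax <- channel_axis(c(0.2, -0.1, 1), point = c(1, 2, 0))
  direct <- radial_profile(cloud, ax)
  merged <- rotational_merge_profile(cloud, ax)
  expect_equal(direct$z, merged$z)
  expect_equal(direct$min_radius, merged$min_radius, tolerance = 1e-9)
})

test_that("profiles are invariant under rotating the assembly about the axis", {
  ring <- make_ring(synthetic_ring_spec(n_subunits = 6))
  ax <- attr(ring, "axis")
  p0 <- radial_profile(ring, ax)
  rot <- transform_assembly(ring, list(rotation = rodrigues(c(0, 0, 1), 0.7), translation = c(0, 0, 0)))
  p1 <- radial_profile(rot, ax)
  expect_equal(p0$z, p1$z)
  expect_equal(p0$min_radius, p1$min_radius, tolerance = 1e-9)
})

test_that("refining the bin width never raises the minimum seen by a coarser bin", {
  set.seed(61)
  cloud <- tibble::tibble(
    chain = "A", resno = 1:200, resname = "GLY", atom = "CA",
    x = rnorm(200, sd = 10), y = rnorm(200, sd = 10), z = runif(200, -10, 10)
  )
  ax <- channel_axis(c(0, 0, 1))
  coarse <- radial_profile(cloud, ax, bin_width = 2)
  fine <- radial_profile(cloud, ax, bin_width = 0.5)
  for (i in seq_len(nrow(coarse))) {
    if (is.na(coarse$min_radius[i])) next
    sub <- fine$min_radius[abs(fine$z - coarse$z[i]) <= 1]
    expect_true(min(sub, na.rm = TRUE) >= coarse$min_radius[i] - 1e-9)
  }
})

test_that("narrowest_point picks the minimal-radius bin with ties to smaller z", {
  prof <- tibble::tibble(
    z = c(0, 1, 2), min_radius = c(20, 8, 15), n_atoms = c(1L, 1L, 1L)
  )
  expect_equal(narrowest_point(prof), tibble::tibble(z = 1, min_radius = 8))
  tie <- tibble::tibble(
    z = c(0, 1, 2), min_radius = c(20, 8, 8), n_atoms = c(1L, 1L, 1L)
  )
  expect_equal(narrowest_point(tie)$z, 1)
  single <- tibble::tibble(z = 5, min_radius = 12, n_atoms = 3L)
  expect_equal(narrowest_point(single)$z, 5)
  empty <- tibble::tibble(z = 0, min_radius = NA_real_, n_atoms = 0L)
  expect_error(narrowest_point(empty), class = "rg_selection_error")
})

test_that("clearance against a reference cylinder uses an inclusive boundary", {
  prof <- tibble::tibble(
    z = 0:2, min_radius = c(11, 9, 10), n_atoms = c(1L, 1L, 1L)
  )
  out <- clearance_vs_reference(prof, reference_diameter = 20)
  expect_equal(out$passable, c(TRUE, FALSE, TRUE))
})
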