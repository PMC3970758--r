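path_at_angles <- function(angles_deg, radius = 10, z = 0) {
  a <- angles_deg * pi / 180
  tibble::tibble(
    chain = "M", resno = seq_along(a), base = "DT",
    x = radius * cos(a), y = radius * sin(a), z = z,
    ref_atom = "C1'"
  )
}

zaxis <- channel_axis(c(0, 0, 1), c_face_sign = 1)

test_that("a counterclockwise-constructed arc reads counterclockwise from the c-face", {
  p <- path_at_angles(c(0, 30, 60, 90))
  pol <- polarity(p, zaxis, view_from = "c_face")
  expect_equal(pol$sense, "counterclockwise")
  expect_equal(pol$net_sweep, 90, tolerance = 1e-9)
})

test_that("reversing the nucleotide order flips the sense and negates the sweep", {
  p <- path_at_angles(c(0, 30, 60, 90))
  rev_p <- p[rev(seq_len(nrow(p))), ]
  pol <- polarity(rev_p, zaxis, view_from = "c_face")
  expect_equal(pol$sense, "clockwise")
  expect_equal(pol$net_sweep, -90, tolerance = 1e-9)
})

test_that("switching the viewing face flips the sense", {
  p <- path_at_angles(c(0, 30, 60, 90))
  a <- polarity(p, zaxis, view_from = "c_face")
  b <- polarity(p, zaxis, view_from = "n_face")
  expect_equal(a$net_sweep, -b$net_sweep, tolerance = 1e-9)
  expect_false(a$sense == b$sense)
})

test_that("polarity is invariant under consistently transformed rigid motions", {
  p <- path_at_angles(seq(0, 150, by = 30))
  set.seed(71)
  for (i in 1:5) {
    rt <- random_rigid_transform()
    moved <- transform_assembly(p, rt)
    ax2 <- channel_axis(
      as.numeric(rt$rotation %*% zaxis$direction),
      as.numeric(rt$rotation %*% zaxis$point + rt$translation),
      c_face_sign = 1
    )
    expect_equal(
      polarity(moved, ax2)$net_sweep,
      polarity(p, zaxis)$net_sweep,
      tolerance = 1e-9
    )
  }
})

test_that("a closed sampled circle sweeps ~360 degrees at any density >= 8", {
  for (n in c(8, 12, 36)) {
    p <- path_at_angles(seq(0, 360, length.out = n + 1))
    expect_equal(abs(polarity(p, zaxis)$net_sweep), 360, tolerance = 1)
  }
})

test_that("polarity rejects degenerate input", {
  expect_error(polarity(path_at_angles(c(0, 30)), zaxis), class = "rg_type_error")
  on_axis <- path_at_angles(c(0, 30, 60))
  on_axis[2, c("x", "y")] <- 0
  expect_error(polarity(on_axis, zaxis), class = "rg_degeneracy_error")
})

test_that("planarity is zero for a flat circle and matches a constructed tilt", {
  flat <- path_at_angles(seq(0, 330, by = 30), z = 5)
  expect_equal(planarity(flat, zaxis), 0, tolerance = 1e-9)
  tilt <- 25 * pi / 180
  rx <- matrix(c(1, 0, 0, 0, cos(tilt), sin(tilt), 0, -sin(tilt), cos(tilt)), 3, 3)
  tilted <- transform_assembly(flat, list(rotation = rx, translation = c(0, 0, 0)))
  expect_equal(planarity(tilted, zaxis), 25, tolerance = 1e-9)
})

test_that("helical-path planarity matches the brute-force plane oracle", {
  for (pars in list(c(r = 6, rise = 1.5), c(r = 2, rise = 4), c(r = 0.5, rise = 6))) {
    i <- 0:11
    helix <- tibble::tibble(
      chain = "M", resno = i + 1, base = "DT",
      x = pars["r"] * cos(i * pi / 6), y = pars["r"] * sin(i * pi / 6),
      z = i * pars["rise"], ref_atom = "C1'"
    )
    expect_equal(
      planarity(helix, zaxis),
      grid_plane_angle(as.matrix(helix[, c("x", "y", "z")]), zaxis),
      tolerance = 1e-3
    )
  }
  # pitch >> radius: the best plane contains the axis
  expect_gt(planarity(tibble::tibble(
    chain = "M", resno = 1:12, base = "DT",
    x = 0.2 * cos((0:11) * pi / 6), y = 0.2 * sin((0:11) * pi / 6),
    z = (0:11) * 6, ref_atom = "C1'"
  ), zaxis), 85)
})

test_that("collinear reference points make planarity fail", {
  line <- tibble::tibble(
    chain = "M", resno = 1:4, base = "DT",
    x = 1:4, y = 2 * (1:4), z = 0, ref_atom = "C1'"
  )
  expect_error(planarity(line, zaxis), class = "rg_degeneracy_error")
})

test_that("stretch segmentation follows residue-number continuity", {
  p1 <- tibble::tibble(chain = "M", resno = 1:7)
  expect_equal(segment_stretches(p1), 7L)
  p2 <- tibble::tibble(chain = "M", resno = c(1:3, 5:7))
  expect_equal(segment_stretches(p2), c(3L, 3L))
  # chains never merge even with continuing numbers
  p3 <- tibble::tibble(chain = c(rep("M", 3), rep("N", 3)), resno = 1:6)
  expect_equal(segment_stretches(p3), c(3L, 3L))
  # list input gives per-hexamer results; totals equal modeled nucleotides
  gapped <- make_dna(synthetic_dna_spec(n_nucleotides = 12, gaps = 5))
  expect_equal(segment_stretches(gapped), c(7L, 4L))
  expect_equal(sum(segment_stretches(gapped)), nrow(gapped))
  both <- segment_stretches(list(h1 = p1, h2 = gapped))
  expect_equal(both$h1, 7L)
  expect_equal(both$h2, c(7L, 4L))
})

test_that("nucleotides are assigned to the contact-majority chain with ties to ring order", {
  prot <- tibble::tibble(
    chain = rep(c("A", "B", "C"), each = 3),
    resno = rep(1:3, 3), resname = "ALA", atom = rep(c("N", "CA", "C"), 3),
    elem = "C",
    x = rep(c(10, -10, 0), each = 3) + rep(c(0, 0.5, 1), 3),
    y = rep(c(0, 0, 10), each = 3),
    z = 0, het = FALSE, polymer = "protein"
  )
  dna <- tibble::tibble(
    chain = "M", resno = 1:3, resname = "DT", atom = "C1'", elem = "C",
    # nt1 near chain A; nt2 far from everything; nt3 equidistant A/B single atoms
    x = c(10.5, 100, 0), y = c(0, 100, 0), z = c(2, 50, 0),
    het = FALSE, polymer = "dna"
  )
  # give nt3 exactly one contact to A and one to B: add one atom each at +/-4
  extra <- tibble::tibble(
    chain = c("A", "B"), resno = 4L, resname = "ALA", atom = "CB", elem = "C",
    x = 0, y = c(4, -4), z = 0, het = FALSE, polymer = "protein"
  )
  asm <- as_assembly(dplyr::bind_rows(
    dplyr::arrange(dplyr::bind_rows(prot, extra), chain, resno), dna
  ))
  ring <- ring_definition(c("A", "B", "C"), c(1, 4))
  path <- extract_na_path(asm, "M")
  out <- assign_nucleotides(asm, ring, path, contact_cutoff = 4.5)
  expect_equal(out$assignments$assigned_chain, c("A", NA, "A"))
  expect_equal(out$per_subunit$n_nucleotides, c(2L, 0L, 0L))
  # counts stable to +/- 0.25 A cutoff changes on this fixture
  for (cut in c(4.25, 4.75)) {
    alt <- assign_nucleotides(asm, ring, path, contact_cutoff = cut)
    expect_equal(alt$per_subunit$n_nucleotides, out$per_subunit$n_nucleotides)
  }
})

test_that("full-occupancy capacity multiplies ring size by the binding increment", {
  expect_identical(full_occupancy_capacity(6, 4), 24L)
  expect_identical(full_occupancy_capacity(6, 1), 6L)
  expect_identical(full_occupancy_capacity(3, 2), 6L)
  expect_error(full_occupancy_capacity(0, 4), class = "rg_type_error")
  expect_error(full_occupancy_capacity(6, -1), class = "rg_type_error")
})
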