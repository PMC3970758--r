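#' Deterministic 30-point monomer template
#'
#' A fixed, chiral, non-planar pseudo-fold of 30 points (a few angstroms
#' across, helix-like) used as the default subunit for synthetic rings. It
#' is a closed-form function of the point index — no randomness — so
#' synthetic fixtures are stable across sessions and platforms.
#'
#' @return A 30 x 3 matrix, centered on its centroid.
#' @export
monomer_template <- function() {
  t <- seq_len(30)
  m <- cbind(
    2.3 * cos(0.9 * t) + 0.15 * t,
    2.3 * sin(0.9 * t) + 1.2 * cos(0.23 * t),
    0.9 * sin(0.31 * t) + 0.08 * t
  )
  sweep(m, 2, colMeans(m))
}

#' Specify a synthetic near-C_n ring
#'
#' @param n_subunits Number of subunits (>= 3).
#' @param ring_radius Distance of each subunit centroid from the axis
#'   (angstroms; default 20, the scale of an MCM N-tier ring).
#' @param monomer Template point matrix (default [monomer_template()]).
#' @param perturbation Either `NULL` (exact C_n), a data frame / list with
#'   per-subunit columns `radial_shift`, `tangential_shift`, `axial_shift`
#'   (angstroms) and `twist_deg`, or a named numeric vector of i.i.d.
#'   Gaussian sigmas for those four components (requires `seed`).
#' @param c_face_sign Which construction-axis direction (+z) points to the
#'   C-terminal face (default +1).
#' @param seed Integer seed; required for random (sigma) perturbations.
#' @return A list of class `rg_ring_spec`.
#' @export
synthetic_ring_spec <- function(n_subunits = 6, ring_radius = 20,
                                monomer = monomer_template(),
                                perturbation = NULL, c_face_sign = 1,
                                seed = NULL) {
  if (n_subunits < 3) {
    rlang::abort("need >= 3 subunits", class = "rg_type_error")
  }
  if (is.numeric(perturbation) && !is.null(names(perturbation)) && is.null(seed)) {
    rlang::abort("random (sigma) perturbations need an explicit seed",
      class = "rg_type_error"
    )
  }
  structure(
    list(
      n_subunits = as.integer(n_subunits), ring_radius = ring_radius,
      monomer = as_points(monomer), perturbation = perturbation,
      c_face_sign = c_face_sign, seed = seed
    ),
    class = "rg_ring_spec"
  )
}

rot_z <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
}

resolve_perturbation <- function(spec) {
  n <- spec$n_subunits
  zero <- tibble::tibble(
    radial_shift = numeric(n), tangential_shift = numeric(n),
    axial_shift = numeric(n), twist_deg = numeric(n)
  )
  p <- spec$perturbation
  if (is.null(p)) {
    return(zero)
  }
  if (is.numeric(p) && !is.null(names(p))) {
    sig <- function(nm) if (nm %in% names(p)) p[[nm]] else 0
    out <- withr::with_seed(spec$seed, tibble::tibble(
      radial_shift = stats::rnorm(n, 0, sig("radial_shift")),
      tangential_shift = stats::rnorm(n, 0, sig("tangential_shift")),
      axial_shift = stats::rnorm(n, 0, sig("axial_shift")),
      twist_deg = stats::rnorm(n, 0, sig("twist_deg"))
    ))
    return(out)
  }
  p <- tibble::as_tibble(as.list(p) |> lapply(function(v) rep_len(v, n)))
  for (col in names(zero)) if (!col %in% names(p)) p[[col]] <- 0
  p[, names(zero)]
}

#' Generate a synthetic near-C_n ring assembly
#'
#' Places `n` copies of the monomer template at equal angles about the +z
#' axis at the ring radius, then applies the per-subunit perturbations in
#' each subunit's local frame (radial = away from axis, tangential = along
#' the ring, axial = +z, twist = rotation about the local vertical through
#' the subunit centroid). With zero perturbation the assembly is exactly
#' C_n symmetric about z. Deterministic given the spec (and seed).
#'
#' @param spec An `rg_ring_spec`.
#' @return An `rg_assembly` (chains `A`, `B`, ...; one `CA` pseudo-atom
#'   per residue) with attributes `axis` (the construction `rg_axis`),
#'   `ring` (matching [ring_definition()]) and `perturbation` (the resolved
#'   per-subunit table) as ground truth.
#' @export
make_ring <- function(spec) {
  if (!inherits(spec, "rg_ring_spec")) {
    rlang::abort("spec must come from synthetic_ring_spec()", class = "rg_type_error")
  }
  n <- spec$n_subunits
  pert <- resolve_perturbation(spec)
  chains <- make_chain_ids(n)
  per_chain <- lapply(seq_len(n), function(k) {
    phi <- 360 * (k - 1) / n
    base <- spec$monomer %*% t(rot_z(pert$twist_deg[k])) # twist in local frame
    base <- sweep(base, 2, c(
      spec$ring_radius + pert$radial_shift[k],
      pert$tangential_shift[k],
      pert$axial_shift[k]
    ), "+")
    placed <- base %*% t(rot_z(phi))
    tibble::tibble(
      chain = chains[k],
      resno = seq_len(nrow(placed)),
      resname = "GLY", atom = "CA", elem = "C",
      x = placed[, 1], y = placed[, 2], z = placed[, 3],
      het = FALSE, polymer = "protein"
    )
  })
  out <- as_assembly(dplyr::bind_rows(per_chain))
  attr(out, "axis") <- channel_axis(c(0, 0, 1), c(0, 0, 0),
    c_face_sign = spec$c_face_sign
  )
  attr(out, "ring") <- ring_definition(chains,
    c(1, nrow(spec$monomer)),
    label = "synthetic ring"
  )
  attr(out, "perturbation") <- pert
  out
}

make_chain_ids <- function(n) {
  if (n <= 26) LETTERS[seq_len(n)] else as.character(seq_len(n))
}

#' Specify a synthetic single-stranded DNA path
#'
#' @param radius Path radius from the construction axis (angstroms).
#' @param z_offset Height of the first nucleotide (angstroms).
#' @param n_nucleotides Number of positions laid out (>= 3).
#' @param angular_step Signed step in degrees between consecutive
#'   nucleotides about +z; the sign fixes the handedness (negative =
#'   clockwise viewed from +z).
#' @param rise_per_nt Axial rise per nucleotide (angstroms; 0 = planar
#'   circle).
#' @param start_angle Angle of the first nucleotide (degrees).
#' @param gaps Integer positions (residue numbers) left unmodeled.
#' @return A list of class `rg_dna_spec`.
#' @export
synthetic_dna_spec <- function(radius = 14, z_offset = 0, n_nucleotides = 12,
                               angular_step = -30, rise_per_nt = 0,
                               start_angle = 0, gaps = integer(0)) {
  if (n_nucleotides < 3) {
    rlang::abort("need >= 3 nucleotides", class = "rg_type_error")
  }
  if (radius <= 0) {
    rlang::abort("radius must be positive", class = "rg_type_error")
  }
  structure(
    list(
      radius = radius, z_offset = z_offset,
      n_nucleotides = as.integer(n_nucleotides),
      angular_step = angular_step, rise_per_nt = rise_per_nt,
      start_angle = start_angle, gaps = as.integer(gaps)
    ),
    class = "rg_dna_spec"
  )
}

#' Generate a synthetic DNA path (and assembly chain)
#'
#' Lays nucleotide reference points on a circular or helical path about
#' +z; residue number i sits at `start_angle + (i-1) * angular_step`
#' degrees and height `z_offset + (i-1) * rise_per_nt`, so 5'-to-3' order
#' is construction order and the sign of `angular_step` fully determines
#' the polarity under a fixed view. Positions listed in `gaps` are
#' omitted, leaving numbering gaps.
#'
#' @param spec An `rg_dna_spec`.
#' @param chain Chain id for the DNA (default `"M"`).
#' @return An `rg_na_path` tibble with an `"assembly"` attribute holding
#'   the same nucleotides as an `rg_assembly` chain of `C1'` pseudo-atoms
#'   (dT residues), mergeable with a host ring via [merge_assemblies()].
#' @export
make_dna <- function(spec, chain = "M") {
  if (!inherits(spec, "rg_dna_spec")) {
    rlang::abort("spec must come from synthetic_dna_spec()", class = "rg_type_error")
  }
  i <- setdiff(seq_len(spec$n_nucleotides), spec$gaps)
  ang <- (spec$start_angle + (i - 1) * spec$angular_step) * pi / 180
  path <- tibble::tibble(
    chain = chain, resno = as.integer(i), base = "DT",
    x = spec$radius * cos(ang),
    y = spec$radius * sin(ang),
    z = spec$z_offset + (i - 1) * spec$rise_per_nt,
    ref_atom = "C1'"
  )
  asm <- as_assembly(tibble::tibble(
    chain = chain, resno = path$resno, resname = "DT", atom = "C1'",
    elem = "C", x = path$x, y = path$y, z = path$z,
    het = FALSE, polymer = "dna"
  ))
  gaps <- path |>
    dplyr::group_by(.data$chain) |>
    dplyr::reframe(gap_after = .data$resno[c(diff(.data$resno) > 1, FALSE)])
  attr(path, "gaps") <- gaps
  attr(path, "assembly") <- asm
  class(path) <- unique(c("rg_na_path", class(path)))
  path
}

#' Merge two assemblies into one
#'
#' @param ... `rg_assembly` objects with disjoint chain ids.
#' @return A single `rg_assembly`; ground-truth attributes of the first
#'   argument are carried over.
#' @export
merge_assemblies <- function(...) {
  parts <- list(...)
  out <- as_assembly(dplyr::bind_rows(lapply(parts, tibble::as_tibble)))
  for (at in c("axis", "ring", "perturbation")) {
    if (!is.null(attr(parts[[1]], at))) attr(out, at) <- attr(parts[[1]], at)
  }
  out
}

#' Simulate an EMSA titration from the Hill model
#'
#' Evaluates the Hill free/bound fractions at each concentration and adds
#' independent Gaussian noise to both bands, truncating the noisy
#' fractions to [0, 1] (a simple error model; the forward model itself is
#' [hill_model()]). Deterministic given the seed.
#'
#' @param conc Concentration ladder (uM).
#' @param k_half,h True Hill parameters.
#' @param noise_sd Noise standard deviation on the fraction scale
#'   (default 0).
#' @param seed Integer seed (required when `noise_sd > 0`).
#' @return A tibble with `conc`, `frac_free`, `frac_bound`.
#' @export
simulate_titration <- function(conc, k_half, h, noise_sd = 0, seed = NULL) {
  if (noise_sd < 0) rlang::abort("noise_sd must be >= 0", class = "rg_domain_error")
  if (noise_sd > 0 && is.null(seed)) {
    rlang::abort("noisy simulations need an explicit seed", class = "rg_type_error")
  }
  out <- hill_model(conc, k_half, h)
  if (noise_sd > 0) {
    out <- withr::with_seed(seed, dplyr::mutate(out,
      frac_free = pmin(1, pmax(0, .data$frac_free + stats::rnorm(dplyr::n(), 0, noise_sd))),
      frac_bound = pmin(1, pmax(0, .data$frac_bound + stats::rnorm(dplyr::n(), 0, noise_sd)))
    ))
  }
  out
}

#' The printed wild-type EMSA concentration ladder
#'
#' Nine-point protein concentration series (uM) used for the wild-type
#' ssDNA titration; exported so simulations and examples share it.
#' @return Numeric vector of length 9.
#' @export
wt_conc_ladder <- function() {
  c(1.4, 2, 2.7, 6.8, 13.5, 20.3, 27, 40.5, 54)
}
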