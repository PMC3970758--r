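#' Build a run configuration
#'
#' Validates and normalizes the configuration for [run_full_analysis()].
#' Unknown fields are rejected so typos fail before any computation.
#'
#' @param structure Path to a coordinate file (PDB/mmCIF).
#' @param rings List of ring specifications, each a list with `chains`
#'   (character vector in ring order), `subdomain` (length-2 residue
#'   range), optional `label` and `dna_chains` (character vector of the
#'   DNA chains bound by that ring).
#' @param probe A list of [probe_spec()] arguments (or an `rg_probe_spec`).
#' @param axis_method `"permutation_rotation"` or `"inertia"`.
#' @param c_face_sign +1 or -1 viewing convention.
#' @param view_from `"c_face"` or `"n_face"` for polarity.
#' @param bin_width Channel profile bin width (angstroms).
#' @param contact_cutoff Nucleotide-assignment contact cutoff (angstroms).
#' @param out_dir Optional output directory for TSV/JSON reports.
#' @return A validated list of class `rg_config`.
#' @export
run_config <- function(structure, rings, probe = list(),
                       axis_method = c("permutation_rotation", "inertia"),
                       c_face_sign = 1,
                       view_from = c("c_face", "n_face"),
                       bin_width = 1.0, contact_cutoff = 4.5,
                       out_dir = NULL) {
  axis_method <- match.arg(axis_method)
  view_from <- match.arg(view_from)
  if (!inherits(probe, "rg_probe_spec")) {
    known <- names(formals(probe_spec))
    unknown <- setdiff(names(probe), known)
    if (length(unknown)) {
      rlang::abort(paste0("unknown probe field(s): ", paste(unknown, collapse = ", ")),
        class = "rg_config_error"
      )
    }
    probe <- do.call(probe_spec, probe)
  }
  if (!length(rings)) {
    rlang::abort("at least one ring must be configured", class = "rg_config_error")
  }
  rings <- lapply(rings, function(r) {
    unknown <- setdiff(names(r), c("chains", "subdomain", "label", "dna_chains"))
    if (length(unknown)) {
      rlang::abort(paste0("unknown ring field(s): ", paste(unknown, collapse = ", ")),
        class = "rg_config_error"
      )
    }
    list(
      ring = ring_definition(r$chains, r$subdomain,
        label = r$label %||% paste(r$chains, collapse = "")
      ),
      dna_chains = as.character(r$dna_chains %||% character(0))
    )
  })
  structure(
    list(
      structure = structure, rings = rings, probe = probe,
      axis_method = axis_method, c_face_sign = c_face_sign,
      view_from = view_from, bin_width = bin_width,
      contact_cutoff = contact_cutoff, out_dir = out_dir
    ),
    class = "rg_config"
  )
}

#' Read a run configuration from YAML
#'
#' @param path YAML file whose top-level keys are the arguments of
#'   [run_config()].
#' @return An `rg_config`.
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- setdiff(names(formals(run_config)), "")
  unknown <- setdiff(names(y), known)
  if (length(unknown)) {
    rlang::abort(paste0("unknown config key(s): ", paste(unknown, collapse = ", ")),
      class = "rg_config_error"
    )
  }
  do.call(run_config, y)
}

#' Run the full ring/DNA analysis
#'
#' For each configured ring: the cyclic-permutation symmetry statistic and
#' per-subunit deviations, the channel axis and radius profile with its
#' narrowest point, the probe-distance classification of all consecutive
#' interfaces, and — when DNA chains are configured — the DNA polarity,
#' planarity, contiguous stretches and per-subunit nucleotide assignment.
#' When `out_dir` is set, tabular results are written as TSV and the
#' summary as JSON.
#'
#' @param config An `rg_config` from [run_config()] or [read_config()], or
#'   a path to a YAML config.
#' @return A list of class `rg_report`, one element per ring, each holding
#'   `symmetry`, `axis`, `profile`, `narrowest`, `interfaces` and (with
#'   DNA) `dna` (list: `polarity`, `planarity_deg`, `stretches`,
#'   `assignment`, `occupancy`).
#' @export
run_full_analysis <- function(config) {
  if (is.character(config)) config <- read_config(config)
  if (!inherits(config, "rg_config")) {
    rlang::abort("config must be an rg_config or a YAML path", class = "rg_config_error")
  }
  assembly <- if (inherits(config$structure, "rg_assembly")) {
    config$structure
  } else {
    read_assembly(config$structure)
  }
  reports <- lapply(config$rings, function(rc) {
    ring <- as_ring(rc$ring, assembly)
    sym <- permutation_rmsd(assembly, ring, c_face_sign = config$c_face_sign)
    axis <- fit_axis(assembly, ring,
      method = config$axis_method,
      c_face_sign = config$c_face_sign
    )
    ring_chain_atoms <- function(a) a$chain %in% ring$chains & a$polymer == "protein"
    profile <- radial_profile(assembly, axis,
      selection = ring_chain_atoms,
      bin_width = config$bin_width
    )
    interfaces <- classify_ring_interfaces(assembly, ring, config$probe)
    dna <- NULL
    if (length(rc$dna_chains)) {
      path <- extract_na_path(assembly, rc$dna_chains)
      assignment <- assign_nucleotides(assembly, ring, path,
        contact_cutoff = config$contact_cutoff
      )
      occupancy <- tibble::tibble(
        chain_i = ring$chains,
        dna_bound = ring$chains %in%
          assignment$assignments$assigned_chain
      )
      dna <- list(
        polarity = polarity(path, axis, view_from = config$view_from),
        planarity_deg = planarity(path, axis),
        stretches = segment_stretches(path),
        assignment = assignment,
        occupancy = engagement_vs_dna(interfaces, occupancy)
      )
    }
    list(
      label = ring$label, symmetry = sym, axis = axis, profile = profile,
      narrowest = narrowest_point(profile), interfaces = interfaces, dna = dna
    )
  })
  names(reports) <- vapply(reports, function(r) r$label, character(1))
  out <- structure(reports, class = "rg_report")
  if (!is.null(config$out_dir)) write_report(out, config$out_dir)
  out
}

#' Write an analysis report to disk
#'
#' @param report An `rg_report` from [run_full_analysis()].
#' @param out_dir Directory (created if needed); per-ring TSV tables plus
#'   one `summary.json` with full precision values.
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  summary <- lapply(report, function(r) {
    slug <- gsub("[^A-Za-z0-9]+", "_", r$label)
    utils::write.table(
      tidy(r$symmetry),
      file.path(out_dir, paste0(slug, "_symmetry.tsv")),
      sep = "\t", row.names = FALSE, quote = FALSE
    )
    utils::write.table(
      r$profile,
      file.path(out_dir, paste0(slug, "_profile.tsv")),
      sep = "\t", row.names = FALSE, quote = FALSE
    )
    utils::write.table(
      r$interfaces,
      file.path(out_dir, paste0(slug, "_interfaces.tsv")),
      sep = "\t", row.names = FALSE, quote = FALSE
    )
    s <- list(
      label = r$label,
      permutation_rmsd = r$symmetry$permutation_rmsd,
      rotation_angle = r$symmetry$rotation_angle,
      axis_direction = r$axis$direction,
      narrowest_z = r$narrowest$z,
      narrowest_radius = r$narrowest$min_radius,
      interfaces = as.list(stats::setNames(
        r$interfaces$distance,
        paste0(r$interfaces$chain_i, "-", r$interfaces$chain_j)
      ))
    )
    if (!is.null(r$dna)) {
      s$dna <- list(
        sense = r$dna$polarity$sense,
        net_sweep = r$dna$polarity$net_sweep,
        planarity_deg = r$dna$planarity_deg,
        stretches = r$dna$stretches,
        per_subunit_nt = as.list(stats::setNames(
          r$dna$assignment$per_subunit$n_nucleotides,
          r$dna$assignment$per_subunit$assigned_chain
        ))
      )
    }
    s
  })
  jsonlite::write_json(
    list(schema = "ringgeom-report/1", rings = summary),
    file.path(out_dir, "summary.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(out_dir)
}

#' @export
print.rg_report <- function(x, ...) {
  for (r in x) {
    cat(sprintf(
      "== %s: permutation RMSD %.3f Å, rotation %.2f°, narrowest %.3f Å at z %.1f\n",
      r$label, r$symmetry$permutation_rmsd, r$symmetry$rotation_angle,
      r$narrowest$min_radius, r$narrowest$z
    ))
    cls <- table(r$interfaces$engagement)
    cat(
      "   interfaces:",
      paste(names(cls), as.integer(cls), sep = "=", collapse = " "), "\n"
    )
    if (!is.null(r$dna)) {
      cat(sprintf(
        "   DNA: %s (sweep %.1f°), plane tilt %.2f°, stretches [%s]\n",
        r$dna$polarity$sense, r$dna$polarity$net_sweep, r$dna$planarity_deg,
        paste(r$dna$stretches, collapse = ", ")
      ))
    }
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
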