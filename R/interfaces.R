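#' Specify the intersubunit probe-distance metric
#'
#' The engagement metric is the distance between one named atom on subunit
#' i and one on its neighbor in a stated angular direction. For PfMCM the
#' defaults are the residue-201 C-alpha of subunit i and the residue-127
#' C-alpha of the counterclockwise neighbor (viewed from the C-terminal
#' face), with interfaces classed engaged below 7.5 A and disengaged above
#' 8.4 A; both residues and thresholds are configuration, not constants,
#' so the metric transfers to other rings.
#'
#' @param residue_a,atom_a Residue number and atom name on subunit i.
#' @param residue_b,atom_b Residue number and atom name on the neighbor.
#' @param neighbor_direction `"counterclockwise"` (default) or
#'   `"clockwise"`, resolved through the channel-axis viewing convention.
#' @param tau_engaged,tau_disengaged Distance thresholds in angstroms;
#'   `0 < tau_engaged <= tau_disengaged`.
#' @return A list of class `rg_probe_spec`.
#' @export
probe_spec <- function(residue_a = 201, atom_a = "CA",
                       residue_b = 127, atom_b = "CA",
                       neighbor_direction = c("counterclockwise", "clockwise"),
                       tau_engaged = 7.5, tau_disengaged = 8.4) {
  neighbor_direction <- match.arg(neighbor_direction)
  if (!(tau_engaged > 0 && tau_engaged <= tau_disengaged)) {
    rlang::abort("need 0 < tau_engaged <= tau_disengaged", class = "rg_type_error")
  }
  structure(
    list(
      residue_a = as.integer(residue_a), atom_a = atom_a,
      residue_b = as.integer(residue_b), atom_b = atom_b,
      neighbor_direction = neighbor_direction,
      tau_engaged = tau_engaged, tau_disengaged = tau_disengaged
    ),
    class = "rg_probe_spec"
  )
}

lookup_atom <- function(assembly, chain, resno, atom) {
  hit <- assembly[
    assembly$chain == chain & assembly$resno == resno &
      assembly$insert == "" & assembly$atom == atom, ,
    drop = FALSE
  ]
  if (nrow(hit) == 0) {
    rlang::abort(
      sprintf("atom not found: chain %s residue %d atom %s", chain, resno, atom),
      class = "rg_lookup_error"
    )
  }
  as.numeric(hit[1, c("x", "y", "z")])
}

#' Probe distance between two subunits
#'
#' Euclidean distance between the probe atom of `chain_i` and the partner
#' probe atom of `chain_j`.
#'
#' @param assembly An `rg_assembly`.
#' @param chain_i,chain_j Chain ids of the subunit pair (residue_a is read
#'   from `chain_i`, residue_b from `chain_j`).
#' @param probe An `rg_probe_spec`.
#' @return Distance in angstroms.
#' @export
probe_distance <- function(assembly, chain_i, chain_j, probe = probe_spec()) {
  assembly <- as_assembly(assembly)
  pa <- lookup_atom(assembly, chain_i, probe$residue_a, probe$atom_a)
  pb <- lookup_atom(assembly, chain_j, probe$residue_b, probe$atom_b)
  sqrt(sum((pa - pb)^2))
}

classify_distance <- function(d, probe) {
  dplyr::case_when(
    d < probe$tau_engaged ~ "engaged",
    d > probe$tau_disengaged ~ "disengaged",
    TRUE ~ "intermediate"
  )
}

#' Classify every consecutive interface of a ring
#'
#' Walks the ring in order (which is counterclockwise under the axis
#' viewing convention) and measures the probe distance for each wrap-around
#' consecutive pair, classifying each interface as `engaged`
#' (distance < tau_engaged), `disengaged` (> tau_disengaged) or
#' `intermediate`. Distances exactly at a threshold fall in the
#' intermediate class, matching the strict inequalities of the
#' classification rule.
#'
#' @inheritParams probe_distance
#' @param ring An `rg_ring`; its chain order defines the counterclockwise
#'   sense.
#' @return A tibble (`chain_i`, `chain_j`, `distance`, `engagement`) with
#'   one row per interface, in ring order.
#' @export
classify_ring_interfaces <- function(assembly, ring, probe = probe_spec()) {
  assembly <- as_assembly(assembly)
  ring <- as_ring(ring, assembly)
  n <- length(ring$chains)
  nb <- if (probe$neighbor_direction == "counterclockwise") 1L else -1L
  j <- ring$chains[((seq_len(n) - 1 + nb) %% n) + 1]
  d <- vapply(seq_len(n), function(k) {
    tryCatch(
      probe_distance(assembly, ring$chains[k], j[k], probe),
      rg_lookup_error = function(e) {
        rlang::abort(
          paste0("interface ", ring$chains[k], "-", j[k], ": ", conditionMessage(e)),
          class = "rg_lookup_error"
        )
      }
    )
  }, numeric(1))
  tibble::tibble(
    chain_i = ring$chains,
    chain_j = j,
    distance = d,
    engagement = factor(classify_distance(d, probe),
      levels = c("engaged", "intermediate", "disengaged")
    )
  )
}

#' Cross engagement classes with observed DNA occupancy
#'
#' Joins the interface classification with a per-interface DNA occupancy
#' annotation (e.g. whether nucleotides were assigned to the interface's
#' first subunit) and counts concordant and discordant interfaces. Under
#' the engagement model, engaged interfaces should carry DNA and
#' disengaged ones should not; `intermediate` interfaces are reported but
#' excluded from the concordance counts by default, since the model makes
#' no prediction between the two thresholds.
#'
#' @param records Interface tibble from [classify_ring_interfaces()].
#' @param dna_occupancy Data frame with columns `chain_i` and `dna_bound`
#'   (logical), one row per interface first-subunit.
#' @param count_intermediate Include intermediate interfaces in the
#'   concordance counts (default FALSE).
#' @return A list with `table` (per-interface join with a `concordant`
#'   column) and `counts` (n_concordant, n_discordant, n_intermediate).
#' @export
engagement_vs_dna <- function(records, dna_occupancy, count_intermediate = FALSE) {
  if (!all(records$chain_i %in% dna_occupancy$chain_i)) {
    rlang::abort("dna_occupancy does not cover the ring", class = "rg_type_error")
  }
  tab <- dplyr::left_join(records, dna_occupancy, by = "chain_i") |>
    dplyr::mutate(
      concordant = dplyr::case_when(
        .data$engagement == "engaged" ~ .data$dna_bound,
        .data$engagement == "disengaged" ~ !.data$dna_bound,
        TRUE ~ NA
      )
    )
  scored <- if (count_intermediate) {
    dplyr::mutate(tab, concordant = dplyr::coalesce(.data$concordant, FALSE))
  } else {
    tab[!is.na(tab$concordant), ]
  }
  list(
    table = tab,
    counts = tibble::tibble(
      n_concordant = sum(scored$concordant, na.rm = TRUE),
      n_discordant = sum(!scored$concordant, na.rm = TRUE),
      n_intermediate = sum(tab$engagement == "intermediate")
    )
  )
}

#' Plot interface distances against the engagement thresholds
#'
#' @param records Tibble from [classify_ring_interfaces()].
#' @param probe The `rg_probe_spec` used (for threshold lines).
#' @return A ggplot of interfaces sorted by distance.
#' @export
plot_interfaces <- function(records, probe = probe_spec()) {
  records <- dplyr::mutate(records,
    interface = paste0(.data$chain_i, "→", .data$chain_j)
  )
  ggplot2::ggplot(
    records,
    ggplot2::aes(
      x = stats::reorder(.data$interface, .data$distance),
      y = .data$distance, fill = .data$engagement
    )
  ) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = probe$tau_engaged, linetype = "dashed") +
    ggplot2::geom_hline(yintercept = probe$tau_disengaged, linetype = "dotted") +
    ggplot2::labs(x = "interface", y = "probe distance (Å)") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
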