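#' Read an atomic assembly into a tidy atom table
#'
#' Parses a PDB or mmCIF coordinate file and returns one row per atom with
#' chain, residue and atom identifiers plus Cartesian coordinates in
#' angstroms. Heteroatoms (metals, ligands, waters) are retained and flagged
#' by `het`; each chain is classified as `"protein"`, `"dna"` or `"other"`
#' from its residue names. Author residue numbering is used throughout.
#'
#' Alternate locations are reduced to a single conformer per atom: the
#' highest-occupancy altloc is kept, ties resolved in favour of altloc
#' `"A"` (then alphabetically). Insertion-coded residues are kept as
#' distinct residues ordered after their base number.
#'
#' @param path Path to a coordinate file.
#' @param format `"pdb"`, `"cif"`, or `"auto"` (default) to infer from the
#'   file extension (`.cif`/`.mmcif` are mmCIF, anything else PDB).
#' @return A tibble of class `rg_assembly` with columns `chain`, `resno`,
#'   `insert`, `resname`, `atom`, `elem`, `x`, `y`, `z`, `het`, `polymer`.
#' @examples
#' ring <- make_ring(synthetic_ring_spec(n_subunits = 6))
#' tmp <- tempfile(fileext = ".pdb")
#' write_assembly_pdb(ring, tmp)
#' read_assembly(tmp)
#' @export
read_assembly <- function(path, format = c("auto", "pdb", "cif")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    rlang::abort(paste0("coordinate file not found: ", path), class = "rg_io_error")
  }
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("cif", "mmcif")) "cif" else "pdb"
  }
  pdb <- tryCatch(
    # read.cif emits advisory warnings (beta status, secondary-structure
    # records) that are irrelevant to coordinate extraction
    if (format == "cif") suppressWarnings(bio3d::read.cif(path, verbose = FALSE))
    else bio3d::read.pdb(path, verbose = FALSE),
    error = function(e) {
      rlang::abort(
        paste0("could not parse '", path, "' as ", format, ": ", conditionMessage(e)),
        class = "rg_parse_error"
      )
    }
  )
  as_assembly(pdb_to_tibble(pdb))
}

# bio3d 'pdb' object -> plain atom tibble (altloc reduction happens here)
pdb_to_tibble <- function(pdb) {
  a <- pdb$atom
  tb <- tibble::tibble(
    chain   = as.character(a$chain),
    resno   = as.integer(a$resno),
    insert  = ifelse(is.na(a$insert) | a$insert == "", "", as.character(a$insert)),
    resname = as.character(a$resid),
    atom    = as.character(a$elety),
    elem    = guess_element(a$elesy, a$elety),
    x       = as.numeric(a$x),
    y       = as.numeric(a$y),
    z       = as.numeric(a$z),
    het     = a$type != "ATOM",
    o       = if (is.null(a$o)) 1 else ifelse(is.na(a$o), 1, as.numeric(a$o)),
    alt     = if (is.null(a$alt)) "" else ifelse(is.na(a$alt), "", as.character(a$alt))
  )
  tb$chain[is.na(tb$chain)] <- " "
  chain_order <- unique(tb$chain)
  tb$row0 <- seq_len(nrow(tb))
  # altloc: keep highest occupancy; ties -> "A", then alphabetical
  tb <- tb |>
    dplyr::group_by(.data$chain, .data$resno, .data$insert, .data$atom) |>
    dplyr::arrange(
      dplyr::desc(.data$o), .data$alt != "A", .data$alt,
      .by_group = TRUE
    ) |>
    dplyr::slice(1L) |>
    dplyr::ungroup()
  tb <- tb[order(match(tb$chain, chain_order), tb$resno, tb$insert, tb$row0), ]
  tb$polymer <- classify_polymer(tb$resname, tb$chain, tb$het)
  tb |> dplyr::select(
    "chain", "resno", "insert", "resname", "atom", "elem",
    "x", "y", "z", "het", "polymer"
  )
}

guess_element <- function(elesy, elety) {
  e <- rep_len(as.character(elesy), length(elety))
  miss <- is.na(e) | e == ""
  # fall back to first alphabetic character of the atom name
  e[miss] <- toupper(substr(gsub("[^A-Za-z].*$", "", gsub("^[0-9]+", "", elety[miss])), 1, 1))
  trimws(e)
}

AMINO3 <- c(
  "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
  "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL",
  "MSE", "SEC", "PYL"
)
NUC_RES <- c("DA", "DC", "DG", "DT", "DU", "DI", "A", "C", "G", "U", "I")

classify_polymer <- function(resname, chain, het) {
  per_chain <- vapply(split(seq_along(chain), chain), function(i) {
    rn <- resname[i][!het[i]]
    if (!length(rn)) rn <- resname[i]
    if (mean(rn %in% AMINO3) > 0.5) "protein"
    else if (mean(rn %in% NUC_RES) > 0.5) "dna"
    else "other"
  }, character(1))
  unname(per_chain[chain])
}

#' Coerce an atom data frame to an assembly
#'
#' Validates the assembly invariants: chain blocks are contiguous (a chain
#' id may not reappear after another chain has started), residues are
#' strictly increasing within each chain (insertion codes order after the
#' base number), and all coordinates are finite.
#'
#' @param df Data frame with at least `chain`, `resno`, `resname`, `atom`,
#'   `x`, `y`, `z`. Missing `insert`, `elem`, `het`, `polymer` columns are
#'   filled with defaults.
#' @return A tibble of class `rg_assembly`.
#' @export
as_assembly <- function(df) {
  df <- tibble::as_tibble(df)
  needed <- c("chain", "resno", "resname", "atom", "x", "y", "z")
  miss <- setdiff(needed, names(df))
  if (length(miss)) {
    rlang::abort(paste0("missing columns: ", paste(miss, collapse = ", ")),
      class = "rg_type_error"
    )
  }
  if (!"insert" %in% names(df)) df$insert <- ""
  if (!"het" %in% names(df)) df$het <- FALSE
  if (!"elem" %in% names(df)) df$elem <- guess_element("", df$atom)
  if (!"polymer" %in% names(df)) {
    df$polymer <- classify_polymer(df$resname, df$chain, df$het)
  }
  if (!all(is.finite(df$x) & is.finite(df$y) & is.finite(df$z))) {
    rlang::abort("non-finite atom coordinates", class = "rg_invariant_error")
  }
  blocks <- rle(df$chain)$values
  if (anyDuplicated(blocks)) {
    rlang::abort(
      paste0(
        "duplicate chain id(s): ",
        paste(unique(blocks[duplicated(blocks)]), collapse = ", ")
      ),
      class = "rg_invariant_error"
    )
  }
  res_ok <- df |>
    dplyr::distinct(.data$chain, .data$resno, .data$insert) |>
    dplyr::group_by(.data$chain) |>
    dplyr::summarise(
      ok = all(diff(.data$resno) > 0 | (diff(.data$resno) == 0 &
        utils::tail(.data$insert, -1) > utils::head(.data$insert, -1))),
      .groups = "drop"
    )
  if (!all(res_ok$ok)) {
    rlang::abort(
      paste0(
        "residue numbers not strictly increasing in chain(s): ",
        paste(res_ok$chain[!res_ok$ok], collapse = ", ")
      ),
      class = "rg_invariant_error"
    )
  }
  class(df) <- unique(c("rg_assembly", class(df)))
  df
}

#' Write an assembly to a PDB file
#'
#' Coordinates are written at PDB precision (3 decimals), so a read/write
#' round trip preserves them to 1e-3 angstrom.
#'
#' @param assembly An `rg_assembly` tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_assembly_pdb <- function(assembly, path) {
  assembly <- as_assembly(assembly)
  xyz <- as.vector(t(as.matrix(assembly[, c("x", "y", "z")])))
  bio3d::write.pdb(
    file = path,
    xyz = xyz,
    type = ifelse(assembly$het, "HETATM", "ATOM"),
    resno = assembly$resno,
    resid = assembly$resname,
    insert = ifelse(assembly$insert == "", "", assembly$insert),
    chain = assembly$chain,
    elety = assembly$atom,
    elesy = assembly$elem
  )
  invisible(path)
}

#' Define a ring of subunits for symmetry and channel analysis
#'
#' A ring definition names the chains in ring order (counterclockwise when
#' viewed from the face declared by the channel-axis convention) and the
#' inclusive residue-number range of the subdomain used for superposition
#' (for MCM N-domains, the OB-fold "C" subdomain; the range is structure
#' specific and must be supplied by the user).
#'
#' @param chains Character vector of >= 3 chain ids in ring order.
#' @param subdomain Length-2 integer vector, inclusive residue range.
#' @param label Optional label for reports.
#' @return A list of class `rg_ring`.
#' @export
ring_definition <- function(chains, subdomain, label = "ring") {
  chains <- as.character(chains)
  if (length(chains) < 3 || anyDuplicated(chains)) {
    rlang::abort("a ring needs >= 3 distinct chain ids", class = "rg_type_error")
  }
  subdomain <- as.integer(subdomain)
  if (length(subdomain) != 2 || diff(subdomain) < 0) {
    rlang::abort("subdomain must be an inclusive [start, end] residue range",
      class = "rg_type_error"
    )
  }
  structure(
    list(chains = chains, subdomain = subdomain, label = as.character(label)),
    class = "rg_ring"
  )
}

as_ring <- function(ring, assembly = NULL) {
  if (!inherits(ring, "rg_ring")) {
    rlang::abort("`ring` must be created with ring_definition()", class = "rg_type_error")
  }
  if (!is.null(assembly)) {
    missing <- setdiff(ring$chains, unique(assembly$chain))
    if (length(missing)) {
      rlang::abort(
        paste0("ring chains absent from assembly: ", paste(missing, collapse = ", ")),
        class = "rg_selection_error"
      )
    }
  }
  ring
}

#' Select corresponding atom coordinates across ring chains
#'
#' Extracts one named atom (default the C-alpha) from every residue of the
#' subdomain range in each ring chain. Residues are matched across chains by
#' author residue number; residues not resolvable (with the named atom) in
#' every chain are dropped everywhere (intersection rule) with a warning, so
#' the returned per-chain coordinate matrices share row-by-row
#' correspondence.
#'
#' @param assembly An `rg_assembly`.
#' @param ring An `rg_ring` from [ring_definition()].
#' @param atom_name Atom name to extract (default `"CA"`).
#' @return A list with `coords` (named list of n_res x 3 matrices, one per
#'   chain, in ring order) and `correspondence` (tibble of the residue
#'   numbers used, plus which were dropped).
#' @export
select_coords <- function(assembly, ring, atom_name = "CA") {
  assembly <- as_assembly(assembly)
  ring <- as_ring(ring, assembly)
  rng <- ring$subdomain
  sel <- assembly |>
    dplyr::filter(
      .data$chain %in% ring$chains,
      .data$resno >= rng[1], .data$resno <= rng[2],
      .data$insert == "",
      .data$atom == atom_name
    )
  if (nrow(sel) == 0) {
    rlang::abort(
      paste0("no '", atom_name, "' atoms in residues ", rng[1], "-", rng[2]),
      class = "rg_selection_error"
    )
  }
  by_chain <- split(sel, factor(sel$chain, levels = ring$chains))
  resno_common <- Reduce(intersect, lapply(by_chain, function(d) d$resno))
  if (length(resno_common) == 0) {
    rlang::abort("empty residue intersection across ring chains",
      class = "rg_selection_error"
    )
  }
  all_resno <- sort(unique(sel$resno))
  dropped <- setdiff(all_resno, resno_common)
  if (length(dropped)) {
    rlang::warn(paste0(
      "dropping ", length(dropped),
      " residue(s) unresolved in some chain(s): ",
      paste(utils::head(dropped, 10), collapse = ", "),
      if (length(dropped) > 10) " ..." else ""
    ))
  }
  resno_common <- sort(resno_common)
  coords <- lapply(by_chain, function(d) {
    d <- d[match(resno_common, d$resno), ]
    m <- as.matrix(d[, c("x", "y", "z")])
    rownames(m) <- resno_common
    m
  })
  list(
    coords = coords,
    correspondence = tibble::tibble(
      resno = all_resno,
      used = all_resno %in% resno_common
    )
  )
}

#' Extract a nucleic-acid path from an assembly
#'
#' Orders the nucleotides of the given DNA chains by ascending residue
#' number (taken as 5' to 3') and records one reference point per
#' nucleotide: the C1' atom if present, else the phosphate P.
#'
#' @param assembly An `rg_assembly`.
#' @param chain_ids Character vector of nucleic-acid chain ids.
#' @return A tibble of class `rg_na_path` with columns `chain`, `resno`,
#'   `base`, `x`, `y`, `z`, `ref_atom`; gaps in residue numbering are
#'   recorded in the `"gaps"` attribute as a tibble of missing runs.
#' @export
extract_na_path <- function(assembly, chain_ids) {
  assembly <- as_assembly(assembly)
  chain_ids <- as.character(chain_ids)
  missing <- setdiff(chain_ids, unique(assembly$chain))
  if (length(missing)) {
    rlang::abort(paste0("chain(s) not in assembly: ", paste(missing, collapse = ", ")),
      class = "rg_selection_error"
    )
  }
  kinds <- assembly |>
    dplyr::filter(.data$chain %in% chain_ids) |>
    dplyr::distinct(.data$chain, .data$polymer)
  bad <- kinds$chain[kinds$polymer != "dna"]
  if (length(bad)) {
    rlang::abort(paste0("chain(s) not nucleic acid: ", paste(bad, collapse = ", ")),
      class = "rg_type_error"
    )
  }
  nt <- assembly |>
    dplyr::filter(.data$chain %in% chain_ids, .data$atom %in% c("C1'", "P")) |>
    dplyr::group_by(.data$chain, .data$resno, .data$resname) |>
    dplyr::arrange(.data$atom != "C1'", .by_group = TRUE) |>
    dplyr::slice(1L) |>
    dplyr::ungroup() |>
    dplyr::arrange(match(.data$chain, chain_ids), .data$resno)
  path <- tibble::tibble(
    chain = nt$chain, resno = nt$resno, base = nt$resname,
    x = nt$x, y = nt$y, z = nt$z,
    ref_atom = nt$atom
  )
  gaps <- path |>
    dplyr::group_by(.data$chain) |>
    dplyr::reframe(gap_after = .data$resno[c(diff(.data$resno) > 1, FALSE)])
  attr(path, "gaps") <- gaps
  class(path) <- unique(c("rg_na_path", class(path)))
  path
}

# full atom set of the path's nucleotides, heavy atoms only
na_path_atoms <- function(assembly, path) {
  assembly |>
    dplyr::filter(
      .data$chain %in% unique(path$chain),
      .data$elem != "H"
    ) |>
    dplyr::semi_join(path, by = c("chain", "resno"))
}
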