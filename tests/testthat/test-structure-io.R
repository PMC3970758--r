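test_that("a minimal PDB parses into a one-chain, two-atom assembly", {
  path <- write_mini_pdb(c(
    pdb_line(1, "N", "ALA", "A", 1, 1.000, 2.000, 3.000),
    pdb_line(2, "CA", "ALA", "A", 1, 2.500, 2.000, 3.000)
  ))
  asm <- read_assembly(path)
  expect_s3_class(asm, "rg_assembly")
  expect_equal(nrow(asm), 2)
  expect_equal(unique(asm$chain), "A")
  expect_equal(asm$x, c(1.0, 2.5))
  expect_equal(unique(asm$polymer), "protein")
})

test_that("the same model read from PDB and mmCIF gives identical coordinates", {
  pdb_path <- write_mini_pdb(c(
    pdb_line(1, "N", "ALA", "A", 1, 1.234, -2.345, 3.456),
    pdb_line(2, "CA", "ALA", "A", 1, 2.500, 0.125, -3.875)
  ))
  cif_path <- tempfile(fileext = ".cif")
  writeLines(c(
    "data_mini",
    "loop_",
    "_atom_site.group_PDB",
    "_atom_site.id",
    "_atom_site.type_symbol",
    "_atom_site.label_atom_id",
    "_atom_site.label_alt_id",
    "_atom_site.label_comp_id",
    "_atom_site.label_asym_id",
    "_atom_site.label_entity_id",
    "_atom_site.label_seq_id",
    "_atom_site.pdbx_PDB_ins_code",
    "_atom_site.Cartn_x",
    "_atom_site.Cartn_y",
    "_atom_site.Cartn_z",
    "_atom_site.occupancy",
    "_atom_site.B_iso_or_equiv",
    "_atom_site.pdbx_formal_charge",
    "_atom_site.auth_seq_id",
    "_atom_site.auth_comp_id",
    "_atom_site.auth_asym_id",
    "_atom_site.auth_atom_id",
    "_atom_site.pdbx_PDB_model_num",
    "ATOM 1 N N . ALA A 1 1 ? 1.234 -2.345 3.456 1.00 0.00 ? 1 ALA A N 1",
    "ATOM 2 C CA . ALA A 1 1 ? 2.500 0.125 -3.875 1.00 0.00 ? 1 ALA A CA 1"
  ), cif_path)
  from_pdb <- read_assembly(pdb_path)
  from_cif <- read_assembly(cif_path)
  expect_equal(
    from_cif[, c("chain", "resno", "atom", "x", "y", "z")],
    from_pdb[, c("chain", "resno", "atom", "x", "y", "z")]
  )
})

test_that("non-contiguous (duplicate) chain blocks are rejected", {
  df <- tibble::tibble(
    chain = c("A", "B", "A"), resno = c(1L, 1L, 2L), resname = "ALA",
    atom = "CA", x = 1:3 + 0, y = 0, z = 0
  )
  expect_error(as_assembly(df), class = "rg_invariant_error")
})

test_that("non-increasing residue numbers and non-finite coordinates are rejected", {
  bad_order <- tibble::tibble(
    chain = "A", resno = c(2L, 1L), resname = "ALA", atom = "CA",
    x = c(0, 1), y = 0, z = 0
  )
  expect_error(as_assembly(bad_order), class = "rg_invariant_error")
  bad_xyz <- tibble::tibble(
    chain = "A", resno = 1:2, resname = "ALA", atom = "CA",
    x = c(0, NaN), y = 0, z = 0
  )
  expect_error(as_assembly(bad_xyz), class = "rg_invariant_error")
})

test_that("write/read round trip preserves coordinates to PDB precision", {
  ring <- make_ring(synthetic_ring_spec(n_subunits = 4))
  path <- tempfile(fileext = ".pdb")
  write_assembly_pdb(ring, path)
  back <- read_assembly(path)
  expect_equal(nrow(back), nrow(ring))
  expect_lt(max(abs(back$x - ring$x), abs(back$y - ring$y), abs(back$z - ring$z)), 5e-4 + 1e-12)
})

test_that("select_coords returns equal-length corresponding arrays per chain", {
  ring <- make_ring(synthetic_ring_spec(n_subunits = 6))
  rd <- ring_definition(LETTERS[1:6], c(1, 10))
  sel <- select_coords(ring, rd)
  expect_length(sel$coords, 6)
  expect_true(all(vapply(sel$coords, nrow, integer(1)) == 10))
  expect_equal(rownames(sel$coords$A), rownames(sel$coords$F))
})

test_that("the intersection rule drops unshared residues everywhere, with a warning", {
  ring <- make_ring(synthetic_ring_spec(n_subunits = 6))
  ring <- ring[!(ring$chain == "C" & ring$resno == 5), ]
  rd <- ring_definition(LETTERS[1:6], c(1, 10))
  expect_warning(sel <- select_coords(as_assembly(ring), rd), "residue")
  expect_true(all(vapply(sel$coords, nrow, integer(1)) == 9))
  expect_false("5" %in% rownames(sel$coords$A))
  expect_false(sel$correspondence$used[sel$correspondence$resno == 5])
})

test_that("selecting an absent atom name fails cleanly", {
  ring <- make_ring(synthetic_ring_spec(n_subunits = 6))
  rd <- ring_definition(LETTERS[1:6], c(1, 10))
  expect_error(select_coords(ring, rd, atom_name = "XX"), class = "rg_selection_error")
})

test_that("extract_na_path orders nucleotides 5'->3' and records gaps", {
  dna <- attr(make_dna(synthetic_dna_spec(n_nucleotides = 9)), "assembly")
  dna <- as_assembly(dna[dna$resno >= 3, ]) # residues 3..9
  path <- extract_na_path(dna, "M")
  expect_equal(nrow(path), 7)
  expect_equal(path$resno, 3:9)
  expect_equal(path$ref_atom, rep("C1'", 7))
  gapped <- as_assembly(dna[!dna$resno %in% 6:7, ]) # 3..5, 8..9
  gpath <- extract_na_path(gapped, "M")
  expect_equal(gpath$resno, c(3:5, 8:9))
  expect_equal(attr(gpath, "gaps")$gap_after, 5)
})

test_that("extract_na_path refuses protein chains", {
  ring <- make_ring(synthetic_ring_spec(n_subunits = 3))
  expect_error(extract_na_path(ring, "A"), class = "rg_type_error")
})
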