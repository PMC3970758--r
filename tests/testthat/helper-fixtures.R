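# Tiny in-code fixtures.

pdb_line <- function(serial, name, resname, chain, resno, x, y, z, record = "ATOM") {
  sprintf(
    "%-6s%5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f",
    record, serial, name, "", resname, chain, resno, "", x, y, z, 1.0, 0.0
  )
}

write_mini_pdb <- function(lines, path = tempfile(fileext = ".pdb")) {
  writeLines(c(lines, "END"), path)
  path
}

# a host ring whose interface probe atoms sit at controlled distances:
# chain k carries residue 201 CA, its counterclockwise neighbor's residue
# 127 CA is placed `dists[k]` angstroms away
ring_with_probe_distances <- function(dists, radius = 20) {
  n <- length(dists)
  chains <- LETTERS[seq_len(n)]
  rows <- list()
  for (k in seq_len(n)) {
    phi <- 2 * pi * (k - 1) / n
    # residue 201 of chain k at the interface midpoint region
    p201 <- c(radius * cos(phi + pi / n), radius * sin(phi + pi / n), 0)
    rows[[length(rows) + 1]] <- tibble::tibble(
      chain = chains[k], resno = c(100L, 201L), resname = "ALA", atom = "CA",
      elem = "C",
      x = c(radius * cos(phi), p201[1]),
      y = c(radius * sin(phi), p201[2]),
      z = c(0, 0), het = FALSE, polymer = "protein"
    )
  }
  asm <- dplyr::bind_rows(rows)
  # place residue 127 of the ccw neighbor at the required distance from
  # chain k's 201, offset along +z so distances are exact by construction
  extra <- lapply(seq_len(n), function(k) {
    j <- chains[(k %% n) + 1]
    p201 <- asm[asm$chain == chains[k] & asm$resno == 201, ]
    tibble::tibble(
      chain = j, resno = 127L, resname = "GLU", atom = "CA", elem = "C",
      x = p201$x, y = p201$y, z = p201$z + dists[k],
      het = FALSE, polymer = "protein"
    )
  })
  asm <- dplyr::bind_rows(asm, dplyr::bind_rows(extra)) |>
    dplyr::arrange(match(chain, chains), resno)
  as_assembly(asm)
}
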