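# Programmatic fixtures: tiny PDB/FASTA files written into tempdir.

pdb_atom_line <- function(serial, resname, chain, resno, x, y, z,
                          elety = "CA", altloc = " ", occ = 1.00,
                          record = "ATOM") {
  sprintf("%-6s%5d %-4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f  0.00           C",
          record, serial, paste0(" ", elety), altloc, resname, chain,
          resno, x, y, z, occ)
}

write_pdb_fixture <- function(lines, path = tempfile(fileext = ".pdb")) {
  writeLines(c(lines, "TER", "END"), path)
  path
}

three_res_pdb <- function() {
  write_pdb_fixture(c(
    pdb_atom_line(1, "ALA", "A", 1, 0.0, 0.0, 0.0),
    pdb_atom_line(2, "GLY", "A", 2, 3.8, 0.0, 0.0),
    pdb_atom_line(3, "LYS", "A", 3, 7.6, 0.0, 0.0)))
}

random_coords <- function(n, scale = 10) {
  matrix(stats::runif(n * 3, 0, scale), n, 3)
}
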