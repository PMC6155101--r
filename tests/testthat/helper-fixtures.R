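# Text fixtures built in code: handwritten PDB and STRIDE snippets for the
# reader edge cases the synthetic generator cannot produce (altlocs,
# missing atoms, multiple chains).

pdb_atom_line <- function(serial, name, resname, chain, resno, x, y, z,
                          alt = " ", ins = " ", occ = 1) {
  sprintf("ATOM  %5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f           C",
          serial, name, alt, resname, chain, resno, ins, x, y, z, occ, 0)
}

write_pdb_fixture <- function(lines) {
  f <- tempfile(fileext = ".pdb")
  writeLines(lines, f)
  f
}

# A minimal 8-residue single-chain file with predictable coordinates.
simple_pdb <- function(chain = "A", n = 8) {
  lines <- vapply(seq_len(n), function(i) {
    pdb_atom_line(i, " CA ", "ALA", chain, i, i * 1.5, i * 0.5, i * 0.25)
  }, character(1))
  write_pdb_fixture(c(lines, "END"))
}

stride_asg_line <- function(resname, chain, resno, ordinal, code) {
  sprintf("ASG  %3s %s %4s %4d    %s             %-11s", resname, chain,
          as.character(resno), ordinal, code, "x")
}

write_stride_fixture <- function(codes, chain = "A", resno = seq_along(codes)) {
  f <- tempfile(fileext = ".stride")
  lines <- c("REM  --------------------",
             vapply(seq_along(codes), function(i) {
               stride_asg_line("ALA", chain, resno[i], i, codes[i])
             }, character(1)))
  writeLines(lines, f)
  f
}

write_segment_fixture <- function(chain, start, end) {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("chain\tstart\tend", paste(chain, start, end, sep = "\t")), f)
  f
}

# n-residue straight-line trace as a PDB file plus a segment table, for
# annotation tests that only care about ranges, not geometry.
linear_pdb <- function(n = 40, chain = "A") {
  lines <- vapply(seq_len(n), function(i) {
    pdb_atom_line(i, " CA ", "GLY", chain, i, i * 3.8, 0, 0)
  }, character(1))
  write_pdb_fixture(c(lines, "END"))
}
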