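test_that("a C-alpha trace round-trips through a PDB file", {
  f <- simple_pdb(n = 8)
  tr <- read_calpha_trace(f, chain = "A")
  expect_s3_class(tr, "calpha_trace")
  expect_equal(nrow(tr), 8)
  expect_equal(tr$resno, 1:8)
  expect_equal(tr$x, (1:8) * 1.5, tolerance = 1e-9)
  expect_equal(tr$y, (1:8) * 0.5, tolerance = 1e-9)
})

test_that("reader errors are classed and distinct", {
  expect_error(read_calpha_trace(tempfile(), "A"), class = "bj_missing_file")
  f <- simple_pdb()
  expect_error(read_calpha_trace(f, chain = "Z"), class = "bj_unknown_chain")
  # chain present but without any CA atom
  g <- write_pdb_fixture(c(
    pdb_atom_line(1, " N  ", "ALA", "A", 1, 0, 0, 0),
    pdb_atom_line(2, " CA ", "ALA", "B", 1, 1, 1, 1), "END"))
  expect_error(suppressWarnings(read_calpha_trace(g, chain = "A")),
               class = "bj_no_calpha")
})

test_that("alternate locations resolve to the highest occupancy", {
  f <- write_pdb_fixture(c(
    pdb_atom_line(1, " CA ", "ALA", "A", 1, 0, 0, 0),
    pdb_atom_line(2, " CA ", "ALA", "A", 2, 1, 1, 1, alt = "A", occ = 0.6),
    pdb_atom_line(3, " CA ", "ALA", "A", 2, 9, 9, 9, alt = "B", occ = 0.4),
    pdb_atom_line(4, " CA ", "ALA", "A", 3, 2, 2, 2),
    "END"))
  tr <- read_calpha_trace(f, chain = "A")
  expect_equal(nrow(tr), 3)
  expect_equal(tr$x[tr$resno == 2], 1, tolerance = 1e-9)

  # occupancy tie: altloc identifier ascending wins
  g <- write_pdb_fixture(c(
    pdb_atom_line(1, " CA ", "ALA", "A", 1, 5, 0, 0, alt = "B", occ = 0.5),
    pdb_atom_line(2, " CA ", "ALA", "A", 1, 7, 0, 0, alt = "A", occ = 0.5),
    "END"))
  tr2 <- read_calpha_trace(g, chain = "A")
  expect_equal(tr2$x, 7, tolerance = 1e-9)
})

test_that("residues lacking a C-alpha are omitted with a warning", {
  f <- write_pdb_fixture(c(
    pdb_atom_line(1, " CA ", "ALA", "A", 1, 0, 0, 0),
    pdb_atom_line(2, " N  ", "ALA", "A", 2, 1, 0, 0),
    pdb_atom_line(3, " CA ", "ALA", "A", 3, 2, 0, 0),
    "END"))
  expect_warning(tr <- read_calpha_trace(f, chain = "A"),
                 class = "bj_missing_calpha")
  expect_equal(tr$resno, c(1L, 3L))
})

test_that("SHEET records are read per chain in record order", {
  mk_sheet <- function(i, chain, s, e) {
    sprintf("SHEET  %3d %3s%2d %3s %1s%4d%1s %3s %1s%4d%1s%2d",
            i, "S1", 4, "ALA", chain, s, " ", "ALA", chain, e, " ", -1L)
  }
  f <- write_pdb_fixture(c(
    mk_sheet(1, "A", 5, 10), mk_sheet(2, "A", 14, 20),
    mk_sheet(3, "B", 3, 9), mk_sheet(4, "A", 25, 30),
    mk_sheet(5, "A", 35, 40),
    pdb_atom_line(1, " CA ", "ALA", "A", 5, 0, 0, 0), "END"))
  st <- read_sheet_strands(f, "A")
  expect_equal(nrow(st), 4)
  expect_equal(st$start_resno, c(5L, 14L, 25L, 35L))
  expect_equal(unique(st$sheet_id), "S1")
  expect_equal(unique(st$source), "sheet_record")

  only_b <- read_sheet_strands(f, "B")
  expect_equal(only_b$start_resno, 3L)

  g <- simple_pdb()
  expect_warning(empty <- read_sheet_strands(g, "A"),
                 class = "bj_no_sheet_records")
  expect_equal(nrow(empty), 0)
})

test_that("STRIDE extended-strand runs become strands", {
  f <- write_stride_fixture(c("E", "E", "E", "C", "C", "E", "E"))
  st <- read_stride_strands(f, "A")
  expect_equal(nrow(st), 2)
  expect_equal(st$start_resno, c(1L, 6L))
  expect_equal(st$end_resno, c(3L, 7L))
  expect_equal(unique(st$source), "stride")

  expect_equal(nrow(read_stride_strands(
    write_stride_fixture(c("C", "H", "T")), "A")), 0)

  single <- read_stride_strands(
    write_stride_fixture(c("C", "E", "C")), "A")
  expect_equal(nrow(single), 1)
  expect_equal(single$start_resno, single$end_resno)
})

test_that("an unparseable STRIDE line is reported with its line number", {
  f <- withr::local_tempfile(fileext = ".stride")
  writeLines(c("REM header", "ASG  ALA A"), f)
  err <- expect_error(read_stride_strands(f, "A"), class = "bj_parse")
  expect_match(conditionMessage(err), "line 2")
})

test_that("segment tables parse, validate ranges and honour insertion codes", {
  f <- write_segment_fixture(c("A", "A", "A"),
                             c("5", "12", "25"), c("10", "18", "30"))
  st <- read_segment_table(f)
  expect_equal(nrow(st), 3)
  expect_equal(st$end_resno, c(10L, 18L, 30L))
  expect_equal(unique(st$source), "user_table")

  withins <- read_segment_table(
    write_segment_fixture("A", "52A", "60"))
  expect_equal(withins$start_resno, 52L)
  expect_equal(withins$start_ins, "A")

  bad <- write_segment_fixture("A", "20", "10")
  err <- expect_error(read_segment_table(bad), class = "bj_invalid_range")
  expect_match(conditionMessage(err), "row 1")

  empty <- withr::local_tempfile(fileext = ".tsv")
  writeLines("chain\tstart\tend", empty)
  expect_equal(nrow(read_segment_table(empty)), 0)
})

test_that("synthetic structures survive the PDB writer/reader round trip", {
  for (spec in list(barrel_spec(4), barrel_spec(8, twist = 0),
                    barrel_spec(12, twist = -95))) {
    b <- generate_barrel(spec)
    f <- withr::local_tempfile(fileext = ".pdb")
    write_pdb(b$trace, b$annotation, f)
    tr <- read_calpha_trace(f, "A")
    expect_equal(nrow(tr), nrow(b$trace))
    expect_lt(max(abs(tr$x - b$trace$x), abs(tr$y - b$trace$y),
                  abs(tr$z - b$trace$z)), 1e-3)
    ann <- build_annotation(read_sheet_strands(f, "A"), tr, merge_gap = 0)
    expect_equal(n_strands(ann), spec$n_strands)
    expect_equal(as.data.frame(ann), as.data.frame(b$annotation))
  }
})
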