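simple_spec <- function(seed = 7) {
  fixture_spec(
    seed, "TSTA", unit_cell(15, 15, 15),
    operators = list(sym_op(diag(c(-1, -1, 1)), c(7.5, 7.5, 0))),
    resolution = 1.75,
    metals = data.frame(element = c("Zn", "Mg"), chain = c("A", "B"),
                        res_no = c(101L, 202L), x = c(5, 10), y = c(5, 10),
                        z = c(5, 10), occupancy = c(1, 0.5),
                        stringsAsFactors = FALSE),
    decoys = data.frame(element = c("O", "N", "C"),
                        x = c(3.1, 6.2, 9.3), y = c(4.4, 5.5, 6.6),
                        z = c(7.7, 8.8, 9.9), stringsAsFactors = FALSE))
}

test_that("resolution, cell, operators and atoms are read from fixed columns", {
  ent <- parse_pdb_entry(build_entry_fixture(simple_spec())$lines)
  expect_equal(ent$pdb_id, "TSTA")
  expect_equal(ent$resolution, 1.75)
  expect_equal(ent$cell$a, 15)
  expect_length(ent$operators, 2)
  expect_true(is_identity_op(ent$operators[[1]]))
  expect_equal(ent$operators[[2]]$rotation, diag(c(-1, -1, 1)))
  expect_equal(ent$operators[[2]]$translation, c(7.5, 7.5, 0))
  expect_equal(nrow(ent$atoms), 5)
  expect_equal(ent$atoms$x[1:2], c(5, 10), tolerance = 1e-3)
})

test_that("a REMARK 2 resolution of 7.00 is read as 7.0", {
  lines <- c("REMARK   2 RESOLUTION.    7.00 ANGSTROMS.",
             "CRYST1   10.000   10.000   10.000  90.00  90.00  90.00 P 1")
  expect_equal(parse_pdb_entry(lines)$resolution, 7.0)
})

test_that("identity-only SMTRY rows give a single identity operator", {
  lines <- c(
    "CRYST1   10.000   10.000   10.000  90.00  90.00  90.00 P 1",
    "REMARK 290   SMTRY1   1  1.000000  0.000000  0.000000        0.00000",
    "REMARK 290   SMTRY2   1  0.000000  1.000000  0.000000        0.00000",
    "REMARK 290   SMTRY3   1  0.000000  0.000000  1.000000        0.00000")
  ent <- parse_pdb_entry(lines)
  expect_length(ent$operators, 1)
  expect_true(is_identity_op(ent$operators[[1]]))
})

test_that("parse errors name the malformed part", {
  expect_error(parse_pdb_entry("ATOM      1  ZN  ZN  A   1"), "CRYST1")
  expect_error(parse_pdb_entry(c(
    "CRYST1   10.000   10.000   10.000  90.00  90.00  90.00 P 1",
    "REMARK 290   SMTRY1   1  1.000000  0.000000  0.000000        0.00000",
    "REMARK 290   SMTRY2   1  0.000000  1.000000  0.000000        0.00000")),
    "SMTRY triplet.*incomplete")
  bad <- build_entry_fixture(simple_spec())$lines
  i <- grep("^HETATM", bad)[1]
  substr(bad[i], 31, 38) <- "  badnum"
  expect_error(parse_pdb_entry(bad), "malformed atom record")
})

test_that("round trip preserves cell, operators and atom fields", {
  ent <- parse_pdb_entry(build_entry_fixture(simple_spec())$lines)
  ent2 <- parse_pdb_entry(write_pdb_entry(ent))
  expect_equal(ent2$cell, ent$cell)
  expect_equal(ent2$operators, ent$operators)
  expect_equal(ent2$atoms, ent$atoms)
  expect_equal(ent2$resolution, ent$resolution)
})

test_that("parsing ignores trailing whitespace and records after END", {
  lines <- build_entry_fixture(simple_spec())$lines
  mangled <- c(paste0(lines, "   "),
               "HETATM 9999  FE  FE  Z 999       1.000   1.000   1.000  1.00 20.00          FE")
  ent <- parse_pdb_entry(lines)
  ent2 <- parse_pdb_entry(mangled)
  expect_equal(ent2$atoms, ent$atoms)
})

test_that("hydrogens are dropped and only the first model is read", {
  lines <- c(
    "CRYST1   10.000   10.000   10.000  90.00  90.00  90.00 P 1",
    "MODEL        1",
    "ATOM      1  CA  GLY A   1       1.000   1.000   1.000  1.00 20.00           C",
    "ATOM      2  H   GLY A   1       1.500   1.000   1.000  1.00 20.00           H",
    "ENDMDL",
    "MODEL        2",
    "ATOM      3  CA  GLY A   1       2.000   2.000   2.000  1.00 20.00           C",
    "ENDMDL",
    "END")
  ent <- parse_pdb_entry(lines)
  expect_equal(nrow(ent$atoms), 1)
  expect_equal(ent$atoms$element, "C")
})

test_that("metal sites are identified by element column, not atom name", {
  lines <- c(
    sprintf("%-62s%4s", "HEADER    TEST ENTRY", "5FVN"),
    "CRYST1   20.000   20.000   20.000  90.00  90.00  90.00 P 1",
    # alpha-carbon: atom name CA but element C -> not a site
    "ATOM      1  CA  GLY A  10       1.000   2.000   3.000  1.00 20.00           C",
    # calcium ion: element CA -> a site
    "HETATM    2 CA    CA F 405       5.000   6.000   7.000  1.00 20.00          CA",
    "HETATM    3 ZN    ZN B 701       9.000   9.000   9.000  0.70 20.00          ZN",
    "END")
  ent <- parse_pdb_entry(lines)
  sites <- extract_metal_sites(ent)
  expect_equal(nrow(sites), 2)
  expect_setequal(sites$element, c("Ca", "Zn"))
  expect_equal(sites$site_id[sites$element == "Ca"], "5FVN.F.405.CA")
  # count agrees with a brute-force scan of the element column
  expect_equal(nrow(sites),
               sum(ent$atoms$element %in% default_metal_elements()))
})

test_that("alternate-location metal records yield separate sites", {
  lines <- c(
    "CRYST1   20.000   20.000   20.000  90.00  90.00  90.00 P 1",
    "HETATM    1 ZN  AZN  A   1       5.000   5.000   5.000  0.50 20.00          ZN",
    "HETATM    2 ZN  BZN  A   1       5.200   5.000   5.000  0.50 20.00          ZN",
    "END")
  sites <- extract_metal_sites(parse_pdb_entry(lines))
  expect_equal(nrow(sites), 2)
  expect_setequal(sites$alt_loc, c("A", "B"))
})

test_that("entries with no metals give an empty site list", {
  lines <- c(
    "CRYST1   20.000   20.000   20.000  90.00  90.00  90.00 P 1",
    "ATOM      1  CA  GLY A  10       1.000   2.000   3.000  1.00 20.00           C",
    "END")
  expect_equal(nrow(extract_metal_sites(parse_pdb_entry(lines))), 0)
})

test_that("site identifiers follow PDBID.chain.residue.ELEMENT and round-trip", {
  expect_equal(site_id("5FVN", "F", 405, "Ca"), "5FVN.F.405.CA")
  expect_equal(site_id("3CIA", "B", 701, "Zn"), "3CIA.B.701.ZN")
  expect_equal(site_id("TEST", "A", 1, "Mg"), "TEST.A.1.MG")
  back <- parse_site_id("5FVN.F.405.CA")
  expect_equal(back$pdb_id, "5FVN")
  expect_equal(back$chain, "F")
  expect_equal(back$res_no, 405L)
  expect_equal(back$element, "Ca")
})

test_that("atom coordinates agree with an independent PDB reader", {
  skip_if_not_installed("bio3d")
  lines <- build_entry_fixture(simple_spec())$lines
  tmp <- withr::local_tempfile(fileext = ".pdb")
  writeLines(lines, tmp)
  ref <- bio3d::read.pdb(tmp)
  ent <- parse_pdb_entry(lines)
  expect_equal(as.matrix(ent$atoms[, c("x", "y", "z")]),
               as.matrix(ref$atom[, c("x", "y", "z")]),
               ignore_attr = TRUE, tolerance = 1e-9)
  expect_equal(ent$atoms$occ, ref$atom$o, ignore_attr = TRUE)
})
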