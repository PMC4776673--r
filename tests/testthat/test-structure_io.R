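ala2 <- c(
  "ATOM      1  CA  ALA A   1      11.104   6.134  -6.504  1.00  0.00           C",
  "ATOM      2  CB  ALA A   1      11.639   6.071  -5.147  1.00  0.00           C")

test_that("well-formed ATOM lines parse into atoms with all identity fields", {
  s <- read_pdb(ala2)
  expect_s3_class(s, "sasa_structure")
  expect_equal(nrow(s$atoms), 2)
  expect_equal(s$chain_ids, "A")
  expect_equal(s$atoms$name, c("CA", "CB"))
  expect_equal(s$atoms$residue_name, c("ALA", "ALA"))
  expect_equal(s$atoms$residue_number, c(1L, 1L))
  expect_equal(s$atoms$x, c(11.104, 11.639))
  expect_equal(s$atoms$element, c("C", "C"))
  expect_false(any(s$atoms$is_hetatm))
  expect_true(all(is.na(s$atoms$radius)))  # unassigned != 0
})

test_that("hydrogens are excluded by default and the empty result is a distinct error", {
  h_line <- "ATOM      1  H   ALA A   1       0.000   0.000   0.000  1.00  0.00           H"
  expect_error(read_pdb(h_line), class = "sasar_no_atoms_error")
  s <- read_pdb(h_line, include_hydrogens = TRUE)
  expect_equal(nrow(s$atoms), 1)
  # legacy file without element columns: name heuristic catches 1HB etc.
  legacy <- "ATOM      1 1HB  ALA A   1       0.000   0.000   0.000  1.00  0.00"
  expect_error(read_pdb(legacy), class = "sasar_no_atoms_error")
})

test_that("HETATM records are kept only on request", {
  hoh <- "HETATM    9  O   HOH A 101       1.000   2.000   3.000  1.00  0.00           O"
  both <- c(ala2, hoh)
  expect_equal(nrow(read_pdb(both)$atoms), 2)
  s <- read_pdb(both, include_hetatm = TRUE)
  expect_equal(nrow(s$atoms), 3)
  expect_true(s$atoms$is_hetatm[3])
  # filtering monotonicity: default atoms are a subset of the inclusive parse
  expect_true(all(read_pdb(both)$atoms$serial %in% s$atoms$serial))
})

test_that("only the first alternate location and first model are read", {
  alt <- c(
    "ATOM      1  CA AALA A   1       0.000   0.000   0.000  0.50  0.00           C",
    "ATOM      2  CA BALA A   1       0.500   0.000   0.000  0.50  0.00           C",
    "ATOM      3  CB  ALA A   1       1.000   1.000   0.000  1.00  0.00           C")
  s <- read_pdb(alt)
  expect_equal(s$atoms$serial, c(1L, 3L))
  multi <- c("MODEL     1", ala2, "ENDMDL", "MODEL     2",
             sub("^ATOM      1", "ATOM      9", ala2[1]), "ENDMDL")
  s2 <- read_pdb(multi)
  expect_equal(nrow(s2$atoms), 2)
  expect_equal(s2$atoms$serial, c(1L, 2L))
})

test_that("malformed fixed-column records raise an error naming the line", {
  bad <- c(ala2[1],
           "ATOM      2  CB  ALA A   1      xx.xxx   6.071  -5.147  1.00  0.00           C")
  err <- expect_error(read_pdb(bad), class = "sasar_parse_error")
  expect_match(conditionMessage(err), "line 2")
  expect_error(read_pdb(character(0)), class = "sasar_no_atoms_error")
})

test_that("chain order follows first appearance in the file", {
  lines <- c(sub(" A ", " B ", ala2[1]), sub(" A ", " X ", ala2[2]),
             sub(" A ", " B ", sub("^ATOM      2", "ATOM      3", ala2[2])))
  s <- read_pdb(lines)
  expect_equal(s$chain_ids, c("B", "X"))
})

test_that("writer emits radius as occupancy and SASA as B factor in %6.2f format", {
  s <- read_pdb(ala2)
  s$atoms$radius <- c(1.88, 1.88)
  res <- list(per_atom_area = c(12.345, 0))
  lines <- write_pdb_sasa(s, res, tempfile())
  expect_equal(substr(lines[1], 55, 60), "  1.88")
  expect_equal(substr(lines[1], 61, 66), " 12.35")
  expect_equal(substr(lines[2], 61, 66), "  0.00")
  expect_error(write_pdb_sasa(s, list(per_atom_area = 1)), "match")
})

test_that("parse-write-parse is the identity on identities and coordinates", {
  p <- random_packing(20, 15, c(1.5, 2), seed = 7)
  s <- assign_radii(read_pdb(c(toy_pdb(p), poly_ala_pdb(3, chain_id = "B"))),
                    unknown = "error") |> suppressWarnings()
  r <- calc_sasa(s)
  f <- tempfile(fileext = ".pdb")
  write_pdb_sasa(s, r, f)
  s2 <- read_pdb(f)
  expect_equal(s2$atoms$name, s$atoms$name)
  expect_equal(s2$atoms$residue_name, s$atoms$residue_name)
  expect_equal(s2$atoms$chain_id, s$atoms$chain_id)
  expect_equal(s2$atoms$residue_number, s$atoms$residue_number)
  expect_equal(s2$atoms$x, s$atoms$x)
  expect_equal(s2$atoms$y, s$atoms$y)
  expect_equal(s2$atoms$z, s$atoms$z)
  # idempotence: writing the re-parsed structure reproduces the bytes
  s2$atoms$radius <- s$atoms$radius
  expect_equal(write_pdb_sasa(s2, r, tempfile()), write_pdb_sasa(s, r, tempfile()))
})

test_that("parser agrees with bio3d on coordinates and atom names", {
  skip_if_not_installed("bio3d")
  f <- tempfile(fileext = ".pdb")
  writeLines(poly_ala_pdb(4), f)
  s <- read_pdb(f)
  ref <- bio3d::read.pdb(f)
  expect_equal(s$atoms$x, ref$atom$x)
  expect_equal(s$atoms$y, ref$atom$y)
  expect_equal(s$atoms$z, ref$atom$z)
  expect_equal(s$atoms$name, ref$atom$elety)
  expect_equal(s$atoms$residue_number, ref$atom$resno)
})

test_that("chain subsetting keeps order and validates chain letters", {
  s <- two_chain_structure()
  sub <- subset_chains(s, "B")
  expect_equal(sub$chain_ids, "B")
  expect_equal(nrow(sub$atoms), sum(s$atoms$chain_id == "B"))
  expect_error(subset_chains(s, "Q"), "unknown chain")
})
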