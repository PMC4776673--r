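test_that("ProtOr classifier covers standard residues with published radii", {
  cl <- builtin_protor_classifier()
  lookup <- function(res, atom) sasar:::classifier_lookup(cl, res, atom)
  # tetrahedral carbon with one hydrogen
  expect_equal(lookup("ALA", "CA")$radius, 1.88)
  expect_equal(lookup("ALA", "CA")$polarity, "apolar")
  # aromatic CH vs bare trigonal carbon
  expect_equal(lookup("PHE", "CD1")$radius, 1.76)
  expect_equal(lookup("PHE", "CG")$radius, 1.61)
  # nitrogen, carbonyl and hydroxyl oxygen, sulfur
  expect_equal(lookup("GLY", "N")$radius, 1.64)
  expect_equal(lookup("ASP", "OD1")$radius, 1.42)
  expect_equal(lookup("SER", "OG")$radius, 1.46)
  expect_equal(lookup("MET", "SD")$radius, 1.77)
  expect_equal(lookup("MET", "SD")$polarity, "polar")
  # phosphorus 1.8 and selenium 1.9
  expect_equal(lookup("DA", "P")$radius, 1.8)
  expect_equal(lookup("MSE", "SE")$radius, 1.9)
  expect_equal(lookup("SEC", "SE")$radius, 1.9)
  # capping groups and water are recognized
  expect_equal(lookup("ACE", "CH3")$radius, 1.88)
  expect_equal(lookup("NH2", "N")$radius, 1.64)
  expect_false(is.null(lookup("HOH", "O")))
  # legacy primed naming: C1* matches C1'
  expect_equal(lookup("A", "C1*")$radius, 1.88)
  # lookups are case-insensitive
  expect_equal(lookup("ala", "ca")$radius, 1.88)
})

test_that("all builtin radii lie in the 1.0-2.5 Angstrom sanity band", {
  for (cl in list(builtin_protor_classifier(), builtin_naccess_classifier())) {
    r <- vapply(cl$residue_atom_map, function(e) e$radius, numeric(1))
    expect_true(all(r >= 1.0 & r <= 2.5))
  }
})

test_that("standard protein atoms classify without fallback, deterministically", {
  s <- read_pdb(poly_ala_pdb(5))
  expect_no_warning(s1 <- assign_radii(s))
  expect_true(all(s1$atoms$radius > 0))
  expect_true(all(s1$atoms$polarity %in% c("polar", "apolar")))
  s2 <- assign_radii(s)
  expect_identical(s1$atoms, s2$atoms)  # pure function of inputs
})

test_that("unmatched atoms fall back to the element vdW radius with a warning", {
  xyz <- "ATOM      1  N1  XYZ A   1       0.000   0.000   0.000  1.00  0.00           N"
  s <- read_pdb(xyz)
  expect_warning(s <- assign_radii(s), "fallback")
  expect_equal(s$atoms$radius, 1.55)     # main-group nitrogen
  expect_equal(s$atoms$polarity, "polar")
  carbon <- sub("           N", "           C", sub(" N1 ", " C9 ", xyz))
  expect_warning(sc <- assign_radii(read_pdb(carbon)), "fallback")
  expect_equal(sc$atoms$radius, 1.70)
  expect_equal(sc$atoms$polarity, "apolar")
})

test_that("atoms of unknown element follow the configured policy", {
  zz <- "ATOM      1 ZZ1  XYZ A   1       0.000   0.000   0.000  1.00  0.00          ZZ"
  s <- read_pdb(zz)
  expect_error(assign_radii(s), class = "sasar_unknown_element_error")
  expect_warning(s2 <- assign_radii(s, unknown = "skip"), "skipped")
  expect_equal(nrow(s2$atoms), 0)
})

test_that("classifier config files parse, validate, and mirror their entries", {
  cfg <- c("# comment", "types:", "C_ALI 2.00 apolar", "atoms:",
           "ALA CB C_ALI")
  cl <- parse_classifier_config(cfg)
  e <- sasar:::classifier_lookup(cl, "ALA", "CB")
  expect_equal(e$radius, 2.00)
  expect_equal(e$polarity, "apolar")
  expect_equal(length(cl$residue_atom_map), 1L)

  empty <- parse_classifier_config("# nothing here")
  expect_equal(length(empty$residue_atom_map), 0L)
  expect_true(all(c("H", "C", "N", "O", "P", "S", "SE") %in%
                    names(empty$element_fallback)))

  err <- expect_error(
    parse_classifier_config(c("types:", "T1 1.5 polar", "atoms:",
                              "ALA CB NOPE")),
    class = "sasar_parse_error")
  expect_match(conditionMessage(err), "line 4")
  expect_error(parse_classifier_config(c("types:", "T1 -1 polar")),
               "positive")
  expect_error(parse_classifier_config(c("types:", "T1 1.5 greasy")),
               "polarity")
  expect_warning(
    cl2 <- parse_classifier_config(c("types:", "T1 1.5 polar", "T2 2.0 apolar",
                                     "atoms:", "ALA CB T1", "ALA CB T2")),
    "last one wins")
  expect_equal(sasar:::classifier_lookup(cl2, "ALA", "CB")$radius, 2.0)
})
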