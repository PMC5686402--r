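# Library builders: amino acids, nucleosides, substitution, diff.

test_that("amino-acid libraries carry the scaffold and contain glycine", {
  ul2 <- build_amino_acid_library(2)
  expect_true(canonical_form(parse_smiles("NCC(=O)O")) %in%
                library_certificates(ul2))
  scaffold <- amino_acid_scaffold()
  expect_true(all(vapply(ul2$molecules, function(m) match_pattern(scaffold, m),
                         logical(1))))
  expect_identical(anyDuplicated(library_certificates(ul2)), 0L)
  expect_error(build_amino_acid_library(1), "max_carbons")
})

test_that("library size is monotone in the carbon bound", {
  ul2 <- build_amino_acid_library(2)
  ul3 <- build_amino_acid_library(3)
  expect_true(length(ul3) >= length(ul2))
  # the C2 members are a subset of the C3 run
  expect_true(all(library_certificates(ul2) %in% library_certificates(ul3)))
  scaffold <- amino_acid_scaffold()
  expect_true(all(vapply(ul3$molecules, function(m) match_pattern(scaffold, m),
                         logical(1))))
})

test_that("CL mode injects the coded amino acids within the carbon bound", {
  cl3 <- build_amino_acid_library(3, mode = "CL")
  coded <- coded_amino_acids()
  nc <- vapply(coded, function(m) sum(m$elements == "C"), integer(1))
  expected_in <- vapply(coded[nc <= 3], canonical_form, character(1))
  expect_true(all(expected_in %in% library_certificates(cl3)))
})

test_that("all 20 coded amino acids match the (proline-tolerant) scaffold", {
  coded <- coded_amino_acids()
  expect_length(coded, 20L)
  sc <- amino_acid_scaffold()
  expect_true(all(vapply(coded, function(m) match_pattern(sc, m), logical(1))))
})

test_that("nucleoside constraints are enforced", {
  expect_error(build_nucleoside_library("C2H6O"), "exactly one B")
  expect_error(nucleoside_constraints(-1), ">= 0")
  # CH3B admits no functional group: the library is empty
  lib <- build_nucleoside_library("CH3B")
  expect_length(lib, 0L)
  # with the functional-group rule and badlist off, count equals the raw count
  lib0 <- build_nucleoside_library("C2H5OB",
                                   nucleoside_constraints(0, badlist = NULL))
  expect_identical(length(lib0), count_isomers("C2H5OB"))
})

test_that("free functional groups count O-H/N-H sites away from B", {
  expect_identical(free_functional_groups(natural_riboside()), 3L)
  expect_identical(free_functional_groups(parse_smiles("OCB")), 1L)
  expect_identical(free_functional_groups(parse_smiles("OB")), 0L)  # on B
  expect_identical(free_functional_groups(parse_smiles("COC")), 0L) # no H
  expect_identical(free_functional_groups(parse_smiles("NCC(=O)O")), 2L)
})

test_that("toy nucleoside space behaves: every member keeps exactly one B", {
  fx <- fixture_generator(1, "toy-nucleosides")
  nb <- vapply(fx$library$molecules,
               function(m) sum(m$elements == "B"), integer(1))
  expect_true(all(nb == 1L))
  # hand-checked smallest members: CH3B exists, CB with 1 H does not
  expect_true(canonical_form(parse_smiles("CCB")) %in%
                library_certificates(fx$library))
})

test_that("heteroatom substitution respects symmetry orbits", {
  # ethanol: one O, one product
  one <- substitute_heteroatom(list(parse_smiles("CCO")), "O", "S", 1)
  expect_length(one, 1L)
  expect_identical(library_certificates(one),
                   canonical_form(parse_smiles("CCS")))
  # ethylene glycol: the two O positions are equivalent, one product only
  glycol <- substitute_heteroatom(list(parse_smiles("OCCO")), "O", "S", 1)
  expect_length(glycol, 1L)
  # asymmetric diol: two distinct mono-thio products
  diol <- substitute_heteroatom(list(parse_smiles("OCCCOC")), "O", "S", 1)
  expect_length(diol, 2L)
  expect_error(substitute_heteroatom(list(parse_smiles("CCO")), "O", "N"),
               "valence mismatch")
})

test_that("substitution equals de-novo generation of the S formula", {
  for (ftxt in c("C2H6O2", "C3H8O2", "C2H4O2")) {
    src <- new_library(enumerate_isomers(ftxt))
    sub <- substitute_heteroatom(src, "O", "S", 1)
    s_formula <- sub("O2", "OS", ftxt)
    denovo <- enumerate_isomers(s_formula)
    expect_setequal(library_certificates(sub),
                    vapply(denovo, canonical_form, character(1)))
  }
})

test_that("library_diff partitions certificates with correct sizes", {
  a <- new_library(enumerate_isomers("C2H6O"), name = "a")
  empty <- new_library(list(), name = "empty")
  d1 <- library_diff(a, a)
  expect_length(d1$only_a, 0L)
  expect_length(d1$only_b, 0L)
  expect_setequal(d1$shared, library_certificates(a))
  d2 <- library_diff(a, empty)
  expect_setequal(d2$only_a, library_certificates(a))
  expect_length(d2$shared, 0L)
  b <- new_library(enumerate_isomers("C2H6O2"), name = "b")
  d3 <- library_diff(a, b)
  expect_identical(length(d3$only_a) + length(d3$shared), length(a))
  expect_identical(length(d3$only_b) + length(d3$shared), length(b))
})

test_that("libraries persist as SMILES plus provenance and re-read", {
  lib <- new_library(enumerate_isomers("C3H6O"), name = "c3h6o")
  path <- tempfile(fileext = ".smi")
  write_library(lib, path)
  expect_true(file.exists(paste0(path, ".json")))
  back <- read_library(path)
  expect_setequal(library_certificates(back), library_certificates(lib))
  # SDF export round-trips atom and bond counts
  sdf <- tempfile(fileext = ".sdf")
  write_sdf(lib, sdf)
  txt <- readLines(sdf)
  expect_identical(sum(txt == "$$$$"), length(lib))
})
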