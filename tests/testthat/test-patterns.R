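# Substructure patterns: parsing, matching vs brute-force embeddings,
# filter accounting.

test_that("pattern parsing handles the subset and rejects the rest", {
  p <- parse_pattern("OO")
  expect_length(p$elements, 2L)
  p2 <- parse_pattern("C(=O)O")
  expect_length(p2$elements, 3L)
  expect_identical(sort(p2$bonds[, 3]), c(1L, 2L))
  p3 <- parse_pattern("[OH1]C[NH2]")
  expect_identical(p3$min_h, c(1L, 0L, 2L))
  p4 <- parse_pattern("*~B")
  expect_identical(p4$elements, c("*", "B"))
  expect_identical(p4$bonds[1, 3], 0L)
  expect_error(parse_pattern("[Zn]"), "unsupported bracket")
  expect_error(parse_pattern("C%C"), "position 2")
  expect_error(parse_pattern("CC.O"), "position 3")
})

test_that("matching agrees with examples and is relabeling-invariant", {
  expect_true(match_pattern("OO", parse_smiles("COOC")))
  expect_false(match_pattern("OO", parse_smiles("OCCO")))
  expect_true(match_pattern("C(=O)[OH1]", parse_smiles("CC(=O)O")))
  expect_false(match_pattern("C(=O)[OH1]", parse_smiles("COC(=O)C")))
  set.seed(23)
  for (i in 1:20) {
    m <- random_molgraph(sample(3:6, 1))
    p <- c("CO", "C~O", "C=C", "[CH1]", "*N")[[sample.int(5, 1)]]
    r <- match_pattern(p, m)
    for (j in 1:5) {
      expect_identical(match_pattern(p, relabel_mol(m, random_permutation(length(m$elements)))),
                       r)
    }
  }
})

test_that("match presence equals positive brute-force embedding count", {
  pats <- c("C", "O", "CC", "CO", "C~O", "C=O", "OO", "COC", "OCO",
            "C(=O)O", "[OH1]C", "[CH2]O")
  mols <- c(enumerate_isomers("C3H8O"), enumerate_isomers("C3H6O"),
            enumerate_isomers("C3H8O2"))
  for (pt in pats) {
    p <- parse_pattern(pt)
    for (m in mols) {
      expect_identical(match_pattern(p, m), count_embeddings_r(p, m) > 0,
                       info = paste(pt, write_smiles(m)))
    }
  }
})

test_that("filter_library accounts removals first-match and sums", {
  mols <- enumerate_isomers("C2H6O2")
  ident <- filter_library(mols, bad = NULL)
  expect_length(ident$kept, length(mols))
  # a badlist of every single-atom pattern empties the output
  allatoms <- filter_library(mols, bad = list("C", "O"))
  expect_length(allatoms$kept, 0L)
  expect_identical(sum(allatoms$report$removed[1:2]), length(mols))
  # peroxide filtering keeps exactly the non-peroxide isomers
  res <- filter_library(mols, bad = list(parse_pattern("OO", name = "OO")))
  manual <- vapply(mols, function(m) !match_pattern("OO", m), logical(1))
  expect_identical(length(res$kept), sum(manual))
  expect_identical(res$report$removed[res$report$pattern == "OO"],
                   sum(!manual))
  # first-match attribution: totals equal the sum of per-pattern counts
  res2 <- filter_library(mols, bad = list(parse_pattern("OO", name = "a"),
                                          parse_pattern("O~O", name = "b")))
  rep2 <- res2$report
  expect_identical(rep2$removed[rep2$pattern == "total_removed"],
                   sum(rep2$removed[rep2$pattern %in% c("a", "b")]))
  expect_identical(rep2$removed[rep2$pattern == "b"], 0L)  # shadowed by a
})

test_that("filtering is independent of input order as a set", {
  mols <- enumerate_isomers("C3H8O2")
  bad <- list(parse_pattern("[OH1]C[OH1]", name = "gem"))
  a <- filter_library(mols, bad)
  b <- filter_library(rev(mols), bad)
  expect_setequal(vapply(a$kept, canonical_form, character(1)),
                  vapply(b$kept, canonical_form, character(1)))
})

test_that("badlist files parse with names, rationales and inline #-bonds", {
  path <- tempfile(fileext = ".smarts")
  writeLines(c("# header comment",
               "peroxide: OO  # oxygen-oxygen",
               "ynol: C#CO  # hash inside a pattern is a triple bond",
               "C=C[OH1]"), path)
  bl <- read_badlist(path)
  expect_length(bl, 3L)
  expect_identical(bl[[1]]$name, "peroxide")
  expect_identical(bl[[1]]$rationale, "oxygen-oxygen")
  expect_identical(bl[[2]]$bonds[1, 3], 3L)  # triple bond survived
  expect_identical(bl[[3]]$name, "C=C[OH1]")
  writeLines(c("x: C", "x: O"), path)
  expect_error(read_badlist(path), "duplicate")
})
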