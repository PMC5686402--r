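# Formula parsing, degree of unsaturation, graphicality, fuzzy expansion.

test_that("formula parsing handles exact, fuzzy and malformed input", {
  f <- parse_formula("C5H9O4B")
  expect_s3_class(f, "formula_exact")
  expect_identical(unclass(f)[c("C", "H", "O", "B")],
                   c(C = 5L, H = 9L, O = 4L, B = 1L))
  fz <- parse_formula("C2-3O0-1H8")
  expect_s3_class(fz, "formula_fuzzy")
  expect_identical(fz["min", "C"], 2L)
  expect_identical(fz["max", "C"], 3L)
  expect_identical(fz["min", "O"], 0L)
  expect_identical(unname(fz[, "H"]), c(8L, 8L))
  expect_error(parse_formula("C2-1H4"), "min exceeds max")
  expect_error(parse_formula("C2Zz4"), "unknown element")
  expect_error(parse_formula("H2"), "non-hydrogen")
})

test_that("formulas round-trip through the canonical formatter", {
  # canonical spellings are fixed points
  for (s in c("C5H9O4B", "C6H6", "CH4O", "C2-6H0-13NO2-4", "C2-3H8O0-1")) {
    expect_identical(format_formula(parse_formula(s)), s)
  }
  # non-canonical input normalizes, then stays stable
  n1 <- format_formula(parse_formula("C2-3O0-1H8"))
  expect_identical(n1, "C2-3H8O0-1")
  expect_identical(format_formula(parse_formula(n1)), n1)
  expect_identical(format_formula(parse_formula("BO4H9C5")), "C5H9O4B")
})

test_that("degree of unsaturation matches closed forms", {
  expect_equal(dbe("C6H6"), 4)
  expect_equal(dbe("CH4"), 0)
  expect_equal(dbe("C5H9O4B"), 1)
  expect_equal(dbe("C2H7N"), 0)
})

test_that("graphicality examples", {
  expect_false(is_graphical("CH5"))   # odd valence sum
  expect_true(is_graphical("C2H6"))
  expect_true(is_graphical("CH2O3"))  # carbonic acid
  expect_false(is_graphical("C2"))    # would need a quadruple bond
  expect_false(is_graphical("CH6"))   # over-saturated
  expect_true(is_graphical("B2"))     # single B-B bond
})

test_that("is_graphical agrees exactly with the generator on small formulae", {
  # every accepted formula yields >= 1 structure; every rejected one yields 0
  elems <- c("C", "N", "O", "S", "B")
  combos <- expand.grid(C = 0:3, N = 0:2, O = 0:2, S = 0:1, B = 0:1)
  combos <- combos[rowSums(combos) >= 1 & rowSums(combos) <= 3, ]
  for (r in seq_len(nrow(combos))) {
    counts <- unlist(combos[r, ])
    counts <- counts[counts > 0]
    vsum <- sum(valence_model()[names(counts)] * counts)
    for (nh in 0:vsum) {
      f <- structure(c(counts, H = nh)[c(counts, H = nh) > 0],
                     class = "formula_exact")
      n_found <- length(brute_force_enumerate(f))
      expect_identical(is_graphical(f), n_found > 0,
                       info = format_formula(f))
    }
  }
})

test_that("fuzzy expansion is ordered, filtered and capped", {
  # degenerate point range: exactly the single formula
  expect_identical(vapply(expand_fuzzy("C2H6"), format_formula, character(1)),
                   "C2H6")
  got <- vapply(expand_fuzzy("C2H6O0-1"), format_formula, character(1))
  expect_identical(got, c("C2H6", "C2H6O"))
  # C2 needs H4 to keep one degree of unsaturation
  got2 <- vapply(expand_fuzzy("C1-2H4"), format_formula, character(1))
  expect_identical(got2, c("CH4", "C2H4"))
  expect_error(expand_fuzzy("C1-8N0-8O0-8S0-8", cap = 50), "narrow")
})

test_that("H-free expansion fills all valence-closing hydrogen counts", {
  # one-carbon slice of a placeholder formula space: C1 N1-2 O0-4 B1, H free
  fs <- expand_fuzzy("C1N1-2O0-4B")
  expect_gt(length(fs), 0)
  for (f in fs) {
    cnt <- unclass(f)
    expect_identical(cnt[["C"]], 1L)
    expect_identical(cnt[["B"]], 1L)
    expect_true(cnt[["N"]] %in% 1:2)
    expect_true(is_graphical(f))
    # parity: every expansion has an even total valence sum
    vsum <- sum(valence_model()[names(cnt)] * cnt)
    expect_true(vsum %% 2 == 0)
  }
  # every expanded formula small enough for the oracle yields >= 1 structure
  small <- fs[vapply(fs, function(f) {
    sum(unclass(f)[setdiff(names(f), "H")]) <= 7
  }, logical(1))]
  counts <- vapply(small, function(f) length(brute_force_enumerate(f)),
                   integer(1))
  expect_gt(length(small), 5)
  expect_true(all(counts >= 1))
})
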