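# Descriptors: additivity, invariance, oracles.

test_that("logP is additive over the shipped atom types", {
  tab <- read.csv(system.file("extdata", "logp_contributions.csv",
                              package = "isogen"), comment.char = "#")
  val <- setNames(tab$value, tab$type)
  # methane: a single aliphatic carbon
  expect_equal(logp(molgraph("C")), unname(val["C_aliphatic"]))
  # methanol by hand: heteroatom-substituted C plus hydroxyl O
  expect_equal(logp(parse_smiles("CO")),
               unname(val["C_hetero"] + val["O_hydroxyl"]))
  # acetic acid by hand
  expect_equal(logp(parse_smiles("CC(=O)O")),
               unname(val["C_aliphatic"] + val["C_carbonyl"] +
                        val["O_carbonyl"] + val["O_hydroxyl"]))
})

test_that("logP orders hydrophobic above polar and is invariant", {
  expect_gt(logp(parse_smiles("CC")), logp(parse_smiles("CO")))
  expect_gt(logp(parse_smiles("CCCC")), logp(parse_smiles("CC")))
  set.seed(5)
  for (i in 1:10) {
    m <- random_molgraph(sample(2:6, 1))
    v <- logp(m)
    for (j in 1:5) {
      expect_equal(logp(relabel_mol(m, random_permutation(length(m$elements)))),
                   v)
    }
  }
})

test_that("vdw volume matches the hand-applied contribution formula", {
  # methane: C + 4 H atoms, 4 bonds, no rings
  expect_equal(vdw_volume(molgraph("C")), 20.58 + 4 * 7.24 - 5.92 * 4)
  # benzene: 6 C + 6 H, 12 bonds, one aromatic ring
  expect_equal(vdw_volume(parse_smiles("C1=CC=CC=C1")),
               6 * 20.58 + 6 * 7.24 - 5.92 * 12 - 14.7)
  # cyclohexane: one non-aromatic ring
  expect_equal(vdw_volume(parse_smiles("C1CCCCC1")),
               6 * 20.58 + 12 * 7.24 - 5.92 * 18 - 3.8)
})

test_that("alkane homologue increments are constant (additivity)", {
  chain <- function(k) parse_smiles(paste(rep("C", k), collapse = ""))
  vols <- vapply(2:6, function(k) vdw_volume(chain(k)), numeric(1))
  incs <- diff(vols)
  expect_true(all(abs(incs - incs[1]) < 1e-9))
  expect_true(all(incs > 0))  # strictly monotone in chain length
})

test_that("Wiener index matches closed forms and the BFS oracle", {
  expect_identical(wiener_index(parse_smiles("CCCC")), 10L)
  expect_identical(wiener_index(parse_smiles("C1CCC1")), 8L)
  expect_identical(wiener_index(molgraph("C")), 0L)
  set.seed(99)
  for (i in 1:100) {
    m <- random_molgraph(sample(2:7, 1))
    expect_identical(wiener_index(m), wiener_by_bfs(m))
  }
})

test_that("pKa classifies coded side chains and returns NA when neutral", {
  aa <- coded_amino_acids()
  expect_true(is.na(pka_estimate(aa$Gly)))
  expect_true(is.na(pka_estimate(aa$Ala)))
  expect_true(is.na(pka_estimate(aa$Ser)))  # aliphatic OH not ionizable
  expect_true(is.na(pka_estimate(aa$Asn)))  # amide excluded from amine class
  expect_equal(pka_estimate(aa$Asp), 4.1)
  expect_equal(pka_estimate(aa$Glu), 4.1)
  expect_equal(pka_estimate(aa$Cys), 8.3)
  expect_equal(pka_estimate(aa$Tyr), 10.1)
  expect_equal(pka_estimate(aa$His), 6.0)
  expect_equal(pka_estimate(aa$Arg), 12.5)
  expect_equal(pka_estimate(aa$Lys), 10.7)
  # classification is invariant under relabeling
  lys <- aa$Lys
  set.seed(3)
  for (j in 1:5) {
    expect_equal(pka_estimate(relabel_mol(lys, random_permutation(length(lys$elements)))),
                 10.7)
  }
})

test_that("property tables have one row per certificate and round-trip", {
  lib <- new_library(coded_amino_acids(), name = "coded20")
  pt <- property_table(lib)
  expect_identical(nrow(pt), 20L)
  expect_identical(anyDuplicated(pt$certificate), 0L)
  # byte-identical CSV on re-run
  f1 <- tempfile(); f2 <- tempfile()
  write.csv(pt, f1, row.names = FALSE)
  write.csv(property_table(lib), f2, row.names = FALSE)
  expect_identical(readLines(f1), readLines(f2))
  # merging an external column preserves row keys
  extra <- data.frame(certificate = pt$certificate,
                      heat_of_formation = seq_len(20))
  pt2 <- property_table(lib, extra = extra)
  expect_identical(nrow(pt2), 20L)
  expect_setequal(pt2$certificate, pt$certificate)
  expect_false(anyNA(pt2$heat_of_formation))
})
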