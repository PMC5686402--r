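# Adaptive-alphabet analysis: range, evenness, dominance, sampling.

toy_set <- function(vals, ids = paste0("x", seq_along(vals))) {
  alphabet_set(ids, data.frame(certificate = ids, v = vals))
}

test_that("range coverage is max minus min over resolved members", {
  expect_equal(range_coverage(toy_set(c(1, 3)), "v"), 2)
  expect_equal(range_coverage(toy_set(c(2, 2, 2)), "v"), 0)
  # adding an inside member leaves the range unchanged
  expect_equal(range_coverage(toy_set(c(0, 5, 10)), "v"),
               range_coverage(toy_set(c(0, 10)), "v"))
  # NA values are excluded
  expect_equal(range_coverage(toy_set(c(0, NA, 4)), "v"), 4)
  expect_error(range_coverage(toy_set(c(1, NA)), "v"), "at least 2")
})

test_that("evenness is 1 for equal spacing, 0 for one-gap extremes", {
  expect_equal(evenness(toy_set(c(0, 1, 2, 3)), "v"), 1)
  expect_equal(evenness(toy_set(c(10, 30, 20, 0)), "v"), 1)  # order-free
  expect_equal(evenness(toy_set(c(0, 0, 0, 10)), "v"), 0)
  e <- evenness(toy_set(c(0, 1, 2, 10)), "v")
  expect_true(e > 0 && e < 1)
  expect_error(evenness(toy_set(c(1, 2)), "v"), "at least 3")
})

test_that("evenness is invariant under affine transforms of the axis", {
  set.seed(17)
  for (i in 1:20) {
    vals <- round(runif(sample(4:10, 1), -5, 5), 3)
    a <- runif(1, 0.1, 10); b <- runif(1, -100, 100)
    expect_equal(evenness(toy_set(vals), "v"),
                 evenness(toy_set(a * vals + b), "v"), tolerance = 1e-9)
  }
})

test_that("the better-relation needs weak dominance plus a strict edge", {
  ids <- paste0("m", 1:8)
  props <- data.frame(certificate = ids,
                      logp = c(0, 1, 2, 3, 0, 2, 4, 6),
                      vdw_volume = c(0, 1, 2, 3, 0, 2, 4, 6),
                      pka = c(0, 1, 2, 3, 0, 2, 4, 6))
  ref <- alphabet_set(ids[1:4], props)
  dom <- alphabet_set(ids[5:8], props)   # same evenness 1, larger range
  expect_false(is_better(ref, ref))      # irreflexive
  expect_true(is_better(dom, ref))
  expect_false(is_better(ref, dom))      # antisymmetric
})

test_that("exhaustive dominance over a 6-molecule toy library agrees", {
  ids <- paste0("t", 1:6)
  props <- data.frame(certificate = ids,
                      logp = c(0, 5, 10, 2, 7, 12),
                      vdw_volume = c(1, 2, 3, 1.5, 2.5, 3.5),
                      pka = c(4, 8, 12, 5, 9, 14))
  ref <- alphabet_set(ids[1:3], props)
  sets <- combn(6, 3)
  for (k in seq_len(ncol(sets))) {
    cand <- alphabet_set(ids[sets[, k]], props)
    # independent dominance check written out directly
    expected <- local({
      comp <- c()
      for (ax in c("logp", "vdw_volume", "pka")) {
        rv <- props[[ax]][sets[, k]]
        fv <- props[[ax]][1:3]
        comp <- c(comp,
                  max(rv) - min(rv) - (max(fv) - min(fv)),
                  evenness(alphabet_set(ids[sets[, k]], props), ax) -
                    evenness(ref, ax))
      }
      all(comp >= 0) && any(comp > 0)
    })
    expect_identical(is_better(cand, ref), expected)
  }
})

test_that("sampling is seeded, bounded and honest about degenerate cases", {
  fx <- fixture_generator(4, "adaptive-synthetic")
  expect_equal(fx$n_subsets, choose(24, 20))
  # n = 0 draws
  r0 <- sample_random_sets(fx$properties, fx$reference, n = 0, seed = 1)
  expect_identical(r0$n_better, 0L)
  # library equal to the reference: every draw IS the reference, never better
  ref_only <- fx$properties[1:20, ]
  rr <- sample_random_sets(ref_only, fx$reference, n = 50, seed = 1)
  expect_identical(rr$n_better, 0L)
  # identical seeds give identical results, different seeds usually differ
  a <- sample_random_sets(fx$properties, fx$reference, n = 300, seed = 42)
  b <- sample_random_sets(fx$properties, fx$reference, n = 300, seed = 42)
  expect_identical(a$n_better, b$n_better)
  expect_identical(a$better_sets, b$better_sets)
  expect_error(sample_random_sets(fx$properties[1:5, ], fx$reference,
                                  n = 1, seed = 1), "smaller")
})

test_that("Monte-Carlo better-fraction converges to the exact enumeration", {
  fx <- fixture_generator(2, "adaptive-synthetic")
  p <- fx$exact_better_fraction
  res <- sample_random_sets(fx$properties, fx$reference, n = 3000, seed = 11)
  se <- sqrt(p * (1 - p) / res$n_sampled)
  expect_lt(abs(res$n_better / res$n_sampled - p), 3 * se)
})
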