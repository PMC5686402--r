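# Deterministic test fixtures, generated in code. Each profile returns
# small inputs with independently known expected values.

#' Generate deterministic test fixtures
#'
#' Profiles:
#' \describe{
#'   \item{`tiny-formulae`}{All graphical CHNO formulae with at most
#'     `max_heavy` (default 4) heavy atoms, with isomer counts from the
#'     brute-force oracle. Returns a data frame (`formula`, `count`).}
#'   \item{`toy-amino-acids`}{A hand-checkable library of small coded amino
#'     acids (glycine, alanine, serine, cysteine, aspartate) with their
#'     property table.}
#'   \item{`toy-nucleosides`}{All placeholder-bearing molecules of the space
#'     `C2-3O0-2B`, with free-functional-group counts.}
#'   \item{`adaptive-synthetic`}{A planted-dominance library of 24 virtual
#'     molecules over the three adaptive axes: a reference alphabet of 20
#'     (nineteen identical values plus one outlier, giving evenness exactly
#'     0 and range 10 on every axis), two "super" molecules extending the
#'     range and two in-range "duds". The exact better-set fraction over
#'     all C(24,20) subsets is computed by complete enumeration and
#'     returned, making Monte-Carlo estimates checkable against an exact
#'     value. Axis scales are seed-jittered affinely (which changes neither
#'     evenness nor dominance).}
#' }
#'
#' @param seed Integer seed; all profiles are deterministic given it.
#' @param profile Profile name (see above).
#' @param max_heavy Heavy-atom cap for `tiny-formulae`.
#' @return Profile-specific list or data frame.
#' @export
fixture_generator <- function(seed, profile = c("tiny-formulae",
                                                "toy-amino-acids",
                                                "toy-nucleosides",
                                                "adaptive-synthetic"),
                              max_heavy = 4) {
  profile <- match.arg(profile)
  switch(profile,
    "tiny-formulae" = .fixture_tiny_formulae(max_heavy),
    "toy-amino-acids" = .fixture_toy_amino_acids(),
    "toy-nucleosides" = .fixture_toy_nucleosides(),
    "adaptive-synthetic" = .fixture_adaptive_synthetic(seed))
}

.fixture_tiny_formulae <- function(max_heavy) {
  elems <- c("C", "N", "O")
  combos <- expand.grid(C = 0:max_heavy, N = 0:max_heavy, O = 0:max_heavy)
  combos <- combos[rowSums(combos) >= 1 & rowSums(combos) <= max_heavy, ]
  rows <- list()
  for (r in seq_len(nrow(combos))) {
    counts <- stats::setNames(as.integer(combos[r, ]), elems)
    counts <- counts[counts > 0]
    vsum <- sum(rep(.valence(names(counts)), counts))
    for (nh in seq(vsum %% 2, vsum, by = 2)) {
      f <- counts
      if (nh > 0) f <- c(f, H = as.integer(nh))
      f <- structure(f, class = "formula_exact")
      if (!is_graphical(f)) next
      rows[[length(rows) + 1]] <- data.frame(
        formula = format_formula(f),
        count = length(brute_force_enumerate(f)))
    }
  }
  do.call(rbind, rows)
}

.fixture_toy_amino_acids <- function() {
  smi <- c(Gly = "NCC(=O)O", Ala = "NC(C)C(=O)O", Ser = "NC(CO)C(=O)O",
           Cys = "NC(CS)C(=O)O", Asp = "NC(CC(=O)O)C(=O)O")
  mols <- lapply(smi, parse_smiles)
  lib <- new_library(mols, name = "toy_amino_acids")
  list(library = lib, properties = property_table(lib))
}

.fixture_toy_nucleosides <- function() {
  mols <- list()
  for (f in expand_fuzzy("C2-3O0-2B")) {
    mols <- c(mols, enumerate_isomers(f))
  }
  lib <- new_library(mols, name = "toy_nucleosides")
  list(library = lib,
       free_functional_groups = vapply(lib$molecules, free_functional_groups,
                                       integer(1)))
}

.fixture_adaptive_synthetic <- function(seed) {
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  base <- c(rep(0, 19), 10,  # reference: evenness 0, range 10 per axis
            20, 20,          # supers: range extenders (dominating members)
            0, 0)            # duds: duplicates of the reference floor
  # A set is better iff it contains a super: without one, its values are
  # either all at the floor (range 0) or reproduce the reference pattern
  # exactly (no strict improvement).
  ids <- sprintf("m%02d", seq_along(base))
  # per-axis affine jitter: scale in [0.5, 2], shift in [-5, 5]
  props <- data.frame(certificate = ids)
  for (ax in c("logp", "vdw_volume", "pka")) {
    a <- stats::runif(1, 0.5, 2)
    b <- stats::runif(1, -5, 5)
    props[[ax]] <- a * base + b
  }
  reference <- alphabet_set(ids[1:20], props)
  # exact better fraction by complete enumeration of all C(24,20) subsets
  all_sets <- utils::combn(length(base), 20)
  better <- logical(ncol(all_sets))
  for (k in seq_len(ncol(all_sets))) {
    cand <- alphabet_set(ids[all_sets[, k]], props)
    better[k] <- is_better(cand, reference)
  }
  list(properties = props, reference = reference,
       exact_better_fraction = mean(better),
       n_subsets = ncol(all_sets))
}
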