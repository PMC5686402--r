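# Virtual compound libraries: certificate-keyed, deduplicated molecule sets
# with provenance, plus the two domain builders (alpha-amino acids and
# nucleoside analogues) and symmetry-aware heteroatom substitution.

#' Construct a library from molecules
#'
#' Molecules are keyed and deduplicated by canonical certificate.
#'
#' @param molecules List of `molgraph` objects.
#' @param name Library name.
#' @param provenance Named list recording how the library was built.
#' @return An object of class `isolibrary`.
#' @export
new_library <- function(molecules, name = "library", provenance = list()) {
  certs <- vapply(molecules, canonical_form, character(1))
  keep <- !duplicated(certs)
  molecules <- stats::setNames(molecules[keep], certs[keep])
  molecules <- molecules[order(names(molecules))]
  structure(list(name = name, molecules = molecules,
                 provenance = c(provenance,
                                list(created = format(Sys.time(), tz = "UTC"),
                                     package_version =
                                       as.character(utils::packageVersion("isogen"))))),
            class = "isolibrary")
}

#' @export
print.isolibrary <- function(x, ...) {
  cat("<library> ", x$name, ": ", length(x$molecules), " molecules\n", sep = "")
  invisible(x)
}

#' @export
length.isolibrary <- function(x) length(x$molecules)

#' Certificates of the molecules in a library
#' @param lib An `isolibrary`.
#' @return Sorted character vector of certificates.
#' @export
library_certificates <- function(lib) names(lib$molecules)

#' SMILES of the molecules in a library (certificate order)
#' @param lib An `isolibrary`.
#' @param placeholder Passed to [write_smiles()].
#' @return Character vector.
#' @export
library_smiles <- function(lib, placeholder = "B") {
  vapply(lib$molecules, write_smiles, character(1), placeholder = placeholder)
}

# ---- alpha-amino acids ---------------------------------------------------

#' The alpha-amino-acid scaffold pattern
#'
#' Amino N (with at least one N-H unless `n_substituted`), alpha carbon with
#' at least one hydrogen, carboxyl group: `H2N-CH(R)-COOH`.
#'
#' @param n_substituted If `TRUE`, the N-H requirement is relaxed so that
#'   N-substituted (proline-like) members match too.
#' @return A `substructure_pattern`.
#' @export
amino_acid_scaffold <- function(n_substituted = FALSE) {
  if (n_substituted) {
    parse_pattern("N[CH1]C(=O)[OH1]", name = "alpha_amino_acid_Nsub",
                  rationale = "alpha-amino acid scaffold, N-substituted allowed")
  } else {
    parse_pattern("[NH1][CH1]C(=O)[OH1]", name = "alpha_amino_acid",
                  rationale = "alpha-amino acid scaffold H2N-CH(R)-COOH")
  }
}

#' Build a virtual alpha-amino-acid library
#'
#' Enumerates all constitutional isomers carrying the alpha-amino-acid
#' scaffold (amino N bonded to an alpha carbon bearing at least one H,
#' bonded to a carboxyl group) over a fuzzy formula space, filtered through
#' a badlist.
#'
#' `mode = "UL"` ("unique" library) covers the formula space exhaustively:
#' carbon 2..`max_carbons` crossed with the nitrogen/oxygen ranges, hydrogen
#' free. `mode = "CL"` ("combined" library) additionally injects the 20
#' genetically coded amino acids (restricted to `max_carbons`), anchoring
#' the library to the coded alphabet; the exhaustive part of a CL run uses
#' the same space as UL.
#'
#' @param max_carbons Maximum carbon count (>= 2; glycine needs 2).
#' @param elements Elements available besides H (default C, N, O; add "S"
#'   to include sulfur directly).
#' @param badlist Forbidden substructures (default: the shipped
#'   plausibility badlist, [default_badlist()]).
#' @param mode `"UL"` or `"CL"`.
#' @param n_range,o_range Nitrogen / oxygen count ranges of the formula
#'   space (defaults 1-2 and 2-3; the scaffold itself needs N1 O2).
#' @param s_range Sulfur range, used only when `"S" %in% elements`.
#' @param n_substituted Relax the N-H scaffold requirement (default FALSE).
#' @param max_emit Per-formula structure cap (see [enumerate_isomers()]).
#' @return An `isolibrary`; every member matches the scaffold pattern.
#' @export
build_amino_acid_library <- function(max_carbons, elements = c("C", "H", "N", "O"),
                                     badlist = default_badlist(),
                                     mode = c("UL", "CL"),
                                     n_range = c(1, 2), o_range = c(2, 3),
                                     s_range = c(0, 1),
                                     n_substituted = FALSE,
                                     max_emit = 2e6) {
  mode <- match.arg(mode)
  if (max_carbons < 2) stop("max_carbons must be >= 2 (glycine has 2 carbons)")
  scaffold <- amino_acid_scaffold(n_substituted)
  space <- paste0("C2-", max_carbons,
                  "N", n_range[1], "-", n_range[2],
                  "O", o_range[1], "-", o_range[2],
                  if ("S" %in% elements) paste0("S", s_range[1], "-", s_range[2]))
  formulas <- expand_fuzzy(space)
  cons <- generation_constraints(badlist = badlist, goodlist = list(scaffold))
  mols <- list()
  reports <- list()
  for (f in formulas) {
    res <- enumerate_isomers(f, cons, max_emit = max_emit)
    reports[[format_formula(f)]] <- attr(res, "run")
    mols <- c(mols, res)
  }
  if (mode == "CL") {
    coded <- coded_amino_acids()
    ok <- vapply(coded, function(m) sum(m$elements == "C") <= max_carbons,
                 logical(1))
    mols <- c(mols, coded[ok])
  }
  lib <- new_library(mols, name = paste0("amino_acids_", mode, "_C", max_carbons),
                     provenance = list(
                       builder = "build_amino_acid_library",
                       mode = mode,
                       formula_space = space,
                       scaffold = scaffold$text,
                       badlist = vapply(.as_pattern_list(badlist),
                                        function(p) p$name, character(1)),
                       n_formulae = length(formulas)))
  attr(lib, "runs") <- reports
  lib
}

#' The 20 genetically coded amino acids
#'
#' Constitutional structures (no stereochemistry) of the standard coded
#' alphabet, read from the shipped SMILES file.
#'
#' @return Named list of `molgraph` objects (three-letter codes).
#' @export
coded_amino_acids <- function() {
  path <- system.file("extdata", "coded_amino_acids.smi", package = "isogen")
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  parts <- strsplit(trimws(lines), "\\s+")
  mols <- lapply(parts, function(p) parse_smiles(p[[1]]))
  names(mols) <- vapply(parts, function(p) p[[2]], character(1))
  mols
}

# ---- nucleoside analogues ------------------------------------------------

#' Nucleoside-analogue generation constraints
#'
#' @param min_free_functional_groups Minimum number of free O-H / N-H sites
#'   (oxygen or nitrogen atoms bearing at least one hydrogen, not bonded to
#'   the placeholder B) required for incorporation into a linear polymer.
#'   Default 2.
#' @param badlist Stability badlist (default
#'   [nucleoside_stability_badlist()]).
#' @return An object of class `nucleoside_constraints`.
#' @export
nucleoside_constraints <- function(min_free_functional_groups = 2,
                                   badlist = nucleoside_stability_badlist()) {
  if (min_free_functional_groups < 0) {
    stop("min_free_functional_groups must be >= 0")
  }
  structure(list(min_free_functional_groups = min_free_functional_groups,
                 badlist = .as_pattern_list(badlist)),
            class = "nucleoside_constraints")
}

#' Count free polymerizable functional groups
#'
#' Number of oxygen or nitrogen atoms that carry at least one implicit
#' hydrogen and are not bonded to the placeholder atom B (sites consumed by
#' the recognition-moiety attachment do not count).
#'
#' @param mol A `molgraph`.
#' @return Integer count.
#' @export
free_functional_groups <- function(mol) {
  h <- implicit_hydrogens(mol)
  b_at <- which(mol$elements == "B")
  near_b <- if (length(b_at)) which(rowSums(mol$adj[, b_at, drop = FALSE] > 0) > 0) else integer(0)
  sum(mol$elements %in% c("O", "N") & h > 0 &
        !(seq_along(mol$elements) %in% near_b))
}

#' The natural riboside (constitutional structure)
#'
#' Beta-ribofuranoside connectivity with the nucleobase replaced by the
#' placeholder B: `OCC1OC(B)C(O)C1O`. Stereochemistry is outside the model,
#' so this one graph stands for all anomers/epimers of the natural ribosides.
#'
#' @return A `molgraph`.
#' @export
natural_riboside <- function() {
  parse_smiles("OCC1OC(B)C(O)C1O")
}

#' Build a nucleoside-analogue library
#'
#' Enumerates all constitutional isomers of each formula in the space (every
#' expansion must contain exactly one placeholder B), removes structures
#' matching the stability badlist, and keeps those with at least
#' `min_free_functional_groups` free O-H/N-H sites. For the natural riboside
#' formula `C5H9O4B` the member with the natural connectivity is flagged in
#' the library annotations.
#'
#' @param space Formula or fuzzy formula (string or parsed) with B fixed
#'   at 1.
#' @param constraints A [nucleoside_constraints()] object.
#' @param max_emit Per-formula cap (see [enumerate_isomers()]).
#' @return An `isolibrary` with an `annotations` data frame (certificate,
#'   smiles, free functional groups, natural-riboside flag) and per-formula
#'   generation runs in the `"runs"` attribute.
#' @export
build_nucleoside_library <- function(space = "C5H9O4B",
                                     constraints = nucleoside_constraints(),
                                     max_emit = 2e6) {
  formulas <- expand_fuzzy(space)
  if (!length(formulas)) stop("formula space is empty or not graphical")
  for (f in formulas) {
    b <- unclass(f)["B"]
    if (is.na(b) || b != 1L) {
      stop("every formula in a nucleoside space must contain exactly one B; ",
           format_formula(f), " does not")
    }
  }
  cons <- generation_constraints(badlist = constraints$badlist)
  mols <- list()
  runs <- list()
  for (f in formulas) {
    res <- enumerate_isomers(f, cons, max_emit = max_emit)
    runs[[format_formula(f)]] <- attr(res, "run")
    mols <- c(mols, res)
  }
  ffg <- vapply(mols, free_functional_groups, integer(1))
  kept <- mols[ffg >= constraints$min_free_functional_groups]
  lib <- new_library(kept, name = "nucleoside_analogues",
                     provenance = list(
                       builder = "build_nucleoside_library",
                       formula_space = if (is.character(space)) space else format_formula(space),
                       badlist = vapply(constraints$badlist,
                                        function(p) p$name, character(1)),
                       min_free_functional_groups =
                         constraints$min_free_functional_groups,
                       n_raw = length(mols)))
  nat_cert <- canonical_form(natural_riboside())
  lib$annotations <- data.frame(
    certificate = library_certificates(lib),
    smiles = unname(library_smiles(lib)),
    free_functional_groups = vapply(lib$molecules, free_functional_groups,
                                    integer(1)),
    natural_riboside = library_certificates(lib) == nat_cert,
    row.names = NULL, stringsAsFactors = FALSE)
  attr(lib, "runs") <- runs
  lib
}

# ---- symmetry-aware substitution and diff --------------------------------

#' Substitute a heteroatom across a library, symmetry-aware
#'
#' For each molecule, replaces subsets of `from` atoms (size 1 to
#' `max_substitutions`) by `to`, emitting one product per orbit of position
#' subsets under the molecule's automorphism group, then deduplicates across
#' the library by certificate. Because the two elements share a valence,
#' the result equals de-novo generation of the substituted formulae under
#' the same constraints - without re-running the generator.
#'
#' @param lib An `isolibrary` (or plain list of `molgraph`s).
#' @param from,to Element symbols with equal valence (default O -> S).
#' @param max_substitutions Maximum number of positions substituted at once.
#' @return An `isolibrary` of substitution products.
#' @examples
#' lib <- new_library(enumerate_isomers("C2H6O2"))
#' thio <- substitute_heteroatom(lib, "O", "S", 1)
#' @export
substitute_heteroatom <- function(lib, from = "O", to = "S",
                                  max_substitutions = 1) {
  if (.valence(from) != .valence(to)) {
    stop("valence mismatch: ", from, " is ", .valence(from), "-valent, ",
         to, " is ", .valence(to), "-valent")
  }
  mols <- if (inherits(lib, "isolibrary")) lib$molecules else lib
  out <- list()
  for (mol in mols) {
    pos <- which(mol$elements == from)
    if (!length(pos)) next
    auts <- automorphism_group(mol)
    for (k in seq_len(min(max_substitutions, length(pos)))) {
      subsets <- if (length(pos) == 1) list(pos)
                 else utils::combn(pos, k, simplify = FALSE)
      keys <- vapply(subsets, function(s) paste(sort(s), collapse = ","),
                     character(1))
      for (i in seq_along(subsets)) {
        s <- subsets[[i]]
        # orbit representative: lexicographically smallest image key
        imgs <- vapply(auts, function(p) paste(sort(p[s]), collapse = ","),
                       character(1))
        if (keys[i] != min(imgs)) next
        elems <- mol$elements
        elems[s] <- to
        out[[length(out) + 1]] <- .molgraph_from_adj(elems, mol$adj)
      }
    }
  }
  new_library(out, name = paste0("substituted_", from, "_to_", to),
              provenance = list(builder = "substitute_heteroatom",
                                from = from, to = to,
                                max_substitutions = max_substitutions))
}

#' Compare two libraries by certificate
#'
#' @param a,b `isolibrary` objects.
#' @return List with `only_a`, `only_b`, `shared` (certificate vectors).
#' @export
library_diff <- function(a, b) {
  ca <- library_certificates(a)
  cb <- library_certificates(b)
  list(only_a = setdiff(ca, cb), only_b = setdiff(cb, ca),
       shared = intersect(ca, cb))
}

# ---- persistence ---------------------------------------------------------

#' Write / read a library (SMILES plus JSON provenance sidecar)
#'
#' `write_library` writes certificate-sorted SMILES, one per line, to
#' `path`, and the provenance to `paste0(path, ".json")`.
#'
#' @param lib An `isolibrary`.
#' @param path Output file path (e.g. `"lib.smi"`).
#' @param placeholder Placeholder token for B (see [write_smiles()]).
#' @return `read_library` returns an `isolibrary`.
#' @export
write_library <- function(lib, path, placeholder = "B") {
  writeLines(unname(library_smiles(lib, placeholder)), path)
  jsonlite::write_json(c(list(name = lib$name, n = length(lib$molecules)),
                         lib$provenance),
                       paste0(path, ".json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_library
#' @export
read_library <- function(path) {
  mols <- read_smiles_file(path)
  prov <- list()
  side <- paste0(path, ".json")
  if (file.exists(side)) prov <- jsonlite::read_json(side)
  name <- if (!is.null(prov$name)) prov$name else basename(path)
  new_library(mols, name = name, provenance = list(read_from = path))
}

#' Export a library as an SDF (MOL V2000) file
#'
#' Hydrogens are written explicitly; the placeholder B is written with the
#' atom symbol given by `placeholder` (default `"R"`, the conventional
#' pseudo-atom label), so downstream tools do not read it as boron.
#'
#' @param lib An `isolibrary` or list of `molgraph`s.
#' @param path Output path.
#' @param placeholder Atom symbol used for B (default `"R"`).
#' @return `path`, invisibly.
#' @export
write_sdf <- function(lib, path, placeholder = "R") {
  mols <- if (inherits(lib, "isolibrary")) lib$molecules else lib
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(mols)) {
    mol <- add_implicit_hydrogens(mols[[i]])
    sym <- mol$elements
    sym[sym == "B"] <- placeholder
    ut <- which(upper.tri(mol$adj) & mol$adj > 0, arr.ind = TRUE)
    writeLines(c(
      if (!is.null(names(mols)[i])) names(mols)[i] else paste0("mol_", i),
      "  isogen", "",
      sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
              length(sym), nrow(ut))), con)
    for (a in seq_along(sym)) {
      writeLines(sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                         0, 0, 0, sym[a]), con)
    }
    for (r in seq_len(nrow(ut))) {
      writeLines(sprintf("%3d%3d%3d  0", ut[r, 1], ut[r, 2],
                         mol$adj[ut[r, 1], ut[r, 2]]), con)
    }
    writeLines(c("M  END", "$$$$"), con)
  }
  invisible(path)
}
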