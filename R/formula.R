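# Exact and fuzzy molecular formulae: parsing, degree of unsaturation,
# graphical realizability, and range expansion.

#' Parse a molecular formula or fuzzy formula
#'
#' Exact formulae look like `"C5H9O4B"`; fuzzy formulae give per-element
#' count ranges, e.g. `"C2-6H0-13N1O2-4"`. Supported elements are C, H, N,
#' O, S and the univalent placeholder B. An exact formula is returned as a
#' named integer vector of class `formula_exact`; a formula containing at
#' least one range is returned as a named 2-row matrix (`min`, `max`) of
#' class `formula_fuzzy`.
#'
#' @param text Formula string.
#' @return A `formula_exact` or `formula_fuzzy` object.
#' @examples
#' parse_formula("C5H9O4B")
#' parse_formula("C2-3O0-1H8")
#' @export
parse_formula <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  text <- gsub("\\s", "", text)
  if (!nzchar(text)) stop("empty formula")
  rx <- "([A-Z][a-z]?)([0-9]+(?:-[0-9]+)?)?"
  m <- gregexpr(rx, text, perl = TRUE)[[1]]
  toks <- regmatches(text, list(m))[[1]]
  if (sum(nchar(toks)) != nchar(text)) stop("malformed formula: ", text)
  known <- names(valence_model())
  mins <- maxs <- integer(0)
  for (tok in toks) {
    sym <- sub("^([A-Z][a-z]?).*$", "\\1", tok)
    if (!(sym %in% known)) stop("unknown element '", sym, "' in formula")
    cnt <- sub("^[A-Z][a-z]?", "", tok)
    if (cnt == "") {
      lo <- hi <- 1L
    } else if (grepl("-", cnt)) {
      parts <- as.integer(strsplit(cnt, "-")[[1]])
      lo <- parts[1]; hi <- parts[2]
      if (lo > hi) stop("malformed range '", tok, "': min exceeds max")
    } else {
      lo <- hi <- as.integer(cnt)
    }
    if (sym %in% names(mins)) {
      mins[sym] <- mins[sym] + lo
      maxs[sym] <- maxs[sym] + hi
    } else {
      mins[sym] <- lo
      maxs[sym] <- hi
    }
  }
  if (all(mins == maxs)) {
    f <- mins[mins > 0]
    if (!length(setdiff(names(f), "H"))) {
      stop("formula needs at least one non-hydrogen atom")
    }
    structure(f, class = "formula_exact")
  } else {
    structure(rbind(min = mins, max = maxs), class = "formula_fuzzy")
  }
}

#' Format a formula back to a string
#'
#' Canonical spelling: element order C, H, other elements alphabetically,
#' the placeholder B last; counts of exactly one are omitted.
#' `format_formula(parse_formula(x))` is idempotent.
#'
#' @param f A `formula_exact` or `formula_fuzzy`.
#' @return A string.
#' @export
format_formula <- function(f) {
  ord <- function(e) c(intersect(c("C", "H"), e),
                       sort(setdiff(e, c("C", "H", "B"))),
                       intersect("B", e))
  num <- function(lo, hi) {
    if (lo == hi) {
      if (lo == 1) "" else as.character(lo)
    } else {
      paste0(lo, "-", hi)
    }
  }
  if (inherits(f, "formula_fuzzy")) {
    e <- ord(colnames(f))
    paste0(vapply(e, function(s) paste0(s, num(f["min", s], f["max", s])),
                  character(1)), collapse = "")
  } else {
    e <- ord(names(f))
    cnt <- unclass(f)
    paste0(vapply(e, function(s) paste0(s, num(cnt[s], cnt[s])),
                  character(1)), collapse = "")
  }
}

#' @export
print.formula_exact <- function(x, ...) {
  cat("<formula> ", format_formula(x), "\n", sep = "")
  invisible(x)
}

#' @export
print.formula_fuzzy <- function(x, ...) {
  cat("<fuzzy formula> ", format_formula(x), "\n", sep = "")
  invisible(x)
}

.as_exact_formula <- function(f) {
  if (is.character(f)) f <- parse_formula(f)
  if (inherits(f, "formula_fuzzy")) stop("an exact formula is required here")
  f
}

#' Degree of unsaturation (rings plus multiple bonds)
#'
#' `dbe = 1 + sum(count(e) * (valence(e) - 2)) / 2` over all elements
#' including hydrogen. Half-integral values signal an impossible (odd
#' valence-sum) formula.
#'
#' @param f Exact formula (string or `formula_exact`).
#' @return A number (may be half-integral or negative for non-graphical
#'   formulae).
#' @examples
#' dbe("C6H6")     # 4: benzene
#' dbe("C5H9O4B")  # 1: one ring or double bond
#' @export
dbe <- function(f) {
  f <- .as_exact_formula(f)
  v <- valence_model()[names(f)]
  1 + sum(unclass(f) * (v - 2)) / 2
}

#' Can a formula be realized as a connected molecular graph?
#'
#' Tests whether a connected multigraph with bond orders 1-3 exists whose
#' atoms carry the formula's element counts with every valence satisfied
#' after implicit hydrogens: even valence sum, non-negative degree of
#' unsaturation, enough bonds to connect all heavy atoms, and a feasible
#' heavy-atom degree sequence.
#'
#' @param f Exact formula (string or `formula_exact`).
#' @return `TRUE` or `FALSE`.
#' @examples
#' is_graphical("CH5")   # FALSE: odd valence sum
#' is_graphical("C2H6")  # TRUE: ethane
#' @export
is_graphical <- function(f) {
  f <- .as_exact_formula(f)
  counts <- unclass(f)
  nH <- if ("H" %in% names(counts)) counts[["H"]] else 0L
  heavy <- counts[setdiff(names(counts), "H")]
  heavy <- heavy[heavy > 0]
  if (!length(heavy)) return(FALSE)
  vals <- rep(.valence(names(heavy)), heavy)
  n <- length(vals)
  vsum <- sum(vals)
  if ((vsum + nH) %% 2 != 0) return(FALSE)       # parity over all atoms
  T <- (vsum - nH) / 2                           # total bond-order sum
  if (T != round(T) || T < n - 1) return(FALSE)  # dbe >= 0, connectable
  if (n == 1) return(nH == vals[1])
  if (nH > vsum - 2 * (n - 1)) return(FALSE)     # every atom needs degree >= 1
  if (n == 2) return(T <= min(3, vals))          # single bond, order-capped
  # feasible heavy degree sequence: d_i in [1, min(v_i, T)] with sum 2T
  if (sum(pmin(vals, T)) < 2 * T) return(FALSE)
  TRUE
}

#' Expand a fuzzy formula into graphical exact formulae
#'
#' Forms the Cartesian product of all element count ranges, drops
#' non-graphical combinations, and returns the rest in deterministic
#' lexicographic order (by element count vectors). When hydrogen is absent
#' from the fuzzy formula it is treated as free: every hydrogen count
#' achievable by valence closure (matching parity, non-negative degree of
#' unsaturation) is expanded.
#'
#' @param f A `formula_fuzzy` (or string), or an exact formula (returned
#'   as-is in a one-element list).
#' @param cap Maximum number of expanded formulae before erroring (guards
#'   against combinatorial explosions). Default 10000.
#' @return List of `formula_exact` objects.
#' @examples
#' expand_fuzzy("C2H6O0-1")
#' @export
expand_fuzzy <- function(f, cap = 10000) {
  if (is.character(f)) f <- parse_formula(f)
  if (inherits(f, "formula_exact")) {
    return(if (is_graphical(f)) list(f) else list())
  }
  elems <- colnames(f)
  h_free <- !("H" %in% elems)
  ranges <- lapply(elems, function(e) seq(f["min", e], f["max", e]))
  names(ranges) <- elems
  grid <- expand.grid(rev(ranges), KEEP.OUT.ATTRS = FALSE)
  grid <- grid[, rev(seq_along(ranges)), drop = FALSE]
  # lexicographic order over element count vectors
  grid <- grid[do.call(order, as.list(grid)), , drop = FALSE]
  out <- list()
  for (r in seq_len(nrow(grid))) {
    counts <- stats::setNames(as.integer(grid[r, ]), elems)
    hs <- if (h_free) {
      heavy <- counts[counts > 0]
      if (!length(setdiff(names(heavy), "H"))) next
      vsum <- sum(rep(.valence(names(heavy)), heavy))
      seq(vsum %% 2, vsum, by = 2)
    } else {
      counts[["H"]]
    }
    for (nh in hs) {
      cand <- counts
      cand["H"] <- as.integer(nh)
      cand <- cand[cand > 0]
      if (!length(setdiff(names(cand), "H"))) next
      if (is_graphical(structure(cand, class = "formula_exact"))) {
        out[[length(out) + 1]] <- structure(cand, class = "formula_exact")
        if (length(out) > cap) {
          stop("fuzzy formula expands to more than ", cap,
               " formulae; narrow the ranges or raise `cap`")
        }
      }
    }
  }
  out
}
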