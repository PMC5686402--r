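# Substructure patterns: a SMARTS subset sufficient for badlist/goodlist
# filtering. Atoms: element symbols C N O S B, wildcard *, and bracket atoms
# [XHn] requiring at least n implicit hydrogens on the matched atom
# (e.g. [OH1] is a hydroxyl oxygen, [NH2] a primary amine nitrogen).
# Bonds: - = # and ~ (any order). Branches and single-digit ring closures.
# Matching is subgraph embedding (not induced): pattern bonds must exist in
# the molecule, extra molecule bonds are allowed.

#' Parse a substructure pattern (SMARTS subset)
#'
#' @param text Pattern string, e.g. `"OO"` (peroxide), `"C(=O)[OH1]"`
#'   (carboxyl), `"C=C[OH1]"` (enol), `"*~B"` (anything bonded to the
#'   placeholder).
#' @param name Optional pattern name (defaults to the pattern text).
#' @param rationale Optional free-text reason the pattern is filtered.
#' @return An object of class `substructure_pattern`.
#' @examples
#' parse_pattern("C(=O)[OH1]", name = "carboxyl")
#' @export
parse_pattern <- function(text, name = text, rationale = "") {
  stopifnot(is.character(text), length(text) == 1)
  chars <- strsplit(text, "")[[1]]
  elements <- character(0)
  min_h <- integer(0)
  bonds <- matrix(integer(0), ncol = 3)
  prev <- NA_integer_
  pending <- -1L  # -1 = unspecified (single); 0 = any (~)
  branch_stack <- integer(0)
  rings <- list()
  add_atom <- function(sym, mh) {
    elements <<- c(elements, sym)
    min_h <<- c(min_h, mh)
    a <- length(elements)
    if (!is.na(prev)) {
      o <- if (pending == -1L) 1L else pending
      bonds <<- rbind(bonds, c(prev, a, o))
    }
    pending <<- -1L
    prev <<- a
  }
  i <- 1L
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch %in% c("C", "N", "O", "S", "B")) {
      add_atom(ch, 0L)
    } else if (ch == "*") {
      add_atom("*", 0L)
    } else if (ch == "[") {
      j <- i + 1L
      while (j <= length(chars) && chars[j] != "]") j <- j + 1L
      if (j > length(chars)) stop("unclosed '[' at position ", i)
      body <- paste0(chars[(i + 1):(j - 1)], collapse = "")
      m <- regmatches(body, regexec("^([CNOSB]|\\*)(H([0-9]*))?$", body))[[1]]
      if (!length(m)) {
        stop("unsupported bracket atom '[", body, "]' at position ", i)
      }
      mh <- if (m[3] == "") 0L else if (m[4] == "") 1L else as.integer(m[4])
      add_atom(m[2], mh)
      i <- j
    } else if (ch == "-") {
      pending <- 1L
    } else if (ch == "=") {
      pending <- 2L
    } else if (ch == "#") {
      pending <- 3L
    } else if (ch == "~") {
      pending <- 0L
    } else if (ch == "(") {
      branch_stack <- c(branch_stack, prev)
    } else if (ch == ")") {
      if (!length(branch_stack)) stop("unbalanced ')' at position ", i)
      prev <- branch_stack[length(branch_stack)]
      branch_stack <- branch_stack[-length(branch_stack)]
    } else if (grepl("^[1-9]$", ch)) {
      d <- ch
      if (is.null(rings[[d]])) {
        rings[[d]] <- list(atom = prev,
                           order = if (pending == -1L) 1L else pending)
        pending <- -1L
      } else {
        o <- max(if (pending == -1L) 1L else pending, rings[[d]]$order)
        bonds <- rbind(bonds, c(rings[[d]]$atom, prev, o))
        rings[[d]] <- NULL
        pending <- -1L
      }
    } else {
      stop("unsupported pattern token '", ch, "' at position ", i)
    }
    i <- i + 1L
  }
  if (!length(elements)) stop("empty pattern")
  if (length(branch_stack)) stop("unbalanced '(' in pattern")
  open <- length(rings) && any(!vapply(rings, is.null, logical(1)))
  if (open) stop("unclosed ring bond(s) in pattern")
  p <- structure(list(elements = elements, min_h = min_h,
                      bonds = bonds, text = text, name = name,
                      rationale = rationale),
                 class = "substructure_pattern")
  .pattern_check_connected(p)
  p
}

.pattern_check_connected <- function(p) {
  n <- length(p$elements)
  if (n == 1) return(invisible(TRUE))
  adj <- matrix(FALSE, n, n)
  for (r in seq_len(nrow(p$bonds))) {
    adj[p$bonds[r, 1], p$bonds[r, 2]] <- TRUE
    adj[p$bonds[r, 2], p$bonds[r, 1]] <- TRUE
  }
  seen <- logical(n)
  seen[1] <- TRUE
  stack <- 1L
  while (length(stack)) {
    u <- stack[length(stack)]
    stack <- stack[-length(stack)]
    nb <- which(adj[u, ] & !seen)
    seen[nb] <- TRUE
    stack <- c(stack, nb)
  }
  if (!all(seen)) stop("pattern graph must be connected")
  invisible(TRUE)
}

#' @export
print.substructure_pattern <- function(x, ...) {
  cat("<pattern> ", x$name, ": ", x$text,
      if (nzchar(x$rationale)) paste0("  (", x$rationale, ")"), "\n", sep = "")
  invisible(x)
}

# format used by the C++ matcher
.pattern_payload <- function(p) {
  list(elements = p$elements, min_h = p$min_h,
       bonds = if (nrow(p$bonds)) p$bonds else matrix(integer(0), ncol = 3))
}

#' Does a pattern occur in a molecule?
#'
#' Tests for a label- and bond-order-consistent subgraph embedding of the
#' pattern into the molecular graph. Wildcard atoms match any element;
#' `~` bonds match any order; bracket `Hn` constraints require at least `n`
#' implicit hydrogens on the matched atom.
#'
#' @param pattern A `substructure_pattern` (or pattern string).
#' @param mol A `molgraph`.
#' @return `TRUE` or `FALSE`.
#' @examples
#' match_pattern("OO", parse_smiles("COOC"))  # peroxide present
#' match_pattern("OO", parse_smiles("OCCO"))  # but not in the glycol
#' @export
match_pattern <- function(pattern, mol) {
  if (is.character(pattern)) pattern <- parse_pattern(pattern)
  validate_molgraph(mol)
  cpp_match(.pattern_payload(pattern), mol$elements,
            .valence(mol$elements), mol$adj)
}

#' Read a badlist / pattern list file
#'
#' Plain text, one SMARTS-subset pattern per line; a `#` at the start of the
#' line or preceded by whitespace begins the pattern's rationale comment
#' (`#` directly inside a pattern is the triple-bond symbol). Blank lines
#' are ignored. An optional `name:` prefix before the pattern sets the
#' pattern name; otherwise the pattern text is the name. Names must be
#' unique.
#'
#' @param path File path.
#' @return A list of `substructure_pattern` objects (class `badlist`).
#' @export
read_badlist <- function(path) {
  lines <- readLines(path)
  out <- list()
  for (ln in lines) {
    rationale <- ""
    if (grepl("(^|\\s)#", ln)) {
      rationale <- trimws(sub("^.*?(^|\\s)#", "", ln))
      ln <- sub("(^|\\s)#.*$", "", ln)
    }
    ln <- trimws(ln)
    if (!nzchar(ln)) next
    name <- ln
    if (grepl("^[A-Za-z0-9_.-]+:\\s", ln)) {
      name <- sub(":\\s.*$", "", ln)
      ln <- trimws(sub("^[A-Za-z0-9_.-]+:\\s+", "", ln))
    }
    out[[length(out) + 1]] <- parse_pattern(ln, name = name,
                                            rationale = rationale)
  }
  nms <- vapply(out, function(p) p$name, character(1))
  if (anyDuplicated(nms)) stop("duplicate pattern names in ", path)
  structure(out, class = "badlist")
}

.as_pattern_list <- function(x) {
  if (is.null(x)) return(list())
  if (inherits(x, "substructure_pattern")) return(list(x))
  lapply(x, function(p) if (is.character(p)) parse_pattern(p) else p)
}

#' Default chemical-plausibility badlist
#'
#' A reconstruction, in spirit, of the kind of forbidden-substructure list
#' used to restrict exhaustive generation to chemically plausible molecules;
#' it is not a copy of any published list. Each pattern carries its
#' rationale. See the shipped file
#' `system.file("extdata", "default_badlist.smarts", package = "isogen")`.
#'
#' @return A `badlist` (list of `substructure_pattern`s).
#' @export
default_badlist <- function() {
  read_badlist(system.file("extdata", "default_badlist.smarts",
                           package = "isogen"))
}

#' Nucleoside stability badlist
#'
#' Patterns for motifs unstable under biochemically relevant aqueous
#' conditions, used when enumerating nucleoside-analogue libraries. A
#' package reconstruction documented pattern-by-pattern in the shipped file
#' `system.file("extdata", "nucleoside_stability.smarts", package="isogen")`.
#'
#' @return A `badlist`.
#' @export
nucleoside_stability_badlist <- function() {
  read_badlist(system.file("extdata", "nucleoside_stability.smarts",
                           package = "isogen"))
}

#' Filter a set of molecules through bad and good patterns
#'
#' Passes molecules that match no badlist pattern and every goodlist
#' pattern. Removals are attributed to the first matching bad pattern
#' (first-match attribution), so per-pattern counts sum to the total
#' removed by the badlist.
#'
#' @param mols List of `molgraph` objects.
#' @param bad Badlist: list of patterns/pattern strings (or `NULL`).
#' @param good Goodlist: list of patterns that must all occur (or `NULL`).
#' @return A list with `kept` (list of molgraphs) and `report` (data frame
#'   with columns `pattern`, `removed`, plus rows for goodlist failures and
#'   the total).
#' @export
filter_library <- function(mols, bad = NULL, good = NULL) {
  bad <- .as_pattern_list(bad)
  good <- .as_pattern_list(good)
  nb <- length(bad)
  bad_counts <- integer(nb)
  good_fail <- 0L
  kept <- list()
  for (mol in mols) {
    hit <- 0L
    for (b in seq_len(nb)) {
      if (match_pattern(bad[[b]], mol)) {
        hit <- b
        break
      }
    }
    if (hit > 0) {
      bad_counts[hit] <- bad_counts[hit] + 1L
      next
    }
    ok <- TRUE
    for (g in good) {
      if (!match_pattern(g, mol)) {
        ok <- FALSE
        break
      }
    }
    if (!ok) {
      good_fail <- good_fail + 1L
      next
    }
    kept[[length(kept) + 1]] <- mol
  }
  report <- data.frame(
    pattern = c(vapply(bad, function(p) p$name, character(1)),
                if (length(good)) "goodlist_failed",
                "total_removed"),
    removed = c(bad_counts, if (length(good)) good_fail,
                sum(bad_counts) + good_fail),
    stringsAsFactors = FALSE)
  list(kept = kept, report = report)
}
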