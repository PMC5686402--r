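# Molecular graph data model: element-labeled connected multigraphs with
# bond orders 1..3 and implicit hydrogens. The unit of enumeration.

#' Construct a molecular graph
#'
#' A molecular graph is a connected multigraph whose nodes are heavy atoms
#' (C, N, O, S, or the univalent placeholder B) and whose edges are covalent
#' bonds of order 1, 2 or 3. Hydrogens are implicit: every atom carries
#' `valence(element) - sum(incident bond orders)` hydrogens. Molecules are
#' neutral and closed-shell; charges, radicals and stereochemistry are not
#' representable.
#'
#' @param elements Character vector of element symbols, one per heavy atom.
#' @param bonds Integer matrix with three columns (atom index `i`, atom index
#'   `j`, bond order 1-3), one row per bond; or `NULL` for a single-atom
#'   molecule.
#' @return An object of class `molgraph`.
#' @examples
#' ethanol <- molgraph(c("C", "C", "O"), rbind(c(1, 2, 1), c(2, 3, 1)))
#' ethanol
#' @export
molgraph <- function(elements, bonds = NULL) {
  elements <- as.character(elements)
  n <- length(elements)
  if (n == 0) stop("a molecule needs at least one heavy atom")
  val <- .valence(elements)  # errors on unsupported elements
  adj <- matrix(0L, n, n)
  if (!is.null(bonds) && length(bonds)) {
    bonds <- matrix(as.integer(bonds), ncol = 3)
    for (r in seq_len(nrow(bonds))) {
      i <- bonds[r, 1]; j <- bonds[r, 2]; o <- bonds[r, 3]
      if (i < 1 || i > n || j < 1 || j > n) stop("bond references missing atom")
      if (i == j) stop("self-loops are not allowed (atom ", i, ")")
      if (o < 1 || o > 3) stop("bond order must be 1, 2 or 3")
      if (adj[i, j] != 0) stop("duplicate bond record for atoms ", i, "-", j)
      adj[i, j] <- o
      adj[j, i] <- o
    }
  }
  m <- structure(list(elements = elements, adj = adj), class = "molgraph")
  validate_molgraph(m)
  m
}

.molgraph_from_adj <- function(elements, adj, validate = FALSE) {
  m <- structure(list(elements = as.character(elements),
                      adj = adj), class = "molgraph")
  if (validate) validate_molgraph(m)
  m
}

#' Validate a molecular graph
#'
#' Checks the structural invariants: supported elements, symmetric bond-order
#' matrix, no over-valent atom (bond-order sum must not exceed the element's
#' fixed valence) and connectivity.
#'
#' @param mol A `molgraph`.
#' @return `mol`, invisibly; errors describe the offending atom.
#' @export
validate_molgraph <- function(mol) {
  stopifnot(inherits(mol, "molgraph"))
  n <- length(mol$elements)
  val <- .valence(mol$elements)
  deg <- rowSums(mol$adj)
  over <- which(deg > val)
  if (length(over)) {
    stop("atom ", over[1], " (", mol$elements[over[1]], ") exceeds valence ",
         val[over[1]], " with bond-order sum ", deg[over[1]])
  }
  if (n > 1 && !.is_connected(mol$adj)) stop("molecular graph is not connected")
  invisible(mol)
}

.is_connected <- function(adj) {
  n <- nrow(adj)
  seen <- logical(n)
  stack <- 1L
  seen[1] <- TRUE
  while (length(stack)) {
    u <- stack[length(stack)]
    stack <- stack[-length(stack)]
    nb <- which(adj[u, ] > 0 & !seen)
    seen[nb] <- TRUE
    stack <- c(stack, nb)
  }
  all(seen)
}

#' Implicit hydrogen counts per atom
#'
#' @param mol A `molgraph`.
#' @return Integer vector: hydrogens carried by each heavy atom.
#' @export
implicit_hydrogens <- function(mol) {
  as.integer(.valence(mol$elements) - rowSums(mol$adj))
}

#' Add implicit hydrogens as explicit atoms
#'
#' Returns a graph in which every heavy atom's free valence has been filled
#' with explicit hydrogen atoms, so each atom's bond-order sum equals its
#' valence.
#'
#' @param mol A `molgraph`.
#' @return A `molgraph` containing explicit `H` atoms.
#' @examples
#' h <- add_implicit_hydrogens(molgraph("C"))
#' table(h$elements)  # CH4
#' @export
add_implicit_hydrogens <- function(mol) {
  validate_molgraph(mol)
  hs <- implicit_hydrogens(mol)
  n <- length(mol$elements)
  ntot <- n + sum(hs)
  adj <- matrix(0L, ntot, ntot)
  adj[seq_len(n), seq_len(n)] <- mol$adj
  elements <- c(mol$elements, rep("H", sum(hs)))
  k <- n
  for (i in seq_len(n)) {
    for (h in seq_len(hs[i])) {
      k <- k + 1L
      adj[i, k] <- 1L
      adj[k, i] <- 1L
    }
  }
  .molgraph_from_adj(elements, adj)
}

#' Molecular formula of a graph
#'
#' @param mol A `molgraph`.
#' @return Named integer vector of element counts, including implicit `H`.
#' @export
mol_formula <- function(mol) {
  counts <- table(mol$elements)
  f <- stats::setNames(as.integer(counts), names(counts))
  nh <- sum(implicit_hydrogens(mol)) + sum(mol$elements == "H")
  f <- f[names(f) != "H"]
  if (nh > 0) f <- c(f, H = nh)
  # Hill-ish display order: C, H, then alphabetical
  ord <- c(intersect(c("C", "H"), names(f)),
           sort(setdiff(names(f), c("C", "H"))))
  f[ord]
}

#' Canonical certificate of a molecular graph
#'
#' The certificate is a string that is identical for any two isomorphic
#' molecular graphs and distinct for non-isomorphic ones. It is computed by
#' ordering atoms by decreasing valence (then element symbol) and finding the
#' lexicographically maximal column-major serialization of the bond-order
#' matrix over all element-preserving atom permutations, by backtracking
#' search with prefix pruning.
#'
#' @param mol A `molgraph`.
#' @return A single string; relabeling the atoms of `mol` never changes it.
#' @examples
#' a <- molgraph(c("C", "C", "O"), rbind(c(1, 2, 1), c(2, 3, 1)))
#' b <- molgraph(c("O", "C", "C"), rbind(c(1, 2, 1), c(2, 3, 1)))
#' identical(canonical_form(a), canonical_form(b))  # TRUE: same ethanol
#' @export
canonical_form <- function(mol) {
  validate_molgraph(mol)
  cpp_certificate(mol$elements, .valence(mol$elements), mol$adj)
}

#' Test two molecular graphs for isomorphism
#'
#' @param a,b `molgraph` objects.
#' @return `TRUE` iff the graphs are isomorphic (identical certificates).
#' @export
are_isomorphic <- function(a, b) {
  identical(canonical_form(a), canonical_form(b))
}

#' Automorphism group of a molecular graph
#'
#' All atom permutations that preserve element labels and bond orders,
#' found by backtracking. The result always contains the identity and is
#' closed under composition.
#'
#' @param mol A `molgraph`.
#' @return A list of integer permutation vectors (`p[i]` is the image of
#'   atom `i`).
#' @examples
#' glycol <- molgraph(c("O", "C", "C", "O"),
#'                    rbind(c(1, 2, 1), c(2, 3, 1), c(3, 4, 1)))
#' length(automorphism_group(glycol))  # 2: identity and the end-to-end flip
#' @export
automorphism_group <- function(mol) {
  validate_molgraph(mol)
  perms <- cpp_automorphisms(mol$elements, .valence(mol$elements), mol$adj)
  lapply(seq_len(nrow(perms)), function(r) as.integer(perms[r, ]))
}

#' Relabel the atoms of a molecular graph
#'
#' Applies a permutation to the atom order; the result represents the same
#' molecule. Mainly useful for testing invariance properties.
#'
#' @param mol A `molgraph`.
#' @param perm Integer permutation of `seq_along(mol$elements)`; position `i`
#'   of the result is atom `perm[i]` of the input.
#' @return A `molgraph`.
#' @export
relabel_mol <- function(mol, perm) {
  stopifnot(sort(perm) == seq_along(mol$elements))
  .molgraph_from_adj(mol$elements[perm], mol$adj[perm, perm, drop = FALSE])
}

#' @export
print.molgraph <- function(x, ...) {
  f <- mol_formula(x)
  cat("<molgraph> ", paste0(names(f), ifelse(f > 1, f, ""), collapse = ""),
      " (", length(x$elements), " heavy atoms, ",
      sum(x$adj[upper.tri(x$adj)] > 0), " bonds)\n", sep = "")
  cat("  SMILES: ", write_smiles(x), "\n", sep = "")
  invisible(x)
}

# reconstruct a molgraph from a generator serialization (column-major upper
# triangle digits) plus the element vector it was generated with
.mol_from_serialization <- function(elements, digits) {
  n <- length(elements)
  adj <- matrix(0L, n, n)
  if (n > 1) {
    o <- as.integer(strsplit(digits, "")[[1]])
    t <- 0L
    for (b in 2:n) {
      for (a in 1:(b - 1)) {
        t <- t + 1L
        adj[a, b] <- o[t]
        adj[b, a] <- o[t]
      }
    }
  }
  .molgraph_from_adj(elements, adj)
}
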