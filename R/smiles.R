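# SMILES subset reader/writer. Dialect: Kekulé only (no aromatic lowercase),
# elements C, N, O, S plus the univalent placeholder written "B" (or any
# token chosen via `placeholder`), bonds - = #, branches, ring closures 1-9.
# Implicit hydrogens follow the package valence model, which coincides with
# the SMILES defaults for C, N, O and S.

#' Write a molecular graph as SMILES
#'
#' @param mol A `molgraph`.
#' @param placeholder Token emitted for the univalent placeholder element
#'   `B` (default `"B"`; use `"[*]"` for tools that would read `B` as boron).
#' @return A SMILES string.
#' @examples
#' write_smiles(molgraph(c("C", "C", "O"), rbind(c(1, 2, 1), c(2, 3, 1))))
#' @export
write_smiles <- function(mol, placeholder = "B") {
  validate_molgraph(mol)
  n <- length(mol$elements)
  adj <- mol$adj
  sym <- mol$elements
  sym[sym == "B"] <- placeholder
  bondsym <- c("", "", "=", "#")  # index by order + 1
  if (n == 1) return(sym[1])

  # DFS spanning tree; back edges become ring closures
  visited <- logical(n)
  ringn <- 0L
  ring_open <- list()   # atom -> vector of closure labels
  ring_bond <- list()   # label -> bond symbol
  for (i in seq_len(n)) ring_open[[i]] <- integer(0)
  tree_children <- vector("list", n)
  parent <- rep(NA_integer_, n)
  # iterative DFS to fix traversal order
  order_stack <- 1L
  visited[1] <- TRUE
  dfs_order <- integer(0)
  while (length(order_stack)) {
    u <- order_stack[length(order_stack)]
    order_stack <- order_stack[-length(order_stack)]
    dfs_order <- c(dfs_order, u)
    nbs <- which(adj[u, ] > 0)
    for (v in rev(nbs)) {
      if (!visited[v]) {
        visited[v] <- TRUE
        parent[v] <- u
        tree_children[[u]] <- c(tree_children[[u]], v)
        order_stack <- c(order_stack, v)
      }
    }
  }
  # back edges: u < v in dfs rank, v not child/parent of u
  rank <- match(seq_len(n), dfs_order)
  for (u in seq_len(n)) {
    for (v in which(adj[u, ] > 0)) {
      if (u < v && !identical(parent[v], u) && !identical(parent[u], v)) {
        ringn <- ringn + 1L
        if (ringn > 9) stop("more than 9 ring closures not supported")
        ring_open[[u]] <- c(ring_open[[u]], ringn)
        ring_open[[v]] <- c(ring_open[[v]], ringn)
        ring_bond[[ringn]] <- bondsym[adj[u, v] + 1]
      }
    }
  }
  seen_ring <- logical(9)
  emit <- function(u, frombond) {
    s <- paste0(frombond, sym[u])
    for (lab in ring_open[[u]]) {
      if (!seen_ring[lab]) {
        s <- paste0(s, ring_bond[[lab]], lab)
        seen_ring[lab] <<- TRUE
      } else {
        s <- paste0(s, lab)
      }
    }
    ch <- tree_children[[u]]
    if (length(ch)) {
      for (k in seq_along(ch)) {
        b <- bondsym[adj[u, ch[k]] + 1]
        child <- emit(ch[k], b)
        if (k < length(ch)) s <- paste0(s, "(", child, ")")
        else s <- paste0(s, child)
      }
    }
    s
  }
  emit(1L, "")
}

#' Parse a SMILES string (package subset)
#'
#' Supports the dialect the package writes: bare atoms `C N O S B`, `[*]` as
#' an alternative spelling of the placeholder, bonds `- = #`, branches and
#' single-digit ring closures. Aromatic lowercase atoms, charges, isotopes
#' and stereo tokens are rejected with the offending position.
#'
#' @param text A SMILES string.
#' @return A `molgraph`.
#' @examples
#' mol <- parse_smiles("OCC1OC(B)C(O)C1O")  # the natural riboside skeleton
#' mol_formula(mol)
#' @export
parse_smiles <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  chars <- strsplit(text, "")[[1]]
  elements <- character(0)
  bonds <- matrix(integer(0), ncol = 3)
  prev <- NA_integer_
  pending <- 1L
  branch_stack <- integer(0)
  rings <- list()  # digit -> list(atom, order)
  i <- 1L
  add_atom <- function(sym) {
    elements <<- c(elements, sym)
    a <- length(elements)
    if (!is.na(prev)) bonds <<- rbind(bonds, c(prev, a, pending))
    pending <<- 1L
    prev <<- a
  }
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch %in% c("C", "N", "O", "S", "B")) {
      add_atom(ch)
    } else if (ch == "[") {
      if (i + 2 <= length(chars) && chars[i + 1] == "*" && chars[i + 2] == "]") {
        add_atom("B")
        i <- i + 2L
      } else {
        stop("unsupported bracket atom at position ", i)
      }
    } else if (ch == "-") {
      pending <- 1L
    } else if (ch == "=") {
      pending <- 2L
    } else if (ch == "#") {
      pending <- 3L
    } else if (ch == "(") {
      branch_stack <- c(branch_stack, prev)
    } else if (ch == ")") {
      if (!length(branch_stack)) stop("unbalanced ')' at position ", i)
      prev <- branch_stack[length(branch_stack)]
      branch_stack <- branch_stack[-length(branch_stack)]
    } else if (grepl("^[1-9]$", ch)) {
      d <- ch
      if (is.null(rings[[d]])) {
        rings[[d]] <- list(atom = prev, order = pending)
        pending <- 1L
      } else {
        o <- max(pending, rings[[d]]$order)
        bonds <- rbind(bonds, c(rings[[d]]$atom, prev, o))
        rings[[d]] <- NULL
        pending <- 1L
      }
    } else {
      stop("unsupported SMILES token '", ch, "' at position ", i)
    }
    i <- i + 1L
  }
  open <- !vapply(rings, is.null, logical(1))
  if (length(rings) && any(open)) stop("unclosed ring bond(s)")
  if (length(branch_stack)) stop("unbalanced '(' in SMILES")
  molgraph(elements, if (nrow(bonds)) bonds else NULL)
}

#' Read / write one-molecule-per-line SMILES files
#'
#' @param mols A list of `molgraph` objects.
#' @param path File path.
#' @param placeholder Passed to [write_smiles()].
#' @return `read_smiles_file` returns a list of `molgraph`s.
#' @export
write_smiles_file <- function(mols, path, placeholder = "B") {
  writeLines(vapply(mols, write_smiles, character(1),
                    placeholder = placeholder), path)
  invisible(path)
}

#' @rdname write_smiles_file
#' @export
read_smiles_file <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  lapply(lines, parse_smiles)
}
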