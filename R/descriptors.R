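# Additive molecular descriptors: atomic-contribution logP, additive van der
# Waals volume with bond/ring corrections, rule-based side-chain pKa class
# lookup, and the Wiener topological index. Parameter tables ship as CSV
# files under inst/extdata; values are internally consistent coarse
# parameterizations (see the tables' header comments for provenance), so
# descriptor values are meaningful relative to each other within a library
# rather than as absolute literature values.

.descriptor_table_env <- new.env(parent = emptyenv())

.load_table <- function(file) {
  if (is.null(.descriptor_table_env[[file]])) {
    path <- system.file("extdata", file, package = "isogen")
    .descriptor_table_env[[file]] <- utils::read.csv(path, comment.char = "#",
                                                     stringsAsFactors = FALSE)
  }
  .descriptor_table_env[[file]]
}

# atom-environment type used by the logP table
.logp_types <- function(mol) {
  n <- length(mol$elements)
  h <- implicit_hydrogens(mol)
  vapply(seq_len(n), function(i) {
    e <- mol$elements[i]
    nb <- which(mol$adj[i, ] > 0)
    het <- sum(mol$elements[nb] %in% c("N", "O", "S"))
    switch(e,
      C = if (any(mol$adj[i, nb] == 2 & mol$elements[nb] == "O")) "C_carbonyl"
          else if (het > 0) "C_hetero"
          else "C_aliphatic",
      O = if (any(mol$adj[i, nb] == 2)) "O_carbonyl"
          else if (h[i] > 0) "O_hydroxyl"
          else "O_ether",
      N = if (h[i] > 0) "N_amine_H" else "N_amine_3",
      S = "S_thio",
      B = "B_placeholder",
      stop("no logP parameter for element ", e))
  }, character(1))
}

#' Atomic-contribution logP
#'
#' Sum of per-atom contributions over coarse atom-environment types
#' (aliphatic vs heteroatom-substituted vs carbonyl carbon; hydroxyl, ether
#' and carbonyl oxygen; N-H vs fully substituted nitrogen; sulfur;
#' placeholder). Hydrogens are folded into their heavy atom's contribution.
#' The shipped table `logp_contributions.csv` documents each type and value.
#' Deterministic and invariant under atom relabeling.
#'
#' @param mol A `molgraph`.
#' @return Numeric logP estimate (unitless).
#' @examples
#' logp(parse_smiles("CC")) > logp(parse_smiles("CO"))  # alkane > alcohol
#' @export
logp <- function(mol) {
  validate_molgraph(mol)
  tab <- .load_table("logp_contributions.csv")
  types <- .logp_types(mol)
  idx <- match(types, tab$type)
  if (anyNA(idx)) {
    stop("no logP parameter for atom environment: ",
         paste(unique(types[is.na(idx)]), collapse = ", "))
  }
  sum(tab$value[idx])
}

# simple cycle enumeration up to length `maxlen` on the heavy-atom graph;
# returns a list of vertex vectors, each cycle once
.simple_cycles <- function(adj, maxlen = 8) {
  n <- nrow(adj)
  cycles <- list()
  seen <- character(0)
  path <- integer(0)
  dfs <- function(start, u) {
    path <<- c(path, u)
    for (v in which(adj[u, ] > 0)) {
      if (v == start && length(path) >= 3) {
        key <- paste(sort(path), collapse = ",")
        if (!(key %in% seen)) {
          # keep only chordless? no: keep all simple cycles; dedup by set
          seen <<- c(seen, key)
          cycles[[length(cycles) + 1]] <<- path
        }
      } else if (!(v %in% path) && v > start && length(path) < maxlen) {
        dfs(start, v)
      }
    }
    path <<- path[-length(path)]
  }
  for (s in seq_len(n)) dfs(s, s)
  cycles
}

# ring counts for the volume correction: total independent rings (cyclomatic
# number) split into aromatic (six-membered all-carbon with alternating
# single/double bonds) and non-aromatic
.ring_counts <- function(mol) {
  n <- length(mol$elements)
  m <- sum(mol$adj[upper.tri(mol$adj)] > 0)
  total <- m - n + 1L  # connected graph
  if (total <= 0) return(c(aromatic = 0L, nonaromatic = 0L))
  aromatic <- 0L
  for (cyc in .simple_cycles(mol$adj, maxlen = 6)) {
    if (length(cyc) != 6) next
    if (!all(mol$elements[cyc] == "C")) next
    orders <- vapply(seq_along(cyc), function(k) {
      mol$adj[cyc[k], cyc[k %% 6 + 1]]
    }, integer(1))
    if (all(sort(unique(orders)) == c(1L, 2L)) && sum(orders == 2) == 3) {
      aromatic <- aromatic + 1L
    }
  }
  aromatic <- min(aromatic, total)
  c(aromatic = aromatic, nonaromatic = total - aromatic)
}

#' Additive van der Waals volume
#'
#' `V = sum(atomic contributions) - 5.92 * N_bonds - 14.7 * R_aromatic -
#' 3.8 * R_nonaromatic` (cubic Angstroms), the bond and ring corrections
#' accounting for sphere overlap; atoms include explicit hydrogens and
#' `N_bonds` counts every bond once regardless of order. Atomic volumes
#' follow Bondi radii (see `vdw_volumes.csv`); the placeholder B is assigned
#' the hydrogen volume, marking a bare attachment point, so that volumes are
#' comparable across members of one placeholder-bearing formula space.
#'
#' @param mol A `molgraph`.
#' @return Volume in cubic Angstroms.
#' @examples
#' vdw_volume(parse_smiles("C"))  # methane
#' @export
vdw_volume <- function(mol) {
  validate_molgraph(mol)
  tab <- .load_table("vdw_volumes.csv")
  vols <- stats::setNames(tab$volume, tab$element)
  h <- implicit_hydrogens(mol)
  counts <- table(mol$elements)
  if (anyNA(vols[names(counts)])) {
    stop("no volume parameter for element(s): ",
         paste(names(counts)[is.na(vols[names(counts)])], collapse = ", "))
  }
  atoms <- sum(vols[mol$elements]) + sum(h) * vols[["H"]]
  n_bonds <- sum(mol$adj[upper.tri(mol$adj)] > 0) + sum(h)
  rc <- .ring_counts(mol)
  unname(atoms - 5.92 * n_bonds - 14.7 * rc[["aromatic"]] -
           3.8 * rc[["nonaromatic"]])
}

# first embedding of a pattern into mol, as pattern->mol atom mapping
.find_embedding <- function(pattern, mol) {
  if (is.character(pattern)) pattern <- parse_pattern(pattern)
  pm <- length(pattern$elements)
  n <- length(mol$elements)
  h <- implicit_hydrogens(mol)
  padj <- matrix(-1L, pm, pm)
  if (nrow(pattern$bonds)) {
    for (r in seq_len(nrow(pattern$bonds))) {
      padj[pattern$bonds[r, 1], pattern$bonds[r, 2]] <- pattern$bonds[r, 3]
      padj[pattern$bonds[r, 2], pattern$bonds[r, 1]] <- pattern$bonds[r, 3]
    }
  }
  asg <- rep(NA_integer_, pm)
  used <- logical(n)
  rec <- function(a) {
    if (a > pm) return(TRUE)
    for (u in seq_len(n)) {
      if (used[u]) next
      if (pattern$elements[a] != "*" &&
          pattern$elements[a] != mol$elements[u]) next
      if (h[u] < pattern$min_h[a]) next
      ok <- TRUE
      for (b in seq_len(a - 1)) {
        po <- padj[a, b]
        if (po < 0) next
        go <- mol$adj[u, asg[b]]
        if (go == 0 || (po > 0 && go != po)) { ok <- FALSE; break }
      }
      if (!ok) next
      asg[a] <<- u
      used[u] <<- TRUE
      if (rec(a + 1)) return(TRUE)
      used[u] <<- FALSE
      asg[a] <<- NA_integer_
    }
    FALSE
  }
  if (rec(1L)) asg else NULL
}

# connected components of an induced subgraph, as molgraphs
.subgraph_components <- function(mol, atoms) {
  if (!length(atoms)) return(list())
  sub <- mol$adj[atoms, atoms, drop = FALSE]
  n <- length(atoms)
  comp <- rep(NA_integer_, n)
  nc <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    nc <- nc + 1L
    stack <- s
    comp[s] <- nc
    while (length(stack)) {
      u <- stack[length(stack)]
      stack <- stack[-length(stack)]
      nb <- which(sub[u, ] > 0 & is.na(comp))
      comp[nb] <- nc
      stack <- c(stack, nb)
    }
  }
  lapply(seq_len(nc), function(k) {
    idx <- which(comp == k)
    .molgraph_from_adj(mol$elements[atoms[idx]],
                       sub[idx, idx, drop = FALSE])
  })
}

#' Rule-based side-chain pKa estimate
#'
#' In the alpha-amino-acid context: locates the scaffold, takes the side
#' chain (all atoms outside the scaffold match), classifies its most
#' relevant ionizable group by substructure (priority: carboxyl, thiol,
#' phenol, imidazole, guanidino, amine), and returns that class's reference
#' pKa from the shipped `pka_classes.csv` table. Amide N-H is not counted as
#' an amine. Returns `NA` when no ionizable group is present (e.g. glycine,
#' or purely aliphatic hydroxyl side chains). For molecules without the
#' scaffold the whole molecule is classified.
#'
#' @param mol A `molgraph`.
#' @return Numeric pKa class value, or `NA` if non-ionizable.
#' @export
pka_estimate <- function(mol) {
  validate_molgraph(mol)
  tab <- .load_table("pka_classes.csv")
  val <- stats::setNames(tab$pka, tab$class)
  emb <- .find_embedding(amino_acid_scaffold(), mol)
  if (is.null(emb)) emb <- .find_embedding(amino_acid_scaffold(TRUE), mol)
  parts <- if (is.null(emb)) {
    list(mol)
  } else {
    .subgraph_components(mol, setdiff(seq_along(mol$elements), emb))
  }
  if (!length(parts)) return(NA_real_)
  classify <- function(m) {
    h <- implicit_hydrogens(m)
    if (match_pattern("C(=O)[OH1]", m)) return(val[["carboxyl"]])
    if (match_pattern("[SH1]", m)) return(val[["thiol"]])
    if (match_pattern("[OH1]C1=CC=CC=C1", m)) return(val[["phenol"]])
    if (length(m$elements) >= 5 && match_pattern("N1C=NC=C1", m)) {
      return(val[["imidazole"]])
    }
    if (match_pattern("N=C(N)N", m)) return(val[["guanidino"]])
    # amine: N with >= 1 H bonded only to saturated atoms; amide N (adjacent
    # carbonyl) and enamine/azole-type N (adjacent sp2 carbon) are not basic
    for (i in which(m$elements == "N" & h > 0)) {
      nb <- which(m$adj[i, ] > 0)
      conjugated <- vapply(nb, function(j) {
        any(m$adj[j, ] >= 2)
      }, logical(1))
      if (!any(conjugated)) return(val[["amine"]])
    }
    NA_real_
  }
  est <- vapply(parts, classify, numeric(1))
  if (all(is.na(est))) NA_real_ else min(est, na.rm = TRUE)
}

#' Wiener index
#'
#' Sum of topological (shortest-path) distances over all unordered pairs of
#' heavy atoms.
#'
#' @param mol A `molgraph`.
#' @return Integer.
#' @examples
#' wiener_index(parse_smiles("CCCC"))  # n-butane: 10
#' @export
wiener_index <- function(mol) {
  validate_molgraph(mol)
  n <- length(mol$elements)
  if (n == 1) return(0L)
  g <- igraph::graph_from_adjacency_matrix(mol$adj > 0, mode = "undirected")
  d <- igraph::distances(g)
  as.integer(sum(d[upper.tri(d)]))
}

#' Property table for a library
#'
#' One row per molecule (certificate order) with the three adaptive-analysis
#' axes plus the Wiener index. Descriptor failures are recorded per row (as
#' `NA` with a message column) rather than aborting the table.
#'
#' @param lib An `isolibrary`, or a named (certificate-keyed) list of
#'   `molgraph`s.
#' @param extra Optional data frame with a `certificate` column to merge in
#'   (e.g. externally computed heats of formation); row keys are preserved.
#' @return A data frame with columns `certificate`, `smiles`, `logp`,
#'   `vdw_volume`, `pka`, `wiener`, and any `extra` columns.
#' @export
property_table <- function(lib, extra = NULL) {
  mols <- if (inherits(lib, "isolibrary")) lib$molecules else lib
  if (!length(mols)) stop("library is empty")
  if (is.null(names(mols))) {
    names(mols) <- vapply(mols, canonical_form, character(1))
  }
  safe <- function(fn, mol) tryCatch(fn(mol), error = function(e) NA_real_)
  tab <- data.frame(
    certificate = names(mols),
    smiles = vapply(mols, write_smiles, character(1)),
    logp = vapply(mols, function(m) safe(logp, m), numeric(1)),
    vdw_volume = vapply(mols, function(m) safe(vdw_volume, m), numeric(1)),
    pka = vapply(mols, function(m) safe(pka_estimate, m), numeric(1)),
    wiener = vapply(mols, function(m) safe(wiener_index, m), numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  if (!is.null(extra)) {
    stopifnot("certificate" %in% names(extra))
    tab <- merge(tab, extra, by = "certificate", all.x = TRUE, sort = TRUE)
  }
  tab[order(tab$certificate), , drop = FALSE]
}
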