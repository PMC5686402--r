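# Shared helpers: small independent oracles (pure R, no reuse of the
# package's C++ search paths) and a seeded random-molecule generator.

# independent isomorphism test by exhaustive permutation search
iso_by_permutation <- function(a, b) {
  na <- length(a$elements)
  if (na != length(b$elements)) return(FALSE)
  if (!identical(sort(a$elements), sort(b$elements))) return(FALSE)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    }
    out
  }
  for (p in perms(seq_len(na))) {
    if (!identical(a$elements, b$elements[p])) next
    if (identical(a$adj, b$adj[p, p, drop = FALSE])) return(TRUE)
  }
  FALSE
}

# independent embedding counter: number of injective label/bond-consistent
# mappings of pattern atoms into mol atoms
count_embeddings_r <- function(pattern, mol) {
  if (is.character(pattern)) pattern <- parse_pattern(pattern)
  pm <- length(pattern$elements)
  n <- length(mol$elements)
  if (pm > n) return(0L)
  h <- implicit_hydrogens(mol)
  padj <- matrix(-1L, pm, pm)
  if (nrow(pattern$bonds)) {
    for (r in seq_len(nrow(pattern$bonds))) {
      padj[pattern$bonds[r, 1], pattern$bonds[r, 2]] <- pattern$bonds[r, 3]
      padj[pattern$bonds[r, 2], pattern$bonds[r, 1]] <- pattern$bonds[r, 3]
    }
  }
  count <- 0L
  asg <- rep(NA_integer_, pm)
  used <- logical(n)
  rec <- function(a) {
    if (a > pm) {
      count <<- count + 1L
      return(invisible(NULL))
    }
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
      rec(a + 1)
      used[u] <<- FALSE
      asg[a] <<- NA_integer_
    }
  }
  rec(1L)
  count
}

# all-pairs shortest-path BFS, independent of igraph
wiener_by_bfs <- function(mol) {
  n <- length(mol$elements)
  if (n == 1) return(0L)
  total <- 0L
  for (s in seq_len(n)) {
    dist <- rep(NA_integer_, n)
    dist[s] <- 0L
    queue <- s
    while (length(queue)) {
      u <- queue[1]
      queue <- queue[-1]
      for (v in which(mol$adj[u, ] > 0)) {
        if (is.na(dist[v])) {
          dist[v] <- dist[u] + 1L
          queue <- c(queue, v)
        }
      }
    }
    total <- total + sum(dist)
  }
  as.integer(total / 2)
}

# seeded random valid molgraph: random spanning tree plus random extra bond
# orders, respecting fixed valences
random_molgraph <- function(n_heavy, elements = c("C", "C", "C", "N", "O")) {
  repeat {
    sym <- sample(elements, n_heavy, replace = TRUE)
    val <- valence_model()[sym]
    adj <- matrix(0L, n_heavy, n_heavy)
    res <- as.integer(val)
    ok <- TRUE
    if (n_heavy > 1) {
      for (v in 2:n_heavy) {
        cand <- which(res[seq_len(v - 1)] > 0)
        if (!length(cand)) { ok <- FALSE; break }
        u <- if (length(cand) == 1) cand else sample(cand, 1)
        adj[u, v] <- adj[v, u] <- 1L
        res[u] <- res[u] - 1L
        res[v] <- res[v] - 1L
      }
    }
    if (!ok) next
    # a few random bond-order increments
    for (k in seq_len(stats::rpois(1, 2))) {
      ij <- which(upper.tri(adj), arr.ind = TRUE)
      ij <- ij[adj[ij] > 0 & adj[ij] < 3, , drop = FALSE]
      ij <- ij[res[ij[, 1]] > 0 & res[ij[, 2]] > 0, , drop = FALSE]
      if (!nrow(ij)) break
      r <- ij[sample.int(nrow(ij), 1), ]
      adj[r[1], r[2]] <- adj[r[1], r[2]] + 1L
      adj[r[2], r[1]] <- adj[r[1], r[2]]
      res[r[1]] <- res[r[1]] - 1L
      res[r[2]] <- res[r[2]] - 1L
    }
    return(structure(list(elements = sym, adj = adj), class = "molgraph"))
  }
}

random_permutation <- function(n) if (n == 1) 1L else sample.int(n)
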