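# Adaptive-alphabet analysis: compare a reference set of monomers (the 20
# coded amino acids) against random same-size sets drawn from a library,
# with respect to range and evenness of selected property axes.

#' Bundle a set of molecules with resolved properties
#'
#' @param certificates Character vector of member certificates (distinct).
#' @param properties Data frame with a `certificate` column and one column
#'   per property axis; must cover all members.
#' @return An object of class `alphabet_set`.
#' @export
alphabet_set <- function(certificates, properties) {
  stopifnot(!anyDuplicated(certificates),
            "certificate" %in% names(properties))
  idx <- match(certificates, properties$certificate)
  if (anyNA(idx)) stop("properties missing for ", sum(is.na(idx)), " member(s)")
  structure(list(certificates = certificates,
                 properties = properties[idx, , drop = FALSE]),
            class = "alphabet_set")
}

.axis_values <- function(s, property) {
  v <- s$properties[[property]]
  if (is.null(v)) stop("unknown property axis: ", property)
  v[!is.na(v)]
}

#' Range covered by a set on one property axis
#'
#' `max - min` over members with the property resolved; members with `NA`
#' (e.g. non-ionizable side chains on the pKa axis) are excluded.
#'
#' @param s An `alphabet_set`.
#' @param property Axis name (column of the property table).
#' @return Numeric range.
#' @export
range_coverage <- function(s, property) {
  v <- .axis_values(s, property)
  if (length(v) < 2) {
    stop("range needs at least 2 members with '", property, "' resolved")
  }
  max(v) - min(v)
}

#' Evenness of a set on one property axis
#'
#' How uniformly the resolved values are spread: `1 - CV(gaps) /
#' sqrt(m - 1)`, where the gaps are the differences between consecutive
#' sorted values, `CV` is their population coefficient of variation, `m` is
#' the number of gaps, and `sqrt(m - 1)` is the CV of the most uneven
#' arrangement (all spread concentrated in a single gap). Clipped to [0, 1]:
#' 1 for perfectly equally spaced values, 0 for the one-gap extreme.
#' Invariant under affine transformation of the axis. All-identical values
#' (zero range) are defined as perfectly even.
#'
#' @inheritParams range_coverage
#' @return Numeric in [0, 1].
#' @examples
#' # equally spaced: evenness 1
#' s <- alphabet_set(letters[1:4],
#'                   data.frame(certificate = letters[1:4], x = 0:3))
#' evenness(s, "x")
#' @export
evenness <- function(s, property) {
  v <- .axis_values(s, property)
  if (length(v) < 3) {
    stop("evenness needs at least 3 members with '", property, "' resolved")
  }
  gaps <- diff(sort(v))
  m <- length(gaps)
  mu <- mean(gaps)
  if (mu == 0) return(1)
  cv <- sqrt(mean((gaps - mu)^2)) / mu
  min(max(1 - cv / sqrt(m - 1), 0), 1)
}

#' Is one set more adaptive than another?
#'
#' `TRUE` iff on every axis the candidate's range and evenness are both at
#' least the reference's, with strict improvement in at least one of the
#' comparisons. Irreflexive by construction (a set never beats itself).
#'
#' @param candidate,reference `alphabet_set` objects.
#' @param axes Character vector of property axes (default the three
#'   adaptive-analysis axes: logP, van der Waals volume, pKa).
#' @return `TRUE` or `FALSE`.
#' @export
is_better <- function(candidate, reference,
                      axes = c("logp", "vdw_volume", "pka")) {
  strict <- FALSE
  for (ax in axes) {
    for (fn in c(range_coverage, evenness)) {
      cv <- fn(candidate, ax)
      rv <- fn(reference, ax)
      if (cv < rv) return(FALSE)
      if (cv > rv) strict <- TRUE
    }
  }
  strict
}

#' Monte-Carlo comparison of random sets against a reference alphabet
#'
#' Draws `n` uniform without-replacement sets of `size` molecules from the
#' library's property table and counts how many are more adaptive than the
#' reference ([is_better()] on all axes). Fully determined by `seed`.
#'
#' @param properties Property table (data frame with `certificate` and the
#'   axis columns), one row per library molecule.
#' @param reference An `alphabet_set` (e.g. the coded amino acids).
#' @param size Set size (default: reference size).
#' @param n Number of random draws.
#' @param seed Integer RNG seed.
#' @param axes Property axes compared (see [is_better()]).
#' @param keep_better Keep the certificates of up to this many better sets
#'   (default 100).
#' @return An object of class `adaptive_result`: `n_sampled`, `n_better`,
#'   `seed`, per-axis reference statistics, and the better sets found.
#' @export
sample_random_sets <- function(properties, reference, size = NULL, n,
                               seed, axes = c("logp", "vdw_volume", "pka"),
                               keep_better = 100) {
  if (is.null(size)) size <- length(reference$certificates)
  if (nrow(properties) < size) {
    stop("library (", nrow(properties), ") is smaller than the set size (",
         size, ")")
  }
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  ref_stats <- do.call(rbind, lapply(axes, function(ax) {
    data.frame(axis = ax,
               range = range_coverage(reference, ax),
               evenness = evenness(reference, ax),
               resolved = length(.axis_values(reference, ax)))
  }))
  n_better <- 0L
  better <- list()
  for (i in seq_len(n)) {
    draw <- sample.int(nrow(properties), size)
    cand <- alphabet_set(properties$certificate[draw], properties)
    if (is_better(cand, reference, axes)) {
      n_better <- n_better + 1L
      if (length(better) < keep_better) {
        better[[length(better) + 1]] <- sort(properties$certificate[draw])
      }
    }
  }
  structure(list(n_sampled = as.integer(n), n_better = n_better,
                 seed = as.integer(seed), set_size = as.integer(size),
                 axes = axes, reference_stats = ref_stats,
                 better_sets = better),
            class = "adaptive_result")
}

#' @export
print.adaptive_result <- function(x, ...) {
  cat("<adaptive result> ", x$n_better, " of ", x$n_sampled,
      " random sets of ", x$set_size, " beat the reference (seed ",
      x$seed, ")\n", sep = "")
  print(x$reference_stats, row.names = FALSE)
  invisible(x)
}
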