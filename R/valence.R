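# Fixed valence model. Lewis octet valences for neutral, closed-shell
# organic atoms; no charges, no radicals, no hypervalency. "B" is not boron
# but a univalent placeholder marking the attachment point of a recognition
# moiety (e.g. a nucleobase) in nucleoside-analogue enumeration.

#' Fixed element valences used throughout the package
#'
#' The valence model assigns every supported element a single fixed valence
#' (the sum of incident bond orders after implicit hydrogens are added):
#' C=4, N=3, O=2, S=2, H=1, and B=1, where `B` is the univalent placeholder
#' atom used to mark the nucleobase attachment point in nucleoside-analogue
#' formulae. Sulfur is divalent only, so that every oxygen position of a
#' generated molecule can be exchanged for sulfur without revisiting
#' valence bookkeeping. Boron itself (trivalent) is not supported.
#'
#' @return Named integer vector mapping element symbol to valence.
#' @examples
#' valence_model()
#' @export
valence_model <- function() {
  c(C = 4L, N = 3L, O = 2L, S = 2L, B = 1L, H = 1L)
}

# heavy elements, i.e. everything the generator places explicitly
.heavy_elements <- c("C", "N", "O", "S", "B")

.valence <- function(sym) {
  v <- valence_model()[sym]
  if (anyNA(v)) {
    stop("unsupported element(s): ",
         paste(unique(sym[is.na(v)]), collapse = ", "))
  }
  unname(v)
}

# canonical atom order used by the certificate and the generator:
# valence descending, then element symbol ascending
.atom_order <- function(sym) {
  order(-.valence(sym), sym)
}
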