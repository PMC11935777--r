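# Amino-acid alphabets, the 7-class conjoint partition, and hydropathy scales.

#' The 20 canonical amino-acid one-letter codes
#'
#' Alphabetical one-letter codes for the 20 canonical residues. Sequences in
#' this package may additionally contain `"X"` for unknown or noncanonical
#' residues; each encoder documents how `X` positions are treated.
#'
#' @return Character vector of length 20.
#' @export
#' @examples
#' amino_acids()
amino_acids <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

# Residue order used by the AAindex1 flat file ("I" line, row-major).
.aaindex_order <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                    "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Conjoint 7-class partition of the amino acids
#'
#' The classical grouping of the 20 residues into seven classes by dipole
#' moment and side-chain volume, used by the conjoint-triad encoder:
#' \{A,G,V\}, \{I,L,F,P\}, \{Y,M,T,S\}, \{H,N,Q,W\}, \{R,K\}, \{D,E\}, \{C\}.
#'
#' @return Named integer vector mapping each canonical residue to its class
#'   index in 1..7.
#' @export
#' @examples
#' conjoint_classes()[c("A", "C", "R")]
conjoint_classes <- function() {
  cls <- list(c("A", "G", "V"),
              c("I", "L", "F", "P"),
              c("Y", "M", "T", "S"),
              c("H", "N", "Q", "W"),
              c("R", "K"),
              c("D", "E"),
              "C")
  out <- integer(20)
  names(out) <- amino_acids()
  for (k in seq_along(cls)) out[cls[[k]]] <- k
  out
}

#' Hydropathy scales
#'
#' Per-residue hydropathy scales used by [hydropathy_features()]:
#' `kyte_doolittle()` is the Kyte-Doolittle hydrophobicity index (positive =
#' hydrophobic); `hopp_woods()` is the Hopp-Woods hydrophilicity index
#' (positive = hydrophilic, roughly anti-correlated with the former).
#'
#' @return Named numeric vector over the 20 canonical residues.
#' @export
#' @examples
#' kyte_doolittle()["I"]  # most hydrophobic residue, 4.5
kyte_doolittle <- function() {
  c(A =  1.8, R = -4.5, N = -3.5, D = -3.5, C =  2.5,
    Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I =  4.5,
    L =  3.8, K = -3.9, M =  1.9, F =  2.8, P = -1.6,
    S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V =  4.2)
}

#' @rdname kyte_doolittle
#' @export
hopp_woods <- function() {
  c(A = -0.5, R =  3.0, N =  0.2, D =  3.0, C = -1.0,
    Q =  0.2, E =  3.0, G =  0.0, H = -0.5, I = -1.8,
    L = -1.8, K =  3.0, M = -1.3, F = -2.5, P =  0.0,
    S =  0.3, T = -0.4, W = -3.4, Y = -2.3, V = -1.5)
}

# seq string -> integer positions in amino_acids() order; NA for 'X'
.seq_ints <- function(seq) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  match(chars, amino_acids())
}
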