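#' Monoisotopic mass constants
#'
#' Monoisotopic residue masses of the 20 canonical amino acids (Da), plus the
#' proton and water masses used throughout fragment and precursor mass
#' arithmetic. All masses in the package are monoisotopic.
#'
#' @format `AA_MONO` is a named numeric vector of length 20 (names are the
#'   one-letter residue codes, alphabetical). `PROTON_MASS` and `WATER_MASS`
#'   are scalars in Da.
#' @name masses
NULL

#' @rdname masses
#' @export
AA_MONO <- c(
  A =  71.03711379, C = 103.00918448, D = 115.02694302, E = 129.04259309,
  F = 147.06841391, G =  57.02146372, H = 137.05891186, I = 113.08406398,
  K = 128.09496302, L = 113.08406398, M = 131.04048461, N = 114.04292744,
  P =  97.05276385, Q = 128.05857751, R = 156.10111102, S =  87.03202841,
  T = 101.04767847, V =  99.06841391, W = 186.07931295, Y = 163.06332853
)

#' @rdname masses
#' @export
PROTON_MASS <- 1.007276466

#' @rdname masses
#' @export
WATER_MASS <- 18.0105646

# residue letters in fixed alphabetical order; index into this vector defines
# the C-terminal-residue feature of the RT encoder
AA_LETTERS <- names(AA_MONO)

#' Neutral monoisotopic mass of a (modified) peptide
#'
#' M = sum of residue masses + sum of per-position mass deltas + water.
#'
#' @param sequence Peptide string over the 20 canonical residues.
#' @param deltas Optional numeric vector of per-position added masses (Da),
#'   length `nchar(sequence)`; `NULL` means unmodified.
#' @return Neutral mass in Da.
#' @export
#' @examples
#' peptide_mass("PEPTIDE")
peptide_mass <- function(sequence, deltas = NULL) {
  aa <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  m <- AA_MONO[aa]
  if (anyNA(m)) {
    stop("non-canonical residue in peptide: ", sequence)
  }
  if (!is.null(deltas)) {
    stopifnot(length(deltas) == length(aa))
    m <- m + deltas
  }
  sum(m) + WATER_MASS
}
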