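# Physical constants and residue tables used throughout the package.
# Residue monoisotopic masses: standard IUPAC values to 5 decimals.

#' Mass constants for peptide HX-MS calculations
#'
#' Monoisotopic mass constants used in m/z and centroid arithmetic:
#' water (18.010565 Da), the proton (1.007276 Da), the C13-C12 mass
#' difference (1.00335 Da, the natural isotope peak spacing before division
#' by charge) and the deuterium-hydrogen mass increment (1.006277 Da, the
#' spacing induced by deuteron incorporation).
#'
#' @format Named numeric vector with elements `water`, `proton`,
#'   `c13_shift`, `d_shift`.
#' @export
hx_constants <- c(
  water    = 18.010565,
  proton   = 1.007276,
  c13_shift = 1.00335,
  d_shift  = 1.006277
)

# residue (i.e. dehydrated amino acid) monoisotopic masses
.AA_MONO <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)

# residue elemental compositions, columns C,H,N,O,S
.AA_FORMULA <- matrix(c(
  # C  H  N  O  S
  2, 3, 1, 1, 0,  # G
  3, 5, 1, 1, 0,  # A
  3, 5, 1, 2, 0,  # S
  5, 7, 1, 1, 0,  # P
  5, 9, 1, 1, 0,  # V
  4, 7, 1, 2, 0,  # T
  3, 5, 1, 1, 1,  # C
  6, 11, 1, 1, 0, # L
  6, 11, 1, 1, 0, # I
  4, 6, 2, 2, 0,  # N
  4, 5, 1, 3, 0,  # D
  5, 8, 2, 2, 0,  # Q
  6, 12, 2, 1, 0, # K
  5, 7, 1, 3, 0,  # E
  5, 9, 1, 1, 1,  # M
  6, 7, 3, 1, 0,  # H
  9, 9, 1, 1, 0,  # F
  6, 12, 4, 1, 0, # R
  9, 9, 1, 2, 0,  # Y
  11, 10, 2, 1, 0 # W
), ncol = 5, byrow = TRUE,
  dimnames = list(names(.AA_MONO), c("C", "H", "N", "O", "S")))

# Natural isotope abundances by extra-neutron count (index 1 = monoisotopic).
.ISO_ABUND <- list(
  C = c(0.9893, 0.0107),
  H = c(0.999885, 0.000115),
  N = c(0.99636, 0.00364),
  O = c(0.99757, 0.00038, 0.00205),
  S = c(0.9499, 0.0075, 0.0425, 0.0001)
)

.assert_sequence <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1L || !nzchar(sequence)) {
    stop("sequence must be a non-empty character scalar", call. = FALSE)
  }
  letters <- strsplit(sequence, "")[[1]]
  bad <- setdiff(letters, names(.AA_MONO))
  if (length(bad)) {
    stop(sprintf("unknown residue letter(s) in sequence '%s': %s",
                 sequence, paste(unique(bad), collapse = ", ")), call. = FALSE)
  }
  letters
}
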