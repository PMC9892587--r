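#' @keywords internal
"_PACKAGE"

# Monoisotopic residue masses (Da) for the 20 standard amino acids,
# free Cys (no fixed modification).
AA_MONO <- c(
  G = 57.021464, A = 71.037114, S = 87.032028, P = 97.052764,
  V = 99.068414, T = 101.047679, C = 103.009185, L = 113.084064,
  I = 113.084064, N = 114.042927, D = 115.026943, Q = 128.058578,
  K = 128.094963, E = 129.042593, M = 131.040485, H = 137.058912,
  F = 147.068414, R = 156.101111, Y = 163.063329, W = 186.079313
)

MASS_WATER  <- 18.010565
MASS_PROTON <- 1.007276
MASS_OX     <- 15.994915   # methionine oxidation (+O)

#' Theoretical monoisotopic [M+H]+ of a peptide
#'
#' Computes the singly protonated monoisotopic mass of a peptide from the
#' standard residue mass table, optionally carrying one or more methionine
#' oxidations (+15.994915 Da each).
#'
#' @param sequence Character vector of peptide sequences (uppercase one-letter
#'   codes over the 20 standard residues).
#' @param n_oxidations Integer vector (recycled) of oxidised methionines per
#'   peptide; must not exceed the number of M residues.
#' @return Numeric vector of [M+H]+ values in Da.
#' @examples
#' mh_mass("STMQELNSR")            # 1065.4993
#' mh_mass("STMQELNSR", 1)         # + 15.994915
#' @export
mh_mass <- function(sequence, n_oxidations = 0L) {
  stopifnot(is.character(sequence), length(sequence) >= 1L)
  n_oxidations <- rep_len(as.integer(n_oxidations), length(sequence))
  vapply(seq_along(sequence), function(i) {
    s <- sequence[i]
    if (is.na(s) || !nzchar(s)) {
      stop("empty peptide sequence", call. = FALSE)
    }
    aa <- strsplit(s, "", fixed = TRUE)[[1L]]
    bad <- which(!aa %in% names(AA_MONO))
    if (length(bad)) {
      stop(sprintf("invalid residue '%s' at position %d in '%s'",
                   aa[bad[1L]], bad[1L], s), call. = FALSE)
    }
    n_ox <- n_oxidations[i]
    if (n_ox < 0L || n_ox > sum(aa == "M")) {
      stop(sprintf("n_oxidations = %d exceeds methionine count in '%s'",
                   n_ox, s), call. = FALSE)
    }
    sum(AA_MONO[aa]) + MASS_WATER + MASS_PROTON + MASS_OX * n_ox
  }, numeric(1))
}
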