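#' The 20 standard amino acids
#'
#' One-letter codes of the twenty proteinogenic amino acids in fixed
#' alphabetical order. Every encoder column layout in this package follows
#' this order, so feature positions are stable across datasets.
#'
#' @format Character vector of length 20.
#' @export
AA_ALPHABET20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                   "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Background amino-acid frequencies
#'
#' Approximate residue frequencies of well-characterised protein databases
#' (Swiss-Prot-like background), used as the default base composition of the
#' synthetic sequence generator. Sums to 1 over [AA_ALPHABET20].
#'
#' @format Named numeric vector of length 20 on the simplex.
#' @export
AA_BACKGROUND <- c(
  A = 0.0826, C = 0.0137, D = 0.0546, E = 0.0672, F = 0.0386,
  G = 0.0708, H = 0.0228, I = 0.0593, K = 0.0581, L = 0.0965,
  M = 0.0241, N = 0.0406, P = 0.0474, Q = 0.0393, R = 0.0553,
  S = 0.0665, T = 0.0536, V = 0.0687, W = 0.0110, Y = 0.0292
)
AA_BACKGROUND <- AA_BACKGROUND / sum(AA_BACKGROUND)

# internal: all 400 ordered residue pairs, first letter major (AA, AC, ..., YY)
aa_pairs <- function(sep = "") {
  as.vector(t(outer(AA_ALPHABET20, AA_ALPHABET20, paste, sep = sep)))
}
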