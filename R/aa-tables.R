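# Residue alphabets and fixed lookup tables used throughout the package.
# The channel order of the one-hot encoding is the alphabetical one-letter
# code; it is part of the model contract (weights are only portable under
# this ordering).

#' Canonical amino-acid alphabet (channel order)
#'
#' The 20 canonical amino acids in alphabetical one-letter-code order. This
#' is the channel order of the one-hot encoding consumed by the model, fixed
#' so that saved weights are portable.
#'
#' @return Character vector of length 20.
#' @export
aa_alphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

# NNK codon multiplicities (N = A/C/G/T, K = G/T; 32 codons total).
# Each amino acid is encoded by the listed number of NNK codons; the amber
# stop TAG is the single stop reachable under NNK and is emitted as "*".
nnk_codon_counts <- function() {
  c(A = 2, C = 1, D = 1, E = 1, F = 1, G = 2, H = 1, I = 1, K = 1, L = 3,
    M = 1, N = 1, P = 2, Q = 1, R = 3, S = 3, T = 2, V = 2, W = 1, Y = 1,
    "*" = 1)
}

#' Kyte-Doolittle hydropathy scale
#'
#' Per-residue hydropathy values used by the hydrophobicity baseline
#' predictor. Positive values are hydrophobic.
#'
#' @return Named numeric vector over the 20 canonical amino acids.
#' @export
kyte_doolittle <- function() {
  c(A =  1.8, C =  2.5, D = -3.5, E = -3.5, F =  2.8,
    G = -0.4, H = -3.2, I =  4.5, K = -3.9, L =  3.8,
    M =  1.9, N = -3.5, P = -1.6, Q = -3.5, R = -4.5,
    S = -0.8, T = -0.7, V =  4.2, W = -0.9, Y = -1.3)
}

# Residue classes used by the default planted grammar. "h" is the
# hydrophobic class, "d" the aggregation-disrupting charged/proline class.
residue_classes <- function() {
  list(
    h = c("F", "I", "L", "M", "V", "W", "Y"),
    d = c("D", "E", "K", "R", "P")
  )
}

# Split peptide strings into a character matrix of residues (ragged lists).
split_residues <- function(x) strsplit(x, "", fixed = TRUE)

# Validate that sequences contain only canonical residues (optionally '*').
assert_residues <- function(x, allow_stop = FALSE, what = "sequence") {
  ok <- c(aa_alphabet(), if (allow_stop) "*")
  bad <- setdiff(unique(unlist(split_residues(x))), ok)
  if (length(bad) > 0) {
    abort(sprintf("invalid residue(s) in %s: %s", what,
                  paste(sQuote(bad), collapse = ", ")))
  }
  invisible(x)
}
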