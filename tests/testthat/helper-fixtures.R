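# Shared fixtures, built in code. Everything here is deterministic.

# Tiny untrained model: cheap forward passes with nontrivial weights.
tiny_model <- function(n_filters = 4, key_len = 3, dense_units = 5,
                       seed = 7) {
  canya_build(canya_config(n_filters = n_filters, key_len = key_len,
                           dense_units = dense_units, seed = seed))
}

# A canya_pwm built by hand from a kmer set with given activations.
manual_pwm <- function(kmers, activations = rep(1, length(kmers)),
                       filter_id = 0L) {
  aa <- aa_alphabet()
  pwm <- matrix(0, 3, 20, dimnames = list(NULL, aa))
  chars <- do.call(rbind, strsplit(kmers, ""))
  for (p in 1:3) {
    tab <- table(factor(chars[, p], levels = aa))
    pwm[p, ] <- as.numeric(tab) / length(kmers)
  }
  structure(list(filter_id = filter_id,
                 kmer_set = stats::setNames(activations, kmers),
                 pwm = pwm),
            class = "canya_pwm")
}

# Position-invariant additive surrogate from a named per-residue weight
# vector (defaults to zero for unnamed residues).
flat_surrogate <- function(w, interactions = NULL) {
  full <- stats::setNames(rep(0, 20), aa_alphabet())
  full[names(w)] <- w
  canya_surrogate(full, interactions = interactions)
}

# Fixed-length random peptides over the 20 canonical residues.
random_peptides <- function(n, len = 20, seed = 1) {
  withr::with_seed(seed, {
    apply(matrix(sample(aa_alphabet(), n * len, replace = TRUE), n, len),
          1, paste0, collapse = "")
  })
}

hydrophobic_set <- c("F", "I", "L", "M", "V", "W", "Y")
disruptor_set <- c("D", "E", "K", "R", "P")
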