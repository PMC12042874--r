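# Replicate training, the KL-divergence interpretability score, and the
# selection rule: among replicates whose mean test AUPR exceeds the median
# of those means, pick the one with the highest interpretability score.

# All 8000 3-mers in deterministic (lexicographic) order.
all_kmers <- function(k = 3) {
  aa <- aa_alphabet()
  grid <- expand.grid(rep(list(aa), k), stringsAsFactors = FALSE)[, k:1]
  sort(apply(grid, 1, paste0, collapse = ""))
}

# Input-gradient attribution with off-simplex correction: the gradient of
# the pre-activation score is mean-centered across the 20 channels at each
# residue position, and the attributed value is the corrected gradient at
# the observed residue.
attribution_positions <- function(model, sequences) {
  grads <- input_gradients(model, sequences)
  vapply(seq_along(sequences), function(i) {
    L <- nchar(sequences[i])
    if (L == 0) return(NA_integer_)
    g <- grads[i, 2 + seq_len(L), , drop = FALSE]
    g <- matrix(g, nrow = L)
    g <- g - rowMeans(g)
    idx <- match(strsplit(sequences[i], "")[[1]], aa_alphabet())
    val <- g[cbind(seq_len(L), idx)]
    which.max(abs(val))
  }, integer(1))
}

# 3-mer centered at `pos`, clipped at the sequence edges.
centered_kmer <- function(sequence, pos, k = 3) {
  L <- nchar(sequence)
  half <- (k - 1) %/% 2
  start <- min(max(pos - half, 1), max(L - k + 1, 1))
  substr(sequence, start, min(start + k - 1, L))
}

#' KL divergence between two kmer count vectors
#'
#' Both counts are aligned on the same kmer universe, smoothed with a
#' pseudocount per bin, normalised, and compared as KL(P || Q) in nats.
#' With `pseudocount = 0`, a point mass compared against a uniform
#' distribution over `k` bins gives exactly `log(k)`.
#'
#' @param p_counts,q_counts Nonnegative count vectors of equal length.
#' @param pseudocount Pseudocount added to every bin (default 0.5).
#' @return KL divergence in nats.
#' @export
kmer_kl <- function(p_counts, q_counts, pseudocount = 0.5) {
  if (length(p_counts) != length(q_counts)) {
    abort("count vectors must share the same kmer universe")
  }
  P <- (p_counts + pseudocount) / sum(p_counts + pseudocount)
  Q <- (q_counts + pseudocount) / sum(q_counts + pseudocount)
  keep <- P > 0
  sum(P[keep] * log(P[keep] / Q[keep]))
}

#' Interpretability score (KL divergence of attributed kmers)
#'
#' Builds the distribution P of 3-mers centered at each sequence's
#' top-attributed position (input-gradient attribution, channel-mean
#' corrected) and the distribution Q of all 3-mers occurring in the same
#' sequences, both over the 8000-kmer universe with a pseudocount of 0.5
#' per bin, and returns KL(P || Q) in nats. Concentrated, consistent
#' attributions give a high score; diffuse attributions give a score near
#' zero.
#'
#' @param model A trained `canya_model` (or any object with an
#'   `attribution` method-compatible gradient); alternatively pass
#'   precomputed positions via `positions`.
#' @param sequences Character vector (>= 100 sequences recommended;
#'   shorter-than-3 sequences are dropped).
#' @param positions Optional integer vector of attributed positions,
#'   bypassing the model attribution (used for closed-form checks).
#' @param pseudocount Pseudocount per kmer bin.
#' @return KL divergence in nats (>= 0).
#' @export
interpretability_score <- function(model, sequences, positions = NULL,
                                   pseudocount = 0.5) {
  keep <- nchar(sequences) >= 3
  sequences <- sequences[keep]
  if (length(sequences) == 0) abort("no sequences of length >= 3")
  if (is.null(positions)) {
    positions <- attribution_positions(model, sequences)
  } else {
    positions <- positions[keep]
  }
  uni <- all_kmers()
  p_kmers <- vapply(seq_along(sequences), function(i)
    centered_kmer(sequences[i], positions[i]), character(1))
  p_kmers <- p_kmers[nchar(p_kmers) == 3]
  q_kmers <- unlist(lapply(sequences, function(s) {
    L <- nchar(s)
    substring(s, seq_len(L - 2), seq_len(L - 2) + 2)
  }))
  kmer_kl(as.numeric(table(factor(p_kmers, levels = uni))),
          as.numeric(table(factor(q_kmers, levels = uni))),
          pseudocount = pseudocount)
}

#' Train replicate models
#'
#' Trains `n_replicates` models with seeds `base_seed + 1 .. base_seed + n`,
#' each evaluated on its own held-out stratified test split, and summarises
#' per-library test AUROC/AUPR plus the interpretability score.
#'
#' @param data Labelled tibble (`aa_seq`, `label`, optional `library_id`).
#' @param n_replicates Number of replicates.
#' @param base_seed Base seed.
#' @param config Model configuration template (the seed field is replaced
#'   per replicate).
#' @param test_fraction Held-out test fraction.
#' @param epochs Optional epoch override.
#' @param interp_n Number of test sequences used for the interpretability
#'   score (capped at the test-set size).
#' @return A list with `models` (list of `canya_model`) and `summaries`
#'   (tibble of class `canya_replicates`: `model_id`, `library_id`,
#'   `auroc`, `aupr`, `mean_aupr`, `interpretability`).
#' @export
train_replicates <- function(data, n_replicates, base_seed = 0,
                             config = canya_config(), test_fraction = 0.1,
                             epochs = NULL, interp_n = 2000) {
  if (n_replicates < 1) abort("n_replicates must be >= 1")
  models <- vector("list", n_replicates)
  rows <- list()
  lib <- if ("library_id" %in% names(data)) data$library_id else
    rep("library", nrow(data))
  for (r in seq_len(n_replicates)) {
    seed_r <- as.integer(base_seed + r)
    cfg <- config; cfg$seed <- seed_r
    test_idx <- stratified_split(data$label, test_fraction, seed_r + 7L, lib)
    train_dat <- data[-test_idx, , drop = FALSE]
    test_dat <- data[test_idx, , drop = FALSE]
    m <- canya_train(canya_build(cfg), train_dat, epochs = epochs)
    sc <- pre_activation(m, test_dat$aa_seq)
    per_lib <- tibble(library_id = lib[test_idx], score = sc,
                      label = test_dat$label) |>
      group_by(.data$library_id) |>
      summarise(auroc = auroc(.data$score, .data$label),
                aupr = aupr(.data$score, .data$label), .groups = "drop")
    n_interp <- min(interp_n, nrow(test_dat))
    interp_seqs <- withr_seed(seed_r + 13L,
      sample(test_dat$aa_seq[nchar(test_dat$aa_seq) >= 3], n_interp))
    interp <- interpretability_score(m, interp_seqs)
    per_lib$model_id <- sprintf("model%03d", r)
    per_lib$mean_aupr <- mean(per_lib$aupr)
    per_lib$interpretability <- interp
    models[[r]] <- m
    rows[[r]] <- per_lib
  }
  summaries <- bind_rows(rows)
  class(summaries) <- c("canya_replicates", class(summaries))
  list(models = models, summaries = summaries)
}

#' Select the replicate for interpretability analyses
#'
#' Among replicates whose mean AUPR across libraries is strictly greater
#' than the median of these means, returns the model with the highest
#' interpretability score (ties broken deterministically by model id). If
#' the strict filter removes every replicate (degenerate equal AUPRs), a
#' non-strict `>= median` filter is used and a message is emitted.
#'
#' @param summaries A `canya_replicates` tibble (one or more rows per
#'   model) or any tibble with `model_id`, `mean_aupr`,
#'   `interpretability`.
#' @return The selected `model_id`.
#' @export
select_model <- function(summaries) {
  per_model <- summaries |>
    group_by(.data$model_id) |>
    summarise(mean_aupr = .data$mean_aupr[1],
              interpretability = .data$interpretability[1],
              .groups = "drop")
  if (nrow(per_model) < 2) {
    if (nrow(per_model) == 1) return(per_model$model_id)
    abort("select_model() needs at least one replicate summary")
  }
  med <- stats::median(per_model$mean_aupr)
  pool <- filter(per_model, .data$mean_aupr > med)
  if (nrow(pool) == 0) {
    inform("all mean AUPRs equal the median; falling back to >= median")
    pool <- filter(per_model, .data$mean_aupr >= med)
  }
  pool <- arrange(pool, desc(.data$interpretability), .data$model_id)
  pool$model_id[1]
}
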