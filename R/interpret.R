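# Filter -> motif PWM extraction and BLOSUM-scored affinity-propagation
# clustering with sign-consistency pruning.

# Activation energies of every possible 3-mer for one filter, computed
# analytically from the filter weights (exp(sum of selected weights + bias)).
kmer_activations <- function(model, filter_id) {
  cfg <- model$config
  aa <- aa_alphabet()
  k <- cfg$filter_len
  kmers <- all_kmers(k)
  w <- matrix(model$weights$Wc[, filter_id], nrow = cfg$n_channels)
  # w[c, p] is the weight of channel c at kmer position p
  idx <- do.call(rbind, split_residues(kmers))
  energy <- numeric(length(kmers))
  for (p in seq_len(k)) {
    energy <- energy + w[match(idx[, p], aa), p]
  }
  stats::setNames(exp(energy + model$weights$bc[filter_id]), kmers)
}

#' Extract the motif PWM of a convolutional filter
#'
#' Enumerates the activation energies of all 8000 3-mers analytically and
#' keeps the smaller of (a) the 10 most-activating kmers and (b) the set of
#' kmers activating at at least 75% of the maximum (i.e. their
#' intersection). The PWM is the per-position residue frequency matrix of
#' the selected kmers. Ties are broken by descending activation, then
#' lexicographically.
#'
#' @param model A `canya_model`.
#' @param filter_id Filter index (1-based).
#' @param top_n Cap on the kmer set (default 10).
#' @param frac Activation fraction threshold (default 0.75).
#' @return A `canya_pwm` object: list with `filter_id`, `kmer_set` (named
#'   activation vector) and `pwm` (filter_len x 20 row-stochastic matrix).
#' @export
extract_pwm <- function(model, filter_id, top_n = 10, frac = 0.75) {
  act <- kmer_activations(model, filter_id)
  ord <- order(-act, names(act))  # descending activation, then lexicographic
  act <- act[ord]
  keep <- act >= frac * act[1]
  kmer_set <- act[keep]
  if (length(kmer_set) > top_n) kmer_set <- kmer_set[seq_len(top_n)]
  k <- model$config$filter_len
  aa <- aa_alphabet()
  pwm <- matrix(0, k, 20, dimnames = list(NULL, aa))
  chars <- do.call(rbind, split_residues(names(kmer_set)))
  for (p in seq_len(k)) {
    tab <- table(factor(chars[, p], levels = aa))
    pwm[p, ] <- as.numeric(tab) / length(kmer_set)
  }
  structure(list(filter_id = filter_id, kmer_set = kmer_set, pwm = pwm),
            class = "canya_pwm")
}

#' @export
print.canya_pwm <- function(x, ...) {
  cat(sprintf("<canya_pwm: filter %d, %d kmers, top %s>\n",
              x$filter_id, length(x$kmer_set), names(x$kmer_set)[1]))
  invisible(x)
}

#' Export PWMs in MEME minimal motif format
#'
#' @param pwms List of `canya_pwm` objects.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_meme <- function(pwms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "",
               paste("ALPHABET=", paste(aa_alphabet(), collapse = "")), ""),
             con)
  for (p in pwms) {
    writeLines(sprintf("MOTIF filter_%d", p$filter_id), con)
    writeLines(sprintf(
      "letter-probability matrix: alength= 20 w= %d nsites= %d",
      nrow(p$pwm), length(p$kmer_set)), con)
    for (r in seq_len(nrow(p$pwm))) {
      writeLines(paste(sprintf("%.6f", p$pwm[r, ]), collapse = " "), con)
    }
    writeLines("", con)
  }
  invisible(path)
}

# BLOSUM62 over the 20 canonical residues (channel order), from Biostrings.
blosum62_matrix <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62[aa_alphabet(), aa_alphabet()]
}

# Affinity propagation (responsibility/availability message passing) on a
# similarity matrix. Returns an exemplar index per point.
affinity_propagation <- function(S, damping = 0.9, max_iter = 1000,
                                 conv_iter = 100, preference = NULL,
                                 seed = 1) {
  n <- nrow(S)
  if (is.null(preference)) preference <- stats::median(S[row(S) != col(S)])
  diag(S) <- preference
  # tiny seeded jitter removes degenerate ties
  S <- S + withr_seed(seed,
    matrix(stats::runif(n * n), n, n)) * 1e-9 * (max(S) - min(S) + 1)
  R <- matrix(0, n, n); A <- matrix(0, n, n)
  ex_prev <- rep(-1L, n); stable <- 0L
  for (it in seq_len(max_iter)) {
    AS <- A + S
    max1 <- apply(AS, 1, max)
    which1 <- max.col(AS, ties.method = "first")
    AS2 <- AS
    AS2[cbind(seq_len(n), which1)] <- -Inf
    max2 <- apply(AS2, 1, max)
    Rnew <- S - max1
    Rnew[cbind(seq_len(n), which1)] <- S[cbind(seq_len(n), which1)] - max2
    R <- damping * R + (1 - damping) * Rnew
    Rp <- pmax(R, 0)
    diag(Rp) <- diag(R)
    colsum <- rep(colSums(Rp), each = n)
    Anew <- matrix(colsum, n, n) - Rp
    dA <- diag(Anew)
    Anew <- pmin(Anew, 0)
    diag(Anew) <- dA
    A <- damping * A + (1 - damping) * Anew
    ex <- which(diag(A + R) > 0)
    if (identical(ex, ex_prev)) stable <- stable + 1L else stable <- 0L
    ex_prev <- ex
    if (stable >= conv_iter && length(ex) > 0) break
  }
  if (length(ex) == 0) return(NULL)
  assign_to <- ex[max.col(S[, ex, drop = FALSE], ties.method = "first")]
  assign_to[ex] <- ex
  assign_to
}

#' Cluster motif PWMs by BLOSUM similarity
#'
#' Each PWM is projected through the BLOSUM62 substitution matrix (dot
#' product of the filter_len x 20 PWM with the 20 x 20 BLOSUM block) and
#' flattened; affinity propagation (negative squared Euclidean similarity,
#' median preference) groups the projections. Clusters are then pruned for
#' sign consistency: the cluster sign is that of its largest-|importance|
#' member, and members whose importance sign disagrees are removed.
#'
#' @param pwms List of `canya_pwm` objects.
#' @param filter_importances Numeric vector of filter-level GIA importance
#'   scores, aligned with `pwms`.
#' @param damping Affinity-propagation damping (raised once on
#'   non-convergence before failing).
#' @param seed Seed for the clustering jitter.
#' @return A tibble of class `canya_clusters`: `filter_id`, `cluster_id`,
#'   `importance`, `pruned` (logical), `cluster_sign`.
#' @export
blosum_cluster <- function(pwms, filter_importances, damping = 0.9,
                           seed = 1) {
  if (length(pwms) < 2) abort("need at least two PWMs to cluster")
  if (length(filter_importances) != length(pwms)) {
    abort("filter_importances must align with pwms")
  }
  B <- blosum62_matrix()
  feats <- t(vapply(pwms, function(p) as.numeric(p$pwm %*% B),
                    numeric(nrow(pwms[[1]]$pwm) * 20)))
  D2 <- as.matrix(stats::dist(feats))^2
  S <- -D2
  assign_to <- affinity_propagation(S, damping = damping, seed = seed)
  if (is.null(assign_to)) {
    assign_to <- affinity_propagation(S, damping = min(damping + 0.05, 0.99),
                                      seed = seed)
  }
  if (is.null(assign_to)) abort("affinity propagation failed to converge")
  cluster_id <- as.integer(factor(assign_to, levels = sort(unique(assign_to))))
  out <- tibble(
    filter_id = vapply(pwms, function(p) p$filter_id, numeric(1)),
    cluster_id = cluster_id,
    importance = filter_importances
  )
  out <- out |>
    group_by(.data$cluster_id) |>
    mutate(cluster_sign = sign(.data$importance[which.max(abs(.data$importance))]),
           pruned = sign(.data$importance) != .data$cluster_sign &
             .data$importance != 0) |>
    ungroup()
  class(out) <- c("canya_clusters", class(out))
  out
}
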