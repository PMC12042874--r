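# Global Importance Analysis: effect sizes of motifs estimated by embedding
# sampled kmers into confidently predicted background sequences and
# averaging the paired change in pre-activation model score. Five
# experiment types: single motif, cluster, multiplicity (1..4 copies),
# positional (positions 1..18) and pairwise interaction.

#' Additive surrogate model
#'
#' A strictly additive per-residue scorer used as an exact oracle for the
#' GIA machinery: the pre-activation score of a peptide is the sum of
#' `weights[residue, position]`, plus optional pairwise interaction terms
#' (`epsilon` times the product of occurrence counts of two literal kmers).
#' On a purely additive surrogate every GIA interaction importance is zero
#' by construction and multiplicity curves are exactly linear.
#'
#' @param weights 20 x 20 matrix (residues in [aa_alphabet()] order by
#'   position 1..20), or a named per-residue vector recycled across
#'   positions.
#' @param interactions Optional tibble with `kmer_a`, `kmer_b`, `epsilon`.
#' @return A `canya_surrogate` object.
#' @export
canya_surrogate <- function(weights, interactions = NULL) {
  if (is.null(dim(weights))) {
    weights <- matrix(weights[aa_alphabet()], nrow = 20, ncol = 20,
                      dimnames = list(aa_alphabet(), NULL))
  }
  stopifnot(nrow(weights) == 20)
  rownames(weights) <- aa_alphabet()
  structure(list(weights = weights, interactions = interactions),
            class = "canya_surrogate")
}

count_kmer <- function(s, kmer) {
  L <- nchar(s); k <- nchar(kmer)
  if (L < k) return(0L)
  sum(substring(s, seq_len(L - k + 1), seq_len(L - k + 1) + k - 1) == kmer)
}

#' @export
pre_activation.canya_surrogate <- function(model, sequences, ...) {
  vapply(sequences, function(s) {
    if (nchar(s) == 0) return(0)
    idx <- match(strsplit(s, "")[[1]], aa_alphabet())
    val <- sum(model$weights[cbind(idx, seq_along(idx))])
    if (!is.null(model$interactions) && nrow(model$interactions) > 0) {
      for (r in seq_len(nrow(model$interactions))) {
        it <- model$interactions[r, ]
        val <- val + it$epsilon * count_kmer(s, it$kmer_a) *
          count_kmer(s, it$kmer_b)
      }
    }
    val
  }, numeric(1), USE.NAMES = FALSE)
}

#' Select GIA background sequences
#'
#' Randomly samples (seeded) full-length (20 residues, stop-free)
#' sequences that the model predicts confidently: aggregators with
#' probability above `thresholds[1]` and non-aggregators below
#' `thresholds[2]`.
#'
#' @param model A `canya_model`.
#' @param dataset Labelled tibble (`aa_seq`, `label`).
#' @param n Number of backgrounds (capped at the qualifying count, with a
#'   warning).
#' @param thresholds Length-2 numeric: aggregator floor, non-aggregator
#'   ceiling, on the probability scale.
#' @param seed Sampling seed.
#' @return Character vector of background sequences.
#' @export
select_backgrounds <- function(model, dataset, n = 25000,
                               thresholds = c(0.3, 0.2), seed = 1) {
  ok_len <- !is.na(dataset$aa_seq) & nchar(dataset$aa_seq) == 20
  full <- dataset[ok_len, , drop = FALSE]
  if (nrow(full) == 0) abort("no full-length sequences in the dataset")
  prob <- stats::plogis(pre_activation(model, full$aa_seq))
  ok <- (full$label == 1 & prob > thresholds[1]) |
    (full$label == 0 & prob < thresholds[2])
  pool <- full$aa_seq[ok]
  if (length(pool) == 0) abort("no confidently predicted sequences qualify")
  if (length(pool) < n) {
    warn(sprintf("only %d qualifying backgrounds (requested %d)",
                 length(pool), n))
    n <- length(pool)
  }
  withr_seed(seed, sample(pool, n))
}

# Kmer sampling table of a feature. For a PWM: probabilities proportional
# to activation / max activation. For a cluster: filter-first (probability
# |importance| / max |importance|), kmer-second.
feature_kmer_sampler <- function(feature) {
  if (inherits(feature, "canya_pwm")) {
    p <- feature$kmer_set / max(feature$kmer_set)
    list(kind = "pwm", id = paste0("filter_", feature$filter_id),
         sample = function(n) {
           sample(names(p), n, replace = TRUE, prob = p / sum(p))
         })
  } else if (inherits(feature, "canya_cluster_feature")) {
    fp <- abs(feature$importances) / max(abs(feature$importances))
    fp <- fp / sum(fp)
    kmer_tabs <- lapply(feature$pwms, function(pw) {
      q <- pw$kmer_set / max(pw$kmer_set)
      q / sum(q)
    })
    list(kind = "cluster", id = paste0("cluster_", feature$cluster_id),
         sample = function(n) {
           f <- sample.int(length(kmer_tabs), n, replace = TRUE, prob = fp)
           vapply(f, function(j) {
             q <- kmer_tabs[[j]]
             sample(names(q), 1, prob = q)
           }, character(1))
         })
  } else {
    abort("feature must be a canya_pwm or canya_cluster_feature")
  }
}

#' Bundle a motif cluster for GIA
#'
#' @param pwms List of member `canya_pwm` objects.
#' @param importances Filter-level GIA importances aligned with `pwms`.
#' @param cluster_id Identifier.
#' @return A `canya_cluster_feature`.
#' @export
cluster_feature <- function(pwms, importances, cluster_id = 1) {
  stopifnot(length(pwms) == length(importances), length(pwms) > 0)
  structure(list(pwms = pwms, importances = importances,
                 cluster_id = cluster_id),
            class = "canya_cluster_feature")
}

embed_kmer <- function(sequences, kmers, positions, k = 3) {
  substr(sequences, positions, positions + k - 1) <- kmers
  sequences
}

gia_result <- function(experiment, feature_id, diffs, positions = NA,
                       extra = list()) {
  n <- length(diffs)
  m <- mean(diffs)
  se <- stats::sd(diffs) / sqrt(n)
  p <- if (stats::sd(diffs) > 0) stats::t.test(diffs)$p.value else
    as.numeric(m == 0)
  out <- tibble(
    experiment = experiment,
    feature_id = feature_id,
    position = if (length(positions) == 1) positions else NA,
    importance = m,
    ci_lo = m - stats::qnorm(0.975) * se,
    ci_hi = m + stats::qnorm(0.975) * se,
    n_backgrounds = n,
    p_value = p
  )
  for (nm in names(extra)) out[[nm]] <- extra[[nm]]
  class(out) <- c("canya_gia", class(out))
  out
}

#' Single-feature GIA importance
#'
#' For each background sequence a kmer is sampled from the feature
#' (activation-ratio probabilities; filter-first then kmer for clusters)
#' and embedded at a position drawn by the position policy; the importance
#' is the mean paired difference in pre-activation score between modified
#' and background sequences, with a normal-approximation CI.
#'
#' @param model Model (or surrogate) exposing [pre_activation()].
#' @param feature A `canya_pwm` or [cluster_feature()].
#' @param backgrounds Character vector of length-20 backgrounds.
#' @param position_policy `"uniform"` (uniform over starts 1..18) or a
#'   fixed integer start position in 1..18.
#' @param seed Sampling seed.
#' @param scale `"pre"` (pre-activation, default) or `"prob"`.
#' @return A one-row `canya_gia` tibble.
#' @export
gia_importance <- function(model, feature, backgrounds,
                           position_policy = "uniform", seed = 1,
                           scale = c("pre", "prob")) {
  scale <- match.arg(scale)
  if (length(backgrounds) == 0) abort("backgrounds must be nonempty")
  sampler <- feature_kmer_sampler(feature)
  n <- length(backgrounds)
  withr_seed(seed, {
    kmers <- sampler$sample(n)
    pos <- gia_positions(position_policy, n)
  })
  modified <- embed_kmer(backgrounds, kmers, pos)
  f <- function(x) {
    v <- pre_activation(model, x)
    if (scale == "prob") stats::plogis(v) else v
  }
  diffs <- f(modified) - f(backgrounds)
  gia_result("cluster_or_filter", sampler$id, diffs,
             positions = if (is.numeric(position_policy)) position_policy
             else NA)
}

gia_positions <- function(position_policy, n) {
  if (identical(position_policy, "uniform")) {
    sample.int(18, n, replace = TRUE)
  } else {
    if (!is.numeric(position_policy) || position_policy < 1 ||
        position_policy > 18) {
      abort("position_policy must be \"uniform\" or an integer in 1..18")
    }
    rep(as.integer(position_policy), n)
  }
}

# Sample an additional start position in 1..18 that does not overlap any
# position already used (kmers span 3 residues). Errors after `tries`.
sample_nonoverlapping <- function(used, tries = 100) {
  for (t in seq_len(tries)) {
    cand <- sample.int(18, 1)
    if (all(abs(cand - used) >= 3)) return(cand)
  }
  abort("could not place a non-overlapping kmer after bounded retries")
}

#' Multiplicity GIA experiment
#'
#' Embeds 1 to `max_copies` kmers into each background at non-overlapping
#' positions, keeping antecedent embeddings fixed as copies are added, and
#' reports the importance per multiplicity along with the R-squared of a
#' linear fit of importance on copy number.
#'
#' @inheritParams gia_importance
#' @param max_copies Maximum kmer copies (default 4).
#' @return A `canya_gia` tibble with one row per multiplicity (column
#'   `copies`); the linearity R-squared is attached as attribute
#'   `"r_squared"`.
#' @export
gia_multiplicity <- function(model, feature, backgrounds, max_copies = 4,
                             seed = 1, scale = c("pre", "prob")) {
  scale <- match.arg(scale)
  if (max_copies < 1 || max_copies > 6) abort("max_copies must be in 1..6")
  sampler <- feature_kmer_sampler(feature)
  n <- length(backgrounds)
  f <- function(x) {
    v <- pre_activation(model, x)
    if (scale == "prob") stats::plogis(v) else v
  }
  base_score <- f(backgrounds)
  current <- backgrounds
  used <- vector("list", n)
  rows <- list()
  withr_seed(seed, {
    for (copy in seq_len(max_copies)) {
      kmers <- sampler$sample(n)
      pos <- vapply(used, function(u)
        if (length(u) == 0) sample.int(18, 1) else sample_nonoverlapping(u),
        integer(1))
      used <- lapply(seq_len(n), function(i) c(used[[i]], pos[i]))
      current <- embed_kmer(current, kmers, pos)
      diffs <- f(current) - base_score
      rows[[copy]] <- gia_result("multiplicity", sampler$id, diffs,
                                 extra = list(copies = copy))
    }
  })
  out <- bind_rows(rows)
  # exact fits are expected on additive surrogates; silence the perfect-fit
  # note from summary.lm
  fit <- stats::lm(importance ~ copies, data = out)
  attr(out, "r_squared") <- suppressWarnings(summary(fit)$r.squared)
  class(out) <- c("canya_gia", class(out))
  out
}

#' Positional GIA experiment
#'
#' Runs one fixed-position GIA experiment for every start position 1..18
#' and reports, per position, the importance and its percent change
#' relative to the position-averaged (global) importance.
#'
#' @inheritParams gia_importance
#' @return A `canya_gia` tibble with 18 rows (`position`,
#'   `percent_change`); the global importance is attached as attribute
#'   `"global_importance"`. When the global importance is numerically
#'   zero, `percent_change` is `NA` and a warning is issued.
#' @export
gia_positional <- function(model, feature, backgrounds, seed = 1,
                           scale = c("pre", "prob")) {
  scale <- match.arg(scale)
  rows <- lapply(1:18, function(p) {
    r <- gia_importance(model, feature, backgrounds, position_policy = p,
                        seed = seed + p, scale = scale)
    r$experiment <- "positional"
    r
  })
  out <- bind_rows(rows)
  global <- mean(out$importance)
  if (abs(global) < 1e-10) {
    warn("global importance is numerically zero; percent change undefined")
    out$percent_change <- NA_real_
  } else {
    out$percent_change <- 100 * (out$importance - global) / abs(global)
  }
  attr(out, "global_importance") <- global
  class(out) <- c("canya_gia", class(out))
  out
}

#' Interaction GIA experiment
#'
#' For each background, kmers from two features are embedded at
#' non-overlapping positions; the interaction importance is
#' `[f(both) + f(background)] - [f(A only) + f(B only)]`, averaged over
#' backgrounds, with a paired two-sided t-test p-value. Self-interaction
#' (`feature_b` identical to `feature_a`) is allowed.
#'
#' @inheritParams gia_importance
#' @param feature_a,feature_b Features (PWM or cluster).
#' @param n_tests Total number of cluster-pair tests for the Bonferroni
#'   threshold reported alongside (`alpha / n_tests`); default 1.
#' @param alpha Family-wise error target (default 0.05).
#' @return A one-row `canya_gia` tibble with `p_value` and
#'   `bonferroni_alpha`.
#' @export
gia_interaction <- function(model, feature_a, feature_b, backgrounds,
                            seed = 1, scale = c("pre", "prob"),
                            n_tests = 1, alpha = 0.05) {
  scale <- match.arg(scale)
  sa <- feature_kmer_sampler(feature_a)
  sb <- feature_kmer_sampler(feature_b)
  n <- length(backgrounds)
  withr_seed(seed, {
    ka <- sa$sample(n)
    kb <- sb$sample(n)
    pa <- sample.int(18, n, replace = TRUE)
    pb <- vapply(pa, sample_nonoverlapping, integer(1))
  })
  f <- function(x) {
    v <- pre_activation(model, x)
    if (scale == "prob") stats::plogis(v) else v
  }
  seq_a <- embed_kmer(backgrounds, ka, pa)
  seq_b <- embed_kmer(backgrounds, kb, pb)
  seq_ab <- embed_kmer(seq_a, kb, pb)
  diffs <- (f(seq_ab) + f(backgrounds)) - (f(seq_a) + f(seq_b))
  out <- gia_result("interaction", paste(sa$id, sb$id, sep = ":"), diffs,
                    extra = list(bonferroni_alpha = alpha / n_tests))
  out
}
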