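# Secondary-structure enrichment: cluster activation profiles along
# annotated amyloid sequences, scored against per-residue structure labels
# (strand / coil / disorder) by rank-based AUROC with a bootstrap CI.

#' Per-residue cluster activation profile
#'
#' The activation of a cluster at each kmer position is the maximum
#' activation energy across its member filters; the kmer value is mapped to
#' the kmer's central residue, so the first and last residues of a
#' sequence carry no value and are excluded downstream.
#'
#' @param model A `canya_model`.
#' @param filter_ids Member filter indices of the cluster (nonempty).
#' @param sequence A protein sequence (length >= filter length).
#' @return Tibble with `position` (central residue, 1-based) and
#'   `activation`.
#' @export
cluster_activation_profile <- function(model, filter_ids, sequence) {
  if (length(filter_ids) == 0) abort("cluster has no member filters")
  act <- filter_activations(model, sequence)
  prof <- apply(act[, filter_ids, drop = FALSE], 1, max)
  offset <- model$config$filter_len %/% 2
  tibble(position = seq_along(prof) + offset, activation = unname(prof))
}

#' Secondary-structure enrichment AUROC of a cluster
#'
#' Concatenates cluster activation profiles and binary structure indicators
#' across all annotated sequences and computes the rank-based AUROC of the
#' given structure label against activation, with a percentile bootstrap CI
#' over residues.
#'
#' @param model A `canya_model`.
#' @param filter_ids Member filter indices of the cluster.
#' @param annotations Structure annotation tibble (`seq_id`, `position`,
#'   `residue`, `label` in `{strand, coil, disorder}`).
#' @param structure_label The structure class scored as positive.
#' @param n_boot Bootstrap resamples.
#' @param seed Bootstrap seed.
#' @return One-row tibble: `structure`, `auroc`, `ci_lo`, `ci_hi`,
#'   `n_pos`, `n_neg`.
#' @export
enrichment_auroc <- function(model, filter_ids, annotations,
                             structure_label = c("strand", "coil",
                                                 "disorder"),
                             n_boot = 500, seed = 1) {
  structure_label <- match.arg(structure_label)
  bad <- setdiff(unique(annotations$label),
                 c("strand", "coil", "disorder"))
  if (length(bad) > 0) {
    abort(sprintf("unknown structure label(s): %s", paste(bad, collapse = ", ")))
  }
  per_seq <- annotations |>
    group_by(.data$seq_id) |>
    group_split()
  vals <- list()
  for (s in per_seq) {
    s <- arrange(s, .data$position)
    if (!identical(s$position, seq_len(nrow(s))) &&
        !identical(as.integer(s$position), seq_len(nrow(s)))) {
      abort(sprintf("annotation positions of %s must cover 1..L exactly",
                    s$seq_id[1]))
    }
    seqc <- paste0(s$residue, collapse = "")
    if (nchar(seqc) < model$config$filter_len) next
    prof <- cluster_activation_profile(model, filter_ids, seqc)
    vals[[length(vals) + 1]] <- tibble(
      activation = prof$activation,
      positive = s$label[prof$position] == structure_label)
  }
  dat <- bind_rows(vals)
  if (sum(dat$positive) == 0 || sum(!dat$positive) == 0) {
    abort("both classes must be present after concatenation")
  }
  point <- auroc(dat$activation, dat$positive)
  boots <- withr_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(nrow(dat), replace = TRUE)
      if (length(unique(dat$positive[idx])) < 2) return(NA_real_)
      auroc(dat$activation[idx], dat$positive[idx])
    }, numeric(1))
  })
  ci <- stats::quantile(boots, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
  tibble(structure = structure_label, auroc = point,
         ci_lo = ci[1], ci_hi = ci[2],
         n_pos = sum(dat$positive), n_neg = sum(!dat$positive))
}
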