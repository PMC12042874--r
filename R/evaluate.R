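# Metrics with bootstrap confidence intervals, simple baselines, and
# construction of external-style evaluation tasks.

#' Rank-based AUROC
#'
#' Mann-Whitney formulation: the probability that a random positive
#' outranks a random negative, with ties counted half.
#'
#' @param scores Numeric scores.
#' @param labels Binary labels (coerced with `as.logical` on 0/1).
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(scores, labels) {
  y <- as.logical(labels)
  n1 <- sum(y); n0 <- sum(!y)
  if (n1 == 0 || n0 == 0) abort("both classes required for AUROC")
  r <- rank(scores)
  (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Trapezoidal area under the precision-recall curve
#'
#' Precision-recall points are computed at every distinct score threshold
#' (descending) and integrated with the trapezoidal rule over recall,
#' anchored at recall 0 with the precision of the highest-scoring
#' threshold. This interpolation convention is fixed so that monitored
#' values are unambiguous.
#'
#' @param scores Numeric scores.
#' @param labels Binary labels.
#' @return AUPR in `[0, 1]`.
#' @export
aupr <- function(scores, labels) {
  y <- as.logical(labels)
  n1 <- sum(y)
  if (n1 == 0 || sum(!y) == 0) abort("both classes required for AUPR")
  ord <- order(scores, decreasing = TRUE)
  y <- y[ord]; s <- scores[ord]
  tp <- cumsum(y)
  fp <- cumsum(!y)
  keep <- c(diff(s) != 0, TRUE)  # last duplicate of each threshold
  tp <- tp[keep]; fp <- fp[keep]
  prec <- tp / (tp + fp)
  rec <- tp / n1
  sum(diff(c(0, rec)) * (prec + c(prec[1], prec[-length(prec)])) / 2)
}

#' AUROC and AUPR with percentile-bootstrap confidence intervals
#'
#' @param scores Numeric scores.
#' @param labels Binary labels.
#' @param n_boot Bootstrap resamples (default 1000).
#' @param seed Seed for the bootstrap.
#' @param conf Confidence level.
#' @return One-row tibble: `auroc`, `auroc_lo`, `auroc_hi`, `aupr`,
#'   `aupr_lo`, `aupr_hi`, `n_pos`, `n_neg`.
#' @export
auroc_auprc <- function(scores, labels, n_boot = 1000, seed = 1,
                        conf = 0.95) {
  y <- as.logical(labels)
  point_roc <- auroc(scores, y)
  point_pr <- aupr(scores, y)
  qs <- c((1 - conf) / 2, 1 - (1 - conf) / 2)
  n <- length(scores)
  boot <- withr_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(n, replace = TRUE)
      if (length(unique(y[idx])) < 2) return(c(NA_real_, NA_real_))
      c(auroc(scores[idx], y[idx]), aupr(scores[idx], y[idx]))
    }, numeric(2))
  })
  ci_roc <- stats::quantile(boot[1, ], qs, na.rm = TRUE, names = FALSE)
  ci_pr <- stats::quantile(boot[2, ], qs, na.rm = TRUE, names = FALSE)
  tibble(auroc = point_roc, auroc_lo = ci_roc[1], auroc_hi = ci_roc[2],
         aupr = point_pr, aupr_lo = ci_pr[1], aupr_hi = ci_pr[2],
         n_pos = sum(y), n_neg = sum(!y))
}

#' Hydrophobicity baseline predictor
#'
#' Sum over residues of a hydropathy scale (Kyte-Doolittle by default).
#'
#' @param sequences Character vector of peptides.
#' @param scale Named numeric vector over the 20 canonical residues.
#' @return Numeric scores.
#' @export
hydrophobicity_baseline <- function(sequences, scale = kyte_doolittle()) {
  if (length(scale) == 0) abort("empty hydrophobicity scale")
  res <- split_residues(sequences)
  vapply(res, function(s) {
    if (length(s) == 0) return(0)
    v <- scale[s]
    if (any(is.na(v))) {
      abort(sprintf("residue(s) missing from the scale: %s",
                    paste(unique(s[is.na(v)]), collapse = ", ")))
    }
    sum(v)
  }, numeric(1))
}

# 20-dimensional residue-count feature matrix.
composition_features <- function(sequences) {
  res <- split_residues(sequences)
  t(vapply(res, function(s)
    as.numeric(table(factor(s, levels = aa_alphabet()))),
    numeric(20)))
}

#' Amino-acid composition baseline
#'
#' Logistic regression on 20-dimensional residue-count features. Degenerate
#' fits (non-converged or aliased coefficients) fall back to a ridge-
#' regularised fit, with a message.
#'
#' @param train Tibble with `aa_seq` and `label`.
#' @param test Tibble with `aa_seq` (defaults to the training set).
#' @return Numeric vector of test-set probabilities.
#' @export
composition_baseline <- function(train, test = train) {
  Xtr <- composition_features(train$aa_seq)
  Xte <- composition_features(test$aa_seq)
  y <- as.numeric(train$label)
  fit <- suppressWarnings(stats::glm.fit(cbind(1, Xtr), y,
                                         family = stats::binomial()))
  if (any(is.na(fit$coefficients)) || !fit$converged) {
    inform("composition baseline: degenerate fit, using ridge regularisation")
    rfit <- glmnet::glmnet(Xtr, y, family = "binomial", alpha = 0,
                           lambda = 1e-3)
    return(as.numeric(predict(rfit, Xte, type = "response")))
  }
  eta <- drop(cbind(1, Xte) %*% fit$coefficients)
  stats::plogis(eta)
}

#' Build a context-free amyloid-region task
#'
#' For each annotated protein, the amyloidogenic region sequences are the
#' positives; the region-excised remainder is concatenated and broken into
#' non-overlapping chunks of the corresponding region length, forming the
#' negative pool, which is downsampled to exactly match the positive count.
#'
#' @param proteins Tibble with columns `protein_id`, `sequence`, and
#'   `regions` (a list-column of tibbles with `start`, `end`, 1-based
#'   inclusive spans), or long format with columns `protein_id`, `sequence`,
#'   `start`, `end`.
#' @param seed Seed for negative downsampling.
#' @return Tibble with `aa_seq`, `label`, `protein_id`; positives and
#'   negatives are exactly balanced.
#' @export
build_context_free_task <- function(proteins, seed = 1) {
  if (!"regions" %in% names(proteins)) {
    proteins <- proteins |>
      tidyr::nest(regions = c("start", "end"))
  }
  pos <- list(); neg <- list()
  for (i in seq_len(nrow(proteins))) {
    seqc <- proteins$sequence[i]
    pid <- proteins$protein_id[i]
    spans <- proteins$regions[[i]]
    L <- nchar(seqc)
    if (nrow(spans) == 0) abort(sprintf("protein %s has no region span", pid))
    if (any(spans$start < 1 | spans$end > L | spans$start > spans$end)) {
      abort(sprintf("region span outside sequence bounds for %s", pid))
    }
    keep <- rep(TRUE, L)
    for (r in seq_len(nrow(spans))) {
      keep[spans$start[r]:spans$end[r]] <- FALSE
      pos[[length(pos) + 1]] <- tibble(
        aa_seq = substr(seqc, spans$start[r], spans$end[r]),
        label = 1L, protein_id = pid,
        target_len = spans$end[r] - spans$start[r] + 1L)
    }
    remainder <- paste0(strsplit(seqc, "")[[1]][keep], collapse = "")
    if (nchar(remainder) == 0) {
      warn(sprintf("region covers all of %s: no negatives from this protein",
                   pid))
      next
    }
    for (r in seq_len(nrow(spans))) {
      len <- spans$end[r] - spans$start[r] + 1L
      n_chunks <- nchar(remainder) %/% len
      if (n_chunks == 0) next
      starts <- (seq_len(n_chunks) - 1L) * len + 1L
      neg[[length(neg) + 1]] <- tibble(
        aa_seq = substring(remainder, starts, starts + len - 1L),
        label = 0L, protein_id = pid, target_len = len)
    }
  }
  pos <- bind_rows(pos); neg <- bind_rows(neg)
  if (nrow(neg) < nrow(pos)) {
    warn("fewer negatives than positives; downsampling positives instead")
    pos <- withr_seed(seed, pos[sample.int(nrow(pos), nrow(neg)), ])
  } else {
    neg <- withr_seed(seed, neg[sample.int(nrow(neg), nrow(pos)), ])
  }
  bind_rows(pos, neg) |> select("aa_seq", "label", "protein_id")
}

#' Filter labelled records by length and whitespace
#'
#' Retains records whose sequence has at least `min_len` residues and
#' contains no whitespace; the amyloid classification field becomes a 0/1
#' label.
#'
#' @param records Tibble with `aa_seq` and `classification`.
#' @param min_len Minimum length (default 10).
#' @param amyloid_value Classification value treated as positive.
#' @return Tibble with `aa_seq`, `label`.
#' @export
build_length_filtered_task <- function(records, min_len = 10,
                                       amyloid_value = "amyloid") {
  if (nrow(records) == 0) {
    return(tibble(aa_seq = character(0), label = integer(0)))
  }
  records |>
    filter(nchar(.data$aa_seq) >= min_len,
           !stringr::str_detect(.data$aa_seq, "\\s")) |>
    mutate(label = as.integer(.data$classification == amyloid_value)) |>
    select("aa_seq", "label")
}
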