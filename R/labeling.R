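# Turning processed aggregation scores and errors into aggregator /
# non-aggregator classes: a minimum input-read filter, mode-centering of the
# score distribution, then a one-sided Z test with Benjamini-Hochberg FDR
# control. Each library is processed separately.

#' Filter records by minimum input reads
#'
#' Keeps records with `input_reads >= threshold` (records with "fewer than
#' `threshold` reads" are removed).
#'
#' @param records Scored-peptide tibble with an `input_reads` column.
#' @param threshold Minimum read count (default 100).
#' @return Filtered tibble.
#' @export
filter_min_reads <- function(records, threshold = 100) {
  if (threshold < 0) abort("threshold must be >= 0")
  filter(records, .data$input_reads >= threshold)
}

#' Center scores on the mode of the score distribution
#'
#' Subtracts the mode of the score distribution, estimated as the argmax of
#' a Gaussian kernel density (Silverman's bandwidth) on a fine grid. The
#' score distribution is dominated by non-aggregating sequences, so the
#' global mode coincides with the non-aggregator mode.
#'
#' @param records Tibble with a `score` column (NAs allowed).
#' @param n_grid Density grid size.
#' @return The input tibble with `score` centered; the shift applied is
#'   attached as attribute `"shift"`.
#' @export
center_scores <- function(records, n_grid = 4096) {
  sc <- records$score[!is.na(records$score)]
  if (length(sc) < 50) abort("mode estimation needs at least 50 scored records")
  if (stats::sd(sc) == 0) {
    shift <- sc[1]
  } else {
    d <- stats::density(sc, bw = "nrd0", n = n_grid)
    shift <- d$x[which.max(d$y)]
  }
  records$score <- records$score - shift
  attr(records, "shift") <- shift
  records
}

#' Classify centered records into aggregators and non-aggregators
#'
#' Each centered score is transformed to `z = score / error`; the one-sided
#' upper-tail normal p-value is Benjamini-Hochberg adjusted across all
#' tested records, and records with adjusted p <= `alpha` are labelled
#' aggregators. Records with missing scores (sequences that produced no
#' reads after selection) are labelled non-aggregators.
#'
#' @param records Tibble with columns `score`, `error` (and optionally
#'   `library_id`; the FDR adjustment is applied within each library).
#' @param alpha FDR level (default 0.05).
#' @return The tibble with added columns `z`, `p_value`, `p_adj`, `label`
#'   (1 = aggregator) and class `canya_labeled`.
#' @export
classify_peptides <- function(records, alpha = 0.05) {
  tested <- !is.na(records$score)
  if (any(records$error[tested] <= 0 | is.na(records$error[tested]))) {
    abort("error must be > 0 for all scored records")
  }
  lib <- if ("library_id" %in% names(records)) records$library_id else
    rep("library", nrow(records))
  z <- p <- padj <- rep(NA_real_, nrow(records))
  z[tested] <- records$score[tested] / records$error[tested]
  p[tested] <- pnorm(z[tested], lower.tail = FALSE)
  for (l in unique(lib)) {
    sel <- tested & lib == l
    padj[sel] <- p.adjust(p[sel], method = "BH")
  }
  records$z <- z
  records$p_value <- p
  records$p_adj <- padj
  records$label <- as.integer(!is.na(padj) & padj <= alpha)
  attr(records, "alpha") <- alpha
  class(records) <- c("canya_labeled", class(records))
  records
}

#' Run the full labelling pipeline on a scored library
#'
#' Applies, in order: the minimum-read filter, stop truncation with
#' duplicate resolution, mode-centering, and Z-test/FDR classification.
#' Truncation happens before centering so that scores entering the test are
#' the per-peptide summaries actually used for training.
#'
#' @param records Scored tibble (`aa_seq` or `aa_raw`, `score`, `error`,
#'   `input_reads`, optionally `library_id`).
#' @param min_reads Minimum input reads.
#' @param alpha FDR level.
#' @param keep_empty Keep length-0 truncations (default TRUE).
#' @return A `canya_labeled` tibble plus a `report` attribute (counts per
#'   class, shift applied, alpha).
#' @export
label_library <- function(records, min_reads = 100, alpha = 0.05,
                          keep_empty = TRUE) {
  if (!"aa_seq" %in% names(records)) {
    records$aa_seq <- truncate_at_stop(records$aa_raw)
  }
  out <- filter_min_reads(records, min_reads)
  out <- center_scores(out)
  shift <- attr(out, "shift")
  out <- classify_peptides(out, alpha = alpha)
  # resolve duplicates created by truncation: mean score, modal label,
  # ties discarded
  lib <- if ("library_id" %in% names(out)) out$library_id else "library"
  dedup <- out |>
    mutate(.lib = lib) |>
    group_by(.data$.lib, .data$aa_seq) |>
    summarise(score = mean(.data$score),
              error = mean(.data$error),
              n_pos = sum(.data$label == 1L),
              n_neg = sum(.data$label == 0L),
              n_obs = n(), .groups = "drop") |>
    filter(.data$n_pos != .data$n_neg | .data$n_obs == 1L) |>
    mutate(label = as.integer(.data$n_pos > .data$n_neg),
           library_id = .data$.lib) |>
    select("library_id", "aa_seq", "score", "error", "label", "n_obs")
  if (!keep_empty) dedup <- filter(dedup, nchar(.data$aa_seq) > 0)
  report <- list(
    n_input = nrow(records),
    n_after_read_filter = nrow(out),
    n_final = nrow(dedup),
    n_aggregator = sum(dedup$label == 1L),
    n_non_aggregator = sum(dedup$label == 0L),
    shift = shift,
    alpha = alpha
  )
  attr(dedup, "report") <- report
  class(dedup) <- c("canya_labeled", class(dedup))
  dedup
}
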