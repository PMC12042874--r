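# Sequence hygiene and the exact input encoding the model consumes.
#
# Layout contract (24 rows x 20 channels): two all-zero pad rows, the one-hot
# residue block, two all-zero pad rows, then rows of -1 masking out the
# remainder up to 24. Channel order is alphabetical (see aa_alphabet()).

#' Truncate sequences at the first stop symbol
#'
#' Returns the prefix preceding the first `*`; sequences without a stop are
#' returned unchanged. Characters other than canonical residues and `*`
#' raise a parse error.
#'
#' @param raw Character vector of raw peptide sequences.
#' @return Character vector of truncated sequences (possibly `""`).
#' @export
truncate_at_stop <- function(raw) {
  if (length(raw) == 0) return(character(0))
  if (any(!nzchar(raw) & !is.na(raw))) {
    # empty input strings are not valid raw reads
    abort("raw sequences must be nonempty")
  }
  assert_residues(raw, allow_stop = TRUE, what = "raw sequence")
  sub("\\*.*$", "", raw)
}

#' Deduplicate truncated sequences
#'
#' Stop-codon truncation maps distinct raw reads onto the same peptide.
#' Duplicate groups are summarised by the mean score and modal label; groups
#' whose labels tie exactly between the two classes are discarded entirely.
#'
#' @param records Tibble with columns `aa_seq`, `score`, `label` (binary);
#'   any other columns are dropped.
#' @return Deduplicated tibble with columns `aa_seq`, `score`, `label`,
#'   `n_obs`.
#' @export
dedup_truncated <- function(records) {
  stopifnot(all(c("aa_seq", "score", "label") %in% names(records)))
  lab <- as.integer(records$label)
  if (!all(lab %in% c(0L, 1L) | is.na(lab))) abort("labels must be binary")
  records |>
    mutate(label = as.integer(.data$label)) |>
    group_by(.data$aa_seq) |>
    summarise(score = mean(.data$score),
              n_pos = sum(.data$label == 1L),
              n_neg = sum(.data$label == 0L),
              n_obs = n(), .groups = "drop") |>
    filter(.data$n_pos != .data$n_neg) |>
    mutate(label = as.integer(.data$n_pos > .data$n_neg)) |>
    select("aa_seq", "score", "label", "n_obs")
}

#' Encode a peptide as the 24 x 20 model input
#'
#' @param p A single peptide string (<= 20 residues, no `*`). Empty strings
#'   are allowed and produce a pad-pad-mask matrix.
#' @return A 24 x 20 numeric matrix.
#' @export
encode_peptide <- function(p) {
  if (length(p) != 1) abort("encode_peptide() takes a single sequence")
  L <- nchar(p)
  if (L > 20) abort("sequences longer than 20 residues go through predict_long()")
  if (L > 0) assert_residues(p)
  m <- matrix(0, nrow = 24, ncol = 20, dimnames = list(NULL, aa_alphabet()))
  if (L > 0) {
    idx <- match(strsplit(p, "")[[1]], aa_alphabet())
    m[cbind(2 + seq_len(L), idx)] <- 1
  }
  if (L < 20) m[(L + 5):24, ] <- -1
  m
}

#' Encode a batch of peptides
#'
#' @param peptides Character vector of peptides (<= 20 residues each).
#' @return Numeric array of dimension `c(length(peptides), 24, 20)`.
#' @export
encode_batch <- function(peptides) {
  out <- array(0, dim = c(length(peptides), 24, 20))
  for (i in seq_along(peptides)) out[i, , ] <- encode_peptide(peptides[i])
  out
}

#' Decode the one-hot block of an encoded peptide
#'
#' Inverse of [encode_peptide()]: recovers the residue string from the
#' one-hot rows (round-trip property).
#'
#' @param m A 24 x 20 encoded matrix.
#' @return The peptide string.
#' @export
decode_peptide <- function(m) {
  stopifnot(identical(dim(m), c(24L, 20L)) || identical(dim(m), c(24, 20)))
  res <- character(0)
  for (r in 3:22) {
    row <- m[r, ]
    if (any(row == 1)) res <- c(res, aa_alphabet()[which(row == 1)])
  }
  paste0(res, collapse = "")
}

#' Read and write FASTA files of protein sequences
#'
#' Thin wrappers around Biostrings; reading upper-cases sequences and
#' returns a tibble, writing takes a tibble with `seq_id` and `aa_seq`.
#'
#' @param path FASTA file path.
#' @return `read_fasta()`: tibble with columns `seq_id`, `aa_seq`.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  tibble(seq_id = names(x), aa_seq = unname(toupper(as.character(x))))
}

#' @rdname read_fasta
#' @param x Tibble with columns `seq_id` and `aa_seq`.
#' @export
write_fasta <- function(x, path) {
  set <- Biostrings::BStringSet(stats::setNames(x$aa_seq, x$seq_id))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}
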