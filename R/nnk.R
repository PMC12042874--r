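# Synthetic NNK peptide libraries with a planted, known aggregation grammar.
#
# The generator emulates the data-generating process the analysis stack
# assumes: residues drawn at NNK codon frequencies (including the amber stop
# '*'), a latent additive score produced by class-pattern motifs with
# position-dependent weights (plus optional pairwise interaction terms),
# Gaussian measurement error, and negative-binomial input read counts.

#' Specify a planted aggregation grammar
#'
#' A grammar is a set of 3-mer residue-class motif effects plus a
#' position-weight profile; it defines the latent additive aggregation score
#' of the synthetic library. Patterns are length-3 strings over class codes
#' defined in `classes` (default: `h` hydrophobic, `d` charged/proline).
#' A window matches a pattern when every residue belongs to the class at its
#' position.
#'
#' @param motif_effects Named numeric vector: names are length-3 class
#'   patterns (e.g. `"hhh"`), values are signed effect sizes.
#' @param position_weight Numeric vector of 18 positive multipliers, one per
#'   possible 3-mer start position of a length-20 peptide.
#' @param interaction_terms Optional tibble with columns `pattern_a`,
#'   `pattern_b`, `epsilon`: an extra `epsilon` is added whenever both
#'   patterns match somewhere in the same peptide.
#' @param noise_sd Standard deviation of the Gaussian measurement error.
#' @param read_mean,read_size Mean and dispersion (`size`) of the
#'   negative-binomial input read-count law.
#' @param classes Named list mapping class codes to residue sets.
#'
#' @return An object of class `canya_grammar`.
#' @export
grammar_spec <- function(motif_effects,
                         position_weight = rep(1, 18),
                         interaction_terms = NULL,
                         noise_sd = 0.5,
                         read_mean = 500,
                         read_size = 5,
                         classes = residue_classes()) {
  if (length(position_weight) != 18 || any(!is.finite(position_weight)) ||
      any(position_weight <= 0)) {
    abort("position_weight must hold exactly 18 finite, positive entries")
  }
  if (length(motif_effects) > 0) {
    if (is.null(names(motif_effects)) || any(!nzchar(names(motif_effects)))) {
      abort("motif_effects must be a named vector of class patterns")
    }
    if (any(nchar(names(motif_effects)) != 3L)) {
      abort("motif patterns must be length-3 class strings")
    }
    if (any(!is.finite(motif_effects))) abort("motif effects must be finite")
    used <- unique(unlist(strsplit(names(motif_effects), "")))
    if (!is.null(interaction_terms)) {
      used <- unique(c(used, unlist(strsplit(
        c(interaction_terms$pattern_a, interaction_terms$pattern_b), ""))))
    }
    missing_cls <- setdiff(used, names(classes))
    if (length(missing_cls) > 0) {
      abort(sprintf("pattern class code(s) not defined: %s",
                    paste(missing_cls, collapse = ", ")))
    }
  }
  if (!is.finite(noise_sd) || noise_sd < 0) abort("noise_sd must be >= 0")
  structure(
    list(motif_effects = motif_effects,
         position_weight = position_weight,
         interaction_terms = interaction_terms,
         noise_sd = noise_sd,
         read_mean = read_mean,
         read_size = read_size,
         classes = classes),
    class = "canya_grammar")
}

#' Default planted grammar
#'
#' Hydrophobic 3-mers promote aggregation (+1), charged/proline 3-mers
#' disrupt it (-1), and effects decay linearly from the N terminus (weight
#' 1.8 at start position 1 down to 0.2 at position 18). Measurement noise SD
#' is 0.5 and input reads follow NB(mean 500, size 5), so the >= 100-read
#' filter removes a known small tail.
#'
#' @return A `canya_grammar`.
#' @export
default_grammar <- function() {
  grammar_spec(
    motif_effects = c(hhh = 1, ddd = -1),
    position_weight = seq(1.8, 0.2, length.out = 18)
  )
}

#' Sample peptides from an NNK library
#'
#' Residues are drawn independently at NNK codon-count frequencies; the
#' amber stop (the only stop reachable under NNK) appears with probability
#' 1/32 per position and is emitted as `"*"`.
#'
#' @param n Number of peptides (>= 1).
#' @param length Peptide length in residues (1..20).
#' @param seed Integer seed; generation is bit-reproducible given the seed.
#'
#' @return A tibble with column `aa_raw` (sequences possibly containing `*`).
#' @export
sample_nnk_peptides <- function(n, length = 20, seed = 1) {
  if (!is.numeric(n) || length(n) != 1 || n < 1) abort("n must be >= 1")
  if (!is.numeric(length) || length(length) != 1 || length < 1 || length > 20) {
    abort("length must be in 1..20")
  }
  n <- as.integer(n); len <- as.integer(length)
  counts <- nnk_codon_counts()
  withr_seed(seed, {
    m <- matrix(sample(names(counts), n * len, replace = TRUE,
                       prob = counts / sum(counts)),
                nrow = n, ncol = len)
    tibble(aa_raw = apply(m, 1, paste0, collapse = ""))
  })
}

# Evaluate the latent additive grammar score of truncated peptides.
latent_grammar_score <- function(peptides, grammar) {
  inter <- grammar$interaction_terms
  pats <- unique(c(names(grammar$motif_effects),
                   if (!is.null(inter)) c(inter$pattern_a, inter$pattern_b)))
  effects <- stats::setNames(rep(0, length(pats)), pats)
  effects[names(grammar$motif_effects)] <- grammar$motif_effects
  memb <- lapply(grammar$classes, function(set) aa_alphabet() %in% set)
  res <- split_residues(peptides)
  match_matrix <- function(s) {
    # windows x patterns logical matrix of class-pattern matches
    L <- length(s)
    if (L < 3 || length(pats) == 0) {
      return(matrix(FALSE, max(L - 2, 0), length(pats)))
    }
    idx <- match(s, aa_alphabet())
    out <- matrix(FALSE, L - 2, length(pats))
    for (j in seq_along(pats)) {
      cls <- strsplit(pats[j], "")[[1]]
      ok <- vapply(1:3, function(k) memb[[cls[k]]][idx[seq_len(L - 2) + k - 1]],
                   logical(L - 2))
      if (is.null(dim(ok))) ok <- matrix(ok, nrow = 1)
      out[, j] <- rowSums(ok) == 3
    }
    out
  }
  vapply(res, function(s) {
    mm <- match_matrix(s)
    if (nrow(mm) == 0) return(0)
    w <- grammar$position_weight[seq_len(nrow(mm))]
    val <- sum(sweep(mm, 1, w, `*`) %*% effects)
    if (!is.null(inter) && nrow(inter) > 0) {
      present <- stats::setNames(colSums(mm) > 0, pats)
      for (r in seq_len(nrow(inter))) {
        if (isTRUE(present[[inter$pattern_a[r]]]) &&
            isTRUE(present[[inter$pattern_b[r]]])) {
          val <- val + inter$epsilon[r]
        }
      }
    }
    val
  }, numeric(1))
}

#' Score a peptide library under a planted grammar
#'
#' The latent score of a peptide is the sum over its 3-mer windows of the
#' matched motif effects times the window start's position weight (plus any
#' interaction terms). The observed score adds Gaussian noise; read counts
#' follow the grammar's negative-binomial law; the ground-truth label is
#' `latent > 0`. Scoring is applied to the stop-truncated sequence, as the
#' labelling pipeline will only ever see the truncated peptide.
#'
#' @param peptides A tibble with column `aa_raw` (or a character vector).
#' @param grammar A [grammar_spec()].
#' @param seed Integer seed for noise and read counts.
#'
#' @return A tibble with columns `aa_raw`, `aa_seq` (truncated), `latent`,
#'   `score`, `error`, `input_reads`, `truth_label`.
#' @export
score_library <- function(peptides, grammar = default_grammar(), seed = 1) {
  if (is.data.frame(peptides)) peptides <- peptides$aa_raw
  assert_residues(peptides, allow_stop = TRUE)
  trunc <- truncate_at_stop(peptides)
  latent <- latent_grammar_score(trunc, grammar)
  n <- length(peptides)
  withr_seed(seed, {
    noise <- rnorm(n, 0, grammar$noise_sd)
    reads <- rnbinom(n, size = grammar$read_size, mu = grammar$read_mean)
  })
  tibble(
    aa_raw = peptides,
    aa_seq = trunc,
    latent = latent,
    score = latent + noise,
    error = rep(grammar$noise_sd, n),
    input_reads = reads,
    truth_label = latent > 0
  )
}

#' Simulate a labelled NNK library end to end
#'
#' Convenience wrapper: samples `n` NNK peptides and scores them under the
#' grammar, producing the table consumed by the labelling pipeline.
#'
#' @inheritParams sample_nnk_peptides
#' @inheritParams score_library
#' @param library_id Library identifier carried through labelling.
#' @return Scored-peptide tibble (see [score_library()]).
#' @export
simulate_library <- function(n, grammar = default_grammar(), seed = 1,
                             length = 20, library_id = "NNK1") {
  pep <- sample_nnk_peptides(n, length = length, seed = seed)
  out <- score_library(pep, grammar, seed = seed + 1L)
  out$library_id <- library_id
  out
}

#' Generate secondary-structure fixtures
#'
#' Builds annotated sequences whose beta-strand stretches are pure
#' hydrophobic runs, disorder stretches are charged/proline runs, and coil
#' regions are drawn from the full NNK residue distribution. Every residue
#' carries exactly one label in `{strand, coil, disorder}`. These fixtures
#' give downstream enrichment scoring a known answer: hydrophobic motif
#' clusters must score strands highly.
#'
#' @param n Number of sequences (>= 1).
#' @param seed Integer seed.
#' @param n_segments Number of segments per sequence.
#' @param segment_len Residues per segment.
#' @param strand_residues,disorder_residues Residue sets used for planted
#'   strand and disorder segments.
#'
#' @return Tibble with columns `seq_id`, `position` (1-based), `residue`,
#'   `label`.
#' @export
make_structure_fixtures <- function(n, seed = 1, n_segments = 6,
                                    segment_len = 6,
                                    strand_residues = c("I", "V", "F"),
                                    disorder_residues = c("D", "E", "K", "R", "P")) {
  if (!is.numeric(n) || length(n) != 1 || n < 1) abort("n must be >= 1")
  counts <- nnk_codon_counts()
  counts <- counts[names(counts) != "*"]
  coil_pool <- names(counts)
  withr_seed(seed, {
    rows <- lapply(seq_len(n), function(i) {
      labs <- sample(c("strand", "coil", "disorder"), n_segments,
                     replace = TRUE, prob = c(0.3, 0.4, 0.3))
      res <- unlist(lapply(labs, function(lab) {
        pool <- switch(lab,
                       strand = strand_residues,
                       disorder = disorder_residues,
                       coil = coil_pool)
        pr <- if (identical(pool, coil_pool)) counts / sum(counts) else NULL
        sample(pool, segment_len, replace = TRUE, prob = pr)
      }))
      tibble(seq_id = sprintf("fix%03d", i),
             position = seq_along(res),
             residue = res,
             label = rep(labs, each = segment_len))
    })
    bind_rows(rows)
  })
}

#' Write / read the scored-peptide table
#'
#' Tab-delimited with columns `aa_seq`, `score`, `error`, `input_reads` and
#' optionally `truth_label` / `library_id`. Missing scores (peptides that
#' vanished after selection) are encoded as `NA`.
#'
#' @param x Scored-peptide tibble.
#' @param path File path.
#' @return `path` (write) or a tibble (read), invisibly for write.
#' @export
write_scored_table <- function(x, path) {
  readr::write_tsv(x, path)
  invisible(path)
}

#' @rdname write_scored_table
#' @export
read_scored_table <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                         na = "NA")
  # the dipeptide "NA" (Asn-Ala) is a real sequence, not a missing value;
  # sequence columns are never missing in this schema
  for (col in intersect(c("aa_seq", "aa_raw"), names(out))) {
    out[[col]][is.na(out[[col]])] <- "NA"
  }
  out
}

#' Write / read structure-annotation tables
#'
#' Tab-delimited per-residue annotations: `seq_id`, `position` (1-based),
#' `residue`, `label` in `{strand, coil, disorder}`.
#'
#' @param x Annotation tibble.
#' @param path File path.
#' @export
write_structure_table <- function(x, path) {
  readr::write_tsv(x, path)
  invisible(path)
}

#' @rdname write_structure_table
#' @export
read_structure_table <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("seq_id", "position", "residue", "label")
  if (!all(need %in% names(out))) {
    abort("structure table must have columns seq_id, position, residue, label")
  }
  out
}

# Run code under a temporary RNG state seeded with `seed`.
withr_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}
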