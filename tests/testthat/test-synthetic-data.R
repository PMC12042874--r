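# NNK sampling, grammar scoring and structure fixtures.

test_that("NNK sampling matches the codon table's closed forms", {
  pep <- sample_nnk_peptides(1000, length = 20, seed = 7)$aa_raw
  # P(no stop in 20 positions) = (31/32)^20
  frac_stop <- mean(grepl("*", pep, fixed = TRUE))
  expect_equal(frac_stop, 1 - (31 / 32)^20, tolerance = 0.05)
  # L:M codon ratio is 3:1
  res <- unlist(strsplit(pep, ""))
  expect_equal(sum(res == "L") / sum(res == "M"), 3, tolerance = 0.15)
  expect_error(sample_nnk_peptides(0), "n must be")
  expect_error(sample_nnk_peptides(10, length = 0), "length must be")
  expect_error(sample_nnk_peptides(10, length = 25), "length must be")
})

test_that("amino-acid frequencies fit the NNK distribution (chi-square)", {
  pep <- sample_nnk_peptides(2500, length = 20, seed = 12)$aa_raw
  res <- unlist(strsplit(pep, ""))
  counts <- canya:::nnk_codon_counts()
  obs <- table(factor(res, levels = names(counts)))
  gof <- suppressWarnings(
    stats::chisq.test(as.numeric(obs), p = counts / sum(counts)))
  expect_gt(gof$p.value, 0.01)
})

test_that("generation is bit-reproducible under a fixed seed", {
  expect_identical(sample_nnk_peptides(50, seed = 3),
                   sample_nnk_peptides(50, seed = 3))
  g <- default_grammar()
  expect_identical(score_library(sample_nnk_peptides(50, seed = 3), g, seed = 5),
                   score_library(sample_nnk_peptides(50, seed = 3), g, seed = 5))
  expect_identical(make_structure_fixtures(5, seed = 2),
                   make_structure_fixtures(5, seed = 2))
})

test_that("latent scores equal brute-force window counting", {
  g <- grammar_spec(motif_effects = c(hhh = 1),
                    position_weight = rep(1, 18), noise_sd = 0)
  # "IIIAAAAAAAAAAAAAAAAA": windows 1..18; all-hydrophobic windows counted
  # by hand on the literal sequence
  s <- "IIIAAAAAAAAAAAAAAAAA"
  chars <- strsplit(s, "")[[1]]
  h <- hydrophobic_set
  expected <- sum(vapply(1:18, function(p) all(chars[p:(p + 2)] %in% h),
                         logical(1)))
  out <- score_library(tibble::tibble(aa_raw = s), g, seed = 1)
  expect_equal(out$latent, expected)
  expect_equal(out$score, expected)  # noise_sd = 0
  # zero-effect grammar: all scores exactly zero
  g0 <- grammar_spec(motif_effects = c(hhh = 0), noise_sd = 0)
  out0 <- score_library(sample_nnk_peptides(20, seed = 1), g0, seed = 1)
  expect_true(all(out0$score == 0))
})

test_that("position weights scale window effects", {
  pw <- seq(1.8, 0.2, length.out = 18)
  g <- grammar_spec(motif_effects = c(hhh = 1, ddd = -1),
                    position_weight = pw, noise_sd = 0)
  # one hydrophobic window at start 1, one disruptor window at start 10
  s <- paste0("IVF", "AAAAAA", "DKP", "AAAAAAAA")
  out <- score_library(tibble::tibble(aa_raw = s), g, seed = 1)
  expect_equal(out$latent, pw[1] - pw[10])
})

test_that("interaction terms add epsilon when both patterns co-occur", {
  it <- tibble::tibble(pattern_a = "hhh", pattern_b = "ddd", epsilon = 0.7)
  g <- grammar_spec(motif_effects = c(hhh = 1, ddd = -1),
                    position_weight = rep(1, 18),
                    interaction_terms = it, noise_sd = 0)
  both <- paste0("IVF", "AAAAAA", "DKP", "AAAAAAAA")
  only_h <- paste0("IVF", paste(rep("A", 17), collapse = ""))
  sc <- score_library(tibble::tibble(aa_raw = c(both, only_h)), g, seed = 1)
  expect_equal(sc$latent[1], 1 - 1 + 0.7)
  expect_equal(sc$latent[2], 1)
})

test_that("noise is calibrated: null peptides have SD near noise_sd", {
  g <- grammar_spec(motif_effects = c(hhh = 1), noise_sd = 0.5)
  # all-A peptides carry no motif; observed scores are pure noise
  pep <- tibble::tibble(aa_raw = rep(strrep("A", 20), 10000))
  out <- score_library(pep, g, seed = 9)
  expect_equal(sd(out$score), 0.5, tolerance = 0.05 * 0.5 / 0.5)
  expect_true(all(out$error == 0.5))
})

test_that("grammar validation rejects malformed specs", {
  expect_error(grammar_spec(c(hhh = 1), position_weight = rep(1, 17)),
               "18")
  expect_error(grammar_spec(c(hhh = 1), position_weight = c(rep(1, 17), -1)),
               "positive")
  expect_error(grammar_spec(c(hhh = Inf)), "finite")
  expect_error(grammar_spec(c(hhhh = 1)), "length-3")
  expect_error(grammar_spec(c(xyz = 1)), "not defined")
})

test_that("structure fixtures label every residue exactly once", {
  fx <- make_structure_fixtures(3, seed = 4, n_segments = 5, segment_len = 4)
  for (id in unique(fx$seq_id)) {
    s <- fx[fx$seq_id == id, ]
    expect_identical(s$position, seq_len(nrow(s)))
    expect_true(all(s$label %in% c("strand", "coil", "disorder")))
  }
  # planted composition: strands hydrophobic, disorder charged/proline
  expect_true(all(fx$residue[fx$label == "strand"] %in% c("I", "V", "F")))
  expect_true(all(fx$residue[fx$label == "disorder"] %in% disruptor_set))
})

test_that("scored tables round-trip through TSV", {
  lib <- simulate_library(30, seed = 2)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_scored_table(lib, path)
  back <- read_scored_table(path)
  expect_equal(as.data.frame(back), as.data.frame(lib))
})
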