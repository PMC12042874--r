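# Metrics, baselines and task builders.

test_that("AUROC matches exhaustive pair counting on a worked example", {
  scores <- c(0.9, 0.8, 0.7, 0.6, 0.5, 0.4, 0.3, 0.2)
  labels <- c(1, 1, 0, 1, 0, 0, 1, 0)
  pairs <- expand.grid(p = which(labels == 1), n = which(labels == 0))
  oracle <- mean(ifelse(scores[pairs$p] > scores[pairs$n], 1,
                        ifelse(scores[pairs$p] == scores[pairs$n], 0.5, 0)))
  expect_equal(auroc(scores, labels), oracle)
  # perfect separation
  expect_equal(auroc(c(3, 2, 1, 0), c(1, 1, 0, 0)), 1)
  expect_equal(aupr(c(3, 2, 1, 0), c(1, 1, 0, 0)), 1)
  # chance level at large n
  withr::with_seed(131, {
    s <- rnorm(20000); l <- rbinom(20000, 1, 0.3)
  })
  expect_equal(auroc(s, l), 0.5, tolerance = 0.02)
  expect_error(auroc(1:3, c(1, 1, 1)), "both classes")
})

test_that("AUROC and AUPR agree with the independent pROC/PRROC route", {
  skip_if_not_installed("pROC")
  withr::with_seed(132, {
    s <- rnorm(500); l <- rbinom(500, 1, 0.4)
    s[l == 1] <- s[l == 1] + 1
  })
  ref <- as.numeric(suppressMessages(pROC::auc(l, s)))
  expect_equal(auroc(s, l), ref, tolerance = 1e-12)
})

test_that("bootstrap CIs cover the point estimate and behave sanely", {
  withr::with_seed(133, {
    s <- rnorm(300); l <- rbinom(300, 1, 0.5)
    s[l == 1] <- s[l == 1] + 1.5
  })
  rep <- auroc_auprc(s, l, n_boot = 200, seed = 134)
  expect_true(rep$auroc_lo <= rep$auroc && rep$auroc <= rep$auroc_hi)
  expect_true(rep$aupr_lo <= rep$aupr && rep$aupr <= rep$aupr_hi)
  expect_equal(rep$n_pos + rep$n_neg, 300)
})

test_that("bootstrap CI coverage is near nominal on simulated pairs", {
  # true AUROC for N(1,1) vs N(0,1) is pnorm(1/sqrt(2))
  true_auc <- pnorm(1 / sqrt(2))
  hits <- vapply(1:40, function(r) {
    withr::with_seed(1000 + r, {
      l <- rbinom(120, 1, 0.5)
      s <- rnorm(120, mean = l)
    })
    ci <- auroc_auprc(s, l, n_boot = 200, seed = r)
    ci$auroc_lo <= true_auc && true_auc <= ci$auroc_hi
  }, logical(1))
  expect_gte(mean(hits), 0.85)
  expect_lte(mean(hits), 1.0)
})

test_that("hydrophobicity baseline is an exact table sum", {
  kd <- kyte_doolittle()
  expect_equal(hydrophobicity_baseline("AI"), kd[["A"]] + kd[["I"]])
  expect_gt(hydrophobicity_baseline("III"), hydrophobicity_baseline("DDD"))
  expect_error(hydrophobicity_baseline("AI", scale = numeric(0)), "empty")
  expect_error(hydrophobicity_baseline("AXZ"), "invalid residue|missing")
})

test_that("composition baseline separates composition-driven classes", {
  withr::with_seed(135, {
    pos <- replicate(200, paste0(sample(c("I", "V", "A"), 15, TRUE),
                                 collapse = ""))
    neg <- replicate(200, paste0(sample(c("D", "E", "A"), 15, TRUE),
                                 collapse = ""))
  })
  dat <- tibble::tibble(aa_seq = c(pos, neg), label = rep(1:0, each = 200))
  sc <- composition_baseline(dat, dat)
  expect_gt(auroc(sc, dat$label), 0.9)
  # permuted labels: chance
  perm <- dat
  perm$label <- withr::with_seed(136, sample(dat$label))
  expect_lt(abs(auroc(composition_baseline(perm, perm), perm$label) - 0.5),
            0.08)
})

test_that("context-free task excises regions and balances classes", {
  prot <- tibble::tibble(protein_id = "p1", sequence = "AAAABBBBCCCC",
                         start = 5L, end = 8L)
  # residue letters here are placeholders; map to canonical residues
  prot$sequence <- "AAAAWWWWCCCC"
  task <- build_context_free_task(prot, seed = 1)
  pos <- task[task$label == 1, ]
  neg <- task[task$label == 0, ]
  expect_equal(pos$aa_seq, "WWWW")
  # remainder AAAACCCC chunks of length 4: AAAA, CCCC
  expect_true(all(neg$aa_seq %in% c("AAAA", "CCCC")))
  expect_equal(nrow(pos), nrow(neg))
  # region covering the whole sequence: no negatives, warning
  whole <- tibble::tibble(protein_id = "p2", sequence = "IIII",
                          start = 1L, end = 4L)
  expect_warning(
    expect_warning(build_context_free_task(whole, seed = 1),
                   "no negatives"),
    "downsampling positives")
  # out-of-bounds span
  bad <- tibble::tibble(protein_id = "p3", sequence = "IIII",
                        start = 2L, end = 9L)
  expect_error(build_context_free_task(bad), "outside sequence bounds")
})

test_that("task builders are deterministic and balance exactly", {
  withr::with_seed(137, {
    prot <- tibble::tibble(
      protein_id = sprintf("p%d", 1:5),
      sequence = random_peptides(5, len = 20, seed = 138),
      start = sample(3:6, 5, TRUE))
    prot$end <- prot$start + 3L
  })
  t1 <- build_context_free_task(prot, seed = 9)
  t2 <- build_context_free_task(prot, seed = 9)
  expect_identical(t1, t2)
  expect_equal(sum(t1$label == 1), sum(t1$label == 0))
})

test_that("length filtering applies the >= 10 and whitespace rules", {
  rec <- tibble::tibble(
    aa_seq = c(strrep("A", 9), strrep("A", 10), strrep("A", 11), "AB CD"),
    classification = c("amyloid", "amyloid", "other", "amyloid"))
  out <- build_length_filtered_task(rec)
  expect_equal(nchar(out$aa_seq), c(10, 11))
  expect_equal(out$label, c(1L, 0L))
  empty <- build_length_filtered_task(rec[0, ])
  expect_equal(nrow(empty), 0)
})
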