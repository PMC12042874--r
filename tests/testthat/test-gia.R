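# Global Importance Analysis against exact additive oracles.

test_that("background selection enforces confidence and length", {
  m <- tiny_model(seed = 81)
  dat <- tibble::tibble(aa_seq = random_peptides(300, seed = 82),
                        label = rep(0:1, 150))
  prob <- plogis(pre_activation(m, dat$aa_seq))
  # choose thresholds that some sequences meet
  thr <- c(stats::quantile(prob, 0.4), stats::quantile(prob, 0.6))
  bg <- suppressWarnings(
    select_backgrounds(m, dat, n = 50, thresholds = thr, seed = 83))
  expect_true(all(nchar(bg) == 20))
  rescored <- plogis(pre_activation(m, bg))
  lab <- dat$label[match(bg, dat$aa_seq)]
  expect_true(all((lab == 1 & rescored > thr[1]) |
                    (lab == 0 & rescored < thr[2])))
  # impossible thresholds give an error
  expect_error(select_backgrounds(m, dat, thresholds = c(1, 0)),
               "no confidently predicted")
  # short sequences never qualify
  short <- tibble::tibble(aa_seq = c("FN", "KL"), label = c(1, 0))
  expect_error(select_backgrounds(m, short), "full-length")
})

test_that("kmer sampling probabilities follow activation ratios", {
  # activations {2, 1, 1} -> ratios {1, .5, .5} -> probabilities {.5, .25, .25}
  pwm <- manual_pwm(c("AAA", "CCC", "DDD"), activations = c(2, 1, 1))
  sampler <- canya:::feature_kmer_sampler(pwm)
  draws <- withr::with_seed(84, sampler$sample(20000))
  freq <- table(factor(draws, levels = c("AAA", "CCC", "DDD"))) / 20000
  expect_equal(as.numeric(freq), c(0.5, 0.25, 0.25), tolerance = 0.03)
})

test_that("constant models have exactly zero GIA importance", {
  m <- tiny_model(seed = 85)
  m$weights$Wc[] <- 0; m$weights$bc[] <- 0
  m$weights$Wd[] <- 0; m$weights$wout[] <- 0
  bg <- random_peptides(40, seed = 86)
  r <- gia_importance(m, manual_pwm("III"), bg, seed = 87)
  expect_equal(r$importance, 0)
  expect_true(r$ci_lo <= r$importance && r$importance <= r$ci_hi)
})

test_that("additive surrogate importance equals the closed-form difference", {
  # surrogate: +1 per I, -1 per D, position-invariant; constant background
  sur <- flat_surrogate(c(I = 1, D = -1))
  bg <- rep(strrep("A", 20), 25)
  r <- gia_importance(sur, manual_pwm("III"), bg, seed = 88)
  # embedding III over AAA changes the score by exactly 3
  expect_equal(r$importance, 3)
  expect_equal(r$n_backgrounds, 25)
  # on heterogeneous backgrounds: equals brute-force average replacement
  bg2 <- random_peptides(60, seed = 89)
  r2 <- gia_importance(sur, manual_pwm("III"), bg2, seed = 90)
  # oracle: reproduce the same kmer/position draws and compute by hand
  withr::with_seed(90, {
    kmers <- canya:::feature_kmer_sampler(manual_pwm("III"))$sample(60)
    pos <- sample.int(18, 60, replace = TRUE)
  })
  w <- stats::setNames(rep(0, 20), aa_alphabet()); w["I"] <- 1; w["D"] <- -1
  oracle <- mean(vapply(seq_along(bg2), function(i) {
    old <- strsplit(substr(bg2[i], pos[i], pos[i] + 2), "")[[1]]
    3 - sum(w[old])
  }, numeric(1)))
  expect_equal(r2$importance, oracle)
})

test_that("multiplicity curves are exactly linear for additive surrogates", {
  sur <- flat_surrogate(c(I = 2))
  bg <- rep(strrep("A", 20), 30)
  feat <- cluster_feature(list(manual_pwm("III")), importances = 1)
  r <- gia_multiplicity(sur, feat, bg, max_copies = 4, seed = 91)
  expect_equal(r$importance, 6 * (1:4))   # 3 residues x weight 2 x copies
  expect_equal(attr(r, "r_squared"), 1)
  expect_equal(nrow(r), 4)
  # copies never overlap: embedded positions differ by >= 3
  # constant model: all importances zero
  m0 <- tiny_model(seed = 92)
  m0$weights$Wc[] <- 0; m0$weights$bc[] <- 0; m0$weights$wout[] <- 0
  r0 <- gia_multiplicity(m0, feat, random_peptides(20, seed = 93), seed = 94)
  expect_true(all(r0$importance == 0))
})

test_that("positional GIA recovers planted position dependence", {
  # surrogate with weight 2 on positions 1..9 and 1 on positions 10..20
  w <- matrix(0, 20, 20, dimnames = list(aa_alphabet(), NULL))
  w["I", 1:9] <- 2; w["I", 10:20] <- 1
  sur <- canya_surrogate(w)
  bg <- rep(strrep("A", 20), 20)
  r <- gia_positional(sur, manual_pwm("III"), bg, seed = 95)
  expect_equal(nrow(r), 18)
  # oracle: embedding III at start p scores sum of w["I", p:(p+2)]
  oracle <- vapply(1:18, function(p) sum(w["I", p:(p + 2)]), numeric(1))
  expect_equal(r$importance, oracle)
  expect_true(all(r$percent_change[1:7] > 0))
  expect_true(all(r$percent_change[10:18] < 0))
  # position-invariant surrogate: percent changes all zero
  rflat <- gia_positional(flat_surrogate(c(I = 1)), manual_pwm("III"),
                          bg, seed = 96)
  expect_equal(rflat$percent_change, rep(0, 18))
})

test_that("interaction importance is zero for additive models", {
  sur <- flat_surrogate(c(I = 1, D = -2))
  bg <- random_peptides(50, seed = 97)
  r <- gia_interaction(sur, manual_pwm("III"), manual_pwm("DDD"), bg,
                       seed = 98)
  expect_lt(abs(r$importance), 1e-12)
  expect_gt(r$p_value, 0.9)
})

test_that("a planted product interaction is recovered within its CI", {
  inter <- tibble::tibble(kmer_a = "III", kmer_b = "DDD", epsilon = 0.4)
  sur <- flat_surrogate(c(I = 1, D = -1), interactions = inter)
  bg <- rep(strrep("A", 20), 40)
  r <- gia_interaction(sur, manual_pwm("III"), manual_pwm("DDD"), bg,
                       seed = 99)
  # backgrounds carry neither kmer, so the interaction term fires only in
  # the doubly embedded sequence: expected importance = epsilon
  expect_gte(0.4, r$ci_lo)
  expect_lte(0.4, r$ci_hi)
  expect_equal(r$importance, 0.4, tolerance = 1e-9)
})

test_that("self-interaction equals the multiplicity-2 deviation identity", {
  # for any model: [f(2 copies) + f(bg)] - 2 f(1 copy) with matched draws;
  # on an additive surrogate both sides are exactly zero
  sur <- flat_surrogate(c(V = 1.5))
  bg <- random_peptides(30, seed = 100)
  r <- gia_interaction(sur, manual_pwm("VVV"), manual_pwm("VVV"), bg,
                       seed = 101)
  expect_lt(abs(r$importance), 1e-12)
})

test_that("background halves give CI-compatible estimates", {
  m <- tiny_model(seed = 103)
  bg <- random_peptides(400, seed = 104)
  r1 <- gia_importance(m, manual_pwm("III"), bg[1:200], seed = 105)
  r2 <- gia_importance(m, manual_pwm("III"), bg[201:400], seed = 106)
  joint_lo <- min(r1$ci_lo, r2$ci_lo)
  joint_hi <- max(r1$ci_hi, r2$ci_hi)
  expect_true(r1$importance >= joint_lo && r1$importance <= joint_hi)
  expect_true(r2$importance >= joint_lo && r2$importance <= joint_hi)
})

test_that("invalid position policies are rejected", {
  sur <- flat_surrogate(c(I = 1))
  bg <- rep(strrep("A", 20), 5)
  expect_error(gia_importance(sur, manual_pwm("III"), bg,
                              position_policy = 19), "1..18")
  expect_error(gia_importance(sur, manual_pwm("III"), character(0)),
               "nonempty")
})
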