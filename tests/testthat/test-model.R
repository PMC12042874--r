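# Architecture contract, forward/backward correctness, training behaviour
# and the long-sequence scorer.

test_that("default architecture has exactly 17,491 parameters", {
  m <- canya_build(canya_config())
  pc <- canya_param_count(m)
  expect_equal(attr(pc, "total"), 17491)
})

test_that("parameter count matches the closed form for small configs", {
  count_formula <- function(Fn, Kl, Du, fl = 3) {
    frames <- 24 - fl + 1
    Fn * fl * 20 + Fn +        # conv kernel + bias
      frames * Fn +            # content positional embeddings
      24 * Kl +                # key-side positional encodings
      3 * (Fn * Kl + Kl) +     # Q, K, V projections with bias
      Kl * Fn + Fn +           # output projection with bias
      Fn * Du + Du +           # dense layer
      Du + 1                   # sigmoid head
  }
  for (cfg in list(c(1, 1, 1), c(3, 2, 5), c(16, 6, 8))) {
    m <- canya_build(canya_config(n_filters = cfg[1], key_len = cfg[2],
                                  dense_units = cfg[3]))
    expect_equal(attr(canya_param_count(m), "total"),
                 count_formula(cfg[1], cfg[2], cfg[3]))
  }
})

test_that("invalid configurations are rejected at construction", {
  expect_error(canya_config(n_filters = 0), "positive integers")
  expect_error(canya_config(dropout_dense = 1), "dropout")
  expect_error(canya_config(epochs = -1), "positive integers")
})

test_that("analytic gradients match finite differences", {
  m <- tiny_model(n_filters = 3, key_len = 2, dense_units = 4, seed = 42)
  peps <- c("FNKLY", "ACDEFGHIKLMNPQRSTVWY", "IIIVVV", "")
  y <- c(1, 0, 1, 0)
  Xm <- canya:::encode_flat(peps)
  loss_fn <- function(model) {
    p <- canya:::canya_forward(model, Xm)$prob
    -mean(y * log(p) + (1 - y) * log(1 - p))
  }
  fw <- canya:::canya_forward(m, Xm, keep = TRUE)
  bw <- canya:::canya_backward(m, fw, (fw$prob - y) / length(y))
  eps <- 1e-6
  withr::with_seed(1, {
    for (nm in names(m$weights)) {
      w <- m$weights[[nm]]
      for (i in sample(length(w), min(4, length(w)))) {
        mp <- m; mp$weights[[nm]][i] <- w[i] + eps
        mm <- m; mm$weights[[nm]][i] <- w[i] - eps
        num <- (loss_fn(mp) - loss_fn(mm)) / (2 * eps)
        expect_equal(bw$grads[[nm]][i], num, tolerance = 1e-4,
                     label = sprintf("grad %s[%d]", nm, i))
      }
    }
  })
})

test_that("probability equals sigmoid of the pre-activation score", {
  m <- tiny_model()
  peps <- random_peptides(20, seed = 5)
  pre <- pre_activation(m, peps)
  prob <- predict(m, peps)$score
  expect_equal(prob, plogis(pre), tolerance = 1e-6)
  expect_true(all(prob > 0 & prob < 1))
  expect_equal(plogis(0), 0.5)  # pre-activation 0 maps to probability 0.5
})

test_that("batch and single-sequence predictions agree", {
  m <- tiny_model(seed = 9)
  peps <- random_peptides(8, seed = 6)
  batch <- predict(m, peps)$score
  single <- vapply(peps, function(p) predict(m, p)$score, numeric(1))
  expect_equal(batch, unname(single), tolerance = 1e-12)
})

test_that("filter activations equal hand-computed convolution energies", {
  m <- tiny_model(n_filters = 1, seed = 11)
  s <- "FNKLYW"
  act <- filter_activations(m, s)
  expect_identical(dim(act), c(4L, 1L))
  w <- matrix(m$weights$Wc[, 1], nrow = 20)
  chars <- strsplit(s, "")[[1]]
  for (p in 1:4) {
    e <- sum(w[cbind(match(chars[p:(p + 2)], aa_alphabet()), 1:3)]) +
      m$weights$bc[1]
    expect_equal(act[p, 1], exp(e))
  }
  # zero filter weights and bias: activations exactly exp(0) = 1
  m0 <- m
  m0$weights$Wc[] <- 0; m0$weights$bc[] <- 0
  expect_true(all(filter_activations(m0, s) == 1))
  # identical sequences give identical grids
  expect_identical(filter_activations(m, s), filter_activations(m, s))
})

test_that("training is deterministic and learns a separable toy problem", {
  # composition-separable toy task: I-rich positive, D-rich negative
  n <- 400
  withr::with_seed(13, {
    pos <- replicate(n / 2, paste0(sample(c("I", "V", "A"), 12, TRUE),
                                   collapse = ""))
    neg <- replicate(n / 2, paste0(sample(c("D", "E", "G"), 12, TRUE),
                                   collapse = ""))
  })
  dat <- tibble::tibble(aa_seq = c(pos, neg),
                        label = rep(1:0, each = n / 2))
  cfg <- canya_config(n_filters = 6, key_len = 3, dense_units = 6,
                      seed = 3, batch_size = 64)
  m1 <- canya_train(canya_build(cfg), dat, epochs = 6)
  m2 <- canya_train(canya_build(cfg), dat, epochs = 6)
  expect_identical(m1$history$loss, m2$history$loss)  # same seed, same run
  expect_identical(m1$weights, m2$weights)
  sc <- pre_activation(m1, dat$aa_seq)
  expect_gt(auroc(sc, dat$label), 0.95)
  expect_true(all(diff(m1$history$lr) <= 0))  # LR never increases
  expect_error(canya_train(canya_build(cfg),
                           dplyr::mutate(dat, label = 1)),
               "both classes")
})

test_that("permuted labels give chance-level performance", {
  withr::with_seed(17, {
    dat <- tibble::tibble(aa_seq = random_peptides(300, seed = 18),
                          label = sample(rep(0:1, 150)))
  })
  cfg <- canya_config(n_filters = 4, key_len = 2, dense_units = 4,
                      seed = 5, batch_size = 64)
  m <- canya_train(canya_build(cfg), dat, epochs = 4)
  test_seqs <- random_peptides(400, seed = 19)
  test_lab <- withr::with_seed(20, sample(rep(0:1, 200)))
  expect_equal(auroc(pre_activation(m, test_seqs), test_lab), 0.5,
               tolerance = 0.06)
})

test_that("long sequences are scored by summarised sliding windows", {
  m <- tiny_model(seed = 23)
  s22 <- random_peptides(1, len = 22, seed = 24)
  # brute-force: 3 windows of length 20
  wins <- substring(s22, 1:3, 20:22)
  probs <- plogis(pre_activation(m, wins))
  expect_equal(predict_long(m, s22), median(probs))
  expect_equal(predict_long(m, s22, summarizer = "min"), min(probs))
  expect_equal(predict_long(m, s22, summarizer = "max"), max(probs))
  expect_equal(predict_long(m, s22, summarizer = "mean"), mean(probs))
  # length 20: single window, summariser irrelevant
  s20 <- substr(s22, 1, 20)
  expect_equal(predict_long(m, s20, "median"), predict_long(m, s20, "min"))
  # routing through predict()
  expect_error(predict(m, s22), "longer than 20")
  expect_equal(predict(m, s22, long = "window")$score,
               plogis(predict_long(m, s22, type = "score")))
})

test_that("checkpoints round-trip", {
  m <- tiny_model(seed = 29)
  path <- withr::local_tempfile(fileext = ".rds")
  canya_save(m, path)
  m2 <- canya_load(path)
  peps <- random_peptides(5, seed = 30)
  expect_equal(pre_activation(m2, peps), pre_activation(m, peps))
})
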