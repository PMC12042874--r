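# The CANYA network: a convolution-attention-dense stack over the 24 x 20
# peptide encoding, implemented directly in R matrix algebra (forward and
# reverse passes). The network is the package's core contribution and is
# authored here rather than delegated to a deep-learning framework.
#
# Layer stack (defaults in parentheses):
#   conv (100 filters, length 3, stride 1, exponential activation, no pooling)
#   -> dropout 0.1
#   -> content positional embeddings added to the motif frames
#   -> single-head self-attention (key length 6) with key-side positional
#      encodings added before the softmax; output projection back to filter
#      space
#   -> dropout 0.1
#   -> mean-pool over frames
#   -> dense (64, ReLU, elastic-net 0.01 on incoming weights) -> dropout 0.4
#   -> 1-unit sigmoid
#
# Under the default configuration the trainable parameter count is 17,491;
# see canya_param_count() for the per-matrix decomposition.

#' Model configuration
#'
#' @param n_filters Number of convolutional filters.
#' @param filter_len Filter length in residues.
#' @param key_len Attention key length (also the value dimension).
#' @param dense_units Units in the fully connected layer.
#' @param dropout_conv,dropout_attn,dropout_dense Dropout rates applied
#'   after the convolution, attention and dense layers.
#' @param elastic_net Elastic-net strength on the attention-to-dense
#'   weights (applied as `elastic_net * (||W||_1 + ||W||_2^2)`).
#' @param epochs Maximum training epochs.
#' @param learning_rate Initial Adam learning rate.
#' @param lr_factor,lr_patience Learning-rate decay factor and patience
#'   (monitoring validation AUPR).
#' @param early_stop_patience Early-stopping patience (validation AUPR).
#' @param batch_size Minibatch size.
#' @param seed Integer seed controlling initialisation and training.
#'
#' @return A `canya_config` list.
#' @export
canya_config <- function(n_filters = 100, filter_len = 3, key_len = 6,
                         dense_units = 64,
                         dropout_conv = 0.1, dropout_attn = 0.1,
                         dropout_dense = 0.4,
                         elastic_net = 0.01,
                         epochs = 100, learning_rate = 1e-3,
                         lr_factor = 0.2, lr_patience = 4,
                         early_stop_patience = 10,
                         batch_size = 128, seed = 1) {
  cfg <- list(n_filters = n_filters, filter_len = filter_len,
              key_len = key_len, dense_units = dense_units,
              dropout_conv = dropout_conv, dropout_attn = dropout_attn,
              dropout_dense = dropout_dense, elastic_net = elastic_net,
              epochs = epochs, learning_rate = learning_rate,
              lr_factor = lr_factor, lr_patience = lr_patience,
              early_stop_patience = early_stop_patience,
              batch_size = batch_size, seed = seed,
              input_len = 24L, n_channels = 20L)
  counts <- c(cfg$n_filters, cfg$filter_len, cfg$key_len, cfg$dense_units,
              cfg$epochs, cfg$batch_size)
  if (any(counts < 1) || any(counts != floor(counts))) {
    abort("all count-valued configuration fields must be positive integers")
  }
  drops <- c(dropout_conv, dropout_attn, dropout_dense)
  if (any(drops < 0 | drops >= 1)) abort("dropout rates must lie in [0, 1)")
  if (cfg$filter_len >= cfg$input_len) abort("filter_len too large for input")
  cfg$n_frames <- cfg$input_len - cfg$filter_len + 1L
  class(cfg) <- "canya_config"
  cfg
}

glorot <- function(nin, nout) {
  lim <- sqrt(6 / (nin + nout))
  matrix(runif(nin * nout, -lim, lim), nin, nout)
}

#' Build an untrained model
#'
#' Initialises all weight matrices (Glorot-uniform projections, zero biases
#' and positional tables) under the configuration seed.
#'
#' @param config A [canya_config()].
#' @return A `canya_model` object (untrained).
#' @export
canya_build <- function(config = canya_config()) {
  cfg <- config
  Fn <- cfg$n_filters; Kl <- cfg$key_len; Du <- cfg$dense_units
  patch <- cfg$filter_len * cfg$n_channels
  withr_seed(cfg$seed, {
    W <- list(
      Wc = glorot(patch, Fn), bc = numeric(Fn),
      Pcont = matrix(0, cfg$n_frames, Fn),
      Pkey = matrix(0, cfg$input_len, Kl),
      Wq = glorot(Fn, Kl), bq = numeric(Kl),
      Wk = glorot(Fn, Kl), bk = numeric(Kl),
      Wv = glorot(Fn, Kl), bv = numeric(Kl),
      Wo = glorot(Kl, Fn), bo = numeric(Fn),
      Wd = glorot(Fn, Du), bd = numeric(Du),
      wout = glorot(Du, 1), bout = 0
    )
  })
  model <- structure(
    list(config = cfg, weights = W, channel_order = aa_alphabet(),
         history = NULL, trained = FALSE),
    class = "canya_model")
  model
}

#' Trainable parameter count and decomposition
#'
#' @param model A `canya_model`.
#' @return A tibble with one row per weight tensor (`tensor`, `n_params`);
#'   the total is attached as attribute `"total"`.
#' @export
canya_param_count <- function(model) {
  W <- model$weights
  out <- tibble(tensor = names(W),
                n_params = vapply(W, function(w) length(w), numeric(1)))
  attr(out, "total") <- sum(out$n_params)
  out
}

#' @export
format.canya_model <- function(x, ...) {
  total <- attr(canya_param_count(x), "total")
  sprintf("<canya_model: %d filters, key length %d, %s, %d parameters>",
          x$config$n_filters, x$config$key_len,
          if (x$trained) "trained" else "untrained", total)
}

#' @export
print.canya_model <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

# Flatten a (B, 24, 20) input array into the (B, 480) row-major layout used
# by the frame-wise convolution, where column (r-1)*20 + c holds X[, r, c].
flatten_input <- function(X) {
  B <- dim(X)[1]
  matrix(aperm(X, c(1, 3, 2)), nrow = B)
}

# Encode peptides straight into the flattened (B, 480) layout; identical to
# flatten_input(encode_batch(x)) but without the intermediate array.
encode_flat <- function(peptides) {
  B <- length(peptides)
  nc <- 20L
  Xm <- matrix(0, B, 24L * nc)
  lens <- nchar(peptides)
  if (any(lens > 20)) abort("sequences longer than 20 residues cannot be encoded")
  res <- split_residues(peptides)
  for (b in seq_len(B)) {
    L <- lens[b]
    if (L > 0) {
      idx <- match(res[[b]], aa_alphabet())
      if (anyNA(idx)) assert_residues(peptides[b])
      Xm[b, (2L + seq_len(L) - 1L) * nc + idx] <- 1
    }
    if (L < 20) Xm[b, ((L + 4L) * nc + 1L):(24L * nc)] <- -1
  }
  Xm
}

# Inverted-dropout mask sampled with runif (cheaper than rbinom).
drop_mask <- function(nr, nc, p) {
  matrix((runif(nr * nc) >= p) / (1 - p), nr, nc)
}

# Forward pass over a flattened batch. Returns intermediates for backprop
# when `keep = TRUE`. Dropout masks are sampled only when `training = TRUE`.
canya_forward <- function(model, Xm, training = FALSE, keep = FALSE) {
  cfg <- model$config; W <- model$weights
  B <- nrow(Xm)
  Fr <- cfg$n_frames; Fn <- cfg$n_filters; Kl <- cfg$key_len
  nc <- cfg$n_channels
  rows_frame <- rep(seq_len(Fr), each = B)   # frame id per row (frame-major)
  group_sample <- rep(seq_len(B), Fr)        # sample id per row
  # convolution with exponential activation, frame-major stacking
  Z <- matrix(0, B * Fr, Fn)
  for (i in seq_len(Fr)) {
    cols <- ((i - 1) * nc + 1):((i + cfg$filter_len - 1) * nc)
    Z[((i - 1) * B + 1):(i * B), ] <-
      Xm[, cols, drop = FALSE] %*% W$Wc
  }
  Z <- sweep(Z, 2, W$bc, `+`)
  Z <- pmin(Z, 30)  # guard exp overflow; activations cap at e^30
  H <- exp(Z)
  M1 <- NULL
  Hd <- H
  if (training && cfg$dropout_conv > 0) {
    M1 <- drop_mask(nrow(H), ncol(H), cfg$dropout_conv)
    Hd <- H * M1
  }
  Fh <- Hd + W$Pcont[rows_frame, , drop = FALSE]
  Q <- sweep(Fh %*% W$Wq, 2, W$bq, `+`)
  K <- sweep(Fh %*% W$Wk, 2, W$bk, `+`)
  # key-side positional encodings, indexed by each frame's central input row
  centre <- seq_len(Fr) + (cfg$filter_len %/% 2)
  K <- K + W$Pkey[centre[rows_frame], , drop = FALSE]
  V <- sweep(Fh %*% W$Wv, 2, W$bv, `+`)
  sc <- 1 / sqrt(Kl)
  # batched attention in array form: Q3[b, i, d] with i the query frame.
  # A is stored as a (B, Fr*Fr) matrix with column (j-1)*Fr + i holding the
  # weight of key frame j for query frame i.
  Q3 <- Q; dim(Q3) <- c(B, Fr, Kl)
  K3 <- K; dim(K3) <- c(B, Fr, Kl)
  V3 <- V; dim(V3) <- c(B, Fr, Kl)
  ii <- rep(seq_len(Fr), times = Fr)
  jj <- rep(seq_len(Fr), each = Fr)
  S <- matrix(0, B, Fr * Fr)
  for (d in seq_len(Kl)) {
    Qd <- Q3[, , d]; dim(Qd) <- c(B, Fr)
    Kd <- K3[, , d]; dim(Kd) <- c(B, Fr)
    S <- S + Qd[, ii, drop = FALSE] * Kd[, jj, drop = FALSE]
  }
  S <- S * sc
  cols_j <- lapply(seq_len(Fr), function(j) (j - 1L) * Fr + seq_len(Fr))
  Mx <- S[, cols_j[[1]], drop = FALSE]
  for (j in 2:Fr) Mx <- pmax(Mx, S[, cols_j[[j]], drop = FALSE])
  for (j in seq_len(Fr)) {
    S[, cols_j[[j]]] <- exp(S[, cols_j[[j]], drop = FALSE] - Mx)
  }
  Rs <- S[, cols_j[[1]], drop = FALSE]
  for (j in 2:Fr) Rs <- Rs + S[, cols_j[[j]], drop = FALSE]
  for (j in seq_len(Fr)) S[, cols_j[[j]]] <- S[, cols_j[[j]], drop = FALSE] / Rs
  A <- S
  O3 <- array(0, c(B, Fr, Kl))
  for (d in seq_len(Kl)) {
    acc <- matrix(0, B, Fr)
    for (j in seq_len(Fr)) {
      acc <- acc + A[, cols_j[[j]], drop = FALSE] * V3[, j, d]
    }
    O3[, , d] <- acc
  }
  O <- O3; dim(O) <- c(B * Fr, Kl)
  U <- sweep(O %*% W$Wo, 2, W$bo, `+`)
  M2 <- NULL
  Ud <- U
  if (training && cfg$dropout_attn > 0) {
    M2 <- drop_mask(nrow(U), ncol(U), cfg$dropout_attn)
    Ud <- U * M2
  }
  pooled <- rowsum(Ud, group_sample) / Fr
  G <- sweep(pooled %*% W$Wd, 2, W$bd, `+`)
  D1 <- pmax(G, 0)
  M4 <- NULL
  D1d <- D1
  if (training && cfg$dropout_dense > 0) {
    M4 <- drop_mask(nrow(D1), ncol(D1), cfg$dropout_dense)
    D1d <- D1 * M4
  }
  yraw <- drop(D1d %*% W$wout) + W$bout
  out <- list(yraw = yraw, prob = stats::plogis(yraw))
  if (keep) {
    out <- c(out, list(Xm = Xm, Z = Z, H = H, M1 = M1, Hd = Hd, Fh = Fh,
                       Q = Q, K = K, V = V, A = A, O = O, U = U,
                       M2 = M2, Ud = Ud, pooled = pooled, G = G, D1 = D1,
                       M4 = M4, D1d = D1d, B = B))
  }
  out
}

# Reverse pass. `dyraw` is dLoss/d(pre-activation output), length B.
# Returns gradients for every weight tensor and, if `input_grad`, the
# gradient with respect to the flattened input.
canya_backward <- function(model, fw, dyraw, input_grad = FALSE) {
  cfg <- model$config; W <- model$weights
  B <- fw$B; Fr <- cfg$n_frames; Fn <- cfg$n_filters; Kl <- cfg$key_len
  nc <- cfg$n_channels
  rows_frame <- rep(seq_len(Fr), each = B)
  g <- matrix(dyraw, ncol = 1)
  dwout <- crossprod(fw$D1d, g)
  dbout <- sum(g)
  dD1d <- g %*% t(W$wout)
  dD1 <- if (is.null(fw$M4)) dD1d else dD1d * fw$M4
  dG <- dD1 * (fw$G > 0)
  dWd <- crossprod(fw$pooled, dG)
  dbd <- colSums(dG)
  dpooled <- dG %*% t(W$Wd)
  dUd <- dpooled[rep(seq_len(B), Fr), , drop = FALSE] / Fr
  dU <- if (is.null(fw$M2)) dUd else dUd * fw$M2
  dWo <- crossprod(fw$O, dU)
  dbo <- colSums(dU)
  dO <- dU %*% t(W$Wo)
  sc <- 1 / sqrt(Kl)
  # batched attention backward in the same (B, Fr*Fr) layout as forward
  A <- fw$A
  ii <- rep(seq_len(Fr), times = Fr)
  jj <- rep(seq_len(Fr), each = Fr)
  cols_j <- lapply(seq_len(Fr), function(j) (j - 1L) * Fr + seq_len(Fr))
  dO3 <- dO; dim(dO3) <- c(B, Fr, Kl)
  Q3 <- fw$Q; dim(Q3) <- c(B, Fr, Kl)
  K3 <- fw$K; dim(K3) <- c(B, Fr, Kl)
  V3 <- fw$V; dim(V3) <- c(B, Fr, Kl)
  dV3 <- array(0, c(B, Fr, Kl))
  dA <- matrix(0, B, Fr * Fr)
  for (d in seq_len(Kl)) {
    dOd <- dO3[, , d]; dim(dOd) <- c(B, Fr)
    Vd <- V3[, , d]; dim(Vd) <- c(B, Fr)
    dA <- dA + dOd[, ii, drop = FALSE] * Vd[, jj, drop = FALSE]
    for (j in seq_len(Fr)) {
      dV3[, j, d] <- rowSums(A[, cols_j[[j]], drop = FALSE] * dOd)
    }
  }
  Tm <- matrix(0, B, Fr)  # per-(sample, query) sum of dA * A over keys
  for (j in seq_len(Fr)) {
    Tm <- Tm + dA[, cols_j[[j]], drop = FALSE] * A[, cols_j[[j]], drop = FALSE]
  }
  dS <- matrix(0, B, Fr * Fr)
  for (j in seq_len(Fr)) {
    dS[, cols_j[[j]]] <- A[, cols_j[[j]], drop = FALSE] *
      (dA[, cols_j[[j]], drop = FALSE] - Tm)
  }
  dQ3 <- array(0, c(B, Fr, Kl))
  dK3 <- array(0, c(B, Fr, Kl))
  for (d in seq_len(Kl)) {
    Kd <- K3[, , d]; dim(Kd) <- c(B, Fr)
    Qd <- Q3[, , d]; dim(Qd) <- c(B, Fr)
    accQ <- matrix(0, B, Fr)
    for (j in seq_len(Fr)) {
      dSj <- dS[, cols_j[[j]], drop = FALSE]
      accQ <- accQ + dSj * Kd[, j]
      dK3[, j, d] <- rowSums(dSj * Qd)
    }
    dQ3[, , d] <- accQ * sc
  }
  dK3 <- dK3 * sc
  dQ <- dQ3; dim(dQ) <- c(B * Fr, Kl)
  dK <- dK3; dim(dK) <- c(B * Fr, Kl)
  dV <- dV3; dim(dV) <- c(B * Fr, Kl)
  centre <- seq_len(Fr) + (cfg$filter_len %/% 2)
  dPkey <- matrix(0, cfg$input_len, Kl)
  dK_by_frame <- rowsum(dK, rows_frame)
  dPkey[centre, ] <- dK_by_frame
  dWq <- crossprod(fw$Fh, dQ); dbq <- colSums(dQ)
  dWk <- crossprod(fw$Fh, dK); dbk <- colSums(dK)
  dWv <- crossprod(fw$Fh, dV); dbv <- colSums(dV)
  dF <- dQ %*% t(W$Wq) + dK %*% t(W$Wk) + dV %*% t(W$Wv)
  dPcont <- rowsum(dF, rows_frame)
  dHd <- dF
  dH <- if (is.null(fw$M1)) dHd else dHd * fw$M1
  dZ <- dH * fw$H
  dWc <- matrix(0, cfg$filter_len * nc, Fn)
  dbc <- colSums(dZ)
  dXm <- if (input_grad) matrix(0, B, cfg$input_len * nc) else NULL
  for (i in seq_len(Fr)) {
    rws <- ((i - 1) * B + 1):(i * B)
    cols <- ((i - 1) * nc + 1):((i + cfg$filter_len - 1) * nc)
    dZi <- dZ[rws, , drop = FALSE]
    dWc <- dWc + crossprod(fw$Xm[, cols, drop = FALSE], dZi)
    if (input_grad) {
      dXm[, cols] <- dXm[, cols] + dZi %*% t(W$Wc)
    }
  }
  grads <- list(Wc = dWc, bc = dbc, Pcont = dPcont, Pkey = dPkey,
                Wq = dWq, bq = dbq, Wk = dWk, bk = dbk, Wv = dWv, bv = dbv,
                Wo = dWo, bo = dbo, Wd = dWd, bd = dbd,
                wout = dwout, bout = dbout)
  list(grads = grads, dXm = dXm)
}

# Chunked, dropout-free forward pass returning pre-activation scores.
forward_scores <- function(model, peptides, chunk = 2048L) {
  n <- length(peptides)
  out <- numeric(n)
  for (s in seq(1, n, by = chunk)) {
    idx <- s:min(s + chunk - 1, n)
    Xm <- encode_flat(peptides[idx])
    out[idx] <- canya_forward(model, Xm)$yraw
  }
  out
}

#' Pre-activation aggregation score
#'
#' The model score before the output sigmoid; all Global Importance
#' Analysis effects are computed on this scale.
#'
#' @param model A fitted model (or additive surrogate).
#' @param sequences Character vector of peptides (<= 20 residues).
#' @param ... Passed to methods.
#' @return Numeric vector of unbounded scores.
#' @export
pre_activation <- function(model, sequences, ...) UseMethod("pre_activation")

#' @export
pre_activation.canya_model <- function(model, sequences, ...) {
  forward_scores(model, sequences)
}

#' Predict aggregation probabilities
#'
#' Sequences of length <= 20 are scored directly; by default longer
#' sequences raise an error and should go through [predict_long()].
#'
#' @param object A `canya_model`.
#' @param sequences Character vector of peptides, or a data frame with an
#'   `aa_seq` column.
#' @param type `"prob"` (sigmoid probabilities) or `"score"`
#'   (pre-activation).
#' @param long `"error"` (default) or `"window"` to route long sequences
#'   through the sliding-window scorer.
#' @param summarizer Window summariser for `long = "window"`.
#' @param ... Unused.
#' @return A tibble with columns `aa_seq` and `score`.
#' @export
predict.canya_model <- function(object, sequences, type = c("prob", "score"),
                                long = c("error", "window"),
                                summarizer = "median", ...) {
  type <- match.arg(type)
  long <- match.arg(long)
  if (is.data.frame(sequences)) sequences <- sequences$aa_seq
  lens <- nchar(sequences)
  score <- numeric(length(sequences))
  short <- lens <= 20
  if (any(!short) && long == "error") {
    abort("sequences longer than 20 residues: use predict_long() or long = \"window\"")
  }
  if (any(short)) score[short] <- forward_scores(object, sequences[short])
  if (any(!short)) {
    score[!short] <- vapply(sequences[!short], function(s)
      predict_long(object, s, summarizer = summarizer, type = "score"),
      numeric(1))
  }
  if (type == "prob") score <- stats::plogis(score)
  tibble(aa_seq = sequences, score = score)
}

#' Score a long sequence by sliding windows
#'
#' Scores every overlapping length-20 window at stride 1 and summarises the
#' window scores (median by default; mean, min and max are selectable).
#'
#' @param model A `canya_model`.
#' @param sequence A single sequence of length >= 20.
#' @param summarizer One of `"median"`, `"mean"`, `"min"`, `"max"`.
#' @param type `"prob"` or `"score"`: scale on which windows are scored and
#'   summarised.
#' @return A single numeric score.
#' @export
predict_long <- function(model, sequence, summarizer = c("median", "mean",
                                                         "min", "max"),
                         type = c("prob", "score")) {
  summarizer <- match.arg(summarizer)
  type <- match.arg(type)
  L <- nchar(sequence)
  if (L < 20) {
    return(predict(model, sequence, type = type, long = "error")$score)
  }
  starts <- seq_len(L - 20 + 1)
  windows <- substring(sequence, starts, starts + 19)
  sc <- forward_scores(model, windows)
  if (type == "prob") sc <- stats::plogis(sc)
  fn <- switch(summarizer, median = stats::median, mean = mean,
               min = min, max = max)
  fn(sc)
}

#' Per-position filter activation energies
#'
#' Post-exponential convolution outputs for every fully contained 3-mer
#' position of a sequence of arbitrary length (>= filter length). No
#' padding is applied: row `p` is the activation of the kmer starting at
#' residue `p`.
#'
#' @param model A `canya_model`.
#' @param sequence A single sequence.
#' @return Matrix of dimension `(n_valid_kmer_positions, n_filters)`.
#' @export
filter_activations <- function(model, sequence) {
  cfg <- model$config
  assert_residues(sequence)
  L <- nchar(sequence)
  fl <- cfg$filter_len
  if (L < fl) abort("sequence shorter than the filter length")
  idx <- match(strsplit(sequence, "")[[1]], aa_alphabet())
  npos <- L - fl + 1
  patch <- matrix(0, npos, fl * cfg$n_channels)
  for (p in seq_len(npos)) {
    ch <- idx[p:(p + fl - 1)]
    patch[p, (seq_len(fl) - 1) * cfg$n_channels + ch] <- 1
  }
  exp(sweep(patch %*% model$weights$Wc, 2, model$weights$bc, `+`))
}

# Gradient of the pre-activation score with respect to the one-hot input,
# dropout-free. Returns a (B, 24, 20) array.
input_gradients <- function(model, peptides, chunk = 1024L) {
  n <- length(peptides)
  out <- array(0, dim = c(n, model$config$input_len, model$config$n_channels))
  for (s in seq(1, n, by = chunk)) {
    idx <- s:min(s + chunk - 1, n)
    Xm <- encode_flat(peptides[idx])
    fw <- canya_forward(model, Xm, training = FALSE, keep = TRUE)
    bw <- canya_backward(model, fw, rep(1, length(idx)), input_grad = TRUE)
    out[idx, , ] <- aperm(array(bw$dXm, dim = c(length(idx),
                                                model$config$n_channels,
                                                model$config$input_len)),
                          c(1, 3, 2))
  }
  out
}
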