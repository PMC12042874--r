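# Training protocol: Adam on binary cross-entropy (the binary KL divergence
# up to a label-entropy constant), validation-AUPR-monitored learning-rate
# decay and early stopping, elastic-net penalty on the attention-to-dense
# weights.

adam_init <- function(W) {
  list(m = lapply(W, function(w) w * 0),
       v = lapply(W, function(w) w * 0),
       t = 0)
}

adam_step <- function(W, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-7) {
  state$t <- state$t + 1
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(W)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    W[[nm]] <- W[[nm]] - lr * (state$m[[nm]] / bc1) /
      (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(W = W, state = state)
}

# Stratified validation split indices: `frac` of each label class (and
# library when present), seed-controlled.
stratified_split <- function(labels, frac, seed, strata = NULL) {
  key <- if (is.null(strata)) as.character(labels) else
    paste(strata, labels, sep = "\r")
  withr_seed(seed, {
    unlist(lapply(split(seq_along(labels), key), function(idx) {
      k <- max(1L, round(length(idx) * frac))
      sample(idx, k)
    }), use.names = FALSE)
  })
}

#' Train a model on a labelled dataset
#'
#' Minimises binary cross-entropy with Adam (default hyperparameters),
#' holding out a stratified validation fraction per library. The validation
#' AUPR is monitored every epoch: the learning rate decays by
#' `config$lr_factor` after `config$lr_patience` epochs without
#' improvement, training stops early after `config$early_stop_patience`
#' epochs without improvement, and the best-AUPR weights are restored.
#'
#' @param model A built `canya_model` (or a `canya_config` to build from).
#' @param data Tibble with columns `aa_seq` and `label` (0/1), optionally
#'   `library_id`.
#' @param val_fraction Stratified validation fraction (default 0.1).
#' @param epochs Optional override of `config$epochs`.
#' @param seed Optional override of `config$seed` for the training phase.
#' @param quiet Suppress per-epoch progress.
#' @return The trained model, with a `history` tibble (epoch, loss,
#'   validation AUPR, learning rate).
#' @export
canya_train <- function(model, data, val_fraction = 0.1, epochs = NULL,
                        seed = NULL, quiet = TRUE) {
  if (inherits(model, "canya_config")) model <- canya_build(model)
  cfg <- model$config
  if (!is.null(epochs)) cfg$epochs <- epochs
  seed <- seed %||% cfg$seed
  y <- as.numeric(data$label)
  if (length(unique(y)) < 2) abort("training data must contain both classes")
  strata <- if ("library_id" %in% names(data)) data$library_id else NULL
  val_idx <- stratified_split(y, val_fraction, seed + 101L, strata)
  if (length(unique(y[val_idx])) < 2 ||
      length(unique(y[-val_idx])) < 2) {
    abort("both classes must be present in train and validation splits")
  }
  Xm_all <- encode_flat(data$aa_seq)
  Xtr <- Xm_all[-val_idx, , drop = FALSE]; ytr <- y[-val_idx]
  Xva <- Xm_all[val_idx, , drop = FALSE]; yva <- y[val_idx]
  W <- model$weights
  state <- adam_init(W)
  lr <- cfg$learning_rate
  best <- list(aupr = -Inf, W = W, epoch = 0L)
  lr_wait <- 0L; stop_wait <- 0L
  hist <- list()
  n <- nrow(Xtr)
  withr_seed(seed, {
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample.int(n)
      tot_loss <- 0
      for (s in seq(1, n, by = cfg$batch_size)) {
        idx <- ord[s:min(s + cfg$batch_size - 1, n)]
        B <- length(idx)
        model$weights <- W
        fw <- canya_forward(model, Xtr[idx, , drop = FALSE],
                            training = TRUE, keep = TRUE)
        p <- fw$prob
        yb <- ytr[idx]
        eps <- 1e-12
        loss <- -mean(yb * log(p + eps) + (1 - yb) * log(1 - p + eps))
        dyraw <- (p - yb) / B
        bw <- canya_backward(model, fw, dyraw)
        g <- bw$grads
        if (cfg$elastic_net > 0) {
          g$Wd <- g$Wd + cfg$elastic_net * (sign(W$Wd) + 2 * W$Wd)
          loss <- loss + cfg$elastic_net *
            (sum(abs(W$Wd)) + sum(W$Wd^2))
        }
        upd <- adam_step(W, g, state, lr)
        W <- upd$W; state <- upd$state
        tot_loss <- tot_loss + loss * B
      }
      model$weights <- W
      val_score <- drop(canya_forward(model, Xva)$yraw)
      val_aupr <- aupr(val_score, yva)
      hist[[ep]] <- tibble(epoch = ep, loss = tot_loss / n,
                           val_aupr = val_aupr, lr = lr)
      if (!quiet) {
        inform(sprintf("epoch %3d  loss %.4f  val AUPR %.4f  lr %.2e",
                       ep, tot_loss / n, val_aupr, lr))
      }
      if (val_aupr > best$aupr) {
        best <- list(aupr = val_aupr, W = W, epoch = ep)
        lr_wait <- 0L; stop_wait <- 0L
      } else {
        lr_wait <- lr_wait + 1L
        stop_wait <- stop_wait + 1L
        if (lr_wait >= cfg$lr_patience) {
          lr <- lr * cfg$lr_factor
          lr_wait <- 0L
        }
        if (stop_wait >= cfg$early_stop_patience) break
      }
    }
  })
  model$weights <- best$W
  model$history <- bind_rows(hist)
  model$best_epoch <- best$epoch
  model$best_val_aupr <- best$aupr
  model$val_idx <- val_idx
  model$trained <- TRUE
  class(model$history) <- c("canya_history", class(model$history))
  model
}

#' Save / load a model checkpoint
#'
#' Checkpoints carry the weights, configuration, channel order and training
#' history.
#'
#' @param model A `canya_model`.
#' @param path File path.
#' @export
canya_save <- function(model, path) {
  saveRDS(unclass(model), path)
  invisible(path)
}

#' @rdname canya_save
#' @export
canya_load <- function(path) {
  obj <- readRDS(path)
  class(obj$config) <- "canya_config"
  if (!identical(obj$channel_order, aa_alphabet())) {
    abort("checkpoint channel order does not match this package's encoding")
  }
  structure(obj, class = "canya_model")
}
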