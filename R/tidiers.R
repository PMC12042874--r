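# broom-style tidiers and ggplot2 autoplot methods for fitted objects and
# result tables.

#' Tidy a fitted model
#'
#' One row per convolutional filter with its top-activating kmer and
#' maximum activation energy.
#'
#' @param x A `canya_model`.
#' @param ... Unused.
#' @return A tibble with `filter_id`, `top_kmer`, `max_activation`,
#'   `n_kmers_75pct`.
#' @method tidy canya_model
#' @export
tidy.canya_model <- function(x, ...) {
  rows <- lapply(seq_len(x$config$n_filters), function(f) {
    act <- kmer_activations(x, f)
    mx <- max(act)
    tibble(filter_id = f,
           top_kmer = names(act)[which.max(act)],
           max_activation = mx,
           n_kmers_75pct = sum(act >= 0.75 * mx))
  })
  bind_rows(rows)
}

#' Glance at a fitted model
#'
#' @param x A `canya_model`.
#' @param ... Unused.
#' @return One-row tibble: `n_params`, `n_filters`, `key_len`,
#'   `dense_units`, `trained`, `epochs_run`, `best_epoch`,
#'   `best_val_aupr`.
#' @method glance canya_model
#' @export
glance.canya_model <- function(x, ...) {
  tibble(
    n_params = attr(canya_param_count(x), "total"),
    n_filters = x$config$n_filters,
    key_len = x$config$key_len,
    dense_units = x$config$dense_units,
    trained = x$trained,
    epochs_run = if (is.null(x$history)) 0L else nrow(x$history),
    best_epoch = x$best_epoch %||% NA_integer_,
    best_val_aupr = x$best_val_aupr %||% NA_real_
  )
}

#' Tidy a motif PWM
#'
#' @param x A `canya_pwm`.
#' @param ... Unused.
#' @return Long tibble: `filter_id`, `position`, `residue`, `prob`.
#' @method tidy canya_pwm
#' @export
tidy.canya_pwm <- function(x, ...) {
  as_tibble(x$pwm) |>
    mutate(position = row_number(), filter_id = x$filter_id) |>
    tidyr::pivot_longer(cols = dplyr::all_of(aa_alphabet()),
                        names_to = "residue", values_to = "prob") |>
    select("filter_id", "position", "residue", "prob")
}

#' Plot training history
#'
#' Loss and validation AUPR per epoch.
#'
#' @param object A `canya_history` tibble (from `model$history`).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot canya_history
#' @export
autoplot.canya_history <- function(object, ...) {
  long <- tidyr::pivot_longer(as_tibble(object),
                              cols = c("loss", "val_aupr"),
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "epoch", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a motif PWM as a letter-height logo
#'
#' Residue letters stacked by per-position probability.
#'
#' @param object A `canya_pwm`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot canya_pwm
#' @export
autoplot.canya_pwm <- function(object, ...) {
  dat <- tidy.canya_pwm(object) |>
    filter(.data$prob > 0) |>
    arrange(.data$position, .data$prob) |>
    group_by(.data$position) |>
    mutate(ymax = cumsum(.data$prob), ymin = .data$ymax - .data$prob,
           ymid = (.data$ymin + .data$ymax) / 2) |>
    ungroup()
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$position, y = .data$ymid)) +
    ggplot2::geom_text(ggplot2::aes(label = .data$residue,
                                    size = .data$prob),
                       show.legend = FALSE) +
    ggplot2::scale_size(range = c(2, 10)) +
    ggplot2::scale_x_continuous(breaks = seq_len(nrow(object$pwm))) +
    ggplot2::labs(x = "motif position", y = "stacked probability",
                  title = sprintf("filter %d", object$filter_id)) +
    ggplot2::theme_minimal()
}

#' Plot GIA results
#'
#' Positional results are drawn as an importance profile over start
#' positions; other experiment types as point estimates with CIs.
#'
#' @param object A `canya_gia` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot canya_gia
#' @export
autoplot.canya_gia <- function(object, ...) {
  dat <- as_tibble(object)
  if (all(dat$experiment == "positional")) {
    ggplot2::ggplot(dat, ggplot2::aes(x = .data$position,
                                      y = .data$importance)) +
      ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_lo,
                                        ymax = .data$ci_hi), alpha = 0.2) +
      ggplot2::geom_line() +
      ggplot2::geom_hline(yintercept = attr(object, "global_importance"),
                          linetype = 2) +
      ggplot2::labs(x = "embedding start position", y = "GIA importance") +
      ggplot2::theme_minimal()
  } else if (all(dat$experiment == "multiplicity")) {
    ggplot2::ggplot(dat, ggplot2::aes(x = .data$copies,
                                      y = .data$importance)) +
      ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ci_lo,
                                            ymax = .data$ci_hi)) +
      ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                           linewidth = 0.3) +
      ggplot2::labs(x = "kmer copies", y = "GIA importance") +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(dat, ggplot2::aes(x = .data$feature_id,
                                      y = .data$importance)) +
      ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ci_lo,
                                            ymax = .data$ci_hi)) +
      ggplot2::geom_hline(yintercept = 0, linetype = 2) +
      ggplot2::coord_flip() +
      ggplot2::labs(x = NULL, y = "GIA importance") +
      ggplot2::theme_minimal()
  }
}

#' Tidy replicate summaries
#'
#' @param x A `canya_replicates` tibble.
#' @param ... Unused.
#' @return The underlying tibble.
#' @method tidy canya_replicates
#' @export
tidy.canya_replicates <- function(x, ...) as_tibble(x)

#' Plot replicate summaries
#'
#' Interpretability score against mean AUPR, one point per replicate.
#'
#' @param object A `canya_replicates` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot canya_replicates
#' @export
autoplot.canya_replicates <- function(object, ...) {
  per_model <- as_tibble(object) |>
    group_by(.data$model_id) |>
    summarise(mean_aupr = .data$mean_aupr[1],
              interpretability = .data$interpretability[1],
              .groups = "drop")
  ggplot2::ggplot(per_model, ggplot2::aes(x = .data$mean_aupr,
                                          y = .data$interpretability)) +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = stats::median(per_model$mean_aupr),
                        linetype = 2) +
    ggplot2::labs(x = "mean test AUPR", y = "interpretability (nats)") +
    ggplot2::theme_minimal()
}
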