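#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_col
#'   geom_hline labs theme_minimal
#' @export
ggplot2::autoplot

#' Plot the optimization trace of a fitted bilinear model
#'
#' Training (and, when recorded, holdout) R-squared per alternating
#' iteration of the chosen initialization.
#'
#' @param object A `tfa_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot tfa_fit
#' @export
autoplot.tfa_fit <- function(object, ...) {
  df <- tibble(iteration = seq_along(object$r2_train),
               set = "train", r2 = object$r2_train)
  if (!is.null(object$r2_holdout) && length(object$r2_holdout) > 0) {
    df <- dplyr::bind_rows(df,
      tibble(iteration = seq_along(object$r2_holdout),
             set = "holdout", r2 = object$r2_holdout))
  }
  ggplot(df, aes(x = .data$iteration, y = .data$r2, colour = .data$set)) +
    geom_line() + geom_point(size = 0.8) +
    labs(x = "alternating iteration", y = expression(R^2), colour = NULL) +
    theme_minimal()
}

#' Plot benchmark metrics with their chance levels
#'
#' @param object A `tfa_metrics`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot tfa_metrics
#' @export
autoplot.tfa_metrics <- function(object, ...) {
  df <- tibble(
    metric = factor(c("direction", "rank percentile", "TFA-mRNA corr."),
                    levels = c("direction", "rank percentile",
                               "TFA-mRNA corr.")),
    value = c(object$direction_fraction * 100,
              object$median_rank_percentile,
              object$positive_corr_fraction * 100),
    chance = c(50, 50, 50))
  df <- df[!is.na(df$value), , drop = FALSE]
  ggplot(df, aes(x = .data$metric, y = .data$value)) +
    geom_col(fill = "steelblue") +
    geom_hline(aes(yintercept = .data$chance), linetype = 2) +
    labs(x = NULL, y = "percent") +
    theme_minimal()
}

#' Plot a time series with its fitted curve
#'
#' @param object A `curve_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot curve_fit
#' @export
autoplot.curve_fit <- function(object, ...) {
  ts <- object$ts
  p <- ggplot(ts, aes(x = .data$time, y = .data$value)) +
    geom_point() +
    labs(x = "time (min)", y = "log2 fold change of activity") +
    theme_minimal()
  if (object$converged) {
    grid <- tibble(time = seq(min(ts$time), max(ts$time), length.out = 200))
    grid$value <- if (object$family == "sigmoid4") {
      do.call(sigmoid4, c(list(t = grid$time), object$params))
    } else {
      do.call(impulse6, c(list(t = grid$time), object$params))
    }
    p <- p + geom_line(data = grid, colour = "firebrick")
  }
  p
}
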