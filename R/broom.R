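#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a fitted bilinear model into an edge-level tibble
#'
#' @param x A `tfa_fit`.
#' @param ... Unused.
#' @return Tibble with one row per network edge: tf, target, constrained
#'   sign and fitted control strength.
#' @method tidy tfa_fit
#' @export
tidy.tfa_fit <- function(x, ...) {
  s <- as_tibble(x$signs)
  s <- s[s$target %in% rownames(x$cs$cs), , drop = FALSE]
  s$cs <- x$cs$cs[cbind(s$target, s$tf)]
  s
}

#' One-row summary of a fitted bilinear model
#'
#' @param x A `tfa_fit`.
#' @param ... Unused.
#' @return Tibble with fit dimensions, chosen initialization, iterations
#'   and final training / holdout R-squared.
#' @method glance tfa_fit
#' @export
glance.tfa_fit <- function(x, ...) {
  tibble(n_genes = nrow(x$cs$cs), n_tfs = ncol(x$cs$cs),
         n_samples = ncol(x$tfa),
         n_edges = sum(sign_matrix(x$signs, rownames(x$cs$cs),
                                   colnames(x$cs$cs)) != 0),
         chosen_init = x$chosen_init,
         iterations_run = x$iterations_run,
         r2_train = x$r2_train[x$iterations_run],
         r2_holdout = if (!is.null(x$r2_holdout))
           max(x$r2_holdout) else NA_real_)
}

#' @export
print.tfa_fit <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(paste0(
    "<tfa_fit> %d genes x %d TFs x %d samples, %d edges\n",
    "  init %d, %d iterations, train R^2 = %.4f%s\n"),
    g$n_genes, g$n_tfs, g$n_samples, g$n_edges, g$chosen_init,
    g$iterations_run, g$r2_train,
    if (is.na(g$r2_holdout)) ""
    else sprintf(", holdout R^2 = %.4f", g$r2_holdout)))
  invisible(x)
}

#' Tidy benchmark metrics into a per-TF tibble
#'
#' @param x A `tfa_metrics`.
#' @param ... Unused.
#' @return The per-TF detail table.
#' @method tidy tfa_metrics
#' @export
tidy.tfa_metrics <- function(x, ...) x$per_tf_detail

#' One-row summary of benchmark metrics
#'
#' @param x A `tfa_metrics`.
#' @param ... Unused.
#' @method glance tfa_metrics
#' @export
glance.tfa_metrics <- function(x, ...) {
  tibble(direction_fraction = x$direction_fraction,
         direction_p = x$direction_p,
         median_rank_percentile = x$median_rank_percentile,
         rank_p = x$rank_p,
         positive_corr_fraction = x$positive_corr_fraction,
         corr_p = x$corr_p)
}

#' Tidy a curve fit into a parameter tibble
#'
#' @param x A `curve_fit`.
#' @param ... Unused.
#' @method tidy curve_fit
#' @export
tidy.curve_fit <- function(x, ...) {
  if (!x$converged) return(tibble(term = character(0), estimate = numeric(0)))
  tibble(term = names(x$params), estimate = unlist(x$params))
}

#' One-row summary of a curve fit
#'
#' @param x A `curve_fit`.
#' @param ... Unused.
#' @method glance curve_fit
#' @export
glance.curve_fit <- function(x, ...) {
  tibble(family = x$family, converged = x$converged,
         r_squared = x$r_squared, bic = x$bic, direction = x$direction,
         n = x$n)
}

#' Glance at a protocol result
#'
#' @param x A `protocol_result`.
#' @param ... Unused.
#' @return One-row tibble of the combined metrics.
#' @method glance protocol_result
#' @export
glance.protocol_result <- function(x, ...) {
  as_tibble(x$combined)
}
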