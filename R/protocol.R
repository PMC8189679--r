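#' Run the three-stage train / refit / evaluate protocol
#'
#' Stage 1 uses dataset 1's expression and perturbation key for network
#' sign constraints and the initial fit (restricted to samples in which a
#' network TF was perturbed, plus unperturbed samples). Stage 2 fixes the
#' learned control strengths and refits activities and baselines to
#' dataset 2's expression with floor-only bounds — dataset 2's
#' perturbation key never reaches either fit. Stage 3 evaluates the
#' refitted activities against dataset 2's key (and TF mRNA, if present).
#' The roles of the datasets are then swapped and the two directions
#' combined: fractions and percentiles by their mean, p-values by Fisher's
#' combined probability test.
#'
#' During the initial fit, dataset 2's expression (only) serves as the
#' holdout for peak-based early stopping; set `use_holdout = FALSE` to
#' stop on training convergence instead.
#'
#' @param ds1,ds2 Lists with elements `expr` (genes x samples matrix),
#'   `key` (a `perturbation_key`) and optionally `tf_mrna`.
#' @param net A `tf_network`, or a `ranked_edges` list to build one from
#'   (with `net_config`).
#' @param sign_mode `"perturbation"` (signs from the training key) or
#'   `"correlation"` (signs from training TF mRNA / target correlations).
#' @param cs_mode `"optimized"` (ALS fit) or `"signed_binary"` (control
#'   strengths fixed at the constraint signs).
#' @param config A [fit_config()].
#' @param net_config A [network_build_config()] when `net` is a ranked
#'   edge list.
#' @param use_holdout Use the second dataset's expression for early
#'   stopping?
#' @param n_boot,eval_seed Bootstrap settings for the correlation metric.
#' @return An object of class `protocol_result`: `per_direction` (two
#'   `tfa_metrics`), `combined` (named list of averaged metrics and
#'   Fisher-combined p-values) and the per-direction fits.
#' @export
run_protocol <- function(ds1, ds2, net,
                         sign_mode = c("perturbation", "correlation"),
                         cs_mode = c("optimized", "signed_binary"),
                         config = fit_config(), net_config = network_build_config(),
                         use_holdout = TRUE, n_boot = 1000, eval_seed = 1) {
  sign_mode <- match.arg(sign_mode)
  cs_mode <- match.arg(cs_mode)
  if (inherits(net, "ranked_edges")) net <- build_network(net, net_config)
  one_direction <- function(train, test) {
    signs <- if (sign_mode == "perturbation") {
      perturbation_signs(train$expr, train$key, net)
    } else {
      if (is.null(train$tf_mrna))
        abort_input("correlation sign mode needs training tf_mrna")
      correlation_signs(train$expr, train$tf_mrna, net)
    }
    tfs <- network_tfs(net)
    if (cs_mode == "optimized") {
      fit <- fit_model(train$expr, net, signs, train$key, config,
                       holdout = if (use_holdout) test$expr else NULL)
      cs <- fit$cs
    } else {
      fit <- NULL
      genes <- intersect(rownames(train$expr), network_targets(net))
      cs <- signed_binary_cs(signs, genes = genes, tfs = tfs)
    }
    refit <- refit_activities(test$expr, cs,
                              floor_bounds(tfs, colnames(test$expr),
                                           config$floor),
                              config)
    metrics <- evaluate_activities(refit$tfa, test$key,
                                   tf_mrna = test$tf_mrna,
                                   n_boot = n_boot, seed = eval_seed,
                                   floor = config$floor)
    list(fit = fit, refit = refit, metrics = metrics)
  }
  d12 <- one_direction(ds1, ds2)
  d21 <- one_direction(ds2, ds1)
  m1 <- d12$metrics; m2 <- d21$metrics
  combined <- list(
    direction_fraction = mean(c(m1$direction_fraction, m2$direction_fraction)),
    direction_p = fisher_combine(c(m1$direction_p, m2$direction_p)),
    median_rank_percentile = mean(c(m1$median_rank_percentile,
                                    m2$median_rank_percentile)),
    rank_p = fisher_combine(c(m1$rank_p, m2$rank_p)),
    positive_corr_fraction = mean(c(m1$positive_corr_fraction,
                                    m2$positive_corr_fraction)),
    corr_p = if (!is.na(m1$corr_p) && !is.na(m2$corr_p))
      fisher_combine(c(m1$corr_p, m2$corr_p)) else NA_real_)
  structure(list(per_direction = list(m1, m2), combined = combined,
                 directions = list(d12 = d12, d21 = d21),
                 net = net, sign_mode = sign_mode, cs_mode = cs_mode),
            class = "protocol_result")
}

#' @export
print.protocol_result <- function(x, ...) {
  cat(sprintf(
    "Train/refit/evaluate protocol (%s signs, %s CS)\ncombined over both directions:\n",
    x$sign_mode, x$cs_mode))
  c <- x$combined
  cat(sprintf("  direction of perturbation : %.3f (p = %.3g)\n",
              c$direction_fraction, c$direction_p))
  cat(sprintf("  median rank percentile    : %.1f (p = %.3g)\n",
              c$median_rank_percentile, c$rank_p))
  if (!is.na(c$positive_corr_fraction))
    cat(sprintf("  positive TFA-mRNA corr.   : %.3f (p = %.3g)\n",
                c$positive_corr_fraction, c$corr_p))
  invisible(x)
}
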