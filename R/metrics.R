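#' Standardize activities to per-TF z-scores of log2 activity
#'
#' Each TF's activities are floored (so exact-zero deletion entries can be
#' logged), log2-transformed and standardized across samples to mean zero
#' and unit standard deviation; constant rows become all-zero. This makes
#' the activity levels of different TFs comparable for ranking.
#'
#' @param tfa TFs x samples activity matrix.
#' @param floor Positive floor applied before the log (default 1e-4).
#' @return TFs x samples matrix of z-scores.
#' @export
standardize_activities <- function(tfa, floor = 1e-4) {
  lg <- log2(pmax(tfa, floor))
  mu <- rowMeans(lg)
  sdv <- apply(lg, 1, stats::sd)
  z <- (lg - mu) / ifelse(sdv == 0, 1, sdv)
  z[sdv == 0, ] <- 0
  z
}

#' Direction-of-perturbation metric
#'
#' Fraction of perturbation samples in which the direction of the
#' perturbation is inferred correctly, given the identity of the perturbed
#' TF: a deletion is correct when the TF's activity in its perturbation
#' sample is below its activity in the unperturbed reference sample, an
#' overexpression when it is above. Ties count as incorrect. The p-value
#' is a two-sided binomial test against chance (0.5).
#'
#' @param tfa TFs x samples activity matrix (raw scale).
#' @param key A `perturbation_key` with an unperturbed reference sample.
#' @return `list(fraction, p_value, per_sample)` where `per_sample` is a
#'   tibble (sample, tf, direction, correct).
#' @export
direction_metric <- function(tfa, key) {
  ref <- key_reference(key)
  if (!ref %in% colnames(tfa))
    abort_input("reference sample '%s' absent from activity matrix", ref)
  rec <- key_records(key)
  rec <- rec[rec$sample %in% colnames(tfa), , drop = FALSE]
  drop <- !(rec$tf %in% rownames(tfa))
  if (any(drop)) {
    warn(sprintf("skipping %d samples whose perturbed TF is absent", sum(drop)))
    rec <- rec[!drop, , drop = FALSE]
  }
  act <- tfa[cbind(rec$tf, rec$sample)]
  act_ref <- tfa[rec$tf, ref]
  correct <- ifelse(rec$direction == "deletion", act < act_ref, act > act_ref)
  p <- stats::binom.test(sum(correct), length(correct), 0.5)$p.value
  list(fraction = mean(correct), p_value = p,
       per_sample = tibble(sample = rec$sample, tf = rec$tf,
                           direction = rec$direction, correct = correct))
}

#' Rank-percentile metric for perturbed TFs
#'
#' In each deletion sample, TFs are ranked by standardized log2 activity
#' from lowest (most negative) to highest; in each overexpression sample,
#' from highest to lowest. The perturbed TF's rank r among n TFs gives the
#' percentile 100 * (1 - (r - 1) / n); ties share the mean rank. The
#' median percentile across perturbation samples is reported with a
#' two-sided binomial sign test of the count of samples above the chance
#' median of 50.
#'
#' @param z Standardized TFs x samples activity matrix
#'   (from [standardize_activities()]).
#' @param key A `perturbation_key`.
#' @return `list(median_percentile, p_value, per_sample)`.
#' @export
rank_percentile_metric <- function(z, key) {
  rec <- key_records(key)
  rec <- rec[rec$sample %in% colnames(z) & rec$tf %in% rownames(z), ,
             drop = FALSE]
  if (nrow(rec) == 0) abort_input("no usable perturbation samples")
  n_tfs <- nrow(z)
  pct <- vapply(seq_len(nrow(rec)), function(i) {
    v <- z[, rec$sample[i]]
    r <- if (rec$direction[i] == "deletion") {
      rank(v, ties.method = "average")          # lowest first
    } else {
      rank(-v, ties.method = "average")         # highest first
    }
    100 * (1 - (r[rec$tf[i]] - 1) / n_tfs)
  }, 0.0)
  above <- sum(pct > 50)
  p <- stats::binom.test(above, length(pct), 0.5)$p.value
  list(median_percentile = stats::median(pct), p_value = p,
       per_sample = tibble(sample = rec$sample, tf = rec$tf,
                           direction = rec$direction, percentile = pct))
}

#' Positive TFA-mRNA correlation metric
#'
#' For each bootstrap resample of the shared samples (with replacement),
#' computes the Pearson correlation of each TF's raw (unlogged,
#' unstandardized) activity with its mRNA level and records the fraction
#' of TFs with a positive correlation; reports the median fraction across
#' bootstraps. TFs with zero variance in a resample are skipped for that
#' resample. The p-value is a two-sided binomial test of the TF count
#' implied by the median fraction against chance (0.5).
#'
#' @param tfa TFs x samples activity matrix (raw scale).
#' @param tf_mrna TFs x samples mRNA expression matrix.
#' @param n_boot Number of bootstrap resamples (default 1000).
#' @param seed Integer seed (fixed seed gives identical output).
#' @return `list(median_fraction, p_value, per_tf)` where `per_tf` holds
#'   each TF's full-sample correlation.
#' @export
positive_correlation_metric <- function(tfa, tf_mrna, n_boot = 1000,
                                        seed = 1) {
  tfs <- intersect(rownames(tfa), rownames(tf_mrna))
  samples <- intersect(colnames(tfa), colnames(tf_mrna))
  if (length(tfs) == 0 || length(samples) < 3)
    abort_input("activity and mRNA matrices share too few TFs or samples")
  A <- tfa[tfs, samples, drop = FALSE]
  M <- tf_mrna[tfs, samples, drop = FALSE]
  set.seed(seed)
  frac <- vapply(seq_len(n_boot), function(b) {
    idx <- sample.int(length(samples), replace = TRUE)
    r <- vapply(seq_along(tfs), function(j) {
      a <- A[j, idx]; m <- M[j, idx]
      if (stats::sd(a) == 0 || stats::sd(m) == 0) return(NA_real_)
      stats::cor(a, m)
    }, 0.0)
    mean(r > 0, na.rm = TRUE)
  }, 0.0)
  med <- stats::median(frac)
  k <- round(med * length(tfs))
  p <- stats::binom.test(k, length(tfs), 0.5)$p.value
  full <- vapply(seq_along(tfs), function(j) {
    if (stats::sd(A[j, ]) == 0 || stats::sd(M[j, ]) == 0) return(NA_real_)
    stats::cor(A[j, ], M[j, ])
  }, 0.0)
  list(median_fraction = med, p_value = p,
       per_tf = tibble(tf = tfs, cor = full))
}

#' Fisher's combined probability test
#'
#' Combines independent p-values via the chi-square statistic
#' `-2 * sum(log(p))` with `2 * length(p)` degrees of freedom.
#'
#' @param p_values Numeric vector of p-values in (0, 1].
#' @return Combined upper-tail probability.
#' @export
fisher_combine <- function(p_values) {
  if (any(p_values <= 0) || any(p_values > 1))
    abort_input("p-values must be in (0, 1]")
  x <- -2 * sum(log(p_values))
  stats::pchisq(x, df = 2 * length(p_values), lower.tail = FALSE)
}

#' Average standardized activities across networks
#'
#' For TFs present in two or more matrices, takes the elementwise mean of
#' their z-score rows over the shared samples; TFs present in exactly one
#' matrix pass through. Every output row is re-standardized. This lets
#' activities inferred from different network maps be combined into one
#' larger panel.
#'
#' @param z_list List of standardized TFs x samples matrices sharing
#'   sample ids.
#' @return Standardized TFs x samples matrix over the union of TFs.
#' @export
average_standardized_tfas <- function(z_list) {
  samples <- Reduce(intersect, lapply(z_list, colnames))
  if (length(samples) == 0) abort_input("matrices share no samples")
  tfs <- unique(unlist(lapply(z_list, rownames)))
  acc <- matrix(0, length(tfs), length(samples),
                dimnames = list(tfs, samples))
  n <- stats::setNames(numeric(length(tfs)), tfs)
  for (z in z_list) {
    r <- rownames(z)
    acc[r, ] <- acc[r, , drop = FALSE] + z[, samples, drop = FALSE]
    n[r] <- n[r] + 1
  }
  avg <- acc / n
  mu <- rowMeans(avg)
  sdv <- apply(avg, 1, stats::sd)
  out <- (avg - mu) / ifelse(sdv == 0, 1, sdv)
  out[sdv == 0, ] <- 0
  out
}

#' Recovery curve for regulators of TF activity
#'
#' In each sample where a known regulator of TF activity is perturbed, all
#' TFs are ranked by the absolute difference between their standardized
#' log activities in the perturbed and unperturbed samples (absolute,
#' because the direction of regulation is not always known). For each
#' percentile threshold, reports the fraction of gold-standard
#' regulator->TF edges whose target TF ranks above the threshold.
#'
#' @param z Standardized TFs x samples activity matrix including the
#'   reference sample.
#' @param key A `perturbation_key` mapping samples to perturbed regulators.
#' @param gold Tibble with columns `regulator`, `target` (a TF id).
#' @param thresholds Percentile grid (default 0..100).
#' @return Tibble (threshold, fraction_recovered) with attributes
#'   `per_edge` (edge-level percentiles) and `coverage` (gold edges whose
#'   target TF or regulator sample is unavailable).
#' @export
regulator_recovery_curve <- function(z, key, gold,
                                     thresholds = seq(0, 100, by = 1)) {
  ref <- key_reference(key)
  rec <- key_records(key)
  rec <- rec[rec$sample %in% colnames(z), , drop = FALSE]
  n_tfs <- nrow(z)
  rows <- list()
  missing <- list()
  for (i in seq_len(nrow(gold))) {
    regu <- gold$regulator[i]; tgt <- gold$target[i]
    smp <- rec$sample[rec$tf == regu]
    if (length(smp) == 0 || !(tgt %in% rownames(z))) {
      missing[[length(missing) + 1]] <- gold[i, ]
      next
    }
    for (s in smp) {
      dz <- abs(z[, s] - z[, ref])
      r <- rank(-dz, ties.method = "average")
      rows[[length(rows) + 1]] <-
        tibble(regulator = regu, target = tgt, sample = s,
               percentile = 100 * (1 - (r[tgt] - 1) / n_tfs))
    }
  }
  per_edge <- dplyr::bind_rows(rows)
  if (nrow(per_edge) == 0) abort_input("no gold edges evaluable")
  curve <- tibble(
    threshold = thresholds,
    fraction_recovered = vapply(thresholds,
                                function(t) mean(per_edge$percentile >= t),
                                0.0))
  attr(curve, "per_edge") <- per_edge
  attr(curve, "coverage") <- dplyr::bind_rows(missing)
  curve
}

#' Bootstrap correlation of control strengths with a covariate
#'
#' For each TF with at least `min_targets` network targets, resamples its
#' target set with replacement and computes the Pearson correlation of the
#' TF's control strengths against a per-target covariate (a second CS
#' matrix fitted independently, or e.g. per-target binding counts); scores
#' the TF by its median correlation across bootstraps. Degenerate
#' (zero-variance) resamples are skipped.
#'
#' @param cs_a A `cs_matrix`.
#' @param covariate Either a second `cs_matrix` or a named numeric vector
#'   of per-target values.
#' @param net A `tf_network` defining each TF's target set.
#' @param min_targets Minimum targets for a TF to qualify (default 5).
#' @param n_boot Bootstrap resamples (default 1000).
#' @param seed Integer seed.
#' @return Tibble (tf, n_targets, median_cor) with attributes
#'   `median_score` (median across TFs) and `fraction_positive`.
#' @export
bootstrap_cs_correlation <- function(cs_a, covariate, net, min_targets = 5,
                                     n_boot = 1000, seed = 1) {
  cov_is_cs <- inherits(covariate, "cs_matrix")
  set.seed(seed)
  rows <- list()
  for (tf in network_tfs(net)) {
    targets <- net$target[net$tf == tf]
    targets <- targets[targets %in% rownames(cs_a$cs)]
    if (cov_is_cs) targets <- targets[targets %in% rownames(covariate$cs)]
    else targets <- targets[targets %in% names(covariate)]
    if (length(targets) < min_targets) next
    a <- cs_a$cs[targets, tf]
    b <- if (cov_is_cs) covariate$cs[targets, tf] else covariate[targets]
    meds <- vapply(seq_len(n_boot), function(i) {
      idx <- sample.int(length(targets), replace = TRUE)
      if (stats::sd(a[idx]) == 0 || stats::sd(b[idx]) == 0) return(NA_real_)
      stats::cor(a[idx], b[idx])
    }, 0.0)
    rows[[tf]] <- tibble(tf = tf, n_targets = length(targets),
                         median_cor = stats::median(meds, na.rm = TRUE))
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) abort_input("no TF has >= %d targets", min_targets)
  attr(out, "median_score") <- stats::median(out$median_cor)
  attr(out, "fraction_positive") <- mean(out$median_cor > 0)
  out
}

#' Evaluate an activity matrix against a held-out perturbation key
#'
#' Bundles the three core accuracy metrics: direction of perturbation,
#' median rank percentile of the perturbed TF (on standardized log2
#' activities) and, when TF mRNA is supplied, the bootstrap
#' positive-correlation fraction.
#'
#' @param tfa TFs x samples activity matrix (raw scale).
#' @param key The evaluation `perturbation_key`.
#' @param tf_mrna Optional TFs x samples mRNA matrix.
#' @param n_boot,seed Bootstrap settings for the correlation metric.
#' @param floor Floor used when standardizing activities.
#' @return An object of class `tfa_metrics`.
#' @export
evaluate_activities <- function(tfa, key, tf_mrna = NULL, n_boot = 1000,
                                seed = 1, floor = 1e-4) {
  dir <- direction_metric(tfa, key)
  z <- standardize_activities(tfa, floor = floor)
  rk <- rank_percentile_metric(z, key)
  corr <- if (!is.null(tf_mrna)) {
    positive_correlation_metric(tfa, tf_mrna, n_boot = n_boot, seed = seed)
  }
  per_tf <- dir$per_sample |>
    dplyr::group_by(.data$tf) |>
    dplyr::summarise(direction_correct = mean(.data$correct),
                     .groups = "drop") |>
    dplyr::left_join(
      rk$per_sample |>
        dplyr::group_by(.data$tf) |>
        dplyr::summarise(rank_percentile = stats::median(.data$percentile),
                         .groups = "drop"),
      by = "tf")
  if (!is.null(corr)) per_tf <- dplyr::left_join(per_tf, corr$per_tf, by = "tf")
  structure(list(direction_fraction = dir$fraction,
                 direction_p = dir$p_value,
                 median_rank_percentile = rk$median_percentile,
                 rank_p = rk$p_value,
                 positive_corr_fraction = corr$median_fraction %||% NA_real_,
                 corr_p = corr$p_value %||% NA_real_,
                 per_tf_detail = per_tf),
            class = "tfa_metrics")
}

#' @export
print.tfa_metrics <- function(x, ...) {
  cat(sprintf(paste0(
    "TF activity benchmark metrics\n",
    "  direction of perturbation : %.3f (p = %.3g)\n",
    "  median rank percentile    : %.1f (p = %.3g)\n",
    "  positive TFA-mRNA corr.   : %s\n"),
    x$direction_fraction, x$direction_p,
    x$median_rank_percentile, x$rank_p,
    if (is.na(x$positive_corr_fraction)) "not computed"
    else sprintf("%.3f (p = %.3g)", x$positive_corr_fraction, x$corr_p)))
  invisible(x)
}
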