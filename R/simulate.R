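#' Configuration of the synthetic perturbation benchmark generator
#'
#' The generator emulates the structure of single-TF perturbation compendia:
#' one unperturbed (wild-type) sample plus one sample per TF deletion and
#' per TF overexpression, with TF-encoding mRNA rows kept separate from
#' target-gene rows.
#'
#' @param n_tfs Number of TFs (default 20).
#' @param n_genes Number of target genes (default 300).
#' @param targets_per_tf Integer range (length 2) of targets per TF
#'   (default 5..15; lower bound at least 2).
#' @param frac_activating Probability an edge activates (default 0.75).
#' @param cs_magnitude Range of absolute control strengths
#'   (default 0.5..2 log2 units per activity unit).
#' @param noise_sd Gaussian expression noise sd in log2 units
#'   (default 0.25).
#' @param ko_fraction,oe_fraction Fractions of TFs receiving a deletion /
#'   an overexpression sample (defaults 1 and 1: every TF gets both).
#' @param n_unperturbed Number of unperturbed samples (default 1); extra
#'   unperturbed samples draw fresh activities from the wild-type
#'   distribution.
#' @param oe_multiplier Overexpression activity as a multiple of the
#'   wild-type activity (default 4).
#' @param mrna_coupling Correlation between a TF's mRNA and its
#'   (standardized) activity (default 0.9).
#' @param activity_jitter_sd Lognormal sd (log scale) of sample-to-sample
#'   variation of non-perturbed activities around the wild-type level
#'   (default 0.1): TF activities fluctuate between conditions even when
#'   the TF itself is not the perturbation target.
#' @param baseline_range Range of per-gene baselines (default 4..10 log2
#'   units).
#' @param seed Integer seed; the same seed yields an identical dataset.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n_tfs = 20, n_genes = 300,
                             targets_per_tf = c(5, 15),
                             frac_activating = 0.75,
                             cs_magnitude = c(0.5, 2),
                             noise_sd = 0.25,
                             ko_fraction = 1, oe_fraction = 1,
                             n_unperturbed = 1,
                             oe_multiplier = 4,
                             mrna_coupling = 0.9,
                             activity_jitter_sd = 0.1,
                             baseline_range = c(4, 10),
                             seed = 1) {
  if (targets_per_tf[1] < 2) abort_input("targets_per_tf lower bound must be >= 2")
  if (n_genes < max(targets_per_tf)) abort_input("n_genes too small for targets_per_tf")
  if (mrna_coupling < 0 || mrna_coupling > 1) abort_input("mrna_coupling must be in [0,1]")
  structure(list(n_tfs = n_tfs, n_genes = n_genes,
                 targets_per_tf = targets_per_tf,
                 frac_activating = frac_activating,
                 cs_magnitude = cs_magnitude, noise_sd = noise_sd,
                 ko_fraction = ko_fraction, oe_fraction = oe_fraction,
                 n_unperturbed = n_unperturbed,
                 oe_multiplier = oe_multiplier,
                 mrna_coupling = mrna_coupling,
                 activity_jitter_sd = activity_jitter_sd,
                 baseline_range = baseline_range, seed = seed),
            class = "generator_config")
}

#' Generate a ground-truth regulatory model and perturbation design
#'
#' Samples a TF network with distinct multi-target TFs, activation /
#' repression edge signs, control strengths and per-gene baselines; builds
#' the perturbation design (one wild-type sample, one deletion sample per
#' KO-designated TF with that TF's activity pinned to zero, one
#' overexpression sample per OE-designated TF at `oe_multiplier` times its
#' wild-type activity); scales each TF's activity row to mean one across
#' samples; and draws TF mRNA as a mixture of the standardized activity
#' and independent noise with the configured coupling, rescaled to
#' expression-like units. Expression itself is generated separately by
#' [generate_expression()].
#'
#' @param config A [generator_config()].
#' @return A list of class `ground_truth` with `net`, `signs`, `cs`
#'   (a `cs_matrix`), `tfa`, `key`, `tf_mrna` and the config.
#' @export
generate_ground_truth <- function(config = generator_config()) {
  set.seed(config$seed)
  tfs <- sprintf("TF%02d", seq_len(config$n_tfs))
  genes <- sprintf("G%04d", seq_len(config$n_genes))
  # distinct multi-target sets; resample on the (rare) collision
  repeat {
    n_t <- sample(seq(config$targets_per_tf[1], config$targets_per_tf[2]),
                  config$n_tfs, replace = TRUE)
    sets <- lapply(n_t, function(k) sort(sample(genes, k)))
    if (!anyDuplicated(vapply(sets, paste, "", collapse = "\r"))) break
  }
  edges <- tibble(tf = rep(tfs, lengths(sets)),
                  target = unlist(sets))
  net <- tf_network(edges)
  sgn <- ifelse(stats::runif(nrow(edges)) < config$frac_activating, 1, -1)
  signs <- sign_constraints(tibble(tf = edges$tf, target = edges$target,
                                   sign = sgn), net = net)
  mag <- stats::runif(nrow(edges), config$cs_magnitude[1], config$cs_magnitude[2])
  csm <- matrix(0, config$n_genes, config$n_tfs,
                dimnames = list(genes, tfs))
  csm[cbind(edges$target, edges$tf)] <- sgn * mag
  baselines <- stats::setNames(
    stats::runif(config$n_genes, config$baseline_range[1],
                 config$baseline_range[2]), genes)
  # perturbation design
  n_ko <- round(config$ko_fraction * config$n_tfs)
  n_oe <- round(config$oe_fraction * config$n_tfs)
  ko_tfs <- tfs[seq_len(n_ko)]
  oe_tfs <- tfs[seq_len(n_oe)]
  n_wt <- max(1, config$n_unperturbed)
  wt_samples <- c("WT", if (n_wt > 1) sprintf("WT%d", seq_len(n_wt - 1) + 1))
  samples <- c(wt_samples,
               if (n_ko > 0) paste0("KO_", ko_tfs),
               if (n_oe > 0) paste0("OE_", oe_tfs))
  key <- perturbation_key(tibble(
    sample = samples,
    tf = c(rep(NA_character_, n_wt), ko_tfs, oe_tfs),
    direction = c(rep("none", n_wt), rep("deletion", n_ko),
                  rep("overexpression", n_oe))))
  wt <- stats::rlnorm(config$n_tfs, meanlog = 0, sdlog = 0.5)
  tfa <- matrix(rep(wt, length(samples)), config$n_tfs,
                dimnames = list(tfs, samples))
  if (config$activity_jitter_sd > 0 && length(samples) > 1) {
    # sample-to-sample fluctuation of non-perturbed activities
    jit <- matrix(stats::rlnorm(config$n_tfs * (length(samples) - 1),
                                0, config$activity_jitter_sd),
                  config$n_tfs)
    tfa[, -1] <- tfa[, -1] * jit
  }
  if (n_wt > 1) {
    extra <- matrix(stats::rlnorm(config$n_tfs * (n_wt - 1), 0, 0.5),
                    config$n_tfs)
    tfa[, wt_samples[-1]] <- extra
  }
  if (n_ko > 0) tfa[cbind(ko_tfs, paste0("KO_", ko_tfs))] <- 0
  if (n_oe > 0) tfa[cbind(oe_tfs, paste0("OE_", oe_tfs))] <-
      config$oe_multiplier * wt[match(oe_tfs, tfs)]
  tfa <- tfa / rowMeans(tfa)  # mean-one activity rows
  # TF mRNA couples to standardized activity
  zact <- t(scale(t(tfa)))
  zact[is.nan(zact)] <- 0
  noise <- matrix(stats::rnorm(length(zact)), nrow(zact))
  zm <- config$mrna_coupling * zact +
    sqrt(1 - config$mrna_coupling^2) * noise
  mrna_level <- stats::runif(config$n_tfs, config$baseline_range[1],
                             config$baseline_range[2])
  tf_mrna <- expression_matrix(
    matrix(zm + mrna_level, nrow(zm), dimnames = dimnames(tfa)))
  structure(list(net = net, signs = signs,
                 cs = cs_matrix(csm, baselines), tfa = tfa, key = key,
                 tf_mrna = tf_mrna, config = config),
            class = "ground_truth")
}

#' Generate an expression dataset from a ground truth
#'
#' Realizes the bilinear model: expression = baseline + CS x TFA plus
#' elementwise Gaussian noise. Rows are target genes only; TF-encoding
#' mRNA lives in the ground truth's `tf_mrna` matrix, mirroring the
#' removal of TF expression rows from fitting input.
#'
#' @param gt A `ground_truth`.
#' @param noise_sd Gaussian noise sd in log2 units (defaults to the
#'   generator config).
#' @param seed Integer seed for the noise draw.
#' @return Genes x samples expression matrix.
#' @export
generate_expression <- function(gt, noise_sd = gt$config$noise_sd, seed = 1) {
  set.seed(seed)
  mu <- predict_expression(gt$cs, gt$tfa)
  noise <- if (noise_sd > 0) {
    matrix(stats::rnorm(length(mu), 0, noise_sd), nrow(mu))
  } else 0
  expression_matrix(mu + noise)
}

#' Flip a fraction of each TF's constraint signs
#'
#' Simulates sign conflicts between perturbation datasets: for each TF in
#' `per_tf_conflict`, the stated fraction of its edges (rounded to a
#' count) has its sign flipped, chosen at random under the seed.
#'
#' @param signs A `sign_constraints` tibble.
#' @param per_tf_conflict Named numeric vector, TF -> conflict fraction in
#'   `[0, 1]`.
#' @param seed Integer seed.
#' @return A `sign_constraints` tibble with flipped entries.
#' @export
corrupt_signs <- function(signs, per_tf_conflict, seed = 1) {
  if (any(per_tf_conflict < 0 | per_tf_conflict > 1))
    abort_input("conflict fractions must be in [0, 1]")
  set.seed(seed)
  out <- as_tibble(signs)
  for (tf in names(per_tf_conflict)) {
    idx <- which(out$tf == tf)
    n_flip <- round(per_tf_conflict[[tf]] * length(idx))
    if (n_flip > 0) {
      flip <- sample(idx, n_flip)
      out$sign[flip] <- -out$sign[flip]
    }
  }
  sign_constraints(out)
}

#' Generate a noisy time series from a sigmoid or impulse curve
#'
#' Evaluates the chosen family at the supplied times, adds Gaussian noise
#' and prepends the (0, 0) anchor of a log fold-change series.
#'
#' @param family `"sigmoid4"` or `"impulse6"`.
#' @param params Named list of curve parameters for the family.
#' @param times Positive observation times (the 0 anchor is prepended).
#' @param noise_sd Gaussian noise sd.
#' @param seed Integer seed.
#' @return A `tfa_timeseries`.
#' @export
generate_timecourse <- function(family = c("sigmoid4", "impulse6"), params,
                                times, noise_sd = 0, seed = 1) {
  family <- match.arg(family)
  set.seed(seed)
  y <- if (family == "sigmoid4") {
    do.call(sigmoid4, c(list(t = times), params))
  } else {
    do.call(impulse6, c(list(t = times), params))
  }
  if (noise_sd > 0) y <- y + stats::rnorm(length(y), 0, noise_sd)
  time_series(c(0, times), c(0, y))
}
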