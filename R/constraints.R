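#' Sign constraints from TF-mRNA / target correlations
#'
#' For each network edge, the control-strength sign is set to the sign of
#' the Pearson correlation between the TF's mRNA profile and the target's
#' expression profile across all samples of the constraint dataset — used
#' even when the correlation is not significant. An exactly zero
#' correlation defaults to +1 (activation, the majority class) with a
#' warning.
#'
#' @param expr Genes x samples expression matrix (target genes).
#' @param tf_mrna TFs x samples expression matrix with a row per network TF.
#' @param net A `tf_network`.
#' @return A `sign_constraints` tibble covering exactly the network edges.
#' @export
correlation_signs <- function(expr, tf_mrna, net) {
  tfs <- network_tfs(net)
  missing_tf <- setdiff(tfs, rownames(tf_mrna))
  if (length(missing_tf) > 0)
    abort_input("tf_mrna lacks a row for TF '%s'", missing_tf[1])
  missing_g <- setdiff(network_targets(net), rownames(expr))
  if (length(missing_g) > 0)
    abort_input("expression matrix lacks a row for target '%s'", missing_g[1])
  samples <- intersect(colnames(tf_mrna), colnames(expr))
  if (length(samples) < 3)
    abort_input("need >= 3 shared samples to correlate")
  zv_tf <- tfs[apply(tf_mrna[tfs, samples, drop = FALSE], 1, stats::sd) == 0]
  if (length(zv_tf) > 0)
    abort_input("zero-variance TF mRNA row: %s", zv_tf[1])
  zv_g <- network_targets(net)[
    apply(expr[network_targets(net), samples, drop = FALSE], 1, stats::sd) == 0]
  if (length(zv_g) > 0)
    abort_input("zero-variance target expression row: %s", zv_g[1])
  r <- vapply(seq_len(nrow(net)), function(i) {
    stats::cor(tf_mrna[net$tf[i], samples], expr[net$target[i], samples])
  }, 0.0)
  if (any(r == 0))
    warn(sprintf("%d edges with exactly zero correlation set to +1", sum(r == 0)))
  sign_constraints(tibble(tf = net$tf, target = net$target,
                          sign = ifelse(r >= 0, 1, -1)),
                   net = net)
}

#' Sign constraints from perturbation responses
#'
#' For each edge, compares the target's expression in the TF's perturbation
#' sample(s) to the designated unperturbed reference. A deletion that
#' lowers the target implies activation (+1) and one that raises it implies
#' repression (-1); overexpression works the other way round. Multiple
#' perturbation samples of the same TF vote by the sign of the mean
#' (direction-oriented) change. A net zero change defaults to +1 with a
#' warning.
#'
#' @param expr Genes x samples expression matrix containing the
#'   perturbation and reference samples.
#' @param key A `perturbation_key`; every network TF needs at least one
#'   perturbation sample.
#' @param net A `tf_network`.
#' @return A `sign_constraints` tibble covering exactly the network edges.
#' @export
perturbation_signs <- function(expr, key, net) {
  ref <- key_reference(key)
  if (!ref %in% colnames(expr))
    abort_input("reference sample '%s' absent from expression matrix", ref)
  rec <- key_records(key)
  rec <- rec[rec$sample %in% colnames(expr), , drop = FALSE]
  tfs <- network_tfs(net)
  no_pert <- setdiff(tfs, rec$tf)
  if (length(no_pert) > 0)
    abort_input("network TF '%s' has no perturbation sample", no_pert[1])
  signs <- numeric(nrow(net))
  for (i in seq_len(nrow(net))) {
    r <- rec[rec$tf == net$tf[i], , drop = FALSE]
    delta <- expr[net$target[i], r$sample] - expr[net$target[i], ref]
    # orient so positive evidence means activation
    oriented <- ifelse(r$direction == "deletion", -delta, delta)
    signs[i] <- sign(mean(oriented))
  }
  if (any(signs == 0)) {
    warn(sprintf("%d edges with zero perturbation response set to +1",
                 sum(signs == 0)))
    signs[signs == 0] <- 1
  }
  sign_constraints(tibble(tf = net$tf, target = net$target, sign = signs),
                   net = net)
}

#' Per-entry activity bounds from a perturbation key
#'
#' Deletion entries are pinned to zero; overexpression entries get a
#' deferred lower bound equal to the same TF's fitted activity in the
#' designated unperturbed sample plus the floor (resolved inside
#' [tfa_step()], which solves the reference sample first); all other
#' entries are bounded below by the activity floor.
#'
#' @param key A `perturbation_key`; must include an unperturbed sample when
#'   overexpression records are present.
#' @param tfs Character vector of TF ids.
#' @param samples Ordered character vector of sample ids (must include the
#'   key's samples).
#' @param floor Positive activity floor (default 1e-4).
#' @return An object of class `activity_bounds` with `lower`/`upper`
#'   TFs x samples matrices, the floor, the deferred overexpression entries
#'   and the reference sample.
#' @export
activity_bounds <- function(key, tfs, samples, floor = 1e-4) {
  if (floor <= 0) abort_input("floor must be positive")
  lower <- matrix(floor, length(tfs), length(samples),
                  dimnames = list(tfs, samples))
  upper <- matrix(Inf, length(tfs), length(samples),
                  dimnames = list(tfs, samples))
  rec <- key_records(key)
  rec <- rec[rec$sample %in% samples & rec$tf %in% tfs, , drop = FALSE]
  del <- rec[rec$direction == "deletion", , drop = FALSE]
  oe <- rec[rec$direction == "overexpression", , drop = FALSE]
  lower[cbind(del$tf, del$sample)] <- 0
  upper[cbind(del$tf, del$sample)] <- 0
  reference <- NA_character_
  if (nrow(oe) > 0) {
    reference <- key_reference(key)
    if (!reference %in% samples)
      abort_input("overexpression bounds need unperturbed sample '%s' present",
                  reference)
  }
  structure(list(lower = lower, upper = upper, floor = floor,
                 oe = oe[, c("tf", "sample")], reference = reference),
            class = "activity_bounds")
}

#' Floor-only activity bounds
#'
#' Bounds that encode no perturbation information: every activity is only
#' required to be at least the floor. Used when refitting activities to a
#' dataset whose perturbation key is reserved for evaluation.
#'
#' @param tfs,samples Identifiers of the bound matrix.
#' @param floor Positive activity floor (default 1e-4).
#' @return An `activity_bounds` object.
#' @export
floor_bounds <- function(tfs, samples, floor = 1e-4) {
  activity_bounds(perturbation_key(tibble(sample = character(0),
                                          tf = character(0),
                                          direction = character(0))),
                  tfs, samples, floor = floor)
}
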