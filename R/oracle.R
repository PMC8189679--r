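#' Multi-start projected-gradient solver for the full bilinear objective
#'
#' Minimizes the whole-model sum of squared errors
#' `||E - b - CS %*% TFA||^2` jointly over control strengths, baselines and
#' activities by projected gradient descent with backtracking line search,
#' from several random feasible starts. Serves as an independent reference
#' solver for validating the alternating least-squares fitter on small
#' instances: it optimizes all parameter blocks at once rather than
#' block-wise.
#'
#' Supports fixed box bounds on activities only (deletion pins and floors);
#' deferred overexpression bounds are not expressible as a fixed box and
#' are rejected.
#'
#' @param expr Genes x samples expression matrix.
#' @param signs A `sign_constraints` tibble (defines edges and CS signs).
#' @param bounds An `activity_bounds` without overexpression entries.
#' @param n_restarts Random restarts (default 20).
#' @param max_iter Gradient iterations per restart (default 2000).
#' @param seed Integer seed.
#' @return `list(sse, cs, tfa)` for the best restart.
#' @export
bilinear_oracle <- function(expr, signs, bounds, n_restarts = 20,
                            max_iter = 2000, seed = 1) {
  if (nrow(bounds$oe) > 0)
    abort_input("oracle supports fixed box bounds only (no overexpression)")
  genes <- rownames(expr)
  tfs <- rownames(bounds$lower)
  samples <- colnames(expr)
  smat <- sign_matrix(signs, genes, tfs)
  lo <- bounds$lower[, samples, drop = FALSE]
  up <- bounds$upper[, samples, drop = FALSE]
  proj_cs <- function(cs) {
    cs[smat == 0] <- 0
    cs[smat > 0] <- pmax(cs[smat > 0], 0)
    cs[smat < 0] <- pmin(cs[smat < 0], 0)
    cs
  }
  obj <- function(cs, b, tfa) sum((expr - b - cs %*% tfa)^2)
  set.seed(seed)
  best <- list(sse = Inf)
  for (rs in seq_len(n_restarts)) {
    cs <- proj_cs(smat * matrix(stats::runif(length(smat), 0.2, 2.0),
                                nrow(smat)))
    b <- rowMeans(expr)
    tfa <- pmin(pmax(matrix(abs(stats::rnorm(length(tfs) * length(samples),
                                             1, 0.5)),
                            length(tfs),
                            dimnames = list(tfs, samples)), lo), up)
    f <- obj(cs, b, tfa)
    step <- 1 / max(1, sum(expr^2))
    for (it in seq_len(max_iter)) {
      R <- cs %*% tfa + b - expr  # b recycles down columns (per-gene)
      g_cs <- 2 * (R %*% t(tfa))
      g_b <- 2 * rowSums(R)
      g_tfa <- 2 * (t(cs) %*% R)
      improved <- FALSE
      for (bt in 1:40) {
        cs2 <- proj_cs(cs - step * g_cs)
        b2 <- b - step * g_b
        tfa2 <- pmin(pmax(tfa - step * g_tfa, lo), up)
        f2 <- obj(cs2, b2, tfa2)
        if (f2 < f) {
          improved <- TRUE
          break
        }
        step <- step / 2
      }
      if (!improved) break
      conv <- (f - f2) < 1e-12 * max(f, 1e-300)
      cs <- cs2; b <- b2; tfa <- tfa2; f <- f2
      step <- step * 1.5
      if (conv) break
    }
    if (f < best$sse)
      best <- list(sse = f, cs = cs_matrix(cs, b), tfa = tfa)
  }
  best
}
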