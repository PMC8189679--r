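#' Fit configuration for the alternating constrained least-squares fitter
#'
#' @param n_inits Number of random sign-respecting initializations of the
#'   control-strength matrix (default 20).
#' @param max_iter Maximum alternating iterations per initialization
#'   (default 100).
#' @param floor Positive activity floor (default 1e-4): all activities
#'   except deletion entries are constrained to be at least this.
#' @param seed Integer seed fixing initialization and tie-breaks; an
#'   identical seed gives an identical fit.
#' @param stopping `"holdout_peak"` stops when holdout R-squared stops
#'   improving (requires a holdout dataset); `"train_converge"` stops when
#'   the relative training SSE change drops below `train_tol`.
#' @param train_tol Relative SSE change threshold (default 1e-6).
#' @param patience Iterations without holdout improvement before stopping
#'   at the recorded peak (default 3).
#' @param holdout_alternations Alternations of the holdout activity refit
#'   run after each training iteration (default 10).
#' @param exclude_deletions_from_mean Exclude deletion (zero) entries from
#'   the mean-one activity normalization? Default `FALSE` (the mean runs
#'   across all samples).
#' @return A list of class `fit_config`.
#' @export
fit_config <- function(n_inits = 20, max_iter = 100, floor = 1e-4,
                       seed = 1,
                       stopping = c("holdout_peak", "train_converge"),
                       train_tol = 1e-6, patience = 3,
                       holdout_alternations = 10,
                       exclude_deletions_from_mean = FALSE) {
  stopping <- match.arg(stopping)
  if (n_inits < 1 || max_iter < 1) abort_input("n_inits and max_iter must be >= 1")
  structure(list(n_inits = n_inits, max_iter = max_iter, floor = floor,
                 seed = seed, stopping = stopping, train_tol = train_tol,
                 patience = patience,
                 holdout_alternations = holdout_alternations,
                 exclude_deletions_from_mean = exclude_deletions_from_mean),
            class = "fit_config")
}

#' Control-strength update step
#'
#' With activities fixed, solves one constrained least-squares problem per
#' gene: minimize the squared reconstruction error over the gene's baseline
#' (unconstrained) and its control strengths, subject to each control
#' strength having the constrained sign (and zero off the network).
#'
#' @param expr Genes x samples expression matrix.
#' @param tfa TFs x samples activity matrix (fixed).
#' @param signs A `sign_constraints` tibble defining the edges and signs.
#' @return A `cs_matrix`.
#' @export
cs_step <- function(expr, tfa, signs) {
  genes <- rownames(expr)
  tfs <- rownames(tfa)
  samples <- colnames(expr)
  M <- cbind(1, t(tfa[, samples, drop = FALSE]))  # samples x (1 + TFs)
  G <- crossprod(M)
  GY <- crossprod(M, t(expr))                     # (1 + TFs) x genes
  smat <- sign_matrix(signs, genes, tfs)
  cs <- matrix(0, length(genes), length(tfs), dimnames = list(genes, tfs))
  baselines <- numeric(length(genes))
  for (i in seq_along(genes)) {
    J <- which(smat[i, ] != 0)
    sol <- cs_solve_gene_ne(G, GY[, i], J, smat[i, J])
    baselines[i] <- sol$baseline
    cs[i, J] <- sol$cs
  }
  names(baselines) <- genes
  cs_matrix(cs, baselines)
}

#' Activity update step
#'
#' With control strengths and baselines fixed, solves one bounded
#' least-squares problem per sample. Deletion entries are pinned at zero;
#' the designated unperturbed reference sample is solved first so that
#' deferred overexpression lower bounds (reference activity + floor)
#' resolve against freshly fitted values; all other entries are bounded
#' below by the floor.
#'
#' @param expr Genes x samples expression matrix.
#' @param cs A `cs_matrix` (fixed).
#' @param bounds An `activity_bounds` object.
#' @return TFs x samples activity matrix.
#' @export
tfa_step <- function(expr, cs, bounds) {
  genes <- intersect(rownames(expr), rownames(cs$cs))
  if (length(genes) == 0) abort_input("no genes shared with the CS matrix")
  expr <- expr[genes, , drop = FALSE]
  X <- cs$cs[genes, , drop = FALSE]
  tfs <- colnames(X)
  samples <- colnames(expr)
  Y <- sweep(expr, 1, cs$baselines[genes], "-")
  lower <- bounds$lower[tfs, samples, drop = FALSE]
  upper <- bounds$upper[tfs, samples, drop = FALSE]
  if (any(lower > upper)) abort_input("infeasible activity bounds")
  tfa <- matrix(0, length(tfs), length(samples),
                dimnames = list(tfs, samples))
  oe_samples <- unique(bounds$oe$sample)
  order_k <- c(setdiff(samples, oe_samples), intersect(samples, oe_samples))
  XtX <- crossprod(X)
  XtY <- crossprod(X, Y)
  # batch unconstrained solution shared by all samples
  B0 <- tryCatch(solve(XtX, XtY), error = function(e) NULL)
  for (k in order_k) {
    lo <- lower[, k]
    fixed <- upper[, k] == 0 & lo == 0
    if (!any(fixed) && !is.null(B0) && all(B0[, k] >= lo - 1e-12)) {
      tfa[, k] <- pmax(B0[, k], lo)
    } else {
      J <- which(!fixed)
      tfa[J, k] <- ls_lower_bounded_ne(XtX[J, J, drop = FALSE], XtY[J, k],
                                       lo[J])
    }
    if (!is.na(bounds$reference) && k == bounds$reference) {
      # resolve deferred overexpression lower bounds
      oe_idx <- cbind(bounds$oe$tf, bounds$oe$sample)
      lower[oe_idx] <- pmax(lower[oe_idx],
                            tfa[bounds$oe$tf, k] + bounds$floor)
    }
  }
  tfa
}

#' Normalize activities to mean one per TF
#'
#' Divides each TF's activity row by its mean across samples and multiplies
#' the TF's control-strength column by the same factor, leaving the product
#' CS x TFA (and hence all predictions) unchanged. Baselines are untouched.
#' Deletion (zero) entries are included in the mean by default.
#'
#' @param cs A `cs_matrix`.
#' @param tfa TFs x samples activity matrix.
#' @param key Optional `perturbation_key`, used only when
#'   `exclude_deletions = TRUE` to drop deletion entries from the mean.
#' @param exclude_deletions Exclude deletion entries from the mean?
#' @return `list(cs, tfa)` with mean-one activity rows.
#' @export
normalize_mean_activity <- function(cs, tfa, key = NULL,
                                    exclude_deletions = FALSE) {
  m <- rowMeans(tfa)
  if (exclude_deletions && !is.null(key)) {
    del <- key_records(key)
    del <- del[del$direction == "deletion" & del$tf %in% rownames(tfa) &
                 del$sample %in% colnames(tfa), , drop = FALSE]
    mask <- matrix(TRUE, nrow(tfa), ncol(tfa), dimnames = dimnames(tfa))
    mask[cbind(del$tf, del$sample)] <- FALSE
    m <- rowSums(tfa * mask) / rowSums(mask)
  }
  if (any(m == 0))
    abort_input("TF '%s' has zero mean activity", rownames(tfa)[m == 0][1])
  tfa_n <- tfa / m
  cs_n <- sweep(cs$cs, 2, m[colnames(cs$cs)], "*")
  list(cs = cs_matrix(cs_n, cs$baselines), tfa = tfa_n)
}

#' Variance explained by a fitted bilinear model
#'
#' R-squared of the reconstruction baseline + CS x TFA against the
#' expression matrix, with the total sum of squares taken around each
#' gene's mean across samples.
#'
#' @param expr Genes x samples expression matrix.
#' @param cs A `cs_matrix`.
#' @param tfa TFs x samples activity matrix.
#' @return R-squared (at most 1).
#' @export
variance_explained <- function(expr, cs, tfa) {
  genes <- intersect(rownames(expr), rownames(cs$cs))
  pred <- predict_expression(cs_subset(cs, genes), tfa[, colnames(expr), drop = FALSE])
  obs <- expr[genes, , drop = FALSE]
  sst <- sum((obs - rowMeans(obs))^2)
  if (sst == 0) abort_input("zero total sum of squares")
  1 - sum((obs - pred)^2) / sst
}

cs_subset <- function(cs, genes) {
  cs_matrix(cs$cs[genes, , drop = FALSE], cs$baselines[genes])
}

model_sse <- function(expr, cs, tfa) {
  sum((expr - predict_expression(cs, tfa))^2)
}

#' Signed-binary control strengths
#'
#' Fixes each edge's control strength at +1 (activation) or -1
#' (repression) per the sign constraints, with all baselines zero (they
#' are refit downstream); used as an unoptimized comparison point.
#'
#' @param signs A `sign_constraints` tibble.
#' @param genes,tfs Optional identifiers for the matrix; default to those
#'   appearing in `signs`.
#' @return A `cs_matrix`.
#' @export
signed_binary_cs <- function(signs, genes = unique(signs$target),
                             tfs = unique(signs$tf)) {
  m <- sign_matrix(signs, genes, tfs)
  cs_matrix(m + 0, stats::setNames(numeric(length(genes)), genes))
}

# One random sign-respecting CS initialization. The augmented CS matrix
# includes the baselines, so they are randomized too (per-gene mean plus
# noise at the row's scale): diversifying the baselines is what actually
# spreads restarts across basins of the bilinear objective.
random_cs_init <- function(signs, genes, tfs, base_means, base_sds) {
  smat <- sign_matrix(signs, genes, tfs)
  mag <- matrix(stats::runif(length(smat), 0.2, 2.0), nrow(smat))
  b <- base_means + stats::rnorm(length(genes), 0, pmax(base_sds, 0.1))
  cs_matrix(smat * mag, stats::setNames(b, genes))
}

#' Fit the constrained bilinear model by alternating least squares
#'
#' Factors log2 expression into control strengths (genes x TFs, sign
#' constrained, zero off-network, plus per-gene baselines) and
#' non-negative TF activities (bounded by the perturbation key: deletions
#' pinned at zero, overexpression at least the unperturbed activity), by
#' alternating exact constrained least-squares updates of the two blocks
#' from several random initializations. After each iteration the mean
#' activity of every TF is normalized to one. When a holdout expression
#' matrix is supplied, activities and baselines are refit to it after each
#' iteration (its perturbation key is never used) and training halts when
#' holdout R-squared peaks; otherwise training runs to SSE convergence.
#' The initialization with the best stopping-criterion R-squared wins.
#'
#' Only samples in which a network TF is perturbed, plus unperturbed
#' samples, are used. Gene rows with zero variance are dropped with a
#' warning. TF-encoding genes are expected to be absent from `expr`.
#'
#' @param expr Genes x samples log2 expression matrix (target genes only).
#' @param net A `tf_network`.
#' @param signs A `sign_constraints` tibble for the network edges.
#' @param key The training dataset's `perturbation_key`.
#' @param config A [fit_config()].
#' @param holdout Optional holdout expression matrix (genes x samples) for
#'   peak-based early stopping.
#' @return An object of class `tfa_fit` with elements `cs` (a
#'   `cs_matrix`), `tfa`, `r2_train`, `r2_holdout`, `chosen_init`,
#'   `iterations_run`, `net`, `signs`.
#' @export
fit_model <- function(expr, net, signs, key, config = fit_config(),
                      holdout = NULL) {
  tfs <- network_tfs(net)
  rec <- key_records(key)
  keep_samples <- intersect(
    colnames(expr),
    c(rec$sample[rec$tf %in% tfs], key_unperturbed(key)))
  if (length(keep_samples) < 2)
    abort_input("fewer than 2 usable samples after perturbation filtering")
  genes <- intersect(rownames(expr), network_targets(net))
  expr <- expr[genes, keep_samples, drop = FALSE]
  zv <- apply(expr, 1, stats::sd) == 0
  if (any(zv)) {
    warn(sprintf("dropping %d zero-variance gene rows", sum(zv)))
    expr <- expr[!zv, , drop = FALSE]
    genes <- rownames(expr)
  }
  bounds <- activity_bounds(key, tfs, keep_samples, floor = config$floor)
  use_holdout <- !is.null(holdout) && config$stopping == "holdout_peak"
  if (use_holdout) {
    h_genes <- intersect(rownames(holdout), genes)
    holdout <- holdout[h_genes, , drop = FALSE]
  }
  base_means <- rowMeans(expr)
  base_sds <- apply(expr, 1, stats::sd)
  sst <- sum((expr - base_means)^2)

  set.seed(config$seed)
  best <- NULL
  for (init in seq_len(config$n_inits)) {
    cs <- random_cs_init(signs, genes, tfs, base_means, base_sds)
    r2_train <- numeric(0)
    r2_hold <- numeric(0)
    peak <- list(r2 = -Inf, cs = NULL, tfa = NULL, iter = 0)
    stall <- 0
    prev_sse <- Inf
    tfa <- NULL
    for (it in seq_len(config$max_iter)) {
      tfa <- tfa_step(expr, cs, bounds)
      cs <- cs_step(expr, tfa, signs)
      nrm <- normalize_mean_activity(cs, tfa, key,
                                     config$exclude_deletions_from_mean)
      cs <- nrm$cs; tfa <- nrm$tfa
      sse <- model_sse(expr, cs, tfa)
      r2_train <- c(r2_train, 1 - sse / sst)
      if (use_holdout) {
        hr <- refit_activities(holdout, cs,
                               floor_bounds(tfs, colnames(holdout),
                                            config$floor),
                               config,
                               max_alt = config$holdout_alternations)
        r2_hold <- c(r2_hold, hr$r2)
        if (hr$r2 > peak$r2 + 1e-9) {
          peak <- list(r2 = hr$r2, cs = cs, tfa = tfa, iter = it)
          stall <- 0
        } else {
          stall <- stall + 1
          if (stall >= config$patience) break
        }
      } else {
        if (is.finite(prev_sse) &&
            (prev_sse - sse) <= config$train_tol * max(prev_sse, 1e-300))
          break
      }
      prev_sse <- sse
    }
    if (!use_holdout || is.null(peak$cs))
      peak <- list(r2 = utils::tail(r2_train, 1), cs = cs, tfa = tfa,
                   iter = length(r2_train))
    score <- if (use_holdout) peak$r2 else utils::tail(r2_train, 1)
    if (is.null(best) || score > best$score) {
      best <- list(score = score, cs = peak$cs, tfa = peak$tfa,
                   r2_train = r2_train, r2_holdout = r2_hold,
                   chosen_init = init, iterations_run = peak$iter)
    }
  }
  structure(list(cs = best$cs, tfa = best$tfa,
                 r2_train = best$r2_train,
                 r2_holdout = if (use_holdout) best$r2_holdout else NULL,
                 chosen_init = best$chosen_init,
                 iterations_run = best$iterations_run,
                 net = net, signs = signs, config = config),
            class = "tfa_fit")
}

#' Refit activities and baselines to a new dataset with fixed CS
#'
#' Holds the non-baseline control strengths fixed and alternates a bounded
#' activity update with a closed-form per-gene baseline update (mean
#' residual) until the SSE converges. No mean-one normalization is applied,
#' so activities stay on the scale set by the control strengths. In the
#' benchmark protocol the bounds carry only the generic activity floor —
#' the new dataset's perturbation key is reserved for evaluation.
#'
#' @param expr2 Genes x samples log2 expression matrix; genes are matched
#'   to the CS gene set by identifier (fit on the intersection).
#' @param cs A `cs_matrix` from an initial fit.
#' @param bounds An `activity_bounds` for the new samples (typically
#'   [floor_bounds()]).
#' @param config A [fit_config()] (tolerance and floor are used).
#' @param max_alt Maximum alternations (default 50).
#' @return `list(tfa, baselines, r2)`.
#' @export
refit_activities <- function(expr2, cs, bounds = NULL,
                             config = fit_config(), max_alt = 50) {
  genes <- intersect(rownames(expr2), rownames(cs$cs))
  if (length(genes) == 0) abort_input("no genes shared with the CS matrix")
  expr2 <- expr2[genes, , drop = FALSE]
  X <- cs$cs[genes, , drop = FALSE]
  tfs <- colnames(X)
  if (is.null(bounds))
    bounds <- floor_bounds(tfs, colnames(expr2), config$floor)
  b <- rowMeans(expr2)
  sst <- sum((expr2 - b)^2)
  prev_sse <- Inf
  tfa <- NULL
  for (it in seq_len(max_alt)) {
    cur <- cs_matrix(X, b)
    tfa <- tfa_step(expr2, cur, bounds)
    fit <- X %*% tfa
    b <- rowMeans(expr2 - fit)
    sse <- sum((sweep(expr2, 1, b, "-") - fit)^2)
    if (is.finite(prev_sse) &&
        (prev_sse - sse) <= 1e-9 * max(prev_sse, 1e-300)) break
    prev_sse <- sse
  }
  list(tfa = tfa, baselines = b, r2 = 1 - sse / sst)
}
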