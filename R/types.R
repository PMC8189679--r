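#' @importFrom rlang abort warn .data
#' @importFrom tibble tibble as_tibble is_tibble
NULL

abort_input <- function(...) abort(sprintf(...), class = "tfactivity_input_error")

#' Construct a validated expression matrix
#'
#' Expression values are log2-scale, genes in rows and samples in columns.
#' The matrix must carry unique gene and sample identifiers as dimnames and
#' contain only finite values; identifiers, not positions, are the API
#' currency everywhere in the package.
#'
#' @param values Numeric matrix (genes x samples) with rownames (gene ids)
#'   and colnames (sample ids).
#' @return The validated numeric matrix.
#' @export
expression_matrix <- function(values) {
  if (!is.matrix(values) || !is.numeric(values))
    abort_input("expression values must be a numeric matrix")
  genes <- rownames(values)
  samples <- colnames(values)
  if (is.null(genes) || is.null(samples))
    abort_input("expression matrix must have gene rownames and sample colnames")
  if (anyDuplicated(genes))
    abort_input("duplicated gene id: %s", genes[duplicated(genes)][1])
  if (anyDuplicated(samples))
    abort_input("duplicated sample id: %s", samples[duplicated(samples)][1])
  bad <- which(!is.finite(values), arr.ind = TRUE)
  if (nrow(bad) > 0)
    abort_input("non-finite expression value at gene '%s', sample '%s'",
                genes[bad[1, 1]], samples[bad[1, 2]])
  values
}

#' Construct a ranked TF-target edge list
#'
#' Edges are ordered by descending score; ties keep their input order
#' (stable sort). Duplicate (tf, target) pairs are rejected. Self edges
#' (tf == target) are dropped unless `allow_self = TRUE`, since TF-encoding
#' genes are removed from expression input before fitting.
#'
#' @param edges Data frame with columns `tf`, `target`, `score`.
#' @param allow_self Keep edges with tf == target? Default `FALSE` (dropped).
#' @return A tibble of class `ranked_edges`, sorted by descending score.
#' @export
ranked_edges <- function(edges, allow_self = FALSE) {
  edges <- as_tibble(edges)
  need <- c("tf", "target", "score")
  if (!all(need %in% names(edges)))
    abort_input("edge list needs columns tf, target, score")
  if (anyNA(edges$score)) {
    i <- which(is.na(edges$score))[1]
    abort_input("missing score for edge %s -> %s", edges$tf[i], edges$target[i])
  }
  if (!allow_self && any(edges$tf == edges$target)) {
    edges <- edges[edges$tf != edges$target, , drop = FALSE]
  }
  pair <- paste(edges$tf, edges$target, sep = "\r")
  if (anyDuplicated(pair))
    abort_input("duplicate edge: %s", gsub("\r", " -> ", pair[duplicated(pair)][1]))
  edges <- edges[order(-edges$score), , drop = FALSE]  # order() is stable
  edges$rank <- seq_len(nrow(edges))
  class(edges) <- c("ranked_edges", class(tibble()))
  edges
}

#' Construct a qualitative TF network map
#'
#' A network map is a set of TF -> target edges. `validate = TRUE` enforces
#' the invariants of a finished network: every TF has at least two targets
#' and no two TFs have identical target sets. Intermediate networks (during
#' pruning) may be built with `validate = FALSE`.
#'
#' @param edges Data frame with columns `tf`, `target`.
#' @param validate Enforce the finished-network invariants?
#' @return A tibble of class `tf_network`.
#' @export
tf_network <- function(edges, validate = TRUE) {
  edges <- as_tibble(edges)[, c("tf", "target")]
  pair <- paste(edges$tf, edges$target, sep = "\r")
  edges <- edges[!duplicated(pair), , drop = FALSE]
  if (validate && nrow(edges) > 0) {
    cnt <- table(edges$tf)
    if (any(cnt < 2))
      abort_input("TF '%s' has fewer than 2 targets", names(cnt)[cnt < 2][1])
    sets <- split(edges$target, edges$tf)
    keys <- vapply(sets, function(s) paste(sort(s), collapse = "\r"), "")
    if (anyDuplicated(keys))
      abort_input("TFs with identical target sets: %s",
                  paste(names(keys)[keys %in% keys[duplicated(keys)]], collapse = ", "))
  }
  class(edges) <- c("tf_network", class(tibble()))
  edges
}

#' @rdname tf_network
#' @param net A `tf_network`.
#' @export
network_tfs <- function(net) unique(net$tf)

#' @rdname tf_network
#' @export
network_targets <- function(net) unique(net$target)

#' Construct a control-strength sign-constraint set
#'
#' One row per network edge with `sign` +1 (activation) or -1 (repression);
#' entries off the network are implicitly zero.
#'
#' @param signs Data frame with columns `tf`, `target`, `sign`.
#' @param net Optional companion `tf_network`; if given, the constraint rows
#'   must cover exactly its edges.
#' @return A tibble of class `sign_constraints`.
#' @export
sign_constraints <- function(signs, net = NULL) {
  signs <- as_tibble(signs)[, c("tf", "target", "sign")]
  if (!all(signs$sign %in% c(-1, 1)))
    abort_input("signs must be +1 or -1")
  if (!is.null(net)) {
    a <- paste(signs$tf, signs$target, sep = "\r")
    b <- paste(net$tf, net$target, sep = "\r")
    if (!setequal(a, b))
      abort_input("sign constraints do not cover exactly the network edges")
  }
  class(signs) <- c("sign_constraints", class(tibble()))
  signs
}

#' Expand sign constraints to a genes x TFs matrix
#'
#' @param signs A `sign_constraints` tibble.
#' @param genes,tfs Row and column identifiers of the output.
#' @return Integer matrix in \{-1, 0, +1\}.
#' @export
sign_matrix <- function(signs, genes, tfs) {
  m <- matrix(0L, length(genes), length(tfs), dimnames = list(genes, tfs))
  keep <- signs$target %in% genes & signs$tf %in% tfs
  s <- signs[keep, , drop = FALSE]
  m[cbind(match(s$target, genes), match(s$tf, tfs))] <- as.integer(s$sign)
  m
}

#' Construct a perturbation key
#'
#' Maps each sample to the TF directly perturbed in it and the direction
#' (`deletion` or `overexpression`); samples with direction `none` are
#' unperturbed. A sample may appear at most once.
#'
#' @param key Data frame with columns `sample`, `tf`, `direction`.
#' @return A tibble of class `perturbation_key`.
#' @export
perturbation_key <- function(key) {
  key <- as_tibble(key)[, c("sample", "tf", "direction")]
  ok <- c("deletion", "overexpression", "none")
  if (!all(key$direction %in% ok))
    abort_input("unknown direction '%s'", setdiff(key$direction, ok)[1])
  if (anyDuplicated(key$sample))
    abort_input("sample '%s' listed twice in perturbation key",
                key$sample[duplicated(key$sample)][1])
  key$tf[key$direction == "none"] <- NA_character_
  class(key) <- c("perturbation_key", class(tibble()))
  key
}

#' @rdname perturbation_key
#' @param key A `perturbation_key`.
#' @export
key_records <- function(key) key[key$direction != "none", , drop = FALSE]

#' @rdname perturbation_key
#' @export
key_unperturbed <- function(key) key$sample[key$direction == "none"]

#' Designated unperturbed reference sample
#'
#' When several unperturbed samples exist, the first in key order is the
#' reference (configurable by reordering the key).
#'
#' @rdname perturbation_key
#' @export
key_reference <- function(key) {
  u <- key_unperturbed(key)
  if (length(u) == 0)
    abort_input("perturbation key has no unperturbed sample")
  u[1]
}

#' Construct a control-strength matrix with per-gene baselines
#'
#' @param cs Numeric genes x TFs matrix with dimnames; zero off-network.
#' @param baselines Named numeric vector of per-gene baselines (log2 units).
#' @return An object of class `cs_matrix`.
#' @export
cs_matrix <- function(cs, baselines) {
  if (is.null(rownames(cs)) || is.null(colnames(cs)))
    abort_input("cs matrix needs gene rownames and TF colnames")
  baselines <- baselines[rownames(cs)]
  if (anyNA(baselines) || any(!is.finite(baselines)))
    abort_input("baselines must be finite and cover every gene")
  names(baselines) <- rownames(cs)
  structure(list(cs = cs, baselines = baselines), class = "cs_matrix")
}

#' @export
print.cs_matrix <- function(x, ...) {
  cat(sprintf("<cs_matrix> %d genes x %d TFs, %d nonzero control strengths\n",
              nrow(x$cs), ncol(x$cs), sum(x$cs != 0)))
  invisible(x)
}

#' Predicted expression under the bilinear model
#'
#' Computes baseline + CS %*% TFA for a control-strength object and an
#' activity matrix.
#'
#' @param cs A `cs_matrix`.
#' @param tfa Numeric TFs x samples activity matrix.
#' @return Genes x samples matrix of predicted log2 expression.
#' @export
predict_expression <- function(cs, tfa) {
  tfs <- colnames(cs$cs)
  pred <- cs$cs %*% tfa[tfs, , drop = FALSE]
  sweep(pred, 1, cs$baselines, "+")
}

check_activity_matrix <- function(tfa) {
  if (is.null(rownames(tfa)) || is.null(colnames(tfa)))
    abort_input("activity matrix needs TF rownames and sample colnames")
  if (any(tfa < 0))
    abort_input("activities must be non-negative")
  invisible(tfa)
}
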