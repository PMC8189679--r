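# Low-level constrained least-squares building blocks.
#
# Every block update in the alternating fit is a least-squares problem with
# one-sided bounds (sign constraints on control strengths, lower bounds on
# activities). All of them reduce to non-negative least squares after sign
# flips / shifts / positive-negative splits, and all are solved on the
# normal equations: the Gram matrix of the design is computed once per
# block update and sub-problems only index into it, which keeps the inner
# loop cheap at compendium scale. The unconstrained solution is tried
# first and accepted whenever it already satisfies the bounds (it is then
# the global optimum of the relaxation, hence of the constrained problem).

# solve M x = v for a symmetric PSD M; Cholesky with a minimum-norm
# pseudoinverse fallback for rank-deficient systems
chol_solve <- function(M, v) {
  x <- tryCatch(backsolve(ch <- chol(M), forwardsolve(t(ch), v)),
                error = function(e) NULL)
  if (is.null(x)) x <- MASS::ginv(M) %*% v
  as.numeric(x)
}

# Lawson-Hanson non-negative least squares on the normal equations:
# minimize ||X b - y||^2 s.t. b >= 0, given XtX = X'X and Xty = X'y.
nnls_ne <- function(XtX, Xty, max_iter = 30 * length(Xty)) {
  n <- length(Xty)
  x <- numeric(n)
  passive <- rep(FALSE, n)
  tol <- 1e-10 * max(abs(Xty), 1)
  for (outer in seq_len(max_iter)) {
    w <- Xty - XtX %*% x
    w[passive] <- -Inf
    j <- which.max(w)
    if (w[j] <= tol) break
    passive[j] <- TRUE
    repeat {
      P <- which(passive)
      s <- numeric(n)
      s[P] <- chol_solve(XtX[P, P, drop = FALSE], Xty[P])
      if (all(s[P] > 0)) {
        x <- s
        break
      }
      neg <- P[s[P] <= 0]
      alpha <- min(x[neg] / (x[neg] - s[neg]))
      x <- x + alpha * (s - x)
      passive[P[x[P] <= tol]] <- FALSE
      x[!passive] <- 0
    }
  }
  x
}

# minimize ||X b - y||^2 s.t. b >= lower elementwise, on the normal
# equations; lower may contain -Inf (free variables, handled by a
# positive/negative split)
ls_lower_bounded_ne <- function(XtX, Xty, lower) {
  b <- chol_solve(XtX, Xty)
  if (all(b >= lower - 1e-12)) return(pmax(b, lower))
  n <- length(Xty)
  free <- !is.finite(lower)
  shift <- ifelse(free, 0, lower)
  v <- Xty - XtX %*% shift
  if (!any(free)) {
    return(as.numeric(nnls_ne(XtX, as.numeric(v)) + shift))
  }
  Fi <- which(free)
  XtX_e <- rbind(cbind(XtX, -XtX[, Fi, drop = FALSE]),
                 cbind(-XtX[Fi, , drop = FALSE],
                       XtX[Fi, Fi, drop = FALSE]))
  v_e <- c(v, -v[Fi])
  z <- nnls_ne(XtX_e, as.numeric(v_e))
  p <- z[seq_len(n)]
  p[Fi] <- p[Fi] - z[n + seq_along(Fi)]
  as.numeric(p + shift)
}

# per-gene control-strength update on precomputed Gram blocks: minimize
# over (b_i, cs_i.) the SSE of e_i = b_i + sum_j cs_ij a_jk subject to
# cs_ij * sign_ij >= 0. G = crossprod(cbind(1, Aact)), gy = t(cbind(1,
# Aact)) %*% y; J indexes the gene's regulator columns of Aact (0-based in
# Aact, hence +1 into G), sgn their constrained signs.
cs_solve_gene_ne <- function(G, gy, J, sgn) {
  idx <- c(1L, J + 1L)
  beta <- chol_solve(G[idx, idx, drop = FALSE], gy[idx])
  cs <- beta[-1]
  if (length(J) == 0 || all(cs * sgn >= -1e-12)) {
    cs[cs * sgn < 0] <- 0
    return(list(baseline = beta[1], cs = cs))
  }
  # variables: signed magnitudes m_j = sgn_j * cs_j >= 0, intercept split
  # b = b+ - b-
  Gjj <- G[J + 1L, J + 1L, drop = FALSE] * outer(sgn, sgn)
  Gj1 <- G[J + 1L, 1L] * sgn
  n1 <- G[1L, 1L]
  XtX <- rbind(cbind(Gjj, Gj1, -Gj1),
               c(Gj1, n1, -n1),
               c(-Gj1, -n1, n1))
  Xty <- c(gy[J + 1L] * sgn, gy[1L], -gy[1L])
  z <- nnls_ne(XtX, Xty)
  k <- length(J)
  list(baseline = z[k + 1] - z[k + 2], cs = z[seq_len(k)] * sgn)
}
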