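#' Time-course container for activity fold changes
#'
#' @param times Strictly increasing non-negative times (minutes), starting
#'   at 0.
#' @param values Log2 fold change of activity relative to time 0 (the first
#'   value is 0 by construction of the fold change).
#' @return A tibble of class `tfa_timeseries`.
#' @export
time_series <- function(times, values) {
  if (length(times) != length(values))
    abort_input("times and values differ in length")
  if (any(diff(times) <= 0)) abort_input("times must be strictly increasing")
  if (times[1] != 0) abort_input("time series must start at time 0")
  ts <- tibble(time = as.numeric(times), value = as.numeric(values))
  class(ts) <- c("tfa_timeseries", class(tibble()))
  ts
}

logistic <- function(x) 1 / (1 + exp(-x))

#' Saturating sigmoid curve
#'
#' `y(t) = y0 + (A - y0) / (1 + exp(-k (t - t0)))` with rate `k > 0`;
#' rises from `y0` toward `A` (or falls when `A < y0`).
#'
#' @param t Time points.
#' @param y0,A,k,t0 Parameters: initial level, asymptote, rate, midpoint.
#' @return Curve values at `t`.
#' @export
sigmoid4 <- function(t, y0, A, k, t0) y0 + (A - y0) * logistic(k * (t - t0))

#' Two-transition impulse curve
#'
#' Product of two logistic transitions,
#' `f(t) = (1/h1) * [h0 + (h1-h0) s(b(t-t1))] * [h2 + (h1-h2) s(-b(t-t2))]`
#' with `s` the logistic function: the response moves from `h0` to a peak
#' (or trough) level `h1` around `t1`, then toward a final level `h2`
#' around `t2 > t1`, both transitions sharing slope `b > 0`.
#'
#' @param t Time points.
#' @param h0,h1,h2 Initial, peak and final levels.
#' @param t1,t2 Transition times (`t1 < t2`).
#' @param beta Shared transition slope (> 0).
#' @return Curve values at `t`.
#' @export
impulse6 <- function(t, h0, h1, h2, t1, t2, beta) {
  (1 / h1) * (h0 + (h1 - h0) * logistic(beta * (t - t1))) *
    (h2 + (h1 - h2) * logistic(-beta * (t - t2)))
}

curve_fit_result <- function(family, params, ts, fitted, converged = TRUE) {
  sse <- sum((ts$value - fitted)^2)
  sst <- sum((ts$value - mean(ts$value))^2)
  n <- nrow(ts)
  k <- length(params)
  r2 <- if (sst > 0) 1 - sse / sst else NA_real_
  direction <- if (family == "sigmoid4") {
    if (params[["A"]] > params[["y0"]]) "increasing" else "decreasing"
  } else {
    if (fitted[n] > fitted[1]) "increasing" else "decreasing"
  }
  structure(list(family = family, params = params, r_squared = r2,
                 sse = sse, n = n,
                 bic = n * log(max(sse, 1e-12) / n) + k * log(n),
                 direction = direction, fitted = fitted, ts = ts,
                 converged = converged),
            class = "curve_fit")
}

#' @export
print.curve_fit <- function(x, ...) {
  if (!x$converged) {
    cat("<curve_fit> failed fit\n")
    return(invisible(x))
  }
  cat(sprintf("<curve_fit> %s: R^2 = %.4f, BIC = %.2f, %s\n",
              x$family, x$r_squared, x$bic, x$direction))
  invisible(x)
}

failed_fit <- function(family, ts) {
  structure(list(family = family, params = NULL, r_squared = NA_real_,
                 sse = Inf, n = nrow(ts), bic = Inf,
                 direction = NA_character_, fitted = NULL, ts = ts,
                 converged = FALSE),
            class = "curve_fit")
}

nls_try <- function(formula, ts, start, lower) {
  tryCatch(
    suppressWarnings(minpack.lm::nlsLM(
      formula, data = ts, start = start, lower = lower,
      control = minpack.lm::nls.lm.control(maxiter = 200))),
    error = function(e) NULL)
}

#' Fit a four-parameter saturating sigmoid to a time series
#'
#' Nonlinear least squares ([sigmoid4()]) with multi-start initialization:
#' midpoints are seeded from quantiles of the time range and levels from
#' the data extremes; the best-SSE converged start wins. Direction is
#' increasing when the asymptote exceeds the initial level. Constant
#' series are flagged low-information (`r_squared` is undefined there).
#'
#' @param ts A `tfa_timeseries` (or tibble with `time`, `value`), at least
#'   5 points.
#' @return A `curve_fit`; a failed-fit marker when no start converges.
#' @export
# linearized initial guess: with levels pinned at the data extremes, the
# logit of the normalized response is linear in time with slope k and
# intercept -k*t0
sigmoid_guess <- function(ts, y0, A) {
  z <- (ts$value - y0) / (A - y0)
  z <- pmin(pmax(z, 0.01), 0.99)
  co <- tryCatch(stats::coef(stats::lm(stats::qlogis(z) ~ ts$time)),
                 error = function(e) NULL)
  if (is.null(co) || !is.finite(co[2]) || abs(co[2]) < 1e-8) return(NULL)
  k <- abs(co[2])
  list(y0 = y0, A = A, k = k, t0 = -co[1] / co[2])
}

fit_sigmoid <- function(ts) {
  ts <- as_tibble(ts)
  if (nrow(ts) < 5) abort_input("sigmoid fit needs >= 5 time points")
  rng <- range(ts$value)
  tspan <- diff(range(ts$time))
  n <- nrow(ts)
  starts <- list()
  add <- function(s) starts[[length(starts) + 1]] <<- lapply(s, unname)
  for (lev in list(c(ts$value[1], ts$value[n]), rng, rev(rng))) {
    if (abs(lev[2] - lev[1]) < 1e-12) next
    g <- sigmoid_guess(ts, lev[1], lev[2])
    if (!is.null(g)) add(g)
  }
  for (k in c(1, 4, 16) / tspan)
    for (t0 in unname(stats::quantile(ts$time, c(0.25, 0.5, 0.75))))
      add(list(y0 = ts$value[1], A = ts$value[n], k = k, t0 = t0))
  best <- NULL
  for (st in starts) {
    fit <- nls_try(value ~ sigmoid4(time, y0, A, k, t0), ts,
                   start = st, lower = c(-Inf, -Inf, 1e-6, -Inf))
    if (is.null(fit)) next
    sse <- sum(stats::resid(fit)^2)
    if (is.null(best) || sse < best$sse) {
      best <- list(sse = sse, coef = stats::coef(fit),
                   fitted = as.numeric(stats::fitted(fit)))
      if (sse < 1e-12) break
    }
  }
  if (is.null(best)) return(failed_fit("sigmoid4", ts))
  # polish the winner
  pol <- nls_try(value ~ sigmoid4(time, y0, A, k, t0), ts,
                 start = as.list(best$coef),
                 lower = c(-Inf, -Inf, 1e-6, -Inf))
  if (!is.null(pol) && sum(stats::resid(pol)^2) < best$sse)
    best <- list(sse = sum(stats::resid(pol)^2), coef = stats::coef(pol),
                 fitted = as.numeric(stats::fitted(pol)))
  curve_fit_result("sigmoid4", as.list(best$coef), ts, best$fitted)
}

#' Fit a six-parameter impulse curve to a time series
#'
#' Nonlinear least squares for the two-transition impulse ([impulse6()])
#' with multi-start initialization bracketing the observed extremum; the
#' transition times are kept ordered. On monotone data the impulse
#' degenerates toward a sigmoid shape (final level near the peak level),
#' and BIC selection then prefers the sigmoid.
#'
#' @param ts A `tfa_timeseries`, at least 7 points.
#' @return A `curve_fit`; a failed-fit marker when no start converges.
#' @export
fit_impulse <- function(ts) {
  ts <- as_tibble(ts)
  if (nrow(ts) < 7) abort_input("impulse fit needs >= 7 time points")
  tspan <- diff(range(ts$time))
  n <- nrow(ts)
  i_ext <- which.max(abs(ts$value - ts$value[1]))
  t_ext <- max(ts$time[i_ext], 0.05 * tspan)
  h1_cands <- unique(c(ts$value[i_ext], max(ts$value), min(ts$value)))
  h1_cands <- utils::head(h1_cands[abs(h1_cands) > 1e-8], 2)
  if (length(h1_cands) == 0) h1_cands <- 1
  t2_cands <- unique(c((t_ext + tspan) / 2,
                       unname(stats::quantile(ts$time, c(0.5, 0.8)))))
  starts <- list()
  for (h1 in h1_cands)
    for (t1 in unique(c(t_ext / 2, t_ext)))
      for (t2 in t2_cands[t2_cands > t1])
        for (beta in c(2 / tspan, 10 / tspan))
          starts[[length(starts) + 1]] <-
            list(h0 = ts$value[1], h1 = unname(h1), h2 = ts$value[n],
                 t1 = unname(t1), t2 = unname(t2), beta = beta)
  lower <- c(-Inf, -Inf, -Inf, -Inf, -Inf, 1e-6)
  best <- NULL
  for (st in starts) {
    fit <- nls_try(value ~ impulse6(time, h0, h1, h2, t1, t2, beta), ts,
                   start = st, lower = lower)
    if (is.null(fit)) next
    cf <- stats::coef(fit)
    if (cf[["t1"]] >= cf[["t2"]]) next
    sse <- sum(stats::resid(fit)^2)
    if (is.null(best) || sse < best$sse) {
      best <- list(sse = sse, coef = cf,
                   fitted = as.numeric(stats::fitted(fit)))
      if (sse < 1e-12) break
    }
  }
  if (is.null(best)) return(failed_fit("impulse6", ts))
  pol <- nls_try(value ~ impulse6(time, h0, h1, h2, t1, t2, beta), ts,
                 start = as.list(best$coef), lower = lower)
  if (!is.null(pol) && sum(stats::resid(pol)^2) < best$sse) {
    cf <- stats::coef(pol)
    if (cf[["t1"]] < cf[["t2"]])
      best <- list(sse = sum(stats::resid(pol)^2), coef = cf,
                   fitted = as.numeric(stats::fitted(pol)))
  }
  curve_fit_result("impulse6", as.list(best$coef), ts, best$fitted)
}

#' Select among curve fits by the Bayes Information Criterion
#'
#' Uses the Gaussian-error profile form `BIC = n log(SSE/n) + k log(n)`
#' with `k` the number of curve parameters; the lowest BIC wins and ties
#' go to the model with fewer parameters.
#'
#' @param fits List of `curve_fit` objects for the same series.
#' @return The selected `curve_fit` (a failed marker if all fits failed).
#' @export
select_by_bic <- function(fits) {
  ok <- Filter(function(f) f$converged, fits)
  if (length(ok) == 0) return(fits[[1]])
  npar <- vapply(ok, function(f) length(f$params), 0L)
  bic <- vapply(ok, function(f) f$bic, 0.0)
  ok[[order(bic, npar)[1]]]
}

#' Fraction of retained fits with increasing direction
#'
#' Drops failed fits and fits whose variance explained falls below the
#' threshold, then reports the fraction of the retained fits classified as
#' increasing. Raising the threshold never increases the retained count.
#'
#' @param fits Named list of `curve_fit` objects (e.g. one per TF).
#' @param r2_threshold Variance-explained threshold in `[0, 1]`
#'   (default 0.85).
#' @return `list(fraction_increasing, n_retained, retained)`; the fraction
#'   is `NA` when nothing is retained.
#' @export
summarize_directions <- function(fits, r2_threshold = 0.85) {
  keep <- Filter(function(f) f$converged && !is.na(f$r_squared) &&
                   f$r_squared >= r2_threshold, fits)
  frac <- if (length(keep) == 0) NA_real_ else {
    mean(vapply(keep, function(f) f$direction == "increasing", TRUE))
  }
  list(fraction_increasing = frac, n_retained = length(keep),
       retained = names(keep))
}
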