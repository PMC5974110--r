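#' Fit a Gaussian empirical null to the central quantiles of a distribution
#'
#' The "deconvolution" at the heart of the method: the bulk of probes on an
#' array fluctuate only stochastically, and differential probes contaminate
#' the tails of a discrimination variable. Fitting the Gaussian null on the
#' central window of the distribution — rather than on all values — keeps the
#' null's scale free of that contamination and yields narrower detection
#' limits.
#'
#' The estimator is a probit-plot regression: order statistics whose plotting
#' positions \eqn{p_k = (k - 0.5)/n} fall inside `[q_lo, q_hi]` are regressed
#' by ordinary least squares on the standard-normal quantiles
#' \eqn{\Phi^{-1}(p_k)}. The intercept estimates the null mean, the slope the
#' null standard deviation; for uncontaminated Gaussian data the plot is a
#' straight line and the fit R-squared is close to 1.
#'
#' @param values Numeric vector of per-probe values of one discrimination
#'   variable. Non-finite values are dropped before fitting.
#' @param q_lo,q_hi Bounds of the central quantile window, fractions in (0,1)
#'   with `q_lo < q_hi`. Default window `(0.25, 0.75)` — the inner half of
#'   the distribution.
#' @return An object of class `gaussian_null`: a list with `mu_hat`,
#'   `sigma_hat` (> 0), `window = c(q_lo, q_hi)`, `n_points_fit`, `fit_r2`,
#'   and `n_total` (finite values seen).
#' @seealso [qgdemar()] which fits the null and calls per-tail detections.
#' @examples
#' set.seed(1)
#' x <- c(rnorm(9500), rnorm(500, 5))  # 5% contaminated
#' fit_gaussian_null(x)                # recovers ~N(0,1) despite the spikes
#' sd(x)                               # whole-sample scale is inflated
#' @export
fit_gaussian_null <- function(values, q_lo = 0.25, q_hi = 0.75) {
  stopifnot(is.numeric(q_lo), is.numeric(q_hi), length(q_lo) == 1L,
            length(q_hi) == 1L)
  if (!(q_lo > 0 && q_hi < 1 && q_lo < q_hi))
    stop("quantile window must satisfy 0 < q_lo < q_hi < 1")
  x <- values[is.finite(values)]
  n <- length(x)
  if (n < 50L)
    stop(errorCondition(
      sprintf("need >= 50 finite values to fit the null (got %d)", n),
      class = c("qgdemar_insufficient_data", "error", "condition")))
  xs <- sort(x)
  p <- (seq_len(n) - 0.5) / n
  in_win <- p >= q_lo & p <= q_hi
  if (sum(in_win) < 10L)
    stop(errorCondition(
      sprintf("only %d order statistics fall in window (%g, %g)",
              sum(in_win), q_lo, q_hi),
      class = c("qgdemar_insufficient_data", "error", "condition")))
  z <- stats::qnorm(p[in_win])
  y <- xs[in_win]
  zbar <- mean(z); ybar <- mean(y)
  szz <- sum((z - zbar)^2)
  szy <- sum((z - zbar) * (y - ybar))
  slope <- szy / szz
  intercept <- ybar - slope * zbar
  syy <- sum((y - ybar)^2)
  r2 <- if (syy > 0) szy^2 / (szz * syy) else 0
  if (!is.finite(slope) || slope <= 0)
    stop(errorCondition(
      "degenerate null: central window has zero (or negative) spread",
      class = c("qgdemar_degenerate_null", "error", "condition")))
  structure(list(mu_hat = intercept, sigma_hat = slope,
                 window = c(q_lo, q_hi), n_points_fit = sum(in_win),
                 fit_r2 = min(max(r2, 0), 1), n_total = n),
            class = "gaussian_null")
}

# full-distribution comparator: plain sample moments, no central trimming
moment_null <- function(values) {
  x <- values[is.finite(values)]
  n <- length(x)
  if (n < 50L)
    stop(errorCondition(
      sprintf("need >= 50 finite values to fit the null (got %d)", n),
      class = c("qgdemar_insufficient_data", "error", "condition")))
  s <- stats::sd(x)
  if (!is.finite(s) || s <= 0)
    stop(errorCondition(
      "degenerate null: data have zero spread",
      class = c("qgdemar_degenerate_null", "error", "condition")))
  structure(list(mu_hat = mean(x), sigma_hat = s, window = c(0, 1),
                 n_points_fit = n, fit_r2 = NA_real_, n_total = n),
            class = "gaussian_null")
}

#' @export
print.gaussian_null <- function(x, ...) {
  cat(sprintf(
    "Gaussian null: mu = %.4f, sigma = %.4f (window %g-%g, %d points%s)\n",
    x$mu_hat, x$sigma_hat, x$window[1], x$window[2], x$n_points_fit,
    if (is.na(x$fit_r2)) "" else sprintf(", fit R2 = %.4f", x$fit_r2)))
  invisible(x)
}

#' Tail-area FDR of a detection threshold under a fitted Gaussian null
#'
#' Estimated false discovery rate, in percent, of calling every value strictly
#' beyond `threshold` in the requested tail:
#' \deqn{FDR\% = 100 \cdot N \cdot p_{tail}(threshold) / n_{detected}}
#' where \eqn{N} is the number of finite values, \eqn{p_{tail}} the Gaussian
#' tail probability under the fitted null, and \eqn{n_{detected}} the observed
#' count strictly beyond the threshold. Capped at 100. When nothing lies
#' beyond the threshold the FDR is undefined and `NA` is returned (mapped to
#' the NDAS outcome upstream).
#'
#' @param null A [`gaussian_null`][fit_gaussian_null] fitted on `values`.
#' @param values The same numeric vector the null was fitted on.
#' @param threshold Candidate threshold, on the variable's scale. Must lie on
#'   the correct side of the null mean for the requested tail.
#' @param tail `"upper"` or `"lower"`.
#' @return FDR in percent (`[0, 100]`), or `NA` if no value is detected.
#' @examples
#' set.seed(1); x <- rnorm(10000)
#' nul <- fit_gaussian_null(x)
#' tail_fdr(nul, x, threshold = 3, tail = "upper")
#' @export
tail_fdr <- function(null, values, threshold, tail = c("upper", "lower")) {
  tail <- match.arg(tail)
  stopifnot(inherits(null, "gaussian_null"), is.numeric(threshold),
            length(threshold) == 1L)
  x <- values[is.finite(values)]
  N <- length(x)
  if (tail == "upper" && threshold <= null$mu_hat)
    stop("upper-tail threshold must exceed the null mean")
  if (tail == "lower" && threshold >= null$mu_hat)
    stop("lower-tail threshold must lie below the null mean")
  n_det <- if (tail == "upper") sum(x > threshold) else sum(x < threshold)
  if (n_det == 0L) return(NA_real_)
  p_tail <- stats::pnorm(threshold, null$mu_hat, null$sigma_hat,
                         lower.tail = (tail == "lower"))
  min(100, 100 * N * p_tail / n_det)
}

#' Least-extreme threshold sustaining a target FDR in one tail
#'
#' Scans candidate thresholds placed at every observed value beyond the null
#' mean in the requested tail, moving outward from the mean, and returns the
#' least extreme candidate whose [tail_fdr()] does not exceed `fdr_target` —
#' i.e. the threshold detecting the most probes subject to the FDR bound.
#' Values exactly equal to a threshold are not detected (detection is strict),
#' which makes tie-breaking deterministic. If no candidate qualifies the tail
#' is NDAS ("not detectable as significant").
#'
#' @inheritParams tail_fdr
#' @param fdr_target Target FDR in percent, in (0, 100].
#' @return A list with `status` (`"detected"` or `"NDAS"`) and, when detected,
#'   `threshold`, `fdr_percent`, and `n_detected`.
#' @examples
#' set.seed(1)
#' x <- c(rnorm(9500), rnorm(500, 4))
#' nul <- fit_gaussian_null(x)
#' select_threshold(nul, x, fdr_target = 5, tail = "upper")
#' @export
select_threshold <- function(null, values, fdr_target = 5,
                             tail = c("upper", "lower")) {
  tail <- match.arg(tail)
  stopifnot(is.numeric(fdr_target), length(fdr_target) == 1L)
  if (!(fdr_target > 0 && fdr_target <= 100))
    stop("fdr_target must be in (0, 100] percent")
  x <- values[is.finite(values)]
  N <- length(x)
  xs <- sort(x)
  if (tail == "upper") {
    cand <- unique(xs[xs > null$mu_hat])            # ascending: least extreme first
    n_det <- N - findInterval(cand, xs)             # strictly greater than cand
    p_tail <- stats::pnorm(cand, null$mu_hat, null$sigma_hat,
                           lower.tail = FALSE)
  } else {
    cand <- unique(xs[xs < null$mu_hat])
    cand <- cand[order(-cand)]                      # descending: least extreme first
    n_det <- findInterval(cand, xs, left.open = TRUE)  # strictly less than cand
    p_tail <- stats::pnorm(cand, null$mu_hat, null$sigma_hat)
  }
  if (!length(cand)) return(list(status = "NDAS"))
  fdr <- pmin(100, 100 * N * p_tail / n_det)
  ok <- which(n_det > 0L & fdr <= fdr_target)
  if (!length(ok)) return(list(status = "NDAS"))
  i <- ok[1L]
  list(status = "detected", threshold = cand[i], fdr_percent = fdr[i],
       n_detected = as.integer(n_det[i]))
}
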