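#' @importFrom stats setNames
new_variable <- function(kind, value, pm, definition) {
  gene <- if (is.null(pm$gene)) NULL else pm$gene[names(value)]
  structure(list(kind = kind, value = value, gene = gene,
                 definition = definition,
                 id = sprintf("%s(%s)", kind, definition)),
            class = "discrimination_variable")
}

#' @export
print.discrimination_variable <- function(x, ...) {
  cat(sprintf("discrimination variable [%s]: %s\n", x$kind, x$definition))
  n_missing <- sum(!is.finite(x$value))
  cat(sprintf("  %d probes (%d missing)\n", length(x$value), n_missing))
  invisible(x)
}

#' Per-probe mean of the replicates of one condition
#'
#' Replicates are averaged before any variable is formed: the method works on
#' one per-condition signal per probe, not on per-replicate ratios. Probes
#' missing in some replicates get the unweighted mean of the available ones;
#' probes missing in all replicates are `NA`.
#'
#' @param pm A [probe_matrix()].
#' @param key A [condition_key()] (or `c(strain, phase)` character pair).
#' @return Named numeric vector, one mean log2 value per probe.
#' @export
condition_mean <- function(pm, key) {
  stopifnot(inherits(pm, "probe_matrix"))
  cols <- condition_samples(pm, key)
  m <- pm$values[, cols, drop = FALSE]
  out <- rowMeans(m, na.rm = TRUE)
  out[!is.finite(out)] <- NA_real_      # all replicates missing
  out
}

#' Log-ratio discrimination variable between two conditions
#'
#' The per-probe difference of mean log2 intensities,
#' `log2(numerator/denominator)` on the intensity scale. Values significantly
#' above the null mean the numerator condition is up-regulated; below, the
#' denominator is up-regulated.
#'
#' @param pm A [probe_matrix()].
#' @param numerator,denominator [condition_key()]s of the two conditions.
#' @return A `discrimination_variable` of kind `"log_ratio"` (log2 units).
#' @export
log_ratio <- function(pm, numerator, denominator) {
  numerator <- as_condition_key(numerator)
  denominator <- as_condition_key(denominator)
  v <- condition_mean(pm, numerator) - condition_mean(pm, denominator)
  new_variable("log_ratio", v, pm,
               sprintf("%s/%s", format(numerator), format(denominator)))
}

#' Super-ratio: the 2x2 factorial interaction statistic
#'
#' The mutant-vs-wild-type log-ratio in one condition minus the same
#' log-ratio in a second condition:
#' \deqn{[\bar{x}(M, c_1) - \bar{x}(WT, c_1)] - [\bar{x}(M, c_2) - \bar{x}(WT, c_2)]}
#' A positive value means the transcriptional change brought by the mutation
#' is greater in `condition_1` than in `condition_2` (a positive interaction
#' between the mutation and the condition factor — e.g. growth rate when the
#' conditions are glucose-limited chemostat vs batch-exponential culture).
#' Exactly antisymmetric in the two conditions, and exactly the difference of
#' the two [log_ratio()]s.
#'
#' @param pm A [probe_matrix()].
#' @param mutant,wildtype Strain labels.
#' @param condition_1,condition_2 Phase labels of the two conditions.
#' @return A `discrimination_variable` of kind `"super_ratio"` (log2 units).
#' @export
super_ratio <- function(pm, mutant, wildtype, condition_1, condition_2) {
  m1 <- condition_mean(pm, condition_key(mutant, condition_1))
  w1 <- condition_mean(pm, condition_key(wildtype, condition_1))
  m2 <- condition_mean(pm, condition_key(mutant, condition_2))
  w2 <- condition_mean(pm, condition_key(wildtype, condition_2))
  v <- (m1 - w1) - (m2 - w2)
  new_variable("super_ratio", v, pm,
               sprintf("[%s-%s]@%s - [%s-%s]@%s", mutant, wildtype,
                       condition_1, mutant, wildtype, condition_2))
}

#' Difference discrimination variable between two conditions
#'
#' The per-probe difference of mean log2 values, `a - b`. The canonical use
#' is the positional control: with `a` the wild type and `b` the delta-N
#' cloning control, values far below zero mark probes over-transcribed by
#' the ectopic insertion (false positives of any mutant-vs-WT contrast) and
#' values far above zero mark attenuated probes (false negatives).
#'
#' @param pm A [probe_matrix()].
#' @param a,b [condition_key()]s.
#' @return A `discrimination_variable` of kind `"difference"` (log2 units).
#' @export
condition_difference <- function(pm, a, b) {
  a <- as_condition_key(a); b <- as_condition_key(b)
  v <- condition_mean(pm, a) - condition_mean(pm, b)
  new_variable("difference", v, pm,
               sprintf("%s - %s", format(a), format(b)))
}

#' Quotient of log2 means (control-chart ratio variable)
#'
#' The literal division of the mean log2 intensities,
#' `mean_log2(numerator) / mean_log2(denominator)` — dimensionless, centred
#' near 1 for unchanged probes, and the variable plotted in control-chart
#' style against the denominator's intensity. This is deliberately distinct
#' from [log_ratio()] (the difference of log2 means) and is never silently
#' substituted for it. Probes whose denominator mean is 0 are flagged
#' missing.
#'
#' @param pm A [probe_matrix()].
#' @param numerator,denominator [condition_key()]s.
#' @return A `discrimination_variable` of kind `"log2_quotient"`
#'   (dimensionless).
#' @export
log2_quotient <- function(pm, numerator, denominator) {
  numerator <- as_condition_key(numerator)
  denominator <- as_condition_key(denominator)
  num <- condition_mean(pm, numerator)
  den <- condition_mean(pm, denominator)
  if (all(den == 0, na.rm = TRUE) || all(is.na(den)))
    stop("denominator condition mean is zero (or missing) for every probe")
  v <- num / den
  v[den == 0] <- NA_real_
  new_variable("log2_quotient", v, pm,
               sprintf("%s / %s", format(numerator), format(denominator)))
}

series_for <- function(pm, spec) {
  # spec: a condition_key -> condition mean; a list of two keys -> log-ratio
  if (inherits(spec, "condition_key")) return(condition_mean(pm, spec))
  if (is.list(spec) && length(spec) == 2L)
    return(condition_mean(pm, as_condition_key(spec[[1]])) -
           condition_mean(pm, as_condition_key(spec[[2]])))
  stop("each series must be a condition_key or a list of two condition_keys")
}

#' Concordance between two expression profiles
#'
#' Ordinary least-squares regression of one per-probe series on another
#' across all probes present in both. Each series is either a condition's
#' mean log2 profile (pass a [condition_key()]) or a log-ratio (pass a list
#' of two keys, numerator first). Two strains sharing most of their
#' transcriptome plot on the identity line with slope near 1 and R-squared
#' near 1.
#'
#' @param pm A [probe_matrix()].
#' @param a,b Series specifications; `a` is regressed on `b`.
#' @return An object of class `concordance`: `slope`, `intercept`,
#'   `r_squared`, `n_probes`.
#' @export
concordance <- function(pm, a, b) {
  ya <- series_for(pm, a)
  xb <- series_for(pm, b)
  keep <- is.finite(ya) & is.finite(xb)
  if (sum(keep) < 3L)
    stop("need at least 3 probes shared by both series")
  y <- ya[keep]; x <- xb[keep]
  sxx <- sum((x - mean(x))^2)
  if (sxx == 0) stop("the x series is constant: slope undefined")
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  syy <- sum((y - mean(y))^2)
  slope <- sxy / sxx
  structure(list(slope = slope, intercept = mean(y) - slope * mean(x),
                 r_squared = if (syy > 0) sxy^2 / (sxx * syy) else 1,
                 n_probes = sum(keep)),
            class = "concordance")
}

#' @export
print.concordance <- function(x, ...) {
  cat(sprintf("concordance: m = %.4f, intercept = %.4f, R2 = %.4f (n = %d)\n",
              x$slope, x$intercept, x$r_squared, x$n_probes))
  invisible(x)
}
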