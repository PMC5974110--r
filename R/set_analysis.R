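# one-decimal rounding; IEEE round-half-to-even, which reproduces the
# printed style of the emulated analyses (6.25 -> 6.2, 13.636 -> 13.6)
round1 <- function(x) round(x, 1)

#' Two-set Venn partition of gene lists
#'
#' Disaggregates two detection lists into exclusive-A, exclusive-B and
#' common components, and reports the percentage of common identifiers
#' against a chosen denominator.
#'
#' @param a,b Character vectors of identifiers in one identifier space.
#' @param denominator Denominator of the percent-common figure: `"union"`
#'   or `"total_sum"` (both the size of the union, counting common
#'   identifiers once) or `"a"` (the size of A).
#' @return A `venn_partition`: `exclusive_a`, `exclusive_b`, `common`,
#'   their counts, `n_union` and `percent_common` (one decimal).
#' @examples
#' venn_partition(letters[1:5], letters[4:8])
#' @export
venn_partition <- function(a, b, denominator = c("union", "total_sum", "a")) {
  denominator <- match.arg(denominator)
  a <- unique(as.character(a)); b <- unique(as.character(b))
  common <- intersect(a, b)
  ex_a <- setdiff(a, b); ex_b <- setdiff(b, a)
  n_union <- length(ex_a) + length(ex_b) + length(common)
  den <- switch(denominator, union = n_union, total_sum = n_union,
                a = length(a))
  structure(list(exclusive_a = ex_a, exclusive_b = ex_b, common = common,
                 n_exclusive_a = length(ex_a), n_exclusive_b = length(ex_b),
                 n_common = length(common), n_union = n_union,
                 denominator = denominator,
                 percent_common = if (den > 0)
                   round1(100 * length(common) / den) else NA_real_),
            class = "venn_partition")
}

#' @export
print.venn_partition <- function(x, ...) {
  cat(sprintf(
    "venn: exclusive A = %d, common = %d, exclusive B = %d (union %d)\n",
    x$n_exclusive_a, x$n_common, x$n_exclusive_b, x$n_union))
  if (!is.na(x$percent_common))
    cat(sprintf("  common = %.1f%% of %s\n", x$percent_common,
                x$denominator))
  invisible(x)
}

#' Overlap percentage of a subset within a total
#'
#' `100 * subset / total`, rounded to one decimal — the "k out of n (x%)"
#' figures of a gene-list report.
#'
#' @param subset_count,total_count Non-negative counts,
#'   `subset_count <= total_count`, `total_count > 0`.
#' @return Percentage with one decimal.
#' @examples
#' overlap_fraction(3, 22)   # 13.6
#' @export
overlap_fraction <- function(subset_count, total_count) {
  if (total_count <= 0) stop("total_count must be > 0")
  if (subset_count < 0 || subset_count > total_count)
    stop("need 0 <= subset_count <= total_count")
  round1(100 * subset_count / total_count)
}

#' Count ratio in "a:1" convention
#'
#' Ratio of two gene-list sizes rounded to one decimal, e.g. the prevalence
#' of one mutant's effects over another's.
#'
#' @param n_a,n_b Counts; `n_b > 0`.
#' @return `n_a / n_b` rounded to one decimal.
#' @examples
#' count_ratio(50, 14)   # 3.6
#' @export
count_ratio <- function(n_a, n_b) {
  if (n_b <= 0) stop("n_b must be > 0")
  round1(n_a / n_b)
}
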