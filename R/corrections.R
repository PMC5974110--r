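#' Genes of the paa (phenylacetate) operon
#'
#' Default operon blacklist for [operon_exclude()]: the paaABCDEFGHIJK
#' operon, the locus hosting the ectopic crp insertion in the emulated
#' experiment (the cloning disrupts paaH and dysregulates the operon). Also
#' shipped as a one-column text file in
#' `system.file("extdata", "paa_operon.txt", package = "qgdemar")`.
#'
#' @format Character vector of 11 gene symbols.
#' @export
paa_operon <- c("paaA", "paaB", "paaC", "paaD", "paaE", "paaF", "paaG",
                "paaH", "paaI", "paaJ", "paaK")

new_correction_report <- function(input, removed, input_id = "detected",
                                  removal_id = "spurious") {
  retained <- setdiff(input, removed)
  structure(list(input_id = input_id, n_input = length(input),
                 removal_id = removal_id, removed = removed,
                 n_removed = length(removed),
                 removed_fraction_pct = if (length(input))
                   100 * length(removed) / length(input) else 0,
                 retained = retained),
            class = "correction_report")
}

#' @export
print.correction_report <- function(x, ...) {
  cat(sprintf(
    "correction: %s (n = %d) minus %s -> removed %d (%.1f%%), retained %d\n",
    x$input_id, x$n_input, x$removal_id, x$n_removed,
    x$removed_fraction_pct, length(x$retained)))
  invisible(x)
}

#' Build spurious-transcription lists from the positional control
#'
#' Runs deconvolution detection on the difference variable
#' `wild type - control` (the delta-N-style cloning control). Probes in the
#' lower tail (control over-transcribed relative to the wild type) are false
#' positives of any mutant-vs-WT contrast; probes in the upper tail
#' (attenuated in the control) are false negatives. Call once per culture
#' phase to get per-phase lists. When the difference carries no signal at
#' all (including the degenerate self-comparison `wt == dn`), both lists
#' are empty.
#'
#' @param pm A [probe_matrix()].
#' @param wt,dn [condition_key()]s of the wild type and the positional
#'   control in one phase.
#' @param q_lo,q_hi Central window for the null fit.
#' @param fdr_target Target FDR percent per tail.
#' @param mode `"quantitative"` (default): the significance-based lists.
#'   `"qualitative"`: exclude by direction of the control's effect
#'   regardless of magnitude — every probe with a negative difference joins
#'   the false-positive list and every positive one the false-negative list
#'   (deliberately over-protective; exposed for comparison).
#' @return List with `false_positive` and `false_negative` probe-id vectors
#'   and, in quantitative mode, `fit` (the underlying [qgdemar()] object, or
#'   `NULL` if the null was degenerate).
#' @export
build_spurious_lists <- function(pm, wt, dn, q_lo = 0.25, q_hi = 0.75,
                                 fdr_target = 5,
                                 mode = c("quantitative", "qualitative")) {
  mode <- match.arg(mode)
  dvar <- condition_difference(pm, wt, dn)
  if (mode == "qualitative") {
    v <- dvar$value
    return(list(false_positive = names(v)[is.finite(v) & v < 0],
                false_negative = names(v)[is.finite(v) & v > 0],
                fit = NULL))
  }
  fit <- tryCatch(
    detect(dvar, q_lo = q_lo, q_hi = q_hi, fdr_target = fdr_target),
    qgdemar_degenerate_null = function(e) NULL)
  if (is.null(fit))
    return(list(false_positive = character(0),
                false_negative = character(0), fit = NULL))
  list(false_positive = detected_probes(fit, "lower"),
       false_negative = detected_probes(fit, "upper"),
       fit = fit)
}

#' Remove spurious identifiers from a detection list
#'
#' Set subtraction with bookkeeping: crossing a detected list against a
#' spurious list retains `detected` minus `spurious` and reports counts and
#' the removed fraction. The canonical use crosses false positives from the
#' positional control against up-regulated lists, and false negatives
#' against down-regulated lists. When a gene map is supplied, matching is
#' done at gene granularity: all probes of a flagged gene are removed.
#'
#' @param detected Character vector of detected identifiers (probe ids or
#'   gene symbols — one identifier space).
#' @param spurious Character vector of spurious identifiers in the same
#'   space.
#' @param gene_map Optional named character vector mapping probe ids to gene
#'   symbols; when given, both lists are interpreted as probe ids and a
#'   probe is removed if its gene symbol matches the gene of any spurious
#'   probe.
#' @param input_id,removal_id Labels recorded in the report.
#' @return A `correction_report`: `retained = detected \ spurious`, counts
#'   and removed fraction in percent. Idempotent in `spurious`.
#' @export
cross_exclude <- function(detected, spurious, gene_map = NULL,
                          input_id = "detected", removal_id = "spurious") {
  detected <- as.character(detected); spurious <- as.character(spurious)
  if (is.null(gene_map)) {
    removed <- intersect(detected, spurious)
  } else {
    bad_genes <- unique(gene_map[spurious])
    bad_genes <- bad_genes[!is.na(bad_genes)]
    g <- gene_map[detected]
    removed <- unique(c(intersect(detected, spurious),
                        detected[!is.na(g) & g %in% bad_genes]))
  }
  new_correction_report(detected, removed, input_id, removal_id)
}

#' Remove genes of an operon blacklist from a detection list
#'
#' The lighter alternative to the positional-control crossing: only the
#' genes of the operon hosting the insertion are excluded, leaving every
#' other detection in place.
#'
#' @param detected Character vector of detected identifiers: gene symbols,
#'   or probe ids if `gene_map` is given.
#' @param operon_genes Character vector of gene symbols to exclude
#'   (default [paa_operon]).
#' @param gene_map Optional named character vector probe id -> gene symbol;
#'   when given, probes whose gene is blacklisted are removed.
#' @return A `correction_report`.
#' @export
operon_exclude <- function(detected, operon_genes = paa_operon,
                           gene_map = NULL) {
  detected <- as.character(detected)
  removed <- if (is.null(gene_map)) {
    intersect(detected, operon_genes)
  } else {
    g <- gene_map[detected]
    detected[!is.na(g) & g %in% operon_genes]
  }
  new_correction_report(detected, removed, removal_id = "operon")
}
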