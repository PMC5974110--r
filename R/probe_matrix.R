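#' Probe-level expression matrix with factorial sample metadata
#'
#' The analysis unit throughout this package is the microarray probe: probes
#' are never summarised into per-gene values. A `probe_matrix` bundles a
#' numeric matrix of log2-normalised intensities (probes x samples) with the
#' factorial metadata (strain, culture phase, replicate) of each sample and an
#' optional gene annotation per probe.
#'
#' @param values Numeric matrix, probes in rows (unique rownames = probe ids),
#'   samples in columns (colnames = sample ids). Values are log2 intensities;
#'   `NA` marks a missing measurement.
#' @param samples Data frame with one row per column of `values` and columns
#'   `sample`, `strain`, `phase`, and optionally `replicate` (integer) and
#'   `growth_rate` (specific growth rate in 1/h; carried as metadata only,
#'   never used in computation).
#' @param gene Optional character vector of gene symbols, one per probe
#'   (`NA` for probes without a gene assignment).
#'
#' @return An object of class `probe_matrix`.
#' @examples
#' vals <- matrix(rnorm(12, 7, 1), 3, 4,
#'                dimnames = list(paste0("p", 1:3), paste0("s", 1:4)))
#' meta <- data.frame(sample = paste0("s", 1:4),
#'                    strain = rep(c("WT", "dcobB"), each = 2),
#'                    phase = "exponential", replicate = rep(1:2, 2))
#' pm <- probe_matrix(vals, meta)
#' pm
#' @export
probe_matrix <- function(values, samples, gene = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || anyDuplicated(rownames(values)))
    stop("probe ids (rownames of `values`) must be present and unique")
  if (is.null(colnames(values)))
    stop("sample ids (colnames of `values`) must be present")
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  req <- c("sample", "strain", "phase")
  miss <- setdiff(req, names(samples))
  if (length(miss))
    stop("`samples` lacks required column(s): ", paste(miss, collapse = ", "))
  if (!setequal(samples$sample, colnames(values)) ||
      anyDuplicated(samples$sample))
    stop("`samples$sample` must match the matrix column names exactly")
  if (anyNA(samples$strain) || anyNA(samples$phase))
    stop("every sample must carry strain and phase labels")
  samples <- samples[match(colnames(values), samples$sample), , drop = FALSE]
  rownames(samples) <- NULL
  if (!is.null(gene)) {
    if (length(gene) != nrow(values))
      stop("`gene` must have one entry per probe")
    gene <- as.character(gene)
    names(gene) <- rownames(values)
  }
  structure(list(values = values, samples = samples, gene = gene),
            class = "probe_matrix")
}

#' @export
print.probe_matrix <- function(x, ...) {
  n_ann <- if (is.null(x$gene)) 0L else sum(!is.na(x$gene) & nzchar(x$gene))
  cat(sprintf("probe_matrix: %d probes x %d samples (%d gene-annotated)\n",
              nrow(x$values), ncol(x$values), n_ann))
  conds <- unique(x$samples[, c("strain", "phase")])
  cat(sprintf("conditions (%d): %s\n", nrow(conds),
              paste(conds$strain, conds$phase, sep = ".", collapse = ", ")))
  invisible(x)
}

#' @export
dim.probe_matrix <- function(x) dim(x$values)

#' Condition key: one cell of the factorial design
#'
#' Identifies a (strain, phase) cell of the design, e.g. the wild type in the
#' glucose-limited chemostat or a mutant in batch-exponential phase.
#'
#' @param strain Strain label (e.g. `"WT"`, `"dcobB"`, `"dN"`).
#' @param phase Culture-phase label (e.g. `"exponential"`, `"stationary"`,
#'   `"chemostat"`).
#' @return An object of class `condition_key`.
#' @examples
#' condition_key("WT", "chemostat")
#' @export
condition_key <- function(strain, phase) {
  stopifnot(is.character(strain), length(strain) == 1L,
            is.character(phase), length(phase) == 1L)
  structure(list(strain = strain, phase = phase), class = "condition_key")
}

#' @export
print.condition_key <- function(x, ...) {
  cat(sprintf("condition: strain=%s phase=%s\n", x$strain, x$phase))
  invisible(x)
}

#' @export
format.condition_key <- function(x, ...) paste(x$strain, x$phase, sep = ".")

as_condition_key <- function(x) {
  if (inherits(x, "condition_key")) return(x)
  if (is.character(x) && length(x) == 2L) return(condition_key(x[[1]], x[[2]]))
  if (is.list(x) && length(x) == 2L)
    return(condition_key(x[[1]], x[[2]]))
  stop("cannot interpret as a condition key: supply condition_key(strain, phase)")
}

# sample ids belonging to one design cell; error if the cell is empty
condition_samples <- function(pm, key) {
  key <- as_condition_key(key)
  hit <- pm$samples$strain == key$strain & pm$samples$phase == key$phase
  if (!any(hit))
    stop(errorCondition(
      sprintf("no samples for condition strain=%s phase=%s",
              key$strain, key$phase),
      class = c("qgdemar_unknown_condition", "error", "condition")))
  pm$samples$sample[hit]
}
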