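#' Read a tab-delimited probe-level expression matrix
#'
#' The canonical interchange format: tab-delimited text, first column
#' `probe_id`, optional second column `gene`, remaining columns one sample
#' each, named in the metadata table. Values are log2-normalised
#' intensities; empty cells or `NA` mark missing values.
#'
#' @param path Path to the file.
#' @param metadata Data frame with columns `sample`, `strain`, `phase` (and
#'   optionally `replicate`, `growth_rate`) covering every sample column.
#' @return A [probe_matrix()].
#' @export
read_probe_matrix <- function(path, metadata) {
  raw <- utils::read.delim(path, check.names = FALSE, colClasses = "character",
                           stringsAsFactors = FALSE)
  if (!ncol(raw) || names(raw)[1] != "probe_id")
    stop("first column must be named 'probe_id'")
  if (anyDuplicated(raw$probe_id))
    stop("duplicate probe ids: ",
         paste(unique(raw$probe_id[duplicated(raw$probe_id)]), collapse = ", "))
  gene <- NULL
  first_sample <- 2L
  if (ncol(raw) >= 2L && names(raw)[2] == "gene") {
    gene <- raw$gene
    gene[!nzchar(gene)] <- NA_character_
    first_sample <- 3L
  }
  sample_cols <- names(raw)[seq(first_sample, ncol(raw))]
  missing_meta <- setdiff(sample_cols, metadata$sample)
  if (length(missing_meta))
    stop("samples without metadata: ", paste(missing_meta, collapse = ", "))
  vals <- matrix(NA_real_, nrow(raw), length(sample_cols),
                 dimnames = list(raw$probe_id, sample_cols))
  for (j in seq_along(sample_cols)) {
    txt <- raw[[sample_cols[j]]]
    num <- suppressWarnings(as.numeric(txt))
    bad <- which(!is.na(txt) & nzchar(txt) & is.na(num))
    if (length(bad))
      stop(sprintf("non-numeric value '%s' in column '%s', data line %d",
                   txt[bad[1]], sample_cols[j], bad[1]))
    vals[, j] <- num
  }
  probe_matrix(vals, metadata[metadata$sample %in% sample_cols, , drop = FALSE],
               gene = gene)
}

#' Write a probe matrix as tab-delimited text
#'
#' Inverse of [read_probe_matrix()]; `read_probe_matrix(write_probe_matrix(pm))`
#' round-trips the matrix.
#'
#' @param pm A [probe_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_probe_matrix <- function(pm, path) {
  stopifnot(inherits(pm, "probe_matrix"))
  df <- data.frame(probe_id = rownames(pm$values), stringsAsFactors = FALSE)
  if (!is.null(pm$gene)) {
    g <- unname(pm$gene); g[is.na(g)] <- ""
    df$gene <- g
  }
  df <- cbind(df, as.data.frame(pm$values))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write sample metadata as tab-delimited text
#' @param pm A [probe_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sample_metadata <- function(pm, path) {
  utils::write.table(pm$samples, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a GEO series-matrix file (optional adapter)
#'
#' Minimal reader for the SOFT-derived series-matrix text format: the
#' expression block between `!series_matrix_table_begin` and
#' `!series_matrix_table_end` is parsed (header row `"ID_REF"` then one
#' sample accession per column). Strain/phase metadata must be supplied
#' externally — GEO sample titles are free text and are not interpreted.
#' Works on local files only; this package never downloads.
#'
#' @param path Path to a (possibly gzipped) series-matrix text file.
#' @param metadata Sample metadata data frame as in [read_probe_matrix()],
#'   with `sample` holding the GEO sample accessions.
#' @param log2_transform If `TRUE`, values are log2-transformed on read
#'   (`log2(x + 1)`). There is no auto-detection of the scale: the caller
#'   states whether the deposited values are linear.
#' @return A [probe_matrix()].
#' @export
read_geo_series_matrix <- function(path, metadata, log2_transform = FALSE) {
  lines <- readLines(path)
  beg <- grep("^!series_matrix_table_begin", lines)
  fin <- grep("^!series_matrix_table_end", lines)
  if (length(beg) != 1L || length(fin) != 1L || fin <= beg + 1L)
    stop("no expression block found: not a series-matrix file?")
  block <- lines[(beg + 1L):(fin - 1L)]
  con <- textConnection(block)
  on.exit(close(con))
  tab <- utils::read.delim(con, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (!grepl("ID_REF", names(tab)[1], fixed = TRUE))
    stop("expression block lacks an ID_REF column")
  ids <- gsub('"', "", as.character(tab[[1]]))
  vals <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(vals) <- "double"
  colnames(vals) <- gsub('"', "", colnames(vals))
  rownames(vals) <- ids
  if (log2_transform) vals <- log2(vals + 1)
  probe_matrix(vals, metadata[metadata$sample %in% colnames(vals), ,
                              drop = FALSE])
}

#' Write a detection result as TSV
#'
#' One row per detected probe: `probe_id`, `gene` (empty when unannotated),
#' `variable_id`, `tail`, `value`, `threshold`, `fdr_percent`.
#'
#' @param fit A [qgdemar()] fit.
#' @param path Output path.
#' @param gene Optional named character vector probe id -> gene symbol.
#' @return The written data frame, invisibly.
#' @export
write_detection_tsv <- function(fit, path, gene = NULL) {
  stopifnot(inherits(fit, "qgdemar"))
  rows <- list()
  for (tail in c("upper", "lower")) {
    tl <- fit$tails[[tail]]
    if (tl$status != "detected" || !length(tl$detected)) next
    g <- if (is.null(gene)) rep("", length(tl$detected)) else {
      gg <- unname(gene[tl$detected]); gg[is.na(gg)] <- ""; gg
    }
    rows[[tail]] <- data.frame(
      probe_id = tl$detected, gene = g, variable_id = fit$variable_id,
      tail = tail, value = unname(fit$values[tl$detected]),
      threshold = tl$threshold, fdr_percent = tl$fdr_percent,
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(probe_id = character(0), gene = character(0),
               variable_id = character(0), tail = character(0),
               value = numeric(0), threshold = numeric(0),
               fdr_percent = numeric(0))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}

#' Write a simulation truth table as TSV
#' @param truth Truth data frame from [simulate_factorial()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth_tsv <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a Venn partition as TSV lists plus a JSON summary
#'
#' @param vp A [venn_partition()].
#' @param prefix Output path prefix; writes `<prefix>_exclusive_a.tsv`,
#'   `<prefix>_exclusive_b.tsv`, `<prefix>_common.tsv` and
#'   `<prefix>_summary.json`.
#' @return Character vector of the written paths, invisibly.
#' @export
write_venn <- function(vp, prefix) {
  stopifnot(inherits(vp, "venn_partition"))
  paths <- c(exclusive_a = paste0(prefix, "_exclusive_a.tsv"),
             exclusive_b = paste0(prefix, "_exclusive_b.tsv"),
             common = paste0(prefix, "_common.tsv"),
             summary = paste0(prefix, "_summary.json"))
  for (nm in c("exclusive_a", "exclusive_b", "common"))
    writeLines(c("id", vp[[nm]]), paths[[nm]])
  jsonlite::write_json(
    list(n_exclusive_a = vp$n_exclusive_a, n_exclusive_b = vp$n_exclusive_b,
         n_common = vp$n_common, n_union = vp$n_union,
         denominator = vp$denominator, percent_common = vp$percent_common),
    paths[["summary"]], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
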