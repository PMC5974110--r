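# build a small probe_matrix from a bare matrix and per-column labels
hand_matrix <- function(values, strain, phase, replicate = NULL,
                        gene = NULL) {
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("p%03d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("s%02d", seq_len(ncol(values)))
  if (is.null(replicate)) {
    replicate <- stats::ave(seq_len(ncol(values)),
                            paste(strain, phase), FUN = seq_along)
  }
  probe_matrix(values,
               data.frame(sample = colnames(values), strain = strain,
                          phase = phase, replicate = replicate,
                          stringsAsFactors = FALSE),
               gene = gene)
}

# two-strain, one-phase simulation parameters with an optional up-spike on
# the mutant-vs-WT ratio; replicate_sd 0.2 with 2 replicates gives the
# log-ratio a null sd of 0.2
two_group_params <- function(n_probes = 2000, frac_up = 0, frac_down = 0,
                             effect = 2, seed = 1, replicates = 2, ...) {
  key_m <- condition_key("M", "exponential")
  key_w <- condition_key("WT", "exponential")
  specs <- if (frac_up > 0 || frac_down > 0)
    list(spike_spec(key_m, key_w, frac_up = frac_up,
                    frac_down = frac_down, effect = effect))
  else list()
  sim_params(n_probes = n_probes, n_annotated = n_probes,
             strains = c("WT", "M"), phases = "exponential",
             growth_rates = c(exponential = 0.62),
             replicates = replicates, spike_specs = specs, seed = seed, ...)
}

mw_ratio <- function(pm) {
  log_ratio(pm, condition_key("M", "exponential"),
            condition_key("WT", "exponential"))
}

# standard two-sided contaminated sample on the variable scale:
# (1 - frac) N(0,1) bulk plus frac/2 spikes at +shift and frac/2 at -shift
contaminated <- function(n, frac, shift, seed) {
  set.seed(seed)
  n_spk <- round(frac * n / 2)
  x <- c(rnorm(n - 2 * n_spk), rnorm(n_spk, shift), rnorm(n_spk, -shift))
  names(x) <- sprintf("p%05d", seq_along(x))
  attr(x, "true_up") <- names(x)[seq(n - 2 * n_spk + 1, n - n_spk)]
  attr(x, "true_down") <- names(x)[seq(n - n_spk + 1, n)]
  x
}
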