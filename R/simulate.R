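#' Spike specification for one ratio-type contrast
#'
#' Describes the differential signal injected into a simulated dataset for
#' one numerator/denominator contrast: a fraction of probes up-regulated in
#' the numerator condition and a fraction up-regulated in the denominator
#' (i.e. down in the ratio), each by a fixed log2 offset.
#'
#' @param numerator,denominator [condition_key()]s of the contrast.
#' @param frac_up,frac_down Fractions of probes spiked in each direction,
#'   each in `[0, 1]` with `frac_up + frac_down < 0.5` (the bulk must stay
#'   null).
#' @param effect Log2 effect size, > 0.
#' @return A `spike_spec` with a `label` identifying the contrast in the
#'   truth table.
#' @export
spike_spec <- function(numerator, denominator, frac_up = 0, frac_down = 0,
                       effect = 2) {
  numerator <- as_condition_key(numerator)
  denominator <- as_condition_key(denominator)
  structure(list(numerator = numerator, denominator = denominator,
                 frac_up = frac_up, frac_down = frac_down, effect = effect,
                 label = sprintf("ratio:%s/%s", format(numerator),
                                 format(denominator))),
            class = "spike_spec")
}

#' Spike specification for an interaction-only contrast
#'
#' Injects probes whose mutant-vs-wild-type effect differs between two
#' conditions: the offset is applied to the (mutant, condition_1) cell only,
#' so the probe lands in the corresponding tail of the
#' [super_ratio()] statistic.
#'
#' @param mutant,wildtype Strain labels.
#' @param condition_1,condition_2 Phase labels (the super-ratio contrasts
#'   condition_1 against condition_2).
#' @inheritParams spike_spec
#' @return An `interaction_spike_spec` with a `label`.
#' @export
interaction_spike_spec <- function(mutant, wildtype, condition_1, condition_2,
                                   frac_up = 0, frac_down = 0, effect = 2) {
  structure(list(mutant = mutant, wildtype = wildtype,
                 condition_1 = condition_1, condition_2 = condition_2,
                 frac_up = frac_up, frac_down = frac_down, effect = effect,
                 label = sprintf("interaction:[%s-%s]@%s-vs-%s", mutant,
                                 wildtype, condition_1, condition_2)),
            class = "interaction_spike_spec")
}

#' Positional-insertion artifact specification
#'
#' Emulates spurious transcription caused by cloning at an ectopic locus: an
#' additive log2 offset on a fraction of probes, applied in the designated
#' strain(s) across every phase. `frac_up` probes are over-expressed in the
#' artifact strains (these become false positives of any mutant-vs-WT
#' contrast and sit in the lower tail of the WT minus control difference);
#' `frac_down` probes are attenuated (false negatives, upper tail of the
#' difference). In the emulated experiment the cloning control and the
#' mutants share the same insertion locus, so `strains` may name several
#' strains carrying the same artifact on the same probes.
#'
#' @param strains Character vector of strain labels carrying the insertion
#'   (default a single delta-N-like control strain).
#' @inheritParams spike_spec
#' @return A `positional_artifact_spec` with a `label`.
#' @export
positional_artifact_spec <- function(strains = "dN", frac_up = 0,
                                     frac_down = 0, effect = 1.5) {
  structure(list(strains = strains, frac_up = frac_up, frac_down = frac_down,
                 effect = effect,
                 label = sprintf("positional:%s",
                                 paste(strains, collapse = "+"))),
            class = "positional_artifact_spec")
}

#' Parameters of a simulated factorial microarray experiment
#'
#' Defaults emulate the structure of the emulated platform and design: an
#' E. coli expression array of 10,207 probes of which 8,662 carry a gene
#' symbol; a wild type plus two mutant strains; batch-exponential,
#' batch-stationary and glucose-limited chemostat phases; triplicate
#' cultures. The per-probe baseline is drawn once from
#' `Normal(null_mu, null_sigma)` and shared across conditions, so every
#' ratio-type variable is centred at zero with scale set by the replicate
#' noise; spikes add fixed log2 offsets in the stated cells. Growth-rate
#' metadata (1/h) is carried per phase but never used in computation.
#'
#' @param n_probes Number of probes.
#' @param n_annotated Number of probes carrying a gene symbol
#'   (`<= n_probes`).
#' @param strains Character vector of strain labels.
#' @param phases Character vector of phase labels.
#' @param growth_rates Optional named numeric vector of specific growth
#'   rates (1/h) per phase, metadata only.
#' @param replicates Replicates per (strain, phase) condition.
#' @param null_mu,null_sigma Mean and spread (log2 units) of the per-probe
#'   baseline intensity across probes; `null_sigma > 0`.
#' @param replicate_sd Within-condition replicate noise standard deviation
#'   (log2 units). The emulated study reports no replicate-variance
#'   estimate, so this is a stated default, not an inference.
#' @param spike_specs List of [spike_spec()]s.
#' @param interaction_spike_specs List of [interaction_spike_spec()]s.
#' @param positional_artifact A [positional_artifact_spec()] or `NULL`.
#' @param seed Integer seed; the seed fully determines the output.
#' @return A validated `sim_params` object.
#' @export
sim_params <- function(n_probes = 10207, n_annotated = 8662,
                       strains = c("WT", "dcobB", "dpatZ"),
                       phases = c("exponential", "stationary", "chemostat"),
                       growth_rates = c(exponential = 0.62, stationary = 0,
                                        chemostat = 0.23),
                       replicates = 3, null_mu = 7.5, null_sigma = 1,
                       replicate_sd = 0.2, spike_specs = list(),
                       interaction_spike_specs = list(),
                       positional_artifact = NULL, seed = 1L) {
  fail <- function(field, msg)
    stop(errorCondition(sprintf("invalid `%s`: %s", field, msg),
                        class = c("qgdemar_invalid_params", "error",
                                  "condition")))
  if (!(is.numeric(n_probes) && n_probes >= 1)) fail("n_probes", "must be >= 1")
  if (n_annotated > n_probes) fail("n_annotated", "must be <= n_probes")
  if (n_annotated < 0) fail("n_annotated", "must be >= 0")
  if (!length(strains)) fail("strains", "must be non-empty")
  if (!length(phases)) fail("phases", "must be non-empty")
  if (!(replicates >= 1)) fail("replicates_per_condition", "must be >= 1")
  if (!(null_sigma > 0)) fail("null_sigma", "must be > 0")
  if (!(replicate_sd >= 0)) fail("replicate_sd", "must be >= 0")
  check_spike <- function(sp, field) {
    if (!(sp$frac_up >= 0 && sp$frac_up <= 1 &&
          sp$frac_down >= 0 && sp$frac_down <= 1))
      fail(field, "fractions must lie in [0, 1]")
    if (sp$frac_up + sp$frac_down >= 0.5)
      fail(field, "up + down fractions must be < 0.5 per contrast")
    if (!(sp$effect > 0)) fail(field, "effect size must be > 0")
  }
  for (sp in spike_specs) {
    if (!inherits(sp, "spike_spec")) fail("spike_specs", "expects spike_spec objects")
    check_spike(sp, "spike_specs")
  }
  for (sp in interaction_spike_specs) {
    if (!inherits(sp, "interaction_spike_spec"))
      fail("interaction_spike_specs", "expects interaction_spike_spec objects")
    check_spike(sp, "interaction_spike_specs")
  }
  if (!is.null(positional_artifact)) {
    if (!inherits(positional_artifact, "positional_artifact_spec"))
      fail("positional_artifact", "expects a positional_artifact_spec")
    check_spike(positional_artifact, "positional_artifact")
    if (!all(positional_artifact$strains %in% strains))
      fail("positional_artifact", "artifact strains must be among `strains`")
  }
  structure(list(n_probes = as.integer(n_probes),
                 n_annotated = as.integer(n_annotated), strains = strains,
                 phases = phases, growth_rates = growth_rates,
                 replicates = as.integer(replicates), null_mu = null_mu,
                 null_sigma = null_sigma, replicate_sd = replicate_sd,
                 spike_specs = spike_specs,
                 interaction_spike_specs = interaction_spike_specs,
                 positional_artifact = positional_artifact,
                 seed = as.integer(seed)),
            class = "sim_params")
}

# deterministic sub-seed per spike stream so adding a spec never perturbs
# the null draw or the other specs' probe picks
derive_seed <- function(seed, k) (seed * 3L + 10007L * k) %% 2147483647L

#' Simulate a factorial probe-level microarray dataset with known truth
#'
#' Draws a per-probe baseline from the stated Gaussian null, adds i.i.d.
#' replicate noise, injects the configured spikes (ratio contrasts,
#' interaction-only, positional artifacts) as additive log2 offsets, and
#' records every injected effect in a truth table. One RNG stream per
#' (spec, role), all derived from `seed`: the same seed gives bit-identical
#' output, and adding a spike spec does not perturb the null draw.
#'
#' @param params A [sim_params()] object.
#' @return A list with `matrix` (a [probe_matrix()]) and `truth` (data frame
#'   `probe_id`, `contrast`, `direction` in -1/0/+1, `effect_size`; only
#'   nonzero-direction rows are stored — absent (probe, contrast) pairs have
#'   direction 0).
#' @examples
#' p <- sim_params(n_probes = 500, n_annotated = 400,
#'                 strains = c("WT", "M"), phases = "exponential",
#'                 replicates = 2, seed = 42)
#' sim <- simulate_factorial(p)
#' sim$matrix
#' @export
simulate_factorial <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  np <- params$n_probes
  conds <- expand.grid(strain = params$strains, phase = params$phases,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  cond_id <- paste(conds$strain, conds$phase, sep = ".")
  nc <- nrow(conds)
  probe_ids <- sprintf("probe_%05d", seq_len(np))

  set.seed(params$seed)                      # null stream
  baseline <- stats::rnorm(np, params$null_mu, params$null_sigma)
  noise <- array(stats::rnorm(np * nc * params$replicates, 0,
                              params$replicate_sd),
                 dim = c(np, nc, params$replicates))

  offsets <- matrix(0, np, nc, dimnames = list(probe_ids, cond_id))
  truth <- list()
  add_truth <- function(ids, label, dir, effect) {
    if (!length(ids)) return()
    truth[[length(truth) + 1L]] <<- data.frame(
      probe_id = ids, contrast = label, direction = dir,
      effect_size = effect, stringsAsFactors = FALSE)
  }
  pick <- function(frac_up, frac_down) {
    n_up <- round(frac_up * np); n_down <- round(frac_down * np)
    sel <- sample.int(np, n_up + n_down)
    list(up = sel[seq_len(n_up)],
         down = if (n_down) sel[n_up + seq_len(n_down)] else integer(0))
  }

  k <- 0L
  for (sp in params$spike_specs) {
    k <- k + 1L
    set.seed(derive_seed(params$seed, k))
    sel <- pick(sp$frac_up, sp$frac_down)
    num <- format(sp$numerator); den <- format(sp$denominator)
    offsets[sel$up, num] <- offsets[sel$up, num] + sp$effect
    offsets[sel$down, den] <- offsets[sel$down, den] + sp$effect
    add_truth(probe_ids[sel$up], sp$label, 1L, sp$effect)
    add_truth(probe_ids[sel$down], sp$label, -1L, sp$effect)
  }
  for (sp in params$interaction_spike_specs) {
    k <- k + 1L
    set.seed(derive_seed(params$seed, k))
    sel <- pick(sp$frac_up, sp$frac_down)
    cell <- paste(sp$mutant, sp$condition_1, sep = ".")
    offsets[sel$up, cell] <- offsets[sel$up, cell] + sp$effect
    offsets[sel$down, cell] <- offsets[sel$down, cell] - sp$effect
    add_truth(probe_ids[sel$up], sp$label, 1L, sp$effect)
    add_truth(probe_ids[sel$down], sp$label, -1L, sp$effect)
  }
  if (!is.null(params$positional_artifact)) {
    sp <- params$positional_artifact
    k <- k + 1L
    set.seed(derive_seed(params$seed, k))
    sel <- pick(sp$frac_up, sp$frac_down)
    for (s in sp$strains) for (ph in params$phases) {
      cell <- paste(s, ph, sep = ".")
      offsets[sel$up, cell] <- offsets[sel$up, cell] + sp$effect
      offsets[sel$down, cell] <- offsets[sel$down, cell] - sp$effect
    }
    add_truth(probe_ids[sel$up], sp$label, 1L, sp$effect)
    add_truth(probe_ids[sel$down], sp$label, -1L, sp$effect)
  }

  vals <- matrix(NA_real_, np, nc * params$replicates)
  samp_names <- character(nc * params$replicates)
  meta <- vector("list", nc * params$replicates)
  j <- 0L
  for (ci in seq_len(nc)) for (r in seq_len(params$replicates)) {
    j <- j + 1L
    vals[, j] <- baseline + offsets[, ci] + noise[, ci, r]
    samp_names[j] <- sprintf("%s.r%d", cond_id[ci], r)
    gr <- params$growth_rates[conds$phase[ci]]
    meta[[j]] <- data.frame(sample = samp_names[j], strain = conds$strain[ci],
                            phase = conds$phase[ci], replicate = r,
                            growth_rate = if (is.null(gr) || is.na(gr))
                              NA_real_ else unname(gr),
                            stringsAsFactors = FALSE)
  }
  dimnames(vals) <- list(probe_ids, samp_names)
  gene <- rep(NA_character_, np)
  if (params$n_annotated > 0)
    gene[seq_len(params$n_annotated)] <-
      sprintf("g%05d", seq_len(params$n_annotated))
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(probe_id = character(0), contrast = character(0),
               direction = integer(0), effect_size = numeric(0))
  list(matrix = probe_matrix(vals, do.call(rbind, meta), gene = gene),
       truth = truth)
}

#' Compare a detection result against simulation truth
#'
#' Per-tail sensitivity (detected true spikes / total true spikes) and
#' realized false discovery proportion (detected non-spikes / detected),
#' with 0/0 reported as `NA` (absent).
#'
#' @param result A [qgdemar()] fit obtained on the simulated data.
#' @param truth The truth table from [simulate_factorial()].
#' @param contrast The contrast label (a string, or a spec object carrying
#'   `$label`) identifying which truth rows apply.
#' @return A `recovery_report`: data frame with one row per tail plus a
#'   pooled row, columns `tail`, `n_true`, `n_detected`, `n_true_detected`,
#'   `sensitivity`, `fdp`.
#' @export
evaluate_detection <- function(result, truth, contrast) {
  stopifnot(inherits(result, "qgdemar"), is.data.frame(truth))
  if (is.list(contrast) && !is.null(contrast$label)) contrast <- contrast$label
  stopifnot(is.character(contrast), length(contrast) == 1L)
  universe <- names(result$values)
  tr <- truth[truth$contrast == contrast, , drop = FALSE]
  if (nrow(tr) && !all(tr$probe_id %in% universe))
    stop("truth and detection result refer to different probe universes")
  true_up <- tr$probe_id[tr$direction > 0]
  true_dn <- tr$probe_id[tr$direction < 0]
  row_for <- function(tail, det, tru) {
    data.frame(tail = tail, n_true = length(tru), n_detected = length(det),
               n_true_detected = length(intersect(det, tru)),
               sensitivity = if (length(tru))
                 length(intersect(det, tru)) / length(tru) else NA_real_,
               fdp = if (length(det))
                 length(setdiff(det, tru)) / length(det) else NA_real_,
               stringsAsFactors = FALSE)
  }
  det_up <- detected_probes(result, "upper")
  det_dn <- detected_probes(result, "lower")
  out <- rbind(row_for("upper", det_up, true_up),
               row_for("lower", det_dn, true_dn),
               row_for("pooled", union(det_up, det_dn),
                       union(true_up, true_dn)))
  class(out) <- c("recovery_report", class(out))
  out
}
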