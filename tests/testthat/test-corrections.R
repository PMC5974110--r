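artifact_world <- function(seed, n_probes = 4000, frac_fp = 0.02,
                           frac_fn = 0.01) {
  # WT, a mutant M and a delta-N-like control; M and dN share the
  # positional insertion, so artifact probes contaminate the M-vs-WT ratio
  sim_params(
    n_probes = n_probes, n_annotated = n_probes,
    strains = c("WT", "M", "dN"), phases = "exponential", replicates = 2,
    growth_rates = c(exponential = 0.62),
    spike_specs = list(spike_spec(condition_key("M", "exponential"),
                                  condition_key("WT", "exponential"),
                                  frac_up = 0.02, effect = 1.5)),
    positional_artifact = positional_artifact_spec(
      strains = c("M", "dN"), frac_up = frac_fp, frac_down = frac_fn,
      effect = 1.5),
    seed = seed)
}

test_that("the positional-control lists recover the injected artifact probes", {
  p <- artifact_world(seed = 41)
  sim <- simulate_factorial(p)
  lists <- build_spurious_lists(sim$matrix, condition_key("WT", "exponential"),
                                condition_key("dN", "exponential"))
  tr <- sim$truth[sim$truth$contrast == p$positional_artifact$label, ]
  over <- tr$probe_id[tr$direction == 1]    # over-expressed in dN => WT-dN << 0
  under <- tr$probe_id[tr$direction == -1]
  expect_gt(length(intersect(lists$false_positive, over)) / length(over), 0.8)
  expect_gt(length(intersect(lists$false_negative, under)) / length(under), 0.8)
  # the lists are dominated by artifact probes, not noise
  expect_gt(mean(lists$false_positive %in% over), 0.8)
})

test_that("without artifacts the spurious lists are empty in most seeds", {
  empty <- 0L
  for (seed in 1:10) {
    sim <- simulate_factorial(sim_params(
      n_probes = 2000, n_annotated = 2000, strains = c("WT", "dN"),
      phases = "exponential", growth_rates = c(exponential = 0.62),
      replicates = 2, seed = seed))
    lists <- build_spurious_lists(sim$matrix,
                                  condition_key("WT", "exponential"),
                                  condition_key("dN", "exponential"))
    if (!length(lists$false_positive) && !length(lists$false_negative))
      empty <- empty + 1L
  }
  expect_gt(empty, 5L)
})

test_that("self-comparison yields empty spurious lists, not an error", {
  sim <- simulate_factorial(two_group_params(n_probes = 500, seed = 2))
  key <- condition_key("WT", "exponential")
  lists <- build_spurious_lists(sim$matrix, key, key)
  expect_identical(lists$false_positive, character(0))
  expect_identical(lists$false_negative, character(0))
})

test_that("qualitative mode excludes by direction regardless of magnitude", {
  p <- artifact_world(seed = 43)
  sim <- simulate_factorial(p)
  keyw <- condition_key("WT", "exponential")
  keyn <- condition_key("dN", "exponential")
  qual <- build_spurious_lists(sim$matrix, keyw, keyn, mode = "qualitative")
  quant <- build_spurious_lists(sim$matrix, keyw, keyn)
  # direction-only exclusion is far broader (over-protective by design)
  expect_gt(length(qual$false_positive), length(quant$false_positive))
  expect_true(all(quant$false_positive %in% qual$false_positive))
})

test_that("cross_exclude is exact set arithmetic with a faithful report", {
  detected <- sprintf("g%02d", 1:10)
  spurious <- c(sprintf("g%02d", 3:6), "other")
  rep_ <- cross_exclude(detected, spurious)
  expect_identical(length(rep_$retained), 6L)
  expect_identical(rep_$n_removed, 4L)
  expect_equal(rep_$removed_fraction_pct, 40)
  expect_identical(rep_$retained, setdiff(detected, spurious))
  # empty spurious set: nothing changes
  rep0 <- cross_exclude(detected, character(0))
  expect_identical(rep0$retained, detected)
  expect_equal(rep0$removed_fraction_pct, 0)
  # empty input: fraction is 0, not NaN
  expect_equal(cross_exclude(character(0), spurious)$removed_fraction_pct, 0)
  # idempotence and partition properties over random sets
  for (seed in 1:5) {
    set.seed(seed)
    a <- sample(sprintf("p%03d", 1:200), 80)
    b <- sample(sprintf("p%03d", 1:200), 50)
    r1 <- cross_exclude(a, b)
    r2 <- cross_exclude(r1$retained, b)
    expect_identical(r2$retained, r1$retained)
    expect_identical(r2$n_removed, 0L)
    expect_true(all(r1$retained %in% a))
    expect_identical(length(r1$retained) + r1$n_removed, length(a))
    expect_true(all(r1$removed %in% b))   # never removes an unlisted probe
  }
})

test_that("gene-granularity crossing removes all probes of a flagged gene", {
  gene_map <- c(p1 = "gA", p2 = "gA", p3 = "gB", p4 = "gC", p5 = NA)
  rep_ <- cross_exclude(c("p1", "p2", "p3", "p5"), "p1", gene_map = gene_map)
  # p1 is spurious; its gene gA flags p2 as well; gB and the unannotated
  # probe survive
  expect_identical(sort(rep_$removed), c("p1", "p2"))
  expect_identical(sort(rep_$retained), c("p3", "p5"))
})

test_that("operon exclusion removes exactly the blacklisted genes", {
  detected <- c("paaH", "fliR", "prpB")
  rep_ <- operon_exclude(detected)
  expect_identical(rep_$removed, "paaH")
  expect_identical(rep_$retained, c("fliR", "prpB"))
  expect_identical(rep_$n_input - rep_$n_removed, 2L)
  # no overlap or empty blacklist: unchanged
  expect_identical(operon_exclude(c("fliR", "prpB"))$retained,
                   c("fliR", "prpB"))
  expect_identical(operon_exclude(detected, character(0))$retained, detected)
  # probe-level input with a gene map
  gm <- c(probe_1 = "paaA", probe_2 = "motA")
  expect_identical(operon_exclude(c("probe_1", "probe_2"),
                                  gene_map = gm)$retained, "probe_2")
  # the shipped blacklist file matches the built-in default
  path <- system.file("extdata", "paa_operon.txt", package = "qgdemar")
  expect_identical(readLines(path), paa_operon)
})

test_that("crossing the positional lists lowers the realized FDP", {
  p <- artifact_world(seed = 47)
  sim <- simulate_factorial(p)
  keym <- condition_key("M", "exponential")
  keyw <- condition_key("WT", "exponential")
  fit <- detect(log_ratio(sim$matrix, keym, keyw), fdr_target = 5)
  true_up <- sim$truth$probe_id[
    sim$truth$contrast == p$spike_specs[[1]]$label & sim$truth$direction == 1]
  det <- detected_probes(fit, "upper")
  lists <- build_spurious_lists(sim$matrix, keyw,
                                condition_key("dN", "exponential"))
  corr <- cross_exclude(det, lists$false_positive)
  fdp <- function(d) length(setdiff(d, true_up)) / max(length(d), 1)
  expect_gt(fdp(det), 0.2)                  # artifacts contaminate the list
  expect_lt(fdp(corr$retained), fdp(det))   # crossing removes them
  expect_gt(length(intersect(corr$retained, true_up)), 0L)
})
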