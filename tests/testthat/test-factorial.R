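make_tiny <- function() {
  # 3 probes, two strains x two phases, 2 replicates; hand-set means
  vals <- cbind(
    "WT.e.1" = c(4, 8, 1), "WT.e.2" = c(6, 8, 1),
    "M.e.1" = c(7, 10, 1), "M.e.2" = c(7, 10, 1),
    "WT.s.1" = c(5, 8, 2), "WT.s.2" = c(5, 8, 2),
    "M.s.1" = c(6, 9, 2), "M.s.2" = c(6, 9, 2))
  rownames(vals) <- c("pA", "pB", "pC")
  hand_matrix(vals,
              strain = rep(c("WT", "M", "WT", "M"), each = 2),
              phase = rep(c("e", "s"), each = 4),
              gene = c("paaH", "yfiQ", NA))
}

test_that("condition_mean averages replicates and flags fully-missing probes", {
  pm <- make_tiny()
  expect_equal(unname(condition_mean(pm, condition_key("WT", "e"))),
               c(5, 8, 1))   # (4+6)/2 etc.
  # single replicate: identity on that column
  one <- hand_matrix(matrix(c(3, 9), 2, 1), strain = "WT", phase = "e")
  expect_equal(unname(condition_mean(one, condition_key("WT", "e"))), c(3, 9))
  # partial missing -> mean of available; all missing -> NA
  v <- pm$values; v["pA", "WT.e.1"] <- NA
  v["pB", c("WT.e.1", "WT.e.2")] <- NA
  pm2 <- probe_matrix(v, pm$samples, gene = pm$gene)
  cm <- condition_mean(pm2, condition_key("WT", "e"))
  expect_equal(unname(cm[c("pA", "pB")]), c(6, NA))
  expect_error(condition_mean(pm, condition_key("WT", "chemostat")),
               class = "qgdemar_unknown_condition")
})

test_that("log_ratio, difference and log2_quotient follow their definitions", {
  pm <- make_tiny()
  ke_m <- condition_key("M", "e"); ke_w <- condition_key("WT", "e")
  lr <- log_ratio(pm, ke_m, ke_w)
  expect_identical(lr$kind, "log_ratio")
  expect_equal(unname(lr$value), c(2, 2, 0))      # means (7,10,1) vs (5,8,1)
  expect_equal(unname(log_ratio(pm, ke_w, ke_w)$value), c(0, 0, 0))
  expect_equal(log_ratio(pm, ke_w, ke_m)$value, -lr$value)

  d <- condition_difference(pm, ke_m, ke_w)
  expect_identical(d$kind, "difference")
  expect_equal(unname(d$value), c(2, 2, 0))
  expect_equal(unname(condition_difference(pm, ke_w, ke_w)$value), c(0, 0, 0))

  q <- log2_quotient(pm, ke_m, ke_w)
  expect_identical(q$kind, "log2_quotient")
  expect_equal(unname(q$value), c(7 / 5, 10 / 8, 1))
  expect_equal(unname(log2_quotient(pm, ke_w, ke_w)$value), c(1, 1, 1))
  # zero denominator mean: probe flagged missing; all-zero -> error
  v <- pm$values; v["pC", c("WT.e.1", "WT.e.2")] <- 0
  pmz <- probe_matrix(v, pm$samples)
  expect_true(is.na(log2_quotient(pmz, ke_m, ke_w)$value[["pC"]]))
  vz <- pm$values; vz[, c("WT.e.1", "WT.e.2")] <- 0
  expect_error(log2_quotient(probe_matrix(vz, pm$samples), ke_m, ke_w),
               "zero")
})

test_that("super_ratio matches its 2x2 definition and identities hold exactly", {
  pm <- make_tiny()
  sr <- super_ratio(pm, "M", "WT", "e", "s")
  # (M-WT)_e = (2,2,0); (M-WT)_s = (1,1,0)
  expect_equal(unname(sr$value), c(1, 1, 0))
  # antisymmetry and compositionality, exactly, on random matrices
  for (seed in 1:5) {
    set.seed(seed)
    vals <- matrix(rnorm(200 * 8, 7, 1), 200, 8)
    pmr <- hand_matrix(vals, strain = rep(c("WT", "M", "WT", "M"), each = 2),
                       phase = rep(c("e", "s"), each = 4))
    s12 <- super_ratio(pmr, "M", "WT", "e", "s")
    s21 <- super_ratio(pmr, "M", "WT", "s", "e")
    expect_equal(s12$value, -s21$value, tolerance = 1e-12)
    lr_e <- log_ratio(pmr, condition_key("M", "e"), condition_key("WT", "e"))
    lr_s <- log_ratio(pmr, condition_key("M", "s"), condition_key("WT", "s"))
    expect_equal(s12$value, lr_e$value - lr_s$value, tolerance = 1e-12)
  }
  # mutant effect identical in both phases -> all zeros
  base <- matrix(rnorm(100 * 4, 7, 1), 100, 4)
  shifted <- cbind(base[, 1:2], base[, 1:2] + 1, base[, 3:4],
                   base[, 3:4] + 1)
  pms <- hand_matrix(shifted, strain = rep(c("WT", "M", "WT", "M"), each = 2),
                     phase = rep(c("e", "s"), each = 4))
  expect_equal(max(abs(super_ratio(pms, "M", "WT", "e", "s")$value)), 0)
})

test_that("interaction-only spikes land in the super-ratio tail and are recovered", {
  spec <- interaction_spike_spec("M", "WT", "chemostat", "exponential",
                                 frac_up = 0.01, effect = 2)
  p <- sim_params(n_probes = 4000, n_annotated = 4000,
                  strains = c("WT", "M"),
                  phases = c("exponential", "chemostat"), replicates = 2,
                  interaction_spike_specs = list(spec), seed = 17)
  sim <- simulate_factorial(p)
  sr <- super_ratio(sim$matrix, "M", "WT", "chemostat", "exponential")
  fit <- detect(sr, fdr_target = 5)
  r <- evaluate_detection(fit, sim$truth, spec)
  expect_gt(r[r$tail == "upper", "sensitivity"], 0.9)
  expect_lt(r[r$tail == "upper", "fdp"], 0.2)
})

test_that("self-comparison of equivalent conditions is NDAS in most seeds", {
  # two strains simulated with no differential signal: the difference
  # variable carries replicate noise only
  ndas <- 0L
  for (seed in 1:10) {
    sim <- simulate_factorial(two_group_params(n_probes = 2000, seed = seed))
    d <- condition_difference(sim$matrix, condition_key("M", "exponential"),
                              condition_key("WT", "exponential"))
    fit <- detect(d, fdr_target = 5)
    if (fit$tails$upper$status == "NDAS" &&
        fit$tails$lower$status == "NDAS") ndas <- ndas + 1L
  }
  expect_gt(ndas, 5L)
})

test_that("concordance recovers slope and R2", {
  pm <- make_tiny()
  self <- concordance(pm, condition_key("WT", "e"), condition_key("WT", "e"))
  expect_equal(self$slope, 1); expect_equal(self$r_squared, 1)
  expect_identical(self$n_probes, 3L)

  # strains sharing the transcriptome: baseline dominates, identity line
  sim <- simulate_factorial(two_group_params(n_probes = 4000, seed = 31))
  cc <- concordance(sim$matrix, condition_key("M", "exponential"),
                    condition_key("WT", "exponential"))
  expect_gt(cc$r_squared, 0.95)
  expect_lt(abs(cc$slope - 1), 0.05)

  # independent profiles: R2 near zero
  set.seed(32)
  v <- cbind(a1 = rnorm(2000, 7), a2 = rnorm(2000, 7),
             b1 = rnorm(2000, 7), b2 = rnorm(2000, 7))
  pmi <- hand_matrix(v, strain = c("A", "A", "B", "B"), phase = "e")
  ci <- concordance(pmi, condition_key("A", "e"), condition_key("B", "e"))
  expect_lt(ci$r_squared, 0.05)

  # agrees with lm() on a noisy regression
  ref <- lm(condition_mean(sim$matrix, condition_key("M", "exponential")) ~
              condition_mean(sim$matrix, condition_key("WT", "exponential")))
  expect_equal(cc$slope, unname(coef(ref)[2]), tolerance = 1e-10)
  expect_equal(cc$intercept, unname(coef(ref)[1]), tolerance = 1e-10)
  expect_equal(cc$r_squared, summary(ref)$r.squared, tolerance = 1e-10)

  # log-ratio pair form and the minimum-probe error
  cr <- concordance(sim$matrix,
                    list(condition_key("M", "exponential"),
                         condition_key("WT", "exponential")),
                    list(condition_key("WT", "exponential"),
                         condition_key("M", "exponential")))
  expect_equal(cr$slope, -1, tolerance = 1e-8)
  tiny <- hand_matrix(matrix(rnorm(4), 2, 2), strain = c("A", "B"),
                      phase = "e")
  v2 <- tiny$values; v2[1, 1] <- NA
  expect_error(concordance(probe_matrix(v2, tiny$samples),
                           condition_key("A", "e"), condition_key("B", "e")),
               "at least 3")
})
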