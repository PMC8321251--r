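test_that("paired log2 fold change matches hand computation", {
  # tumor = normal everywhere -> 0
  coh <- toy_cohort(matrix(c(3, 7), 1, 2), matrix(c(3, 7), 1, 2))
  expect_equal(unname(paired_log2fc(toy_cohort(
    matrix(c(3, 7, 5), 1, 3), matrix(c(3, 7, 5), 1, 3)), "I")), 0)
  # pairs (3,1), (7,3): mean(log2 4 - log2 2, log2 8 - log2 4) = 1
  coh <- toy_cohort(matrix(c(3, 7, 3), 1, 3), matrix(c(1, 3, 1), 1, 3))
  expect_equal(unname(paired_log2fc(coh, "I")), 1.0)
  # doubling tumor values adds ~1 in the large-count limit
  tum <- matrix(c(4000, 8000, 6000), 1, 3)
  nor <- matrix(c(2000, 3000, 2500), 1, 3)
  l1 <- paired_log2fc(toy_cohort(tum, nor), "I")
  l2 <- paired_log2fc(toy_cohort(2 * tum, nor), "I")
  expect_equal(unname(l2 - l1), 1, tolerance = 0.01)
  expect_error(paired_log2fc(toy_cohort(matrix(1, 1, 2), matrix(1, 1, 2)),
                             "I"), "3 pairs")
})

test_that("paired t statistics match the closed form and t.test", {
  # differences (1,2,3) on the log2(x+1) scale: t = 2/(1/sqrt(3)) = 3.464,
  # two-sided p from t(2) ~ 0.0742
  nor <- matrix(2^c(3, 4, 5) - 1, 1, 3)
  tum <- matrix(2^(c(3, 4, 5) + c(1, 2, 3)) - 1, 1, 3)
  res <- paired_t_test(toy_cohort(tum, nor), "I")
  expect_equal(res$t_stat, 2 / (1 / sqrt(3)), tolerance = 1e-10)
  expect_equal(res$p_value, 2 * stats::pt(-2 * sqrt(3), df = 2),
               tolerance = 1e-12)
  expect_equal(res$p_value, 0.0742, tolerance = 1e-3)

  # all-zero differences -> t = 0, p = 1
  res0 <- paired_t_test(toy_cohort(matrix(5, 1, 4), matrix(5, 1, 4)), "I")
  expect_equal(res0$t_stat, 0)
  expect_equal(res0$p_value, 1)

  # constant nonzero differences are degenerate: p -> 0 with a log line
  tum <- matrix(2^(c(3, 4, 5, 6) + 1) - 1, 1, 4)
  nor <- matrix(2^c(3, 4, 5, 6) - 1, 1, 4)
  expect_message(resd <- paired_t_test(toy_cohort(tum, nor), "I"),
                 "degenerate")
  expect_equal(resd$p_value, 0)
  expect_true(is.infinite(resd$t_stat))

  # random matrix agrees with stats::t.test gene by gene
  set.seed(77)
  tum <- matrix(2^matrix(rnorm(50, 6), 10, 5) - 1, 10, 5)
  nor <- matrix(2^matrix(rnorm(50, 6), 10, 5) - 1, 10, 5)
  coh <- toy_cohort(tum, nor)
  res <- paired_t_test(coh, "I")
  for (i in c(1, 5, 10)) {
    ref <- stats::t.test(log2(tum[i, ] + 1), log2(nor[i, ] + 1),
                         paired = TRUE)
    expect_equal(res$t_stat[i], unname(ref$statistic), tolerance = 1e-10)
    expect_equal(res$p_value[i], ref$p.value, tolerance = 1e-10)
  }
})

test_that("DEG calls require both thresholds jointly", {
  de <- data.frame(gene = c("a", "b", "c", "d"),
                   log2fc = c(0.4, -0.7, 0.9, 0.5),
                   t_stat = 0,
                   p_value = c(0.01, 0.01, 0.2, 0.04))
  degs <- call_degs(de, p_cut = 0.05, lfc_cut = 0.5)
  expect_identical(as.character(degs), c("b", "d"))
  # boundary |lfc| = cut passes (>=), boundary p = cut fails (<)
  de2 <- data.frame(gene = "x", log2fc = 0.5, t_stat = 0, p_value = 0.05)
  expect_length(call_degs(de2), 0)
  de2$p_value <- 0.049
  expect_identical(as.character(call_degs(de2)), "x")
})

test_that("null p-values are uniform and DEG counts match the implied rate", {
  sim <- simulate_cohort(simulation_config(
    n_genes = 2000, n_tfs = 10, stages = "I", pairs_per_stage = 10,
    module_sizes = integer(0), deg_log2fc = 0, deg_frac_per_stage = 0,
    n_disease_genes_per_stage = 0, background_altered_frac = 0,
    n_decoy_edges = 10, seed = 31))
  de <- paired_t_test(sim$cohort, "I")
  ks <- stats::ks.test(de$p_value, "punif")
  expect_gt(ks$p.value, 0.01)
  # joint p/lfc null rate from independent normal theory (mean and sd of
  # normal samples are independent)
  set.seed(1)
  B <- 2e5
  sd_d <- sqrt(2)          # difference sd at noise_sd = 1
  n <- 10
  m <- rnorm(B, 0, sd_d / sqrt(n))
  s <- sd_d * sqrt(rchisq(B, n - 1) / (n - 1))
  p <- 2 * stats::pt(-abs(m / (s / sqrt(n))), n - 1)
  rate <- mean(p < 0.05 & abs(m) >= 0.5)
  count <- length(call_degs(de))
  interval <- stats::qbinom(c(0.005, 0.995), 2000, rate)
  expect_gte(count, interval[1])
  expect_lte(count, interval[2])
})

test_that("planted DEGs are recovered with high sensitivity and bounded FDR", {
  hits <- vapply(1:5, function(sd) {
    sim <- simulate_cohort(simulation_config(
      n_genes = 500, n_tfs = 20, stages = "I", pairs_per_stage = 30,
      module_sizes = c(40), deg_log2fc = 1, deg_frac_per_stage = 0.2,
      n_disease_genes_per_stage = 2, n_decoy_edges = 50, seed = sd))
    planted <- sim$truth$deg_genes_by_stage[["I"]]
    called <- call_degs(paired_t_test(sim$cohort, "I"))
    c(sens = length(intersect(called, planted)) / length(planted),
      fdr = if (length(called) > 0)
        length(setdiff(called, planted)) / length(called) else 0)
  }, c(sens = 0, fdr = 0))
  expect_gte(stats::median(hits["sens", ]), 0.9)
  expect_lte(stats::median(hits["fdr", ]), 0.2)
})
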