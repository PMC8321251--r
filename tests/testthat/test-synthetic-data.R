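test_that("configuration invariants are enforced with named errors", {
  expect_error(simulation_config(pairs_per_stage = 2), "pairs_per_stage")
  expect_error(simulation_config(within_module_cor = 1.3),
               "within_module_cor")
  expect_error(simulation_config(module_sizes = rep(100, 30)),
               "module_sizes")
  expect_error(simulation_config(hyper_beta = 0.7), "hyper_beta")
  expect_error(simulation_config(hypo_beta = 0.3), "hyper_beta")
  expect_error(simulation_config(missing_frac = -0.1), "missing_frac")
  expect_error(simulation_config(background_beta_range = c(0.6, 0.3)),
               "background_beta_range")
})

test_that("identical seeds give identical cohorts and byte-identical fixtures", {
  cfg <- simulation_config(n_genes = 120, n_tfs = 12, pairs_per_stage = 4,
                           module_sizes = c(25), n_decoy_edges = 60,
                           n_disease_genes_per_stage = 2, seed = 9)
  s1 <- simulate_cohort(cfg)
  s2 <- simulate_cohort(cfg)
  expect_identical(s1$cohort$expression, s2$cohort$expression)
  expect_identical(s1$truth, s2$truth)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_fixture(s1$cohort, s1$prior, s1$truth, d1)
  write_fixture(s2$cohort, s2$prior, s2$truth, d2)
  for (f in list.files(d1))
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = f)
})

test_that("beta values stay in [0,1] and expression is non-negative", {
  sim <- small_sim(seed = 4)
  expect_gte(min(sim$cohort$beta_sites), 0)
  expect_lte(max(sim$cohort$beta_sites), 1)
  expect_gte(min(sim$cohort$expression), 0)
})

test_that("a zero-effect cohort yields ~5% DEG calls at p < 0.05", {
  sim <- simulate_cohort(simulation_config(
    n_genes = 2000, n_tfs = 10, stages = "I", pairs_per_stage = 10,
    module_sizes = integer(0), deg_log2fc = 0, deg_frac_per_stage = 0,
    n_disease_genes_per_stage = 0, background_altered_frac = 0,
    n_decoy_edges = 10, seed = 21))
  de <- paired_t_test(sim$cohort, "I")
  n_calls <- length(call_degs(de, p_cut = 0.05, lfc_cut = 0))
  interval <- stats::qbinom(c(0.005, 0.995), 2000, 0.05)
  expect_gte(n_calls, interval[1])
  expect_lte(n_calls, interval[2])
})

test_that("planted module correlation matches its target within 0.1", {
  # one 50-gene module at target 0.8, 30 pairs, averaged over 20 seeds
  means <- vapply(1:20, function(sd) {
    sim <- simulate_cohort(simulation_config(
      n_genes = 120, n_tfs = 10, stages = "I", pairs_per_stage = 30,
      module_sizes = 50, within_module_cor = 0.8,
      n_disease_genes_per_stage = 0, n_decoy_edges = 20, seed = sd))
    members <- setdiff(names(sim$truth$module_membership),
                       unique(sim$prior$tf))
    cols <- sim$cohort$metadata$sample_id[
      sim$cohort$metadata$condition == "tumor"]
    r <- stats::cor(t(log2(sim$cohort$expression[members, cols] + 1)))
    mean(r[upper.tri(r)])
  }, 0)
  expect_lt(abs(mean(means) - 0.8), 0.1)
})

test_that("planted effect sizes are recovered with slope near 1", {
  slopes <- vapply(1:20, function(sd) {
    sim <- simulate_cohort(simulation_config(
      n_genes = 300, n_tfs = 20, stages = "I", pairs_per_stage = 30,
      module_sizes = c(40), deg_frac_per_stage = 0.3,
      n_disease_genes_per_stage = 2, n_decoy_edges = 50, seed = sd))
    planted <- sim$truth$deg_genes_by_stage[["I"]]
    expected <- sim$truth$expr_sign[planted] * 1.5
    realized <- paired_log2fc(sim$cohort, "I")[planted]
    unname(stats::coef(stats::lm(realized ~ expected))[2])
  }, 0)
  expect_gte(stats::median(slopes), 0.8)
  expect_lte(stats::median(slopes), 1.2)
})

test_that("methylation shift and expression shift are sign-opposed", {
  sim <- small_sim(seed = 6)
  coh <- sim$cohort
  gb <- quiet(aggregate_beta(coh$beta_sites, coh$cpg_map))
  md <- coh$metadata
  altered <- c(sim$truth$hyper_genes, sim$truth$hypo_genes)
  bshift <- rowMeans(gb[altered, md$sample_id[md$condition == "tumor"]]) -
    rowMeans(gb[altered, md$sample_id[md$condition == "normal"]])
  # expression shift in the stages where the gene is differentially
  # expressed; genes never DE contribute a random sign
  lfc <- rowMeans(vapply(cohort_stages(coh),
                         function(s) paired_log2fc(coh, s)[altered],
                         numeric(length(altered))))
  expect_gte(mean(sign(bshift) != sign(lfc)), 0.9)
})

test_that("fixtures round-trip through the readers", {
  sim <- simulate_cohort(simulation_config(
    n_genes = 100, n_tfs = 10, pairs_per_stage = 4, module_sizes = c(20),
    n_disease_genes_per_stage = 1, n_decoy_edges = 40,
    missing_frac = 0.1, seed = 2))
  d <- withr::local_tempdir()
  write_fixture(sim$cohort, sim$prior, sim$truth, d)
  # NA tokens appear at roughly the configured rate
  expect_equal(mean(is.na(sim$cohort$expression)), 0.1, tolerance = 0.25)
  raw <- as.matrix(utils::read.delim(file.path(d, "expression.tsv"),
                                     row.names = 1))
  expect_equal(mean(is.na(raw)), mean(is.na(sim$cohort$expression)))
  # complete rows reproduce to near machine precision
  keep <- stats::complete.cases(sim$cohort$expression)
  expect_equal(raw[keep, ], sim$cohort$expression[keep, ],
               tolerance = 1e-12, ignore_attr = TRUE)
  tr <- read_ground_truth(file.path(d, "ground_truth.tsv"))
  expect_identical(tr$deg_genes_by_stage,
                   lapply(sim$truth$deg_genes_by_stage, sort))
  expect_identical(sort(tr$hyper_genes), sort(sim$truth$hyper_genes))
  expect_setequal(names(tr$module_membership),
                  names(sim$truth$module_membership))
  inp <- quiet(read_cohort_dir(d, max_missing_frac = 0.5))
  expect_s3_class(inp$cohort, "paired_cohort")
  expect_identical(sort(unique(inp$prior$tf)), sort(unique(sim$prior$tf)))
})
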