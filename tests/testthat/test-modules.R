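test_that("co-expression dissimilarity is 1 - |cor| with brute force", {
  set.seed(8)
  tum <- matrix(2^matrix(rnorm(6 * 10, 6), 6, 10) - 1, 6, 10,
                dimnames = list(sprintf("g%d", 1:6), NULL))
  # gene 2 = affine copy of gene 1, gene 3 = anti-correlated copy
  tum[2, ] <- 2^(2 * log2(tum[1, ] + 1)) - 1
  tum[3, ] <- 2^(12 - log2(tum[1, ] + 1)) - 1
  coh <- toy_cohort(tum, tum)
  d <- coexpression_dissimilarity(coh, rownames(tum), "I")
  expect_equal(unname(d["g1", "g2"]), 0, tolerance = 1e-10)
  expect_equal(unname(d["g1", "g3"]), 0, tolerance = 1e-10)  # |cor|
  expect_true(isSymmetric(d))
  expect_true(all(diag(d) == 0))
  cols <- coh$metadata$sample_id[coh$metadata$condition == "tumor"]
  for (i in 1:5) for (j in (i + 1):6) {
    ref <- 1 - abs(stats::cor(log2(tum[i, ] + 1), log2(tum[j, ] + 1)))
    expect_equal(unname(d[i, j]), ref, tolerance = 1e-10)
  }
})

test_that("UPGMA tree matches hand-computed merge heights", {
  dm <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  dm["a", "b"] <- dm["b", "a"] <- 1
  dm["c", "d"] <- dm["d", "c"] <- 2
  dm["a", "c"] <- dm["c", "a"] <- 4
  dm["a", "d"] <- dm["d", "a"] <- 6
  dm["b", "c"] <- dm["c", "b"] <- 5
  dm["b", "d"] <- dm["d", "b"] <- 7
  tr <- hierarchical_tree(dm)
  # ab at 1, cd at 2, then (ab)(cd) at mean(4,6,5,7) = 5.5
  expect_equal(tr$height, c(1, 2, 5.5))
  expect_error(hierarchical_tree(matrix(c(0, 1, 2, 0), 2, 2)),
               "not symmetric")
})

make_block_diss <- function(sizes, within = 0.1, between = 0.9, seed = 1) {
  set.seed(seed)
  n <- sum(sizes)
  lab <- rep(seq_along(sizes), sizes)
  d <- matrix(between + runif(n * n, -0.03, 0.03), n, n)
  for (k in seq_along(sizes)) {
    idx <- which(lab == k)
    d[idx, idx] <- within + runif(length(idx)^2, -0.03, 0.03)
  }
  d <- (d + t(d)) / 2
  diag(d) <- 0
  dimnames(d) <- list(sprintf("g%03d", 1:n), sprintf("g%03d", 1:n))
  attr(d, "blocks") <- lab
  d
}

test_that("well-separated blocks merge internally before joining", {
  d <- make_block_diss(c(10, 10))
  tr <- hierarchical_tree(d)
  blocks <- attr(d, "blocks")
  # the first n - 2 merges never join the two blocks
  for (j in seq_len(nrow(tr$merge) - 1)) {
    leaves <- stageGRN:::tree_leafset(tr, j)
    expect_equal(length(unique(blocks[leaves])), 1)
  }
})

test_that("tree permutation only relabels leaves", {
  d <- make_block_diss(c(8, 8))
  tr1 <- hierarchical_tree(d)
  perm <- sample(nrow(d))
  tr2 <- hierarchical_tree(d[perm, perm])
  expect_equal(sort(tr1$height), sort(tr2$height), tolerance = 1e-12)
  c1 <- stats::cutree(tr1, 2)
  c2 <- stats::cutree(tr2, 2)[rownames(d)]
  expect_equal(adjusted_rand_index(c1, c2), 1)
})

test_that("dynamic tree cut respects the minimum module size", {
  d <- make_block_diss(c(10, 10))
  tr <- hierarchical_tree(d)
  expect_true(all(dynamic_tree_cut(tr, min_module_size = 30) == 0))

  # two blocks of 40 at low noise split into exactly two pure modules
  sim <- simulate_cohort(simulation_config(
    n_genes = 90, n_tfs = 4, stages = "I", pairs_per_stage = 30,
    module_sizes = c(40, 40), within_module_cor = 0.9, noise_sd = 0.3,
    n_disease_genes_per_stage = 0, n_decoy_edges = 10, seed = 5))
  genes <- names(sim$truth$module_membership)
  d2 <- coexpression_dissimilarity(sim$cohort, genes, "I")
  labs <- dynamic_tree_cut(hierarchical_tree(d2), min_module_size = 30)
  assigned <- labs[labs != 0]
  expect_equal(length(unique(assigned)), 2)
  expect_gte(length(assigned), 0.9 * length(genes))
  for (k in unique(assigned)) {
    planted <- sim$truth$module_membership[names(assigned)[assigned == k]]
    expect_equal(length(unique(planted)), 1)   # block purity
  }
  # every non-grey module respects the minimum size
  expect_true(all(table(assigned) >= 30))
})

test_that("module recovery on the default simulation is near-perfect", {
  sim <- simulate_cohort(simulation_config(seed = 23))
  universe <- names(sim$truth$module_membership)
  d <- coexpression_dissimilarity(sim$cohort, universe, "II")
  labs <- dynamic_tree_cut(hierarchical_tree(d))
  scored <- names(labs)[labs != 0]
  ari <- adjusted_rand_index(labs[scored],
                             sim$truth$module_membership[scored])
  expect_gte(ari, 0.8)
  # agreement with the independent ARI implementation
  if (requireNamespace("mclust", quietly = TRUE)) {
    expect_equal(ari, mclust::adjustedRandIndex(
      labs[scored], sim$truth$module_membership[scored]), tolerance = 1e-12)
  }
})

test_that("color assignment orders modules by size with gene-id tie-break", {
  raw <- stats::setNames(c(rep(1L, 3), rep(2L, 5), rep(3L, 4), 0L),
                         sprintf("g%02d", 1:13))
  part <- assign_colors(raw, "I")
  expect_identical(unname(part$assignment[raw == 2L][1]), "turquoise")
  expect_identical(unname(part$assignment[raw == 3L][1]), "blue")
  expect_identical(unname(part$assignment[raw == 1L][1]), "brown")
  expect_identical(unname(part$assignment["g13"]), "grey")
  expect_identical(module_colors(part), c("turquoise", "blue", "brown"))
  # equal sizes: the module containing the smallest gene id comes first
  raw2 <- stats::setNames(c(rep(2L, 3), rep(1L, 3)), sprintf("g%02d", 1:6))
  part2 <- assign_colors(raw2)
  expect_identical(unname(part2$assignment["g01"]), "turquoise")
  # no modules at all
  expect_true(all(assign_colors(stats::setNames(integer(2),
                                                c("a", "b")))$assignment ==
                    "grey"))
})

test_that("detected partitions are deterministic and cover the node set", {
  sim <- small_sim(seed = 3)
  net <- quiet(build_stage_network(sim$cohort, sim$prior, "I"))
  p1 <- quiet(detect_modules(sim$cohort, net))
  p2 <- quiet(detect_modules(sim$cohort, net))
  expect_identical(p1$assignment, p2$assignment)
  expect_setequal(names(p1$assignment), net$nodes)
  sizes <- table(p1$assignment)
  expect_true(all(sizes[names(sizes) != "grey"] >= 30))
})
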