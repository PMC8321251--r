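write_lines_tsv <- function(lines, path) writeLines(lines, path)

test_that("missing-value filtering and median imputation follow the 15% rule", {
  p <- withr::local_tempfile(fileext = ".tsv")
  # g1: 2/10 missing (0.2 > 0.15 -> dropped); g2: 1/10 missing (imputed)
  hdr <- paste(c("gene", paste0("s", 1:10)), collapse = "\t")
  g1 <- paste(c("g1", 1, 2, "NA", 4, 5, 6, "NA", 8, 9, 10), collapse = "\t")
  g2 <- paste(c("g2", 1, 2, 3, 4, "NA", 6, 7, 8, 9, 100), collapse = "\t")
  g3 <- paste(c("g3", 1:10), collapse = "\t")
  write_lines_tsv(c(hdr, g1, g2, g3), p)
  m <- quiet(read_expression(p, max_missing_frac = 0.15))
  expect_identical(rownames(m), c("g2", "g3"))
  expect_equal(unname(m["g2", "s5"]), median(c(1, 2, 3, 4, 6, 7, 8, 9, 100)))
  expect_equal(unname(m["g3", ]), as.numeric(1:10))

  # complete matrix comes back unchanged
  m2 <- quiet(read_expression(p, max_missing_frac = 1))
  expect_identical(rownames(m2), c("g1", "g2", "g3"))
})

test_that("readers reject malformed input naming the offender", {
  p <- withr::local_tempfile(fileext = ".tsv")
  write_lines_tsv(c("gene\ts1\ts2", "g1\t-1\t2"), p)
  expect_error(read_expression(p), "negative.*g1.*s1")
  write_lines_tsv(c("gene\ts1", "g1\t1", "g1\t2"), p)
  expect_error(read_expression(p), "duplicate")
  write_lines_tsv(c("site\ts1\ts2", "cg1\t0.5\t1.2"), p)
  expect_error(read_beta(p), "cg1.*s2")
  write_lines_tsv(c("sample_id\tpatient_id\tcondition\tstage",
                    "a_T\tpa\ttumor\tI"), p)
  expect_error(read_metadata(p), "pa")
  expect_error(read_expression(tempfile()), "not found")
})

test_that("GMT parsing returns named member sets", {
  p <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("setA\tdesc\tg1\tg2\tg3", "setB\tother\tg2\tg9"), p)
  sets <- read_gmt(p)
  expect_identical(names(sets), c("setA", "setB"))
  expect_identical(sets$setA, c("g1", "g2", "g3"))
  expect_identical(sets$setB, c("g2", "g9"))
  writeLines("broken\tonly-two-fields", p)
  expect_error(read_gmt(p), "malformed")
})

test_that("TF prior construction drops self-pairs and duplicates", {
  pr <- quiet(tf_target_prior(data.frame(
    tf = c("t1", "t1", "t1", "t2", "a"),
    target = c("a", "a", "t1", "b", "t1"))))
  expect_equal(nrow(pr), 3)
  expect_false(any(pr$tf == pr$target))
  # a target that is also a TF elsewhere is a legitimate pair
  expect_true(any(pr$tf == "a" | pr$target == "a"))
})

test_that("network writer round-trips edges, weights and GraphML", {
  edges <- data.frame(tf = c("t1", "t1", "t2"),
                      target = c("a", "b", "a"),
                      pcc = c(0.91234567891234, -0.654, 0.77),
                      p = c(1e-8, 0.002, 0.04))
  net <- stageGRN:::new_stage_network("I", edges)
  p_e <- withr::local_tempfile(fileext = ".tsv")
  p_g <- withr::local_tempfile(fileext = ".graphml")
  write_network(net, p_e, p_g)
  back <- read_network(p_e, "I")
  expect_identical(back$edges$tf, net$edges$tf)
  expect_equal(back$edges$pcc, net$edges$pcc, tolerance = 1e-12)
  expect_equal(back$edges$p, net$edges$p, tolerance = 1e-12)
  g <- igraph::read_graph(p_g, format = "graphml")
  expect_equal(igraph::ecount(g), 3)
  expect_setequal(round(igraph::E(g)$pcc, 6), round(edges$pcc, 6))

  # empty network -> header-only edge file
  empty <- stageGRN:::new_stage_network("I", edges[0, ])
  write_network(empty, p_e)
  expect_identical(readLines(p_e), "tf\ttarget\tpcc\tp")
})

test_that("partition writer emits one row per gene including grey", {
  part <- assign_colors(stats::setNames(c(1L, 1L, 2L, 0L),
                                        c("g1", "g2", "g3", "g4")), "I")
  p <- withr::local_tempfile(fileext = ".tsv")
  write_partition(part, p)
  back <- read_partition(p, "I")
  expect_identical(back$assignment, part$assignment)
  expect_true("grey" %in% back$assignment)
})

test_that("candidate reports round-trip through JSON", {
  rep0 <- structure(list(
    stages = list(I = list(correlation_core = c("a", "b"),
                           topology_core = "a", candidates = "a",
                           specific_modules = "turquoise")),
    shared_genes = character(0)), class = "candidate_report")
  p <- withr::local_tempfile(fileext = ".json")
  write_report(rep0, p)
  back <- read_report(p)
  expect_identical(back$stages$I$candidates, "a")
  expect_identical(back$stages$I$correlation_core, c("a", "b"))
})

test_that("cohort construction enforces pairing and value ranges", {
  tum <- matrix(1:4, 2, 2)
  nor <- matrix(1:4, 2, 2)
  coh <- toy_cohort(tum, nor)
  expect_s3_class(coh, "paired_cohort")
  md_bad <- coh$metadata[-1, ]
  expect_error(paired_cohort(coh$expression[, md_bad$sample_id], NULL, NULL,
                             md_bad), "unpaired")
  bad_beta <- matrix(2, 1, 4,
                     dimnames = list("cg1", coh$metadata$sample_id))
  expect_error(paired_cohort(coh$expression, bad_beta, NULL, coh$metadata),
               "beta")
})
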