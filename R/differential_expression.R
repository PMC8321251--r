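#' Per-gene paired log2 fold change for one stage
#'
#' For every gene, the mean over patients of
#' `log2(tumor + 1) - log2(normal + 1)`, the standard variance-stabilized
#' fold change for FPKM-scale data.
#'
#' @param cohort a [paired_cohort()].
#' @param stage stage label.
#' @return Named numeric vector (one entry per gene).
#' @export
paired_log2fc <- function(cohort, stage) {
  pm <- stage_pair_matrices(cohort, stage)
  if (pm$n_pairs < 3) sg_stop("stage %s has fewer than 3 pairs", stage)
  rowMeans(pm$tumor - pm$normal)
}

#' Paired t-test per gene for one stage
#'
#' Two-sided paired t-test on per-patient differences of log2(x+1)
#' expression, with `n_pairs - 1` degrees of freedom. Genes with zero
#' difference variance get `t = 0, p = 1` when the mean difference is also
#' zero; a nonzero mean with zero variance is degenerate and is reported
#' as `p = 0` with `t = +/-Inf` and a logged warning.
#'
#' @param cohort a [paired_cohort()].
#' @param stage stage label.
#' @return data.frame with columns `gene`, `log2fc`, `t_stat`, `p_value`.
#' @export
paired_t_test <- function(cohort, stage) {
  pm <- stage_pair_matrices(cohort, stage)
  n <- pm$n_pairs
  if (n < 3) sg_stop("stage %s has fewer than 3 pairs", stage)
  d <- pm$tumor - pm$normal
  m <- rowMeans(d)
  s <- sqrt(rowSums((d - m)^2) / (n - 1))
  t_stat <- m / (s / sqrt(n))
  p <- 2 * stats::pt(-abs(t_stat), df = n - 1)
  zero_var <- s == 0
  if (any(zero_var & m == 0)) {
    t_stat[zero_var & m == 0] <- 0
    p[zero_var & m == 0] <- 1
  }
  degen <- zero_var & m != 0
  if (any(degen)) {
    sg_log("paired_t_test: %d degenerate genes (zero variance, nonzero mean)",
           sum(degen))
    t_stat[degen] <- sign(m[degen]) * Inf
    p[degen] <- 0
  }
  data.frame(gene = rownames(d), log2fc = unname(m), t_stat = unname(t_stat),
             p_value = unname(p), stringsAsFactors = FALSE)
}

#' Call differentially expressed genes
#'
#' A gene is a DEG when `p_value < p_cut` and `|log2fc| >= lfc_cut`
#' jointly hold. Raw p-values are thresholded by default;
#' `adjust = "BH"` switches to Benjamini-Hochberg adjusted values.
#'
#' @param de data.frame from [paired_t_test()].
#' @param p_cut p-value threshold, default 0.05.
#' @param lfc_cut absolute log2-fold-change threshold, default 0.5.
#' @param adjust `"none"` (default) or `"BH"`.
#' @return Sorted character vector of DEG ids; the input table with an
#'   `is_deg` column is attached as attribute `"table"`.
#' @export
call_degs <- function(de, p_cut = 0.05, lfc_cut = 0.5, adjust = "none") {
  stopifnot_scalar_prob(p_cut, "p_cut")
  if (lfc_cut < 0) sg_stop("'lfc_cut' must be non-negative")
  p <- if (identical(adjust, "BH"))
    stats::p.adjust(de$p_value, "BH") else de$p_value
  de$is_deg <- p < p_cut & abs(de$log2fc) >= lfc_cut
  out <- sort(de$gene[de$is_deg])
  attr(out, "table") <- de
  out
}

#' Differential expression for every stage of a cohort
#' @inheritParams call_degs
#' @param cohort a [paired_cohort()].
#' @return Named list per stage with elements `table` (the per-gene test
#'   results with `is_deg`) and `degs` (the DEG id vector).
#' @export
run_differential_expression <- function(cohort, p_cut = 0.05, lfc_cut = 0.5,
                                        adjust = "none") {
  stats::setNames(lapply(cohort_stages(cohort), function(s) {
    de <- paired_t_test(cohort, s)
    degs <- call_degs(de, p_cut, lfc_cut, adjust)
    list(table = attr(degs, "table"), degs = as.character(degs))
  }), cohort_stages(cohort))
}
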