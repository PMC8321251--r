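#' Aggregate CpG-site beta values to gene level
#'
#' Per gene and sample, the arithmetic mean beta over that gene's mapped
#' CpG sites. Sites absent from the matrix and genes with zero mapped
#' sites are dropped with a logged count. Invariant to site ordering.
#'
#' @param beta_sites site x sample beta matrix.
#' @param cpg_map data.frame with columns `site`, `gene`.
#' @return Gene x sample matrix with values in [0, 1].
#' @export
aggregate_beta <- function(beta_sites, cpg_map) {
  known <- cpg_map$site %in% rownames(beta_sites)
  if (any(!known))
    sg_log("aggregate_beta: dropped %d unmapped sites", sum(!known))
  cpg_map <- cpg_map[known, , drop = FALSE]
  if (nrow(cpg_map) == 0)
    return(matrix(numeric(0), 0, ncol(beta_sites),
                  dimnames = list(NULL, colnames(beta_sites))))
  m <- beta_sites[cpg_map$site, , drop = FALSE]
  g <- factor(cpg_map$gene, levels = unique(cpg_map$gene))
  out <- rowsum(m, g) / as.vector(table(g))
  rownames(out) <- levels(g)
  out
}

#' Classify genes as hyper-/hypomethylated in a stage's tumor samples
#'
#' Status is decided by the mean beta over the stage's tumor samples with
#' strict thresholds: `hyper` above `beta_hyper`, `hypo` below
#' `beta_hypo`, otherwise `neither` (boundary values are `neither`).
#' `mode = "delta"` instead thresholds the tumor-minus-normal difference
#' at `+/-delta_cut`.
#'
#' @param gene_beta gene x sample beta matrix from [aggregate_beta()].
#' @param metadata cohort metadata (columns `sample_id`, `condition`,
#'   `stage`).
#' @param stage stage label.
#' @param beta_hyper,beta_hypo absolute thresholds (defaults 0.8 / 0.2).
#' @param mode `"absolute"` (default) or `"delta"`.
#' @param delta_cut threshold on tumor - normal mean beta in delta mode.
#' @return data.frame with columns `gene`, `mean_beta_tumor`,
#'   `mean_beta_normal`, `methyl_status`.
#' @export
classify_methylation <- function(gene_beta, metadata, stage,
                                 beta_hyper = 0.8, beta_hypo = 0.2,
                                 mode = c("absolute", "delta"),
                                 delta_cut = 0.2) {
  mode <- match.arg(mode)
  tum <- metadata$sample_id[metadata$stage == stage &
                              metadata$condition == "tumor"]
  nor <- metadata$sample_id[metadata$stage == stage &
                              metadata$condition == "normal"]
  if (length(tum) == 0) sg_stop("stage %s has no tumor samples", stage)
  mt <- rowMeans(gene_beta[, tum, drop = FALSE])
  mn <- if (length(nor) > 0)
    rowMeans(gene_beta[, nor, drop = FALSE]) else rep(NA_real_, nrow(gene_beta))
  status <- rep("neither", nrow(gene_beta))
  if (mode == "absolute") {
    status[mt > beta_hyper] <- "hyper"
    status[mt < beta_hypo] <- "hypo"
  } else {
    dlt <- mt - mn
    status[dlt > delta_cut] <- "hyper"
    status[dlt < -delta_cut] <- "hypo"
  }
  data.frame(gene = rownames(gene_beta), mean_beta_tumor = unname(mt),
             mean_beta_normal = unname(mn), methyl_status = status,
             stringsAsFactors = FALSE)
}

#' Candidate gene universe for one stage
#'
#' The intersection of the stage's DEGs with its hyper- or hypomethylated
#' genes; the gene universe on which the stage network's targets are
#' constrained.
#'
#' @param degs character vector of DEG ids.
#' @param status data.frame from [classify_methylation()].
#' @return Sorted character vector.
#' @export
candidate_universe <- function(degs, status) {
  meth <- status$gene[status$methyl_status %in% c("hyper", "hypo")]
  sort(intersect(degs, meth))
}

#' Per-stage gene status table
#'
#' Joins differential-expression calls with methylation classification
#' into one table per stage, flagging candidate-universe genes.
#'
#' @param de_stage element of [run_differential_expression()] output.
#' @param status data.frame from [classify_methylation()].
#' @return data.frame with per-gene `log2fc`, `p_value`, `is_deg`,
#'   `mean_beta_tumor`, `mean_beta_normal`, `methyl_status`,
#'   `is_candidate`.
#' @export
gene_status_table <- function(de_stage, status) {
  tab <- merge(de_stage$table, status, by = "gene", all.x = TRUE)
  tab$methyl_status[is.na(tab$methyl_status)] <- "neither"
  tab$is_candidate <- tab$is_deg & tab$methyl_status != "neither"
  tab[order(tab$gene), ]
}

#' Methylation-expression inverse-trend summary for one stage
#'
#' Per gene, the Spearman correlation between gene-level beta and
#' expression across the stage's samples (tumor and normal), plus the
#' fraction of `candidates` with negative correlation. Constant vectors
#' give NA.
#'
#' @param gene_beta gene x sample beta matrix.
#' @param expression gene x sample expression matrix.
#' @param metadata cohort metadata.
#' @param stage stage label.
#' @param candidates genes over which the negative fraction is summarized
#'   (default: all shared genes).
#' @return List with `rho` (named vector) and `frac_negative`.
#' @export
methylation_expression_trend <- function(gene_beta, expression, metadata,
                                         stage, candidates = NULL) {
  cols <- metadata$sample_id[metadata$stage == stage]
  if (length(cols) < 3) sg_stop("stage %s has fewer than 3 samples", stage)
  genes <- intersect(rownames(gene_beta), rownames(expression))
  b <- gene_beta[genes, cols, drop = FALSE]
  e <- expression[genes, cols, drop = FALSE]
  rb <- t(apply(b, 1, rank))
  re <- t(apply(e, 1, rank))
  rbz <- row_standardize(rb)
  rez <- row_standardize(re)
  rho <- rowSums(rbz * rez) / (length(cols) - 1)
  rho[attr(rbz, "constant") | attr(rez, "constant")] <- NA_real_
  names(rho) <- genes
  sel <- if (is.null(candidates)) genes else intersect(candidates, genes)
  list(rho = rho,
       frac_negative = mean(rho[sel] < 0, na.rm = TRUE))
}
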