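#' Correlation-core genes of one module
#'
#' Computes all pairwise Pearson correlations within the module over the
#' stage's tumor samples (log2(x+1) scale). A gene is core when the
#' fraction of other module genes with `|r| >= r_cut` and `p < p_cut` is
#' at least `min_partner_frac`.
#'
#' @param cohort a [paired_cohort()].
#' @param genes module gene ids (>= 2, else empty result).
#' @param stage stage label.
#' @param r_cut correlation magnitude cutoff, default 0.8.
#' @param p_cut p-value cutoff, default 0.05.
#' @param min_partner_frac minimum qualifying-partner fraction, default
#'   0.1 (use `1 / (length(genes) - 1)` for the permissive ">= 1
#'   partner" rule).
#' @param adjust `"none"` (default) or `"BH"` on the pair p-values.
#' @return Sorted character vector of core genes.
#' @export
correlation_core_genes <- function(cohort, genes, stage, r_cut = 0.8,
                                   p_cut = 0.05, min_partner_frac = 0.1,
                                   adjust = "none") {
  stopifnot_scalar_prob(r_cut, "r_cut")
  stopifnot_scalar_prob(p_cut, "p_cut")
  stopifnot_scalar_prob(min_partner_frac, "min_partner_frac")
  if (length(genes) < 2) return(character(0))
  cols <- stage_samples(cohort, stage, "tumor")
  z <- row_standardize(log2p1(cohort$expression[genes, cols, drop = FALSE]))
  n <- length(cols)
  r <- tcrossprod(z) / (n - 1)
  p <- cor_p_value(r, n)
  if (identical(adjust, "BH")) {
    up <- upper.tri(p)
    p[up] <- stats::p.adjust(p[up], "BH")
    p[lower.tri(p)] <- t(p)[lower.tri(p)]
  }
  qual <- abs(r) >= r_cut & p < p_cut
  diag(qual) <- FALSE
  frac <- rowSums(qual) / (length(genes) - 1)
  sort(genes[frac >= min_partner_frac])
}

#' Topology-core genes from centrality scores
#'
#' Combines the per-metric top-fraction hub sets (degree, betweenness,
#' closeness). The default union reads "hubs screened by any of the three
#' parameters are core"; `combine = "intersection"` requires all three.
#'
#' @param scores data.frame from [centrality_scores()].
#' @param frac top fraction per metric, default 0.05.
#' @param combine `"union"` (default) or `"intersection"`.
#' @return Sorted character vector of core genes.
#' @export
topology_core_genes <- function(scores, frac = 0.05,
                                combine = c("union", "intersection")) {
  combine <- match.arg(combine)
  tops <- top_fraction(scores, frac)
  if (combine == "union") sort(unique(unlist(tops)))
  else sort(Reduce(intersect, tops))
}

#' Candidate disease genes as the intersection of the two core sets
#' @param correlation_core,topology_core character vectors computed on
#'   the same module set.
#' @return Sorted character vector.
#' @export
predict_candidates <- function(correlation_core, topology_core) {
  sort(intersect(correlation_core, topology_core))
}

#' Genes shared by every stage's candidate set
#' @param per_stage_candidates named list (>= 2 stages) of candidate gene
#'   vectors.
#' @return Sorted character vector (empty if any stage set is empty).
#' @export
shared_across_stages <- function(per_stage_candidates) {
  if (length(per_stage_candidates) < 2) sg_stop("need at least 2 stages")
  sort(Reduce(intersect, per_stage_candidates))
}

#' Per-stage candidate report over the stage's specific modules
#'
#' For each specific module: correlation-core genes, topology-core genes
#' (centralities on the module subgraph of the stage network) and their
#' intersection; stage-level sets are the unions over the stage's
#' specific modules. Per-gene annotations carry module, degree,
#' betweenness, closeness and the maximum within-module |r|.
#'
#' @param cohort a [paired_cohort()].
#' @param network the stage's `stage_network`.
#' @param partition the stage's `module_partition`.
#' @param specific_modules colors of the stage's specific modules.
#' @param r_cut,p_cut,min_partner_frac forwarded to
#'   [correlation_core_genes()].
#' @param top_frac,combine forwarded to [topology_core_genes()].
#' @return List with `correlation_core`, `topology_core`, `candidates`,
#'   `per_gene` (data.frame), `modules` (per-module core sets).
#' @export
stage_candidates <- function(cohort, network, partition, specific_modules,
                             r_cut = 0.8, p_cut = 0.05,
                             min_partner_frac = 0.1, top_frac = 0.05,
                             combine = "union") {
  corr_core <- character(0)
  topo_core <- character(0)
  per_gene <- list()
  mod_out <- list()
  for (cl in specific_modules) {
    genes <- module_genes(partition, cl)
    cc <- correlation_core_genes(cohort, genes, network$stage, r_cut, p_cut,
                                 min_partner_frac)
    g <- module_subgraph(network, genes)
    sc <- centrality_scores(g)
    tc <- if (nrow(sc) > 0) topology_core_genes(sc, top_frac, combine)
          else character(0)
    corr_core <- union(corr_core, cc)
    topo_core <- union(topo_core, tc)
    if (length(genes) >= 2) {
      cols <- stage_samples(cohort, network$stage, "tumor")
      z <- row_standardize(log2p1(cohort$expression[genes, cols,
                                                    drop = FALSE]))
      r <- tcrossprod(z) / (length(cols) - 1)
      diag(r) <- 0
      max_r <- apply(abs(r), 1, max)
    } else max_r <- stats::setNames(rep(NA_real_, length(genes)), genes)
    sc$module <- cl
    sc$max_abs_cor <- unname(max_r[sc$gene])
    per_gene[[cl]] <- sc
    mod_out[[cl]] <- list(correlation_core = cc, topology_core = tc,
                          candidates = predict_candidates(cc, tc))
  }
  list(correlation_core = sort(corr_core),
       topology_core = sort(topo_core),
       candidates = predict_candidates(corr_core, topo_core),
       per_gene = if (length(per_gene) > 0) do.call(rbind, per_gene)
                  else NULL,
       modules = mod_out)
}
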