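#' Stage-exclusive differentially expressed genes
#'
#' Per stage, the DEGs appearing in that stage's set and in no other
#' stage's; the resulting sets are disjoint by construction.
#'
#' @param deg_sets named list (stage -> character vector of DEG ids),
#'   length >= 2.
#' @return Named list of sorted character vectors.
#' @export
stage_exclusive_genes <- function(deg_sets) {
  if (length(deg_sets) < 2) sg_stop("need at least 2 stages")
  stages <- names(deg_sets)
  out <- stats::setNames(lapply(stages, function(s) {
    others <- unique(unlist(deg_sets[setdiff(stages, s)]))
    sort(setdiff(deg_sets[[s]], others))
  }), stages)
  stopifnot(all(table(unlist(out)) == 1))  # disjointness invariant
  out
}

#' Select a stage's specific modules
#'
#' Tests each non-grey module for over-representation of the stage's
#' stage-specific genes with the hypergeometric upper tail (universe =
#' the partition's full node set, grey included) and flags modules with
#' Benjamini-Hochberg FDR below `fdr_cut`. `top_k` instead selects the k
#' modules with the largest specific-gene counts, mirroring selection by
#' inspection of counts.
#'
#' @param partition a `module_partition`.
#' @param specific_genes stage-specific gene ids for this stage.
#' @param fdr_cut BH FDR threshold, default 0.05.
#' @param top_k optional integer overriding the FDR rule.
#' @return data.frame with one row per non-grey module: `module`,
#'   `gene_count`, `specific_gene_count`, `enrichment_p`, `fdr`,
#'   `is_specific_module`.
#' @export
select_specific_modules <- function(partition, specific_genes,
                                    fdr_cut = 0.05, top_k = NULL) {
  universe <- names(partition$assignment)
  spec <- intersect(specific_genes, universe)
  cols <- module_colors(partition)
  if (length(cols) == 0)
    return(data.frame(module = character(0), gene_count = integer(0),
                      specific_gene_count = integer(0),
                      enrichment_p = numeric(0), fdr = numeric(0),
                      is_specific_module = logical(0),
                      stringsAsFactors = FALSE))
  rows <- lapply(cols, function(cl) {
    mem <- module_genes(partition, cl)
    k <- length(intersect(mem, spec))
    p <- hypergeometric_p(k, length(mem), length(spec), length(universe))
    data.frame(module = cl, gene_count = length(mem),
               specific_gene_count = k, enrichment_p = p,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab$fdr <- stats::p.adjust(tab$enrichment_p, "BH")
  if (is.null(top_k)) {
    tab$is_specific_module <- tab$fdr < fdr_cut & tab$specific_gene_count > 0
  } else {
    ord <- order(-tab$specific_gene_count, tab$enrichment_p, tab$module)
    chosen <- tab$module[ord][seq_len(min(top_k, nrow(tab)))]
    tab$is_specific_module <- tab$module %in% chosen &
      tab$specific_gene_count > 0
  }
  tab
}
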