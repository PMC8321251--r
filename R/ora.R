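#' Hypergeometric upper-tail over-representation p-value
#'
#' `P(X >= overlap)` for drawing `module_size` genes without replacement
#' from a universe containing `set_size` annotated genes.
#'
#' @param overlap observed overlap count.
#' @param module_size number of genes in the module.
#' @param set_size number of annotated genes in the universe.
#' @param universe_size universe size.
#' @return p-value in (0, 1].
#' @export
hypergeometric_p <- function(overlap, module_size, set_size, universe_size) {
  if (any(c(overlap, module_size, set_size, universe_size) < 0) ||
      overlap > min(module_size, set_size) ||
      module_size > universe_size || set_size > universe_size)
    sg_stop("inconsistent counts: overlap=%d module=%d set=%d universe=%d",
            overlap, module_size, set_size, universe_size)
  if (overlap == 0) return(1)
  stats::phyper(overlap - 1, set_size, universe_size - set_size,
                module_size, lower.tail = FALSE)
}

#' Hypergeometric over-representation analysis of modules against gene sets
#'
#' One test per (non-grey module, gene set); gene sets are intersected
#' with the universe before testing. BH FDR is computed across each
#' module's tests; `significant` uses the raw p-value against `p_cut`
#' (the FDR column is informational).
#'
#' @param partition a `module_partition`.
#' @param gene_sets named list of gene id vectors (e.g. [read_gmt()]).
#' @param universe background gene ids; defaults to the partition's node
#'   set.
#' @param p_cut raw p-value threshold, default 0.01.
#' @return data.frame with columns `module`, `gene_set`, `overlap`,
#'   `module_size`, `set_size`, `universe_size`, `p_value`, `bh_fdr`,
#'   `significant`.
#' @export
ora <- function(partition, gene_sets, universe = NULL, p_cut = 0.01) {
  stopifnot_scalar_prob(p_cut, "p_cut")
  if (is.null(universe)) universe <- names(partition$assignment)
  universe <- unique(universe)
  if (!all(names(partition$assignment) %in% universe))
    sg_stop("universe must contain all partition genes")
  cols <- module_colors(partition)
  empty <- data.frame(module = character(0), gene_set = character(0),
                      overlap = integer(0), module_size = integer(0),
                      set_size = integer(0), universe_size = integer(0),
                      p_value = numeric(0), bh_fdr = numeric(0),
                      significant = logical(0), stringsAsFactors = FALSE)
  if (length(gene_sets) == 0 || length(cols) == 0) return(empty)
  rows <- list()
  for (cl in cols) {
    mem <- module_genes(partition, cl)
    for (gs in names(gene_sets)) {
      set_in_univ <- intersect(gene_sets[[gs]], universe)
      k <- length(intersect(mem, set_in_univ))
      p <- hypergeometric_p(k, length(mem), length(set_in_univ),
                            length(universe))
      rows[[length(rows) + 1L]] <- data.frame(
        module = cl, gene_set = gs, overlap = k, module_size = length(mem),
        set_size = length(set_in_univ), universe_size = length(universe),
        p_value = p, stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  tab$bh_fdr <- stats::ave(tab$p_value, tab$module,
                           FUN = function(p) stats::p.adjust(p, "BH"))
  tab$significant <- tab$p_value < p_cut
  tab
}
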