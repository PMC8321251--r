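#' Pearson correlation with a two-sided p-value
#'
#' Textbook Pearson r with the t-transform p-value:
#' `t = r * sqrt((n - 2) / (1 - r^2))` against a t distribution with
#' `n - 2` degrees of freedom.
#'
#' @param x,y numeric vectors of equal length >= 3, both non-constant.
#' @return List with elements `r` and `p`.
#' @export
pearson_with_p <- function(x, y) {
  if (length(x) != length(y)) sg_stop("x and y have different lengths")
  n <- length(x)
  if (n < 3) sg_stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    sg_stop("zero variance input to pearson_with_p")
  r <- stats::cor(x, y)
  p <- cor_p_value(r, n)
  list(r = r, p = p)
}

# vectorized two-sided p for Pearson r at sample size n
cor_p_value <- function(r, n) {
  r2 <- pmin(r^2, 1)
  tt <- abs(r) * sqrt((n - 2) / pmax(1 - r2, .Machine$double.eps))
  p <- 2 * stats::pt(-tt, df = n - 2)
  p[r2 >= 1] <- 0
  p
}

#' Restrict a TF->target prior to a candidate universe
#'
#' Keeps pairs whose target lies in `universe`; TFs are unrestricted
#' (a TF need not itself pass the DEG/methylation filter).
#'
#' @param prior a [tf_target_prior()] edge table.
#' @param universe character vector of allowed target genes.
#' @return Filtered [tf_target_prior()].
#' @export
filter_prior <- function(prior, universe) {
  out <- prior[prior$target %in% universe, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("tf_target_prior", "data.frame")
  out
}

new_stage_network <- function(stage, edges) {
  edges <- edges[order(edges$tf, edges$target), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(stage = stage, edges = edges,
                 nodes = sort(unique(c(edges$tf, edges$target)))),
            class = "stage_network")
}

#' @export
print.stage_network <- function(x, ...) {
  cat(sprintf("stage_network '%s': %d nodes, %d edges\n",
              x$stage, length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Build one stage-specific TF->target regulatory network
#'
#' Computes the Pearson correlation of each prior pair over the stage's
#' tumor samples on the log2(x+1) scale and keeps directed edges with
#' `|r| >= pcc_cutoff` (`signed = TRUE` requires `r >= pcc_cutoff`
#' instead). Pairs with a gene absent from the expression matrix or with
#' zero variance are dropped with a logged count.
#'
#' @param cohort a [paired_cohort()].
#' @param prior a (typically universe-filtered) [tf_target_prior()].
#' @param stage stage label.
#' @param pcc_cutoff correlation magnitude cutoff, default 0.5.
#' @param signed keep only positive correlations when TRUE.
#' @param samples `"tumor"` (default) or `"all"`: which of the stage's
#'   samples the correlation is computed over.
#' @return A `stage_network`: directed edges with `pcc` and `p`
#'   attributes, node set = endpoints of retained edges.
#' @export
build_stage_network <- function(cohort, prior, stage, pcc_cutoff = 0.5,
                                signed = FALSE,
                                samples = c("tumor", "all")) {
  samples <- match.arg(samples)
  stopifnot_scalar_prob(pcc_cutoff, "pcc_cutoff")
  cols <- if (samples == "tumor") stage_samples(cohort, stage, "tumor")
          else cohort$metadata$sample_id[cohort$metadata$stage == stage]
  if (length(cols) < 3) sg_stop("stage %s has fewer than 3 samples", stage)
  genes <- rownames(cohort$expression)
  keep <- prior$tf %in% genes & prior$target %in% genes
  if (any(!keep))
    sg_log("build_stage_network[%s]: dropped %d pairs with unmeasured genes",
           stage, sum(!keep))
  pr <- prior[keep, , drop = FALSE]
  empty <- data.frame(tf = character(0), target = character(0),
                      pcc = numeric(0), p = numeric(0),
                      stringsAsFactors = FALSE)
  if (nrow(pr) == 0) return(new_stage_network(stage, empty))
  need <- unique(c(pr$tf, pr$target))
  z <- row_standardize(log2p1(cohort$expression[need, cols, drop = FALSE]))
  const <- attr(z, "constant")
  n <- length(cols)
  r <- rowSums(z[pr$tf, , drop = FALSE] * z[pr$target, , drop = FALSE]) /
    (n - 1)
  bad <- const[match(pr$tf, need)] | const[match(pr$target, need)]
  if (any(bad)) {
    sg_log("build_stage_network[%s]: dropped %d pairs with constant genes",
           stage, sum(bad))
    pr <- pr[!bad, , drop = FALSE]
    r <- r[!bad]
  }
  p <- cor_p_value(r, n)
  keep_edge <- if (signed) r >= pcc_cutoff else abs(r) >= pcc_cutoff
  edges <- data.frame(tf = pr$tf, target = pr$target, pcc = unname(r),
                      p = unname(p), stringsAsFactors = FALSE)
  net <- new_stage_network(stage, edges[keep_edge, , drop = FALSE])
  sg_log("build_stage_network[%s]: %d nodes, %d edges (|r| >= %.2f)",
         stage, length(net$nodes), nrow(net$edges), pcc_cutoff)
  net
}

# igraph view of a stage network
network_igraph <- function(network, directed = TRUE) {
  if (nrow(network$edges) == 0)
    return(igraph::make_empty_graph(n = length(network$nodes),
                                    directed = directed))
  g <- igraph::graph_from_data_frame(network$edges, directed = directed,
                                     vertices = network$nodes)
  g
}
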