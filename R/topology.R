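#' Undirected module subgraph of a stage network
#'
#' Keeps the edges of the stage network with both endpoints in the module,
#' drops direction and collapses parallel/reciprocal edges. All module
#' genes are vertices, including isolated ones.
#'
#' @param network a `stage_network`.
#' @param genes module gene ids (subset of the network's nodes).
#' @return An undirected simple [igraph] graph.
#' @export
module_subgraph <- function(network, genes) {
  if (!all(genes %in% network$nodes))
    sg_stop("module genes missing from the network: %s",
            paste(utils::head(setdiff(genes, network$nodes), 3),
                  collapse = ", "))
  e <- network$edges
  e <- e[e$tf %in% genes & e$target %in% genes, , drop = FALSE]
  if (nrow(e) == 0)
    return(igraph::make_empty_graph(n = 0, directed = FALSE) +
             igraph::vertices(sort(genes)))
  g <- igraph::graph_from_data_frame(e[, c("tf", "target")],
                                     directed = FALSE,
                                     vertices = sort(genes))
  igraph::simplify(g)
}

#' Degree, betweenness and closeness centrality of a module graph
#'
#' Degree; betweenness by all-pairs shortest-path counting with even
#' split over equal-length paths, normalized by `(n-1)(n-2)/2`; closeness
#' with the Wasserman-Faust component-size correction so disconnected
#' modules get finite values:
#' `((r-1)/(n-1)) * ((r-1)/sum(d))` with `r` the number of vertices
#' reachable from the gene. Isolated vertices and graphs with fewer than
#' 3 vertices get zero betweenness.
#'
#' @param graph an undirected [igraph] graph, >= 1 vertex.
#' @return data.frame with columns `gene`, `degree`, `betweenness`,
#'   `closeness`, sorted by gene.
#' @export
centrality_scores <- function(graph) {
  n <- igraph::vcount(graph)
  if (n == 0)
    return(data.frame(gene = character(0), degree = integer(0),
                      betweenness = numeric(0), closeness = numeric(0),
                      stringsAsFactors = FALSE))
  deg <- igraph::degree(graph)
  btw <- if (n >= 3) igraph::betweenness(graph, normalized = TRUE)
         else rep(0, n)
  D <- igraph::distances(graph)
  clo <- vapply(seq_len(n), function(i) {
    d <- D[i, -i]
    reach <- d[is.finite(d)]
    if (length(reach) == 0 || n == 1) return(0)
    ((length(reach)) / (n - 1)) * (length(reach) / sum(reach))
  }, 0)
  out <- data.frame(gene = igraph::V(graph)$name %||%
                      as.character(seq_len(n)),
                    degree = as.integer(deg), betweenness = unname(btw),
                    closeness = unname(clo), stringsAsFactors = FALSE)
  out[order(out$gene), , drop = FALSE]
}

#' Top fraction of genes per centrality metric, with tie expansion
#'
#' For each metric, the `ceiling(frac * n)` highest-scoring genes,
#' expanded to include every gene tied with the boundary value. Output is
#' monotone non-decreasing in `frac`.
#'
#' @param scores data.frame from [centrality_scores()].
#' @param frac fraction in (0, 1], default 0.05.
#' @param metrics which score columns to rank.
#' @return Named list (metric -> sorted character vector of genes).
#' @export
top_fraction <- function(scores, frac = 0.05,
                         metrics = c("degree", "betweenness", "closeness")) {
  if (!(frac > 0 && frac <= 1)) sg_stop("'frac' must be in (0, 1]")
  n <- nrow(scores)
  k <- ceiling(frac * n)
  stats::setNames(lapply(metrics, function(mt) {
    v <- scores[[mt]]
    if (n == 0) return(character(0))
    boundary <- sort(v, decreasing = TRUE)[k]
    sort(scores$gene[v >= boundary])
  }), metrics)
}

#' Log-log degree-frequency power-law summary
#'
#' Least-squares slope and r-squared of `log(frequency)` on
#' `log(degree)` over positive degrees; descriptive only. Needs at least
#' 3 distinct positive degrees, otherwise both values are NA.
#'
#' @param graph an undirected [igraph] graph.
#' @return List with `slope` and `r_squared`.
#' @export
degree_powerlaw_summary <- function(graph) {
  deg <- igraph::degree(graph)
  tab <- table(deg[deg > 0])
  if (length(tab) < 3) return(list(slope = NA_real_, r_squared = NA_real_))
  x <- log(as.numeric(names(tab)))
  y <- log(as.numeric(tab))
  fit <- stats::lm.fit(cbind(1, x), y)
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((y - mean(y))^2)
  list(slope = unname(fit$coefficients[2]),
       r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_)
}
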