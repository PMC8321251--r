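# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths (igraph, phyper, vectorized correlation):
# brute-force breadth-first search, explicit path enumeration and direct
# summation of hypergeometric masses.

# adjacency list from an edge matrix (2 columns of vertex indices)
oracle_adjlist <- function(n, edges) {
  adj <- vector("list", n)
  for (i in seq_len(nrow(edges))) {
    a <- edges[i, 1]; b <- edges[i, 2]
    if (a == b) next
    adj[[a]] <- union(adj[[a]], b)
    adj[[b]] <- union(adj[[b]], a)
  }
  adj
}

oracle_bfs <- function(adj, s) {
  n <- length(adj)
  dist <- rep(Inf, n)
  dist[s] <- 0
  q <- s
  while (length(q) > 0) {
    v <- q[1]; q <- q[-1]
    for (w in adj[[v]]) {
      if (is.infinite(dist[w])) {
        dist[w] <- dist[v] + 1
        q <- c(q, w)
      }
    }
  }
  dist
}

# enumerate every shortest s->t path by backtracking over the BFS
# predecessor structure; returns a list of vertex sequences
oracle_all_shortest_paths <- function(adj, dist, t) {
  if (is.infinite(dist[t])) return(list())
  if (dist[t] == 0) return(list(t))
  preds <- Filter(function(w) dist[w] == dist[t] - 1, adj[[t]])
  out <- list()
  for (p in preds) {
    for (path in oracle_all_shortest_paths(adj, dist, p))
      out[[length(out) + 1L]] <- c(path, t)
  }
  out
}

# degree, normalized betweenness and Wasserman-Faust closeness by
# exhaustive shortest-path enumeration; vertices indexed 1..n
oracle_centrality <- function(n, edges) {
  adj <- oracle_adjlist(n, edges)
  deg <- vapply(adj, length, 1L)
  btw <- rep(0, n)
  clo <- rep(0, n)
  dists <- lapply(seq_len(n), function(s) oracle_bfs(adj, s))
  for (s in seq_len(n)) {
    d <- dists[[s]]
    reach <- which(is.finite(d) & seq_len(n) != s)
    if (length(reach) > 0 && n > 1)
      clo[s] <- (length(reach) / (n - 1)) * (length(reach) / sum(d[reach]))
    if (n < 3) next
    for (t in seq_len(n)) {
      if (t <= s || is.infinite(d[t]) || d[t] == 0) next
      paths <- oracle_all_shortest_paths(adj, d, t)
      if (length(paths) == 0) next
      inner <- table(unlist(lapply(paths, function(p) p[-c(1, length(p))])))
      if (length(inner) > 0) {
        idx <- as.integer(names(inner))
        btw[idx] <- btw[idx] + as.numeric(inner) / length(paths)
      }
    }
  }
  if (n >= 3) btw <- btw / ((n - 1) * (n - 2) / 2)
  list(degree = deg, betweenness = btw, closeness = clo)
}

# upper-tail hypergeometric by direct summation of point masses computed
# from binomial coefficients
oracle_hyper_upper <- function(overlap, module_size, set_size, universe_size) {
  if (overlap == 0) return(1)
  kmax <- min(module_size, set_size)
  mass <- vapply(overlap:kmax, function(k) {
    exp(lchoose(set_size, k) + lchoose(universe_size - set_size,
                                       module_size - k) -
          lchoose(universe_size, module_size))
  }, 0)
  sum(mass)
}

# random undirected simple graph with vertex names, as an edge data.frame
random_test_graph <- function(n, p = 0.15) {
  vn <- sprintf("v%02d", seq_len(n))
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  keep <- stats::runif(nrow(pairs)) < p
  list(n = n, names = vn,
       edges = pairs[keep, , drop = FALSE])
}

# tiny hand-built paired cohort: expression matrix given per stage as
# genes x (pairs) tumor/normal values
toy_cohort <- function(tumor, normal, stage = "I", beta_sites = NULL,
                       cpg_map = NULL) {
  stopifnot(identical(dim(tumor), dim(normal)))
  np <- ncol(tumor)
  pid <- sprintf("P%s_%02d", stage, seq_len(np))
  md <- data.frame(
    sample_id = c(paste0(pid, "_T"), paste0(pid, "_N")),
    patient_id = c(pid, pid),
    condition = rep(c("tumor", "normal"), each = np),
    stage = stage, stringsAsFactors = FALSE)
  expr <- cbind(tumor, normal)
  colnames(expr) <- md$sample_id
  if (is.null(rownames(expr)))
    rownames(expr) <- sprintf("g%02d", seq_len(nrow(expr)))
  paired_cohort(expr, beta_sites, cpg_map, md)
}

# quick default-ish simulation at reduced size for unit tests
small_sim <- function(seed = 1, ...) {
  simulate_cohort(simulation_config(
    n_genes = 400, n_tfs = 40, pairs_per_stage = 20,
    module_sizes = c(60, 80), n_disease_genes_per_stage = 4,
    n_decoy_edges = 400, seed = seed, ...))
}

quiet <- function(expr) suppressMessages(expr)
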