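#' Co-expression dissimilarity over a stage's tumor samples
#'
#' `d(i, j) = 1 - |pearson(expr_i, expr_j)|` on the log2(x+1) scale.
#' Constant genes have all their correlations treated as 0 (d = 1),
#' logged. Optionally replaces `|cor|` with the topological overlap of a
#' soft-thresholded adjacency (`tom = TRUE`, power `beta`).
#'
#' @param cohort a [paired_cohort()].
#' @param genes genes to include (>= 2).
#' @param stage stage label.
#' @param tom use topological-overlap dissimilarity instead of 1 - |cor|.
#' @param beta soft-threshold power for the TOM adjacency, default 6.
#' @return Symmetric matrix with zero diagonal and values in [0, 1].
#' @export
coexpression_dissimilarity <- function(cohort, genes, stage, tom = FALSE,
                                       beta = 6) {
  if (length(genes) < 2) sg_stop("need at least 2 genes")
  cols <- stage_samples(cohort, stage, "tumor")
  x <- log2p1(cohort$expression[genes, cols, drop = FALSE])
  z <- row_standardize(x)
  const <- attr(z, "constant")
  if (any(const))
    sg_log("coexpression_dissimilarity: %d constant genes (d = 1)",
           sum(const))
  r <- tcrossprod(z) / (ncol(z) - 1)
  a <- pmin(abs(r), 1)
  diag(a) <- 1
  if (tom) {
    adj <- a^beta
    diag(adj) <- 0
    k <- rowSums(adj)
    num <- adj %*% adj + adj
    den <- outer(k, k, pmin) + 1 - adj
    a <- num / den
    diag(a) <- 1
  }
  d <- 1 - a
  d[d < 0] <- 0
  diag(d) <- 0
  dimnames(d) <- list(genes, genes)
  d
}

#' Average-linkage hierarchical clustering tree
#'
#' UPGMA merge tree of a symmetric dissimilarity matrix (via
#' [stats::hclust()], which breaks merge ties deterministically), the
#' input for [dynamic_tree_cut()].
#'
#' @param dissimilarity symmetric numeric matrix with zero diagonal.
#' @return An [stats::hclust] object.
#' @export
hierarchical_tree <- function(dissimilarity) {
  if (!isSymmetric(unname(dissimilarity), tol = 1e-8))
    sg_stop("dissimilarity matrix is not symmetric")
  stats::hclust(stats::as.dist(dissimilarity), method = "average")
}

#' Adaptive (dynamic) tree cut into modules of a minimum size
#'
#' Cuts a dendrogram into modules adaptively rather than at a fixed
#' height. First, a cut level is selected from the distribution of merge
#' heights: if a dominant gap (>= 15% of the height range, searched above
#' the lower height quartile) separates within-cluster from
#' between-cluster merges, the cut is placed in that gap; otherwise at
#' `cut_height` times the tree height. Maximal subtrees below the cut
#' level with at least `min_module_size` leaves become module candidates;
#' smaller ones are left unassigned (label 0, the grey pool). Candidates
#' are then refined recursively: a branch is split further when the
#' relative height gap between its merge and its children exceeds a
#' `deep_split`-controlled tolerance and both children reach the minimum
#' size. Deterministic given its input.
#'
#' @param tree an [stats::hclust] dendrogram.
#' @param min_module_size minimum module size, default 30.
#' @param deep_split integer 0-4; larger values split more aggressively
#'   (gap tolerances 0.40, 0.25, 0.15, 0.08, 0.04). Default 2.
#' @param cut_height fallback cut level as a fraction of the tree height
#'   when no dominant gap exists, default 0.99.
#' @return Integer vector of raw module labels per leaf (0 = unassigned),
#'   named by leaf labels.
#' @export
dynamic_tree_cut <- function(tree, min_module_size = 30, deep_split = 2,
                             cut_height = 0.99) {
  if (!deep_split %in% 0:4) sg_stop("'deep_split' must be 0, 1, 2, 3 or 4")
  labels_out <- stats::setNames(integer(length(tree$labels)), tree$labels)
  n <- length(tree$labels)
  if (n < min_module_size || n < 2) return(labels_out)
  gap_tol <- c(0.40, 0.25, 0.15, 0.08, 0.04)[deep_split + 1]

  h <- tree$height
  tau <- {
    hs <- sort(h)
    rng <- hs[length(hs)] - hs[1]
    lo <- stats::quantile(hs, 0.25, names = FALSE)
    tau_default <- cut_height * hs[length(hs)]
    if (length(hs) >= 3 && rng > 0) {
      gaps <- diff(hs)
      ok <- hs[-length(hs)] >= lo
      if (any(ok) && max(gaps[ok]) >= 0.15 * rng) {
        i <- which(ok)[which.max(gaps[ok])]
        (hs[i] + hs[i + 1]) / 2
      } else tau_default
    } else tau_default
  }

  m <- tree$merge
  nm <- nrow(m)
  size <- integer(nm)
  leafset <- vector("list", nm)
  for (j in seq_len(nm)) {
    get_part <- function(k) if (k < 0) -k else leafset[[k]]
    leafset[[j]] <- c(get_part(m[j, 1]), get_part(m[j, 2]))
    size[j] <- length(leafset[[j]])
  }
  node_height <- function(k) if (k < 0) 0 else h[k]
  node_size <- function(k) if (k < 0) 1L else size[k]

  clusters <- list()
  emit <- function(leaves) clusters[[length(clusters) + 1L]] <<- leaves

  refine <- function(j) {
    # j is an internal node forming a module candidate; split if the
    # children are well separated and both large enough
    repeat {
      a <- m[j, 1]; b <- m[j, 2]
      hj <- h[j]
      if (hj <= 0) break
      g <- (hj - max(node_height(a), node_height(b))) / hj
      if (g >= gap_tol && node_size(a) >= min_module_size &&
          node_size(b) >= min_module_size && a > 0 && b > 0) {
        refine(a)
        j <- b
        next
      }
      break
    }
    emit(leafset[[j]])
  }

  # find maximal subtrees with height <= tau starting from the root
  stack <- nm
  while (length(stack) > 0) {
    j <- stack[length(stack)]
    stack <- stack[-length(stack)]
    if (j < 0) next                      # singleton above tau -> grey
    if (h[j] <= tau) {
      if (size[j] >= min_module_size) refine(j)  # else grey
    } else {
      stack <- c(stack, m[j, 1], m[j, 2])
    }
  }

  for (i in seq_along(clusters)) labels_out[tree$labels[clusters[[i]]]] <- i
  labels_out
}

# leaf indices under internal node j of an hclust tree
tree_leafset <- function(tree, j) {
  m <- tree$merge
  out <- integer(0)
  stack <- j
  while (length(stack) > 0) {
    k <- stack[length(stack)]
    stack <- stack[-length(stack)]
    if (k < 0) out <- c(out, -k) else stack <- c(stack, m[k, 1], m[k, 2])
  }
  out
}

# WGCNA-standard module color order
.MODULE_COLORS <- c(
  "turquoise", "blue", "brown", "yellow", "green", "red", "black", "pink",
  "magenta", "purple", "greenyellow", "tan", "salmon", "cyan",
  "midnightblue", "lightcyan", "grey60", "lightgreen", "lightyellow",
  "royalblue", "darkred", "darkgreen", "darkturquoise", "darkgrey",
  "orange", "darkorange", "white", "skyblue", "saddlebrown", "steelblue",
  "paleturquoise", "violet", "darkolivegreen", "darkmagenta")

#' Assign standard module colors by size rank
#'
#' Modules are sorted by size descending (ties broken by the smallest
#' member gene id) and named in the standard color order (turquoise,
#' blue, brown, ...); unassigned genes become `grey`.
#'
#' @param raw_labels integer labels from [dynamic_tree_cut()]
#'   (0 = unassigned), named by gene.
#' @param stage stage label carried on the partition.
#' @return A `module_partition`: list with `stage` and `assignment`
#'   (named character vector gene -> color).
#' @export
assign_colors <- function(raw_labels, stage = NA_character_) {
  assignment <- stats::setNames(rep("grey", length(raw_labels)),
                                names(raw_labels))
  ids <- setdiff(sort(unique(raw_labels)), 0L)
  if (length(ids) > 0) {
    info <- data.frame(
      id = ids,
      size = vapply(ids, function(i) sum(raw_labels == i), 1L),
      first = vapply(ids, function(i) min(names(raw_labels)[raw_labels == i]),
                     ""))
    info <- info[order(-info$size, info$first), ]
    colors <- c(.MODULE_COLORS,
                paste0("module", seq_len(max(0, nrow(info) -
                                               length(.MODULE_COLORS)))))
    for (k in seq_len(nrow(info)))
      assignment[raw_labels == info$id[k]] <- colors[k]
  }
  structure(list(stage = stage, assignment = assignment),
            class = "module_partition")
}

#' @export
print.module_partition <- function(x, ...) {
  tab <- sort(table(x$assignment), decreasing = TRUE)
  cat(sprintf("module_partition '%s': %d genes, %d modules\n", x$stage,
              length(x$assignment), sum(names(tab) != "grey")))
  print(tab)
  invisible(x)
}

#' Gene members of one module
#' @param partition a `module_partition`.
#' @param color module color label.
#' @return Sorted character vector of gene ids.
#' @export
module_genes <- function(partition, color) {
  sort(names(partition$assignment)[partition$assignment == color])
}

#' Non-grey module colors of a partition, largest first
#' @param partition a `module_partition`.
#' @return Character vector of colors.
#' @export
module_colors <- function(partition) {
  tab <- table(partition$assignment)
  tab <- tab[names(tab) != "grey"]
  names(sort(tab, decreasing = TRUE))
}

#' Detect co-expression modules on a stage network's node set
#'
#' Composition of [coexpression_dissimilarity()], [hierarchical_tree()],
#' [dynamic_tree_cut()] and [assign_colors()] over the network's nodes.
#'
#' @param cohort a [paired_cohort()].
#' @param network a `stage_network`.
#' @param min_module_size minimum module size, default 30.
#' @param deep_split,cut_height forwarded to [dynamic_tree_cut()].
#' @param tom,beta forwarded to [coexpression_dissimilarity()].
#' @return A `module_partition` over the network's node set (all grey
#'   when the network has fewer nodes than `min_module_size`).
#' @export
detect_modules <- function(cohort, network, min_module_size = 30,
                           deep_split = 2, cut_height = 0.99, tom = FALSE,
                           beta = 6) {
  nodes <- network$nodes
  if (length(nodes) < 2)
    return(structure(list(stage = network$stage,
                          assignment = stats::setNames(
                            rep("grey", length(nodes)), nodes)),
                     class = "module_partition"))
  d <- coexpression_dissimilarity(cohort, nodes, network$stage, tom, beta)
  tr <- hierarchical_tree(d)
  raw <- dynamic_tree_cut(tr, min_module_size, deep_split, cut_height)
  assign_colors(raw, network$stage)
}
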