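# All files are tab-separated UTF-8 with "NA" as the missing token.

write_tsv_df <- function(df, path) {
  ok <- try(utils::write.table(df, path, sep = "\t", quote = FALSE,
                               row.names = FALSE, na = "NA",
                               fileEncoding = "UTF-8"), silent = TRUE)
  if (inherits(ok, "try-error")) sg_stop("failed to write '%s'", path)
  invisible(path)
}

write_matrix_tsv <- function(m, id_col, path) {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  write_tsv_df(df, path)
}

read_tsv_checked <- function(path, required_cols = NULL) {
  if (!file.exists(path)) sg_stop("file not found: '%s'", path)
  d <- utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                         stringsAsFactors = FALSE, na.strings = "NA")
  if (!is.null(required_cols) && !all(required_cols %in% names(d)))
    sg_stop("'%s' must have columns: %s", path,
            paste(required_cols, collapse = ", "))
  d
}

read_matrix_tsv <- function(path) {
  d <- read_tsv_checked(path)
  ids <- as.character(d[[1]])
  if (anyDuplicated(ids))
    sg_stop("duplicate row id '%s' in '%s'", ids[duplicated(ids)][1], path)
  m <- as.matrix(d[, -1, drop = FALSE])
  if (!is.numeric(m)) sg_stop("non-numeric entries in '%s'", path)
  rownames(m) <- ids
  m
}

#' Read a gene expression matrix with missing-value filtering
#'
#' Reads a genes x samples TSV (gene id in the first column, sample ids in
#' the header). Genes whose fraction of missing entries exceeds
#' `max_missing_frac` are dropped (the count is logged); remaining missing
#' entries are imputed with the per-gene median over observed samples.
#'
#' @param path TSV path.
#' @param max_missing_frac per-gene missing-fraction threshold, default
#'   0.15.
#' @return Numeric matrix, all values finite and non-negative.
#' @export
read_expression <- function(path, max_missing_frac = 0.15) {
  stopifnot_scalar_prob(max_missing_frac, "max_missing_frac")
  m <- read_matrix_tsv(path)
  if (any(m < 0, na.rm = TRUE)) {
    bad <- which(m < 0, arr.ind = TRUE)[1, ]
    sg_stop("negative expression at gene %s, sample %s in '%s'",
            rownames(m)[bad[1]], colnames(m)[bad[2]], path)
  }
  miss <- rowMeans(is.na(m))
  drop <- miss > max_missing_frac
  if (any(drop)) {
    sg_log("read_expression: dropped %d/%d genes with missing fraction > %.2f",
           sum(drop), nrow(m), max_missing_frac)
    m <- m[!drop, , drop = FALSE]
  }
  nas <- which(is.na(m), arr.ind = TRUE)
  if (nrow(nas) > 0) {
    med <- apply(m, 1, stats::median, na.rm = TRUE)
    m[nas] <- med[nas[, 1]]
    sg_log("read_expression: imputed %d entries with per-gene medians",
           nrow(nas))
  }
  m
}

#' Read a CpG-site beta-value matrix
#' @param path TSV path (site id first column, sample ids in header).
#' @return Numeric site x sample matrix with entries in [0, 1].
#' @export
read_beta <- function(path) {
  m <- read_matrix_tsv(path)
  bad <- which(!is.na(m) & (m < 0 | m > 1), arr.ind = TRUE)
  if (nrow(bad) > 0)
    sg_stop("beta value %.3f outside [0,1] at site %s, sample %s in '%s'",
            m[bad[1, 1], bad[1, 2]], rownames(m)[bad[1, 1]],
            colnames(m)[bad[1, 2]], path)
  m
}

#' Read a CpG-site to gene map
#' @param path two-column TSV (`site`, `gene`).
#' @return data.frame with columns `site`, `gene`.
#' @export
read_cpg_map <- function(path) {
  d <- read_tsv_checked(path, c("site", "gene"))
  if (anyDuplicated(d$site))
    sg_stop("duplicate site '%s' in '%s'", d$site[duplicated(d$site)][1], path)
  d[, c("site", "gene")]
}

#' Construct a TF->target prior edge table
#'
#' Deduplicates pairs and drops self-pairs (logged). Used both by the
#' simulator and by [read_tf_targets()].
#'
#' @param edges data.frame with columns `tf`, `target` (NULL allowed).
#' @param quiet suppress the log line.
#' @return data.frame of class `tf_target_prior` with unique, self-free
#'   `tf`/`target` character columns.
#' @export
tf_target_prior <- function(edges, quiet = FALSE) {
  if (is.null(edges) || nrow(edges) == 0)
    edges <- data.frame(tf = character(0), target = character(0),
                        stringsAsFactors = FALSE)
  edges <- data.frame(tf = as.character(edges$tf),
                      target = as.character(edges$target),
                      stringsAsFactors = FALSE)
  n0 <- nrow(edges)
  edges <- unique(edges)
  self <- edges$tf == edges$target
  if (any(self) && !quiet)
    sg_log("tf_target_prior: dropped %d self-pairs", sum(self))
  edges <- edges[!self, , drop = FALSE]
  if (n0 > nrow(edges) + sum(self) && !quiet)
    sg_log("tf_target_prior: removed %d duplicate pairs",
           n0 - nrow(edges) - sum(self))
  rownames(edges) <- NULL
  class(edges) <- c("tf_target_prior", "data.frame")
  edges
}

#' Read TF->target prior pairs
#' @param path two-column TSV (`tf`, `target`), e.g. as exported from a
#'   regulatory-network database.
#' @return A [tf_target_prior()] edge table.
#' @export
read_tf_targets <- function(path) {
  tf_target_prior(read_tsv_checked(path, c("tf", "target")))
}

#' Read sample metadata and enforce tumor/normal pairing
#' @param path TSV with columns `sample_id`, `patient_id`, `condition`,
#'   `stage`.
#' @return Validated metadata data.frame.
#' @export
read_metadata <- function(path) {
  d <- read_tsv_checked(path, c("sample_id", "patient_id", "condition",
                                "stage"))
  d[] <- lapply(d, as.character)
  if (anyDuplicated(d$sample_id))
    sg_stop("duplicate sample id '%s' in '%s'",
            d$sample_id[duplicated(d$sample_id)][1], path)
  if (!all(d$condition %in% c("tumor", "normal")))
    sg_stop("condition column of '%s' must be 'tumor'/'normal'", path)
  validate_pairing(d)
  d
}

#' Read gene sets in GMT format
#'
#' Each line is: set name, description, then member genes, tab-separated.
#'
#' @param path GMT file path.
#' @return Named list of character vectors of member genes.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) sg_stop("file not found: '%s'", path)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) sg_stop("malformed GMT line: '%s'", substr(l, 1, 40))
    unique(f[-(1:2)])
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], "")
  if (anyDuplicated(names(sets))) sg_stop("duplicate gene-set names in '%s'", path)
  sets
}

#' Read a full cohort fixture directory
#'
#' Convenience loader combining the individual readers over the layout
#' written by [write_fixture()].
#'
#' @param directory fixture directory.
#' @param max_missing_frac forwarded to [read_expression()].
#' @return A list with `cohort` (a [paired_cohort()]) and `prior`.
#' @export
read_cohort_dir <- function(directory, max_missing_frac = 0.15) {
  expr <- read_expression(file.path(directory, "expression.tsv"),
                          max_missing_frac)
  beta <- read_beta(file.path(directory, "beta.tsv"))
  cmap <- read_cpg_map(file.path(directory, "cpg_map.tsv"))
  md <- read_metadata(file.path(directory, "metadata.tsv"))
  prior <- read_tf_targets(file.path(directory, "tf_targets.tsv"))
  list(cohort = paired_cohort(expr, beta, cmap, md), prior = prior)
}

#' Write a stage network as an edge list and GraphML
#'
#' @param network a `stage_network` from [build_stage_network()].
#' @param path_edges TSV path for the edge list (columns `tf`, `target`,
#'   `pcc`, `p`).
#' @param path_graphml optional GraphML path carrying the same attributes.
#' @return Invisibly, the edge-list path.
#' @export
write_network <- function(network, path_edges, path_graphml = NULL) {
  write_tsv_df(network$edges, path_edges)
  if (!is.null(path_graphml)) {
    g <- network_igraph(network, directed = TRUE)
    ok <- try(igraph::write_graph(g, path_graphml, format = "graphml"),
              silent = TRUE)
    if (inherits(ok, "try-error"))
      sg_stop("failed to write GraphML '%s'", path_graphml)
  }
  invisible(path_edges)
}

#' Read a stage network edge list written by [write_network()]
#' @param path_edges edge-list TSV.
#' @param stage stage label to attach.
#' @return A `stage_network` object.
#' @export
read_network <- function(path_edges, stage = NA_character_) {
  d <- read_tsv_checked(path_edges, c("tf", "target", "pcc", "p"))
  new_stage_network(stage, d)
}

#' Write a module partition (one row per gene, including grey)
#' @param partition a `module_partition` from [assign_colors()].
#' @param path output TSV path.
#' @export
write_partition <- function(partition, path) {
  write_tsv_df(data.frame(gene = names(partition$assignment),
                          module = unname(partition$assignment),
                          stringsAsFactors = FALSE), path)
}

#' Read a module partition written by [write_partition()]
#' @param path partition TSV.
#' @param stage stage label to attach.
#' @return A `module_partition` object.
#' @export
read_partition <- function(path, stage = NA_character_) {
  d <- read_tsv_checked(path, c("gene", "module"))
  structure(list(stage = stage,
                 assignment = stats::setNames(d$module, d$gene)),
            class = "module_partition")
}

#' Write a candidate report as JSON
#' @param report a `candidate_report` from [predict_report()] /
#'   [run_pipeline()].
#' @param path output JSON path.
#' @export
write_report <- function(report, path) {
  ok <- try(jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                                 digits = NA, pretty = TRUE, null = "null"),
            silent = TRUE)
  if (inherits(ok, "try-error")) sg_stop("failed to write '%s'", path)
  invisible(path)
}

#' Read a candidate report written by [write_report()]
#' @param path JSON path.
#' @return A `candidate_report` list.
#' @export
read_report <- function(path) {
  r <- jsonlite::read_json(path, simplifyVector = TRUE)
  class(r) <- "candidate_report"
  r
}
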