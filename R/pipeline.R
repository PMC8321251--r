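#' Pipeline configuration
#'
#' Collects every threshold of the analysis with the method's printed
#' defaults: DEG p < 0.05 and |log2FC| >= 0.5; beta > 0.8 hyper / < 0.2
#' hypo (strict); |PCC| >= 0.5 for network edges; minimum module size 30;
#' correlation-core cutoffs (0.8, 0.05); top 5% hubs with tie expansion;
#' enrichment p < 0.01; per-gene missing fraction 0.15.
#'
#' @param p_cut,lfc_cut DEG thresholds.
#' @param beta_hyper,beta_hypo methylation status thresholds.
#' @param pcc_cutoff network correlation cutoff.
#' @param min_module_size minimum module size.
#' @param r_cut,core_p_cut,min_partner_frac correlation-core rule.
#' @param top_frac,combine topology-core rule.
#' @param ora_p_cut enrichment p-value cutoff.
#' @param max_missing_frac missing-value gene filter.
#' @param specific_fdr BH FDR cutoff for specific-module selection.
#' @param specific_top_k optional count-based specific-module rule.
#' @param deep_split,cut_height,tom,tom_beta tree-cut / dissimilarity
#'   options.
#' @param signed_network require positive correlations for edges.
#' @param network_samples `"tumor"` or `"all"`.
#' @param seed integer seed recorded in the run manifest.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(p_cut = 0.05, lfc_cut = 0.5, beta_hyper = 0.8,
                            beta_hypo = 0.2, pcc_cutoff = 0.5,
                            min_module_size = 30, r_cut = 0.8,
                            core_p_cut = 0.05, min_partner_frac = 0.1,
                            top_frac = 0.05, combine = "union",
                            ora_p_cut = 0.01, max_missing_frac = 0.15,
                            specific_fdr = 0.05, specific_top_k = NULL,
                            deep_split = 2, cut_height = 0.99, tom = FALSE,
                            tom_beta = 6, signed_network = FALSE,
                            network_samples = "tumor", seed = 1L) {
  cfg <- as.list(environment())
  for (f in c("p_cut", "beta_hyper", "beta_hypo", "pcc_cutoff", "r_cut",
              "core_p_cut", "min_partner_frac", "ora_p_cut",
              "max_missing_frac", "specific_fdr"))
    stopifnot_scalar_prob(cfg[[f]], f)
  if (cfg$lfc_cut < 0) sg_stop("'lfc_cut' must be non-negative")
  if (!(cfg$top_frac > 0 && cfg$top_frac <= 1))
    sg_stop("'top_frac' must be in (0, 1]")
  if (cfg$min_module_size < 2) sg_stop("'min_module_size' must be >= 2")
  class(cfg) <- "pipeline_config"
  cfg
}

#' Load a pipeline configuration from a YAML file
#' @param path YAML file whose keys are [pipeline_config()] arguments.
#' @return A `pipeline_config`.
#' @export
pipeline_config_from_yaml <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0)
    sg_stop("unknown config keys: %s", paste(unknown, collapse = ", "))
  do.call(pipeline_config, vals)
}

#' Run the full analysis on an in-memory cohort
#'
#' Executes the whole method: per-stage paired differential expression,
#' methylation classification and candidate universe, TF->target network
#' construction by correlation filtering, module detection, stage-specific
#' module selection, module topology, correlation/topology core genes and
#' their intersection, and cross-stage shared genes. Deterministic given
#' its inputs.
#'
#' @param cohort a [paired_cohort()].
#' @param prior a [tf_target_prior()].
#' @param config a [pipeline_config()].
#' @param gene_sets optional named list of gene sets for enrichment.
#' @param truth optional ground-truth list; adds recovery metrics
#'   (per-stage precision/recall of planted disease genes, module ARI).
#' @return A `pipeline_result` list: `stages` (per-stage de/status/
#'   universe/network/partition/specificity/candidates/enrichment),
#'   `report` (a `candidate_report`), `recovery` (or NULL), `config`.
#' @export
run_pipeline <- function(cohort, prior, config = pipeline_config(),
                         gene_sets = NULL, truth = NULL) {
  stages <- cohort_stages(cohort)
  de <- run_differential_expression(cohort, config$p_cut, config$lfc_cut)
  gene_beta <- aggregate_beta(cohort$beta_sites, cohort$cpg_map)

  per_stage <- stats::setNames(vector("list", length(stages)), stages)
  for (s in stages) {
    status <- classify_methylation(gene_beta, cohort$metadata, s,
                                   config$beta_hyper, config$beta_hypo)
    universe <- candidate_universe(de[[s]]$degs, status)
    sg_log("stage %s: %d DEGs, %d candidate-universe genes",
           s, length(de[[s]]$degs), length(universe))
    net <- build_stage_network(cohort, filter_prior(prior, universe), s,
                               config$pcc_cutoff, config$signed_network,
                               config$network_samples)
    part <- detect_modules(cohort, net, config$min_module_size,
                           config$deep_split, config$cut_height,
                           config$tom, config$tom_beta)
    per_stage[[s]] <- list(
      de = de[[s]],
      status = gene_status_table(de[[s]], status),
      universe = universe, network = net, partition = part)
  }

  specific <- stage_exclusive_genes(
    stats::setNames(lapply(stages, function(s) de[[s]]$degs), stages))
  for (s in stages) {
    spec_tab <- select_specific_modules(per_stage[[s]]$partition,
                                        specific[[s]], config$specific_fdr,
                                        config$specific_top_k)
    spec_mods <- spec_tab$module[spec_tab$is_specific_module]
    sg_log("stage %s: %d specific genes, specific modules: %s", s,
           length(specific[[s]]),
           if (length(spec_mods)) paste(spec_mods, collapse = ", ")
           else "(none)")
    cand <- stage_candidates(cohort, per_stage[[s]]$network,
                             per_stage[[s]]$partition, spec_mods,
                             config$r_cut, config$core_p_cut,
                             config$min_partner_frac, config$top_frac,
                             config$combine)
    enr <- if (!is.null(gene_sets))
      ora(per_stage[[s]]$partition, gene_sets, p_cut = config$ora_p_cut)
    per_stage[[s]]$specific_genes <- specific[[s]]
    per_stage[[s]]$specificity <- spec_tab
    per_stage[[s]]$specific_modules <- spec_mods
    per_stage[[s]]$candidates <- cand
    per_stage[[s]]$enrichment <- enr
  }

  report <- structure(list(
    stages = stats::setNames(lapply(stages, function(s) {
      c(per_stage[[s]]$candidates[c("correlation_core", "topology_core",
                                    "candidates")],
        list(specific_modules = per_stage[[s]]$specific_modules))
    }), stages),
    shared_genes = if (length(stages) >= 2)
      shared_across_stages(lapply(per_stage, function(x)
        x$candidates$candidates)) else character(0)),
    class = "candidate_report")

  recovery <- if (!is.null(truth))
    recovery_metrics(per_stage, report, truth) else NULL

  structure(list(stages = per_stage, report = report, recovery = recovery,
                 config = config), class = "pipeline_result")
}

# precision/recall of planted disease genes and module ARI per stage
recovery_metrics <- function(per_stage, report, truth) {
  stages <- names(per_stage)
  per <- stats::setNames(lapply(stages, function(s) {
    pred <- report$stages[[s]]$candidates
    planted <- truth$disease_genes_by_stage[[s]] %||% character(0)
    tp <- length(intersect(pred, planted))
    part <- per_stage[[s]]$partition$assignment
    scored <- intersect(names(part)[part != "grey"],
                        names(truth$module_membership))
    ari <- if (length(scored) >= 2)
      adjusted_rand_index(part[scored], truth$module_membership[scored])
    else NA_real_
    list(n_predicted = length(pred), n_planted = length(planted),
         precision = if (length(pred) > 0) tp / length(pred) else NA_real_,
         recall = if (length(planted) > 0) tp / length(planted) else NA_real_,
         module_ari = ari)
  }), stages)
  pan <- truth$pan_stage_drivers %||% character(0)
  list(per_stage = per,
       pan_driver_shared = if (length(pan) > 0)
         length(intersect(report$shared_genes, pan)) > 0 else NA)
}

#' @export
print.candidate_report <- function(x, ...) {
  for (s in names(x$stages)) {
    st <- x$stages[[s]]
    cat(sprintf("stage %s: %d candidates (corr core %d, topo core %d) in modules [%s]\n",
                s, length(st$candidates), length(st$correlation_core),
                length(st$topology_core),
                paste(st$specific_modules, collapse = ", ")))
    if (length(st$candidates) > 0)
      cat("  ", paste(st$candidates, collapse = ", "), "\n")
  }
  cat("shared across stages:",
      if (length(x$shared_genes)) paste(x$shared_genes, collapse = ", ")
      else "(none)", "\n")
  invisible(x)
}

#' Run the full analysis from files and write every result
#'
#' File-based orchestration of [run_pipeline()]: reads the fixture-layout
#' inputs, runs all stages, and writes per-stage DEG tables, gene status
#' tables, networks (edge list + GraphML), partitions, specificity
#' tables, topology scores, enrichment tables, the candidate report and a
#' run manifest (config, package version, input paths, recovery metrics
#' when ground truth is supplied). Reruns with identical config and
#' inputs produce byte-identical outputs.
#'
#' @param input_dir directory in the [write_fixture()] layout; a
#'   `ground_truth.tsv` present there is used for recovery metrics.
#' @param out_dir output directory, created if needed.
#' @param config a [pipeline_config()].
#' @param gmt_path optional GMT file for enrichment.
#' @return Invisibly, the `pipeline_result`.
#' @export
run_all <- function(input_dir, out_dir, config = pipeline_config(),
                    gmt_path = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_con <- file(file.path(out_dir, "run.log"), open = "wt")
  .sg_env$log_con <- log_con
  on.exit({ close(log_con); .sg_env$log_con <- NULL }, add = TRUE)

  inp <- read_cohort_dir(input_dir, config$max_missing_frac)
  truth_path <- file.path(input_dir, "ground_truth.tsv")
  truth <- if (file.exists(truth_path)) read_ground_truth(truth_path)
  gene_sets <- if (!is.null(gmt_path)) read_gmt(gmt_path)

  res <- run_pipeline(inp$cohort, inp$prior, config, gene_sets, truth)

  for (s in names(res$stages)) {
    st <- res$stages[[s]]
    pre <- file.path(out_dir, paste0("stage_", s, "_"))
    write_tsv_df(st$de$table, paste0(pre, "degs.tsv"))
    write_tsv_df(st$status, paste0(pre, "gene_status.tsv"))
    write_network(st$network, paste0(pre, "network_edges.tsv"),
                  paste0(pre, "network.graphml"))
    write_partition(st$partition, paste0(pre, "partition.tsv"))
    write_tsv_df(st$specificity, paste0(pre, "specificity.tsv"))
    if (!is.null(st$candidates$per_gene))
      write_tsv_df(st$candidates$per_gene, paste0(pre, "topology.tsv"))
    if (!is.null(st$enrichment))
      write_tsv_df(st$enrichment, paste0(pre, "enrichment.tsv"))
  }
  write_report(res$report, file.path(out_dir, "candidate_report.json"))
  manifest <- list(package = "stageGRN",
                   version = as.character(utils::packageVersion("stageGRN")),
                   input_dir = basename(normalizePath(input_dir)),
                   config = unclass(config),
                   recovery = res$recovery)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(res)
}
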