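#' Configuration for the synthetic paired-cohort simulator
#'
#' Defines the conditions of a simulated multi-stage paired tumor/normal
#' cohort with planted differentially expressed genes, methylation-altered
#' genes, co-expression modules wired by transcription-factor (TF) priors,
#' and planted disease (driver) genes. Defaults describe a desk-scale
#' breast-cancer-like cohort: three stages, 50 tumor/normal pairs each,
#' 2,000 genes of which 100 are TFs, four planted modules (the largest
#' shared by all stages, the others each tied to one stage).
#'
#' @param n_genes total number of genes (TFs included).
#' @param n_tfs number of genes designated as transcription factors.
#' @param stages character vector of stage labels.
#' @param pairs_per_stage tumor/normal pairs per stage (scalar, >= 3).
#' @param module_sizes integer vector of planted module member counts
#'   (driver TFs are added on top). When two or more modules are planted
#'   and at least two stages exist, the last module is the pan-stage
#'   module hosting pan-stage drivers; the preceding modules are assigned
#'   home stages round-robin.
#' @param within_module_cor target pairwise correlation between module
#'   member genes, in [0, 1].
#' @param driver_cor target correlation among planted driver genes; drivers
#'   couple to their module factor more strongly than ordinary members.
#' @param deg_log2fc planted tumor-vs-normal effect size on the log2 scale.
#' @param deg_frac_per_stage target fraction of all genes differentially
#'   expressed per stage (module-implied DEGs are topped up with
#'   background genes to approach this fraction).
#' @param stage_exclusive_frac target fraction of each stage's DEGs that
#'   are exclusive to that stage.
#' @param hyper_beta,hypo_beta tumor-side target beta level of planted
#'   hyper-/hypomethylated genes; must satisfy
#'   `hypo_beta < 0.2 < 0.8 < hyper_beta`.
#' @param background_beta_range interval for unaltered gene beta levels.
#' @param background_altered_frac fraction of genes planted as
#'   methylation-altered background (altered but not differentially
#'   expressed), exercising the intersection filter.
#' @param cpgs_per_gene CpG sites simulated per gene.
#' @param noise_sd residual standard deviation on the log2 scale.
#' @param n_disease_genes_per_stage planted drivers per stage; when a
#'   pan-stage module exists, `min(3, n)` of them are pan-stage drivers
#'   shared by every stage.
#' @param n_decoy_edges uniformly random TF->target prior edges added on
#'   top of the planted module wiring.
#' @param missing_frac fraction of expression entries set to NA
#'   (missing completely at random); 0 keeps the matrix complete.
#' @param seed integer seed; identical configurations give identical
#'   cohorts.
#' @return A validated `simulation_config` list.
#' @seealso [simulate_cohort()]
#' @export
simulation_config <- function(n_genes = 2000,
                              n_tfs = 100,
                              stages = c("I", "II", "III"),
                              pairs_per_stage = 50,
                              module_sizes = c(120, 100, 90, 300),
                              within_module_cor = 0.7,
                              driver_cor = 0.9,
                              deg_log2fc = 1.5,
                              deg_frac_per_stage = 0.25,
                              stage_exclusive_frac = 0.3,
                              hyper_beta = 0.9,
                              hypo_beta = 0.1,
                              background_beta_range = c(0.3, 0.6),
                              background_altered_frac = 0.025,
                              cpgs_per_gene = 3,
                              noise_sd = 1,
                              n_disease_genes_per_stage = 10,
                              n_decoy_edges = 3000,
                              missing_frac = 0,
                              seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes), n_tfs = as.integer(n_tfs),
              stages = as.character(stages),
              pairs_per_stage = as.integer(pairs_per_stage),
              module_sizes = as.integer(module_sizes),
              within_module_cor = within_module_cor,
              driver_cor = driver_cor,
              deg_log2fc = deg_log2fc,
              deg_frac_per_stage = deg_frac_per_stage,
              stage_exclusive_frac = stage_exclusive_frac,
              hyper_beta = hyper_beta, hypo_beta = hypo_beta,
              background_beta_range = background_beta_range,
              background_altered_frac = background_altered_frac,
              cpgs_per_gene = as.integer(cpgs_per_gene),
              noise_sd = noise_sd,
              n_disease_genes_per_stage = as.integer(n_disease_genes_per_stage),
              n_decoy_edges = as.integer(n_decoy_edges),
              missing_frac = missing_frac,
              seed = as.integer(seed))
  validate_simulation_config(cfg)
  class(cfg) <- "simulation_config"
  cfg
}

validate_simulation_config <- function(cfg) {
  for (f in c("within_module_cor", "driver_cor", "deg_frac_per_stage",
              "stage_exclusive_frac", "background_altered_frac",
              "missing_frac"))
    stopifnot_scalar_prob(cfg[[f]], f)
  if (cfg$n_genes < 1) sg_stop("'n_genes' must be positive")
  if (cfg$n_tfs < 0 || cfg$n_tfs > cfg$n_genes)
    sg_stop("'n_tfs' must lie in [0, n_genes]")
  if (length(cfg$stages) < 1 || anyDuplicated(cfg$stages))
    sg_stop("'stages' must be non-empty unique labels")
  if (cfg$pairs_per_stage < 3)
    sg_stop("'pairs_per_stage' must be at least 3")
  if (sum(cfg$module_sizes) > cfg$n_genes)
    sg_stop("'module_sizes' sum exceeds n_genes")
  if (any(cfg$module_sizes < 2))
    sg_stop("'module_sizes' entries must be >= 2")
  if (!(cfg$hypo_beta < 0.2 && cfg$hyper_beta > 0.8))
    sg_stop("'hyper_beta'/'hypo_beta' must satisfy hypo < 0.2 < 0.8 < hyper")
  if (length(cfg$background_beta_range) != 2 ||
      cfg$background_beta_range[1] >= cfg$background_beta_range[2] ||
      any(cfg$background_beta_range < 0 | cfg$background_beta_range > 1))
    sg_stop("'background_beta_range' must be an increasing interval in [0,1]")
  if (cfg$noise_sd <= 0) sg_stop("'noise_sd' must be positive")
  if (cfg$cpgs_per_gene < 1) sg_stop("'cpgs_per_gene' must be >= 1")
  if (cfg$n_disease_genes_per_stage < 0)
    sg_stop("'n_disease_genes_per_stage' must be >= 0")
  invisible(cfg)
}

# fraction of a home module's members exclusive to its home stage, and of
# the pan module's members shared by all stages; fixed design constants
.HOME_EXCLUSIVE_FRAC <- 0.4
.PAN_SHARED_FRAC <- 0.4

#' Simulate a paired tumor/normal cohort with planted ground truth
#'
#' Draws a full synthetic cohort under a latent log2-scale Gaussian model:
#' each gene's log2 expression is baseline + module factor + stage-specific
#' tumor effect + noise, exponentiated to a non-negative FPKM-like scale
#' (`2^z - 1`). Module members load on a shared per-patient factor giving
#' pairwise correlation `within_module_cor` (drivers load more strongly,
#' `driver_cor`). The factor is shared between a patient's tumor and normal
#' sample, so planted effects are recovered by a paired test. Methylation
#' is a per-gene logit-normal beta replicated over `cpgs_per_gene` sites
#' with site-level jitter; planted hyper/hypomethylated genes have their
#' expression shift sign-opposed to the beta shift. The TF->target prior
#' contains the planted module wiring (each module has at least one driver
#' TF covering all members) plus uniformly random decoy edges.
#'
#' @param config a [simulation_config()].
#' @return A list with elements `cohort` (a [paired_cohort()]),
#'   `prior` (a [tf_target_prior()] edge data.frame) and `truth`
#'   (list: `deg_genes_by_stage`, `hyper_genes`, `hypo_genes`,
#'   `module_membership`, `disease_genes_by_stage`, `tf_target_edges`,
#'   `stage_specific_genes`).
#' @examples
#' sim <- simulate_cohort(simulation_config(
#'   n_genes = 200, n_tfs = 20, pairs_per_stage = 5,
#'   module_sizes = c(30, 30), n_disease_genes_per_stage = 2,
#'   n_decoy_edges = 50, seed = 7))
#' sim$cohort
#' @export
simulate_cohort <- function(config) {
  validate_simulation_config(config)
  cfg <- config
  set.seed(cfg$seed)
  S <- length(cfg$stages)
  K <- length(cfg$module_sizes)
  wid <- max(4, nchar(as.character(cfg$n_genes)))
  genes <- sprintf(paste0("G%0", wid, "d"), seq_len(cfg$n_genes))
  tfs <- genes[seq_len(cfg$n_tfs)]
  non_tf <- setdiff(genes, tfs)

  ## ---- module homes and drivers -------------------------------------
  has_pan <- K >= 2 && S >= 2
  home_modules <- if (K == 0) integer(0) else seq_len(if (has_pan) K - 1 else K)
  pan_module <- if (has_pan) K else NA_integer_
  home_stage <- if (length(home_modules) > 0)
    cfg$stages[(home_modules - 1) %% S + 1] else character(0)

  n_dis <- cfg$n_disease_genes_per_stage
  n_pan_drivers <- if (has_pan && n_dis > 0) min(3L, n_dis) else 0L
  n_excl_drivers <- if (K > 0) n_dis - n_pan_drivers else 0L
  need_tfs <- n_excl_drivers * S + n_pan_drivers
  if (need_tfs > cfg$n_tfs)
    sg_stop("'n_tfs' too small for %d drivers", need_tfs)

  tf_pool <- sample(tfs)
  taken <- 0L
  draw_tfs <- function(k) {
    out <- tf_pool[taken + seq_len(k)]
    taken <<- taken + k
    out
  }
  excl_drivers <- stats::setNames(
    lapply(cfg$stages, function(s) draw_tfs(n_excl_drivers)), cfg$stages)
  pan_drivers <- draw_tfs(n_pan_drivers)

  # drivers attach to the module whose home is their stage; stages without
  # a home module place their exclusive drivers on the pan module
  module_drivers <- vector("list", K)
  for (m in seq_len(K)) module_drivers[[m]] <- character(0)
  for (i in seq_along(cfg$stages)) {
    s <- cfg$stages[i]
    m <- home_modules[which(home_stage == s)]
    m <- if (length(m) > 0) m[1] else pan_module
    if (!is.na(m))
      module_drivers[[m]] <- c(module_drivers[[m]], excl_drivers[[s]])
  }
  if (has_pan)
    module_drivers[[pan_module]] <- c(module_drivers[[pan_module]], pan_drivers)
  # every planted module needs at least one covering TF even without drivers
  # wire each module with roughly one TF per 30 members: the attached
  # drivers plus auxiliary (non-driver) TFs, so that in-module degrees are
  # smoothly distributed and every module has at least one covering TF
  module_aux_tfs <- vector("list", K)
  if (K > 0) {
    n_aux <- vapply(seq_len(K), function(m)
      max(if (length(module_drivers[[m]]) == 0) 1L else 0L,
          as.integer(round(cfg$module_sizes[m] / 30)) -
            length(module_drivers[[m]])), 1L)
    if (taken + sum(n_aux) > cfg$n_tfs)
      sg_stop("'n_tfs' too small to wire every planted module")
    for (m in seq_len(K)) module_aux_tfs[[m]] <- draw_tfs(n_aux[m])
  }
  all_drivers <- unique(unlist(module_drivers))
  all_aux <- unique(unlist(module_aux_tfs))

  ## ---- module membership --------------------------------------------
  member_pool <- sample(non_tf)
  used <- 0L
  module_members <- vector("list", K)
  for (m in seq_len(K)) {
    module_members[[m]] <- member_pool[used + seq_len(cfg$module_sizes[m])]
    used <- used + cfg$module_sizes[m]
  }
  bg_genes <- member_pool[seq.int(used + 1L, length.out = length(member_pool) - used)]

  module_of <- stats::setNames(rep(NA_integer_, cfg$n_genes), genes)
  for (m in seq_len(K)) {
    module_of[module_members[[m]]] <- m
    module_of[module_drivers[[m]]] <- m
    module_of[module_aux_tfs[[m]]] <- m
  }

  ## ---- DEG structure -------------------------------------------------
  deg_excl <- stats::setNames(vector("list", S), cfg$stages)   # exclusive
  for (s in cfg$stages) deg_excl[[s]] <- character(0)
  deg_shared <- character(0)                                    # all stages

  for (m in seq_len(K)) {
    mem <- module_members[[m]]
    if (!is.na(pan_module) && m == pan_module) {
      n_sh <- round(.PAN_SHARED_FRAC * length(mem))
      deg_shared <- c(deg_shared, mem[seq_len(n_sh)])
      rest <- mem[seq.int(n_sh + 1L, length.out = length(mem) - n_sh)]
      slice <- split(rest, rep(cfg$stages, length.out = length(rest)))
      for (s in cfg$stages)
        deg_excl[[s]] <- c(deg_excl[[s]], slice[[s]] %||% character(0))
    } else {
      n_ex <- round(.HOME_EXCLUSIVE_FRAC * length(mem))
      s <- home_stage[which(home_modules == m)]
      deg_excl[[s]] <- c(deg_excl[[s]], mem[seq_len(n_ex)])
      deg_shared <- c(deg_shared,
                      mem[seq.int(n_ex + 1L, length.out = length(mem) - n_ex)])
    }
  }
  for (s in cfg$stages) deg_excl[[s]] <- c(deg_excl[[s]], excl_drivers[[s]])
  deg_shared <- c(deg_shared, pan_drivers)

  # top up with background genes towards the target DEG fractions
  bg_cursor <- 0L
  draw_bg <- function(k) {
    k <- max(0L, min(k, length(bg_genes) - bg_cursor))
    out <- bg_genes[bg_cursor + seq_len(k)]
    bg_cursor <<- bg_cursor + k
    out
  }
  target_total <- round(cfg$deg_frac_per_stage * cfg$n_genes)
  target_excl <- round(cfg$stage_exclusive_frac * target_total)
  for (s in cfg$stages)
    deg_excl[[s]] <- c(deg_excl[[s]],
                       draw_bg(target_excl - length(deg_excl[[s]])))
  deg_shared <- c(deg_shared,
                  draw_bg(target_total - target_excl - length(deg_shared)))
  deg_by_stage <- stats::setNames(
    lapply(cfg$stages, function(s) sort(unique(c(deg_shared, deg_excl[[s]])))),
    cfg$stages)

  ## ---- methylation status --------------------------------------------
  altered <- unique(c(unlist(module_members), all_drivers,
                      draw_bg(round(cfg$background_altered_frac * cfg$n_genes))))
  meth_dir <- stats::setNames(sample(c(1, -1), length(altered), replace = TRUE),
                              altered)  # 1 = hyper, -1 = hypo
  hyper_genes <- sort(names(meth_dir)[meth_dir == 1])
  hypo_genes <- sort(names(meth_dir)[meth_dir == -1])

  # expression effect sign: opposed to the beta shift for altered genes,
  # random for the remaining DEGs
  all_deg <- unique(unlist(deg_by_stage))
  expr_sign <- stats::setNames(sample(c(1, -1), length(all_deg), replace = TRUE),
                               all_deg)
  opposed <- intersect(all_deg, altered)
  expr_sign[opposed] <- -meth_dir[opposed]

  ## ---- samples --------------------------------------------------------
  md <- do.call(rbind, lapply(cfg$stages, function(s) {
    pid <- sprintf("P%s_%03d", s, seq_len(cfg$pairs_per_stage))
    data.frame(sample_id = c(rbind(paste0(pid, "_T"), paste0(pid, "_N"))),
               patient_id = rep(pid, each = 2),
               condition = rep(c("tumor", "normal"), cfg$pairs_per_stage),
               stage = s, stringsAsFactors = FALSE)
  }))
  n_samp <- nrow(md)
  patients <- unique(md$patient_id)

  ## ---- expression -----------------------------------------------------
  mu <- stats::runif(cfg$n_genes, 2, 8)
  loading <- rep(0, cfg$n_genes)
  names(loading) <- genes
  loading[!is.na(module_of)] <- sqrt(cfg$within_module_cor)
  loading[all_drivers] <- sqrt(cfg$driver_cor)

  fac <- if (K > 0)
    matrix(stats::rnorm(K * length(patients)), K, length(patients),
           dimnames = list(NULL, patients)) else NULL
  # standardize factor scores within each stage's patients so the planted
  # within-module correlation is realized per stage, not just in
  # expectation over cohorts
  if (!is.null(fac)) {
    pat_stage <- md$stage[match(patients, md$patient_id)]
    for (s in cfg$stages) {
      idx <- which(pat_stage == s)
      fs <- fac[, idx, drop = FALSE]
      fac[, idx] <- sweep(fs - rowMeans(fs), 1, apply(fs, 1, stats::sd), "/")
    }
  }
  z <- matrix(stats::rnorm(cfg$n_genes * n_samp), cfg$n_genes, n_samp,
              dimnames = list(genes, md$sample_id))
  z <- z * (cfg$noise_sd * sqrt(1 - loading^2))   # residual, recycled by row
  if (K > 0) {
    fs <- fac[, md$patient_id, drop = FALSE]      # K x samples
    in_mod <- !is.na(module_of)
    z[in_mod, ] <- z[in_mod, ] +
      (cfg$noise_sd * loading[in_mod]) * fs[module_of[in_mod], , drop = FALSE]
  }
  z <- z + mu
  # stage-specific tumor effects
  for (s in cfg$stages) {
    cols <- md$sample_id[md$stage == s & md$condition == "tumor"]
    gset <- deg_by_stage[[s]]
    if (length(gset) > 0 && cfg$deg_log2fc != 0)
      z[gset, cols] <- z[gset, cols] + expr_sign[gset] * cfg$deg_log2fc
  }
  expr <- pmax(2^z - 1, 0)

  ## ---- methylation -----------------------------------------------------
  base_beta <- stats::runif(cfg$n_genes, cfg$background_beta_range[1],
                            cfg$background_beta_range[2])
  names(base_beta) <- genes
  target_t <- base_beta
  target_t[hyper_genes] <- cfg$hyper_beta
  target_t[hypo_genes] <- cfg$hypo_beta
  theta <- matrix(stats::qlogis(base_beta), cfg$n_genes, n_samp,
                  dimnames = list(genes, md$sample_id))
  tum_cols <- md$condition == "tumor"
  theta[, tum_cols] <- stats::qlogis(target_t)
  theta <- theta + matrix(stats::rnorm(cfg$n_genes * n_samp, 0, 0.25),
                          cfg$n_genes, n_samp)
  n_sites <- cfg$n_genes * cfg$cpgs_per_gene
  site_ids <- sprintf("cg%07d", seq_len(n_sites))
  site_gene <- rep(genes, each = cfg$cpgs_per_gene)
  site_eff <- stats::rnorm(n_sites, 0, 0.15)
  beta_sites <- stats::plogis(
    theta[rep(seq_len(cfg$n_genes), each = cfg$cpgs_per_gene), , drop = FALSE] +
      site_eff)
  rownames(beta_sites) <- site_ids
  cpg_map <- data.frame(site = site_ids, gene = site_gene,
                        stringsAsFactors = FALSE)

  ## ---- TF prior --------------------------------------------------------
  true_edges <- NULL
  if (K > 0) {
    true_edges <- do.call(rbind, lapply(seq_len(K), function(m) {
      wired <- c(module_drivers[[m]], module_aux_tfs[[m]])
      mem <- module_members[[m]]
      do.call(rbind, lapply(seq_along(wired), function(i) {
        cov <- if (i == 1) 1 else stats::runif(1, 0.6, 1)
        tg <- if (cov >= 1) mem else sample(mem, max(1, round(cov * length(mem))))
        data.frame(tf = wired[i], target = tg, stringsAsFactors = FALSE)
      }))
    }))
  }
  decoys <- data.frame(
    tf = sample(tfs, cfg$n_decoy_edges, replace = TRUE),
    target = sample(genes, cfg$n_decoy_edges, replace = TRUE),
    stringsAsFactors = FALSE)
  prior <- tf_target_prior(rbind(true_edges, decoys), quiet = TRUE)

  ## ---- missingness ------------------------------------------------------
  if (cfg$missing_frac > 0) {
    idx <- which(stats::runif(length(expr)) < cfg$missing_frac)
    expr[idx] <- NA_real_
  }

  cohort <- paired_cohort(expr, beta_sites, cpg_map, md)

  membership <- module_of[!is.na(module_of)]
  truth <- list(
    deg_genes_by_stage = deg_by_stage,
    hyper_genes = hyper_genes,
    hypo_genes = hypo_genes,
    module_membership = stats::setNames(paste0("M", membership),
                                        names(membership)),
    disease_genes_by_stage = stats::setNames(
      lapply(cfg$stages, function(s) sort(c(excl_drivers[[s]], pan_drivers))),
      cfg$stages),
    pan_stage_drivers = sort(pan_drivers),
    tf_target_edges = true_edges,
    stage_specific_genes = stats::setNames(
      lapply(cfg$stages, function(s) sort(unique(deg_excl[[s]]))), cfg$stages),
    expr_sign = expr_sign)

  list(cohort = cohort, prior = prior, truth = truth, config = cfg)
}

#' Write a simulated cohort as a plain-text fixture directory
#'
#' Emits the exact TSV dialects consumed by the package readers
#' (tab-separated, UTF-8, `NA` missing token): `expression.tsv`,
#' `beta.tsv`, `cpg_map.tsv`, `tf_targets.tsv`, `metadata.tsv` and a long
#' `ground_truth.tsv` (columns `field`, `key`, `gene`). Round-trips
#' losslessly through [read_expression()], [read_beta()] and friends.
#'
#' @param cohort a [paired_cohort()].
#' @param prior a [tf_target_prior()] edge table.
#' @param truth ground-truth list from [simulate_cohort()] (or NULL).
#' @param directory output directory, created if needed.
#' @return Invisibly, the vector of file paths written.
#' @export
write_fixture <- function(cohort, prior, truth, directory) {
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  paths <- c(expression = file.path(directory, "expression.tsv"),
             beta = file.path(directory, "beta.tsv"),
             cpg_map = file.path(directory, "cpg_map.tsv"),
             tf_targets = file.path(directory, "tf_targets.tsv"),
             metadata = file.path(directory, "metadata.tsv"),
             ground_truth = file.path(directory, "ground_truth.tsv"))
  write_matrix_tsv(cohort$expression, "gene", paths["expression"])
  write_matrix_tsv(cohort$beta_sites, "site", paths["beta"])
  write_tsv_df(cohort$cpg_map, paths["cpg_map"])
  write_tsv_df(prior[, c("tf", "target")], paths["tf_targets"])
  write_tsv_df(cohort$metadata, paths["metadata"])
  write_tsv_df(ground_truth_to_long(truth), paths["ground_truth"])
  invisible(paths)
}

ground_truth_to_long <- function(truth) {
  if (is.null(truth))
    return(data.frame(field = character(0), key = character(0),
                      gene = character(0), stringsAsFactors = FALSE))
  rows <- list()
  add <- function(field, key, gene) {
    if (length(gene) > 0)
      rows[[length(rows) + 1L]] <<- data.frame(
        field = field, key = key, gene = gene, stringsAsFactors = FALSE)
  }
  for (s in names(truth$deg_genes_by_stage))
    add("deg", s, truth$deg_genes_by_stage[[s]])
  add("hyper", "", truth$hyper_genes)
  add("hypo", "", truth$hypo_genes)
  if (length(truth$module_membership) > 0)
    add("module", unname(truth$module_membership),
        names(truth$module_membership))
  for (s in names(truth$disease_genes_by_stage))
    add("disease", s, truth$disease_genes_by_stage[[s]])
  add("pan_driver", "", truth$pan_stage_drivers)
  if (!is.null(truth$tf_target_edges) && nrow(truth$tf_target_edges) > 0)
    add("tf_edge", truth$tf_target_edges$tf, truth$tf_target_edges$target)
  for (s in names(truth$stage_specific_genes))
    add("specific", s, truth$stage_specific_genes[[s]])
  do.call(rbind, rows)
}

#' Read a ground-truth table written by [write_fixture()]
#' @param path path to `ground_truth.tsv`.
#' @return A ground-truth list in the [simulate_cohort()] layout.
#' @export
read_ground_truth <- function(path) {
  d <- read_tsv_checked(path, c("field", "key", "gene"))
  pick <- function(f) d[d$field == f, , drop = FALSE]
  by_key <- function(f) {
    x <- pick(f)
    lapply(split(x$gene, x$key), sort)
  }
  mod <- pick("module")
  edg <- pick("tf_edge")
  list(deg_genes_by_stage = by_key("deg"),
       hyper_genes = sort(pick("hyper")$gene),
       hypo_genes = sort(pick("hypo")$gene),
       module_membership = stats::setNames(mod$key, mod$gene),
       disease_genes_by_stage = by_key("disease"),
       pan_stage_drivers = sort(pick("pan_driver")$gene),
       tf_target_edges = if (nrow(edg) > 0)
         data.frame(tf = edg$key, target = edg$gene,
                    stringsAsFactors = FALSE) else NULL,
       stage_specific_genes = by_key("specific"))
}
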