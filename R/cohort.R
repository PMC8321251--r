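#' Paired tumor/normal multi-stage cohort
#'
#' Container for a patient-paired expression + methylation cohort. Every
#' tumor sample must have exactly one normal sample from the same patient
#' and stage; expression is a non-negative FPKM-like gene x sample matrix
#' and methylation a CpG-site x sample matrix of beta values in [0, 1].
#'
#' @param expression numeric gene x sample matrix, non-negative (NA allowed
#'   only when the cohort is destined for [read_expression()]-style
#'   filtering/imputation, e.g. fixtures written with missingness).
#' @param beta_sites numeric CpG-site x sample matrix with values in [0, 1].
#' @param cpg_map data.frame with columns `site`, `gene`.
#' @param metadata data.frame with columns `sample_id`, `patient_id`,
#'   `condition` ("tumor"/"normal") and `stage`.
#' @return An object of class `paired_cohort`.
#' @export
paired_cohort <- function(expression, beta_sites, cpg_map, metadata) {
  req <- c("sample_id", "patient_id", "condition", "stage")
  if (!all(req %in% names(metadata)))
    sg_stop("metadata must have columns %s", paste(req, collapse = ", "))
  metadata$sample_id <- as.character(metadata$sample_id)
  metadata$patient_id <- as.character(metadata$patient_id)
  metadata$condition <- as.character(metadata$condition)
  metadata$stage <- as.character(metadata$stage)
  if (anyDuplicated(metadata$sample_id))
    sg_stop("duplicate sample ids: %s",
            paste(unique(metadata$sample_id[duplicated(metadata$sample_id)]),
                  collapse = ", "))
  if (!all(metadata$condition %in% c("tumor", "normal")))
    sg_stop("condition must be 'tumor' or 'normal'")
  if (!setequal(colnames(expression), metadata$sample_id))
    sg_stop("expression samples and metadata samples differ")
  validate_pairing(metadata)
  if (!is.null(beta_sites)) {
    bad <- which(!is.na(beta_sites) & (beta_sites < 0 | beta_sites > 1),
                 arr.ind = TRUE)
    if (nrow(bad) > 0)
      sg_stop("beta value outside [0,1] at site %s, sample %s",
              rownames(beta_sites)[bad[1, 1]], colnames(beta_sites)[bad[1, 2]])
    if (!setequal(colnames(beta_sites), metadata$sample_id))
      sg_stop("beta samples and metadata samples differ")
    beta_sites <- beta_sites[, metadata$sample_id, drop = FALSE]
  }
  if (any(expression < 0, na.rm = TRUE))
    sg_stop("expression contains negative values")
  structure(
    list(expression = expression[, metadata$sample_id, drop = FALSE],
         beta_sites = beta_sites,
         cpg_map = cpg_map,
         metadata = metadata),
    class = "paired_cohort")
}

# every tumor sample needs exactly one normal with same patient_id and stage
validate_pairing <- function(metadata) {
  split_pat <- split(metadata, metadata$patient_id)
  bad <- names(Filter(function(d) {
    !(nrow(d) == 2 && setequal(d$condition, c("tumor", "normal")) &&
        length(unique(d$stage)) == 1)
  }, split_pat))
  if (length(bad) > 0)
    sg_stop("unpaired or inconsistent patients: %s",
            paste(sort(bad), collapse = ", "))
  invisible(TRUE)
}

#' @export
print.paired_cohort <- function(x, ...) {
  md <- x$metadata
  cat("paired_cohort:", nrow(x$expression), "genes x",
      ncol(x$expression), "samples\n")
  if (!is.null(x$beta_sites))
    cat("  methylation:", nrow(x$beta_sites), "CpG sites\n")
  tab <- table(md$stage[md$condition == "tumor"])
  cat("  pairs per stage:",
      paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = ", "),
      "\n")
  invisible(x)
}

#' Stage labels present in a cohort
#' @param cohort a [paired_cohort()].
#' @return character vector of stage labels in order of first appearance.
#' @export
cohort_stages <- function(cohort) unique(cohort$metadata$stage)

# sample ids for a stage/condition, ordered by patient id so tumor and
# normal vectors align pairwise
stage_samples <- function(cohort, stage, condition) {
  md <- cohort$metadata
  md <- md[md$stage == stage & md$condition == condition, , drop = FALSE]
  md <- md[order(md$patient_id), , drop = FALSE]
  md$sample_id
}

# paired log2(x+1) expression matrices (genes x patients) for one stage
stage_pair_matrices <- function(cohort, stage) {
  tum <- stage_samples(cohort, stage, "tumor")
  nor <- stage_samples(cohort, stage, "normal")
  if (length(tum) != length(nor))
    sg_stop("stage %s is not fully paired", stage)
  list(tumor = log2p1(cohort$expression[, tum, drop = FALSE]),
       normal = log2p1(cohort$expression[, nor, drop = FALSE]),
       n_pairs = length(tum))
}
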