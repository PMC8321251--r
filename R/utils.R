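#' @keywords internal
"_PACKAGE"

#' @importFrom stats median setNames
#' @importFrom utils read.delim
NULL

# log2(x + 1) variance-stabilizing transform used for all FPKM-scale tests
log2p1 <- function(x) log2(x + 1)

`%||%` <- function(a, b) if (is.null(a)) b else a

# lightweight condition-free logger: messages go to stderr; when a log file
# connection is registered (run_all) lines are duplicated there without
# timestamps so that reruns are byte-identical
.sg_env <- new.env(parent = emptyenv())

sg_log <- function(fmt, ...) {
  line <- sprintf(fmt, ...)
  message("[stageGRN] ", line)
  con <- .sg_env$log_con
  if (!is.null(con)) writeLines(line, con)
  invisible(line)
}

sg_stop <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

stopifnot_scalar_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    sg_stop("'%s' must be a single value in [0, 1], got %s", name,
            paste(format(x), collapse = ","))
  invisible(x)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same objects,
#' used to score recovery of planted module membership. Computed from the
#' contingency table with the Hubert-Arabie correction.
#'
#' @param a,b label vectors of equal length (any atomic type).
#' @return A number in [-1, 1]; 1 means identical partitions.
#' @examples
#' adjusted_rand_index(c(1, 1, 2, 2), c("x", "x", "y", "y"))
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) sg_stop("partitions have different lengths")
  n <- length(a)
  if (n < 2) return(1)
  tab <- table(a, b)
  ch2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(ch2(tab))
  sum_a <- sum(ch2(rowSums(tab)))
  sum_b <- sum(ch2(colSums(tab)))
  expected <- sum_a * sum_b / ch2(n)
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(1)
  (sum_ij - expected) / (max_idx - expected)
}

# row-standardize a matrix (mean 0, sd 1 per row); rows with zero variance
# become all-zero and are reported via attribute "constant"
row_standardize <- function(m) {
  mu <- rowMeans(m)
  cen <- m - mu
  s <- sqrt(rowSums(cen^2) / (ncol(m) - 1))
  const <- s == 0 | !is.finite(s)
  s[const] <- 1
  out <- cen / s
  out[const, ] <- 0
  attr(out, "constant") <- const
  out
}
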