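## Differential expression: TMM normalization and a negative-binomial
## log-linear model with a single common dispersion, via edgeR.

#' Trimmed-mean-of-M-values (TMM) normalization factors
#'
#' Between-sample scaling factors from doubly trimmed, precision-weighted
#' log-ratios of library-size-normalized counts, relative to the column
#' whose upper quartile is closest to the mean upper quartile. Factors
#' are rescaled to geometric mean 1, so they are invariant to rescaling
#' all columns by a common constant.
#'
#' @param counts genes x samples integer matrix.
#' @param trim_m,trim_a two-sided trim fractions for the log-ratio (M)
#'   and average-abundance (A) dimensions.
#' @return list with `factors` (named, geometric mean 1) and
#'   `lib_sizes` (column sums).
#' @export
tmm_factors <- function(counts, trim_m = 0.30, trim_a = 0.05) {
  if (ncol(counts) < 2L) stop("need >= 2 samples")
  lib <- colSums(counts)
  if (any(lib == 0)) stop("sample(s) with all-zero counts: ",
                          paste(colnames(counts)[lib == 0], collapse = ", "))
  f <- edgeR::calcNormFactors(counts, method = "TMM",
                              logratioTrim = trim_m, sumTrim = trim_a)
  names(f) <- colnames(counts)
  list(factors = f, lib_sizes = lib)
}

#' Negative-binomial differential expression test
#'
#' Fits a per-gene NB log-linear model of counts on the two-level group
#' factor with offset `log(lib_size * factor)`, a single common
#' dispersion shared across genes (profile-likelihood estimate), and a
#' likelihood-ratio chi-squared test (1 df) of the group coefficient.
#' Genes with zero counts in every sample are reported with
#' `log2_fc = 0`, `p_value = 1` and `zero_flag = TRUE` rather than
#' entering the fit.
#'
#' @param counts genes x samples integer matrix.
#' @param factors output of [tmm_factors()] (or `NULL` to recompute).
#' @param condition tumor/normal vector, length `ncol(counts)`; fold
#'   changes are tumor relative to normal.
#' @return data.frame with `gene_id`, `log2_fc`, `p_value`, `fdr`,
#'   `zero_flag`, plus the common `dispersion` as an attribute.
#' @export
nb_test <- function(counts, factors = NULL, condition = NULL) {
  cond <- .as_condition(condition)
  if (any(table(cond) < 2L)) stop("both groups need >= 2 samples")
  if (is.null(factors)) factors <- tmm_factors(counts)
  zero <- rowSums(counts) == 0L
  y <- edgeR::DGEList(counts = counts[!zero, , drop = FALSE],
                      lib.size = factors$lib_sizes,
                      norm.factors = factors$factors, group = cond)
  design <- stats::model.matrix(~cond)
  y <- edgeR::estimateGLMCommonDisp(y, design)
  fit <- edgeR::glmFit(y, design, dispersion = y$common.dispersion)
  lrt <- edgeR::glmLRT(fit, coef = 2L)
  tab <- lrt$table
  out <- data.frame(gene_id = rownames(counts), log2_fc = 0,
                    p_value = 1, fdr = NA_real_, zero_flag = zero,
                    row.names = NULL, stringsAsFactors = FALSE)
  idx <- match(rownames(tab), rownames(counts))
  out$log2_fc[idx] <- tab$logFC
  out$p_value[idx] <- tab$PValue
  out$fdr <- bh_adjust(out$p_value)
  attr(out, "dispersion") <- y$common.dispersion
  out
}

#' Call differentially expressed genes
#'
#' A gene is differentially expressed when its absolute log2 fold change
#' strictly exceeds `lfc_threshold` and its FDR is strictly below
#' `fdr_threshold`; direction follows the sign of the fold change.
#'
#' @param stats output of [nb_test()].
#' @param lfc_threshold minimum |log2 fold change|.
#' @param fdr_threshold FDR cutoff.
#' @return list with character vectors `up` and `down` and the retained
#'   `records` (with a `direction` column).
#' @export
call_degs <- function(stats, lfc_threshold = 1.5, fdr_threshold = 0.05) {
  keep <- abs(stats$log2_fc) > lfc_threshold & stats$fdr < fdr_threshold &
    !stats$zero_flag
  rec <- stats[keep, , drop = FALSE]
  rec$direction <- ifelse(rec$log2_fc > 0, "up", "down")
  rownames(rec) <- NULL
  list(up = rec$gene_id[rec$direction == "up"],
       down = rec$gene_id[rec$direction == "down"],
       records = rec)
}

#' Log2 counts-per-million on TMM-effective library sizes
#'
#' The normalized expression values used for methylation-expression
#' correlation: `log2(count / (lib_size * factor) * 1e6 + 1)`.
#'
#' @inheritParams nb_test
#' @return numeric matrix, genes x samples.
#' @export
normalize_expression <- function(counts, factors = NULL) {
  if (is.null(factors)) factors <- tmm_factors(counts)
  eff <- factors$lib_sizes * factors$factors[colnames(counts)]
  log2(sweep(counts, 2L, eff, `/`) * 1e6 + 1)
}
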