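## Probe-level QC and missing-value handling preceding differential
## methylation analysis.

#' Filter probes by SNP overlap, chromosome X, and missingness
#'
#' Removes probes flagged as SNP-overlapping, probes on chromosome X, and
#' probes whose missing fraction exceeds `max_missing` (strictly; a probe
#' with exactly 10% missing cells is kept at the default). Each removed
#' probe is accounted to the first matching reason in the order
#' SNP -> chrX -> missingness, so the QC report partitions the input.
#'
#' @param beta beta matrix (probes x samples, `NA` = missing).
#' @param ann probe annotation covering every probe in `beta`.
#' @param max_missing maximum tolerated missing fraction per probe.
#' @return list with `beta` (the retained submatrix) and `report`, a list
#'   of counts (`n_input_probes`, `n_removed_snp`, `n_removed_chrX`,
#'   `n_removed_missing`, `n_retained`).
#' @export
filter_probes <- function(beta, ann, max_missing = 0.10) {
  missing_ann <- setdiff(rownames(beta), ann$probe_id)
  if (length(missing_ann))
    stop("probe(s) absent from annotation: ",
         paste(utils::head(missing_ann, 5L), collapse = ", "))
  a <- ann[match(rownames(beta), ann$probe_id), ]
  snp <- a$snp_flag
  chrx <- !snp & a$chromosome %in% c("chrX", "X")
  miss_frac <- rowMeans(is.na(beta))
  miss <- !snp & !chrx & miss_frac > max_missing
  keep <- !(snp | chrx | miss)
  report <- list(n_input_probes = nrow(beta),
                 n_removed_snp = sum(snp),
                 n_removed_chrX = sum(chrx),
                 n_removed_missing = sum(miss),
                 n_retained = sum(keep))
  list(beta = beta[keep, , drop = FALSE], report = report)
}

#' Impute missing beta values by per-probe means
#'
#' When a condition vector is supplied and every condition has at least
#' three samples, each missing cell is replaced by the probe mean within
#' the sample's condition (falling back to the probe's global mean if a
#' condition has no observed value for that probe); otherwise the global
#' per-probe mean is used. Observed values are never modified and all
#' imputed values lie in \[0, 1\].
#'
#' @param beta beta matrix.
#' @param condition optional vector (length `ncol(beta)`) of
#'   tumor/normal labels used for within-condition imputation.
#' @return beta matrix without missing values.
#' @export
impute_missing <- function(beta, condition = NULL) {
  if (!anyNA(beta)) return(beta)
  all_missing <- rowSums(!is.na(beta)) == 0L
  if (any(all_missing))
    stop("probe(s) with no observed values: ",
         paste(utils::head(rownames(beta)[all_missing], 5L), collapse = ", "))
  global <- rowMeans(beta, na.rm = TRUE)
  use_groups <- !is.null(condition) &&
    all(table(condition) >= 3L) && length(unique(condition)) > 1L
  if (use_groups) {
    condition <- as.character(condition)
    for (g in unique(condition)) {
      cols <- condition == g
      sub <- beta[, cols, drop = FALSE]
      gm <- rowMeans(sub, na.rm = TRUE)
      gm[is.nan(gm)] <- global[is.nan(gm)]
      idx <- which(is.na(sub), arr.ind = TRUE)
      if (nrow(idx)) sub[idx] <- gm[idx[, 1L]]
      beta[, cols] <- sub
    }
  } else {
    idx <- which(is.na(beta), arr.ind = TRUE)
    beta[idx] <- global[idx[, 1L]]
  }
  beta
}
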