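## Differential methylation: Wilcoxon rank-sum tests per probe, BH
## adjustment, DMC calling by effect-size and FDR thresholds, promoter
## mapping to genes, and genomic-context summaries.

## exact two-sided rank-sum p by enumeration of all C(N, n1) group
## assignments of the (midrank-tied) ranks; two-sided mass defined by
## deviation of the rank sum from its exchangeable-null expectation
.wilcox_exact_p <- function(r, n1, combs = NULL) {
  N <- length(r)
  if (is.null(combs)) combs <- utils::combn(N, n1)
  W <- colSums(matrix(r[combs], nrow = n1))
  E <- n1 * mean(r)
  obs <- abs(sum(r[seq_len(n1)]) - E)
  mean(abs(W - E) >= obs - 1e-9)
}

## tie-corrected normal approximation (no continuity correction)
.wilcox_normal_p <- function(r, n1) {
  N <- length(r)
  n2 <- N - n1
  W <- sum(r[seq_len(n1)])
  E <- n1 * (N + 1) / 2
  ties <- table(r)
  v <- n1 * n2 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  if (v <= 0) return(1)
  2 * stats::pnorm(-abs(W - E) / sqrt(v))
}

#' Per-probe Wilcoxon rank-sum tests
#'
#' Two-sided tests of each probe's beta values between two sample groups.
#' Ties are midranked. When both groups have at most eight samples the
#' p-value is exact, computed by full enumeration of all group
#' assignments of the observed ranks; otherwise a tie-corrected normal
#' approximation is used. A probe whose values are all identical gets
#' p = 1.
#'
#' @param beta beta matrix without missing values.
#' @param groups vector (length `ncol(beta)`) with two levels; the first
#'   column group (by factor order) contributes the rank-sum statistic.
#' @param exact_max largest per-group size for which the exact
#'   enumeration is used.
#' @return data.frame with `probe_id`, `statistic` (rank sum of group 1)
#'   and `p_value`.
#' @export
wilcoxon_dmc <- function(beta, groups, exact_max = 8L) {
  g <- factor(groups)
  if (nlevels(g) != 2L) stop("groups must have exactly two levels")
  if (any(table(g) < 2L)) stop("both groups need >= 2 samples")
  if (anyNA(beta)) stop("beta must be imputed before testing")
  i1 <- which(g == levels(g)[1L])
  i2 <- which(g == levels(g)[2L])
  n1 <- length(i1); n2 <- length(i2)
  ord <- c(i1, i2)
  exact <- n1 <= exact_max && n2 <= exact_max
  combs <- if (exact) utils::combn(n1 + n2, n1) else NULL
  res <- apply(beta[, ord, drop = FALSE], 1L, function(x) {
    r <- rank(x)
    W <- sum(r[seq_len(n1)])
    p <- if (exact) .wilcox_exact_p(r, n1, combs) else .wilcox_normal_p(r, n1)
    c(W, p)
  })
  data.frame(probe_id = rownames(beta), statistic = res[1L, ],
             p_value = pmin(res[2L, ], 1), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up false-discovery-rate control with monotonicity enforcement, as
#' implemented by [stats::p.adjust()] with `method = "BH"`.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return adjusted values in \[0, 1\], in the input order.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Per-probe differential methylation statistics
#'
#' Group means, tumor-minus-normal difference, Wilcoxon p-value and BH
#' FDR for every probe.
#'
#' @param beta imputed beta matrix.
#' @param condition tumor/normal vector, length `ncol(beta)`.
#' @inheritParams wilcoxon_dmc
#' @return data.frame with `probe_id`, `mean_beta_tumor`,
#'   `mean_beta_normal`, `delta`, `p_value`, `fdr`.
#' @export
dmc_stats <- function(beta, condition, exact_max = 8L) {
  cond <- .as_condition(condition)
  tum <- rowMeans(beta[, cond == "tumor", drop = FALSE])
  nor <- rowMeans(beta[, cond == "normal", drop = FALSE])
  w <- wilcoxon_dmc(beta, cond, exact_max = exact_max)
  data.frame(probe_id = rownames(beta),
             mean_beta_tumor = tum, mean_beta_normal = nor,
             delta = tum - nor, p_value = w$p_value,
             fdr = bh_adjust(w$p_value), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Call differentially methylated CpGs
#'
#' A probe is a DMC when its absolute mean methylation difference
#' strictly exceeds `delta_threshold` and its FDR is strictly below
#' `fdr_threshold`; direction is hyper for positive delta, hypo
#' otherwise. FDR is computed over all tested probes before either
#' filter is applied.
#'
#' @param stats output of [dmc_stats()].
#' @param delta_threshold minimum absolute tumor-normal beta difference.
#' @param fdr_threshold FDR cutoff.
#' @return the retained rows of `stats` with an added `direction`
#'   column (`hyper`/`hypo`).
#' @export
call_dmcs <- function(stats, delta_threshold = 0.2, fdr_threshold = 0.05) {
  keep <- abs(stats$delta) > delta_threshold & stats$fdr < fdr_threshold
  out <- stats[keep, , drop = FALSE]
  out$direction <- ifelse(out$delta > 0, "hyper", "hypo")
  rownames(out) <- NULL
  out
}

#' Map DMCs to differentially methylated genes via promoter probes
#'
#' A gene is hypermethylated when at least one hyper DMC links to it
#' through a promoter region class, and analogously hypomethylated; a
#' gene can appear in both sets only with promoter DMCs of both
#' directions.
#'
#' @param dmcs DMC table from [call_dmcs()].
#' @param ann probe annotation.
#' @param promoter_regions region classes treated as promoter.
#' @return list with `hyper_genes` and `hypo_genes`, each a named list
#'   mapping gene to the supporting promoter DMC probe ids.
#' @export
map_dmcs_to_genes <- function(dmcs, ann,
                              promoter_regions = PROMOTER_REGIONS) {
  links <- probe_gene_links(ann)
  links <- links[links$gene_region %in% promoter_regions, , drop = FALSE]
  one_dir <- function(dir) {
    ids <- dmcs$probe_id[dmcs$direction == dir]
    sub <- links[links$probe_id %in% ids, , drop = FALSE]
    if (!nrow(sub)) return(structure(list(), names = character()))
    split(sub$probe_id, sub$gene)
  }
  list(hyper_genes = one_dir("hyper"), hypo_genes = one_dir("hypo"))
}

#' Genomic-context summary of DMCs
#'
#' Counts and within-class direction fractions of hyper- and
#' hypomethylated CpGs across genomic location classes (whole array,
#' promoters, CpG islands, CGI promoters), the six CGI relations, and
#' the six gene-region classes. A probe linked to several genes counts
#' once per class it belongs to.
#'
#' @inheritParams map_dmcs_to_genes
#' @return list of data.frames `location`, `cgi_relation`,
#'   `gene_region`, each with columns `class`, `hyper`, `hypo`,
#'   `hyper_fraction`, `hypo_fraction`.
#' @export
context_summary <- function(dmcs, ann,
                            promoter_regions = PROMOTER_REGIONS) {
  a <- ann[match(dmcs$probe_id, ann$probe_id), , drop = FALSE]
  dir <- dmcs$direction
  in_prom <- vapply(strsplit(a$gene_region, ";"), function(r)
    any(r %in% promoter_regions), TRUE)
  in_prom[is.na(in_prom)] <- FALSE
  in_cgi <- a$cgi_relation == "Island"
  tally <- function(sel_list) {
    rows <- lapply(names(sel_list), function(nm) {
      sel <- sel_list[[nm]]
      h <- sum(dir == "hyper" & sel); l <- sum(dir == "hypo" & sel)
      tot <- h + l
      data.frame(class = nm, hyper = h, hypo = l,
                 hyper_fraction = if (tot) h / tot else 0,
                 hypo_fraction = if (tot) l / tot else 0,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  }
  loc <- tally(list(all = rep(TRUE, nrow(dmcs)), promoter = in_prom,
                    CGI = in_cgi, CGI_promoter = in_cgi & in_prom))
  cgi <- tally(stats::setNames(
    lapply(CGI_RELATIONS, function(r) a$cgi_relation == r), CGI_RELATIONS))
  reg <- tally(stats::setNames(lapply(GENE_REGIONS, function(r)
    vapply(strsplit(a$gene_region, ";"), function(g) r %in% g, TRUE)),
    GENE_REGIONS))
  list(location = loc, cgi_relation = cgi, gene_region = reg)
}
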