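## Integration of methylation and expression: quadrant intersections of
## differentially methylated and expressed genes, local (promoter CpG ->
## own gene) and distant (CpG -> other DEGs) Pearson correlation, and a
## self-contained hypergeometric gene-set enrichment.

#' Classify genes by methylation and expression direction
#'
#' Intersects promoter-based differentially methylated gene sets with
#' up/down differentially expressed gene sets into the four quadrants
#' hyper-up, hyper-down, hypo-up and hypo-down.
#'
#' @param dmg output of [map_dmcs_to_genes()].
#' @param degs output of [call_degs()] (or any list with `up`/`down`).
#' @return list of character vectors `hyper_up`, `hyper_down`,
#'   `hypo_up`, `hypo_down`.
#' @export
quadrant_classify <- function(dmg, degs) {
  hyper <- names(dmg$hyper_genes)
  hypo <- names(dmg$hypo_genes)
  list(hyper_up = sort(intersect(hyper, degs$up)),
       hyper_down = sort(intersect(hyper, degs$down)),
       hypo_up = sort(intersect(hypo, degs$up)),
       hypo_down = sort(intersect(hypo, degs$down)))
}

## Pearson r and its two-sided t-test p for paired finite vectors
.cor_test <- function(x, y) {
  n <- length(x)
  r <- suppressWarnings(stats::cor(x, y))  # NA for a constant vector
  if (is.na(r)) return(c(NA_real_, NA_real_))
  if (abs(r) >= 1) return(c(r, 0))
  t <- r * sqrt((n - 2) / (1 - r^2))
  c(r, 2 * stats::pt(-abs(t), df = n - 2))
}

.correlate_pairs <- function(pairs, beta, expr, r_threshold, fdr_threshold) {
  shared <- intersect(colnames(beta), colnames(expr))
  rows <- vector("list", nrow(pairs))
  skipped <- character()
  for (i in seq_len(nrow(pairs))) {
    p <- pairs$probe_id[i]; g <- pairs$gene[i]
    x <- beta[p, shared]; y <- expr[g, shared]
    ok <- is.finite(x) & is.finite(y)
    if (sum(ok) < 3L) {
      warning("pair ", p, "-", g, " has < 3 shared samples; skipped")
      skipped <- c(skipped, paste0(p, ":", g)); next
    }
    rp <- .cor_test(x[ok], y[ok])
    if (is.na(rp[1L])) {           # constant vector, r undefined
      skipped <- c(skipped, paste0(p, ":", g)); next
    }
    rows[[i]] <- data.frame(probe_id = p, gene_id = g, r = rp[1L],
                            p_value = rp[2L], stringsAsFactors = FALSE)
  }
  rec <- do.call(rbind, rows)
  if (is.null(rec))
    rec <- data.frame(probe_id = character(), gene_id = character(),
                      r = numeric(), p_value = numeric())
  rec$fdr <- bh_adjust(rec$p_value)
  rec$significant <- abs(rec$r) > r_threshold & rec$fdr < fdr_threshold
  list(records = rec, skipped = skipped)
}

#' Local methylation-expression correlation
#'
#' Pearson correlation between every promoter CpG and the expression of
#' the gene it links to, over shared samples, with BH adjustment across
#' all tested pairs of the call. A pair is significant when
#' `|r| > r_threshold` and `fdr < fdr_threshold`. Genes are classified
#' `positive` or `negative` when all their significant pairs agree in
#' sign, `both` when signs mix.
#'
#' @param beta imputed beta matrix.
#' @param expr normalized expression matrix (see
#'   [normalize_expression()]); columns must overlap `beta`'s.
#' @param ann probe annotation.
#' @param r_threshold,fdr_threshold significance cutoffs.
#' @param promoter_regions region classes treated as promoter.
#' @return list with `records` (one row per tested pair: `probe_id`,
#'   `gene_id`, `r`, `p_value`, `fdr`, `significant`, `mode`),
#'   `gene_class` (named character) and `skipped` (degenerate pairs).
#' @export
local_correlation <- function(beta, expr, ann, r_threshold = 0.3,
                              fdr_threshold = 0.05,
                              promoter_regions = PROMOTER_REGIONS) {
  links <- probe_gene_links(ann)
  links <- links[links$gene_region %in% promoter_regions &
                   links$probe_id %in% rownames(beta) &
                   links$gene %in% rownames(expr), , drop = FALSE]
  pairs <- unique(links[c("probe_id", "gene")])
  out <- .correlate_pairs(pairs, beta, expr, r_threshold, fdr_threshold)
  out$records$mode <- if (nrow(out$records)) "local" else character()
  sig <- out$records[out$records$significant, , drop = FALSE]
  cls <- vapply(split(sig$r, sig$gene_id), function(r) {
    if (all(r > 0)) "positive" else if (all(r < 0)) "negative" else "both"
  }, "")
  out$gene_class <- cls
  out
}

#' Distant methylation-expression correlation
#'
#' Tests every CpG from the differentially methylated-and-expressed
#' genes against every differentially expressed gene, excluding
#' self-pairs (a CpG with its own source gene). Reports, separately for
#' hyper- and hypomethylated source genes, the fraction of significant
#' correlations that are negative vs positive.
#'
#' @param beta imputed beta matrix restricted (by the caller or here via
#'   `cpg_genes`) to the CpGs of interest.
#' @param expr normalized expression matrix over the DEGs.
#' @param cpg_genes data.frame with `probe_id`, `gene` (the CpG's source
#'   gene) and `direction` (`hyper`/`hypo` methylation of the source
#'   gene).
#' @param deg_ids character vector of DEG gene ids to test against.
#' @inheritParams local_correlation
#' @return list with `records` (as in [local_correlation()], `mode =
#'   "distant"`, plus `source_direction`) and `summary`, a data.frame
#'   per source direction with significant-pair counts and the
#'   negative/positive fractions.
#' @export
distant_correlation <- function(beta, expr, cpg_genes, deg_ids,
                                r_threshold = 0.3, fdr_threshold = 0.05) {
  deg_ids <- intersect(deg_ids, rownames(expr))
  if (!length(deg_ids) || !nrow(cpg_genes))
    return(list(records = data.frame(), summary = data.frame()))
  pairs <- expand.grid(probe_id = cpg_genes$probe_id, gene = deg_ids,
                       stringsAsFactors = FALSE)
  src <- cpg_genes$gene[match(pairs$probe_id, cpg_genes$probe_id)]
  pairs <- pairs[src != pairs$gene, , drop = FALSE]     # exclude self-pairs
  out <- .correlate_pairs(pairs, beta, expr, r_threshold, fdr_threshold)
  rec <- out$records
  rec$mode <- if (nrow(rec)) "distant" else character()
  rec$source_direction <- cpg_genes$direction[match(rec$probe_id,
                                                    cpg_genes$probe_id)]
  sig <- rec[rec$significant, , drop = FALSE]
  summ <- do.call(rbind, lapply(c("hyper", "hypo"), function(d) {
    r <- sig$r[sig$source_direction == d]
    n <- length(r)
    data.frame(source_direction = d, n_significant = n,
               frac_negative = if (n) mean(r < 0) else NA_real_,
               frac_positive = if (n) mean(r > 0) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  list(records = rec, summary = summ, skipped = out$skipped)
}

#' Hypergeometric gene-set enrichment
#'
#' Upper-tail hypergeometric test of the overlap between a query gene
#' list and each gene set, with BH adjustment across sets. A generic,
#' self-contained over-representation analysis in the style of GO/KEGG
#' enrichment tools.
#'
#' @param query character vector of genes (must lie in `universe`).
#' @param universe background gene list.
#' @param gene_sets named list of character vectors (e.g. from
#'   [read_gmt()]); members outside `universe` are ignored.
#' @return data.frame sorted by ascending p with `set`, `set_size`,
#'   `overlap`, `fold`, `p_value`, `fdr`.
#' @export
geneset_enrichment <- function(query, universe, gene_sets) {
  if (!length(universe)) stop("empty universe")
  universe <- unique(universe)
  query <- unique(query)
  if (length(setdiff(query, universe)))
    stop("query genes outside the universe")
  N <- length(universe); n <- length(query)
  rows <- lapply(names(gene_sets), function(nm) {
    set <- intersect(gene_sets[[nm]], universe)
    K <- length(set)
    k <- length(intersect(query, set))
    p <- if (K == 0) 1 else
      stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set = nm, set_size = K, overlap = k,
               fold = if (K > 0 && n > 0) (k / n) / (K / N) else NA_real_,
               p_value = min(p, 1), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- bh_adjust(out$p_value)
  out[order(out$p_value), , drop = FALSE]
}
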