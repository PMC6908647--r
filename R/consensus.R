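## CIMP subtype discovery: variable CGI-promoter probe selection,
## subsampled K-means consensus clustering, and cluster-clinical
## association tests.

#' Select the most variable CGI-promoter probes
#'
#' A probe is retained when it lies in a CpG island, links to at least
#' one gene through a promoter region class, has tumor standard
#' deviation strictly above `sd_min`, and has normal mean strictly below
#' `normal_mean_max`.
#'
#' @param beta_tumor,beta_normal imputed beta matrices over the same
#'   probes.
#' @param ann probe annotation.
#' @param sd_min tumor SD threshold (strict).
#' @param normal_mean_max normal-mean ceiling (strict).
#' @param promoter_regions region classes treated as promoter.
#' @return character vector of probe ids.
#' @export
select_variable_probes <- function(beta_tumor, beta_normal, ann,
                                   sd_min = 0.2, normal_mean_max = 0.05,
                                   promoter_regions = PROMOTER_REGIONS) {
  stopifnot(nrow(beta_tumor) > 0L, nrow(beta_normal) > 0L)
  probes <- rownames(beta_tumor)
  a <- ann[match(probes, ann$probe_id), ]
  in_prom <- vapply(strsplit(a$gene_region, ";"), function(r)
    any(r %in% promoter_regions), TRUE)
  in_prom[is.na(in_prom)] <- FALSE
  sds <- apply(beta_tumor, 1L, stats::sd)
  nmean <- rowMeans(beta_normal[probes, , drop = FALSE])
  probes[a$cgi_relation == "Island" & in_prom & sds > sd_min &
           nmean < normal_mean_max]
}

## k-means++ seeding followed by Lloyd iterations; best of n_restarts
.kmeans_pp <- function(X, k, n_restarts = 10L) {
  n <- nrow(X)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    centers <- matrix(NA_real_, k, ncol(X))
    centers[1L, ] <- X[sample.int(n, 1L), ]
    d2 <- rowSums((X - matrix(centers[1L, ], n, ncol(X), TRUE))^2)
    if (k > 1L) for (j in 2:k) {
      pick <- if (all(d2 == 0)) sample.int(n, 1L) else
        sample.int(n, 1L, prob = d2)
      centers[j, ] <- X[pick, ]
      d2 <- pmin(d2, rowSums((X - matrix(centers[j, ], n, ncol(X), TRUE))^2))
    }
    centers <- centers[!duplicated(centers), , drop = FALSE]
    km <- suppressWarnings(stats::kmeans(X, centers = centers,
                                         iter.max = 50L))
    if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
  }
  best
}

#' Consensus K-means clustering
#'
#' Repeatedly subsamples columns (samples) without replacement, runs
#' K-means with Euclidean distance and k-means++ initialisation, and
#' accumulates how often each sample pair lands in the same cluster
#' among the runs where both were drawn. Final labels come from
#' average-linkage hierarchical clustering of `1 - consensus` cut at
#' `k`. Each repetition derives its own seed from `seed`, so results are
#' reproducible.
#'
#' @param beta_subset probes x samples matrix (typically the output of
#'   [select_variable_probes()] rows).
#' @param k number of clusters (>= 2, <= samples).
#' @param n_reps number of subsampled clustering repetitions.
#' @param subsample_frac fraction of samples drawn per repetition.
#' @param seed integer seed.
#' @param n_restarts k-means++ restarts per repetition.
#' @return a `consensus_result` list: `consensus` (samples x samples in
#'   \[0, 1\], symmetric, unit diagonal), `labels` (named integer),
#'   `selected_probe_ids`, `cluster_means` (per-cluster mean beta over
#'   the selected probes), `k`, `seed`.
#' @export
consensus_cluster <- function(beta_subset, k, n_reps = 1000,
                              subsample_frac = 0.8, seed = 1,
                              n_restarts = 10L) {
  n <- ncol(beta_subset)
  if (k < 2L) stop("k must be >= 2")
  if (k > n) stop("k exceeds the number of samples")
  X <- t(beta_subset)
  m <- max(k, round(subsample_frac * n))
  co <- matrix(0, n, n)
  drawn <- matrix(0, n, n)
  for (rep in seq_len(n_reps)) {
    set.seed(.child_seed(seed, rep))
    idx <- sort(sample.int(n, m))
    km <- .kmeans_pp(X[idx, , drop = FALSE], k, n_restarts)
    same <- outer(km$cluster, km$cluster, `==`)
    co[idx, idx] <- co[idx, idx] + same
    drawn[idx, idx] <- drawn[idx, idx] + 1
  }
  if (any(drawn == 0))
    stop("some sample pairs were never co-sampled; increase n_reps")
  consensus <- co / drawn
  diag(consensus) <- 1
  dimnames(consensus) <- list(colnames(beta_subset), colnames(beta_subset))
  hc <- stats::hclust(stats::as.dist(1 - consensus), method = "average")
  labels <- stats::cutree(hc, k = k)
  cluster_means <- tapply(colMeans(beta_subset), labels, mean)
  structure(list(consensus = consensus, labels = labels,
                 selected_probe_ids = rownames(beta_subset),
                 cluster_means = cluster_means, k = k, seed = seed),
            class = "consensus_result")
}

#' @export
print.consensus_result <- function(x, ...) {
  cat("Consensus clustering:", length(x$labels), "samples, k =", x$k, "\n")
  print(table(cluster = x$labels))
  cat("per-cluster mean beta:",
      paste(sprintf("%d: %.3f", seq_along(x$cluster_means),
                    x$cluster_means), collapse = ", "), "\n")
  invisible(x)
}

#' Fisher's exact test of a clinical feature across clusters
#'
#' Builds the clusters x levels contingency table and tests
#' independence. Small tables (both margins within 2 x 3, or total count
#' at most 30) are tested exactly; larger tables use a Monte-Carlo
#' estimate over `B` sampled tables with a fixed seed, reported with its
#' standard error.
#'
#' @param labels cluster labels.
#' @param feature categorical clinical feature, same length.
#' @param B Monte-Carlo table count for large tables.
#' @param seed seed for the Monte-Carlo path.
#' @return list with `p_value`, `method` (`"exact"`/`"monte_carlo"`) and
#'   `se` (`NA` for exact).
#' @export
cluster_association <- function(labels, feature, B = 100000, seed = 1) {
  keep <- !is.na(feature) & !is.na(labels)
  tab <- table(labels[keep], feature[keep])
  tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  if (ncol(tab) < 2L || nrow(tab) < 2L) {
    warning("feature or labels have a single level; p = 1")
    return(list(p_value = 1, method = "degenerate", se = NA_real_))
  }
  small <- (min(dim(tab)) <= 2L && max(dim(tab)) <= 3L) || sum(tab) <= 30
  if (small) {
    p <- stats::fisher.test(tab)$p.value
    list(p_value = p, method = "exact", se = NA_real_)
  } else {
    set.seed(seed)
    p <- stats::fisher.test(tab, simulate.p.value = TRUE, B = B)$p.value
    list(p_value = p, method = "monte_carlo",
         se = sqrt(p * (1 - p) / B))
  }
}

#' One-way ANOVA of methylation level across clusters
#'
#' Classical fixed-effects one-way analysis of variance of a per-sample
#' methylation summary (e.g. the mean beta over the selected probes)
#' across cluster labels.
#'
#' @param labels cluster labels (>= 2 clusters, each with >= 2 samples).
#' @param values numeric vector, same length.
#' @return list with `F` and `p_value`. With zero between-group
#'   variance `F = 0`, p = 1; with zero within-group variance the
#'   p-value underflows to 0 (below machine minimum).
#' @export
cluster_methylation_anova <- function(labels, values) {
  g <- factor(labels)
  if (nlevels(g) < 2L) stop("need >= 2 clusters")
  if (any(table(g) < 2L)) stop("every cluster needs >= 2 samples")
  a <- suppressWarnings(stats::anova(stats::lm(values ~ g)))
  Fv <- a$`F value`[1L]
  p <- a$`Pr(>F)`[1L]
  if (is.nan(Fv)) { Fv <- 0; p <- 1 }   # zero variance everywhere
  if (a$`Sum Sq`[2L] <= 1e-12 * a$`Sum Sq`[1L]) { # zero within-group variance
    Fv <- Inf; p <- 0
  }
  list(F = Fv, p_value = p)
}
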