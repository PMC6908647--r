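## Synthetic multi-cancer cohort generator. Emulates the data regimes the
## pipeline was designed for: bounded, bimodal 450K-style beta values with
## heteroskedastic Beta noise, tumor hypermethylation shifts at planted
## CpGs (cancer-type-specific or shared across types), a CIMP-like block of
## variable CpG-island promoter probes carrying a planted cluster
## structure, negative-binomial counts coupled to promoter methylation on
## the log scale, and missing-at-random cells.

#' Configuration for a synthetic multi-cancer methylation cohort
#'
#' Defaults define the package's reference simulation: three cancer types
#' (the first is the target), 100 tumors / 100 normals for the target and
#' 50/50 for each other type, 2000 probes, 500 genes, four target-specific
#' hypermethylation markers and six markers shared by all tumor types, a
#' mean beta shift of 0.4, and a three-cluster CIMP block.
#'
#' @param n_cancer_types number of simulated cancer types (>= 2); the first
#'   is the target cancer.
#' @param n_tumors,n_normals per-type sample counts, recycled to
#'   `n_cancer_types`.
#' @param n_probes,n_genes array and transcriptome sizes.
#' @param n_specific_markers CpGs hypermethylated only in target tumors.
#' @param n_shared_markers CpGs hypermethylated in tumors of every type.
#' @param n_hypo_markers CpGs hypomethylated in target tumors (gene-body
#'   probes; they never enter the candidate funnel but give the DMC mix
#'   both directions).
#' @param n_cimp_probes size of the variable CGI-promoter block carrying
#'   the planted cluster structure.
#' @param n_cimp_clusters number of planted CIMP clusters among target
#'   tumors (default 3: high / intermediate / low).
#' @param hyper_delta mean beta shift at planted markers, in (0, 1).
#' @param beta_precision concentration `kappa` of the Beta noise
#'   (`Beta(mu*kappa, (1-mu)*kappa)`); larger is less noisy.
#' @param coupling_strength methylation-to-expression effect on the
#'   natural-log NB mean per unit beta; negative couples hypermethylation
#'   to silencing.
#' @param nb_dispersion negative-binomial dispersion of the counts.
#' @param n_extra_degs planted methylation-independent DE genes per
#'   direction (log2 fold change +/- `extra_deg_lfc`).
#' @param extra_deg_lfc absolute log2 fold change of the extra DE genes.
#' @param missing_rate fraction of beta cells set missing, in \[0, 0.5).
#' @param snp_frac,chrx_frac fraction of background probes flagged as
#'   SNP-overlapping / placed on chromosome X.
#' @param seed integer seed; identical seeds give bit-identical cohorts.
#' @return a `cohort_config` list.
#' @export
cohort_config <- function(n_cancer_types = 3,
                          n_tumors = c(100, 50, 50),
                          n_normals = c(100, 50, 50),
                          n_probes = 2000,
                          n_genes = 500,
                          n_specific_markers = 4,
                          n_shared_markers = 6,
                          n_hypo_markers = 8,
                          n_cimp_probes = 60,
                          n_cimp_clusters = 3,
                          hyper_delta = 0.4,
                          beta_precision = 50,
                          coupling_strength = -5,
                          nb_dispersion = 0.1,
                          n_extra_degs = 30,
                          extra_deg_lfc = 3,
                          missing_rate = 0.05,
                          snp_frac = 0.03,
                          chrx_frac = 0.03,
                          seed = 1) {
  cfg <- list(n_cancer_types = as.integer(n_cancer_types),
              n_tumors = rep_len(as.integer(n_tumors), n_cancer_types),
              n_normals = rep_len(as.integer(n_normals), n_cancer_types),
              n_probes = as.integer(n_probes),
              n_genes = as.integer(n_genes),
              n_specific_markers = as.integer(n_specific_markers),
              n_shared_markers = as.integer(n_shared_markers),
              n_hypo_markers = as.integer(n_hypo_markers),
              n_cimp_probes = as.integer(n_cimp_probes),
              n_cimp_clusters = as.integer(n_cimp_clusters),
              hyper_delta = hyper_delta,
              beta_precision = beta_precision,
              coupling_strength = coupling_strength,
              nb_dispersion = nb_dispersion,
              n_extra_degs = as.integer(n_extra_degs),
              extra_deg_lfc = extra_deg_lfc,
              missing_rate = missing_rate,
              snp_frac = snp_frac,
              chrx_frac = chrx_frac,
              seed = as.integer(seed))
  if (cfg$n_cancer_types < 2L) stop("need at least 2 cancer types")
  if (any(c(cfg$n_tumors, cfg$n_normals, cfg$n_probes, cfg$n_genes) < 1L))
    stop("all sample/probe/gene counts must be positive")
  if (cfg$hyper_delta <= 0 || cfg$hyper_delta >= 1)
    stop("hyper_delta must lie in (0, 1)")
  if (cfg$missing_rate < 0 || cfg$missing_rate >= 0.5)
    stop("missing_rate must lie in [0, 0.5)")
  if (cfg$n_specific_markers + cfg$n_shared_markers > cfg$n_probes)
    stop("more planted markers than probes")
  if (cfg$n_specific_markers + cfg$n_shared_markers + cfg$n_hypo_markers +
        cfg$n_cimp_probes > cfg$n_probes)
    stop("planted marker and CIMP blocks exceed n_probes")
  if (cfg$n_cimp_clusters < 2L) stop("need at least 2 CIMP clusters")
  structure(cfg, class = "cohort_config")
}

## draw Beta(mu*kappa, (1-mu)*kappa) with mu clamped away from {0,1}
.rbeta_mu <- function(n, mu, kappa) {
  mu <- pmin(pmax(mu, 0.02), 0.98)
  stats::rbeta(n, mu * kappa, (1 - mu) * kappa)
}

#' Generate a synthetic multi-cancer cohort with known ground truth
#'
#' See [cohort_config()] for the generative model. All randomness is
#' governed by `config$seed`; identical configurations produce
#' bit-identical cohorts.
#'
#' @param config a [cohort_config()].
#' @return a `meth_cohort` list with elements `beta` (probes x samples,
#'   `NA` = missing), `ann` (manifest data.frame), `counts` (genes x
#'   target-cancer samples), `samples` (sample sheet) and `truth`, a list
#'   holding `specific_marker_probe_ids`, `shared_marker_probe_ids`,
#'   `cimp_probe_ids`, `true_cluster_labels` (named, target tumors),
#'   `true_degs` (data.frame gene/log2_fc/source) and `coupling`
#'   (data.frame probe_id/gene/sign).
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  cfg <- config

  types <- paste0("CT", seq_len(cfg$n_cancer_types))
  sample_rows <- do.call(rbind, lapply(seq_along(types), function(t) {
    data.frame(
      sample_id = c(sprintf("%s_T%03d", types[t], seq_len(cfg$n_tumors[t])),
                    sprintf("%s_N%03d", types[t], seq_len(cfg$n_normals[t]))),
      condition = rep(c("tumor", "normal"), c(cfg$n_tumors[t], cfg$n_normals[t])),
      cancer_type = types[t], stringsAsFactors = FALSE)
  }))
  samples <- sample_rows
  n_samp <- nrow(samples)
  tumor_of <- function(t) samples$sample_id[samples$cancer_type == t &
                                              samples$condition == "tumor"]

  ## probe layout: [specific | shared | cimp | background]
  probes <- sprintf("cg%07d", seq_len(cfg$n_probes))
  i_spec <- seq_len(cfg$n_specific_markers)
  i_shared <- cfg$n_specific_markers + seq_len(cfg$n_shared_markers)
  i_hypo <- cfg$n_specific_markers + cfg$n_shared_markers +
    seq_len(cfg$n_hypo_markers)
  i_cimp <- cfg$n_specific_markers + cfg$n_shared_markers +
    cfg$n_hypo_markers + seq_len(cfg$n_cimp_probes)
  i_bg <- setdiff(seq_len(cfg$n_probes), c(i_spec, i_shared, i_hypo, i_cimp))

  genes <- sprintf("G%04d", seq_len(cfg$n_genes))
  marker_genes <- genes[seq_len(length(i_spec) + length(i_shared))]
  other_genes <- setdiff(genes, marker_genes)

  ## annotation
  ann <- data.frame(probe_id = probes,
                    chromosome = sample(paste0("chr", 1:22), cfg$n_probes,
                                        replace = TRUE),
                    position = sample.int(1e8, cfg$n_probes, replace = TRUE),
                    gene = "", gene_region = "",
                    cgi_relation = sample(CGI_RELATIONS, cfg$n_probes,
                                          replace = TRUE, prob = c(.3, .12,
                                            .12, .08, .08, .3)),
                    snp_flag = FALSE, stringsAsFactors = FALSE)
  ann$gene[c(i_spec, i_shared)] <- marker_genes
  ann$gene_region[c(i_spec, i_shared)] <- "TSS200"
  ann$cgi_relation[c(i_spec, i_shared)] <- "Island"
  if (length(i_hypo)) {
    ann$gene[i_hypo] <- sample(other_genes, length(i_hypo), replace = TRUE)
    ann$gene_region[i_hypo] <- "Body"
    ann$cgi_relation[i_hypo] <- "OpenSea"
  }
  ann$gene[i_cimp] <- sample(other_genes, length(i_cimp), replace = TRUE)
  ann$gene_region[i_cimp] <- sample(c("TSS200", "TSS1500"), length(i_cimp),
                                    replace = TRUE)
  ann$cgi_relation[i_cimp] <- "Island"
  ann$gene[i_bg] <- sample(c(other_genes, rep("", length(other_genes) %/% 3)),
                           length(i_bg), replace = TRUE)
  has_gene <- i_bg[ann$gene[i_bg] != ""]
  ann$gene_region[has_gene] <- sample(GENE_REGIONS, length(has_gene),
                                      replace = TRUE)
  ann$snp_flag[i_bg] <- stats::runif(length(i_bg)) < cfg$snp_frac
  on_x <- i_bg[stats::runif(length(i_bg)) < cfg$chrx_frac]
  ann$chromosome[on_x] <- "chrX"

  ## mean-beta surface: background bimodal, constant across samples
  mu <- matrix(0, cfg$n_probes, n_samp, dimnames = list(probes,
                                                        samples$sample_id))
  bg_low <- stats::runif(length(i_bg)) < 0.5
  bg_mu <- ifelse(bg_low, stats::runif(length(i_bg), 0.03, 0.15),
                  stats::runif(length(i_bg), 0.70, 0.92))
  mu[i_bg, ] <- bg_mu
  mu[c(i_spec, i_shared), ] <- 0.08
  mu[i_spec, tumor_of(types[1L])] <- 0.08 + cfg$hyper_delta
  for (t in types) mu[i_shared, tumor_of(t)] <- 0.08 + cfg$hyper_delta
  mu[i_hypo, ] <- 0.75
  mu[i_hypo, tumor_of(types[1L])] <- 0.75 - cfg$hyper_delta

  ## CIMP block: normals (and non-target tumors) lowly methylated; target
  ## tumors get per-cluster mean offsets spanning low -> high
  mu[i_cimp, ] <- 0.03
  target_tumors <- tumor_of(types[1L])
  cl <- sample(rep_len(seq_len(cfg$n_cimp_clusters), length(target_tumors)))
  names(cl) <- target_tumors
  cl_means <- seq(0.15, 0.75, length.out = cfg$n_cimp_clusters)
  mu[i_cimp, target_tumors] <- matrix(cl_means[cl], length(i_cimp),
                                      length(target_tumors), byrow = TRUE)

  beta <- matrix(.rbeta_mu(length(mu), as.vector(mu), cfg$beta_precision),
                 nrow(mu), ncol(mu), dimnames = dimnames(mu))

  ## clinical covariates for target samples, loosely tied to the clusters
  samples$histology <- NA_character_
  samples$hpv_status <- NA_character_
  samples$hpv_clade <- NA_character_
  ti <- match(target_tumors, samples$sample_id)
  samples$histology[ti] <- sample(c("squamous", "adeno", "adenosquamous"),
                                  length(ti), TRUE, prob = c(.8, .17, .03))
  low_cl <- which.min(cl_means)
  samples$hpv_status[ti] <- ifelse(cl == low_cl &
                                     stats::runif(length(ti)) < 0.15,
                                   "negative", "positive")
  samples$hpv_clade[ti] <- ifelse(samples$hpv_status[ti] == "positive",
                                  sample(c("A9", "A7"), length(ti), TRUE,
                                         prob = c(.7, .3)), "none")

  ## expression for the target cancer only
  target_ids <- samples$sample_id[samples$cancer_type == types[1L]]
  log_mu0 <- stats::runif(cfg$n_genes, log(50), log(2000))
  names(log_mu0) <- genes
  lmu <- matrix(log_mu0, cfg$n_genes, length(target_ids),
                dimnames = list(genes, target_ids))
  coupled_probes <- probes[c(i_spec, i_shared)]
  beta_c <- beta[coupled_probes, target_ids, drop = FALSE]  # realized betas
  centred <- beta_c - rowMeans(beta_c)
  lmu[marker_genes, ] <- lmu[marker_genes, ] + cfg$coupling_strength * centred

  is_target_tumor <- samples$condition[match(target_ids,
                                             samples$sample_id)] == "tumor"
  deg_pool <- setdiff(other_genes, unique(ann$gene[i_cimp]))
  extra_up <- deg_pool[seq_len(cfg$n_extra_degs)]
  extra_dn <- deg_pool[cfg$n_extra_degs + seq_len(cfg$n_extra_degs)]
  lmu[extra_up, is_target_tumor] <- lmu[extra_up, is_target_tumor] +
    cfg$extra_deg_lfc * log(2)
  lmu[extra_dn, is_target_tumor] <- lmu[extra_dn, is_target_tumor] -
    cfg$extra_deg_lfc * log(2)

  lib <- stats::runif(length(target_ids), 0.7, 1.3)
  lmu <- sweep(lmu, 2L, log(lib), `+`)
  counts <- matrix(stats::rnbinom(length(lmu), mu = exp(lmu),
                                  size = 1 / cfg$nb_dispersion),
                   nrow(lmu), ncol(lmu), dimnames = dimnames(lmu))
  storage.mode(counts) <- "integer"

  if (cfg$missing_rate > 0)
    beta <- inject_missing(beta, cfg$missing_rate,
                           seed = .child_seed(cfg$seed, 7L))

  marker_lfc <- cfg$coupling_strength * cfg$hyper_delta / log(2)
  truth <- list(
    specific_marker_probe_ids = probes[i_spec],
    shared_marker_probe_ids = probes[i_shared],
    hypo_marker_probe_ids = probes[i_hypo],
    cimp_probe_ids = probes[i_cimp],
    true_cluster_labels = cl,
    true_degs = rbind(
      data.frame(gene = marker_genes, log2_fc = marker_lfc,
                 source = "coupled", stringsAsFactors = FALSE),
      data.frame(gene = extra_up, log2_fc = cfg$extra_deg_lfc,
                 source = "planted", stringsAsFactors = FALSE),
      data.frame(gene = extra_dn, log2_fc = -cfg$extra_deg_lfc,
                 source = "planted", stringsAsFactors = FALSE)),
    coupling = data.frame(probe_id = coupled_probes, gene = marker_genes,
                          sign = sign(cfg$coupling_strength),
                          stringsAsFactors = FALSE),
    target_cancer = types[1L])

  structure(list(beta = beta, ann = ann, counts = counts, samples = samples,
                 truth = truth, config = cfg),
            class = "meth_cohort")
}

#' Set a random fraction of beta cells to missing
#'
#' Missingness is completely at random per cell. With `rate = 0` the input
#' is returned unchanged; the same seed always yields the same mask.
#'
#' @param beta beta matrix.
#' @param rate missing fraction in \[0, 1).
#' @param seed integer seed for the mask.
#' @return the matrix with `NA`s injected.
#' @export
inject_missing <- function(beta, rate, seed = 1) {
  if (rate < 0 || rate >= 1) stop("rate must lie in [0, 1)")
  if (rate == 0) return(beta)
  set.seed(seed)
  mask <- stats::runif(length(beta)) < rate
  beta[mask] <- NA_real_
  beta
}

#' @export
print.meth_cohort <- function(x, ...) {
  cat("Synthetic methylation cohort:",
      nrow(x$beta), "probes x", ncol(x$beta), "samples;",
      nrow(x$counts), "genes x", ncol(x$counts), "expression samples\n")
  cat("  cancer types:", paste(unique(x$samples$cancer_type),
                               collapse = ", "),
      "(target:", x$truth$target_cancer, ")\n")
  cat("  planted:", length(x$truth$specific_marker_probe_ids),
      "specific +", length(x$truth$shared_marker_probe_ids),
      "shared markers,", length(x$truth$cimp_probe_ids), "CIMP probes\n")
  invisible(x)
}

#' Write a cohort's tables to a directory
#'
#' Emits `beta.tsv`, `manifest.tsv`, `counts.tsv`, `samples.tsv` and
#' `truth.json` under `dir`.
#'
#' @param cohort a `meth_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "meth_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_beta_matrix(cohort$beta, file.path(dir, "beta.tsv"))
  write_manifest(cohort$ann, file.path(dir, "manifest.tsv"))
  write_counts(cohort$counts, file.path(dir, "counts.tsv"))
  write_sample_sheet(cohort$samples, file.path(dir, "samples.tsv"))
  truth <- cohort$truth
  truth$true_cluster_labels <- as.list(truth$true_cluster_labels)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
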