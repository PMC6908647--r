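# Shared fixtures: cohorts are generated in code and cached per test run.

.cohort_cache <- new.env(parent = emptyenv())

cached_cohort <- function(key, cfg) {
  if (is.null(.cohort_cache[[key]]))
    assign(key, generate_cohort(cfg), envir = .cohort_cache)
  get(key, envir = .cohort_cache)
}

# the reference simulation: default study conditions, fixed seed
default_cohort <- function() cached_cohort("default", cohort_config(seed = 101))

# a lighter cohort for unit tests that only need structure, not power
small_cohort <- function() {
  cached_cohort("small", cohort_config(
    n_tumors = c(50, 30, 30), n_normals = c(50, 30, 30),
    n_probes = 600, n_genes = 200, n_cimp_probes = 40,
    n_extra_degs = 15, seed = 202))
}

# annotation row builder for hand-made fixtures
make_ann <- function(probe_id, gene = "", gene_region = "",
                     cgi_relation = "OpenSea", chromosome = "chr1",
                     snp_flag = FALSE, position = 1000) {
  data.frame(probe_id = probe_id, chromosome = chromosome,
             position = position, gene = gene, gene_region = gene_region,
             cgi_relation = cgi_relation, snp_flag = snp_flag,
             stringsAsFactors = FALSE)
}

# target-cancer beta/labels convenience
target_beta <- function(cohort, impute = TRUE) {
  s <- cohort$samples
  ids <- s$sample_id[s$cancer_type == cohort$truth$target_cancer]
  b <- cohort$beta[, ids, drop = FALSE]
  cond <- as.character(s$condition[match(ids, s$sample_id)])
  if (impute) b <- impute_missing(b, cond)
  list(beta = b, condition = cond, ids = ids)
}
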