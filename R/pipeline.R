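## End-to-end marker-discovery workflow: QC -> DMC -> DEG -> integration
## -> candidates -> cross-cancer specificity screen -> information-gain
## filter -> SBFS -> cross-validated evaluation. Driven by a flat
## key = value configuration whose defaults are the pipeline's standard
## thresholds.

#' Default pipeline configuration
#'
#' Flat named list of every stage parameter: QC missingness cutoff
#' (0.10), DMC delta (> 0.2) and FDR (< 0.05), DEG |log2 FC| (> 1.5) and
#' FDR (< 0.05), information-gain cutoff (> 0.3 bits, 10 bins), SBFS
#' evaluator folds (5), final CV folds (10), and the run seed.
#'
#' @return named list of defaults; override entries and pass to
#'   [run_pipeline()].
#' @export
default_pipeline_config <- function() {
  list(`qc.max_missing` = 0.10,
       `dmc.delta_threshold` = 0.2,
       `dmc.fdr_threshold` = 0.05,
       `deg.lfc_threshold` = 1.5,
       `deg.fdr_threshold` = 0.05,
       `ig.threshold` = 0.3,
       `ig.n_bins` = 10,
       `sbfs.folds` = 5,
       `cv.folds` = 10,
       seed = 1)
}

#' Read / write a flat `key = value` pipeline configuration file
#'
#' Lines are `key = value`; blank lines and `#` comments are ignored.
#' Values that parse as numbers become numeric.
#'
#' @param path config file path.
#' @return named list.
#' @export
read_pipeline_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[grepl("=", lines)])
  kv <- strsplit(lines, "\\s*=\\s*")
  vals <- lapply(kv, function(p) {
    v <- p[2L]
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) num else v
  })
  stats::setNames(vals, vapply(kv, `[[`, "", 1L))
}

#' @rdname read_pipeline_config
#' @param config named list.
#' @export
write_pipeline_config <- function(config, path) {
  writeLines(paste(names(config), unlist(config), sep = " = "), path)
  invisible(path)
}

#' Run the full marker-discovery pipeline
#'
#' Executes the workflow on either a `meth_cohort` object or on the
#' input tables referenced by the configuration (`input.beta`,
#' `input.manifest`, `input.counts`, `input.samples`). The first cancer
#' type in the sample sheet is the target unless `target.cancer_type`
#' says otherwise. One table is written per stage plus a JSON summary;
#' every threshold used is logged. A stage that leaves no candidates
#' stops the run with status `"no_candidates"` rather than an error.
#'
#' @param config named list or path to a `key = value` file; unset keys
#'   take [default_pipeline_config()] values.
#' @param cohort optional `meth_cohort` used instead of `input.*` paths.
#' @param outdir output directory; defaults to `config$outdir`, else a
#'   fresh temporary directory.
#' @return a `pipeline_result` list: `status` (`"ok"` or
#'   `"no_candidates"`), `summary` (what the JSON holds), `panel`
#'   (`marker_panel` or `NULL`), `report` (`eval_report` or `NULL`),
#'   `outdir`.
#' @export
run_pipeline <- function(config = list(), cohort = NULL, outdir = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  cfg <- utils::modifyList(default_pipeline_config(), config)
  outdir <- outdir %||% cfg$outdir %||% tempfile("methpanel_run_")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  logfile <- file.path(outdir, "run.log")
  logln <- function(...) cat(..., "\n", sep = "", file = logfile,
                             append = TRUE)
  cat("", file = logfile)
  for (k in setdiff(names(cfg), "outdir"))
    logln("config ", k, " = ", format(cfg[[k]]))

  if (is.null(cohort)) {
    for (k in c("input.beta", "input.manifest", "input.counts",
                "input.samples"))
      if (is.null(cfg[[k]])) stop("config key '", k, "' is required")
    cohort <- list(beta = read_beta_matrix(cfg[["input.beta"]]),
                   ann = read_manifest(cfg[["input.manifest"]]),
                   counts = read_counts(cfg[["input.counts"]]),
                   samples = read_sample_sheet(cfg[["input.samples"]]))
  }
  beta <- cohort$beta; ann <- cohort$ann
  counts <- cohort$counts; samples <- cohort$samples
  samples$condition <- .as_condition(samples$condition)
  target <- cfg[["target.cancer_type"]] %||% samples$cancer_type[1L]
  seed <- as.integer(cfg$seed)
  fail <- function(stage, why) {
    logln("STOP at ", stage, ": ", why)
    summary <- list(status = "no_candidates", stage = stage, reason = why,
                    target_cancer = target)
    jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
    structure(list(status = "no_candidates", summary = summary,
                   panel = NULL, report = NULL, outdir = outdir),
              class = "pipeline_result")
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  ## -- QC + imputation ------------------------------------------------
  qc <- stage("qc", filter_probes(beta, ann,
                                  max_missing = cfg[["qc.max_missing"]]))
  jsonlite::write_json(qc$report, file.path(outdir, "qc_report.json"),
                       auto_unbox = TRUE, digits = NA)
  logln("qc retained ", qc$report$n_retained, "/",
        qc$report$n_input_probes, " probes")
  in_target <- samples$cancer_type == target
  target_ids <- samples$sample_id[in_target]
  cond_all <- as.character(samples$condition)[match(colnames(qc$beta),
                                                    samples$sample_id)]
  beta_imp <- stage("impute", impute_missing(qc$beta, cond_all))

  ## -- differential methylation (target cancer) -----------------------
  b_t <- beta_imp[, intersect(colnames(beta_imp), target_ids), drop = FALSE]
  cond_t <- samples$condition[match(colnames(b_t), samples$sample_id)]
  dstats <- stage("dmc", dmc_stats(b_t, cond_t))
  dmcs <- call_dmcs(dstats, cfg[["dmc.delta_threshold"]],
                    cfg[["dmc.fdr_threshold"]])
  utils::write.table(dmcs, file.path(outdir, "dmc_table.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  logln("dmc called ", nrow(dmcs), " (|delta| > ",
        cfg[["dmc.delta_threshold"]], ", fdr < ",
        cfg[["dmc.fdr_threshold"]], ")")
  if (!nrow(dmcs)) return(fail("dmc", "no differentially methylated CpGs"))

  ## -- differential expression (target cancer) ------------------------
  cts <- counts[, intersect(colnames(counts), target_ids), drop = FALSE]
  cond_e <- samples$condition[match(colnames(cts), samples$sample_id)]
  nstats <- stage("deg", nb_test(cts, condition = cond_e))
  degs <- call_degs(nstats, cfg[["deg.lfc_threshold"]],
                    cfg[["deg.fdr_threshold"]])
  utils::write.table(degs$records, file.path(outdir, "deg_table.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  logln("deg called ", nrow(degs$records), " (|log2fc| > ",
        cfg[["deg.lfc_threshold"]], ", fdr < ",
        cfg[["deg.fdr_threshold"]], ")")

  ## -- integration: promoter DMGs x DEGs -------------------------------
  dmg <- map_dmcs_to_genes(dmcs, ann)
  quad <- quadrant_classify(dmg, degs)
  logln("quadrants: hyper_down = ", length(quad$hyper_down),
        ", hyper_up = ", length(quad$hyper_up),
        ", hypo_down = ", length(quad$hypo_down),
        ", hypo_up = ", length(quad$hypo_up))
  if (!length(quad$hyper_down))
    return(fail("integration", "no hyper-down genes"))

  ## -- candidate funnel ------------------------------------------------
  cands <- build_candidates(dmcs, quad$hyper_down, ann)
  utils::write.table(cands, file.path(outdir, "candidates_initial.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!nrow(cands)) return(fail("candidates", "no candidate CpGs"))

  other_types <- setdiff(unique(samples$cancer_type), target)
  other_tables <- lapply(other_types, function(t) {
    ids <- samples$sample_id[samples$cancer_type == t]
    b <- beta_imp[, intersect(colnames(beta_imp), ids), drop = FALSE]
    cond <- samples$condition[match(colnames(b), samples$sample_id)]
    call_dmcs(dmc_stats(b, cond), cfg[["dmc.delta_threshold"]],
              cfg[["dmc.fdr_threshold"]])
  })
  names(other_tables) <- other_types
  spec <- specificity_filter(cands, other_tables)
  utils::write.table(spec, file.path(outdir, "candidates_specific.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  logln("specificity screen kept ", length(unique(spec$probe_id)),
        " of ", length(unique(cands$probe_id)), " candidate probes")
  if (!nrow(spec)) return(fail("specificity", "no cancer-specific CpGs"))

  labels_t <- as.character(cond_t)
  uniq <- spec[!duplicated(spec$probe_id), , drop = FALSE]
  igf <- ig_filter(uniq, b_t, labels_t, threshold = cfg[["ig.threshold"]],
                   n_bins = cfg[["ig.n_bins"]])
  utils::write.table(igf, file.path(outdir, "candidates_ig.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  logln("information-gain filter kept ", nrow(igf), " probes (> ",
        cfg[["ig.threshold"]], " bits)")
  if (!nrow(igf)) return(fail("ig_filter", "no CpGs above the IG cutoff"))

  ## -- SBFS + evaluation -----------------------------------------------
  panel <- sbfs(igf, b_t, labels_t, folds = cfg[["sbfs.folds"]],
                seed = seed)
  jsonlite::write_json(
    list(probes = panel$probes,
         coefficients = as.list(coef(panel)),
         cv_accuracy = panel$accuracy, seed = seed),
    file.path(outdir, "panel.json"), auto_unbox = TRUE, digits = NA)
  report <- cross_validate(t(b_t[panel$probes, , drop = FALSE]), labels_t,
                           folds = cfg[["cv.folds"]],
                           seed = .child_seed(seed, 99L))
  utils::write.table(as.data.frame(report),
                     file.path(outdir, "eval_report.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  logln("final panel: ", paste(panel$probes, collapse = ", "),
        " | pooled CV AUC = ", format(report$auc))

  summary <- list(
    status = "ok", target_cancer = target, seed = seed,
    n_probes_retained = qc$report$n_retained,
    n_dmcs = nrow(dmcs),
    n_dmcs_hyper = sum(dmcs$direction == "hyper"),
    n_degs = nrow(degs$records),
    n_hyper_down_genes = length(quad$hyper_down),
    n_candidates_initial = length(unique(cands$probe_id)),
    n_candidates_specific = length(unique(spec$probe_id)),
    n_candidates_ig = nrow(igf),
    panel = panel$probes,
    panel_size = length(panel$probes),
    cv_auc = report$auc,
    cv_accuracy = panel$accuracy)
  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  structure(list(status = "ok", summary = summary, panel = panel,
                 report = report, outdir = outdir,
                 dmcs = dmcs, degs = degs, quadrants = quad),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("methpanel pipeline run:", x$status, "\n")
  if (x$status == "ok") {
    cat("  DMCs:", x$summary$n_dmcs, "| DEGs:", x$summary$n_degs,
        "| hyper-down genes:", x$summary$n_hyper_down_genes, "\n")
    cat("  candidate funnel:", x$summary$n_candidates_initial, "->",
        x$summary$n_candidates_specific, "->", x$summary$n_candidates_ig,
        "-> panel of", x$summary$panel_size, "\n")
    cat("  pooled CV AUC:", sprintf("%.3f", x$summary$cv_auc), "\n")
  } else {
    cat("  stopped at stage '", x$summary$stage, "': ", x$summary$reason,
        "\n", sep = "")
  }
  cat("  outputs in ", x$outdir, "\n", sep = "")
  invisible(x)
}
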