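## Marker discovery: candidate construction from hyper-down genes,
## cross-cancer specificity screening, information-gain filtering, and
## sequential backward feature selection (SBFS) wrapped around a
## cross-validated ridge-logistic evaluator. This hybrid filter+wrapper
## scheme is the package's core contribution.

.candidate_set <- function(df, stage) {
  rownames(df) <- NULL
  structure(df, stage = stage, class = c("candidate_set", "data.frame"))
}

#' Build the initial candidate CpG set
#'
#' Candidates are the hypermethylated DMCs whose probe links, through a
#' promoter region class, to a hypermethylated-and-downregulated
#' (hyper-down) gene — the tumor-suppressor-silencing pool.
#'
#' @param dmcs DMC table from [call_dmcs()].
#' @param hyper_down_genes character vector of hyper-down genes (e.g.
#'   `quadrant_classify(...)$hyper_down`).
#' @param ann probe annotation.
#' @param promoter_regions region classes treated as promoter.
#' @return a `candidate_set` data.frame (`probe_id`, `gene`, `delta`,
#'   `fdr`) with stage `"initial"`.
#' @export
build_candidates <- function(dmcs, hyper_down_genes, ann,
                             promoter_regions = PROMOTER_REGIONS) {
  links <- probe_gene_links(ann)
  links <- links[links$gene_region %in% promoter_regions &
                   links$gene %in% hyper_down_genes, , drop = FALSE]
  hyper <- dmcs[dmcs$direction == "hyper", , drop = FALSE]
  m <- merge(unique(links[c("probe_id", "gene")]),
             hyper[c("probe_id", "delta", "fdr")], by = "probe_id")
  m <- m[order(m$probe_id, m$gene), ]
  .candidate_set(m, "initial")
}

#' Screen candidates against other cancers' DMC tables
#'
#' A candidate survives only if its probe is not a DMC (either
#' direction) in any other cancer type. Adding more tables can only
#' shrink the retained set.
#'
#' @param candidates a `candidate_set`.
#' @param other_dmc_tables list of DMC tables (as from [call_dmcs()]),
#'   one per other cancer type.
#' @return the retained `candidate_set`, stage
#'   `"specificity_filtered"`.
#' @export
specificity_filter <- function(candidates, other_dmc_tables) {
  foreign <- unique(unlist(lapply(other_dmc_tables, `[[`, "probe_id")))
  keep <- !(candidates$probe_id %in% foreign)
  .candidate_set(candidates[keep, , drop = FALSE], "specificity_filtered")
}

#' Information gain of a beta vector about a binary label
#'
#' Mutual information, in bits, between the label and the beta values
#' discretized into `n_bins` equal-width bins over \[0, 1\]:
#' `IG = H(X) - H(X|Y)`. Always non-negative and bounded by
#' `min(H(X), H(Y))`; a constant vector has zero gain.
#'
#' @param x numeric vector of beta values in \[0, 1\].
#' @param y binary labels (both classes must occur).
#' @param n_bins number of equal-width bins.
#' @return information gain in bits.
#' @export
information_gain <- function(x, y, n_bins = 10L) {
  if (!all(is.finite(x))) stop("x must be finite")
  y <- factor(y)
  if (nlevels(y) != 2L) stop("y must contain exactly two classes")
  bin <- pmin(pmax(floor(pmin(pmax(x, 0), 1) * n_bins) + 1L, 1L), n_bins)
  n <- length(x)
  hx <- .entropy_bits(tabulate(bin, n_bins))
  hxy <- 0
  for (lev in levels(y)) {
    sel <- y == lev
    hxy <- hxy + sum(sel) / n * .entropy_bits(tabulate(bin[sel], n_bins))
  }
  max(hx - hxy, 0)
}

#' Filter candidates by information gain
#'
#' Computes the information gain of every candidate probe over the
#' given labels, keeps those strictly above `threshold`, and sorts the
#' survivors by descending gain.
#'
#' @param candidates a `candidate_set`.
#' @param beta imputed beta matrix containing the candidate probes.
#' @param labels tumor/normal labels for `beta`'s columns.
#' @param threshold minimum information gain in bits (strict).
#' @param n_bins discretization bins.
#' @return the retained `candidate_set` with an added `ig` column,
#'   sorted by descending `ig`; stage `"ig_filtered"`.
#' @export
ig_filter <- function(candidates, beta, labels, threshold = 0.3,
                      n_bins = 10L) {
  if (!nrow(candidates))
    return(.candidate_set(cbind(candidates, ig = numeric()), "ig_filtered"))
  ig <- vapply(candidates$probe_id, function(p)
    information_gain(beta[p, ], labels, n_bins), 0)
  out <- candidates
  out$ig <- ig
  out <- out[ig > threshold, , drop = FALSE]
  out <- out[order(-out$ig, out$probe_id), , drop = FALSE]
  .candidate_set(out, "ig_filtered")
}

## default SBFS evaluator: stratified k-fold CV accuracy of the ridge
## logistic classifier; folds fixed once per SBFS run for comparability
.cv_accuracy_evaluator <- function(folds = 5L, l2 = 1e-4) {
  function(X, y, fold_id) {
    pred <- rep(NA_real_, length(y))
    for (f in unique(fold_id)) {
      tr <- fold_id != f
      fit <- fit_logistic(X[tr, , drop = FALSE], y[tr], l2 = l2)
      pred[!tr] <- .predict_logit(fit, X[!tr, , drop = FALSE])
    }
    mean((pred >= 0.5) == (y == 1))
  }
}

#' Sequential backward feature selection over candidate CpGs
#'
#' Starting from the full (information-gain-filtered) candidate set,
#' repeatedly removes the single probe whose removal maximizes the
#' cross-validated accuracy of a ridge-logistic classifier; ties are
#' broken by removing the probe with the lowest information gain, then
#' by probe id. Every visited subset is recorded and the subset with
#' the globally highest accuracy is returned (ties: the smallest
#' subset, then lexicographic order). The final classifier is refit on
#' all samples over the winning subset.
#'
#' @param candidates a `candidate_set` with an `ig` column (from
#'   [ig_filter()]).
#' @param beta imputed beta matrix containing the candidate probes.
#' @param labels tumor/normal labels for `beta`'s columns.
#' @param folds cross-validation folds of the internal evaluator.
#' @param l2 ridge penalty of the logistic fits.
#' @param seed integer seed governing the fold assignment; the whole
#'   trajectory is deterministic given the seed.
#' @return a `marker_panel` object: `probes`, `coefficients`,
#'   `intercept`, `accuracy` (best CV accuracy), `trajectory`
#'   (data.frame of visited subsets), `seed`, `folds`.
#' @export
sbfs <- function(candidates, beta, labels, folds = 5L, l2 = 1e-4,
                 seed = 1) {
  if (!nrow(candidates)) stop("no candidates to select from")
  probes <- candidates$probe_id
  ig <- if ("ig" %in% names(candidates))
    stats::setNames(candidates$ig, probes)
  else stats::setNames(rep(0, length(probes)), probes)
  y <- .as_binary(labels)
  X_all <- t(beta[probes, , drop = FALSE])
  fold_id <- .stratified_folds(y, folds, seed)
  evaluate <- .cv_accuracy_evaluator(folds, l2)

  current <- probes
  visited <- list()
  score <- function(set) {
    tryCatch(evaluate(X_all[, set, drop = FALSE], y, fold_id),
             error = function(e) {
               message("subset {", paste(set, collapse = ","),
                       "} skipped: ", conditionMessage(e))
               NA_real_
             })
  }
  visited[[1L]] <- list(set = current, acc = score(current))
  while (length(current) > 1L) {
    accs <- vapply(current, function(f) score(setdiff(current, f)), 0)
    best <- max(accs, na.rm = TRUE)
    cand <- current[!is.na(accs) & accs == best]
    drop <- cand[order(ig[cand], cand)][1L]   # lowest IG, then probe id
    current <- setdiff(current, drop)
    visited[[length(visited) + 1L]] <- list(set = current,
                                            acc = best)
  }
  accs <- vapply(visited, `[[`, 0, "acc")
  sizes <- lengths(lapply(visited, `[[`, "set"))
  keys <- vapply(visited, function(v) paste(sort(v$set), collapse = ","), "")
  best_i <- order(-accs, sizes, keys)[1L]
  best_set <- sort(visited[[best_i]]$set)

  fit <- fit_logistic(X_all[, best_set, drop = FALSE], y, l2 = l2)
  structure(list(probes = best_set,
                 coefficients = fit$coefficients,
                 intercept = fit$intercept,
                 accuracy = accs[best_i],
                 trajectory = data.frame(
                   step = seq_along(visited), size = sizes,
                   accuracy = accs,
                   subset = keys, stringsAsFactors = FALSE),
                 seed = seed, folds = folds, l2 = l2),
            class = "marker_panel")
}

#' @export
print.marker_panel <- function(x, ...) {
  cat("Methylation marker panel (", length(x$probes), " CpGs), CV accuracy ",
      sprintf("%.3f", x$accuracy), "\n", sep = "")
  cat("  probes:", paste(x$probes, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.marker_panel <- function(object, ...) {
  cat("Marker panel over", length(object$probes), "CpGs\n")
  print(data.frame(term = c("(intercept)", object$probes),
                   estimate = c(object$intercept, object$coefficients)))
  cat("Best cross-validated accuracy:", sprintf("%.3f", object$accuracy),
      "over", nrow(object$trajectory), "visited subsets\n")
  invisible(object)
}

#' @export
coef.marker_panel <- function(object, ...) {
  c("(Intercept)" = object$intercept,
    stats::setNames(object$coefficients, object$probes))
}

#' Predict tumor probability from a marker panel
#'
#' @param object a `marker_panel`.
#' @param newdata either a samples x probes matrix or a probes x samples
#'   beta matrix (orientation detected from dimnames); must contain all
#'   panel probes.
#' @param type `"response"` (probability), `"link"` (log-odds) or
#'   `"class"` (`tumor`/`normal` at cutoff 0.5).
#' @param ... unused.
#' @return numeric or character vector, one value per sample.
#' @export
predict.marker_panel <- function(object, newdata,
                                 type = c("response", "link", "class"),
                                 ...) {
  type <- match.arg(type)
  if (all(object$probes %in% rownames(newdata)))
    newdata <- t(newdata[object$probes, , drop = FALSE])
  miss <- setdiff(object$probes, colnames(newdata))
  if (length(miss))
    stop("panel probe(s) missing from newdata: ",
         paste(miss, collapse = ", "))
  eta <- drop(newdata[, object$probes, drop = FALSE] %*%
                object$coefficients) + object$intercept
  switch(type,
         link = eta,
         response = stats::plogis(eta),
         class = ifelse(stats::plogis(eta) >= 0.5, "tumor", "normal"))
}

#' @export
plot.marker_panel <- function(x, newdata = NULL, labels = NULL, ...) {
  if (is.null(newdata) || is.null(labels))
    stop("supply newdata and labels to plot a ROC curve")
  scores <- predict(x, newdata)
  auc <- roc_auc(scores, labels)
  curve <- attr(auc, "curve")
  graphics::plot(curve$fpr, curve$tpr, type = "l",
                 xlab = "False-positive rate", ylab = "True-positive rate",
                 main = sprintf("Marker panel ROC (AUC = %.3f)",
                                as.numeric(auc)), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(auc)
}
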