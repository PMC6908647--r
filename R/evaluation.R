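## Classifier training and evaluation: ridge-penalized logistic
## regression fit by Newton iterations, confusion-matrix metrics,
## rank-based ROC AUC, stratified cross-validation, and frozen-model
## evaluation on external sets.

#' Ridge-penalized logistic regression
#'
#' Maximum penalized likelihood by Newton-Raphson with step halving.
#' The intercept is unpenalized; a small default ridge term keeps the
#' optimum finite even on separable data. Convergence requires the
#' largest coefficient change to drop below `tol` within `max_iter`
#' iterations, otherwise an error carrying the iteration trace is
#' raised. The fit is fully deterministic.
#'
#' @param X samples x features numeric matrix.
#' @param y binary labels (0/1, logical, or tumor/normal).
#' @param l2 ridge penalty on the feature coefficients.
#' @param tol convergence tolerance on the coefficient update.
#' @param max_iter Newton iteration cap.
#' @return a `logit_fit` list: `coefficients` (named), `intercept`,
#'   `iterations`, `converged`.
#' @export
fit_logistic <- function(X, y, l2 = 1e-4, tol = 1e-8, max_iter = 100L) {
  X <- as.matrix(X)
  y <- .as_binary(y)
  if (length(unique(y)) < 2L || min(table(y)) < 2L)
    stop("need >= 2 samples in each class")
  n <- nrow(X); p <- ncol(X)
  Xa <- cbind(`(Intercept)` = 1, X)
  pen <- c(0, rep(l2, p))             # intercept unpenalized
  b <- rep(0, p + 1L)
  loglik <- function(b) {
    eta <- drop(Xa %*% b)
    sum(y * eta - log1p(exp(eta))) - sum(pen * b^2) / 2
  }
  ll <- loglik(b)
  trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    eta <- drop(Xa %*% b)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-12)
    grad <- drop(crossprod(Xa, y - mu)) - pen * b
    H <- crossprod(Xa * w, Xa) + diag(pen, p + 1L)
    step <- solve(H, grad)
    new_b <- b + step
    new_ll <- loglik(new_b)
    halvings <- 0L
    while (new_ll < ll - 1e-12 && halvings < 30L) {  # step halving
      step <- step / 2
      new_b <- b + step
      new_ll <- loglik(new_b)
      halvings <- halvings + 1L
    }
    delta <- max(abs(new_b - b))
    b <- new_b; ll <- new_ll
    trace <- c(trace, delta)
    if (delta < tol)
      return(structure(list(coefficients = stats::setNames(unname(b[-1L]),
                                                           colnames(X)),
                            intercept = unname(b[1L]), iterations = it,
                            converged = TRUE), class = "logit_fit"))
  }
  stop("logistic fit did not converge in ", max_iter,
       " iterations; update trace: ",
       paste(signif(utils::tail(trace, 5L), 3), collapse = ", "))
}

.predict_logit <- function(fit, X) {
  stats::plogis(drop(as.matrix(X) %*% fit$coefficients) + fit$intercept)
}

## deterministic stratified fold assignment
.stratified_folds <- function(y, folds, seed) {
  set.seed(seed)
  fold_id <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    fold_id[idx] <- rep_len(seq_len(folds), length(idx))
  }
  fold_id
}

#' Per-class metrics from confusion counts
#'
#' `tp_rate = TP/(TP+FN)`, `fp_rate = FP/(FP+TN)`,
#' `precision = TP/(TP+FP)` (0 when undefined) and
#' `f_measure = 2 * precision * tp_rate / (precision + tp_rate)`
#' (0 when both terms are 0).
#'
#' @param counts data.frame with columns `class`, `tp`, `fp`, `fn`,
#'   `tn` (one row per class).
#' @return data.frame with `class`, `tp_rate`, `fp_rate`, `precision`,
#'   `f_measure`.
#' @export
metrics_from_confusion <- function(counts) {
  safe_div <- function(a, b) ifelse(b == 0, 0, a / b)
  tp_rate <- safe_div(counts$tp, counts$tp + counts$fn)
  fp_rate <- safe_div(counts$fp, counts$fp + counts$tn)
  precision <- safe_div(counts$tp, counts$tp + counts$fp)
  f <- ifelse(precision + tp_rate == 0, 0,
              2 * precision * tp_rate / (precision + tp_rate))
  data.frame(class = counts$class, tp_rate = tp_rate, fp_rate = fp_rate,
             precision = precision, f_measure = f,
             stringsAsFactors = FALSE)
}

#' Class-size-weighted average of per-class metrics
#'
#' @param metrics data.frame of per-class metric columns (any numeric
#'   columns are averaged).
#' @param class_sizes positive sizes, one per row of `metrics`.
#' @return one-row data.frame of weighted means.
#' @export
weighted_average <- function(metrics, class_sizes) {
  if (any(class_sizes <= 0)) stop("class sizes must be positive")
  w <- class_sizes / sum(class_sizes)
  num <- vapply(metrics, is.numeric, TRUE)
  out <- as.data.frame(lapply(metrics[num], function(v) sum(w * v)))
  out
}

#' Rank-based ROC AUC
#'
#' The probability that a random positive outscores a random negative,
#' with ties counted one half (Mann-Whitney formulation). The
#' trapezoidal ROC curve points are attached as attribute `"curve"`.
#'
#' @param scores numeric scores, higher = more tumor-like.
#' @param labels binary labels (positive = tumor / 1 / TRUE).
#' @return AUC as a single number with a `curve` attribute
#'   (data.frame `fpr`, `tpr`).
#' @export
roc_auc <- function(scores, labels) {
  y <- .as_binary(labels)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)
  auc <- (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  ord <- order(scores, decreasing = TRUE)
  tpr <- c(0, cumsum(y[ord] == 1) / n1)
  fpr <- c(0, cumsum(y[ord] == 0) / n0)
  structure(auc, curve = data.frame(fpr = fpr, tpr = tpr))
}

.eval_report <- function(scores, y, folds = NA_integer_, seed = NA_integer_) {
  scores <- unname(scores)
  pred <- as.integer(scores >= 0.5)
  counts <- data.frame(
    class = c("tumor", "normal"),
    tp = c(sum(pred == 1 & y == 1), sum(pred == 0 & y == 0)),
    fp = c(sum(pred == 1 & y == 0), sum(pred == 0 & y == 1)),
    fn = c(sum(pred == 0 & y == 1), sum(pred == 1 & y == 0)),
    tn = c(sum(pred == 0 & y == 0), sum(pred == 1 & y == 1)),
    stringsAsFactors = FALSE)
  per_class <- metrics_from_confusion(counts)
  auc <- if (length(unique(y)) == 2L) as.numeric(roc_auc(scores, y))
         else NA_real_
  per_class$auc <- auc                 # AUC is class-symmetric in 2 classes
  per_class$n <- c(sum(y == 1), sum(y == 0))
  present <- per_class$n > 0
  weighted <- weighted_average(
    per_class[present, c("tp_rate", "fp_rate", "precision", "f_measure",
                         "auc")],
    per_class$n[present])
  structure(list(per_class = per_class, weighted = weighted, auc = auc,
                 confusion = counts, scores = scores, labels = y,
                 folds = folds, seed = seed),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, digits = 3, ...) {
  tab <- rbind(
    data.frame(row = c("Tumor", "Normal"),
               x$per_class[c("tp_rate", "fp_rate", "precision",
                             "f_measure", "auc")]),
    cbind(data.frame(row = "Average"), x$weighted))
  colnames(tab) <- c("", "TP rate", "FP rate", "Precision", "F-measure",
                     "AUC")
  print(format(tab, digits = digits), row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.eval_report <- function(x, ...) {
  rbind(cbind(data.frame(row = c("Tumor", "Normal")),
              x$per_class[c("tp_rate", "fp_rate", "precision",
                            "f_measure", "auc")]),
        cbind(data.frame(row = "Average"), x$weighted))
}

#' Stratified k-fold cross-validation of a CpG panel
#'
#' Randomly assigns samples to stratified folds from the seed, fits the
#' ridge-logistic classifier on the training folds, scores the held-out
#' fold, pools the held-out scores, and reports per-class and weighted
#' metrics at probability cutoff 0.5 plus the pooled AUC. If the rarer
#' class has fewer samples than `folds`, the fold count is reduced with
#' a warning; a training fold that loses a class triggers one refold
#' from a derived seed.
#'
#' @param X samples x features matrix.
#' @param y binary labels.
#' @param folds number of folds (default 10).
#' @param seed integer seed for the fold assignment.
#' @param l2 ridge penalty.
#' @return an `eval_report`; print it for a per-class + Average table.
#' @export
cross_validate <- function(X, y, folds = 10L, seed = 1, l2 = 1e-4) {
  X <- as.matrix(X)
  y <- .as_binary(y)
  m <- min(table(y))
  if (m < folds) {
    folds <- max(2L, m)
    warning("reducing folds to ", folds, " (smallest class has ", m,
            " samples)")
  }
  fold_id <- .stratified_folds(y, folds, seed)
  for (attempt in 1:2) {
    ok <- all(vapply(seq_len(folds), function(f)
      length(unique(y[fold_id != f])) == 2L, TRUE))
    if (ok) break
    message("degenerate fold encountered; refolding")
    fold_id <- .stratified_folds(y, folds, .child_seed(seed, attempt))
  }
  scores <- rep(NA_real_, length(y))
  for (f in seq_len(folds)) {
    tr <- fold_id != f
    fit <- fit_logistic(X[tr, , drop = FALSE], y[tr], l2 = l2)
    scores[!tr] <- .predict_logit(fit, X[!tr, , drop = FALSE])
  }
  .eval_report(scores, y, folds = folds, seed = seed)
}

#' Evaluate a frozen marker panel on an external cohort
#'
#' Applies the panel's fitted classifier to a validation matrix and
#' reports the per-class + weighted-average metric table.
#'
#' @param panel a `marker_panel` (from [sbfs()]).
#' @param X_val validation data: samples x probes matrix or probes x
#'   samples beta matrix; must contain every panel probe.
#' @param y_val binary labels for the validation samples.
#' @return an `eval_report`.
#' @export
evaluate_external <- function(panel, X_val, y_val) {
  scores <- predict(panel, X_val)
  .eval_report(scores, .as_binary(y_val))
}
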