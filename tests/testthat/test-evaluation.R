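test_that("ridge-logistic fits satisfy closed-form and symmetry checks", {
  # all-zero design: intercept is the log-odds of prevalence, slopes zero
  X <- matrix(0, 20, 2, dimnames = list(NULL, c("a", "b")))
  y <- rep(c(1, 0), c(14, 6))
  fit <- fit_logistic(X, y)
  expect_equal(unname(fit$coefficients), c(0, 0))
  expect_equal(fit$intercept, log(14 / 6), tolerance = 1e-6)

  # mirrored data gives negated coefficients
  set.seed(71)
  X2 <- matrix(rnorm(60), 30, 2)
  y2 <- as.integer(X2[, 1] + rnorm(30, 0, 0.5) > 0)
  f1 <- fit_logistic(X2, y2)
  f2 <- fit_logistic(-X2, 1 - y2)
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-6)
  expect_equal(f1$intercept, -f2$intercept, tolerance = 1e-6)

  # perfectly separable data still converges to finite coefficients
  xs <- matrix(c(rep(-1, 10), rep(1, 10)), ncol = 1)
  f3 <- fit_logistic(xs, rep(c(0, 1), each = 10))
  expect_true(f3$converged)
  expect_true(all(is.finite(c(f3$coefficients, f3$intercept))))
})

test_that("confusion metrics reproduce the published validation table", {
  counts <- data.frame(class = c("tumor", "normal"),
                       tp = c(3, 20), fp = c(0, 3),
                       fn = c(3, 0), tn = c(20, 3))
  m <- metrics_from_confusion(counts)
  expect_equal(round(m$f_measure[1], 3), 0.667)
  expect_equal(round(m$f_measure[2], 3), 0.930)
  expect_equal(round(m$precision[2], 3), 0.870)
  expect_equal(m$tp_rate, c(0.5, 1))
  expect_equal(m$fp_rate, c(0, 0.5))

  w <- weighted_average(m[c("tp_rate", "fp_rate", "precision", "f_measure")],
                        c(6, 20))
  expect_equal(round(w$tp_rate, 3), 0.885)
  expect_equal(round(w$precision, 3), 0.900)
  expect_equal(round(w$f_measure, 3), 0.869)
  expect_equal(round(w$fp_rate, 3), 0.385)

  perfect <- metrics_from_confusion(
    data.frame(class = "tumor", tp = 10, fp = 0, fn = 0, tn = 10))
  expect_equal(unlist(perfect[-1]),
               c(tp_rate = 1, fp_rate = 0, precision = 1, f_measure = 1))
  # equal metrics average to themselves; invalid sizes rejected
  expect_equal(weighted_average(data.frame(a = c(0.7, 0.7)), c(3, 9))$a, 0.7)
  expect_error(weighted_average(data.frame(a = 1), 0), "positive")
})

test_that("rank-based AUC matches the pairwise oracle and tie conventions", {
  expect_equal(as.numeric(roc_auc(c(1, 2, 3, 11, 12, 13),
                                  rep(c(0, 1), each = 3))), 1)
  expect_equal(as.numeric(roc_auc(rep(0.4, 8), rep(c(0, 1), 4))), 0.5)

  set.seed(81)
  scores <- sample(seq(0, 1, 0.1), 12, TRUE)   # duplicates force ties
  labels <- rep(c(0, 1), each = 6)
  got <- as.numeric(roc_auc(scores, labels))
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  acc <- 0
  for (p in pos) for (q in neg)
    acc <- acc + (p > q) + 0.5 * (p == q)
  expect_equal(got, acc / (length(pos) * length(neg)))
  # invariance under strictly monotone transforms
  expect_equal(as.numeric(roc_auc(exp(3 * scores), labels)), got)
  expect_error(roc_auc(scores, rep(1, 12)), "both classes")
})

test_that("cross-validation recovers planted panels and respects the seed", {
  coh <- default_cohort()
  tb <- target_beta(coh)
  X <- t(tb$beta[coh$truth$specific_marker_probe_ids, ])
  rep1 <- cross_validate(X, tb$condition, folds = 10, seed = 5)
  expect_gte(rep1$auc, 0.95)
  rep2 <- cross_validate(X, tb$condition, folds = 10, seed = 5)
  expect_identical(rep1$scores, rep2$scores)
  expect_equal(as.data.frame(rep1), as.data.frame(rep2))

  set.seed(99)
  shuffled <- sample(tb$condition)
  rep0 <- cross_validate(X, shuffled, folds = 10, seed = 5)
  expect_lt(abs(rep0$auc - 0.5), 0.1)

  small <- c(which(tb$condition == "tumor")[1:6],
             which(tb$condition == "normal")[1:6])
  expect_warning(cross_validate(X[small, ], tb$condition[small], folds = 10,
                                seed = 1),
                 "reducing folds")
})

test_that("external evaluation applies a frozen model consistently", {
  coh <- default_cohort()
  tb <- target_beta(coh)
  planted <- c(coh$truth$specific_marker_probe_ids,
               coh$truth$shared_marker_probe_ids)
  cands <- data.frame(probe_id = planted, gene = "G", delta = 0.4,
                      fdr = 1e-4)
  igf <- ig_filter(cands, tb$beta, tb$condition)
  panel <- sbfs(igf, tb$beta, tb$condition, seed = 3)

  # resubstitution equals a manual application of the frozen classifier
  rep_tr <- evaluate_external(panel, tb$beta, tb$condition)
  manual <- predict(panel, tb$beta)
  expect_equal(rep_tr$scores, unname(manual))
  expect_gte(rep_tr$auc, 0.95)

  # transfer to a fresh cohort drawn with the same generative parameters
  coh2 <- generate_cohort(cohort_config(seed = 777))
  tb2 <- target_beta(coh2)
  rep_ext <- evaluate_external(panel, tb2$beta, tb2$condition)
  expect_gte(rep_ext$auc, 0.95)

  # missing probe is reported by name
  b_missing <- tb2$beta[setdiff(rownames(tb2$beta), panel$probes[1]), ]
  expect_error(evaluate_external(panel, b_missing, tb2$condition),
               panel$probes[1])

  # degenerate one-class validation set stays well-defined
  null_panel <- panel
  null_panel$coefficients[] <- 0
  null_panel$intercept <- -1          # every probability below 0.5
  tum_only <- tb2$beta[, tb2$condition == "tumor", drop = FALSE]
  rep_deg <- evaluate_external(null_panel, tum_only,
                               rep("tumor", ncol(tum_only)))
  expect_equal(rep_deg$per_class$tp_rate[1], 0)
  expect_equal(rep_deg$per_class$f_measure[1], 0)
})
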