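test_that("candidate construction joins hyper DMCs to hyper-down promoters", {
  ann <- make_ann(c("cg1", "cg2", "cg3"),
                  gene = c("GA", "GA", "GA"),
                  gene_region = c("Body", "TSS200", "TSS1500"))
  dmcs <- data.frame(probe_id = c("cg1", "cg2", "cg3"),
                     delta = c(0.3, 0.3, -0.3), fdr = 1e-3,
                     direction = c("hyper", "hyper", "hypo"))
  out <- build_candidates(dmcs, "GA", ann)
  expect_equal(out$probe_id, "cg2")   # Body excluded, hypo excluded
  expect_equal(attr(out, "stage"), "initial")
  expect_equal(nrow(build_candidates(dmcs, character(), ann)), 0)
})

test_that("candidate sets equal a brute-force join on cohort data", {
  coh <- small_cohort()
  tb <- target_beta(coh)
  dmcs <- call_dmcs(dmc_stats(tb$beta, tb$condition))
  hd <- names(map_dmcs_to_genes(dmcs, coh$ann)$hyper_genes)
  cands <- build_candidates(dmcs, hd, coh$ann)
  links <- probe_gene_links(coh$ann)
  want <- character()
  for (i in seq_len(nrow(links))) {
    if (!links$gene_region[i] %in% c("TSS1500", "TSS200")) next
    if (!links$gene[i] %in% hd) next
    d <- dmcs[dmcs$probe_id == links$probe_id[i], ]
    if (nrow(d) && d$direction == "hyper")
      want <- union(want, links$probe_id[i])
  }
  expect_setequal(unique(cands$probe_id), want)
})

test_that("specificity screening removes probes seen in any other cancer", {
  cands <- build_candidates(
    data.frame(probe_id = c("cg1", "cg2"), delta = 0.3, fdr = 1e-3,
               direction = "hyper"),
    "GA", make_ann(c("cg1", "cg2"), gene = "GA", gene_region = "TSS200"))
  other <- list(BLCA = data.frame(probe_id = "cg1"))
  out <- specificity_filter(cands, other)
  expect_equal(out$probe_id, "cg2")
  expect_equal(attr(out, "stage"), "specificity_filtered")
  # empty tables -> identity; more tables can only shrink the set
  expect_equal(specificity_filter(cands, list())$probe_id, cands$probe_id)
  out2 <- specificity_filter(cands, c(other,
                                      list(LUAD = data.frame(probe_id = "cg2"))))
  expect_true(all(out2$probe_id %in% out$probe_id))
})

test_that("planted specific markers survive screening exactly", {
  coh <- small_cohort()
  flt <- filter_probes(coh$beta, coh$ann)
  cond <- as.character(coh$samples$condition[match(colnames(flt$beta),
                                                   coh$samples$sample_id)])
  imp <- impute_missing(flt$beta, cond)
  by_type <- function(type) {
    ids <- coh$samples$sample_id[coh$samples$cancer_type == type]
    b <- imp[, intersect(colnames(imp), ids)]
    call_dmcs(dmc_stats(b, coh$samples$condition[
      match(colnames(b), coh$samples$sample_id)]))
  }
  dmcs <- by_type("CT1")
  dmg <- map_dmcs_to_genes(dmcs, coh$ann)
  degs <- call_degs(nb_test(coh$counts, condition = coh$samples$condition[
    match(colnames(coh$counts), coh$samples$sample_id)]))
  hyper_down <- quadrant_classify(dmg, degs)$hyper_down
  cands <- build_candidates(dmcs, hyper_down, coh$ann)
  spec <- specificity_filter(cands, lapply(c("CT2", "CT3"), by_type))
  expect_setequal(unique(spec$probe_id), coh$truth$specific_marker_probe_ids)
})

test_that("information gain matches the joint-entropy oracle and its bounds", {
  expect_equal(information_gain(rep(0.5, 20), rep(c(0, 1), 10)), 0)
  # perfect separation of two equal classes -> 1 bit
  expect_equal(information_gain(c(rep(0.05, 10), rep(0.95, 10)),
                                rep(c("a", "b"), each = 10)), 1)
  set.seed(41)
  for (rep_i in 1:10) {
    n <- sample(10:30, 1)
    x <- runif(n)
    y <- sample(c("a", "b"), n, TRUE)
    if (length(unique(y)) < 2) y[1:2] <- c("a", "b")
    bins <- sample(c(4L, 8L, 10L), 1)
    got <- information_gain(x, y, bins)
    expect_equal(got, oracle_ig(x, y, bins), tolerance = 1e-12)
    expect_gte(got, 0)
    hy <- -sum(prop.table(table(y)) * log2(prop.table(table(y))))
    expect_lte(got, hy + 1e-12)
  }
  expect_error(information_gain(runif(5), rep("a", 5)), "two classes")
})

test_that("IG filtering is strict, sorted, and separates signal from noise", {
  coh <- default_cohort()
  tb <- target_beta(coh)
  planted <- c(coh$truth$specific_marker_probe_ids,
               coh$truth$shared_marker_probe_ids)
  cands <- data.frame(probe_id = planted, gene = "G", delta = 0.4,
                      fdr = 1e-4)
  out <- ig_filter(cands, tb$beta, tb$condition)
  expect_setequal(out$probe_id, planted)      # all planted markers pass
  expect_true(all(diff(out$ig) <= 0))        # descending order
  # exact-threshold boundary excludes
  ig1 <- out$ig[1]
  out2 <- ig_filter(cands, tb$beta, tb$condition, threshold = ig1)
  expect_false(out$probe_id[1] %in% out2$probe_id)

  # null probes with shuffled labels essentially never pass 0.3 bits
  set.seed(55)
  nullb <- matrix(runif(200 * length(tb$condition)), 200,
                  dimnames = list(paste0("np", 1:200), colnames(tb$beta)))
  shuffled <- sample(tb$condition)
  nullc <- data.frame(probe_id = rownames(nullb), gene = "G", delta = 0,
                      fdr = 1)
  kept <- ig_filter(nullc, nullb, shuffled)
  expect_lte(nrow(kept) / 200, 0.01)
})

test_that("SBFS finds the exhaustive-search optimum on small problems", {
  set.seed(61)
  n <- 60
  y <- rep(c("normal", "tumor"), each = n / 2)
  informative <- function() c(runif(n / 2, 0, 0.3), runif(n / 2, 0.6, 1))
  noise <- function() runif(n)
  beta <- rbind(cgA = informative(), cgB = informative(),
                cgC = noise(), cgD = noise(), cgE = noise(), cgF = noise())
  colnames(beta) <- paste0("s", 1:n)
  cands <- data.frame(probe_id = rownames(beta), gene = "G", delta = 0.4,
                      fdr = 1e-4,
                      ig = vapply(rownames(beta), function(p)
                        information_gain(beta[p, ], y), 0))
  panel <- sbfs(cands, beta, y, folds = 5, seed = 17)
  # exhaustive oracle over all 63 non-empty subsets with the same folds
  y01 <- as.integer(y == "tumor")
  fold_id <- methpanel:::.stratified_folds(y01, 5L, 17)
  cv_acc <- function(set) {
    X <- t(beta[set, , drop = FALSE])
    pred <- numeric(n)
    for (f in unique(fold_id)) {
      fit <- fit_logistic(X[fold_id != f, , drop = FALSE], y01[fold_id != f])
      pred[fold_id == f] <- methpanel:::.predict_logit(
        fit, X[fold_id == f, , drop = FALSE])
    }
    mean((pred >= 0.5) == (y01 == 1))
  }
  best <- 0
  for (k in 1:6) {
    combos <- combn(rownames(beta), k)
    for (j in seq_len(ncol(combos)))
      best <- max(best, cv_acc(combos[, j]))
  }
  expect_equal(panel$accuracy, best)
  expect_true(all(panel$probes %in% c("cgA", "cgB")))

  # determinism: identical removal trajectory under the same seed
  panel2 <- sbfs(cands, beta, y, folds = 5, seed = 17)
  expect_identical(panel$trajectory, panel2$trajectory)
  expect_identical(panel$probes, panel2$probes)

  # single candidate is returned as the panel
  single <- sbfs(cands[1, ], beta, y, folds = 5, seed = 17)
  expect_equal(single$probes, "cgA")
})
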