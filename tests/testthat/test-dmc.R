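test_that("exact Wilcoxon matches full enumeration, including ties", {
  b <- rbind(p1 = c(0.1, 0.2, 0.3, 0.7, 0.8, 0.9))
  colnames(b) <- paste0("s", 1:6)
  g <- rep(c("a", "b"), each = 3)
  res <- wilcoxon_dmc(b, g)
  expect_equal(res$p_value, 0.1)      # 2 / C(6,3) most extreme split

  tied <- rbind(p1 = rep(0.5, 8))
  colnames(tied) <- paste0("s", 1:8)
  expect_equal(wilcoxon_dmc(tied, rep(c("a", "b"), each = 4))$p_value, 1)

  set.seed(42)
  for (sizes in list(c(5, 5), c(3, 6), c(8, 8))) {
    x1 <- round(runif(sizes[1]), 1)   # rounding forces ties
    x2 <- round(runif(sizes[2]), 1)
    m <- rbind(p = c(x1, x2))
    colnames(m) <- paste0("s", seq_len(sum(sizes)))
    got <- wilcoxon_dmc(m, rep(c("a", "b"), sizes))$p_value
    expect_equal(got, enum_wilcox_p(x1, x2))
  }
})

test_that("normal-approximation p-values are sane for larger groups", {
  set.seed(7)
  b <- matrix(runif(50 * 40), 50, 40,
              dimnames = list(paste0("cg", 1:50), paste0("s", 1:40)))
  g <- rep(c("tumor", "normal"), each = 20)
  p <- wilcoxon_dmc(b, g)$p_value
  expect_true(all(p >= 0 & p <= 1))
  # a strong shift must be detected
  b[1, 1:20] <- b[1, 1:20] + 2
  expect_lt(wilcoxon_dmc(b, g)$p_value[1], 1e-5)
})

test_that("BH adjustment reproduces the hand step-up and is monotone", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(bh_adjust(0.4), 0.4)
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  set.seed(5)
  p <- runif(100)
  q <- bh_adjust(p)
  expect_true(all(q >= p))
  perm <- sample(100)
  expect_equal(bh_adjust(p[perm]), q[perm])  # permutation equivariance
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("DMC calling applies strict thresholds and assigns direction", {
  stats <- data.frame(probe_id = c("a", "b", "c"),
                      mean_beta_tumor = c(0.5, 0.2, 0.6),
                      mean_beta_normal = c(0.3, 0.5, 0.3),
                      delta = c(0.20, -0.30, 0.30),
                      p_value = c(1e-4, 1e-4, 1e-4),
                      fdr = c(1e-3, 1e-3, 1e-3))
  out <- call_dmcs(stats)
  expect_false("a" %in% out$probe_id)      # delta exactly 0.2 excluded
  expect_equal(out$direction[out$probe_id == "b"], "hypo")
  expect_equal(out$direction[out$probe_id == "c"], "hyper")
})

test_that("planted markers are recovered as hyper DMCs at n = 50/50", {
  coh <- small_cohort()                  # 50/50 target samples
  flt <- filter_probes(coh$beta, coh$ann)
  cond <- as.character(coh$samples$condition[match(colnames(flt$beta),
                                                   coh$samples$sample_id)])
  imp <- impute_missing(flt$beta, cond)
  tids <- coh$samples$sample_id[coh$samples$cancer_type == "CT1"]
  bt <- imp[, intersect(colnames(imp), tids)]
  ct <- coh$samples$condition[match(colnames(bt), coh$samples$sample_id)]
  dmcs <- call_dmcs(dmc_stats(bt, ct))
  planted_hyper <- c(coh$truth$specific_marker_probe_ids,
                     coh$truth$shared_marker_probe_ids)
  hyper <- dmcs$probe_id[dmcs$direction == "hyper"]
  expect_gte(mean(planted_hyper %in% hyper), 0.95)
  planted_hypo <- coh$truth$hypo_marker_probe_ids
  expect_gte(mean(planted_hypo %in%
                    dmcs$probe_id[dmcs$direction == "hypo"]), 0.95)
})

test_that("DMC-to-gene promoter mapping follows the region rules", {
  ann <- make_ann(c("cg1", "cg2", "cg3"),
                  gene = c("GA", "GB", "GB"),
                  gene_region = c("Body", "TSS200", "TSS1500"))
  dmcs <- data.frame(probe_id = c("cg1", "cg2", "cg3"),
                     delta = c(0.3, 0.3, -0.3), fdr = 1e-3,
                     direction = c("hyper", "hyper", "hypo"))
  dmg <- map_dmcs_to_genes(dmcs, ann)
  expect_false("GA" %in% names(dmg$hyper_genes))  # Body-only link
  expect_true("GB" %in% names(dmg$hyper_genes))
  expect_true("GB" %in% names(dmg$hypo_genes))    # both directions allowed
})

test_that("promoter gene mapping matches a brute-force scan on a cohort", {
  coh <- small_cohort()
  tb <- target_beta(coh)
  dmcs <- call_dmcs(dmc_stats(tb$beta, tb$condition))
  dmg <- map_dmcs_to_genes(dmcs, coh$ann)
  # brute force over every probe-gene link
  links <- probe_gene_links(coh$ann)
  expected_hyper <- character()
  for (i in seq_len(nrow(links))) {
    if (!links$gene_region[i] %in% c("TSS1500", "TSS200")) next
    d <- dmcs[dmcs$probe_id == links$probe_id[i], ]
    if (nrow(d) && d$direction == "hyper")
      expected_hyper <- union(expected_hyper, links$gene[i])
  }
  expect_setequal(names(dmg$hyper_genes), expected_hyper)
})

test_that("context summaries count every DMC once per class", {
  ann <- make_ann(paste0("cg", 1:4), gene = "G", gene_region = "TSS200",
                  cgi_relation = "Island")
  dmcs <- data.frame(probe_id = paste0("cg", 1:4),
                     direction = c("hyper", "hyper", "hypo", "hypo"))
  s <- context_summary(dmcs, ann)
  isl <- s$cgi_relation[s$cgi_relation$class == "Island", ]
  expect_equal(isl$hyper, 2)
  expect_equal(isl$hyper_fraction, 0.5)
  expect_equal(isl$hyper_fraction + isl$hypo_fraction, 1)

  empty <- context_summary(dmcs[0, ], ann)
  expect_true(all(empty$location$hyper == 0 & empty$location$hypo == 0))

  # conservation on a real cohort: hyper + hypo = total in every class
  coh <- small_cohort()
  tb <- target_beta(coh)
  dm <- call_dmcs(dmc_stats(tb$beta, tb$condition))
  cs <- context_summary(dm, coh$ann)
  expect_equal(cs$location$hyper[cs$location$class == "all"] +
                 cs$location$hypo[cs$location$class == "all"], nrow(dm))
  expect_true(all(cs$location$hyper + cs$location$hypo <= nrow(dm)))
})
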