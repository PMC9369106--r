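test_that("exact permutation p-values equal the enumeration oracle", {
  withr::with_seed(41, {
    # two groups, n = 8
    v <- rnorm(8)
    lab <- rep(c("a", "b"), each = 4)
    res <- association_p(v, lab)
    expect_equal(res$method, "exact")
    expect_equal(res$p_value, oracle_perm_p(v, lab))

    # perfectly ordered labels
    v2 <- 1:8
    res2 <- association_p(v2, lab)
    expect_equal(res2$p_value, oracle_perm_p(v2, lab))
    expect_equal(res2$p_value, 2 / choose(8, 4))  # identity + mirror image

    # three groups with ties in the values
    v3 <- c(1, 1, 2, 5, 5, 9, 10, 3, 3)
    lab3 <- rep(c("a", "b", "c"), each = 3)
    res3 <- association_p(v3, lab3)
    expect_equal(res3$method, "exact")
    expect_equal(res3$p_value, oracle_perm_p(v3, lab3))
  })
})

test_that("degenerate and invalid association inputs are handled", {
  expect_equal(association_p(rep(2, 6), rep(c("a", "b"), 3))$p_value, 1)
  expect_error(association_p(1:4, rep("a", 4)), "distinct labels")
  expect_error(association_p(1:4, c("a", "a", "b", "b"), n_perm = 10), ">= 99")
})

test_that("Monte-Carlo p agrees with exact enumeration within 3 MC errors", {
  withr::with_seed(8, {
    for (i in 1:5) {
      v <- rnorm(9)
      lab <- rep(c("a", "b", "c"), each = 3)
      exact <- association_p(v, lab)$p_value
      r <- rank(v)
      gid <- as.integer(factor(lab))
      n_perm <- 4999L
      mc <- cpp_perm_count(matrix(r, nrow = 1), gid - 1L, n_perm, 77L + i)
      p_mc <- (1 + mc$count[1]) / (1 + n_perm)
      se <- sqrt(exact * (1 - exact) / n_perm)
      expect_lt(abs(p_mc - exact), 3 * se + 2 / n_perm)
    }
  })
})

test_that("Monte-Carlo permutation stream is deterministic for a fixed seed", {
  v <- rnorm(30)
  lab <- rep(c("a", "b"), 15)
  p1 <- association_p(v, lab, n_perm = 999, seed = 5)$p_value
  p2 <- association_p(v, lab, n_perm = 999, seed = 5)$p_value
  expect_identical(p1, p2)
})

test_that("best_cutoff scans midpoints and breaks ties toward smaller values", {
  out <- best_cutoff(c(1, 2, 10, 11), c("A", "A", "B", "B"))
  expect_equal(out$cutoff, 6)

  inter <- best_cutoff(c(1, 2, 3, 4), c("A", "B", "A", "B"))
  perfect <- best_cutoff(c(1, 2, 3, 4), c("A", "A", "B", "B"))
  expect_lt(inter$statistic, perfect$statistic)

  expect_error(best_cutoff(rep(5, 4), c("A", "A", "B", "B")), "equal")

  # min_child can rule out every midpoint
  expect_null(best_cutoff(c(1, 2, 3, 4), c("A", "A", "B", "B"), min_child = 3))
})

test_that("a planted expression threshold is recovered by best_cutoff", {
  withr::with_seed(61, {
    lo <- rnbinom(20, mu = 610 / 2, size = 1 / 0.15)
    hi <- rnbinom(20, mu = 610 * 2, size = 1 / 0.15)
    out <- best_cutoff(c(lo, hi), rep(c("low", "high"), each = 20))
    acc <- mean(c(lo <= out$cutoff, hi > out$cutoff))
    expect_gte(acc, 0.9)
    expect_gt(out$cutoff, 610 / 1.5)
    expect_lt(out$cutoff, 610 * 1.5)
  })
})

test_that("fit_ctree finds a dominant marker and respects alpha", {
  panel <- build_panel(10, n_negative = 2, required_genes = "AQP1")
  eff <- tibble::tibble(gene = "AQP1", entity = "A", log2fc = 3)
  spec <- cohort_spec(c(A = 10L, B = 10L), effects = eff, scale_sd = 0,
                      seed = 23L)
  co <- simulate_cohort(spec, panel)
  fit <- fit_ctree(co$counts, co$labels, seed = 2)
  expect_equal(split_genes(fit), "AQP1")
  expect_equal(glance(fit)$depth, 1)

  null_fit <- fit_ctree(co$counts, co$labels, alpha = 0, seed = 2)
  expect_equal(glance(null_fit)$n_splits, 0)
  expect_equal(tidy(null_fit)$type, "leaf")
})

test_that("fit_ctree recovers the planted three-tier marker hierarchy", {
  panel <- small_tree_panel(50)
  # graded strengths force the tier order
  eff <- tree_marker_effects(c(2.5, 2, 1.6))
  spec <- cohort_spec(setNames(rep(15L, 4), orbital_entities()),
                      effects = eff,
                      gene_means = marker_gene_baselines(2), seed = 101L)
  co <- simulate_cohort(spec, panel)
  fit <- fit_ctree(co$counts, co$labels, seed = 7)
  expect_equal(split_genes(fit)[1:3], c("PLA2G2A", "RBM47", "AQP1"))
})

test_that("the tree is invariant to sample order and monotone transforms", {
  panel <- small_tree_panel(20)
  spec <- cohort_spec(setNames(rep(8L, 4), orbital_entities()),
                      effects = tree_marker_effects(2.5),
                      gene_means = marker_gene_baselines(2), seed = 55L)
  co <- simulate_cohort(spec, panel)
  fit <- fit_ctree(co$counts, co$labels, seed = 3)

  perm <- withr::with_seed(1, sample(nrow(co$labels)))
  counts_p <- co$counts[, c(META_COLS, co$labels$sample_id[perm])]
  fit_p <- fit_ctree(counts_p, co$labels[perm, ], seed = 3)
  expect_equal(split_genes(fit_p), split_genes(fit))
  expect_equal(glance(fit_p)$n_nodes, glance(fit)$n_nodes)

  # strictly monotone transform of one gene: same structure, new cutoff scale
  logd <- co$counts
  row <- which(logd$probe_name == "PLA2G2A")
  for (s in co$labels$sample_id) logd[[s]][row] <- log1p(logd[[s]][row])
  fit_l <- fit_ctree(logd, co$labels, seed = 3)
  expect_equal(split_genes(fit_l), split_genes(fit))
  td <- tidy(fit_l)
  pla <- td[td$type == "split" & td$gene == "PLA2G2A", ]
  expect_true(all(pla$cutoff < 20))  # cutoff now on the log scale
})

test_that("under shuffled labels the tree rarely splits at all", {
  panel <- build_panel(30, n_negative = 2)
  spec <- cohort_spec(c(A = 10L, B = 10L), scale_sd = 0, seed = 303L)
  co <- simulate_cohort(spec, panel)
  splits <- withr::with_seed(42, {
    vapply(1:20, function(i) {
      lab <- co$labels
      lab$entity <- sample(lab$entity)
      glance(fit_ctree(co$counts, lab, seed = i))$n_splits
    }, numeric(1))
  })
  expect_lte(mean(splits > 0), 0.15)  # Bonferroni keeps FWER near alpha
})

test_that("prediction routes by cutoffs, reports leaf proportions, and
           errors on missing genes", {
  panel <- build_panel(5, n_negative = 2, required_genes = "AQP1")
  eff <- tibble::tibble(gene = "AQP1", entity = "A", log2fc = 3)
  spec <- cohort_spec(c(A = 8L, B = 8L), effects = eff, scale_sd = 0, seed = 9L)
  co <- simulate_cohort(spec, panel)
  fit <- fit_ctree(co$counts, co$labels, seed = 4)
  expect_equal(split_genes(fit), "AQP1")
  cut <- tidy(fit)$cutoff[1]

  probe <- make_counts(c("AQP1", "G0002", "G0003", "G0004", "G0005"),
                       rep("Endogenous", 5),
                       matrix(c(cut, 1, 1, 1, 1,          # exactly at cutoff
                                cut + 1, 1, 1, 1, 1), ncol = 2))
  pred <- predict(fit, probe)
  expect_equal(pred$pred_class, c("B", "A"))  # at-cutoff routes left (low side)

  # leaf-only tree returns its class distribution everywhere
  leaf_fit <- fit_ctree(co$counts, co$labels, alpha = 0, seed = 4)
  pred_leaf <- predict(leaf_fit, probe)
  expect_equal(pred_leaf$A, c(0.5, 0.5))

  missing <- probe[probe$probe_name != "AQP1", ]
  expect_error(predict(fit, missing), "AQP1")
})

test_that("leave-one-out tree classification recovers planted structure", {
  panel <- small_tree_panel(20)
  spec <- cohort_spec(setNames(rep(15L, 4), orbital_entities()),
                      effects = tree_marker_effects(2),
                      gene_means = marker_gene_baselines(2), seed = 77L)
  co <- simulate_cohort(spec, panel)
  cv <- loocv_ctree(co$counts, co$labels, seed = 5)
  expect_equal(nrow(cv), 60)
  expect_gte(mean(cv$correct), 0.9)
})
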