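test_that("rank-test branch agrees with the exhaustive enumeration oracle", {
  x <- c(1, 2, 3); y <- c(10, 11, 12)
  # alpha_normality = 2 forces the non-parametric branch
  res <- test_gene(c(x, y), rep(c(TRUE, FALSE), each = 3), alpha_normality = 2)
  expect_equal(res$test, "wilcoxon")
  expect_equal(res$p_value, oracle_wilcox_p(x, y))
  expect_equal(res$direction, "down")

  withr::with_seed(21, {
    for (i in 1:10) {
      x <- rpois(4, 30); y <- rpois(5, 45)
      res <- test_gene(c(x, y), c(rep(TRUE, 4), rep(FALSE, 5)),
                       alpha_normality = 2)
      if (res$test == "wilcoxon" && !anyDuplicated(c(x, y))) {
        expect_equal(res$p_value, oracle_wilcox_p(x, y))
      }
    }
  })
})

test_that("test_gene gates on normality and handles degenerate input", {
  withr::with_seed(5, {
    x <- rnorm(20); y <- rnorm(20) + 1
    res <- test_gene(c(x, y), rep(c(TRUE, FALSE), each = 20))
    expect_equal(res$test, "t")
    expect_equal(res$p_value, t.test(x, y)$p.value)

    skewed <- c(rexp(20)^3, rexp(20)^3 + 50)
    res2 <- test_gene(skewed, rep(c(TRUE, FALSE), each = 20))
    expect_equal(res2$test, "wilcoxon")
  })

  same <- rep(3, 8)
  res <- test_gene(same, rep(c(TRUE, FALSE), each = 4))
  expect_equal(res$p_value, 1)
  expect_true(is.na(res$direction))

  expect_error(test_gene(1:4, c(TRUE, FALSE, FALSE, FALSE)), ">= 2 samples")
})

test_that("test_gene p-values are invariant under sample reordering", {
  withr::with_seed(17, {
    v <- rpois(14, 40)
    g <- rep(c(TRUE, FALSE), 7)
    p1 <- test_gene(v, g)$p_value
    o <- sample(14)
    p2 <- test_gene(v[o], g[o])$p_value
    expect_equal(p1, p2)
  })
})

test_that("BH adjustment matches the brute-force step-up oracle", {
  withr::with_seed(9, {
    for (i in 1:10) {
      p <- runif(sample(3:20, 1))
      expect_equal(p.adjust(p, method = "BH"), oracle_bh(p))
    }
  })
  # single test: adjustment is the identity
  expect_equal(p.adjust(0.04, method = "BH"), 0.04)
})

test_that("differential_genes flags planted markers and respects the mask", {
  panel <- build_panel(40, n_housekeeping = 4, n_negative = 4,
                       required_genes = c("AQP1", "RPS27A"))
  eff <- tibble::tibble(gene = c("AQP1", "RPS27A"),
                        entity = c("NSOI", "NSOI"), log2fc = c(2, -2))
  spec <- cohort_spec(c(NSOI = 15L, `IgG4-ROD` = 15L, MALT = 15L),
                      effects = eff,
                      gene_means = c(AQP1 = 100, RPS27A = 4000), seed = 13L)
  co <- simulate_cohort(spec, panel)
  norm <- normalize_counts(co$counts)
  mask <- noise_filter(norm, co$labels)
  de <- differential_genes(norm, co$labels, mask = mask)
  expect_true(all(de$adj_p >= de$p_value - 1e-12))
  expect_setequal(unique(de$entity), c("NSOI", "IgG4-ROD", "MALT"))
  expect_true(all(de$gene %in% expressed_genes(mask)))

  nsoi <- de[de$entity == "NSOI", ]
  expect_equal(nsoi$direction[nsoi$gene == "RPS27A"], "down")
  expect_true(nsoi$significant[nsoi$gene == "RPS27A"])
  expect_equal(nsoi$direction[nsoi$gene == "AQP1"], "up")
})

test_that("under the null the raw false-positive rate is near alpha and
           FDR keeps discoveries near zero", {
  panel <- build_panel(400, n_housekeeping = 4, n_negative = 4)
  spec <- cohort_spec(c(A = 10L, B = 10L), scale_sd = 0, seed = 77L)
  co <- simulate_cohort(spec, panel)
  de <- differential_genes(co$counts, co$labels)
  expect_lt(abs(mean(de$p_value <= 0.05) - 0.05), 0.035)
  expect_lte(sum(de$significant), 2)
})

test_that("significant-set size is non-increasing in alpha", {
  panel <- build_panel(60, n_negative = 4)
  eff <- tibble::tibble(gene = sprintf("G%04d", 1:10), entity = "A", log2fc = 1.5)
  spec <- cohort_spec(c(A = 12L, B = 12L), effects = eff, scale_sd = 0, seed = 3L)
  co <- simulate_cohort(spec, panel)
  sizes <- vapply(c(0.2, 0.1, 0.05, 0.01), function(a) {
    sum(differential_genes(co$counts, co$labels, alpha = a)$significant)
  }, numeric(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("overlap_sets computes pairwise intersections and percentages", {
  out <- overlap_sets(list(A = c("x", "y", "z"), B = c("y", "z", "w")))
  expect_equal(out$overlap, 2)
  expect_equal(out$pct_of_set1, 100 * 2 / 3)

  disj <- overlap_sets(list(A = "a", B = "b", C = "c"))
  expect_true(all(disj$overlap == 0))
  expect_equal(nrow(disj), 3)  # all unordered pairs

  out2 <- overlap_sets(list(A = c("x", "x", "y"), B = c("y")))
  expect_equal(out2$size1, 2)  # duplicates ignored
  expect_true(all(out2$overlap <= pmin(out2$size1, out2$size2)))
})

test_that("shared planted markers surface in both entities' overlap sets", {
  # CLIC4 and NRP1 carry a down rule for lymphoma and an up rule for
  # IgG4-ROD; AQP1 is up for NSOI and down for lymphoma. Genes shared
  # between two panels must land in both entities' significant sets.
  co <- simulate_cohort(validation_cohort_spec(strength = 2, seed = 19L),
                        validation_panel())
  norm <- normalize_counts(co$counts)
  de <- differential_genes(norm, co$labels)
  sets <- significant_sets(de)
  expect_true(all(c("CLIC4", "NRP1") %in% sets[["MALT"]]))
  expect_true(all(c("CLIC4", "NRP1") %in% sets[["IgG4-ROD"]]))
  expect_true("AQP1" %in% sets[["MALT"]])
  expect_true("AQP1" %in% sets[["NSOI"]])
  ov <- overlap_sets(sets)
  pair <- function(a, b) {
    ov$overlap[(ov$set1 == a & ov$set2 == b) | (ov$set1 == b & ov$set2 == a)]
  }
  expect_gte(pair("MALT", "IgG4-ROD"), 2)
  expect_gte(pair("MALT", "NSOI"), 1)
  expect_true(all(ov$overlap <= pmin(ov$size1, ov$size2)))
})
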