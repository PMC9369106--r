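test_that("build_panel places required genes first with deterministic filler", {
  p <- build_panel(3, required_genes = "AQP1")
  expect_equal(p$probe_name, c("AQP1", "G0002", "G0003"))
  expect_equal(p$probe_class, rep("Endogenous", 3))

  p2 <- build_panel(3, required_genes = "AQP1")
  expect_identical(p, p2)

  big <- screening_panel()
  expect_equal(sum(big$probe_class == "Endogenous"), 1364)
  expect_equal(sum(big$probe_class == "Housekeeping"), 30)
  expect_false(anyDuplicated(big$probe_name) > 0)

  controls_only <- build_panel(0, n_housekeeping = 2, n_negative = 2,
                               n_positive = 2)
  expect_equal(nrow(controls_only), 6)
  expect_false("Endogenous" %in% controls_only$probe_class)

  expect_error(build_panel(1, required_genes = c("A", "B")), "smaller")
  expect_error(build_panel(3, required_genes = c("A", "A")), "duplicates")
})

test_that("cohort presets reproduce the study group sizes", {
  scr <- screening_cohort_spec(seed = 1)
  expect_equal(sum(scr$groups), 12)
  expect_equal(unname(scr$groups), rep(3L, 4))
  val <- validation_cohort_spec(seed = 1)
  expect_equal(sum(val$groups), 48)
  expect_equal(val$groups[["NSOI"]], 24L)
  expect_equal(val$groups[["IgG4-ROD"]], 11L)
  expect_equal(val$groups[["MALT"]], 13L)
})

test_that("simulate_cohort matches the spec exactly and reproducibly", {
  panel <- small_tree_panel(10)
  spec <- cohort_spec(c(A = 4L, B = 5L), seed = 42L)
  co <- simulate_cohort(spec, panel)
  expect_equal(nrow(co$labels), 9)
  expect_equal(table(co$labels$entity)[["A"]], 4)
  expect_equal(sample_ids(co$counts), co$labels$sample_id)

  co2 <- simulate_cohort(spec, panel)
  expect_identical(co$counts, co2$counts)

  set.seed(123)
  rng_before <- .Random.seed
  simulate_cohort(spec, panel)
  expect_identical(rng_before, .Random.seed)

  expect_error(simulate_cohort(spec, panel[0, ]), "non-empty")
  bad <- tibble::tibble(gene = "AQP1", entity = "Nope", log2fc = 1)
  expect_error(cohort_spec(c(A = 3L), effects = bad), "Nope")
})

test_that("positive controls form a fixed ladder and counts are integers", {
  panel <- small_tree_panel(5)
  co <- simulate_cohort(cohort_spec(c(A = 3L), seed = 2L), panel)
  pos <- co$counts[co$counts$probe_class == "Positive", ]
  vals <- as.matrix(pos[, co$labels$sample_id])
  expect_true(all(vals == vals[, 1]))
  expect_equal(vals[, 1] / vals[2, 1], c(4, 1), ignore_attr = TRUE)
  endo <- as.matrix(co$counts[, co$labels$sample_id])
  expect_true(all(endo == round(endo)))
  expect_true(all(endo >= 0))
})

test_that("with no effects the count model is centred on baseline_mean", {
  panel <- build_panel(20)
  spec <- cohort_spec(c(A = 500L, B = 500L), baseline_mean = 250,
                      dispersion = 0.15, scale_sd = 0, seed = 99L)
  co <- simulate_cohort(spec, panel)
  m <- as.matrix(co$counts[, co$labels$sample_id])
  mu_hat <- rowMeans(m)
  se <- apply(m, 1, sd) / sqrt(ncol(m))
  expect_true(all(abs(mu_hat - 250) < 3 * se + 1e-9))
})

test_that("with no effects genes are exchangeable across entities", {
  panel <- build_panel(5)
  spec <- cohort_spec(c(A = 100L, B = 100L, C = 100L), scale_sd = 0, seed = 7L)
  co <- simulate_cohort(spec, panel)
  m <- as.matrix(co$counts[, co$labels$sample_id])
  ps <- apply(m, 1, function(v) {
    stats::kruskal.test(v, factor(co$labels$entity))$p.value
  })
  expect_true(all(ps > 0.001))
})

test_that("default_marker_effects encodes the published directions", {
  eff <- default_marker_effects(2)
  get <- function(g, e) eff$log2fc[eff$gene == g & eff$entity == e]
  expect_equal(get("RPS27A", "NSOI"), -2)
  expect_equal(get("RAC1", "MALT"), -2)
  expect_equal(get("ADAM9", "IgG4-ROD"), 2)
  expect_equal(get("AQP1", "NSOI"), 2)
  expect_equal(get("AQP1", "rNSOI"), 2)
  expect_equal(get("AQP1", "MALT"), -2)
  expect_error(default_marker_effects(0), "> 0")
})

test_that("marker baselines respect every cut-off constraint at strength 2", {
  s <- 2
  base <- marker_gene_baselines(s)
  panels <- published_panels()
  for (i in seq_len(nrow(panels))) {
    g <- panels$gene[i]
    cut <- panels$cutoff[i]
    if (panels$direction[i] == "up") {
      expect_lt(base[[g]], cut)          # unaffected samples stay below
      expect_gt(base[[g]] * 2^s, cut)    # target entity crosses above
    } else {
      expect_gt(base[[g]], cut)
      expect_lt(base[[g]] * 2^(-s), cut)
    }
  }
})

test_that("planted effects are recovered in direction by diffexp", {
  panel <- build_panel(30, n_housekeeping = 4, n_negative = 4,
                       required_genes = c("AQP1", "RPS27A"))
  eff <- tibble::tibble(gene = c("AQP1", "RPS27A"), entity = "NSOI",
                        log2fc = c(2, -2))
  spec <- cohort_spec(c(NSOI = 30L, MALT = 30L), effects = eff,
                      gene_means = c(AQP1 = 100, RPS27A = 4000), seed = 5L)
  co <- simulate_cohort(spec, panel)
  de <- differential_genes(normalize_counts(co$counts), co$labels)
  nsoi <- de[de$entity == "NSOI", ]
  expect_equal(nsoi$direction[nsoi$gene == "AQP1"], "up")
  expect_equal(nsoi$direction[nsoi$gene == "RPS27A"], "down")
  expect_true(nsoi$significant[nsoi$gene == "AQP1"])
  expect_true(nsoi$significant[nsoi$gene == "RPS27A"])
})
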