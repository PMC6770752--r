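test_that("module PC1 scores are centred, oriented and scale with data", {
  v <- rbind(g1 = c(1, 2, 3), g2 = c(1, 2, 3))
  colnames(v) <- paste0("s", 1:3)
  sc <- module_pc1(make_expr(v), c("g1", "g2"))
  expect_equal(mean(sc$pc1_scores), 0, tolerance = 1e-12)
  expect_equal(unname(sc$pc1_scores / sc$pc1_scores[3]), c(-1, 0, 1))
  expect_gt(sc$pc1_scores[3], 0)  # oriented along mean expression
  expect_equal(sc$variance_explained, 1)

  expect_error(module_pc1(make_expr(v), "g1"), "at least 2 genes")
})

test_that("uncorrelated noise spreads variance across components", {
  set.seed(42)
  v <- matrix(rnorm(20 * 60), 20)
  sc <- module_pc1(make_expr(v), sprintf("g%02d", 1:20))
  # for iid noise the top component carries only slightly more than the
  # average share 1/p (Marchenko-Pastur edge ~ (1+sqrt(p/n))^2/p = 0.125)
  expect_gt(sc$variance_explained, 1 / 20)
  expect_lt(sc$variance_explained, 0.2)
})

test_that("sign-flipping the expression matrix cannot change the scan", {
  set.seed(9)
  v <- matrix(rnorm(8 * 12), 8)
  ex <- make_expr(v)
  flipped <- make_expr(-v)
  genes <- feature_ids(ex)
  a <- module_pc1(ex, genes)
  b <- module_pc1(flipped, genes)
  # distances between samples are what the test consumes; identical either way
  expect_equal(abs(a$pc1_scores), abs(b$pc1_scores), tolerance = 1e-9)
  labs <- rep(c("x", "y"), each = 6)
  pa <- permanova(a$pc1_scores, labs, seed = 3)
  pb <- permanova(b$pc1_scores, labs, seed = 3)
  expect_equal(pa$pseudo_F, pb$pseudo_F, tolerance = 1e-10)
  expect_identical(pa$p_value, pb$p_value)
})

test_that("pseudo-F on 1-D Euclidean data is the classical ANOVA F", {
  # hand-partitioned example: {1,2} vs {3,4}
  res <- permanova(c(1, 2, 3, 4), c("a", "a", "b", "b"))
  expect_equal(res$pseudo_F, 8)
  expect_identical(res$method, "exhaustive")
  expect_equal(res$p_value, 1 / 3)  # 2 of 6 assignments reach F = 8

  for (seed in 1:10) {
    set.seed(seed)
    n_per <- sample(3:9, 3)
    y <- rnorm(sum(n_per))
    g <- factor(rep(letters[1:3], n_per))
    f_aov <- summary(stats::aov(y ~ g))[[1]]$`F value`[1]
    res <- permanova(y, g, exhaustive = FALSE, n_perm = 19, seed = 1)
    expect_equal(res$pseudo_F, f_aov, tolerance = 1e-10)
  }
})

test_that("pseudo-F matches vegan::adonis2 on multivariate data", {
  skip_if_not_installed("vegan")
  set.seed(21)
  y <- matrix(rnorm(18 * 3), 18)
  y[1:9, 1] <- y[1:9, 1] + 1.5
  g <- rep(c("p", "q"), each = 9)
  ref <- vegan::adonis2(stats::dist(y) ~ g, permutations = 99)
  res <- permanova(stats::dist(y), g, exhaustive = FALSE, n_perm = 99,
                   seed = 2)
  expect_equal(res$pseudo_F, ref$F[1], tolerance = 1e-8)
})

test_that("exhaustive and Monte-Carlo p-values agree on fixtures", {
  set.seed(5)
  y <- c(rnorm(6), rnorm(6) + 1)
  g <- rep(c("a", "b"), each = 6)
  pe <- permanova(y, g, exhaustive = TRUE)$p_value
  pm <- permanova(y, g, exhaustive = FALSE, n_perm = 10000,
                  seed = 8)$p_value
  expect_lt(abs(pe - pm), 2 / sqrt(10000))
})

test_that("permanova p is invariant to sample order and label names", {
  set.seed(13)
  y <- rnorm(14)
  g <- rep(c("ctl", "trt"), 7)
  base <- permanova(y, g, exhaustive = FALSE, n_perm = 499, seed = 99)
  o <- sample(14)
  reord <- permanova(y[o], g[o], exhaustive = FALSE, n_perm = 499, seed = 99)
  expect_identical(base$p_value, reord$p_value)
  expect_equal(base$pseudo_F, reord$pseudo_F, tolerance = 1e-12)
  renamed <- permanova(y, ifelse(g == "ctl", "zzz", "aaa"),
                       exhaustive = FALSE, n_perm = 499, seed = 99)
  expect_identical(base$p_value, renamed$p_value)
})

test_that("degenerate permanova inputs are handled explicitly", {
  expect_error(permanova(1:5, c("a", "a", "a", "a", "b")), "2 samples")
  expect_warning(res <- permanova(rep(2, 8), rep(c("a", "b"), 4)),
                 "identical")
  expect_identical(res$p_value, 1)
  expect_true(is.nan(res$pseudo_F))
  # p respects the Monte-Carlo lower bound 1/(n_perm + 1)
  y <- c(rep(0, 10), rep(10, 10))
  res <- permanova(y, rep(c("a", "b"), each = 10), exhaustive = FALSE,
                   n_perm = 99, seed = 1)
  expect_gte(res$p_value, 1 / 100)
})

test_that("the scan flags shifted modules with the right direction", {
  spec <- synthetic_spec(n_genes = 80,
                         n_samples = c(negative = 25, PAX3 = 26, PAX7 = 7),
                         module_sizes = c(20, 15), delta = c(2, -2),
                         cnv_module = 0)
  sim <- simulate_expression(spec, seed = 3)
  ms <- as_module_set(sim$truth$modules)
  res <- diff_module_scan(sim$expr, ms, sim$annotation, "neg_vs_pos",
                          seed = 10)
  expect_identical(res$module_id, c("block1", "block2"))  # size order
  expect_true(all(res$p_value < 0.05))
  expect_identical(res$direction,
                   c("up", "down"))  # delta +2 up, -2 down in positives
  expect_identical(res$significant, res$p_value < 0.05)

  again <- diff_module_scan(sim$expr, ms, sim$annotation, "neg_vs_pos",
                            seed = 10)
  expect_identical(res, again)  # reproducible under the same seed

  # PAX3 vs PAX7 contrast runs on the fusion-positive subset only
  res37 <- diff_module_scan(sim$expr, ms, sim$annotation, "pax3_vs_pax7",
                            seed = 10)
  expect_identical(nrow(res37), 2L)
  expect_true(all(res37$n_perm == 999))
})

test_that("scan errors on an empty contrast group", {
  spec <- synthetic_spec(n_genes = 40,
                         n_samples = c(negative = 10, PAX3 = 8, PAX7 = 0),
                         module_sizes = c(10), delta = c(0), cnv_module = 0)
  sim <- simulate_expression(spec, seed = 2)
  ms <- as_module_set(sim$truth$modules)
  expect_error(diff_module_scan(sim$expr, ms, sim$annotation,
                                "pax3_vs_pax7"),
               "empty contrast group")
})
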