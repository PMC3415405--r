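test_that("pooled_variance_ttest matches closed-form arithmetic", {
  sheet <- data.frame(sample_id = sprintf("s%d", 1:6),
                      group = rep(c("A", "B"), each = 3))
  m <- tiny_matrix(matrix(c(1, 2, 3, 4, 5, 6), 1, 6), probes = "t1",
                   samples = sheet$sample_id)
  res <- pooled_variance_ttest(m, sheet, "A", "B")
  expect_equal(res$s2, 1)
  expect_equal(res$df, 4L, ignore_attr = TRUE)
  expect_equal(res$t, -3 / sqrt(2 / 3), tolerance = 1e-6)   # -3.674
  expect_equal(res$p, 2 * pt(-3 / sqrt(2 / 3), 4), tolerance = 1e-10)  # 0.02131
  expect_equal(res$ratio, 2^(2 - 5))

  # identical groups: t = 0, p = 1
  m0 <- tiny_matrix(matrix(c(1, 2, 3, 1, 2, 3), 1, 6), probes = "t1",
                    samples = sheet$sample_id)
  r0 <- pooled_variance_ttest(m0, sheet, "A", "B")
  expect_equal(r0$t, 0)
  expect_equal(r0$p, 1)

  # degenerate variance: flagged p = 1 when means agree, error otherwise
  const <- tiny_matrix(matrix(5, 1, 6), probes = "t1", samples = sheet$sample_id)
  expect_warning(rc <- pooled_variance_ttest(const, sheet, "A", "B"),
                 "zero pooled variance")
  expect_true(rc$zero_variance)
  expect_equal(rc$p, 1)
  shifted <- tiny_matrix(matrix(rep(c(1, 2), each = 3), 1, 6), probes = "t1",
                         samples = sheet$sample_id)
  expect_error(pooled_variance_ttest(shifted, sheet, "A", "B"),
               "zero pooled variance")
})

test_that("anova_groups agrees with R's lm oracle and the t-test identity", {
  sheet <- data.frame(sample_id = sprintf("s%d", 1:6),
                      group = rep(c("A", "B", "C"), each = 2))
  m <- tiny_matrix(matrix(1:6, 1, 6), probes = "t1", samples = sheet$sample_id)
  res <- anova_groups(m, sheet, c("A", "B", "C"))
  # frozen from anova(lm(x ~ g)) on (1,2),(3,4),(5,6): F = 16, p = 0.02509
  expect_equal(res$F, 16)
  expect_equal(res$p, 0.02509457, tolerance = 1e-6)

  # property: random matrices agree with lm per transcript
  set.seed(5)
  sheet2 <- tiny_sheet(c("A", "B", "C"), 4L)
  x <- matrix(rnorm(10 * 12, 8), 10, 12)
  m2 <- tiny_matrix(x, samples = sheet2$sample_id)
  res2 <- anova_groups(m2, sheet2, c("A", "B", "C"))
  for (i in c(1, 4, 10)) {
    a <- anova(lm(x[i, ] ~ factor(sheet2$group)))
    expect_equal(res2$F[i], a$`F value`[1], tolerance = 1e-10)
    expect_equal(res2$p[i], a$`Pr(>F)`[1], tolerance = 1e-10)
  }

  # constant transcripts: F = 0, p = 1
  mc <- tiny_matrix(matrix(3, 2, 12), samples = sheet2$sample_id)
  expect_warning(rc <- anova_groups(mc, sheet2, c("A", "B", "C")), NA)
  expect_equal(rc$F, c(0, 0))
  expect_equal(rc$p, c(1, 1))

  # F = t^2 identity on every two-group instance
  tt <- pooled_variance_ttest(m2, sheet2, "A", "B", variance_groups = c("A", "B"))
  aa <- anova_groups(m2, sheet2, c("A", "B"))
  expect_equal(aa$F, tt$t^2, tolerance = 1e-10)
  expect_equal(aa$p, tt$p, tolerance = 1e-10)
})

test_that("expected_null_count and the merge rule follow the threshold contract", {
  expect_identical(expected_null_count(11224, 0.01), 112L)
  expect_identical(expected_null_count(0, 0.5), 0L)
  expect_identical(expected_null_count(1000, 0.05), 50L)
  expect_error(expected_null_count(100, 1.2), "alpha")

  p33 <- c(rep(0.005, 33), rep(0.5, 11224 - 33))
  d33 <- merge_decision(p33, alpha = 0.01)
  expect_identical(d33$observed, 33L)
  expect_identical(d33$expected, 112L)
  expect_true(d33$merged)
  expect_lt(d33$binomial_p, 1e-10)

  p249 <- c(rep(0.005, 249), rep(0.5, 11224 - 249))
  expect_false(merge_decision(p249, alpha = 0.01)$merged)

  expect_error(merge_decision(numeric(0)), "at least one")
  expect_error(merge_decision(c(0.5, 1.2)), "\\[0, 1\\]")

  # ecdf diagnostics cover the full range
  expect_equal(nrow(d33$ecdf_curve), 11224L)
  expect_equal(max(d33$ecdf_curve$cdf), 1)
})

test_that("merge_decision is monotone: smaller p-values never force a merge", {
  set.seed(99)
  for (i in 1:50) {
    m <- sample(50:2000, 1)
    alpha <- sample(c(0.01, 0.05), 1)
    p <- runif(m)
    base <- merge_decision(p, alpha)
    extra <- runif(sample(1:20, 1), 0, alpha * 0.999)
    grown <- merge_decision(c(p, extra), alpha)
    if (!base$merged) expect_false(grown$merged)
  }
})

test_that("merge counts are calibrated under uniform p-values", {
  set.seed(123)
  d <- merge_decision(runif(10000), alpha = 0.01)
  se <- sqrt(10000 * 0.01 * 0.99)
  expect_lt(abs(d$observed - 100), 3 * se)
})

test_that("pca_scores is deterministic, sign-fixed and separates planted groups", {
  set.seed(3)
  x <- matrix(rnorm(50 * 12, 8), 50, 12)
  x[1:20, 7:12] <- x[1:20, 7:12] + 2   # planted separation axis
  m <- tiny_matrix(x)
  pc <- pca_scores(m, n_components = 3)
  expect_equal(dim(pc$scores), c(12L, 3L))
  # duplicated sample profiles get identical scores
  xd <- cbind(x, x[, 1])
  dimnames(xd) <- list(sprintf("p%02d", 1:50), sprintf("s%02d", 1:13))
  pcd <- pca_scores(ExpressionMatrix(xd), 2)
  expect_equal(unname(pcd$scores[13, ]), unname(pcd$scores[1, ]), tolerance = 1e-8)
  # variance conservation
  expect_lte(sum(pc$explained_variance), pc$total_variance + 1e-8)
  expect_equal(sum(pc$explained_fraction <= 1), 3L)
  # planted axis shows up on PC1
  lab <- rep(c("a", "b"), each = 6)
  expect_gt(silhouette_1d(pc$scores[, 1], lab), 0.5)
  # orthonormal loadings
  expect_equal(crossprod(pc$loadings), diag(3), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_error(pca_scores(m, 13), "n_components")
})

test_that("de_select thresholds and recovers planted effects", {
  expect_identical(de_select(c(a = 1, b = 1)), character(0))
  expect_identical(de_select(c(a = 0.04, b = 0.06), 0.05), "a")
  expect_error(de_select(c(0.2, 0.3)), "named")

  # scaled-down power check (the acceptance suite runs the 100-seed version)
  recalls <- vapply(1:20, function(s) {
    cfg <- sim_config(n_genes = 300L, chromosomes = c(chr1 = 200L, chr21 = 100L),
                      group_sizes = c("2N" = 4L, "CHD-" = 20L, AVSD = 20L,
                                      ASD = 4L, VSD = 4L),
                      n_de_per_contrast = c(AVSD = 30L, "ASD+VSD" = 0L),
                      de_log2fc_range = c(1.0, 1.0), seed = 600L + s)
    ds <- generate_dataset(cfg)
    gm <- collapse_probes(quantile_normalize(expression_call(ds$expression, ds$samples)),
                          ds$annotation)
    de <- de_select(pooled_variance_ttest(gm, ds$samples, "AVSD", "CHD-"), 0.05)
    truth <- rownames(ds$truth$de_flags)[ds$truth$de_flags[, "AVSD"]]
    mean(intersect(truth, rownames(gm$values)) %in% de)
  }, numeric(1))
  expect_gte(mean(recalls), 0.9)
})
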