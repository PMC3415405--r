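test_that("generation is bit-reproducible and respects the null configuration", {
  cfg <- small_sim(seed = 7L)
  d1 <- generate_dataset(cfg)
  d2 <- generate_dataset(cfg)
  expect_identical(d1$expression$values, d2$expression$values)
  expect_identical(d1$expression$detection_p, d2$expression$detection_p)
  expect_identical(d1$truth, d2$truth)

  null_cfg <- small_sim(n_de_per_contrast = c(AVSD = 0L, "ASD+VSD" = 0L),
                        dosage_fraction = 0, de_log2fc_range = c(0, 0))
  nd <- generate_dataset(null_cfg)
  expect_false(any(nd$truth$de_flags))
  expect_true(all(nd$truth$class_label == "none"))
  # group means equal in expectation: per-group means of expressed genes agree
  sheet <- nd$samples
  gm <- collapse_probes(nd$expression, nd$annotation)
  mns <- vapply(unique(sheet$group), function(g)
    mean(gm$values[, sheet$sample_id[sheet$group == g]]), numeric(1))
  expect_lt(max(mns) - min(mns), 0.1)
})

test_that("planted cluster occupies the requested annotation ranks and is DE", {
  cfg <- small_sim(planted_cluster = list(chromosome = "chr21", start = 10L,
                                          k = 3L, contrast = "AVSD"))
  ds <- generate_dataset(cfg)
  tr <- ds$truth
  expect_length(tr$cluster$members, 3L)
  go <- gene_order_table(ds$annotation)
  ranks <- go$order_index[match(tr$cluster$members, go$gene)]
  expect_equal(sort(ranks), 10:12, ignore_attr = TRUE)
  expect_true(all(go$chromosome[match(tr$cluster$members, go$gene)] == "chr21"))
  expect_true(all(tr$de_flags[tr$cluster$members, "AVSD"]))
  expect_true(all(tr$expressed[tr$cluster$members]))
})

test_that("planted class genes satisfy their class rule on the true effects", {
  cfg <- small_sim(class_quota = c(IA = 10L, IB = 10L, IIA = 10L, IIB = 10L),
                   group_sizes = c("2N" = 6L, "CHD-" = 8L, AVSD = 6L,
                                   ASD = 5L, VSD = 5L))
  tr <- generate_dataset(cfg)$truth
  lab <- tr$class_label
  delta <- tr$effect_log2fc[, "AVSD"]
  chd <- tr$chd_vs_2n_log2fc
  for (g in names(lab)[lab != "none"]) {
    cls <- as.character(lab[[g]])
    if (cls %in% c("IA", "IB")) expect_gt(abs(delta[[g]]), abs(chd[[g]]))
    else expect_lt(abs(delta[[g]]), abs(chd[[g]]))
    if (cls == "IA") expect_gt(abs(chd[[g]]), log2(1.05))
    if (cls == "IB") expect_equal(chd[[g]], 0)
    case_total <- chd[[g]] + delta[[g]]
    if (cls == "IIA") expect_gt(abs(case_total), log2(1.05))
    if (cls == "IIB") expect_lt(abs(case_total), log2(1.05))
    expect_true(tr$de_flags[g, "AVSD"])
  }
  # classes never collide with the dosage genes
  expect_length(intersect(names(lab)[lab != "none"], tr$dosage_genes), 0L)
})

test_that("dosage genes carry a ~1.5x trisomic ratio and effects are recoverable", {
  cfg <- sim_config(n_genes = 600L,
                    chromosomes = c(chr1 = 200L, chr21 = 400L),
                    group_sizes = c("2N" = 20L, "CHD-" = 20L, AVSD = 4L,
                                    ASD = 4L, VSD = 4L),
                    n_de_per_contrast = c(AVSD = 200L, "ASD+VSD" = 0L),
                    de_log2fc_range = c(0.3, 1.0), low_expr_fraction = 0,
                    seed = 11L)
  ds <- generate_dataset(cfg)
  gm <- collapse_probes(ds$expression, ds$annotation)
  sheet <- ds$samples
  mean_g <- function(g) rowMeans(gm$values[, sheet$sample_id[sheet$group == g]])
  ratio_chd_2n <- 2^(mean_g("CHD-") - mean_g("2N"))
  expect_gt(mean(ratio_chd_2n[ds$truth$dosage_genes]), 1.4)
  expect_lt(mean(ratio_chd_2n[ds$truth$dosage_genes]), 1.6)

  # per-gene log2 fold changes estimated at n = 20/group recover the truth
  flagged <- rownames(ds$truth$de_flags)[ds$truth$de_flags[, "AVSD"]]
  # AVSD itself is small here; use the planted effect against its own groups
  cfg2 <- sim_config(n_genes = 300L, chromosomes = c(chr1 = 300L),
                     trisomy_chrom = "chr1",
                     group_sizes = c("2N" = 4L, "CHD-" = 20L, AVSD = 20L,
                                     ASD = 4L, VSD = 4L),
                     n_de_per_contrast = c(AVSD = 200L, "ASD+VSD" = 0L),
                     dosage_fraction = 0, low_expr_fraction = 0, seed = 12L)
  ds2 <- generate_dataset(cfg2)
  gm2 <- collapse_probes(ds2$expression, ds2$annotation)
  sh2 <- ds2$samples
  est <- rowMeans(gm2$values[, sh2$sample_id[sh2$group == "AVSD"]]) -
    rowMeans(gm2$values[, sh2$sample_id[sh2$group == "CHD-"]])
  flagged2 <- rownames(ds2$truth$de_flags)[ds2$truth$de_flags[, "AVSD"]]
  bias <- mean(est[flagged2] - ds2$truth$effect_log2fc[flagged2, "AVSD"])
  expect_lt(abs(bias), 0.05)
})

test_that("infeasible configurations fail with informative errors", {
  expect_error(small_sim(group_sizes = c("2N" = 1L, "CHD-" = 8L, AVSD = 6L,
                                         ASD = 5L, VSD = 5L)), "at least 2")
  expect_error(small_sim(dosage_fraction = 1.2), "dosage_fraction")
  expect_error(small_sim(planted_cluster = list(chromosome = "chr21",
                                                start = 99L, k = 5L,
                                                contrast = "AVSD")),
               "does not fit")
  expect_error(small_sim(class_quota = c(IA = 0L, IB = 0L, IIA = 0L, IIB = 0L,
                                         III = 1L)), "unknown class")
  expect_error(generate_dataset(small_sim(n_genes = 50L,
                                          chromosomes = c(chr21 = 50L),
                                          class_quota = c(IB = 60L))),
               "class IB quota")
})

test_that("generate_genesets honours the planted overlap contract", {
  ds <- generate_dataset(small_sim())
  genes <- unique(ds$annotation$gene)
  targets <- sort(sample(genes, 20))

  cat1 <- generate_genesets(ds$annotation, n_sets = 5,
                            enriched_set = list(name = "exact", targets = targets,
                                                overlap_fraction = 1),
                            seed = 1)
  expect_setequal(cat1$exact, targets)

  cat2 <- generate_genesets(ds$annotation, n_sets = 50,
                            set_size_range = c(5, 100), seed = 2)
  expect_length(cat2, 50L)
  expect_true(all(unlist(cat2) %in% genes))
  sizes <- lengths(cat2)
  expect_true(all(sizes >= 5 & sizes <= 100))

  expect_error(generate_genesets(ds$annotation,
                                 enriched_set = list(name = "x", targets = targets,
                                                     overlap_fraction = 1.5)),
               "overlap_fraction")
})

test_that("a zero-overlap set shows no enrichment on average", {
  ds <- generate_dataset(small_sim())
  genes <- unique(ds$annotation$gene)
  factors <- vapply(1:400, function(s) {
    set.seed(s)
    targets <- sample(genes, 40)
    cat0 <- generate_genesets(genes, n_sets = 0,
                              enriched_set = list(name = "null", targets = targets,
                                                  size = 40, overlap_fraction = 0),
                              seed = s + 1)
    # an independent DE draw: enrichment of the set in it should average 1
    de <- sample(genes, 50)
    b <- length(intersect(de, cat0$null))
    enrichment_factor(length(genes), length(cat0$null), length(de), b)
  }, numeric(1))
  se <- stats::sd(factors) / sqrt(length(factors))
  expect_lt(abs(mean(factors) - 1), 3 * se + 1e-9)
})

test_that("datasets round-trip through the plain-text writers", {
  ds <- generate_dataset(small_sim(n_genes = 60L, chromosomes = c(chr1 = 40L, chr21 = 20L),
                                   n_de_per_contrast = c(AVSD = 5L, "ASD+VSD" = 5L)))
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  m <- read_expression_tsv(file.path(dir, "expression.tsv"))
  expect_equal(m$values, ds$expression$values, tolerance = 1e-9)
  expect_equal(m$detection_p, ds$expression$detection_p, tolerance = 1e-9)
  ann <- read_annotation_tsv(file.path(dir, "annotation.tsv"))
  expect_equal(ann, ds$annotation)
  sheet <- read_sample_sheet(file.path(dir, "samples.tsv"))
  expect_equal(sheet, ds$samples)

  catalog <- generate_genesets(ds$annotation, n_sets = 4, set_size_range = c(3, 10))
  gmt <- file.path(dir, "sets.gmt")
  write_gmt(catalog, gmt)
  back <- read_gmt(gmt)
  expect_equal(lapply(back, as.character), lapply(catalog, as.character),
               ignore_attr = TRUE)
})
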