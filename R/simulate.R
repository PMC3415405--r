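#' @name simulate
#' @title Synthetic expression cohorts with planted ground truth
#'
#' @description
#' The generator emulates the statistical structure the analysis assumes for
#' lymphoblastoid-cell-line bead arrays from a trisomy-21 heart-defect
#' cohort: log2-normal intensities with per-gene noise, a ~1.5x gene-dosage
#' effect on a subset of trisomy-chromosome genes in all trisomic groups,
#' group-specific differentially expressed genes, planted genes of each
#' dosage class (IA/IB/IIA/IIB), an optional run of contiguous DE genes on
#' one chromosome, and detection p-values that fail for low-intensity probes.
#' Alongside the data it returns the ground truth needed for recovery tests.
NULL

# Approximate shares of protein-coding genes per chromosome, used to
# apportion simulated genes when no chromosome layout is supplied.
CODING_GENE_COUNTS <- c(
  chr1 = 2058, chr2 = 1309, chr3 = 1078, chr4 = 752, chr5 = 876,
  chr6 = 1048, chr7 = 989, chr8 = 677, chr9 = 786, chr10 = 733,
  chr11 = 1298, chr12 = 1034, chr13 = 327, chr14 = 830, chr15 = 613,
  chr16 = 873, chr17 = 1197, chr18 = 270, chr19 = 1472, chr20 = 544,
  chr21 = 233, chr22 = 488, chrX = 842)

# Planted (chd-vs-2N, case-vs-chd) log2 effect pairs per dosage class.
# IA/IB/IIA keep magnitudes >= 0.2 log2 units apart so the |case-chd| vs
# |chd-2N| comparison is not a coin flip at realistic noise; IIB is the
# boundary class (opposite-sign cancellation forces |chd| - |delta| to equal
# the residual case-vs-2N effect), so its gap is 0.05 with 2^0.05 = 1.035
# inside the 0.95-1.05 equality band.
CLASS_EFFECTS <- list(
  IA = c(chd = 0.4, delta = 0.6),
  IB = c(chd = 0.0, delta = 0.6),
  IIA = c(chd = 0.8, delta = -0.4),
  IIB = c(chd = 0.6, delta = -0.55))

default_chromosomes <- function(n_genes) {
  share <- CODING_GENE_COUNTS / sum(CODING_GENE_COUNTS)
  counts <- floor(share * n_genes)
  short <- n_genes - sum(counts)
  if (short > 0) {
    top <- order(share * n_genes - counts, decreasing = TRUE)[seq_len(short)]
    counts[top] <- counts[top] + 1L
  }
  counts[counts > 0]
}

contrast_groups <- function(contrast, groups) {
  g <- strsplit(contrast, "+", fixed = TRUE)[[1]]
  if (!all(g %in% groups))
    stop(sprintf("contrast '%s' names group(s) absent from group_sizes", contrast))
  g
}

#' Simulation configuration
#'
#' Defaults mirror the cohort the pipeline targets: 12 euploid controls
#' (`2N`), 22 trisomic individuals without heart defect (`CHD-`), and defect
#' subgroups of 7 (`AVSD`), 8 (`ASD`) and 6 (`VSD`); roughly 10,000 genes of
#' which ~10% fall below the detection floor (leaving a universe near the
#' ~9,758 expressed genes of a typical LCL bead-array run, measured by
#' ~1.15 probes per gene); a dosage effect of log2(1.5) on 30% of the
#' trisomy-chromosome genes in every trisomic group; and per-gene noise SD
#' drawn from \[0.1, 0.3\] log2 units, the usual bead-array replicate range.
#'
#' @param n_genes total number of simulated genes.
#' @param n_probes_per_gene probes per gene (default 1).
#' @param extra_probe_fraction fraction of genes receiving one extra probe
#'   (default 0.15, emulating the probe/gene ratio of pangenomic chips).
#' @param chromosomes named integer vector (chromosome -> gene count);
#'   default apportions `n_genes` by real coding-gene shares.
#' @param group_sizes named integer vector of samples per group (each >= 2).
#' @param trisomy_chrom chromosome carried in three copies (default
#'   `"chr21"`).
#' @param dosage_fraction fraction of expressed trisomy-chromosome genes with
#'   a dosage effect (default 0.30).
#' @param dosage_log2fc dosage effect size (default `log2(1.5)`).
#' @param n_de_per_contrast named counts of planted DE genes per case
#'   contrast; contrast names are case groups, with `+` joining merged groups
#'   (default `c(AVSD = 400, "ASD+VSD" = 450)`).
#' @param de_log2fc_range interval for planted |log2 fold change|.
#' @param planted_cluster optional
#'   `list(chromosome =, start =, k =, contrast =)`: the `k` genes at
#'   within-chromosome ranks `start, ..., start + k - 1` (1-based) become DE
#'   for `contrast`, forming a contiguous run.
#' @param class_quota named counts of planted genes per dosage class
#'   (`IA`, `IB`, `IIA`, `IIB`).
#' @param class_contrast case contrast carrying the class-quota genes
#'   (default `"AVSD"`).
#' @param noise_sd range of per-gene noise SD (log2 units).
#' @param baseline_range log2 baseline intensity range of expressed genes.
#' @param low_expr_fraction fraction of genes simulated below the detection
#'   floor.
#' @param low_expr_range log2 baseline range of the low-intensity genes.
#' @param detection_floor intensity below which detection p-values are drawn
#'   high (documentation of the regime boundary; the two baseline ranges sit
#'   on either side of it).
#' @param seed integer master seed; phase streams (structure, intensities,
#'   detection) are derived by fixed offsets.
#' @return list of class `SimConfig`.
#' @export
sim_config <- function(n_genes = 10000L,
                       n_probes_per_gene = 1L,
                       extra_probe_fraction = 0.15,
                       chromosomes = NULL,
                       group_sizes = c("2N" = 12L, "CHD-" = 22L, AVSD = 7L,
                                       ASD = 8L, VSD = 6L),
                       trisomy_chrom = "chr21",
                       dosage_fraction = 0.30,
                       dosage_log2fc = log2(1.5),
                       n_de_per_contrast = c(AVSD = 400L, "ASD+VSD" = 450L),
                       de_log2fc_range = c(0.3, 1.0),
                       planted_cluster = NULL,
                       class_quota = c(IA = 0L, IB = 0L, IIA = 0L, IIB = 0L),
                       class_contrast = "AVSD",
                       noise_sd = c(0.1, 0.3),
                       baseline_range = c(6.5, 12),
                       low_expr_fraction = 0.10,
                       low_expr_range = c(4, 5.5),
                       detection_floor = 6.0,
                       seed = 1L) {
  if (is.null(chromosomes)) chromosomes <- default_chromosomes(n_genes)
  chromosomes <- round(chromosomes)
  storage.mode(chromosomes) <- "integer"
  if (sum(chromosomes) != n_genes)
    n_genes <- sum(chromosomes)  # explicit layout wins over the count
  if (any(chromosomes <= 0)) stop("chromosome gene counts must be positive")
  if (n_probes_per_gene < 1) stop("n_probes_per_gene must be >= 1")
  if (extra_probe_fraction < 0 || extra_probe_fraction > 1)
    stop("extra_probe_fraction must be in [0, 1]")
  if (any(group_sizes < 2)) stop("every group needs at least 2 samples")
  if (dosage_fraction < 0 || dosage_fraction > 1)
    stop("dosage_fraction must be in [0, 1]")
  if (!trisomy_chrom %in% names(chromosomes))
    stop("trisomy_chrom not in the chromosome layout")
  if (length(de_log2fc_range) != 2 || any(de_log2fc_range < 0) ||
      de_log2fc_range[1] > de_log2fc_range[2])
    stop("de_log2fc_range must be a non-negative interval")
  if (low_expr_fraction < 0 || low_expr_fraction >= 1)
    stop("low_expr_fraction must be in [0, 1)")
  groups <- names(group_sizes)
  for (ct in names(n_de_per_contrast)) contrast_groups(ct, groups)
  bad_class <- setdiff(names(class_quota), names(CLASS_EFFECTS))
  if (length(bad_class)) stop("unknown class(es): ", paste(bad_class, collapse = ", "))
  if (any(class_quota > 0)) {
    contrast_groups(class_contrast, groups)
    if (!"2N" %in% groups || !"CHD-" %in% groups)
      stop("class quotas need both '2N' and 'CHD-' groups")
  }
  if (!is.null(planted_cluster)) {
    pc <- planted_cluster
    need <- c("chromosome", "start", "k", "contrast")
    if (!is.list(pc) || !all(need %in% names(pc)))
      stop("planted_cluster needs fields: ", paste(need, collapse = ", "))
    if (!pc$chromosome %in% names(chromosomes))
      stop("planted cluster chromosome not in layout")
    if (pc$start < 1 || pc$start + pc$k - 1 > chromosomes[[pc$chromosome]])
      stop("planted cluster does not fit on ", pc$chromosome)
    if (!pc$contrast %in% names(n_de_per_contrast))
      stop("planted cluster contrast must be one of the DE contrasts")
  }
  structure(list(
    n_genes = as.integer(n_genes), n_probes_per_gene = as.integer(n_probes_per_gene),
    extra_probe_fraction = extra_probe_fraction, chromosomes = chromosomes,
    group_sizes = group_sizes, trisomy_chrom = trisomy_chrom,
    dosage_fraction = dosage_fraction, dosage_log2fc = dosage_log2fc,
    n_de_per_contrast = n_de_per_contrast, de_log2fc_range = de_log2fc_range,
    planted_cluster = planted_cluster, class_quota = class_quota,
    class_contrast = class_contrast, noise_sd = noise_sd,
    baseline_range = baseline_range, low_expr_fraction = low_expr_fraction,
    low_expr_range = low_expr_range, detection_floor = detection_floor,
    seed = as.integer(seed)), class = "SimConfig")
}

#' Generate a synthetic expression dataset with ground truth
#'
#' Intensities are additive on the log2 scale: per-gene baseline + per-probe
#' affinity + group effect + Normal(0, sigma_g) noise. All trisomic groups
#' receive the dosage effect on the dosage genes; case contrasts add their
#' planted DE effects to the case group(s); class-quota genes receive the
#' effect pairs of their class. Detection p-values are Uniform(0, 0.005) for
#' expressed probes and Uniform(0.2, 1) for probes below the detection floor.
#' Generation is bit-reproducible for a fixed config.
#'
#' @param config a [sim_config()] object.
#' @return list with `expression` ([ExpressionMatrix()], probe level),
#'   `annotation` (probe TSV-shaped data.frame), `samples` (sample sheet),
#'   `truth` (class `SyntheticTruth`: `de_flags` and `effect_log2fc` gene x
#'   contrast matrices, `chd_vs_2n_log2fc`, `class_label`, `cluster`,
#'   `dosage_genes`, `expressed`), and the `config`.
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  cfg <- config
  set.seed(cfg$seed)                       # phase 1: structure
  chroms <- cfg$chromosomes
  n_genes <- sum(chroms)
  gene <- sprintf("G%05d", seq_len(n_genes))
  chromosome <- rep(names(chroms), chroms)
  rank <- unlist(lapply(chroms, seq_len), use.names = FALSE)
  start <- (rank - 1L) * 50000L
  end <- start + 2000L

  cluster_genes <- character(0)
  if (!is.null(cfg$planted_cluster)) {
    pc <- cfg$planted_cluster
    sel <- chromosome == pc$chromosome &
      rank >= pc$start & rank <= pc$start + pc$k - 1L
    cluster_genes <- gene[sel]
  }

  n_low <- round(cfg$low_expr_fraction * n_genes)
  low_genes <- sample(setdiff(gene, cluster_genes), n_low)
  expressed <- !(gene %in% low_genes)
  mu <- numeric(n_genes)
  mu[expressed] <- stats::runif(sum(expressed), cfg$baseline_range[1],
                                cfg$baseline_range[2])
  mu[!expressed] <- stats::runif(sum(!expressed), cfg$low_expr_range[1],
                                 cfg$low_expr_range[2])
  sigma <- stats::runif(n_genes, cfg$noise_sd[1], cfg$noise_sd[2])

  tri_expr <- gene[expressed & chromosome == cfg$trisomy_chrom]
  dosage_genes <- sort(sample(tri_expr,
                              round(cfg$dosage_fraction * length(tri_expr))))

  contrasts <- names(cfg$n_de_per_contrast)
  eff <- matrix(0, n_genes, length(contrasts), dimnames = list(gene, contrasts))
  chd_eff <- stats::setNames(numeric(n_genes), gene)
  class_label <- rep("none", n_genes)
  pool <- setdiff(gene[expressed], cluster_genes)
  # class genes must not overlap dosage genes: their chd-vs-2N effect is the
  # class's own, or the truth label would contradict the planted effects
  class_pool <- setdiff(pool, dosage_genes)
  for (cl in names(cfg$class_quota)) {
    q <- cfg$class_quota[[cl]]
    if (q == 0) next
    if (length(class_pool) < q)
      stop(sprintf("class %s quota (%d) infeasible: only %d eligible genes left",
                   cl, q, length(class_pool)))
    gsel <- sample(class_pool, q)
    class_pool <- setdiff(class_pool, gsel)
    pool <- setdiff(pool, gsel)
    signs <- sample(c(-1, 1), q, replace = TRUE)
    ce <- CLASS_EFFECTS[[cl]]
    chd_eff[gsel] <- signs * ce[["chd"]]
    eff[gsel, cfg$class_contrast] <- signs * ce[["delta"]]
    class_label[match(gsel, gene)] <- cl
  }
  for (ct in contrasts) {
    nde <- cfg$n_de_per_contrast[[ct]]
    if (nde == 0) next
    if (length(pool) < nde)
      stop(sprintf("n_de_per_contrast[%s] = %d infeasible: only %d eligible genes",
                   ct, nde, length(pool)))
    gsel <- sample(pool, nde)              # contrasts may overlap, as observed
    mag <- stats::runif(nde, cfg$de_log2fc_range[1], cfg$de_log2fc_range[2])
    eff[gsel, ct] <- sample(c(-1, 1), nde, replace = TRUE) * mag
  }
  if (length(cluster_genes)) {
    mag <- stats::runif(length(cluster_genes), cfg$de_log2fc_range[1],
                        cfg$de_log2fc_range[2])
    eff[cluster_genes, cfg$planted_cluster$contrast] <- mag   # upregulated run
  }
  de_flags <- eff != 0

  groups <- names(cfg$group_sizes)
  geff <- matrix(0, n_genes, length(groups), dimnames = list(gene, groups))
  ds_groups <- setdiff(groups, "2N")
  dosage_vec <- (gene %in% dosage_genes) * cfg$dosage_log2fc + chd_eff
  for (g in ds_groups) geff[, g] <- geff[, g] + dosage_vec
  for (ct in contrasts)
    for (g in contrast_groups(ct, groups)) geff[, g] <- geff[, g] + eff[, ct]

  gidx <- rep(seq_len(n_genes), each = cfg$n_probes_per_gene)
  n_extra <- round(cfg$extra_probe_fraction * n_genes)
  if (n_extra > 0) gidx <- sort(c(gidx, sample(seq_len(n_genes), n_extra)))
  n_probes <- length(gidx)
  probe_id <- sprintf("P%06d", seq_len(n_probes))
  affinity <- stats::rnorm(n_probes, 0, 0.25)

  n_samples <- sum(cfg$group_sizes)
  sample_id <- sprintf("S%02d", seq_len(n_samples))
  sample_group <- rep(groups, cfg$group_sizes)

  set.seed(cfg$seed + 1L)                  # phase 2: intensities
  noise <- matrix(stats::rnorm(n_probes * n_samples, 0, sigma[gidx]),
                  n_probes, n_samples)
  values <- mu[gidx] + affinity + geff[gidx, sample_group, drop = FALSE] + noise
  dimnames(values) <- list(probe_id, sample_id)

  set.seed(cfg$seed + 2L)                  # phase 3: detection
  detection <- matrix(NA_real_, n_probes, n_samples,
                      dimnames = list(probe_id, sample_id))
  expr_probe <- expressed[gidx]
  detection[expr_probe, ] <- stats::runif(sum(expr_probe) * n_samples, 0, 0.005)
  detection[!expr_probe, ] <- stats::runif(sum(!expr_probe) * n_samples, 0.2, 1)

  annotation <- data.frame(probe_id = probe_id, gene = gene[gidx],
                           chromosome = chromosome[gidx], start = start[gidx],
                           end = end[gidx], stringsAsFactors = FALSE)
  samples <- data.frame(sample_id = sample_id, group = sample_group,
                        stringsAsFactors = FALSE)
  truth <- structure(list(
    genes = gene,
    contrasts = contrasts,
    expressed = stats::setNames(expressed, gene),
    de_flags = de_flags,
    effect_log2fc = eff,
    chd_vs_2n_log2fc = stats::setNames(dosage_vec, gene),
    class_label = stats::setNames(factor(class_label,
                                         levels = c(names(CLASS_EFFECTS), "none")),
                                  gene),
    cluster = if (length(cluster_genes))
      list(chromosome = cfg$planted_cluster$chromosome,
           members = cluster_genes,
           contrast = cfg$planted_cluster$contrast) else NULL,
    dosage_genes = dosage_genes), class = "SyntheticTruth")

  list(expression = ExpressionMatrix(values, detection),
       annotation = annotation, samples = samples, truth = truth,
       config = cfg)
}

#' Generate a gene-set catalog, optionally with one planted enriched set
#'
#' Random sets are drawn uniformly from the annotated genes. The planted set
#' contains `round(overlap_fraction * size)` genes sampled from
#' `enriched_set$targets` and the remainder from non-targets, so downstream
#' enrichment should rank it first when the targets are differentially
#' expressed.
#'
#' @param annotation probe annotation data.frame, or a character vector of
#'   gene ids.
#' @param n_sets number of random sets.
#' @param set_size_range integer interval of set sizes.
#' @param enriched_set optional `list(name =, targets =, size = NULL,
#'   overlap_fraction =)`; `size` defaults to `length(targets)`.
#' @param seed integer seed.
#' @return named list of character vectors (writable with [write_gmt()]);
#'   the enriched set, if any, comes first.
#' @export
generate_genesets <- function(annotation, n_sets = 50L,
                              set_size_range = c(5L, 100L),
                              enriched_set = NULL, seed = 1L) {
  genes <- if (is.data.frame(annotation)) unique(annotation$gene)
           else unique(as.character(annotation))
  if (set_size_range[2] > length(genes))
    stop("set sizes exceed the number of annotated genes")
  set.seed(seed)
  catalog <- list()
  if (!is.null(enriched_set)) {
    es <- enriched_set
    if (!all(c("name", "targets", "overlap_fraction") %in% names(es)))
      stop("enriched_set needs 'name', 'targets', 'overlap_fraction'")
    if (es$overlap_fraction < 0 || es$overlap_fraction > 1)
      stop("overlap_fraction must be in [0, 1]")
    size <- if (is.null(es$size)) length(es$targets) else es$size
    targets <- intersect(es$targets, genes)
    b <- round(es$overlap_fraction * size)
    if (b > length(targets))
      stop("overlap_fraction asks for more target genes than available")
    others <- setdiff(genes, targets)
    if (size - b > length(others))
      stop("enriched set size exceeds available non-target genes")
    members <- c(if (b > 0) sample(targets, b),
                 if (size - b > 0) sample(others, size - b))
    catalog[[es$name]] <- sort(members)
  }
  sizes <- sample(seq(set_size_range[1], set_size_range[2]), n_sets,
                  replace = TRUE)
  for (i in seq_len(n_sets))
    catalog[[sprintf("set_%03d", i)]] <- sort(sample(genes, sizes[i]))
  catalog
}

#' Synthetic stand-in for a fetal-heart expressed-gene list
#'
#' Builds a gene list covering `target_coverage` of the supplied target
#' genes (e.g. truly dysregulated genes) and `coverage` of the remaining
#' genes — a synthetic substitute for a heart-expression catalog compiled
#' from public repositories, used by [heart_overlap()].
#'
#' @param genes the gene universe.
#' @param target_genes genes to over-cover.
#' @param coverage background coverage fraction (default 0.5).
#' @param target_coverage coverage among targets (default 0.65).
#' @param seed integer seed.
#' @return character vector of gene ids.
#' @export
generate_heart_list <- function(genes, target_genes = character(0),
                                coverage = 0.5, target_coverage = 0.65,
                                seed = 1L) {
  set.seed(seed)
  targets <- intersect(target_genes, genes)
  others <- setdiff(genes, targets)
  sort(c(sample(targets, round(target_coverage * length(targets))),
         sample(others, round(coverage * length(others)))))
}

#' @export
print.SimConfig <- function(x, ...) {
  cat(sprintf("SimConfig: %d genes on %d chromosomes; groups: %s; seed %d\n",
              x$n_genes, length(x$chromosomes),
              paste(sprintf("%s=%d", names(x$group_sizes), x$group_sizes),
                    collapse = ", "),
              x$seed))
  invisible(x)
}

#' @export
print.SyntheticTruth <- function(x, ...) {
  cat(sprintf("SyntheticTruth: %d genes (%d expressed); DE per contrast: %s; classes: %s\n",
              length(x$genes), sum(x$expressed),
              paste(sprintf("%s=%d", colnames(x$de_flags),
                            colSums(x$de_flags)), collapse = ", "),
              paste(sprintf("%s=%d", levels(x$class_label),
                            as.integer(table(x$class_label))), collapse = ", ")))
  invisible(x)
}

#' Write a generated dataset to a directory of plain-text files
#'
#' @param dataset result of [generate_dataset()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly. Files: `expression.tsv`, `annotation.tsv`,
#'   `samples.tsv`, `truth.tsv`.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_expression_tsv(dataset$expression, file.path(dir, "expression.tsv"))
  write_annotation_tsv(dataset$annotation, file.path(dir, "annotation.tsv"))
  write_sample_sheet(dataset$samples, file.path(dir, "samples.tsv"))
  tr <- dataset$truth
  truth_df <- data.frame(gene = tr$genes, expressed = tr$expressed,
                         class = as.character(tr$class_label),
                         chd_vs_2n_log2fc = tr$chd_vs_2n_log2fc,
                         stringsAsFactors = FALSE)
  for (ct in tr$contrasts) {
    truth_df[[paste0("de_", ct)]] <- tr$de_flags[, ct]
    truth_df[[paste0("log2fc_", ct)]] <- tr$effect_log2fc[, ct]
  }
  data.table::fwrite(truth_df, file.path(dir, "truth.tsv"), sep = "\t")
  invisible(dir)
}
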