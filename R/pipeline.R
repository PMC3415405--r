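#' Pipeline configuration
#'
#' Collects every stage parameter with defaults at the analysis' canonical
#' values: detection calls at the 1% level on >= 4 arrays per group, a merge
#' decision at the 1% level, DE at the 5% level, run lengths k in {2, 3}.
#' Input is either a [sim_config()] (synthetic run) or a list of paths to
#' the expression/annotation/sample TSVs.
#'
#' @param sim a [sim_config()] object, or NULL when `input` paths are given.
#' @param input optional `list(expression =, annotation =, samples =)` paths.
#' @param alpha_detect detection-call significance level.
#' @param min_arrays minimum detected arrays per group for the call.
#' @param alpha_merge threshold for the group-merge decision.
#' @param alpha_de threshold declaring a transcript differentially expressed.
#' @param equality_mode,equality_band forwarded to [classification_rules()].
#' @param collapse probe-to-gene collapse rule.
#' @param k_values run lengths tested by the positional scan.
#' @param cluster_method,n_sims forwarded to [cluster_pvalue()].
#' @param n_genesets,geneset_size_range random catalog used when none is
#'   supplied.
#' @param gmt optional path to a GMT catalog (overrides the random catalog).
#' @param seed master seed; stage streams are derived by fixed offsets.
#' @param out_dir optional directory for artifacts (TSVs, report JSON).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(), input = NULL,
                            alpha_detect = 0.01, min_arrays = 4L,
                            alpha_merge = 0.01, alpha_de = 0.05,
                            equality_mode = "pvalue",
                            equality_band = c(0.95, 1.05),
                            collapse = "max-mean",
                            k_values = c(2L, 3L),
                            cluster_method = "exact", n_sims = 1e5,
                            n_genesets = 50L, geneset_size_range = c(5L, 100L),
                            gmt = NULL, seed = 1L, out_dir = NULL) {
  if (is.null(sim) && is.null(input))
    stop("either a simulation config or input paths are required")
  for (a in c("alpha_detect", "alpha_merge", "alpha_de")) {
    v <- get(a)
    if (!is.numeric(v) || length(v) != 1 || v <= 0 || v >= 1)
      stop(a, " must be a single value in (0, 1)")
  }
  if (!is.numeric(min_arrays) || min_arrays < 1)
    stop("min_arrays must be a positive count")
  if (!is.numeric(k_values) || any(k_values < 1))
    stop("k_values must be positive run lengths")
  collapse <- match.arg(collapse, c("max-mean", "first"))
  equality_mode <- match.arg(equality_mode, c("pvalue", "ratio-band", "both"))
  cluster_method <- match.arg(cluster_method, c("exact", "monte-carlo"))
  structure(mget(names(formals(sys.function()))), class = "pipeline_config")
}

read_stage_inputs <- function(cfg) {
  if (!is.null(cfg$sim)) {
    sim <- cfg$sim
    sim$seed <- cfg$seed
    return(generate_dataset(sim))
  }
  paths <- cfg$input
  need <- c("expression", "annotation", "samples")
  if (!all(need %in% names(paths)))
    stop("input needs paths: ", paste(need, collapse = ", "))
  list(expression = read_expression_tsv(paths$expression),
       annotation = read_annotation_tsv(paths$annotation),
       samples = read_sample_sheet(paths$samples),
       truth = NULL, config = NULL)
}

#' Run the full analysis pipeline
#'
#' Stage order follows the analysis narrative: expression calls ->
#' quantile normalization -> subgroup structure (pairwise tests among the
#' defect subgroups and the merge decision) -> probe-to-gene collapse ->
#' ANOVA and case-vs-`CHD-` contrasts -> DE selection -> dosage
#' classification -> positional cluster scan -> gene-set enrichment and
#' heart-list overlap. Identical config and seed reproduce the identical
#' report.
#'
#' @param cfg a [pipeline_config()].
#' @return list of class `pipeline_run` with `report` (plain-list summary,
#'   JSON-serializable) and `results` (stage objects: matrices, DE tables,
#'   classifications, scans, enrichments). When `cfg$out_dir` is set the
#'   report and key tables are written there.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  t0 <- proc.time()[["elapsed"]]
  stage_log <- list()
  tick <- function(name, counts) {
    stage_log[[name]] <<- c(list(elapsed_s = round(proc.time()[["elapsed"]] - t0, 3)),
                            counts)
  }

  data <- read_stage_inputs(cfg)
  m <- data$expression
  sheet <- validate_sample_sheet(data$samples, m)
  ann <- data$annotation
  tick("input", list(n_probes = nrow(m$values), n_samples = ncol(m$values)))

  called <- expression_call(m, sheet, alpha = cfg$alpha_detect,
                            min_arrays = cfg$min_arrays)
  tick("expression_call", list(n_probes = nrow(called$values),
                               n_dropped = attr(called, "n_dropped")))

  normalized <- quantile_normalize(called)
  tick("quantile_normalize", list(n_probes = nrow(normalized$values)))

  # Subgroup structure among the defect groups, at probe level: pairwise
  # tests with variance pooled over the defect subgroups, then the merge rule
  # on the weakest contrast.
  subgroup <- c("AVSD", "ASD", "VSD")
  merge <- NULL
  pair_counts <- NULL
  work_sheet <- sheet
  if (all(subgroup %in% sheet$group)) {
    pairs <- utils::combn(subgroup, 2, simplify = FALSE)
    pair_tabs <- lapply(pairs, function(pr)
      pooled_variance_ttest(normalized, sheet, pr[1], pr[2],
                            variance_groups = subgroup))
    names(pair_tabs) <- vapply(pairs, paste, character(1), collapse = "/")
    pair_counts <- vapply(pair_tabs, function(d) sum(d$p < cfg$alpha_merge),
                          integer(1))
    merge <- merge_decision(pair_tabs[["ASD/VSD"]]$p, alpha = cfg$alpha_merge,
                            contrast = "ASD/VSD")
    if (merge$merged)
      work_sheet$group[work_sheet$group %in% c("ASD", "VSD")] <- "ASD+VSD"
    tick("merge_decision", list(pairwise_below_alpha = as.list(pair_counts),
                                observed = merge$observed,
                                expected = merge$expected,
                                merged = merge$merged))
  }

  genes_m <- collapse_probes(normalized, ann, rule = cfg$collapse)
  background <- rownames(genes_m$values)
  tick("collapse_probes", list(n_genes = length(background)))

  case_groups <- intersect(c("AVSD", "ASD+VSD", "ASD", "VSD"),
                           unique(work_sheet$group))
  case_groups <- setdiff(case_groups, c("CHD-", "2N"))
  anova_tab <- NULL
  if ("CHD-" %in% work_sheet$group && length(case_groups) >= 1) {
    anova_tab <- anova_groups(genes_m, work_sheet, c("CHD-", case_groups))
    tick("anova", list(groups = length(case_groups) + 1L,
                       n_below_alpha = sum(anova_tab$p < cfg$alpha_de)))
  }

  de_tables <- list()
  de_tables_probe <- list()
  de_sets <- list()
  for (g in case_groups) {
    de_tables[[g]] <- pooled_variance_ttest(genes_m, work_sheet, g, "CHD-",
                                            variance_groups = c("CHD-", case_groups))
    de_tables_probe[[g]] <- pooled_variance_ttest(normalized, work_sheet, g, "CHD-",
                                                  variance_groups = c("CHD-", case_groups))
    de_sets[[g]] <- de_select(de_tables[[g]], cfg$alpha_de)
  }
  de_counts <- lapply(case_groups, function(g)
    list(probes = length(de_select(de_tables_probe[[g]], cfg$alpha_de)),
         genes = length(de_sets[[g]])))
  names(de_counts) <- case_groups
  overlap <- if (length(case_groups) >= 2)
    length(Reduce(intersect, de_sets[case_groups[1:2]])) else NULL
  tick("diffexp", list(de = de_counts, overlap_genes = overlap))

  classifications <- list()
  if (all(c("2N", "CHD-") %in% work_sheet$group)) {
    rules <- classification_rules(equality_band = cfg$equality_band,
                                  equality_mode = cfg$equality_mode,
                                  alpha = cfg$alpha_de)
    chd_2n <- pooled_variance_ttest(genes_m, work_sheet, "CHD-", "2N")
    for (g in case_groups) {
      case_2n <- pooled_variance_ttest(genes_m, work_sheet, g, "2N")
      classifications[[g]] <- classify_table(de_tables[[g]], chd_2n, case_2n,
                                             rules)
    }
    tick("classify", lapply(classifications, function(cl) as.list(cl$counts)))
  }

  scans <- list()
  for (g in case_groups)
    scans[[g]] <- triplet_scan(de_sets[[g]], background, ann,
                               k_values = cfg$k_values,
                               method = cfg$cluster_method,
                               n_sims = cfg$n_sims, seed = cfg$seed + 2L,
                               alpha = 0.05)
  flagged <- lapply(scans, function(s)
    s[s$flagged, c("chromosome", "k", "p"), drop = FALSE])
  tick("positional", lapply(flagged, function(f)
    if (nrow(f)) sprintf("%s k=%d p=%.3g", f$chromosome, f$k, f$p) else character(0)))

  catalog <- if (!is.null(cfg$gmt)) read_gmt(cfg$gmt) else
    generate_genesets(ann, n_sets = cfg$n_genesets,
                      set_size_range = cfg$geneset_size_range,
                      seed = cfg$seed + 1L)
  enrichments <- list()
  hearts <- list()
  heart_list <- NULL
  if (!is.null(data$truth)) {
    truth_de <- rownames(data$truth$de_flags)[rowSums(data$truth$de_flags) > 0]
    heart_list <- generate_heart_list(background,
                                      intersect(truth_de, background),
                                      seed = cfg$seed + 3L)
  }
  for (g in case_groups) {
    if (!length(de_sets[[g]])) next
    enrichments[[g]] <- geneset_enrichment(de_sets[[g]], background, catalog)
    if (!is.null(heart_list))
      hearts[[g]] <- heart_overlap(de_sets[[g]], heart_list, background)
  }
  tick("enrichment", list(
    n_sets = length(catalog),
    top_set = lapply(enrichments, function(e)
      list(set = e$set[1], p = e$p[1], factor = round(e$factor[1], 2))),
    heart_fraction = lapply(hearts, function(h) round(h$fraction, 4))))

  report <- list(
    tool = "chdsig", version = as.character(utils::packageVersion("chdsig")),
    seed = cfg$seed,
    parameters = list(alpha_detect = cfg$alpha_detect,
                      min_arrays = cfg$min_arrays,
                      alpha_merge = cfg$alpha_merge, alpha_de = cfg$alpha_de,
                      equality_mode = cfg$equality_mode,
                      collapse = cfg$collapse,
                      k_values = as.integer(cfg$k_values)),
    stages = stage_log)

  results <- list(expression = genes_m, normalized_probes = normalized,
                  sheet = work_sheet, merge = merge,
                  anova = anova_tab, de_tables = de_tables,
                  de_sets = de_sets, classifications = classifications,
                  scans = scans, enrichments = enrichments, hearts = hearts,
                  catalog = catalog, truth = data$truth)

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(report, file.path(cfg$out_dir, "run_report.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = 10)
    for (g in names(de_tables))
      data.table::fwrite(de_tables[[g]],
                         file.path(cfg$out_dir, sprintf("de_%s.tsv", gsub("[+]", "p", g))),
                         sep = "\t")
    for (g in names(scans)) {
      data.table::fwrite(scans[[g]],
                         file.path(cfg$out_dir, sprintf("positional_%s.tsv", gsub("[+]", "p", g))),
                         sep = "\t")
      write_runs_bed(scans[[g]],
                     file.path(cfg$out_dir, sprintf("runs_%s.bed", gsub("[+]", "p", g))))
    }
    for (g in names(enrichments))
      data.table::fwrite(enrichments[[g]],
                         file.path(cfg$out_dir, sprintf("enrichment_%s.tsv", gsub("[+]", "p", g))),
                         sep = "\t")
  }

  structure(list(report = report, results = results), class = "pipeline_run")
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat("chdsig pipeline run (seed", x$report$seed, ")\n")
  for (nm in names(x$report$stages))
    cat(sprintf("  %-18s %ss\n", nm, x$report$stages[[nm]]$elapsed_s))
  invisible(x)
}

#' Read a pipeline run configuration from JSON or YAML
#'
#' The file mirrors [pipeline_config()]; a `sim` block mirrors
#' [sim_config()]. YAML requires the `yaml` package; JSON uses jsonlite.
#'
#' @param path config file path (`.json`, `.yml` or `.yaml`).
#' @return A `pipeline_config` object.
#' @export
read_run_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yml", "yaml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("YAML configs need the 'yaml' package; use JSON instead")
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE)
  sim <- NULL
  if (!is.null(raw$sim)) {
    sim_args <- raw$sim
    for (nm in c("group_sizes", "chromosomes", "n_de_per_contrast", "class_quota"))
      if (!is.null(sim_args[[nm]])) sim_args[[nm]] <- unlist(sim_args[[nm]])
    if (!is.null(sim_args$planted_cluster))
      sim_args$planted_cluster <- as.list(sim_args$planted_cluster)
    sim <- do.call(sim_config, sim_args)
  }
  args <- raw[setdiff(names(raw), "sim")]
  args$sim <- sim
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(args), known)
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  do.call(pipeline_config, args)
}
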