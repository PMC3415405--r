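#' Per-chromosome enrichment of differentially expressed genes
#'
#' For each chromosome, tests whether the DE set over-represents that
#' chromosome's expressed genes: upper-tail hypergeometric p for drawing at
#' least `d_c` chromosome genes when `|de|` genes are drawn from the
#' background, plus the enrichment factor `(d_c/|de|) / (N_c/|background|)`.
#'
#' @param de character vector of DE gene ids (subset of `background`).
#' @param background character vector of expressed gene ids.
#' @param ann probe or gene annotation with `gene` and `chromosome`.
#' @return data.frame per chromosome: `chromosome`, `n_genes` (N_c), `n_de`
#'   (d_c), `factor`, `p`.
#' @export
chromosome_enrichment <- function(de, background, ann) {
  if (!all(de %in% background)) stop("de must be a subset of background")
  go <- gene_order_table(ann)
  if (!all(background %in% go$gene))
    stop("unannotated background gene(s): ",
         paste(utils::head(setdiff(background, go$gene), 5), collapse = ", "))
  chrom <- go$chromosome[match(background, go$gene)]
  n_bg <- length(background)
  n_de <- length(de)
  is_de <- background %in% de
  chroms <- unique(go$chromosome[match(background, go$gene)])
  res <- lapply(sort(chroms), function(cc) {
    on_c <- chrom == cc
    N_c <- sum(on_c)
    d_c <- sum(on_c & is_de)
    data.frame(chromosome = cc, n_genes = N_c, n_de = d_c,
               factor = if (n_de > 0) (d_c / n_de) / (N_c / n_bg) else NA_real_,
               p = stats::phyper(d_c - 1, N_c, n_bg - N_c, n_de,
                                 lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Maximal runs of contiguous flags
#'
#' Returns the maximal runs of consecutive `TRUE` values of length at least
#' `k`, in the supplied order (the annotation's within-chromosome expressed
#' gene order for positional scans). A run longer than `k` is reported once,
#' with its full length.
#'
#' @param flags logical vector ordered along one chromosome.
#' @param k minimum run length.
#' @return data.frame with `start` (1-based index) and `length`.
#' @export
find_runs <- function(flags, k = 2L) {
  flags <- as.logical(flags)
  if (k < 1) stop("k must be >= 1")
  if (!length(flags)) return(data.frame(start = integer(0), length = integer(0)))
  r <- rle(flags)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= k
  data.frame(start = starts[keep], length = r$lengths[keep])
}

# Number of binary sequences of n_zero zeros and n_one ones with no run of
# >= k consecutive ones: place the ones into the n_zero + 1 gaps with every
# gap < k (bounded stars-and-bars, inclusion-exclusion).
count_no_run <- function(n_one, n_zero, k) {
  jmax <- n_one %/% k
  j <- 0:jmax
  terms <- lchoose(n_zero + 1, j) + lchoose(n_one - j * k + n_zero, n_zero)
  sum((-1)^j * exp(terms))
}

#' Probability of at least one run of k contiguous DE genes
#'
#' Null model: the `d` DE positions are drawn uniformly without replacement
#' among the `N` ordered expressed-gene positions of a chromosome ("gene
#' expression and regulation are independent of localization"). The exact
#' value uses a closed-form inclusion-exclusion count of arrangements with
#' no run of length >= k, so it is available at any problem size; a
#' Monte-Carlo estimate (with binomial standard error) is provided as an
#' independent route.
#'
#' @param N number of expressed genes on the chromosome.
#' @param d number of DE genes among them (`k <= d <= N`).
#' @param k run length of interest (2 = doublet, 3 = triplet).
#' @param method `"exact"` (default) or `"monte-carlo"`.
#' @param n_sims Monte-Carlo draws (default 1e5).
#' @param seed optional seed for the Monte-Carlo draws.
#' @return list of class `cluster_test`: `N`, `d`, `k`, `p`, `method`,
#'   `n_sims`, `se` (NA for exact).
#' @export
cluster_pvalue <- function(N, d, k, method = c("exact", "monte-carlo"),
                           n_sims = 1e5, seed = NULL) {
  method <- match.arg(method)
  if (k < 1) stop("k must be >= 1")
  if (k > d) stop("k > d: a run of ", k, " DE genes is impossible with d = ", d)
  if (d > N) stop("d must not exceed N")
  if (method == "exact") {
    p <- 1 - count_no_run(d, N - d, k) / exp(lchoose(N, d))
    p <- min(max(p, 0), 1)
    se <- NA_real_
  } else {
    if (!is.null(seed)) set.seed(seed)
    hits <- 0L
    for (i in seq_len(n_sims)) {
      s <- sort.int(sample.int(N, d))
      hit <- if (k == 1L) TRUE else any(s[k:d] - s[seq_len(d - k + 1L)] == k - 1L)
      hits <- hits + hit
    }
    p <- hits / n_sims
    se <- sqrt(p * (1 - p) / n_sims)
  }
  structure(list(N = N, d = d, k = k, p = p, method = method,
                 n_sims = if (method == "exact") NA_integer_ else as.integer(n_sims),
                 se = se),
            class = "cluster_test")
}

#' @export
print.cluster_test <- function(x, ...) {
  cat(sprintf("P(>= 1 run of %d among %d DE of %d genes) = %.4g [%s%s]\n",
              x$k, x$d, x$N, x$p, x$method,
              if (is.na(x$se)) "" else sprintf(", se = %.2g", x$se)))
  invisible(x)
}

#' Scan chromosomes for doublets/triplets of contiguous DE genes
#'
#' Orders each chromosome's expressed genes by genomic position, finds
#' maximal runs of DE genes of length >= k for each requested k, and attaches
#' the null probability of observing at least one such run
#' ([cluster_pvalue()]; p = 1 when no run is observed). Chromosomes with
#' p < `alpha` and at least one observed run are flagged.
#'
#' @param de DE gene ids (subset of `background`); empty input returns an
#'   empty result.
#' @param background expressed gene ids (the positional universe).
#' @param ann annotation with `gene`, `chromosome`, `start`.
#' @param k_values run lengths to test (default `c(2, 3)`).
#' @param method,n_sims,seed forwarded to [cluster_pvalue()].
#' @param alpha flagging threshold (default 0.05).
#' @return data.frame per chromosome x k: `chromosome`, `k`, `n_genes`,
#'   `n_de`, `observed_runs`, `p`, `method`, `flagged`; detected runs (with
#'   member genes) are attached as attribute `runs`.
#' @export
triplet_scan <- function(de, background, ann, k_values = c(2L, 3L),
                         method = c("exact", "monte-carlo"),
                         n_sims = 1e5, seed = NULL, alpha = 0.05) {
  method <- match.arg(method)
  empty <- data.frame(chromosome = character(0), k = integer(0),
                      n_genes = integer(0), n_de = integer(0),
                      observed_runs = integer(0), p = numeric(0),
                      method = character(0), flagged = logical(0))
  if (!length(de)) return(empty)
  if (!all(de %in% background)) stop("de must be a subset of background")
  go <- gene_order_table(ann)
  go <- go[go$gene %in% background, ]
  rows <- list()
  run_rows <- list()
  for (cc in sort(unique(go$chromosome))) {
    gc <- go[go$chromosome == cc, ]
    gc <- gc[order(gc$start), ]
    flags <- gc$gene %in% de
    N_c <- nrow(gc)
    d_c <- sum(flags)
    for (k in k_values) {
      runs <- find_runs(flags, k)
      observed <- nrow(runs)
      if (observed > 0) {
        ct <- cluster_pvalue(N_c, d_c, k, method = method,
                             n_sims = n_sims, seed = seed)
        p <- ct$p
        used <- ct$method
        for (r in seq_len(observed)) {
          idx <- runs$start[r]:(runs$start[r] + runs$length[r] - 1L)
          run_rows[[length(run_rows) + 1L]] <- data.frame(
            chromosome = cc, k = as.integer(k), start = runs$start[r],
            length = runs$length[r],
            genes = paste(gc$gene[idx], collapse = ","),
            bp_start = gc$start[idx[1]], bp_end = gc$end[idx[length(idx)]],
            stringsAsFactors = FALSE)
        }
      } else {
        p <- 1
        used <- method
      }
      rows[[length(rows) + 1L]] <- data.frame(
        chromosome = cc, k = as.integer(k), n_genes = N_c, n_de = d_c,
        observed_runs = observed, p = p, method = used,
        flagged = observed > 0 & p < alpha, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "runs") <- if (length(run_rows)) do.call(rbind, run_rows) else NULL
  out
}

#' Write detected runs as a BED track
#'
#' @param scan result of [triplet_scan()] (its `runs` attribute is used).
#' @param path output BED file (0-based half-open, as the annotation).
#' @return `path`, invisibly; no file is written when no runs were found.
#' @export
write_runs_bed <- function(scan, path) {
  runs <- attr(scan, "runs")
  if (is.null(runs)) return(invisible(path))
  bed <- data.frame(chrom = runs$chromosome, start = runs$bp_start,
                    end = runs$bp_end,
                    name = paste0("k", runs$k, ":", runs$genes))
  data.table::fwrite(bed, path, sep = "\t", col.names = FALSE)
  invisible(path)
}
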