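group_value_matrix <- function(m, sheet, group) {
  ids <- intersect(group_samples(sheet, group), colnames(m$values))
  if (!length(ids)) stop(sprintf("group '%s' has no samples in the matrix", group))
  m$values[, ids, drop = FALSE]
}

pooled_within_group <- function(m, sheet, groups) {
  ss <- 0
  df <- 0L
  means <- list()
  ns <- integer(0)
  for (g in groups) {
    xg <- group_value_matrix(m, sheet, g)
    n <- ncol(xg)
    if (n < 2) stop(sprintf("variance group '%s' has fewer than 2 samples", g))
    mu <- rowMeans(xg)
    ss <- ss + rowSums((xg - mu)^2)
    df <- df + (n - 1L)
    means[[g]] <- mu
    ns[g] <- n
  }
  list(s2 = ss / df, df = df, means = means, n = ns, ss = ss)
}

#' Pairwise t-test with a global common variance
#'
#' Per-transcript two-sample t-test whose variance is the within-group
#' variance pooled across `variance_groups` (by default every group in the
#' sheet), i.e. a single global estimate of the common variance reused for
#' each pairwise contrast:
#' \deqn{s^2 = \sum_g (n_g - 1) s_g^2 / \sum_g (n_g - 1), \quad
#'       t = (\bar x_A - \bar x_B) / \sqrt{s^2 (1/n_A + 1/n_B)}}
#' with \eqn{df = \sum_g (n_g - 1)}. Setting `variance_groups` to just the
#' two compared groups recovers the ordinary pooled two-sample t-test.
#'
#' @param m gene- or probe-level [ExpressionMatrix()] (log2 scale).
#' @param sheet sample sheet.
#' @param group_a,group_b group labels to compare (ratio reported as A over B).
#' @param variance_groups groups entering the pooled variance; must contain
#'   `group_a` and `group_b`. Default: all groups in the sheet.
#' @return data.frame with one row per transcript: group means, pooled `s2`,
#'   `df`, `t`, two-sided `p`, linear-scale geometric `ratio`
#'   (\eqn{2^{\bar x_A - \bar x_B}}) and a `zero_variance` flag (such
#'   transcripts get t = 0, p = 1 when the means agree; differing means with
#'   zero pooled variance raise an error). The contrast name is attached as
#'   attribute `contrast`.
#' @export
pooled_variance_ttest <- function(m, sheet, group_a, group_b,
                                  variance_groups = NULL) {
  m <- as_expression_matrix(m)
  sheet <- validate_sample_sheet(sheet)
  if (is.null(variance_groups)) variance_groups <- unique(sheet$group)
  if (!all(c(group_a, group_b) %in% variance_groups))
    stop("group_a and group_b must be among variance_groups")
  pw <- pooled_within_group(m, sheet, variance_groups)
  ma <- pw$means[[group_a]]
  mb <- pw$means[[group_b]]
  na <- pw$n[[group_a]]
  nb <- pw$n[[group_b]]
  se <- sqrt(pw$s2 * (1 / na + 1 / nb))
  zero <- pw$s2 <= 0
  if (any(zero & abs(ma - mb) > 0))
    stop("zero pooled variance with differing means for transcript(s): ",
         paste(utils::head(rownames(m$values)[zero & abs(ma - mb) > 0], 5),
               collapse = ", "))
  tt <- ifelse(zero, 0, (ma - mb) / se)
  p <- ifelse(zero, 1, 2 * stats::pt(-abs(tt), df = pw$df))
  if (any(zero))
    warning(sum(zero), " transcript(s) with zero pooled variance; p set to 1")
  out <- data.frame(
    transcript = rownames(m$values),
    mean_a = unname(ma), mean_b = unname(mb), n_a = na, n_b = nb,
    s2 = unname(pw$s2), df = pw$df, t = unname(tt), p = unname(p),
    ratio = unname(2^(ma - mb)),
    zero_variance = unname(zero),
    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "contrast") <- paste0(group_a, "_vs_", group_b)
  out
}

#' Per-transcript one-way ANOVA across groups
#'
#' Standard one-way fixed-effects F test per transcript:
#' \eqn{F = MS_{between} / MS_{within}} with
#' \eqn{df = (k - 1, \sum_g (n_g - 1))}. On a two-group design `F`
#' equals the square of the [pooled_variance_ttest()] statistic computed with
#' the same two variance groups.
#'
#' @param m [ExpressionMatrix()] (log2 scale).
#' @param sheet sample sheet.
#' @param groups group labels entering the ANOVA (>= 2, each >= 2 samples).
#' @return data.frame with `transcript`, per-group means, `F`, `df1`, `df2`,
#'   `p`, and a `zero_variance` flag (all-constant transcripts get F = 0,
#'   p = 1).
#' @export
anova_groups <- function(m, sheet, groups) {
  m <- as_expression_matrix(m)
  sheet <- validate_sample_sheet(sheet)
  if (length(groups) < 2) stop("ANOVA needs at least 2 groups")
  pw <- pooled_within_group(m, sheet, groups)
  n_tot <- sum(pw$n)
  grand <- Reduce(`+`, Map(function(mu, n) mu * n, pw$means, as.list(pw$n))) / n_tot
  ssb <- Reduce(`+`, Map(function(mu, n) n * (mu - grand)^2, pw$means, as.list(pw$n)))
  df1 <- length(groups) - 1L
  df2 <- pw$df
  msw <- pw$ss / df2
  zero <- msw <= 0
  if (any(zero & ssb > 0))
    stop("zero within-group variance with differing group means for: ",
         paste(utils::head(rownames(m$values)[zero & ssb > 0], 5), collapse = ", "))
  f <- ifelse(zero, 0, (ssb / df1) / msw)
  p <- ifelse(zero, 1, stats::pf(f, df1, df2, lower.tail = FALSE))
  out <- data.frame(transcript = rownames(m$values), stringsAsFactors = FALSE,
                    row.names = NULL)
  for (g in groups) out[[paste0("mean_", g)]] <- unname(pw$means[[g]])
  out$F <- unname(f)
  out$df1 <- df1
  out$df2 <- df2
  out$p <- unname(p)
  out$zero_variance <- unname(zero)
  out
}

#' Expected number of sub-threshold p-values under the global null
#'
#' @param m number of tests performed.
#' @param alpha significance level in (0, 1).
#' @return `round(m * alpha)` as an integer (e.g. 112 for 11,224 tests at the
#'   1% level).
#' @export
expected_null_count <- function(m, alpha) {
  if (m < 0) stop("m must be non-negative")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  as.integer(round(m * alpha))
}

#' Group-merge decision from p-value uniformity
#'
#' Decides whether a pairwise contrast shows *less* differential expression
#' than expected under the global null: with `D` the observed number of
#' p-values below `alpha` and `E = round(m * alpha)` the null expectation,
#' the two groups are merged when `D < E`. The empirical CDF of the p-values
#' and a one-sided lower-tail binomial p-value for `D` versus
#' `Binomial(m, alpha)` are attached as diagnostics (the binomial p is
#' informative, not a gate).
#'
#' @param pvals per-transcript p-values in \[0, 1\] (non-empty).
#' @param alpha threshold defining "differentially expressed" (default 0.01).
#' @param contrast optional contrast label carried into the result.
#' @return Object of class `merge_decision`: list with `contrast`, `m`,
#'   `observed`, `expected`, `alpha`, `merged`, `binomial_p`, `ecdf_curve`.
#' @export
merge_decision <- function(pvals, alpha = 0.01, contrast = NA_character_) {
  pvals <- as.numeric(pvals)
  if (!length(pvals)) stop("merge_decision needs at least one p-value")
  if (anyNA(pvals) || any(pvals < 0 | pvals > 1))
    stop("p-values must lie in [0, 1]")
  m <- length(pvals)
  D <- sum(pvals < alpha)
  E <- expected_null_count(m, alpha)
  structure(list(
    contrast = contrast,
    m = m,
    observed = D,
    expected = E,
    alpha = alpha,
    merged = D < E,
    binomial_p = stats::pbinom(D, m, alpha),
    ecdf_curve = data.frame(p = sort(pvals), cdf = seq_len(m) / m)
  ), class = "merge_decision")
}

#' @export
print.merge_decision <- function(x, ...) {
  cat(sprintf("Merge decision%s: D = %d observed p < %g vs E = %d expected -> %s (binomial p = %.3g)\n",
              if (is.na(x$contrast)) "" else paste0(" [", x$contrast, "]"),
              x$observed, x$alpha, x$expected,
              if (x$merged) "MERGE" else "keep separate", x$binomial_p))
  invisible(x)
}

#' Principal component scores of sample expression profiles
#'
#' Transcripts are centered (per row) before the decomposition; component
#' signs are fixed by forcing the loading of largest magnitude on each
#' component to be positive, so scores are fully deterministic.
#'
#' @param m [ExpressionMatrix()].
#' @param n_components number of components to return.
#' @return list with `scores` (samples x components), `loadings`,
#'   `explained_variance` (per component) and `explained_fraction`.
#' @export
pca_scores <- function(m, n_components = 2L) {
  m <- as_expression_matrix(m)
  x <- t(m$values)                       # samples x transcripts
  if (n_components > min(dim(x)))
    stop(sprintf("n_components = %d exceeds min(samples, transcripts) = %d",
                 n_components, min(dim(x))))
  xc <- scale(x, center = TRUE, scale = FALSE)
  pc <- stats::prcomp(xc, center = FALSE, scale. = FALSE)
  k <- n_components
  rot <- pc$rotation[, seq_len(k), drop = FALSE]
  sco <- pc$x[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(rot[, j]))
    if (rot[i, j] < 0) {
      rot[, j] <- -rot[, j]
      sco[, j] <- -sco[, j]
    }
  }
  list(scores = sco, loadings = rot,
       explained_variance = pc$sdev[seq_len(k)]^2,
       explained_fraction = (pc$sdev^2 / sum(pc$sdev^2))[seq_len(k)],
       total_variance = sum(pc$sdev^2))
}

#' Threshold p-values into a differentially-expressed id set
#'
#' @param pvals named numeric vector of p-values, or a data.frame with
#'   `transcript` and `p` columns (e.g. from [pooled_variance_ttest()]).
#' @param alpha DE threshold (default 0.05).
#' @return Character vector of transcript ids with p < alpha.
#' @export
de_select <- function(pvals, alpha = 0.05) {
  if (is.data.frame(pvals)) {
    stopifnot(all(c("transcript", "p") %in% names(pvals)))
    return(pvals$transcript[pvals$p < alpha])
  }
  if (is.null(names(pvals))) stop("p-value vector must be named by transcript")
  names(pvals)[pvals < alpha]
}

#' Benjamini-Hochberg adjusted p-values (informational column)
#'
#' @param p numeric p-values.
#' @return BH-adjusted q-values; no gatekeeping in this pipeline uses them.
#' @keywords internal
bh_adjust <- function(p) stats::p.adjust(p, method = "BH")
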