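#' Rules for the four-class dosage classification
#'
#' Differentially expressed genes (case vs `CHD-`) are partitioned by two
#' questions: is the case-vs-`CHD-` effect larger in magnitude than the
#' `CHD-`-vs-`2N` effect (class I) or smaller (class II), and is the relevant
#' secondary contrast "equal" (subclass B) or not (subclass A)? For class I
#' the equality criterion is applied to `CHD-` vs `2N`; for class II, to
#' case (`CHD+`) vs `2N`. "Equal" can mean p >= alpha (`pvalue`), a geometric
#' ratio inside `equality_band` (`ratio-band`), or both.
#'
#' @param equality_band linear-scale ratio interval treated as "no change"
#'   (default \[0.95, 1.05\]; must contain 1).
#' @param equality_mode `"pvalue"` (default), `"ratio-band"`, or `"both"`.
#' @param alpha significance level for the DE and equality calls (default 0.05).
#' @return list of class `classification_rules`.
#' @export
classification_rules <- function(equality_band = c(0.95, 1.05),
                                 equality_mode = c("pvalue", "ratio-band", "both"),
                                 alpha = 0.05) {
  equality_mode <- match.arg(equality_mode)
  if (length(equality_band) != 2 || equality_band[1] > 1 || equality_band[2] < 1)
    stop("equality_band must be an interval containing 1")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  structure(list(equality_band = equality_band, equality_mode = equality_mode,
                 alpha = alpha), class = "classification_rules")
}

equality_call <- function(ratio, p, rules) {
  by_p <- !is.na(p) & p >= rules$alpha
  by_band <- ratio >= rules$equality_band[1] & ratio <= rules$equality_band[2]
  switch(rules$equality_mode,
         "pvalue" = by_p,
         "ratio-band" = by_band,
         "both" = by_p & by_band)
}

#' Classify genes by effect-magnitude comparison and equality calls
#'
#' Vectorized classification of one case contrast. Effect magnitudes are
#' compared on the |log2 ratio| scale; an exact tie is resolved to class II
#' (conservative) and flagged. Genes not differentially expressed in the
#' case-vs-`CHD-` contrast get class `none`.
#'
#' @param genes data.frame with columns `gene`, `ratio_chd_2n`, `p_chd_2n`
#'   (the `CHD-` vs `2N` contrast), `ratio_case_chd`, `p_case_chd` (the case
#'   vs `CHD-` contrast), and optionally `ratio_case_2n`, `p_case_2n`
#'   (case vs `2N`; the ratio is derived as the product when absent, the p is
#'   required for the class-II equality call under `pvalue`/`both` modes).
#' @param rules a [classification_rules()] object.
#' @return The input with added columns `ratio_case_2n`, `class`
#'   (factor IA/IB/IIA/IIB/none) and `magnitude_tie`.
#' @export
classify_genes <- function(genes, rules = classification_rules()) {
  stopifnot(is.data.frame(genes))
  need <- c("gene", "ratio_chd_2n", "p_chd_2n", "ratio_case_chd", "p_case_chd")
  if (!all(need %in% names(genes)))
    stop("missing columns: ", paste(setdiff(need, names(genes)), collapse = ", "))
  if (any(genes$ratio_chd_2n <= 0 | genes$ratio_case_chd <= 0))
    stop("ratios must be positive (geometric, linear scale)")
  if (!"ratio_case_2n" %in% names(genes))
    genes$ratio_case_2n <- genes$ratio_case_chd * genes$ratio_chd_2n
  if (!"p_case_2n" %in% names(genes)) {
    if (rules$equality_mode != "ratio-band")
      stop("p_case_2n is required under equality_mode = '", rules$equality_mode, "'")
    genes$p_case_2n <- NA_real_
  }

  de <- genes$p_case_chd < rules$alpha
  l_case <- abs(log2(genes$ratio_case_chd))
  l_chd <- abs(log2(genes$ratio_chd_2n))
  tie <- l_case == l_chd
  class_one <- l_case > l_chd
  eq_chd <- equality_call(genes$ratio_chd_2n, genes$p_chd_2n, rules)
  eq_case <- equality_call(genes$ratio_case_2n, genes$p_case_2n, rules)

  cls <- rep("none", nrow(genes))
  cls[de & class_one & !eq_chd] <- "IA"
  cls[de & class_one & eq_chd] <- "IB"
  cls[de & !class_one & !eq_case] <- "IIA"
  cls[de & !class_one & eq_case] <- "IIB"
  genes$class <- factor(cls, levels = c("IA", "IB", "IIA", "IIB", "none"))
  genes$magnitude_tie <- de & tie
  genes
}

#' Classification table from pairwise differential-expression results
#'
#' Joins the three pairwise contrasts of one case group, applies
#' [classify_genes()], and tabulates the class sizes (the four classes
#' partition the DE set; class IIB can legitimately be empty).
#'
#' @param case_vs_chd,chd_vs_2n data.frames from [pooled_variance_ttest()]
#'   (columns `transcript`, `ratio`, `p`) for case vs `CHD-` and `CHD-` vs
#'   `2N`.
#' @param case_vs_2n optional same-shape data.frame for case vs `2N`;
#'   required unless `rules$equality_mode == "ratio-band"`.
#' @param rules a [classification_rules()] object.
#' @return list with `genes` (the classified table) and `counts` (named
#'   vector over IA, IB, IIA, IIB, none).
#' @export
classify_table <- function(case_vs_chd, chd_vs_2n, case_vs_2n = NULL,
                           rules = classification_rules()) {
  for (d in list(case_vs_chd, chd_vs_2n))
    if (!all(c("transcript", "ratio", "p") %in% names(d)))
      stop("contrast tables need 'transcript', 'ratio' and 'p' columns")
  genes <- data.frame(gene = case_vs_chd$transcript,
                      ratio_case_chd = case_vs_chd$ratio,
                      p_case_chd = case_vs_chd$p,
                      stringsAsFactors = FALSE)
  i <- match(genes$gene, chd_vs_2n$transcript)
  if (anyNA(i)) stop("chd_vs_2n is missing ", sum(is.na(i)), " transcript(s)")
  genes$ratio_chd_2n <- chd_vs_2n$ratio[i]
  genes$p_chd_2n <- chd_vs_2n$p[i]
  if (!is.null(case_vs_2n)) {
    j <- match(genes$gene, case_vs_2n$transcript)
    if (anyNA(j)) stop("case_vs_2n is missing ", sum(is.na(j)), " transcript(s)")
    genes$ratio_case_2n <- case_vs_2n$ratio[j]
    genes$p_case_2n <- case_vs_2n$p[j]
  }
  genes <- classify_genes(genes, rules)
  counts <- table(genes$class)
  list(genes = genes, counts = stats::setNames(as.integer(counts), names(counts)))
}
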