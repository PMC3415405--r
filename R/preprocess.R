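#' Expression call from detection p-values
#'
#' Retains the probes whose signal is called significant (detection p-value
#' below `alpha`) in at least `min_arrays` samples of **each** named group.
#' This mirrors the bead-array convention of requiring reproducible detection
#' within every analysis group before a transcript enters the statistics
#' (defaults: detection at the 1% level on at least 4 arrays per group).
#'
#' @param m [ExpressionMatrix()] with detection p-values.
#' @param sheet sample sheet (`sample_id`, `group`).
#' @param groups character vector of group labels to screen; defaults to all
#'   groups present in the sheet.
#' @param alpha detection significance level (default 0.01).
#' @param min_arrays minimum number of detected arrays per group (default 4;
#'   use 9 for the larger trisomic-vs-euploid design).
#' @return The filtered `ExpressionMatrix` (samples unchanged, probe order
#'   preserved), with attribute `n_dropped`.
#' @export
expression_call <- function(m, sheet, groups = NULL, alpha = 0.01, min_arrays = 4L) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (is.null(m$detection_p)) stop("expression_call needs detection p-values")
  sheet <- validate_sample_sheet(sheet, m)
  if (is.null(groups)) groups <- unique(sheet$group)
  keep <- rep(TRUE, nrow(m$values))
  for (g in groups) {
    ids <- intersect(group_samples(sheet, g), colnames(m$values))
    if (length(ids) < min_arrays)
      stop(sprintf("group '%s' has %d samples, fewer than min_arrays = %d",
                   g, length(ids), min_arrays))
    detected <- rowSums(m$detection_p[, ids, drop = FALSE] < alpha)
    keep <- keep & (detected >= min_arrays)
  }
  out <- m[keep, ]
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Quantile normalization
#'
#' Forces every sample to share one empirical intensity distribution: the
#' reference vector is the across-sample mean of the sorted columns, and each
#' sample's values are replaced by the reference values at their ranks.
#' Tied observations within a sample receive the mean of the reference values
#' over the tied span, so the transform is rank-preserving and idempotent.
#'
#' @param m [ExpressionMatrix()] or numeric matrix; at least 2 samples, no
#'   missing values (imputation is out of scope).
#' @return Object of the same class with normalized values (detection
#'   p-values, if any, are carried through untouched).
#' @export
quantile_normalize <- function(m) {
  is_em <- inherits(m, "ExpressionMatrix")
  x <- if (is_em) m$values else as.matrix(m)
  if (ncol(x) < 2) stop("quantile normalization needs at least 2 samples")
  if (anyNA(x)) stop("missing values are not supported")
  ref <- rowMeans(apply(x, 2, sort, method = "quick"))
  out <- x
  for (j in seq_len(ncol(x))) {
    o <- order(x[, j])
    sorted <- x[o, j]
    # tied spans are adjacent after sorting; average the reference over each
    grp <- cumsum(!duplicated(sorted))
    out[o, j] <- stats::ave(ref, grp, FUN = mean)
  }
  if (is_em) ExpressionMatrix(out, m$detection_p) else out
}

#' Collapse probe-level rows to one row per gene
#'
#' With `rule = "max-mean"` (the common bead-array summarization) the probe
#' with the highest mean intensity represents its gene; `rule = "first"`
#' keeps the first annotated probe. The probe-to-gene mapping used is
#' attached as attribute `probe_map`.
#'
#' @param m probe-level [ExpressionMatrix()].
#' @param ann annotation data.frame mapping `probe_id` to `gene`.
#' @param rule `"max-mean"` or `"first"`.
#' @return Gene-level `ExpressionMatrix` (rownames are gene symbols).
#' @export
collapse_probes <- function(m, ann, rule = c("max-mean", "first")) {
  rule <- match.arg(rule)
  stopifnot(inherits(m, "ExpressionMatrix"))
  validate_annotation(ann)
  probes <- rownames(m$values)
  idx <- match(probes, ann$probe_id)
  if (anyNA(idx))
    stop("unannotated probe(s): ",
         paste(utils::head(probes[is.na(idx)], 5), collapse = ", "))
  gene <- ann$gene[idx]
  score <- if (rule == "max-mean") rowMeans(m$values) else -seq_along(probes)
  ord <- order(gene, -score)
  pick <- ord[!duplicated(gene[ord])]
  pick <- sort(pick)  # preserve input probe order among representatives
  out <- m[pick, ]
  map <- data.frame(gene = gene[pick], probe_id = probes[pick],
                    stringsAsFactors = FALSE)
  rownames(out$values) <- map$gene
  if (!is.null(out$detection_p)) rownames(out$detection_p) <- map$gene
  attr(out, "probe_map") <- map
  out
}
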