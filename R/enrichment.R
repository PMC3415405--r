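#' GOrilla-style enrichment factor
#'
#' Fold over-representation of a gene set within a target list, from the
#' quadruple (N, B, n, b): N background genes of which B belong to the set,
#' n target (differentially expressed) genes of which b belong to the set.
#' \deqn{factor = (b/n) / (B/N)}
#' Summaries print it to 2 decimals; full precision is kept internally, and
#' the identity `b = factor * B * n / N` holds exactly.
#'
#' @param N total background genes (> 0).
#' @param B background genes in the set (0 < B <= N).
#' @param n target genes (0 < n <= N).
#' @param b target genes in the set (0 <= b <= min(B, n)).
#' @return The enrichment factor (numeric).
#' @export
enrichment_factor <- function(N, B, n, b) {
  if (n <= 0 || B <= 0) stop("n and B must be positive")
  if (N < n || N < B) stop("N must be at least max(B, n)")
  if (b < 0 || b > min(B, n)) stop("b must lie in [0, min(B, n)]")
  (b / n) / (B / N)
}

#' Hypergeometric upper-tail enrichment p-value
#'
#' \eqn{P(X \ge b)} for \eqn{X \sim} Hypergeometric(N, B, n): the chance of
#' drawing at least `b` set members when `n` genes are sampled without
#' replacement from a background of `N` containing `B` set members.
#' Delegates to [stats::phyper()], which works on stable log-probabilities.
#'
#' @inheritParams enrichment_factor
#' @return p-value in (0, 1\]; `b = 0` gives exactly 1.
#' @export
hypergeom_tail <- function(N, B, n, b) {
  if (n <= 0 || B <= 0) stop("n and B must be positive")
  if (N < n || N < B) stop("N must be at least max(B, n)")
  if (b < 0 || b > min(B, n)) stop("b must lie in [0, min(B, n)]")
  stats::phyper(b - 1, B, N - B, n, lower.tail = FALSE)
}

#' Gene-set enrichment of a DE list against a GMT catalog
#'
#' Each set is first intersected with the background (so B counts only
#' expressed set members), then scored with the enrichment factor and the
#' hypergeometric upper tail. Records are sorted by p; a Benjamini-Hochberg
#' q column is attached for information only.
#'
#' @param de DE gene ids (subset of `background`).
#' @param background expressed-gene universe (non-empty).
#' @param catalog named list of gene sets (see [read_gmt()]).
#' @return data.frame of class `enrichment_table`: `set`, `N`, `B`, `n`, `b`,
#'   `factor`, `p`, `q`, sorted by `p`. Sets with no expressed member get
#'   `factor = NA`, `p = 1`.
#' @export
geneset_enrichment <- function(de, background, catalog) {
  if (!length(background)) stop("background must be non-empty")
  background <- unique(background)
  de <- unique(de)
  if (!all(de %in% background)) stop("de must be a subset of background")
  if (is.null(names(catalog))) stop("catalog sets must be named")
  N <- length(background)
  n <- length(de)
  rows <- lapply(names(catalog), function(nm) {
    set_bg <- intersect(catalog[[nm]], background)
    B <- length(set_bg)
    b <- length(intersect(de, set_bg))
    data.frame(set = nm, N = N, B = B, n = n, b = b,
               factor = if (B > 0 && n > 0) enrichment_factor(N, B, n, b) else NA_real_,
               p = if (B > 0 && n > 0) hypergeom_tail(N, B, n, b) else 1,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p)
  out <- out[order(out$p, out$set), ]
  rownames(out) <- NULL
  class(out) <- c("enrichment_table", "data.frame")
  out
}

#' @export
print.enrichment_table <- function(x, n = 10L, ...) {
  cat(sprintf("Gene-set enrichment: %d sets, background N = %d, target n = %d\n",
              nrow(x), x$N[1], x$n[1]))
  top <- utils::head(x, n)
  for (i in seq_len(nrow(top)))
    cat(sprintf("  %-30s p=%.3g  %.2f (%d,%d,%d,%d)\n", top$set[i], top$p[i],
                top$factor[i], top$N[i], top$B[i], top$n[i], top$b[i]))
  invisible(x)
}

#' Overlap of DE genes with a (fetal) heart expression list
#'
#' Reports the fraction of DE genes present in the heart-expressed list and
#' the corresponding enrichment record against the expressed background.
#'
#' @param de DE gene ids (non-empty, subset of `background`).
#' @param heart_list gene ids expressed in heart tissue (intersected with the
#'   background before counting).
#' @param background expressed-gene universe.
#' @return list with `fraction` (|de intersect heart| / |de|) and `record`
#'   (one-row data.frame as in [geneset_enrichment()]).
#' @export
heart_overlap <- function(de, heart_list, background) {
  if (!length(de)) stop("de must be non-empty")
  if (!all(de %in% background)) stop("de must be a subset of background")
  fraction <- length(intersect(de, heart_list)) / length(unique(de))
  record <- geneset_enrichment(de, background, list(heart = unique(heart_list)))
  list(fraction = fraction, record = record[, setdiff(names(record), "q")])
}
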