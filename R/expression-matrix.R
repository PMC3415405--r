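#' Probe- or gene-level expression matrix with detection p-values
#'
#' Lightweight container pairing a log2-intensity matrix with an optional
#' matrix of per-probe, per-sample detection p-values (the significance of
#' signal above array background, as exported by bead-array scanners).
#' Rows are probes (or genes after [collapse_probes()]), columns are samples;
#' both dimensions carry unique identifiers in their dimnames.
#'
#' @param values numeric matrix of log2 intensities with rownames (probe ids)
#'   and colnames (sample ids).
#' @param detection_p optional numeric matrix of detection p-values in
#'   \[0, 1\], same shape and dimnames as `values`.
#' @return An object of class `ExpressionMatrix`: a list with elements
#'   `values` and `detection_p`.
#' @examples
#' v <- matrix(rnorm(6, 8), 3, 2, dimnames = list(paste0("P", 1:3), c("a", "b")))
#' em <- ExpressionMatrix(v)
#' dim(em)
#' @export
ExpressionMatrix <- function(values, detection_p = NULL) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("'values' must be numeric")
  if ((nrow(values) > 0 && is.null(rownames(values))) ||
      (ncol(values) > 0 && is.null(colnames(values))))
    stop("'values' must have probe rownames and sample colnames")
  if (anyDuplicated(rownames(values))) stop("duplicate probe ids")
  if (anyDuplicated(colnames(values))) stop("duplicate sample ids")
  if (!is.null(detection_p)) {
    detection_p <- as.matrix(detection_p)
    if (!identical(dim(detection_p), dim(values)))
      stop("'detection_p' and 'values' must share their shape")
    if (!identical(dimnames(detection_p), dimnames(values)))
      stop("'detection_p' and 'values' must share dimnames")
    if (length(detection_p)) {
      rng <- range(detection_p)
      if (is.na(rng[1]) || rng[1] < 0 || rng[2] > 1)
        stop("'detection_p' must lie in [0, 1] with no missing values")
    }
  }
  structure(list(values = values, detection_p = detection_p),
            class = "ExpressionMatrix")
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' @export
dimnames.ExpressionMatrix <- function(x) dimnames(x$values)

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d features x %d samples (%s detection p-values)\n",
              nrow(x$values), ncol(x$values),
              if (is.null(x$detection_p)) "without" else "with"))
  invisible(x)
}

#' Subset an ExpressionMatrix by probes and/or samples
#'
#' @param x an [ExpressionMatrix()].
#' @param i,j probe / sample indices (any form accepted by matrix indexing).
#' @param ... ignored.
#' @return An `ExpressionMatrix` restricted to the requested rows/columns.
#' @export
`[.ExpressionMatrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$values))
  if (missing(j)) j <- seq_len(ncol(x$values))
  ExpressionMatrix(x$values[i, j, drop = FALSE],
                   if (!is.null(x$detection_p)) x$detection_p[i, j, drop = FALSE])
}

as_expression_matrix <- function(m) {
  if (inherits(m, "ExpressionMatrix")) m else ExpressionMatrix(as.matrix(m))
}

#' Validate a sample sheet against an expression matrix
#'
#' A sample sheet is a data.frame with columns `sample_id` and `group`
#' (optionally covariates such as age or sex). Groups follow the cohort
#' design: euploid controls (`2N`), trisomic individuals without a heart
#' defect (`CHD-`), and the defect subgroups `AVSD`, `ASD`, `VSD` (or the
#' merged `ASD+VSD` after an explicit merge decision).
#'
#' @param sheet data.frame with `sample_id` and `group` columns.
#' @param m optional [ExpressionMatrix()] whose samples must all be present.
#' @return The sheet, invisibly, with `sample_id`/`group` as character.
#' @export
validate_sample_sheet <- function(sheet, m = NULL) {
  if (!is.data.frame(sheet) || !all(c("sample_id", "group") %in% names(sheet)))
    stop("sample sheet needs 'sample_id' and 'group' columns")
  sheet$sample_id <- as.character(sheet$sample_id)
  sheet$group <- as.character(sheet$group)
  if (anyDuplicated(sheet$sample_id)) stop("duplicate sample ids in sheet")
  if (!is.null(m)) {
    missing_ids <- setdiff(colnames(m$values), sheet$sample_id)
    if (length(missing_ids))
      stop("samples absent from sheet: ", paste(missing_ids, collapse = ", "))
  }
  invisible(sheet)
}

group_samples <- function(sheet, group) {
  sheet$sample_id[sheet$group == group]
}
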