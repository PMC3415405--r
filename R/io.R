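#' Read and write the pipeline's plain-text interchange formats
#'
#' Expression matrices travel as GenomeStudio-style TSV: a `probe_id` column
#' followed, per sample, by `AVG_Signal.<sample>` and `Detection.Pval.<sample>`
#' columns. Annotations, sample sheets and truth tables are plain TSV; gene
#' sets use the standard GMT format (set name, description, then tab-separated
#' gene symbols, one set per line).
#'
#' @name chdsig-io
NULL

#' @rdname chdsig-io
#' @param m an [ExpressionMatrix()] (detection p-values required for writing).
#' @param path file path.
#' @return `read_expression_tsv` returns an [ExpressionMatrix()]; writers
#'   return `path` invisibly.
#' @export
write_expression_tsv <- function(m, path) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  samples <- colnames(m$values)
  out <- data.table::data.table(probe_id = rownames(m$values))
  for (s in samples) {
    out[[paste0("AVG_Signal.", s)]] <- m$values[, s]
    if (!is.null(m$detection_p))
      out[[paste0("Detection.Pval.", s)]] <- m$detection_p[, s]
  }
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}

#' @rdname chdsig-io
#' @export
read_expression_tsv <- function(path) {
  dt <- data.table::fread(path, sep = "\t")
  if (!"probe_id" %in% names(dt)) stop("expression TSV lacks 'probe_id'")
  sig_cols <- grep("^AVG_Signal\\.", names(dt), value = TRUE)
  det_cols <- grep("^Detection\\.Pval\\.", names(dt), value = TRUE)
  if (!length(sig_cols)) stop("expression TSV lacks AVG_Signal columns")
  samples <- sub("^AVG_Signal\\.", "", sig_cols)
  values <- as.matrix(dt[, sig_cols, with = FALSE])
  dimnames(values) <- list(dt$probe_id, samples)
  detection <- NULL
  if (length(det_cols)) {
    det_samples <- sub("^Detection\\.Pval\\.", "", det_cols)
    if (!setequal(det_samples, samples))
      stop("Detection.Pval columns do not match AVG_Signal columns")
    detection <- as.matrix(dt[, paste0("Detection.Pval.", samples), with = FALSE])
    dimnames(detection) <- list(dt$probe_id, samples)
  }
  ExpressionMatrix(values, detection)
}

#' @rdname chdsig-io
#' @param ann annotation data.frame (`probe_id`, `gene`, `chromosome`,
#'   `start`, `end`; coordinates 0-based half-open).
#' @export
write_annotation_tsv <- function(ann, path) {
  data.table::fwrite(ann[, c("probe_id", "gene", "chromosome", "start", "end")],
                     path, sep = "\t")
  invisible(path)
}

#' @rdname chdsig-io
#' @export
read_annotation_tsv <- function(path) {
  ann <- as.data.frame(data.table::fread(path, sep = "\t"))
  validate_annotation(ann)
  ann
}

#' @rdname chdsig-io
#' @param sheet sample sheet data.frame (`sample_id`, `group`).
#' @export
write_sample_sheet <- function(sheet, path) {
  data.table::fwrite(sheet, path, sep = "\t")
  invisible(path)
}

#' @rdname chdsig-io
#' @export
read_sample_sheet <- function(path) {
  sheet <- as.data.frame(data.table::fread(path, sep = "\t",
                                           colClasses = list(character = "sample_id")))
  validate_sample_sheet(sheet)
  sheet
}

#' @rdname chdsig-io
#' @param catalog named list of character vectors (gene sets); an optional
#'   `description` attribute per set is written to the GMT second column.
#' @export
write_gmt <- function(catalog, path) {
  if (is.null(names(catalog)) || anyDuplicated(names(catalog)))
    stop("catalog must be a uniquely named list of gene sets")
  lines <- vapply(names(catalog), function(nm) {
    desc <- attr(catalog[[nm]], "description")
    if (is.null(desc)) desc <- "na"
    paste(c(nm, desc, catalog[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname chdsig-io
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < 3L
  if (any(bad)) stop("malformed GMT line(s): ", paste(which(bad), collapse = ", "))
  catalog <- lapply(parts, function(p) {
    genes <- unique(p[-(1:2)])
    attr(genes, "description") <- p[2]
    genes
  })
  names(catalog) <- vapply(parts, `[[`, character(1), 1L)
  if (anyDuplicated(names(catalog))) stop("duplicate set names in GMT")
  catalog
}

validate_annotation <- function(ann) {
  need <- c("probe_id", "gene", "chromosome", "start", "end")
  if (!all(need %in% names(ann)))
    stop("annotation needs columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(ann$probe_id)) stop("annotation has duplicate probe ids")
  per_gene_chrom <- tapply(ann$chromosome, ann$gene, function(x) length(unique(x)))
  if (any(per_gene_chrom > 1))
    stop("gene(s) mapped to more than one chromosome: ",
         paste(utils::head(names(per_gene_chrom)[per_gene_chrom > 1]), collapse = ", "))
  invisible(ann)
}

#' Gene-level genomic order table from a probe annotation
#'
#' Collapses a probe annotation to one row per gene and attaches the
#' within-chromosome order index (rank by `start`), the ordering used by the
#' positional cluster statistics.
#'
#' @param ann probe annotation data.frame.
#' @return data.frame with `gene`, `chromosome`, `start`, `end`, `order_index`
#'   (1-based rank within chromosome).
#' @export
gene_order_table <- function(ann) {
  validate_annotation(ann)
  g <- ann[!duplicated(ann$gene), c("gene", "chromosome", "start", "end")]
  g <- g[order(g$chromosome, g$start, g$gene), ]
  g$order_index <- stats::ave(g$start, g$chromosome,
                              FUN = function(x) seq_along(x))
  rownames(g) <- NULL
  g
}
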