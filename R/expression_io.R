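#' Expression matrix container
#'
#' A thin validated wrapper around a numeric matrix of log2 expression
#' values with probes (or genes) as rows and samples as columns.
#'
#' @param values Numeric matrix, probes x samples.
#' @param probe_ids Character vector of row identifiers.
#' @param sample_ids Character vector of column identifiers.
#' @return An object of class `ExpressionMatrix` (a named numeric matrix
#'   with dimnames set to the identifiers).
#' @export
expression_matrix <- function(values,
                              probe_ids = rownames(values),
                              sample_ids = colnames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(probe_ids) || is.null(sample_ids)) {
    stop("probe_ids and sample_ids are required")
  }
  probe_ids <- as.character(probe_ids)
  sample_ids <- as.character(sample_ids)
  if (length(probe_ids) != nrow(values)) {
    stop("probe_ids length does not match row count")
  }
  if (length(sample_ids) != ncol(values)) {
    stop("sample_ids length does not match column count")
  }
  if (anyDuplicated(probe_ids)) {
    stop("duplicated probe ids: ",
         paste(unique(probe_ids[duplicated(probe_ids)]), collapse = ", "))
  }
  if (anyDuplicated(sample_ids)) {
    stop("duplicated sample ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  }
  if (!all(is.finite(values))) stop("expression values must all be finite")
  dimnames(values) <- list(probe_ids, sample_ids)
  class(values) <- c("ExpressionMatrix", class(values))
  values
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d probes x %d samples\n", nrow(x), ncol(x)))
  cat(sprintf("  value range: [%.3f, %.3f]\n", min(x), max(x)))
  invisible(x)
}

#' Read an expression table
#'
#' Reads a probes-x-samples expression matrix from a plain TSV file
#' (header row of sample ids, first column of probe ids) or from a GEO
#' Series Matrix file, in which only the block delimited by
#' `!series_matrix_table_begin` / `!series_matrix_table_end` is parsed.
#'
#' @param path Path to the file.
#' @param format `"tsv"` or `"geo_series_matrix"`.
#' @return An [expression_matrix()].
#' @export
read_expression_table <- function(path, format = c("tsv", "geo_series_matrix")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file does not exist: ", path)
  lines <- readLines(path)
  if (format == "geo_series_matrix") {
    begin <- grep("^!series_matrix_table_begin", lines)
    end <- grep("^!series_matrix_table_end", lines)
    if (length(begin) != 1L || length(end) != 1L || end <= begin + 1L) {
      stop("series matrix table markers not found or empty in ", path)
    }
    lines <- lines[(begin + 1L):(end - 1L)]
    # GEO quotes identifiers; strip the quotes before parsing
    lines <- gsub("\"", "", lines, fixed = TRUE)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n_col <- length(fields[[1L]])
  bad <- which(vapply(fields, length, integer(1)) != n_col)
  if (length(bad)) {
    stop(sprintf("malformed table: line %d has %d fields, expected %d",
                 bad[1L], length(fields[[bad[1L]]]), n_col))
  }
  header <- fields[[1L]]
  body <- fields[-1L]
  probe_ids <- vapply(body, `[[`, character(1), 1L)
  values <- matrix(NA_real_, nrow = length(body), ncol = n_col - 1L)
  for (i in seq_along(body)) {
    v <- suppressWarnings(as.numeric(body[[i]][-1L]))
    if (anyNA(v)) {
      stop(sprintf("malformed table: non-numeric value on line %d", i + 1L))
    }
    values[i, ] <- v
  }
  expression_matrix(values, probe_ids = probe_ids, sample_ids = header[-1L])
}

#' Write an expression table as TSV
#'
#' Inverse of [read_expression_table()] for the TSV dialect; values are
#' written with full precision so a read/write round trip is lossless.
#'
#' @param E An [expression_matrix()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_expression_table <- function(E, path) {
  header <- paste(c("probe_id", colnames(E)), collapse = "\t")
  rows <- vapply(seq_len(nrow(E)), function(i) {
    paste(c(rownames(E)[i], format(E[i, ], digits = 17, trim = TRUE,
                                   scientific = FALSE)),
          collapse = "\t")
  }, character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Probe-to-gene annotation table
#'
#' @param probe_id Character vector of unique probe identifiers.
#' @param gene_symbol Character vector of gene symbols, one per probe.
#' @return A data.frame of class `ProbeAnnotation`.
#' @export
probe_annotation <- function(probe_id, gene_symbol) {
  probe_id <- as.character(probe_id)
  gene_symbol <- as.character(gene_symbol)
  if (length(probe_id) != length(gene_symbol)) {
    stop("probe_id and gene_symbol must have equal length")
  }
  if (anyDuplicated(probe_id)) stop("duplicated probe ids in annotation")
  if (any(!nzchar(gene_symbol))) stop("empty gene symbols in annotation")
  ann <- data.frame(probe_id = probe_id, gene_symbol = gene_symbol,
                    stringsAsFactors = FALSE)
  class(ann) <- c("ProbeAnnotation", class(ann))
  ann
}

#' Read a two-column probe annotation TSV
#'
#' @param path Path to a TSV with columns probe_id and gene_symbol.
#' @return A [probe_annotation()].
#' @export
read_probe_annotation <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("probe_id", "gene_symbol") %in% names(tab))) {
    stop("annotation file must have probe_id and gene_symbol columns")
  }
  probe_annotation(tab$probe_id, tab$gene_symbol)
}

#' Elementwise log2 transform
#'
#' @param E An [expression_matrix()] on the raw intensity scale.
#' @param offset Non-negative constant added before taking log2.
#' @return An [expression_matrix()] of log2(value + offset).
#' @export
log2_transform <- function(E, offset = 0) {
  if (offset < 0) stop("offset must be >= 0")
  if (any(unclass(E) + offset <= 0)) {
    stop("nonpositive values after offset; log2 undefined")
  }
  expression_matrix(log2(unclass(E) + offset),
                    probe_ids = rownames(E), sample_ids = colnames(E))
}

#' Keep the most variable probes
#'
#' Retains the `ceiling(fraction * P)` probes with the largest sample
#' variance (n-1 denominator) across samples. Ties on variance are broken
#' by ascending probe id; the original row order of retained probes is
#' preserved.
#'
#' @param E An [expression_matrix()] with at least 2 samples.
#' @param fraction Fraction of probes to keep, in (0, 1].
#' @return The filtered [expression_matrix()].
#' @export
filter_top_variance <- function(E, fraction = 0.05) {
  if (!(fraction > 0 && fraction <= 1)) stop("fraction must be in (0, 1]")
  if (ncol(E) < 2) stop("variance filter needs at least 2 samples")
  n_keep <- as.integer(ceiling(fraction * nrow(E)))
  v <- apply(unclass(E), 1L, stats::var)
  ord <- order(-v, rownames(E))           # variance desc, probe id asc on ties
  keep <- sort(ord[seq_len(n_keep)])      # preserve original row order
  expression_matrix(unclass(E)[keep, , drop = FALSE],
                    probe_ids = rownames(E)[keep], sample_ids = colnames(E))
}

#' Collapse probes to genes by per-sample median
#'
#' Each gene's value in a sample is the median over that gene's probes;
#' single-probe genes pass through unchanged. Gene rows are ordered by
#' first appearance of the gene among the probes of `E`.
#'
#' @param E An [expression_matrix()] with probe rows.
#' @param ann A [probe_annotation()] covering every probe of `E`.
#' @return An [expression_matrix()] with gene rows.
#' @export
collapse_probes_to_genes <- function(E, ann) {
  idx <- match(rownames(E), ann$probe_id)
  if (anyNA(idx)) {
    stop("probes missing from annotation: ",
         paste(utils::head(rownames(E)[is.na(idx)], 10L), collapse = ", "))
  }
  genes <- ann$gene_symbol[idx]
  ug <- unique(genes)
  out <- matrix(NA_real_, nrow = length(ug), ncol = ncol(E))
  rows_by_gene <- split(seq_len(nrow(E)), factor(genes, levels = ug))
  for (g in seq_along(ug)) {
    rows <- rows_by_gene[[g]]
    out[g, ] <- if (length(rows) == 1L) unclass(E)[rows, ] else
      apply(unclass(E)[rows, , drop = FALSE], 2L, stats::median)
  }
  expression_matrix(out, probe_ids = ug, sample_ids = colnames(E))
}
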