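#' Gene signature with per-gene weights
#'
#' @param name Signature name.
#' @param genes Character vector of unique gene symbols.
#' @param weights Numeric weights per gene; +1/-1 for signed signatures,
#'   all +1 for module means (the default).
#' @return A `GeneSignature` list.
#' @export
gene_signature <- function(name, genes, weights = rep(1, length(genes))) {
  genes <- as.character(genes)
  if (anyDuplicated(genes)) stop("duplicate genes in signature ", name)
  if (length(weights) != length(genes)) stop("one weight per gene required")
  if (any(!is.finite(weights)) || any(weights == 0)) {
    stop("weights must be finite and nonzero")
  }
  structure(list(name = name, genes = genes, weights = as.numeric(weights)),
            class = "GeneSignature")
}

#' Build a signed two-class signature from a reference data set
#'
#' For each retained gene the weight is +1 when its mean expression in the
#' second class exceeds the first-class mean, and -1 when lower (for the
#' M2/M1 macrophage signature: +1 when higher in M2 than in M1). Genes
#' with exactly equal class means are dropped.
#'
#' @param E_ref Gene-collapsed [expression_matrix()] of the reference set.
#' @param labels Two-class factor per reference sample; the second level is
#'   the "+1" direction class.
#' @param retained Character vector of genes to weight (e.g. from
#'   [select_q0_genes()]), all present in `E_ref`.
#' @param name Signature name.
#' @return A [gene_signature()] with weights in {+1, -1}; dropped
#'   equal-mean genes are recorded in the `dropped` attribute.
#' @export
build_signed_signature <- function(E_ref, labels, retained, name = "M2/M1") {
  if (!length(retained)) stop("empty retained gene list")
  missing <- setdiff(retained, rownames(E_ref))
  if (length(missing)) {
    stop("retained genes absent from reference: ",
         paste(utils::head(missing, 10L), collapse = ", "))
  }
  labels <- as.factor(labels)
  if (nlevels(labels) != 2) stop("labels must have exactly two classes")
  hi <- labels == levels(labels)[2L]
  X <- unclass(E_ref)[retained, , drop = FALSE]
  diff <- rowMeans(X[, hi, drop = FALSE]) - rowMeans(X[, !hi, drop = FALSE])
  dropped <- retained[diff == 0]
  keep <- diff != 0
  sig <- gene_signature(name, retained[keep], sign(diff[keep]))
  attr(sig, "dropped") <- dropped
  sig
}

#' Score a weighted-mean signature per sample
#'
#' The score of sample s is (sum_g w_g x_gs) / G over the G signature
#' genes measured in `E` (after median probe collapse when an annotation is
#' supplied). Unmeasured signature genes are dropped; the measured
#' fraction is attached as an attribute.
#'
#' @param E An [expression_matrix()]; gene rows, or probe rows together
#'   with `ann`.
#' @param sig A [gene_signature()].
#' @param ann Optional [probe_annotation()] to collapse probe rows first.
#' @return Named numeric score per sample, with attribute
#'   `measured_fraction`.
#' @export
score_signature <- function(E, sig, ann = NULL) {
  if (!is.null(ann)) E <- collapse_probes_to_genes(E, ann)
  present <- sig$genes %in% rownames(E)
  if (!any(present)) stop("no signature gene measured in the matrix")
  genes <- sig$genes[present]
  w <- sig$weights[present]
  score <- as.numeric(w %*% unclass(E)[genes, , drop = FALSE]) / length(genes)
  names(score) <- colnames(E)
  attr(score, "measured_fraction") <- mean(present)
  score
}

#' Unweighted module-mean scores
#'
#' For each named gene list, the per-sample mean of gene-collapsed
#' expression: the metagene convention used for immune modules (HCK, LCK,
#' IgG, STAT1, Interferon, MHC-I, MHC-II) and for proliferation, VEGF and
#' glycolysis scores.
#'
#' @param E An [expression_matrix()] with gene rows (or probe rows plus
#'   `ann`).
#' @param modules Named list of gene vectors.
#' @param ann Optional [probe_annotation()].
#' @return Numeric matrix modules x samples.
#' @export
score_module_mean <- function(E, modules, ann = NULL) {
  if (!is.null(ann)) E <- collapse_probes_to_genes(E, ann)
  if (is.null(names(modules)) || any(!nzchar(names(modules)))) {
    stop("modules must be a named list")
  }
  out <- matrix(NA_real_, nrow = length(modules), ncol = ncol(E),
                dimnames = list(names(modules), colnames(E)))
  for (m in names(modules)) {
    genes <- intersect(modules[[m]], rownames(E))
    if (!length(genes)) stop("module has no measured gene: ", m)
    out[m, ] <- colMeans(unclass(E)[genes, , drop = FALSE])
  }
  out
}

#' Nearest-centroid (single sample predictor) classification
#'
#' Assigns each sample to the centroid class with which its profile is
#' most correlated over the genes shared between matrix and model;
#' "unclassified" when the best correlation falls below
#' `min_correlation`. Ties go to the earlier class in the model.
#'
#' @param E An [expression_matrix()] with gene rows (or probes plus `ann`).
#' @param centroids Numeric matrix genes x classes with gene rownames and
#'   class colnames.
#' @param ann Optional [probe_annotation()].
#' @param correlation_kind `"pearson"` or `"spearman"`.
#' @param min_correlation Threshold below which a sample is unclassified.
#' @param min_genes Minimum shared genes required (default 10).
#' @return Data.frame with sample_id, label, best_correlation, plus one
#'   correlation column per class.
#' @export
nearest_centroid_classify <- function(E, centroids, ann = NULL,
                                      correlation_kind = c("pearson", "spearman"),
                                      min_correlation = 0.1, min_genes = 10) {
  correlation_kind <- match.arg(correlation_kind)
  if (!is.null(ann)) E <- collapse_probes_to_genes(E, ann)
  centroids <- as.matrix(centroids)
  shared <- intersect(rownames(E), rownames(centroids))
  if (length(shared) < min_genes) {
    stop(sprintf("only %d centroid genes measured (floor %d)",
                 length(shared), min_genes))
  }
  R <- stats::cor(unclass(E)[shared, , drop = FALSE],
                  centroids[shared, , drop = FALSE],
                  method = correlation_kind)
  best <- max.col(R, ties.method = "first")
  best_cor <- R[cbind(seq_len(nrow(R)), best)]
  label <- ifelse(best_cor < min_correlation, "unclassified",
                  colnames(centroids)[best])
  out <- data.frame(sample_id = colnames(E), label = label,
                    best_correlation = best_cor, stringsAsFactors = FALSE)
  cbind(out, as.data.frame(R))
}

#' Read gene modules from a GMT-like TSV
#'
#' Each line: module name, description, then gene symbols, tab-separated.
#'
#' @param path File path.
#' @return Named list of gene vectors.
#' @export
read_gmt_modules <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- vapply(fields, length, integer(1)) < 3L
  if (any(short)) stop("GMT line with no genes at line ", which(short)[1L])
  mods <- lapply(fields, function(f) f[-(1:2)])
  names(mods) <- vapply(fields, `[[`, character(1), 1L)
  mods
}

#' Write gene modules to a GMT-like TSV
#' @param modules Named list of gene vectors.
#' @param path Output path.
#' @param descriptions Optional descriptions per module.
#' @return Invisibly, `path`.
#' @export
write_gmt_modules <- function(modules, path, descriptions = names(modules)) {
  writeLines(vapply(seq_along(modules), function(i) {
    paste(c(names(modules)[i], descriptions[i], modules[[i]]), collapse = "\t")
  }, character(1)), path)
  invisible(path)
}

#' Read/write a signed signature as two-column TSV (gene, weight)
#' @param path File path.
#' @param name Signature name (read direction).
#' @return A [gene_signature()].
#' @export
read_signed_signature <- function(path, name = basename(path)) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  gene_signature(name, tab[[1L]], tab[[2L]])
}

#' @rdname read_signed_signature
#' @param sig A [gene_signature()].
#' @export
write_signed_signature <- function(sig, path) {
  utils::write.table(data.frame(gene_symbol = sig$genes, weight = sig$weights),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a centroid matrix TSV (first column gene, remaining columns classes)
#' @param path File path.
#' @return Numeric matrix genes x classes.
#' @export
read_centroid_model <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(m) <- tab[[1L]]
  storage.mode(m) <- "double"
  m
}
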