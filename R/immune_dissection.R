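#' Ward clustering of samples on a score matrix, cut into k groups
#'
#' Agglomerative clustering with Ward linkage on Euclidean distances of
#' per-feature standardized scores (z-scores across samples), with the
#' tree cut into `k` groups. Deterministic: ties in the merge sequence are
#' resolved by the fixed ordering of `stats::hclust`.
#'
#' @param X Numeric matrix, features x samples.
#' @param k Number of groups.
#' @param standardize Z-score each feature first (default TRUE).
#' @return Integer group label per sample, named by sample id.
#' @export
ward_cluster_cut <- function(X, k, standardize = TRUE) {
  X <- as.matrix(X)
  if (k > ncol(X)) stop("k exceeds the number of samples")
  if (standardize) {
    sds <- apply(X, 1L, stats::sd)
    sds[sds == 0] <- 1                # constant features contribute nothing
    X <- (X - rowMeans(X)) / sds
  }
  hc <- stats::hclust(stats::dist(t(X)), method = "ward.D2")
  stats::cutree(hc, k = k)
}

#' Dissect immune response into HIR and LIR groups
#'
#' Computes the immune metagene scores (module means) and the signed
#' M2/M1 score on the given samples (typically restricted to the two
#' basal-like-enriched clusters), Ward-clusters the samples into two
#' groups on the standardized metagenes, and labels the group with the
#' higher grand mean of metagene scores HIR (high immune response), the
#' other LIR.
#'
#' @param E An [expression_matrix()] (probes x samples).
#' @param modules Named list of immune module gene sets (the seven
#'   metagenes by default convention).
#' @param m2m1_sig A signed [gene_signature()] (may be NULL to skip).
#' @param ann A [probe_annotation()].
#' @param samples Optional sample ids to restrict to (e.g. the union of
#'   the two basal clusters).
#' @param include_m2m1_in_clustering Cluster on the seven metagenes only
#'   (default) or append the M2/M1 score as an extra feature.
#' @return An `ImmuneProfile` list: `sample_ids`, `metagene_scores`
#'   (modules x samples), `m2m1`, `group` ("HIR"/"LIR" per sample).
#' @export
dissect_immune_response <- function(E, modules, m2m1_sig, ann,
                                    samples = colnames(E),
                                    include_m2m1_in_clustering = FALSE) {
  samples <- intersect(colnames(E), samples)
  if (length(samples) < 4) stop("need at least 4 samples to dissect")
  Es <- expression_matrix(unclass(E)[, samples, drop = FALSE],
                          probe_ids = rownames(E), sample_ids = samples)
  G <- collapse_probes_to_genes(Es, ann)
  scores <- score_module_mean(G, modules)
  m2m1 <- if (is.null(m2m1_sig)) NULL else score_signature(G, m2m1_sig)
  feat <- scores
  if (include_m2m1_in_clustering && !is.null(m2m1)) {
    feat <- rbind(scores, m2m1 = m2m1)
  }
  cut <- ward_cluster_cut(feat, k = 2)
  grand <- vapply(1:2, function(g) mean(scores[, cut == g]), numeric(1))
  hir <- which.max(grand)
  group <- ifelse(cut == hir, "HIR", "LIR")
  names(group) <- samples
  structure(list(sample_ids = samples, metagene_scores = scores,
                 m2m1 = m2m1, group = group),
            class = "ImmuneProfile")
}

#' @export
print.ImmuneProfile <- function(x, ...) {
  cat(sprintf("ImmuneProfile: %d samples (%d HIR / %d LIR), %d metagenes\n",
              length(x$sample_ids), sum(x$group == "HIR"),
              sum(x$group == "LIR"), nrow(x$metagene_scores)))
  invisible(x)
}

#' Per-module two-group comparison of metagene scores
#'
#' For each module: group means, mean difference (group2 - group1) and the
#' two-sided Welch t-test p-value.
#'
#' @param scores Modules x samples score matrix.
#' @param groups Two-level factor per sample.
#' @return Data.frame (module, mean_1, mean_2, difference, p_value).
#' @export
compare_metagenes_between_clusters <- function(scores, groups) {
  groups <- as.factor(groups)
  if (nlevels(groups) != 2) stop("exactly two groups required")
  g1 <- groups == levels(groups)[1L]
  res <- data.frame(module = rownames(scores),
                    mean_1 = rowMeans(scores[, g1, drop = FALSE]),
                    mean_2 = rowMeans(scores[, !g1, drop = FALSE]),
                    stringsAsFactors = FALSE)
  res$difference <- res$mean_2 - res$mean_1
  res$p_value <- vapply(seq_len(nrow(scores)), function(i) {
    a <- scores[i, g1]; b <- scores[i, !g1]
    if (length(a) < 2 || length(b) < 2 ||
        (stats::sd(a) == 0 && stats::sd(b) == 0)) return(NA_real_)
    stats::t.test(b, a)$p.value
  }, numeric(1))
  names(res)[2:3] <- paste0("mean_", levels(groups))
  rownames(res) <- NULL
  res
}
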