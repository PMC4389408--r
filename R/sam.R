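## Two-class SAM: relative difference d_i = (mean2 - mean1) / (s_i + s0),
## s_i the pooled standard error, s0 the fudge factor chosen by the
## coefficient-of-variation criterion; q-values from label permutations.

sam_statistics <- function(X, is2, s0) {
  n1 <- sum(!is2); n2 <- sum(is2)
  m1 <- rowMeans(X[, !is2, drop = FALSE])
  m2 <- rowMeans(X[, is2, drop = FALSE])
  ss1 <- rowSums((X[, !is2, drop = FALSE] - m1)^2)
  ss2 <- rowSums((X[, is2, drop = FALSE] - m2)^2)
  s <- sqrt((1 / n1 + 1 / n2) * (ss1 + ss2) / (n1 + n2 - 2))
  list(d = (m2 - m1) / (s + s0), s = s, r = m2 - m1)
}

## Tusher's fudge factor: among candidate s0 = percentiles of s (0,5,...,100),
## pick the one minimizing the coefficient of variation of the d spread
## (MAD within 100 s-quantile bins) as a function of s.
sam_choose_s0 <- function(r, s) {
  cand <- unique(stats::quantile(s, probs = seq(0, 1, by = 0.05), names = FALSE))
  qs <- stats::quantile(s, probs = seq(0, 1, by = 0.01), names = FALSE)
  bin <- cut(s, breaks = unique(qs), include.lowest = TRUE)
  cv <- vapply(cand, function(s0) {
    d <- r / (s + s0)
    v <- tapply(d, bin, stats::mad)
    v <- v[!is.na(v)]
    if (mean(v) == 0) Inf else stats::sd(v) / mean(v)
  }, numeric(1))
  cand[which.min(cv)]
}

#' Two-class SAM with permutation q-values
#'
#' Computes the SAM relative difference per probe and estimates each
#' probe's q-value (in percent) from label permutations: at the threshold
#' |d| of the probe, the q-value is the estimated false discovery rate
#' pi0 * median permuted call count / observed call count, made monotone
#' non-increasing in |d|.
#'
#' @param E An [expression_matrix()] (probes x samples).
#' @param labels Two-class factor/character vector per sample; statistics
#'   are oriented as second level minus first level.
#' @param n_perm Number of label permutations (default 300).
#' @param seed Integer seed (mandatory for reproducible q-values).
#' @param s0 Optional fudge factor; chosen by the CV criterion when NULL.
#' @return A `SamResult` list: `probe_ids`, `d`, `s`, `s0`, `q` (percent,
#'   in [0,100]), `classes`, `n_perm`, `seed`.
#' @export
sam_two_class <- function(E, labels, n_perm = 300, seed, s0 = NULL) {
  if (missing(seed)) stop("seed is required")
  X <- unclass(E)
  labels <- as.factor(labels)
  if (nlevels(labels) != 2) stop("labels must have exactly two classes")
  if (length(labels) != ncol(X)) stop("one label per sample required")
  if (any(table(labels) < 2)) stop("each class needs at least 2 samples")
  if (n_perm < 10) warning("fewer than 10 permutations: unstable q-values")
  is2 <- labels == levels(labels)[2L]
  obs0 <- sam_statistics(X, is2, 0)
  if (is.null(s0)) s0 <- sam_choose_s0(obs0$r, obs0$s)
  obs <- sam_statistics(X, is2, s0)
  n <- ncol(X)

  perm_abs <- with_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      idx <- sample.int(n)
      abs(sam_statistics(X[, idx, drop = FALSE], is2, s0)$d)
    }, numeric(nrow(X)))
  })
  perm_abs <- matrix(perm_abs, nrow = nrow(X))

  ## pi0: fraction of null probes, from the central 50% of the permuted d
  qlim <- stats::quantile(perm_abs, 0.5)
  pi0 <- min(1, sum(abs(obs$d) <= qlim) / (0.5 * length(obs$d)))

  abs_d <- abs(obs$d)
  ord <- order(-abs_d)
  sorted <- abs_d[ord]
  ## observed calls at threshold |d_i| = rank of |d_i| from the top
  obs_calls <- seq_along(sorted)
  ## permuted calls at each threshold: median over permutations of the
  ## count of permuted |d*| >= threshold
  perm_calls <- vapply(seq_len(ncol(perm_abs)), function(b) {
    col <- perm_abs[, b]
    length(col) - findInterval(sorted, sort(col), left.open = TRUE)
  }, numeric(length(sorted)))
  perm_calls <- matrix(perm_calls, nrow = length(sorted))
  med_false <- apply(perm_calls, 1L, stats::median)
  fdr_sorted <- pmin(100, 100 * pi0 * med_false / obs_calls)
  ## q_i = smallest FDR over thresholds at or below |d_i|; this makes q
  ## monotone non-increasing in |d|
  q_sorted <- rev(cummin(rev(fdr_sorted)))
  q <- numeric(length(abs_d))
  q[ord] <- q_sorted
  res <- list(probe_ids = rownames(X), d = stats::setNames(obs$d, rownames(X)),
              s = stats::setNames(obs$s, rownames(X)), s0 = s0,
              q = stats::setNames(q, rownames(X)),
              classes = levels(labels), n_perm = n_perm, seed = seed,
              pi0 = pi0)
  class(res) <- "SamResult"
  res
}

#' @export
print.SamResult <- function(x, ...) {
  cat(sprintf("SamResult: %d probes, contrast %s - %s\n",
              length(x$d), x$classes[2L], x$classes[1L]))
  cat(sprintf("  s0 = %.4g, pi0 = %.3f, %d probes at q = 0%%\n",
              x$s0, x$pi0, sum(x$q == 0)))
  invisible(x)
}

#' Genes whose probes all reach a 0% q-value
#'
#' A gene is retained when every one of its probes has q-value 0%; its
#' direction is the sign of the mean of its probes' d statistics. Genes
#' whose significant probes disagree in sign are excluded (and reported in
#' the `conflicted` attribute).
#'
#' @param res A `SamResult`.
#' @param ann A [probe_annotation()] covering every probe in `res`.
#' @return Data.frame (gene_symbol, sign) with attribute `conflicted`.
#' @export
select_q0_genes <- function(res, ann) {
  idx <- match(res$probe_ids, ann$probe_id)
  if (anyNA(idx)) {
    stop("probes missing from annotation: ",
         paste(utils::head(res$probe_ids[is.na(idx)], 10L), collapse = ", "))
  }
  genes <- ann$gene_symbol[idx]
  keep <- tapply(res$q, genes, function(qq) all(qq == 0))
  sgn <- tapply(res$d, genes, function(dd) sign(mean(dd)))
  consistent <- tapply(res$d, genes, function(dd) {
    all(sign(dd) == sign(dd[1L])) && sign(dd[1L]) != 0
  })
  retained <- names(keep)[keep & consistent]
  conflicted <- names(keep)[keep & !consistent]
  out <- data.frame(gene_symbol = retained,
                    sign = as.numeric(sgn[retained]),
                    stringsAsFactors = FALSE)
  out <- out[order(out$gene_symbol), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "conflicted") <- conflicted
  out
}
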