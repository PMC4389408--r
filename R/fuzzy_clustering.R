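#' Centred Pearson dissimilarity between sample profiles
#'
#' d(i,j) = 1 - rho(i,j), where rho is the Pearson correlation between the
#' expression profiles of samples i and j over the probes of `E`. Values
#' lie in [0, 2]; each sample has distance 0 to itself.
#'
#' @param E An [expression_matrix()], probes x samples, >= 2 probes.
#' @return A `DissimilarityMatrix`: symmetric samples x samples matrix with
#'   zero diagonal and sample ids as dimnames.
#' @export
centred_pearson_dissimilarity <- function(E) {
  X <- unclass(E)
  if (nrow(X) < 2) stop("need at least 2 features per sample")
  sds <- apply(X, 2L, stats::sd)
  if (any(sds == 0)) {
    stop("constant expression profile; correlation undefined for sample(s): ",
         paste(colnames(X)[sds == 0], collapse = ", "))
  }
  d <- 1 - stats::cor(X)
  d[d < 0] <- 0                       # clip tiny negative rounding noise
  diag(d) <- 0
  structure(d, class = c("DissimilarityMatrix", class(d)))
}

validate_dissimilarity <- function(D) {
  D <- as.matrix(D)
  if (nrow(D) != ncol(D)) stop("dissimilarity matrix must be square")
  if (!all(is.finite(D))) stop("dissimilarity entries must be finite")
  if (any(D < 0)) stop("dissimilarity entries must be >= 0")
  if (max(abs(D - t(D))) > 1e-8) stop("dissimilarity matrix must be symmetric")
  if (any(abs(diag(D)) > 1e-12)) stop("self-dissimilarity must be 0")
  D
}

#' Fuzzy-clustering objective
#'
#' Evaluates the membership-weighted within-cluster dissimilarity criterion
#' sum_k [ sum_ij u(i,k)^r u(j,k)^r d(i,j) ] / [ 2 sum_j u(j,k)^r ]
#' that the fuzzy clustering minimizes.
#'
#' @param u Membership matrix, samples x clusters; rows sum to 1.
#' @param D Symmetric dissimilarity matrix, samples x samples.
#' @param r Fuzziness index, > 1.
#' @return The objective value (scalar, >= 0).
#' @export
fanny_objective <- function(u, D, r = 2) {
  u <- as.matrix(u)
  D <- validate_dissimilarity(D)
  if (nrow(u) != nrow(D)) stop("membership and dissimilarity dimensions disagree")
  if (max(abs(rowSums(u) - 1)) > 1e-6) stop("membership rows must sum to 1")
  M <- u^r
  sum(colSums(M * (D %*% M)) / (2 * colSums(M)))
}

## Membership update for one object: linearized objective with the
## simplex constraint, exponent 1/(r-1); nonpositive "distances" get all mass.
fanny_update_row <- function(e, r) {
  if (any(e <= 0)) {
    u <- as.numeric(e == min(e))
    return(u / sum(u))
  }
  w <- (1 / e)^(1 / (r - 1))
  w / sum(w)
}

fanny_init_seeds <- function(D, k) {
  n <- nrow(D)
  pick <- which(D == max(D), arr.ind = TRUE)[1L, ]
  seeds <- as.integer(pick)
  while (length(seeds) < k) {
    cand <- setdiff(seq_len(n), seeds)
    mind <- apply(D[cand, seeds, drop = FALSE], 1L, min)
    seeds <- c(seeds, cand[which.max(mind)])
  }
  seeds[seq_len(k)]
}

fanny_run <- function(D, u, r, max_iter, tol) {
  n <- nrow(D); k <- ncol(u)
  M <- u^r
  DM <- D %*% M
  Tk <- colSums(M)
  obj <- sum(colSums(M * DM) / (2 * Tk))
  trace <- obj
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    u_prev <- u; M_prev <- M; DM_prev <- DM; Tk_prev <- Tk
    for (i in seq_len(n)) {
      Nk <- colSums(M * DM)
      e <- DM[i, ] / Tk - Nk / (2 * Tk^2)
      new_u <- fanny_update_row(e, r)
      new_m <- new_u^r
      dm <- new_m - M[i, ]
      if (any(dm != 0)) {
        DM <- DM + outer(D[, i], dm)
        Tk <- Tk + dm
        M[i, ] <- new_m
        u[i, ] <- new_u
      }
    }
    new_obj <- sum(colSums(M * DM) / (2 * Tk))
    if (new_obj > obj + 1e-12) {       # safeguard: never accept an uphill sweep
      u <- u_prev; M <- M_prev; DM <- DM_prev; Tk <- Tk_prev
      converged <- TRUE
      break
    }
    trace <- c(trace, new_obj)
    if (abs(obj - new_obj) <= tol * max(abs(obj), 1e-12)) {
      obj <- new_obj
      converged <- TRUE
      break
    }
    obj <- new_obj
  }
  list(u = u, objective = obj, iterations = length(trace) - 1L,
       converged = converged, objective_trace = trace)
}

#' Fuzzy clustering of a dissimilarity matrix
#'
#' Minimizes the criterion of [fanny_objective()] by cyclic membership
#' updates, starting from a deterministic seeding on the k most mutually
#' distant samples plus optional seeded random restarts; the best restart
#' is returned.
#'
#' @param D Symmetric dissimilarity matrix (e.g. from
#'   [centred_pearson_dissimilarity()]).
#' @param k Number of clusters.
#' @param r Fuzziness index (> 1); 2 by default.
#' @param max_iter Maximum update sweeps per restart.
#' @param tol Relative objective-change convergence threshold.
#' @param n_restarts Total restarts (first is deterministic).
#' @param seed Integer seed for the random restarts.
#' @return A `FuzzyPartition`: list with membership matrix `u` (samples x
#'   clusters, rows summing to 1), `objective`, `iterations`, `converged`,
#'   and `k`, `r`.
#' @export
fanny_fit <- function(D, k, r = 2, max_iter = 500, tol = 1e-9,
                      n_restarts = 3, seed = 1) {
  D <- validate_dissimilarity(D)
  n <- nrow(D)
  if (k < 1) stop("k must be >= 1")
  if (k > n) stop("k exceeds the number of samples")
  ids <- rownames(D)
  if (k == 1L) {
    u <- matrix(1, n, 1, dimnames = list(ids, "C1"))
    p <- list(u = u, objective = sum(D) / (2 * n), iterations = 0L,
              converged = TRUE, k = 1L, r = r)
    class(p) <- "FuzzyPartition"
    return(p)
  }
  starts <- list()
  seeds <- fanny_init_seeds(D, k)
  u0 <- 1 / (D[, seeds, drop = FALSE] + 0.01)
  starts[[1L]] <- u0 / rowSums(u0)
  if (n_restarts > 1L) {
    starts <- c(starts, with_seed(seed, {
      lapply(seq_len(n_restarts - 1L), function(s) {
        u0 <- matrix(stats::runif(n * k), n, k)
        u0 / rowSums(u0)
      })
    }))
  }
  best <- NULL
  for (u0 in starts) {
    fit <- fanny_run(D, u0, r, max_iter, tol)
    if (is.null(best) || fit$objective < best$objective) best <- fit
  }
  if (!best$converged) {
    warning("fuzzy clustering did not converge within max_iter sweeps")
  }
  dimnames(best$u) <- list(ids, paste0("C", seq_len(k)))
  p <- list(u = best$u, objective = best$objective,
            iterations = best$iterations, converged = best$converged,
            objective_trace = best$objective_trace,
            k = as.integer(k), r = r)
  class(p) <- "FuzzyPartition"
  p
}

#' @export
print.FuzzyPartition <- function(x, ...) {
  cat(sprintf("FuzzyPartition: %d samples, k = %d, r = %g\n",
              nrow(x$u), x$k, x$r))
  cat(sprintf("  objective %.6g after %d sweeps (converged: %s)\n",
              x$objective, x$iterations, x$converged))
  cat("  crisp sizes:", paste(table(crisp_assign(x)), collapse = " / "), "\n")
  invisible(x)
}

#' Crisp cluster assignment from fuzzy memberships
#'
#' Each sample is assigned to its maximum-membership cluster; ties go to
#' the lowest cluster index.
#'
#' @param p A `FuzzyPartition` (or a bare membership matrix).
#' @return Integer vector of cluster labels, named by sample id.
#' @export
crisp_assign <- function(p) {
  u <- if (inherits(p, "FuzzyPartition")) p$u else as.matrix(p)
  lab <- max.col(u, ties.method = "first")
  names(lab) <- rownames(u)
  lab
}

#' Membership-strength diagnostics per cluster
#'
#' Summarizes how crisply each cluster holds its members: minimum and
#' median winning membership, and the count above `threshold`. For a
#' designated cluster pair it also reports, over the samples crisply
#' assigned to either cluster, the per-sample absolute membership gap and
#' how many fall below `gap_threshold`.
#'
#' @param p A `FuzzyPartition`.
#' @param threshold Winning-membership threshold (default 0.9).
#' @param gap_pair Optional integer pair of cluster indices.
#' @param gap_threshold Gap threshold (default 0.2).
#' @return List with a `clusters` data.frame (cluster, n, min, median,
#'   n_above_threshold) and, if `gap_pair` given, `gap` (named numeric) and
#'   `n_below_gap_threshold`.
#' @export
membership_diagnostics <- function(p, threshold = 0.9, gap_pair = NULL,
                                   gap_threshold = 0.2) {
  u <- p$u
  lab <- crisp_assign(p)
  win <- u[cbind(seq_len(nrow(u)), lab)]
  k <- ncol(u)
  clusters <- data.frame(
    cluster = seq_len(k),
    n = vapply(seq_len(k), function(kk) sum(lab == kk), integer(1)),
    min = NA_real_, median = NA_real_, n_above_threshold = NA_integer_)
  for (kk in seq_len(k)) {
    w <- win[lab == kk]
    if (length(w)) {
      clusters$min[kk] <- min(w)
      clusters$median[kk] <- stats::median(w)
      clusters$n_above_threshold[kk] <- sum(w > threshold)
    }
  }
  out <- list(clusters = clusters, threshold = threshold)
  if (!is.null(gap_pair)) {
    a <- gap_pair[1L]; b <- gap_pair[2L]
    sel <- lab %in% c(a, b)
    gap <- abs(u[sel, a] - u[sel, b])
    names(gap) <- rownames(u)[sel]
    out$gap <- gap
    out$n_below_gap_threshold <- sum(gap < gap_threshold)
    out$gap_threshold <- gap_threshold
  }
  out
}

#' Dunn and Calinski-Harabasz indices over a range of cluster numbers
#'
#' For each k the fuzzy clustering is run and crisply assigned; the Dunn
#' index (minimum single-linkage inter-cluster dissimilarity over maximum
#' intra-cluster diameter, on `D`) and the Calinski-Harabasz index
#' (between/within trace ratio in Euclidean probe space on `E`) are
#' computed on the crisp partition. Degenerate cases (empty crisp cluster,
#' zero diameter) are recorded as NA.
#'
#' @param E The filtered [expression_matrix()] used to build `D`.
#' @param D The dissimilarity matrix clustered on.
#' @param k_range Integer vector of cluster numbers (default 2:10).
#' @param ... Passed to [fanny_fit()].
#' @return Data.frame with columns k, dunn, calinski_harabasz.
#' @export
validity_indices <- function(E, D, k_range = 2:10, ...) {
  D <- validate_dissimilarity(D)
  n <- nrow(D)
  if (any(k_range < 2 | k_range > n - 1)) {
    stop("k_range must lie within [2, n_samples - 1]")
  }
  k_range <- sort(unique(as.integer(k_range)))
  res <- data.frame(k = k_range, dunn = NA_real_,
                    calinski_harabasz = NA_real_)
  X <- t(unclass(E))                   # samples x probes
  for (i in seq_along(k_range)) {
    k <- k_range[i]
    lab <- crisp_assign(fanny_fit(D, k, ...))
    if (length(unique(lab)) < k) {
      warning(sprintf("empty crisp cluster at k = %d; indices set NA", k))
      next
    }
    res$dunn[i] <- dunn_index(D, lab)
    res$calinski_harabasz[i] <- calinski_harabasz_index(X, lab)
  }
  res
}

#' Dunn index of a crisp partition on a dissimilarity matrix
#'
#' Original definition: minimum inter-cluster single-linkage dissimilarity
#' divided by the maximum intra-cluster diameter. NA when the maximum
#' diameter is zero.
#'
#' @param D Dissimilarity matrix.
#' @param labels Crisp cluster labels.
#' @return Scalar index (or NA).
#' @export
dunn_index <- function(D, labels) {
  D <- as.matrix(D)
  ks <- unique(labels)
  diam <- max(vapply(ks, function(k) {
    idx <- which(labels == k)
    if (length(idx) < 2) 0 else max(D[idx, idx])
  }, numeric(1)))
  if (diam == 0) return(NA_real_)
  sep <- Inf
  for (a in seq_along(ks)) for (b in seq_along(ks)) {
    if (a < b) {
      sep <- min(sep, min(D[labels == ks[a], labels == ks[b]]))
    }
  }
  sep / diam
}

#' Calinski-Harabasz index of a crisp partition
#'
#' Between-cluster over within-cluster trace ratio,
#' [trace(B)/(k-1)] / [trace(W)/(n-k)], in Euclidean feature space.
#'
#' @param X Samples x features matrix.
#' @param labels Crisp cluster labels.
#' @return Scalar index.
#' @export
calinski_harabasz_index <- function(X, labels) {
  X <- as.matrix(X)
  n <- nrow(X)
  ks <- unique(labels)
  k <- length(ks)
  if (k < 2 || k >= n) stop("need 2 <= k < n")
  grand <- colMeans(X)
  trW <- 0; trB <- 0
  for (kk in ks) {
    idx <- which(labels == kk)
    cen <- colMeans(X[idx, , drop = FALSE])
    trW <- trW + sum(sweep(X[idx, , drop = FALSE], 2L, cen)^2)
    trB <- trB + length(idx) * sum((cen - grand)^2)
  }
  (trB / (k - 1)) / (trW / (n - k))
}

#' Barycentric plot coordinates of fuzzy memberships
#'
#' Each sample is placed at the membership-weighted barycentre of the
#' cluster vertices (for k = 3, inside the triangle whose corners are the
#' clusters).
#'
#' @param p A `FuzzyPartition`.
#' @param vertices k x 2 numeric matrix of vertex coordinates; defaults to
#'   the unit equilateral triangle for k = 3, otherwise points on the unit
#'   circle.
#' @return Samples x 2 coordinate matrix.
#' @export
barycentric_coordinates <- function(p, vertices = NULL) {
  u <- p$u
  k <- ncol(u)
  if (is.null(vertices)) {
    ang <- pi / 2 + 2 * pi * (seq_len(k) - 1) / k
    vertices <- cbind(cos(ang), sin(ang))
  }
  vertices <- as.matrix(vertices)
  if (nrow(vertices) != k || ncol(vertices) != 2) {
    stop("vertices must be a k x 2 matrix")
  }
  xy <- u %*% vertices
  colnames(xy) <- c("x", "y")
  xy
}
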