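test_that("centred Pearson dissimilarity matches 1 - correlation", {
  E <- random_expression(20, 5, seed = 2)
  D <- centred_pearson_dissimilarity(E)
  expect_equal(diag(unclass(D)), setNames(rep(0, 5), colnames(E)))
  # textbook formula oracle per pair
  X <- unclass(E)
  for (i in 1:4) for (j in (i + 1):5) {
    x <- X[, i] - mean(X[, i]); y <- X[, j] - mean(X[, j])
    rho <- sum(x * y) / sqrt(sum(x^2) * sum(y^2))
    expect_equal(D[i, j], 1 - rho, tolerance = 1e-12)
  }
  # anti-correlated profiles sit at distance 2
  x <- rnorm(10)
  A <- toy_expression(cbind(x, -x))
  expect_equal(centred_pearson_dissimilarity(A)[1, 2], 2)
  # constant profile is rejected by name
  B <- toy_expression(cbind(x, rep(1, 10)), samples = c("ok", "flat"))
  expect_error(centred_pearson_dissimilarity(B), "flat")
})

test_that("fuzzy objective equals direct summation of the criterion", {
  D <- matrix(c(0, 1, 2, 1, 0, 3, 2, 3, 0), 3, 3)
  u <- matrix(0.5, 3, 2)
  expect_equal(fanny_objective(u, D, r = 2),
               objective_by_summation(u, D, r = 2))
  # uniform memberships, r = 2: per-cluster numerator 2*(1+2+3)/16, T = 3/4
  expect_equal(fanny_objective(u, D, 2), 2 * (12 / 16) / (2 * 0.75))
  # a hard partition with zero within-cluster dissimilarity scores 0
  D0 <- matrix(c(0, 0, 5, 0, 0, 5, 5, 5, 0), 3, 3)
  u0 <- rbind(c(1, 0), c(1, 0), c(0, 1))
  expect_equal(fanny_objective(u0, D0), 0)
  # permuting cluster columns leaves the value unchanged
  u2 <- random_membership(6, 3, seed = 4)
  D2 <- unclass(centred_pearson_dissimilarity(random_expression(15, 6, seed = 5)))
  expect_equal(fanny_objective(u2, D2), fanny_objective(u2[, c(3, 1, 2)], D2))
  expect_error(fanny_objective(u2[1:4, ], D2), "disagree")
})

test_that("k = 1 gives unit memberships and the analytic objective", {
  D <- unclass(centred_pearson_dissimilarity(random_expression(10, 6, seed = 6)))
  p <- fanny_fit(D, 1)
  expect_true(all(p$u == 1))
  expect_equal(p$objective, sum(D) / (2 * 6))
})

test_that("two tight pairs are crisply separated and beat a dense grid", {
  # two pairs of near-duplicate profiles, far apart
  D <- matrix(2, 4, 4)
  D[1, 2] <- D[2, 1] <- 0.05
  D[3, 4] <- D[4, 3] <- 0.05
  diag(D) <- 0
  p <- fanny_fit(D, 2, r = 2, seed = 1)
  lab <- crisp_assign(p)
  expect_equal(lab[1], lab[2])
  expect_equal(lab[3], lab[4])
  expect_true(all(p$u[cbind(1:4, lab)] > 0.9))
  expect_lte(p$objective, grid_search_objective(D, resolution = 0.05) + 1e-9)
})

test_that("membership rows sum to one and the objective never increases", {
  for (seed in 1:3) {
    D <- unclass(centred_pearson_dissimilarity(
      random_expression(30, 12, seed = seed)))
    p <- fanny_fit(D, 3, seed = seed)
    expect_true(all(abs(rowSums(p$u) - 1) < 1e-9))
    expect_true(all(p$u >= 0 & p$u <= 1))
    expect_true(all(diff(p$objective_trace) <= 1e-12))
  }
})

test_that("fuzzy partition agrees with the reference FANNY implementation", {
  skip_if_not_installed("cluster")
  coh <- generate_tnbc_cohort(cohort_spec(n_samples = 45, seed = 8))
  D <- centred_pearson_dissimilarity(filter_top_variance(coh$expression, 0.05))
  ours <- fanny_fit(D, 3, r = 2, seed = 1)
  ref <- cluster::fanny(stats::as.dist(unclass(D)), k = 3, memb.exp = 2,
                        maxit = 2000)
  expect_equal(matched_accuracy(crisp_assign(ours), ref$clustering), 1)
  # same criterion value attained within numerical slack
  expect_equal(ours$objective, ref$objective[["objective"]], tolerance = 1e-4)
})

test_that("crisp assignment is the row argmax with low-index tie-break", {
  u <- rbind(c(0.73, 0.17, 0.10), c(0.5, 0.5, 0), c(0.2, 0.3, 0.5))
  expect_equal(unname(crisp_assign(u)), c(1, 1, 3))
  U <- random_membership(50, 4, seed = 11)
  expect_equal(unname(crisp_assign(U)),
               apply(U, 1, function(r) which(r == max(r))[1]))
})

test_that("membership diagnostics summarize winning memberships and gaps", {
  u <- rbind(c(0.73, 0.27), c(0.98, 0.02), c(0.99, 0.01), c(0.1, 0.9))
  p <- structure(list(u = u, k = 2), class = "FuzzyPartition")
  d <- membership_diagnostics(p, threshold = 0.9, gap_pair = c(1, 2),
                              gap_threshold = 0.2)
  expect_equal(d$clusters$min[1], 0.73)
  expect_equal(d$clusters$median[1], 0.98)
  expect_equal(d$clusters$n_above_threshold[1], 2L)
  expect_equal(unname(d$gap), abs(u[, 1] - u[, 2]))
  expect_equal(d$n_below_gap_threshold, 0L)
  # degenerate: everything in one cluster, all memberships 1
  p1 <- structure(list(u = cbind(rep(1, 3), 0), k = 2),
                  class = "FuzzyPartition")
  d1 <- membership_diagnostics(p1, threshold = 0.5)
  expect_equal(d1$clusters$min[1], 1)
  expect_equal(d1$clusters$n[2], 0L)
  expect_true(is.na(d1$clusters$median[2]))
})

test_that("diagnostics and objective are invariant to cluster relabelling", {
  u <- random_membership(20, 3, seed = 13)
  D <- unclass(centred_pearson_dissimilarity(random_expression(25, 20, seed = 13)))
  perm <- c(2, 3, 1)
  expect_equal(fanny_objective(u, D), fanny_objective(u[, perm], D))
  p <- structure(list(u = u, k = 3), class = "FuzzyPartition")
  pp <- structure(list(u = u[, perm], k = 3), class = "FuzzyPartition")
  da <- membership_diagnostics(p)$clusters
  db <- membership_diagnostics(pp)$clusters
  expect_equal(da[perm, -1], db[, -1], ignore_attr = TRUE)
})

test_that("validity indices favour the planted number of clusters", {
  # two well-separated spherical blobs
  X <- with_seed(21, cbind(matrix(rnorm(10 * 8), 10), matrix(rnorm(10 * 8, 6), 10)))
  E <- toy_expression(X)
  D <- centred_pearson_dissimilarity(E)
  # k > 2 leaves crisp clusters empty here, which warns by design
  vi <- suppressWarnings(validity_indices(E, D, k_range = 2:5, seed = 1))
  expect_equal(vi$k[which.max(vi$calinski_harabasz)], 2)
  # toy instance: both indices match brute-force formula evaluation
  lab <- crisp_assign(fanny_fit(D, 2, seed = 1))
  d <- unclass(D)
  intra <- max(sapply(1:2, function(k) {
    idx <- which(lab == k); if (length(idx) < 2) 0 else max(d[idx, idx]) }))
  inter <- min(d[lab == 1, lab == 2])
  expect_equal(vi$dunn[1], inter / intra)
  Xs <- t(unclass(E)); n <- nrow(Xs)
  grand <- colMeans(Xs); trW <- 0; trB <- 0
  for (k in 1:2) {
    idx <- which(lab == k); cen <- colMeans(Xs[idx, , drop = FALSE])
    trW <- trW + sum(t(t(Xs[idx, , drop = FALSE]) - cen)^2)
    trB <- trB + length(idx) * sum((cen - grand)^2)
  }
  expect_equal(vi$calinski_harabasz[1], (trB / 1) / (trW / (n - 2)))
})

test_that("Dunn index is absent when the maximum diameter is zero", {
  D <- matrix(0, 4, 4)
  expect_true(is.na(dunn_index(D, c(1, 1, 2, 2))))
})

test_that("barycentric coordinates are the membership-weighted vertices", {
  v <- rbind(c(0, 0), c(1, 0), c(0.5, 1))
  u <- rbind(c(1, 0, 0), c(1, 1, 1) / 3)
  p <- structure(list(u = u, k = 3), class = "FuzzyPartition")
  xy <- barycentric_coordinates(p, v)
  expect_equal(unname(xy[1, ]), c(0, 0))
  expect_equal(unname(xy[2, ]), colMeans(v))
  U <- random_membership(10, 3, seed = 17)
  p2 <- structure(list(u = U, k = 3), class = "FuzzyPartition")
  expect_equal(unclass(barycentric_coordinates(p2, v)),
               U %*% v, ignore_attr = TRUE)
  expect_error(barycentric_coordinates(p2, v[1:2, ]), "k x 2")
})
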