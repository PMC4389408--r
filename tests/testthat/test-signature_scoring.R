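test_that("signed weights follow the class-mean direction and drop ties", {
  E <- toy_expression(rbind(c(6, 6, 8, 8),     # up in second class
                            c(9, 9, 7, 7),     # down
                            c(5, 5, 5, 5)),    # exactly equal: dropped
                      probes = c("gUP", "gDN", "gEQ"))
  lab <- factor(rep(c("M1", "M2"), each = 2), levels = c("M1", "M2"))
  sig <- build_signed_signature(E, lab, c("gUP", "gDN", "gEQ"))
  expect_equal(sig$genes, c("gUP", "gDN"))
  expect_equal(unname(sig$weights), c(1, -1))
  expect_equal(attr(sig, "dropped"), "gEQ")
  expect_error(build_signed_signature(E, lab, character(0)), "empty")
  expect_error(build_signed_signature(E, lab, "absent"), "absent")
})

test_that("weighted-mean scores match hand arithmetic and plain means", {
  E <- toy_expression(rbind(10, 8, 6), probes = c("g1", "g2", "g3"),
                      samples = "s1")
  sig <- gene_signature("toy", c("g1", "g2", "g3"), c(1, 1, -1))
  expect_equal(as.numeric(score_signature(E, sig)), (10 + 8 - 6) / 3)
  allpos <- gene_signature("mean", c("g1", "g2", "g3"))
  expect_equal(as.numeric(score_signature(E, allpos)), mean(c(10, 8, 6)))
  # unmeasured genes are dropped and the measured fraction reported
  sig2 <- gene_signature("partial", c("g1", "g2", "gMISSING"), c(1, -1, 1))
  sc <- score_signature(E, sig2)
  expect_equal(as.numeric(sc), (10 - 8) / 2)
  expect_equal(attr(sc, "measured_fraction"), 2 / 3)
  sig3 <- gene_signature("none", "gNOWHERE")
  expect_error(score_signature(E, sig3), "no signature gene")
})

test_that("signature scoring is linear in the expression values", {
  A <- random_expression(8, 4, seed = 1)
  B <- random_expression(8, 4, seed = 2)
  sig <- gene_signature("s", rownames(A)[1:5], c(1, -1, 1, 1, -1))
  AB <- toy_expression(unclass(A) + unclass(B), probes = rownames(A),
                       samples = colnames(A))
  expect_equal(score_signature(AB, sig),
               score_signature(A, sig) + score_signature(B, sig),
               ignore_attr = TRUE)
})

test_that("module means equal per-module gene averages", {
  E <- toy_expression(rbind(c(9.68, 1), c(13.75, 2), c(4, 3)),
                      probes = c("gA", "gB", "gC"))
  sc <- score_module_mean(E, list(pair = c("gA", "gB"), single = "gC"))
  expect_equal(sc["pair", 1], (9.68 + 13.75) / 2)   # = 11.715
  expect_equal(sc["single", ], unclass(E)["gC", ])
  # random modules vs independent group-by-mean recomputation
  R <- random_expression(20, 5, seed = 3)
  mods <- list(m1 = rownames(R)[1:7], m2 = rownames(R)[8:20])
  sc2 <- score_module_mean(R, mods)
  for (m in names(mods)) {
    expect_equal(sc2[m, ], colMeans(unclass(R)[mods[[m]], ]))
  }
  expect_error(score_module_mean(R, list(empty = "nope")), "empty")
  # adding a constant to every gene of a sample shifts the score by it
  S <- unclass(R); S[, 2] <- S[, 2] + 1.25
  sc3 <- score_module_mean(toy_expression(S, rownames(R), colnames(R)), mods)
  expect_equal(sc3["m1", 2], sc2["m1", 2] + 1.25)
})

test_that("nearest-centroid assignment follows the best correlation", {
  with_seed(5, {
    cen <- matrix(rnorm(60, 8), 20, 3,
                  dimnames = list(sprintf("g%02d", 1:20), c("A", "B", "C")))
    E <- toy_expression(cbind(cen[, 2] + rnorm(20, 0, 0.01), cen[, 1]),
                        probes = rownames(cen), samples = c("sB", "sA"))
    res <- nearest_centroid_classify(E, cen)
    expect_equal(res$label, c("B", "A"))
    expect_equal(res$best_correlation[2], 1)
    # brute-force correlation table oracle
    R <- cor(unclass(E), cen)
    expect_equal(as.matrix(res[, c("A", "B", "C")]), R, ignore_attr = TRUE)
    # per-sample affine transforms leave Pearson assignment unchanged
    E2 <- toy_expression(sweep(unclass(E) * 3, 2, c(-2, 5), "+"),
                         probes = rownames(cen), samples = colnames(E))
    expect_equal(nearest_centroid_classify(E2, cen)$label, res$label)
  })
})

test_that("low correlations fall to unclassified and small overlaps error", {
  # a sample orthogonal to every centroid stays unclassified
  cen <- matrix(rep(c(1, -1), 10), 20, 2,
                dimnames = list(sprintf("g%02d", 1:20), c("A", "B")))
  x <- rep(c(1, 1, -1, -1), 5)          # orthogonal to the alternating pattern
  E <- toy_expression(cbind(x), probes = rownames(cen), samples = "s")
  res <- nearest_centroid_classify(E, cen, min_correlation = 0.1)
  expect_equal(res$label, "unclassified")
  expect_error(nearest_centroid_classify(E, cen[1:5, ], min_genes = 10),
               "floor")
})

test_that("module and signature file formats round-trip", {
  mods <- list(alpha = c("g1", "g2"), beta = c("g3", "g4", "g5"))
  p1 <- withr::local_tempfile(fileext = ".gmt")
  write_gmt_modules(mods, p1)
  expect_equal(read_gmt_modules(p1), mods)
  sig <- gene_signature("sig", c("g1", "g2"), c(1, -1))
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_signed_signature(sig, p2)
  sig2 <- read_signed_signature(p2, "sig")
  expect_equal(sig2$genes, sig$genes)
  expect_equal(sig2$weights, sig$weights)
})
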