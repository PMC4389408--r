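# Fixture builders and independent oracles shared across test files.

toy_expression <- function(values, probes = NULL, samples = NULL) {
  values <- as.matrix(values)
  if (is.null(probes)) probes <- sprintf("p%02d", seq_len(nrow(values)))
  if (is.null(samples)) samples <- sprintf("s%02d", seq_len(ncol(values)))
  expression_matrix(values, probe_ids = probes, sample_ids = samples)
}

random_expression <- function(n_probes, n_samples, seed = 1, mean = 8, sd = 1) {
  with_seed(seed, toy_expression(
    matrix(rnorm(n_probes * n_samples, mean, sd), n_probes, n_samples)))
}

# A valid random membership matrix (rows sum to 1).
random_membership <- function(n, k, seed = 1) {
  with_seed(seed, {
    u <- matrix(runif(n * k), n, k)
    u / rowSums(u)
  })
}

# Brute-force evaluation of the fuzzy criterion by direct double summation.
objective_by_summation <- function(u, D, r = 2) {
  k <- ncol(u)
  total <- 0
  for (kk in seq_len(k)) {
    num <- 0
    for (i in seq_len(nrow(u))) for (j in seq_len(nrow(u))) {
      num <- num + u[i, kk]^r * u[j, kk]^r * D[i, j]
    }
    total <- total + num / (2 * sum(u[, kk]^r))
  }
  total
}

# Dense grid search over memberships for k = 2 at the given resolution;
# returns the best objective found. For n >= 4 the grid is evaluated in
# chunks over the first coordinate to bound memory.
grid_search_objective <- function(D, r = 2, resolution = 0.01) {
  n <- nrow(D)
  g <- seq(0, 1, by = resolution)
  eval_grid <- function(U1) {
    M1 <- U1^r
    M2 <- (1 - U1)^r
    obj <- rowSums((M1 %*% D) * M1) / (2 * rowSums(M1)) +
      rowSums((M2 %*% D) * M2) / (2 * rowSums(M2))
    min(obj, na.rm = TRUE)
  }
  if (n <= 3) {
    return(eval_grid(as.matrix(expand.grid(rep(list(g), n)))))
  }
  best <- Inf
  rest <- rep(list(g), n - 1L)
  for (u1 in g) {
    best <- min(best, eval_grid(as.matrix(expand.grid(c(list(u1), rest)))))
  }
  best
}

# Ward agglomeration via the explicit Lance-Williams recurrence on squared
# Euclidean distances (merge criterion and updates equivalent to ward.D2).
ward_lance_williams <- function(X, k) {
  # X: features x samples (standardized by the caller if desired)
  n <- ncol(X)
  d2 <- as.matrix(dist(t(X)))^2
  active <- seq_len(n)
  sizes <- rep(1, n)
  members <- as.list(seq_len(n))
  while (length(active) > k) {
    # Ward merge cost between clusters a,b is (na*nb/(na+nb)) * ||ca-cb||^2;
    # with the recurrence below d2 holds exactly those squared distances,
    # so pick the minimum off-diagonal entry among active clusters
    best <- c(NA, NA); best_val <- Inf
    for (ai in seq_along(active)) for (bi in seq_along(active)) {
      if (ai < bi) {
        a <- active[ai]; b <- active[bi]
        cost <- sizes[a] * sizes[b] / (sizes[a] + sizes[b]) * d2[a, b]
        if (cost < best_val) { best_val <- cost; best <- c(a, b) }
      }
    }
    a <- best[1]; b <- best[2]
    for (cc in setdiff(active, c(a, b))) {
      na <- sizes[a]; nb <- sizes[b]; nc <- sizes[cc]
      d2[a, cc] <- d2[cc, a] <-
        ((na + nc) * d2[a, cc] + (nb + nc) * d2[b, cc] - nc * d2[a, b]) /
        (na + nb + nc)
    }
    sizes[a] <- sizes[a] + sizes[b]
    members[[a]] <- c(members[[a]], members[[b]])
    active <- setdiff(active, b)
  }
  lab <- integer(n)
  for (g in seq_along(active)) lab[members[[active[g]]]] <- g
  lab
}

# Manual logrank statistic from the pooled observed-minus-expected table.
logrank_by_hand <- function(time, event, groups) {
  groups <- as.factor(groups)
  lev <- levels(groups)
  times <- sort(unique(time[event == 1]))
  O <- E <- setNames(numeric(length(lev)), lev)
  V <- 0
  for (t in times) {
    at_risk <- time >= t
    d <- sum(event == 1 & time == t)
    n <- sum(at_risk)
    for (g in lev) {
      ng <- sum(at_risk & groups == g)
      O[g] <- O[g] + sum(event == 1 & time == t & groups == g)
      E[g] <- E[g] + d * ng / n
    }
    n1 <- sum(at_risk & groups == lev[1])
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O[lev[1]] - E[lev[1]])^2 / V
}

# Two-group agreement after optimally permuting one labelling (3 classes).
matched_accuracy <- function(a, b) {
  la <- sort(unique(a)); lb <- sort(unique(b))
  perms <- list(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1), c(3,1,2), c(3,2,1))
  best <- 0
  fa <- match(a, la); fb <- match(b, lb)
  for (p in perms) best <- max(best, mean(p[fa] == fb))
  best
}
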