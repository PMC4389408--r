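## Nearest-shrunken-centroid classification: class centroids are shrunk
## toward the overall centroid by soft-thresholding their standardized
## deviations; the shrinkage delta is chosen by cross-validation with the
## one-standard-error rule.

pam_components <- function(X, labels) {
  classes <- levels(labels)
  n <- ncol(X); k <- length(classes)
  if (n <= k) stop("need more samples than classes to pool a variance")
  overall <- rowMeans(X)
  cent <- vapply(classes, function(cl)
    rowMeans(X[, labels == cl, drop = FALSE]), numeric(nrow(X)))
  cent <- matrix(cent, nrow = nrow(X),
                 dimnames = list(rownames(X), classes))
  nk <- as.integer(table(labels)[classes])
  ss <- 0
  for (i in seq_len(k)) {
    ss <- ss + rowSums((X[, labels == classes[i], drop = FALSE] - cent[, i])^2)
  }
  s <- sqrt(ss / (n - k))
  s0 <- stats::median(s)
  mk <- sqrt(1 / nk - 1 / n)
  dkg <- sweep(cent - overall, 1L, s + s0, "/")
  dkg <- sweep(dkg, 2L, mk, "/")
  list(classes = classes, overall = overall, cent = cent, s = s, s0 = s0,
       mk = mk, dkg = dkg, nk = nk, n = n)
}

pam_shrink <- function(comp, delta) {
  d <- abs(comp$dkg) - delta
  d[d < 0] <- 0
  dprime <- sign(comp$dkg) * d
  shrunken <- comp$overall +
    sweep(sweep(dprime, 2L, comp$mk, "*"), 1L, comp$s + comp$s0, "*")
  list(dprime = dprime, centroids = shrunken)
}

pam_discriminant <- function(Xnew, centroids, s_tot, priors) {
  k <- ncol(centroids)
  out <- matrix(NA_real_, ncol(Xnew), k,
                dimnames = list(colnames(Xnew), colnames(centroids)))
  for (j in seq_len(k)) {
    out[, j] <- colSums(((Xnew - centroids[, j]) / s_tot)^2) - 2 * log(priors[j])
  }
  out
}

#' Train a nearest-shrunken-centroid (PAM) classifier
#'
#' Class centroid deviations from the overall centroid, standardized by
#' the pooled within-class standard deviation (plus its median as offset),
#' are soft-thresholded by delta. Delta is selected as the largest value
#' whose stratified cross-validated error is within one standard error of
#' the minimum.
#'
#' @param E Training [expression_matrix()] (features x samples).
#' @param labels Class label per training sample (>= 2 classes, each with
#'   at least `cv_folds` members).
#' @param delta_grid Candidate shrinkage thresholds; defaults to 30 values
#'   from 0 to the largest standardized deviation.
#' @param cv_folds Stratified folds (default 5).
#' @param seed Integer seed controlling fold assignment.
#' @param priors Class priors; default the training frequencies.
#' @return A `PamModel` list: class_names, overall_centroid,
#'   class_centroids (shrunken), shrunken_deviations, pooled_sd, s0_pam,
#'   delta, priors, cv_error_curve, n_nonzero_genes.
#' @export
pam_train <- function(E, labels, delta_grid = NULL, cv_folds = 5, seed = 1,
                      priors = NULL) {
  X <- unclass(E)
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) < 2) stop("at least 2 classes required")
  if (any(table(labels) < cv_folds)) {
    stop("a class is smaller than cv_folds; reduce the number of folds")
  }
  comp <- pam_components(X, labels)
  if (is.null(delta_grid)) {
    delta_grid <- seq(0, max(abs(comp$dkg)), length.out = 30)
  }
  delta_grid <- sort(delta_grid)
  if (is.null(priors)) priors <- as.numeric(table(labels)) / length(labels)
  names(priors) <- levels(labels)
  if (abs(sum(priors) - 1) > 1e-8) stop("priors must sum to 1")

  folds <- with_seed(seed, {
    f <- integer(length(labels))
    for (cl in levels(labels)) {
      idx <- which(labels == cl)
      f[idx] <- sample(rep_len(seq_len(cv_folds), length(idx)))
    }
    f
  })
  err <- matrix(NA_real_, cv_folds, length(delta_grid))
  for (fold in seq_len(cv_folds)) {
    tr <- folds != fold
    comp_tr <- tryCatch(
      pam_components(X[, tr, drop = FALSE], droplevels(labels[tr])),
      error = function(e) NULL)        # degenerate training split: skip fold
    if (is.null(comp_tr)) next
    for (j in seq_along(delta_grid)) {
      sh <- pam_shrink(comp_tr, delta_grid[j])
      disc <- pam_discriminant(X[, !tr, drop = FALSE], sh$centroids,
                               comp_tr$s + comp_tr$s0,
                               priors[comp_tr$classes])
      pred <- comp_tr$classes[max.col(-disc, ties.method = "first")]
      err[fold, j] <- mean(pred != as.character(labels[!tr]))
    }
  }
  n_folds_used <- sum(stats::complete.cases(err))
  if (n_folds_used == 0 || length(delta_grid) == 1L) {
    delta <- delta_grid[1L]
    cv_err <- colMeans(err, na.rm = TRUE)
    cv_se <- rep(NA_real_, length(delta_grid))
  } else {
    cv_err <- colMeans(err, na.rm = TRUE)
    cv_se <- apply(err, 2L, stats::sd, na.rm = TRUE) / sqrt(n_folds_used)
    best <- which.min(cv_err)
    ok <- which(cv_err <= cv_err[best] + cv_se[best])
    delta <- delta_grid[max(ok)]        # one-standard-error rule
  }

  sh <- pam_shrink(comp, delta)
  model <- list(class_names = levels(labels),
                overall_centroid = comp$overall,
                class_centroids = sh$centroids,
                shrunken_deviations = sh$dprime,
                pooled_sd = comp$s, s0_pam = comp$s0,
                delta = delta, priors = priors,
                cv_error_curve = data.frame(delta = delta_grid,
                                            error = cv_err, se = cv_se),
                n_nonzero_genes = sum(rowSums(sh$dprime != 0) > 0),
                feature_ids = rownames(X))
  class(model) <- "PamModel"
  model
}

#' @export
print.PamModel <- function(x, ...) {
  cat(sprintf("PamModel: %d classes, delta = %.3f, %d/%d genes active\n",
              length(x$class_names), x$delta, x$n_nonzero_genes,
              length(x$feature_ids)))
  invisible(x)
}

#' Predict classes with a trained PAM model
#'
#' Discriminant score per class: squared standardized distance to the
#' shrunken centroid minus twice the log prior; the smallest score wins.
#' Model genes missing from the new matrix are dropped from all centroids
#' symmetrically, provided at least `min_overlap` of them are measured.
#'
#' @param model A `PamModel` from [pam_train()].
#' @param E_new New [expression_matrix()] on the same feature space.
#' @param min_overlap Minimum fraction of model genes required (default
#'   0.8).
#' @return Data.frame: sample_id, label, then one discriminant column per
#'   class.
#' @export
pam_predict <- function(model, E_new, min_overlap = 0.8) {
  X <- unclass(E_new)
  shared <- intersect(model$feature_ids, rownames(X))
  frac <- length(shared) / length(model$feature_ids)
  if (frac < min_overlap) {
    stop(sprintf("only %.0f%% of model genes measured (floor %.0f%%)",
                 100 * frac, 100 * min_overlap))
  }
  idx <- match(shared, model$feature_ids)
  disc <- pam_discriminant(X[shared, , drop = FALSE],
                           model$class_centroids[idx, , drop = FALSE],
                           (model$pooled_sd + model$s0_pam)[idx],
                           model$priors)
  label <- model$class_names[max.col(-disc, ties.method = "first")]
  out <- data.frame(sample_id = colnames(X), label = label,
                    stringsAsFactors = FALSE)
  colnames(disc) <- paste0("score_", model$class_names)
  cbind(out, as.data.frame(disc))
}

#' Serialize / restore a PAM model as JSON
#' @param model A `PamModel`.
#' @param path Output path.
#' @return Invisibly, `path` (write) or the restored `PamModel` (read).
#' @export
write_pam_model <- function(model, path) {
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    stop("jsonlite is required for model serialization")
  }
  obj <- unclass(model)
  obj$class_centroids <- as.data.frame(obj$class_centroids)
  obj$shrunken_deviations <- as.data.frame(obj$shrunken_deviations)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_pam_model
#' @export
read_pam_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("class_centroids", "shrunken_deviations")) {
    obj[[f]] <- as.matrix(obj[[f]])
    rownames(obj[[f]]) <- obj$feature_ids
  }
  for (f in c("overall_centroid", "pooled_sd")) {
    obj[[f]] <- stats::setNames(as.numeric(obj[[f]]), obj$feature_ids)
  }
  obj$priors <- stats::setNames(as.numeric(obj$priors), obj$class_names)
  class(obj) <- "PamModel"
  obj
}
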