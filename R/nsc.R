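# Class-wise sufficient statistics shared by all shrinkage levels.
nsc_stats <- function(X, y) {
  X <- as.matrix(X)
  y <- factor(y)
  classes <- sort(levels(droplevels(y)))
  y <- factor(as.character(y), levels = classes)
  n <- nrow(X)
  n_k <- table(y)
  if (length(classes) < 2) abort("need at least 2 classes")
  if (any(n_k < 2)) abort("every class needs at least 2 samples")
  overall <- colMeans(X)
  centroids <- t(vapply(classes, function(k) colMeans(X[y == k, , drop = FALSE]),
                        numeric(ncol(X))))
  # pooled within-class SD per feature, n - K degrees of freedom
  ss <- Reduce(`+`, lapply(classes, function(k) {
    Z <- sweep(X[y == k, , drop = FALSE], 2, centroids[k, ])
    colSums(Z^2)
  }))
  s_i <- sqrt(ss / (n - length(classes)))
  s0 <- median(s_i)
  m_k <- sqrt(1 / as.numeric(n_k) - 1 / n)
  names(m_k) <- classes
  d_ik <- t(vapply(classes, function(k) {
    (centroids[k, ] - overall) / (m_k[k] * (s_i + s0))
  }, numeric(ncol(X))))
  list(classes = classes, n = n, n_k = as.numeric(n_k), priors = as.numeric(n_k) / n,
       overall = overall, centroids = centroids, s_i = s_i, s0 = s0,
       m_k = m_k, d_ik = d_ik, features = colnames(X) %||%
         paste0("f", seq_len(ncol(X))))
}

nsc_shrink <- function(st, delta) {
  d_shrunk <- sign(st$d_ik) * pmax(abs(st$d_ik) - delta, 0)
  shrunken <- sweep(d_shrunk * (st$s_i + st$s0)[col(d_shrunk)] *
                      st$m_k[row(d_shrunk)], 2, st$overall, `+`)
  # rows are classes, columns features
  dimnames(shrunken) <- list(st$classes, st$features)
  list(d_shrunk = d_shrunk, shrunken_centroids = shrunken,
       surviving = st$features[colSums(abs(d_shrunk) > 0) > 0])
}

#' Fit a nearest shrunken centroid (NSC) classifier
#'
#' Class centroids are soft-thresholded toward the overall centroid in units
#' of the standardized centroid difference
#' `d_ik = (xbar_ik - xbar_i) / (m_k (s_i + s0))` with
#' `m_k = sqrt(1/n_k - 1/n)`, pooled within-class SD `s_i` and fudge
#' constant `s0 = median(s_i)`; shrunken differences are
#' `sign(d) max(|d| - delta, 0)`. Features whose differences shrink to zero
#' in every class drop out of the classifier, yielding a sparse subtype
#' signature. Class priors are the empirical class frequencies.
#'
#' @param X Samples x features numeric matrix (log2 scale).
#' @param y Class labels, one per row of `X`.
#' @param delta Shrinkage threshold (>= 0); at 0 the shrunken centroids equal
#'   the raw class centroids.
#' @return An `nsc_model` object.
#' @export
fit_nsc <- function(X, y, delta = 0) {
  stopifnot(delta >= 0)
  st <- nsc_stats(X, y)
  sh <- nsc_shrink(st, delta)
  structure(c(st, sh, list(delta = delta)), class = "nsc_model")
}

#' Predict subtype labels with an NSC model
#'
#' Discriminant score per class:
#' `sum_i (x_i - xbar'_ik)^2 / (s_i + s0)^2 - 2 log pi_k`; the predicted
#' label is the argmin, ties broken toward the lexicographically smallest
#' class label. At full shrinkage every class centroid equals the overall
#' centroid and the prior term alone decides.
#'
#' @param object An `nsc_model`.
#' @param newdata Feature vector or samples x features matrix matching the
#'   training feature space.
#' @param ... Unused.
#' @return Tibble with `label` and one score column per class.
#' @export
predict.nsc_model <- function(object, newdata, ...) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$features)) {
    abort(sprintf("newdata has %d features, model expects %d",
                  ncol(newdata), length(object$features)))
  }
  w <- (object$s_i + object$s0)^2
  scores <- vapply(seq_along(object$classes), function(k) {
    Z <- sweep(newdata, 2, object$shrunken_centroids[k, ])
    rowSums(sweep(Z^2, 2, w, `/`)) - 2 * log(object$priors[k])
  }, numeric(nrow(newdata)))
  scores <- matrix(scores, nrow = nrow(newdata),
                   dimnames = list(NULL, object$classes))
  # classes are sorted, so which.min ties break lexicographically
  label <- object$classes[apply(scores, 1, which.min)]
  dplyr::bind_cols(tibble(label = label), as_tibble(scores))
}

stratified_folds <- function(y, folds) {
  idx <- integer(length(y))
  for (k in unique(y)) {
    members <- sample(which(y == k))
    idx[members] <- rep_len(sample(folds), length(members))
  }
  idx
}

#' Repeated stratified cross-validation of the NSC classifier
#'
#' Repeats stratified k-fold cross-validation over a grid of shrinkage
#' thresholds, picks the threshold with the smallest mean CV error (ties
#' broken toward larger thresholds, i.e. fewer features), and reports
#' per-class sensitivity (true positives over condition positives) and
#' specificity (true negatives over condition negatives) from the held-out
#' predictions at the chosen threshold. Classes never predicted positive
#' are marked not-applicable (`NA` specificity), mirroring how predictive
#' statistics are reported when a class attracts no predictions.
#'
#' @param X Samples x features matrix (log2 scale).
#' @param y Class labels.
#' @param folds Number of folds (default 10); reduced with a warning when a
#'   class is smaller than the fold count.
#' @param iterations Number of repeated shuffles (default 50; increase to
#'   1000 for a full-scale run).
#' @param delta_grid Shrinkage grid; default 30 even values from 0 to
#'   `max |d_ik|` of the full-data fit.
#' @param seed Seed for the fold shuffling (mandatory).
#' @return An `nsc_cv` object: `error_by_delta`, `chosen_delta`,
#'   `class_stats` (Se/Sp), `accuracy`, `model` (full-data fit at the chosen
#'   threshold), `surviving_features`, `iterations`.
#' @export
cross_validate_nsc <- function(X, y, folds = 10, iterations = 50,
                               delta_grid = NULL, seed) {
  if (missing(seed)) abort("`seed` is mandatory for reproducible folds")
  X <- as.matrix(X)
  y <- factor(y)
  iterations <- check_scalar_count(iterations, "iterations")
  st_full <- nsc_stats(X, y)
  if (is.null(delta_grid)) {
    delta_grid <- seq(0, max(abs(st_full$d_ik)), length.out = 30)
  }
  min_class <- min(table(y))
  if (min_class < folds) {
    warn(sprintf("smallest class has %d samples; reducing folds from %d",
                 min_class, folds))
    folds <- max(2, min_class)
  }
  set.seed(seed)
  classes <- st_full$classes
  err <- matrix(0, nrow = iterations, ncol = length(delta_grid))
  # held-out confusion at each delta, pooled over iterations and folds
  conf <- array(0, dim = c(length(classes), length(classes), length(delta_grid)),
                dimnames = list(truth = classes, pred = classes, NULL))
  for (it in seq_len(iterations)) {
    fold_id <- stratified_folds(as.character(y), folds)
    wrong <- numeric(length(delta_grid))
    for (f in seq_len(folds)) {
      test <- fold_id == f
      st <- nsc_stats(X[!test, , drop = FALSE], y[!test])
      for (d in seq_along(delta_grid)) {
        sh <- nsc_shrink(st, delta_grid[d])
        model <- structure(c(st, sh, list(delta = delta_grid[d])),
                           class = "nsc_model")
        pred <- predict(model, X[test, , drop = FALSE])$label
        wrong[d] <- wrong[d] + sum(pred != as.character(y)[test])
        tab <- table(factor(as.character(y)[test], levels = classes),
                     factor(pred, levels = classes))
        conf[, , d] <- conf[, , d] + tab
      }
    }
    err[it, ] <- wrong / nrow(X)
  }
  mean_err <- colMeans(err)
  best <- max(which(mean_err == min(mean_err)))   # ties -> larger delta
  chosen <- delta_grid[best]
  cm <- conf[, , best]
  class_stats <- tibble(
    class = classes,
    n = as.numeric(rowSums(cm)),
    sensitivity = unname(diag(cm) / rowSums(cm)),
    specificity = map_dbl(seq_along(classes), function(k) {
      tn <- sum(cm[-k, -k])
      fp <- sum(cm[-k, k])
      if (sum(cm[, k]) == 0) NA_real_ else tn / (tn + fp)
    })
  )
  model <- fit_nsc(X, y, delta = chosen)
  structure(list(
    error_by_delta = tibble(delta = delta_grid, cv_error = mean_err),
    chosen_delta = chosen,
    accuracy = sum(diag(cm)) / sum(cm),
    class_stats = class_stats,
    confusion = cm,
    model = model,
    surviving_features = model$surviving,
    iterations = iterations, folds = folds
  ), class = "nsc_cv")
}

#' @export
print.nsc_model <- function(x, ...) {
  cat(sprintf("Nearest shrunken centroid model: %d classes, %d features, delta = %.3g\n",
              length(x$classes), length(x$features), x$delta))
  cat(sprintf("  surviving features: %d\n", length(x$surviving)))
  invisible(x)
}

#' @export
print.nsc_cv <- function(x, ...) {
  cat(sprintf("NSC cross-validation: %d x %d-fold, chosen delta = %.3g, accuracy = %.3f\n",
              x$iterations, x$folds, x$chosen_delta, x$accuracy))
  print(x$class_stats)
  invisible(x)
}

#' Tidy an NSC model into per-feature, per-class centroid differences
#'
#' @param x An `nsc_model`.
#' @param ... Unused.
#' @return Tibble `feature`, `class`, `d`, `d_shrunk`, `shrunken_centroid`,
#'   `surviving`.
#' @export
tidy.nsc_model <- function(x, ...) {
  expand_grid(class = x$classes, feature = x$features) %>%
    mutate(
      d = as.vector(t(x$d_ik))[row_number()],
      d_shrunk = as.vector(t(x$d_shrunk))[row_number()],
      shrunken_centroid = as.vector(t(x$shrunken_centroids))[row_number()],
      surviving = .data$feature %in% x$surviving
    )
}

#' @export
glance.nsc_model <- function(x, ...) {
  tibble(n = x$n, n_classes = length(x$classes),
         n_features = length(x$features),
         n_surviving = length(x$surviving), delta = x$delta, s0 = x$s0)
}

#' Tidy cross-validation results: per-class predictive statistics
#'
#' @param x An `nsc_cv`.
#' @param ... Unused.
#' @export
tidy.nsc_cv <- function(x, ...) x$class_stats

#' @export
glance.nsc_cv <- function(x, ...) {
  tibble(accuracy = x$accuracy, chosen_delta = x$chosen_delta,
         n_surviving = length(x$surviving_features),
         iterations = x$iterations, folds = x$folds)
}

#' Cross-validation error profile over the shrinkage grid
#'
#' @param object An `nsc_cv`.
#' @param ... Unused.
#' @return A ggplot of mean CV error against the shrinkage threshold, with
#'   the chosen threshold marked.
#' @export
autoplot.nsc_cv <- function(object, ...) {
  ggplot(object$error_by_delta, aes(x = .data$delta, y = .data$cv_error)) +
    geom_line() +
    geom_point(size = 1) +
    geom_vline(xintercept = object$chosen_delta, linetype = "dashed") +
    labs(x = "shrinkage threshold", y = "mean CV error",
         title = sprintf("NSC cross-validation (%d x %d-fold)",
                         object$iterations, object$folds)) +
    theme_minimal()
}
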