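# Independent reference implementations used as oracles. These deliberately
# use brute force / closed forms and share no code with the package.

# Exact two-sided Mann-Whitney p by enumeration of all rank splits of the
# pooled tie-free sample.
oracle_mwu_exact <- function(x, y) {
  nx <- length(x)
  pooled <- c(x, y)
  stopifnot(!anyDuplicated(pooled))
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  splits <- combn(length(pooled), nx)
  u_all <- apply(splits, 2, function(idx) sum(r[idx]) - nx * (nx + 1) / 2)
  mu <- nx * length(y) / 2
  # two-sided: splits at least as extreme (distance from the mean) as observed
  mean(abs(u_all - mu) >= abs(u_obs - mu))
}

# Exact null distribution of U for group sizes (nx, ny): returns a function
# mapping an observed U to the two-sided enumeration p.
oracle_mwu_pfun <- function(nx, ny) {
  n <- nx + ny
  splits <- combn(n, nx)
  u_all <- apply(splits, 2, function(idx) sum(idx) - nx * (nx + 1) / 2)
  mu <- nx * ny / 2
  function(u_obs) mean(abs(u_all - mu) >= abs(u_obs - mu))
}

# Hypergeometric tail P(X >= k) by brute-force enumeration of all C(N, n)
# draws from a universe with K marked elements.
oracle_hypergeom <- function(k, K, n, N) {
  if (n == 0) return(as.numeric(k <= 0))
  draws <- combn(N, n)
  overlaps <- colSums(draws <= K)   # elements 1..K are the marked ones
  mean(overlaps >= k)
}

# Welch two-sample t-test from the textbook closed form.
oracle_welch <- function(a, b) {
  va <- var(a) / length(a)
  vb <- var(b) / length(b)
  t_stat <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  2 * pt(-abs(t_stat), df)
}

# Median polish by plain row/column sweeps, run far past convergence.
oracle_median_polish <- function(M, iter = 500) {
  overall <- 0
  row_eff <- rep(0, nrow(M))
  col_eff <- rep(0, ncol(M))
  R <- M
  for (i in seq_len(iter)) {
    rm <- apply(R, 1, median)
    R <- sweep(R, 1, rm)
    row_eff <- row_eff + rm
    cm <- median(col_eff)
    overall <- overall + cm
    col_eff <- col_eff - cm
    cm2 <- apply(R, 2, median)
    R <- sweep(R, 2, cm2)
    col_eff <- col_eff + cm2
    rm2 <- median(row_eff)
    overall <- overall + rm2
    row_eff <- row_eff - rm2
  }
  list(overall = overall, row = row_eff, col = col_eff, residuals = R)
}

# Brute-force complete linkage: recompute every inter-cluster distance from
# scratch at every step.
oracle_complete_linkage_heights <- function(d) {
  d <- as.matrix(d)
  clusters <- as.list(seq_len(nrow(d)))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(Inf, NA, NA)
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (i >= j) next
        dd <- max(d[clusters[[i]], clusters[[j]]])
        if (dd < best[1]) best <- c(dd, i, j)
      }
    }
    heights <- c(heights, best[1])
    clusters[[best[2]]] <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters[[best[3]]] <- NULL
  }
  heights
}

# Diagonal-covariance nearest-centroid classifier (the delta = 0 reference).
oracle_nearest_centroid <- function(X_train, y_train, X_test, s0_from) {
  classes <- sort(unique(as.character(y_train)))
  centroids <- t(vapply(classes, function(k) {
    colMeans(X_train[y_train == k, , drop = FALSE])
  }, numeric(ncol(X_train))))
  n <- nrow(X_train)
  ss <- Reduce(`+`, lapply(classes, function(k) {
    Z <- sweep(X_train[y_train == k, , drop = FALSE], 2, centroids[k, ])
    colSums(Z^2)
  }))
  s_i <- sqrt(ss / (n - length(classes)))
  s0 <- median(s_i)
  priors <- as.numeric(table(factor(y_train, classes))) / n
  scores <- vapply(seq_along(classes), function(k) {
    Z <- sweep(X_test, 2, centroids[k, ])
    rowSums(sweep(Z^2, 2, (s_i + s0)^2, `/`)) - 2 * log(priors[k])
  }, numeric(nrow(X_test)))
  classes[apply(matrix(scores, nrow = nrow(X_test)), 1, which.min)]
}

# Small fully-analyzable spot tibble for filter/calibration unit tests.
make_spot <- function(array_id = "A1", probe_id = "miR-001",
                      probe_class = "mirna",
                      fg_s = 250, bg_s = 50, frac_s = 0.9,
                      fg_r = 250, bg_r = 50, frac_r = 0.9, bg_sd = 5) {
  tibble::tibble(
    array_id = array_id, probe_id = probe_id, probe_class = probe_class,
    ch_sample_fg = fg_s, ch_sample_bg = bg_s, ch_sample_bg_sd = bg_sd,
    ch_sample_frac_px2sd = frac_s,
    ch_ref_fg = fg_r, ch_ref_bg = bg_r, ch_ref_bg_sd = bg_sd,
    ch_ref_frac_px2sd = frac_r
  )
}
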