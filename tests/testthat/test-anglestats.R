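# Distribution summaries, pairwise statistics, PCA, separation report.

test_that("distribution summaries match small-sample arithmetic", {
  s <- summarize_distribution(c(10, 20, 30, 40, 50))
  expect_equal(s$median, 30); expect_equal(s$q25, 20); expect_equal(s$q75, 40)
  expect_length(s$outliers, 0)
  expect_equal(s$whisker_low, 10); expect_equal(s$whisker_high, 50)
  # IQR = 0: every deviating point is an outlier, KDE degenerate when constant
  s2 <- summarize_distribution(c(rep(90, 59), 0))
  expect_equal(s2$outliers, 0)
  s3 <- summarize_distribution(rep(45, 10))
  expect_true(s3$degenerate); expect_null(s3$kde)
  # quartiles equal the sort-based linear interpolation oracle
  set.seed(21)
  draws <- c(rnorm(30, 40, 5), rnorm(30, 130, 10))
  sm <- summarize_distribution(draws)
  v <- sort(draws); n <- length(v)
  oracle_q <- function(p) { h <- (n - 1) * p + 1
    v[floor(h)] + (h - floor(h)) * (v[floor(h) + 1] - v[floor(h)]) }
  expect_equal(sm$q25, oracle_q(0.25)); expect_equal(sm$median, oracle_q(0.5))
  expect_equal(sm$q75, oracle_q(0.75))
  # KDE integrates to ~1
  dx <- diff(sm$kde$x[1:2])
  expect_lt(abs(sum(sm$kde$y) * dx - 1), 0.01)
  expect_error(summarize_distribution(c(1, 2, 3)), "N >= 4")
})

test_that("pairwise statistics agree with from-scratch formulas", {
  set.seed(7)
  a <- runif(10, 0, 180); b <- runif(10, 0, 180)
  ps <- pairwise_stats(a, b)
  expect_lt(abs(ps$pearson_r - bf_pearson(a, b)), 1e-12)
  expect_lt(abs(ps$spearman_rho - bf_spearman(a, b)), 1e-12)
  expect_lt(abs(ps$chi2_stat - bf_chi2_paired(a, b)), 1e-12)
  expect_equal(ps$chi2_df, 9)
  # identity and reversal
  id <- pairwise_stats(a, a)
  expect_equal(id$pearson_r, 1); expect_equal(id$spearman_rho, 1)
  expect_equal(id$chi2_stat, 0)
  inc <- sort(b)
  rev_ <- pairwise_stats(rev(inc), inc)
  expect_equal(rev_$spearman_rho, -1)
  # ties get average ranks
  at <- c(1, 2, 2, 3); bt <- c(4, 5, 6, 7)
  expect_lt(abs(pairwise_stats(at, bt)$spearman_rho - bf_spearman(at, bt)), 1e-12)
  # degenerate series
  z <- pairwise_stats(rep(10, 10), a)
  expect_true(is.na(z$pearson_r))
  # zero expected values are floored and flagged
  fz <- pairwise_stats(c(0, 10, 20, 30), c(0, 10, 20, 30))
  expect_true(fz$chi2_floored)
  expect_error(pairwise_stats(a, b[1:5]), "equal length")
})

test_that("binned chi-square uses shared Sturges bins", {
  set.seed(8)
  a <- runif(60, 0, 180); b <- runif(60, 0, 180)
  ps <- pairwise_stats(a, b, chi2_mode = "binned")
  k <- sturges_bins(60)
  expect_equal(ps$chi2_df, k - 1)
  expect_gte(ps$chi2_stat, 0)
})

test_that("standardized PCA matches the correlation-eigen oracle", {
  set.seed(14)
  x <- matrix(rnorm(4 * 6), 4, 6) + outer(rnorm(4), rep(1, 6))
  p <- pca_angles(x)
  o <- bf_pca_eigen(x)
  k <- length(p$explained_variance_ratio)
  expect_lt(max(abs(p$explained_variance_ratio - o$ratio[1:k])), 1e-9)
  expect_lt(abs(sum(p$explained_variance_ratio) - 1), 1e-9)
  expect_true(all(diff(p$explained_variance_ratio) <= 1e-12))
  # components orthonormal
  expect_equal(unname(crossprod(p$loadings)), diag(ncol(p$loadings)),
               tolerance = 1e-9)
  # sign convention: largest loading positive
  expect_true(all(apply(p$loadings, 2, function(l) l[which.max(abs(l))] > 0)))
})

test_that("PCA handles perfect correlation and zero-variance columns", {
  v <- rnorm(20)
  two <- cbind(v, 2 * v + 3)
  p <- pca_angles(two)
  expect_equal(p$explained_variance_ratio[1], 1)
  # independent standardized variables: ratios near 1/p
  set.seed(15)
  big <- matrix(rnorm(4000 * 4), 4000, 4)
  pb <- pca_angles(big)
  expect_lt(max(abs(pb$explained_variance_ratio - 0.25)), 0.03)
  withz <- cbind(matrix(rnorm(30), 10, 3), 0)
  expect_warning(pz <- pca_angles(withz), "zero-variance")
  expect_equal(ncol(pz$loadings), 3)
  expect_error(pca_angles(matrix(c(1, NA, 2, 3), 2)), "missing")
})

test_that("separation reports are symmetric and detect identical samples", {
  set.seed(16)
  base <- runif(30, 20, 40)
  twins <- list(a.1 = base, a.2 = base, b.1 = base, b.2 = base)
  rep0 <- separation_report(twins)
  expect_equal(rep0$min_between, 0, tolerance = 1e-9)
  expect_equal(rep0$centroid_distances, t(rep0$centroid_distances))
  near <- list(a.1 = runif(30, 10, 50), a.2 = runif(30, 10, 50),
               b.1 = runif(30, 120, 160), b.2 = runif(30, 120, 160))
  rep1 <- separation_report(near)
  expect_gt(rep1$min_between, 0)
  expect_gt(rep1$separation_ratio, 1)
  expect_error(separation_report(list(a = base)), ">= 2 samples")
})

test_that("the silhouette-style score agrees with the cluster package", {
  skip_if_not_installed("cluster")
  set.seed(17)
  x <- rbind(matrix(rnorm(20, 0), 10, 2), matrix(rnorm(20, 4), 10, 2))
  lab <- rep(c("u", "v"), each = 10)
  own <- orientfilm:::silhouette_score(x, lab)
  ref <- mean(cluster::silhouette(as.integer(factor(lab)), stats::dist(x))[, 3])
  expect_lt(abs(own - ref), 1e-9)
})
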