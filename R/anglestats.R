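# Cross-sample statistics on angle series: distribution summaries,
# correlation tests, chi-square comparison, standardized PCA, and a
# separation report.

series_angles <- function(x) {
  if (inherits(x, "angle_series")) x$angle else as.numeric(x)
}

#' Distribution summary of an angle series
#'
#' Quartiles by linear interpolation (type 7), 1.5-IQR outlier rule,
#' whiskers at the most extreme non-outlier points, and a Gaussian KDE with
#' Silverman's bandwidth for the violin curve. With all-identical angles
#' the IQR is 0, every other value is an outlier, and the KDE is flagged
#' degenerate.
#'
#' @param series an \code{angle_series} or numeric vector (N >= 4), degrees.
#' @return object of class \code{"angle_distribution"}: \code{median},
#'   \code{q25}, \code{q75}, \code{whisker_low}, \code{whisker_high},
#'   \code{outliers}, \code{kde} (list x, y or NULL), \code{degenerate}.
#' @export
summarize_distribution <- function(series) {
  a <- series_angles(series)
  if (length(a) < 4) stop("need N >= 4 angles", call. = FALSE)
  q <- stats::quantile(a, c(0.25, 0.5, 0.75), names = FALSE)
  iqr <- q[3] - q[1]
  lo <- q[1] - 1.5 * iqr; hi <- q[3] + 1.5 * iqr
  out <- a[a < lo | a > hi]
  inl <- a[a >= lo & a <= hi]
  degenerate <- stats::sd(a) == 0
  kde <- if (degenerate) NULL else {
    d <- stats::density(a, bw = "nrd0")
    list(x = d$x, y = d$y)
  }
  structure(list(median = q[2], q25 = q[1], q75 = q[3],
                 whisker_low = min(inl), whisker_high = max(inl),
                 outliers = out, kde = kde, degenerate = degenerate,
                 n = length(a)), class = "angle_distribution")
}

#' @export
print.angle_distribution <- function(x, ...) {
  cat(sprintf("angle distribution (N = %d): median %.1f, IQR [%.1f, %.1f], %d outlier(s)%s\n",
              x$n, x$median, x$q25, x$q75, length(x$outliers),
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Box/violin plot of angle series
#'
#' Boxplots with 1.5-IQR whiskers over violin-style density outlines, one
#' per series. Outliers are dropped from the drawn violins (statistics in
#' [pairwise_stats()] always use the full series).
#'
#' @param series_list named list of angle series.
#' @param drop_outliers drop 1.5-IQR outliers from the violin curves.
#' @export
plot_angle_violins <- function(series_list, drop_outliers = TRUE) {
  vals <- lapply(series_list, series_angles)
  graphics::plot(NULL, xlim = c(0.5, length(vals) + 0.5), ylim = c(0, 180),
                 xaxt = "n", xlab = "", ylab = "orientation (deg)")
  graphics::axis(1, at = seq_along(vals), labels = names(vals))
  for (i in seq_along(vals)) {
    v <- vals[[i]]
    if (drop_outliers) {
      s <- summarize_distribution(v)
      v <- v[v >= s$whisker_low & v <= s$whisker_high]
    }
    if (stats::sd(v) > 0) {
      d <- stats::density(v, bw = "nrd0")
      wdt <- 0.4 * d$y / max(d$y)
      graphics::polygon(c(i - wdt, rev(i + wdt)), c(d$x, rev(d$x)),
                        col = "gray90", border = "gray50")
    }
    graphics::boxplot(vals[[i]], at = i, add = TRUE, axes = FALSE,
                      boxwex = 0.25, outpch = 0, outcol = "red",
                      medcol = "red")
  }
  invisible(series_list)
}

#' Pairwise statistics between two angle series
#'
#' Pearson and Spearman correlations on the paired values, and a
#' chi-square goodness-of-fit of series a against series b. The default
#' chi-square pairs the sorted (quantile-matched) values and uses b as the
#' expectation, \eqn{\chi^2 = \sum_i (a_{(i)} - b_{(i)})^2 / b_{(i)}}, with
#' a two-sided p-value from the chi-square distribution at N - 1 degrees
#' of freedom; \code{chi2_mode = "binned"} instead compares counts in
#' shared Sturges bins. Angles are folded into [0, 180) first. Expected
#' values of 0 in a chi-square term are floored at \code{eps} and flagged.
#'
#' @param a,b angle series of equal length.
#' @param chi2_mode \code{"paired"} (default) or \code{"binned"}.
#' @param eps floor for zero expected values.
#' @return object of class \code{"pairwise_stats"} with fields
#'   \code{pearson_r}, \code{pearson_p}, \code{spearman_rho},
#'   \code{spearman_p}, \code{chi2_stat}, \code{chi2_df}, \code{chi2_p},
#'   \code{chi2_floored}.
#' @export
pairwise_stats <- function(a, b, chi2_mode = c("paired", "binned"), eps = 1e-6) {
  chi2_mode <- match.arg(chi2_mode)
  va <- fold180(series_angles(a)); vb <- fold180(series_angles(b))
  if (length(va) != length(vb)) stop("series must have equal length", call. = FALSE)
  n <- length(va)
  if (stats::sd(va) == 0 || stats::sd(vb) == 0) {
    pr <- list(estimate = NA_real_, p.value = NA_real_)
    sp <- list(estimate = NA_real_, p.value = NA_real_)
  } else {
    pr <- stats::cor.test(va, vb, method = "pearson")
    sp <- suppressWarnings(stats::cor.test(va, vb, method = "spearman"))
  }
  floored <- FALSE
  if (chi2_mode == "paired") {
    sa <- sort(va); sb <- sort(vb)
    den <- sb
    if (any(den <= 0)) { den <- pmax(den, eps); floored <- TRUE }
    stat <- sum((sa - sb)^2 / den)
    df <- n - 1
  } else {
    k <- sturges_bins(n)
    rng <- range(c(va, vb))
    if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
    br <- seq(rng[1], rng[2], length.out = k + 1)
    ca <- graphics::hist(va, breaks = br, plot = FALSE)$counts
    cb <- graphics::hist(vb, breaks = br, plot = FALSE)$counts
    expd <- cb
    if (any(expd <= 0)) { expd <- pmax(expd, eps); floored <- TRUE }
    stat <- sum((ca - expd)^2 / expd)
    df <- k - 1
  }
  p_lower <- stats::pchisq(stat, df)
  chi2_p <- min(1, 2 * min(p_lower, 1 - p_lower))
  structure(list(pearson_r = unname(pr$estimate), pearson_p = pr$p.value,
                 spearman_rho = unname(sp$estimate), spearman_p = sp$p.value,
                 chi2_stat = stat, chi2_df = df, chi2_p = chi2_p,
                 chi2_mode = chi2_mode, chi2_floored = floored),
            class = "pairwise_stats")
}

#' @export
print.pairwise_stats <- function(x, ...) {
  cat(sprintf("Pearson r = %.4f (p = %.3g); Spearman rho = %.4f (p = %.3g)\n",
              x$pearson_r, x$pearson_p, x$spearman_rho, x$spearman_p))
  cat(sprintf("chi-square (%s) = %.4g, df = %d, two-sided p = %.3g\n",
              x$chi2_mode, x$chi2_stat, x$chi2_df, x$chi2_p))
  invisible(x)
}

#' Standardized principal component analysis of angle variables
#'
#' Columns are standardized to mean 0 / sd 1 (so each angle variable
#' contributes equally) and the correlation-matrix eigenstructure is
#' extracted via [stats::prcomp]. Zero-variance columns are dropped with a
#' warning. Sign convention: the largest-magnitude loading of each
#' component is made positive.
#'
#' @param x observations x variables numeric matrix (>= 2 rows and
#'   columns, no missing values).
#' @param standardize scale columns to unit variance (default TRUE).
#' @return object of class \code{"angle_pca"}: \code{loadings}
#'   (variables x components), \code{scores} (observations x components),
#'   \code{explained_variance_ratio}.
#' @export
pca_angles <- function(x, standardize = TRUE) {
  x <- as.matrix(x)
  if (nrow(x) < 2 || ncol(x) < 2) stop("need >= 2 observations and variables")
  if (anyNA(x)) stop("missing values not allowed", call. = FALSE)
  v <- apply(x, 2, stats::var)
  if (standardize && any(v == 0)) {
    warning(sprintf("dropping %d zero-variance column(s)", sum(v == 0)))
    x <- x[, v > 0, drop = FALSE]
    if (ncol(x) < 2) stop("fewer than 2 non-constant variables remain")
  }
  pc <- stats::prcomp(x, center = TRUE, scale. = standardize)
  flip <- apply(pc$rotation, 2, function(l) sign(l[which.max(abs(l))]))
  flip[flip == 0] <- 1
  loadings <- sweep(pc$rotation, 2, flip, `*`)
  scores <- sweep(pc$x, 2, flip, `*`)
  evr <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(loadings = loadings, scores = scores,
                 explained_variance_ratio = evr,
                 standardized = standardize), class = "angle_pca")
}

#' @export
print.angle_pca <- function(x, ...) {
  k <- min(4, length(x$explained_variance_ratio))
  cat(sprintf("standardized PCA: %d components; explained variance ratio: %s\n",
              length(x$explained_variance_ratio),
              paste(sprintf("%.3f", x$explained_variance_ratio[1:k]), collapse = ", ")))
  invisible(x)
}

#' Build a samples x angle-variables matrix from series
#'
#' Each series becomes one row; \code{align = "sorted"} (default) sorts
#' each series ascending so column j is the j-th order statistic, making
#' columns comparable across samples; \code{"as_recorded"} keeps the
#' ROI/rank order.
#'
#' @param series_list list of angle series of equal length.
#' @param align \code{"sorted"} or \code{"as_recorded"}.
#' @return numeric matrix with one row per series.
#' @export
angle_series_matrix <- function(series_list, align = c("sorted", "as_recorded")) {
  align <- match.arg(align)
  vals <- lapply(series_list, series_angles)
  n <- unique(lengths(vals))
  if (length(n) != 1) stop("all series must have equal length", call. = FALSE)
  m <- do.call(rbind, if (align == "sorted") lapply(vals, sort) else vals)
  rownames(m) <- names(series_list)
  m
}

#' Separation of samples in the PCA score plane
#'
#' Runs [pca_angles()] on the sorted angle-series matrix, then reports
#' pairwise Euclidean distances between per-sample centroids in the first
#' two components, the mean within-sample pairwise replicate distance, the
#' ratio of the two, and a mean silhouette-style score (replicates
#' clustered by sample). Purely descriptive.
#'
#' @param series_list list of angle series; sample identity is taken from
#'   the \code{sample_id} attribute, or from names of the form
#'   \code{"<sample>.<replicate>"}, or supplied via \code{sample_of}.
#' @param sample_of optional character vector assigning each series to a
#'   sample.
#' @return object of class \code{"separation_report"}:
#'   \code{centroid_distances} (matrix), \code{min_between},
#'   \code{mean_within}, \code{separation_ratio} (min between-centroid
#'   distance over twice the mean within-sample distance),
#'   \code{silhouette}, \code{pca}.
#' @export
separation_report <- function(series_list, sample_of = NULL) {
  if (is.null(sample_of)) {
    sample_of <- vapply(seq_along(series_list), function(i) {
      sid <- attr(series_list[[i]], "sample_id")
      if (!is.null(sid)) as.character(sid)
      else sub("\\..*$", "", names(series_list)[i] %||% as.character(i))
    }, character(1))
  }
  samples <- unique(sample_of)
  if (length(samples) < 2) stop("need >= 2 samples", call. = FALSE)
  m <- angle_series_matrix(series_list)
  if (all(apply(m, 2, stats::var) == 0)) {
    # every series identical: no variance to decompose, all scores collapse
    pca <- NULL
    sc <- matrix(0, nrow(m), 2)
  } else {
    pca <- pca_angles(m)
    sc <- pca$scores
    sc <- if (ncol(sc) >= 2) sc[, 1:2, drop = FALSE] else cbind(sc[, 1], 0)
  }
  cents <- do.call(rbind, lapply(samples, function(s)
    colMeans(sc[sample_of == s, , drop = FALSE])))
  rownames(cents) <- samples
  cd <- as.matrix(stats::dist(cents))
  within <- unlist(lapply(samples, function(s) {
    pts <- sc[sample_of == s, , drop = FALSE]
    if (nrow(pts) < 2) return(numeric())
    as.numeric(stats::dist(pts))
  }))
  mean_within <- if (length(within)) mean(within) else 0
  min_between <- min(cd[upper.tri(cd)])
  sil <- silhouette_score(sc, sample_of)
  structure(list(centroid_distances = cd,
                 min_between = min_between,
                 mean_within = mean_within,
                 separation_ratio = if (mean_within > 0) min_between / (2 * mean_within) else Inf,
                 silhouette = sil, pca = pca, samples = samples),
            class = "separation_report")
}

# Mean silhouette of points labelled by sample (Euclidean); NA when every
# sample has a single replicate.
silhouette_score <- function(x, labels) {
  if (all(table(labels) < 2)) return(NA_real_)
  d <- as.matrix(stats::dist(x))
  n <- nrow(x)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    a <- if (sum(own) > 1) mean(d[i, own & seq_len(n) != i]) else 0
    b <- min(vapply(setdiff(unique(labels), labels[i]), function(l)
      mean(d[i, labels == l]), numeric(1)))
    s[i] <- if (max(a, b) > 0) (b - a) / max(a, b) else 0
  }
  mean(s)
}

#' @export
print.separation_report <- function(x, ...) {
  cat(sprintf("separation report over %d samples:\n", length(x$samples)))
  cat(sprintf("  min between-centroid distance: %.3f\n", x$min_between))
  cat(sprintf("  mean within-sample distance:   %.3f\n", x$mean_within))
  cat(sprintf("  separation ratio (>1 = separated): %.2f; silhouette %.3f\n",
              x$separation_ratio, x$silhouette))
  invisible(x)
}
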