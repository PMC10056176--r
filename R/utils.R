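# Internal numerical helpers shared across the pipeline.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so generators stay pure functions.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("`seed` must be a single finite number", call. = FALSE)
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  expr
}

stopifnot_finite <- function(...) {
  args <- list(...)
  nm <- names(args)
  for (i in seq_along(args)) {
    if (!is.numeric(args[[i]]) || any(!is.finite(args[[i]])))
      stop(sprintf("parameter `%s` must be finite numeric", nm[i]), call. = FALSE)
  }
  invisible(TRUE)
}

check_image <- function(image, min_dim = 1L) {
  if (!is.matrix(image) || !is.numeric(image))
    stop("image must be a numeric matrix (rows = y, cols = x)", call. = FALSE)
  if (any(!is.finite(image)))
    stop("image contains non-finite intensities", call. = FALSE)
  if (nrow(image) < min_dim || ncol(image) < min_dim)
    stop(sprintf("image must be at least %dx%d", min_dim, min_dim), call. = FALSE)
  invisible(image)
}

# Half-sample symmetric ("reflect", edge repeated) index vector for length n
# padded by r on each side: ..., 2, 1 | 1, 2, ..., n | n, n-1, ...
reflect_index <- function(n, r) {
  if (r >= n) {
    # fold repeatedly for very large pads
    idx <- seq_len(n)
    period <- c(idx, rev(idx))
    full <- rep(period, length.out = r + n + r + 2L * length(period))
    # locate phase so that positions r+1 .. r+n equal 1..n
    # simpler: build directly by mapping positions
    pos <- seq(-r + 1L, n + r)
    m <- ((pos - 1L) %% (2L * n))
    return(ifelse(m < n, m + 1L, 2L * n - m))
  }
  c(rev(seq_len(r)), seq_len(n), n + 1L - seq_len(r))
}

pad_reflect <- function(x, r) {
  x[reflect_index(nrow(x), r), reflect_index(ncol(x), r), drop = FALSE]
}

# Separable correlation with a symmetric 1-D kernel under reflective padding.
# Uses stats::filter (C loop) column-wise, then row-wise.
sep_filter_reflect <- function(x, kernel) {
  r <- (length(kernel) - 1L) %/% 2L
  if (r == 0L) return(x * kernel)
  xp <- pad_reflect(x, r)
  f1 <- stats::filter(xp, kernel, sides = 2)           # down columns
  f2 <- t(stats::filter(t(f1), kernel, sides = 2))     # along rows
  out <- f2[(r + 1L):(r + nrow(x)), (r + 1L):(r + ncol(x)), drop = FALSE]
  matrix(as.numeric(out), nrow(x), ncol(x))
}

# One-axis correlation (axis = 1 along rows/y, axis = 2 along columns/x).
axis_filter_reflect <- function(x, kernel, axis) {
  r <- (length(kernel) - 1L) %/% 2L
  if (axis == 1L) {
    xp <- x[reflect_index(nrow(x), r), , drop = FALSE]
    f <- stats::filter(xp, kernel, sides = 2)
    matrix(as.numeric(f[(r + 1L):(r + nrow(x)), , drop = FALSE]), nrow(x), ncol(x))
  } else {
    xp <- x[, reflect_index(ncol(x), r), drop = FALSE]
    f <- t(stats::filter(t(xp), kernel, sides = 2))
    matrix(as.numeric(f[, (r + 1L):(r + ncol(x)), drop = FALSE]), nrow(x), ncol(x))
  }
}

gaussian_kernel <- function(sigma, radius = ceiling(3 * sigma)) {
  t <- seq(-radius, radius)
  k <- exp(-t^2 / (2 * sigma^2))
  k / sum(k)
}

gaussian_deriv_kernel <- function(sigma, radius = ceiling(3 * sigma)) {
  t <- seq(-radius, radius)
  k <- -t * exp(-t^2 / (2 * sigma^2)) / sigma^2
  # normalize so that response to a unit ramp is exactly 1
  k / sum(-t * k)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Degrees <-> radians
deg2rad <- function(d) d * pi / 180
rad2deg <- function(r) r * 180 / pi

# Fold an angle in degrees into [0, 180)
fold180 <- function(a) {
  a <- a %% 180
  a[a < 0] <- a[a < 0] + 180
  a[a >= 180] <- 0   # guard: (-eps) %% 180 can round to exactly 180
  a
}

# Circular mean of orientation angles (degrees, period 180), optional weights.
circular_mean_180 <- function(angles_deg, weights = NULL) {
  a <- deg2rad(2 * angles_deg)
  if (is.null(weights)) weights <- rep(1, length(a))
  s <- sum(weights * sin(a)); c <- sum(weights * cos(a))
  fold180(rad2deg(atan2(s, c)) / 2)
}

# Smallest difference between two orientations on the 180-degree circle.
angle_diff_180 <- function(a, b) {
  d <- abs(fold180(a) - fold180(b))
  pmin(d, 180 - d)
}
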