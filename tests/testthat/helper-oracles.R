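# Independent brute-force oracles and small fixture builders.

# Rasterized disk of radius r (pixel centers inside the circle).
rasterize_disk <- function(r, pad = 3L) {
  n <- 2L * r + 2L * pad
  cx <- (n + 1) / 2
  X <- matrix(seq_len(n), n, n, byrow = TRUE)
  Y <- matrix(seq_len(n), n, n)
  (X - cx)^2 + (Y - cx)^2 <= r^2
}

rasterize_square <- function(s, pad = 3L) {
  n <- s + 2L * pad
  m <- matrix(FALSE, n, n)
  m[(pad + 1):(pad + s), (pad + 1):(pad + s)] <- TRUE
  m
}

# Half-sample symmetric mirror of index i into 1..n (independent of the
# package's implementation).
mirror_idx <- function(i, n) {
  p <- ((i - 1) %% (2 * n))
  p[p < 0] <- p[p < 0] + 2 * n
  ifelse(p < n, p + 1, 2 * n - p)
}

# Brute-force Niblack window mean/sd/threshold at pixel (i, j).
bf_niblack_at <- function(img, i, j, r, k) {
  rows <- mirror_idx((i - r):(i + r), nrow(img))
  cols <- mirror_idx((j - r):(j + r), ncol(img))
  v <- as.vector(img[rows, cols])
  m <- mean(v)
  S <- sqrt(mean((v - m)^2))
  c(m = m, S = S, thr = m + k * S)
}

# From-scratch Pearson correlation (sums of products).
bf_pearson <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  num <- n * sum(x * y) - sx * sy
  den <- sqrt(n * sum(x^2) - sx^2) * sqrt(n * sum(y^2) - sy^2)
  num / den
}

# Spearman rho via explicit average ranks + Pearson on ranks.
bf_spearman <- function(x, y) bf_pearson(rank(x), rank(y))

# Paired-sorted chi-square with expectation from b.
bf_chi2_paired <- function(a, b) sum((sort(a) - sort(b))^2 / sort(b))

# PCA of the correlation matrix by eigen-decomposition (independent of the
# prcomp/SVD route used in the package).
bf_pca_eigen <- function(x) {
  e <- eigen(stats::cor(x), symmetric = TRUE)
  list(values = e$values, ratio = e$values / sum(e$values), vectors = e$vectors)
}

# Direct-summation Gaussian-windowed structure tensor at a pixel.
bf_structure_tensor_at <- function(fx, fy, i, j, sigma) {
  r <- ceiling(3 * sigma)
  t <- seq(-r, r)
  k1 <- exp(-t^2 / (2 * sigma^2)); k1 <- k1 / sum(k1)
  K <- outer(k1, k1)
  rows <- mirror_idx((i - r):(i + r), nrow(fx))
  cols <- mirror_idx((j - r):(j + r), ncol(fx))
  c(Jxx = sum(K * fx[rows, cols]^2),
    Jxy = sum(K * fx[rows, cols] * fy[rows, cols]),
    Jyy = sum(K * fy[rows, cols]^2))
}
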