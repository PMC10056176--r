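# Connected-component extraction and per-object shape statistics.

#' Label connected foreground components and measure their shapes
#'
#' Finds maximal connected components of the foreground under 4- or
#' 8-connectivity (run-based union-find) and computes per-object shape
#' statistics: pixel area, boundary perimeter, circularity, moment-ellipse
#' aspect ratio, centroid, and a border-touching flag.
#'
#' The perimeter estimator counts the crack edges of the object boundary
#' (unit edges between foreground and background pixels, hole boundaries
#' included) and subtracts an anti-bias chamfer of 0.38 per boundary turn,
#' calibrated so that digitized disks of radius 10--80 px are measured
#' within about 1% of \eqn{2\pi r}. Naive crack counting would otherwise
#' overestimate smooth perimeters by up to a factor \eqn{4/\pi} and depress
#' circularity.
#'
#' @param mask a \code{binary_mask} from [apply_threshold()] or a logical
#'   matrix.
#' @param connectivity 8 (default; diagonal neighbors connect) or 4.
#' @return object of class \code{"segmented_objects"}: a data frame with
#'   columns \code{label}, \code{area} (px^2), \code{perimeter} (px),
#'   \code{circularity}, \code{aspect_ratio}, \code{centroid_x},
#'   \code{centroid_y}, \code{ellipse_major}, \code{ellipse_minor},
#'   \code{touches_border}; the integer label matrix is attached as
#'   attribute \code{"labels"}.
#' @export
label_objects <- function(mask, connectivity = 8) {
  m <- if (inherits(mask, "binary_mask")) mask$pixels else mask
  if (!is.matrix(m) || !is.logical(m)) stop("mask must be a logical matrix")
  if (!connectivity %in% c(4, 8)) stop("connectivity must be 4 or 8")
  h <- nrow(m); w <- ncol(m)
  lab <- matrix(0L, h, w)
  empty <- data.frame(label = integer(), area = numeric(), perimeter = numeric(),
                      circularity = numeric(), aspect_ratio = numeric(),
                      centroid_x = numeric(), centroid_y = numeric(),
                      ellipse_major = numeric(), ellipse_minor = numeric(),
                      touches_border = logical())
  wh <- which(m)
  if (length(wh) == 0L)
    return(structure(empty, labels = lab, connectivity = connectivity,
                     class = c("segmented_objects", "data.frame")))
  r <- ((wh - 1L) %% h) + 1L
  cc <- ((wh - 1L) %/% h) + 1L
  o <- order(r, cc)
  r <- r[o]; cc <- cc[o]
  newrun <- c(TRUE, diff(cc) != 1L | diff(r) != 0L)
  run_id <- cumsum(newrun)
  nrun <- run_id[length(run_id)]
  run_row <- r[newrun]
  run_s <- cc[newrun]
  run_e <- cc[c(newrun[-1], TRUE)]   # last pixel of each run

  # union-find over runs
  parent <- seq_len(nrun)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  slack <- if (connectivity == 8) 1L else 0L
  rows_of <- split(seq_len(nrun), run_row)
  row_keys <- as.integer(names(rows_of))
  for (ri in seq_along(row_keys)[-1]) {
    if (row_keys[ri] - row_keys[ri - 1L] != 1L) next
    prev <- rows_of[[ri - 1L]]; cur <- rows_of[[ri]]
    i <- 1L; j <- 1L
    while (i <= length(prev) && j <= length(cur)) {
      a <- prev[i]; b <- cur[j]
      if (run_s[b] <= run_e[a] + slack && run_e[b] >= run_s[a] - slack) {
        ra <- find(a); rb <- find(b)
        if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
      }
      if (run_e[a] < run_e[b]) i <- i + 1L else j <- j + 1L
    }
  }
  root <- vapply(seq_len(nrun), find, integer(1))
  lbl <- match(root, unique(root))
  # paint label matrix
  lens <- run_e - run_s + 1L
  px_idx <- sequence(lens, from = run_row + (run_s - 1L) * h, by = h)
  lab[px_idx] <- rep.int(lbl, lens)

  # per-object moments
  wh <- px_idx
  lv <- rep.int(lbl, lens)
  x <- ((wh - 1L) %/% h) + 1L
  y <- ((wh - 1L) %% h) + 1L
  n_obj <- max(lbl)
  sums <- rowsum(cbind(1, x, y, x^2, y^2, x * y,
                       x == 1L | x == w | y == 1L | y == h), lv)
  A <- sums[, 1]
  mx <- sums[, 2] / A; my <- sums[, 3] / A
  cxx <- sums[, 4] / A - mx^2
  cyy <- sums[, 5] / A - my^2
  cxy <- sums[, 6] / A - mx * my
  border <- sums[, 7] > 0
  t1 <- (cxx + cyy) / 2
  t2 <- sqrt(((cxx - cyy) / 2)^2 + cxy^2)
  l1 <- pmax(t1 + t2, 0); l2 <- pmax(t1 - t2, 0)
  major <- 4 * sqrt(l1); minor <- 4 * sqrt(l2)
  ar <- ifelse(A == 1, 1, ifelse(l2 <= 1e-12, Inf, sqrt(l1 / l2)))
  per <- perimeter_by_object(lab, n_obj, h, w)
  circ <- circularity(A, per)
  out <- data.frame(label = seq_len(n_obj), area = A, perimeter = per,
                    circularity = circ, aspect_ratio = ar,
                    centroid_x = mx, centroid_y = my,
                    ellipse_major = major, ellipse_minor = minor,
                    touches_border = border)
  structure(out, labels = lab, connectivity = connectivity,
            class = c("segmented_objects", "data.frame"))
}

# Crack-edge and turn counts per object; perimeter = E - 0.38 * T.
perimeter_by_object <- function(lab, n_obj, h, w) {
  per <- numeric(n_obj)
  # bounding boxes
  wh <- which(lab > 0L)
  lv <- lab[wh]
  x <- ((wh - 1L) %/% h) + 1L
  y <- ((wh - 1L) %% h) + 1L
  x0 <- tapply(x, lv, min); x1 <- tapply(x, lv, max)
  y0 <- tapply(y, lv, min); y1 <- tapply(y, lv, max)
  for (k in seq_len(n_obj)) {
    sub <- lab[y0[k]:y1[k], x0[k]:x1[k], drop = FALSE] == k
    st <- crack_stats(sub)
    per[k] <- st[1] - 0.38 * st[2]
  }
  per
}

# E = crack edges between fg and bg (object padded with background);
# T = boundary turns, counted at lattice vertices: a 2x2 neighborhood with
# 1 or 3 foreground pixels is one turn, a diagonal pair is two.
crack_stats <- function(m) {
  h <- nrow(m); w <- ncol(m)
  p <- matrix(FALSE, h + 2L, w + 2L)
  p[2:(h + 1L), 2:(w + 1L)] <- m
  E <- sum(p[-1, ] != p[-nrow(p), ]) + sum(p[, -1] != p[, -ncol(p)])
  a <- p[-nrow(p), -ncol(p)]; b <- p[-nrow(p), -1]
  cc <- p[-1, -ncol(p)]; d <- p[-1, -1]
  s <- a + b + cc + d
  diag_conf <- (s == 2L) & ((a & d) | (b & cc))
  TT <- sum(s == 1L | s == 3L) + 2L * sum(diag_conf)
  c(E, TT)
}

#' Circularity of an object
#'
#' \eqn{4 \pi A / P^2}, clamped to at most 1 (rasterized near-disks can
#' slightly exceed 1 under an unbiased perimeter estimator). 1 for an ideal
#' disk, \eqn{\pi/4 \approx 0.785} for an ideal square.
#'
#' @param area object area, px^2 (or any consistent unit).
#' @param perimeter object perimeter, px (> 0).
#' @return dimensionless circularity in (0, 1].
#' @export
circularity <- function(area, perimeter) {
  if (any(perimeter <= 0)) stop("perimeter must be > 0", call. = FALSE)
  clamp(4 * pi * area / perimeter^2, 0, 1)
}

#' Aspect ratio of a pixel set
#'
#' Ratio of the major to minor axis of the ellipse with the same second
#' central moments as the pixel set. A single pixel has aspect ratio 1;
#' perfectly collinear pixels return \code{Inf}.
#'
#' @param x,y pixel coordinates of one object.
#' @return dimensionless aspect ratio >= 1.
#' @export
aspect_ratio <- function(x, y) {
  n <- length(x)
  if (n != length(y) || n < 1) stop("x and y must be equal-length, non-empty")
  if (n == 1) return(1)
  cxx <- mean(x^2) - mean(x)^2
  cyy <- mean(y^2) - mean(y)^2
  cxy <- mean(x * y) - mean(x) * mean(y)
  t1 <- (cxx + cyy) / 2
  t2 <- sqrt(((cxx - cyy) / 2)^2 + cxy^2)
  l1 <- t1 + t2; l2 <- t1 - t2
  if (l2 <= 1e-12) return(Inf)
  sqrt(l1 / l2)
}

#' Sturges histogram bin count
#'
#' \eqn{k = \lceil 1 + 3.322 \log_{10} n \rceil}; 1 for n = 1.
#'
#' @param n number of observations (>= 1).
#' @return integer bin count.
#' @export
sturges_bins <- function(n) {
  if (any(n < 1)) stop("n must be >= 1", call. = FALSE)
  as.integer(ceiling(1 + 3.322 * log10(n)))
}

#' Summarize segmented objects
#'
#' Object count, total area (converted to mm^2 when a pixel scale is known),
#' Sturges-binned histograms of circularity and aspect ratio, and the
#' fractions of objects with circularity or aspect ratio within
#' \code{near_1_tol} of 1.
#'
#' @param objects a \code{segmented_objects} data frame.
#' @param scale_px_per_mm pixels per millimeter; if NULL, areas stay in px^2
#'   (with a notice).
#' @param near_1_tol tolerance for the "approximately 1" fractions,
#'   in (0, 0.5).
#' @return object of class \code{"shape_summary"}.
#' @export
summarize_shapes <- function(objects, scale_px_per_mm = NULL, near_1_tol = 0.1) {
  if (near_1_tol <= 0 || near_1_tol >= 0.5)
    stop("near_1_tol must be in (0, 0.5)", call. = FALSE)
  n <- nrow(objects)
  total_px <- sum(objects$area)
  if (is.null(scale_px_per_mm)) {
    message("summarize_shapes: no pixel scale given, areas reported in px^2")
    total_mm2 <- NA_real_
  } else {
    total_mm2 <- total_px / scale_px_per_mm^2
  }
  sturges_hist <- function(v) {
    if (n == 0L) return(list(breaks = numeric(), counts = integer()))
    k <- sturges_bins(n)
    v_fin <- v[is.finite(v)]
    rng <- range(v_fin)
    if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
    br <- seq(rng[1], rng[2], length.out = k + 1)
    hh <- graphics::hist(pmin(pmax(v, rng[1]), rng[2]), breaks = br, plot = FALSE)
    list(breaks = hh$breaks, counts = hh$counts)
  }
  structure(list(
    count = n,
    total_area_px2 = total_px,
    total_area_mm2 = total_mm2,
    circ_histogram = sturges_hist(objects$circularity),
    ar_histogram = sturges_hist(objects$aspect_ratio),
    fraction_circ_near_1 = if (n) mean(abs(objects$circularity - 1) <= near_1_tol) else NA_real_,
    fraction_ar_near_1 = if (n) mean(abs(objects$aspect_ratio - 1) <= near_1_tol) else NA_real_,
    near_1_tol = near_1_tol), class = "shape_summary")
}

#' @export
print.shape_summary <- function(x, ...) {
  cat(sprintf("shape summary: %d objects, total area %.1f px^2%s\n",
              x$count, x$total_area_px2,
              if (is.na(x$total_area_mm2)) "" else sprintf(" (%.2f mm^2)", x$total_area_mm2)))
  if (x$count > 0)
    cat(sprintf("  fraction with Circ ~ 1 (tol %.2f): %.2f; AR ~ 1: %.2f\n",
                x$near_1_tol, x$fraction_circ_near_1, x$fraction_ar_near_1))
  invisible(x)
}
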