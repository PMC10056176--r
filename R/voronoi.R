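# Voronoi tessellation of object centroids and the Voronoi regularity index.

#' Voronoi tessellation of points in a rectangular window
#'
#' Euclidean Voronoi diagram computed by half-plane clipping: each seed's
#' cell starts as the window rectangle and is clipped against the
#' perpendicular bisector of every other seed (nearest seeds first, with a
#' distance cutoff that prunes seeds too far away to cut the current cell).
#' Cells are clipped to the window; a cell is flagged unbounded/border if
#' its clipped polygon touches the window boundary (its unclipped region is
#' infinite or reaches outside the window).
#'
#' @param points n x 2 matrix (or data frame) of seed coordinates (x, y),
#'   n >= 3, not all collinear. Exact duplicate seeds are merged with a
#'   warning.
#' @param window \code{c(xmin, ymin, xmax, ymax)}; defaults to the bounding
#'   box of the points.
#' @return object of class \code{"voronoi_diagram"}: \code{seeds} (n x 2),
#'   \code{cells} (list of polygon vertex matrices, counter-clockwise),
#'   \code{bounded} (logical; FALSE when the cell touches the window
#'   boundary), \code{window}.
#' @export
tessellate <- function(points, window = NULL) {
  pts <- as.matrix(points)
  if (ncol(pts) != 2L) stop("points must have two columns (x, y)", call. = FALSE)
  if (anyDuplicated(pts)) {
    warning("duplicate seeds merged")
    pts <- unique(pts)
  }
  n <- nrow(pts)
  if (n < 3L) stop("need at least 3 distinct points", call. = FALSE)
  # collinearity check via second singular value of centered coordinates
  ctr <- sweep(pts, 2, colMeans(pts))
  sv <- svd(ctr, nu = 0, nv = 0)$d
  if (sv[2] <= 1e-12 * max(sv[1], 1))
    stop("degenerate input: all points are collinear", call. = FALSE)
  if (is.null(window))
    window <- c(min(pts[, 1]), min(pts[, 2]), max(pts[, 1]), max(pts[, 2]))
  wx0 <- window[1]; wy0 <- window[2]; wx1 <- window[3]; wy1 <- window[4]
  base_poly <- cbind(c(wx0, wx1, wx1, wx0), c(wy0, wy0, wy1, wy1))
  tol <- 1e-9 * max(wx1 - wx0, wy1 - wy0)
  cells <- vector("list", n)
  bounded <- logical(n)
  for (i in seq_len(n)) {
    pi_ <- pts[i, ]
    d2 <- (pts[, 1] - pi_[1])^2 + (pts[, 2] - pi_[2])^2
    ord <- order(d2)
    poly <- base_poly
    for (j in ord) {
      if (j == i) next
      # prune: a seed farther than twice the max vertex distance cannot cut
      rmax2 <- max((poly[, 1] - pi_[1])^2 + (poly[, 2] - pi_[2])^2)
      if (d2[j] > 4 * rmax2) break
      poly <- clip_halfplane(poly, pi_, pts[j, ])
      if (nrow(poly) < 3L) break
    }
    cells[[i]] <- poly
    on_border <- nrow(poly) == 0L ||
      any(abs(poly[, 1] - wx0) < tol | abs(poly[, 1] - wx1) < tol |
          abs(poly[, 2] - wy0) < tol | abs(poly[, 2] - wy1) < tol)
    bounded[i] <- !on_border
  }
  structure(list(seeds = pts, cells = cells, bounded = bounded, window = window),
            class = "voronoi_diagram")
}

# Sutherland-Hodgman clip of a convex polygon by the half-plane of points
# closer to `a` than to `b` (i.e. (q - m) . (b - a) <= 0, m the midpoint).
clip_halfplane <- function(poly, a, b) {
  nv <- nrow(poly)
  if (nv == 0L) return(poly)
  dir <- b - a
  m <- (a + b) / 2
  val <- (poly[, 1] - m[1]) * dir[1] + (poly[, 2] - m[2]) * dir[2]
  inside <- val <= 0
  if (all(inside)) return(poly)
  if (!any(inside)) return(poly[0, , drop = FALSE])
  nxt <- c(2:nv, 1L)
  out <- matrix(0, nv + 2L, 2L); k <- 0L
  for (e in seq_len(nv)) {
    f <- nxt[e]
    if (inside[e]) { k <- k + 1L; out[k, ] <- poly[e, ] }
    if (inside[e] != inside[f]) {
      t <- val[e] / (val[e] - val[f])
      k <- k + 1L
      out[k, ] <- poly[e, ] + t * (poly[f, ] - poly[e, ])
    }
  }
  out[seq_len(k), , drop = FALSE]
}

polygon_area <- function(p) {
  n <- nrow(p)
  if (n < 3L) return(0)
  j <- c(2:n, 1L)
  abs(sum(p[, 1] * p[j, 2] - p[j, 1] * p[, 2])) / 2
}

polygon_centroid <- function(p) {
  n <- nrow(p)
  j <- c(2:n, 1L)
  cr <- p[, 1] * p[j, 2] - p[j, 1] * p[, 2]
  a <- sum(cr) / 2
  if (abs(a) < 1e-300) return(colMeans(p))
  c(sum((p[, 1] + p[j, 1]) * cr), sum((p[, 2] + p[j, 2]) * cr)) / (6 * a)
}

#' Voronoi regularity index
#'
#' Pools the distances from each included cell's center to its polygon
#' vertices and returns \code{VRI = mean(D) / sd(D)}. Large values indicate
#' a regular (lattice-like) seed arrangement; values near zero indicate
#' irregular/random arrangements. A perfectly regular pattern has all
#' distances equal (sd 0) and returns \code{Inf} with a
#' \code{regular_pattern} flag.
#'
#' @param diagram a \code{voronoi_diagram}.
#' @param include_unbounded include cells touching the window boundary
#'   (default FALSE: clipping distorts their distances).
#' @param cell_center \code{"centroid"} (polygon centroid of the clipped
#'   cell, default) or \code{"seed"} (the generator point).
#' @param per_cell_mean if TRUE, use each cell's mean center-to-vertex
#'   distance as one observation instead of pooling all distances.
#' @return object of class \code{"vri_result"}: \code{vri}, \code{D_mean},
#'   \code{D_sd}, \code{n_cells_used}, \code{regular_pattern},
#'   \code{distances}.
#' @export
vri <- function(diagram, include_unbounded = FALSE,
                cell_center = c("centroid", "seed"), per_cell_mean = FALSE) {
  if (!inherits(diagram, "voronoi_diagram")) stop("diagram must be a voronoi_diagram")
  cell_center <- match.arg(cell_center)
  use <- if (include_unbounded) rep(TRUE, length(diagram$cells)) else diagram$bounded
  use <- use & vapply(diagram$cells, nrow, integer(1)) >= 3L
  if (sum(use) < 2L) stop("need at least 2 included cells", call. = FALSE)
  dist_list <- lapply(which(use), function(i) {
    p <- diagram$cells[[i]]
    ctr <- if (cell_center == "centroid") polygon_centroid(p) else diagram$seeds[i, ]
    sqrt((p[, 1] - ctr[1])^2 + (p[, 2] - ctr[2])^2)
  })
  d <- if (per_cell_mean) vapply(dist_list, mean, numeric(1)) else unlist(dist_list)
  D_mean <- mean(d); D_sd <- stats::sd(d)
  regular <- !is.finite(D_sd) || D_sd <= 1e-9 * D_mean
  structure(list(vri = if (regular) Inf else D_mean / D_sd,
                 D_mean = D_mean, D_sd = D_sd,
                 n_cells_used = sum(use),
                 regular_pattern = regular,
                 distances = d), class = "vri_result")
}

#' @export
print.vri_result <- function(x, ...) {
  cat(sprintf("VRI = %s (D mean %.4g, sd %.4g, %d cells%s)\n",
              if (is.finite(x$vri)) sprintf("%.3f", x$vri) else "Inf",
              x$D_mean, x$D_sd, x$n_cells_used,
              if (x$regular_pattern) ", regular pattern" else ""))
  invisible(x)
}

#' Voronoi seeds from segmented objects
#'
#' Uses object centroids as tessellation generators; duplicate centroids
#' are merged with a warning.
#'
#' @param objects a \code{segmented_objects} data frame (>= 3 objects).
#' @return matrix of (x, y) seed coordinates.
#' @export
seeds_from_objects <- function(objects) {
  if (nrow(objects) < 3L) stop("need at least 3 objects", call. = FALSE)
  pts <- cbind(x = objects$centroid_x, y = objects$centroid_y)
  if (anyDuplicated(pts)) {
    warning("objects with identical centroids merged into one seed")
    pts <- unique(pts)
  }
  pts
}
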