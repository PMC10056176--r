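# ROI tiling, per-ROI directional summaries, orientation histograms, and
# angle-series collection.

#' Tile an image with square regions of interest
#'
#' Deterministic grid layout: ROI origins are evenly spaced so the tiles
#' cover the whole frame, with zero overlap when the counts divide the
#' image evenly and minimal overlap otherwise. With \code{n_rois = 1} the
#' single ROI is centered.
#'
#' @param image_shape \code{c(height, width)} px.
#' @param n_rois number of ROIs (>= 1).
#' @param roi_size \code{c(width, height)} of each ROI in px (a scalar is
#'   recycled; default 250, the footprint of a 2.0 x 2.0 mm region at
#'   125 px/mm).
#' @return data frame with columns \code{id}, \code{x0}, \code{y0} (1-based
#'   top-left corner), \code{w}, \code{h}.
#' @export
tile_rois <- function(image_shape, n_rois = 20, roi_size = 250) {
  H <- image_shape[1]; W <- image_shape[2]
  if (length(roi_size) == 1L) roi_size <- c(roi_size, roi_size)
  rw <- roi_size[1]; rh <- roi_size[2]
  if (rw > W || rh > H) stop("ROI larger than image", call. = FALSE)
  if (n_rois < 1L) stop("n_rois must be >= 1", call. = FALSE)
  nc <- max(1L, ceiling(sqrt(n_rois * W / H)))
  nr <- ceiling(n_rois / nc)
  xo <- if (nc == 1L) round((W - rw) / 2) else round((seq_len(nc) - 1L) * (W - rw) / (nc - 1L))
  yo <- if (nr == 1L) round((H - rh) / 2) else round((seq_len(nr) - 1L) * (H - rh) / (nr - 1L))
  g <- expand.grid(x0 = xo + 1L, y0 = yo + 1L)[seq_len(n_rois), , drop = FALSE]
  data.frame(id = seq_len(n_rois), x0 = g$x0, y0 = g$y0, w = rw, h = rh,
             row.names = NULL)
}

#' Directional summary of one region of interest
#'
#' Aggregates the per-pixel structure tensors over the ROI (a plain average
#' of the tensor entries, which weights pixels by their gradient energy so
#' textureless pixels do not dilute the estimate), then reports the
#' dominant orientation and the eigen-ellipse of the aggregated tensor:
#' axes proportional to the square roots of its eigenvalues, elongation =
#' major/minor. Also detects up to \code{max_peaks} modal angles of the
#' coherency-and-energy-weighted angle histogram, so that a ROI straddling
#' two differently oriented subdomains reports both directions even though
#' its aggregated ellipse looks nearly isotropic.
#'
#' @param orientation an \code{orientation_field}.
#' @param tensor the matching \code{structure_tensor_field}.
#' @param roi one row of [tile_rois()] (or a list with x0, y0, w, h).
#' @param max_peaks maximum number of modal angles reported.
#' @param iso_elongation elongation below which the ROI is flagged
#'   near-isotropic.
#' @return object of class \code{"roi_summary"}: \code{dominant_theta}
#'   (deg), \code{mean_coherency}, \code{elongation}, \code{ellipse}
#'   (major, minor, direction), \code{peak_angles}, \code{near_isotropic},
#'   \code{mean_tensor}.
#' @export
summarize_roi <- function(orientation, tensor, roi, max_peaks = 3L,
                          iso_elongation = 1.5) {
  rows <- roi$y0:(roi$y0 + roi$h - 1L)
  cols <- roi$x0:(roi$x0 + roi$w - 1L)
  if (max(rows) > nrow(orientation$theta) || max(cols) > ncol(orientation$theta))
    stop("ROI outside the field", call. = FALSE)
  Jxx <- mean(tensor$Jxx[rows, cols]); Jxy <- mean(tensor$Jxy[rows, cols])
  Jyy <- mean(tensor$Jyy[rows, cols])
  th <- orientation$theta[rows, cols]
  ok <- !is.na(th)
  if (!any(ok)) {
    return(structure(list(dominant_theta = NA_real_, mean_coherency = 0,
                          elongation = 1, ellipse = c(major = 0, minor = 0, direction = NA),
                          peak_angles = numeric(), near_isotropic = TRUE,
                          mean_tensor = matrix(c(Jxx, Jxy, Jxy, Jyy), 2)),
                     class = "roi_summary"))
  }
  dom <- tensor_theta_deg(Jxx, Jxy, Jyy)
  t1 <- (Jxx + Jyy) / 2
  t2 <- sqrt(((Jxx - Jyy) / 2)^2 + Jxy^2)
  l1 <- max(t1 + t2, 0); l2 <- max(t1 - t2, 0)
  elong <- if (l2 <= 1e-15 * max(l1, 1e-300)) Inf else sqrt(l1 / l2)
  wgt <- (orientation$coherency * orientation$energy)[rows, cols]
  peaks <- histogram_peaks(th[ok], wgt[ok], max_peaks = max_peaks)
  structure(list(dominant_theta = dom,
                 mean_coherency = mean(orientation$coherency[rows, cols]),
                 elongation = elong,
                 ellipse = c(major = sqrt(l1), minor = sqrt(l2), direction = dom),
                 peak_angles = peaks,
                 near_isotropic = is.finite(elong) && elong < iso_elongation,
                 mean_tensor = matrix(c(Jxx, Jxy, Jxy, Jyy), 2)),
            class = "roi_summary")
}

#' @export
print.roi_summary <- function(x, ...) {
  cat(sprintf("ROI summary: dominant theta %.1f deg, mean C %.3f, elongation %.2f%s\n",
              x$dominant_theta, x$mean_coherency, x$elongation,
              if (x$near_isotropic) " (near-isotropic)" else ""))
  if (length(x$peak_angles))
    cat("  peak angles:", paste(sprintf("%.1f", x$peak_angles), collapse = ", "), "\n")
  invisible(x)
}

# Modal angles of a weighted 2-degree-bin histogram on [0,180): smoothed
# with a 3-bin circular mean; peaks are local maxima above 1.5x the uniform
# level, ordered by mass (ties: larger mass, then smaller angle); sub-bin
# position refined by parabolic interpolation.
histogram_peaks <- function(angles, weights, max_peaks = 3L, bin_deg = 2,
                            min_rel = 1.5) {
  nb <- as.integer(180 / bin_deg)
  bin <- pmin(floor(fold180(angles) / bin_deg), nb - 1L) + 1L
  mass <- vapply(seq_len(nb), function(b) sum(weights[bin == b]), numeric(1))
  tot <- sum(mass)
  if (tot <= 0) return(numeric())
  sm <- (mass + mass[c(nb, 1:(nb - 1))] + mass[c(2:nb, 1)]) / 3
  lev <- min_rel * tot / nb
  left <- sm[c(nb, 1:(nb - 1))]; right <- sm[c(2:nb, 1)]
  is_peak <- sm >= left & sm > right & sm > lev
  idx <- which(is_peak)
  if (!length(idx)) return(numeric())
  idx <- idx[order(-sm[idx], idx)]
  idx <- idx[seq_len(min(max_peaks, length(idx)))]
  vapply(idx, function(b) {
    l <- sm[if (b == 1L) nb else b - 1L]; cmass <- sm[b]; r <- sm[if (b == nb) 1L else b + 1L]
    den <- l - 2 * cmass + r
    off <- if (abs(den) < 1e-300) 0 else clamp(0.5 * (l - r) / den, -0.5, 0.5)
    fold180((b - 0.5 + off) * bin_deg)
  }, numeric(1))
}

#' Weighted orientation histogram of a region
#'
#' Angular histogram on [0, 180) with period-180 wraparound, optionally
#' weighted per pixel by coherency or coherency x energy, normalized to
#' total mass 1. The result can be drawn as a polar plot.
#'
#' @param orientation an \code{orientation_field}.
#' @param region optional logical matrix selecting pixels (default: all).
#' @param weights \code{"coherency_energy"} (default), \code{"coherency"},
#'   or \code{"none"}.
#' @param n_bins number of angular bins (>= 4).
#' @return object of class \code{"orientation_histogram"}: \code{breaks}
#'   (deg), \code{centers}, \code{mass} (sums to 1).
#' @export
orientation_histogram <- function(orientation, region = NULL,
                                  weights = c("coherency_energy", "coherency", "none"),
                                  n_bins = 36) {
  weights <- match.arg(weights)
  if (n_bins < 4L) stop("n_bins must be >= 4", call. = FALSE)
  th <- orientation$theta
  sel <- if (is.null(region)) !is.na(th) else region & !is.na(th)
  if (!any(sel)) stop("empty region (no defined orientations)", call. = FALSE)
  wgt <- switch(weights,
                none = rep(1, sum(sel)),
                coherency = orientation$coherency[sel],
                coherency_energy = (orientation$coherency * orientation$energy)[sel])
  bw <- 180 / n_bins
  bin <- pmin(floor(fold180(th[sel]) / bw), n_bins - 1L) + 1L
  mass <- vapply(seq_len(n_bins), function(b) sum(wgt[bin == b]), numeric(1))
  if (sum(mass) <= 0) stop("region has zero total weight", call. = FALSE)
  structure(list(breaks = seq(0, 180, by = bw),
                 centers = seq(bw / 2, 180 - bw / 2, by = bw),
                 mass = mass / sum(mass), weights = weights),
            class = "orientation_histogram")
}

#' @export
plot.orientation_histogram <- function(x, ...) {
  a <- deg2rad(c(x$centers, x$centers + 180))
  r <- c(x$mass, x$mass)
  graphics::plot(r * cos(a), -r * sin(a), type = "l", asp = 1,
                 xlab = "", ylab = "", main = "orientation distribution", ...)
  graphics::abline(h = 0, v = 0, col = "gray80")
  invisible(x)
}

#' Collect an angle series over ROIs
#'
#' Runs the orientation analysis over an image, tiles it with ROIs, and
#' records the top \code{peaks_per_roi} modal angles of every ROI (padded
#' with the ROI's dominant angle when fewer peaks exist). 20 ROIs x 3
#' peaks gives the customary series of N = 60 orientations per sample.
#' All angles lie in [0, 180).
#'
#' @param image grayscale matrix, or a precomputed \code{orientation_field}
#'   (then \code{tensor} must be supplied too).
#' @param rois ROI table from [tile_rois()]; built automatically from
#'   \code{n_rois}/\code{roi_size} when NULL.
#' @param peaks_per_roi angles recorded per ROI.
#' @param n_rois,roi_size used when \code{rois} is NULL.
#' @param operator,window_sigma orientation analysis parameters.
#' @param sample_id optional label carried into cross-sample statistics.
#' @param tensor precomputed \code{structure_tensor_field} when
#'   \code{image} is an \code{orientation_field}.
#' @return object of class \code{"angle_series"}: data frame with columns
#'   \code{roi_id}, \code{rank}, \code{angle}; attributes \code{sample_id}
#'   and \code{n}.
#' @export
collect_angle_series <- function(image, rois = NULL, peaks_per_roi = 3L,
                                 n_rois = 20L, roi_size = 250,
                                 operator = "riesz", window_sigma = 8,
                                 sample_id = NULL, tensor = NULL) {
  if (inherits(image, "orientation_field")) {
    orient <- image
    if (is.null(tensor)) stop("supply the structure tensor with a precomputed field")
  } else {
    tensor <- structure_tensor(gradient(image, operator), window_sigma)
    orient <- orientation_and_coherency(tensor)
  }
  shape <- dim(orient$theta)
  if (is.null(rois)) rois <- tile_rois(shape, n_rois, roi_size)
  out <- do.call(rbind, lapply(seq_len(nrow(rois)), function(i) {
    s <- summarize_roi(orient, tensor, rois[i, ], max_peaks = peaks_per_roi)
    ang <- s$peak_angles
    if (length(ang) < peaks_per_roi)
      ang <- c(ang, rep(if (is.na(s$dominant_theta)) 0 else s$dominant_theta,
                        peaks_per_roi - length(ang)))
    data.frame(roi_id = rois$id[i], rank = seq_len(peaks_per_roi),
               angle = fold180(ang))
  }))
  structure(out, sample_id = sample_id, n = nrow(out),
            class = c("angle_series", "data.frame"))
}

#' @export
print.angle_series <- function(x, ...) {
  cat(sprintf("angle series%s: N = %d orientations over %d ROIs\n",
              if (is.null(attr(x, "sample_id"))) "" else
                paste0(" for ", attr(x, "sample_id")),
              nrow(x), length(unique(x$roi_id))))
  print.data.frame(utils::head(x, 6))
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}
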