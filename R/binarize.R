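# Local Niblack thresholding of grayscale images into foreground masks
# (pathway a of the workflow), plus coverage quantification.

#' Select the best-contrasted channel of an RGB image
#'
#' Scores each 8-bit channel by its intensity standard deviation and returns
#' the highest-scoring one as the grayscale working image (ties broken by
#' channel order R < G < B). A grayscale matrix passes through unchanged
#' with a notice.
#'
#' @param image either an h x w x 3 numeric array or a grayscale matrix.
#' @param channel \code{"auto"} (default) or one of \code{"r"},
#'   \code{"g"}, \code{"b"} to override the automatic choice.
#' @return list with \code{image} (grayscale matrix), \code{channel}
#'   (\code{"r"}, \code{"g"}, \code{"b"} or \code{"gray"}), and
#'   \code{scores} (named sd of each channel, NULL for grayscale input).
#' @export
select_channel <- function(image, channel = c("auto", "r", "g", "b")) {
  channel <- match.arg(channel)
  if (is.matrix(image)) {
    message("select_channel: grayscale input, returned unchanged")
    return(list(image = image, channel = "gray", scores = NULL))
  }
  if (!(is.array(image) && length(dim(image)) == 3L && dim(image)[3] == 3L))
    stop("expected an h x w x 3 RGB array or a grayscale matrix", call. = FALSE)
  scores <- c(r = stats::sd(image[, , 1]), g = stats::sd(image[, , 2]),
              b = stats::sd(image[, , 3]))
  pick <- if (channel == "auto") which.max(scores) else match(channel, c("r", "g", "b"))
  list(image = image[, , pick], channel = c("r", "g", "b")[pick], scores = scores)
}

#' Niblack local threshold field
#'
#' Per-pixel threshold \code{thr = m + k * S}, where \code{m} and \code{S}
#' are the mean and (population) standard deviation of the intensities in
#' the (2 radius + 1)^2 window centered at the pixel, with reflective
#' boundary padding. Implemented with integral images; a brute-force window
#' oracle reproduces it to machine precision.
#'
#' @param image grayscale numeric matrix.
#' @param radius window half-size in pixels (window is (2r+1) x (2r+1)).
#' @param k dimensionless Niblack weight; negative values lower the
#'   threshold below the local mean (default -0.2, suited to dark
#'   foreground on a lighter substrate).
#' @return object of class \code{"threshold_field"}: matrices \code{thr},
#'   \code{m}, \code{S} plus the parameters.
#' @export
niblack_field <- function(image, radius, k = -0.2) {
  check_image(image)
  stopifnot_finite(radius = radius, k = k)
  radius <- as.integer(radius)
  if (radius < 1L) stop("radius must be >= 1", call. = FALSE)
  if (radius >= min(dim(image)))
    stop("radius too large: reflective padding degenerates for radius >= min(h, w)",
         call. = FALSE)
  st <- window_mean_sd(image, radius)
  structure(list(thr = st$m + k * st$S, m = st$m, S = st$S,
                 radius = radius, k = k), class = "threshold_field")
}

# Integral-image window mean and population SD with reflective padding.
window_mean_sd <- function(image, r) {
  p <- pad_reflect(image, r)
  n <- (2 * r + 1)^2
  s1 <- box_sum(p, r)
  s2 <- box_sum(p * p, r)
  m <- s1 / n
  v <- s2 / n - m * m
  v[v < 0] <- 0
  list(m = m, S = sqrt(v))
}

# Sum over (2r+1)^2 windows of the padded matrix, valid region only.
box_sum <- function(p, r) {
  cs <- apply(p, 2, cumsum)
  cs <- rbind(0, cs)
  colsum <- cs[(2 * r + 2):nrow(cs), , drop = FALSE] - cs[1:(nrow(cs) - 2 * r - 1), , drop = FALSE]
  cs2 <- t(apply(colsum, 1, cumsum))
  cs2 <- cbind(0, cs2)
  cs2[, (2 * r + 2):ncol(cs2), drop = FALSE] - cs2[, 1:(ncol(cs2) - 2 * r - 1), drop = FALSE]
}

#' Apply a threshold field to an image
#'
#' \code{dark_foreground}: foreground where pixel < threshold;
#' \code{bright_foreground}: foreground where pixel > threshold. Pixels
#' exactly equal to their threshold are background under either polarity.
#'
#' @param image grayscale matrix.
#' @param field a \code{threshold_field} (or a plain matrix/scalar of
#'   thresholds).
#' @param polarity \code{"dark_foreground"} or \code{"bright_foreground"}.
#' @return object of class \code{"binary_mask"}: logical matrix
#'   \code{pixels} plus \code{coverage}, the foreground fraction.
#' @export
apply_threshold <- function(image, field,
                            polarity = c("dark_foreground", "bright_foreground")) {
  polarity <- match.arg(polarity)
  thr <- if (inherits(field, "threshold_field")) field$thr else field
  if (is.matrix(thr) && !all(dim(thr) == dim(image)))
    stop("image/threshold shape mismatch", call. = FALSE)
  px <- if (polarity == "dark_foreground") image < thr else image > thr
  structure(list(pixels = px, coverage = mean(px), polarity = polarity),
            class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("binary mask %d x %d, coverage %.4f (%s)\n",
              nrow(x$pixels), ncol(x$pixels), x$coverage, x$polarity))
  invisible(x)
}

#' One-call Niblack binarization
#'
#' @inheritParams niblack_field
#' @inheritParams apply_threshold
#' @return a \code{binary_mask}.
#' @export
niblack_binarize <- function(image, radius, k = -0.2,
                             polarity = "dark_foreground") {
  apply_threshold(image, niblack_field(image, radius, k), polarity)
}

#' Global Otsu threshold (baseline)
#'
#' Plain global-threshold baseline for contrast with the local Niblack
#' method: maximizes the between-class variance over a 256-level histogram.
#'
#' @param image grayscale matrix; intensities on 0..255 (values in [0, 1]
#'   are scaled up automatically).
#' @return scalar threshold on the input's intensity scale.
#' @export
otsu_threshold <- function(image) {
  check_image(image)
  scale01 <- max(image) <= 1
  x <- if (scale01) image * 255 else image
  counts <- tabulate(pmin(pmax(floor(x), 0), 255) + 1L, nbins = 256L)
  p <- counts / sum(counts)
  levels <- 0:255
  omega <- cumsum(p)
  mu <- cumsum(p * levels)
  mu_t <- mu[256]
  between <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  between[!is.finite(between)] <- 0
  thr <- levels[which.max(between)] + 0.5
  if (scale01) thr / 255 else thr
}

#' Relative coverage with respect to a reference sample
#'
#' Percentage change of a segmented area with respect to the reference
#' sample's segmented area: \code{100 * (area - reference_area) /
#' reference_area}. Self-comparison returns exactly 0.
#'
#' @param area segmented area (any unit, commonly mm^2).
#' @param reference_area reference segmented area (> 0), same unit.
#' @return signed percentage.
#' @export
relative_coverage <- function(area, reference_area) {
  stopifnot_finite(area = area, reference_area = reference_area)
  if (any(reference_area <= 0)) stop("reference_area must be > 0", call. = FALSE)
  100 * (area - reference_area) / reference_area
}

#' Sweep Niblack radii and report coverage stability
#'
#' Evaluates a grid of radii and reports the resulting mask coverage so the
#' operator can judge a stable plateau. The choice of radius is
#' image-dependent and is never made silently: this utility only reports.
#'
#' @param image grayscale matrix.
#' @param radii integer vector of window half-sizes to evaluate.
#' @inheritParams niblack_field
#' @inheritParams apply_threshold
#' @return data frame with columns \code{radius} and \code{coverage}.
#' @export
niblack_radius_sweep <- function(image, radii, k = -0.2,
                                 polarity = "dark_foreground") {
  data.frame(
    radius = radii,
    coverage = vapply(radii, function(r)
      niblack_binarize(image, r, k, polarity)$coverage, numeric(1)))
}
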