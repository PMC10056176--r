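#' Image gradient field
#'
#' Computes the two partial derivatives of a grayscale image with a selectable
#' gradient operator. The image is a numeric matrix in image coordinates:
#' rows index \code{y} (increasing downward), columns index \code{x}.
#'
#' Operators:
#' \describe{
#'   \item{\code{"finite_difference"}}{Central differences in the interior,
#'     one-sided at the first/last row and column.}
#'   \item{\code{"gaussian"}}{Separable derivative-of-Gaussian at scale
#'     \code{sigma_d}, reflective boundaries.}
#'   \item{\code{"riesz"}}{First-order Riesz transform applied in the
#'     frequency domain with multipliers \eqn{-i\,\omega_j/\|\omega\|}
#'     (zero at DC); a rotation- and scale-invariant derivative pair that
#'     does not amplify high frequencies.}
#' }
#'
#' @param image numeric matrix, at least 3x3.
#' @param operator one of \code{"riesz"}, \code{"gaussian"},
#'   \code{"finite_difference"}.
#' @param sigma_d derivative scale in pixels (Gaussian operator only).
#' @return object of class \code{"gradient_field"}: list with per-pixel
#'   matrices \code{fx} (derivative along x/columns), \code{fy} (along
#'   y/rows) and the operator name.
#' @export
gradient <- function(image, operator = c("riesz", "gaussian", "finite_difference"),
                     sigma_d = 1) {
  check_image(image, min_dim = 3L)
  operator <- match.arg(operator)
  h <- nrow(image); w <- ncol(image)
  if (operator == "finite_difference") {
    fx <- matrix(0, h, w); fy <- matrix(0, h, w)
    fx[, 2:(w - 1)] <- (image[, 3:w] - image[, 1:(w - 2)]) / 2
    fx[, 1] <- image[, 2] - image[, 1]
    fx[, w] <- image[, w] - image[, w - 1]
    fy[2:(h - 1), ] <- (image[3:h, ] - image[1:(h - 2), ]) / 2
    fy[1, ] <- image[2, ] - image[1, ]
    fy[h, ] <- image[h, ] - image[h - 1, ]
  } else if (operator == "gaussian") {
    stopifnot_finite(sigma_d = sigma_d)
    if (sigma_d <= 0) stop("sigma_d must be > 0", call. = FALSE)
    g <- gaussian_kernel(sigma_d)
    d <- gaussian_deriv_kernel(sigma_d)
    # stats::filter computes a correlation; the derivative kernel is odd, so
    # flip it to get a convolution (true derivative sign).
    fx <- axis_filter_reflect(axis_filter_reflect(image, rev(d), 2L), g, 1L)
    fy <- axis_filter_reflect(axis_filter_reflect(image, rev(d), 1L), g, 2L)
  } else {
    gr <- riesz_gradient(image)
    fx <- gr$fx; fy <- gr$fy
  }
  structure(list(fx = fx, fy = fy, operator = operator), class = "gradient_field")
}

# Riesz transform pair via FFT: Fx = ifft(-i wx/|w| F), Fy analogous.
riesz_gradient <- function(image) {
  h <- nrow(image); w <- ncol(image)
  F <- stats::fft(image)
  wy <- c(0:(floor(h / 2)), -(ceiling(h / 2) - 1):-1) / h   # cycles/px, row freqs
  wx <- c(0:(floor(w / 2)), -(ceiling(w / 2) - 1):-1) / w
  WY <- matrix(wy, h, w)
  WX <- matrix(wx, h, w, byrow = TRUE)
  mag <- sqrt(WX^2 + WY^2)
  mag[1, 1] <- 1  # DC: multiplier forced to zero below
  MX <- -1i * WX / mag
  MY <- -1i * WY / mag
  MX[1, 1] <- 0; MY[1, 1] <- 0
  fx <- Re(stats::fft(F * MX, inverse = TRUE)) / (h * w)
  fy <- Re(stats::fft(F * MY, inverse = TRUE)) / (h * w)
  list(fx = fx, fy = fy)
}

#' Windowed structure tensor field
#'
#' Smooths the gradient product images \eqn{f_x^2}, \eqn{f_x f_y},
#' \eqn{f_y^2} with a normalized Gaussian window (reflective boundaries),
#' yielding the per-pixel 2x2 structure tensor
#' \eqn{J = [[J_{xx}, J_{xy}], [J_{xy}, J_{yy}]]}.
#'
#' @param grad a \code{gradient_field} from [gradient()].
#' @param window_sigma Gaussian window sigma in pixels (> 0).
#' @return object of class \code{"structure_tensor_field"}: matrices
#'   \code{Jxx}, \code{Jxy}, \code{Jyy} plus \code{window_sigma}.
#' @export
structure_tensor <- function(grad, window_sigma) {
  if (!inherits(grad, "gradient_field")) stop("grad must be a gradient_field")
  stopifnot_finite(window_sigma = window_sigma)
  if (window_sigma <= 0) stop("window_sigma must be > 0", call. = FALSE)
  k <- gaussian_kernel(window_sigma)
  structure(list(
    Jxx = sep_filter_reflect(grad$fx * grad$fx, k),
    Jxy = sep_filter_reflect(grad$fx * grad$fy, k),
    Jyy = sep_filter_reflect(grad$fy * grad$fy, k),
    window_sigma = window_sigma,
    operator = grad$operator
  ), class = "structure_tensor_field")
}

# Orientation angle (degrees, [0,180)) of a tensor given its entries.
# theta = 1/2 atan2(2 Jxy, Jyy - Jxx); 0 deg = horizontal structures,
# angles increase counter-clockwise on screen (y-down image coordinates).
tensor_theta_deg <- function(Jxx, Jxy, Jyy) {
  fold180(rad2deg(0.5 * atan2(2 * Jxy, Jyy - Jxx)))
}

#' Orientation and coherency from a structure tensor field
#'
#' Per pixel: orientation \eqn{\theta = \frac12 \mathrm{atan2}(2 J_{xy},
#' J_{yy} - J_{xx})} in degrees on \eqn{[0, 180)} (the orientation of image
#' structures, i.e. intensity isolines), coherency
#' \eqn{C = \sqrt{(J_{yy}-J_{xx})^2 + 4 J_{xy}^2} / (J_{xx}+J_{yy})}
#' \eqn{= (\lambda_1-\lambda_2)/(\lambda_1+\lambda_2) \in [0,1]}, and the
#' tensor energy (trace). Pixels whose energy falls below \code{eps_rel}
#' times the maximum energy get \code{theta = NA} and \code{C = 0}.
#'
#' @param tensor a \code{structure_tensor_field}.
#' @param eps_rel relative energy floor below which theta is undefined.
#' @return object of class \code{"orientation_field"}: matrices
#'   \code{theta} (deg, NA where undefined), \code{coherency}, \code{energy}.
#' @export
orientation_and_coherency <- function(tensor, eps_rel = 1e-12) {
  if (!inherits(tensor, "structure_tensor_field"))
    stop("tensor must be a structure_tensor_field")
  Jxx <- tensor$Jxx; Jxy <- tensor$Jxy; Jyy <- tensor$Jyy
  energy <- Jxx + Jyy
  floor_e <- eps_rel * max(energy, 0)
  defined <- energy > floor_e & energy > 0
  theta <- tensor_theta_deg(Jxx, Jxy, Jyy)
  theta[!defined] <- NA_real_
  C <- matrix(0, nrow(Jxx), ncol(Jxx))
  C[defined] <- sqrt((Jyy[defined] - Jxx[defined])^2 + 4 * Jxy[defined]^2) /
    energy[defined]
  C <- clamp(C, 0, 1)
  structure(list(theta = theta, coherency = C, energy = energy,
                 window_sigma = tensor$window_sigma, operator = tensor$operator),
            class = "orientation_field")
}

#' @export
print.orientation_field <- function(x, ...) {
  ok <- !is.na(x$theta)
  cat(sprintf("orientation field %d x %d (operator %s, window sigma %s)\n",
              nrow(x$theta), ncol(x$theta),
              x$operator %||% "?", format(x$window_sigma)))
  cat(sprintf("  defined pixels: %.1f%%; mean coherency %.3f; dominant angle %.1f deg\n",
              100 * mean(ok), mean(x$coherency),
              dominant_angle(x)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Full orientation analysis of an image
#'
#' Convenience wrapper: gradient -> structure tensor -> orientation/coherency.
#'
#' @inheritParams gradient
#' @inheritParams structure_tensor
#' @return an \code{orientation_field}.
#' @export
orientation_analysis <- function(image, operator = "riesz", window_sigma = 8,
                                 sigma_d = 1) {
  orientation_and_coherency(
    structure_tensor(gradient(image, operator, sigma_d = sigma_d), window_sigma))
}

#' Dominant orientation of a field or region
#'
#' Energy-and-coherency-weighted circular mean (period 180 degrees) of the
#' per-pixel orientations. A border margin can be excluded to avoid boundary
#' artifacts of the gradient operators.
#'
#' @param field an \code{orientation_field}.
#' @param margin border width in pixels excluded from the average.
#' @return dominant angle in degrees, in [0, 180).
#' @export
dominant_angle <- function(field, margin = 0L) {
  th <- field$theta; wgt <- field$coherency * field$energy
  if (margin > 0L) {
    h <- nrow(th); w <- ncol(th)
    keep_r <- (margin + 1L):(h - margin); keep_c <- (margin + 1L):(w - margin)
    th <- th[keep_r, keep_c]; wgt <- wgt[keep_r, keep_c]
  }
  ok <- !is.na(th) & wgt > 0
  if (!any(ok)) return(NA_real_)
  circular_mean_180(th[ok], wgt[ok])
}

#' Render an HSB orientation map
#'
#' Hue encodes orientation (theta/180 of the color wheel), saturation encodes
#' coherency, brightness is the normalized input image. Pixels with undefined
#' orientation are rendered gray (saturation 0).
#'
#' @param orientation an \code{orientation_field}.
#' @param image the source grayscale matrix (same shape).
#' @return an h x w x 3 RGB array in [0, 1].
#' @export
render_hsb <- function(orientation, image) {
  th <- orientation$theta
  if (!all(dim(th) == dim(image))) stop("shape mismatch", call. = FALSE)
  rng <- range(image)
  v <- if (diff(rng) > 0) (image - rng[1]) / diff(rng) else image * 0
  s <- orientation$coherency
  s[is.na(th)] <- 0
  hdeg <- th / 180 * 360
  hdeg[is.na(hdeg)] <- 0
  hsv_to_rgb_array(hdeg, s, v)
}

# Vectorized HSV -> RGB (h in degrees [0,360), s,v in [0,1]).
hsv_to_rgb_array <- function(h, s, v) {
  c_ <- v * s
  hp <- (h %% 360) / 60
  x <- c_ * (1 - abs(hp %% 2 - 1))
  m <- v - c_
  r <- g <- b <- h * 0
  i <- floor(hp)
  r[i == 0 | i == 5] <- c_[i == 0 | i == 5]
  r[i == 1 | i == 4] <- x[i == 1 | i == 4]
  g[i == 0 | i == 3] <- x[i == 0 | i == 3]
  g[i == 1 | i == 2] <- c_[i == 1 | i == 2]
  b[i == 2 | i == 5] <- x[i == 2 | i == 5]
  b[i == 3 | i == 4] <- c_[i == 3 | i == 4]
  out <- array(0, c(nrow(h), ncol(h), 3L))
  out[, , 1] <- r + m; out[, , 2] <- g + m; out[, , 3] <- b + m
  out
}

#' Render a coherency map
#'
#' Linear map of coherency C in [0,1] to 8-bit gray levels: bright regions
#' are locally oriented, dark regions isotropic.
#'
#' @param orientation an \code{orientation_field}.
#' @return integer matrix of gray levels 0..255.
#' @export
render_coherency <- function(orientation) {
  matrix(as.integer(round(clamp(orientation$coherency, 0, 1) * 255)),
         nrow(orientation$coherency), ncol(orientation$coherency))
}

#' Rotate an image about its center
#'
#' Bilinear resampling; \code{angle_deg} > 0 rotates image structures
#' counter-clockwise on screen, i.e. a structure at orientation theta maps to
#' theta + angle. Pixels sampled from outside the source are set to
#' \code{fill} (defaults to the image mean).
#'
#' @param image numeric matrix.
#' @param angle_deg rotation in degrees.
#' @param fill fill value for out-of-source pixels.
#' @return rotated matrix, same shape.
#' @export
rotate_image <- function(image, angle_deg, fill = mean(image)) {
  h <- nrow(image); w <- ncol(image)
  a <- deg2rad(angle_deg)
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  X <- matrix(seq_len(w), h, w, byrow = TRUE) - cx
  Y <- matrix(seq_len(h), h, w) - cy
  # inverse transform of M = [[cos, sin], [-sin, cos]] (y-down screen CCW)
  xs <- cos(a) * X - sin(a) * Y + cx
  ys <- sin(a) * X + cos(a) * Y + cy
  x0 <- floor(xs); y0 <- floor(ys)
  dx <- xs - x0; dy <- ys - y0
  inside <- x0 >= 1 & x0 + 1 <= w & y0 >= 1 & y0 + 1 <= h
  out <- matrix(fill, h, w)
  g <- function(r, c) image[cbind(r, c)]
  ii <- which(inside)
  out[ii] <- (1 - dx[ii]) * (1 - dy[ii]) * g(y0[ii], x0[ii]) +
    dx[ii] * (1 - dy[ii]) * g(y0[ii], x0[ii] + 1L) +
    (1 - dx[ii]) * dy[ii] * g(y0[ii] + 1L, x0[ii]) +
    dx[ii] * dy[ii] * g(y0[ii] + 1L, x0[ii] + 1L)
  out
}
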