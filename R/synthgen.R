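# Synthetic biofilm-like images and point patterns with known ground truth.
# These emulate crystal-violet-stained biofilm in stereomicroscopy frames:
# dark biomass on a lighter substrate, colony-scale blobs, and mosaic
# subdomains with locally preferred texture orientations.

#' Generate an oriented band-pass texture
#'
#' Band-pass-filtered white noise with an orientation-selective Fourier mask:
#' a radial Gaussian band around frequency \code{1/wavelength} and an angular
#' von-Mises weighting whose concentration grows with
#' \code{anisotropy}. \code{anisotropy = 0} yields isotropic filtered noise;
#' \code{anisotropy = 1} yields a pure 1-D pattern (a random-phase grating)
#' whose intensity is constant along the target orientation. The dominant
#' structure-tensor orientation of the result equals \code{angle}.
#'
#' Angle convention (shared with [orientation_and_coherency()]): degrees in
#' [0, 180), 0 = horizontal structures, increasing counter-clockwise on
#' screen, image coordinates with y increasing downward.
#'
#' @param size \code{c(height, width)} in pixels.
#' @param angle target structure orientation in degrees, [0, 180).
#' @param anisotropy orientation strength in [0, 1].
#' @param wavelength dominant texture wavelength in pixels (>= 2).
#' @param seed RNG seed; same (arguments, seed) reproduce bit-identical output.
#' @return numeric matrix, standardized to mean 0 / sd 1.
#' @export
gen_oriented_texture <- function(size, angle, anisotropy, wavelength, seed = 1) {
  stopifnot_finite(size = size, angle = angle, anisotropy = anisotropy,
                   wavelength = wavelength)
  if (length(size) != 2L || any(size < 8))
    stop("size must be c(height, width), both >= 8", call. = FALSE)
  if (angle < 0 || angle >= 180) stop("angle must be in [0, 180)", call. = FALSE)
  if (anisotropy < 0 || anisotropy > 1) stop("anisotropy must be in [0, 1]", call. = FALSE)
  if (wavelength < 2) stop("wavelength must be >= 2 px", call. = FALSE)
  h <- as.integer(size[1]); w <- as.integer(size[2])
  with_seed(seed, {
    if (anisotropy >= 1) {
      tex <- grating_1d(h, w, angle, wavelength)
    } else {
      tex <- masked_noise_texture(h, w, angle, anisotropy, wavelength)
    }
    (tex - mean(tex)) / stats::sd(tex)
  })
}

# Pure 1-D pattern: random-phase sum of sinusoids along the normal direction.
grating_1d <- function(h, w, angle, wavelength) {
  th <- deg2rad(angle)
  X <- matrix(seq_len(w), h, w, byrow = TRUE)
  Y <- matrix(seq_len(h), h, w)
  t <- X * sin(th) + Y * cos(th)    # varies across stripes, constant along them
  nharm <- 6L
  f <- (1 / wavelength) * exp(stats::rnorm(nharm, 0, 0.08))
  ph <- stats::runif(nharm, 0, 2 * pi)
  amp <- stats::runif(nharm, 0.5, 1)
  out <- matrix(0, h, w)
  for (j in seq_len(nharm)) out <- out + amp[j] * cos(2 * pi * f[j] * t + ph[j])
  out
}

# Band-pass noise with angular von-Mises mask in the frequency domain.
masked_noise_texture <- function(h, w, angle, anisotropy, wavelength) {
  W <- matrix(stats::rnorm(h * w), h, w)
  F <- stats::fft(W)
  wy <- c(0:(floor(h / 2)), -(ceiling(h / 2) - 1):-1) / h
  wx <- c(0:(floor(w / 2)), -(ceiling(w / 2) - 1):-1) / w
  WY <- matrix(wy, h, w)
  WX <- matrix(wx, h, w, byrow = TRUE)
  rho <- sqrt(WX^2 + WY^2)
  rho0 <- 1 / wavelength
  radial <- exp(-(rho - rho0)^2 / (2 * (rho0 / 3)^2))
  if (anisotropy > 0) {
    # energy concentrates around the gradient (normal) direction beta = 90 - angle
    beta <- deg2rad(90 - angle)
    phi <- atan2(WY, WX)
    kappa <- (4 * anisotropy / (1 - anisotropy))^2
    angular <- exp(kappa * (cos(2 * (phi - beta)) - 1))
  } else {
    angular <- 1
  }
  mask <- radial * angular
  mask[1, 1] <- 0
  Re(stats::fft(F * mask, inverse = TRUE)) / (h * w)
}

#' Specification of a synthetic biofilm image
#'
#' Bundles all parameters of [gen_biofilm_image()] and validates their
#' invariants (levels, coverage range, non-overlapping subdomains).
#'
#' Each subdomain is a list with fields \code{region} (either
#' \code{c(x0, y0, x1, y1)} in pixels, 1-based inclusive, or an n x 2 matrix
#' of polygon vertices), \code{angle} (degrees in [0,180)) and
#' \code{anisotropy} in [0,1].
#'
#' @param image_size \code{c(height, width)} px.
#' @param coverage_target foreground (biofilm) fraction in [0, 1].
#' @param subdomains list of subdomain descriptors (see Details); defaults to
#'   an isotropic full-frame texture.
#' @param texture_wavelength dominant texture wavelength, px.
#' @param colony_count number of dark colony blobs.
#' @param colony_radius_range \code{c(min, max)} blob radius, px.
#' @param background_level,foreground_level 8-bit intensities of the lighter
#'   substrate and the dark stained biofilm (foreground < background).
#' @param noise_sd additive Gaussian noise sd, intensity units.
#' @param rng_seed integer seed.
#' @return object of class \code{"biofilm_spec"}.
#' @export
biofilm_spec <- function(image_size = c(384, 384),
                         coverage_target = 0.65,
                         subdomains = NULL,
                         texture_wavelength = 16,
                         colony_count = 25,
                         colony_radius_range = c(8, 24),
                         background_level = 180,
                         foreground_level = 70,
                         noise_sd = 3,
                         rng_seed = 1) {
  stopifnot_finite(image_size = image_size, coverage_target = coverage_target,
                   texture_wavelength = texture_wavelength,
                   colony_count = colony_count,
                   colony_radius_range = colony_radius_range,
                   background_level = background_level,
                   foreground_level = foreground_level,
                   noise_sd = noise_sd, rng_seed = rng_seed)
  if (coverage_target < 0 || coverage_target > 1)
    stop("coverage_target must be in [0, 1]", call. = FALSE)
  if (foreground_level >= background_level)
    stop("foreground_level must be below background_level (dark biofilm on lighter substrate)",
         call. = FALSE)
  if (max(colony_radius_range) > min(image_size) / 2)
    stop("colony radii exceed image size", call. = FALSE)
  if (is.null(subdomains))
    subdomains <- list(list(region = c(1, 1, image_size[2], image_size[1]),
                            angle = 0, anisotropy = 0))
  # subdomains must not overlap
  acc <- matrix(0L, image_size[1], image_size[2])
  for (sd_ in subdomains) {
    m <- region_mask(sd_$region, image_size[1], image_size[2])
    acc <- acc + m
    if (any(acc > 1L)) stop("subdomain regions overlap", call. = FALSE)
  }
  structure(list(image_size = as.integer(image_size),
                 coverage_target = coverage_target,
                 subdomains = subdomains,
                 texture_wavelength = texture_wavelength,
                 colony_count = as.integer(colony_count),
                 colony_radius_range = colony_radius_range,
                 background_level = background_level,
                 foreground_level = foreground_level,
                 noise_sd = noise_sd,
                 rng_seed = rng_seed),
            class = "biofilm_spec")
}

#' Partition an image frame into a rectangular mosaic of oriented subdomains
#'
#' @param image_size \code{c(height, width)} px.
#' @param angles vector of target angles (degrees), recycled across tiles.
#' @param grid \code{c(rows, cols)} of the mosaic.
#' @param anisotropy orientation strength shared by all tiles.
#' @return list of subdomain descriptors for [biofilm_spec()].
#' @export
mosaic_subdomains <- function(image_size, angles, grid = c(2, 2), anisotropy = 0.9) {
  h <- image_size[1]; w <- image_size[2]
  ys <- round(seq(0, h, length.out = grid[1] + 1))
  xs <- round(seq(0, w, length.out = grid[2] + 1))
  out <- list(); k <- 0L
  for (r in seq_len(grid[1])) for (c in seq_len(grid[2])) {
    k <- k + 1L
    out[[k]] <- list(region = c(xs[c] + 1, ys[r] + 1, xs[c + 1], ys[r + 1]),
                     angle = angles[(k - 1L) %% length(angles) + 1L],
                     anisotropy = anisotropy)
  }
  out
}

# Logical mask of a rectangle c(x0,y0,x1,y1) or polygon (n x 2 matrix of x,y).
region_mask <- function(region, h, w) {
  if (is.matrix(region)) {
    X <- matrix(seq_len(w), h, w, byrow = TRUE)
    Y <- matrix(seq_len(h), h, w)
    m <- matrix(point_in_polygon(as.vector(X), as.vector(Y),
                                 region[, 1], region[, 2]), h, w)
  } else {
    if (length(region) != 4L) stop("rectangular region must be c(x0, y0, x1, y1)")
    m <- matrix(FALSE, h, w)
    m[max(1, region[2]):min(h, region[4]), max(1, region[1]):min(w, region[3])] <- TRUE
  }
  m
}

# Even-odd ray-casting point-in-polygon test, vectorized over query points.
point_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    cross <- ((vy[i] > py) != (vy[j] > py)) &
      (px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i])
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

#' Generate a synthetic biofilm image with ground truth
#'
#' Composites a noiseless field from oriented subdomain textures, dark
#' colony blobs with smoothed edges, and a low-frequency coverage
#' modulation; maps it onto the intensity range so that exactly the
#' \code{coverage_target} darkest fraction falls below the
#' foreground/background midpoint (the coverage is enforced by thresholding
#' the composite at an intensity quantile); then adds Gaussian noise.
#' The ground-truth coverage mask marks pixels whose noiseless intensity is
#' below the midpoint of the foreground and background levels.
#'
#' @param spec a [biofilm_spec()].
#' @return object of class \code{"synthetic_biofilm"}: list with
#'   \code{image} (numeric matrix, 0..255), \code{truth} (list:
#'   \code{coverage_mask} logical matrix, \code{angle_map} degrees with NA
#'   on isotropic pixels, \code{subdomains} data frame,
#'   \code{realized_coverage}), and the \code{spec}.
#' @export
gen_biofilm_image <- function(spec) {
  if (!inherits(spec, "biofilm_spec")) stop("spec must be a biofilm_spec")
  h <- spec$image_size[1]; w <- spec$image_size[2]
  with_seed(spec$rng_seed, {
    sub_seeds <- sample.int(2^30, length(spec$subdomains) + 2L)
    comp <- matrix(0, h, w)
    angle_map <- matrix(NA_real_, h, w)
    tab <- data.frame(id = integer(), angle = numeric(), anisotropy = numeric())
    for (i in seq_along(spec$subdomains)) {
      sd_ <- spec$subdomains[[i]]
      m <- region_mask(sd_$region, h, w)
      if (!any(m)) next
      tex <- gen_oriented_texture(c(h, w), sd_$angle, sd_$anisotropy,
                                  spec$texture_wavelength, seed = sub_seeds[i])
      comp[m] <- comp[m] + tex[m]
      if (sd_$anisotropy > 0) angle_map[m] <- sd_$angle
      tab <- rbind(tab, data.frame(id = i, angle = sd_$angle,
                                   anisotropy = sd_$anisotropy))
    }
    # low-frequency coverage modulation (isotropic, colony-scale)
    lf <- gen_oriented_texture(c(h, w), 0, 0, min(h, w) / 3,
                               seed = sub_seeds[length(spec$subdomains) + 1L])
    comp <- comp + 0.6 * lf
    # dark colony blobs with smoothed (logistic) edges
    if (spec$colony_count > 0L) {
      cx <- stats::runif(spec$colony_count, 1, w)
      cy <- stats::runif(spec$colony_count, 1, h)
      cr <- stats::runif(spec$colony_count, spec$colony_radius_range[1],
                         spec$colony_radius_range[2])
      for (j in seq_len(spec$colony_count)) {
        s <- max(1, cr[j] / 6)
        x0 <- max(1L, floor(cx[j] - cr[j] - 4 * s)); x1 <- min(w, ceiling(cx[j] + cr[j] + 4 * s))
        y0 <- max(1L, floor(cy[j] - cr[j] - 4 * s)); y1 <- min(h, ceiling(cy[j] + cr[j] + 4 * s))
        X <- matrix(x0:x1, y1 - y0 + 1L, x1 - x0 + 1L, byrow = TRUE)
        Y <- matrix(y0:y1, y1 - y0 + 1L, x1 - x0 + 1L)
        d <- sqrt((X - cx[j])^2 + (Y - cy[j])^2)
        comp[y0:y1, x0:x1] <- comp[y0:y1, x0:x1] -
          2.5 / (1 + exp((d - cr[j]) / s))
      }
    }
    # enforce coverage: threshold the composite at its coverage quantile and
    # map intensities so that quantile -> midpoint of the two levels
    qc <- stats::quantile(comp, spec$coverage_target, names = FALSE)
    mid <- (spec$foreground_level + spec$background_level) / 2
    span <- spec$background_level - spec$foreground_level
    # steep logistic: stained biofilm boundaries are sharp, the intensity
    # histogram strongly bimodal
    wdt <- 0.015 * stats::sd(comp)
    noiseless <- spec$foreground_level +
      span * stats::plogis((comp - qc) / wdt)
    # restore within-phase texture without ever crossing the midpoint
    # (so the coverage mask stays exactly the sub-midpoint pixel set)
    delta <- clamp(0.03 * span * comp,
                   -0.6 * abs(noiseless - mid), 0.6 * abs(noiseless - mid))
    noiseless <- noiseless + delta
    mask <- noiseless < mid
    image <- clamp(noiseless + stats::rnorm(h * w, 0, spec$noise_sd), 0, 255)
    structure(list(
      image = image,
      truth = list(coverage_mask = mask,
                   angle_map = angle_map,
                   subdomains = tab,
                   realized_coverage = mean(mask)),
      spec = spec), class = "synthetic_biofilm")
  })
}

#' @export
print.synthetic_biofilm <- function(x, ...) {
  cat(sprintf("synthetic biofilm image %d x %d: coverage %.3f (target %.3f), %d subdomains, %d colonies\n",
              nrow(x$image), ncol(x$image), x$truth$realized_coverage,
              x$spec$coverage_target, length(x$spec$subdomains),
              x$spec$colony_count))
  invisible(x)
}

#' Generate a 2-D point pattern
#'
#' Fixtures for Voronoi regularity validation: a square lattice, a jittered
#' lattice (i.i.d. Gaussian displacement, reflected back into the window),
#' or uniform (binomial/Poisson-type) random points.
#'
#' @param kind \code{"lattice"}, \code{"jittered_lattice"} or \code{"poisson"}.
#' @param n number of points (>= 3).
#' @param window \code{c(width, height)} of the rectangular window with
#'   origin (0, 0).
#' @param jitter_sd Gaussian displacement sd (jittered lattice only).
#' @param seed RNG seed.
#' @param spacing optional explicit lattice spacing; if given, the window
#'   must hold at least \code{n} lattice sites at that spacing.
#' @return object of class \code{"point_pattern"}: list with \code{points}
#'   (n x 2 matrix of x, y), \code{kind}, \code{window}, \code{spacing}.
#' @export
gen_point_pattern <- function(kind = c("lattice", "jittered_lattice", "poisson"),
                              n, window = c(1, 1), jitter_sd = 0, seed = 1,
                              spacing = NULL) {
  kind <- match.arg(kind)
  stopifnot_finite(n = n, window = window, jitter_sd = jitter_sd)
  if (n < 3) stop("n must be >= 3", call. = FALSE)
  W <- window[1]; H <- window[2]
  with_seed(seed, {
    if (kind == "poisson") {
      pts <- cbind(x = stats::runif(n, 0, W), y = stats::runif(n, 0, H))
      sp <- NA_real_
    } else {
      if (!is.null(spacing)) {
        mx <- floor(W / spacing); my <- floor(H / spacing)
        if (mx * my < n)
          stop("n exceeds lattice capacity of the window at this spacing", call. = FALSE)
        sx <- sy <- spacing
      } else {
        mx <- ceiling(sqrt(n * W / H)); my <- ceiling(n / mx)
        sx <- W / mx; sy <- H / my
      }
      g <- expand.grid(ix = seq_len(mx), iy = seq_len(my))
      g <- g[order(g$iy, g$ix), , drop = FALSE][seq_len(n), , drop = FALSE]
      pts <- cbind(x = (g$ix - 0.5) * sx, y = (g$iy - 0.5) * sy)
      sp <- min(sx, sy)
      if (kind == "jittered_lattice" && jitter_sd > 0) {
        pts[, 1] <- reflect_into(pts[, 1] + stats::rnorm(n, 0, jitter_sd), 0, W)
        pts[, 2] <- reflect_into(pts[, 2] + stats::rnorm(n, 0, jitter_sd), 0, H)
      }
    }
    structure(list(points = pts, kind = kind, window = c(W, H), spacing = sp),
              class = "point_pattern")
  })
}

# Reflect coordinates back into [lo, hi] (keeps points inside the window).
reflect_into <- function(x, lo, hi) {
  span <- hi - lo
  y <- (x - lo) %% (2 * span)
  lo + ifelse(y > span, 2 * span - y, y)
}
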