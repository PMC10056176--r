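# ROI tiling, directional summaries, histograms, angle series.

test_that("ROI tiling produces exact partitions and centered single ROIs", {
  r <- tile_rois(c(1000, 1000), 16, 250)
  expect_equal(nrow(r), 16)
  expect_equal(sort(unique(r$x0)), c(1, 251, 501, 751))
  expect_equal(sort(unique(r$y0)), c(1, 251, 501, 751))
  r20 <- tile_rois(c(1800, 1800), 20, 250)
  expect_equal(length(unique(r20$x0)), 5)
  expect_equal(length(unique(r20$y0)), 4)
  expect_true(all(r20$x0 >= 1 & r20$x0 + r20$w - 1 <= 1800))
  expect_true(all(r20$y0 >= 1 & r20$y0 + r20$h - 1 <= 1800))
  r1 <- tile_rois(c(500, 500), 1, 250)
  expect_equal(c(r1$x0, r1$y0), c(126, 126))
  expect_error(tile_rois(c(100, 100), 4, 250), "larger than image")
})

test_that("ROI summaries recover gratings, flag isotropy, and split mosaics", {
  g <- gen_oriented_texture(c(300, 300), 60, 1, 16, seed = 2)
  tn <- structure_tensor(gradient(g, "riesz"), 8)
  fld <- orientation_and_coherency(tn)
  roi <- list(x0 = 26, y0 = 26, w = 250, h = 250)
  s <- summarize_roi(fld, tn, roi)
  expect_lt(orientfilm:::angle_diff_180(s$dominant_theta, 60), 1)
  expect_gte(s$elongation, 5)
  expect_false(s$near_isotropic)
  # internal consistency: dominant theta equals the angle of the mean tensor
  J <- s$mean_tensor
  expect_lt(abs(s$dominant_theta -
                orientfilm:::tensor_theta_deg(J[1, 1], J[1, 2], J[2, 2])), 1e-9)

  for (sd_ in 1:5) {
    gi <- gen_oriented_texture(c(300, 300), 0, 0, 16, seed = sd_)
    tni <- structure_tensor(gradient(gi, "riesz"), 8)
    si <- summarize_roi(orientation_and_coherency(tni), tni, roi)
    expect_lte(si$elongation, 1.3)
    expect_true(si$near_isotropic)
  }

  m <- rbind(gen_oriented_texture(c(150, 300), 0, 1, 16, seed = 3),
             gen_oriented_texture(c(150, 300), 90, 1, 16, seed = 4))
  tnm <- structure_tensor(gradient(m, "riesz"), 8)
  sm <- summarize_roi(orientation_and_coherency(tnm), tnm, roi)
  expect_equal(length(sm$peak_angles), 2)
  errs <- vapply(c(0, 90), function(a)
    min(orientfilm:::angle_diff_180(sm$peak_angles, a)), numeric(1))
  expect_lt(max(errs), 2)
  expect_lt(sm$elongation, 1.5)   # two equal orthogonal populations cancel
})

test_that("ROIs inside ground-truth subdomains recover the target angle", {
  angs <- c(0, 45, 60, 135)
  subs <- mosaic_subdomains(c(300, 300), angs, grid = c(2, 2), anisotropy = 0.9)
  comp <- matrix(0, 300, 300)
  for (i in seq_along(subs)) {
    tex <- gen_oriented_texture(c(300, 300), subs[[i]]$angle,
                                subs[[i]]$anisotropy, 16, seed = 20 + i)
    msk <- orientfilm:::region_mask(subs[[i]]$region, 300, 300)
    comp[msk] <- tex[msk]
  }
  tn <- structure_tensor(gradient(comp, "riesz"), 8)
  fld <- orientation_and_coherency(tn)
  centers <- list(c(30, 30), c(30, 180), c(180, 30), c(180, 180))  # (y0, x0)
  for (i in seq_along(subs)) {
    roi <- list(x0 = centers[[i]][2], y0 = centers[[i]][1], w = 90, h = 90)
    s <- summarize_roi(fld, tn, roi)
    expect_lt(orientfilm:::angle_diff_180(s$dominant_theta, angs[i]), 2,
              label = sprintf("subdomain %d at %d deg", i, angs[i]))
  }
})

test_that("elongation grows with anisotropy", {
  lv <- c(0, 0.2, 0.4, 0.6, 0.8, 0.95)
  roi <- list(x0 = 16, y0 = 16, w = 160, h = 160)
  rho <- vapply(1:5, function(s) {
    el <- vapply(lv, function(a) {
      g <- gen_oriented_texture(c(192, 192), 30, a, 16, seed = s)
      tn <- structure_tensor(gradient(g, "riesz"), 8)
      summarize_roi(orientation_and_coherency(tn), tn, roi)$elongation
    }, numeric(1))
    stats::cor(el, lv, method = "spearman")
  }, numeric(1))
  expect_true(all(rho > 0.9))
})

test_that("orientation histograms are normalized and mode-dominated on gratings", {
  g <- gen_oriented_texture(c(192, 192), 45, 1, 16, seed = 5)
  fld <- orientation_analysis(g, "riesz", 8)
  h <- orientation_histogram(fld, n_bins = 18)
  expect_equal(sum(h$mass), 1)
  expect_gte(max(h$mass), 0.8)
  expect_equal(h$centers[which.max(h$mass)], 45)
  # isotropic: no bin much above the uniform level (unweighted pixel counts)
  worst <- vapply(1:10, function(s) {
    gi <- gen_oriented_texture(c(256, 256), 0, 0, 16, seed = s)
    max(orientation_histogram(orientation_analysis(gi, "riesz", 8),
                              weights = "none", n_bins = 18)$mass)
  }, numeric(1))
  expect_lt(max(worst), 2 / 18)
  expect_error(orientation_histogram(fld, n_bins = 2), "n_bins")
  expect_error(orientation_histogram(fld, region = matrix(FALSE, 192, 192)),
               "empty region")
})

test_that("angle series have N = n_rois x peaks_per_roi in [0, 180)", {
  g <- gen_oriented_texture(c(600, 600), 45, 1, 16, seed = 5)
  s60 <- collect_angle_series(g, n_rois = 20, roi_size = 250)
  expect_equal(nrow(s60), 60)
  expect_true(all(s60$angle >= 0 & s60$angle < 180))
  expect_true(all(abs(s60$angle - 45) < 2))
  s20 <- collect_angle_series(g, n_rois = 20, roi_size = 250, peaks_per_roi = 1)
  expect_equal(nrow(s20), 20)
})
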