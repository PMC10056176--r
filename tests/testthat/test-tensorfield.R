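# Gradient operators, structure tensor, orientation/coherency, renders.

test_that("gradients vanish on constants and recover ramps", {
  const <- matrix(7, 16, 16)
  for (op in c("finite_difference", "gaussian", "riesz")) {
    g <- gradient(const, op)
    expect_lt(max(abs(g$fx)), 1e-9)
    expect_lt(max(abs(g$fy)), 1e-9)
  }
  ramp <- matrix(seq_len(32), 32, 32, byrow = TRUE)  # f = x
  g <- gradient(ramp, "finite_difference")
  expect_equal(g$fx[5:28, 5:28], matrix(1, 24, 24))
  expect_lt(max(abs(g$fy[5:28, 5:28])), 1e-12)
  expect_error(gradient(const, "sobel"), "riesz")
})

test_that("the Riesz pair is axis-pure on 1-D sinusoids", {
  x <- matrix(seq_len(128), 128, 128, byrow = TRUE)
  img <- cos(2 * pi * x / 16)
  g <- gradient(img, "riesz")
  expect_lt(max(abs(g$fy)), 1e-6 * max(abs(g$fx)))
  # and antisymmetric: y-sinusoid maps to fy
  gy <- gradient(t(img), "riesz")
  expect_lt(max(abs(gy$fx)), 1e-6 * max(abs(gy$fy)))
})

test_that("structure tensor equals the direct-summation oracle", {
  set.seed(12)
  img <- matrix(runif(32 * 32), 32, 32)
  gr <- gradient(img, "finite_difference")
  tn <- structure_tensor(gr, 2)
  for (i in c(1, 9, 20, 32)) for (j in c(1, 16, 32)) {
    o <- bf_structure_tensor_at(gr$fx, gr$fy, i, j, 2)
    expect_lt(abs(tn$Jxx[i, j] - o["Jxx"]), 1e-6)
    expect_lt(abs(tn$Jxy[i, j] - o["Jxy"]), 1e-6)
    expect_lt(abs(tn$Jyy[i, j] - o["Jyy"]), 1e-6)
  }
  expect_error(structure_tensor(gr, 0), "window_sigma")
  # positive semidefinite up to rounding
  expect_gte(min(tn$Jxx), 0); expect_gte(min(tn$Jyy), 0)
  expect_gte(min(tn$Jxx * tn$Jyy - tn$Jxy^2), -1e-9)
})

test_that("orientation and coherency match the eigen-decomposition", {
  set.seed(13)
  img <- gen_oriented_texture(c(64, 64), 70, 0.6, 12, seed = 4)
  tn <- structure_tensor(gradient(img, "riesz"), 4)
  fld <- orientation_and_coherency(tn)
  expect_true(all(fld$coherency >= 0 & fld$coherency <= 1))
  idx <- cbind(sample(64, 40, TRUE), sample(64, 40, TRUE))
  for (k in seq_len(40)) {
    i <- idx[k, 1]; j <- idx[k, 2]
    J <- matrix(c(tn$Jxx[i, j], tn$Jxy[i, j], tn$Jxy[i, j], tn$Jyy[i, j]), 2)
    ev <- eigen(J, symmetric = TRUE)$values
    expect_lt(abs(fld$coherency[i, j] - (ev[1] - ev[2]) / (ev[1] + ev[2])), 1e-9)
  }
})

test_that("closed-form tensor cases give the expected angle and coherency", {
  # isotropic tensor: C = 0, theta undefined
  tn <- structure(list(Jxx = matrix(1, 4, 4), Jxy = matrix(0, 4, 4),
                       Jyy = matrix(1, 4, 4), window_sigma = 1,
                       operator = "riesz"), class = "structure_tensor_field")
  fld <- orientation_and_coherency(tn)
  expect_true(all(fld$coherency == 0))
  expect_false(any(is.na(fld$theta)))   # energy present, theta defined
  # vertical stripes: intensity varies along x only -> theta 90, C 1
  x <- matrix(seq_len(96), 96, 96, byrow = TRUE)
  fld2 <- orientation_analysis(cos(2 * pi * x / 12), "riesz", 6)
  inner <- fld2$theta[20:77, 20:77]
  expect_lt(max(orientfilm:::angle_diff_180(inner, 90)), 0.5)
  expect_gt(mean(fld2$coherency[20:77, 20:77]), 0.99)
  # zero-energy pixels are flagged undefined
  fld3 <- orientation_and_coherency(
    structure(list(Jxx = matrix(0, 4, 4), Jxy = matrix(0, 4, 4),
                   Jyy = matrix(0, 4, 4), window_sigma = 1, operator = "riesz"),
              class = "structure_tensor_field"))
  expect_true(all(is.na(fld3$theta)))
})

test_that("theta is invariant to affine intensity changes", {
  img <- gen_oriented_texture(c(96, 96), 25, 0.9, 14, seed = 6)
  f1 <- orientation_analysis(img, "gaussian", 6)
  f2 <- orientation_analysis(3.7 * img + 42, "gaussian", 6)
  ok <- !is.na(f1$theta) & !is.na(f2$theta)
  expect_lt(max(orientfilm:::angle_diff_180(f1$theta[ok], f2$theta[ok])), 1e-6)
})

test_that("Riesz orientation is stable under wavelength doubling", {
  f1 <- orientation_analysis(gen_oriented_texture(c(192, 192), 50, 1, 8, seed = 3),
                             "riesz", 4)
  f2 <- orientation_analysis(gen_oriented_texture(c(192, 192), 50, 1, 16, seed = 3),
                             "riesz", 8)
  expect_lt(orientfilm:::angle_diff_180(dominant_angle(f1, 16),
                                        dominant_angle(f2, 16)), 0.5)
  c1 <- mean(f1$coherency[17:176, 17:176])
  c2 <- mean(f2$coherency[17:176, 17:176])
  expect_lt(abs(c1 - c2), 0.02)
})

test_that("renderings encode orientation, coherency and brightness", {
  img <- gen_oriented_texture(c(64, 64), 45, 1, 12, seed = 2)
  fld <- orientation_analysis(img, "riesz", 6)
  rgb <- render_hsb(fld, img)
  expect_equal(dim(rgb), c(64, 64, 3))
  expect_true(all(rgb >= 0 & rgb <= 1))
  # brightness = max(R,G,B) equals the normalized input
  v <- pmax(rgb[, , 1], pmax(rgb[, , 2], rgb[, , 3]))
  expect_equal(v, (img - min(img)) / diff(range(img)), tolerance = 1e-9)
  # C = 0 everywhere -> gray output
  tn0 <- structure(list(Jxx = matrix(1, 8, 8), Jxy = matrix(0, 8, 8),
                        Jyy = matrix(1, 8, 8), window_sigma = 1,
                        operator = "riesz"), class = "structure_tensor_field")
  f0 <- orientation_and_coherency(tn0)
  rgb0 <- render_hsb(f0, matrix(runif(64), 8, 8))
  expect_equal(rgb0[, , 1], rgb0[, , 2])
  expect_equal(rgb0[, , 2], rgb0[, , 3])
  expect_error(render_hsb(fld, matrix(0, 5, 5)), "mismatch")
  # coherency map: linear 0..255
  cm <- render_coherency(f0)
  expect_true(all(cm == 0))
  f1 <- orientation_and_coherency(
    structure(list(Jxx = matrix(1, 8, 8), Jxy = matrix(0, 8, 8),
                   Jyy = matrix(0, 8, 8), window_sigma = 1, operator = "riesz"),
              class = "structure_tensor_field"))
  expect_true(all(render_coherency(f1) == 255))
})

test_that("a mosaic's anisotropic subdomain is brighter in the coherency map", {
  top <- gen_oriented_texture(c(64, 128), 30, 0.95, 12, seed = 1)
  bottom <- gen_oriented_texture(c(64, 128), 30, 0, 12, seed = 2)
  fld <- orientation_analysis(rbind(top, bottom), "riesz", 6)
  cm <- render_coherency(fld)
  expect_gt(mean(cm[1:56, ]), mean(cm[73:128, ]) + 50)
})
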