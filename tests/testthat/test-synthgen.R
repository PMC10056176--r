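# Synthetic generators: determinism, orientation fidelity, coverage
# fidelity, point patterns.

test_that("generators are pure functions of their seed", {
  t1 <- gen_oriented_texture(c(64, 64), 30, 0.7, 12, seed = 5)
  t2 <- gen_oriented_texture(c(64, 64), 30, 0.7, 12, seed = 5)
  expect_identical(t1, t2)
  expect_false(identical(t1, gen_oriented_texture(c(64, 64), 30, 0.7, 12, seed = 6)))

  s1 <- gen_biofilm_image(biofilm_spec(image_size = c(96, 96), rng_seed = 3))
  s2 <- gen_biofilm_image(biofilm_spec(image_size = c(96, 96), rng_seed = 3))
  expect_identical(s1$image, s2$image)

  p1 <- gen_point_pattern("poisson", 500, seed = 1)
  p2 <- gen_point_pattern("poisson", 500, seed = 1)
  expect_identical(p1$points, p2$points)

  # the global RNG stream is left untouched
  set.seed(42); before <- .Random.seed
  invisible(gen_oriented_texture(c(32, 32), 10, 0.5, 8, seed = 9))
  expect_identical(before, .Random.seed)
})

test_that("anisotropy = 1 yields a pure 1-D pattern along the target angle", {
  g <- gen_oriented_texture(c(256, 256), 0, 1, 16, seed = 1)
  # horizontal structures: every row is constant
  expect_lt(max(apply(g, 1, function(r) diff(range(r)))), 1e-9)
  g90 <- gen_oriented_texture(c(256, 256), 90, 1, 16, seed = 1)
  expect_lt(max(apply(g90, 2, function(cc) diff(range(cc)))), 1e-9)
})

test_that("oriented textures carry their target structure-tensor angle", {
  for (ang in c(0, 30, 45, 60, 90, 135)) {
    for (an in c(0.8, 1)) {
      g <- gen_oriented_texture(c(192, 192), ang, an, 16, seed = 11)
      fld <- orientation_analysis(g, "riesz", 8)
      expect_lt(orientfilm:::angle_diff_180(dominant_angle(fld, margin = 16), ang),
                2, label = sprintf("angle %s anisotropy %s", ang, an))
    }
  }
})

test_that("mean coherency is monotone in anisotropy and low for isotropic noise", {
  cmeans <- vapply(c(0, 0.25, 0.5, 0.75, 0.95), function(a) {
    g <- gen_oriented_texture(c(192, 192), 40, a, 16, seed = 7)
    mean(orientation_analysis(g, "riesz", 8)$coherency)
  }, numeric(1))
  expect_true(all(diff(cmeans) > 0))
  expect_lte(cmeans[1], 0.3)
})

test_that("biofilm images hit their coverage target and validate inputs", {
  for (cv in c(0.3, 0.65, 0.85)) {
    sb <- gen_biofilm_image(biofilm_spec(image_size = c(192, 192),
                                         coverage_target = cv, rng_seed = 2))
    expect_lt(abs(sb$truth$realized_coverage - cv), 0.02)
    expect_true(is.logical(sb$truth$coverage_mask))
    expect_identical(dim(sb$truth$coverage_mask), dim(sb$image))
  }
  # degenerate case: zero coverage, no colonies, isotropic
  sb0 <- gen_biofilm_image(biofilm_spec(image_size = c(96, 96),
                                        coverage_target = 0, colony_count = 0))
  expect_equal(sb0$truth$realized_coverage, 0)
  expect_false(any(sb0$truth$coverage_mask))

  expect_error(biofilm_spec(coverage_target = 1.2), "coverage")
  expect_error(biofilm_spec(foreground_level = 200, background_level = 100),
               "foreground")
  expect_error(biofilm_spec(image_size = c(64, 64),
                            colony_radius_range = c(10, 200)), "radii")
  expect_error(gen_oriented_texture(c(64, 64), NaN, 0.5, 8), "finite")
  expect_error(gen_oriented_texture(c(64, 64), 30, 0.5, 1), "wavelength")
})

test_that("the ground-truth angle map covers exactly the anisotropic subdomains", {
  subs <- list(list(region = c(1, 1, 48, 96), angle = 30, anisotropy = 0.9),
               list(region = c(49, 1, 96, 96), angle = 120, anisotropy = 0))
  sb <- gen_biofilm_image(biofilm_spec(image_size = c(96, 96), subdomains = subs,
                                       colony_count = 0))
  expect_true(all(sb$truth$angle_map[, 1:48] == 30))
  expect_true(all(is.na(sb$truth$angle_map[, 49:96])))
  expect_error(biofilm_spec(image_size = c(96, 96), subdomains = list(
    list(region = c(1, 1, 60, 96), angle = 0, anisotropy = 1),
    list(region = c(50, 1, 96, 96), angle = 90, anisotropy = 1))), "overlap")
})

test_that("point patterns match their definitions", {
  lat <- gen_point_pattern("lattice", 100, c(1, 1))
  d <- as.matrix(dist(lat$points)); diag(d) <- Inf
  nn <- apply(d, 1, min)
  expect_lt(diff(range(nn)), 1e-12)          # equal nearest-neighbor distances
  jit0 <- gen_point_pattern("jittered_lattice", 100, c(1, 1), jitter_sd = 0)
  expect_equal(jit0$points, lat$points)
  jit <- gen_point_pattern("jittered_lattice", 100, c(1, 1), jitter_sd = 0.05,
                           seed = 2)
  expect_true(all(jit$points >= 0 & jit$points <= 1))
  expect_error(gen_point_pattern("poisson", 2), "n must be")
  expect_error(gen_point_pattern("lattice", 100, c(1, 1), spacing = 0.5),
               "capacity")
})
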