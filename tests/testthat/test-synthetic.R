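test_that("phantom generation is a pure function of geometry and seed", {
  g <- small_geometry()
  p1 <- generate_cross_section_phantom(g, seed = 11)
  p2 <- generate_cross_section_phantom(g, seed = 11)
  expect_identical(p1$coefficients, p2$coefficients)
  expect_identical(p1$strain_field$values, p2$strain_field$values)
  expect_identical(lapply(p1$undeformed_regions$chains, identity),
                   lapply(p2$undeformed_regions$chains, identity))
})

test_that("requested region proportions are realised in rasterized area", {
  g <- phantom_geometry(proportions = c(A1 = 0.4, A5 = 0.3, A4 = 0.3))
  ph <- generate_cross_section_phantom(g, seed = 2)
  ts <- ph$undeformed_regions
  poly <- region_polygon(ts, "A5")
  lo <- apply(poly, 2, min) - 1; hi <- apply(poly, 2, max) + 1
  pts <- grid_points(lo, hi, 1)                       # 1 um raster oracle
  a5 <- sum(points_in_polygon(pts, poly)) * 1
  wall <- abs(polygon_area(boundary_ring(ts, "outer"))) -
    abs(polygon_area(boundary_ring(ts, "lumen")))
  expect_lt(abs(a5 / wall - 0.3), 0.02)
})

test_that("phantom invariants hold: boundary consistency, tiling, smoothness", {
  ph <- generate_cross_section_phantom(small_geometry(), seed = 5)
  ts <- ph$undeformed_regions

  ## displacement restricted to boundaries reproduces deformed contours
  lum <- boundary_ring(ts, "lumen")
  expect_lt(max(abs(lum + ph$displacement(lum) -
                      contour_points(ph$deformed_lumen))), 1e-9)
  out <- boundary_ring(ts, "outer")
  expect_lt(max(abs(out + ph$displacement(out) -
                      contour_points(ph$deformed_outer))), 1e-9)

  ## regions tile the wall: areas conserve, pairwise overlaps negligible
  wall <- abs(polygon_area(out)) - abs(polygon_area(lum))
  expect_lt(abs(sum(region_areas(ts)) - wall) / wall, 0.01)
  labs <- names(ts$regions)
  pts <- grid_points(apply(out, 2, min), apply(out, 2, max), 3)
  hits <- sapply(labs, function(l) points_in_polygon(pts, region_polygon(ts, l)))
  counts <- colSums(hits)
  overlap <- sum(rowSums(hits) > 1)
  expect_lt(overlap, 0.005 * min(counts))

  ## C1 smoothness: bounded finite-difference second derivatives
  th <- seq(0, 2 * pi, length.out = 73)[-73]
  r0 <- mean(sqrt(rowSums(lum^2))) * 1.2
  probe <- cbind(r0 * cos(th), r0 * sin(th))
  h <- 0.5
  hx <- matrix(c(h, 0), nrow(probe), 2, byrow = TRUE)
  d2 <- (ph$displacement(probe + hx) - 2 * ph$displacement(probe) +
           ph$displacement(probe - hx)) / h^2
  expect_true(all(is.finite(d2)))
  expect_lt(max(abs(d2)), 0.1)     # um^-1, smooth at the wall scale
})

test_that("zero deformation amplitude leaves contours untouched", {
  g <- small_geometry(deformation_amplitude_um = 0)
  ph <- generate_cross_section_phantom(g, seed = 7)
  expect_identical(contour_points(ph$deformed_lumen),
                   boundary_ring(ph$undeformed_regions, "lumen"))
})

test_that("synthetic strain fields are region-coded with clipped noise", {
  ph <- generate_cross_section_phantom(small_geometry(), seed = 9)
  lv <- c(A1 = 0.12, A2 = 0.05, A3 = 0.05, A4 = 0.1, A5 = 0.03)

  f0 <- generate_strain_field(ph$deformed_regions, lv, noise_sd = 0,
                              resolution_um = 20, seed = 1)
  gs0 <- group_strains(f0, ph$deformed_regions)
  for (l in names(gs0$samples)) {
    expect_true(all(gs0$samples[[l]] == lv[[l]]))
  }

  f1 <- generate_strain_field(ph$deformed_regions, lv, noise_sd = 0.02,
                              resolution_um = 20, seed = 1)
  gs1 <- group_strains(f1, ph$deformed_regions)
  for (l in names(gs1$samples)) {
    n <- length(gs1$samples[[l]])
    expect_lt(abs(mean(gs1$samples[[l]]) - lv[[l]]), 2 * 0.02 / sqrt(n) + 1e-3)
  }
  f2 <- generate_strain_field(ph$deformed_regions, lv, noise_sd = 0.02,
                              resolution_um = 20, seed = 1)
  expect_identical(f1$values, f2$values)
  expect_error(generate_strain_field(ph$deformed_regions, lv, resolution_um = -1),
               "resolution")
})

test_that("volume pairs realise the requested affine warp", {
  vp0 <- generate_volume_pair(c(24, 24, 24), rep(0, 12), noise_sd = 0, seed = 3)
  expect_identical(vp0$reference, vp0$target)

  ## pure translation: brute-force cross-correlation peak at +2 on axis 1
  p <- rep(0, 12); p[10] <- 2
  vp <- generate_volume_pair(c(24, 24, 24), p, seed = 3)
  shifts <- -4:4
  cc <- vapply(shifts, function(s) {
    i <- 5:19
    sum(vp$reference[i, 6:18, 6:18] * vp$target[i + s, 6:18, 6:18])
  }, numeric(1))
  expect_equal(shifts[which.max(cc)], 2L)

  vp2 <- generate_volume_pair(c(24, 24, 24), p, seed = 3)
  expect_identical(vp$target, vp2$target)

  big <- rep(0, 12); big[10] <- 15
  expect_error(generate_volume_pair(c(24, 24, 24), big), "outside")
})

test_that("group datasets have the designed skewness structure", {
  gd <- generate_group_dataset(2, 2, seed = 21, samples_per_specimen = 10000)
  for (s in gd$aaa$samples) expect_gt(compute_sdi(s)$skewness, 0)
  for (s in gd$non_aaa$samples) expect_lt(compute_sdi(s)$skewness, 0)
  expect_true(all(unlist(gd$aaa$samples) > -0.5))
  expect_true(all(unlist(gd$non_aaa$samples) > -0.5))
  gd2 <- generate_group_dataset(2, 2, seed = 21, samples_per_specimen = 10000)
  expect_identical(gd$aaa$samples, gd2$aaa$samples)
  expect_error(generate_group_dataset(0, 2), "counts")
})
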