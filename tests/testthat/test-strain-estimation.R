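test_that("warp parameters map onto the deformation gradient layout", {
  p <- rep(0, 12); p[4] <- 0.05
  F1 <- warp_to_deformation_gradient(warp_parameters(p))
  expect_equal(F1[1, 2], 0.05)
  expect_equal(diag(F1), rep(1, 3))

  p2 <- rep(0, 12); p2[1] <- 0.1
  expect_equal(unclass(warp_to_deformation_gradient(p2))[1:3, 1:3],
               diag(c(1.1, 1, 1)), ignore_attr = TRUE)

  expect_identical(unclass(warp_to_deformation_gradient(rep(0, 12)))[1:3, 1:3],
                   diag(3), ignore_attr = TRUE)
  expect_warning(warp_to_deformation_gradient(c(-2, rep(0, 11))), "determinant")
  expect_error(warp_parameters(1:5), "12")
})

test_that("principal Green-Lagrange strain matches closed forms and an eigen oracle", {
  expect_equal(green_lagrange_principal(diag(3))$E1, 0)
  expect_equal(green_lagrange_principal(diag(c(1.1, 1, 1)))$E1,
               (1.1^2 - 1) / 2, tolerance = 1e-12)

  ## simple shear: oracle = roots of the characteristic polynomial of
  ## E = (F'F - I)/2, computed independently of eigen()
  F2 <- matrix(c(1, 0, 0.2, 1), 2, 2)
  E <- (t(F2) %*% F2 - diag(2)) / 2
  tr <- E[1, 1] + E[2, 2]; dt <- E[1, 1] * E[2, 2] - E[1, 2] * E[2, 1]
  oracle <- (tr + sqrt(tr^2 - 4 * dt)) / 2
  expect_equal(green_lagrange_principal(F2)$E1, oracle, tolerance = 1e-12)

  ## pure rotation carries no strain
  th <- 0.4
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  expect_lt(abs(green_lagrange_principal(R)$E1), 1e-9)
})

test_that("warp estimation recovers exact affine warps", {
  vp0 <- generate_volume_pair(c(28, 28, 28), rep(0, 12), seed = 2)
  fit0 <- estimate_warp(vp0)
  expect_lt(max(abs(as.numeric(fit0$p))), 1e-6)
  expect_true(fit0$converged)

  p_true <- c(0.08, -0.03, 0.01, 0.02, 0.05, -0.02, 0.01, -0.01, 0.04,
              0.1, -0.08, 0.05)
  for (s in 1:3) {
    vp <- generate_volume_pair(c(32, 32, 32), p_true, noise_sd = 0, seed = s)
    fit <- estimate_warp(vp)
    expect_lt(max(abs(as.numeric(fit$p) - p_true)), 1e-3)
  }
})

test_that("flat-texture windows are refused", {
  vp <- generate_volume_pair(c(24, 24, 24), rep(0, 12), seed = 2)
  vp$reference[] <- 1; vp$target[] <- 1
  expect_error(estimate_warp(vp), "flat")
})

test_that("strain from noisy pairs stays within 0.005 of truth", {
  p_true <- c(0.06, -0.02, 0.01, 0.02, 0.04, -0.01, 0.0, -0.01, 0.03,
              0.3, -0.2, 0.1)
  E1_true <- green_lagrange_principal(
    warp_to_deformation_gradient(warp_parameters(p_true)))$E1
  errs <- vapply(1:20, function(s) {
    vp <- generate_volume_pair(c(28, 28, 28), p_true, noise_sd = 0.01, seed = s)
    fit <- estimate_warp(vp)
    Fm <- diag(3) + matrix(as.numeric(fit$p)[1:9], 3, 3)
    abs(green_lagrange_principal(Fm)$E1 - E1_true)
  }, numeric(1))
  expect_lt(max(errs), 0.005)
})

test_that("objectivity: rotating both volumes leaves E1 unchanged", {
  ## 90-degree grid rotation of both volumes about the z axis is an exact
  ## relabelling; the estimated E1 must agree to optimizer precision
  p_true <- c(0.06, 0.01, 0, 0.01, 0.03, 0, 0, 0, 0.02, 0, 0, 0)
  vp <- generate_volume_pair(c(28, 28, 28), p_true, seed = 6)
  rot <- function(v) aperm(v[, dim(v)[2]:1, , drop = FALSE], c(2, 1, 3))
  vpr <- vp
  vpr$reference <- rot(vp$reference); vpr$target <- rot(vp$target)
  win <- list(lo = c(8L, 8L, 8L), hi = c(21L, 21L, 21L))  # symmetric under the rotation
  E1a <- green_lagrange_principal(
    diag(3) + matrix(as.numeric(estimate_warp(vp, window = win)$p)[1:9], 3, 3))$E1
  E1b <- green_lagrange_principal(
    diag(3) + matrix(as.numeric(estimate_warp(vpr, window = win)$p)[1:9], 3, 3))$E1
  expect_lt(abs(E1a - E1b), 1e-6)
})

test_that("tiled strain fields resolve homogeneous and two-zone warps", {
  ## zero deformation
  vp0 <- generate_volume_pair(c(28, 28, 28), rep(0, 12), seed = 4)
  sf0 <- strain_field_from_volumes(vp0, window_vox = 16)
  expect_lt(max(abs(sf0$E1), na.rm = TRUE), 1e-4)

  ## homogeneous affine: uniform field at the closed-form E1
  p <- c(0.05, 0, 0, 0, 0.03, 0, 0, 0, 0.02, 0, 0, 0)
  vp1 <- generate_volume_pair(c(36, 36, 36), p, seed = 4)
  sf1 <- strain_field_from_volumes(vp1, window_vox = 16)
  E1t <- green_lagrange_principal(warp_to_deformation_gradient(p))$E1
  expect_lt(max(abs(sf1$E1 - E1t), na.rm = TRUE), 1e-3)

  ## two-zone stretch: per-zone median within 0.005 of each closed form
  shape <- c(56, 28, 28)
  nb <- 140
  blobs <- withr::with_seed(8, list(
    c = cbind(runif(nb, -2, shape[1] + 2), runif(nb, -2, shape[2] + 2),
              runif(nb, -2, shape[3] + 2)),
    a = runif(nb, 0.5, 1) * sample(c(-1, 1), nb, TRUE),
    s = runif(nb, 0.85, 1.25) * 2.2))
  tex <- function(pts) {
    out <- numeric(nrow(pts))
    for (k in seq_len(nb)) {
      out <- out + blobs$a[k] *
        exp(-((pts[, 1] - blobs$c[k, 1])^2 + (pts[, 2] - blobs$c[k, 2])^2 +
                (pts[, 3] - blobs$c[k, 3])^2) / (2 * blobs$s[k]^2))
    }
    out
  }
  grid <- as.matrix(expand.grid(seq_len(shape[1]), seq_len(shape[2]),
                                seq_len(shape[3])))
  ref <- array(tex(grid), dim = shape)
  ## backward map: left zone stretched by 1.06 about x = 14, right identity,
  ## smooth blend around the midline
  s_left <- 1.06; c_left <- 14; mid <- 28.5
  w <- 1 / (1 + exp((grid[, 1] - mid) / 1.5))
  xb <- grid
  xb[, 1] <- w * (c_left + (grid[, 1] - c_left) / s_left) + (1 - w) * grid[, 1]
  tgt <- array(tex(xb), dim = shape)
  pairz <- list(reference = ref, target = tgt, voxel_size_um = 40)
  sfz <- strain_field_from_volumes(pairz, window_vox = 14)
  xs <- sfz$centers[[1]]
  left <- sfz$E1[xs < 22, , , drop = FALSE]
  right <- sfz$E1[xs > 35, , , drop = FALSE]
  expect_lt(abs(median(left, na.rm = TRUE) - (s_left^2 - 1) / 2), 0.005)
  expect_lt(abs(median(right, na.rm = TRUE) - 0), 0.005)
})
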