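test_that("a source sampled from the target registers with zero motion", {
  tgt <- circle_contour(n = 4000, r = 500)
  src <- contour(contour_points(tgt)[seq(1, 4000, by = 20), ], role = "lumen")
  r <- cpd_nonrigid(src, tgt)
  expect_lt(r$rmse, 1e-6)
  expect_lt(max(abs(r$displacement)), 1e-6)
  expect_true(r$ordering_preserved)
})

test_that("registration is deterministic and translation-invariant", {
  src <- circle_contour(n = 120, r = 500)
  th <- seq(0, 2 * pi, length.out = 4001)[-4001]
  r2 <- 500 * (1 + 0.05 * cos(3 * th + 0.7))
  tgt <- contour(cbind(r2 * cos(th), r2 * sin(th)), role = "lumen")

  a <- cpd_nonrigid(src, tgt)
  b <- cpd_nonrigid(src, tgt)
  expect_identical(a$displacement, b$displacement)

  shift <- c(1234.5, -987.6)
  src2 <- contour(contour_points(src) + rep(shift, each = 120), role = "lumen")
  tgt2 <- contour(contour_points(tgt) + rep(shift, each = 4000), role = "lumen")
  c2 <- cpd_nonrigid(src2, tgt2)
  expect_lt(max(abs(c2$displacement - a$displacement)), 1e-6)

  expect_error(cpd_nonrigid(src, contour_points(tgt)[rep(1, 100), ] +
                              matrix(0, 100, 2)), "degenerate")
})

test_that("stronger smoothing never roughens the displacement field", {
  src <- circle_contour(n = 120, r = 500)
  th <- seq(0, 2 * pi, length.out = 4001)[-4001]
  r2 <- 500 * (1 + 0.05 * cos(3 * th + 0.7))
  tgt <- contour(cbind(r2 * cos(th), r2 * sin(th)), role = "lumen")
  roughness <- function(r) {
    d <- r$displacement
    sum(diff(diff(rbind(d, d[1:2, ])))^2)
  }
  vals <- vapply(c(0.1, 0.5, 2, 5), function(l) {
    roughness(cpd_nonrigid(src, tgt, smoothing_weight = l))
  }, numeric(1))
  expect_true(all(diff(vals) <= abs(vals[-length(vals)]) * 1e-3))
})

test_that("multi-step registration chains, sums and gates correctly", {
  src <- circle_contour(n = 100, r = 500)
  th <- seq(0, 2 * pi, length.out = 4001)[-4001]
  r2 <- 500 * (1 + 0.04 * cos(2 * th))
  tgt <- contour(cbind(r2 * cos(th), r2 * sin(th)), role = "outer")

  single <- multistep_register(src, tgt, auxiliaries = NULL)
  direct <- cpd_nonrigid(src, tgt)
  expect_equal(single$steps_used, 1L)
  expect_equal(single$displacement, direct$displacement)

  aux <- make_auxiliary_contours(src, tgt, fractions = c(1 / 3, 2 / 3))
  multi <- multistep_register(src, tgt, auxiliaries = aux, aux_density = 3000)
  expect_equal(multi$steps_used, 3L)
  ## displacement additivity: moved = source + total displacement
  expect_lt(max(abs(contour_points(multi$moved) -
                      (contour_points(src) + multi$displacement))), 1e-9)
})

test_that("validation gate applies role thresholds, ordering and uniformity", {
  mk <- function(rmse, ordering = TRUE, uniformity = 0.9) {
    structure(list(rmse = rmse, ordering_preserved = ordering,
                   uniformity = uniformity, steps_used = 1L),
              class = "registration_result")
  }
  expect_true(validate_registration(mk(0.09), "lumen")$pass)
  expect_false(validate_registration(mk(0.5), "lumen")$pass)
  expect_true(validate_registration(mk(0.5), "outer")$pass)
  expect_false(validate_registration(mk(0.09, ordering = FALSE), "lumen")$pass)
  expect_false(validate_registration(mk(0.09, uniformity = 0.2), "lumen")$pass)
  bad <- validate_registration(mk(0.5, FALSE, 0.1), "lumen")
  expect_length(bad$reasons, 3L)
})
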