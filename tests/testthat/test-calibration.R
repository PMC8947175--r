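test_that("noiseless proportional controls give the exact factors", {
  s <- toy_control(bx = 2, by = 3)
  expect_equal(estimate_x(s, quantile = 1), 2, tolerance = 1e-12)
  expect_equal(estimate_y(s, quantile = 1), 3, tolerance = 1e-12)
  f <- calibrate(list(s), quantile = 1)
  expect_equal(f$x, 2, tolerance = 1e-12)
  expect_equal(f$y, 3, tolerance = 1e-12)
  expect_equal(f$n_control_images, 1L)
})

test_that("a dark dsDNA channel gives factor zero, empty masks error", {
  s <- toy_control()
  s$dsdna <- matrix(0, nrow(s$dsdna), ncol(s$dsdna))
  expect_equal(estimate_x(s, quantile = 1), 0)
  no_mito <- channel_stack(s$dsdna + 1, s$h2b, blank_mat(48), 0.5)
  expect_error(estimate_x(no_mito), "mitochondrial mask")
  no_nuc <- channel_stack(s$dsdna + 1, blank_mat(48), s$hsp60, 0.5)
  expect_error(estimate_y(no_nuc), "nuclear mask")
  expect_error(calibrate(list()), "non-empty")
  expect_error(estimate_x(s, quantile = 0), "quantile")
})

test_that("the estimate is non-decreasing in the quantile", {
  s <- toy_control(bx = 1.5)
  # spread the mitochondrial ratio deterministically around 1.5
  sel <- s$hsp60 > 0
  mult <- matrix(1, nrow(s$dsdna), ncol(s$dsdna))
  mult[sel] <- seq(0.9, 1.1, length.out = sum(sel))
  s$dsdna <- s$dsdna * mult
  qs <- c(0.5, 0.9, 0.99, 1)
  est <- vapply(qs, function(q) estimate_x(s, quantile = q), numeric(1))
  expect_true(all(diff(est) >= 0))
  # with no boundary erosion, quantile 1 is the max masked ratio
  expect_equal(estimate_x(s, quantile = 1, boundary_erode_px = 0),
               max((s$dsdna / s$hsp60)[s$hsp60 > 0.5 & s$h2b < 0.5]),
               tolerance = 1e-12)
})

test_that("factors are equivariant under intensity rescaling", {
  s <- toy_control(bx = 2, by = 3)
  x0 <- estimate_x(s, quantile = 1); y0 <- estimate_y(s, quantile = 1)
  s2 <- s; s2$dsdna <- 4 * s$dsdna
  expect_equal(estimate_x(s2, quantile = 1), 4 * x0, tolerance = 1e-12)
  expect_equal(estimate_y(s2, quantile = 1), 4 * y0, tolerance = 1e-12)
  s3 <- s; s3$hsp60 <- 2 * s$hsp60
  expect_equal(estimate_x(s3, quantile = 1), x0 / 2, tolerance = 1e-12)
})

test_that("verify_factors reports zero positive residual at quantile 1", {
  controls <- list(toy_control(bx = 2, by = 3, id = "a"),
                   toy_control(bx = 2, by = 3, id = "b"))
  f <- calibrate(controls, quantile = 1)
  rep <- verify_factors(controls, f)
  expect_equal(nrow(rep), 2L)
  expect_true(all(rep$frac_pos_mito == 0))
  expect_true(all(rep$frac_pos_nuclear == 0))
  # inflating a factor can never increase the positive fraction
  f10 <- calibration_factors(10 * f$x, 10 * f$y, f$quantile)
  rep10 <- verify_factors(controls, f10)
  expect_true(all(rep10$frac_pos_mito == 0))
  # an undersized factor leaves positive residual behind
  f_lo <- calibration_factors(f$x / 2, f$y / 2, f$quantile)
  rep_lo <- verify_factors(controls, f_lo)
  expect_gt(rep_lo$frac_pos_mito[1], 0)
  expect_gt(rep_lo$frac_pos_nuclear[1], 0)
})

test_that("sub-unit quantiles leave at most the matching residual fraction", {
  s <- toy_control(bx = 1.5)
  sel <- s$hsp60 > 0
  mult <- matrix(1, nrow(s$dsdna), ncol(s$dsdna))
  mult[sel] <- seq(0.9, 1.1, length.out = sum(sel))
  s$dsdna <- s$dsdna * mult
  f <- calibrate(list(s), quantile = 0.99)
  rep <- verify_factors(list(s), f)
  expect_lte(rep$frac_pos_mito[1], 0.01)
  expect_lte(rep$frac_pos_nuclear[1], 0.01)
})
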