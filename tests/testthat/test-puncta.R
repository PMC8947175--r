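sub_img <- function(values, pixel = 0.5) {
  s <- channel_stack(values, matrix(0, nrow(values), ncol(values)),
                     matrix(0, nrow(values), ncol(values)), pixel)
  subtract(s, calibration_factors(0, 0))
}

disc_mask <- function(size, cy, cx, r, r_in = 0) {
  d2 <- outer((seq_len(size) - cy)^2, (seq_len(size) - cx)^2, `+`)
  d2 <= r^2 & d2 >= r_in^2
}

test_that("binarization follows the >= threshold convention", {
  two <- matrix(c(rep(0, 20), rep(1, 16)), 6)
  m <- binarize(sub_img(two))
  expect_equal(m, two == 1, ignore_attr = TRUE)
  # fixed threshold includes the boundary value
  p <- detection_params(threshold_method = "fixed", fixed_threshold = 0.5)
  m2 <- binarize(matrix(c(0.49, 0.5, 0.51, 0), 2), p)
  expect_identical(as.vector(m2), c(FALSE, TRUE, TRUE, FALSE))
  expect_warning(m3 <- binarize(matrix(0, 4, 4)), "all-zero")
  expect_false(any(m3))
})

test_that("Otsu threshold maximises between-class variance (oracle)", {
  set.seed(21)
  v <- matrix(c(rnorm(400, 0.1, 0.05), rnorm(400, 0.9, 0.05)), 40)
  v[v < 0] <- 0
  th <- attr(binarize(sub_img(v)), "threshold")
  expect_gt(th, 0.3); expect_lt(th, 0.7)
  expect_equal(th, oracle_otsu(as.vector(v)), tolerance = 1e-12)
  # and on a second, asymmetric mixture
  v2 <- matrix(c(rexp(600, 8), rnorm(100, 0.8, 0.03)), 20)
  v2[v2 < 0] <- 0
  expect_equal(attr(binarize(sub_img(v2)), "threshold"),
               oracle_otsu(as.vector(v2)), tolerance = 1e-12)
})

test_that("area is measured in physical units with inclusive bounds", {
  f <- calibration_factors(1, 1)
  # 3x3 solid square at 0.5 um/px: 9 px * 0.25 = 2.25 um^2, kept
  m <- matrix(FALSE, 12, 12); m[5:7, 5:7] <- TRUE
  p <- find_puncta(m, blank_mat(12), f, 0.5)
  expect_equal(p$area_um2, 2.25)
  expect_identical(p$classification, "ectopic_mito")
  # a single pixel at 0.5 um/px is 0.25 um^2 < 2, rejected
  m1 <- matrix(FALSE, 8, 8); m1[4, 4] <- TRUE
  expect_identical(find_puncta(m1, blank_mat(8), f, 0.5)$classification,
                   "rejected_size")
  # inclusive bounds at 1 um/px: 2 px = 2 um^2 kept, 20 px kept, 21 px not
  m2 <- matrix(FALSE, 10, 10); m2[5, 5:6] <- TRUE
  expect_identical(find_puncta(m2, blank_mat(10), f, 1)$classification,
                   "ectopic_mito")
  m20 <- matrix(FALSE, 12, 12); m20[4:7, 4:8] <- TRUE
  expect_identical(find_puncta(m20, blank_mat(12), f, 1)$classification,
                   "ectopic_mito")
  m21 <- matrix(FALSE, 12, 12); m21[4:6, 4:10] <- TRUE
  expect_identical(find_puncta(m21, blank_mat(12), f, 1)$classification,
                   "rejected_size")
})

test_that("a rasterised disc is highly circular, an annulus is a donut", {
  f <- calibration_factors(1, 1)
  d <- disc_mask(31, 16, 16, 10)
  p <- find_puncta(d, blank_mat(31), f, 0.4)
  expect_gte(p$circularity, 0.9)
  expect_equal(p$euler_number, 1)
  expect_equal(p$area_um2, sum(d) * 0.16)
  ring <- disc_mask(31, 16, 16, 6, r_in = 3)
  pr <- find_puncta(ring, blank_mat(31), f, 0.45)
  expect_equal(pr$euler_number, 0)
  expect_identical(pr$classification, "nuclear_origin_donut")
  # with donut exclusion off the ring passes (area and shape permitting)
  params_off <- detection_params(exclude_donuts = FALSE)
  pr2 <- find_puncta(ring, blank_mat(31), f, 0.45, params_off)
  expect_identical(pr2$classification, "ectopic_mito")
})

test_that("histone overlap reclassifies puncta as nuclear origin", {
  f <- calibration_factors(1, 1)
  m <- matrix(FALSE, 12, 12); m[5:8, 5:8] <- TRUE
  h2b <- blank_mat(12); h2b[5:8, 5:6] <- 1   # half the punctum
  p <- find_puncta(m, h2b, f, 0.5)
  expect_equal(p$histone_overlap_fraction, 0.5)
  expect_identical(p$classification, "nuclear_origin_overlap")
  lax <- detection_params(histone_overlap_max_fraction = 0.6)
  expect_identical(find_puncta(m, h2b, f, 0.5, lax)$classification,
                   "ectopic_mito")
  # donut precedence beats overlap: a histone-covered ring is a donut
  ring <- disc_mask(31, 16, 16, 6, r_in = 3)
  h2b_full <- matrix(1, 31, 31)
  expect_identical(find_puncta(ring, h2b_full, f, 0.45)$classification,
                   "nuclear_origin_donut")
})

test_that("classification is invariant under translation", {
  set.seed(22)
  base <- matrix(FALSE, 40, 40)
  base[6:9, 6:9] <- TRUE
  base <- base | disc_mask(40, 25, 20, 5) | disc_mask(40, 14, 30, 6, 3)
  h2b <- blank_mat(40); h2b[6:9, 6:9] <- 1
  f <- calibration_factors(1, 1)
  p0 <- find_puncta(base, h2b, f, 0.5)
  shift <- function(m, dr, dc) {
    out <- matrix(FALSE, nrow(m), ncol(m))
    out[(1 + dr):nrow(m), (1 + dc):ncol(m)] <-
      m[1:(nrow(m) - dr), 1:(ncol(m) - dc)]
    out
  }
  p1 <- find_puncta(shift(base, 3, 2), shift(h2b > 0, 3, 2) + 0, f, 0.5)
  expect_equal(sort(p0$classification), sort(p1$classification))
  expect_equal(sort(p0$area_um2), sort(p1$area_um2))
  expect_equal(sort(p0$perimeter_um), sort(p1$perimeter_um))
})

test_that("connectivity 4 and 8 differ on diagonal contacts", {
  m <- matrix(FALSE, 6, 6)
  m[2, 2] <- m[3, 3] <- TRUE
  f <- calibration_factors(1, 1)
  expect_equal(nrow(find_puncta(m, blank_mat(6), f, 1)), 1L)
  p4 <- detection_params(connectivity = 4)
  expect_equal(nrow(find_puncta(m, blank_mat(6), f, 1, p4)), 2L)
})

test_that("parameter validation rejects inconsistent settings", {
  expect_error(detection_params(min_area_um2 = 20, max_area_um2 = 2), "<")
  expect_error(detection_params(min_circularity = -1), "circularity")
  expect_error(detection_params(connectivity = 6), "connectivity")
  expect_error(detection_params(threshold_method = "fixed"),
               "fixed_threshold")
  # the circularity ceiling is capped at 1
  expect_equal(detection_params(max_circularity = 2)$max_circularity, 1)
})

test_that("the full pipeline composes on a synthetic field", {
  sp <- scene_spec(n_cells = 2, n_ectopic_puncta = 4, seed = 5,
                   field_size_px = c(192L, 192L))
  sc <- render_scene(sp)
  ctrl <- render_scene(scene_spec(n_cells = 2, seed = 6,
                                  field_size_px = c(192L, 192L)))
  f <- calibrate(list(ctrl$stack))
  r <- detect(sc$stack, f)
  expect_s3_class(r, "detection_result")
  expect_equal(r$n_ectopic, 4)
  expect_equal(r$n_cells, 2)
  expect_equal(r$dots_per_cell, 2)
  expect_output(print(r), "ectopic puncta 4")
  # empty noise-only field yields no puncta
  empty <- render_scene(scene_spec(n_cells = 0, seed = 7,
                                   field_size_px = c(128L, 128L)))
  r0 <- detect(empty$stack, f)
  expect_equal(r0$n_ectopic, 0)
  expect_true(is.na(r0$dots_per_cell))
})
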