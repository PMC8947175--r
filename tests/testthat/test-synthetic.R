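test_that("rendering is a pure function of the spec", {
  sp <- scene_preset("gba_kd", seed = 17)
  a <- render_scene(sp); b <- render_scene(sp)
  expect_identical(a$stack$dsdna, b$stack$dsdna)
  expect_identical(a$stack$h2b, b$stack$h2b)
  expect_identical(a$stack$hsp60, b$stack$hsp60)
  expect_identical(a$truth, b$truth)
})

test_that("ground truth bookkeeping matches the spec", {
  sp <- scene_spec(n_cells = 3, n_ectopic_puncta = 10, n_nuclear_dots = 2,
                   n_donuts = 1, seed = 4)
  tr <- render_scene(sp)$truth
  expect_equal(sum(tr$type == "nucleus"), 3)
  expect_equal(sum(tr$type == "ectopic_punctum"), 10)
  expect_equal(sum(tr$type == "nuclear_dot"), 2)
  expect_equal(sum(tr$type == "donut"), 1)
  expect_equal(attr(tr, "true_factors"), c(x = 1.5, y = 3))
  # ectopic areas are inside the requested range (rasterisation slack)
  ar <- tr$area_um2[tr$type == "ectopic_punctum"]
  expect_true(all(ar > 2 & ar < 14))
})

test_that("an empty noiseless spec renders an all-zero stack", {
  sp <- scene_spec(n_cells = 0, noise_sigma = 0, seed = 1,
                   field_size_px = c(64L, 64L))
  st <- render_scene(sp)$stack
  expect_true(all(st$dsdna == 0) && all(st$h2b == 0) && all(st$hsp60 == 0))
})

test_that("presets honour their condition contracts", {
  for (seed in 1:10) {
    ctl <- scene_preset("control", seed)
    tf <- scene_preset("tfam_kd", seed)
    gb <- scene_preset("gba_kd", seed)
    expect_lte(ctl$n_ectopic_puncta, 1)
    expect_equal(ctl$n_nuclear_dots, 0L)
    expect_true(tf$n_ectopic_puncta %in% 8:15)
    expect_gt(tf$n_ectopic_puncta, ctl$n_ectopic_puncta)
    expect_true(gb$n_ectopic_puncta %in% 4:8)
    expect_true(gb$n_nuclear_dots %in% 3:6)
    expect_gte(gb$n_nuclear_dots, 1)
  }
  expect_error(scene_preset("mystery", 1))
  expect_error(scene_spec(n_cells = -1), ">= 0")
})

test_that("overcrowded fields fail with an explicit error", {
  sp <- scene_spec(field_size_px = c(64L, 64L), n_cells = 1,
                   n_ectopic_puncta = 150, seed = 2)
  expect_error(render_scene(sp), "crowded")
})

test_that("object stages are independent: dots only add local signal", {
  sp0 <- scene_preset("tfam_kd", seed = 8)
  sp1 <- sp0; sp1$n_nuclear_dots <- 3L
  a <- render_scene(sp0); b <- render_scene(sp1)
  d <- abs(b$stack$dsdna - a$stack$dsdna)
  changed <- which(d > 1e-12, arr.ind = TRUE)
  dots <- b$truth[b$truth$type == "nuclear_dot", ]
  near_dot <- function(r, c) any((r - dots$centroid_row)^2 +
                                   (c - dots$centroid_col)^2 <= 16^2)
  expect_true(all(mapply(near_dot, changed[, 1], changed[, 2])))
  # the noise field itself is unchanged far from the dots
  expect_identical(a$stack$hsp60, b$stack$hsp60)
})

test_that("calibration recovers the true bleed under bounded noise", {
  ctl <- lapply(1:5, function(i) {
    sp <- scene_preset("control", seed = 300 + i)
    sp$noise_model <- "uniform"; sp$noise_sigma <- 0.05
    render_scene(sp)$stack
  })
  x <- estimate_x(ctl, 0.999); y <- estimate_y(ctl, 0.999)
  expect_lt(abs(x - 1.5) / 1.5, 0.15)
  expect_lt(abs(y - 3) / 3, 0.15)
})

test_that("detection scoring matches hand-checked cases", {
  sc <- render_scene(scene_spec(n_cells = 2, n_ectopic_puncta = 5,
                                seed = 9, field_size_px = c(192L, 192L)))
  ctrl <- render_scene(scene_spec(n_cells = 2, seed = 10,
                                  field_size_px = c(192L, 192L)))
  f <- calibrate(list(ctrl$stack))
  r <- detect(sc$stack, f)
  sc_score <- score_detection(r, sc$truth)
  expect_equal(sc_score$n_true, 5)
  expect_equal(sc_score$sensitivity, 1)
  expect_equal(sc_score$false_positives, 0)
})
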