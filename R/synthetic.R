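# Synthetic triple-stained fields with ground truth.
#
# The generator emulates the structures the method must separate: bright
# H2B-positive nuclei whose DNA also stains for dsDNA (factor
# bleed_y_true), a curvilinear Hsp60-positive mitochondrial network with
# nucleoid hot spots whose dsDNA signal is proportional to Hsp60 (factor
# bleed_x_true -- the confound calibration must remove), free-standing
# ectopic dsDNA-only puncta (the objects to count), histone-positive
# nuclear-origin dots, and dsDNA rings ("donuts") with faint sub-threshold
# H2B. Objects are placed with exclusion margins so ground-truth classes
# stay unambiguous; rendering is a pure function of the spec, including
# its seed.

mix_seed <- function(seed, salt) {
  as.integer(((as.numeric(seed) %% 2147483647) * 97 + salt * 10007) %%
               2147483647)
}

with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  expr
}

#' Synthetic scene specification
#'
#' Parameters of one rendered field. Defaults describe a 79 x 79 um
#' confocal field (256 px at 0.31 um/px) of HeLa-like cells; intensities
#' are on a unit scale where a punctum has amplitude 1.
#'
#' @param field_size_px height/width in pixels (length-2).
#' @param pixel_size_um physical pixel size (um/px).
#' @param n_cells number of nuclei.
#' @param n_ectopic_puncta ectopic (mitochondria-derived, marker-free)
#'   dsDNA puncta.
#' @param ectopic_area_range_um2 area range the puncta are drawn from.
#' @param n_nuclear_dots histone-positive cytoplasmic dots.
#' @param n_donuts dsDNA rings with faint (sub-threshold) H2B.
#' @param bleed_x_true dsDNA signal per unit Hsp60 inside mitochondria.
#' @param bleed_y_true dsDNA signal per unit H2B inside nuclei.
#' @param psf_sigma_px gaussian point-spread sigma (px).
#' @param noise_model `"gaussian"` (additive, sd = `noise_sigma` in punctum
#'   amplitude units), `"uniform"` (bounded multiplicative,
#'   value * (1 + U(-noise_sigma, noise_sigma)); the model under which the
#'   "residual <= 0 in controls" calibration rule is well-posed) or
#'   `"poisson_gaussian"` (shot noise scaled so sd = `noise_sigma` at unit
#'   intensity, plus 20 % read noise).
#' @param noise_sigma noise level, see `noise_model`.
#' @param seed integer; fixes the scene exactly.
#' @return An object of class `scene_spec`.
#' @seealso [scene_preset()], [render_scene()]
#' @export
scene_spec <- function(field_size_px = c(256L, 256L), pixel_size_um = 0.31,
                       n_cells = 5L, n_ectopic_puncta = 0L,
                       ectopic_area_range_um2 = c(3, 12),
                       n_nuclear_dots = 0L, n_donuts = 0L,
                       bleed_x_true = 1.5, bleed_y_true = 3,
                       psf_sigma_px = 1, noise_model = c(
                         "gaussian", "uniform", "poisson_gaussian"),
                       noise_sigma = 0.057, seed = 1L) {
  noise_model <- match.arg(noise_model)
  counts <- c(n_cells, n_ectopic_puncta, n_nuclear_dots, n_donuts)
  if (any(counts < 0)) stop("all counts must be >= 0", call. = FALSE)
  if (pixel_size_um <= 0) stop("pixel_size_um must be positive",
                               call. = FALSE)
  if (length(ectopic_area_range_um2) != 2L ||
      ectopic_area_range_um2[1] > ectopic_area_range_um2[2])
    stop("bad ectopic_area_range_um2", call. = FALSE)
  structure(list(field_size_px = as.integer(field_size_px),
                 pixel_size_um = pixel_size_um,
                 n_cells = as.integer(n_cells),
                 n_ectopic_puncta = as.integer(n_ectopic_puncta),
                 ectopic_area_range_um2 = ectopic_area_range_um2,
                 n_nuclear_dots = as.integer(n_nuclear_dots),
                 n_donuts = as.integer(n_donuts),
                 bleed_x_true = bleed_x_true, bleed_y_true = bleed_y_true,
                 psf_sigma_px = psf_sigma_px, noise_model = noise_model,
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "scene_spec")
}

#' Scene presets for the three experimental conditions
#'
#' Seeded specs emulating the phenotypes the method distinguishes:
#' `control` fields have at most one ectopic punctum and no nuclear-origin
#' dots; `tfam_kd` fields (destabilised mitochondrial DNA) have many
#' histone-negative ectopic puncta; `gba_kd` fields mix ectopic puncta
#' with histone-positive nuclear-origin dots.
#'
#' @param name `"control"`, `"tfam_kd"` or `"gba_kd"`.
#' @param seed integer; drawn counts and the rendering are functions of it.
#' @return A [scene_spec()].
#' @export
scene_preset <- function(name = c("control", "tfam_kd", "gba_kd"),
                         seed = 1L) {
  name <- match.arg(name)
  with_seed(mix_seed(seed, 99L), {
    n_cells <- sample(4:6, 1L)
    counts <- switch(name,
      control = list(ect = sample(0:1, 1L, prob = c(0.7, 0.3)), dots = 0L,
                     donuts = 0L),
      tfam_kd = list(ect = sample(8:15, 1L), dots = 0L, donuts = 0L),
      gba_kd = list(ect = sample(4:8, 1L), dots = sample(3:6, 1L),
                    donuts = 0L))
    scene_spec(n_cells = n_cells, n_ectopic_puncta = counts$ect,
               n_nuclear_dots = counts$dots, n_donuts = counts$donuts,
               seed = seed)
  })
}

# --- drawing primitives (operate in place on a matrix patch) ------------

draw_disc <- function(img, cy, cx, r, value, r_in = 0) {
  h <- nrow(img); w <- ncol(img)
  rad <- ceiling(r)
  rs <- max(1L, floor(cy - rad)):min(h, ceiling(cy + rad))
  cs <- max(1L, floor(cx - rad)):min(w, ceiling(cx + rad))
  if (length(rs) == 0L || length(cs) == 0L) return(list(img = img, n = 0L))
  d2 <- outer((rs - cy)^2, (cs - cx)^2, `+`)
  sel <- d2 <= r^2 & d2 >= r_in^2
  img[rs, cs][sel] <- img[rs, cs][sel] + value
  list(img = img, n = sum(sel))
}

draw_ellipse <- function(img, cy, cx, a, b, theta, value) {
  h <- nrow(img); w <- ncol(img)
  rad <- ceiling(max(a, b))
  rs <- max(1L, floor(cy - rad)):min(h, ceiling(cy + rad))
  cs <- max(1L, floor(cx - rad)):min(w, ceiling(cx + rad))
  dy <- matrix(rs - cy, length(rs), length(cs))
  dx <- matrix(cs - cx, length(rs), length(cs), byrow = TRUE)
  u <- dx * cos(theta) + dy * sin(theta)
  v <- -dx * sin(theta) + dy * cos(theta)
  sel <- (u / a)^2 + (v / b)^2 <= 1
  img[rs, cs][sel] <- img[rs, cs][sel] + value
  list(img = img, n = sum(sel))
}

# gaussian PSF applied to all three channels in one filter2 call
blur_channels <- function(chans, sigma) {
  if (sigma <= 0) return(chans)
  H <- nrow(chans[[1]]); W <- ncol(chans[[1]])
  img <- EBImage::Image(array(unlist(chans, use.names = FALSE),
                              dim = c(H, W, length(chans))))
  r <- max(2L, as.integer(2 * ceiling(3 * sigma) + 1))
  br <- EBImage::makeBrush(if (r %% 2L) r else r + 1L, shape = "gaussian",
                           sigma = sigma)
  out <- EBImage::imageData(EBImage::filter2(img, br,
                                             boundary = "replicate"))
  lapply(seq_along(chans), function(k) matrix(out[, , k], H, W))
}

# --- object placement ---------------------------------------------------

place_free_object <- function(H, W, robj, margin, nuclei, net_pts, placed,
                              retries = 800L) {
  lo_r <- robj + 2; hi_r <- H - robj - 1
  lo_c <- robj + 2; hi_c <- W - robj - 1
  if (hi_r <= lo_r || hi_c <= lo_c)
    stop("field too crowded: object does not fit", call. = FALSE)
  for (i in seq_len(retries)) {
    r0 <- stats::runif(1, lo_r, hi_r)
    c0 <- stats::runif(1, lo_c, hi_c)
    if (nrow(nuclei) > 0 &&
        any((r0 - nuclei$row)^2 + (c0 - nuclei$col)^2 <
            (nuclei$r + robj + margin + 2)^2)) next
    if (!is.null(net_pts) && nrow(net_pts) > 0 &&
        min((r0 - net_pts[, 1])^2 + (c0 - net_pts[, 2])^2) <
        (robj + margin + 3)^2) next
    if (nrow(placed) > 0 &&
        any((r0 - placed$row)^2 + (c0 - placed$col)^2 <
            (placed$r + robj + margin)^2)) next
    return(c(r0, c0))
  }
  stop("field too crowded: could not place object after ", retries,
       " attempts", call. = FALSE)
}

# --- renderer -----------------------------------------------------------

#' Render a synthetic scene
#'
#' Deterministically renders the three channels described by a
#' [scene_spec()] (same spec, bit-identical output) and returns them with
#' the ground-truth object table. Each rendering stage (nuclei, network,
#' ectopic puncta, nuclear dots, donuts, noise) uses its own seed derived
#' from `spec$seed`, so adding objects of one type leaves all other
#' stages -- including the noise field of the additive models --
#' unchanged.
#'
#' @param spec a [scene_spec()].
#' @return List with `stack` (a [channel_stack()]), `truth` (data.frame
#'   of `object_id`, `type`, `centroid_row`, `centroid_col`, `area_um2`,
#'   with the true bleed factors in `attr(truth, "true_factors")`) and
#'   `spec`.
#' @examples
#' sc <- render_scene(scene_preset("gba_kd", seed = 7))
#' table(sc$truth$type)
#' @export
render_scene <- function(spec) {
  if (!inherits(spec, "scene_spec")) stop("spec must be a scene_spec",
                                          call. = FALSE)
  H <- spec$field_size_px[1]; W <- spec$field_size_px[2]
  s <- spec$pixel_size_um
  psf <- spec$psf_sigma_px
  margin <- 3 + ceiling(2 * psf)
  truth <- list()
  oid <- 0L
  add_truth <- function(type, row, col, area_um2) {
    oid <<- oid + 1L
    truth[[oid]] <<- data.frame(object_id = oid, type = type,
                                centroid_row = row, centroid_col = col,
                                area_um2 = area_um2,
                                stringsAsFactors = FALSE)
  }

  # stage 1: nuclei
  h2b_nuc <- matrix(0, H, W)
  nuclei <- data.frame(row = numeric(0), col = numeric(0), r = numeric(0))
  with_seed(mix_seed(spec$seed, 1L), {
    for (i in seq_len(spec$n_cells)) {
      r <- stats::runif(1, 21, 26)
      placed <- FALSE
      for (try in 1:500) {
        r0 <- stats::runif(1, r + 2, H - r - 1)
        c0 <- stats::runif(1, r + 2, W - r - 1)
        if (nrow(nuclei) == 0 ||
            all((r0 - nuclei$row)^2 + (c0 - nuclei$col)^2 >
                (nuclei$r + r + 6)^2)) { placed <- TRUE; break }
      }
      if (!placed) stop("field too crowded: cannot place nucleus ", i,
                        call. = FALSE)
      ecc <- stats::runif(1, 0.85, 1)
      theta <- stats::runif(1, 0, pi)
      amp <- stats::runif(1, 0.9, 1.1)
      de <- draw_ellipse(h2b_nuc, r0, c0, r / sqrt(ecc), r * sqrt(ecc),
                         theta, amp)
      h2b_nuc <- de$img
      nuclei[nrow(nuclei) + 1L, ] <- c(r0, c0, r)
      add_truth("nucleus", r0, c0, de$n * s^2)
    }
  })

  # stage 2: mitochondrial network with nucleoid hot spots
  mito <- matrix(0, H, W)
  net_pts <- NULL
  if (spec$n_cells > 0) with_seed(mix_seed(spec$seed, 2L), {
    net_gap <- margin + 2
    pts_all <- list()
    nucleoid_ctr <- list()
    for (i in seq_len(nrow(nuclei))) {
      for (f in seq_len(sample(2:3, 1L))) {
        phi <- stats::runif(1, 0, 2 * pi)
        start_r <- nuclei$row[i] + (nuclei$r[i] + net_gap + 2) * sin(phi)
        start_c <- nuclei$col[i] + (nuclei$r[i] + net_gap + 2) * cos(phi)
        L <- sample(60:110, 1L)
        th <- phi + pi / 2 * sample(c(-1, 1), 1) +
          cumsum(stats::rnorm(L, 0, 0.35))
        pr <- start_r + cumsum(1.4 * sin(th))
        pc <- start_c + cumsum(1.4 * cos(th))
        keep <- pr > 2 & pr < H - 1 & pc > 2 & pc < W - 1
        for (k in seq_len(nrow(nuclei)))
          keep <- keep & ((pr - nuclei$row[k])^2 + (pc - nuclei$col[k])^2 >
                            (nuclei$r[k] + net_gap)^2)
        if (!any(keep)) next
        pr <- pr[keep]; pc <- pc[keep]
        pts_all[[length(pts_all) + 1L]] <- cbind(pr, pc)
        add_truth("mito_segment", mean(pr), mean(pc),
                  length(pr) * 1.4 * 3 * s^2)
        # nucleoid hot spots every ~7th retained path point
        if (length(pr) >= 4) {
          sel <- seq(4L, length(pr), by = 7L)
          nucleoid_ctr[[length(nucleoid_ctr) + 1L]] <-
            cbind(pr[sel], pc[sel])
        }
      }
    }
    if (length(nucleoid_ctr)) {
      # all nucleoid discs (r = 1.5 px) in one accumulation pass
      ctr <- do.call(rbind, nucleoid_ctr)
      off <- which(outer((-2:2)^2, (-2:2)^2, `+`) <= 1.5^2,
                   arr.ind = TRUE) - 3L
      rows <- rep(round(ctr[, 1]), each = nrow(off)) + off[, 1]
      cols <- rep(round(ctr[, 2]), each = nrow(off)) + off[, 2]
      ok <- rows >= 1 & rows <= H & cols >= 1 & cols <= W
      cnt <- tabulate(rows[ok] + (cols[ok] - 1L) * H, H * W)
      mito <- mito + 0.8 * matrix(cnt, H, W)
    }
    if (length(pts_all)) {
      net_pts <- do.call(rbind, pts_all)
      net_mask <- matrix(FALSE, H, W)
      net_mask[cbind(round(net_pts[, 1]), round(net_pts[, 2]))] <- TRUE
      net_mask <- box_dilate(net_mask, 1L)
      mito <- mito + net_mask
    }
  })

  # stages 3-5: free-standing objects (ectopic puncta, nuclear dots,
  # donuts), mutually exclusive placements
  placed <- data.frame(row = numeric(0), col = numeric(0), r = numeric(0))
  ect <- matrix(0, H, W)
  with_seed(mix_seed(spec$seed, 3L), {
    for (i in seq_len(spec$n_ectopic_puncta)) {
      area <- stats::runif(1, spec$ectopic_area_range_um2[1],
                           spec$ectopic_area_range_um2[2])
      r <- sqrt(area / pi) / s
      pos <- place_free_object(H, W, r, margin, nuclei, net_pts, placed)
      dd <- draw_disc(ect, pos[1], pos[2], r, 1.0)
      ect <- dd$img
      placed[nrow(placed) + 1L, ] <- c(pos, r)
      add_truth("ectopic_punctum", pos[1], pos[2], dd$n * s^2)
    }
  })
  dots_ds <- matrix(0, H, W); dots_h2b <- matrix(0, H, W)
  with_seed(mix_seed(spec$seed, 4L), {
    for (i in seq_len(spec$n_nuclear_dots)) {
      area <- stats::runif(1, 3, 10)
      r <- sqrt(area / pi) / s
      pos <- place_free_object(H, W, r, margin, nuclei, net_pts, placed)
      dd <- draw_disc(dots_ds, pos[1], pos[2], r, 1.0)
      dots_ds <- dd$img
      dots_h2b <- draw_disc(dots_h2b, pos[1], pos[2], r, 0.9)$img
      placed[nrow(placed) + 1L, ] <- c(pos, r)
      add_truth("nuclear_dot", pos[1], pos[2], dd$n * s^2)
    }
  })
  donut_ds <- matrix(0, H, W); donut_h2b <- matrix(0, H, W)
  with_seed(mix_seed(spec$seed, 5L), {
    for (i in seq_len(spec$n_donuts)) {
      r_out <- stats::runif(1, 6, 8)
      r_in <- 0.5 * r_out   # ring 3-4 px thick, lumen survives the PSF
      pos <- place_free_object(H, W, r_out, margin, nuclei, net_pts, placed)
      dd <- draw_disc(donut_ds, pos[1], pos[2], r_out, 1.5, r_in = r_in)
      donut_ds <- dd$img
      donut_h2b <- draw_disc(donut_h2b, pos[1], pos[2], r_out, 0.05)$img
      placed[nrow(placed) + 1L, ] <- c(pos, r_out)
      add_truth("donut", pos[1], pos[2], dd$n * s^2)
    }
  })

  h2b <- h2b_nuc + dots_h2b + donut_h2b
  hsp60 <- mito
  dsdna <- spec$bleed_y_true * h2b_nuc + spec$bleed_x_true * mito +
    ect + dots_ds + donut_ds

  bl <- blur_channels(list(dsdna, h2b, hsp60), psf)
  dsdna <- bl[[1]]; h2b <- bl[[2]]; hsp60 <- bl[[3]]

  # stage 6: noise (per-channel draws come from one seeded stream; the
  # additive/multiplicative models draw a full field per channel, so the
  # noise realisation does not depend on scene content)
  if (spec$noise_sigma > 0) with_seed(mix_seed(spec$seed, 6L), {
    noisy <- function(m) {
      switch(spec$noise_model,
        gaussian = m + matrix(stats::rnorm(H * W, 0, spec$noise_sigma),
                              H, W),
        uniform = m * (1 + matrix(stats::runif(H * W, -spec$noise_sigma,
                                               spec$noise_sigma), H, W)),
        poisson_gaussian = {
          photons <- 1 / spec$noise_sigma^2
          matrix(stats::rpois(H * W, pmax(m, 0) * photons) / photons, H, W) +
            matrix(stats::rnorm(H * W, 0, 0.2 * spec$noise_sigma), H, W)
        })
    }
    dsdna <- noisy(dsdna); h2b <- noisy(h2b); hsp60 <- noisy(hsp60)
  })

  truth_df <- if (length(truth)) do.call(rbind, truth) else
    data.frame(object_id = integer(0), type = character(0),
               centroid_row = numeric(0), centroid_col = numeric(0),
               area_um2 = numeric(0), stringsAsFactors = FALSE)
  attr(truth_df, "true_factors") <- c(x = spec$bleed_x_true,
                                      y = spec$bleed_y_true)
  stack <- channel_stack(pmax(dsdna, 0), pmax(h2b, 0), pmax(hsp60, 0),
                         pixel_size_um = s,
                         image_id = sprintf("scene_seed%d", spec$seed))
  list(stack = stack, truth = truth_df, spec = spec)
}

#' Score a detection result against ground truth
#'
#' Greedily matches detected ectopic puncta to ground-truth ectopic
#' puncta by centroid distance and reports sensitivity and false calls.
#'
#' @param result a [detect()] result.
#' @param truth the ground-truth table from [render_scene()].
#' @param max_dist_um maximum centroid distance for a match.
#' @param pixel_size_um pixel size used to convert the distance.
#' @return List with `n_true`, `n_detected`, `n_matched`, `sensitivity`
#'   (`NA` when no true puncta) and `false_positives`.
#' @export
score_detection <- function(result, truth, max_dist_um = 2,
                            pixel_size_um = 0.31) {
  tr <- truth[truth$type == "ectopic_punctum", , drop = FALSE]
  det <- result$puncta[result$puncta$classification == "ectopic_mito", ,
                       drop = FALSE]
  max_px <- max_dist_um / pixel_size_um
  n_true <- nrow(tr); n_det <- nrow(det)
  matched <- 0L
  if (n_true > 0 && n_det > 0) {
    d <- outer(det$centroid_row, tr$centroid_row, `-`)^2 +
      outer(det$centroid_col, tr$centroid_col, `-`)^2
    d <- sqrt(d)
    while (TRUE) {
      m <- which(d == min(d), arr.ind = TRUE)[1, , drop = FALSE]
      if (d[m] > max_px) break
      matched <- matched + 1L
      d[m[1], ] <- Inf; d[, m[2]] <- Inf
      if (all(!is.finite(d))) break
    }
  }
  list(n_true = n_true, n_detected = n_det, n_matched = matched,
       sensitivity = if (n_true > 0) matched / n_true else NA_real_,
       false_positives = n_det - matched)
}
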