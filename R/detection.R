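#' Puncta detection parameters
#'
#' Filter and classification settings for dsDNA puncta. Defaults are the
#' HeLa values: area 2--20 um^2 inclusive, circularity 0.1--1.0
#' (`4 * pi * area / perimeter^2`, capped at 1), ring ("donut") exclusion
#' by Euler number, and a cap on the fraction of punctum pixels overlapping
#' the histone-H2B-positive mask. The size range can be adapted to other
#' cell types.
#'
#' @param min_area_um2,max_area_um2 inclusive area bounds in um^2.
#' @param min_circularity,max_circularity circularity bounds; the upper
#'   bound is capped at 1.
#' @param threshold_method `"otsu"` (on the nonzero pixels of the
#'   subtracted image) or `"fixed"`.
#' @param fixed_threshold threshold value when `threshold_method="fixed"`.
#' @param connectivity pixel connectivity for components, 4 or 8
#'   (default 8, the common particle-analysis convention).
#' @param histone_overlap_max_fraction puncta whose histone-positive pixel
#'   fraction exceeds this are classified as nuclear-origin, not ectopic.
#' @param exclude_donuts classify components containing holes
#'   (Euler number < 1) as nuclear-origin rings.
#' @param min_hole_area_px smallest background region (px) that counts as
#'   a hole for the Euler number; isolated sub-threshold pixels inside an
#'   otherwise solid punctum are noise dropouts, not a ring lumen.
#' @return An object of class `detection_params`.
#' @export
detection_params <- function(min_area_um2 = 2, max_area_um2 = 20,
                             min_circularity = 0.1, max_circularity = 1.0,
                             threshold_method = c("otsu", "fixed"),
                             fixed_threshold = NULL,
                             connectivity = 8L,
                             histone_overlap_max_fraction = 0.3,
                             exclude_donuts = TRUE,
                             min_hole_area_px = 4L) {
  threshold_method <- match.arg(threshold_method)
  if (!(min_area_um2 > 0 && min_area_um2 < max_area_um2))
    stop("need 0 < min_area_um2 < max_area_um2", call. = FALSE)
  max_circularity <- min(max_circularity, 1.0)
  if (!(min_circularity >= 0 && min_circularity <= max_circularity))
    stop("need 0 <= min_circularity <= max_circularity <= 1", call. = FALSE)
  if (!connectivity %in% c(4L, 8L))
    stop("connectivity must be 4 or 8", call. = FALSE)
  if (threshold_method == "fixed" &&
      (!is.numeric(fixed_threshold) || length(fixed_threshold) != 1L))
    stop("fixed_threshold required for threshold_method='fixed'",
         call. = FALSE)
  if (histone_overlap_max_fraction < 0 || histone_overlap_max_fraction > 1)
    stop("histone_overlap_max_fraction must be in [0, 1]", call. = FALSE)
  structure(list(min_area_um2 = min_area_um2, max_area_um2 = max_area_um2,
                 min_circularity = min_circularity,
                 max_circularity = max_circularity,
                 threshold_method = threshold_method,
                 fixed_threshold = fixed_threshold,
                 connectivity = as.integer(connectivity),
                 histone_overlap_max_fraction = histone_overlap_max_fraction,
                 exclude_donuts = isTRUE(exclude_donuts),
                 min_hole_area_px = as.integer(min_hole_area_px)),
            class = "detection_params")
}

#' Binarize a subtracted image
#'
#' Threshold chosen by Otsu's method on the nonzero pixels (the clipped
#' zeros would otherwise swamp the background class) or supplied as a
#' fixed value; the mask is TRUE where `value >= threshold`. An all-zero
#' image yields an all-FALSE mask with a warning, not an error.
#'
#' @param image a `subtracted_image` or non-negative numeric matrix.
#' @param params a [detection_params()] object.
#' @return Logical matrix with the chosen threshold in
#'   `attr(, "threshold")`.
#' @export
binarize <- function(image, params = detection_params()) {
  v <- if (inherits(image, "subtracted_image")) image$values else image
  if (!is.matrix(v)) stop("image must be a matrix or subtracted_image",
                          call. = FALSE)
  if (any(v < 0)) stop("binarize expects a non-negative image",
                       call. = FALSE)
  if (params$threshold_method == "fixed") {
    th <- params$fixed_threshold
  } else {
    th <- otsu_threshold(v, ignore_zero = TRUE)
    if (is.na(th)) {
      warning("all-zero image: returning empty mask")
      mask <- matrix(FALSE, nrow(v), ncol(v))
      attr(mask, "threshold") <- NA_real_
      return(mask)
    }
  }
  mask <- v >= th
  attr(mask, "threshold") <- th
  mask
}

#' Measure and classify puncta in a binary mask
#'
#' Finds connected components, measures each (area in um^2, perimeter by
#' the weighted boundary-configuration estimator, circularity
#' `min(1, 4 * pi * area / perimeter^2)`, Euler number, centroid,
#' histone-overlap fraction) and classifies it by the first failing rule
#' in the fixed order size, shape, donut, histone overlap; a component
#' passing all rules is `ectopic_mito`. The histone-overlap fraction is
#' the fraction of component pixels where the y-scaled H2B signal exceeds
#' its Otsu threshold.
#'
#' @param mask logical matrix (from [binarize()]).
#' @param h2b the histone-H2B channel, same shape as `mask`.
#' @param factors a [calibration_factors()] object (supplies y).
#' @param pixel_size_um physical pixel size, um/px.
#' @param params a [detection_params()] object.
#' @return A data.frame, one row per component: `label`, `area_um2`,
#'   `perimeter_um`, `circularity`, `euler_number`, `centroid_row`,
#'   `centroid_col` (pixels), `histone_overlap_fraction`,
#'   `classification` (one of `ectopic_mito`, `nuclear_origin_donut`,
#'   `nuclear_origin_overlap`, `rejected_size`, `rejected_shape`).
#' @export
find_puncta <- function(mask, h2b, factors, pixel_size_um,
                        params = detection_params()) {
  if (!identical(dim(mask), dim(h2b)))
    stop("mask and h2b shape mismatch", call. = FALSE)
  lab <- label_components(mask, params$connectivity)
  n <- max(lab)
  empty <- data.frame(label = integer(0), area_um2 = numeric(0),
                      perimeter_um = numeric(0), circularity = numeric(0),
                      euler_number = integer(0), centroid_row = numeric(0),
                      centroid_col = numeric(0),
                      histone_overlap_fraction = numeric(0),
                      classification = character(0),
                      stringsAsFactors = FALSE)
  if (n == 0L) return(empty)

  nuc_sig <- factors$y * h2b
  th_n <- otsu_threshold(nuc_sig)
  nuc_mask <- if (is.na(th_n) || max(nuc_sig) == 0) {
    matrix(FALSE, nrow(h2b), ncol(h2b))
  } else nuc_sig > th_n

  px2 <- pixel_size_um^2
  nr <- nrow(lab)
  idx <- which(lab > 0L)
  labv <- lab[idx]
  rr <- (idx - 1L) %% nr + 1L
  cc <- (idx - 1L) %/% nr + 1L
  area_px <- tabulate(labv, n)
  crow <- rowsum(rr, labv)[, 1] / area_px
  ccol <- rowsum(cc, labv)[, 1] / area_px
  ovl <- rowsum(as.numeric(nuc_mask[idx]), labv)[, 1] / area_px

  if (params$connectivity == 8L) {
    # 8-connected components are never 8-adjacent to one another, so the
    # boundary-configuration weights and the hole search can be computed
    # on the whole image at once
    m <- lab > 0L
    er <- m & shift_mat(m, 1L, 0L, FALSE) & shift_mat(m, -1L, 0L, FALSE) &
      shift_mat(m, 0L, 1L, FALSE) & shift_mat(m, 0L, -1L, FALSE)
    b <- (m & !er) + 0L
    n4 <- shift_mat(b, 1L, 0L) + shift_mat(b, -1L, 0L) +
      shift_mat(b, 0L, 1L) + shift_mat(b, 0L, -1L)
    n8 <- shift_mat(b, 1L, 1L) + shift_mat(b, 1L, -1L) +
      shift_mat(b, -1L, 1L) + shift_mat(b, -1L, -1L)
    w <- numeric(50)                 # w[code + 1] = weight of that code
    w[c(5, 7, 15, 17, 25, 27) + 1L] <- 1
    w[c(21, 33) + 1L] <- sqrt(2)
    w[c(13, 23) + 1L] <- (1 + sqrt(2)) / 2
    pw <- matrix(0, nr, ncol(lab))
    sel <- b == 1L
    pw[sel] <- w[2L + 2L * n4[sel] + 10L * n8[sel]]
    perim <- rowsum(pw[idx], labv)[, 1]

    # holes: a component can only contain one if its bounding box holds
    # enough background pixels, which spares the hole search for the
    # numerous tiny noise specks
    euler <- rep(1L, n)
    idx_by_lab <- split(idx, labv)
    for (i in seq_len(n)) {
      ii <- idx_by_lab[[i]]
      ri <- (ii - 1L) %% nr + 1L
      ci <- (ii - 1L) %/% nr + 1L
      r0 <- min(ri); c0 <- min(ci)
      h_i <- max(ri) - r0 + 1L; w_i <- max(ci) - c0 + 1L
      if (h_i * w_i - length(ii) < params$min_hole_area_px) next
      sub <- matrix(FALSE, h_i, w_i)
      sub[cbind(ri - r0 + 1L, ci - c0 + 1L)] <- TRUE
      euler[i] <- 1L - count_holes(sub, 8L, params$min_hole_area_px)
    }
  } else {
    idx_by_lab <- split(idx, labv)
    perim <- numeric(n); euler <- integer(n)
    for (i in seq_len(n)) {
      ii <- idx_by_lab[[i]]
      ri <- (ii - 1L) %% nr + 1L
      ci <- (ii - 1L) %/% nr + 1L
      r0 <- min(ri); c0 <- min(ci)
      sub <- matrix(FALSE, max(ri) - r0 + 1L, max(ci) - c0 + 1L)
      sub[cbind(ri - r0 + 1L, ci - c0 + 1L)] <- TRUE
      perim[i] <- config_perimeter(sub)
      euler[i] <- 1L - count_holes(sub, 4L, params$min_hole_area_px)
    }
  }

  circ <- ifelse(perim > 0, pmin(1, 4 * pi * area_px / perim^2), 1)
  area <- area_px * px2
  cls <- rep("ectopic_mito", n)
  cls[ovl > params$histone_overlap_max_fraction] <- "nuclear_origin_overlap"
  if (params$exclude_donuts) cls[euler < 1L] <- "nuclear_origin_donut"
  cls[circ < params$min_circularity |
        circ > params$max_circularity] <- "rejected_shape"
  cls[area < params$min_area_um2 | area > params$max_area_um2] <-
    "rejected_size"

  out <- data.frame(label = seq_len(n), area_um2 = area,
                    perimeter_um = perim * pixel_size_um,
                    circularity = circ, euler_number = euler,
                    centroid_row = crow, centroid_col = ccol,
                    histone_overlap_fraction = ovl, classification = cls,
                    stringsAsFactors = FALSE)
  attr(out, "labels") <- lab
  out
}

#' Full per-image detection pipeline
#'
#' Composes subtraction, optional shared contrast, binarization, punctum
#' measurement/classification and nucleus counting into the per-field
#' summary: the number of ectopic mitochondrial-DNA puncta and the
#' dots-per-cell ratio. With `variant = "subtract1"` the H2B channel is
#' not subtracted, and the histone-overlap rule is the discriminator for
#' nuclear-origin dots; with `"subtract2"` it acts as a safeguard.
#'
#' @param stack a [channel_stack()].
#' @param factors a [calibration_factors()] object.
#' @param params a [detection_params()] object.
#' @param nucleus_params a [nucleus_params()] object.
#' @param variant `"subtract2"` or `"subtract1"`.
#' @param contrast optional shared contrast window (length-2 numeric)
#'   applied between subtraction and thresholding.
#' @param keep_masks keep the punctum and nucleus label matrices in the
#'   result (off by default to keep batch runs light).
#' @return An object of class `detection_result`: `image_id`, `puncta`
#'   (the [find_puncta()] table), `n_ectopic`, `n_cells`, `dots_per_cell`
#'   (`NA` when no cells), `threshold`, `params`, `factors`, `variant`.
#' @examples
#' sc <- render_scene(scene_preset("tfam_kd", seed = 3))
#' f <- calibrate(render_scene(scene_preset("control", seed = 3))$stack)
#' detect(sc$stack, f)
#' @export
detect <- function(stack, factors, params = detection_params(),
                   nucleus_params = ectopuncta::nucleus_params(),
                   variant = c("subtract2", "subtract1"),
                   contrast = NULL, keep_masks = FALSE) {
  variant <- match.arg(variant)
  sub <- subtract(stack, factors, variant)
  if (!is.null(contrast)) sub <- apply_contrast(sub, contrast)
  mask <- binarize(sub, params)
  puncta <- find_puncta(mask, stack$h2b, factors, stack$pixel_size_um,
                        params)
  cells <- count_cells(stack$h2b, stack$pixel_size_um, nucleus_params)
  n_ect <- sum(puncta$classification == "ectopic_mito")
  res <- list(image_id = stack$image_id, puncta = puncta,
              n_ectopic = n_ect, n_cells = cells$n_cells,
              dots_per_cell = dots_per_cell(n_ect, cells$n_cells),
              threshold = attr(mask, "threshold"),
              params = params, factors = factors, variant = variant)
  if (keep_masks) {
    res$puncta_labels <- attr(puncta, "labels")
    res$nucleus_labels <- cells$labels
  }
  attr(res$puncta, "labels") <- NULL
  structure(res, class = "detection_result")
}

#' @export
print.detection_result <- function(x, ...) {
  cat("<detection_result> ", x$image_id, " (", x$variant, ")\n", sep = "")
  tab <- table(x$puncta$classification)
  cat(sprintf("  %d component(s): %s\n", nrow(x$puncta),
              if (nrow(x$puncta)) paste(names(tab), tab, sep = "=",
                                        collapse = ", ") else "none"))
  cat(sprintf("  ectopic puncta %d, cells %d, dots per cell %s\n",
              x$n_ectopic, x$n_cells,
              if (is.na(x$dots_per_cell)) "NA (no cells)" else
                sprintf("%.3g", x$dots_per_cell)))
  invisible(x)
}

#' @export
summary.detection_result <- function(object, ...) {
  cbind(data.frame(image_id = object$image_id), object$puncta)
}
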