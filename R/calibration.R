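#' Calibration factors for channel subtraction
#'
#' Holds the multipliers applied to the Hsp60 channel (`x`) and the
#' histone-H2B channel (`y`) before subtraction from the dsDNA channel,
#' together with the settings that produced them. The defining property,
#' estimated from control images, is that the subtraction drives the
#' corresponding DNA signal to (at most) zero in controls: at
#' `quantile = 1` this is the literal "residual <= 0 at every masked
#' control pixel" rule; the default 0.999 tolerates isolated hot pixels.
#'
#' @param x non-negative scalar, Hsp60 multiplier.
#' @param y non-negative scalar, histone-H2B multiplier.
#' @param quantile scalar in (0, 1], the ratio quantile used to estimate
#'   both factors.
#' @param mask_method `"otsu"` or `"fixed"`: how the marker masks were
#'   thresholded.
#' @param n_control_images number of control images pooled.
#' @param boundary_erode_px box half-width (px) by which marker masks were
#'   eroded (and the nuclear exclusion dilated) before pooling ratios, to
#'   keep PSF-mixed boundary pixels out of the estimate.
#' @return An object of class `calibration_factors`.
#' @seealso [calibrate()], [estimate_x()], [estimate_y()], [subtract()]
#' @export
calibration_factors <- function(x, y, quantile = 1,
                                mask_method = c("otsu", "fixed"),
                                n_control_images = 1L,
                                boundary_erode_px = 1L) {
  mask_method <- match.arg(mask_method)
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0)
    stop("x must be a non-negative scalar", call. = FALSE)
  if (!is.numeric(y) || length(y) != 1L || !is.finite(y) || y < 0)
    stop("y must be a non-negative scalar", call. = FALSE)
  if (!is.numeric(quantile) || length(quantile) != 1L ||
      quantile <= 0 || quantile > 1)
    stop("quantile must be in (0, 1]", call. = FALSE)
  structure(list(x = as.numeric(x), y = as.numeric(y),
                 quantile = as.numeric(quantile), mask_method = mask_method,
                 n_control_images = as.integer(n_control_images),
                 boundary_erode_px = as.integer(boundary_erode_px)),
            class = "calibration_factors")
}

#' @export
print.calibration_factors <- function(x, ...) {
  cat("<calibration_factors>\n")
  cat(sprintf("  x (Hsp60 multiplier): %.6g\n", x$x))
  cat(sprintf("  y (H2B multiplier):   %.6g\n", x$y))
  cat(sprintf("  ratio quantile %.4g, %s masks, %d control image(s)\n",
              x$quantile, x$mask_method, x$n_control_images))
  invisible(x)
}

as_stack_list <- function(controls) {
  if (inherits(controls, "channel_stack")) controls <- list(controls)
  if (!is.list(controls) || length(controls) == 0L ||
      !all(vapply(controls, inherits, logical(1), "channel_stack")))
    stop("controls must be a non-empty list of channel_stack objects",
         call. = FALSE)
  controls
}

# Marker masks used for calibration on one stack. The mitochondrial mask
# is Hsp60 above its threshold, eroded, minus a dilated nuclear mask; the
# nuclear mask is H2B above its threshold, eroded. Erosion/dilation keep
# pixels whose intensities mix neighbouring structures through the PSF out
# of the pixelwise ratios.
calibration_masks <- function(stack, mask_method = "otsu",
                              boundary_erode_px = 1L,
                              hsp60_threshold = NULL, h2b_threshold = NULL) {
  th_h <- if (identical(mask_method, "fixed")) hsp60_threshold else
    otsu_threshold(stack$hsp60)
  th_n <- if (identical(mask_method, "fixed")) h2b_threshold else
    otsu_threshold(stack$h2b)
  mito <- if (is.null(th_h) || is.na(th_h)) {
    matrix(FALSE, nrow(stack$hsp60), ncol(stack$hsp60))
  } else stack$hsp60 > th_h
  nuc <- if (is.null(th_n) || is.na(th_n)) {
    matrix(FALSE, nrow(stack$h2b), ncol(stack$h2b))
  } else stack$h2b > th_n
  k <- boundary_erode_px
  list(mito = box_erode(mito, k) & !box_dilate(nuc, k),
       nuc = box_erode(nuc, k),
       hsp60_threshold = th_h, h2b_threshold = th_n)
}

pooled_ratio <- function(controls, which = c("x", "y"), mask_method,
                         boundary_erode_px, ...) {
  which <- match.arg(which)
  ratios <- numeric(0)
  for (s in controls) {
    m <- calibration_masks(s, mask_method, boundary_erode_px, ...)
    if (which == "x") {
      sel <- m$mito
      ratios <- c(ratios, s$dsdna[sel] / s$hsp60[sel])
    } else {
      sel <- m$nuc
      ratios <- c(ratios, s$dsdna[sel] / s$h2b[sel])
    }
  }
  ratios
}

#' Estimate the Hsp60 multiplier x from control images
#'
#' Over all pixels of all control images inside the mitochondrial mask
#' (Hsp60 above threshold) and outside the nuclear mask (H2B above
#' threshold), returns the given quantile of the pixelwise ratio
#' dsDNA / Hsp60. With `quantile = 1` the residual
#' `dsDNA - x * Hsp60` is then <= 0 at every masked control pixel -- the
#' rule that defines x. Pixels whose Hsp60 is below its threshold are
#' excluded, never divided by.
#'
#' @param controls a `channel_stack` or list of them (control condition).
#' @param quantile scalar in (0, 1]; 1 gives the literal rule, the default
#'   0.999 is robust to isolated hot pixels.
#' @param mask_method `"otsu"` (default) or `"fixed"` (supply
#'   `hsp60_threshold` / `h2b_threshold`).
#' @param boundary_erode_px erosion half-width for the masks, see
#'   [calibration_factors()].
#' @param ... fixed thresholds when `mask_method = "fixed"`.
#' @return Non-negative scalar x.
#' @export
estimate_x <- function(controls, quantile = 0.999,
                       mask_method = c("otsu", "fixed"),
                       boundary_erode_px = 1L, ...) {
  mask_method <- match.arg(mask_method)
  controls <- as_stack_list(controls)
  if (quantile <= 0 || quantile > 1)
    stop("quantile must be in (0, 1]", call. = FALSE)
  r <- pooled_ratio(controls, "x", mask_method, boundary_erode_px, ...)
  if (length(r) == 0L)
    stop("empty mitochondrial mask: no Hsp60 signal above threshold",
         call. = FALSE)
  stats::quantile(r, quantile, names = FALSE, type = 1)
}

#' Estimate the histone-H2B multiplier y from control images
#'
#' As [estimate_x()], with the ratio dsDNA / H2B evaluated inside the
#' nuclear (H2B above threshold) mask; with `quantile = 1` the residual
#' `dsDNA - y * H2B` is <= 0 at every masked control pixel.
#'
#' @inheritParams estimate_x
#' @return Non-negative scalar y.
#' @export
estimate_y <- function(controls, quantile = 0.999,
                       mask_method = c("otsu", "fixed"),
                       boundary_erode_px = 1L, ...) {
  mask_method <- match.arg(mask_method)
  controls <- as_stack_list(controls)
  if (quantile <= 0 || quantile > 1)
    stop("quantile must be in (0, 1]", call. = FALSE)
  r <- pooled_ratio(controls, "y", mask_method, boundary_erode_px, ...)
  if (length(r) == 0L)
    stop("empty nuclear mask: no H2B signal above threshold", call. = FALSE)
  stats::quantile(r, quantile, names = FALSE, type = 1)
}

#' Estimate both calibration factors from a pooled control batch
#'
#' One (x, y) pair per experiment batch: all control images are pooled and
#' the resulting factors are applied unchanged to every condition of the
#' batch, so that all samples are treated identically.
#'
#' @inheritParams estimate_x
#' @return A [calibration_factors()] object.
#' @examples
#' sc <- render_scene(scene_preset("control", seed = 1))
#' calibrate(list(sc$stack), quantile = 0.999)
#' @export
calibrate <- function(controls, quantile = 0.999,
                      mask_method = c("otsu", "fixed"),
                      boundary_erode_px = 1L, ...) {
  mask_method <- match.arg(mask_method)
  controls <- as_stack_list(controls)
  calibration_factors(
    x = estimate_x(controls, quantile, mask_method, boundary_erode_px, ...),
    y = estimate_y(controls, quantile, mask_method, boundary_erode_px, ...),
    quantile = quantile, mask_method = mask_method,
    n_control_images = length(controls),
    boundary_erode_px = boundary_erode_px)
}

#' Verify calibration factors on control images
#'
#' Reports, per image, the fraction of masked pixels whose residual after
#' the calibrated subtraction is still positive: `dsDNA - x * Hsp60` on
#' the mitochondrial mask and `dsDNA - y * H2B` on the nuclear mask. For
#' factors estimated at `quantile = 1` on the same images both fractions
#' are 0 -- the property that defines the factors. Positivity is judged
#' against a small relative tolerance so that floating-point round-off in
#' an exact cancellation does not count as residual signal.
#'
#' @param controls a `channel_stack` or list of them.
#' @param factors a [calibration_factors()] object.
#' @param tol relative tolerance (fraction of the image's dsDNA maximum)
#'   above which a residual counts as positive.
#' @param ... fixed thresholds when the factors used `mask_method="fixed"`.
#' @return A data.frame with columns `image_id`, `frac_pos_mito`,
#'   `frac_pos_nuclear`.
#' @export
verify_factors <- function(controls, factors, tol = 1e-9, ...) {
  controls <- as_stack_list(controls)
  if (!inherits(factors, "calibration_factors"))
    stop("factors must be a calibration_factors object", call. = FALSE)
  rows <- lapply(controls, function(s) {
    m <- calibration_masks(s, factors$mask_method, factors$boundary_erode_px,
                           ...)
    eps <- tol * max(s$dsdna, 1)
    fm <- if (any(m$mito)) {
      mean((s$dsdna - factors$x * s$hsp60)[m$mito] > eps)
    } else NA_real_
    fn <- if (any(m$nuc)) {
      mean((s$dsdna - factors$y * s$h2b)[m$nuc] > eps)
    } else NA_real_
    data.frame(image_id = s$image_id, frac_pos_mito = fm,
               frac_pos_nuclear = fn, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
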