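#' Calibrated channel subtraction
#'
#' Produces the analysis image from which puncta are called:
#' `subtract1` removes the scaled mitochondrial signal,
#' `dsDNA - x * Hsp60`; `subtract2` additionally removes the scaled
#' nuclear signal, `dsDNA - x * Hsp60 - y * H2B`. Negative results are
#' clipped to 0 (downstream thresholding assumes non-negative input, and
#' display-image subtraction saturates at zero); no other transformation
#' is applied at this stage.
#'
#' @param stack a [channel_stack()].
#' @param factors a [calibration_factors()] object.
#' @param variant `"subtract2"` (default, both markers removed) or
#'   `"subtract1"` (Hsp60 only; nuclear-origin structures are then
#'   discriminated by histone overlap during detection).
#' @return An object of class `subtracted_image` with fields `values`
#'   (non-negative matrix), `variant`, `factors`, `contrast_window`
#'   (`NULL` until [apply_contrast()]), `image_id`, `pixel_size_um`.
#' @examples
#' s <- channel_stack(matrix(200, 2, 2), matrix(30, 2, 2), matrix(50, 2, 2),
#'                    pixel_size_um = 0.31)
#' f <- calibration_factors(x = 2, y = 1)
#' subtract(s, f, "subtract2")$values[1, 1]   # 200 - 100 - 30 = 70
#' @export
subtract <- function(stack, factors, variant = c("subtract2", "subtract1")) {
  variant <- match.arg(variant)
  if (!inherits(stack, "channel_stack"))
    stop("stack must be a channel_stack", call. = FALSE)
  if (!inherits(factors, "calibration_factors"))
    stop("factors must be a calibration_factors object", call. = FALSE)
  d <- dim(stack$dsdna)
  if (!identical(dim(stack$hsp60), d) || !identical(dim(stack$h2b), d))
    stop("channel shape mismatch", call. = FALSE)   # defensive re-check
  v <- stack$dsdna - factors$x * stack$hsp60
  if (variant == "subtract2") v <- v - factors$y * stack$h2b
  structure(list(values = pmax(v, 0), variant = variant, factors = factors,
                 contrast_window = NULL, image_id = stack$image_id,
                 pixel_size_um = stack$pixel_size_um),
            class = "subtracted_image")
}

#' @export
print.subtracted_image <- function(x, ...) {
  cat("<subtracted_image> ", x$image_id, " (", x$variant, ")\n", sep = "")
  cat(sprintf("  %d x %d px, max %.4g", nrow(x$values), ncol(x$values),
              max(x$values)))
  if (!is.null(x$contrast_window))
    cat(sprintf(", contrast window [%.4g, %.4g]",
                x$contrast_window[1], x$contrast_window[2]))
  cat("\n")
  invisible(x)
}

#' Batch-consistent linear contrast window
#'
#' Linearly rescales a subtracted image from `[low, high]` to `[0, 1]`,
#' clipping outside. The same window must be used for every image of a
#' batch so that all samples are compared under identical display/analysis
#' conditions; [contrast_window()] derives such a shared window from the
#' batch.
#'
#' @param image a `subtracted_image`.
#' @param window numeric length-2, `c(low, high)` with `low < high`, in
#'   the intensity units of the subtracted image.
#' @return The rescaled `subtracted_image`, window recorded in
#'   `contrast_window`.
#' @export
apply_contrast <- function(image, window) {
  if (!inherits(image, "subtracted_image"))
    stop("image must be a subtracted_image", call. = FALSE)
  if (!is.numeric(window) || length(window) != 2L ||
      !all(is.finite(window)) || window[1] >= window[2])
    stop("degenerate contrast window: need low < high", call. = FALSE)
  v <- (image$values - window[1]) / (window[2] - window[1])
  image$values <- pmin(pmax(v, 0), 1)
  image$contrast_window <- as.numeric(window)
  image
}

#' Shared contrast window for a batch of subtracted images
#'
#' Default window `(0, q)` where `q` is the `upper_quantile` quantile of
#' the pooled subtracted values of the batch (typically the controls).
#'
#' @param images a `subtracted_image` or list of them.
#' @param upper_quantile quantile defining the upper bound, default 0.999.
#' @return Numeric length-2 window.
#' @export
contrast_window <- function(images, upper_quantile = 0.999) {
  if (inherits(images, "subtracted_image")) images <- list(images)
  if (!is.list(images) || length(images) == 0L ||
      !all(vapply(images, inherits, logical(1), "subtracted_image")))
    stop("images must be subtracted_image objects", call. = FALSE)
  v <- unlist(lapply(images, `[[`, "values"), use.names = FALSE)
  hi <- stats::quantile(v, upper_quantile, names = FALSE)
  if (hi <= 0) hi <- max(v, .Machine$double.eps)
  c(0, hi)
}
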