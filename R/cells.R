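#' Nucleus segmentation parameters
#'
#' Settings for counting cells from the histone-H2B (nuclear) channel.
#' The area floor must exceed the puncta detector's upper area bound so
#' that nuclei and puncta are never confusable.
#'
#' @param min_nucleus_area_um2 components below this are discarded
#'   (default 40 um^2, well above the 20 um^2 punctum ceiling).
#' @param threshold_method `"otsu"` or `"fixed"`.
#' @param fixed_threshold threshold when `threshold_method = "fixed"`.
#' @param split_touching split touching nuclei by distance-transform
#'   watershed (default TRUE).
#' @param connectivity 4 or 8.
#' @param watershed_tolerance minimum distance-map depth (px) separating
#'   two nuclei before they are split; small values over-segment single
#'   elongated nuclei.
#' @return An object of class `nucleus_params`.
#' @export
nucleus_params <- function(min_nucleus_area_um2 = 40,
                           threshold_method = c("otsu", "fixed"),
                           fixed_threshold = NULL,
                           split_touching = TRUE,
                           connectivity = 8L,
                           watershed_tolerance = 2) {
  threshold_method <- match.arg(threshold_method)
  if (min_nucleus_area_um2 <= 20)
    stop("min_nucleus_area_um2 must exceed the punctum area ceiling (20)",
         call. = FALSE)
  structure(list(min_nucleus_area_um2 = min_nucleus_area_um2,
                 threshold_method = threshold_method,
                 fixed_threshold = fixed_threshold,
                 split_touching = isTRUE(split_touching),
                 connectivity = as.integer(connectivity),
                 watershed_tolerance = watershed_tolerance),
            class = "nucleus_params")
}

#' Count cells from the histone-H2B channel
#'
#' Nuclei proxy for cells: threshold H2B, fill holes, drop components
#' below the area floor, optionally split touching nuclei by watershed on
#' the distance transform. Border-touching nuclei are counted (the
#' per-field ratio uses whole-field counts). An empty field returns 0.
#'
#' @param h2b non-negative numeric matrix, the H2B channel.
#' @param pixel_size_um physical pixel size, um/px.
#' @param params a [nucleus_params()] object.
#' @return List with `n_cells` (non-negative integer) and `labels`
#'   (integer label matrix).
#' @export
count_cells <- function(h2b, pixel_size_um,
                        params = nucleus_params()) {
  if (!is.matrix(h2b) || any(h2b < 0))
    stop("h2b must be a non-negative matrix", call. = FALSE)
  zero <- list(n_cells = 0L, labels = matrix(0L, nrow(h2b), ncol(h2b)))
  th <- if (params$threshold_method == "fixed") params$fixed_threshold else
    otsu_threshold(h2b)
  if (is.na(th) || max(h2b) == 0 || max(h2b) <= th) return(zero)
  mask <- h2b > th
  if (!any(mask)) return(zero)
  mask <- matrix(as.integer(EBImage::fillHull(mask + 0L)) > 0,
                 nrow(mask), ncol(mask))
  min_px <- params$min_nucleus_area_um2 / pixel_size_um^2

  if (params$split_touching) {
    dm <- EBImage::distmap(mask + 0L)
    lab <- EBImage::watershed(dm, tolerance = params$watershed_tolerance,
                              ext = 1L)
    lab <- matrix(as.integer(lab), nrow(mask), ncol(mask))
  } else {
    lab <- label_components(mask, params$connectivity)
  }
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= min_px)
  if (length(keep) == 0L) return(zero)
  relab <- integer(length(sizes))
  relab[keep] <- seq_along(keep)
  out <- matrix(0L, nrow(mask), ncol(mask))
  pos <- lab > 0L
  out[pos] <- relab[lab[pos]]
  list(n_cells = length(keep), labels = out)
}

#' Ectopic dots per cell
#'
#' The field-level summary statistic: number of ectopic mitochondrial-DNA
#' puncta divided by the number of cells. Undefined (returned as `NA`,
#' excluded from group means) when the field contains no cells.
#'
#' @param n_ectopic non-negative integer count of ectopic puncta.
#' @param n_cells non-negative integer cell count.
#' @return Scalar ratio, or `NA_real_` when `n_cells` is 0.
#' @export
dots_per_cell <- function(n_ectopic, n_cells) {
  if (n_ectopic < 0 || n_cells < 0)
    stop("counts must be non-negative", call. = FALSE)
  if (n_cells == 0) return(NA_real_)
  n_ectopic / n_cells
}
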