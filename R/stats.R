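#' Summarize detection results by condition
#'
#' Aggregates per-image [detect()] results into per-condition summaries:
#' number of images, mean and standard error of the mean of the
#' dots-per-cell ratio. The per-image ratio is the statistical unit.
#' Images whose ratio is undefined (no cells) are excluded from the mean
#' and counted in an `exclusions` column.
#'
#' @param results list of `detection_result` objects, or a data.frame
#'   with columns `image_id`, `n_ectopic`, `n_cells`, `dots_per_cell`
#'   (e.g. a per-image table written by the command-line interface).
#' @param conditions either a named character vector mapping `image_id`
#'   to condition, or a data.frame with columns `image_id` and
#'   `condition`. Every image must be mapped.
#' @return An object of class `puncta_summary`: `summary` (one row per
#'   condition: `condition`, `n_images`, `exclusions`,
#'   `mean_dots_per_cell`, `sem_dots_per_cell`), `images` (tidy per-image
#'   table) and `values` (named list of per-image ratios by condition).
#' @export
summarize_results <- function(results, conditions) {
  if (inherits(results, "detection_result")) results <- list(results)
  if (is.data.frame(results)) {
    need <- c("image_id", "n_ectopic", "n_cells", "dots_per_cell")
    if (!all(need %in% names(results)))
      stop("results data.frame needs columns ",
           paste(need, collapse = ", "), call. = FALSE)
    img <- results[, need]
  } else {
    if (!all(vapply(results, inherits, logical(1), "detection_result")))
      stop("results must be detection_result objects", call. = FALSE)
    img <- do.call(rbind, lapply(results, function(r) {
      data.frame(image_id = r$image_id, n_ectopic = r$n_ectopic,
                 n_cells = r$n_cells, dots_per_cell = r$dots_per_cell,
                 stringsAsFactors = FALSE)
    }))
  }
  if (is.data.frame(conditions)) {
    cond_map <- stats::setNames(as.character(conditions$condition),
                                conditions$image_id)
  } else cond_map <- conditions
  unmapped <- setdiff(img$image_id, names(cond_map))
  if (length(unmapped))
    stop("unmapped image_id: ", paste(unmapped, collapse = ", "),
         call. = FALSE)
  img$condition <- unname(cond_map[img$image_id])

  values <- list()
  rows <- lapply(split(img, img$condition), function(g) {
    v <- g$dots_per_cell
    ok <- v[!is.na(v)]
    values[[g$condition[1]]] <<- ok
    data.frame(condition = g$condition[1], n_images = length(ok),
               exclusions = sum(is.na(v)),
               mean_dots_per_cell = if (length(ok)) mean(ok) else NA_real_,
               sem_dots_per_cell = if (length(ok) > 1)
                 stats::sd(ok) / sqrt(length(ok)) else NA_real_,
               stringsAsFactors = FALSE)
  })
  structure(list(summary = do.call(rbind, c(rows,
                                            list(make.row.names = FALSE))),
                 images = img[, c("image_id", "condition", "n_ectopic",
                                  "n_cells", "dots_per_cell")],
                 values = values),
            class = "puncta_summary")
}

#' @export
print.puncta_summary <- function(x, ...) {
  cat("<puncta_summary> (dots per cell, mean +/- SEM per condition)\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Bar plot of group means with SEM error bars
#'
#' @param x a `puncta_summary`.
#' @param ... passed to [graphics::barplot()].
#' @export
plot.puncta_summary <- function(x, ...) {
  s <- x$summary
  top <- max(c(s$mean_dots_per_cell,
               s$mean_dots_per_cell + 2 * s$sem_dots_per_cell, 0.1),
             na.rm = TRUE)
  mids <- graphics::barplot(s$mean_dots_per_cell, names.arg = s$condition,
                            ylab = "ectopic mtDNA dots per cell",
                            ylim = c(0, top), ...)
  ok <- !is.na(s$sem_dots_per_cell) & s$sem_dots_per_cell > 0
  if (any(ok))
    graphics::arrows(mids[ok], s$mean_dots_per_cell[ok] -
                       s$sem_dots_per_cell[ok],
                     mids[ok], s$mean_dots_per_cell[ok] +
                       s$sem_dots_per_cell[ok],
                     angle = 90, code = 3, length = 0.06)
  invisible(mids)
}

#' Two-group comparison of dots-per-cell ratios
#'
#' Classical two-sample Student's t-test with pooled variance (two-sided
#' p from the t distribution on `n_a + n_b - 2` degrees of freedom),
#' matching the arithmetic-means comparison used for the per-condition
#' ratios; Welch's unequal-variance form is available via `welch = TRUE`.
#' Groups whose pooled variance is zero are an error rather than `p = 0`.
#'
#' @param a,b numeric vectors of per-image ratios (length >= 2 each), or
#'   elements of a [summarize_results()] `values` list.
#' @param welch use Welch's t instead of the pooled-variance form.
#' @return List with `t`, `df`, `p_value`, `mean_a`, `mean_b`, `method`.
#' @examples
#' compare_groups(c(1, 1.2, 0.8), c(2, 2.2, 1.8))
#' @export
compare_groups <- function(a, b, welch = FALSE) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2 || length(b) < 2)
    stop("each group needs at least 2 defined ratios", call. = FALSE)
  if (anyNA(a) || anyNA(b)) stop("undefined ratios in input", call. = FALSE)
  ht <- tryCatch(
    stats::t.test(a, b, var.equal = !welch),
    error = function(e) {
      if (grepl("constant", conditionMessage(e)))
        stop("zero pooled variance: groups are constant, t undefined",
             call. = FALSE)
      stop(e)
    })
  structure(list(t = unname(ht$statistic), df = unname(ht$parameter),
                 p_value = ht$p.value, mean_a = mean(a), mean_b = mean(b),
                 method = if (welch) "welch" else "student"),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s t-test: t = %.4g, df = %.4g, p = %.4g\n",
              if (x$method == "student") "Student's (pooled)" else "Welch's",
              x$t, x$df, x$p_value))
  cat(sprintf("  group means: %.4g vs %.4g\n", x$mean_a, x$mean_b))
  invisible(x)
}
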