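#' Voxel-wise relative-error image against a reference reconstruction
#'
#' `RE = (I_x - I_GS) / I_GS` where the gold standard `I_GS` is the reference
#' reconstruction. Only voxels inside `mask` whose reference activity is at
#' least `act_floor_bqml` are evaluable; other voxels are excluded (returned
#' as `NA`), not zero-filled, so they cannot dilute the error statistics.
#'
#' @param img_x `image_volume` under evaluation.
#' @param img_gs Reference `image_volume`.
#' @param mask Logical array (typically the pelvic mask).
#' @param act_floor_bqml Activity threshold on the reference image (Bq/ml).
#' @return List: `re` (`image_volume(dimensionless)` with `NA` outside the
#'   evaluable set) and `evaluable_mask`.
#' @export
relative_error_image <- function(img_x, img_gs, mask, act_floor_bqml = 300) {
  stop_if_grid_mismatch(img_x, img_gs)
  if (!identical(dim(mask), dim(img_x$data))) stop("mask shape mismatch")
  evaluable <- mask & img_gs$data >= act_floor_bqml
  if (!any(evaluable)) stop("no evaluable voxels above the activity floor")
  re <- array(NA_real_, dim = dim(img_x$data))
  re[evaluable] <- (img_x$data[evaluable] - img_gs$data[evaluable]) /
    img_gs$data[evaluable]
  list(re = with_data(img_x, re, role = "dimensionless"),
       evaluable_mask = evaluable)
}

#' Voxel-based error metrics of a relative-error image
#'
#' Summarizes the relative-error field over the evaluable voxels:
#' `MAPE = 100 * mean(|RE|)` and `RMSPE = 100 * sqrt(mu^2 + sigma^2)` where
#' `mu`, `sigma` are the mean and (population) standard deviation of RE over
#' the mask — equivalently `RMSPE = 100 * sqrt(mean(RE^2))`, which the
#' population-variance convention makes exact.
#'
#' @param re_image Output of [relative_error_image()], or an
#'   `image_volume`/array of RE values.
#' @param evaluable_mask Logical array; defaults to the one recorded in
#'   `re_image`.
#' @return A list of class `metrics_result`: `mu_re`, `sigma_re`, `mape`,
#'   `rmspe` (percent) and `n_mask`.
#' @export
compute_metrics <- function(re_image, evaluable_mask = NULL) {
  if (is.list(re_image) && !is.null(re_image$re)) {
    if (is.null(evaluable_mask)) evaluable_mask <- re_image$evaluable_mask
    re_image <- re_image$re
  }
  arr <- if (inherits(re_image, "image_volume")) re_image$data else re_image
  vals <- if (is.null(evaluable_mask)) arr[!is.na(arr)] else arr[evaluable_mask]
  if (!length(vals) || any(is.na(vals))) stop("evaluable set empty or has NA")
  mu <- mean(vals)
  sigma <- sqrt(mean((vals - mu)^2))
  structure(list(mu_re = mu, sigma_re = sigma,
                 mape = 100 * mean(abs(vals)),
                 rmspe = 100 * sqrt(mu^2 + sigma^2),
                 n_mask = length(vals)),
            class = "metrics_result")
}

#' @export
print.metrics_result <- function(x, ...) {
  cat(sprintf("MAPE %.2f%%  RMSPE %.2f%%  (mu %.4f, sigma %.4f, n=%d)\n",
              x$mape, x$rmspe, x$mu_re, x$sigma_re, x$n_mask))
  invisible(x)
}

#' Lesion-level SUVmax errors across PET images
#'
#' For every lesion, takes the maximum standardized uptake value within its
#' ROI in each image and reports the relative and absolute percentage error
#' against the gold-standard image. SUV is a linear rescaling of activity by
#' body weight over injected dose; it cancels in relative errors, so the
#' constants only affect the reported SUV column. The ROI defines the region:
#' lesions straddling the pelvic-mask edge are still measured over their full
#' ROI.
#'
#' @param lesions List of lesions (as in a `phantom`).
#' @param pet_images Named list of `image_volume`s, including the reference.
#' @param gs_name Name of the gold-standard entry in `pet_images`.
#' @param weight_kg,dose_bq SUV scaling constants.
#' @return A data.frame with one row per lesion x compared image: `lesion_id`,
#'   `tissue_class`, `image`, `suvmax`, `suvmax_gs`, `rel_error`,
#'   `abs_pct_error`.
#' @export
lesion_metrics <- function(lesions, pet_images, gs_name = "pet_ctmr",
                           weight_kg = 85, dose_bq = 150e6) {
  if (!gs_name %in% names(pet_images))
    stop("gold standard image '", gs_name, "' not in pet_images")
  suv_scale <- (weight_kg * 1000) / dose_bq
  rows <- list()
  for (l in lesions) {
    if (!any(l$roi_mask)) {
      rows[[length(rows) + 1L]] <- data.frame(
        lesion_id = l$id, tissue_class = l$tissue_class,
        image = NA_character_, suvmax = NA_real_, suvmax_gs = NA_real_,
        rel_error = NA_real_, abs_pct_error = NA_real_)
      next
    }
    gs_max <- max(pet_images[[gs_name]]$data[l$roi_mask]) * suv_scale
    for (nm in setdiff(names(pet_images), gs_name)) {
      sm <- max(pet_images[[nm]]$data[l$roi_mask]) * suv_scale
      re <- if (gs_max > 0) (sm - gs_max) / gs_max else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        lesion_id = l$id, tissue_class = l$tissue_class, image = nm,
        suvmax = sm, suvmax_gs = gs_max, rel_error = re,
        abs_pct_error = 100 * abs(re))
    }
  }
  do.call(rbind, rows)
}

#' Paired nonparametric comparison of per-subject metrics
#'
#' Two-sided Wilcoxon signed-rank test between paired per-subject values
#' (e.g. RMSPE of two reconstruction methods over the same subjects). When
#' `b` is a named list, one test per entry is run and the p-values are
#' Benjamini-Hochberg adjusted across the family. Identical pairs (all-zero
#' differences) are reported as a degenerate case rather than an error.
#'
#' @param a Numeric vector of per-subject values.
#' @param b Numeric vector paired with `a`, or a named list of such vectors.
#' @param alpha Significance level (default 0.05).
#' @return A data.frame with columns `comparison`, `n`, `statistic`, `p`,
#'   `p_adj`, `significant`, `degenerate`.
#' @export
paired_compare <- function(a, b, alpha = 0.05) {
  bs <- if (is.list(b)) b else list(b = b)
  res <- lapply(names(bs), function(nm) {
    bb <- bs[[nm]]
    if (length(a) != length(bb)) stop("paired samples differ in length")
    if (length(a) < 5) stop("need at least 5 pairs")
    d <- a - bb
    if (all(d == 0))
      return(data.frame(comparison = nm, n = length(a), statistic = NA_real_,
                        p = 1, degenerate = TRUE))
    wt <- suppressWarnings(stats::wilcox.test(a, bb, paired = TRUE,
                                              alternative = "two.sided"))
    data.frame(comparison = nm, n = length(a),
               statistic = unname(wt$statistic), p = wt$p.value,
               degenerate = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out$significant <- out$p_adj < alpha
  out[, c("comparison", "n", "statistic", "p", "p_adj", "significant",
          "degenerate")]
}

#' Unpaired nonparametric comparison of two groups
#'
#' Two-sided Mann-Whitney U test (e.g. RMSPE between two tracer groups).
#' Inputs consisting of a single repeated value in both groups are reported
#' as degenerate.
#'
#' @param group_a,group_b Numeric vectors.
#' @param alpha Significance level.
#' @return A one-row data.frame: `n_a`, `n_b`, `statistic` (U), `p`,
#'   `significant`, `degenerate`.
#' @export
unpaired_compare <- function(group_a, group_b, alpha = 0.05) {
  if (!length(group_a) || !length(group_b)) stop("both groups must be non-empty")
  degenerate <- length(unique(c(group_a, group_b))) == 1L
  if (degenerate)
    return(data.frame(n_a = length(group_a), n_b = length(group_b),
                      statistic = NA_real_, p = 1, significant = FALSE,
                      degenerate = TRUE))
  wt <- suppressWarnings(stats::wilcox.test(group_a, group_b,
                                            alternative = "two.sided"))
  data.frame(n_a = length(group_a), n_b = length(group_b),
             statistic = unname(wt$statistic), p = wt$p.value,
             significant = wt$p.value < alpha, degenerate = degenerate)
}

#' Median [min, max] summary string
#'
#' Values throughout reports are given as medians with ranges in brackets.
#' @param x Numeric vector.
#' @param digits Significant digits.
#' @return A character scalar like `"12.1 [8.6, 15.4]"`.
#' @export
median_range <- function(x, digits = 3) {
  fmt <- function(v) formatC(signif(v, digits), format = "fg")
  sprintf("%s [%s, %s]", fmt(stats::median(x)), fmt(min(x)), fmt(max(x)))
}
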