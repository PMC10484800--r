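#' Voxel-wise attenuation-correction error map
#'
#' The central quantity of the method: the relative error that the four-class
#' attenuation model introduces at each voxel,
#' `C = (PET_4C - PET_CTMR) / PET_4C`. Applying `C` to `PET_4C` recovers the
#' reference image exactly; a network that predicts `C` from MR and the
#' four-class mu-map can therefore correct PET images without
#' re-reconstruction.
#'
#' `C` is only defined where the pelvic mask holds and `PET_4C` is at least
#' `floor_bqml` (the map is a ratio and meaningless in near-zero activity);
#' elsewhere it is exactly 0 and excluded from `valid_mask`.
#'
#' @param pet4c,petref Co-registered `image_volume`s (four-class and
#'   reference reconstructions).
#' @param pelvic_mask Logical array.
#' @param floor_bqml Activity floor (Bq/ml) below which the map is undefined.
#' @return A list of class `correction_map`: `volume`
#'   (`image_volume(dimensionless)`) and `valid_mask`.
#' @export
compute_correction_map <- function(pet4c, petref, pelvic_mask,
                                   floor_bqml = 300) {
  stop_if_grid_mismatch(pet4c, petref)
  if (!identical(dim(pelvic_mask), dim(pet4c$data)))
    stop("pelvic mask shape mismatch")
  if (floor_bqml <= 0) stop("floor_bqml must be positive")
  valid <- pelvic_mask & pet4c$data >= floor_bqml
  cmap <- array(0, dim = dim(pet4c$data))
  cmap[valid] <- (pet4c$data[valid] - petref$data[valid]) / pet4c$data[valid]
  correction_map(with_data(pet4c, cmap, role = "dimensionless"), valid)
}

correction_map <- function(volume, valid_mask) {
  stopifnot(inherits(volume, "image_volume"))
  if (any(!is.finite(volume$data[valid_mask])))
    stop("non-finite correction values inside valid_mask")
  if (any(volume$data[!valid_mask] != 0))
    stop("correction map must be exactly 0 outside valid_mask")
  structure(list(volume = volume, valid_mask = valid_mask),
            class = "correction_map")
}

#' @export
print.correction_map <- function(x, ...) {
  v <- x$volume$data[x$valid_mask]
  cat(sprintf("<correction_map> %d valid voxels, range [%.3f, %.3f]\n",
              sum(x$valid_mask),
              if (length(v)) min(v) else NA, if (length(v)) max(v) else NA))
  invisible(x)
}

#' Apply a correction map to a four-class PET image
#'
#' Inverts the correction-map definition: `PET_cor = PET_4C * (1 - C)` within
#' the map's valid region, and leaves `PET_4C` untouched elsewhere. The
#' output is clamped at zero, so over-corrections (`C > 1`) cannot produce
#' negative activity.
#'
#' @param pet4c `image_volume` on the map's grid.
#' @param cmap A `correction_map` (exact or predicted).
#' @return `image_volume(activity_bqml)`: the corrected image `PET_cor`.
#' @export
apply_correction_map <- function(pet4c, cmap) {
  stop_if_grid_mismatch(pet4c, cmap$volume)
  cv <- cmap$volume$data
  if (any(!is.finite(cv[cmap$valid_mask])))
    stop("non-finite correction values inside valid_mask")
  out <- pet4c$data
  out[cmap$valid_mask] <- pet4c$data[cmap$valid_mask] *
    (1 - cv[cmap$valid_mask])
  out[out < 0] <- 0
  with_data(pet4c, out, role = "activity_bqml")
}

#' Clamp a (predicted) correction map to a physical range
#'
#' Network predictions are unconstrained; before application they are clamped
#' to a configurable range (default [-2, 1]) so a single wild prediction
#' cannot more than triple or fully null a voxel.
#'
#' @param cmap A `correction_map`.
#' @param range Length-2 clamp interval.
#' @return A `correction_map`.
#' @export
clamp_correction_map <- function(cmap, range = c(-2, 1)) {
  v <- cmap$volume$data
  v[cmap$valid_mask] <- pmin(pmax(v[cmap$valid_mask], range[1]), range[2])
  correction_map(with_data(cmap$volume, v), cmap$valid_mask)
}

#' Write a correction map as NIfTI with its valid mask as a companion volume
#' @param cmap A `correction_map`.
#' @param path Output path; the mask takes a `_mask` suffix.
#' @return `path`, invisibly.
#' @export
write_correction_map <- function(cmap, path) {
  write_volume(cmap$volume, path)
  mask_path <- sub("(\\.nii(\\.gz)?)$", "_mask\\1", path)
  write_volume(image_volume(cmap$valid_mask * 1, cmap$volume$spacing),
               mask_path)
  invisible(path)
}

#' Read a correction map written by [write_correction_map()]
#' @param path Path passed to [write_correction_map()].
#' @return A `correction_map`.
#' @export
read_correction_map <- function(path) {
  vol <- read_volume(path, "dimensionless")
  mask_path <- sub("(\\.nii(\\.gz)?)$", "_mask\\1", path)
  mask <- read_volume(mask_path)$data > 0.5
  vol$data[!mask] <- 0
  correction_map(vol, mask)
}
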