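#' 3D image volume with voxel spacing and physical origin
#'
#' The basic container used throughout the package: a 3D numeric array plus
#' voxel spacing (mm), origin (mm, position of the centre of voxel
#' \code{[1,1,1]}) and a semantic role tag. The role determines value-range
#' checks: linear attenuation coefficients and activity concentrations must be
#' non-negative, CT values must lie in the Hounsfield range [-1024, 3000].
#'
#' @param data 3D numeric array.
#' @param spacing Numeric length-3, voxel size in mm; strictly positive.
#' @param origin Numeric length-3, mm.
#' @param role One of `"hu"`, `"lac_cm"`, `"activity_bqml"`, `"mr_intensity"`,
#'   `"label"`, `"dimensionless"`.
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                         role = "dimensionless") {
  roles <- c("hu", "lac_cm", "activity_bqml", "mr_intensity", "label",
             "dimensionless")
  role <- match.arg(role, roles)
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be three strictly positive numbers (mm)")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be three finite numbers (mm)")
  vol <- structure(list(data = data, spacing = spacing, origin = origin,
                        role = role),
                   class = "image_volume")
  validate_volume(vol)
  vol
}

validate_volume <- function(vol) {
  d <- vol$data
  if (vol$role == "lac_cm" && any(d < 0, na.rm = TRUE))
    stop("lac_cm volume contains negative values")
  if (vol$role == "activity_bqml" && any(d < 0, na.rm = TRUE))
    stop("activity_bqml volume contains negative values")
  if (vol$role == "hu" && (any(d < -1024, na.rm = TRUE) ||
                           any(d > 3000, na.rm = TRUE)))
    stop("hu volume outside [-1024, 3000]")
  invisible(vol)
}

#' @export
print.image_volume <- function(x, ...) {
  cat(sprintf("<image_volume %s> %s, spacing %s mm\n", x$role,
              paste(dim(x$data), collapse = "x"),
              paste(format(x$spacing), collapse = "x")))
  invisible(x)
}

#' @export
dim.image_volume <- function(x) dim(x$data)

#' Replace the data of a volume, keeping grid and role
#' @param vol An `image_volume`.
#' @param data Replacement 3D array of identical shape.
#' @param role Optional new role tag.
#' @return A new `image_volume`.
#' @export
with_data <- function(vol, data, role = vol$role) {
  stopifnot(inherits(vol, "image_volume"))
  if (!identical(dim(data), dim(vol$data)))
    stop("replacement data shape differs from volume shape")
  image_volume(data, vol$spacing, vol$origin, role)
}

same_grid <- function(a, b, tol = 1e-6) {
  identical(dim(a$data), dim(b$data)) &&
    max(abs(a$spacing - b$spacing)) < tol &&
    max(abs(a$origin - b$origin)) < tol
}

stop_if_grid_mismatch <- function(a, b) {
  if (!same_grid(a, b)) stop("volumes are not on the same grid")
  invisible(TRUE)
}

#' Write a volume to a NIfTI-1 file
#'
#' Spacing is carried in the NIfTI pixdim; the role is not representable in
#' NIfTI and should be tracked by the caller (phantom directories carry a JSON
#' sidecar).
#'
#' @param vol An `image_volume` (or a logical/numeric 3D array).
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  if (inherits(vol, "image_volume")) {
    arr <- vol$data
    sp <- vol$spacing
  } else {
    arr <- vol
    sp <- c(1, 1, 1)
  }
  storage.mode(arr) <- "double"
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- sp
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI-1 file as an image volume
#' @param path Path to a `.nii`/`.nii.gz` file.
#' @param role Role tag to assign (NIfTI does not store one).
#' @return An `image_volume`.
#' @export
read_volume <- function(path, role = "dimensionless") {
  img <- RNifti::readNifti(path)
  arr <- array(as.numeric(img), dim = dim(img))
  sp <- RNifti::pixdim(img)[seq_len(3)]
  image_volume(arr, spacing = sp, role = role)
}

#' Resample a volume onto the grid of another by trilinear interpolation
#'
#' Used when externally supplied volumes are not already on the PET grid.
#' Points outside the source extent take `fill`.
#'
#' @param vol Source `image_volume`.
#' @param target `image_volume` defining the output grid.
#' @param fill Value outside the source volume.
#' @return `image_volume` on the target grid with the source's role.
#' @export
resample_to_grid <- function(vol, target, fill = 0) {
  if (same_grid(vol, target)) return(with_data(target, vol$data, role = vol$role))
  dsrc <- dim(vol$data)
  dtg <- dim(target$data)
  # target voxel centres in source continuous index coordinates (1-based)
  ax <- lapply(1:3, function(k) {
    mm <- target$origin[k] + (seq_len(dtg[k]) - 1) * target$spacing[k]
    (mm - vol$origin[k]) / vol$spacing[k] + 1
  })
  g <- expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]])
  out <- trilinear_sample(vol$data, g$x, g$y, g$z, fill)
  image_volume(array(out, dtg), target$spacing, target$origin, vol$role)
}

trilinear_sample <- function(arr, x, y, z, fill = 0) {
  d <- dim(arr)
  x0 <- floor(x); y0 <- floor(y); z0 <- floor(z)
  fx <- x - x0; fy <- y - y0; fz <- z - z0
  inside <- x >= 1 & x <= d[1] & y >= 1 & y <= d[2] & z >= 1 & z <= d[3]
  cl <- function(v, n) pmin(pmax(v, 1), n)
  x0 <- cl(x0, d[1]); y0 <- cl(y0, d[2]); z0 <- cl(z0, d[3])
  x1 <- cl(x0 + 1, d[1]); y1 <- cl(y0 + 1, d[2]); z1 <- cl(z0 + 1, d[3])
  at <- function(i, j, k) arr[cbind(i, j, k)]
  v <- (1 - fx) * ((1 - fy) * ((1 - fz) * at(x0, y0, z0) + fz * at(x0, y0, z1)) +
                   fy * ((1 - fz) * at(x0, y1, z0) + fz * at(x0, y1, z1))) +
       fx * ((1 - fy) * ((1 - fz) * at(x1, y0, z0) + fz * at(x1, y0, z1)) +
             fy * ((1 - fz) * at(x1, y1, z0) + fz * at(x1, y1, z1)))
  v[!inside] <- fill
  v
}
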