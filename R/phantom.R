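#' Specification of a randomized synthetic pelvic phantom
#'
#' Defines the geometry and intensity statistics of one synthetic "patient":
#' an elliptical body cross-section with a subcutaneous fat ring, a set of
#' cortical-bone structures with marrow interiors, and spherical lesions with
#' a fixed lesion-to-background activity ratio. All randomness is governed by
#' `seed`; two phantoms generated from identical specs are bit-identical.
#'
#' @param shape Grid dimensions (nx, ny, nz).
#' @param spacing Voxel size in mm.
#' @param body_semiaxes In-plane body ellipse semi-axes (mm) before jitter.
#' @param body_jitter Relative uniform jitter applied to the semi-axes.
#' @param n_bones Number of bone structures (elliptical cortical shells with
#'   marrow cores, extruded through the slab).
#' @param bone_outer_mm Range of bone outer semi-axes (mm).
#' @param bone_shell_mm Range of cortical shell thickness (mm).
#' @param bone_jitter_mm Uniform in-plane jitter of bone centres (mm).
#' @param n_bone_lesions,n_soft_lesions Lesion counts per tissue class.
#' @param lesion_diameter_mm Lesion diameter range (mm); must be at least two
#'   voxels in every axis.
#' @param activity_ratio Lesion-to-background activity ratio (> 1).
#' @param background_bqml Background activity concentration (Bq/ml) in tissue.
#' @param fat_ring_fraction Body-ellipse radius fraction beyond which tissue
#'   is subcutaneous fat.
#' @param pelvic_z_fraction Axial slab (fractions of the z extent) used as the
#'   default pelvic mask.
#' @param seed Integer seed.
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(64, 64, 32),
                         spacing = c(6, 6, 6),
                         body_semiaxes = c(170, 110),
                         body_jitter = 0.08,
                         n_bones = 3,
                         bone_outer_mm = c(20, 34),
                         bone_shell_mm = c(4, 9),
                         bone_jitter_mm = 12,
                         n_bone_lesions = 2,
                         n_soft_lesions = 3,
                         lesion_diameter_mm = c(14, 26),
                         activity_ratio = 4,
                         background_bqml = 5000,
                         fat_ring_fraction = 0.82,
                         pelvic_z_fraction = c(0.1, 0.9),
                         seed = 1) {
  spec <- list(shape = as.integer(shape), spacing = as.numeric(spacing),
               body_semiaxes = body_semiaxes, body_jitter = body_jitter,
               n_bones = as.integer(n_bones), bone_outer_mm = bone_outer_mm,
               bone_shell_mm = bone_shell_mm, bone_jitter_mm = bone_jitter_mm,
               n_bone_lesions = as.integer(n_bone_lesions),
               n_soft_lesions = as.integer(n_soft_lesions),
               lesion_diameter_mm = lesion_diameter_mm,
               activity_ratio = activity_ratio,
               background_bqml = background_bqml,
               fat_ring_fraction = fat_ring_fraction,
               pelvic_z_fraction = pelvic_z_fraction,
               seed = as.integer(seed))
  class(spec) <- "phantom_spec"
  if (length(spec$shape) != 3L || any(spec$shape[1:2] < 16) || spec$shape[3] < 2)
    stop("shape must be (nx, ny, nz) with nx, ny >= 16 and nz >= 2")
  if (any(spec$spacing <= 0)) stop("spacing must be positive")
  if (min(spec$lesion_diameter_mm) < 2 * max(spec$spacing))
    stop("lesion diameter must be at least 2 voxels in every axis")
  if (spec$activity_ratio <= 1) stop("activity_ratio must exceed 1")
  if (spec$background_bqml <= 0) stop("background_bqml must be positive")
  spec
}

# Tissue label codes used throughout
LBL_AIR <- 0L; LBL_FAT <- 1L; LBL_SOFT <- 2L; LBL_CORT <- 3L; LBL_MARROW <- 4L

#' Generate one synthetic co-registered pelvic dataset
#'
#' Produces co-registered tissue labels, a CT volume (HU), Dixon in-phase and
#' out-of-phase MR volumes, and a tracer activity map with lesions, emulating
#' one patient's same-day PET/CT + PET/MR data. Cortical bone and air carry
#' (near-)zero MR signal, reflecting the fast T2* decay that makes bone
#' invisible to Dixon segmentation; marrow is given a fat-like signal.
#' Deterministic given `spec$seed`.
#'
#' @param spec A [phantom_spec()].
#' @return A list of class `phantom` with elements `labels`, `ct`, `dixon_ip`,
#'   `dixon_op`, `activity` (all [image_volume()]s), `lesions` (list),
#'   `body_mask`, `pelvic_mask` (logical arrays) and `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  d <- spec$shape; sp <- spec$spacing
  # voxel-centre coordinates (mm) relative to the grid centre
  xs <- (seq_len(d[1]) - (d[1] + 1) / 2) * sp[1]
  ys <- (seq_len(d[2]) - (d[2] + 1) / 2) * sp[2]
  X <- matrix(rep(xs, d[2]), d[1], d[2])
  Y <- matrix(rep(ys, each = d[1]), d[1], d[2])

  a0 <- spec$body_semiaxes[1] * runif(1, 1 - spec$body_jitter, 1 + spec$body_jitter)
  b0 <- spec$body_semiaxes[2] * runif(1, 1 - spec$body_jitter, 1 + spec$body_jitter)
  # anatomy varies smoothly along z: the body tapers and the bone structures
  # drift and change calibre, so every axial slice has a distinct geometry,
  # as in real pelvic data
  body_taper <- runif(1, -0.08, 0.08)
  body_phase <- runif(1, 0, 2 * pi)

  # bone structures: nominal femoral-head / sacral positions, jittered
  nominal <- list(c(-0.52, 0.05), c(0.52, 0.05), c(0, -0.38),
                  c(-0.25, 0.45), c(0.25, 0.45))
  n_b <- min(spec$n_bones, length(nominal))
  bones <- lapply(seq_len(n_b), function(k) {
    list(cx = nominal[[k]][1] * a0 + runif(1, -1, 1) * spec$bone_jitter_mm,
         cy = nominal[[k]][2] * b0 + runif(1, -1, 1) * spec$bone_jitter_mm,
         rx = runif(1, spec$bone_outer_mm[1], spec$bone_outer_mm[2]),
         ry = runif(1, spec$bone_outer_mm[1], spec$bone_outer_mm[2]),
         shell = runif(1, spec$bone_shell_mm[1], spec$bone_shell_mm[2]),
         drift_x = runif(1, -0.5, 0.5) * spec$bone_jitter_mm,
         drift_y = runif(1, -0.5, 0.5) * spec$bone_jitter_mm,
         taper = runif(1, -0.25, 0.25),
         phase = runif(1, 0, 2 * pi))
  })

  labels <- array(LBL_AIR, dim = d)
  body_mask <- array(FALSE, dim = d)
  for (z in seq_len(d[3])) {
    u <- if (d[3] > 1) (z - 1) / (d[3] - 1) - 0.5 else 0   # -0.5 .. 0.5
    a <- a0 * (1 + body_taper * u + 0.03 * sin(2 * pi * u + body_phase))
    b <- b0 * (1 + body_taper * u)
    rell <- sqrt((X / a)^2 + (Y / b)^2)
    body2d <- rell <= 1
    lab2d <- matrix(LBL_AIR, d[1], d[2])
    lab2d[body2d] <- LBL_SOFT
    lab2d[body2d & rell > spec$fat_ring_fraction] <- LBL_FAT
    for (bn in bones) {
      s <- 1 + bn$taper * u + 0.1 * sin(2 * pi * u + bn$phase)
      s <- max(s, 0.3)
      cx <- bn$cx + bn$drift_x * 2 * u
      cy <- bn$cy + bn$drift_y * 2 * u
      rx <- bn$rx * s; ry <- bn$ry * s
      r2o <- ((X - cx) / rx)^2 + ((Y - cy) / ry)^2
      r2i <- ((X - cx) / max(rx - bn$shell, 3))^2 +
        ((Y - cy) / max(ry - bn$shell, 3))^2
      inside_body <- rell <= 0.92        # keep bone clear of the skin line
      lab2d[r2o <= 1 & r2i > 1 & inside_body] <- LBL_CORT
      lab2d[r2i <= 1 & inside_body] <- LBL_MARROW
    }
    labels[, , z] <- lab2d
    body_mask[, , z] <- body2d
  }

  nvox <- prod(d)
  ct <- array(-1000, dim = d)
  draw <- function(mask, lo, hi) {
    n <- sum(mask); if (n) ct[mask] <<- runif(n, lo, hi)
  }
  draw(labels == LBL_FAT, -120, -80)
  draw(labels == LBL_SOFT, 20, 60)
  draw(labels == LBL_CORT, 700, 1500)
  draw(labels == LBL_MARROW, 100, 300)

  # class-conditional Dixon intensities: fat bright IP / dark OP, soft tissue
  # similar IP and OP, bone and air near zero
  ip <- array(0, dim = d); op <- array(0, dim = d)
  dix <- function(mask, m_ip, s_ip, m_op, s_op) {
    n <- sum(mask)
    if (n) {
      ip[mask] <<- pmax(rnorm(n, m_ip, s_ip), 0)
      op[mask] <<- pmax(rnorm(n, m_op, s_op), 0)
    }
  }
  dix(labels == LBL_FAT, 1000, 30, 220, 25)
  dix(labels == LBL_SOFT, 620, 30, 560, 30)
  dix(labels == LBL_MARROW, 900, 35, 250, 25)
  dix(labels == LBL_CORT, 2, 1, 2, 1)
  dix(labels == LBL_AIR, 2, 1, 2, 1)

  activity <- array(0, dim = d)
  activity[labels != LBL_AIR] <- spec$background_bqml

  # spherical lesions with known ground-truth uptake
  lesions <- list()
  n_per <- c(bone = spec$n_bone_lesions, soft_tissue = spec$n_soft_lesions)
  vx <- (seq_len(d[1]) - (d[1] + 1) / 2) * sp[1]
  vy <- (seq_len(d[2]) - (d[2] + 1) / 2) * sp[2]
  vz <- (seq_len(d[3]) - (d[3] + 1) / 2) * sp[3]
  lesion_id <- 0L
  for (cls in names(n_per)) {
    target_lbl <- if (cls == "bone") c(LBL_CORT, LBL_MARROW) else LBL_SOFT
    for (i in seq_len(n_per[[cls]])) {
      lesion_id <- lesion_id + 1L
      placed <- FALSE
      for (try in 1:60) {
        radius <- runif(1, spec$lesion_diameter_mm[1], spec$lesion_diameter_mm[2]) / 2
        # candidate centres: matching tissue, away from the axial ends
        zin <- seq(2, d[3] - 1)
        cand <- which(labels %in% target_lbl &
                        slice_index_array(d) %in% zin)
        if (!length(cand)) break
        cidx <- arrayInd(sample(cand, 1), d)
        cm <- c(vx[cidx[1]], vy[cidx[2]], vz[cidx[3]])
        dx2 <- outer(outer((vx - cm[1])^2, (vy - cm[2])^2, "+"),
                     (vz - cm[3])^2, "+")
        roi <- dx2 <= radius^2
        if (!any(roi)) next
        if (all(body_mask[roi])) {
          prev <- vapply(lesions, function(l) any(l$roi_mask & roi), logical(1))
          if (!any(prev)) {
            activity[roi] <- spec$background_bqml * spec$activity_ratio
            lesions[[lesion_id]] <- structure(
              list(id = lesion_id, tissue_class = cls, center_mm = cm,
                   radius_mm = radius, roi_mask = roi),
              class = "lesion")
            placed <- TRUE
            break
          }
        }
      }
      if (!placed)
        stop(sprintf("failed to place %s lesion %d: phantom too small for spec",
                     cls, i))
    }
  }

  ph <- structure(
    list(labels = image_volume(labels, sp, role = "label"),
         ct = image_volume(ct, sp, role = "hu"),
         dixon_ip = image_volume(ip, sp, role = "mr_intensity"),
         dixon_op = image_volume(op, sp, role = "mr_intensity"),
         activity = image_volume(activity, sp, role = "activity_bqml"),
         lesions = lesions, body_mask = body_mask, pelvic_mask = NULL,
         spec = spec),
    class = "phantom")
  ph$pelvic_mask <- make_pelvic_mask(ph, spec$pelvic_z_fraction)
  ph
}

slice_index_array <- function(d) {
  array(rep(seq_len(d[3]), each = d[1] * d[2]), dim = d)
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("<phantom> %s voxels, %d lesions (%d bone), seed %d\n",
              paste(dim(x$labels$data), collapse = "x"), length(x$lesions),
              sum(vapply(x$lesions, function(l) l$tissue_class == "bone",
                         logical(1))),
              x$spec$seed))
  invisible(x)
}

#' Axial slab mask of the pelvic region
#'
#' The bone-insertion and evaluation region covers the slices from roughly
#' the upper thighs to the lower lumbar spine. The exact anatomical endpoints
#' are configurable as fractions of the axial extent; the mask is the slab
#' intersected with the body mask.
#'
#' @param phantom A `phantom`.
#' @param z_fraction_range Pair `(lo, hi)` with `0 <= lo < hi <= 1`; slices
#'   with zero-based index in `[lo*Nz, hi*Nz)` are retained.
#' @return A logical array.
#' @export
make_pelvic_mask <- function(phantom, z_fraction_range = c(0.1, 0.9)) {
  lo <- z_fraction_range[1]; hi <- z_fraction_range[2]
  if (!(lo >= 0 && lo < hi && hi <= 1))
    stop("need 0 <= lo < hi <= 1")
  d <- dim(phantom$labels$data)
  idx0 <- seq_len(d[3]) - 1
  keep <- idx0 >= lo * d[3] - 1e-9 & idx0 < hi * d[3] - 1e-9
  if (!any(keep)) stop("empty axial slab")
  slab <- array(rep(keep, each = d[1] * d[2]), dim = d)
  phantom$body_mask & slab
}

#' Body contour from an MR intensity volume
#'
#' Splits the intensity histogram with Otsu's threshold, then per axial slice
#' fills interior holes and keeps the largest connected component, so that
#' signal-free interior structures (cortical bone, bowel gas) remain inside
#' the contour.
#'
#' @param volume `image_volume` with MR intensities (or any non-constant
#'   scalar volume).
#' @return Logical array of the body interior.
#' @export
body_contour_mask <- function(volume) {
  arr <- if (inherits(volume, "image_volume")) volume$data else volume
  rng <- range(arr)
  if (diff(rng) <= 0) stop("degenerate intensity histogram: constant volume")
  nv <- (arr - rng[1]) / diff(rng)
  d <- dim(arr)
  th <- EBImage::otsu(matrix(nv, nrow = d[1]), range = c(0, 1))
  mask <- nv > th
  out <- array(FALSE, dim = d)
  for (z in seq_len(d[3])) {
    sl <- mask[, , z]
    if (!any(sl)) next
    filled <- EBImage::fillHull(EBImage::Image(sl * 1)) > 0.5
    lbl <- EBImage::bwlabel(EBImage::Image(filled * 1))
    tab <- tabulate(as.integer(lbl))
    if (length(tab)) {
      keep <- which.max(tab)
      out[, , z] <- as.integer(lbl) == keep
    }
  }
  out
}

#' Write a phantom to a directory of NIfTI files plus JSON sidecars
#' @param phantom A `phantom`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_phantom <- function(phantom, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_volume(phantom$labels, file.path(dir, "labels.nii.gz"))
  write_volume(phantom$ct, file.path(dir, "ct.nii.gz"))
  write_volume(phantom$dixon_ip, file.path(dir, "dixon_ip.nii.gz"))
  write_volume(phantom$dixon_op, file.path(dir, "dixon_op.nii.gz"))
  write_volume(phantom$activity, file.path(dir, "activity.nii.gz"))
  sp <- phantom$labels$spacing
  write_volume(image_volume(phantom$body_mask * 1, sp),
               file.path(dir, "body_mask.nii.gz"))
  write_volume(image_volume(phantom$pelvic_mask * 1, sp),
               file.path(dir, "pelvic_mask.nii.gz"))
  les <- lapply(phantom$lesions, function(l)
    list(id = l$id, tissue_class = l$tissue_class,
         center_mm = l$center_mm, radius_mm = l$radius_mm))
  jsonlite::write_json(les, file.path(dir, "lesions.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(unclass(phantom$spec), file.path(dir, "spec.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a phantom written by [write_phantom()]
#' @param dir Directory containing the phantom files.
#' @return A `phantom`.
#' @export
read_phantom <- function(dir) {
  spec <- jsonlite::read_json(file.path(dir, "spec.json"), simplifyVector = TRUE)
  spec <- do.call(phantom_spec, spec[names(spec) %in% names(formals(phantom_spec))])
  labels <- read_volume(file.path(dir, "labels.nii.gz"), "label")
  d <- dim(labels$data); sp <- labels$spacing
  vx <- (seq_len(d[1]) - (d[1] + 1) / 2) * sp[1]
  vy <- (seq_len(d[2]) - (d[2] + 1) / 2) * sp[2]
  vz <- (seq_len(d[3]) - (d[3] + 1) / 2) * sp[3]
  les_raw <- jsonlite::read_json(file.path(dir, "lesions.json"),
                                 simplifyVector = FALSE)
  lesions <- lapply(les_raw, function(l) {
    cm <- unlist(l$center_mm)
    dx2 <- outer(outer((vx - cm[1])^2, (vy - cm[2])^2, "+"), (vz - cm[3])^2, "+")
    structure(list(id = l$id, tissue_class = l$tissue_class, center_mm = cm,
                   radius_mm = l$radius_mm,
                   roi_mask = dx2 <= l$radius_mm^2),
              class = "lesion")
  })
  ph <- structure(
    list(labels = labels,
         ct = read_volume(file.path(dir, "ct.nii.gz"), "hu"),
         dixon_ip = read_volume(file.path(dir, "dixon_ip.nii.gz"), "mr_intensity"),
         dixon_op = read_volume(file.path(dir, "dixon_op.nii.gz"), "mr_intensity"),
         activity = read_volume(file.path(dir, "activity.nii.gz"),
                                "activity_bqml"),
         lesions = lesions,
         body_mask = read_volume(file.path(dir, "body_mask.nii.gz"))$data > 0.5,
         pelvic_mask = read_volume(file.path(dir, "pelvic_mask.nii.gz"))$data > 0.5,
         spec = spec),
    class = "phantom")
  ph
}
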