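#' Bilinear Hounsfield-to-LAC transform at 511 keV
#'
#' CT numbers are mapped to linear attenuation coefficients with the standard
#' two-segment form: below the breakpoint the water-scaled line
#' `water_lac * (1000 + HU) / 1000` (zero at -1000 HU, `water_lac` at 0 HU),
#' above it a continuous linear segment with a reduced slope accounting for
#' the higher effective Z of bone. The default constants (water LAC
#' 0.096 cm^-1, breakpoint 0 HU, bone slope 5.64e-5 cm^-1 per HU) follow the
#' commonly used 511 keV bilinear calibration family and are configurable.
#'
#' @param water_lac LAC of water at 511 keV (cm^-1).
#' @param breakpoint_hu Breakpoint between the two segments (HU).
#' @param slope_above LAC increment per HU above the breakpoint (cm^-1/HU).
#' @return A list of class `hu_lac_transform`.
#' @export
hu_lac_transform <- function(water_lac = 0.096, breakpoint_hu = 0,
                             slope_above = 5.64e-5) {
  if (water_lac <= 0) stop("water_lac must be positive")
  if (slope_above < 0) stop("slope_above must be non-negative")
  structure(list(water_lac = water_lac, breakpoint_hu = breakpoint_hu,
                 slope_above = slope_above),
            class = "hu_lac_transform")
}

hu_to_lac_scalar <- function(hu, t) {
  base <- t$water_lac * (1000 + pmin(hu, t$breakpoint_hu)) / 1000
  above <- pmax(hu - t$breakpoint_hu, 0) * t$slope_above
  pmax(base + above, 0)
}

#' Scale a CT volume to linear attenuation coefficients at 511 keV
#'
#' @param ct `image_volume` with role `hu`.
#' @param transform A [hu_lac_transform()].
#' @return `image_volume` with role `lac_cm`.
#' @export
hu_to_lac <- function(ct, transform = hu_lac_transform()) {
  stopifnot(inherits(ct, "image_volume"))
  if (ct$role != "hu") stop("hu_to_lac expects a volume with role 'hu'")
  lac <- hu_to_lac_scalar(ct$data, transform)
  with_data(ct, lac, role = "lac_cm")
}

#' Four-class Dixon-based mu-map
#'
#' Segments the body into fat and soft tissue from the Dixon in-phase /
#' out-of-phase pair and assigns each class its predefined LAC; everything
#' outside the body contour is background air (LAC 0). Bone carries no MR
#' signal and is absorbed into soft tissue, which is precisely the error the
#' rest of the package studies. No lung class is needed in a pelvic field of
#' view.
#'
#' Fat is identified by the fat-fraction proxy `(IP - OP) / (2 * IP)`: near
#' 0.5 for fat (out-of-phase cancellation) and near 0 for water-dominated
#' tissue. With magnitude MR images the proxy cannot exceed 0.5, so the
#' decision threshold sits at the midpoint of the separable gap (default
#' 0.25).
#'
#' @param dixon_ip,dixon_op `image_volume`s with role `mr_intensity`.
#' @param body Logical array: body contour mask.
#' @param class_lacs Named LACs (cm^-1) for `air`, `fat`, `soft_tissue`.
#' @param fat_fraction_threshold Proxy threshold above which a voxel is fat.
#' @return A list of class `mu_map` with elements `volume`
#'   (`image_volume(lac_cm)`), `provenance = "four_class"` and `class_lacs`.
#' @export
four_class_mumap <- function(dixon_ip, dixon_op, body,
                             class_lacs = c(air = 0, fat = 0.0854,
                                            soft_tissue = 0.1),
                             fat_fraction_threshold = 0.25) {
  stop_if_grid_mismatch(dixon_ip, dixon_op)
  if (!any(body)) stop("empty body mask")
  ip <- dixon_ip$data; op <- dixon_op$data
  ff <- array(0, dim = dim(ip))
  pos <- ip > 0
  ff[pos] <- (ip[pos] - op[pos]) / (2 * ip[pos])
  lac <- array(class_lacs[["air"]], dim = dim(ip))
  lac[body] <- class_lacs[["soft_tissue"]]
  lac[body & ff > fat_fraction_threshold] <- class_lacs[["fat"]]
  mu_map(with_data(dixon_ip, lac, role = "lac_cm"), "four_class", class_lacs)
}

mu_map <- function(volume, provenance, class_lacs = NULL) {
  stopifnot(inherits(volume, "image_volume"), volume$role == "lac_cm")
  provenance <- match.arg(provenance, c("four_class", "reference"))
  structure(list(volume = volume, provenance = provenance,
                 class_lacs = class_lacs),
            class = "mu_map")
}

#' @export
print.mu_map <- function(x, ...) {
  cat(sprintf("<mu_map %s> range [%.4f, %.4f] cm^-1\n", x$provenance,
              min(x$volume$data), max(x$volume$data)))
  invisible(x)
}

#' Insert CT bone information into a four-class mu-map
#'
#' Builds the reference-standard mu-map: soft-tissue classes come from the
#' Dixon segmentation, and bone is transferred from the LAC-scaled CT. Bone
#' information is defined as all voxels whose CT-derived LAC exceeds
#' `threshold_lac` (default 0.1 cm^-1), and is only inserted within the
#' pelvic mask. The input map is not modified.
#'
#' @param mu4c A four-class `mu_map`.
#' @param ct_lac `image_volume(lac_cm)` from [hu_to_lac()].
#' @param pelvic_mask Logical array restricting the insertion region.
#' @param threshold_lac LAC threshold (cm^-1) defining bone.
#' @return A `mu_map` with provenance `"reference"`.
#' @export
insert_bone <- function(mu4c, ct_lac, pelvic_mask, threshold_lac = 0.1) {
  stopifnot(inherits(mu4c, "mu_map"))
  if (threshold_lac <= 0) stop("threshold_lac must be positive")
  stop_if_grid_mismatch(mu4c$volume, ct_lac)
  if (!identical(dim(pelvic_mask), dim(ct_lac$data)))
    stop("pelvic mask shape mismatch")
  out <- mu4c$volume$data
  sel <- (ct_lac$data > threshold_lac) & pelvic_mask
  out[sel] <- ct_lac$data[sel]
  mu_map(with_data(mu4c$volume, out), "reference", mu4c$class_lacs)
}

#' Write a mu-map as NIfTI plus a provenance sidecar
#' @param mu A `mu_map`.
#' @param path Output `.nii`/`.nii.gz` path; the sidecar takes `.json`.
#' @return `path`, invisibly.
#' @export
write_mumap <- function(mu, path) {
  write_volume(mu$volume, path)
  side <- sub("\\.nii(\\.gz)?$", ".json", path)
  jsonlite::write_json(list(provenance = mu$provenance,
                            class_lacs = as.list(mu$class_lacs)),
                       side, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a mu-map written by [write_mumap()]
#' @param path Path to the NIfTI file.
#' @return A `mu_map`.
#' @export
read_mumap <- function(path) {
  side <- sub("\\.nii(\\.gz)?$", ".json", path)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  mu_map(read_volume(path, "lac_cm"), meta$provenance,
         unlist(meta$class_lacs))
}
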