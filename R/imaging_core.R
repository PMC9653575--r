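#' @useDynLib petmtv, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats quantile rnorm runif sd cor.test pf pt qf median
#' @importFrom utils head tail
NULL

# organ label map shared across the package (and NIfTI label volumes)
ORGAN_NAMES <- c("brain", "heart", "kidney_left", "kidney_right", "bladder")
ORGAN_LABELS <- stats::setNames(1:5, ORGAN_NAMES)

#' Define a voxel grid
#'
#' A regular 3D grid in world (mm) coordinates. Axis convention: x runs
#' patient left to right, y anterior to posterior, z inferior to superior.
#' Voxel indices are 0-based; the center of voxel `(i, j, k)` sits at
#' `origin + c(i, j, k) * spacing`.
#'
#' @param shape integer triple, number of voxels along x, y, z (all >= 1).
#' @param spacing numeric triple, voxel edge lengths in mm (all > 0).
#' @param origin numeric triple, world position (mm) of the first voxel
#'   center.
#' @return An object of class `voxel_grid`.
#' @export
voxel_grid <- function(shape, spacing, origin = c(0, 0, 0)) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(is.na(shape)) || any(shape < 1L))
    stop("shape must be three integers >= 1")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be three positive numbers (mm)")
  origin <- as.numeric(origin)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("origin must be three finite numbers (mm)")
  structure(list(shape = shape, spacing = spacing, origin = origin),
            class = "voxel_grid")
}

#' Voxel volume of a grid in cubic centimeters
#'
#' @param grid a [voxel_grid()].
#' @return `prod(spacing) / 1000`, the volume of one voxel in cm^3.
#' @export
voxel_volume_cm3 <- function(grid) {
  stopifnot(inherits(grid, "voxel_grid"))
  prod(grid$spacing) / 1000
}

same_grid <- function(a, b, tol = 1e-6) {
  all(a$shape == b$shape) &&
    all(abs(a$spacing - b$spacing) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}

#' Construct a scalar image volume
#'
#' @param values 3D numeric array matching `grid$shape`; Hounsfield units for
#'   CT, SUV (g/mL) for PET.
#' @param grid a [voxel_grid()].
#' @param modality `"CT"` or `"PET"`. PET values must be finite and
#'   non-negative.
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(values, grid, modality = c("CT", "PET")) {
  modality <- match.arg(modality)
  stopifnot(inherits(grid, "voxel_grid"))
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("values must be a 3D array")
  if (!all(dim(values) == grid$shape))
    stop("values array shape must equal grid shape")
  if (any(!is.finite(values)))
    stop("values must be finite")
  if (modality == "PET" && any(values < 0))
    stop("PET values must be non-negative (SUV)")
  structure(list(values = values, grid = grid, modality = modality),
            class = "image_volume")
}

#' Construct a binary mask on a grid
#'
#' @param values 3D logical array matching `grid$shape`.
#' @param grid a [voxel_grid()].
#' @param label character name of the structure (organ or lesion).
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(values, grid, label = "mask") {
  stopifnot(inherits(grid, "voxel_grid"))
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("values must be a 3D array")
  if (!all(dim(values) == grid$shape))
    stop("mask shape must equal grid shape")
  storage.mode(values) <- "logical"
  if (any(is.na(values))) stop("mask must not contain NA")
  structure(list(values = values, grid = grid, label = label),
            class = "binary_mask")
}

#' Physical volume of a binary mask in cubic centimeters
#'
#' @param mask a [binary_mask()].
#' @return voxel count times voxel volume, in cm^3.
#' @export
mask_volume_cm3 <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  sum(mask$values) * voxel_volume_cm3(mask$grid)
}

#' Bundle the five physiologically FDG-avid organ masks
#'
#' Brain, heart, left and right kidney, and bladder masks on one common grid.
#' The masks must be pairwise disjoint.
#'
#' @param brain,heart,kidney_left,kidney_right,bladder [binary_mask()]
#'   objects sharing one grid.
#' @return An object of class `organ_mask_set` (a named list of masks with a
#'   `grid` attribute).
#' @export
organ_mask_set <- function(brain, heart, kidney_left, kidney_right, bladder) {
  masks <- list(brain = brain, heart = heart, kidney_left = kidney_left,
                kidney_right = kidney_right, bladder = bladder)
  for (m in masks) stopifnot(inherits(m, "binary_mask"))
  g <- masks[[1]]$grid
  for (m in masks[-1])
    if (!same_grid(g, m$grid)) stop("all organ masks must share one grid")
  acc <- array(0L, g$shape)
  for (m in masks) acc <- acc + m$values
  if (any(acc > 1L)) stop("organ masks must be pairwise disjoint")
  structure(c(masks, list(grid = g)), class = "organ_mask_set")
}

organ_union <- function(organs) {
  u <- array(FALSE, organs$grid$shape)
  for (nm in ORGAN_NAMES) u <- u | organs[[nm]]$values
  u
}

# ---- NIfTI I/O -------------------------------------------------------------

grid_from_nifti <- function(img) {
  d <- dim(img)
  if (length(d) != 3L)
    stop("expected a 3D image, got ", length(d), " dimensions (format error)")
  xf <- RNifti::xform(img)
  spacing <- abs(RNifti::pixdim(img))[1:3]
  origin <- as.numeric(xf[1:3, 4])
  voxel_grid(d, spacing, origin)
}

nifti_with_grid <- function(values, grid) {
  img <- RNifti::asNifti(values)
  img <- RNifti::`pixdim<-`(img, grid$spacing)
  m <- diag(c(grid$spacing, 1))
  m[1:3, 4] <- grid$origin
  RNifti::`qform<-`(img, structure(m, code = 2L))
}

#' Read a 3D volume from a NIfTI file
#'
#' Spacing and origin are taken from the file header. The array is used in
#' the package's stated axis convention; files written by [write_volume()]
#' round-trip exactly.
#'
#' @param path path to a `.nii` / `.nii.gz` file.
#' @param modality `"CT"` or `"PET"`.
#' @return An [image_volume()].
#' @export
read_volume <- function(path, modality = c("CT", "PET")) {
  modality <- match.arg(modality)
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  grid <- grid_from_nifti(img)
  image_volume(array(as.numeric(img), dim(img)), grid, modality)
}

#' Write a volume to a NIfTI file
#'
#' @param volume an [image_volume()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "image_volume"))
  RNifti::writeNifti(nifti_with_grid(volume$values, volume$grid), path)
  invisible(path)
}

#' Write an organ mask set as a labeled NIfTI volume
#'
#' Label map: 1 brain, 2 heart, 3 kidney_left, 4 kidney_right, 5 bladder,
#' 0 background.
#'
#' @param organs an [organ_mask_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_organ_masks <- function(organs, path) {
  stopifnot(inherits(organs, "organ_mask_set"))
  lab <- array(0L, organs$grid$shape)
  for (nm in ORGAN_NAMES) lab[organs[[nm]]$values] <- ORGAN_LABELS[[nm]]
  RNifti::writeNifti(nifti_with_grid(lab, organs$grid), path)
  invisible(path)
}

#' Read an organ mask set from a labeled NIfTI volume
#'
#' @param path path to a label volume written with the package's label map.
#' @return An [organ_mask_set()].
#' @export
read_organ_masks <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  grid <- grid_from_nifti(img)
  lab <- array(as.integer(round(img)), dim(img))
  masks <- lapply(ORGAN_NAMES, function(nm)
    binary_mask(lab == ORGAN_LABELS[[nm]], grid, nm))
  do.call(organ_mask_set, masks)
}

#' Convert an activity-concentration volume to body-weight SUV
#'
#' `SUV = C * weight / dose` with `C` in Bq/mL, the injected dose in Bq
#' (decay-corrected to scan start) and body weight in grams.
#'
#' @param activity an [image_volume()] of activity concentration (Bq/mL).
#' @param injected_dose_bq injected dose in Bq, > 0.
#' @param body_weight_g body weight in grams, > 0.
#' @return A PET [image_volume()] in SUV.
#' @export
to_suv <- function(activity, injected_dose_bq, body_weight_g) {
  stopifnot(inherits(activity, "image_volume"))
  if (!is.numeric(injected_dose_bq) || length(injected_dose_bq) != 1 ||
      !is.finite(injected_dose_bq) || injected_dose_bq <= 0)
    stop("injected_dose_bq must be a positive number")
  if (!is.numeric(body_weight_g) || length(body_weight_g) != 1 ||
      !is.finite(body_weight_g) || body_weight_g <= 0)
    stop("body_weight_g must be a positive number")
  image_volume(activity$values * body_weight_g / injected_dose_bq,
               activity$grid, "PET")
}

grid_extent <- function(grid) {
  lo <- grid$origin - grid$spacing / 2
  hi <- grid$origin + (grid$shape - 0.5) * grid$spacing
  rbind(lo, hi)
}

#' Resample a binary mask onto another grid
#'
#' Nearest-neighbor assignment in world coordinates: every target voxel takes
#' the value of the source voxel whose center is closest (ties resolved
#' toward the larger index). Target voxels outside the source extent are
#' FALSE.
#'
#' @param mask a [binary_mask()].
#' @param target a [voxel_grid()] overlapping the mask's grid in physical
#'   space.
#' @return A [binary_mask()] on `target`.
#' @export
resample_mask <- function(mask, target) {
  stopifnot(inherits(mask, "binary_mask"), inherits(target, "voxel_grid"))
  src <- mask$grid
  es <- grid_extent(src); et <- grid_extent(target)
  if (any(es[2, ] < et[1, ]) || any(et[2, ] < es[1, ]))
    stop("source and target grids do not overlap in physical space")
  if (same_grid(src, target))
    return(binary_mask(mask$values, target, mask$label))
  map_axis <- function(ax) {
    w <- target$origin[ax] + (seq_len(target$shape[ax]) - 1) * target$spacing[ax]
    j <- floor((w - src$origin[ax]) / src$spacing[ax] + 0.5) + 1
    j[j < 1 | j > src$shape[ax]] <- NA_integer_
    j
  }
  jx <- map_axis(1); jy <- map_axis(2); jz <- map_axis(3)
  out <- array(FALSE, target$shape)
  vx <- !is.na(jx); vy <- !is.na(jy); vz <- !is.na(jz)
  if (any(vx) && any(vy) && any(vz))
    out[vx, vy, vz] <- mask$values[jx[vx], jy[vy], jz[vz], drop = FALSE]
  binary_mask(out, target, mask$label)
}

#' Dilate or erode a mask with a spherical structuring element
#'
#' The ball radius is specified in mm and converted to voxel offsets with the
#' grid's anisotropic spacing.
#'
#' @param mask a [binary_mask()].
#' @param radius_mm ball radius in mm (>= 0; 0 returns the mask unchanged).
#' @return A [binary_mask()].
#' @export
dilate_mask <- function(mask, radius_mm) {
  stopifnot(inherits(mask, "binary_mask"), radius_mm >= 0)
  if (radius_mm == 0) return(mask)
  v <- cpp_morph_ball(as.logical(mask$values), mask$grid$shape,
                      mask$grid$spacing, radius_mm, TRUE)
  binary_mask(array(v, mask$grid$shape), mask$grid, mask$label)
}

#' @rdname dilate_mask
#' @export
erode_mask <- function(mask, radius_mm) {
  stopifnot(inherits(mask, "binary_mask"), radius_mm >= 0)
  if (radius_mm == 0) return(mask)
  v <- cpp_morph_ball(as.logical(mask$values), mask$grid$shape,
                      mask$grid$spacing, radius_mm, FALSE)
  binary_mask(array(v, mask$grid$shape), mask$grid, mask$label)
}
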