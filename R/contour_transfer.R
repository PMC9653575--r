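# CT-to-PET contour transfer: organ contours drawn on the CT grid are
# adapted to the PET tracer distribution by nearest-neighbor resampling,
# intensity thresholding from eroded seeds, and connected region growing
# within a safety margin around the original contour.

#' Configure contour transfer
#'
#' @param margin_mm dilation radius around the resampled contour that bounds
#'   the region growing (physical millimetres).
#' @param erosion_mm erosion radius producing the interior seed region.
#' @param threshold_fraction the grow threshold is this fraction of the 95th
#'   SUV percentile inside the resampled contour.
#' @param mode `"none"` grows by 26-connectivity above the threshold;
#'   `"fast_marching"` orders the growth by shortest SUV-weighted travel
#'   time from the seeds (higher uptake = faster front), then keeps voxels
#'   above the same threshold. Both stay inside the margin.
#' @return An object of class `transfer_params`.
#' @export
transfer_params <- function(margin_mm = 12, erosion_mm = 4,
                            threshold_fraction = 0.5,
                            mode = c("none", "fast_marching")) {
  mode <- match.arg(mode)
  stopifnot(margin_mm >= 0, erosion_mm >= 0,
            threshold_fraction > 0, threshold_fraction <= 1)
  structure(list(margin_mm = margin_mm, erosion_mm = erosion_mm,
                 threshold_fraction = threshold_fraction, mode = mode),
            class = "transfer_params")
}

transfer_one <- function(pet, mask, params) {
  grid <- pet$grid
  res <- resample_mask(mask, grid)
  if (!any(res$values))
    return(list(mask = res, threshold = NA_real_, note = "empty"))
  suv_in <- pet$values[res$values]
  p95 <- quantile(suv_in, 0.95, names = FALSE)
  thr <- params$threshold_fraction * p95
  seeds <- erode_mask(res, params$erosion_mm)$values & (pet$values >= thr)
  allowed <- dilate_mask(res, params$margin_mm)$values
  if (!any(seeds)) {
    warning(sprintf("organ '%s': no seed voxels above threshold; keeping resampled contour",
                    mask$label))
    return(list(mask = res, threshold = thr, note = "no_seeds"))
  }
  grown <- if (params$mode == "fast_marching") {
    cpp_front_grow(pet$values, seeds, allowed, thr, grid$shape,
                   grid$spacing, 26L)
  } else {
    cpp_region_grow(pet$values, seeds, allowed, thr, grid$shape, 26L)
  }
  list(mask = binary_mask(array(grown, grid$shape), grid, mask$label),
       threshold = thr, note = "grown")
}

#' Adapt CT organ contours to the PET grid
#'
#' For each organ: nearest-neighbor resample the CT-grid contour to the PET
#' grid; compute a grow threshold as `threshold_fraction` times the 95th SUV
#' percentile inside it; take seeds as the contour eroded by `erosion_mm`
#' intersected with voxels at or above the threshold; grow 26-connected from
#' the seeds over suprathreshold voxels, never leaving the contour dilated
#' by `margin_mm`. An organ whose resampled contour is empty stays empty;
#' one with no seeds keeps the resampled contour and raises a warning.
#' Finally, voxels claimed by several organs are assigned to the organ where
#' the voxel's SUV is largest relative to that organ's 95th percentile, so
#' the returned set is disjoint.
#'
#' @param pet a PET [image_volume()] in SUV units.
#' @param organs an [organ_mask_set()] on the CT grid.
#' @param params a [transfer_params()].
#' @return `list(organs, thresholds)`: the adapted [organ_mask_set()] on the
#'   PET grid and the per-organ grow thresholds (SUV).
#' @export
transfer_contours <- function(pet, organs, params = transfer_params()) {
  stopifnot(inherits(pet, "image_volume"), inherits(organs, "organ_mask_set"),
            inherits(params, "transfer_params"))
  if (pet$modality != "PET") stop("pet must be a PET image_volume")
  out <- lapply(ORGAN_NAMES, function(nm) transfer_one(pet, organs[[nm]], params))
  names(out) <- ORGAN_NAMES
  masks <- lapply(out, `[[`, "mask")
  p95s <- vapply(out, function(o)
    if (is.na(o$threshold)) NA_real_ else o$threshold / params$threshold_fraction,
    numeric(1))

  # Disjointify: contested voxels go to the organ with the highest
  # SUV relative to that organ's own p95 (brighter organs don't swallow
  # their dimmer neighbors' boundary voxels).
  counts <- Reduce(`+`, lapply(masks, function(m) m$values + 0L))
  contested <- which(counts > 1L)
  if (length(contested)) {
    score <- matrix(-Inf, length(contested), length(ORGAN_NAMES))
    for (j in seq_along(ORGAN_NAMES)) {
      m <- masks[[j]]
      inm <- m$values[contested]
      score[inm, j] <- pet$values[contested[inm]] / p95s[j]
    }
    win <- max.col(score, ties.method = "first")
    for (j in seq_along(ORGAN_NAMES)) {
      drop <- contested[win != j]
      masks[[j]]$values[drop] <- FALSE
    }
  }
  set <- organ_mask_set(masks$brain, masks$heart, masks$kidney_left,
                        masks$kidney_right, masks$bladder)
  list(organs = set,
       thresholds = vapply(out, `[[`, numeric(1), "threshold"))
}

#' Analysis space for lesion quantification
#'
#' The voxels eligible to contain lesions: the whole PET volume (optionally
#' restricted to body voxels above `body_threshold` SUV) minus all adapted
#' organ masks.
#'
#' @param pet a PET [image_volume()].
#' @param organs an [organ_mask_set()] on the PET grid.
#' @param body_threshold SUV floor defining the body; the default 0 keeps
#'   every voxel.
#' @return A [binary_mask()] on the PET grid.
#' @export
analysis_space <- function(pet, organs, body_threshold = 0) {
  stopifnot(inherits(pet, "image_volume"), inherits(organs, "organ_mask_set"))
  if (!same_grid(pet$grid, organs$grid))
    stop("organs must live on the PET grid; run transfer_contours() first")
  keep <- pet$values >= body_threshold
  keep[organ_union(organs)] <- FALSE
  binary_mask(array(keep, pet$grid$shape), pet$grid, "analysis_space")
}
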