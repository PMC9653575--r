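# Metabolic tumor volume engine: trapezoid urinary exclusion zone, global
# 41%-of-SUVmax thresholding, 26-connected clustering, volume/zone
# screening, and the iterative re-thresholding loop that removes screened
# hottest clusters from the analysis space.

#' Configure MTV computation
#'
#' @param threshold_fraction lesion threshold as a fraction of the global
#'   SUVmax (default 0.41).
#' @param min_volume_cm3 clusters must be strictly larger than this to be
#'   candidates (default 1 cm^3).
#' @param screen_volume_cm3 candidates strictly smaller than this are
#'   screened out as too small to be reliable lesions (default 2 cm^3).
#' @param connectivity voxel connectivity for clustering (6, 18 or 26).
#' @param zone_fraction with the `"majority"` rule, a candidate is screened
#'   when more than this fraction of its voxels lies inside the exclusion
#'   zone.
#' @param zone_rule `"majority"`, `"any_overlap"` (one voxel suffices) or
#'   `"centroid"` (screen when the centroid falls in the zone).
#' @param max_iterations safety cap on the re-thresholding loop.
#' @return An object of class `mtv_params`.
#' @export
mtv_params <- function(threshold_fraction = 0.41, min_volume_cm3 = 1,
                       screen_volume_cm3 = 2, connectivity = 26L,
                       zone_fraction = 0.5,
                       zone_rule = c("majority", "any_overlap", "centroid"),
                       max_iterations = 100L) {
  zone_rule <- match.arg(zone_rule)
  stopifnot(threshold_fraction > 0, threshold_fraction < 1,
            min_volume_cm3 >= 0, screen_volume_cm3 >= min_volume_cm3,
            connectivity %in% c(6L, 18L, 26L),
            zone_fraction > 0, zone_fraction < 1, max_iterations >= 1)
  structure(list(threshold_fraction = threshold_fraction,
                 min_volume_cm3 = min_volume_cm3,
                 screen_volume_cm3 = screen_volume_cm3,
                 connectivity = as.integer(connectivity),
                 zone_fraction = zone_fraction, zone_rule = zone_rule,
                 max_iterations = as.integer(max_iterations)),
            class = "mtv_params")
}

axis_centers <- function(grid, ax) {
  grid$origin[ax] + (seq_len(grid$shape[ax]) - 1) * grid$spacing[ax]
}

mask_bbox <- function(values) {
  idx <- which(values, arr.ind = TRUE)
  if (nrow(idx) == 0) return(NULL)
  list(min = apply(idx, 2, min), max = apply(idx, 2, max),
       centroid = colMeans(idx))
}

#' Build the trapezoid urinary exclusion zone
#'
#' A per-slice rectangular prism interpolated between a top base at the
#' kidneys and a bottom base at the bladder: the top slice is the most
#' superior kidney voxel, the bottom slice the bladder's axial center
#' (rounded z-centroid). The top base spans x between the two kidney
#' x-centroids and y over the combined kidney y-extent; the bottom base is
#' the bladder's bounding rectangle in its central slice. The four bounds
#' are linearly interpolated on every slice in between, sweeping out the
#' trapezoid that tracks the ureters.
#'
#' @param organs an [organ_mask_set()] on the PET grid with non-empty
#'   kidneys and bladder.
#' @return An object of class `trapezoid_zone` with fields `mask` (a
#'   [binary_mask()]), slice range `z_top`/`z_bottom`, and the per-slice
#'   voxel-index `bounds` matrix (columns x0, x1, y0, y1).
#' @export
build_exclusion_zone <- function(organs) {
  stopifnot(inherits(organs, "organ_mask_set"))
  grid <- organs$grid
  kl <- mask_bbox(organs$kidney_left$values)
  kr <- mask_bbox(organs$kidney_right$values)
  bl <- mask_bbox(organs$bladder$values)
  if (is.null(kl) || is.null(kr) || is.null(bl))
    stop("exclusion zone needs both kidneys and the bladder to be non-empty")
  z_top <- max(kl$max[3], kr$max[3])
  z_bottom <- as.integer(round(bl$centroid[3]))
  if (z_bottom > z_top)
    stop("bladder center lies superior to the kidneys; cannot build the zone")
  top_x <- sort(c(kl$centroid[1], kr$centroid[1]))
  top_y <- c(min(kl$min[2], kr$min[2]), max(kl$max[2], kr$max[2]))
  bslice <- organs$bladder$values[, , z_bottom]
  bidx <- which(bslice, arr.ind = TRUE)
  bot_x <- range(bidx[, 1]); bot_y <- range(bidx[, 2])

  zs <- z_top:z_bottom
  frac <- if (length(zs) > 1) (z_top - zs) / (z_top - z_bottom) else 0
  bounds <- cbind(x0 = top_x[1] + frac * (bot_x[1] - top_x[1]),
                  x1 = top_x[2] + frac * (bot_x[2] - top_x[2]),
                  y0 = top_y[1] + frac * (bot_y[1] - top_y[1]),
                  y1 = top_y[2] + frac * (bot_y[2] - top_y[2]))
  rownames(bounds) <- zs
  mask <- array(FALSE, grid$shape)
  xi <- seq_len(grid$shape[1]); yi <- seq_len(grid$shape[2])
  for (i in seq_along(zs)) {
    mask[, , zs[i]] <- outer(xi >= bounds[i, "x0"] & xi <= bounds[i, "x1"],
                             yi >= bounds[i, "y0"] & yi <= bounds[i, "y1"],
                             `&`)
  }
  structure(list(mask = binary_mask(mask, grid, "exclusion_zone"),
                 z_top = as.integer(z_top), z_bottom = z_bottom,
                 bounds = bounds),
            class = "trapezoid_zone")
}

#' Global SUVmax over the analysis space
#'
#' @param pet a PET [image_volume()].
#' @param space a [binary_mask()] of analyzable voxels.
#' @return `list(suvmax, index)` where `index` is the linear voxel index of
#'   the maximum (ties broken by the smallest index).
#' @export
global_suvmax <- function(pet, space) {
  stopifnot(inherits(pet, "image_volume"), inherits(space, "binary_mask"))
  if (!same_grid(pet$grid, space$grid)) stop("pet and space grids differ")
  idx <- which(space$values)
  if (length(idx) == 0) stop("no analyzable voxels in the analysis space")
  v <- pet$values[idx]
  k <- which.max(v)  # which.max returns the first (smallest-index) maximum
  list(suvmax = v[k], index = idx[k])
}

#' Cluster suprathreshold voxels
#'
#' Voxels of `space` with SUV at or above `threshold` are grouped into
#' connected components.
#'
#' @param pet a PET [image_volume()].
#' @param space a [binary_mask()] of analyzable voxels.
#' @param threshold SUV cutoff (inclusive).
#' @param connectivity 6, 18 or 26.
#' @return A list of clusters, each `list(voxels, volume_cm3, suvmax,
#'   suvmax_index)`; `voxels` are linear indices.
#' @export
cluster_suprathreshold <- function(pet, space, threshold, connectivity = 26L) {
  stopifnot(inherits(pet, "image_volume"), inherits(space, "binary_mask"))
  sel <- space$values & (pet$values >= threshold)
  lab <- cpp_label_components(as.logical(sel), pet$grid$shape,
                              as.integer(connectivity))
  n <- max(lab)
  if (n == 0) return(list())
  vv <- voxel_volume_cm3(pet$grid)
  lapply(seq_len(n), function(i) {
    vox <- which(lab == i)
    v <- pet$values[vox]
    k <- which.max(v)
    list(voxels = vox, volume_cm3 = length(vox) * vv, suvmax = v[k],
         suvmax_index = vox[k])
  })
}

zone_overlap_fraction <- function(cluster, zone) {
  sum(zone$mask$values[cluster$voxels]) / length(cluster$voxels)
}

screen_one <- function(cluster, zone, params, grid) {
  if (cluster$volume_cm3 <= params$min_volume_cm3) return("not_candidate")
  if (cluster$volume_cm3 < params$screen_volume_cm3) return("screened_small")
  if (!is.null(zone)) {
    hit <- switch(params$zone_rule,
      majority = zone_overlap_fraction(cluster, zone) > params$zone_fraction,
      any_overlap = any(zone$mask$values[cluster$voxels]),
      centroid = {
        ai <- arrayInd(cluster$voxels, grid$shape)
        cz <- round(colMeans(ai))
        idx <- cz[1] + (cz[2] - 1) * grid$shape[1] +
          (cz[3] - 1) * grid$shape[1] * grid$shape[2]
        zone$mask$values[idx]
      })
    if (hit) return("screened_zone")
  }
  "retained"
}

#' Screen candidate clusters
#'
#' Applies the volume and exclusion-zone rules: clusters not strictly above
#' `min_volume_cm3` are non-candidates; candidates strictly below
#' `screen_volume_cm3` are screened as too small; candidates matching the
#' zone rule (by default, more than half their voxels in the zone) are
#' screened as urinary activity.
#'
#' @param clusters output of [cluster_suprathreshold()].
#' @param zone a `trapezoid_zone`, or `NULL` to skip zone screening.
#' @param params an [mtv_params()].
#' @param grid the PET [voxel_grid()].
#' @return `clusters` with a `status` field added: `"retained"`,
#'   `"not_candidate"`, `"screened_small"` or `"screened_zone"`.
#' @export
screen_candidates <- function(clusters, zone, params, grid) {
  lapply(clusters, function(cl) {
    cl$status <- screen_one(cl, zone, params, grid)
    cl
  })
}

#' Compute metabolic tumor volume
#'
#' Iterative global-threshold MTV: find the SUVmax over the analysis space,
#' threshold at `threshold_fraction * SUVmax`, cluster, and screen. If the
#' cluster containing the SUVmax voxel is screened out or is not a
#' candidate, its voxels are removed from the analysis space and the
#' procedure repeats with the new (lower) SUVmax. It stops when the hottest
#' cluster is retained, or the space empties. Retained clusters from the
#' final iteration are the lesions; MTV is their total volume.
#'
#' @param pet a PET [image_volume()].
#' @param space a [binary_mask()] of analyzable voxels (see
#'   [analysis_space()]).
#' @param zone a `trapezoid_zone` from [build_exclusion_zone()], or `NULL`.
#' @param params an [mtv_params()].
#' @return An object of class `mtv_result`: `mtv_cm3`, `suvmax` (max over
#'   retained lesions, `NA` if none), `global_suvmax` (first-iteration
#'   maximum), `threshold`, `lesions` (retained clusters), `n_lesions`, and
#'   a per-iteration `trace`.
#' @export
compute_mtv <- function(pet, space, zone = NULL, params = mtv_params()) {
  stopifnot(inherits(pet, "image_volume"), inherits(space, "binary_mask"),
            inherits(params, "mtv_params"))
  if (!same_grid(pet$grid, space$grid)) stop("pet and space grids differ")
  if (!is.null(zone)) {
    stopifnot(inherits(zone, "trapezoid_zone"))
    if (!same_grid(zone$mask$grid, pet$grid))
      stop("zone and pet grids differ")
  }
  space <- binary_mask(space$values, space$grid, space$label)
  trace <- list()
  first_suvmax <- NA_real_
  result <- NULL
  for (it in seq_len(params$max_iterations)) {
    if (!any(space$values)) break
    gm <- global_suvmax(pet, space)
    if (it == 1) first_suvmax <- gm$suvmax
    thr <- params$threshold_fraction * gm$suvmax
    clusters <- screen_candidates(
      cluster_suprathreshold(pet, space, thr, params$connectivity),
      zone, params, pet$grid)
    status <- vapply(clusters, `[[`, character(1), "status")
    hot <- which(vapply(clusters, function(cl)
      gm$index %in% cl$voxels, logical(1)))
    trace[[it]] <- list(iteration = it, suvmax = gm$suvmax, threshold = thr,
                        n_clusters = length(clusters),
                        statuses = table(factor(status, levels = c(
                          "retained", "not_candidate", "screened_small",
                          "screened_zone"))),
                        hot_status = if (length(hot)) status[hot] else NA_character_)
    if (length(hot) && status[hot] == "retained") {
      result <- clusters[status == "retained"]
      break
    }
    # Drop the disqualified hottest cluster (it always exists: the SUVmax
    # voxel is suprathreshold by construction) and re-threshold.
    space$values[clusters[[hot]]$voxels] <- FALSE
  }
  if (is.null(result)) result <- list()
  mtv <- sum(vapply(result, `[[`, numeric(1), "volume_cm3"))
  suvmax <- if (length(result))
    max(vapply(result, `[[`, numeric(1), "suvmax")) else NA_real_
  structure(list(mtv_cm3 = mtv, suvmax = suvmax,
                 global_suvmax = first_suvmax,
                 threshold = if (length(trace)) trace[[length(trace)]]$threshold else NA_real_,
                 lesions = result, n_lesions = length(result),
                 iterations = length(trace), trace = trace,
                 params = params),
            class = "mtv_result")
}

#' @export
print.mtv_result <- function(x, ...) {
  cat(sprintf("MTV result: %.2f cm^3 across %d lesion(s)\n", x$mtv_cm3,
              x$n_lesions))
  cat(sprintf("  SUVmax (lesions): %s   global SUVmax: %s\n",
              format(x$suvmax, digits = 4), format(x$global_suvmax, digits = 4)))
  cat(sprintf("  final threshold: %s SUV after %d iteration(s)\n",
              format(x$threshold, digits = 4), x$iterations))
  invisible(x)
}
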