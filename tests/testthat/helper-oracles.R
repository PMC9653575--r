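# Slow, obviously-correct reference implementations used to validate the
# fast production code paths.

# Nearest-neighbor mask resampling by looping over every target voxel.
oracle_resample <- function(mask, target) {
  out <- array(FALSE, target$shape)
  src <- mask$grid
  for (ix in seq_len(target$shape[1])) for (iy in seq_len(target$shape[2]))
    for (iz in seq_len(target$shape[3])) {
      w <- target$origin + (c(ix, iy, iz) - 1) * target$spacing
      j <- floor((w - src$origin) / src$spacing + 0.5) + 1
      if (all(j >= 1) && all(j <= src$shape))
        out[ix, iy, iz] <- mask$values[j[1], j[2], j[3]]
    }
  out
}

# Connected-component labeling by repeated flood fill over an explicit
# neighbor list.
oracle_components <- function(mask, connectivity = 26L) {
  dims <- dim(mask)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  d <- rowSums(abs(offs))
  offs <- switch(as.character(connectivity),
                 "6" = offs[d == 1, , drop = FALSE],
                 "18" = offs[d >= 1 & d <= 2, , drop = FALSE],
                 "26" = offs[d >= 1, , drop = FALSE])
  lab <- array(0L, dims)
  cur <- 0L
  for (i in which(mask)) {
    if (lab[i] != 0L) next
    cur <- cur + 1L
    queue <- matrix(arrayInd(i, dims), ncol = 3)
    lab[i] <- cur
    while (nrow(queue) > 0) {
      v <- queue[1, ]; queue <- queue[-1, , drop = FALSE]
      for (r in seq_len(nrow(offs))) {
        nb <- v + offs[r, ]
        if (any(nb < 1) || any(nb > dims)) next
        if (mask[nb[1], nb[2], nb[3]] && lab[nb[1], nb[2], nb[3]] == 0L) {
          lab[nb[1], nb[2], nb[3]] <- cur
          queue <- rbind(queue, nb)
        }
      }
    }
  }
  lab
}

# Normalize a component labeling so that label identity does not matter:
# the sorted list of sorted per-component voxel-index sets.
canonical_components <- function(lab) {
  comps <- split(which(lab > 0), lab[lab > 0])
  comps <- lapply(comps, sort)
  comps[order(vapply(comps, min, numeric(1)))]
}

random_mask_grid <- function(shape, p = 0.3) {
  voxel_grid(shape, spacing = runif(3, 1, 5), origin = runif(3, -10, 10))
}

# Independent R re-implementation of the full iterative MTV loop, written
# directly from the method description with no shared code, used as an
# oracle against compute_mtv().
oracle_mtv <- function(pet, space, zone_mask, params) {
  vv <- prod(pet$grid$spacing) / 1000
  space <- space$values
  repeat {
    idx <- which(space)
    if (length(idx) == 0) return(list(mtv = 0, lesions = list()))
    suvmax <- max(pet$values[idx])
    thr <- params$threshold_fraction * suvmax
    sel <- array(space & pet$values >= thr, pet$grid$shape)
    lab <- oracle_components(sel, params$connectivity)
    comps <- canonical_components(lab)
    status <- vapply(comps, function(vox) {
      vol <- length(vox) * vv
      if (vol <= params$min_volume_cm3) return("not_candidate")
      if (vol < params$screen_volume_cm3) return("screened_small")
      if (!is.null(zone_mask) &&
          mean(zone_mask[vox]) > params$zone_fraction) return("screened_zone")
      "retained"
    }, character(1))
    hot_idx <- idx[which.max(pet$values[idx])]
    hot <- which(vapply(comps, function(vox) hot_idx %in% vox, logical(1)))
    if (status[hot] == "retained")
      return(list(mtv = sum(lengths(comps[status == "retained"])) * vv,
                  lesions = comps[status == "retained"]))
    space[comps[[hot]]] <- FALSE
  }
}
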