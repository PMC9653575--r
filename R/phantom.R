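# Synthetic whole-body FDG-PET/CT phantom: ellipsoidal avid organs, optional
# ureter-like streaks, spherical lesions of known voxelized volume, optional
# PSF blur and noise. Ground truth (organ and lesion masks, total MTV) is
# defined on the pre-blur, pre-noise voxelization.

#' Specify an ellipsoidal organ for the phantom
#'
#' @param name one of `"brain"`, `"heart"`, `"kidney_left"`,
#'   `"kidney_right"`, `"bladder"`.
#' @param center_mm world coordinates (mm) of the ellipsoid center.
#' @param radii_mm semi-axes in mm (all > 0).
#' @param hu CT intensity inside the organ (Hounsfield units).
#' @param suv PET uptake inside the organ (SUV).
#' @return An object of class `organ_spec`.
#' @export
organ_spec <- function(name, center_mm, radii_mm, hu, suv) {
  stopifnot(name %in% ORGAN_NAMES, length(center_mm) == 3,
            length(radii_mm) == 3, all(radii_mm > 0), suv >= 0)
  structure(list(name = name, center = as.numeric(center_mm),
                 radii = as.numeric(radii_mm), hu = hu, suv = suv),
            class = "organ_spec")
}

#' Specify a spherical lesion for the phantom
#'
#' @param center_mm world coordinates (mm) of the sphere center.
#' @param radius_mm sphere radius in mm (> 0).
#' @param suv PET uptake inside the lesion; must exceed the background.
#' @return An object of class `lesion_spec`.
#' @export
lesion_spec <- function(center_mm, radius_mm, suv) {
  stopifnot(length(center_mm) == 3, radius_mm > 0, suv > 0)
  structure(list(center = as.numeric(center_mm), radius = radius_mm,
                 suv = suv), class = "lesion_spec")
}

default_organs <- function() {
  list(
    brain = organ_spec("brain", c(190, 190, 570), c(55, 65, 50), 40, 7),
    heart = organ_spec("heart", c(175, 185, 420), c(50, 55, 45), 55, 5),
    kidney_left = organ_spec("kidney_left", c(130, 210, 300), c(22, 28, 45), 45, 6),
    kidney_right = organ_spec("kidney_right", c(250, 210, 300), c(22, 28, 45), 45, 6),
    bladder = organ_spec("bladder", c(190, 230, 120), c(30, 30, 28), 5, 6)
  )
}

#' Specify a whole-body phantom
#'
#' Defaults give a 96 x 96 x 160 grid at 4 mm isotropic spacing spanning
#' roughly skull to thighs: a body envelope (head, neck and torso of
#' soft tissue, derived from the organ geometry) surrounded by air, the five
#' avid organs, and ureter streaks from the renal pelves to the bladder.
#' Inside the body the tracer background is `background_suv`; outside it is
#' `air_suv`. Ground-truth masks are always the pre-blur, pre-noise
#' voxelizations.
#'
#' @param grid a [voxel_grid()].
#' @param background_suv tracer uptake of non-avid tissue inside the body
#'   (SUV).
#' @param background_hu CT intensity of non-avid soft tissue inside the
#'   body.
#' @param air_hu,air_suv CT intensity and tracer uptake outside the body.
#' @param organs named list of five [organ_spec()]s.
#' @param lesions list of [lesion_spec()]s; must not overlap organs or each
#'   other.
#' @param ureters `TRUE` to draw two tube-like streaks of urinary activity
#'   from the kidneys' inferior poles to the bladder.
#' @param ureter_radius_mm,ureter_suv geometry and uptake of the streaks.
#' @param context_tissues `TRUE` to paint the high-contrast context tissues
#'   that surround the avid organs on real CT (skull shell around the brain,
#'   lungs flanking the heart, fat capsules around kidneys and bladder).
#'   They are painted before the organs and never alter the ground truth.
#' @param blur_fwhm_mm Gaussian PSF full width at half maximum in mm applied
#'   to the PET volume (0 = none).
#' @param noise_sd_suv additive Gaussian noise SD in SUV on PET (0 = none);
#'   values are clamped at 0.
#' @param ct_noise_sd_hu additive Gaussian noise SD on CT (0 = none).
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid = voxel_grid(c(96, 96, 160), c(4, 4, 4)),
                         background_suv = 1, background_hu = 30,
                         air_hu = -100, air_suv = 0.05,
                         organs = default_organs(), lesions = list(),
                         ureters = TRUE, ureter_radius_mm = 4,
                         ureter_suv = 4, context_tissues = TRUE,
                         blur_fwhm_mm = 0, noise_sd_suv = 0,
                         ct_noise_sd_hu = 0) {
  stopifnot(inherits(grid, "voxel_grid"), background_suv >= 0, air_suv >= 0,
            air_suv < background_suv, air_hu < background_hu,
            blur_fwhm_mm >= 0, noise_sd_suv >= 0, ct_noise_sd_hu >= 0)
  if (!setequal(names(organs), ORGAN_NAMES))
    stop("organs must be a named list covering exactly: ",
         paste(ORGAN_NAMES, collapse = ", "))
  for (o in organs) stopifnot(inherits(o, "organ_spec"))
  for (l in lesions) {
    stopifnot(inherits(l, "lesion_spec"))
    if (l$suv <= background_suv)
      stop("lesion uptake must exceed the background uptake")
  }
  kl <- organs$kidney_left; kr <- organs$kidney_right; bl <- organs$bladder
  if (!(kl$center[1] < kr$center[1]))
    stop("left kidney center must have smaller x than right kidney center")
  if (!(min(kl$center[3], kr$center[3]) > bl$center[3]))
    stop("kidneys must be superior (larger z) to the bladder center")
  ext <- grid_extent(grid)
  for (o in organs)
    if (any(o$center - o$radii < ext[1, ]) || any(o$center + o$radii > ext[2, ]))
      stop("organ ", o$name, " does not fit inside the grid")
  structure(list(grid = grid, background_suv = background_suv,
                 background_hu = background_hu, air_hu = air_hu,
                 air_suv = air_suv, organs = organs,
                 lesions = lesions, ureters = ureters,
                 ureter_radius_mm = ureter_radius_mm, ureter_suv = ureter_suv,
                 context_tissues = isTRUE(context_tissues),
                 blur_fwhm_mm = blur_fwhm_mm, noise_sd_suv = noise_sd_suv,
                 ct_noise_sd_hu = ct_noise_sd_hu),
            class = "phantom_spec")
}

# world-coordinate axes of voxel centers
grid_axes <- function(grid) {
  lapply(1:3, function(ax)
    grid$origin[ax] + (seq_len(grid$shape[ax]) - 1) * grid$spacing[ax])
}

rasterize_ellipsoid <- function(grid, center, radii) {
  ax <- grid_axes(grid)
  dx2 <- ((ax[[1]] - center[1]) / radii[1])^2
  dy2 <- ((ax[[2]] - center[2]) / radii[2])^2
  dz2 <- ((ax[[3]] - center[3]) / radii[3])^2
  outer(outer(dx2, dy2, `+`), dz2, `+`) <= 1
}

# capsule: all voxels within radius r of the segment a-b (world mm)
rasterize_capsule <- function(grid, a, b, r) {
  ax <- grid_axes(grid)
  out <- array(FALSE, grid$shape)
  lo <- pmin(a, b) - r; hi <- pmax(a, b) + r
  ix <- which(ax[[1]] >= lo[1] & ax[[1]] <= hi[1])
  iy <- which(ax[[2]] >= lo[2] & ax[[2]] <= hi[2])
  iz <- which(ax[[3]] >= lo[3] & ax[[3]] <= hi[3])
  if (!length(ix) || !length(iy) || !length(iz)) return(out)
  g <- expand.grid(x = ax[[1]][ix], y = ax[[2]][iy], z = ax[[3]][iz])
  ab <- b - a
  len2 <- sum(ab^2)
  px <- g$x - a[1]; py <- g$y - a[2]; pz <- g$z - a[3]
  t <- if (len2 > 0) pmin(pmax((px * ab[1] + py * ab[2] + pz * ab[3]) / len2, 0), 1) else 0
  d2 <- (px - t * ab[1])^2 + (py - t * ab[2])^2 + (pz - t * ab[3])^2
  sub <- array(d2 <= r^2, c(length(ix), length(iy), length(iz)))
  out[ix, iy, iz] <- sub
  out
}

# Body envelope derived from the (possibly jittered) organ geometry: a head
# ellipsoid around the brain, a torso ellipsoid enclosing heart, kidneys and
# bladder with generous soft-tissue margins, and a neck capsule joining
# them. The envelope gives the CT anatomical context (body outline against
# air) that real scans have.
body_geometry <- function(organs) {
  br <- organs$brain
  torso_organs <- organs[c("heart", "kidney_left", "kidney_right", "bladder")]
  xc <- mean(vapply(torso_organs, function(o) o$center[1], numeric(1)))
  yc <- mean(vapply(torso_organs, function(o) o$center[2], numeric(1)))
  z_top <- organs$heart$center[3] + organs$heart$radii[3] + 70
  z_bot <- organs$bladder$center[3] - organs$bladder$radii[3] - 40
  rx <- max(vapply(torso_organs, function(o)
    abs(o$center[1] - xc) + o$radii[1], numeric(1))) + 25
  ry <- max(vapply(torso_organs, function(o)
    abs(o$center[2] - yc) + o$radii[2], numeric(1))) + 25
  list(head = list(center = br$center, radii = br$radii + 18),
       torso = list(center = c(xc, yc, (z_top + z_bot) / 2),
                    radii = c(rx, ry, (z_top - z_bot) / 2)),
       neck = list(from = br$center, to = c(xc, yc, z_top), radius = 30))
}

rasterize_body <- function(grid, organs) {
  b <- body_geometry(organs)
  rasterize_ellipsoid(grid, b$head$center, b$head$radii) |
    rasterize_ellipsoid(grid, b$torso$center, b$torso$radii) |
    rasterize_capsule(grid, b$neck$from, b$neck$to, b$neck$radius)
}

# High-contrast context tissues surrounding the avid organs, mirroring the
# interfaces that make the organs identifiable on real CT: a bony skull
# shell around the brain, air-density lungs flanking the heart, and fat
# capsules around the kidneys and the bladder. All are clipped to the body
# envelope and painted before the organs, so the ground-truth masks are
# unaffected.
CONTEXT_TISSUES <- list(bone = list(hu = 800, suv = 0.3),
                        lung = list(hu = -750, suv = 0.2),
                        fat = list(hu = -90, suv = 0.3))

rasterize_context <- function(grid, organs, body) {
  br <- organs$brain; ht <- organs$heart
  skull <- rasterize_ellipsoid(grid, br$center, br$radii + 8) &
    !rasterize_ellipsoid(grid, br$center, br$radii + 2)
  lung_r <- c(0.9 * ht$radii[1], 1.1 * ht$radii[2], 1.6 * ht$radii[3])
  dx <- ht$radii[1] + 0.55 * lung_r[1]
  lungs <- rasterize_ellipsoid(grid, ht$center + c(-dx, 0, 0.3 * ht$radii[3]),
                               lung_r) |
    rasterize_ellipsoid(grid, ht$center + c(dx, 0, 0.3 * ht$radii[3]), lung_r)
  fat <- array(FALSE, grid$shape)
  for (nm in c("kidney_left", "kidney_right", "bladder")) {
    o <- organs[[nm]]
    pad <- if (nm == "bladder") 12 else 10
    fat <- fat | rasterize_ellipsoid(grid, o$center, o$radii + pad)
  }
  list(bone = skull & body, lung = lungs & body, fat = fat & body)
}

ureter_path <- function(organs) {
  bl <- organs$bladder
  entry <- c(bl$center[1], bl$center[2], bl$center[3] + bl$radii[3] + 2)
  lapply(c("kidney_left", "kidney_right"), function(nm) {
    k <- organs[[nm]]
    medial <- if (k$center[1] < bl$center[1]) 1 else -1
    pelvis <- c(k$center[1] + medial * 0.6 * k$radii[1], k$center[2],
                k$center[3] - 0.6 * k$radii[3])
    list(from = pelvis, to = entry)
  })
}

#' Generate a synthetic paired CT/PET phantom case
#'
#' Rasterizes the spec onto its grid; applies PSF blur and noise to the PET
#' volume after the ground-truth masks are taken, so `truth_mtv_cm3` always
#' equals the voxelized lesion volume sum. Identical `(spec, seed)` give a
#' bit-identical case.
#'
#' @param spec a [phantom_spec()].
#' @param seed integer RNG seed for the noise draws.
#' @return An object of class `phantom_case` with elements `ct`, `pet`
#'   ([image_volume()]s), `body` (the body-envelope [binary_mask()]),
#'   `truth_organs` ([organ_mask_set()]),
#'   `truth_lesions` (list of [binary_mask()]), `truth_mtv_cm3`,
#'   `truth_suvmax` (hottest lesion uptake, `NA` if no lesions), `spec`, and
#'   `seed`.
#' @export
generate_phantom <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "phantom_spec"))
  grid <- spec$grid
  vv <- voxel_volume_cm3(grid)
  organ_masks <- lapply(spec$organs, function(o)
    rasterize_ellipsoid(grid, o$center, o$radii))
  lesion_masks <- lapply(spec$lesions, function(l)
    rasterize_ellipsoid(grid, l$center, rep(l$radius, 3)))
  org_union <- Reduce(`|`, organ_masks, array(FALSE, grid$shape))
  les_acc <- array(0L, grid$shape)
  for (i in seq_along(lesion_masks)) {
    if (any(lesion_masks[[i]] & org_union))
      stop("lesion ", i, " overlaps an organ; ground truth would be ambiguous")
    les_acc <- les_acc + lesion_masks[[i]]
  }
  if (any(les_acc > 1L)) stop("lesions overlap each other")

  body <- rasterize_body(grid, spec$organs)
  for (nm in ORGAN_NAMES)
    if (any(organ_masks[[nm]] & !body))
      stop("organ ", nm, " pokes outside the body envelope")
  for (i in seq_along(lesion_masks))
    if (any(lesion_masks[[i]] & !body))
      stop("lesion ", i, " lies outside the body envelope")

  ct <- array(spec$air_hu, grid$shape)
  pet <- array(spec$air_suv, grid$shape)
  ct[body] <- spec$background_hu
  pet[body] <- spec$background_suv
  if (isTRUE(spec$context_tissues)) {
    ctx <- rasterize_context(grid, spec$organs, body)
    for (nm in names(ctx)) {
      keep <- ctx[[nm]] & !org_union
      ct[keep] <- CONTEXT_TISSUES[[nm]]$hu
      pet[keep] <- CONTEXT_TISSUES[[nm]]$suv
    }
  }
  for (nm in ORGAN_NAMES) {
    o <- spec$organs[[nm]]
    ct[organ_masks[[nm]]] <- o$hu
    pet[organ_masks[[nm]]] <- o$suv
  }
  if (isTRUE(spec$ureters)) {
    for (p in ureter_path(spec$organs)) {
      tube <- rasterize_capsule(grid, p$from, p$to, spec$ureter_radius_mm)
      pet[tube] <- pmax(pet[tube], spec$ureter_suv)
    }
  }
  for (i in seq_along(lesion_masks))
    pet[lesion_masks[[i]]] <- spec$lesions[[i]]$suv

  set.seed(seed)
  if (spec$ct_noise_sd_hu > 0)
    ct <- ct + array(rnorm(length(ct), 0, spec$ct_noise_sd_hu), dim(ct))
  if (spec$blur_fwhm_mm > 0) {
    sigma_vox <- (spec$blur_fwhm_mm / 2.3548) / grid$spacing
    pet <- cpp_gaussian_blur3d(pet, grid$shape, sigma_vox)
  }
  if (spec$noise_sd_suv > 0)
    pet <- pet + array(rnorm(length(pet), 0, spec$noise_sd_suv), dim(pet))
  pet <- pmax(pet, 0)
  dim(pet) <- grid$shape

  truth_organs <- do.call(organ_mask_set, lapply(ORGAN_NAMES, function(nm)
    binary_mask(organ_masks[[nm]], grid, nm)))
  truth_lesions <- lapply(seq_along(lesion_masks), function(i)
    binary_mask(lesion_masks[[i]], grid, paste0("lesion_", i)))
  truth_mtv <- sum(vapply(truth_lesions, mask_volume_cm3, numeric(1)))
  truth_suvmax <- if (length(spec$lesions))
    max(vapply(spec$lesions, function(l) l$suv, numeric(1))) else NA_real_
  structure(list(ct = image_volume(ct, grid, "CT"),
                 pet = image_volume(pet, grid, "PET"),
                 body = binary_mask(body, grid, "body"),
                 truth_organs = truth_organs, truth_lesions = truth_lesions,
                 truth_mtv_cm3 = truth_mtv, truth_suvmax = truth_suvmax,
                 spec = spec, seed = seed),
            class = "phantom_case")
}

#' Variation ranges for cohort generation
#'
#' @param lesion_count integer range `c(lo, hi)` of lesions per case.
#' @param lesion_radius_mm radius range in mm.
#' @param lesion_suv uptake range in SUV.
#' @param organ_jitter_mm uniform per-axis organ-center jitter half-width in
#'   mm.
#' @param avoid_zone keep lesion centers clear of the urinary corridor
#'   between the kidneys and the bladder (emulates nodal/extranodal disease
#'   away from the urinary tract so the generated truth is unambiguous).
#' @return An object of class `cohort_variation`.
#' @export
cohort_variation <- function(lesion_count = c(1, 5),
                             lesion_radius_mm = c(8, 20),
                             lesion_suv = c(7, 12),
                             organ_jitter_mm = 8,
                             avoid_zone = TRUE) {
  stopifnot(length(lesion_count) == 2, length(lesion_radius_mm) == 2,
            length(lesion_suv) == 2)
  if (lesion_count[1] > lesion_count[2] || lesion_count[1] < 0 ||
      lesion_radius_mm[1] > lesion_radius_mm[2] || lesion_radius_mm[1] <= 0 ||
      lesion_suv[1] > lesion_suv[2] || lesion_suv[1] <= 0 ||
      organ_jitter_mm < 0)
    stop("degenerate variation ranges")
  structure(list(lesion_count = as.integer(lesion_count),
                 lesion_radius_mm = lesion_radius_mm,
                 lesion_suv = lesion_suv, organ_jitter_mm = organ_jitter_mm,
                 avoid_zone = avoid_zone),
            class = "cohort_variation")
}

# frustum membership test in world mm, mirroring the trapezoid exclusion
# zone: linear interpolation between the kidney midlines/extents at the top
# and the bladder extents at its central plane
in_urinary_corridor <- function(p, organs, margin) {
  kl <- organs$kidney_left; kr <- organs$kidney_right; bl <- organs$bladder
  z_top <- max(kl$center[3] + kl$radii[3], kr$center[3] + kr$radii[3])
  z_bot <- bl$center[3]
  if (p[3] > z_top + margin || p[3] < z_bot - margin) return(FALSE)
  t <- if (z_top > z_bot) (p[3] - z_bot) / (z_top - z_bot) else 1
  t <- min(max(t, 0), 1)
  x_top <- c(kl$center[1], kr$center[1])
  y_top <- c(min(kl$center[2] - kl$radii[2], kr$center[2] - kr$radii[2]),
             max(kl$center[2] + kl$radii[2], kr$center[2] + kr$radii[2]))
  x_bot <- c(bl$center[1] - bl$radii[1], bl$center[1] + bl$radii[1])
  y_bot <- c(bl$center[2] - bl$radii[2], bl$center[2] + bl$radii[2])
  xb <- x_bot + t * (x_top - x_bot)
  yb <- y_bot + t * (y_top - y_bot)
  p[1] >= xb[1] - margin && p[1] <= xb[2] + margin &&
    p[2] >= yb[1] - margin && p[2] <= yb[2] + margin
}

jitter_organs <- function(organs, jitter_mm) {
  if (jitter_mm <= 0) return(organs)
  out <- lapply(organs, function(o) {
    o$center <- o$center + runif(3, -jitter_mm, jitter_mm)
    o
  })
  names(out) <- names(organs)
  out
}

sample_lesions <- function(spec, var, max_tries = 2000) {
  n <- if (var$lesion_count[1] == var$lesion_count[2]) var$lesion_count[1]
       else sample(seq(var$lesion_count[1], var$lesion_count[2]), 1)
  ext <- grid_extent(spec$grid)
  lo <- ext[1, ] + 20; hi <- ext[2, ] - 20
  body <- body_geometry(spec$organs)
  inside_body <- function(c_, r) {
    # require the whole sphere inside the head or torso ellipsoid
    any(vapply(body[c("head", "torso")], function(e) {
      shrunk <- e$radii - (r + 4)
      all(shrunk > 0) && sum(((c_ - e$center) / shrunk)^2) <= 1
    }, logical(1)))
  }
  placed <- list()
  for (i in seq_len(n)) {
    r <- runif(1, var$lesion_radius_mm[1], var$lesion_radius_mm[2])
    suv <- runif(1, var$lesion_suv[1], var$lesion_suv[2])
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      c_ <- c(runif(1, lo[1] + r, hi[1] - r), runif(1, lo[2] + r, hi[2] - r),
              runif(1, lo[3] + r, hi[3] - r))
      clear <- inside_body(c_, r)
      if (clear) for (o in spec$organs) {
        if (sum(((c_ - o$center) / (o$radii + r + 6))^2) <= 1) { clear <- FALSE; break }
      }
      if (clear && isTRUE(var$avoid_zone) &&
          in_urinary_corridor(c_, spec$organs, r + 10)) clear <- FALSE
      if (clear) for (p in placed)
        if (sqrt(sum((c_ - p$center)^2)) < r + p$radius + 6) { clear <- FALSE; break }
      if (clear) { placed[[length(placed) + 1]] <- lesion_spec(c_, r, suv); ok <- TRUE; break }
    }
    if (!ok) stop("could not place lesion ", i, " after ", max_tries, " tries")
  }
  placed
}

#' Generate a reproducible cohort of phantom cases
#'
#' Each case draws an independent lesion configuration (count, size, uptake,
#' position) and jittered organ geometry from `variation`, around
#' `base_spec`. With a fixed seed the cohort is bit-reproducible.
#'
#' @param base_spec a [phantom_spec()]; its lesion list is replaced by the
#'   sampled configurations.
#' @param n number of cases (>= 1).
#' @param variation a [cohort_variation()].
#' @param seed integer RNG seed.
#' @return A list of `n` `phantom_case` objects.
#' @export
generate_cohort <- function(base_spec, n, variation = cohort_variation(),
                            seed = 1L) {
  stopifnot(inherits(base_spec, "phantom_spec"),
            inherits(variation, "cohort_variation"))
  if (!is.numeric(n) || length(n) != 1 || n < 1)
    stop("n must be a positive integer")
  map_cohort(base_spec, n, identity, variation = variation, seed = seed)
}

#' Stream over a synthetic cohort
#'
#' Generates the same cases as [generate_cohort()] (identical seeds and
#' sampling order) but applies `fn` to each case as it is produced and keeps
#' only `fn`'s return value, so a whole cohort of full volumes is never held
#' in memory at once.
#'
#' @param base_spec,n,variation,seed as in [generate_cohort()].
#' @param fn a function of one `phantom_case`.
#' @return `list` of the `n` values of `fn`.
#' @export
map_cohort <- function(base_spec, n, fn, variation = cohort_variation(),
                       seed = 1L) {
  stopifnot(inherits(base_spec, "phantom_spec"),
            inherits(variation, "cohort_variation"), is.function(fn))
  if (!is.numeric(n) || length(n) != 1 || n < 1)
    stop("n must be a positive integer")
  n <- as.integer(n)
  set.seed(seed)
  case_seeds <- sample.int(.Machine$integer.max, n)
  lapply(seq_len(n), function(i) {
    set.seed(case_seeds[i])
    spec <- base_spec
    spec$organs <- jitter_organs(base_spec$organs, variation$organ_jitter_mm)
    spec$lesions <- sample_lesions(spec, variation)
    case <- generate_phantom(spec, seed = case_seeds[i])
    case$id <- i
    fn(case)
  })
}

#' Write a phantom case to disk
#'
#' Writes `ct.nii.gz`, `pet.nii.gz`, `organs.nii.gz` (label map),
#' `lesions.nii.gz` (one label per lesion), and a `truth.json` sidecar with
#' lesion volumes, total MTV, seed, and the spec echo.
#'
#' @param case a `phantom_case`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_phantom_case <- function(case, dir) {
  stopifnot(inherits(case, "phantom_case"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_volume(case$ct, file.path(dir, "ct.nii.gz"))
  write_volume(case$pet, file.path(dir, "pet.nii.gz"))
  write_organ_masks(case$truth_organs, file.path(dir, "organs.nii.gz"))
  lab <- array(0L, case$pet$grid$shape)
  for (i in seq_along(case$truth_lesions)) lab[case$truth_lesions[[i]]$values] <- i
  RNifti::writeNifti(nifti_with_grid(lab, case$pet$grid),
                     file.path(dir, "lesions.nii.gz"))
  truth <- list(
    truth_mtv_cm3 = case$truth_mtv_cm3,
    truth_suvmax = case$truth_suvmax,
    lesion_volumes_cm3 = vapply(case$truth_lesions, mask_volume_cm3, numeric(1)),
    seed = case$seed,
    spec = list(shape = case$spec$grid$shape, spacing = case$spec$grid$spacing,
                background_suv = case$spec$background_suv,
                blur_fwhm_mm = case$spec$blur_fwhm_mm,
                noise_sd_suv = case$spec$noise_sd_suv,
                lesions = lapply(case$spec$lesions, unclass))
  )
  jsonlite::write_json(truth, file.path(dir, "truth.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}
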