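
# A clean two-grid scene: CT grid at 2 mm, PET grid at 4 mm, one bright
# "organ" blob per mask with uniform uptake.
transfer_scene <- function() {
  ct_grid <- voxel_grid(c(40L, 40L, 40L), c(2, 2, 2))
  pet_grid <- voxel_grid(c(20L, 20L, 20L), c(4, 4, 4))
  mk <- function(xs, ys, zs, label) {
    v <- array(FALSE, ct_grid$shape); v[xs, ys, zs] <- TRUE
    binary_mask(v, ct_grid, label)
  }
  organs <- organ_mask_set(
    brain = mk(16:26, 16:26, 30:38, "brain"),
    heart = mk(8:16, 8:16, 20:26, "heart"),
    kidney_left = mk(4:12, 22:30, 10:18, "kidney_left"),
    kidney_right = mk(28:36, 22:30, 10:18, "kidney_right"),
    bladder = mk(16:26, 16:26, 2:8, "bladder"))
  pet <- image_volume(array(1, pet_grid$shape), pet_grid, "PET")
  paint <- function(pet, mask, suv) {
    res <- resample_mask(mask, pet_grid)
    pet$values[res$values] <- suv
    pet
  }
  pet <- paint(pet, organs$brain, 7)
  pet <- paint(pet, organs$heart, 5)
  pet <- paint(pet, organs$kidney_left, 6)
  pet <- paint(pet, organs$kidney_right, 6)
  pet <- paint(pet, organs$bladder, 6)
  list(pet = pet, organs = organs, pet_grid = pet_grid, ct_grid = ct_grid)
}

test_that("transfer recovers uniform organs exactly on a clean scene", {
  sc <- transfer_scene()
  tr <- transfer_contours(sc$pet, sc$organs)
  for (nm in c("brain", "heart", "kidney_left", "kidney_right", "bladder")) {
    want <- resample_mask(sc$organs[[nm]], sc$pet_grid)
    expect_identical(tr$organs[[nm]]$values, want$values)
  }
  # thresholds are half the organ p95 = half the uniform uptake
  expect_equal(unname(tr$thresholds["brain"]), 3.5)
  expect_equal(unname(tr$thresholds["heart"]), 2.5)
})

test_that("transferred organs follow tracer spill-out within the margin", {
  sc <- transfer_scene()
  # uptake leaks one PET voxel beyond the heart contour in +x
  res <- resample_mask(sc$organs$heart, sc$pet_grid)
  idx <- which(res$values, arr.ind = TRUE)
  leak <- idx[idx[, 1] == max(idx[, 1]), , drop = FALSE]
  leak[, 1] <- leak[, 1] + 1
  sc$pet$values[leak] <- 5
  tr <- transfer_contours(sc$pet, sc$organs)
  expect_true(all(tr$organs$heart$values[res$values]))
  expect_true(all(tr$organs$heart$values[leak]))
  expect_gt(sum(tr$organs$heart$values), sum(res$values))
})

test_that("growth never escapes the safety margin", {
  sc <- transfer_scene()
  # a bright bridge from the heart to far away; growth must stop at margin
  sc$pet$values[, 3, 12] <- 5
  sc$pet$values[3, , 12] <- 5
  tr <- transfer_contours(sc$pet, sc$organs,
                          transfer_params(margin_mm = 8))
  allowed <- dilate_mask(resample_mask(sc$organs$heart, sc$pet_grid), 8)
  expect_true(all(allowed$values[tr$organs$heart$values]))
})

test_that("an organ with empty resampled contour stays empty", {
  sc <- transfer_scene()
  tiny <- sc$organs
  # brain mask entirely outside any PET voxel center mapping? simplest:
  # empty CT mask resamples to empty
  tiny$brain$values[] <- FALSE
  organs <- organ_mask_set(tiny$brain, tiny$heart, tiny$kidney_left,
                           tiny$kidney_right, tiny$bladder)
  tr <- transfer_contours(sc$pet, organs)
  expect_equal(sum(tr$organs$brain$values), 0)
  expect_true(is.na(tr$thresholds["brain"]))
})

test_that("cold organs fall back to the resampled contour with a warning", {
  sc <- transfer_scene()
  res <- resample_mask(sc$organs$bladder, sc$pet_grid)
  core <- erode_mask(res, 4)
  # bright rim, cold core: the organ p95 sets a threshold no seed can reach
  sc$pet$values[res$values] <- 10
  sc$pet$values[core$values] <- 0
  expect_warning(tr <- transfer_contours(sc$pet, sc$organs), "no seed")
  expect_identical(tr$organs$bladder$values, res$values)
})

test_that("contested voxels are assigned to exactly one organ", {
  sc <- transfer_scene()
  # move kidneys adjacent so their grown contours could overlap
  tr <- transfer_contours(sc$pet, sc$organs,
                          transfer_params(margin_mm = 40))
  counts <- tr$organs$kidney_left$values + tr$organs$kidney_right$values +
    tr$organs$heart$values + tr$organs$brain$values + tr$organs$bladder$values
  expect_true(all(counts <= 1))
})

test_that("fast marching mode reproduces the clean-scene recovery", {
  sc <- transfer_scene()
  tr <- transfer_contours(sc$pet, sc$organs,
                          transfer_params(mode = "fast_marching"))
  for (nm in c("heart", "bladder")) {
    want <- resample_mask(sc$organs[[nm]], sc$pet_grid)
    expect_identical(tr$organs[[nm]]$values, want$values)
  }
})

test_that("analysis_space removes organs and respects the body threshold", {
  sc <- transfer_scene()
  tr <- transfer_contours(sc$pet, sc$organs)
  sp <- analysis_space(sc$pet, tr$organs)
  expect_false(any(sp$values & petmtv:::organ_union(tr$organs)))
  expect_equal(sum(sp$values) + sum(petmtv:::organ_union(tr$organs)),
               prod(sc$pet_grid$shape))
  sp2 <- analysis_space(sc$pet, tr$organs, body_threshold = 2)
  expect_lt(sum(sp2$values), sum(sp$values))
  # grid mismatch is an error
  expect_error(analysis_space(sc$pet, sc$organs), "PET grid")
})

test_that("transfer on a clean phantom keeps organ uptake out of the space", {
  spec <- phantom_spec(grid = voxel_grid(c(48L, 48L, 64L), c(8, 8, 10)))
  case <- generate_phantom(spec, seed = 3)
  tr <- transfer_contours(case$pet, case$truth_organs)
  sp <- analysis_space(case$pet, tr$organs)
  # every organ voxel is excluded: remaining uptake is background/ureter only
  expect_lte(max(case$pet$values[sp$values]), spec$ureter_suv)
})
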