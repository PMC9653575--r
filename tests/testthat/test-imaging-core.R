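test_that("voxel_grid validates inputs and computes volume", {
  g <- voxel_grid(c(4, 5, 6), c(2, 3, 4), c(-1, 0, 1))
  expect_identical(g$shape, c(4L, 5L, 6L))
  expect_equal(voxel_volume_cm3(g), 2 * 3 * 4 / 1000)
  expect_error(voxel_grid(c(0, 5, 6), c(2, 3, 4)))
  expect_error(voxel_grid(c(4, 5, 6), c(2, -3, 4)))
  expect_error(voxel_grid(c(4, 5), c(2, 3, 4)))
})

test_that("image_volume enforces PET non-negativity and shape", {
  g <- voxel_grid(c(3, 3, 3), c(1, 1, 1))
  ok <- image_volume(array(1, c(3, 3, 3)), g, "PET")
  expect_s3_class(ok, "image_volume")
  expect_error(image_volume(array(-1, c(3, 3, 3)), g, "PET"),
               "non-negative")
  expect_error(image_volume(array(1, c(3, 3, 2)), g, "CT"))
  # CT may be negative (Hounsfield units)
  expect_s3_class(image_volume(array(-100, c(3, 3, 3)), g, "CT"),
                  "image_volume")
})

test_that("mask volume matches voxel count times voxel volume", {
  g <- voxel_grid(c(4, 4, 4), c(2, 2, 2.5))
  v <- array(FALSE, c(4, 4, 4)); v[1:2, 1, 1] <- TRUE
  m <- binary_mask(v, g, "m")
  expect_equal(mask_volume_cm3(m), 2 * (2 * 2 * 2.5) / 1000)
})

test_that("organ_mask_set rejects overlapping or mismatched masks", {
  g <- voxel_grid(c(4, 4, 4), c(1, 1, 1))
  mk <- function(ix, label) {
    v <- array(FALSE, c(4, 4, 4)); v[ix] <- TRUE
    binary_mask(v, g, label)
  }
  s <- organ_mask_set(mk(1, "brain"), mk(2, "heart"), mk(3, "kidney_left"),
                      mk(4, "kidney_right"), mk(5, "bladder"))
  expect_s3_class(s, "organ_mask_set")
  expect_error(organ_mask_set(mk(1, "brain"), mk(1, "heart"),
                              mk(3, "kidney_left"), mk(4, "kidney_right"),
                              mk(5, "bladder")),
               "disjoint")
})

test_that("to_suv is linear in activity and validates arguments", {
  g <- voxel_grid(c(2, 2, 2), c(1, 1, 1))
  act <- image_volume(array(1000, c(2, 2, 2)), g, "PET")
  s1 <- to_suv(act, injected_dose_bq = 7e7, body_weight_g = 70000)
  expect_equal(s1$values[1, 1, 1], 1000 * 70000 / 7e7)
  s2 <- to_suv(act, injected_dose_bq = 7e7, body_weight_g = 140000)
  expect_equal(s2$values, 2 * s1$values)
  expect_error(to_suv(act, injected_dose_bq = 7e7, body_weight_g = 0))
  expect_error(to_suv(act, injected_dose_bq = -1, body_weight_g = 70000))
})

test_that("NIfTI round-trip preserves values, spacing and origin", {
  g <- voxel_grid(c(5, 6, 7), c(1.5, 2, 2.5), c(-3, 4, 12))
  set.seed(9)
  vol <- image_volume(array(runif(5 * 6 * 7), c(5, 6, 7)), g, "PET")
  f <- tempfile(fileext = ".nii.gz")
  write_volume(vol, f)
  back <- read_volume(f, "PET")
  expect_equal(back$values, vol$values, tolerance = 1e-6)
  expect_equal(back$grid$spacing, g$spacing, tolerance = 1e-6)
  expect_equal(back$grid$origin, g$origin, tolerance = 1e-6)
  expect_identical(back$grid$shape, g$shape)
})

test_that("organ mask set survives a NIfTI label-map round trip", {
  g <- voxel_grid(c(6, 6, 6), c(2, 2, 2))
  mk <- function(ix, label) {
    v <- array(FALSE, c(6, 6, 6)); v[ix] <- TRUE
    binary_mask(v, g, label)
  }
  s <- organ_mask_set(mk(1:3, "brain"), mk(10:12, "heart"),
                      mk(30, "kidney_left"), mk(40, "kidney_right"),
                      mk(50:55, "bladder"))
  f <- tempfile(fileext = ".nii.gz")
  write_organ_masks(s, f)
  back <- read_organ_masks(f)
  for (nm in c("brain", "heart", "kidney_left", "kidney_right", "bladder"))
    expect_identical(back[[nm]]$values, s[[nm]]$values)
})

test_that("read_volume errors on missing files", {
  expect_error(read_volume(tempfile(fileext = ".nii.gz"), "PET"))
})

test_that("resample_mask matches the brute-force oracle on random grids", {
  set.seed(101)
  for (rep in 1:20) {
    src <- voxel_grid(sample(3:9, 3, replace = TRUE),
                      runif(3, 1, 5), runif(3, -5, 5))
    tgt <- voxel_grid(sample(3:9, 3, replace = TRUE),
                      runif(3, 1, 5), runif(3, -5, 5))
    m <- binary_mask(array(runif(prod(src$shape)) < 0.4, src$shape), src, "m")
    got <- tryCatch(resample_mask(m, tgt), error = function(e) e)
    if (inherits(got, "error")) {
      # only acceptable error: disjoint extents
      expect_match(conditionMessage(got), "overlap")
    } else {
      expect_identical(got$values, oracle_resample(m, tgt))
    }
  }
})

test_that("resample_mask onto the same grid is the identity", {
  g <- voxel_grid(c(7, 5, 4), c(2, 3, 1), c(1, 1, 1))
  set.seed(3)
  m <- binary_mask(array(runif(prod(g$shape)) < 0.5, g$shape), g, "m")
  expect_identical(resample_mask(m, g)$values, m$values)
})

test_that("dilation and erosion are monotone and approximately inverse-ordered", {
  g <- voxel_grid(c(11, 11, 11), c(2, 2, 2))
  v <- array(FALSE, c(11, 11, 11)); v[4:8, 4:8, 4:8] <- TRUE
  m <- binary_mask(v, g, "cube")
  d <- dilate_mask(m, 4)
  e <- erode_mask(m, 4)
  expect_true(all(m$values[e$values]))       # erosion shrinks
  expect_true(all(d$values[m$values]))       # dilation grows
  expect_true(sum(e$values) < sum(m$values))
  expect_true(sum(d$values) > sum(m$values))
  # eroding the dilation recovers at least the original cube
  ed <- erode_mask(d, 4)
  expect_true(all(ed$values[m$values]))
})
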