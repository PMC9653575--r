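# A tiny synthetic training world: 32 x 32 x 6 CT volumes with one bright
# square per organ-bearing slice, used for fast optimizer/interface checks.
toy_case <- function(seed) {
  set.seed(seed)
  g <- voxel_grid(c(32L, 32L, 6L), c(4, 4, 10))
  v <- array(rnorm(prod(g$shape), 0, 5), g$shape)
  lab <- array(0L, g$shape)
  v[8:16, 8:16, 2] <- 100; lab[8:16, 8:16, 2] <- 1L
  v[18:26, 18:26, 4] <- 60; lab[18:26, 18:26, 4] <- 2L
  list(ct = image_volume(v, g, "CT"), labels = lab)
}

test_that("unet_config validates and exposes the dilated preset", {
  cfg <- unet_config()
  expect_equal(cfg$n_classes, 6L)
  expect_equal(cfg$dilation, rep(1L, 5))
  expect_equal(unet_config(dilated_bottleneck = TRUE)$dilation,
               c(1L, 1L, 1L, 2L, 4L))
  expect_error(unet_config(dilation = c(1, 2)))
  expect_error(unet_config(n_classes = 1))
  expect_error(train_config(split = c(0.5, 0.2, 0.2)), "sum to 1")
})

test_that("model construction is seed-reproducible with a known size", {
  set.seed(11)
  a <- build_residual_unet(unet_config(base_channels = 4L))
  set.seed(11)
  b <- build_residual_unet(unet_config(base_channels = 4L))
  expect_equal(n_parameters(a), 131014)
  expect_gt(n_parameters(build_residual_unet(unet_config(base_channels = 8L))),
            n_parameters(a))
  x <- matrix(rnorm(32 * 32), 32)
  expect_identical(petmtv:::cpp_unet_predict(a$ptr, x),
                   petmtv:::cpp_unet_predict(b$ptr, x))
})

test_that("predictions are valid distributions and save/load round-trips", {
  set.seed(4)
  m <- build_residual_unet(unet_config(base_channels = 4L))
  x <- matrix(rnorm(32 * 32), 32)
  p <- petmtv:::cpp_unet_predict(m$ptr, x)
  expect_equal(dim(p), c(32, 32, 6))
  expect_true(all(p >= 0))
  expect_lt(max(abs(apply(p, c(1, 2), sum) - 1)), 1e-8)
  f <- tempfile(fileext = ".rds")
  save_unet(m, f)
  m2 <- load_unet(f)
  expect_identical(petmtv:::cpp_unet_predict(m2$ptr, x), p)
  expect_equal(m2$config, m$config)
})

test_that("preprocess_ct standardizes and clips as documented", {
  g <- voxel_grid(c(8L, 8L, 4L), c(4, 4, 4))
  set.seed(2)
  v <- array(runif(prod(g$shape), -100, 200), g$shape)
  pre <- preprocess_ct(image_volume(v, g, "CT"))
  expect_equal(mean(pre$values), 0, tolerance = 1e-12)
  expect_equal(sd(as.numeric(pre$values)), 1, tolerance = 1e-12)
  # clipping at 1%/99% of max: an extreme spike is pulled in
  v2 <- v; v2[1, 1, 1] <- 1e6
  pre2 <- preprocess_ct(image_volume(v2, g, "CT"))
  r2 <- v2 - min(v2)
  expect_lt(diff(range(pre2$values)) * sd(pmin(pmax(r2, 0.01 * max(r2)),
                                               0.99 * max(r2))),
            diff(range(v2)) * 1.0001)  # sanity: bounded after clipping
  expect_equal(max(table(pre2$values[c(1)])), 1)
  # percentile mode clips at the empirical quantiles
  pre3 <- preprocess_ct(image_volume(v2, g, "CT"), clip_mode = "percentile")
  expect_lt(diff(range(pre3$values)), diff(range(pre2$values)))
  # constant volume maps to zeros
  flat <- preprocess_ct(image_volume(array(7, g$shape), g, "CT"))
  expect_true(all(flat$values == 0))
})

test_that("dice_coefficient handles overlap, empties, and grid mismatch", {
  g <- voxel_grid(c(6L, 6L, 6L), c(1, 1, 1))
  a <- array(FALSE, g$shape); b <- a
  a[1:3, 1, 1] <- TRUE   # |A| = 3
  b[2:5, 1, 1] <- TRUE   # |B| = 4, overlap 2
  expect_equal(dice_coefficient(binary_mask(a, g, "a"), binary_mask(b, g, "b")),
               2 * 2 / (3 + 4))
  e <- binary_mask(array(FALSE, g$shape), g, "e")
  expect_equal(dice_coefficient(e, e), 1)
  g2 <- voxel_grid(c(6L, 6L, 6L), c(2, 2, 2))
  expect_error(dice_coefficient(binary_mask(a, g, "a"),
                                binary_mask(b, g2, "b")), "grid")
})

test_that("combined_loss is zero for a perfect prediction and validates", {
  H <- 4L; W <- 4L; K <- 3L
  labels <- matrix(sample(0:2, H * W, replace = TRUE), H)
  probs <- array(0, c(H, W, K))
  for (i in 1:H) for (j in 1:W) probs[i, j, labels[i, j] + 1] <- 1
  expect_lt(combined_loss(probs, labels), 1e-6)
  uni <- array(1 / K, c(H, W, K))
  expect_gt(combined_loss(uni, labels), combined_loss(probs, labels))
  # CE-only weight reproduces -mean(log p_true)
  expect_equal(combined_loss(uni, labels, weight = 1), log(K))
  bad <- probs; bad[1, 1, ] <- c(0.5, 0.2, 0.2)
  expect_error(combined_loss(bad, labels), "sum to 1")
  expect_error(combined_loss(probs[, , 1], labels))
})

test_that("augment_pair is exact at identity and swaps kidneys on flip", {
  x <- matrix(rnorm(32 * 32), 32)
  y <- matrix(0L, 32, 32); y[5:10, 20:25] <- 3L; y[20:24, 4:8] <- 5L
  a <- augment_pair(x, y, rotation_deg = 0, translation_vox = 0,
                    scale_range = c(1, 1), flip_prob = 0)
  expect_identical(a$slice, x)
  expect_identical(a$labels, y)
  b <- augment_pair(x, y, rotation_deg = 0, translation_vox = 0,
                    scale_range = c(1, 1), flip_prob = 1, seed = 9)
  expect_equal(b$slice, x[nrow(x):1, ])
  # left kidney label (3) becomes right kidney (4); bladder (5) unchanged
  expect_setequal(unique(as.integer(b$labels)), c(0L, 4L, 5L))
  # seeded draws are reproducible
  c1 <- augment_pair(x, y, seed = 31)
  c2 <- augment_pair(x, y, seed = 31)
  expect_identical(c1$slice, c2$slice)
  expect_identical(c1$params, c2$params)
})

test_that("a short training run reduces the loss on a toy problem", {
  cases <- lapply(1:4, toy_case)
  set.seed(21)
  model <- build_residual_unet(unet_config(base_channels = 4L))
  cfg <- train_config(max_epochs = 6, rotation_deg = 0, translation_mm = 0,
                      scale_range = c(1, 1), flip_prob = 0,
                      split = c(0.5, 0.25, 0.25), slices_per_volume = 2L,
                      background_slices = 1L, seed = 22)
  fit <- train_segmentation(model, cases, cfg)
  expect_length(fit$history$loss, 6)
  expect_lt(fit$history$loss[6], fit$history$loss[1])
  expect_named(fit$history$dice_test,
               c("brain", "heart", "kidney_left", "kidney_right", "bladder"))
  expect_equal(sort(unlist(fit$history$split, use.names = FALSE)), 1:4)
})

test_that("the learning-rate schedule is constant then geometric", {
  cfg <- train_config(max_epochs = 10, lr_init = 1e-3, lr_final = 1e-5,
                      lr_decay_start = 0.6)
  lr <- vapply(1:10, petmtv:::epoch_lr, numeric(1), cfg = cfg)
  expect_true(all(lr[1:6] == 1e-3))
  expect_equal(lr[10], 1e-5)
  # geometric: constant ratio over the decay segment
  ratios <- lr[8:10] / lr[7:9]
  expect_equal(max(ratios) - min(ratios), 0, tolerance = 1e-12)
})

test_that("fine_tune resets the head and can restrict the trainable scope", {
  cases <- lapply(1:2, toy_case)
  set.seed(33)
  model <- build_residual_unet(unet_config(base_channels = 4L))
  x <- matrix(rnorm(32 * 32), 32)
  p0 <- petmtv:::cpp_unet_predict(model$ptr, x)
  before <- petmtv:::cpp_unet_get_params(model$ptr)
  # max_epochs = 0: only the final layer is re-initialized
  r <- fine_tune(model, cases, train_config(max_epochs = 0, seed = 34))
  expect_false(identical(petmtv:::cpp_unet_predict(r$model$ptr, x), p0))
  after <- petmtv:::cpp_unet_get_params(r$model$ptr)
  # only the output layer differs after a bare reset
  expect_false(identical(before$outconv, after$outconv))
  expect_identical(before$enc, after$enc)
  expect_identical(before$dec, after$dec)
  # final_layer_only training leaves all convolution weights in the body
  # untouched (batch-norm running statistics are diagnostics and may move)
  base <- petmtv:::cpp_unet_get_params(r$model$ptr)
  r2 <- fine_tune(r$model, cases,
                  train_config(max_epochs = 1, trainable_scope = "final_layer_only",
                               rotation_deg = 0, translation_mm = 0,
                               scale_range = c(1, 1), flip_prob = 0,
                               slices_per_volume = 2L, background_slices = 0L,
                               seed = 35))
  after2 <- petmtv:::cpp_unet_get_params(r2$model$ptr)
  expect_false(identical(base$outconv, after2$outconv))
  for (lv in seq_along(base$enc)) {
    expect_identical(base$enc[[lv]]$c1, after2$enc[[lv]]$c1)
    expect_identical(base$enc[[lv]]$c2, after2$enc[[lv]]$c2)
  }
  # an all-layers epoch moves the body convolutions too
  r3 <- fine_tune(r2$model, cases,
                  train_config(max_epochs = 1, trainable_scope = "all_layers",
                               rotation_deg = 0, translation_mm = 0,
                               scale_range = c(1, 1), flip_prob = 0,
                               slices_per_volume = 2L, background_slices = 0L,
                               seed = 36))
  after3 <- petmtv:::cpp_unet_get_params(r3$model$ptr)
  expect_false(identical(after2$enc[[1]]$c1, after3$enc[[1]]$c1))
  # labels beyond the class count are rejected
  bad <- toy_case(1); bad$labels[1, 1, 1] <- 99L
  expect_error(fine_tune(model, list(bad), train_config(max_epochs = 0)),
               "class count")
})

test_that("segment_organs returns clean, disjoint masks on the CT grid", {
  set.seed(44)
  model <- build_residual_unet(unet_config(base_channels = 4L))
  g <- voxel_grid(c(32L, 32L, 4L), c(4, 4, 10))
  ct <- image_volume(array(rnorm(prod(g$shape), 30, 10), g$shape), g, "CT")
  for (post in c(TRUE, FALSE)) {
    seg <- segment_organs(model, ct, postprocess = post)
    expect_s3_class(seg, "organ_mask_set")
    total <- Reduce(`+`, lapply(seg, function(m) m$values + 0))
    expect_true(all(total <= 1))
    for (m in seg) expect_true(same_grid(m$grid, g))
  }
  seg <- segment_organs(model, ct, postprocess = TRUE)
  # postprocessed brain/heart/bladder are single connected components
  for (nm in c("brain", "heart", "bladder")) {
    v <- seg[[nm]]$values
    if (any(v)) {
      lab <- petmtv:::cpp_label_components(as.logical(v), g$shape, 26L)
      expect_equal(max(lab), 1)
    }
  }
  # kidneys: when both present, left centroid is left of right centroid
  kl <- seg$kidney_left$values; kr <- seg$kidney_right$values
  if (any(kl) && any(kr)) {
    expect_lt(mean(which(kl, arr.ind = TRUE)[, 1]),
              mean(which(kr, arr.ind = TRUE)[, 1]))
  }
})
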