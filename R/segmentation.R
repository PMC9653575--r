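# CT multi-organ segmentation: 2D dilated residual U-Net trained slice-wise
# on axial CT with a combined cross-entropy + soft-Dice objective, Adam, and
# affine augmentation; inference restacks per-slice argmax labels to 3D.

#' Configure the residual U-Net
#'
#' The encoder and decoder each consist of five residual cascades (two 3x3
#' convolutions per block with batch normalization and an identity or 1x1
#' shortcut). Downsampling is 2x2 max pooling, upsampling bilinear
#' interpolation, and encoder features are concatenated to the matching
#' decoder level (skip connections). Output is one channel per class at the
#' input resolution.
#'
#' @param n_classes number of output classes (5 organs + background = 6).
#' @param base_channels channel width of the first cascade; doubled per
#'   level.
#' @param dilation convolution dilation rate per level (length 5). The
#'   default is 1 everywhere; `dilated_bottleneck = TRUE` uses rates
#'   `c(1, 1, 1, 2, 4)` in the deepest cascades.
#' @param dilated_bottleneck convenience switch for the dilated preset.
#' @return An object of class `unet_config`.
#' @export
unet_config <- function(n_classes = 6L, base_channels = 8L,
                        dilation = NULL, dilated_bottleneck = FALSE) {
  if (is.null(dilation))
    dilation <- if (dilated_bottleneck) c(1L, 1L, 1L, 2L, 4L) else rep(1L, 5L)
  stopifnot(length(dilation) == 5, all(dilation >= 1), n_classes >= 2,
            base_channels >= 1)
  structure(list(n_classes = as.integer(n_classes),
                 base_channels = as.integer(base_channels),
                 dilation = as.integer(dilation)),
            class = "unet_config")
}

#' Configure training
#'
#' Defaults follow the reference schedule: Adam with weight decay `1e-4`,
#' learning rate initialized at `3e-4` and decayed to `3e-6` after about 60%
#' of the epochs (geometric interpolation over the remaining epochs), a
#' combined cross-entropy + Dice loss with equal weight, affine augmentation
#' (rotation, translation, scaling, flipping), and a 5:1:4
#' train:validation:test split.
#'
#' @param max_epochs maximum training epochs (0 is allowed and meaningful
#'   only for [fine_tune()], which then just resets the output layer).
#' @param lr_init,lr_final initial and final learning rates (> 0).
#' @param lr_decay_start fraction of `max_epochs` after which the decay
#'   begins.
#' @param weight_decay L2 penalty coupled into the Adam update.
#' @param loss_weight weight `w` of cross-entropy in
#'   `w * CE + (1 - w) * (1 - Dice)`.
#' @param rotation_deg,translation_mm,scale_range,flip_prob augmentation
#'   ranges; set all to zero/identity to disable.
#' @param split train:validation:test fractions (must sum to 1).
#' @param slices_per_volume,background_slices axial slices sampled per
#'   training volume (foreground slices picked evenly, plus random
#'   background slices).
#' @param trainable_scope `"all_layers"` or `"final_layer_only"` (used by
#'   [fine_tune()]).
#' @param seed RNG seed for shuffling, augmentation, and initialization.
#' @param verbose print per-epoch loss.
#' @return An object of class `train_config`.
#' @export
train_config <- function(max_epochs = 100L, lr_init = 3e-4, lr_final = 3e-6,
                         lr_decay_start = 0.6, weight_decay = 1e-4,
                         loss_weight = 0.5, rotation_deg = 10,
                         translation_mm = 8, scale_range = c(0.9, 1.1),
                         flip_prob = 0.5, split = c(5, 1, 4) / 10,
                         slices_per_volume = 8L, background_slices = 2L,
                         trainable_scope = c("all_layers", "final_layer_only"),
                         seed = 1L, verbose = FALSE) {
  trainable_scope <- match.arg(trainable_scope)
  stopifnot(lr_init > 0, lr_final > 0, max_epochs >= 0,
            lr_decay_start > 0, lr_decay_start <= 1,
            loss_weight >= 0, loss_weight <= 1, length(split) == 3)
  if (abs(sum(split) - 1) > 1e-8) stop("split fractions must sum to 1")
  structure(list(max_epochs = as.integer(max_epochs), lr_init = lr_init,
                 lr_final = lr_final, lr_decay_start = lr_decay_start,
                 weight_decay = weight_decay, loss_weight = loss_weight,
                 rotation_deg = rotation_deg, translation_mm = translation_mm,
                 scale_range = scale_range, flip_prob = flip_prob,
                 split = split, slices_per_volume = as.integer(slices_per_volume),
                 background_slices = as.integer(background_slices),
                 trainable_scope = trainable_scope, seed = seed,
                 verbose = isTRUE(verbose)),
            class = "train_config")
}

#' Build a residual U-Net model
#'
#' Weights are He-initialized from R's RNG, so `set.seed()` before the call
#' makes the build reproducible. In-plane input sizes must be divisible by
#' 16 (four pooling stages).
#'
#' @param config a [unet_config()].
#' @return An object of class `residual_unet` holding the model handle.
#' @export
build_residual_unet <- function(config = unet_config()) {
  stopifnot(inherits(config, "unet_config"))
  ptr <- cpp_unet_create(config$n_classes, config$base_channels,
                         config$dilation)
  structure(list(ptr = ptr, config = config), class = "residual_unet")
}

#' Number of trainable parameters of a model
#' @param model a `residual_unet`.
#' @return integer count of weights, biases, and batch-norm scales/shifts.
#' @export
n_parameters <- function(model) {
  stopifnot(inherits(model, "residual_unet"))
  cpp_unet_nparams(model$ptr)
}

#' Save / load model weights
#'
#' @param model a `residual_unet`.
#' @param path file path for the checkpoint (a serialized parameter list
#'   with the architecture configuration embedded).
#' @return `save_unet` returns `path` invisibly; `load_unet` returns a
#'   `residual_unet`.
#' @export
save_unet <- function(model, path) {
  stopifnot(inherits(model, "residual_unet"))
  params <- cpp_unet_get_params(model$ptr)
  saveRDS(list(config = model$config, params = params), path)
  invisible(path)
}

#' @rdname save_unet
#' @export
load_unet <- function(path) {
  obj <- readRDS(path)
  model <- build_residual_unet(obj$config)
  cpp_unet_set_params(model$ptr, obj$params)
  model
}

#' Preprocess a CT volume for the network
#'
#' Shifts the volume to non-negative values, clips intensities to
#' 1-99% of the maximum (i.e., to `[0.01 * max, 0.99 * max]`), and applies
#' Z-score standardization over the whole volume (zero-variance volumes map
#' to all zeros). Set `clip_mode = "percentile"` to clip at the 1st and 99th
#' intensity percentiles instead.
#'
#' @param volume a CT [image_volume()].
#' @param clip_mode `"max_fraction"` (default) or `"percentile"`.
#' @return An [image_volume()] of standardized values.
#' @export
preprocess_ct <- function(volume, clip_mode = c("max_fraction", "percentile")) {
  clip_mode <- match.arg(clip_mode)
  stopifnot(inherits(volume, "image_volume"))
  v <- volume$values
  if (length(v) == 0) stop("empty volume")
  v <- v - min(v)
  if (clip_mode == "max_fraction") {
    m <- max(v)
    v <- pmin(pmax(v, 0.01 * m), 0.99 * m)
  } else {
    q <- quantile(v, c(0.01, 0.99), names = FALSE)
    v <- pmin(pmax(v, q[1]), q[2])
  }
  s <- sd(as.numeric(v))
  v <- if (s > 0) (v - mean(v)) / s else array(0, dim(v))
  dim(v) <- volume$grid$shape
  image_volume(v, volume$grid, "CT")
}

#' Dice overlap coefficient between two masks
#'
#' `2 |A and B| / (|A| + |B|)`; defined as 1 when both masks are empty.
#'
#' @param a,b [binary_mask()] objects on the same grid.
#' @return A scalar in `[0, 1]`.
#' @export
dice_coefficient <- function(a, b) {
  stopifnot(inherits(a, "binary_mask"), inherits(b, "binary_mask"))
  if (!same_grid(a$grid, b$grid)) stop("masks must share one grid")
  na <- sum(a$values); nb <- sum(b$values)
  if (na + nb == 0) return(1)
  2 * sum(a$values & b$values) / (na + nb)
}

#' Combined cross-entropy and soft-Dice loss
#'
#' `w * CE + (1 - w) * (1 - soft-Dice)`, where the soft Dice is averaged
#' over the foreground classes present in `labels` (absent classes are
#' penalized by the cross-entropy term alone; a pure-background target makes
#' the Dice term vanish). Computed from per-pixel class probabilities.
#'
#' @param probs array `H x W x K` of class probabilities (summing to 1 per
#'   pixel).
#' @param labels integer matrix `H x W` of target classes in `0:(K-1)`.
#' @param weight cross-entropy weight `w` in `[0, 1]`.
#' @return A non-negative scalar.
#' @export
combined_loss <- function(probs, labels, weight = 0.5) {
  if (length(dim(probs)) != 3) stop("probs must be an H x W x K array")
  if (!all(dim(probs)[1:2] == dim(labels)))
    stop("probs and labels shapes do not match")
  sums <- apply(probs, c(1, 2), sum)
  if (max(abs(sums - 1)) > 1e-6)
    stop("probabilities must sum to 1 at every pixel")
  cpp_combined_loss(probs, matrix(as.integer(labels), nrow(labels)), weight)
}

#' Jointly augment a CT slice and its label map
#'
#' Samples one affine transform (rotation, translation, isotropic scale,
#' left-right flip) and applies it to both: bilinear interpolation for the
#' image, nearest-neighbor for the labels. A left-right flip also swaps the
#' left/right kidney labels so laterality stays anatomically consistent.
#'
#' @param slice numeric matrix (preprocessed CT slice).
#' @param labels integer matrix of the same shape, values in 0-5.
#' @param rotation_deg,translation_vox,scale_range,flip_prob sampling ranges.
#' @param seed optional seed making the draw reproducible.
#' @return `list(slice, labels, params)`.
#' @export
augment_pair <- function(slice, labels, rotation_deg = 10,
                         translation_vox = 2, scale_range = c(0.9, 1.1),
                         flip_prob = 0.5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ang <- runif(1, -rotation_deg, rotation_deg)
  tx <- runif(1, -translation_vox, translation_vox)
  ty <- runif(1, -translation_vox, translation_vox)
  sc <- runif(1, scale_range[1], scale_range[2])
  flip <- runif(1) < flip_prob
  out <- cpp_affine_slice(slice, matrix(as.integer(labels), nrow(labels)),
                          ang, tx, ty, sc, flip)
  lab <- out$labels
  if (flip) {
    kl <- lab == ORGAN_LABELS[["kidney_left"]]
    kr <- lab == ORGAN_LABELS[["kidney_right"]]
    lab[kl] <- ORGAN_LABELS[["kidney_right"]]
    lab[kr] <- ORGAN_LABELS[["kidney_left"]]
  }
  list(slice = out$image, labels = lab,
       params = list(rotation = ang, tx = tx, ty = ty, scale = sc, flip = flip))
}

labels_from_case <- function(case) {
  lab <- array(0L, case$ct$grid$shape)
  for (nm in ORGAN_NAMES) lab[case$truth_organs[[nm]]$values] <- ORGAN_LABELS[[nm]]
  lab
}

as_training_case <- function(x) {
  if (inherits(x, "phantom_case"))
    list(ct = x$ct, labels = labels_from_case(x))
  else if (is.list(x) && inherits(x$ct, "image_volume") && is.array(x$labels))
    x
  else stop("training cases must be phantom_case objects or list(ct, labels)")
}

select_slices <- function(labels, n_fg, n_bg) {
  fg <- which(apply(labels > 0, 3, any))
  bg <- setdiff(seq_len(dim(labels)[3]), fg)
  if (length(fg) > n_fg)
    fg <- fg[unique(round(seq(1, length(fg), length.out = n_fg)))]
  if (length(bg) > n_bg) bg <- sort(sample(bg, n_bg))
  sort(c(fg, bg))
}

split_cases <- function(n, split) {
  n_train <- round(split[1] * n)
  n_val <- round(split[2] * n)
  n_train <- max(1L, min(n_train, n - 1L))
  n_val <- max(0L, min(n_val, n - n_train - 1L))
  idx <- seq_len(n)
  list(train = idx[seq_len(n_train)],
       val = if (n_val > 0) idx[n_train + seq_len(n_val)] else integer(0),
       test = idx[(n_train + n_val + 1):n])
}

epoch_lr <- function(epoch, cfg) {
  start <- ceiling(cfg$lr_decay_start * cfg$max_epochs)
  if (epoch <= start || cfg$max_epochs == start) return(cfg$lr_init)
  frac <- (epoch - start) / (cfg$max_epochs - start)
  exp(log(cfg$lr_init) + frac * (log(cfg$lr_final) - log(cfg$lr_init)))
}

dice_by_organ <- function(model, cases) {
  out <- sapply(cases, function(case) {
    pred <- segment_organs(model, case$ct)
    grid <- case$ct$grid
    vapply(ORGAN_NAMES, function(nm) {
      truth <- binary_mask(array(case$labels == ORGAN_LABELS[[nm]],
                                 grid$shape), grid, nm)
      dice_coefficient(pred[[nm]], truth)
    }, numeric(1))
  })
  if (is.null(dim(out))) out <- matrix(out, ncol = 1, dimnames = list(ORGAN_NAMES, NULL))
  rowMeans(out)
}

train_loop <- function(model, train_cases, cfg, final_only) {
  pre <- lapply(train_cases, function(cs) {
    vol <- preprocess_ct(cs$ct)
    sel <- select_slices(cs$labels, cfg$slices_per_volume, cfg$background_slices)
    list(values = vol$values, labels = cs$labels, slices = sel,
         spacing = cs$ct$grid$spacing)
  })
  pool <- do.call(rbind, lapply(seq_along(pre), function(i)
    cbind(i, pre[[i]]$slices)))
  losses <- numeric(cfg$max_epochs)
  augment <- cfg$rotation_deg > 0 || cfg$translation_mm > 0 ||
    cfg$flip_prob > 0 || any(cfg$scale_range != 1)
  for (epoch in seq_len(cfg$max_epochs)) {
    lr <- epoch_lr(epoch, cfg)
    ord <- sample(nrow(pool))
    tot <- 0
    for (r in ord) {
      vi <- pool[r, 1]; zi <- pool[r, 2]
      x <- pre[[vi]]$values[, , zi]
      y <- matrix(as.integer(pre[[vi]]$labels[, , zi]), nrow(x))
      if (augment) {
        tv <- cfg$translation_mm / mean(pre[[vi]]$spacing[1:2])
        a <- augment_pair(x, y, cfg$rotation_deg, tv, cfg$scale_range,
                          cfg$flip_prob)
        x <- a$slice; y <- a$labels
      }
      tot <- tot + cpp_unet_train_step(model$ptr, x, y, cfg$loss_weight, lr,
                                       cfg$weight_decay, final_only)
    }
    losses[epoch] <- tot / nrow(pool)
    if (cfg$verbose)
      message(sprintf("epoch %d/%d  lr %.2g  loss %.4f", epoch,
                      cfg$max_epochs, lr, losses[epoch]))
  }
  losses
}

#' Train the segmentation network
#'
#' Splits the cases train:validation:test per `cfg$split` (in the given
#' order), trains slice-wise on the training split with the configured
#' schedule and augmentation, and evaluates per-organ Dice on the validation
#' and test splits at the end.
#'
#' @param model a `residual_unet` from [build_residual_unet()].
#' @param cases list of `phantom_case` objects or `list(ct, labels)` pairs
#'   (labels: 3D integer array, 0-5).
#' @param cfg a [train_config()].
#' @return `list(model, history)` where `history` has per-epoch training
#'   `loss`, per-organ `dice_val` and `dice_test`, and the `split` indices.
#' @export
train_segmentation <- function(model, cases, cfg = train_config()) {
  stopifnot(inherits(model, "residual_unet"), inherits(cfg, "train_config"))
  if (length(cases) < 1) stop("need at least one training case")
  cases <- lapply(cases, as_training_case)
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  sp <- split_cases(length(cases), cfg$split)
  losses <- train_loop(model, cases[sp$train], cfg, final_only = FALSE)
  history <- list(loss = losses, split = sp,
                  dice_val = if (length(sp$val)) dice_by_organ(model, cases[sp$val]) else NULL,
                  dice_test = if (length(sp$test)) dice_by_organ(model, cases[sp$test]) else NULL)
  list(model = model, history = history)
}

#' Fine-tune a pre-trained network
#'
#' Re-initializes the final output layer to random values, then trains
#' either the full network or only that layer, per `cfg$trainable_scope`.
#' With `max_epochs = 0` the model is returned in the reset state.
#'
#' @inheritParams train_segmentation
#' @return `list(model, history)` as in [train_segmentation()].
#' @export
fine_tune <- function(model, cases, cfg = train_config()) {
  stopifnot(inherits(model, "residual_unet"), inherits(cfg, "train_config"))
  cases <- lapply(cases, as_training_case)
  maxlab <- max(0L, vapply(cases, function(cs) max(cs$labels), integer(1)))
  if (maxlab >= model$config$n_classes)
    stop("label values exceed the model's class count")
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  cpp_unet_reset_final(model$ptr)
  if (cfg$max_epochs == 0)
    return(list(model = model, history = list(loss = numeric(0))))
  sp <- split_cases(length(cases), cfg$split)
  losses <- train_loop(model, cases[sp$train], cfg,
                       final_only = cfg$trainable_scope == "final_layer_only")
  history <- list(loss = losses, split = sp,
                  dice_val = if (length(sp$val)) dice_by_organ(model, cases[sp$val]) else NULL,
                  dice_test = if (length(sp$test)) dice_by_organ(model, cases[sp$test]) else NULL)
  list(model = model, history = history)
}

largest_components <- function(values, grid, k = 1L) {
  lab <- cpp_label_components(as.logical(values), grid$shape, 26L)
  if (!any(lab > 0)) return(list())
  tab <- sort(table(lab[lab > 0]), decreasing = TRUE)
  ids <- as.integer(names(tab))[seq_len(min(k, length(tab)))]
  lapply(ids, function(id) array(lab == id, grid$shape))
}

#' Segment the avid organs on a CT volume
#'
#' Runs per-slice inference, takes the per-pixel argmax, and restacks to 3D.
#' With `postprocess = TRUE` each of brain/heart/bladder keeps its largest
#' 26-connected component, and the two kidney classes are pooled, split into
#' connected components, and re-assigned left/right by x-centroid (the two
#' largest components; a single component goes to the side of its centroid).
#'
#' @param model a trained `residual_unet`.
#' @param ct a CT [image_volume()].
#' @param postprocess apply the component cleanup described above.
#' @return An [organ_mask_set()] on the CT grid.
#' @export
segment_organs <- function(model, ct, postprocess = TRUE) {
  stopifnot(inherits(model, "residual_unet"), inherits(ct, "image_volume"))
  pre <- preprocess_ct(ct)
  grid <- ct$grid
  lab <- array(0L, grid$shape)
  for (z in seq_len(grid$shape[3])) {
    probs <- cpp_unet_predict(model$ptr, pre$values[, , z])
    lab[, , z] <- max.col(matrix(probs, ncol = dim(probs)[3]),
                          ties.method = "first") - 1L
  }
  masks <- list()
  if (postprocess) {
    for (nm in c("brain", "heart", "bladder")) {
      comp <- largest_components(lab == ORGAN_LABELS[[nm]], grid, 1L)
      v <- if (length(comp)) comp[[1]] else array(FALSE, grid$shape)
      masks[[nm]] <- binary_mask(v, grid, nm)
    }
    kid <- lab == ORGAN_LABELS[["kidney_left"]] | lab == ORGAN_LABELS[["kidney_right"]]
    comp <- largest_components(kid, grid, 2L)
    empty <- array(FALSE, grid$shape)
    if (length(comp) == 0) {
      masks$kidney_left <- binary_mask(empty, grid, "kidney_left")
      masks$kidney_right <- binary_mask(empty, grid, "kidney_right")
    } else {
      cx <- vapply(comp, function(m)
        mean(which(m, arr.ind = TRUE)[, 1]), numeric(1))
      if (length(comp) == 1) {
        left <- cx[1] <= (grid$shape[1] + 1) / 2
        masks$kidney_left <- binary_mask(if (left) comp[[1]] else empty, grid, "kidney_left")
        masks$kidney_right <- binary_mask(if (left) empty else comp[[1]], grid, "kidney_right")
      } else {
        ord <- order(cx)
        masks$kidney_left <- binary_mask(comp[[ord[1]]], grid, "kidney_left")
        masks$kidney_right <- binary_mask(comp[[ord[2]]], grid, "kidney_right")
      }
    }
  } else {
    for (nm in ORGAN_NAMES)
      masks[[nm]] <- binary_mask(array(lab == ORGAN_LABELS[[nm]], grid$shape),
                                 grid, nm)
  }
  organ_mask_set(masks$brain, masks$heart, masks$kidney_left,
                 masks$kidney_right, masks$bladder)
}
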