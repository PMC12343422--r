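#' 3D U-Net configuration
#'
#' The segmentation network: `n_levels` resolution levels, each with two
#' 3x3x3 convolutions followed by group normalisation and rectified linear
#' units, 2x2x2 max pooling between levels on the way down and
#' nearest-neighbour upsampling with skip concatenation on the way up, and a
#' 1x1x1 classifier head. Channel widths double per level from
#' `base_channels`. Trained with Adam at `learning_rate` on patches of
#' `patch_size` sampled at `stride`, batch size 1, minimising per-voxel
#' cross-entropy plus soft multi-class Dice.
#'
#' The default is the desk-scale profile (64x48x32 patches, stride 16x12x8);
#' the full-scale profile (128x96x64 patches, stride 32x24x16, four levels)
#' is available by argument.
#'
#' @param n_levels Resolution levels (3 = two poolings).
#' @param base_channels Channels at the finest level.
#' @param n_classes Output classes (3: background/portal/hepatic; 5 adds
#'   liver and spleen).
#' @param gn_groups Preferred group count for group normalisation (clamped
#'   to the channel count).
#' @param patch_size,stride Integer length-3; every `patch_size` must be
#'   divisible by `2^(n_levels - 1)` and `stride <= patch_size` per axis.
#' @param learning_rate,epochs,ce_weight,dice_weight Optimisation settings.
#' @param seed Seed for weight init and patch shuffling.
#' @return A `unet_config`.
#' @export
unet_config <- function(n_levels = 3L, base_channels = 16L, n_classes = 3L,
                        gn_groups = 8L, patch_size = c(64L, 48L, 32L),
                        stride = c(16L, 12L, 8L), learning_rate = 1e-3,
                        epochs = 200L, ce_weight = 1, dice_weight = 1,
                        seed = 1L) {
  patch_size <- as.integer(patch_size)
  stride <- as.integer(stride)
  div <- 2L^(n_levels - 1L)
  if (any(patch_size %% div != 0L))
    stop_hepavol("hepavol_config",
                 "patch_size must be divisible by %d per axis", div)
  if (any(stride > patch_size) || any(stride < 1L))
    stop_hepavol("hepavol_config", "stride must be in [1, patch_size]")
  structure(list(n_levels = as.integer(n_levels),
                 base_channels = as.integer(base_channels),
                 in_channels = 1L, n_classes = as.integer(n_classes),
                 gn_groups = as.integer(gn_groups), patch_size = patch_size,
                 stride = stride, learning_rate = learning_rate,
                 epochs = as.integer(epochs), ce_weight = ce_weight,
                 dice_weight = dice_weight, seed = as.integer(seed)),
            class = "unet_config")
}

#' Instantiate a network from a configuration
#'
#' Allocates and seeds the parameter vector (He initialisation for
#' convolution weights, zero biases, unit group-norm gains).
#'
#' @param config A [unet_config()].
#' @return A `unet_network`: list with `params` (numeric vector), `config`
#'   and the internal `layout`.
#' @export
build_network <- function(config) {
  stopifnot(inherits(config, "unet_config"))
  lay <- .unet_layout(config$n_levels, config$base_channels,
                      config$in_channels, config$n_classes)
  n <- as.integer(lay$n_params)
  params <- numeric(n)
  with_seed(config$seed, {
    for (i in seq_along(lay$cout)) {
      fan_in <- lay$cin[i] * lay$kernel[i]
      nw <- lay$cout[i] * fan_in
      w0 <- lay$w_offset[i]
      params[w0 + seq_len(nw)] <- rnorm(nw, sd = sqrt(2 / fan_in))
      if (lay$gn[i] == 1L)
        params[lay$gamma_offset[i] + seq_len(lay$cout[i])] <- 1
    }
  })
  structure(list(params = params, config = config, layout = lay,
                 loss_trace = NULL), class = "unet_network")
}

#' @export
print.unet_network <- function(x, ...) {
  cat(sprintf("<unet_network> %d levels, base %d, %d classes, %s params%s\n",
              x$config$n_levels, x$config$base_channels, x$config$n_classes,
              format(length(x$params), big.mark = ","),
              if (is.null(x$loss_trace)) " (untrained)" else ""))
  invisible(x)
}

# Forward pass on one patch -> class-probability array (K x voxels).
unet_forward_probs <- function(network, patch) {
  dims <- dim(patch)
  .unet_infer(network$params, as.numeric(patch), dims, network$config)
}

#' Patch origin grid for training and sliding-window inference
#'
#' Regular grid of 1-based patch origins at the given stride; the final
#' origin per axis is clamped so the last patch touches the volume boundary.
#' Optionally oversamples patches containing vessel foreground.
#'
#' @param volume_dim Integer length-3 volume shape.
#' @param patch_size,stride Integer length-3.
#' @param foreground_bias Optional list with `mask` (binary array) and
#'   `times` (integer): patches whose center region intersects the mask are
#'   repeated `times` times.
#' @return Integer matrix, one row per origin, columns x/y/z. For a volume
#'   smaller than the patch, a single origin at 1 (the caller pads).
#' @export
sample_patches <- function(volume_dim, patch_size, stride,
                           foreground_bias = NULL) {
  origins_axis <- function(n, p, s) {
    if (n <= p) return(1L)
    o <- seq.int(1L, n - p + 1L, by = s)
    if (o[length(o)] != n - p + 1L) o <- c(o, n - p + 1L)
    o
  }
  g <- expand.grid(x = origins_axis(volume_dim[1], patch_size[1], stride[1]),
                   y = origins_axis(volume_dim[2], patch_size[2], stride[2]),
                   z = origins_axis(volume_dim[3], patch_size[3], stride[3]))
  m <- as.matrix(g)
  if (!is.null(foreground_bias)) {
    hits <- vapply(seq_len(nrow(m)), function(i) {
      o <- m[i, ]
      hi <- pmin(o + patch_size - 1L, volume_dim)
      any(foreground_bias$mask[o[1]:hi[1], o[2]:hi[2], o[3]:hi[3]] != 0)
    }, logical(1))
    m <- rbind(m, m[rep(which(hits), foreground_bias$times - 1L), ,
                    drop = FALSE])
  }
  m
}

# Pad an array symmetrically with zeros up to at least `target` per axis.
pad_to <- function(arr, target, fill = 0) {
  d <- dim(arr)
  if (all(d >= target)) return(list(arr = arr, offset = c(0L, 0L, 0L)))
  nd <- pmax(d, target)
  lo <- (nd - d) %/% 2L
  out <- array(fill, nd)
  out[lo[1] + seq_len(d[1]), lo[2] + seq_len(d[2]), lo[3] + seq_len(d[3])] <- arr
  list(arr = out, offset = lo)
}

#' Augmentation parameters
#'
#' The training-time augmentation suite: elastic deformation (random coarse
#' displacement grid upsampled with cubic splines), random axis flips,
#' random rotation by 90 degrees (on axis pairs of equal length), random
#' small rotation (+/- 15 degrees), random contrast scaling, additive
#' Gaussian noise and Poisson noise. Geometric transforms are applied
#' identically to image and label (labels resampled nearest-neighbour);
#' intensity transforms touch the image only.
#'
#' @param p_elastic,p_flip,p_rot90,p_rot_small,p_contrast,p_gauss,p_poisson
#'   Per-transform application probabilities.
#' @param elastic_magnitude Displacement SD in voxels at the control grid.
#' @param elastic_grid Control-grid spacing in voxels.
#' @param rot_small_deg Maximum small-rotation angle (degrees).
#' @param contrast_range Multiplicative contrast factor range.
#' @param gaussian_sigma Additive noise SD.
#' @param poisson_scale Photon-count scale for Poisson noise.
#' @return An `augmentation_params` list.
#' @export
augmentation_params <- function(p_elastic = 0.3, p_flip = 0.5, p_rot90 = 0.3,
                                p_rot_small = 0.3, p_contrast = 0.3,
                                p_gauss = 0.3, p_poisson = 0.2,
                                elastic_magnitude = 2, elastic_grid = 8L,
                                rot_small_deg = 15,
                                contrast_range = c(0.8, 1.2),
                                gaussian_sigma = 0.03, poisson_scale = 200) {
  structure(as.list(environment()), class = "augmentation_params")
}

# Cubic-spline upsample of a coarse displacement grid to full resolution.
upsample_spline3 <- function(coarse, full_dim) {
  a <- coarse
  for (ax in 1:3) {
    d <- dim(a)
    n_out <- full_dim[ax]
    xin <- seq(0, 1, length.out = d[ax])
    xout <- seq(0, 1, length.out = n_out)
    a <- apply(a, setdiff(1:3, ax), function(v)
      spline(xin, v, xout = xout, method = "natural")$y)
    # apply collapses the target axis to dim 1; rotate it back into place
    perm <- order(c(ax, setdiff(1:3, ax)))
    a <- aperm(array(a, c(n_out, d[setdiff(1:3, ax)])), perm)
  }
  a
}

# Rotation displacement field (about the volume center, axis k, angle rad).
rotation_displacement <- function(dims, axis, theta) {
  ctr <- (dims + 1) / 2
  ix <- seq_len(dims[1]) - ctr[1]
  iy <- seq_len(dims[2]) - ctr[2]
  iz <- seq_len(dims[3]) - ctr[3]
  X <- array(rep(ix, times = dims[2] * dims[3]), dims)
  Y <- array(rep(rep(iy, each = dims[1]), times = dims[3]), dims)
  Z <- array(rep(iz, each = dims[1] * dims[2]), dims)
  cs <- cos(theta); sn <- sin(theta)
  # inverse rotation of the in-plane coordinates (backward warp)
  if (axis == 3L) {
    sx <- cs * X + sn * Y; sy <- -sn * X + cs * Y; sz <- Z
  } else if (axis == 2L) {
    sx <- cs * X + sn * Z; sz <- -sn * X + cs * Z; sy <- Y
  } else {
    sy <- cs * Y + sn * Z; sz <- -sn * Y + cs * Z; sx <- X
  }
  list(dx = sx - X, dy = sy - Y, dz = sz - Z)
}

#' Augment an image/label patch pair
#'
#' @param image_patch,label_patch Congruent 3D arrays.
#' @param params An [augmentation_params()].
#' @return List with transformed `image` and `label` arrays. Uses the
#'   current RNG stream; seed via `set.seed()` (or [train()]'s seed) for
#'   reproducibility.
#' @export
augment <- function(image_patch, label_patch, params = augmentation_params()) {
  if (!identical(dim(image_patch), dim(label_patch)))
    stop_hepavol("hepavol_shape_mismatch", "image and label shapes differ")
  img <- image_patch
  lab <- label_patch
  d <- dim(img)
  warp_both <- function(dx, dy, dz) {
    img <<- .warp_volume(img, d, dx, dy, dz, FALSE, 0)
    lab <<- array(as.integer(.warp_volume(lab + 0.0, d, dx, dy, dz, TRUE, 0)), d)
  }
  if (runif(1) < params$p_elastic) {
    cg <- pmax(2L, ceiling(d / params$elastic_grid))
    disp <- lapply(1:3, function(k)
      upsample_spline3(array(rnorm(prod(cg), sd = params$elastic_magnitude),
                             cg), d))
    warp_both(disp[[1]], disp[[2]], disp[[3]])
  }
  if (runif(1) < params$p_rot_small) {
    ax <- sample(3L, 1)
    th <- runif(1, -params$rot_small_deg, params$rot_small_deg) * pi / 180
    rd <- rotation_displacement(d, ax, th)
    warp_both(rd$dx, rd$dy, rd$dz)
  }
  if (runif(1) < params$p_flip) {
    ax <- sample(3L, 1)
    idx <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
    idx[[ax]] <- rev(idx[[ax]])
    img <- img[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
    lab <- lab[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  }
  if (runif(1) < params$p_rot90) {
    axes <- which(outer(d, d, `==`) & upper.tri(diag(3)), arr.ind = TRUE)
    if (nrow(axes) > 0) { # 90-degree rotation needs two equal axes
      pr <- axes[sample(nrow(axes), 1), ]
      perm <- 1:3
      perm[pr[1]] <- pr[2]; perm[pr[2]] <- pr[1]
      img <- aperm(img, perm)
      lab <- aperm(lab, perm)
      idx <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
      idx[[pr[1]]] <- rev(idx[[pr[1]]])
      img <- img[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
      lab <- lab[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
    }
  }
  if (runif(1) < params$p_contrast) {
    f <- runif(1, params$contrast_range[1], params$contrast_range[2])
    m <- mean(img)
    img <- (img - m) * f + m
  }
  if (runif(1) < params$p_gauss)
    img <- img + array(rnorm(length(img), sd = params$gaussian_sigma), d)
  if (runif(1) < params$p_poisson) {
    s <- params$poisson_scale
    base <- pmax(img - min(img), 0)
    img <- img + (array(rpois(length(base), base * s), d) / s - base)
  }
  list(image = img, label = lab)
}

# Extract patch (and pad if needed) at origin o.
extract_patch <- function(arr, o, p) {
  d <- dim(arr)
  hi <- pmin(o + p - 1L, d)
  out <- arr[o[1]:hi[1], o[2]:hi[2], o[3]:hi[3], drop = FALSE]
  if (!all(dim(out) == p)) out <- pad_to(out, p)$arr
  out
}

#' Train the network on labelled cases
#'
#' Patch-based optimisation with Adam (batch size 1): per epoch, one
#' vessel-biased patch per case in a seeded random order, optionally
#' augmented. Records the per-epoch mean loss and keeps the best-loss
#' parameters (fixed-epoch budget with best-loss checkpointing). A
#' non-finite loss aborts with a diagnostic.
#'
#' @param network A [build_network()] result.
#' @param cases List of cases, each a list with `image` (`image_volume` or
#'   array) and `labels` (`label_volume` or integer array of class indices
#'   0..K-1 in the network's class convention).
#' @param augment_params `NULL` to disable augmentation, or an
#'   [augmentation_params()].
#' @param verbose Print the loss every few epochs?
#' @return The network with trained `params` and a `loss_trace` vector.
#' @export
train <- function(network, cases, augment_params = NULL, verbose = FALSE) {
  stopifnot(inherits(network, "unet_network"))
  if (length(cases) == 0L)
    stop_hepavol("hepavol_empty_input", "no training cases")
  cfg <- network$config
  prep <- lapply(cases, function(cs) {
    img <- as_volume_data(cs$image)
    lab <- as_volume_data(cs$labels)
    if (!identical(dim(img), dim(lab)))
      stop_hepavol("hepavol_shape_mismatch", "case image/label shapes differ")
    img <- pad_to(img, cfg$patch_size)$arr
    lab <- pad_to(lab, cfg$patch_size)$arr
    vessel <- array(as.integer(lab == 1L | lab == 2L), dim(lab))
    orig <- sample_patches(dim(img), cfg$patch_size, cfg$stride,
                           foreground_bias = list(mask = vessel, times = 2L))
    list(img = img, lab = lab, orig = orig)
  })
  p <- network$params
  m <- numeric(length(p)); v <- numeric(length(p))
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  t <- 0L
  trace <- numeric(cfg$epochs)
  best <- list(loss = Inf, params = p)
  with_seed(cfg$seed + 1L, {
    for (ep in seq_len(cfg$epochs)) {
      losses <- numeric(0)
      for (ci in sample(length(prep))) {
        cs <- prep[[ci]]
        o <- cs$orig[sample(nrow(cs$orig), 1L), ]
        img <- extract_patch(cs$img, o, cfg$patch_size)
        lab <- extract_patch(cs$lab, o, cfg$patch_size)
        if (!is.null(augment_params)) {
          au <- augment(img, lab, augment_params)
          img <- au$image; lab <- au$label
        }
        res <- .unet_loss_grad(p, as.numeric(img),
                               as.integer(lab), dim(img), cfg,
                               cfg$ce_weight, cfg$dice_weight)
        if (!is.finite(res$loss))
          stop_hepavol("hepavol_numeric",
                       "non-finite loss at epoch %d (ce=%g, dice=%g)",
                       ep, res$ce, res$soft_dice)
        t <- t + 1L
        g <- res$grad
        m <- b1 * m + (1 - b1) * g
        v <- b2 * v + (1 - b2) * g^2
        mhat <- m / (1 - b1^t)
        vhat <- v / (1 - b2^t)
        p <- p - cfg$learning_rate * mhat / (sqrt(vhat) + eps)
        losses <- c(losses, res$loss)
      }
      trace[ep] <- mean(losses)
      if (trace[ep] < best$loss) best <- list(loss = trace[ep], params = p)
      if (verbose && (ep %% 10 == 0 || ep == 1))
        message(sprintf("epoch %d/%d  loss %.4f", ep, cfg$epochs, trace[ep]))
    }
  })
  network$params <- best$params
  network$loss_trace <- trace
  network
}

#' Segment a volume by sliding-window inference
#'
#' Class probabilities are computed per patch on the configured grid,
#' averaged over overlapping patches, and argmaxed per voxel (ties broken
#' toward the lowest class index). Volumes smaller than the patch are
#' zero-padded symmetrically and the prediction cropped back.
#'
#' @param network A trained `unet_network`.
#' @param volume `image_volume` or 3D array. If an array is given without
#'   spacing, 1 mm isotropic is assumed with a warning.
#' @param stride Optional stride override (default: the training stride).
#' @return A `label_volume` of predicted class indices (0-based convention
#'   of the network's classes).
#' @export
predict_volume <- function(network, volume, stride = NULL) {
  cfg <- network$config
  if (inherits(volume, "image_volume")) {
    spacing <- volume$spacing
    arr <- volume$data
  } else {
    warning("no spacing metadata; assuming 1 mm isotropic")
    spacing <- c(1, 1, 1)
    arr <- volume
  }
  stride <- if (is.null(stride)) cfg$stride else as.integer(stride)
  pd <- pad_to(arr, cfg$patch_size)
  work <- pd$arr
  d <- dim(work)
  K <- cfg$n_classes
  acc <- array(0, c(d, K))
  cnt <- array(0, d)
  origins <- sample_patches(d, cfg$patch_size, stride)
  for (i in seq_len(nrow(origins))) {
    o <- origins[i, ]
    hi <- o + cfg$patch_size - 1L
    patch <- work[o[1]:hi[1], o[2]:hi[2], o[3]:hi[3], drop = FALSE]
    probs <- unet_forward_probs(network, patch) # K x voxels
    for (k in seq_len(K)) {
      acc[o[1]:hi[1], o[2]:hi[2], o[3]:hi[3], k] <-
        acc[o[1]:hi[1], o[2]:hi[2], o[3]:hi[3], k] +
        array(probs[k, ], cfg$patch_size)
    }
    cnt[o[1]:hi[1], o[2]:hi[2], o[3]:hi[3]] <-
      cnt[o[1]:hi[1], o[2]:hi[2], o[3]:hi[3]] + 1
  }
  pred <- array(0L, d)
  flat <- matrix(acc, ncol = K)
  pred[] <- max.col(flat, ties.method = "first") - 1L
  off <- pd$offset
  dd <- dim(arr)
  pred <- pred[off[1] + seq_len(dd[1]), off[2] + seq_len(dd[2]),
               off[3] + seq_len(dd[3]), drop = FALSE]
  label_volume(pred, spacing)
}

#' Stratified k-fold cross-validation
#'
#' Partitions cases into k folds stratified by group label (falling back to
#' an unstratified partition with a warning when a stratum is smaller than
#' k), trains on k-1 folds and evaluates per-case Dice on the held-out fold.
#'
#' @param cases List of cases (as in [train()]).
#' @param k Number of folds (>= 2).
#' @param group_labels Character vector, one per case.
#' @param config A [unet_config()].
#' @param seed Fold-assignment seed.
#' @param augment_params Optional augmentation for training.
#' @return List of `fold_report`s: `fold_id`, `train_ids`, `test_ids`,
#'   `per_case` data.frame (case, overall and vessel Dice), `mean_dice`.
#' @export
crossvalidate <- function(cases, k = 3L, group_labels = NULL,
                          config = unet_config(), seed = 1L,
                          augment_params = NULL) {
  n <- length(cases)
  if (k < 2L) stop_hepavol("hepavol_config", "k must be >= 2")
  if (is.null(group_labels)) group_labels <- rep("all", n)
  fold <- integer(n)
  with_seed(seed, {
    strata <- split(seq_len(n), group_labels)
    if (any(vapply(strata, length, 1L) < k)) {
      warning("stratum smaller than k; falling back to unstratified folds")
      strata <- list(seq_len(n))
    }
    for (s in strata) {
      s <- sample(s)
      fold[s] <- rep_len(seq_len(k), length(s))
    }
  })
  lapply(seq_len(k), function(f) {
    test_ids <- which(fold == f)
    train_ids <- setdiff(seq_len(n), test_ids)
    net <- build_network(config)
    net <- train(net, cases[train_ids], augment_params = augment_params)
    per <- lapply(test_ids, function(i) {
      gt <- as_volume_data(cases[[i]]$labels)
      pr <- predict_volume(net, cases[[i]]$image)$data
      data.frame(case = i,
                 dice_overall = dice(pr != 0, gt != 0),
                 dice_vessel = dice(pr == 1L | pr == 2L,
                                    gt == 1L | gt == 2L),
                 dice_portal = dice(pr == 1L, gt == 1L),
                 dice_hepatic = dice(pr == 2L, gt == 2L))
    })
    per <- do.call(rbind, per)
    structure(list(fold_id = f, train_ids = train_ids, test_ids = test_ids,
                   per_case = per, mean_dice = mean(per$dice_vessel)),
              class = "fold_report")
  })
}
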