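tiny_cfg <- function(...) {
  unet_config(n_levels = 2L, base_channels = 4L, n_classes = 3L,
              patch_size = c(16L, 16L, 8L), stride = c(8L, 8L, 4L),
              epochs = 5L, seed = 3L, ...)
}

test_that("configuration enforces divisibility and stride bounds", {
  expect_error(unet_config(patch_size = c(63, 48, 32)),
               class = "hepavol_config")
  expect_error(unet_config(patch_size = c(64, 48, 32),
                           stride = c(65, 12, 8)),
               class = "hepavol_config")
  cfg <- unet_config()
  expect_equal(cfg$patch_size, c(64L, 48L, 32L))
  expect_equal(cfg$stride, c(16L, 12L, 8L))
})

test_that("forward pass preserves spatial shape over random valid configs", {
  set.seed(8)
  for (i in 1:4) {
    nl <- sample(2:3, 1)
    div <- 2^(nl - 1)
    ps <- div * sample(2:4, 3, replace = TRUE)
    k <- sample(2:4, 1)
    cfg <- unet_config(n_levels = nl, base_channels = 2 * sample(1:2, 1),
                       n_classes = k, patch_size = ps, stride = ps,
                       seed = i)
    net <- build_network(cfg)
    x <- array(rnorm(prod(ps)), ps)
    probs <- hepavol:::unet_forward_probs(net, x)
    expect_equal(dim(probs), c(k, prod(ps)))
    expect_equal(colSums(probs), rep(1, prod(ps)), tolerance = 1e-5)
  }
})

test_that("patch origin grids clamp the final patch to the boundary", {
  o <- sample_patches(c(128, 128, 128), c(64, 64, 64), c(32, 32, 32))
  expect_equal(nrow(o), 27) # origins 1, 33, 65 per axis
  expect_true(all(o <= 128 - 64 + 1))
  # stride = patch on an exact multiple: non-overlapping tiling
  o2 <- sample_patches(c(64, 64, 64), c(32, 32, 32), c(32, 32, 32))
  expect_equal(nrow(o2), 8)
  # volume smaller than patch: a single padded origin
  o3 <- sample_patches(c(20, 20, 20), c(32, 32, 32), c(8, 8, 8))
  expect_equal(nrow(o3), 1)
  # vessel-biased oversampling repeats foreground patches
  m <- array(0L, c(64, 64, 64)); m[40, 40, 40] <- 1L
  o4 <- sample_patches(c(64, 64, 64), c(32, 32, 32), c(32, 32, 32),
                       foreground_bias = list(mask = m, times = 3L))
  expect_gt(nrow(o4), nrow(o2))
})

test_that("geometric augmentations move image and label together", {
  set.seed(21)
  img <- array(rnorm(16 * 16 * 16), c(16, 16, 16))
  lab <- array(0L, c(16, 16, 16)); lab[6:9, 4:7, 10:12] <- 1L
  # flips preserve the voxel multiset and track labels
  p_flip <- augmentation_params(p_elastic = 0, p_flip = 1, p_rot90 = 0,
                                p_rot_small = 0, p_contrast = 0,
                                p_gauss = 0, p_poisson = 0)
  au <- augment(img, lab, p_flip)
  expect_equal(sort(as.vector(au$image)), sort(as.vector(img)))
  expect_equal(sum(au$label), sum(lab))
  expect_equal(sort(au$image[au$label == 1L]), sort(img[lab == 1L]))
  # four quarter-turns compose to the identity
  p_rot <- augmentation_params(p_elastic = 0, p_flip = 0, p_rot90 = 1,
                               p_rot_small = 0, p_contrast = 0,
                               p_gauss = 0, p_poisson = 0)
  cur_i <- img; cur_l <- lab
  set.seed(5)
  ax <- sample(3L, 1) # the axis augment() will draw first
  set.seed(5)
  for (r in 1:4) {
    au2 <- augment(cur_i, cur_l, p_rot)
    cur_i <- au2$image; cur_l <- au2$label
    set.seed(5) # same axis pair every turn
  }
  expect_equal(cur_i, img)
  expect_identical(cur_l, lab)
  # zero-magnitude elastic deformation is the identity
  p_el <- augmentation_params(p_elastic = 1, elastic_magnitude = 0,
                              p_flip = 0, p_rot90 = 0, p_rot_small = 0,
                              p_contrast = 0, p_gauss = 0, p_poisson = 0)
  au3 <- augment(img, lab, p_el)
  expect_equal(au3$image, img, tolerance = 1e-6)
  expect_identical(au3$label, lab)
  # a tracked landmark moves with the image under small rotation
  p_sr <- augmentation_params(p_elastic = 0, p_flip = 0, p_rot90 = 0,
                              p_rot_small = 1, p_contrast = 0,
                              p_gauss = 0, p_poisson = 0)
  marker <- array(0, c(16, 16, 16)); marker[4, 12, 8] <- 100
  mlab <- array(0L, c(16, 16, 16)); mlab[4, 12, 8] <- 1L
  set.seed(9)
  au4 <- augment(marker, mlab, p_sr)
  peak_img <- which(au4$image == max(au4$image), arr.ind = TRUE)[1, ]
  peak_lab <- which(au4$label == 1L, arr.ind = TRUE)[1, ]
  expect_lte(max(abs(peak_img - peak_lab)), 1)
  expect_error(augment(img, lab[1:8, , ]), class = "hepavol_shape_mismatch")
})

test_that("intensity augmentations never touch the label map", {
  set.seed(3)
  img <- array(runif(8^3), c(8, 8, 8))
  lab <- array(sample(0:2, 8^3, TRUE), c(8, 8, 8))
  p <- augmentation_params(p_elastic = 0, p_flip = 0, p_rot90 = 0,
                           p_rot_small = 0, p_contrast = 1, p_gauss = 1,
                           p_poisson = 1)
  au <- augment(img, lab, p)
  expect_identical(au$label, lab)
  expect_false(identical(au$image, img))
})

test_that("training bookkeeping behaves: lr 0, empty cases, loss trace", {
  img <- array(rnorm(16 * 16 * 8), c(16, 16, 8))
  lab <- array(sample(0:2, 16 * 16 * 8, TRUE), c(16, 16, 8))
  cs <- list(list(image = img, labels = lab))
  net0 <- build_network(tiny_cfg(learning_rate = 0))
  tr <- train(net0, cs)
  expect_equal(diff(range(tr$loss_trace)), 0, tolerance = 1e-5)
  expect_identical(tr$params, net0$params)
  expect_error(train(net0, list()), class = "hepavol_empty_input")
  net1 <- train(build_network(tiny_cfg()), cs)
  expect_length(net1$loss_trace, 5)
  expect_true(all(is.finite(net1$loss_trace)))
})

test_that("analytic gradients match finite differences without pooling", {
  cfg <- unet_config(n_levels = 1, base_channels = 2, n_classes = 2,
                     patch_size = c(6, 6, 4), stride = c(6, 6, 4), seed = 5)
  net <- build_network(cfg)
  set.seed(2)
  img <- array(rnorm(6 * 6 * 4), c(6, 6, 4))
  lab <- array(sample(0:1, 6 * 6 * 4, TRUE), c(6, 6, 4))
  p <- net$params
  g <- hepavol:::.unet_loss_grad(p, as.numeric(img), as.integer(lab),
                                 dim(img), cfg, 1, 1)$grad
  set.seed(3)
  dirv <- rnorm(length(p)); dirv <- dirv / sqrt(sum(dirv^2))
  h <- 3e-3
  lp <- hepavol:::.unet_loss_grad(p + h * dirv, as.numeric(img),
                                  as.integer(lab), dim(img), cfg, 1, 1)$loss
  lm <- hepavol:::.unet_loss_grad(p - h * dirv, as.numeric(img),
                                  as.integer(lab), dim(img), cfg, 1, 1)$loss
  expect_equal(sum(g * dirv), (lp - lm) / (2 * h), tolerance = 5e-3)
})

test_that("sliding-window prediction stitches exactly when non-overlapping", {
  cfg <- tiny_cfg()
  net <- build_network(cfg)
  vol <- array(rnorm(32 * 32 * 16), c(32, 32, 16))
  pred <- suppressWarnings(predict_volume(net, vol,
                                          stride = cfg$patch_size))
  # manual per-patch argmax on the exact tiling
  manual <- array(NA_integer_, dim(vol))
  for (o1 in c(1, 17)) for (o2 in c(1, 17)) for (o3 in c(1, 9)) {
    patch <- vol[o1:(o1 + 15), o2:(o2 + 15), o3:(o3 + 7)]
    probs <- hepavol:::unet_forward_probs(net, patch)
    manual[o1:(o1 + 15), o2:(o2 + 15), o3:(o3 + 7)] <-
      array(max.col(t(probs), ties.method = "first") - 1L, dim(patch))
  }
  expect_identical(pred$data, manual)
  expect_true(all(pred$data %in% 0:2))
  # an all-zero-parameter network is constant: ties broken to class 0
  net0 <- build_network(cfg)
  net0$params[] <- 0
  p0 <- suppressWarnings(predict_volume(net0, array(0, c(16, 16, 8))))
  expect_true(all(p0$data == 0L))
  # spacing metadata missing -> warning and 1 mm assumption
  expect_warning(predict_volume(net, vol), "1 mm")
  pv <- predict_volume(net, image_volume(vol, c(2, 2, 2)))
  expect_equal(pv$spacing, c(2, 2, 2))
})

test_that("training improves vessel Dice on an easy two-class phantom", {
  # high-contrast blob: the learning smoke property at miniature scale
  img <- array(0, c(16, 16, 8))
  lab <- array(0L, c(16, 16, 8))
  lab[5:12, 5:12, 3:6] <- 1L
  img[lab == 1L] <- 1
  set.seed(1)
  img <- img + array(rnorm(length(img), sd = 0.05), dim(img))
  cfg <- unet_config(n_levels = 3, base_channels = 4, n_classes = 3,
                     patch_size = c(16, 16, 8), stride = c(8, 8, 4),
                     epochs = 40, seed = 2)
  net0 <- build_network(cfg)
  d0 <- dice(suppressWarnings(predict_volume(net0, img))$data == 1L,
             lab == 1L)
  net <- train(net0, list(list(image = img, labels = lab)))
  d1 <- dice(suppressWarnings(predict_volume(net, img))$data == 1L,
             lab == 1L)
  expect_gt(d1, 0.8)
  expect_gte(d1 - d0, 0.3)
})

test_that("cross-validation folds are stratified, disjoint and exhaustive", {
  mkcase <- function(i) {
    img <- array(rnorm(8^3), c(8, 8, 8))
    lab <- array(0L, c(8, 8, 8)); lab[3:6, 3:6, 3:6] <- 1L
    list(image = image_volume(img), labels = label_volume(lab))
  }
  cases <- lapply(1:12, mkcase)
  groups <- rep(c("non-ACLD", "ACLD"), times = c(3, 9))
  cfg <- unet_config(n_levels = 2, base_channels = 2, n_classes = 2,
                     patch_size = c(8, 8, 8), stride = c(8, 8, 8),
                     epochs = 1, seed = 1)
  folds <- crossvalidate(cases, k = 3, group_labels = groups, config = cfg,
                         seed = 4)
  test_sets <- lapply(folds, `[[`, "test_ids")
  expect_equal(sort(unlist(test_sets)), 1:12)      # exhaustive partition
  expect_equal(anyDuplicated(unlist(test_sets)), 0) # disjoint
  for (f in folds) {
    expect_length(intersect(f$train_ids, f$test_ids), 0)
    # stratification: each fold holds one non-ACLD and three ACLD
    expect_equal(sum(groups[f$test_ids] == "non-ACLD"), 1)
  }
  folds2 <- crossvalidate(cases, k = 3, group_labels = groups, config = cfg,
                          seed = 4)
  expect_identical(lapply(folds2, `[[`, "test_ids"), test_sets)
  # small stratum falls back with a warning
  expect_warning(crossvalidate(cases[1:4], k = 2,
                               group_labels = c("a", "a", "a", "b"),
                               config = cfg, seed = 1),
                 "unstratified")
})

test_that("networks round-trip through the JSON checkpoint", {
  net <- build_network(tiny_cfg())
  net$loss_trace <- c(1, 0.5)
  tf <- tempfile(fileext = ".json")
  save_network(net, tf)
  back <- load_network(tf)
  expect_equal(back$params, net$params)
  expect_equal(unclass(back$config), unclass(net$config))
  unlink(tf)
})
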