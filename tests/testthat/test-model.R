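# Localizer: DSNT head, target heatmaps, the Euclidean + divergence loss,
# hand-derived backprop, augmentation and aspect-preserving resize.

test_that("DSNT reads one-hot and uniform heatmaps per the grid formula", {
  expect_equal(dsnt_grid(3), c(-2 / 3, 0, 2 / 3))
  hm <- array(0, c(3, 3, 1, 1)); hm[2, 2, 1, 1] <- 1   # center of odd grid
  expect_equal(as.vector(dsnt_coords(hm)), c(0, 0))
  hm2 <- array(0, c(3, 3, 1, 1)); hm2[1, 1, 1, 1] <- 1 # pixel k = 1 of n = 3
  expect_equal(as.vector(dsnt_coords(hm2)), c(-2 / 3, -2 / 3))
  un <- array(1 / 25, c(5, 5, 1, 1))
  expect_equal(as.vector(dsnt_coords(un)), c(0, 0), tolerance = 1e-12)
})

test_that("DSNT equals the brute-force expectation on random heatmaps", {
  set.seed(5)
  p <- softmax_heatmaps(array(rnorm(6 * 10 * 3 * 2), c(6, 10, 3, 2)))
  expect_true(all(abs(apply(p, 3:4, sum) - 1) < 1e-12))
  co <- dsnt_coords(p)
  gx <- dsnt_grid(10); gy <- dsnt_grid(6)
  worst <- 0
  for (n in 1:2) for (k in 1:3) {
    m <- p[, , k, n]
    worst <- max(worst,
                 abs(sum(sweep(m, 2, gx, "*")) - co[1, k, n]),
                 abs(sum(sweep(m, 1, gy, "*")) - co[2, k, n]))
  }
  expect_lt(worst, 1e-10)
})

test_that("target heatmaps are normalized Gaussians with the right mode", {
  gt <- array(c(-0.5, 0.25, 0.1, -0.7), c(2, 2, 1))
  hm <- target_heatmap(gt, nh = 12, nw = 12, sigma_hm = 1)
  expect_equal(as.vector(apply(hm, 3:4, sum)), c(1, 1), tolerance = 1e-9)
  for (k in 1:2) {
    am <- which(hm[, , k, 1] == max(hm[, , k, 1]), arr.ind = TRUE)
    jx <- (gt[1, k, 1] * 12 + 11) / 2  # 0-based continuous pixel
    jy <- (gt[2, k, 1] * 12 + 11) / 2
    expect_equal(unname(am[1, "row"]) - 1, round(jy))
    expect_equal(unname(am[1, "col"]) - 1, round(jx))
  }
  # small-sigma limit: DSNT of the target approaches gt within half a pixel
  hs <- target_heatmap(gt, 12, 12, sigma_hm = 0.3)
  co <- dsnt_coords(hs)
  expect_true(all(abs(co - gt) <= 1 / 12 + 1e-9))  # half pixel = 1/n normalized
})

test_that("the loss is zero at perfect prediction and splits as documented", {
  gt <- array(c(0.2, -0.3), c(2, 1, 1))
  hm_gt <- target_heatmap(gt, 8, 8, 1)
  l0 <- dsnt_loss(gt, gt, hm_gt, hm_gt)
  expect_equal(l0$loss, 0)
  # 3-4-5 offset in normalized units: Euclidean term exactly 1
  pred <- gt + array(c(0.6, 0.8), c(2, 1, 1))
  l1 <- dsnt_loss(pred, gt, hm_gt, hm_gt)
  expect_equal(l1$euclidean, 1, tolerance = 1e-12)
  expect_equal(l1$divergence, 0)
  # JS term equals a direct summation oracle on a 5x5 pair
  set.seed(9)
  p <- softmax_heatmaps(array(rnorm(25), c(5, 5, 1, 1)))
  q <- softmax_heatmaps(array(rnorm(25), c(5, 5, 1, 1)))
  pm <- matrix(p, 25); qm <- matrix(q, 25); mm <- (pm + qm) / 2
  direct <- 0.5 * sum(pm * log(pm / mm)) + 0.5 * sum(qm * log(qm / mm))
  l2 <- dsnt_loss(gt, gt, p, q)
  expect_equal(l2$divergence, direct, tolerance = 1e-10)
  # non-normalized heatmaps violate the contract
  bad <- p * 2
  expect_error(dsnt_loss(gt, gt, bad, q), class = "fedspine_contract_error")
})

test_that("analytic gradients match finite differences on a tiny model", {
  cfg <- model_config(input_size = 16, n_stacks = 1, base_channels = 2,
                      heatmap_stride = 2, n_landmarks = 3)
  expect_lt(count_params(init_model_params(cfg, 1)), 1000)
  expect_lt(gradient_check(cfg, seed = 3), 1e-4)
  # and through intermediate supervision with two stacks
  cfg2 <- model_config(16, n_stacks = 2, base_channels = 2, heatmap_stride = 2,
                       n_landmarks = 3)
  expect_lt(gradient_check(cfg2, seed = 4, n_check = 150), 1e-4)
})

test_that("the default model emits 29 heatmaps and finite coordinates", {
  cfg <- model_config_tiny(32)
  params <- init_model_params(cfg, 2)
  imgs <- list(matrix(runif(32 * 32), 32), matrix(runif(32 * 32), 32))
  fw <- model_forward(params, cfg, imgs)
  expect_equal(dim(fw$heatmaps[[1]]), c(8, 8, 29, 2))
  expect_equal(dim(fw$coords), c(2, 29, 2))
  expect_true(all(is.finite(fw$coords)))
  expect_true(all(abs(apply(fw$heatmaps[[1]], 3:4, sum) - 1) < 1e-9))
  expect_error(model_forward(params, cfg, list(matrix(0, 16, 16))),
               class = "fedspine_config_error")
})

test_that("pixel/normalized coordinate maps are mutual inverses", {
  px <- c(0, 7.25, 31, 63)
  v <- px_to_norm(px, 64, 4)
  expect_equal(norm_to_px(v, 64, 4), px, tolerance = 1e-12)
  # center of the image maps to 0
  expect_equal(px_to_norm(31.5, 64, 4), 0)
})

test_that("augmentation is seed-deterministic and rotation-consistent", {
  r <- random_lm(60, canvas = c(64, 64), spacing = 6)
  img <- render_image(r$lm, center_profile("A", 1, noise_sd = 0.02), 1)
  a1 <- augment(img, r$lm, rng_seed = 5)
  a2 <- augment(img, r$lm, rng_seed = 5)
  expect_identical(a1$image, a2$image)
  expect_identical(a1$landmarks$points, a2$landmarks$points)
  # zero rotation bound: landmarks bit-identical
  a0 <- augment(img, r$lm, rng_seed = 6, rotation_max = 0)
  expect_identical(a0$landmarks$points, r$lm$points)
  # explicit rotation equals the rotation-matrix oracle
  rot <- rotate_sample(img, r$lm, 10)
  th <- 10 * pi / 180
  ctr <- c((64 - 1) / 2, (64 - 1) / 2)
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  oracle <- t(R %*% (t(r$lm$points) - ctr) + ctr)
  expect_lt(max(abs(rot$landmarks$points - oracle)), 1e-9)
})

test_that("aspect-preserving resize pads symmetrically and round-trips", {
  img_sq <- matrix(runif(32 * 32), 32)
  r <- resize_with_aspect(img_sq, NULL, 64)
  expect_equal(r$transform$pad, c(0, 0))
  expect_equal(dim(r$image), c(64, 64))
  # 25 x 50 -> 64: scale 64/50, horizontal pad (64 - 32)/2
  img_rect <- matrix(runif(25 * 50), nrow = 25)  # H=25, W=50
  lm <- random_lm(61)$lm
  lm$points <- cbind(x = runif(29, 2, 47), y = runif(29, 2, 22))
  rownames(lm$points) <- landmark_names()
  lm$image_size <- c(50, 25)
  rr <- resize_with_aspect(img_rect, lm, 64)
  expect_equal(rr$transform$scale, 64 / 50)
  expect_equal(rr$transform$pad[2], floor((64 - 32) / 2))
  back <- map_landmarks_back(rr$landmarks$points, rr$transform)
  expect_lt(max(abs(back - lm$points)), 1e-6)
})

test_that("checkpoints reload bit-stably", {
  cfg <- micro_config()
  params <- init_model_params(cfg, 3)
  f <- tempfile(fileext = ".rds")
  on.exit(unlink(f))
  save_checkpoint(params, cfg, list(note = "test"), f)
  ck <- load_checkpoint(f)
  expect_identical(flatten_params(ck$params), flatten_params(params))
  expect_identical(ck$config$input_size, cfg$input_size)
})

test_that("a tiny model overfits eight synthetic images (sanity of learning)", {
  cfg <- model_config_tiny(64)
  samples <- generate_cohort(list(center_profile("A", 1)), 3, rng_seed = 5,
                             canvas = c(64, 64), spacing_mm = 6)[1:8]
  x <- fedspine:::images_to_batch(lapply(samples, `[[`, "image"), 64)
  gt <- fedspine:::landmarks_to_gt(samples, cfg)
  params <- init_model_params(cfg, 1)
  opt <- fedspine:::adam_init(params)
  for (step in 1:200) {
    r <- model_loss_and_grad(params, cfg, x, gt)
    st <- fedspine:::adam_step(params, r$grads, opt, 1e-3)
    params <- st$params; opt <- st$state
  }
  preds <- predict_landmarks(params, cfg, samples)
  err_px <- vapply(1:8, function(i)
    mean(sqrt(rowSums((preds[[i]]$points - samples[[i]]$landmarks$points)^2))), 0)
  expect_lt(mean(err_px), 2)
})
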