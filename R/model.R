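# Stacked-hourglass landmark localizer with a DSNT head.
#
# Architecture (per config): a stem of 3x3 convolutions with 2x2 max pools
# down to the heatmap resolution (input_size / heatmap_stride), then
# `n_stacks` hourglass modules. Each module is a symmetric two-level
# encoder-decoder with skip connections fused by addition, a 1x1 head
# emitting one heatmap logit per landmark, and (between stacks) 1x1 remap
# convolutions feeding features and heatmaps back into the trunk
# (intermediate supervision). All activations are ReLU. The backward pass is
# hand-derived and verified against finite differences in the tests.

#' Model configuration
#'
#' @param input_size square input side in pixels; must be divisible by
#'   `heatmap_stride * 4` (the hourglass descends two further levels).
#' @param n_stacks number of stacked hourglass modules.
#' @param base_channels trunk feature channels.
#' @param heatmap_stride input-to-heatmap downscaling factor (power of two).
#' @param n_landmarks number of output heatmaps (29 under the default schema).
#' @param sigma_hm std of the Gaussian target heatmaps, in heatmap pixels.
#' @param divergence heatmap divergence of the loss: `"js"` or `"kl"`.
#' @return object of class `model_config`.
#' @export
model_config <- function(input_size = 64, n_stacks = 1, base_channels = 16,
                         heatmap_stride = 4, n_landmarks = 29, sigma_hm = 1,
                         divergence = "js") {
  k <- log2(heatmap_stride)
  if (k < 1 || k != round(k))
    stop_fedspine("heatmap_stride must be a power of two >= 2", "fedspine_config_error")
  if (input_size %% (heatmap_stride * 4) != 0)
    stop_fedspine("input_size must be divisible by heatmap_stride * 4",
                  "fedspine_config_error")
  if (sigma_hm <= 0) stop_fedspine("sigma_hm must be > 0", "fedspine_config_error")
  structure(list(input_size = as.integer(input_size), n_stacks = as.integer(n_stacks),
                 base_channels = as.integer(base_channels),
                 heatmap_stride = as.integer(heatmap_stride),
                 n_landmarks = as.integer(n_landmarks), sigma_hm = sigma_hm,
                 divergence = divergence, n_stem = as.integer(k)),
            class = "model_config")
}

#' Full-scale preset: 768 px input, two stacked hourglass modules
#' @return a `model_config`.
#' @export
model_config_full <- function() {
  model_config(input_size = 768, n_stacks = 2, base_channels = 64,
               heatmap_stride = 4, n_landmarks = 29, sigma_hm = 1)
}

#' Desk-scale preset used throughout the tests
#' @param input_size input side (default 64).
#' @return a `model_config`.
#' @export
model_config_tiny <- function(input_size = 64) {
  model_config(input_size = input_size, n_stacks = 1, base_channels = 16,
               heatmap_stride = 4, n_landmarks = 29, sigma_hm = 1)
}

layer_specs <- function(config) {
  C <- config$base_channels; K <- config$n_landmarks
  sp <- list(stem_in = c(3, 3, 1, C))
  for (j in seq_len(config$n_stem)) sp[[paste0("stem_", j)]] <- c(3, 3, C, C)
  for (i in seq_len(config$n_stacks)) {
    pre <- paste0("s", i, "_")
    for (nm in c("pre", "d1", "d2", "bott", "sk2", "g2", "sk1", "g1"))
      sp[[paste0(pre, nm)]] <- c(3, 3, C, C)
    sp[[paste0(pre, "head")]] <- c(1, 1, C, K)
    if (i < config$n_stacks) {
      sp[[paste0(pre, "remap_f")]] <- c(1, 1, C, C)
      sp[[paste0(pre, "remap_h")]] <- c(1, 1, K, C)
    }
  }
  sp
}

#' Initialize model parameters (He-normal weights, zero biases)
#'
#' @param config a `model_config`.
#' @param seed integer seed.
#' @return named, ordered parameter list; the model's ParamVector skeleton.
#' @export
init_model_params <- function(config, seed) {
  sp <- layer_specs(config)
  with_seed(seed, {
    lapply(sp, function(d) {
      fan_in <- d[1] * d[2] * d[3]
      W <- array(stats::rnorm(prod(d), 0, sqrt(2 / fan_in)), dim = d)
      list(W = W, b = numeric(d[4]))
    })
  })
}

relu <- function(x) { x[x < 0] <- 0; x }

conv_f <- function(x, p) conv2d_fwd(x, p$W, p$b)

# Forward pass through the trunk; returns per-stack heatmap logits and,
# optionally, every intermediate needed by the backward pass.
hg_forward <- function(params, config, x, keep = FALSE) {
  cache <- if (keep) list(x = x) else NULL
  a <- relu(conv_f(x, params$stem_in))
  if (keep) cache$stem <- list(list(pre = x, post = a))
  for (j in seq_len(config$n_stem)) {
    pl <- maxpool2_fwd(a)
    z <- conv_f(pl$y, params[[paste0("stem_", j)]])
    a2 <- relu(z)
    if (keep) cache$stem[[j + 1]] <- list(pre_pool = a, pool = pl, pooled = pl$y, post = a2)
    a <- a2
  }
  logits_all <- vector("list", config$n_stacks)
  stacks <- if (keep) vector("list", config$n_stacks) else NULL
  xin <- a
  for (i in seq_len(config$n_stacks)) {
    pre <- paste0("s", i, "_")
    r0 <- relu(conv_f(xin, params[[paste0(pre, "pre")]]))
    p1 <- maxpool2_fwd(r0); f1 <- relu(conv_f(p1$y, params[[paste0(pre, "d1")]]))
    p2 <- maxpool2_fwd(f1); f2 <- relu(conv_f(p2$y, params[[paste0(pre, "d2")]]))
    f3 <- relu(conv_f(f2, params[[paste0(pre, "bott")]]))
    sk2 <- relu(conv_f(f1, params[[paste0(pre, "sk2")]]))
    u2 <- upsample2_fwd(f3) + sk2
    g2 <- relu(conv_f(u2, params[[paste0(pre, "g2")]]))
    sk1 <- relu(conv_f(r0, params[[paste0(pre, "sk1")]]))
    u1 <- upsample2_fwd(g2) + sk1
    g1 <- relu(conv_f(u1, params[[paste0(pre, "g1")]]))
    logits <- conv_f(g1, params[[paste0(pre, "head")]])
    logits_all[[i]] <- logits
    if (keep)
      stacks[[i]] <- list(xin = xin, r0 = r0, p1 = p1, f1 = f1, p2 = p2, f2 = f2,
                          f3 = f3, sk2 = sk2, u2 = u2, g2 = g2, sk1 = sk1,
                          u1 = u1, g1 = g1, logits = logits)
    if (i < config$n_stacks) {
      xin <- xin + conv_f(g1, params[[paste0(pre, "remap_f")]]) +
        conv_f(logits, params[[paste0(pre, "remap_h")]])
    }
  }
  if (keep) cache$stacks <- stacks
  list(logits = logits_all, cache = cache)
}

# Backward pass: gradients of all parameters given per-stack logit gradients.
hg_backward <- function(params, config, cache, glogits) {
  grads <- lapply(params, function(p) list(W = array(0, dim(p$W)), b = numeric(length(p$b))))
  conv_b <- function(xin, name, gy) {
    r <- conv2d_bwd(xin, params[[name]]$W, gy)
    grads[[name]]$W <<- grads[[name]]$W + r$gW
    grads[[name]]$b <<- grads[[name]]$b + r$gb
    r$gx
  }
  relu_b <- function(g, act) { g[act <= 0] <- 0; g }

  gxin <- NULL  # gradient flowing into the current stack's input
  for (i in rev(seq_len(config$n_stacks))) {
    pre <- paste0("s", i, "_")
    st <- cache$stacks[[i]]
    glog <- glogits[[i]]
    gg1 <- NULL
    gxin_here <- NULL
    if (i < config$n_stacks) {
      # xin_{i+1} = xin_i + remap_f(g1) + remap_h(logits)
      gxin_here <- gxin
      gg1 <- conv_b(st$g1, paste0(pre, "remap_f"), gxin)
      glog <- glog + conv_b(st$logits, paste0(pre, "remap_h"), gxin)
    }
    g_g1 <- conv_b(st$g1, paste0(pre, "head"), glog)
    if (!is.null(gg1)) g_g1 <- g_g1 + gg1
    gu1 <- conv_b(st$u1, paste0(pre, "g1"), relu_b(g_g1, st$g1))
    # u1 = upsample(g2) + sk1
    gr0_skip <- conv_b(st$r0, paste0(pre, "sk1"), relu_b(gu1, st$sk1))
    gg2 <- upsample2_bwd(gu1)
    gu2 <- conv_b(st$u2, paste0(pre, "g2"), relu_b(gg2, st$g2))
    gf1_skip <- conv_b(st$f1, paste0(pre, "sk2"), relu_b(gu2, st$sk2))
    gf3 <- upsample2_bwd(gu2)
    gf2 <- conv_b(st$f2, paste0(pre, "bott"), relu_b(gf3, st$f3))
    gp2 <- conv_b(st$p2$y, paste0(pre, "d2"), relu_b(gf2, st$f2))
    gf1 <- maxpool2_bwd(gp2, st$p2$idx, dim(st$f1)) + gf1_skip
    gp1 <- conv_b(st$p1$y, paste0(pre, "d1"), relu_b(gf1, st$f1))
    gr0 <- maxpool2_bwd(gp1, st$p1$idx, dim(st$r0)) + gr0_skip
    gx_stack <- conv_b(st$xin, paste0(pre, "pre"), relu_b(gr0, st$r0))
    gxin <- if (is.null(gxin_here)) gx_stack else gx_stack + gxin_here
  }
  # stem (reverse)
  ga <- gxin
  for (j in rev(seq_len(config$n_stem))) {
    stc <- cache$stem[[j + 1]]
    gpooled <- conv_b(stc$pooled, paste0("stem_", j), relu_b(ga, stc$post))
    ga <- maxpool2_bwd(gpooled, stc$pool$idx, dim(stc$pre_pool))
  }
  gx <- conv_b(cache$x, "stem_in", relu_b(ga, cache$stem[[1]]$post))
  list(grads = grads, gx = gx)
}

images_to_batch <- function(images, input_size) {
  N <- length(images)
  x <- array(0, c(input_size, input_size, 1, N))
  for (n in seq_len(N)) {
    im <- images[[n]]
    if (is.null(im) || nrow(im) != input_size || ncol(im) != input_size)
      stop_fedspine("image size does not match model config", "fedspine_config_error")
    x[, , 1, n] <- im
  }
  x
}

#' Forward pass: heatmaps per stack and predicted normalized coordinates
#'
#' @param params parameter list from [init_model_params()].
#' @param config the matching `model_config`.
#' @param images list of input matrices (or an (H, W, 1, N) array) matching
#'   `config$input_size`.
#' @return list(heatmaps = per-stack list of (nh, nw, K, N) normalized
#'   heatmap arrays, coords = (2, K, N) normalized coordinates from the last
#'   stack).
#' @export
model_forward <- function(params, config, images) {
  x <- if (is.array(images) && length(dim(images)) == 4) images
       else images_to_batch(images, config$input_size)
  if (dim(x)[1] != config$input_size || dim(x)[2] != config$input_size)
    stop_fedspine("image size does not match model config", "fedspine_config_error")
  fw <- hg_forward(params, config, x, keep = FALSE)
  hms <- lapply(fw$logits, softmax_heatmaps)
  coords <- dsnt_coords(hms[[length(hms)]])
  if (any(!is.finite(coords)))
    stop_fedspine("non-finite coordinates in forward pass", "fedspine_numeric_error")
  list(heatmaps = hms, coords = coords)
}

#' Loss and parameter gradients for one batch
#'
#' Applies the training loss (Euclidean coordinate error plus heatmap
#' divergence, intermediate supervision averaged over stacks) and
#' backpropagates to every parameter.
#'
#' @param params parameter list.
#' @param config `model_config`.
#' @param x input array (H, W, 1, N).
#' @param gt ground-truth normalized coordinates (2, K, N).
#' @return list(loss, euclidean, divergence, grads, coords).
#' @export
model_loss_and_grad <- function(params, config, x, gt) {
  fw <- hg_forward(params, config, x, keep = TRUE)
  S <- config$n_stacks
  nh <- dim(fw$logits[[1]])[1]; nw <- dim(fw$logits[[1]])[2]
  hm_gt <- target_heatmap(gt, nh, nw, config$sigma_hm)
  glogits <- vector("list", S)
  tot <- eu <- dv <- 0
  coords_last <- NULL
  for (i in seq_len(S)) {
    hm <- softmax_heatmaps(fw$logits[[i]])
    coords <- dsnt_coords(hm)
    ls <- dsnt_loss(coords, gt, hm, hm_gt, divergence = config$divergence, grad = TRUE)
    tot <- tot + ls$loss / S; eu <- eu + ls$euclidean / S; dv <- dv + ls$divergence / S
    glogits[[i]] <- softmax_dsnt_backward(hm, ls$gcoords, ls$ghm) / S
    if (i == S) coords_last <- coords
  }
  bw <- hg_backward(params, config, fw$cache, glogits)
  list(loss = tot, euclidean = eu, divergence = dv, grads = bw$grads,
       coords = coords_last)
}

# ---- coordinate frames ----

#' Convert input-image pixel coordinates to normalized DSNT coordinates
#'
#' @param px matrix/array of x or y pixel values (0-based, pixel centers).
#' @param input_size input side in pixels.
#' @param stride heatmap stride.
#' @return normalized values in (-1, 1).
#' @export
px_to_norm <- function(px, input_size, stride) {
  n <- input_size / stride
  j <- (px + 0.5) / stride - 0.5          # continuous heatmap pixel
  (2 * j + 1 - n) / n
}

#' Convert normalized DSNT coordinates back to input pixels
#'
#' Inverse of [px_to_norm()].
#' @param v normalized values.
#' @param input_size input side in pixels.
#' @param stride heatmap stride.
#' @return 0-based pixel coordinates.
#' @export
norm_to_px <- function(v, input_size, stride) {
  n <- input_size / stride
  j <- (v * n + n - 1) / 2
  (j + 0.5) * stride - 0.5
}

landmarks_to_gt <- function(samples, config) {
  K <- config$n_landmarks
  N <- length(samples)
  gt <- array(0, c(2, K, N))
  nm <- landmark_names()
  for (n in seq_len(N)) {
    pts <- samples[[n]]$landmarks$points[nm, , drop = FALSE]
    gt[1, , n] <- px_to_norm(pts[, 1], config$input_size, config$heatmap_stride)
    gt[2, , n] <- px_to_norm(pts[, 2], config$input_size, config$heatmap_stride)
  }
  gt
}

# ---- checkpointing ----

#' Save a model checkpoint (parameters + config + metadata)
#'
#' @param params parameter list.
#' @param config `model_config`.
#' @param meta arbitrary metadata list.
#' @param path output file.
#' @export
save_checkpoint <- function(params, config, meta = list(), path) {
  saveRDS(list(params = params, config = config, meta = meta,
               format_version = 1L), path)
  invisible(path)
}

#' Load a model checkpoint; bit-stable with [save_checkpoint()]
#'
#' @param path checkpoint file.
#' @return list(params, config, meta).
#' @export
load_checkpoint <- function(path) readRDS(path)

#' Finite-difference gradient check of the full model backward pass
#'
#' Compares the analytic gradient of the training loss with central finite
#' differences on `n_check` randomly chosen parameters.
#'
#' @param config a small `model_config`.
#' @param seed integer seed.
#' @param n_check number of coordinates to probe (default: all).
#' @param eps finite-difference step.
#' @return max relative error over probed coordinates.
#' @export
gradient_check <- function(config, seed = 1, n_check = NULL, eps = 1e-5) {
  params <- init_model_params(config, seed)
  with_seed(derive_seed(seed, "gc-data"), {
    x <- array(stats::runif(config$input_size^2), c(config$input_size, config$input_size, 1, 1))
    gt <- array(stats::runif(2 * config$n_landmarks, -0.6, 0.6),
                c(2, config$n_landmarks, 1))
  })
  an <- model_loss_and_grad(params, config, x, gt)
  gflat <- flatten_params(an$grads)
  th <- flatten_params(params)
  idx <- seq_along(th)
  if (!is.null(n_check) && n_check < length(idx))
    idx <- with_seed(derive_seed(seed, "gc-idx"), sample(idx, n_check))
  relerr <- 0
  for (i in idx) {
    thp <- th; thp[i] <- thp[i] + eps
    thm <- th; thm[i] <- thm[i] - eps
    lp <- model_loss_and_grad(unflatten_params(thp, params), config, x, gt)$loss
    lm_ <- model_loss_and_grad(unflatten_params(thm, params), config, x, gt)$loss
    fd <- (lp - lm_) / (2 * eps)
    denom <- max(abs(fd), abs(gflat[i]), 1e-6)
    relerr <- max(relerr, abs(fd - gflat[i]) / denom)
  }
  relerr
}
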