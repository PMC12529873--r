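# Training-time augmentation and geometric preprocessing. Photometric
# transforms (histogram equalization, coarse dropout, brightness/contrast,
# blur, noise) never touch the landmarks; rotation transforms image and
# landmarks with the same matrix about the image center. Everything is
# deterministic per seed.

bilinear_sample <- function(img, sx, sy) {
  H <- nrow(img); W <- ncol(img)
  sx <- clamp(sx, 0, W - 1); sy <- clamp(sy, 0, H - 1)
  x0 <- floor(sx); y0 <- floor(sy)
  x1 <- pmin(x0 + 1, W - 1); y1 <- pmin(y0 + 1, H - 1)
  fx <- sx - x0; fy <- sy - y0
  idx <- function(yy, xx) img[cbind(as.vector(yy) + 1, as.vector(xx) + 1)]
  v <- (1 - fx) * (1 - fy) * idx(y0, x0) + fx * (1 - fy) * idx(y0, x1) +
    (1 - fx) * fy * idx(y1, x0) + fx * fy * idx(y1, x1)
  matrix(v, H, W)
}

#' Rotate an image and its landmarks about the image center
#'
#' @param image H x W matrix.
#' @param lm a `landmark_set` (or NULL).
#' @param angle_deg rotation in degrees (positive: x-toward-y in image
#'   coordinates, i.e. clockwise on screen with y pointing down).
#' @return list(image, landmarks).
#' @export
rotate_sample <- function(image, lm, angle_deg) {
  if (angle_deg == 0) return(list(image = image, landmarks = lm))
  H <- nrow(image); W <- ncol(image)
  cx <- (W - 1) / 2; cy <- (H - 1) / 2
  th <- deg2rad(angle_deg)
  ct <- cos(th); st <- sin(th)
  xs <- matrix(rep(0:(W - 1), each = H), H, W) - cx
  ys <- matrix(rep(0:(H - 1), W), H, W) - cy
  # inverse map for the image, forward map for the landmarks
  sx <- ct * xs + st * ys + cx
  sy <- -st * xs + ct * ys + cy
  img2 <- bilinear_sample(image, sx, sy)
  if (!is.null(lm)) {
    p <- lm$points
    px <- p[, 1] - cx; py <- p[, 2] - cy
    p2 <- cbind(x = ct * px - st * py + cx, y = st * px + ct * py + cy)
    rownames(p2) <- rownames(p)
    lm <- landmark_set(p2, lm$pixel_spacing_mm, lm$facing, lm$image_size,
                       validate = FALSE)
  }
  list(image = img2, landmarks = lm)
}

hist_equalize <- function(img) {
  r <- rank(img, ties.method = "average")
  matrix((r - 1) / (length(r) - 1), nrow(img), ncol(img))
}

box_blur3 <- function(img) {
  H <- nrow(img); W <- ncol(img)
  p <- img[c(1, 1:H, H), c(1, 1:W, W)]  # edge-replicated pad
  out <- (p[1:H, 1:W] + p[1:H, 2:(W + 1)] + p[1:H, 3:(W + 2)] +
          p[2:(H + 1), 1:W] + p[2:(H + 1), 2:(W + 1)] + p[2:(H + 1), 3:(W + 2)] +
          p[3:(H + 2), 1:W] + p[3:(H + 2), 2:(W + 1)] + p[3:(H + 2), 3:(W + 2)]) / 9
  out
}

#' Stochastic training augmentation
#'
#' Applies, with seed-determined draws: contrast-limited-style histogram
#' equalization, coarse dropout patches, brightness and contrast jitter,
#' box blur, Gaussian noise, and a random rotation within
#' `c(-rotation_max, rotation_max)` degrees that transforms the landmarks
#' consistently. Photometric steps leave landmarks untouched.
#'
#' @param image H x W matrix in \[0, 1\].
#' @param lm the matching `landmark_set`.
#' @param rng_seed integer seed.
#' @param rotation_max rotation bound in degrees (default 10).
#' @return list(image, landmarks).
#' @export
augment <- function(image, lm, rng_seed, rotation_max = 10) {
  draws <- with_seed(rng_seed, list(
    eq = stats::runif(1) < 0.25,
    drop = stats::runif(1) < 0.3,
    n_rect = sample(1:3, 1),
    rect = matrix(stats::runif(12), 3, 4),
    bright = stats::runif(1, -0.15, 0.15),
    contrast = stats::runif(1, 0.85, 1.15),
    blur = stats::runif(1) < 0.3,
    noise_sd = stats::runif(1, 0, 0.03),
    noise = stats::rnorm(length(image)),
    angle = if (rotation_max > 0) stats::runif(1, -rotation_max, rotation_max) else 0
  ))
  H <- nrow(image); W <- ncol(image)
  if (draws$eq) image <- 0.5 * image + 0.5 * hist_equalize(image)
  if (draws$drop) {
    fill <- mean(image)
    for (r in seq_len(draws$n_rect)) {
      rw <- max(2, round(draws$rect[r, 3] * 0.2 * W))
      rh <- max(2, round(draws$rect[r, 4] * 0.2 * H))
      x0 <- 1 + round(draws$rect[r, 1] * (W - rw))
      y0 <- 1 + round(draws$rect[r, 2] * (H - rh))
      image[y0:(y0 + rh - 1), x0:(x0 + rw - 1)] <- fill
    }
  }
  image <- (image - 0.5) * draws$contrast + 0.5 + draws$bright
  if (draws$blur) image <- box_blur3(image)
  if (draws$noise_sd > 0)
    image <- image + draws$noise_sd * matrix(draws$noise, H, W)
  image <- clamp(image, 0, 1)
  rotate_sample(image, lm, draws$angle)
}

# Catmull-Rom (Keys, a = -0.5) cubic interpolation weights
.cubic_w <- function(t) {
  a <- -0.5
  at <- abs(t)
  w <- numeric(length(t))
  i1 <- at <= 1
  w[i1] <- (a + 2) * at[i1]^3 - (a + 3) * at[i1]^2 + 1
  i2 <- at > 1 & at < 2
  w[i2] <- a * at[i2]^3 - 5 * a * at[i2]^2 + 8 * a * at[i2] - 4 * a
  w
}

# dense resampling matrix (n_in x n_out) for bicubic scaling
.cubic_mat <- function(n_in, n_out) {
  s <- n_out / n_in
  M <- matrix(0, n_in, n_out)
  for (j in 0:(n_out - 1)) {
    src <- (j + 0.5) / s - 0.5
    base <- floor(src)
    taps <- (base - 1):(base + 2)
    w <- .cubic_w(src - taps)
    taps <- clamp(taps, 0, n_in - 1)  # edge-replicate
    for (k in 1:4) M[taps[k] + 1, j + 1] <- M[taps[k] + 1, j + 1] + w[k]
  }
  sweep(M, 2, colSums(M), "/")
}

#' Resize to a square target with preserved aspect ratio
#'
#' Scales the longest side to `target_size` with bicubic interpolation, pads
#' the short side symmetrically with the median border intensity, and maps
#' the landmarks by the same affine transform. The returned `transform`
#' allows predictions to be mapped back to the original pixel frame with
#' [map_landmarks_back()].
#'
#' @param image H x W matrix.
#' @param lm matching `landmark_set` (or NULL).
#' @param target_size output side in pixels.
#' @return list(image, landmarks, transform = list(scale, pad, orig_size)).
#' @export
resize_with_aspect <- function(image, lm, target_size) {
  H <- nrow(image); W <- ncol(image)
  scale <- target_size / max(H, W)
  newH <- if (H >= W) target_size else max(1L, as.integer(round(H * scale)))
  newW <- if (W > H) target_size else max(1L, as.integer(round(W * scale)))
  rs <- t(.cubic_mat(H, newH)) %*% image %*% .cubic_mat(W, newW)
  pad_x <- floor((target_size - newW) / 2)
  pad_y <- floor((target_size - newH) / 2)
  border <- c(rs[1, ], rs[newH, ], rs[, 1], rs[, newW])
  fill <- stats::median(border)
  out <- matrix(fill, target_size, target_size)
  out[(pad_y + 1):(pad_y + newH), (pad_x + 1):(pad_x + newW)] <- rs
  tr <- list(scale = scale, pad = c(pad_x, pad_y), orig_size = c(W, H))
  if (!is.null(lm)) {
    p <- lm$points
    p2 <- cbind(x = (p[, 1] + 0.5) * scale - 0.5 + pad_x,
                y = (p[, 2] + 0.5) * scale - 0.5 + pad_y)
    rownames(p2) <- rownames(p)
    lm <- landmark_set(p2, lm$pixel_spacing_mm / scale, lm$facing,
                       c(target_size, target_size), validate = FALSE)
  }
  list(image = out, landmarks = lm, transform = tr)
}

#' Map landmark coordinates back to the original pixel frame
#'
#' Inverse of the affine transform recorded by [resize_with_aspect()].
#'
#' @param points n x 2 matrix of (x, y) in the resized frame.
#' @param transform the `transform` element from [resize_with_aspect()].
#' @return n x 2 matrix in original pixels.
#' @export
map_landmarks_back <- function(points, transform) {
  cbind(x = (points[, 1] - transform$pad[1] + 0.5) / transform$scale - 0.5,
        y = (points[, 2] - transform$pad[2] + 0.5) / transform$scale - 0.5)
}
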