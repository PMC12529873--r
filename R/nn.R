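# DSNT coordinate head, heatmap losses and the Adam optimizer.
#
# Heatmaps live on an (nh x nw) grid; after spatial softmax each landmark's
# heatmap is a probability distribution. The DSNT output is its expectation
# over fixed normalized coordinate grids with values (2k - (n+1))/n for
# k = 1..n, so coordinates lie in (-1, 1) independent of resolution.

#' Normalized DSNT coordinate grid
#'
#' @param n number of pixels along the axis.
#' @return numeric vector of length `n` with values (2k - (n+1))/n.
#' @export
dsnt_grid <- function(n) (2 * seq_len(n) - (n + 1)) / n

# heatmap array (nh, nw, K, N) -> matrix (nh*nw, K*N)
hm_as_mat <- function(hm) {
  d <- dim(hm)
  dim(hm) <- c(d[1] * d[2], d[3] * d[4])
  hm
}

#' Spatial softmax normalization of heatmap logits
#'
#' @param logits array (nh, nw, K, N).
#' @return array of same shape; each (K, N) slice is nonnegative and sums to 1.
#' @export
softmax_heatmaps <- function(logits) {
  d <- dim(logits)
  m <- hm_as_mat(logits)
  mx <- apply(m, 2, max)
  e <- exp(sweep(m, 2, mx))
  p <- sweep(e, 2, colSums(e), "/")
  dim(p) <- d
  p
}

#' DSNT: expectation of normalized heatmaps over the coordinate grids
#'
#' @param hm array (nh, nw, K, N) of normalized heatmaps.
#' @return array (2, K, N); rows are (x, y) in normalized (-1, 1) units.
#' @export
dsnt_coords <- function(hm) {
  d <- dim(hm)
  nh <- d[1]; nw <- d[2]
  gx <- dsnt_grid(nw); gy <- dsnt_grid(nh)
  GX <- rep(gx, each = nh)  # index r = h + nh*w
  GY <- rep(gy, times = nw)
  m <- hm_as_mat(hm)
  cx <- as.vector(crossprod(m, GX))
  cy <- as.vector(crossprod(m, GY))
  out <- rbind(cx, cy)
  dim(out) <- c(2, d[3], d[4])
  out
}

#' Gaussian target heatmaps from ground-truth normalized coordinates
#'
#' Isotropic Gaussian of standard deviation `sigma_hm` (heatmap pixels)
#' centered at the ground-truth location on the heatmap grid, renormalized to
#' sum to 1.
#'
#' @param gt array (2, K, N) of normalized coordinates.
#' @param nh,nw heatmap height and width.
#' @param sigma_hm Gaussian std in heatmap pixels.
#' @return array (nh, nw, K, N) of normalized heatmaps.
#' @export
target_heatmap <- function(gt, nh, nw, sigma_hm = 1) {
  K <- dim(gt)[2]; N <- dim(gt)[3]
  gtm <- matrix(gt, 2, K * N)
  # continuous 0-based pixel position of the target on the heatmap grid
  jx <- (gtm[1, ] * nw + nw - 1) / 2
  jy <- (gtm[2, ] * nh + nh - 1) / 2
  ex <- exp(-(outer(0:(nw - 1), jx, "-"))^2 / (2 * sigma_hm^2))  # nw x KN
  ey <- exp(-(outer(0:(nh - 1), jy, "-"))^2 / (2 * sigma_hm^2))  # nh x KN
  m <- ey[rep(seq_len(nh), nw), , drop = FALSE] *
    ex[rep(seq_len(nw), each = nh), , drop = FALSE]
  m <- sweep(m, 2, colSums(m), "/")
  dim(m) <- c(nh, nw, K, N)
  m
}

.xlogx <- function(a, b) {
  # sum a * log(a/b) with the 0 log 0 = 0 convention, columnwise
  out <- a * (log(pmax(a, 1e-300)) - log(pmax(b, 1e-300)))
  out[a <= 0] <- 0
  colSums(out)
}

#' Jensen-Shannon divergence between heatmap distributions, columnwise
#'
#' @param p,q matrices (pixels x distributions), columns summing to 1.
#' @return numeric vector of divergences per column (nats).
#' @export
js_divergence <- function(p, q) {
  m <- (p + q) / 2
  0.5 * .xlogx(p, m) + 0.5 * .xlogx(q, m)
}

#' DSNT training loss: Euclidean coordinate error plus heatmap divergence
#'
#' Mean over landmarks and batch of the Euclidean distance between predicted
#' and ground-truth normalized coordinates, plus the mean divergence
#' D(target heatmap, predicted heatmap). D is Jensen-Shannon by default;
#' `divergence = "kl"` selects KL(target || predicted).
#'
#' @param coords predicted coordinates, array (2, K, N).
#' @param gt ground-truth coordinates, array (2, K, N).
#' @param hm predicted normalized heatmaps (nh, nw, K, N).
#' @param hm_gt target heatmaps, same shape.
#' @param divergence `"js"` or `"kl"`.
#' @param grad also return gradients w.r.t. `coords` and `hm`.
#' @return list(loss, euclidean, divergence, and optionally gcoords, ghm).
#' @export
dsnt_loss <- function(coords, gt, hm, hm_gt, divergence = c("js", "kl"), grad = FALSE) {
  divergence <- match.arg(divergence)
  d <- dim(hm)
  KN <- d[3] * d[4]
  p <- hm_as_mat(hm); q <- hm_as_mat(hm_gt)
  sums <- colSums(p)
  if (any(abs(sums - 1) > 1e-6))
    stop_fedspine("predicted heatmaps are not normalized to sum 1",
                  "fedspine_contract_error")
  if (any(abs(colSums(q) - 1) > 1e-6))
    stop_fedspine("target heatmaps are not normalized to sum 1",
                  "fedspine_contract_error")
  dxy <- matrix(coords - gt, 2, KN)
  dist <- sqrt(colSums(dxy^2))
  L_e <- mean(dist)
  if (divergence == "js") {
    div <- js_divergence(p, q)
  } else {
    div <- .xlogx(q, p)
  }
  L_d <- mean(div)
  out <- list(loss = L_e + L_d, euclidean = L_e, divergence = L_d)
  if (grad) {
    gc <- sweep(dxy, 2, pmax(dist, 1e-8), "/") / KN
    dim(gc) <- dim(coords)
    if (divergence == "js") {
      m <- (p + q) / 2
      gp <- 0.5 * (log(pmax(p, 1e-300)) - log(pmax(m, 1e-300))) / KN
    } else {
      gp <- -(q / pmax(p, 1e-300)) / KN
    }
    dim(gp) <- d
    out$gcoords <- gc
    out$ghm <- gp
  }
  out
}

# Backprop total heatmap gradient (from the coordinate head and the
# divergence term) through the spatial softmax to logits.
softmax_dsnt_backward <- function(hm, gcoords, ghm) {
  d <- dim(hm)
  nh <- d[1]; nw <- d[2]
  GX <- rep(dsnt_grid(nw), each = nh)
  GY <- rep(dsnt_grid(nh), times = nw)
  p <- hm_as_mat(hm)
  gcm <- matrix(gcoords, 2, d[3] * d[4])
  gtot <- outer(GX, gcm[1, ]) + outer(GY, gcm[2, ]) + hm_as_mat(ghm)
  dot <- colSums(gtot * p)
  gz <- p * sweep(gtot, 2, dot)
  dim(gz) <- d
  gz
}

# ---- parameter containers ----

#' Flatten a model parameter list into a ParamVector
#'
#' The flat view concatenates every layer's weights and biases in the fixed
#' order defined by the model config; it is the unit of federated exchange.
#'
#' @param params named list of list(W, b).
#' @return numeric vector.
#' @export
flatten_params <- function(params) unlist(params, use.names = FALSE)

#' Restore a parameter list from its flat ParamVector
#'
#' @param vec numeric vector from [flatten_params()].
#' @param skeleton a parameter list with the target shapes.
#' @return parameter list with `vec`'s values.
#' @export
unflatten_params <- function(vec, skeleton) {
  pos <- 0L
  for (ln in names(skeleton)) {
    for (fn in names(skeleton[[ln]])) {
      n <- length(skeleton[[ln]][[fn]])
      if (n == 0L) next
      a <- vec[(pos + 1L):(pos + n)]
      dim(a) <- dim(skeleton[[ln]][[fn]])
      skeleton[[ln]][[fn]] <- a
      pos <- pos + n
    }
  }
  stopifnot(pos == length(vec))
  skeleton
}

#' Total number of trainable parameters
#' @param params parameter list.
#' @return integer count.
#' @export
count_params <- function(params) length(flatten_params(params))

# ---- Adam ----

adam_init <- function(params) {
  n <- length(flatten_params(params))
  list(m = numeric(n), v = numeric(n), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  g <- flatten_params(grads)
  th <- flatten_params(params)
  state$t <- state$t + 1L
  state$m <- beta1 * state$m + (1 - beta1) * g
  state$v <- beta2 * state$v + (1 - beta2) * g^2
  mhat <- state$m / (1 - beta1^state$t)
  vhat <- state$v / (1 - beta2^state$t)
  th <- th - lr * mhat / (sqrt(vhat) + eps)
  list(params = unflatten_params(th, params), state = state)
}
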