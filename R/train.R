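# Centralized and per-hospital local training pipelines: Adam over the DSNT
# loss, step learning-rate decay, early stopping on the validation metric and
# best-validation checkpoint selection. The same inner epoch loop drives
# federated clients, so single-client federated training coincides with local
# training under matched seeds.

#' Training configuration
#'
#' Defaults follow the study schedules: 200 epochs, learning rate 1e-4
#' reduced by a factor of 10 after 50 epochs, early stopping after 10
#' validation epochs without improvement, batch size 8.
#'
#' @param mode `"centralized"`, `"local"` or `"federated"`.
#' @param epochs maximum epochs.
#' @param lr base learning rate.
#' @param lr_decay list(factor, after_epochs) or NULL.
#' @param early_stop_patience consecutive non-improving validation epochs
#'   before stopping; NULL disables.
#' @param batch_size minibatch size.
#' @param seed integer seed (initialization and data order).
#' @param augment apply training augmentation.
#' @param checkpoint_metric `"landmark_error"` (mean validation landmark
#'   error, mm) or `"loss"` (validation DSNT loss).
#' @return object of class `train_config`.
#' @export
train_config <- function(mode = c("centralized", "local", "federated"),
                         epochs = 200L, lr = 1e-4,
                         lr_decay = list(factor = 0.1, after_epochs = 50),
                         early_stop_patience = 10L, batch_size = 8L, seed = 1L,
                         augment = FALSE,
                         checkpoint_metric = c("landmark_error", "loss")) {
  mode <- match.arg(mode)
  checkpoint_metric <- match.arg(checkpoint_metric)
  stopifnot(epochs >= 0, lr > 0, batch_size >= 1)
  structure(list(mode = mode, epochs = as.integer(epochs), lr = lr,
                 lr_decay = lr_decay, early_stop_patience = early_stop_patience,
                 batch_size = as.integer(batch_size), seed = as.integer(seed),
                 augment = augment, checkpoint_metric = checkpoint_metric),
            class = "train_config")
}

#' Step learning-rate schedule
#'
#' Base rate before the decay threshold; `base * factor` at and after it.
#' Indices are 0-based (epochs or federated rounds), so with
#' `after = 50` epochs 0..49 run at the base rate and epoch 50 is decayed.
#'
#' @param index 0-based epoch or round index.
#' @param base base learning rate.
#' @param decay list(factor, after_epochs or after_rounds), or NULL.
#' @return learning rate for the index.
#' @export
lr_schedule <- function(index, base, decay = NULL) {
  if (is.null(decay)) return(base)
  after <- decay$after_epochs %||% decay$after_rounds
  if (index >= after) base * decay$factor else base
}

# ---- early stopping / checkpoint selection state machine ----

es_init <- function(patience, tol = 1e-6) {
  list(best = Inf, best_index = NA_integer_, bad = 0L, n = 0L,
       patience = patience, tol = tol, stop = FALSE)
}

es_update <- function(state, metric) {
  state$n <- state$n + 1L
  if (metric < state$best - state$tol) {     # strict improvement with tolerance
    state$best <- metric
    state$best_index <- state$n
    state$bad <- 0L
  } else {
    state$bad <- state$bad + 1L
    if (!is.null(state$patience) && state$bad >= state$patience) state$stop <- TRUE
  }
  state
}

#' Trace early stopping and checkpoint selection over a scripted metric sequence
#'
#' Feeds a given validation-metric sequence through the exact state machine
#' used by the training loops.
#'
#' @param metrics numeric vector of per-epoch validation metrics.
#' @param patience early-stop patience (NULL disables).
#' @param tol improvement tolerance.
#' @return list(stopped_epoch, best_epoch, best_metric).
#' @export
run_scripted_training <- function(metrics, patience, tol = 1e-6) {
  st <- es_init(patience, tol)
  stopped <- length(metrics)
  for (i in seq_along(metrics)) {
    st <- es_update(st, metrics[i])
    if (st$stop) { stopped <- i; break }
  }
  list(stopped_epoch = stopped, best_epoch = st$best_index, best_metric = st$best)
}

# ---- inner epoch loop (shared with federated clients) ----

make_training_batch <- function(samples, config, augment_seed = NULL) {
  if (!is.null(augment_seed)) {
    samples <- lapply(seq_along(samples), function(i) {
      s <- samples[[i]]
      a <- augment(s$image, s$landmarks, derive_seed(augment_seed, s$image_id))
      list(image = a$image, landmarks = a$landmarks)
    })
  }
  list(x = images_to_batch(lapply(samples, `[[`, "image"), config$input_size),
       gt = landmarks_to_gt(samples, config))
}

train_epochs <- function(params, opt_state, samples, config, lr_fn, n_epochs,
                         base_seed, epoch_offset = 0L, batch_size = 8L,
                         augment = FALSE, mu = 0, global_params = NULL) {
  N <- length(samples)
  losses <- numeric(n_epochs)
  g_flat_global <- if (mu > 0) flatten_params(global_params) else NULL
  for (e in seq_len(n_epochs)) {
    gep <- epoch_offset + e - 1L
    lr_e <- lr_fn(gep)
    ord <- with_seed(derive_seed(base_seed, "order", gep), sample(N))
    batch_starts <- seq(1, N, by = batch_size)
    eloss <- 0
    for (bs in batch_starts) {
      idx <- ord[bs:min(bs + batch_size - 1, N)]
      aug_seed <- if (augment) derive_seed(base_seed, "aug", gep) else NULL
      bt <- make_training_batch(samples[idx], config, aug_seed)
      r <- model_loss_and_grad(params, config, bt$x, bt$gt)
      grads <- r$grads
      if (mu > 0) {
        gf <- flatten_params(grads) + mu * (flatten_params(params) - g_flat_global)
        grads <- unflatten_params(gf, grads)
      }
      st <- adam_step(params, grads, opt_state, lr_e)
      params <- st$params; opt_state <- st$state
      eloss <- eloss + r$loss * length(idx)
    }
    losses[e] <- eloss / N
  }
  list(params = params, opt_state = opt_state, train_loss = losses)
}

#' Validation metric of a parameter set
#'
#' @param params parameter list.
#' @param config `model_config`.
#' @param samples validation `spine_sample`s.
#' @param metric `"landmark_error"` (mean per-image mean landmark error, mm)
#'   or `"loss"` (mean DSNT loss).
#' @param batch_size forward batch size.
#' @return scalar metric (lower is better).
#' @export
validation_metric <- function(params, config, samples,
                              metric = "landmark_error", batch_size = 16L) {
  N <- length(samples)
  if (N == 0) return(NA_real_)
  tot <- 0
  for (bs in seq(1, N, by = batch_size)) {
    idx <- bs:min(bs + batch_size - 1, N)
    bt <- make_training_batch(samples[idx], config)
    if (metric == "loss") {
      fw <- hg_forward(params, config, bt$x, keep = FALSE)
      hm <- softmax_heatmaps(fw$logits[[config$n_stacks]])
      d <- dim(hm)
      hm_gt <- target_heatmap(bt$gt, d[1], d[2], config$sigma_hm)
      ls <- dsnt_loss(dsnt_coords(hm), bt$gt, hm, hm_gt, divergence = config$divergence)
      tot <- tot + ls$loss * length(idx)
    } else {
      preds <- predict_landmarks(params, config, samples[idx])
      errs <- vapply(seq_along(idx), function(i)
        mean(landmark_error(preds[[i]], samples[[idx[i]]]$landmarks)$per_point), 0)
      tot <- tot + sum(errs)
    }
  }
  tot / N
}

train_run <- function(samples_train, samples_val, config, tcfg,
                      init_params = NULL, sgd_seed = NULL) {
  if (!length(samples_train)) stop_fedspine("empty training split", "fedspine_config_error")
  params <- init_params %||% init_model_params(config, derive_seed(tcfg$seed, "init"))
  if (tcfg$epochs == 0)
    return(structure(list(best_params = params, final_params = params,
                          best_val_metric = NA_real_, stopped_epoch = 0L,
                          history = data.frame(epoch = integer(), lr = numeric(),
                                               train_loss = numeric(), val_metric = numeric())),
                     class = "fit_result"))
  sgd_seed <- sgd_seed %||% derive_seed(tcfg$seed, "sgd", "all")
  opt <- adam_init(params)
  es <- es_init(tcfg$early_stop_patience)
  best_params <- params
  hist <- vector("list", tcfg$epochs)
  lr_fn <- function(ep) lr_schedule(ep, tcfg$lr, tcfg$lr_decay)
  stopped <- tcfg$epochs
  for (ep in seq_len(tcfg$epochs)) {
    r <- train_epochs(params, opt, samples_train, config, lr_fn, 1L, sgd_seed,
                      epoch_offset = ep - 1L, batch_size = tcfg$batch_size,
                      augment = tcfg$augment)
    params <- r$params; opt <- r$opt_state
    vm <- validation_metric(params, config, samples_val, tcfg$checkpoint_metric)
    if (is.na(vm)) {  # no validation data: keep last parameters, never stop early
      best_params <- params
      hist[[ep]] <- data.frame(epoch = ep, lr = lr_fn(ep - 1L),
                               train_loss = r$train_loss, val_metric = NA_real_)
      next
    }
    es2 <- es_update(es, vm)
    if (identical(es2$best_index, es2$n)) best_params <- params
    es <- es2
    hist[[ep]] <- data.frame(epoch = ep, lr = lr_fn(ep - 1L),
                             train_loss = r$train_loss, val_metric = vm)
    if (es$stop) { stopped <- ep; break }
  }
  structure(list(best_params = best_params, final_params = params,
                 best_val_metric = es$best,
                 best_epoch = es$best_index, stopped_epoch = stopped,
                 history = do.call(rbind, hist[!vapply(hist, is.null, TRUE)])),
            class = "fit_result")
}

split_samples <- function(samples, split, which_split, center = NULL) {
  sel <- split$split == which_split
  if (!is.null(center)) sel <- sel & split$center_id == center
  ids <- split$image_id[sel]
  samples[vapply(samples, `[[`, "", "image_id") %in% ids]
}

#' Centralized training: one model on the pooled training data
#'
#' Pools every center's training split, checkpoints on the pooled validation
#' split, and applies the configured learning-rate decay and early stopping.
#'
#' @param samples full cohort (list of `spine_sample`s).
#' @param split a `split_assignment`.
#' @param config `model_config`.
#' @param tcfg `train_config`.
#' @param init_params optional initial parameters (otherwise seeded init).
#' @param sgd_seed optional explicit seed for data order/augmentation.
#' @return a `fit_result`: best_params, best_val_metric, stopped_epoch, history.
#' @export
train_centralized <- function(samples, split, config, tcfg,
                              init_params = NULL, sgd_seed = NULL) {
  train_run(split_samples(samples, split, "train"),
            split_samples(samples, split, "validation"),
            config, tcfg, init_params, sgd_seed)
}

#' Local training: one model on a single hospital's data
#'
#' @param samples full cohort.
#' @param split a `split_assignment`.
#' @param center_id the hospital to train on.
#' @param config `model_config`.
#' @param tcfg `train_config`.
#' @param init_params optional initial parameters.
#' @param sgd_seed optional explicit data-order seed.
#' @return a `fit_result`.
#' @export
train_local <- function(samples, split, center_id, config, tcfg,
                        init_params = NULL, sgd_seed = NULL) {
  train_run(split_samples(samples, split, "train", center_id),
            split_samples(samples, split, "validation", center_id),
            config, tcfg, init_params,
            sgd_seed %||% derive_seed(tcfg$seed, "sgd", center_id))
}
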