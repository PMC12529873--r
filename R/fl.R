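# Cross-silo federated core: FedAvg, FedOpt and FedProx as pure
# parameter-space operations, plus the synchronous round loop. Clients expose
# only a ClientUpdate (parameters + sample count + scalar metrics); no raw
# samples ever cross the server boundary. Client updates are always reduced
# in sorted client_id order so results are machine-reproducible regardless of
# scheduling order.

#' Construct a ClientUpdate
#'
#' @param params parameter list conforming to the shared model config.
#' @param n_samples client training-set size (the aggregation weight n_k).
#' @param client_id client label.
#' @param round_metrics named list of scalar metrics for the round.
#' @return object of class `client_update`.
#' @export
client_update <- function(params, n_samples, client_id, round_metrics = list()) {
  if (n_samples <= 0) stop_fedspine("n_samples must be > 0", "fedspine_protocol_error")
  structure(list(params = params, n_samples = as.integer(n_samples),
                 client_id = client_id, round_metrics = round_metrics),
            class = "client_update")
}

#' Federated schedule with the study's per-strategy defaults
#'
#' FedAvg: 10 local epochs x 30 rounds, client LR 1e-4 decayed x0.1 after 15
#' rounds. FedOpt: 3 x 100, client LR 1e-3, server LR 1e-4 (adaptive-moment
#' server optimizer). FedProx: 10 x 100, client LR 1e-4, proximal mu
#' (default 0.01), plain weighted-average aggregation with an optional
#' server damping factor.
#'
#' @param strategy `"fedavg"`, `"fedopt"` or `"fedprox"`.
#' @param ... overrides of the strategy defaults (local_epochs, rounds,
#'   client_lr, server_lr, lr_decay, mu, betas, tau, server_opt,
#'   server_damping).
#' @return object of class `fl_schedule`.
#' @export
fl_schedule <- function(strategy = c("fedavg", "fedopt", "fedprox"), ...) {
  strategy <- match.arg(strategy)
  def <- switch(strategy,
    fedavg = list(local_epochs = 10L, rounds = 30L, client_lr = 1e-4,
                  lr_decay = list(factor = 0.1, after_rounds = 15), server_lr = NULL,
                  mu = 0, server_opt = "average", server_damping = NULL,
                  betas = c(0.9, 0.999), tau = 1e-9),
    fedopt = list(local_epochs = 3L, rounds = 100L, client_lr = 1e-3,
                  lr_decay = NULL, server_lr = 1e-4, mu = 0, server_opt = "adam",
                  server_damping = NULL, betas = c(0.9, 0.999), tau = 1e-9),
    fedprox = list(local_epochs = 10L, rounds = 100L, client_lr = 1e-4,
                   lr_decay = NULL, server_lr = NULL, mu = 0.01,
                   server_opt = "average", server_damping = NULL,
                   betas = c(0.9, 0.999), tau = 1e-9))
  ov <- list(...)
  for (nm in names(ov)) def[[nm]] <- ov[[nm]]
  def$strategy <- strategy
  stopifnot(def$local_epochs >= 1, def$rounds >= 0, def$mu >= 0)
  structure(def, class = "fl_schedule")
}

check_updates <- function(updates) {
  if (!length(updates)) stop_fedspine("no client updates", "fedspine_aggregation_error")
  len0 <- length(flatten_params(updates[[1]]$params))
  for (u in updates)
    if (length(flatten_params(u$params)) != len0)
      stop_fedspine("client parameter shapes do not conform", "fedspine_protocol_error")
  updates[order(vapply(updates, `[[`, "", "client_id"))]
}

#' FedAvg aggregation: sample-size-weighted parameter average
#'
#' Elementwise sum of (n_k / sum n) * theta_k over clients, reduced in sorted
#' client_id order.
#'
#' @param updates list of `client_update`s.
#' @return aggregated parameter list.
#' @export
fedavg_aggregate <- function(updates) {
  updates <- check_updates(updates)
  n <- vapply(updates, function(u) as.numeric(u$n_samples), 0)
  w <- n / sum(n)
  acc <- w[1] * flatten_params(updates[[1]]$params)
  if (length(updates) > 1)
    for (i in 2:length(updates))
      acc <- acc + w[i] * flatten_params(updates[[i]]$params)
  unflatten_params(acc, updates[[1]]$params)
}

#' Initialize server state
#'
#' @param global_params initial global parameter list.
#' @return object of class `server_state` (global params, server-optimizer
#'   moments, round counter).
#' @export
server_state <- function(global_params) {
  n <- length(flatten_params(global_params))
  structure(list(global_params = global_params,
                 opt = list(m = numeric(n), v = numeric(n)),
                 round_index = 0L),
            class = "server_state")
}

#' FedOpt server step: adaptive-moment update on the pseudo-gradient
#'
#' The pseudo-gradient is g = global - fedavg(updates). In `"adam"` mode the
#' server applies a FedAdam-style update m <- b1 m + (1-b1) g,
#' v <- b2 v + (1-b2) g^2, global <- global - server_lr * m / (sqrt(v) + tau).
#' In `"average"` mode the server moves plainly along -g with step server_lr;
#' at server_lr = 1 this reproduces FedAvg exactly.
#'
#' @param state a `server_state`.
#' @param updates list of `client_update`s.
#' @param schedule an `fl_schedule` (server_lr, betas, tau, server_opt).
#' @return updated `server_state` (round_index incremented).
#' @export
fedopt_server_step <- function(state, updates, schedule) {
  avg <- fedavg_aggregate(updates)
  if (identical(schedule$server_opt, "average")) {
    lr <- schedule$server_lr %||% 1
    if (lr == 1) {
      state$global_params <- avg
    } else {
      gf <- flatten_params(state$global_params) - flatten_params(avg)
      state$global_params <- unflatten_params(
        flatten_params(state$global_params) - lr * gf, state$global_params)
    }
  } else {
    g <- flatten_params(state$global_params) - flatten_params(avg)
    b <- schedule$betas
    state$opt$m <- b[1] * state$opt$m + (1 - b[1]) * g
    state$opt$v <- b[2] * state$opt$v + (1 - b[2]) * g^2
    step <- schedule$server_lr * state$opt$m / (sqrt(state$opt$v) + schedule$tau)
    state$global_params <- unflatten_params(
      flatten_params(state$global_params) - step, state$global_params)
  }
  state$round_index <- state$round_index + 1L
  state
}

#' FedProx client objective: base loss plus proximal penalty
#'
#' @param base_loss function(params) -> scalar local loss.
#' @param params client parameter list.
#' @param global_params current global parameter list.
#' @param mu proximal coefficient (>= 0).
#' @return base_loss(params) + (mu / 2) * ||params - global_params||^2.
#' @export
fedprox_client_objective <- function(base_loss, params, global_params, mu) {
  if (mu < 0) stop_fedspine("mu must be >= 0", "fedspine_config_error")
  pen <- if (mu > 0)
    (mu / 2) * sum((flatten_params(params) - flatten_params(global_params))^2) else 0
  base_loss(params) + pen
}

# One client's local fit for a round; returns only a ClientUpdate.
local_client_fit <- function(client, global_params, schedule, config, lr,
                             round_index, rng_seed, dry_run = FALSE) {
  if (dry_run)
    return(client_update(global_params, client$n_train, client$client_id,
                         list(epochs_run = schedule$local_epochs)))
  r <- train_epochs(global_params, adam_init(global_params), client$train, config,
                    function(ep) lr, schedule$local_epochs,
                    base_seed = client$sgd_seed,
                    epoch_offset = round_index * schedule$local_epochs,
                    batch_size = client$batch_size %||% 8L,
                    augment = isTRUE(client$augment),
                    mu = schedule$mu, global_params = global_params)
  client_update(r$params, client$n_train, client$client_id,
                list(train_loss = r$train_loss[length(r$train_loss)],
                     epochs_run = schedule$local_epochs))
}

#' Run one synchronous federated round
#'
#' Broadcasts the global parameters, lets every client train
#' `schedule$local_epochs` epochs on its private training split (with the
#' FedProx proximal term when `strategy = "fedprox"`), collects the
#' ClientUpdates and aggregates them per strategy.
#'
#' @param state a `server_state`.
#' @param clients list of clients: list(client_id, train, n_train, sgd_seed).
#' @param schedule an `fl_schedule`.
#' @param config shared `model_config`.
#' @param rng_seed integer seed.
#' @param dry_run only count scheduled epochs; no training.
#' @return list(state, updates_meta = per-client metrics data.frame).
#' @export
run_round <- function(state, clients, schedule, config, rng_seed, dry_run = FALSE) {
  r <- state$round_index
  lr <- lr_schedule(r, schedule$client_lr, schedule$lr_decay)
  ord <- order(vapply(clients, `[[`, "", "client_id"))
  updates <- lapply(clients[ord], local_client_fit, global_params = state$global_params,
                    schedule = schedule, config = config, lr = lr,
                    round_index = r, rng_seed = rng_seed, dry_run = dry_run)
  meta <- data.frame(
    round = r + 1L,
    client = vapply(updates, `[[`, "", "client_id"),
    n_samples = vapply(updates, function(u) u$n_samples, 0L),
    epochs_run = vapply(updates, function(u)
      as.numeric(u$round_metrics$epochs_run %||% NA_real_), 0),
    train_loss = vapply(updates, function(u) u$round_metrics$train_loss %||% NA_real_, 0),
    lr = lr)
  if (dry_run) {
    state$round_index <- state$round_index + 1L
  } else if (schedule$strategy == "fedopt") {
    state <- fedopt_server_step(state, updates, schedule)
  } else {
    agg <- fedavg_aggregate(updates)
    if (schedule$strategy == "fedprox" && !is.null(schedule$server_damping)) {
      d <- schedule$server_damping
      agg <- unflatten_params(
        flatten_params(state$global_params) +
          d * (flatten_params(agg) - flatten_params(state$global_params)),
        state$global_params)
    }
    state$global_params <- agg
    state$round_index <- state$round_index + 1L
  }
  list(state = state, updates_meta = meta)
}

#' Run a full federated simulation
#'
#' Builds one client per center from the split, runs `schedule$rounds`
#' synchronous rounds, tracks the pooled-validation metric each round and
#' returns the parameters achieving the best validation metric alongside the
#' full history and the round loop's epoch counters.
#'
#' @param samples full cohort (list of `spine_sample`s).
#' @param split a `split_assignment`.
#' @param schedule an `fl_schedule`.
#' @param config shared `model_config`.
#' @param rng_seed integer master seed.
#' @param dry_run count scheduled epochs only (no training, no validation).
#' @param init_params optional initial global parameters.
#' @param batch_size client minibatch size.
#' @param augment client-side augmentation flag.
#' @return list(best_params, final_params, best_round, history,
#'   counters = list(total_local_epochs_per_client, rounds_run)).
#' @export
run_fl <- function(samples, split, schedule, config, rng_seed, dry_run = FALSE,
                   init_params = NULL, batch_size = 8L, augment = FALSE) {
  centers <- sort(unique(split$center_id))
  clients <- lapply(centers, function(cid) {
    tr <- split_samples(samples, split, "train", cid)
    list(client_id = cid, train = tr, n_train = length(tr),
         sgd_seed = derive_seed(rng_seed, "sgd", cid),
         batch_size = batch_size, augment = augment)
  })
  clients <- clients[vapply(clients, function(cl) cl$n_train > 0, TRUE)]
  if (!length(clients)) stop_fedspine("no clients with training data", "fedspine_config_error")
  val <- if (!dry_run) split_samples(samples, split, "validation") else list()

  state <- server_state(init_params %||% init_model_params(config, derive_seed(rng_seed, "init")))
  best_params <- state$global_params
  best_metric <- Inf; best_round <- 0L
  hist <- list()
  counters <- stats::setNames(numeric(length(clients)),
                              vapply(clients, `[[`, "", "client_id"))
  rounds <- schedule$rounds
  if (rounds >= 1) for (r in seq_len(rounds)) {
    rr <- run_round(state, clients, schedule, config, rng_seed, dry_run = dry_run)
    state <- rr$state
    m <- rr$updates_meta
    counters[m$client] <- counters[m$client] + m$epochs_run
    if (!dry_run && length(val)) {
      vm <- validation_metric(state$global_params, config, val)
      m$val_metric <- vm
      if (vm < best_metric - 1e-6) {
        best_metric <- vm; best_params <- state$global_params; best_round <- r
      }
    } else m$val_metric <- NA_real_
    hist[[r]] <- m
  }
  if (!is.finite(best_metric)) best_params <- state$global_params
  list(best_params = best_params, final_params = state$global_params,
       best_round = best_round, best_val_metric = best_metric,
       history = if (length(hist)) do.call(rbind, hist) else NULL,
       counters = list(total_local_epochs_per_client = counters,
                       rounds_run = state$round_index))
}

#' Write a federated round history as CSV
#'
#' @param history the `history` data.frame from [run_fl()].
#' @param path output csv.
#' @export
write_fl_history <- function(history, path) {
  utils::write.csv(history, path, row.names = FALSE)
  invisible(path)
}
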