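# Desk-scale end-to-end study: the three training arms (centralized,
# per-hospital local, FedAvg) on a heterogeneous four-center synthetic
# cohort, followed by the cross-site evaluation matrix. This is the
# scaled-down mirror of the full simulation: the full schedules remain
# available through train_config()/fl_schedule() defaults, while the desk
# preset trades resolution and epochs for single-CPU runtimes.

#' Scheduled local-epoch totals per client, from the round loop's counters
#'
#' Dry-runs the federated round loop (no training) for the requested
#' strategies at their default schedules and returns each strategy's total
#' scheduled local epochs per client as counted by the loop itself.
#'
#' @param strategies strategy names.
#' @param rng_seed integer seed (cohort plumbing only).
#' @return named numeric vector of total local epochs per client.
#' @export
schedule_totals <- function(strategies = c("fedavg", "fedopt", "fedprox"),
                            rng_seed = 1L) {
  profiles <- default_center_profiles()
  samples <- generate_cohort(profiles, n_patients = 20, rng_seed = rng_seed,
                             canvas = c(64, 64), spacing_mm = 6, render = FALSE)
  split <- suppressWarnings(split_cohort(samples, rng_seed = rng_seed))
  config <- model_config_tiny()
  vapply(strategies, function(s) {
    res <- run_fl(samples, split, fl_schedule(s), config, rng_seed, dry_run = TRUE)
    tot <- unique(res$counters$total_local_epochs_per_client)
    stopifnot(length(tot) == 1)  # every client is scheduled identically
    tot
  }, 0)
}

pooled_angle_mae <- function(records) {
  pi_ <- do.call(rbind, lapply(records, `[[`, "per_image"))
  mean(unlist(pi_[c("SS_err", "PT_err", "PI_err", "LL_err")]), na.rm = TRUE)
}

pooled_landmark_err <- function(records) {
  pi_ <- do.call(rbind, lapply(records, `[[`, "per_image"))
  mean(pi_$landmark_err_mm, na.rm = TRUE)
}

#' Run the desk-scale three-arm study on a synthetic four-center cohort
#'
#' Generates a heterogeneous cohort from [default_center_profiles()], applies
#' the patient-level center-stratified 80/10/10 split, trains the centralized
#' model, one local model per hospital and a FedAvg model, and evaluates all
#' of them on every center's held-out test set.
#'
#' @param seed integer master seed.
#' @param n_patients cohort size (default 120).
#' @param input_size image side in pixels (default 48; the physical field of
#'   view is kept at 384 mm regardless of resolution).
#' @param lr learning rate for all arms (desk-scale default 1e-3).
#' @param centralized_epochs,local_epochs max epochs for those arms.
#' @param fed_local_epochs,fed_rounds FedAvg schedule.
#' @param patience early-stop patience for centralized/local arms.
#' @param strategies extra federated strategies to train besides FedAvg
#'   (e.g. `c("fedopt", "fedprox")`), run at the same desk-scale rounds.
#' @return list of summary metrics, the evaluation records and fitted arms.
#' @export
run_desk_study <- function(seed, n_patients = 120, input_size = 48, lr = 1e-3,
                           centralized_epochs = 30, local_epochs = 30,
                           fed_local_epochs = 5, fed_rounds = 6, patience = 10,
                           strategies = character()) {
  profiles <- default_center_profiles()
  spacing <- 384 / input_size
  samples <- generate_cohort(profiles, n_patients, derive_seed(seed, "cohort"),
                             canvas = c(input_size, input_size), spacing_mm = spacing)
  split <- split_cohort(samples, rng_seed = derive_seed(seed, "split"))
  config <- model_config_tiny(input_size)
  train_pats <- function(center = NULL)
    unique(split$patient_id[split$split == "train" &
                              (if (is.null(center)) TRUE else split$center_id == center)])

  cent <- train_centralized(samples, split, config,
                            train_config("centralized", epochs = centralized_epochs,
                                         lr = lr, lr_decay = NULL,
                                         early_stop_patience = patience,
                                         seed = derive_seed(seed, "cent")))
  centers <- sort(unique(split$center_id))
  locals <- lapply(centers, function(cid)
    train_local(samples, split, cid, config,
                train_config("local", epochs = local_epochs, lr = lr,
                             lr_decay = NULL, early_stop_patience = patience,
                             seed = derive_seed(seed, "local", cid))))
  names(locals) <- centers

  fed_sched <- fl_schedule("fedavg", local_epochs = fed_local_epochs,
                           rounds = fed_rounds, client_lr = lr, lr_decay = NULL)
  fed <- run_fl(samples, split, fed_sched, config, derive_seed(seed, "fedavg"))
  extra <- lapply(strategies, function(s) {
    sc <- fl_schedule(s, rounds = fed_rounds,
                      local_epochs = if (s == "fedopt") 3L else fed_local_epochs,
                      client_lr = lr)
    run_fl(samples, split, sc, config, derive_seed(seed, s))
  })
  names(extra) <- strategies

  models <- c(
    list(centralized = list(params = cent$best_params, config = config,
                            train_center = "all", train_patient_ids = train_pats()),
         fedavg = list(params = fed$best_params, config = config,
                       train_center = "all", train_patient_ids = train_pats())),
    stats::setNames(lapply(centers, function(cid)
      list(params = locals[[cid]]$best_params, config = config, train_center = cid,
           train_patient_ids = train_pats(cid))), paste0("local:", centers)),
    stats::setNames(lapply(strategies, function(s)
      list(params = extra[[s]]$best_params, config = config, train_center = "all",
           train_patient_ids = train_pats())), strategies)
  )
  records <- cross_site_matrix(models, samples, split)
  is_model <- function(id) vapply(records, function(r) r$model_id == id, TRUE)
  is_local <- vapply(records, function(r) startsWith(r$model_id, "local:"), TRUE)
  is_ext <- vapply(records, function(r) r$scope == "external", TRUE)

  metrics <- list(
    centralized_angle_mae = pooled_angle_mae(records[is_model("centralized")]),
    fedavg_angle_mae = pooled_angle_mae(records[is_model("fedavg")]),
    local_internal_angle_mae = pooled_angle_mae(records[is_local & !is_ext]),
    local_external_angle_mae = pooled_angle_mae(records[is_local & is_ext]),
    centralized_landmark_err_mm = pooled_landmark_err(records[is_model("centralized")]),
    fedavg_landmark_err_mm = pooled_landmark_err(records[is_model("fedavg")]),
    local_external_landmark_err_mm = pooled_landmark_err(records[is_local & is_ext]),
    n_images = length(samples), n_patients = n_patients
  )
  metrics$fedavg_vs_centralized_ratio <-
    metrics$fedavg_angle_mae / metrics$centralized_angle_mae
  for (s in strategies)
    metrics[[paste0(s, "_angle_mae")]] <- pooled_angle_mae(records[is_model(s)])
  list(metrics = metrics, records = records, split = split,
       fits = list(centralized = cent, locals = locals, fedavg = fed, extra = extra),
       config = config)
}
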