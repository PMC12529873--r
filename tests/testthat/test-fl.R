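# Federated core: aggregation operators, server optimizers, the proximal
# objective, round-loop determinism and the privacy contract.

fake_update <- function(theta, n, id) {
  client_update(list(l1 = list(W = array(theta, c(length(theta), 1, 1, 1)),
                               b = numeric(1))),
                n_samples = n, client_id = id)
}

random_params <- function(seed, shape = c(3, 3, 2, 2)) {
  with_seed(seed, list(a = list(W = array(rnorm(prod(shape)), shape),
                                b = rnorm(shape[4])),
                       b = list(W = array(rnorm(8), c(2, 1, 2, 2)), b = rnorm(2))))
}

test_that("fedavg_aggregate is the sample-size-weighted mean", {
  # scalar oracle: theta1 = 0 (n=3), theta2 = 1 (n=1) -> 0.25
  agg <- fedavg_aggregate(list(fake_update(0, 3, "a"), fake_update(1, 1, "b")))
  expect_equal(as.vector(agg$l1$W), 0.25)
  # identical clients -> unchanged; single client -> bitwise unchanged
  th <- random_params(1)
  u <- list(client_update(th, 5, "a"), client_update(th, 9, "b"))
  expect_equal(flatten_params(fedavg_aggregate(u)), flatten_params(th))
  expect_identical(flatten_params(fedavg_aggregate(list(client_update(th, 4, "x")))),
                   flatten_params(th))
  expect_error(fedavg_aggregate(list()), class = "fedspine_aggregation_error")
  bad <- list(client_update(th, 2, "a"),
              client_update(list(a = th$a), 2, "b"))
  expect_error(fedavg_aggregate(bad), class = "fedspine_protocol_error")
})

test_that("fedavg_aggregate matches a brute-force per-parameter loop to 1e-12", {
  ups <- lapply(1:4, function(i) client_update(random_params(i), i * 3, paste0("c", i)))
  agg <- flatten_params(fedavg_aggregate(ups))
  n <- c(3, 6, 9, 12); w <- n / sum(n)
  flats <- lapply(ups, function(u) flatten_params(u$params))
  brute <- vapply(seq_along(agg), function(j)
    sum(vapply(1:4, function(i) w[i] * flats[[i]][j], 0)), 0)
  expect_lt(max(abs(agg - brute)), 1e-12)
  # permutation invariance in client order (sorted reduction)
  agg_perm <- flatten_params(fedavg_aggregate(ups[c(3, 1, 4, 2)]))
  expect_identical(agg, agg_perm)
})

test_that("fedopt server step: fixed point, FedAvg reduction, scalar oracle", {
  th <- random_params(2)
  st <- server_state(th)
  sched <- fl_schedule("fedopt")
  # all clients return the global parameters: pseudo-gradient 0, no movement
  ups <- list(client_update(th, 3, "a"), client_update(th, 5, "b"))
  st1 <- fedopt_server_step(st, ups, sched)
  expect_equal(flatten_params(st1$global_params), flatten_params(th))
  expect_equal(st1$round_index, 1L)
  # plain-average mode with server_lr = 1 reduces exactly to FedAvg
  sched_avg <- fl_schedule("fedopt", server_opt = "average", server_lr = 1)
  ups2 <- lapply(1:3, function(i) client_update(random_params(10 + i), i, paste0("c", i)))
  st2 <- fedopt_server_step(server_state(th), ups2, sched_avg)
  expect_identical(flatten_params(st2$global_params),
                   flatten_params(fedavg_aggregate(ups2)))
  # scalar adaptive step against hand arithmetic
  g0 <- 0.3; lr <- 0.1; b <- c(0.9, 0.999); tau <- 1e-9
  stS <- server_state(list(l = list(W = array(1, c(1, 1, 1, 1)), b = numeric(0))))
  upS <- list(client_update(list(l = list(W = array(1 - g0, c(1, 1, 1, 1)),
                                          b = numeric(0))), 1, "a"))
  schedS <- fl_schedule("fedopt", server_lr = lr, betas = b, tau = tau)
  outS <- fedopt_server_step(stS, upS, schedS)
  m <- (1 - b[1]) * g0; v <- (1 - b[2]) * g0^2
  expect_lt(abs(as.vector(outS$global_params$l$W) - (1 - lr * m / (sqrt(v) + tau))),
            1e-12)
})

test_that("the proximal objective adds (mu/2) ||theta - global||^2", {
  th <- random_params(3); gl <- random_params(4)
  base <- function(p) 2.5
  expect_identical(fedprox_client_objective(base, th, gl, 0), 2.5)
  expect_identical(fedprox_client_objective(base, th, th, 5), 2.5)
  # mu = 2, ||delta||^2 = 4 -> penalty 4
  a <- list(l = list(W = array(c(2, 0), c(2, 1, 1, 1)), b = numeric(0)))
  b2 <- list(l = list(W = array(c(0, 0), c(2, 1, 1, 1)), b = numeric(0)))
  expect_equal(fedprox_client_objective(function(p) 0, a, b2, 2), 4)
  expect_error(fedprox_client_objective(base, th, gl, -1),
               class = "fedspine_config_error")
})

test_that("FedOpt plain-average and FedProx mu=0 match the FedAvg trajectory bit-for-bit", {
  mc <- micro_cohort()
  cfg <- micro_config()
  init <- init_model_params(cfg, 77)
  run <- function(sched) run_fl(mc$samples, mc$split, sched, cfg, rng_seed = 5,
                                init_params = init, batch_size = 4)
  base <- fl_schedule("fedavg", local_epochs = 1, rounds = 2, client_lr = 1e-3,
                      lr_decay = NULL)
  ravg <- run(base)
  ropt <- run(fl_schedule("fedopt", local_epochs = 1, rounds = 2, client_lr = 1e-3,
                          server_opt = "average", server_lr = 1))
  rprox <- run(fl_schedule("fedprox", local_epochs = 1, rounds = 2, client_lr = 1e-3,
                           mu = 0))
  expect_bitwise_equal(ropt$final_params, ravg$final_params)
  expect_bitwise_equal(rprox$final_params, ravg$final_params)
  # a positive mu genuinely changes the trajectory
  rmu <- run(fl_schedule("fedprox", local_epochs = 1, rounds = 2, client_lr = 1e-3,
                         mu = 0.5))
  expect_false(identical(flatten_params(rmu$final_params),
                         flatten_params(ravg$final_params)))
})

test_that("single-client FedAvg coincides with local training under matched seeds", {
  profs <- list(A = center_profile("A", 1, noise_sd = 0.02))
  samples <- generate_cohort(profs, 6, rng_seed = 41, canvas = c(16, 16),
                             spacing_mm = 24)
  split <- split_cohort(samples, rng_seed = 41)
  cfg <- micro_config()
  init <- init_model_params(cfg, 9)
  sched <- fl_schedule("fedavg", local_epochs = 3, rounds = 1, client_lr = 1e-3,
                       lr_decay = NULL)
  fl <- run_fl(samples, split, sched, cfg, rng_seed = 5, init_params = init,
               batch_size = 4)
  tcfg <- train_config("local", epochs = 3, lr = 1e-3, lr_decay = NULL,
                       early_stop_patience = NULL, batch_size = 4, seed = 1)
  loc <- train_local(samples, split, "A", cfg, tcfg, init_params = init,
                     sgd_seed = derive_seed(5, "sgd", "A"))
  # same init, same per-epoch seeds, one aggregation of one client: identical
  expect_bitwise_equal(fl$final_params, loc$final_params)
})

test_that("round loop is deterministic and clients expose only ClientUpdates", {
  mc <- micro_cohort()
  cfg <- micro_config()
  sched <- fl_schedule("fedavg", local_epochs = 1, rounds = 2, client_lr = 1e-3,
                       lr_decay = NULL)
  r1 <- run_fl(mc$samples, mc$split, sched, cfg, rng_seed = 8, batch_size = 4)
  r2 <- run_fl(mc$samples, mc$split, sched, cfg, rng_seed = 8, batch_size = 4)
  expect_bitwise_equal(r1$final_params, r2$final_params)
  expect_identical(r1$history, r2$history)
  # privacy contract: what a client returns to the server carries parameters
  # and counts only, never samples or images
  upd <- fedspine:::local_client_fit(
    list(client_id = "A", train = mc$samples[1:4], n_train = 4,
         sgd_seed = 1, batch_size = 4),
    init_model_params(cfg, 1), sched, cfg, lr = 1e-3, round_index = 0L,
    rng_seed = 1)
  expect_s3_class(upd, "client_update")
  expect_setequal(names(upd), c("params", "n_samples", "client_id", "round_metrics"))
  expect_true(all(vapply(upd$round_metrics, is.numeric, TRUE)))
  has_sample <- function(x) {
    if (inherits(x, "spine_sample") || inherits(x, "landmark_set")) return(TRUE)
    if (is.list(x)) return(any(vapply(x, has_sample, TRUE)))
    FALSE
  }
  expect_false(has_sample(upd))
})

test_that("the dry-run round loop counts the scheduled local epochs", {
  mc <- micro_cohort()
  cfg <- micro_config()
  res <- run_fl(mc$samples, mc$split, fl_schedule("fedavg"), cfg, rng_seed = 1,
                dry_run = TRUE)
  expect_true(all(res$counters$total_local_epochs_per_client == 300))
  expect_equal(res$counters$rounds_run, 30L)
  # rounds = 0 returns the initial parameters and no history
  init <- init_model_params(cfg, 4)
  r0 <- run_fl(mc$samples, mc$split, fl_schedule("fedavg", rounds = 0), cfg,
               rng_seed = 1, init_params = init)
  expect_bitwise_equal(r0$final_params, init)
  expect_null(r0$history)
})
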