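# Shared in-code fixtures. Everything is generated programmatically; heavier
# objects are memoised per test run.

.fx <- new.env(parent = emptyenv())

# a landmark set with explicit sacral/femoral geometry; all other points at
# harmless defaults
fixture_pelvis <- function(ant, post, mid = NULL, H = c(50, 150), fem_gap = c(5, 0),
                           facing = "anterior_is_plus_x", size = c(256, 256),
                           spacing = 1) {
  nm <- landmark_names()
  pts <- matrix(rep(c(60, 40), each = 29), 29, 2, dimnames = list(nm, c("x", "y")))
  pts["S1_ant", ] <- ant
  pts["S1_post", ] <- post
  pts["S1_mid", ] <- if (is.null(mid)) (ant + post) / 2 else mid
  pts["fem_head_L", ] <- H + fem_gap
  pts["fem_head_R", ] <- H - fem_gap
  landmark_set(pts, spacing, facing, size, validate = FALSE)
}

# a generator-built landmark set for random valid angles
random_lm <- function(seed, canvas = c(256, 256), spacing = 1.5) {
  a <- with_seed(seed, angle_set(SS = runif(1, 3, 70), PT = runif(1, -25, 45),
                                 LL = runif(1, -10, 90)))
  list(angles = a,
       lm = build_landmarks(a, derive_seed(seed, "m"), canvas = canvas,
                            spacing_mm = spacing))
}

two_center_profiles <- function() {
  list(A = center_profile("A", 0.5, pi_mean = 56, pi_sd = 6, noise_sd = 0.02),
       B = center_profile("B", 0.5, pi_mean = 45, pi_sd = 6, noise_sd = 0.05,
                          intensity_shift = 0.05))
}

# micro model + cohort at 16 px, cached (used by FL / training determinism tests)
micro_config <- function() model_config(input_size = 16, n_stacks = 1,
                                        base_channels = 2, heatmap_stride = 2,
                                        n_landmarks = 29)

micro_cohort <- function() {
  if (is.null(.fx$micro)) {
    samples <- generate_cohort(two_center_profiles(), n_patients = 8, rng_seed = 11,
                               canvas = c(16, 16), spacing_mm = 24)
    split <- suppressWarnings(split_cohort(samples, rng_seed = 11))
    .fx$micro <- list(samples = samples, split = split)
  }
  .fx$micro
}

# small rendered cohort at 32 px for evaluation-level tests
eval_cohort <- function() {
  if (is.null(.fx$evalc)) {
    samples <- generate_cohort(two_center_profiles(), n_patients = 20, rng_seed = 21,
                               canvas = c(32, 32), spacing_mm = 12)
    split <- suppressWarnings(split_cohort(samples, rng_seed = 21))
    .fx$evalc <- list(samples = samples, split = split,
                      config = model_config(32, 1, 2, 2, 29))
  }
  .fx$evalc
}

expect_bitwise_equal <- function(a, b) {
  expect_identical(flatten_params(a), flatten_params(b))
}
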