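# Synthetic cohort generator: angle sampling, landmark construction closure,
# rendering, cohort allocation and the patient-level split.

test_that("sample_angles follows the generative model deterministically", {
  prof <- center_profile("X", 1, pi_mean = 52, pi_sd = 0,
                         pt_fraction_mean = 0.25, pt_fraction_sd = 0,
                         ll_slope = 1, ll_intercept = 0, ll_sd = 0)
  a <- sample_angles(prof, 99)
  expect_equal(unname(unclass(a)[c("PI", "PT", "SS", "LL")]), c(52, 13, 39, 52))
  # constructed identity and determinism
  prof2 <- center_profile("Y", 1)
  for (s in 1:20) {
    d <- unclass(sample_angles(prof2, s))
    expect_equal(d[["PI"]] - d[["PT"]] - d[["SS"]], 0)
  }
  expect_identical(sample_angles(prof2, 7), sample_angles(prof2, 7))
})

test_that("build_landmarks closes the angle contract and is deterministic", {
  a <- angle_set(SS = 39, PT = 13, LL = 55)
  lm <- build_landmarks(a, 123)
  got <- unclass(compute_angles(lm))
  expect_equal(got[["PI"]], 52, tolerance = 1e-6)
  expect_equal(got[["SS"]], 39, tolerance = 1e-6)
  expect_equal(got[["LL"]], 55, tolerance = 1e-6)
  expect_identical(build_landmarks(a, 123)$points, lm$points)
  # SS = 0: flat sacral endplate
  lm0 <- build_landmarks(angle_set(SS = 0.5, PT = 10, LL = 40), 5)
  expect_equal(abs(lm0$points["S1_ant", 2] - lm0$points["S1_post", 2]),
               tan(0.5 * pi / 180) * abs(lm0$points["S1_ant", 1] - lm0$points["S1_post", 1]),
               tolerance = 1e-9)
})

test_that("renderer is deterministic, appearance-sensitive, landmark-neutral", {
  a <- angle_set(SS = 40, PT = 12, LL = 52)
  lm <- build_landmarks(a, 8, canvas = c(64, 64), spacing_mm = 6)
  prof0 <- center_profile("Z", 1, noise_sd = 0, intensity_shift = 0, contrast_scale = 1)
  img1 <- render_image(lm, prof0, rng_seed = 4)
  img2 <- render_image(lm, prof0, rng_seed = 4)
  expect_identical(img1, img2)
  expect_true(all(img1 >= 0 & img1 <= 1))
  # mean intensity rises with intensity_shift on a fixed seed
  prof_hi <- center_profile("Z", 1, noise_sd = 0, intensity_shift = 0.1)
  expect_gt(mean(render_image(lm, prof_hi, rng_seed = 4)), mean(img1))
  # occlusion bars never move landmarks: the landmark set is an input and the
  # ground-truth angles recompute unchanged afterwards
  img3 <- render_image(lm, prof0, rng_seed = 4, occlusion_bars = 2)
  expect_false(identical(img3, img1))
  expect_equal(unclass(compute_angles(lm))[["PI"]],
               unclass(a)[["PI"]], tolerance = 1e-6)
})

test_that("largest-remainder apportionment reproduces the center shares", {
  expect_identical(largest_remainder(100, c(.45, .35, .14, .06)),
                   c(45L, 35L, 14L, 6L))
  expect_identical(largest_remainder(4, rep(.25, 4)), rep(1L, 4))
  expect_equal(sum(largest_remainder(37, c(.45, .35, .14, .06))), 37)
})

test_that("generate_cohort allocates patients by share and passes validation", {
  samples <- generate_cohort(default_center_profiles(), 100, rng_seed = 13,
                             canvas = c(64, 64), spacing_mm = 6, render = FALSE)
  pats <- unique(data.frame(p = vapply(samples, `[[`, "", "patient_id"),
                            c = vapply(samples, `[[`, "", "center_id")))
  expect_equal(as.integer(table(pats$c)[c("BCN", "BOR", "MAD", "IST")]),
               c(45L, 35L, 14L, 6L))
  # every sample passes the inclusion filter; visits within 3-4
  nv <- table(vapply(samples, `[[`, "", "patient_id"))
  expect_true(all(nv %in% 3:4))
  viol <- lapply(samples[seq(1, length(samples), by = 7)],
                 function(s) validate_annotation(s$landmarks))
  expect_true(all(lengths(viol) == 0))
  # closure for every generated sample
  worst <- max(vapply(samples, function(s)
    max(abs(unclass(compute_angles(s$landmarks)) - unclass(s$true_angles))), 0))
  expect_lt(worst, 1e-6)
  # determinism: cohort generation is a pure function of (profiles, n, seed)
  again <- generate_cohort(default_center_profiles(), 100, rng_seed = 13,
                           canvas = c(64, 64), spacing_mm = 6, render = FALSE)
  expect_identical(lapply(again, `[[`, "landmarks"),
                   lapply(samples, `[[`, "landmarks"))
  expect_error(generate_cohort(list(center_profile("A", 0.5)), 10, 1),
               class = "fedspine_config_error")
})

test_that("visit-level perturbations stay within 2 degrees of the base visit", {
  samples <- generate_cohort(two_center_profiles(), 6, rng_seed = 17,
                             canvas = c(64, 64), spacing_mm = 6, render = FALSE)
  by_pat <- split(samples, vapply(samples, `[[`, "", "patient_id"))
  for (g in by_pat) {
    angs <- do.call(rbind, lapply(g, function(s) unclass(s$true_angles)))
    rng <- apply(angs, 2, function(x) max(x) - min(x))
    expect_true(all(rng[c("PI", "LL")] <= 4 + 1e-9))  # +-2 deg around the base
  }
})

test_that("center heterogeneity in mean PI exceeds 8 degrees", {
  profs <- default_center_profiles()
  mu <- vapply(names(profs), function(cn)
    mean(vapply(1:60, function(i)
      unclass(sample_angles(profs[[cn]], derive_seed(1, cn, i)))[["PI"]], 0)), 0)
  expect_gt(max(mu) - min(mu), 8)
})

test_that("split is patient-level, center-stratified, leak-free, deterministic", {
  samples <- generate_cohort(two_center_profiles(), 40, rng_seed = 19,
                             canvas = c(64, 64), spacing_mm = 6, render = FALSE)
  sp <- split_cohort(samples, rng_seed = 3)
  expect_setequal(sp$image_id, vapply(samples, `[[`, "", "image_id"))
  # all images of a patient share one split
  byp <- tapply(sp$split, sp$patient_id, function(x) length(unique(x)))
  expect_true(all(byp == 1))
  # per-center patient counts within 1 of the 80/10/10 targets
  pats <- unique(sp[, c("patient_id", "center_id", "split")])
  for (cid in unique(pats$center_id)) {
    n <- table(factor(pats$split[pats$center_id == cid],
                      levels = c("train", "validation", "test")))
    tot <- sum(n)
    expect_true(all(abs(n - tot * c(.8, .1, .1)) <= 1))
  }
  expect_identical(split_cohort(samples, rng_seed = 3), sp)
  expect_false(identical(split_cohort(samples, rng_seed = 4)$split, sp$split))
  expect_warning(split_cohort(samples[1:3], rng_seed = 1), "degenerate")
  expect_error(split_cohort(samples, fractions = c(.8, .1, .2)),
               class = "fedspine_config_error")
})

test_that("cohort export writes the documented annotation artifacts", {
  samples <- generate_cohort(two_center_profiles(), 4, rng_seed = 23,
                             canvas = c(64, 64), spacing_mm = 6, render = FALSE)
  sp <- suppressWarnings(split_cohort(samples, rng_seed = 1))
  d <- tempfile()
  on.exit(unlink(d, recursive = TRUE))
  write_cohort(samples, sp, d)
  expect_true(all(file.exists(file.path(d, c("annotations.json", "annotations.csv",
                                             "angles.csv", "split.csv")))))
  ang <- utils::read.csv(file.path(d, "angles.csv"))
  expect_equal(nrow(ang), length(samples))
  expect_equal(ang$PI, ang$PT + ang$SS, tolerance = 1e-6)
})
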