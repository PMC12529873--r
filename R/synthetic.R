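# Synthetic multi-hospital cohort generator. Pseudo-radiographs are drawn
# from a parametric sagittal spine model whose landmarks are constructed so
# that the four lumbopelvic angles recomputed from them equal the sampled
# ground truth exactly (angle closure is the generator's correctness
# contract). Center profiles encode the non-IID structure of a cross-silo
# study: unequal sample shares, shifted angle distributions, and distinct
# image appearance.

#' Define a hospital (center) generating profile
#'
#' @param center_id short center label.
#' @param share fraction of total patients contributed by this center.
#' @param pi_mean,pi_sd pelvic incidence distribution, degrees.
#' @param pt_fraction_mean,pt_fraction_sd pelvic tilt as a fraction of PI.
#' @param ll_slope,ll_intercept,ll_sd lumbar lordosis model
#'   LL ~ ll_slope * PI + ll_intercept + N(0, ll_sd), degrees.
#' @param intensity_shift,contrast_scale,noise_sd image appearance knobs.
#' @param visits_min,visits_max follow-up images per patient (inclusive range).
#' @return object of class `center_profile`.
#' @export
center_profile <- function(center_id, share,
                           pi_mean = 52, pi_sd = 10,
                           pt_fraction_mean = 0.28, pt_fraction_sd = 0.08,
                           ll_slope = 0.85, ll_intercept = 10, ll_sd = 6,
                           intensity_shift = 0, contrast_scale = 1, noise_sd = 0.04,
                           visits_min = 3L, visits_max = 4L) {
  stopifnot(share > 0, pi_sd >= 0, pt_fraction_sd >= 0, ll_sd >= 0,
            visits_min >= 1, visits_min <= visits_max)
  structure(list(center_id = center_id, share = share, pi_mean = pi_mean,
                 pi_sd = pi_sd, pt_fraction_mean = pt_fraction_mean,
                 pt_fraction_sd = pt_fraction_sd, ll_slope = ll_slope,
                 ll_intercept = ll_intercept, ll_sd = ll_sd,
                 intensity_shift = intensity_shift, contrast_scale = contrast_scale,
                 noise_sd = noise_sd, visits_min = as.integer(visits_min),
                 visits_max = as.integer(visits_max)),
            class = "center_profile")
}

#' Default four-center study profiles
#'
#' Four hospitals with patient shares 0.45/0.35/0.14/0.06. The smallest
#' center (`IST`) emulates a younger, more heterogeneous cohort: lower mean
#' pelvic incidence and larger variance, plus the most distinct image
#' appearance. Between-center differences in mean PI exceed 8 degrees by
#' construction.
#'
#' @return named list of four `center_profile`s (shares sum to 1).
#' @export
default_center_profiles <- function() {
  list(
    BCN = center_profile("BCN", 0.45, pi_mean = 56, pi_sd = 9,
                         pt_fraction_mean = 0.30, pt_fraction_sd = 0.07,
                         ll_slope = 0.85, ll_intercept = 12, ll_sd = 6,
                         intensity_shift = 0.00, contrast_scale = 1.00, noise_sd = 0.03),
    BOR = center_profile("BOR", 0.35, pi_mean = 52, pi_sd = 8,
                         pt_fraction_mean = 0.26, pt_fraction_sd = 0.07,
                         ll_slope = 0.80, ll_intercept = 14, ll_sd = 6,
                         intensity_shift = 0.05, contrast_scale = 0.90, noise_sd = 0.04),
    MAD = center_profile("MAD", 0.14, pi_mean = 50, pi_sd = 9,
                         pt_fraction_mean = 0.28, pt_fraction_sd = 0.08,
                         ll_slope = 0.85, ll_intercept = 8, ll_sd = 7,
                         intensity_shift = -0.04, contrast_scale = 1.10, noise_sd = 0.05),
    IST = center_profile("IST", 0.06, pi_mean = 44, pi_sd = 12,
                         pt_fraction_mean = 0.20, pt_fraction_sd = 0.10,
                         ll_slope = 0.95, ll_intercept = 6, ll_sd = 9,
                         intensity_shift = 0.08, contrast_scale = 1.25, noise_sd = 0.06)
  )
}

#' Sample a ground-truth AngleSet from a center profile
#'
#' PI ~ N(pi_mean, pi_sd); PT = PI * f with f ~ N(pt_fraction_mean,
#' pt_fraction_sd); SS = PI - PT; LL = ll_slope * PI + ll_intercept +
#' N(0, ll_sd). Draws outside the valid clinical ranges (SS in \[0.5, 88\],
#' PT in (-80, 80), LL in (-80, 170)) are rejected and redrawn, with a final
#' deterministic clamp as a safety net. Deterministic given the seed.
#'
#' @param profile a `center_profile`.
#' @param rng_seed integer seed.
#' @return an `angle_set` satisfying PI = PT + SS exactly.
#' @export
sample_angles <- function(profile, rng_seed) {
  with_seed(rng_seed, {
    for (i in 1:50) {
      PI <- stats::rnorm(1, profile$pi_mean, profile$pi_sd)
      f <- stats::rnorm(1, profile$pt_fraction_mean, profile$pt_fraction_sd)
      PT <- PI * f
      SS <- PI - PT
      LL <- profile$ll_slope * PI + profile$ll_intercept + stats::rnorm(1, 0, profile$ll_sd)
      if (SS >= 0.5 && SS <= 88 && PT > -80 && PT < 80 && LL > -80 && LL < 170) break
    }
    SS <- clamp(SS, 0.5, 88); PT <- clamp(PT, -79, 79); LL <- clamp(LL, -79, 169)
    angle_set(SS = SS, PT = PT, LL = LL)
  })
}

# Plate direction (posterior->anterior) and cranial plate normal for an
# endplate inclined phi radians (anterior end caudal), in y-down coordinates.
.plate_u <- function(phi, s) c(s * cos(phi), sin(phi))
.plate_n <- function(phi, s) c(s * sin(phi), -cos(phi))

#' Construct the 29 landmarks realizing a given AngleSet
#'
#' Places the sacral endplate at slope SS (anterior end caudal, the
#' orientation under which PI = PT + SS holds), the bicoxofemoral point at
#' pelvic-thickness distance from the sacral midpoint along the direction
#' making angle PT with the vertical, femoral head centers symmetric about
#' it, and the lumbar vertebrae (L5 up to T12) as corner quadrilaterals whose
#' endplate inclinations interpolate linearly from the sacral plate to the L1
#' superior endplate, which subtends exactly LL. Per-vertebra heights, widths
#' and disc spaces are jittered by `morphology_seed`. If the construction
#' leaves the canvas it is retried at progressively smaller scale, then fails.
#'
#' @param angles an `angle_set` (LL interpreted at the L1 superior endplate).
#' @param morphology_seed integer seed for morphological jitter.
#' @param canvas c(width, height) pixels.
#' @param spacing_mm mm per pixel.
#' @param facing patient facing direction.
#' @return a `landmark_set`; recomputing SS/PT/PI/LL from it reproduces
#'   `angles` to well below 1e-6 degrees.
#' @export
build_landmarks <- function(angles, morphology_seed, canvas = c(256, 256),
                            spacing_mm = 1.5, facing = "anterior_is_plus_x") {
  a <- unclass(angles)
  s <- if (identical(facing, "anterior_is_minus_x")) -1 else 1
  SS <- deg2rad(a[["SS"]]); PT <- deg2rad(a[["PT"]]); LL <- deg2rad(a[["LL"]])

  with_seed(morphology_seed, {
    jit <- function(base, frac) base * stats::runif(1, 1 - frac, 1 + frac)
    sac_len <- jit(35, 0.06)          # mm
    pelvic_T <- jit(70, 0.08)
    fem_dx <- jit(4, 0.3); fem_dy <- jit(1.2, 0.3)
    heights <- vapply(1:6, function(i) jit(26, 0.08), 0)  # L5..T12 body heights
    discs <- vapply(1:6, function(i) jit(9, 0.12), 0)
    widths <- vapply(1:6, function(i) jit(33, 0.08), 0)
    cx_jit <- stats::runif(1, -0.03, 0.03); cy_jit <- stats::runif(1, -0.03, 0.03)
  })

  # endplate inclinations: 10 plates from L5-inferior (t = 0.1) to
  # L1-superior (t = 1), continuing gently through T12
  t_plates <- seq(0.1, 1, by = 0.1)
  phis <- SS - t_plates * LL
  phi_T12i <- SS - 1.05 * LL
  phi_T12s <- SS - 1.10 * LL

  build_rel <- function(sc) {
    p <- list()
    M <- c(0, 0)
    u_sac <- .plate_u(SS, s)
    p[["S1_ant"]] <- M + sc * (sac_len / 2) * u_sac
    p[["S1_post"]] <- M - sc * (sac_len / 2) * u_sac
    p[["S1_mid"]] <- M
    H <- M + sc * pelvic_T * c(s * sin(PT), cos(PT))
    p[["fem_head_L"]] <- H + sc * c(s * fem_dx, fem_dy)
    p[["fem_head_R"]] <- H - sc * c(s * fem_dx, fem_dy)

    levels <- c("L5", "L4", "L3", "L2", "L1", "T12")
    c_prev <- M; phi_prev <- SS
    for (i in seq_along(levels)) {
      if (levels[i] == "T12") {
        phi_inf <- phi_T12i; phi_sup <- phi_T12s
      } else {
        phi_inf <- phis[2 * i - 1]; phi_sup <- phis[2 * i]
      }
      c_inf <- c_prev + sc * discs[i] * .plate_n((phi_prev + phi_inf) / 2, s)
      c_sup <- c_inf + sc * heights[i] * .plate_n((phi_inf + phi_sup) / 2, s)
      hw_i <- sc * widths[i] / 2
      p[[paste0(levels[i], "_ainf")]] <- c_inf + hw_i * .plate_u(phi_inf, s)
      p[[paste0(levels[i], "_pinf")]] <- c_inf - hw_i * .plate_u(phi_inf, s)
      p[[paste0(levels[i], "_asup")]] <- c_sup + hw_i * .plate_u(phi_sup, s)
      p[[paste0(levels[i], "_psup")]] <- c_sup - hw_i * .plate_u(phi_sup, s)
      c_prev <- c_sup; phi_prev <- phi_sup
    }
    do.call(rbind, p)
  }

  W <- canvas[1]; H <- canvas[2]
  margin <- 2
  sc <- 1
  for (attempt in 1:8) {
    pts_mm <- build_rel(sc)
    pts_px <- pts_mm / spacing_mm
    # center the bounding box on the (slightly jittered) canvas center
    bb_lo <- apply(pts_px, 2, min); bb_hi <- apply(pts_px, 2, max)
    ctr <- (bb_lo + bb_hi) / 2
    target <- c((W - 1) / 2 * (1 + cx_jit), (H - 1) / 2 * (1 + cy_jit))
    pts_px <- sweep(pts_px, 2, ctr - target)
    if (all(pts_px[, 1] >= margin) && all(pts_px[, 1] <= W - 1 - margin) &&
        all(pts_px[, 2] >= margin) && all(pts_px[, 2] <= H - 1 - margin)) {
      pts_px <- pts_px[landmark_names(), ]
      colnames(pts_px) <- c("x", "y")
      return(landmark_set(pts_px, spacing_mm, facing, canvas))
    }
    sc <- sc * 0.85
  }
  stop_fedspine("landmark construction does not fit the canvas even after rescaling",
                "fedspine_canvas_error")
}

# distance from each pixel of a window to a segment, vectorized
.seg_dist <- function(px, py, a, b) {
  ab <- b - a
  len2 <- sum(ab^2)
  if (len2 < 1e-12) return(sqrt((px - a[1])^2 + (py - a[2])^2))
  t <- clamp(((px - a[1]) * ab[1] + (py - a[2]) * ab[2]) / len2, 0, 1)
  sqrt((px - (a[1] + t * ab[1]))^2 + (py - (a[2] + t * ab[2]))^2)
}

#' Render a pseudo-radiograph from a LandmarkSet
#'
#' Draws vertebral endplate quadrilaterals, the sacral endplate, and
#' femoral-head circles as bright anti-aliased strokes on a noisy background,
#' then applies the center profile's intensity shift, contrast scale and
#' Gaussian noise. Optionally overlays bright occluding bars (a surrogate for
#' spinal instrumentation) that never move the landmarks. Values in \[0, 1\];
#' rendering never alters the landmark coordinates.
#'
#' @param lm a `landmark_set`.
#' @param profile a `center_profile` (appearance fields).
#' @param rng_seed integer seed (noise and bar placement).
#' @param occlusion_bars number of instrumentation-like bars (default 0).
#' @return H x W numeric matrix, rows indexing y.
#' @export
render_image <- function(lm, profile, rng_seed, occlusion_bars = 0L) {
  W <- as.integer(lm$image_size[1]); H <- as.integer(lm$image_size[2])
  img <- matrix(0.28, H, W)
  xs <- matrix(rep(0:(W - 1), each = H), H, W)
  ys <- matrix(rep(0:(H - 1), W), H, W)
  stroke <- matrix(0, H, W)
  width_px <- max(0.7, 0.9 / lm$pixel_spacing_mm)

  paint_seg <- function(a, b) {
    lo_x <- max(0, floor(min(a[1], b[1]) - 3 * width_px))
    hi_x <- min(W - 1, ceiling(max(a[1], b[1]) + 3 * width_px))
    lo_y <- max(0, floor(min(a[2], b[2]) - 3 * width_px))
    hi_y <- min(H - 1, ceiling(max(a[2], b[2]) + 3 * width_px))
    if (lo_x > hi_x || lo_y > hi_y) return()
    ix <- (lo_x:hi_x) + 1L; iy <- (lo_y:hi_y) + 1L
    d <- .seg_dist(xs[iy, ix, drop = FALSE], ys[iy, ix, drop = FALSE], a, b)
    stroke[iy, ix] <<- pmax(stroke[iy, ix], exp(-(d / width_px)^2 / 2))
  }
  quad <- function(level) {
    p <- lm$points
    corners <- p[paste0(level, c("_asup", "_psup", "_pinf", "_ainf")), ]
    for (k in 1:4) paint_seg(corners[k, ], corners[(k %% 4) + 1, ])
  }
  for (lv in c("T12", "L1", "L2", "L3", "L4", "L5")) quad(lv)
  paint_seg(lm$points["S1_ant", ], lm$points["S1_post", ])
  r_fem <- 10 / lm$pixel_spacing_mm
  for (fh in c("fem_head_L", "fem_head_R")) {
    cth <- lm$points[fh, ]
    lo_x <- max(0, floor(cth[1] - r_fem - 3)); hi_x <- min(W - 1, ceiling(cth[1] + r_fem + 3))
    lo_y <- max(0, floor(cth[2] - r_fem - 3)); hi_y <- min(H - 1, ceiling(cth[2] + r_fem + 3))
    if (lo_x > hi_x || lo_y > hi_y) next
    ix <- (lo_x:hi_x) + 1L; iy <- (lo_y:hi_y) + 1L
    d <- abs(sqrt((xs[iy, ix, drop = FALSE] - cth[1])^2 +
                  (ys[iy, ix, drop = FALSE] - cth[2])^2) - r_fem)
    stroke[iy, ix] <- pmax(stroke[iy, ix], exp(-(d / width_px)^2 / 2))
  }

  img <- img + 0.55 * stroke
  with_seed(rng_seed, {
    if (occlusion_bars > 0) {
      for (b in seq_len(occlusion_bars)) {
        x0 <- stats::runif(1, 0.1, 0.9) * W
        wbar <- stats::runif(1, 1.5, 3.5)
        bar <- exp(-((xs - x0) / wbar)^2 / 2)
        img <- pmax(img, 0.85 * bar)
      }
    }
    img <- (img - 0.5) * profile$contrast_scale + 0.5 + profile$intensity_shift
    if (profile$noise_sd > 0)
      img <- img + matrix(stats::rnorm(H * W, 0, profile$noise_sd), H, W)
  })
  clamp(img, 0, 1)
}

#' Largest-remainder apportionment
#'
#' Allocates `n` integer units to categories proportionally to `shares`,
#' assigning remainders to the largest fractional parts; ties broken by
#' category order (reproducibility over elegance).
#'
#' @param n total units.
#' @param shares nonnegative weights.
#' @return integer vector summing to `n`.
#' @export
largest_remainder <- function(n, shares) {
  shares <- shares / sum(shares)
  raw <- n * shares
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    frac <- raw - base
    ord <- order(-frac, seq_along(frac))  # ties: earlier category first
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  as.integer(base)
}

#' Generate a multi-center synthetic cohort
#'
#' Allocates `n_patients` across centers by largest-remainder rounding of the
#' profile shares; each patient receives a base AngleSet from their center's
#' profile and 3-4 (per profile) follow-up images, each with a small
#' (<= 2 degree) angle perturbation and fresh morphology/rendering noise.
#' Fully deterministic given (profiles, n_patients, rng_seed).
#'
#' @param profiles list of `center_profile`s; shares must sum to 1 (1e-9).
#' @param n_patients total patients (>= number of centers).
#' @param rng_seed integer master seed.
#' @param canvas c(width, height) pixels.
#' @param spacing_mm mm per pixel.
#' @param render render images (set FALSE for split/geometry-only studies).
#' @param occlusion_prob probability a visit image gets an occluding bar.
#' @return list of `spine_sample`s: image (or NULL), landmarks, true_angles,
#'   patient_id, center_id, visit, image_id, seed_trace.
#' @export
generate_cohort <- function(profiles, n_patients, rng_seed,
                            canvas = c(256, 256), spacing_mm = 1.5,
                            render = TRUE, occlusion_prob = 0) {
  shares <- vapply(profiles, `[[`, 0, "share")
  if (abs(sum(shares) - 1) > 1e-9)
    stop_fedspine("center shares must sum to 1", "fedspine_config_error")
  if (n_patients < length(profiles))
    stop_fedspine("need at least one patient per center", "fedspine_config_error")
  counts <- largest_remainder(n_patients, shares)

  samples <- list()
  for (ci in seq_along(profiles)) {
    prof <- profiles[[ci]]
    for (pi_ in seq_len(counts[ci])) {
      patient_id <- sprintf("%s_P%03d", prof$center_id, pi_)
      seed_p <- derive_seed(rng_seed, "patient", prof$center_id, pi_)
      base_angles <- sample_angles(prof, seed_p)
      n_visits <- with_seed(derive_seed(seed_p, "visits"),
                            sample(prof$visits_min:prof$visits_max, 1))
      for (v in seq_len(n_visits)) {
        seed_v <- derive_seed(seed_p, "visit", v)
        ang <- with_seed(seed_v, {
          dPI <- clamp(stats::rnorm(1, 0, 0.8), -2, 2)
          dPT <- clamp(stats::rnorm(1, 0, 0.8), -2, 2)
          dLL <- clamp(stats::rnorm(1, 0, 0.8), -2, 2)
          a <- unclass(base_angles)
          PIv <- a[["PI"]] + dPI; PTv <- clamp(a[["PT"]] + dPT, -79, 79)
          SSv <- PIv - PTv
          if (SSv < 0.5) { SSv <- 0.5; PTv <- PIv - SSv }
          if (SSv > 88) { SSv <- 88; PTv <- PIv - SSv }
          angle_set(SS = SSv, PT = PTv, LL = clamp(a[["LL"]] + dLL, -79, 169))
        })
        lm <- build_landmarks(ang, derive_seed(seed_v, "morph"),
                              canvas = canvas, spacing_mm = spacing_mm)
        occl <- if (occlusion_prob > 0)
          with_seed(derive_seed(seed_v, "occl"),
                    as.integer(stats::runif(1) < occlusion_prob)) else 0L
        img <- if (render) render_image(lm, prof, derive_seed(seed_v, "render"),
                                        occlusion_bars = occl) else NULL
        samples[[length(samples) + 1L]] <- structure(
          list(image = img, landmarks = lm, true_angles = compute_angles(lm),
               patient_id = patient_id, center_id = prof$center_id, visit = v,
               image_id = sprintf("%s_V%d", patient_id, v),
               seed_trace = c(seed_p, seed_v)),
          class = "spine_sample")
      }
    }
  }
  samples
}

#' Patient-level, center-stratified split
#'
#' Shuffles the patients of each center with the seed, apportions them to
#' train/validation/test by largest-remainder rounding of `fractions`, and
#' assigns every image of a patient to that patient's split (no leakage).
#'
#' @param samples list of `spine_sample`s.
#' @param fractions named or positional c(train, validation, test), sum 1.
#' @param rng_seed integer seed.
#' @return `split_assignment`: data.frame(image_id, patient_id, center_id, split).
#' @export
split_cohort <- function(samples, fractions = c(train = 0.8, validation = 0.1, test = 0.1),
                         rng_seed = 1L) {
  if (abs(sum(fractions) - 1) > 1e-9)
    stop_fedspine("split fractions must sum to 1", "fedspine_config_error")
  split_names <- names(fractions) %||% c("train", "validation", "test")
  meta <- data.frame(image_id = vapply(samples, `[[`, "", "image_id"),
                     patient_id = vapply(samples, `[[`, "", "patient_id"),
                     center_id = vapply(samples, `[[`, "", "center_id"),
                     stringsAsFactors = FALSE)
  out <- NULL
  for (cid in unique(meta$center_id)) {
    pats <- unique(meta$patient_id[meta$center_id == cid])
    if (length(pats) < 3)
      warning(sprintf("center %s has %d patient(s); split is degenerate", cid, length(pats)))
    ord <- with_seed(derive_seed(rng_seed, "split", cid), sample(length(pats)))
    pats <- pats[ord]
    counts <- largest_remainder(length(pats), fractions)
    assign_split <- rep(split_names, counts)
    map <- stats::setNames(assign_split, pats)
    sub <- meta[meta$center_id == cid, ]
    sub$split <- unname(map[sub$patient_id])
    out <- rbind(out, sub)
  }
  out <- out[match(meta$image_id, out$image_id), ]
  rownames(out) <- NULL
  class(out) <- c("split_assignment", "data.frame")
  out
}

#' Write a cohort to disk (PNG images + JSON/CSV annotations + split CSV)
#'
#' @param samples list of `spine_sample`s.
#' @param split optional `split_assignment`.
#' @param dir output directory (created).
#' @param write_images write PNGs (requires the `png` package).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(samples, split = NULL, dir, write_images = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_annotations_json(samples, file.path(dir, "annotations.json"))
  write_annotations_csv(samples, file.path(dir, "annotations.csv"))
  ang <- do.call(rbind, lapply(samples, function(s)
    data.frame(image_id = s$image_id, t(unclass(s$true_angles)))))
  utils::write.csv(ang, file.path(dir, "angles.csv"), row.names = FALSE)
  if (!is.null(split))
    utils::write.csv(as.data.frame(split), file.path(dir, "split.csv"), row.names = FALSE)
  if (write_images && requireNamespace("png", quietly = TRUE)) {
    img_dir <- file.path(dir, "images")
    dir.create(img_dir, showWarnings = FALSE)
    for (s in samples)
      if (!is.null(s$image))
        png::writePNG(s$image, file.path(img_dir, paste0(s$image_id, ".png")))
  }
  invisible(dir)
}
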