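# Lumbopelvic parameter geometry. All angles follow the standard clinical
# (Duval-Beaupere) definitions, computed in image coordinates (y axis points
# down) with the patient's facing direction recorded explicitly, so that the
# anatomical identity PI = PT + SS holds analytically. Angles are in degrees,
# double precision, never rounded here.

facing_sign <- function(lm) if (identical(lm$facing, "anterior_is_minus_x")) -1 else 1

.pt2 <- function(lm, name) {
  p <- lm$points[name, ]
  if (is.null(p) || any(!is.finite(p)))
    stop_fedspine(paste0("landmark ", name, " missing or non-finite"), "fedspine_geometry_error")
  as.numeric(p)
}

# Signed endplate inclination: angle of the posterior->anterior plate
# direction above the image horizontal, positive when the anterior end is
# caudal (lower). Shared by SS, PI and LL.
plate_angle <- function(ant, post, s) {
  d <- ant - post
  if (sqrt(sum(d^2)) < 1e-9)
    stop_fedspine("degenerate endplate: anterior and posterior points coincide",
                  "fedspine_geometry_error")
  rad2deg(atan2(d[2], s * d[1]))
}

bicoxofemoral_point <- function(lm) {
  (.pt2(lm, "fem_head_L") + .pt2(lm, "fem_head_R")) / 2
}

#' Sacral slope (SS)
#'
#' Unsigned acute angle between the sacral upper endplate line and the image
#' horizontal, in degrees (range \[0, 90)).
#'
#' @param lm a `landmark_set`.
#' @return degrees.
#' @export
compute_SS <- function(lm) {
  a <- plate_angle(.pt2(lm, "S1_ant"), .pt2(lm, "S1_post"), facing_sign(lm))
  a <- abs(a)
  if (a > 90) a <- 180 - a
  a
}

#' Pelvic tilt (PT)
#'
#' Signed angle between the vertical through the bicoxofemoral point H
#' (midpoint of the femoral head centers) and the segment from H to the
#' sacral endplate midpoint M; positive when M lies posterior to H.
#'
#' @param lm a `landmark_set`.
#' @return degrees.
#' @export
compute_PT <- function(lm) {
  H <- bicoxofemoral_point(lm)
  M <- .pt2(lm, "S1_mid")
  w <- H - M
  if (sqrt(sum(w^2)) < 1e-9)
    stop_fedspine("degenerate pelvis: bicoxofemoral point coincides with sacral midpoint",
                  "fedspine_geometry_error")
  rad2deg(atan2(facing_sign(lm) * w[1], w[2]))
}

#' Pelvic incidence (PI)
#'
#' Signed angle between the perpendicular to the sacral endplate at its
#' midpoint M (taken on the caudal side, toward the femoral heads) and the
#' segment from M to the bicoxofemoral point H. With these sign conventions
#' PI = PT + SS holds exactly for anatomically oriented landmarks.
#'
#' @param lm a `landmark_set`.
#' @return degrees.
#' @export
compute_PI <- function(lm) {
  s <- facing_sign(lm)
  A <- .pt2(lm, "S1_ant"); P <- .pt2(lm, "S1_post")
  M <- .pt2(lm, "S1_mid")
  H <- bicoxofemoral_point(lm)
  u <- A - P
  if (sqrt(sum(u^2)) < 1e-9)
    stop_fedspine("degenerate sacral endplate", "fedspine_geometry_error")
  w <- H - M
  if (sqrt(sum(w^2)) < 1e-9)
    stop_fedspine("degenerate pelvis: H coincides with M", "fedspine_geometry_error")
  n <- c(u[2], -u[1])              # perpendicular to the endplate
  # caudal side: positive y (image y points down); for a vertical endplate
  # fall back to the side facing the femoral heads
  if (n[2] < 0 || (n[2] == 0 && sum(n * w) < 0)) n <- -n
  # inclination of the caudal perpendicular from vertical (posterior-positive)
  psi <- rad2deg(atan2(-s * n[1], n[2]))
  pt <- rad2deg(atan2(s * w[1], w[2]))
  psi + pt
}

#' Lumbar lordosis (LL)
#'
#' Sagittal angle between the superior endplate of `upper_level` and the
#' sacral upper endplate, signed positive for lordotic (posteriorly opening)
#' curvature.
#'
#' @param lm a `landmark_set`.
#' @param upper_level `"L1"` (default) or `"T12"`.
#' @return degrees.
#' @export
compute_LL <- function(lm, upper_level = c("L1", "T12")) {
  upper_level <- match.arg(upper_level)
  s <- facing_sign(lm)
  phi_sac <- plate_angle(.pt2(lm, "S1_ant"), .pt2(lm, "S1_post"), s)
  phi_up <- plate_angle(.pt2(lm, paste0(upper_level, "_asup")),
                        .pt2(lm, paste0(upper_level, "_psup")), s)
  phi_sac - phi_up
}

#' Construct an AngleSet
#'
#' @param SS,PT,PI,LL degrees. If `PI` is missing it is completed as PT + SS.
#' @return named numeric vector of class `angle_set`.
#' @export
angle_set <- function(SS, PT, PI = PT + SS, LL) {
  structure(c(SS = SS, PT = PT, PI = PI, LL = LL), class = "angle_set")
}

#' Compute all four lumbopelvic angles of a LandmarkSet
#'
#' @param lm a `landmark_set`.
#' @param upper_level upper endplate for LL, `"L1"` or `"T12"`.
#' @return an `angle_set` (SS, PT, PI, LL in degrees).
#' @export
compute_angles <- function(lm, upper_level = "L1") {
  angle_set(SS = compute_SS(lm), PT = compute_PT(lm), PI = compute_PI(lm),
            LL = compute_LL(lm, upper_level))
}

#' Per-angle absolute error
#'
#' @param pred,gt `angle_set`s (or named vectors with SS, PT, PI, LL).
#' @return named numeric vector |pred - gt| in degrees.
#' @export
angle_abs_error <- function(pred, gt) {
  nm <- c("SS", "PT", "PI", "LL")
  abs(unclass(pred)[nm] - unclass(gt)[nm])
}

#' Landmark localization error in millimetres
#'
#' Euclidean distance between corresponding predicted and ground-truth
#' landmarks, converted to mm via the shared pixel spacing, with per-level
#' (T12...L5, sacrum, femoral_heads) means.
#'
#' @param pred,gt `landmark_set`s on the same schema and pixel spacing.
#' @return object of class `landmark_error`: list(per_point, per_level) in mm.
#' @export
landmark_error <- function(pred, gt) {
  if (!isTRUE(all.equal(pred$pixel_spacing_mm, gt$pixel_spacing_mm, tolerance = 1e-12)))
    stop_fedspine("pixel spacing mismatch between prediction and ground truth",
                  "fedspine_unit_error")
  nm <- landmark_names()
  if (!all(nm %in% rownames(pred$points)) || !all(nm %in% rownames(gt$points)))
    stop_fedspine("landmark schema mismatch", "fedspine_schema_error")
  d <- pred$points[nm, , drop = FALSE] - gt$points[nm, , drop = FALSE]
  per_point <- sqrt(rowSums(d^2)) * gt$pixel_spacing_mm
  lv <- landmark_levels()[nm]
  per_level <- tapply(per_point, lv, mean)
  per_level <- per_level[unique(lv)]
  structure(list(per_point = per_point, per_level = per_level),
            class = "landmark_error")
}
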