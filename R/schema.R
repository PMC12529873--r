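# 29-landmark annotation schema for sagittal lumbopelvic radiographs and the
# LandmarkSet container: 6 vertebrae (T12-L5) x 4 endplate corners, 3 sacral
# upper-endplate points, 2 femoral head centers.

.VERTEBRAE <- c("T12", "L1", "L2", "L3", "L4", "L5")
.CORNERS <- c("asup", "psup", "ainf", "pinf")  # anterior/posterior x superior/inferior

#' Names of the 29 landmarks, in canonical order
#'
#' Vertebral corner names are `<level>_<corner>` with corners `asup`
#' (anterior-superior), `psup`, `ainf`, `pinf`; the sacral upper endplate
#' contributes `S1_ant`, `S1_post`, `S1_mid`; femoral head centers are
#' `fem_head_L` and `fem_head_R`.
#'
#' @return character vector of length 29.
#' @export
landmark_names <- function() {
  c(as.vector(t(outer(.VERTEBRAE, .CORNERS, paste, sep = "_"))),
    "S1_ant", "S1_post", "S1_mid", "fem_head_L", "fem_head_R")
}

#' Anatomical level of each landmark
#'
#' @return named character vector mapping landmark name to its level
#'   (`T12` ... `L5`, `sacrum`, `femoral_heads`).
#' @export
landmark_levels <- function() {
  nm <- landmark_names()
  lv <- sub("_(asup|psup|ainf|pinf)$", "", nm)
  lv[grepl("^S1_", nm)] <- "sacrum"
  lv[grepl("^fem_head_", nm)] <- "femoral_heads"
  names(lv) <- nm
  lv
}

#' Construct a LandmarkSet
#'
#' A LandmarkSet holds the 29 named keypoints of one sagittal image in
#' continuous, 0-based pixel coordinates (origin at the center of the top-left
#' pixel, y axis pointing down), together with the isotropic pixel spacing and
#' the patient facing direction.
#'
#' @param points numeric 29 x 2 matrix (columns x, y) with rownames from
#'   [landmark_names()], in any order.
#' @param pixel_spacing_mm mm per pixel, > 0.
#' @param facing `"anterior_is_plus_x"` or `"anterior_is_minus_x"`.
#' @param image_size integer c(width, height) in pixels.
#' @param validate validate invariants (default TRUE).
#' @return object of class `landmark_set`.
#' @export
landmark_set <- function(points, pixel_spacing_mm, facing = "anterior_is_plus_x",
                         image_size, validate = TRUE) {
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  lm <- structure(list(points = points,
                       pixel_spacing_mm = as.numeric(pixel_spacing_mm),
                       facing = facing,
                       image_size = as.numeric(image_size)),
                  class = "landmark_set")
  if (validate) {
    v <- validate_annotation(lm, check_bounds = FALSE)
    if (length(v)) stop_fedspine(paste0("invalid LandmarkSet: ",
                                        paste(vapply(v, `[[`, "", "message"), collapse = "; ")),
                                 "fedspine_schema_error")
    lm$points <- lm$points[landmark_names(), , drop = FALSE]  # canonical order
    colnames(lm$points) <- c("x", "y")
  }
  lm
}

#' Validate a landmark annotation against the inclusion rule
#'
#' Mirrors the study inclusion criterion (a complete, visible set of
#' landmarks) as a reporting filter: a sample is includable iff this returns
#' an empty list. Violations are `missing_landmark`, `duplicate_landmark`,
#' `unknown_landmark`, `nonfinite_coordinate`, `out_of_field`, and config
#' problems (`bad_spacing`, `bad_facing`).
#'
#' @param lm a `landmark_set` (possibly malformed; this never errors).
#' @param check_bounds also flag coordinates outside the image field.
#' @return list of violations, each a list(code, landmark, message).
#' @export
validate_annotation <- function(lm, check_bounds = TRUE) {
  out <- list()
  add <- function(code, landmark, msg)
    out[[length(out) + 1L]] <<- list(code = code, landmark = landmark, message = msg)
  pts <- lm$points
  nm <- rownames(pts)
  want <- landmark_names()
  for (w in setdiff(want, nm)) add("missing_landmark", w, paste0("missing landmark ", w))
  for (u in setdiff(nm, want)) add("unknown_landmark", u, paste0("unknown landmark ", u))
  for (d in unique(nm[duplicated(nm)])) add("duplicate_landmark", d, paste0("duplicated landmark ", d))
  if (!is.null(pts) && ncol(pts) == 2) {
    bad <- nm[!stats::complete.cases(pts) | !is.finite(pts[, 1]) | !is.finite(pts[, 2])]
    for (b in bad) add("nonfinite_coordinate", b, paste0("non-finite coordinate at ", b))
    if (check_bounds && length(lm$image_size) == 2) {
      w <- lm$image_size[1]; h <- lm$image_size[2]
      oob <- is.finite(pts[, 1]) & is.finite(pts[, 2]) &
        (pts[, 1] < 0 | pts[, 1] > w - 1 | pts[, 2] < 0 | pts[, 2] > h - 1)
      for (b in nm[oob]) add("out_of_field", b, paste0("coordinate outside image field at ", b))
    }
  }
  if (!is.numeric(lm$pixel_spacing_mm) || length(lm$pixel_spacing_mm) != 1 ||
      !is.finite(lm$pixel_spacing_mm) || lm$pixel_spacing_mm <= 0)
    add("bad_spacing", NA_character_, "pixel_spacing_mm must be a positive number")
  if (!identical(lm$facing, "anterior_is_plus_x") && !identical(lm$facing, "anterior_is_minus_x"))
    add("bad_facing", NA_character_, "facing must be anterior_is_plus_x or anterior_is_minus_x")
  out
}

#' @export
print.landmark_set <- function(x, ...) {
  cat(sprintf("<landmark_set> %d points, %.3g mm/px, %s, image %dx%d\n",
              nrow(x$points), x$pixel_spacing_mm, x$facing,
              as.integer(x$image_size[1]), as.integer(x$image_size[2])))
  invisible(x)
}

# ---- annotation I/O (JSON object-per-image and flat CSV dialect) ----

lm_to_record <- function(lm, image_id, patient_id = NA, center_id = NA, visit = NA) {
  pts <- lapply(seq_len(nrow(lm$points)), function(i) unname(lm$points[i, ]))
  names(pts) <- rownames(lm$points)
  list(image_id = image_id, patient_id = patient_id, center_id = center_id,
       visit = visit, pixel_spacing_mm = lm$pixel_spacing_mm, facing = lm$facing,
       image_size = unname(lm$image_size), points = pts)
}

#' Write landmark annotations to JSON
#'
#' One JSON object per image: `{image_id, patient_id, center_id, visit,
#' pixel_spacing_mm, facing, image_size, points: {name: [x, y]}}`.
#'
#' @param samples list of `spine_sample` objects (or bare `landmark_set`s).
#' @param path output file.
#' @export
write_annotations_json <- function(samples, path) {
  recs <- lapply(samples, function(s) {
    if (inherits(s, "landmark_set"))
      lm_to_record(s, image_id = "image")
    else
      lm_to_record(s$landmarks, s$image_id, s$patient_id, s$center_id, s$visit)
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read landmark annotations from JSON
#'
#' @param path file written by [write_annotations_json()].
#' @return list of records, each with `$landmarks` (a `landmark_set`) and ids.
#' @export
read_annotations_json <- function(path) {
  recs <- jsonlite::read_json(path)
  lapply(recs, function(r) {
    pts <- do.call(rbind, lapply(r$points, function(p) as.numeric(unlist(p))))
    rownames(pts) <- names(r$points)
    list(image_id = r$image_id, patient_id = r$patient_id, center_id = r$center_id,
         visit = r$visit,
         landmarks = landmark_set(pts, r$pixel_spacing_mm, r$facing,
                                  as.numeric(unlist(r$image_size))))
  })
}

#' Write landmark annotations as flat CSV (one row per point)
#'
#' @param samples list of `spine_sample`s.
#' @param path output csv.
#' @export
write_annotations_csv <- function(samples, path) {
  rows <- do.call(rbind, lapply(samples, function(s) {
    lm <- s$landmarks
    data.frame(image_id = s$image_id, patient_id = s$patient_id,
               center_id = s$center_id, visit = s$visit,
               pixel_spacing_mm = lm$pixel_spacing_mm, facing = lm$facing,
               image_width = lm$image_size[1], image_height = lm$image_size[2],
               landmark = rownames(lm$points),
               x = lm$points[, 1], y = lm$points[, 2],
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Read the flat CSV annotation dialect
#'
#' @param path csv written by [write_annotations_csv()].
#' @return as [read_annotations_json()].
#' @export
read_annotations_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  lapply(split(d, d$image_id), function(g) {
    pts <- cbind(x = g$x, y = g$y)
    rownames(pts) <- g$landmark
    list(image_id = g$image_id[1], patient_id = g$patient_id[1],
         center_id = g$center_id[1], visit = g$visit[1],
         landmarks = landmark_set(pts, g$pixel_spacing_mm[1], g$facing[1],
                                  c(g$image_width[1], g$image_height[1])))
  })
}
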