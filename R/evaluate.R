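# Evaluation surface of the study: per-vertebra localization error, per-angle
# absolute error stratified by hospital, the internal/external cross-site
# matrix, and percentage-of-correct-predictions (PCP) curves. Angle errors
# are computed in the original (pre-resize) pixel frame; per-image errors are
# aggregated first per image, then averaged.

#' Predict landmark sets for a batch of samples
#'
#' Runs the forward pass, converts the DSNT coordinates to input pixels and
#' maps them back to each sample's original frame (via `sample$transform`
#' when present).
#'
#' @param params parameter list.
#' @param config `model_config`.
#' @param samples list of `spine_sample`s (images must match the config size).
#' @param batch_size forward batch size.
#' @return list of predicted `landmark_set`s (same spacing/facing as inputs).
#' @export
predict_landmarks <- function(params, config, samples, batch_size = 16L) {
  out <- vector("list", length(samples))
  nm <- landmark_names()
  for (bs in seq(1, length(samples), by = batch_size)) {
    idx <- bs:min(bs + batch_size - 1, length(samples))
    fw <- model_forward(params, config, lapply(samples[idx], `[[`, "image"))
    for (i in seq_along(idx)) {
      s <- samples[[idx[i]]]
      px <- cbind(x = norm_to_px(fw$coords[1, , i], config$input_size, config$heatmap_stride),
                  y = norm_to_px(fw$coords[2, , i], config$input_size, config$heatmap_stride))
      if (!is.null(s$transform)) px <- map_landmarks_back(px, s$transform)
      gt <- s$gt_landmarks %||% s$landmarks
      rownames(px) <- nm
      out[[idx[i]]] <- landmark_set(px, gt$pixel_spacing_mm, gt$facing,
                                    gt$image_size, validate = FALSE)
    }
  }
  out
}

#' Evaluate a model on a test split
#'
#' Computes per-image landmark errors (mm) and per-angle absolute errors
#' (degrees, from landmarks recomputed in the original frame), then
#' aggregates mean/sd/median per image. Refuses to run if any test patient
#' appears in the supplied training patient set (leakage guard).
#'
#' @param params parameter list.
#' @param config `model_config`.
#' @param samples test `spine_sample`s.
#' @param model_id label (`centralized`, `fedavg`, `local:<center>`, ...).
#' @param train_center `"all"` or a center id.
#' @param test_center test-set center label.
#' @param train_patient_ids optional patient ids seen in training.
#' @param predict_fn optional predictor `function(samples) -> list of
#'   landmark_set`; replaces the model forward pass (useful for oracle and
#'   reference predictors).
#' @return object of class `eval_record`: summary stats plus `$per_image`.
#' @export
evaluate_model <- function(params, config, samples, model_id = "model",
                           train_center = "all", test_center = "pooled",
                           train_patient_ids = NULL, predict_fn = NULL) {
  if (!length(samples)) stop_fedspine("empty test split", "fedspine_config_error")
  test_pats <- unique(vapply(samples, `[[`, "", "patient_id"))
  if (!is.null(train_patient_ids) && length(intersect(test_pats, train_patient_ids)))
    stop_fedspine("data leakage: test patients present in training set",
                  "fedspine_leakage_error")
  preds <- if (is.null(predict_fn)) predict_landmarks(params, config, samples)
           else predict_fn(samples)
  rows <- lapply(seq_along(samples), function(i) {
    s <- samples[[i]]
    le <- landmark_error(preds[[i]], s$landmarks)
    pa <- tryCatch(compute_angles(preds[[i]]),
                   error = function(e) angle_set(SS = NA_real_, PT = NA_real_,
                                                 PI = NA_real_, LL = NA_real_))
    ae <- angle_abs_error(pa, s$true_angles)
    cbind(data.frame(image_id = s$image_id, patient_id = s$patient_id,
                     center_id = s$center_id,
                     landmark_err_mm = mean(le$per_point)),
          as.data.frame(t(le$per_level)),
          data.frame(SS_err = ae[["SS"]], PT_err = ae[["PT"]],
                     PI_err = ae[["PI"]], LL_err = ae[["LL"]]))
  })
  per_image <- do.call(rbind, rows)
  ang_stats <- lapply(c("SS", "PT", "PI", "LL"), function(a) {
    e <- per_image[[paste0(a, "_err")]]
    c(mean = mean(e, na.rm = TRUE), sd = stats::sd(e), median = stats::median(e, na.rm = TRUE))
  })
  names(ang_stats) <- c("SS", "PT", "PI", "LL")
  scope <- if (train_center == "all") "internal"
           else if (identical(train_center, test_center)) "internal" else "external"
  structure(list(model_id = model_id, train_center = train_center,
                 test_center = test_center, scope = scope,
                 n_images = nrow(per_image),
                 landmark_err_mm = c(mean = mean(per_image$landmark_err_mm),
                                     sd = stats::sd(per_image$landmark_err_mm),
                                     median = stats::median(per_image$landmark_err_mm)),
                 per_level_mm = colMeans(per_image[, unique(landmark_levels()), drop = FALSE]),
                 angle_errors = ang_stats,
                 per_image = per_image),
            class = "eval_record")
}

#' Internal/external cross-site evaluation matrix
#'
#' Evaluates every model on every center's held-out test split. Local models
#' are tagged `internal` on their own center and `external` elsewhere;
#' centralized and federated models are evaluated on every center's test set.
#'
#' @param models named list; each element list(params, config, train_center,
#'   train_patient_ids).
#' @param samples full cohort.
#' @param split a `split_assignment`.
#' @return list of `eval_record`s (one per model x center).
#' @export
cross_site_matrix <- function(models, samples, split) {
  centers <- sort(unique(split$center_id))
  records <- list()
  for (mid in names(models)) {
    m <- models[[mid]]
    for (cid in centers) {
      te <- split_samples(samples, split, "test", cid)
      if (!length(te)) stop_fedspine(paste0("missing test split for center ", cid),
                                     "fedspine_config_error")
      records[[length(records) + 1L]] <-
        evaluate_model(m$params, m$config, te, model_id = mid,
                       train_center = m$train_center %||% "all", test_center = cid,
                       train_patient_ids = m$train_patient_ids)
    }
  }
  records
}

#' Tidy data.frame view of evaluation records
#'
#' @param records list of `eval_record`s.
#' @return one row per record with summary columns.
#' @export
records_to_df <- function(records) {
  do.call(rbind, lapply(records, function(r) {
    data.frame(model_id = r$model_id, train_center = r$train_center,
               test_center = r$test_center, scope = r$scope, n_images = r$n_images,
               landmark_err_mm = r$landmark_err_mm[["mean"]],
               SS_mae = r$angle_errors$SS[["mean"]], PT_mae = r$angle_errors$PT[["mean"]],
               PI_mae = r$angle_errors$PI[["mean"]], LL_mae = r$angle_errors$LL[["mean"]])
  }))
}

#' Percentage of correct predictions at error thresholds
#'
#' Fraction of errors less than or equal to each threshold (inclusive
#' comparison).
#'
#' @param errors nonempty numeric vector of absolute errors (degrees).
#' @param thresholds thresholds in degrees (default 1..15).
#' @return data.frame(threshold, fraction), nondecreasing in threshold.
#' @export
pcp <- function(errors, thresholds = 1:15) {
  if (!length(errors)) stop_fedspine("empty error vector", "fedspine_evaluation_error")
  data.frame(threshold = thresholds,
             fraction = vapply(thresholds, function(t) mean(errors <= t, na.rm = TRUE), 0))
}

#' Per-angle and pooled PCP curves from per-image errors
#'
#' @param per_image the `$per_image` table of an `eval_record` (or rbind of
#'   several), with SS_err/PT_err/PI_err/LL_err columns.
#' @param thresholds degrees (default 1..15).
#' @return data.frame(angle, threshold, fraction); `angle = "pooled"` pools
#'   all four parameters.
#' @export
pcp_curves <- function(per_image, thresholds = 1:15) {
  angs <- c("SS", "PT", "PI", "LL")
  out <- lapply(angs, function(a)
    cbind(angle = a, pcp(per_image[[paste0(a, "_err")]], thresholds)))
  pooled <- unlist(per_image[paste0(angs, "_err")], use.names = FALSE)
  out[[length(out) + 1L]] <- cbind(angle = "pooled", pcp(pooled, thresholds))
  do.call(rbind, out)
}

boxplot_stats <- function(x) {
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), na.rm = TRUE, names = FALSE)
  iqr <- q[3] - q[1]
  lo <- q[1] - 1.5 * iqr; hi <- q[3] + 1.5 * iqr
  c(q1 = q[1], median = q[2], q3 = q[3],
    whisker_low = min(x[x >= lo], na.rm = TRUE),
    whisker_high = max(x[x <= hi], na.rm = TRUE))
}

#' Write the evaluation report
#'
#' Emits tidy CSVs (records, per-image errors, per-level localization errors,
#' per-angle boxplot statistics, PCP curves), a JSON summary, and (optionally,
#' when ggplot2 is available) per-vertebra error and PCP figures. File
#' contents are deterministic given the inputs.
#'
#' @param records list of `eval_record`s.
#' @param out_dir output directory (created).
#' @param thresholds PCP thresholds, degrees.
#' @param figures also render PNG figures.
#' @return invisible vector of written paths.
#' @export
report <- function(records, out_dir, thresholds = 1:15, figures = FALSE) {
  if (!length(records)) stop_fedspine("no records to report", "fedspine_config_error")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  w <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    paths <<- c(paths, p)
  }
  df <- records_to_df(records)
  w(df, "records.csv")
  per_image <- do.call(rbind, lapply(records, function(r)
    cbind(model_id = r$model_id, test_center = r$test_center, scope = r$scope,
          r$per_image)))
  w(per_image, "per_image.csv")
  lev <- do.call(rbind, lapply(records, function(r)
    data.frame(model_id = r$model_id, test_center = r$test_center,
               level = names(r$per_level_mm), err_mm = unname(r$per_level_mm))))
  w(lev, "per_level.csv")
  bx <- do.call(rbind, lapply(split(per_image, per_image$model_id), function(g) {
    do.call(rbind, lapply(c("SS", "PT", "PI", "LL"), function(a)
      data.frame(model_id = g$model_id[1], angle = a,
                 t(boxplot_stats(g[[paste0(a, "_err")]])))))
  }))
  rownames(bx) <- NULL
  w(bx, "boxplot_stats.csv")
  pc <- do.call(rbind, lapply(split(per_image, per_image$model_id), function(g)
    cbind(model_id = g$model_id[1], pcp_curves(g, thresholds))))
  rownames(pc) <- NULL
  w(pc, "pcp.csv")
  summ <- lapply(split(df, df$model_id), function(g)
    list(landmark_err_mm = mean(g$landmark_err_mm),
         angle_mae = mean(c(g$SS_mae, g$PT_mae, g$PI_mae, g$LL_mae)),
         n_images = sum(g$n_images)))
  jsonlite::write_json(summ, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  paths <- c(paths, file.path(out_dir, "summary.json"))
  if (figures && requireNamespace("ggplot2", quietly = TRUE)) {
    g1 <- ggplot2::ggplot(lev, ggplot2::aes(x = level, y = err_mm, fill = model_id)) +
      ggplot2::geom_col(position = "dodge") +
      ggplot2::labs(y = "mean localization error (mm)", x = NULL)
    ggplot2::ggsave(file.path(out_dir, "per_vertebra_error.png"), g1,
                    width = 7, height = 4, dpi = 120)
    g2 <- ggplot2::ggplot(pc[pc$angle == "pooled", ],
                          ggplot2::aes(threshold, fraction, colour = model_id)) +
      ggplot2::geom_line() + ggplot2::geom_point() +
      ggplot2::labs(x = "error threshold (deg)", y = "fraction correct")
    ggplot2::ggsave(file.path(out_dir, "pcp.png"), g2, width = 6, height = 4, dpi = 120)
  }
  invisible(paths)
}
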