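#' Default run configuration
#'
#' Aggregates every stage's parameters into one serializable list. Defaults
#' equal the published values where one exists (FCM: 2 clusters, exponent
#' 2, tolerance 0.0005, 100 iterations, threshold 0.5; GVF: mu = 0.1;
#' snake: alpha = 0.01, beta = 0; stepwise: p_enter = 0.10,
#' p_remove = 0.15) and this package's documented choices elsewhere
#' (GLCM quantization, snake numerics, phantom margin).
#'
#' @param ... Named overrides for any nested field, e.g.
#'   `run_config(fcm = list(threshold = 0.6))` (partial lists are merged).
#' @return A nested list of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- list(
    fcm = list(n_clusters = 2L, weighting_exponent = 2, stop_criterion = 5e-4,
               max_iterations = 100L, threshold = 0.5, seed = 1L),
    gvf = list(mu = 0.1, n_iterations = 80L, time_step = 1),
    snake = list(alpha = 0.01, beta = 0, gamma = 1, max_iterations = 400L,
                 convergence_tol = 0.01, resample_spacing = 1,
                 resample_every = 10L, normalize_force = TRUE, force_floor = 0.1),
    edge = list(presmooth_sigma = 1),
    glcm = list(levels = 64L, d = 1L),
    shape = list(radial_bins = 10L),
    stepwise = list(p_enter = 0.10, p_remove = 0.15, feature_pool = "all",
                    max_steps = 50L),
    refine = list(margin = 10L),
    seed = 1L
  )
  dots <- list(...)
  for (nm in names(dots)) {
    if (is.list(dots[[nm]]) && is.list(cfg[[nm]])) {
      cfg[[nm]][names(dots[[nm]])] <- dots[[nm]]
    } else cfg[[nm]] <- dots[[nm]]
  }
  structure(cfg, class = "run_config")
}

#' Save / load a run configuration as YAML
#'
#' The round trip `load_config(save_config(cfg, path))` reproduces the
#' configuration exactly.
#'
#' @param config A [run_config()].
#' @param path YAML file path.
#' @return `save_config()` returns `path` invisibly; `load_config()` the
#'   `run_config`.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname save_config
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(run_config, raw)
}

cfg_fcm <- function(cfg) do.call(fcm_params, cfg$fcm)
cfg_gvf <- function(cfg) do.call(gvf_params, cfg$gvf)
cfg_snake <- function(cfg) do.call(snake_params, cfg$snake)
cfg_stepwise <- function(cfg) do.call(stepwise_config, cfg$stepwise)

#' Segment and characterize one lesion
#'
#' Runs the full per-lesion chain: fuzzy c-means initial segmentation of
#' the ROI, GVF-snake refinement, and extraction of the 21-component
#' feature vector (13 texture + 8 morphology) from the refined mask.
#' Stage failures are rethrown with the failing stage named.
#'
#' @param image Grayscale image matrix.
#' @param roi An [roi_box()] enclosing the lesion.
#' @param config A [run_config()].
#' @return A list: `initial_mask`, `refined_mask`, `contour`
#'   (`snake_contour` of the refined boundary), `features` (one-row
#'   tibble).
#' @examples
#' ph <- make_phantom(phantom_spec(seed = 5))
#' res <- run_lesion(ph$image, roi_box(30, 30, 99, 99))
#' res$features
#' @export
run_lesion <- function(image, roi, config = run_config()) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
  }
  initial <- stage("fcm_segmentation",
                   initial_segment(image, roi, cfg_fcm(config)))
  refined <- stage("gvf_snake",
                   refine(image, initial, cfg_gvf(config), cfg_snake(config),
                          presmooth_sigma = config$edge$presmooth_sigma,
                          margin = config$refine$margin))
  features <- stage("features",
                    lesion_features(image, refined,
                                    levels = config$glcm$levels,
                                    radial_bins = config$shape$radial_bins))
  list(initial_mask = initial, refined_mask = refined,
       contour = attr(refined, "contour"), features = features)
}

#' Default ROI for a phantom: the ground-truth bounding box padded
#'
#' @param mask Logical ground-truth mask.
#' @param pad Padding in pixels.
#' @return An [roi_box()].
#' @export
phantom_roi <- function(mask, pad = 12L) {
  rows <- range(which(rowSums(mask) > 0))
  cols <- range(which(colSums(mask) > 0))
  roi_box(max(1L, rows[1] - pad), max(1L, cols[1] - pad),
          min(nrow(mask), rows[2] + pad), min(ncol(mask), cols[2] + pad))
}

#' Run the full segmentation-and-classification study on a cohort
#'
#' For every lesion: initial and refined segmentation plus feature
#' extraction from both the refined mask and the reference mask. Then the
#' segmentation evaluation battery ([batch_evaluate()]) and, if requested,
#' leave-one-out stepwise-discriminant classification on both feature sets
#' with ROC analysis and the DeLong paired AUC comparison — mirroring the
#' comparison of computer-derived versus reference-derived features.
#' Per-lesion failures are logged and skipped; the run aborts if more than
#' 20 percent of lesions fail.
#'
#' @param cohort A list of lesions as produced by [make_cohort()] (elements
#'   with `image`, `mask` (reference), `label`), or any list of such
#'   elements; an element may carry its own `roi`.
#' @param config A [run_config()].
#' @param classify Run the classification stage (needs both classes and
#'   n >= 8).
#' @param outdir Optional directory; when given, masks (PNG), contours and
#'   features (CSV), the evaluation summary (CSV) and the classification
#'   report (JSON) are written there.
#' @return A list: `evaluation` (see [batch_evaluate()]), `features`
#'   (tibble of per-lesion features from the refined masks, with `label`),
#'   `features_reference` (same from reference masks), `classification`
#'   (list with `roc_refined`, `roc_reference`, `delong`,
#'   `selected_refined`, `selected_reference`) or `NULL`, and `failures`
#'   (tibble).
#' @export
run_study <- function(cohort, config = run_config(), classify = TRUE,
                      outdir = NULL) {
  stopifnot(length(cohort) >= 3)
  results <- purrr::map(seq_along(cohort), function(i) {
    item <- cohort[[i]]
    roi <- if (!is.null(item$roi)) item$roi else phantom_roi(item$mask)
    tryCatch(
      {
        res <- run_lesion(item$image, roi, config)
        res$features_reference <- lesion_features(
          item$image, item$mask, levels = config$glcm$levels,
          radial_bins = config$shape$radial_bins)
        res$label <- item$label
        res$ok <- TRUE
        res
      },
      error = function(e) list(ok = FALSE, error = conditionMessage(e),
                               label = item$label)
    )
  })
  ok <- vapply(results, `[[`, TRUE, "ok")
  failures <- tibble::tibble(
    id = which(!ok),
    error = vapply(results[!ok], `[[`, "", "error")
  )
  if (mean(!ok) > 0.2)
    stop(sprintf("%d of %d lesions failed segmentation", sum(!ok), length(ok)),
         call. = FALSE)
  keep <- which(ok)
  good <- results[keep]
  evaluation <- batch_evaluate(
    purrr::map(good, "initial_mask"),
    purrr::map(good, "refined_mask"),
    purrr::map(cohort[keep], "mask"),
    ids = keep
  )
  labels <- vapply(good, `[[`, "", "label")
  features <- dplyr::bind_cols(
    tibble::tibble(id = keep, label = labels),
    dplyr::bind_rows(purrr::map(good, "features")))
  features_reference <- dplyr::bind_cols(
    tibble::tibble(id = keep, label = labels),
    dplyr::bind_rows(purrr::map(good, "features_reference")))
  classification <- NULL
  if (classify && length(unique(labels)) == 2L && length(keep) >= 8L) {
    sw <- cfg_stepwise(config)
    scores_ref <- loocv_scores(features_reference, sw)
    scores_cmp <- loocv_scores(features, sw)
    roc_cmp <- roc_analysis(scores_cmp$score, scores_cmp$label)
    roc_ref <- roc_analysis(scores_ref$score, scores_ref$label)
    classification <- list(
      roc_refined = roc_cmp,
      roc_reference = roc_ref,
      delong = compare_auc(roc_cmp, roc_ref),
      selected_refined = stepwise_select(features, sw),
      selected_reference = stepwise_select(features_reference, sw)
    )
  }
  out <- list(evaluation = evaluation, features = features,
              features_reference = features_reference,
              classification = classification, failures = failures)
  if (!is.null(outdir)) write_study_outputs(out, good, keep, outdir)
  out
}

write_study_outputs <- function(out, good, keep, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  for (k in seq_along(good)) {
    id <- keep[k]
    write_gray_png(good[[k]]$initial_mask,
                   file.path(outdir, sprintf("mask_initial_%03d.png", id)))
    write_gray_png(good[[k]]$refined_mask,
                   file.path(outdir, sprintf("mask_refined_%03d.png", id)))
    write_contour_csv(good[[k]]$contour,
                      file.path(outdir, sprintf("contour_%03d.csv", id)))
  }
  utils::write.csv(out$features, file.path(outdir, "features.csv"),
                   row.names = FALSE)
  utils::write.csv(out$evaluation$per_lesion,
                   file.path(outdir, "evaluation_per_lesion.csv"),
                   row.names = FALSE)
  utils::write.csv(out$evaluation$summary,
                   file.path(outdir, "evaluation_summary.csv"),
                   row.names = FALSE)
  if (!is.null(out$classification)) {
    cls <- out$classification
    report <- list(
      selected_refined = cls$selected_refined,
      selected_reference = cls$selected_reference,
      refined = unclass(glance(cls$roc_refined)),
      reference = unclass(glance(cls$roc_reference)),
      delong_p = cls$delong$p_value
    )
    jsonlite::write_json(report, file.path(outdir, "classification.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(outdir)
}
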