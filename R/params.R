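#' Segmentation parameters
#'
#' The tunable variables of the segmentation pipeline. Pixel-valued
#' parameters (`ridge_scale`, sigmas, `max_trace_distance`) are in pixels
#' of the xy grid; `max_intercentroid_distance` and the volume constraints
#' are in micrometres and converted with the volume calibration.
#'
#' @param smoothing_sigma optional pre-smoothing sigma in px (0 = off).
#' @param ridge_scale ridge filter scale in px, about the envelope
#'   half-thickness.
#' @param dog_sigma_small,dog_sigma_large Difference-of-Gaussian sigmas
#'   (px) for seed detection; small < large.
#' @param seed_threshold minimum DoG response for a seed, in intensity
#'   units of the input image. The one variable that typically needs
#'   retuning when bit depth changes.
#' @param max_trace_distance maximum cumulative ridge path length in px.
#' @param intensity_drop_fraction tracing stops when the ridge response
#'   falls below this fraction of the response at the root (relative, so
#'   invariant to global intensity rescaling).
#' @param sharp_turn_max_angle stop threshold (degrees) on the turning
#'   angle accumulated over `turn_window` steps.
#' @param max_intercentroid_distance maximum 2D centroid distance (um)
#'   between areas linked across planes.
#' @param overlap_threshold minimum area-overlap fraction for a link;
#'   with `overlap_mode = "max"` the larger of the two per-area fractions
#'   must pass.
#' @param max_jump maximum number of planes a link may span.
#' @param min_volume,max_volume emitted volume constraints in um^3.
#' @param min_span minimum number of occupied planes an emitted volume
#'   must have; single-plane detections are typically noise.
#' @param enable_ir_split,enable_cd_split,enable_smoothing post-processing
#'   toggles (intensity-ratio split, centroid-displacement split,
#'   morphological smoothing).
#' @param classifier_path optional path to a trained classifier TSV.
#' @param smoothing_z when smoothing is on, average each plane with its
#'   two z neighbours (weights 1-2-1) before the in-plane Gaussian;
#'   adjacent planes are structurally similar, so this suppresses noise
#'   with little geometric cost.
#' @param min_separation minimum seed spacing in px (default
#'   `2 * dog_sigma_small`).
#' @param posterior_cutoff classifier acceptance cut on P(valid).
#' @param turn_window steps over which the turning angle is measured.
#' @param branch_depth maximum child-ridglet generations.
#' @param ir_prominence,cd_prominence peak prominence factors for the two
#'   splitting procedures.
#' @param cd_min_peak_px absolute floor (in xy pixels) a centroid
#'   displacement peak must exceed; guards against splitting on
#'   digitisation jitter.
#' @param overlap_mode `"max"` or `"min"` of the two per-area overlap
#'   fractions.
#' @param max_seeds_per_plane cap on seeds traced per plane.
#' @param response_smooth sigma (px) of a Gaussian applied to the ridge
#'   response field before crest extraction; regularises the crest under
#'   noise without blurring the underlying image.
#' @return object of class `SegmentationParams` (a named list).
#' @export
seg_params <- function(smoothing_sigma = 0,
                       ridge_scale = 1.5,
                       dog_sigma_small = 1.5,
                       dog_sigma_large = 3,
                       seed_threshold = 100,
                       max_trace_distance = 300,
                       intensity_drop_fraction = 0.08,
                       sharp_turn_max_angle = 150,
                       max_intercentroid_distance = 8,
                       overlap_threshold = 0.35,
                       max_jump = 2,
                       min_volume = 40,
                       max_volume = 2000,
                       min_span = 2,
                       enable_ir_split = TRUE,
                       enable_cd_split = TRUE,
                       enable_smoothing = TRUE,
                       classifier_path = "",
                       smoothing_z = TRUE,
                       min_separation = NULL,
                       posterior_cutoff = 0.5,
                       turn_window = 5,
                       branch_depth = 3,
                       ir_prominence = 1.5,
                       cd_prominence = 3,
                       cd_min_peak_px = 3,
                       overlap_mode = "max",
                       max_seeds_per_plane = 400,
                       response_smooth = 0) {
  p <- list(smoothing_sigma = smoothing_sigma, ridge_scale = ridge_scale,
            dog_sigma_small = dog_sigma_small, dog_sigma_large = dog_sigma_large,
            seed_threshold = seed_threshold, max_trace_distance = max_trace_distance,
            intensity_drop_fraction = intensity_drop_fraction,
            sharp_turn_max_angle = sharp_turn_max_angle,
            max_intercentroid_distance = max_intercentroid_distance,
            overlap_threshold = overlap_threshold, max_jump = max_jump,
            min_volume = min_volume, max_volume = max_volume,
            min_span = min_span,
            enable_ir_split = enable_ir_split, enable_cd_split = enable_cd_split,
            enable_smoothing = enable_smoothing, classifier_path = classifier_path,
            smoothing_z = smoothing_z,
            min_separation = if (is.null(min_separation)) 2 * dog_sigma_small else min_separation,
            posterior_cutoff = posterior_cutoff, turn_window = turn_window,
            branch_depth = branch_depth, ir_prominence = ir_prominence,
            cd_prominence = cd_prominence, cd_min_peak_px = cd_min_peak_px,
            overlap_mode = overlap_mode, max_seeds_per_plane = max_seeds_per_plane,
            response_smooth = response_smooth)
  class(p) <- "SegmentationParams"
  validate_params(p)
  p
}

validate_params <- function(p) {
  chk <- function(cond, msg) if (!cond) stopf("nucridge_bad_params", msg)
  chk(p$smoothing_sigma >= 0, "smoothing_sigma must be >= 0")
  chk(p$ridge_scale > 0, "ridge_scale must be > 0")
  chk(p$dog_sigma_small > 0 && p$dog_sigma_small < p$dog_sigma_large,
      "need 0 < dog_sigma_small < dog_sigma_large")
  chk(p$intensity_drop_fraction > 0 && p$intensity_drop_fraction < 1,
      "intensity_drop_fraction must be in (0, 1)")
  chk(p$overlap_threshold > 0 && p$overlap_threshold <= 1,
      "overlap_threshold must be in (0, 1]")
  chk(p$max_jump >= 1, "max_jump must be >= 1")
  chk(p$min_volume < p$max_volume, "min_volume must be < max_volume")
  chk(p$overlap_mode %in% c("max", "min"), "overlap_mode must be 'max' or 'min'")
  invisible(p)
}

LOGICAL_PARAMS <- c("enable_ir_split", "enable_cd_split", "enable_smoothing",
                    "smoothing_z")

#' Save / load segmentation parameters as flat key=value text
#'
#' @param params a [seg_params()] object.
#' @param path text file.
#' @return `save_params` returns `path` invisibly; `load_params` a
#'   validated [seg_params()] object. Keys missing from the file keep
#'   their defaults (a file omitting `smoothing_sigma` loads with
#'   smoothing off).
#' @export
save_params <- function(params, path) {
  ln <- vapply(names(params), function(k) {
    v <- params[[k]]
    sprintf("%s = %s", k, if (is.character(v)) v else format(v, digits = 12))
  }, character(1))
  writeLines(ln, path)
  invisible(path)
}

#' @rdname save_params
#' @export
load_params <- function(path) {
  if (!file.exists(path)) stopf("nucridge_missing_file", "no such file: %s", path)
  ln <- trimws(readLines(path, warn = FALSE))
  ln <- ln[nzchar(ln) & !startsWith(ln, "#")]
  bad <- !grepl("=", ln, fixed = TRUE)
  if (any(bad)) stopf("nucridge_bad_params", "malformed line: %s", ln[bad][1])
  keys <- trimws(sub("=.*$", "", ln))
  vals <- trimws(sub("^[^=]*=", "", ln))
  p <- seg_params()
  unknown <- setdiff(keys, names(p))
  if (length(unknown)) stopf("nucridge_bad_params", "unknown key: %s", unknown[1])
  for (i in seq_along(keys)) {
    k <- keys[i]
    p[[k]] <- if (k %in% LOGICAL_PARAMS) as.logical(vals[i])
      else if (k %in% c("classifier_path", "overlap_mode")) vals[i]
      else as.numeric(vals[i])
  }
  validate_params(p)
  p
}
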