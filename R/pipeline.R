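#' Run the full analysis pipeline on a video stack
#'
#' Tracks sperm heads, converts tracks to physical units, computes per-cell
#' kinematics (optionally mapped through per-parameter calibrations), grades
#' each cell, summarises the sample, counts cells over the opening frames
#' and, when a concentration calibration is supplied, converts the count to
#' a concentration. Fully deterministic for a given input stack and
#' configuration.
#'
#' @param frames grayscale frame array (h x w x n), or a path accepted by
#'   [read_video()]
#' @param fps frame rate (Hz)
#' @param microns_per_pixel spatial calibration (um/px)
#' @param tracker a [tracker_config()]
#' @param path_cfg a [path_config()]
#' @param thresholds a [grade_thresholds()]
#' @param conc_calib optional [fit_concentration_curve()] result
#' @param kin_calibs optional list of [fit_linear_calibration()] objects
#' @param count_frames opening frames used for the concentration count
#' @return list with `tracks`, `profiles` (incl. `grade`), `summary`
#'   (a [summarize_sample()] object, with `concentration` when calibrated),
#'   and `mean_count`
#' @export
run_pipeline <- function(frames, fps, microns_per_pixel,
                         tracker = tracker_config(),
                         path_cfg = path_config(),
                         thresholds = grade_thresholds(),
                         conc_calib = NULL, kin_calibs = NULL,
                         count_frames = 10L) {
  if (is.character(frames))
    frames <- read_video(frames, fps = fps,
                         microns_per_pixel = microns_per_pixel)$frames
  tracks <- track_video(frames, tracker)
  mean_count <- count_in_first_frames(frames, count_frames, tracker)

  if (nrow(tracks) == 0L) {
    warning("no cells tracked; returning an empty summary")
    summary <- structure(list(n_cells = 0L, pct_rapid = NA_real_,
                              pct_slow = NA_real_, pct_npim = NA_real_,
                              grades = character(0), stats = NULL),
                         class = "sample_summary")
    profiles <- NULL
  } else {
    profiles <- profile_tracks(tracks, microns_per_pixel, fps, path_cfg)
    if (!is.null(kin_calibs))
      profiles <- apply_calibration(profiles, kin_calibs)
    profiles$grade <- grade_cells(profiles, thresholds)
    summary <- suppressWarnings(summarize_sample(profiles, thresholds))
    if (nrow(profiles) < 200L)
      warning(sprintf("only %d cells analysed; WHO6 recommends > 200",
                      nrow(profiles)))
  }
  if (!is.null(conc_calib))
    summary$concentration <- estimate_concentration(mean_count, conc_calib)
  list(tracks = tracks, profiles = profiles, summary = summary,
       mean_count = mean_count)
}
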