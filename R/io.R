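#' Read a grayscale video stack
#'
#' Supports a multi-page TIFF file or a directory of numbered PNG/TIFF
#' frames (sorted by file name). Pixel values are returned on the 0..255
#' scale. Acquisition metadata that the container cannot carry must be
#' supplied explicitly: a missing `fps` or `microns_per_pixel` is an error,
#' never a silent default.
#'
#' @param path TIFF file or frame directory
#' @param fps frame rate (Hz); required
#' @param microns_per_pixel spatial calibration (um/px); required
#' @return list with `frames` (integer array h x w x n) and `meta` (list:
#'   fps, microns_per_pixel, width, height, n_frames, source)
#' @export
read_video <- function(path, fps = NULL, microns_per_pixel = NULL) {
  if (is.null(fps)) stop("missing required metadata: fps", call. = FALSE)
  if (is.null(microns_per_pixel))
    stop("missing required metadata: microns_per_pixel", call. = FALSE)
  if (!file.exists(path)) stop("cannot read: ", path, call. = FALSE)
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.(png|tif|tiff)$",
                             ignore.case = TRUE, full.names = TRUE))
    if (length(files) == 0L) stop("no frames found in ", path, call. = FALSE)
    mats <- lapply(files, read_frame_file)
  } else {
    pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
    if (!is.list(pages)) pages <- list(pages)
    mats <- lapply(pages, to_gray255)
  }
  d1 <- dim(mats[[1]])
  if (!all(vapply(mats, function(m) identical(dim(m), d1), logical(1))))
    stop("frame-size mismatch across stack", call. = FALSE)
  frames <- array(0L, dim = c(d1[1], d1[2], length(mats)))
  for (i in seq_along(mats)) frames[, , i] <- mats[[i]]
  list(frames = frames,
       meta = list(fps = fps, microns_per_pixel = microns_per_pixel,
                   width = d1[2], height = d1[1],
                   n_frames = length(mats), source = path))
}

read_frame_file <- function(f) {
  if (grepl("\\.png$", f, ignore.case = TRUE)) {
    if (!requireNamespace("png", quietly = TRUE))
      stop("package 'png' is required to read PNG frames", call. = FALSE)
    to_gray255(png::readPNG(f))
  } else {
    to_gray255(tiff::readTIFF(f))
  }
}

to_gray255 <- function(img) {
  if (length(dim(img)) == 3L) img <- img[, , 1]
  m <- round(img * 255)
  storage.mode(m) <- "integer"
  m
}

#' Write a video stack as a multi-page TIFF
#'
#' Round-trips exactly with [read_video()] for 8-bit data.
#'
#' @param frames integer array h x w x n (0..255)
#' @param path output file
#' @return `path`, invisibly
#' @export
write_video_tiff <- function(frames, path) {
  n <- frame_count(frames)
  pages <- lapply(seq_len(n), function(t) frames[, , t] / 255)
  tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  invisible(path)
}

fmt_num <- function(x) {
  ifelse(is.na(x), "", formatC(x, digits = 17, format = "g"))
}

#' Write / read a track table as CSV
#'
#' Coordinates are written with 17 significant digits so the round trip is
#' exact. Columns: track_id, frame (0-based), x_px, y_px (0-based pixel
#' centers). The schema is recorded in a `#` header comment.
#'
#' @param tracks data.frame from [track_video()]
#' @param path CSV file
#' @return `path` (writer) or the track data.frame (reader)
#' @export
write_tracks_csv <- function(tracks, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# spermtrackr tracks v1: track_id,frame,x_px,y_px (0-based)", con)
  df <- data.frame(track_id = tracks$track_id, frame = tracks$frame,
                   x_px = fmt_num(tracks$x_px), y_px = fmt_num(tracks$y_px))
  write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_tracks_csv
#' @export
read_tracks_csv <- function(path) {
  df <- read.csv(path, comment.char = "#")
  data.frame(track_id = as.integer(df$track_id), frame = as.integer(df$frame),
             x_px = as.numeric(df$x_px), y_px = as.numeric(df$y_px))
}

#' Write / read a concentration calibration as JSON
#'
#' @param calib a [fit_concentration_curve()] result
#' @param path JSON file
#' @return `path` (writer) or a `concentration_calibration` (reader)
#' @export
write_calibration_json <- function(calib, path) {
  jsonlite::write_json(list(slope = calib$slope, intercept = calib$intercept,
                            r2 = calib$r2, n = calib$n),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_calibration_json
#' @export
read_calibration_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(slope = x$slope, intercept = x$intercept,
                 r2 = x$r2, n = x$n),
            class = "concentration_calibration")
}

#' Write per-cell kinematics results as CSV
#'
#' One row per cell: track_id, n_points, duration_s, vsl, vcl, vap, lin_pct,
#' alh_max, bcf (empty when not reported), grade.
#'
#' @param profiles profile data.frame with a `grade` column
#' @param path CSV file
#' @return `path`, invisibly
#' @export
write_profiles_csv <- function(profiles, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# spermtrackr per-cell results v1", con)
  df <- data.frame(track_id = profiles$track_id,
                   n_points = profiles$n_points,
                   duration_s = fmt_num(profiles$duration_s),
                   vsl = fmt_num(profiles$vsl),
                   vcl = fmt_num(profiles$vcl),
                   vap = fmt_num(profiles$vap),
                   lin_pct = fmt_num(100 * profiles$lin),
                   alh_max = fmt_num(profiles$alh_max),
                   bcf = fmt_num(profiles$bcf),
                   grade = profiles$grade)
  write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Bundled duplicate semen-analysis measurements
#'
#' Duplicate concentration (M/mL) and motility-grading (%) measurements of
#' six semen samples, each analysed twice by two automated analysers
#' ("casa" and "model"), from a published two-method repeatability
#' comparison. Columns: sample, method, metric (concentration, npim, slow,
#' rapid), m1, m2.
#'
#' @return data.frame with 48 rows
#' @export
repeatability_example <- function() {
  read.csv(system.file("extdata", "duplicate_semen_measurements.csv",
                       package = "spermtrackr", mustWork = TRUE),
           stringsAsFactors = FALSE)
}
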