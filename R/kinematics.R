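#' Path-analysis configuration
#'
#' Controls how the smoothed average swimming path is computed and how BCF
#' is reported.
#'
#' @param smoothing_window odd number of frames for the centered moving
#'   average defining the average path, or `NULL` (default) to select a
#'   window of about one beat period per track automatically (see
#'   [select_smoothing_window()])
#' @param bcf_vsl_min BCF is not reported for cells with VSL at or below
#'   this value (um/s, default 2): at such low velocities the instantaneous
#'   and average paths barely separate and the crossing count is unreliable
#' @param pilot_window_s length (s) of the pilot smoothing window used when
#'   `smoothing_window` is `NULL`
#' @return an object of class `path_config`
#' @export
path_config <- function(smoothing_window = NULL, bcf_vsl_min = 2,
                        pilot_window_s = 0.2) {
  if (!is.null(smoothing_window)) {
    smoothing_window <- as.integer(smoothing_window)
    if (smoothing_window < 3L || smoothing_window %% 2L == 0L)
      stop("smoothing_window must be odd and >= 3", call. = FALSE)
  }
  structure(list(smoothing_window = smoothing_window,
                 bcf_vsl_min = bcf_vsl_min,
                 pilot_window_s = pilot_window_s),
            class = "path_config")
}

#' Convert a pixel track to physical units
#'
#' @param track data.frame with columns `frame` (0-based), `x_px`, `y_px`
#' @param microns_per_pixel spatial calibration (um/px, > 0)
#' @param fps frame rate (Hz, > 0)
#' @return data.frame with columns `time` (s), `x_um`, `y_um` and attribute
#'   `fps`
#' @export
to_microns <- function(track, microns_per_pixel, fps) {
  if (is.null(microns_per_pixel) || is.null(fps) ||
      !is.finite(microns_per_pixel) || !is.finite(fps))
    stop("microns_per_pixel and fps are required", call. = FALSE)
  if (microns_per_pixel <= 0 || fps <= 0)
    stop("microns_per_pixel and fps must be > 0", call. = FALSE)
  out <- data.frame(time = track$frame / fps,
                    x_um = track$x_px * microns_per_pixel,
                    y_um = track$y_px * microns_per_pixel)
  attr(out, "fps") <- fps
  out
}

traj_duration <- function(traj) traj$time[nrow(traj)] - traj$time[1]

#' Straight-line velocity (VSL)
#'
#' Distance between the first and last tracked points divided by the track
#' duration.
#'
#' @param traj data.frame with `time`, `x_um`, `y_um`
#' @return VSL in um/s
#' @export
compute_vsl <- function(traj) {
  n <- nrow(traj)
  if (n < 2L) stop("need at least 2 points", call. = FALSE)
  dur <- traj_duration(traj)
  if (dur <= 0) stop("duration must be > 0", call. = FALSE)
  sqrt((traj$x_um[n] - traj$x_um[1])^2 + (traj$y_um[n] - traj$y_um[1])^2) / dur
}

#' Curvilinear velocity (VCL)
#'
#' Sum of the straight-line distances between consecutive tracked points
#' divided by the track duration.
#'
#' @inheritParams compute_vsl
#' @return VCL in um/s
#' @export
compute_vcl <- function(traj) {
  n <- nrow(traj)
  if (n < 2L) stop("need at least 2 points", call. = FALSE)
  polyline_length(cbind(traj$x_um, traj$y_um)) / traj_duration(traj)
}

#' Smoothed average swimming path
#'
#' Centered moving average of the coordinates with symmetric end treatment:
#' the track is extended by odd (point-symmetric) reflection about its end
#' points so the full window applies everywhere. The output has the same
#' number of points, preserves the end points exactly (the reflected pairs
#' average back to the end point), and leaves affine paths unchanged.
#' Shrinking the window towards the ends instead would leave the raw beat
#' oscillation in the path ends and bias VAP upwards for slow cells with
#' vigorous beats.
#'
#' @inheritParams compute_vsl
#' @param cfg a [path_config()] with a numeric `smoothing_window`, or an odd
#'   integer window
#' @return data.frame with the same columns as `traj`, smoothed
#' @export
average_path <- function(traj, cfg = path_config(smoothing_window = 11L)) {
  w <- if (inherits(cfg, "path_config")) cfg$smoothing_window else as.integer(cfg)
  if (is.null(w)) stop("average_path needs a numeric smoothing_window; ",
                       "use kinematic_profile() for automatic selection",
                       call. = FALSE)
  n <- nrow(traj)
  if (w > n) stop("smoothing_window exceeds track length", call. = FALSE)
  h <- (w - 1L) %/% 2L
  smooth1 <- function(v) {
    if (h == 0L) return(v)
    pad <- c(2 * v[1] - v[(1 + h):2], v, 2 * v[n] - v[(n - 1):(n - h)])
    cs <- c(0, cumsum(pad))
    (cs[(1 + w):(n + w)] - cs[1:n]) / w
  }
  out <- data.frame(time = traj$time,
                    x_um = smooth1(traj$x_um),
                    y_um = smooth1(traj$y_um))
  attr(out, "fps") <- attr(traj, "fps")
  out
}

#' Average-path velocity (VAP)
#'
#' Polyline length of the smoothed average path divided by the track
#' duration, clamped into `[VSL, VCL]` (the clamp only absorbs rounding at
#' the 1e-9 relative level; smoothing preserves the end points so
#' VAP >= VSL holds by construction).
#'
#' @inheritParams average_path
#' @return VAP in um/s
#' @export
compute_vap <- function(traj, cfg = path_config(smoothing_window = 11L)) {
  ap <- average_path(traj, cfg)
  vap <- polyline_length(cbind(ap$x_um, ap$y_um)) / traj_duration(traj)
  min(max(vap, compute_vsl(traj)), compute_vcl(traj))
}

#' Linearity (LIN)
#'
#' VSL/VCL, a straightness fraction in `[0, 1]`; defined as 0 when VCL = 0
#' (an immotile cell has no path to be straight about). Reported as percent
#' in CSV outputs.
#'
#' @param vsl straight-line velocity (um/s)
#' @param vcl curvilinear velocity (um/s)
#' @return LIN as a fraction
#' @export
compute_lin <- function(vsl, vcl) {
  if (vcl < 0) stop("vcl must be >= 0", call. = FALSE)
  if (vcl == 0) 0 else min(vsl / vcl, 1)
}

# signed perpendicular offset of each raw point from the smoothed path,
# measured against the local tangent of the segment at the same arc index
lateral_offsets <- function(traj, smoothed) {
  n <- nrow(traj)
  seg <- pmin(seq_len(n), n - 1L)          # segment i -> i+1, last point reuses n-1
  tx <- smoothed$x_um[seg + 1L] - smoothed$x_um[seg]
  ty <- smoothed$y_um[seg + 1L] - smoothed$y_um[seg]
  len <- sqrt(tx^2 + ty^2)
  dx <- traj$x_um - smoothed$x_um
  dy <- traj$y_um - smoothed$y_um
  off <- ifelse(len > 1e-12, (tx * dy - ty * dx) / len, 0)
  off
}

#' Maximum amplitude of lateral head displacement (ALH_max)
#'
#' Maximum perpendicular distance from the raw samples to the nearest
#' segment of the smoothed average-path polyline. Within half a smoothing
#' window of the track ends the average path is poorly determined (any
#' boundary rule distorts it there), so the maximum is taken over the
#' interior samples; distances are still measured against the full
#' polyline.
#'
#' @inheritParams average_path
#' @return ALH_max in um
#' @export
compute_alh_max <- function(traj, cfg = path_config(smoothing_window = 11L)) {
  smoothed <- average_path(traj, cfg)
  n <- nrow(traj)
  w <- if (inherits(cfg, "path_config")) cfg$smoothing_window else as.integer(cfg)
  trim <- min((w - 1L) %/% 2L, max(0L, (n - 5L) %/% 2L))
  keep <- (1L + trim):(n - trim)
  max(point_polyline_distances(cbind(traj$x_um, traj$y_um)[keep, , drop = FALSE],
                               cbind(smoothed$x_um, smoothed$y_um)))
}

# min distance from each point to any segment of a polyline
point_polyline_distances <- function(pts, poly) {
  n <- nrow(poly)
  ax <- poly[-n, 1]; ay <- poly[-n, 2]
  bx <- poly[-1, 1]; by <- poly[-1, 2]
  ux <- bx - ax; uy <- by - ay
  L2 <- ux^2 + uy^2
  vapply(seq_len(nrow(pts)), function(i) {
    px <- pts[i, 1]; py <- pts[i, 2]
    tt <- ifelse(L2 > 0, ((px - ax) * ux + (py - ay) * uy) / L2, 0)
    tt <- pmin(pmax(tt, 0), 1)
    sqrt(min((px - (ax + tt * ux))^2 + (py - (ay + tt * uy))^2))
  }, numeric(1))
}

#' Beat-cross frequency (BCF)
#'
#' Number of sign changes of the signed lateral offset of the raw track from
#' its smoothed average path, divided by the track duration. Zero-offset
#' samples inherit the preceding sign. Not reported (`NA`) for cells with
#' VSL at or below `cfg$bcf_vsl_min` (default 2 um/s), and capped at fps/2:
#' crossing rates above the Nyquist frequency are aliases, not beats.
#'
#' @inheritParams average_path
#' @param vsl the track's VSL (um/s); computed from `traj` when missing
#' @return BCF in Hz, or `NA_real_` when not reported
#' @export
compute_bcf <- function(traj, cfg = path_config(smoothing_window = 11L),
                        vsl = NULL) {
  if (is.null(vsl)) vsl <- compute_vsl(traj)
  if (vsl <= cfg$bcf_vsl_min) return(NA_real_)
  smoothed <- average_path(traj, cfg)
  off <- lateral_offsets(traj, smoothed)
  crossings <- count_sign_changes(off)
  bcf <- crossings / traj_duration(traj)
  fps <- attr(traj, "fps")
  if (!is.null(fps)) bcf <- min(bcf, fps / 2)
  bcf
}

count_sign_changes <- function(x) {
  s <- sign(x)
  # zero samples inherit the previous sign
  for (i in seq_along(s)) if (s[i] == 0 && i > 1) s[i] <- s[i - 1]
  s <- s[s != 0]
  if (length(s) < 2L) return(0L)
  sum(diff(s) != 0)
}

#' Select an average-path smoothing window
#'
#' Estimates the beat period from the lateral-offset crossing rate against a
#' pilot window of `cfg$pilot_window_s` seconds and returns the odd frame
#' count closest to two beat periods, clamped to `[5, n]`. A boxcar window
#' spanning a whole number of beat cycles nearly annihilates the
#' oscillation from the average path, and the residual at two periods is
#' about half that at one, which keeps ALH (and the path length entering
#' VAP) close to truth across beat frequencies; a non-oscillating track
#' keeps the pilot window.
#'
#' @inheritParams compute_vsl
#' @param cfg a [path_config()]
#' @return an odd integer window (frames)
#' @export
select_smoothing_window <- function(traj, cfg = path_config()) {
  n <- nrow(traj)
  fps <- attr(traj, "fps")
  if (is.null(fps)) fps <- (n - 1) / traj_duration(traj)
  max_w <- if (n %% 2L == 0L) n - 1L else n
  pilot <- min(round_odd(fps * cfg$pilot_window_s, lo = 5L), max_w)
  smoothed <- average_path(traj, path_config(smoothing_window = pilot))
  crossings <- count_sign_changes(lateral_offsets(traj, smoothed))
  dur <- traj_duration(traj)
  if (crossings < 2L || dur <= 0) return(as.integer(pilot))
  beat_period_s <- 2 * dur / crossings   # two crossings per beat
  as.integer(min(round_odd(2 * fps * beat_period_s, lo = 5L), max_w))
}

#' Full kinematic profile of one trajectory
#'
#' Computes the six CASA parameters for one cell. With
#' `cfg$smoothing_window = NULL` the average-path window is selected per
#' track by [select_smoothing_window()].
#'
#' @inheritParams compute_vsl
#' @param cfg a [path_config()]
#' @return one-row data.frame: `n_points`, `duration_s`, `vsl`, `vcl`,
#'   `vap`, `lin` (fraction), `alh_max`, `bcf` (`NA` when not reported),
#'   `max_excursion` (max distance from the starting point, um, used by the
#'   immotility rule), `smoothing_window`
#' @export
kinematic_profile <- function(traj, cfg = path_config()) {
  n <- nrow(traj)
  if (n < 2L) stop("need at least 2 points", call. = FALSE)
  vsl <- compute_vsl(traj)
  vcl <- compute_vcl(traj)
  excur <- max(sqrt((traj$x_um - traj$x_um[1])^2 + (traj$y_um - traj$y_um[1])^2))
  if (vcl == 0) {
    return(data.frame(n_points = n, duration_s = traj_duration(traj),
                      vsl = 0, vcl = 0, vap = 0, lin = 0, alh_max = 0,
                      bcf = NA_real_, max_excursion = excur,
                      smoothing_window = NA_integer_))
  }
  w <- if (is.null(cfg$smoothing_window)) select_smoothing_window(traj, cfg)
       else min(cfg$smoothing_window, if (n %% 2L == 0L) n - 1L else n)
  wcfg <- path_config(smoothing_window = w, bcf_vsl_min = cfg$bcf_vsl_min)
  data.frame(n_points = n, duration_s = traj_duration(traj),
             vsl = vsl, vcl = vcl,
             vap = compute_vap(traj, wcfg),
             lin = compute_lin(vsl, vcl),
             alh_max = compute_alh_max(traj, wcfg),
             bcf = compute_bcf(traj, wcfg, vsl = vsl),
             max_excursion = excur,
             smoothing_window = w)
}

#' Kinematic profiles for every track in a table
#'
#' @param tracks data.frame with `track_id`, `frame`, `x_px`, `y_px` (as
#'   returned by [track_video()]), or with `cell_id`, `frame`, `x_um`,
#'   `y_um` (simulator ground truth; set `microns_per_pixel = 1` upstream)
#' @param microns_per_pixel spatial calibration (um/px)
#' @param fps frame rate (Hz)
#' @param cfg a [path_config()]
#' @return data.frame with one row per track: `track_id` plus the
#'   [kinematic_profile()] columns
#' @export
profile_tracks <- function(tracks, microns_per_pixel, fps, cfg = path_config()) {
  if ("cell_id" %in% names(tracks) && !"track_id" %in% names(tracks))
    names(tracks)[names(tracks) == "cell_id"] <- "track_id"
  if ("x_um" %in% names(tracks) && !"x_px" %in% names(tracks)) {
    tracks$x_px <- tracks$x_um / microns_per_pixel
    tracks$y_px <- tracks$y_um / microns_per_pixel
  }
  ids <- unique(tracks$track_id)
  out <- do.call(rbind, lapply(ids, function(id) {
    tr <- tracks[tracks$track_id == id, , drop = FALSE]
    tr <- tr[order(tr$frame), , drop = FALSE]
    cbind(track_id = id,
          kinematic_profile(to_microns(tr, microns_per_pixel, fps), cfg))
  }))
  rownames(out) <- NULL
  out
}
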