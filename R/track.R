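#' Tracker configuration
#'
#' Parameters of the sperm-head detector and the pyramidal Lucas-Kanade
#' tracker. Detection selects high-contrast corner-like maxima of the
#' Shi-Tomasi response (which sperm heads are, while low-contrast debris is
#' not); tracking propagates each head frame to frame by coarse-to-fine
#' optical flow with a forward-backward consistency check.
#'
#' @param max_features maximum number of detections per frame
#' @param quality_level relative corner-strength threshold in (0, 1];
#'   detections must exceed `quality_level * max(response)`
#' @param min_feature_distance minimum distance between detections and
#'   between a new detection and an existing track (px)
#' @param pyramid_levels number of pyramid levels (>= 1)
#' @param search_window optical-flow integration window size (px, odd)
#' @param redetect_interval enrol new detections every this many frames
#' @param fb_error_max forward-backward consistency bound (px); a track
#'   terminates when exceeded
#' @param min_track_length minimum track length kept in the output (frames);
#'   0.5 s worth of frames is a good default (30 at 60 fps)
#' @param merge_distance if two active tracks come closer than this (px) the
#'   younger one terminates
#' @param max_iter,eps iteration cap and convergence tolerance of the flow
#'   solver
#' @return an object of class `tracker_config`
#' @export
tracker_config <- function(max_features = 400L, quality_level = 0.05,
                           min_feature_distance = 8, pyramid_levels = 3L,
                           search_window = 15L, redetect_interval = 5L,
                           fb_error_max = 2, min_track_length = 30L,
                           merge_distance = 5, max_iter = 20L, eps = 0.01) {
  if (pyramid_levels < 1L) stop("pyramid_levels must be >= 1", call. = FALSE)
  if (min_feature_distance <= 0) stop("min_feature_distance must be > 0", call. = FALSE)
  if (redetect_interval < 1L) stop("redetect_interval must be >= 1", call. = FALSE)
  if (quality_level <= 0 || quality_level > 1)
    stop("quality_level must be in (0, 1]", call. = FALSE)
  structure(list(max_features = as.integer(max_features),
                 quality_level = quality_level,
                 min_feature_distance = min_feature_distance,
                 pyramid_levels = as.integer(pyramid_levels),
                 search_window = as.integer(search_window),
                 redetect_interval = as.integer(redetect_interval),
                 fb_error_max = fb_error_max,
                 min_track_length = as.integer(min_track_length),
                 merge_distance = merge_distance,
                 max_iter = as.integer(max_iter), eps = eps),
            class = "tracker_config")
}

#' Detect sperm-head centroids in one frame
#'
#' Computes the Shi-Tomasi minimum-eigenvalue corner response on a lightly
#' blurred copy of the frame, keeps local maxima above
#' `quality_level * max(response)`, suppresses detections closer than
#' `min_feature_distance` (strongest first), and refines each to a sub-pixel
#' centroid by intensity-weighted averaging.
#'
#' @param frame 2D grayscale matrix
#' @param config a [tracker_config()]
#' @return data.frame with 0-based sub-pixel columns `x_px`, `y_px` and the
#'   corner `response`; zero rows for an empty or constant frame
#' @export
detect_heads <- function(frame, config = tracker_config()) {
  I <- as_image(frame)
  empty <- data.frame(x_px = numeric(0), y_px = numeric(0), response = numeric(0))
  if (diff(range(I)) < 1e-9) return(empty)
  B <- cv_gauss_blur(I, 1.0)
  R <- cv_corner_response(B, 2L)
  thr <- config$quality_level * max(R)
  nr <- nrow(R); nc <- ncol(R)
  if (nr < 5L || nc < 5L) return(empty)
  core <- R[3:(nr - 2), 3:(nc - 2)]
  is_max <- core >= thr
  for (dy in -1:1) for (dx in -1:1) {
    if (dx == 0L && dy == 0L) next
    is_max <- is_max & (core >= R[(3 + dy):(nr - 2 + dy), (3 + dx):(nc - 2 + dx)])
  }
  idx <- which(is_max, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(empty)
  cand <- data.frame(row = idx[, 1] + 2L, col = idx[, 2] + 2L,
                     response = core[idx])
  cand <- cand[order(-cand$response), , drop = FALSE]
  # greedy non-maximum suppression by distance
  keep <- integer(0)
  kx <- numeric(0); ky <- numeric(0)
  md2 <- config$min_feature_distance^2
  for (i in seq_len(nrow(cand))) {
    x <- cand$col[i] - 1; y <- cand$row[i] - 1
    if (length(keep) > 0 && min((kx - x)^2 + (ky - y)^2) < md2) next
    keep <- c(keep, i); kx <- c(kx, x); ky <- c(ky, y)
    if (length(keep) >= config$max_features) break
  }
  cand <- cand[keep, , drop = FALSE]
  # sub-pixel refinement: intensity centroid in a 7x7 window
  ref <- t(vapply(seq_len(nrow(cand)), function(i) {
    centroid_refine(B, cand$col[i] - 1, cand$row[i] - 1, 3L)
  }, numeric(2)))
  data.frame(x_px = ref[, 1], y_px = ref[, 2], response = cand$response)
}

centroid_refine <- function(I, x, y, r) {
  nr <- nrow(I); nc <- ncol(I)
  cols <- max(1L, round(x) + 1 - r):min(nc, round(x) + 1 + r)
  rows <- max(1L, round(y) + 1 - r):min(nr, round(y) + 1 + r)
  patch <- I[rows, cols, drop = FALSE]
  wgt <- patch - min(patch)
  s <- sum(wgt)
  if (s <= 0) return(c(x, y))
  c(sum(t(wgt) * (cols - 1)) / s, sum(wgt * (rows - 1)) / s)
}

build_pyramid <- function(I, levels, half_win) {
  pyr <- vector("list", levels)
  pyr[[1]] <- I
  for (l in seq_len(levels - 1L)) {
    prev <- pyr[[l]]
    if (min(dim(prev)) < 2 * (2 * half_win + 3)) {
      pyr <- pyr[seq_len(l)]
      break
    }
    pyr[[l + 1]] <- cv_pyr_down(prev)
  }
  pyr
}

# pyramidal LK for a set of points between two frames; returns new positions
# and per-point success. Prebuilt pyramids may be supplied to avoid
# recomputation when several point sets are tracked between the same frames.
lk_track <- function(prev, nxt, pts, config, pyr_p = NULL, pyr_n = NULL) {
  half <- (config$search_window - 1L) %/% 2L
  if (is.null(pyr_p)) pyr_p <- build_pyramid(prev, config$pyramid_levels, half)
  if (is.null(pyr_n)) pyr_n <- build_pyramid(nxt, config$pyramid_levels, half)
  L <- min(length(pyr_p), length(pyr_n))
  n <- nrow(pts)
  g <- matrix(0, n, 2)
  ok <- rep(TRUE, n)
  for (lev in L:1) {
    scale <- 2^(lev - 1)
    res <- cv_lk_level(pyr_p[[lev]], pyr_n[[lev]], pts / scale, g,
                       half, config$max_iter, config$eps)
    ok <- ok & res$ok
    g <- if (lev > 1) 2 * res$flow else res$flow
  }
  list(pts = pts + g, ok = ok)
}

#' Track sperm heads through a video
#'
#' Detects heads in the first frame, propagates each one frame to frame with
#' pyramidal Lucas-Kanade optical flow, and manages identities: a track
#' terminates when the flow solver fails or the forward-backward error
#' exceeds `fb_error_max`; every `redetect_interval` frames new detections
#' not within `min_feature_distance` of an active track are enrolled with
#' fresh IDs; when two active tracks come within `merge_distance` the
#' younger (higher ID) terminates. Tracks shorter than `min_track_length`
#' frames are dropped from the output.
#'
#' @param frames array height x width x n_frames (grayscale)
#' @param config a [tracker_config()]
#' @return data.frame with columns `track_id`, `frame` (0-based), `x_px`,
#'   `y_px` (0-based sub-pixel pixel centers), ordered by track then frame
#' @export
track_video <- function(frames, config = tracker_config()) {
  n_frames <- frame_count(frames)
  if (n_frames < 2L) stop("need at least 2 frames", call. = FALSE)

  next_id <- 1L
  active <- list()   # each: id, born, x, y vectors (per frame since born)
  done <- list()

  enrol <- function(det, frame_idx, active, next_id) {
    if (nrow(det) == 0L) return(list(active = active, next_id = next_id))
    if (length(active) > 0) {
      ax <- vapply(active, function(tr) tr$x[length(tr$x)], numeric(1))
      ay <- vapply(active, function(tr) tr$y[length(tr$y)], numeric(1))
      d2 <- outer(det$x_px, ax, "-")^2 + outer(det$y_px, ay, "-")^2
      det <- det[apply(d2, 1, min) >= config$min_feature_distance^2, , drop = FALSE]
    }
    for (i in seq_len(nrow(det))) {
      active[[length(active) + 1]] <- list(id = next_id, born = frame_idx,
                                           x = det$x_px[i], y = det$y_px[i])
      next_id <- next_id + 1L
    }
    list(active = active, next_id = next_id)
  }

  half <- (config$search_window - 1L) %/% 2L
  first <- get_frame(frames, 1L)
  e <- enrol(detect_heads(first, config), 0L, active, next_id)
  active <- e$active; next_id <- e$next_id

  prev <- first
  pyr_prev <- build_pyramid(prev, config$pyramid_levels, half)
  for (t in 2:n_frames) {
    nxt <- get_frame(frames, t)
    pyr_nxt <- build_pyramid(nxt, config$pyramid_levels, half)
    if (length(active) > 0) {
      pts <- cbind(vapply(active, function(tr) tr$x[length(tr$x)], numeric(1)),
                   vapply(active, function(tr) tr$y[length(tr$y)], numeric(1)))
      fwd <- lk_track(prev, nxt, pts, config, pyr_prev, pyr_nxt)
      bwd <- lk_track(nxt, prev, fwd$pts, config, pyr_nxt, pyr_prev)
      fb <- sqrt(rowSums((bwd$pts - pts)^2))
      alive <- fwd$ok & bwd$ok & fb <= config$fb_error_max
      # merge rule: of two tracks closer than merge_distance, the younger dies
      if (sum(alive) > 1) {
        ia <- which(alive)
        px <- fwd$pts[ia, 1]; py <- fwd$pts[ia, 2]
        ids <- vapply(active[ia], function(tr) tr$id, integer(1))
        o <- order(ids)
        kept_x <- numeric(0); kept_y <- numeric(0)
        for (j in o) {
          if (length(kept_x) > 0 &&
              min((kept_x - px[j])^2 + (kept_y - py[j])^2) < config$merge_distance^2) {
            alive[ia[j]] <- FALSE
          } else {
            kept_x <- c(kept_x, px[j]); kept_y <- c(kept_y, py[j])
          }
        }
      }
      new_active <- list()
      for (i in seq_along(active)) {
        if (alive[i]) {
          tr <- active[[i]]
          tr$x <- c(tr$x, fwd$pts[i, 1])
          tr$y <- c(tr$y, fwd$pts[i, 2])
          new_active[[length(new_active) + 1]] <- tr
        } else {
          done[[length(done) + 1]] <- active[[i]]
        }
      }
      active <- new_active
    }
    if ((t - 1L) %% config$redetect_interval == 0L) {
      e <- enrol(detect_heads(nxt, config), t - 1L, active, next_id)
      active <- e$active; next_id <- e$next_id
    }
    prev <- nxt
    pyr_prev <- pyr_nxt
  }
  done <- c(done, active)
  done <- Filter(function(tr) length(tr$x) >= config$min_track_length, done)
  if (length(done) == 0L)
    return(data.frame(track_id = integer(0), frame = integer(0),
                      x_px = numeric(0), y_px = numeric(0)))
  out <- do.call(rbind, lapply(done, function(tr) {
    data.frame(track_id = tr$id,
               frame = tr$born + seq_along(tr$x) - 1L,
               x_px = tr$x, y_px = tr$y)
  }))
  out[order(out$track_id, out$frame), , drop = FALSE]
}

#' Mean number of cells detected over the first frames of a video
#'
#' Tracks the opening frames of one or two recordings and returns the mean
#' number of distinct cells present per frame; with two videos of the same
#' sample the two means are averaged. This count feeds the concentration
#' calibration line (see [fit_concentration_curve()]).
#'
#' @param frames a frame array, or a list of two frame arrays (two
#'   recordings of one sample)
#' @param n_frames number of opening frames to use (default 10)
#' @param config a [tracker_config()]
#' @return mean detected-cell count (possibly fractional)
#' @export
count_in_first_frames <- function(frames, n_frames = 10L, config = tracker_config()) {
  if (is.list(frames) && !is.array(frames))
    return(mean(vapply(frames, count_in_first_frames, numeric(1),
                       n_frames = n_frames, config = config)))
  if (n_frames < 1L) stop("n_frames must be >= 1", call. = FALSE)
  avail <- frame_count(frames)
  if (avail < n_frames) {
    warning(sprintf("only %d frames available; counting over those", avail))
    n_frames <- avail
  }
  sub <- frames[, , seq_len(n_frames), drop = FALSE]
  if (n_frames == 1L)
    return(nrow(detect_heads(get_frame(sub, 1L), config)))
  cfg <- config
  cfg$min_track_length <- 1L
  cfg$redetect_interval <- 1L
  tr <- track_video(sub, cfg)
  if (nrow(tr) == 0L) return(0)
  mean(tabulate(tr$frame + 1L, nbins = n_frames))
}
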