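#' Render trajectories into an 8-bit grayscale video stack
#'
#' Each cell is drawn as a bright isotropic Gaussian blob of scale
#' `config$head_sigma` at its per-frame position (bright heads on a dark
#' background, as in negative phase contrast). Low-contrast, slowly drifting
#' debris blobs and additive Gaussian noise are overlaid, and intensities are
#' quantised to 8 bits. Rendering is deterministic given `config$rng_seed`.
#'
#' @param trajectories data.frame with columns `cell_id`, `frame` (0-based),
#'   `x_um`, `y_um`, as produced by [simulate_cells()]
#' @param config a [sim_config()] object; all positions must lie inside
#'   `config$field_size`
#' @return an integer array of dimension height x width x n_frames with
#'   values in 0..255; pixel (row r, col c) has 0-based center
#'   (x, y) = (c - 1, r - 1)
#' @export
render_video <- function(trajectories, config) {
  stopifnot(inherits(config, "sim_config"))
  mpp <- config$microns_per_pixel
  w <- as.integer(round(config$field_size[1] / mpp))
  h <- as.integer(round(config$field_size[2] / mpp))
  n_frames <- max(2L, as.integer(round(config$fps * config$duration)))
  has_cells <- !is.null(trajectories) && nrow(trajectories) > 0
  if (has_cells) {
    if (any(trajectories$x_um < 0 | trajectories$x_um > config$field_size[1] |
            trajectories$y_um < 0 | trajectories$y_um > config$field_size[2]))
      stop("trajectories do not fit within field_size", call. = FALSE)
    n_frames <- max(n_frames, max(trajectories$frame) + 1L)
  }

  with_seed(if (is.null(config$rng_seed)) NULL else config$rng_seed + 1L, {
    ids <- if (has_cells) sort(unique(trajectories$cell_id)) else integer(0)
    amp <- setNames(runif(length(ids), 140, 180), ids)
    # debris: larger, dim, nearly static blobs
    nd <- config$n_debris
    deb <- if (nd > 0) {
      data.frame(x = runif(nd, 0, config$field_size[1]),
                 y = runif(nd, 0, config$field_size[2]),
                 vx = runif(nd, -1, 1), vy = runif(nd, -1, 1),
                 amp = runif(nd, 12, 25), sigma = runif(nd, 2, 4))
    } else NULL

    sig_px <- config$head_sigma / mpp
    out <- array(0L, dim = c(h, w, n_frames))
    by_frame <- if (has_cells) split(trajectories, trajectories$frame) else list()
    for (t in seq_len(n_frames)) {
      img <- matrix(config$background, h, w)
      fr <- by_frame[[as.character(t - 1L)]]
      if (!is.null(fr)) {
        for (k in seq_len(nrow(fr))) {
          img <- add_blob(img, fr$x_um[k] / mpp, fr$y_um[k] / mpp,
                          amp[[as.character(fr$cell_id[k])]], sig_px)
        }
      }
      if (!is.null(deb)) {
        tt <- (t - 1L) / config$fps
        for (k in seq_len(nrow(deb))) {
          img <- add_blob(img, (deb$x[k] + deb$vx[k] * tt) / mpp,
                          (deb$y[k] + deb$vy[k] * tt) / mpp,
                          deb$amp[k], deb$sigma[k] / mpp)
        }
      }
      if (config$noise_sd > 0)
        img <- img + matrix(rnorm(h * w, 0, config$noise_sd), h, w)
      out[, , t] <- quantise8(img)
    }
    out
  })
}

# add a Gaussian blob at 0-based pixel center (cx, cy) onto a local window
add_blob <- function(img, cx, cy, amp, sigma) {
  h <- nrow(img); w <- ncol(img)
  r <- ceiling(4 * sigma)
  cols <- max(1L, floor(cx + 1 - r)):min(w, ceiling(cx + 1 + r))
  rows <- max(1L, floor(cy + 1 - r)):min(h, ceiling(cy + 1 + r))
  if (length(cols) == 0L || length(rows) == 0L) return(img)
  dx2 <- ((cols - 1) - cx)^2
  dy2 <- ((rows - 1) - cy)^2
  img[rows, cols] <- img[rows, cols] +
    amp * exp(-outer(dy2, dx2, "+") / (2 * sigma^2))
  img
}

quantise8 <- function(img) {
  m <- round(img)
  m[m < 0] <- 0
  m[m > 255] <- 255
  storage.mode(m) <- "integer"
  m
}

#' Apply imaging perturbations to a video stack
#'
#' Scales intensities by `(1 + brightness_percent/100)` with saturation at
#' 255 (the 8-bit maximum) and/or mirrors frames about an image axis.
#' Applying the same flip twice restores the original stack.
#'
#' @param frames integer array height x width x n_frames (0..255)
#' @param brightness_percent percent brightness change (> -100)
#' @param flip_axis `NULL` for no flip, `"horizontal"` to mirror x
#'   (reverse columns), `"vertical"` to mirror y (reverse rows)
#' @return perturbed stack of the same dimensions
#' @export
perturb_video <- function(frames, brightness_percent = 0, flip_axis = NULL) {
  if (brightness_percent <= -100)
    stop("brightness_percent must be > -100", call. = FALSE)
  d <- dim(frames)
  if (length(d) != 3L) stop("frames must be a 3D array", call. = FALSE)
  out <- frames
  if (brightness_percent != 0) {
    out <- round(out * (1 + brightness_percent / 100))
    out[out > 255L] <- 255L
    storage.mode(out) <- "integer"
    dim(out) <- d
  }
  if (!is.null(flip_axis)) {
    if (flip_axis == "horizontal") out <- out[, d[2]:1, , drop = FALSE]
    else if (flip_axis == "vertical") out <- out[d[1]:1, , , drop = FALSE]
    else stop("unknown flip_axis: ", flip_axis, call. = FALSE)
  }
  out
}
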