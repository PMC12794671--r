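#' Motion parameters for one simulated sperm cell
#'
#' Describes a cell swimming along a smooth average path (straight line or
#' circular arc of constant curvature) with a sinusoidal lateral oscillation
#' of its head about that path. An immotile cell has zero progressive speed
#' and zero lateral amplitude.
#'
#' @param progressive_speed speed along the average path (um/s, >= 0)
#' @param lateral_amplitude amplitude A of the lateral head oscillation (um, >= 0)
#' @param beat_frequency beat frequency f_b of the lateral oscillation (Hz, >= 0);
#'   the curvilinear track crosses the average path twice per beat, so the
#'   true beat-cross frequency is `2 * beat_frequency`
#' @param beat_phase phase of the oscillation at t = 0 (radians)
#' @param heading initial direction of the average path (radians)
#' @param path_curvature signed curvature of the average path (1/um; 0 = straight;
#'   magnitudes of ~0.1-0.3 give the tight circling of a few-micron radius seen
#'   in poorly progressive cells)
#' @param start_position numeric length-2, starting position (um)
#' @return an object of class `cell_motion_params`
#' @export
cell_motion_params <- function(progressive_speed, lateral_amplitude = 0,
                               beat_frequency = 0, beat_phase = 0,
                               heading = 0, path_curvature = 0,
                               start_position = c(0, 0)) {
  vals <- c(progressive_speed, lateral_amplitude, beat_frequency, beat_phase,
            heading, path_curvature, start_position)
  stopifnot_finite(vals, "cell_motion_params")
  if (progressive_speed < 0 || lateral_amplitude < 0 || beat_frequency < 0)
    stop("progressive_speed, lateral_amplitude and beat_frequency must be >= 0",
         call. = FALSE)
  if (length(start_position) != 2L)
    stop("start_position must have length 2", call. = FALSE)
  structure(list(progressive_speed = progressive_speed,
                 lateral_amplitude = lateral_amplitude,
                 beat_frequency = beat_frequency,
                 beat_phase = beat_phase,
                 heading = heading,
                 path_curvature = path_curvature,
                 start_position = as.numeric(start_position)),
            class = "cell_motion_params")
}

#' Simulation configuration
#'
#' Acquisition and scene settings for the synthetic video generator. The
#' defaults emulate a 10X negative phase-contrast-like recording: 60 fps for
#' 2 s, 0.65 um/px, bright sperm heads on a dark background.
#'
#' @param fps frame rate (Hz)
#' @param duration recording length (s)
#' @param field_size numeric length-2, field of view (um)
#' @param microns_per_pixel spatial calibration (um/px)
#' @param n_cells_by_grade named integer vector with counts for
#'   `rapid`, `slow`, `nonprogressive`, `immotile`
#' @param head_sigma Gaussian scale of the rendered head (um)
#' @param noise_sd additive Gaussian noise (8-bit intensity units)
#' @param n_debris number of low-contrast, near-static debris blobs
#' @param chamber_depth_um depth of the imaging chamber (um), used to convert
#'   cells-in-field to a true concentration in millions/mL
#' @param background background intensity level (8-bit units)
#' @param rng_seed integer seed; identical configuration implies identical
#'   video and ground truth
#' @return an object of class `sim_config`
#' @export
sim_config <- function(fps = 60, duration = 2,
                       field_size = c(665.6, 665.6),
                       microns_per_pixel = 0.65,
                       n_cells_by_grade = c(rapid = 10, slow = 10,
                                            nonprogressive = 10, immotile = 10),
                       head_sigma = 1.6, noise_sd = 5, n_debris = 5,
                       chamber_depth_um = 20, background = 15,
                       rng_seed = 1L) {
  if (fps <= 0 || duration <= 0) stop("fps and duration must be > 0", call. = FALSE)
  if (microns_per_pixel <= 0) stop("microns_per_pixel must be > 0", call. = FALSE)
  grades <- c("rapid", "slow", "nonprogressive", "immotile")
  n <- setNames(integer(4), grades)
  n[names(n_cells_by_grade)] <- as.integer(n_cells_by_grade)
  if (any(n < 0)) stop("cell counts must be >= 0", call. = FALSE)
  structure(list(fps = fps, duration = duration,
                 field_size = as.numeric(field_size),
                 microns_per_pixel = microns_per_pixel,
                 n_cells_by_grade = n, head_sigma = head_sigma,
                 noise_sd = noise_sd, n_debris = as.integer(n_debris),
                 chamber_depth_um = chamber_depth_um,
                 background = background,
                 rng_seed = as.integer(rng_seed)),
            class = "sim_config")
}

# closed-form position on the average path at times t (vectorised)
avg_path_position <- function(params, t) {
  v <- params$progressive_speed
  th <- params$heading
  k <- params$path_curvature
  p0 <- params$start_position
  if (abs(k) < 1e-9) {
    cbind(p0[1] + v * t * cos(th), p0[2] + v * t * sin(th))
  } else {
    # constant-speed motion on a circle of signed radius 1/k
    ang <- th + v * k * t
    cbind(p0[1] + (sin(ang) - sin(th)) / k,
          p0[2] + (-cos(ang) + cos(th)) / k)
  }
}

# closed-form full position: average path + A sin(2 pi f t + phi) along the
# left unit normal of the path
curve_position <- function(params, t) {
  base <- avg_path_position(params, t)
  A <- params$lateral_amplitude
  if (A == 0) return(base)
  ang <- params$heading + params$progressive_speed * params$path_curvature * t
  off <- A * sin(2 * pi * params$beat_frequency * t + params$beat_phase)
  base + cbind(-sin(ang), cos(ang)) * off
}

polyline_length <- function(xy) {
  if (nrow(xy) < 2L) return(0)
  sum(sqrt(rowSums(diff(xy)^2)))
}

#' Generate one cell's trajectory with analytic ground truth
#'
#' Samples the closed-form swimming curve at the camera frame rate and
#' computes the true kinematics of the continuous curve independently of any
#' downstream estimator: VSL from the curve endpoints, VCL by fine polyline
#' quadrature (`oversample` points per frame interval), VAP as the arc speed
#' of the average path, ALH_max = A and beat-cross rate = 2 f_b by
#' construction.
#'
#' @param params a [cell_motion_params()] object
#' @param fps frame rate (Hz)
#' @param duration recording length (s); the sampled track has
#'   `round(fps * duration)` frames
#' @param oversample quadrature refinement factor for the true VCL (>= 10)
#' @return a list with `trajectory` (data.frame: time, x_um, y_um; attribute
#'   `fps`) and `truth` (one-row data.frame: vsl, vcl, vap, lin, alh_max,
#'   bcf, grade)
#' @export
make_trajectory <- function(params, fps, duration, oversample = 10L) {
  if (!inherits(params, "cell_motion_params"))
    stop("params must be a cell_motion_params object", call. = FALSE)
  if (fps <= 0 || duration <= 0) stop("fps and duration must be > 0", call. = FALSE)
  n <- max(2L, as.integer(round(fps * duration)))
  t <- (seq_len(n) - 1L) / fps
  xy <- curve_position(params, t)
  traj <- data.frame(time = t, x_um = xy[, 1], y_um = xy[, 2])
  attr(traj, "fps") <- fps

  span <- t[n]
  immotile <- params$progressive_speed == 0 && params$lateral_amplitude == 0
  if (immotile) {
    truth <- data.frame(vsl = 0, vcl = 0, vap = 0, lin = 0, alh_max = 0,
                        bcf = 0, grade = "immotile", stringsAsFactors = FALSE)
  } else {
    tf <- seq(0, span, length.out = (n - 1L) * max(10L, as.integer(oversample)) + 1L)
    vcl <- polyline_length(curve_position(params, tf)) / span
    vsl <- sqrt(sum((xy[n, ] - xy[1, ])^2)) / span
    vap <- params$progressive_speed
    truth <- data.frame(
      vsl = vsl, vcl = vcl, vap = vap,
      lin = if (vcl > 0) vsl / vcl else 0,
      alh_max = params$lateral_amplitude,
      bcf = 2 * params$beat_frequency,
      grade = grade_from_vsl(vsl), stringsAsFactors = FALSE)
  }
  list(trajectory = traj, truth = truth)
}

# WHO6 grade implied by a true VSL for a motile cell
grade_from_vsl <- function(vsl, rapid_min = 25, slow_min = 5) {
  if (vsl >= rapid_min) "rapid" else if (vsl >= slow_min) "slow" else "nonprogressive"
}

# draw motion parameters for one cell of a requested WHO grade, rejection
# sampling until the true VSL of the realised curve falls in the grade's
# interval
draw_cell_params <- function(grade, fps, duration) {
  for (attempt in 1:200) {
    p <- switch(grade,
      rapid = cell_motion_params(
        progressive_speed = runif(1, 27, 60),
        lateral_amplitude = runif(1, 1.5, 3.5),
        beat_frequency = runif(1, 4, 10),
        beat_phase = runif(1, 0, 2 * pi),
        heading = runif(1, 0, 2 * pi),
        path_curvature = if (runif(1) < 0.8) 0 else runif(1, -0.008, 0.008)),
      slow = cell_motion_params(
        progressive_speed = runif(1, 6, 24),
        lateral_amplitude = runif(1, 1, 3),
        beat_frequency = runif(1, 4, 10),
        beat_phase = runif(1, 0, 2 * pi),
        heading = runif(1, 0, 2 * pi),
        path_curvature = if (runif(1) < 0.7) 0 else runif(1, -0.015, 0.015)),
      nonprogressive = cell_motion_params(
        progressive_speed = runif(1, 0.5, 4.5),
        lateral_amplitude = runif(1, 0.3, 1.5),
        beat_frequency = runif(1, 3, 8),
        beat_phase = runif(1, 0, 2 * pi),
        heading = runif(1, 0, 2 * pi),
        path_curvature = if (runif(1) < 0.5) 0 else runif(1, -0.15, 0.15)),
      immotile = cell_motion_params(0, 0, 0, 0,
                                    heading = runif(1, 0, 2 * pi)),
      stop("unknown grade: ", grade, call. = FALSE))
    tr <- make_trajectory(p, fps, duration)
    if (tr$truth$grade == grade) return(list(params = p, sim = tr))
  }
  stop("could not realise a cell of grade '", grade, "'", call. = FALSE)
}

#' Simulate a full sample: cells, trajectories and ground truth
#'
#' Draws the grade mixture of `config`, places each cell so that its whole
#' trajectory stays inside the field with a minimum spacing between starting
#' positions, and returns sampled trajectories plus the analytic ground
#' truth. Deterministic given `config$rng_seed`.
#'
#' @param config a [sim_config()] object
#' @param min_separation_um minimum distance between starting positions (um)
#' @param margin_um margin kept free at the field border (um)
#' @return a list with `trajectories` (data.frame: cell_id, frame, x_um,
#'   y_um), `truth` (per-cell data.frame incl. grade), `params` (list of
#'   [cell_motion_params()]), `n_cells`, and `true_concentration` (M/mL,
#'   from cells-in-field and the chamber depth)
#' @export
simulate_cells <- function(config, min_separation_um = 6, margin_um = 4) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$rng_seed, {
    grades <- rep(names(config$n_cells_by_grade), config$n_cells_by_grade)
    starts <- matrix(numeric(0), ncol = 2)
    traj_list <- list()
    truth_list <- list()
    params_list <- list()
    fs <- config$field_size
    for (i in seq_along(grades)) {
      placed <- FALSE
      for (attempt in 1:5000) {
        drawn <- draw_cell_params(grades[i], config$fps, config$duration)
        rel <- as.matrix(drawn$sim$trajectory[, c("x_um", "y_um")])
        lo <- apply(rel, 2, min)
        hi <- apply(rel, 2, max)
        room <- fs - 2 * margin_um - (hi - lo)
        if (any(room < 0)) next  # path longer than the field allows
        origin <- c(runif(1, margin_um - lo[1], margin_um - lo[1] + room[1]),
                    runif(1, margin_um - lo[2], margin_um - lo[2] + room[2]))
        start <- rel[1, ] + origin
        if (nrow(starts) > 0 &&
            min(sqrt(colSums((t(starts) - start)^2))) < min_separation_um) next
        starts <- rbind(starts, start)
        tr <- drawn$sim$trajectory
        tr$x_um <- tr$x_um + origin[1]
        tr$y_um <- tr$y_um + origin[2]
        traj_list[[i]] <- data.frame(cell_id = i,
                                     frame = seq_len(nrow(tr)) - 1L,
                                     x_um = tr$x_um, y_um = tr$y_um)
        truth_list[[i]] <- cbind(cell_id = i, drawn$sim$truth)
        p <- drawn$params
        p$start_position <- start
        params_list[[i]] <- p
        placed <- TRUE
        break
      }
      if (!placed)
        stop("field too small for the requested cell count", call. = FALSE)
    }
    n <- length(grades)
    vol_ml <- prod(fs) * config$chamber_depth_um * 1e-12  # um^3 -> mL
    list(trajectories = do.call(rbind, traj_list),
         truth = do.call(rbind, truth_list),
         params = params_list,
         n_cells = n,
         true_concentration = n / vol_ml / 1e6)
  })
}

#' Simulate a sample and render its video
#'
#' Convenience wrapper running [simulate_cells()] and [render_video()] under
#' one configuration.
#'
#' @inheritParams simulate_cells
#' @return the [simulate_cells()] list with an additional `frames` element
#'   (the rendered 8-bit grayscale stack)
#' @export
simulate_sample <- function(config, min_separation_um = 6, margin_um = 4) {
  cells <- simulate_cells(config, min_separation_um, margin_um)
  cells$frames <- render_video(cells$trajectories, config)
  cells
}
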