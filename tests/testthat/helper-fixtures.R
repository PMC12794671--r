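# Shared fixtures, built in code at test time.

# a small, fast scene: 64 x 64 um field, 1 s at 60 fps
small_config <- function(n_by_grade = c(rapid = 2, slow = 2,
                                        nonprogressive = 2, immotile = 2),
                         seed = 42L, duration = 1, noise_sd = 4) {
  sim_config(fps = 60, duration = duration,
             field_size = c(120, 120), microns_per_pixel = 0.65,
             n_cells_by_grade = n_by_grade, noise_sd = noise_sd,
             n_debris = 2, rng_seed = seed)
}

# render a set of hand-placed static or moving blobs on a small canvas;
# traj: list of n x 2 matrices of per-frame (x_um, y_um)
blob_video <- function(traj_list, n_frames, field_um = c(80, 80),
                       noise_sd = 0, seed = 1L, mpp = 0.65, fps = 60) {
  cfg <- sim_config(fps = fps, duration = n_frames / fps,
                    field_size = field_um, microns_per_pixel = mpp,
                    n_cells_by_grade = c(), noise_sd = noise_sd,
                    n_debris = 0, rng_seed = seed)
  tr <- do.call(rbind, lapply(seq_along(traj_list), function(i) {
    m <- traj_list[[i]]
    data.frame(cell_id = i, frame = seq_len(nrow(m)) - 1L,
               x_um = m[, 1], y_um = m[, 2])
  }))
  list(frames = render_video(tr, cfg), config = cfg, trajectories = tr)
}

# straight-line constant-velocity blob trajectory
line_traj <- function(start, vel_um_per_frame, n_frames) {
  cbind(start[1] + (seq_len(n_frames) - 1) * vel_um_per_frame[1],
        start[2] + (seq_len(n_frames) - 1) * vel_um_per_frame[2])
}

# a tracker configuration suited to short test clips
test_tracker <- function(...) {
  args <- list(...)
  if (!"min_track_length" %in% names(args)) args$min_track_length <- 5L
  do.call(tracker_config, args)
}
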