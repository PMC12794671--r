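test_that("detection finds isolated blobs to sub-pixel accuracy and ignores blank frames", {
  expect_equal(nrow(detect_heads(matrix(50, 64, 64))), 0)

  v <- blob_video(list(line_traj(c(31.2, 42.7), c(0, 0), 3)), 3)
  d <- detect_heads(v$frames[, , 1], test_tracker())
  expect_equal(nrow(d), 1)
  mpp <- v$config$microns_per_pixel
  expect_lt(abs(d$x_px - 31.2 / mpp), 0.5)
  expect_lt(abs(d$y_px - 42.7 / mpp), 0.5)
})

test_that("detection separates many blobs and respects max_features", {
  set.seed(31)
  # 20 cells on a grid, jittered, all >= 10 px apart
  grid <- expand.grid(x = seq(10, 70, by = 15), y = seq(10, 70, by = 15))[1:20, ]
  traj <- lapply(seq_len(nrow(grid)), function(i)
    line_traj(c(grid$x[i], grid$y[i]) + runif(2, -2, 2), c(0, 0), 3))
  v <- blob_video(traj, 3)
  d <- detect_heads(v$frames[, , 1], test_tracker())
  expect_equal(nrow(d), 20)
  d5 <- detect_heads(v$frames[, , 1], test_tracker(max_features = 5L))
  expect_equal(nrow(d5), 5)
})

test_that("static scenes yield static full-length tracks", {
  traj <- lapply(list(c(15, 15), c(50, 20), c(30, 55)), function(s)
    line_traj(s, c(0, 0), 20))
  v <- blob_video(traj, 20, noise_sd = 2, seed = 8L)
  tracks <- track_video(v$frames, test_tracker())
  expect_equal(length(unique(tracks$track_id)), 3)
  for (id in unique(tracks$track_id)) {
    tr <- tracks[tracks$track_id == id, ]
    expect_equal(nrow(tr), 20)
    expect_lt(max(sqrt(diff(tr$x_px)^2 + diff(tr$y_px)^2)), 0.2)
  }
})

test_that("a moving blob is tracked with small per-frame error", {
  mpp <- 0.65
  v <- blob_video(list(line_traj(c(10, 20), c(2 * mpp, 0.8 * mpp), 30)), 30)
  tracks <- track_video(v$frames, test_tracker())
  expect_equal(length(unique(tracks$track_id)), 1)
  tr <- tracks[order(tracks$frame), ]
  expect_equal(nrow(tr), 30)
  true_x <- (10 + 2 * mpp * tr$frame) / mpp
  true_y <- (20 + 0.8 * mpp * tr$frame) / mpp
  err <- sqrt((tr$x_px - true_x)^2 + (tr$y_px - true_y)^2)
  expect_lt(mean(err), 0.5)
})

test_that("tracks never duplicate a frame or an ID", {
  sam <- simulate_sample(small_config(seed = 21L))
  tracks <- track_video(sam$frames, test_tracker())
  key <- paste(tracks$track_id, tracks$frame)
  expect_equal(anyDuplicated(key), 0L)
  # frame indices strictly increasing and contiguous within each track
  for (id in unique(tracks$track_id)) {
    f <- tracks$frame[tracks$track_id == id]
    expect_true(all(diff(f) == 1L))
  }
})

test_that("crossing blobs do not produce identity switches beyond merge_distance", {
  mpp <- 0.65
  n <- 40
  a <- line_traj(c(10, 26), c(1.3, 0.33), n)   # crosses b mid-way
  b <- line_traj(c(10, 39), c(1.3, -0.33), n)
  v <- blob_video(list(a, b), n)
  tracks <- track_video(v$frames, test_tracker())
  expect_gte(length(unique(tracks$track_id)), 1)
  cfg <- test_tracker()
  sep <- sqrt(rowSums((a - b)^2)) / mpp   # true cell separation per frame, px
  for (id in unique(tracks$track_id)) {
    tr <- tracks[tracks$track_id == id, ]
    da <- sqrt((tr$x_px - a[tr$frame + 1, 1] / mpp)^2 +
               (tr$y_px - a[tr$frame + 1, 2] / mpp)^2)
    db <- sqrt((tr$x_px - b[tr$frame + 1, 1] / mpp)^2 +
               (tr$y_px - b[tr$frame + 1, 2] / mpp)^2)
    # the track must always sit on one of the two true cells...
    expect_lte(max(pmin(da, db)), cfg$merge_distance)
    # ...and may only change which cell it follows while the two true
    # trajectories are themselves within merge distance (no teleporting
    # between well-separated cells)
    assigned <- ifelse(da <= db, "a", "b")
    switches <- which(diff(as.integer(factor(assigned, c("a", "b")))) != 0)
    for (s in switches)
      expect_lte(sep[tr$frame[s] + 1], 2 * cfg$merge_distance)
  }
})

test_that("tracking a flipped video mirrors the x-coordinates", {
  sam <- simulate_sample(small_config(seed = 13L))
  tracks <- track_video(sam$frames, test_tracker())
  flipped <- track_video(perturb_video(sam$frames, 0, "horizontal"), test_tracker())
  w <- dim(sam$frames)[2]
  # match by (frame, y) and compare mirrored x
  key_a <- paste(tracks$frame, round(tracks$y_px))
  key_b <- paste(flipped$frame, round(flipped$y_px))
  common <- intersect(key_a, key_b)
  expect_gt(length(common), 0.8 * nrow(tracks))
  xa <- tracks$x_px[match(common, key_a)]
  xb <- flipped$x_px[match(common, key_b)]
  expect_lt(max(abs((w - 1 - xb) - xa)), 1)
})

test_that("most motile cells are recovered over most of the video", {
  cfg <- small_config(n_by_grade = c(rapid = 4, slow = 4, nonprogressive = 4,
                                     immotile = 0), seed = 33L)
  sam <- simulate_sample(cfg)
  tracks <- track_video(sam$frames, test_tracker())
  n_frames <- dim(sam$frames)[3]
  mpp <- cfg$microns_per_pixel
  recovered <- 0
  for (cid in unique(sam$trajectories$cell_id)) {
    truth <- sam$trajectories[sam$trajectories$cell_id == cid, ]
    best <- 0
    for (id in unique(tracks$track_id)) {
      tr <- tracks[tracks$track_id == id, ]
      m <- merge(tr, truth, by = "frame")
      if (nrow(m) == 0) next
      d <- sqrt((m$x_px - m$x_um / mpp)^2 + (m$y_px - m$y_um / mpp)^2)
      if (median(d) < 3) best <- max(best, nrow(m))
    }
    if (best >= 0.8 * n_frames) recovered <- recovered + 1
  }
  expect_gte(recovered, 0.9 * 12)
})

test_that("first-frame counting matches the scene and averages two videos", {
  expect_equal(count_in_first_frames(array(7L, dim = c(32, 32, 12)), 10,
                                     test_tracker()), 0)
  set.seed(14)
  grid <- expand.grid(x = seq(8, 72, by = 8), y = seq(8, 72, by = 8))
  pick <- grid[sample(nrow(grid), 30), ]
  traj <- lapply(seq_len(nrow(pick)), function(i)
    line_traj(c(pick$x[i], pick$y[i]), runif(2, -0.2, 0.2), 12))
  v <- blob_video(traj, 12, noise_sd = 3, seed = 2L)
  cnt <- count_in_first_frames(v$frames, 10, test_tracker())
  expect_gte(cnt, 29)
  expect_lte(cnt, 31)
  # stated averaging rule over two recordings of one sample
  expect_equal(count_in_first_frames(list(v$frames, v$frames), 10,
                                     test_tracker()), cnt)
  expect_warning(count_in_first_frames(v$frames[, , 1:6], 10, test_tracker()),
                 "6 frames")
})
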