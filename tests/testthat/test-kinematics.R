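sine_traj <- function(speed = 50, A = 2, f = 5, fps = 60, dur = 1,
                      phase = 0, heading = 0, curv = 0) {
  make_trajectory(cell_motion_params(speed, A, f, phase, heading, curv),
                  fps, dur)$trajectory
}

test_that("pixel-to-micron conversion applies scale and frame clock", {
  tr <- data.frame(frame = c(0L, 30L), x_px = c(10, 20), y_px = c(20, 40))
  um <- to_microns(tr, 0.5, 60)
  expect_equal(um$x_um, c(5, 10))
  expect_equal(um$y_um, c(10, 20))
  expect_equal(um$time, c(0, 0.5))
  id <- to_microns(tr, 1, 1)
  expect_equal(id$x_um, tr$x_px)
  expect_error(to_microns(tr, NULL, 60), "required")
  expect_error(to_microns(tr, -1, 60), "> 0")
})

test_that("VSL and VCL follow their endpoint and polyline definitions", {
  line <- data.frame(time = c(0, 1), x_um = c(0, 50), y_um = c(0, 0))
  expect_equal(compute_vsl(line), 50)
  expect_equal(compute_vcl(line), 50)

  square <- data.frame(time = 0:4, x_um = c(0, 10, 10, 0, 0),
                       y_um = c(0, 0, 10, 10, 0))
  expect_equal(compute_vsl(square), 0)
  expect_equal(compute_vcl(square), 10)

  expect_error(compute_vsl(line[1, , drop = FALSE]), "2 points")

  # sine cell against the independent dense polyline oracle
  traj <- sine_traj()
  span <- traj$time[nrow(traj)]
  tt <- seq(0, span, length.out = 1000)
  xy <- cbind(50 * tt, 2 * sin(2 * pi * 5 * tt))
  oracle <- sum(sqrt(rowSums(diff(xy)^2))) / span
  expect_equal(compute_vcl(traj), oracle, tolerance = 0.02)
})

test_that("average path fixes straight lines and damps oscillation", {
  line <- data.frame(time = seq(0, 1, length.out = 31),
                     x_um = seq(0, 30, length.out = 31),
                     y_um = seq(0, 15, length.out = 31))
  sm <- average_path(line, path_config(smoothing_window = 7L))
  expect_equal(sm$x_um, line$x_um, tolerance = 1e-12)
  expect_equal(sm$y_um, line$y_um, tolerance = 1e-12)

  const <- data.frame(time = 0:10 / 10, x_um = rep(3, 11), y_um = rep(4, 11))
  smc <- average_path(const, path_config(smoothing_window = 5L))
  expect_equal(smc$x_um, const$x_um)

  # residual oscillation after a one-beat-period window is small
  traj <- sine_traj(speed = 50, A = 2, f = 5, fps = 60)
  w <- select_smoothing_window(traj)
  smoothed <- average_path(traj, path_config(smoothing_window = w))
  core <- 15:45  # away from the shrinking-window ends
  expect_lt(max(abs(smoothed$y_um[core])), 0.15 * 2)

  expect_error(average_path(line, path_config(smoothing_window = 101L)),
               "exceeds track length")
})

test_that("VAP tracks the progressive speed and sits between VSL and VCL", {
  line <- data.frame(time = seq(0, 1, length.out = 61),
                     x_um = seq(0, 40, length.out = 61), y_um = 0)
  expect_equal(compute_vap(line, path_config(smoothing_window = 5L)), 40,
               tolerance = 1e-9)
  prof <- kinematic_profile(sine_traj(speed = 50, A = 2, f = 5))
  expect_lt(abs(prof$vap - 50) / 50, 0.05)
  expect_gte(prof$vcl + 1e-9 * prof$vcl, prof$vap)
  expect_gte(prof$vap + 1e-9 * prof$vcl, prof$vsl)
})

test_that("LIN follows VSL/VCL with the zero-VCL convention", {
  expect_equal(compute_lin(25, 50), 0.5)
  expect_equal(compute_lin(0, 0), 0)
  line <- data.frame(time = c(0, 0.5, 1), x_um = c(0, 25, 50), y_um = 0)
  expect_equal(compute_lin(compute_vsl(line), compute_vcl(line)), 1)
})

test_that("ALH_max recovers the lateral amplitude and scales with it", {
  line <- data.frame(time = seq(0, 1, length.out = 61),
                     x_um = seq(0, 40, length.out = 61), y_um = 0)
  expect_equal(compute_alh_max(line, path_config(smoothing_window = 5L)), 0,
               tolerance = 1e-9)
  p1 <- kinematic_profile(sine_traj(A = 2))
  expect_lt(abs(p1$alh_max - 2) / 2, 0.15)
  p2 <- kinematic_profile(sine_traj(A = 4))
  expect_equal(p2$alh_max / p1$alh_max, 2, tolerance = 0.1)
})

test_that("BCF counts crossings and applies the low-VSL reporting rule", {
  prof <- kinematic_profile(sine_traj(speed = 50, A = 2, f = 5))
  expect_lt(abs(prof$bcf - 10), 1)

  line <- data.frame(time = seq(0, 1, length.out = 61),
                     x_um = seq(0, 40, length.out = 61), y_um = 0)
  expect_equal(compute_bcf(line, path_config(smoothing_window = 5L)), 0)

  # VSL exactly at the threshold: not reported (the rule is <=)
  slow <- sine_traj(speed = 2, A = 1, f = 5, dur = 2)
  vsl <- compute_vsl(slow)
  expect_true(is.na(compute_bcf(slow, path_config(smoothing_window = 11L),
                                vsl = 2)))
  fast <- kinematic_profile(sine_traj(speed = 30, A = 2, f = 7))
  expect_false(is.na(fast$bcf))
})

test_that("kinematics are invariant under rigid motions and reflection", {
  traj <- sine_traj(speed = 30, A = 2, f = 6, phase = 0.4, heading = 0.3)
  base <- kinematic_profile(traj, path_config(smoothing_window = 11L))
  th <- 1.2
  rot <- traj
  rot$x_um <- cos(th) * traj$x_um - sin(th) * traj$y_um + 100
  rot$y_um <- sin(th) * traj$x_um + cos(th) * traj$y_um - 40
  attr(rot, "fps") <- attr(traj, "fps")
  flip <- traj
  flip$x_um <- -traj$x_um
  attr(flip, "fps") <- attr(traj, "fps")
  for (other in list(rot, flip)) {
    prof <- kinematic_profile(other, path_config(smoothing_window = 11L))
    for (p in c("vsl", "vcl", "vap", "lin", "alh_max", "bcf"))
      expect_equal(prof[[p]], base[[p]], tolerance = 1e-9)
  }
})

test_that("finer sampling of the same curve never shortens the polyline", {
  p <- cell_motion_params(40, 2.5, 7, 0.2, 0.5)
  v60 <- compute_vcl(make_trajectory(p, 60, 1)$trajectory)
  v120 <- compute_vcl(make_trajectory(p, 120, 1)$trajectory)
  expect_gte(v120, v60 - 1e-9)
})

test_that("BCF never exceeds the Nyquist frequency", {
  set.seed(77)
  fps <- 60
  for (i in 1:5) {
    # jittered track: the crossing count saturates, the report must not
    jitter <- data.frame(time = (0:59) / fps,
                         x_um = (0:59) * 0.5 + rnorm(60, 0, 0.3),
                         y_um = rnorm(60, 0, 0.3))
    attr(jitter, "fps") <- fps
    bcf <- compute_bcf(jitter, path_config(smoothing_window = 11L))
    if (!is.na(bcf)) expect_lte(bcf, fps / 2)
  }
})

test_that("kinematic recovery on a simulated panel is accurate at 60 fps", {
  set.seed(101)
  rel <- data.frame()
  for (i in 1:40) {
    speed <- runif(1, 6, 60)
    A <- runif(1, 1, 3.5)
    f <- runif(1, 4, 10)
    p <- cell_motion_params(speed, A, f, runif(1, 0, 2 * pi), runif(1, 0, 2 * pi))
    sim <- make_trajectory(p, 60, 2)
    prof <- kinematic_profile(sim$trajectory)
    rel <- rbind(rel, data.frame(
      vsl = abs(prof$vsl - sim$truth$vsl) / sim$truth$vsl,
      vcl = abs(prof$vcl - sim$truth$vcl) / sim$truth$vcl,
      vap = abs(prof$vap - sim$truth$vap) / sim$truth$vap,
      alh = abs(prof$alh_max - sim$truth$alh_max) / sim$truth$alh_max,
      bcf = abs(prof$bcf - sim$truth$bcf)))
  }
  expect_lt(median(rel$vsl), 0.05)
  expect_lt(median(rel$vcl), 0.05)
  expect_lt(median(rel$vap), 0.05)
  expect_lt(median(rel$alh), 0.15)
  expect_lte(median(rel$bcf), 1)
})
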