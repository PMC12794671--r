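test_that("immotile and degenerate cells give zero kinematic truth", {
  still <- make_trajectory(cell_motion_params(0, 0), fps = 60, duration = 1)
  expect_true(all(still$trajectory$x_um == still$trajectory$x_um[1]))
  expect_true(all(still$trajectory$y_um == still$trajectory$y_um[1]))
  expect_equal(still$truth$vsl, 0)
  expect_equal(still$truth$vcl, 0)
  expect_equal(still$truth$alh_max, 0)
  expect_identical(still$truth$grade, "immotile")

  straight <- make_trajectory(cell_motion_params(50, 0, 0, heading = 0.7),
                              fps = 60, duration = 1)
  expect_equal(straight$truth$vsl, 50, tolerance = 1e-12)
  expect_equal(straight$truth$vcl, 50, tolerance = 1e-12)
  expect_equal(straight$truth$vap, 50, tolerance = 1e-12)
  expect_equal(straight$truth$lin, 1, tolerance = 1e-12)
})

test_that("sine-cell truth matches an independent dense polyline oracle", {
  p <- cell_motion_params(50, 2, 5, beat_phase = 0.3, heading = 0.2)
  sim <- make_trajectory(p, fps = 60, duration = 1)
  expect_equal(sim$truth$alh_max, 2)
  expect_equal(sim$truth$bcf, 10)  # crossings per second = 2 f_b

  # oracle: brute-force 1000-sample polyline on the closed-form curve
  n <- nrow(sim$trajectory)
  span <- (n - 1) / 60
  tt <- seq(0, span, length.out = 1000)
  base <- cbind(50 * tt * cos(0.2), 50 * tt * sin(0.2))
  off <- 2 * sin(2 * pi * 5 * tt + 0.3)
  xy <- base + cbind(-sin(0.2), cos(0.2))[rep(1, 1000), ] * off
  oracle_vcl <- sum(sqrt(rowSums(diff(xy)^2))) / span
  expect_equal(sim$truth$vcl, oracle_vcl, tolerance = 0.01)
  # lateral zero-crossing count of the closed form: 2 f_b per second
  expect_equal(sum(diff(sign(off[off != 0])) != 0) / span, 10, tolerance = 0.11)
})

test_that("trajectory truth converges under quadrature refinement", {
  p <- cell_motion_params(35, 3, 8, heading = 1.1, path_curvature = 0.01)
  v10 <- make_trajectory(p, 60, 1, oversample = 10L)$truth$vcl
  v100 <- make_trajectory(p, 60, 1, oversample = 100L)$truth$vcl
  expect_lt(abs(v10 - v100) / v100, 0.001)
})

test_that("ground truth is internally consistent across a simulated panel", {
  cells <- simulate_cells(small_config(seed = 5L))
  expect_equal(cells$truth$lin,
               ifelse(cells$truth$vcl > 0, cells$truth$vsl / cells$truth$vcl, 0),
               tolerance = 1e-12)
  expect_true(all(cells$truth$vcl >= cells$truth$vsl - 1e-9))
  # every generated cell's true VSL lies inside its requested grade interval
  expect_true(all(cells$truth$vsl[cells$truth$grade == "rapid"] >= 25))
  slow <- cells$truth$vsl[cells$truth$grade == "slow"]
  expect_true(all(slow >= 5 & slow < 25))
  expect_true(all(cells$truth$vsl[cells$truth$grade == "nonprogressive"] < 5))
  expect_true(all(cells$truth$vsl[cells$truth$grade == "immotile"] == 0))
})

test_that("non-finite motion parameters are rejected", {
  expect_error(cell_motion_params(NA_real_), "non-finite")
  expect_error(cell_motion_params(10, Inf), "non-finite")
  expect_error(cell_motion_params(-1), ">= 0")
})

test_that("rendering is deterministic and respects the field bound", {
  cfg <- small_config(seed = 9L)
  a <- simulate_sample(cfg)
  b <- simulate_sample(cfg)
  expect_identical(a$frames, b$frames)
  expect_identical(a$truth, b$truth)

  outside <- data.frame(cell_id = 1L, frame = 0:1,
                        x_um = c(10, 500), y_um = c(10, 10))
  expect_error(render_video(outside, cfg), "field_size")
  tight <- sim_config(field_size = c(12, 12),
                      n_cells_by_grade = c(rapid = 30), rng_seed = 1L)
  expect_error(simulate_cells(tight), "field too small")
})

test_that("an empty noiseless scene renders uniform frames and one static cell stays put", {
  cfg <- sim_config(fps = 30, duration = 0.2, field_size = c(40, 40),
                    microns_per_pixel = 0.5, n_cells_by_grade = c(),
                    noise_sd = 0, n_debris = 0, rng_seed = 1L)
  fr <- render_video(NULL, cfg)
  expect_true(all(fr == fr[1, 1, 1]))

  v <- blob_video(list(line_traj(c(30, 35), c(0, 0), 10)), 10)
  cents <- sapply(1:10, function(t) {
    d <- detect_heads(v$frames[, , t], test_tracker())
    c(d$x_px[1], d$y_px[1])
  })
  expect_equal(ncol(cents), 10)
  expect_lt(max(abs(cents[1, ] - cents[1, 1])), 0.1)
  expect_lt(max(abs(cents[2, ] - cents[2, 1])), 0.1)
})

test_that("brightness and flip perturbations behave as involutions/scalings", {
  v <- blob_video(list(line_traj(c(20, 20), c(0.5, 0.2), 12)), 12,
                  noise_sd = 3, seed = 3L)
  fr <- v$frames
  expect_identical(perturb_video(fr, 0, NULL), fr)
  expect_identical(perturb_video(perturb_video(fr, 0, "horizontal"), 0, "horizontal"), fr)
  expect_identical(perturb_video(perturb_video(fr, 0, "vertical"), 0, "vertical"), fr)
  expect_error(perturb_video(fr, 0, "diagonal"), "unknown flip_axis")
  expect_error(perturb_video(fr, -150), "brightness_percent")

  mid <- array(100L, dim = c(8, 8, 2))
  expect_equal(mean(perturb_video(mid, 10)) / mean(mid), 1.10, tolerance = 1e-9)
  sat <- array(250L, dim = c(4, 4, 2))
  expect_true(all(perturb_video(sat, 10) == 255L))
})
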