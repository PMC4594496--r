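noiseless <- function(alpha = 0, f = 1, A = 50, dur = 15, shape = "line")
  generate_stroke_series(
    trajectory_params(amplitude = A, frequency = f,
                      ovalization_ratio = alpha, noise_sd = 0),
    shape, dur)

test_that("cycle segmentation matches a brute-force extrema scan", {
  for (f in c(1, 1.3, 2.4)) {
    traj <- noiseless(f = f, shape = "circle")
    cyc <- segment_cycles(traj)
    expect_equal(nrow(cyc), oracle_cycle_count(traj$y_mm))
    expect_equal(nrow(cyc), floor(15 * f) - (15 * f == floor(15 * f)))
  }
  # half-open convention: every sample belongs to exactly one cycle
  cyc <- segment_cycles(noiseless(f = 1.3, shape = "circle"))
  expect_true(all(cyc$start[-1] == cyc$end[-nrow(cyc)]))
})

test_that("non-cyclic trajectories yield no cycles", {
  ramp <- data.frame(time_s = seq(0, 5, by = 0.01),
                     x_mm = 0, y_mm = seq(0, 50, length.out = 501))
  expect_equal(nrow(segment_cycles(ramp)), 0L)
  expect_error(ovalization_index(ramp), class = "cl_no_cycle")
  expect_error(drawing_frequency(ramp), class = "cl_no_cycle")
})

test_that("trajectory validation rejects malformed input", {
  expect_error(segment_cycles(data.frame(time_s = 1, x_mm = 1, y_mm = 1)),
               class = "cl_invalid_parameter")
  bad <- data.frame(time_s = c(0, 1, 1), x_mm = 0, y_mm = c(0, 1, 0))
  expect_error(segment_cycles(bad), class = "cl_invalid_parameter")
  nonfin <- data.frame(time_s = 0:2, x_mm = c(0, NA, 0), y_mm = c(0, 1, 0))
  expect_error(segment_cycles(nonfin), class = "cl_invalid_parameter")
})

test_that("smoothing and prominence suppress jitter extrema", {
  p <- trajectory_params(frequency = 1, noise_sd = 1, seed = 8)
  traj <- generate_stroke_series(p, "line", 15)
  cyc <- segment_cycles(traj)
  expect_true(nrow(cyc) %in% 13:15)  # noise must not multiply cycle count
  expect_equal(drawing_frequency(traj), 1, tolerance = 0.05)
})

test_that("OI hits its analytic anchors and closed form", {
  expect_equal(ovalization_index(noiseless(shape = "circle"))$oi, 100)
  expect_equal(ovalization_index(noiseless(alpha = 0))$oi, 0)
  for (alpha in seq(0.1, 1, by = 0.1))
    expect_equal(ovalization_index(noiseless(alpha = alpha))$oi,
                 100 * alpha, tolerance = 1 / (100 * alpha) + 1e-8)
  # numerical-integration oracle at the spec's example ratio
  expect_equal(ovalization_index(noiseless(alpha = 0.3))$oi,
               oracle_ellipse_oi(0.3 * 50, 50), tolerance = 0.5 / 30)
})

test_that("OI is invariant to translation, uniform scaling, time reversal", {
  p <- trajectory_params(ovalization_ratio = 0.4, noise_sd = 0.5, seed = 4)
  traj <- generate_stroke_series(p, "line", 15)
  base <- ovalization_index(traj)$oi

  shifted <- traj
  shifted$x_mm <- shifted$x_mm + 123
  shifted$y_mm <- shifted$y_mm - 47
  expect_equal(ovalization_index(shifted)$oi, base, tolerance = 1e-12)

  scaled <- traj
  scaled$x_mm <- scaled$x_mm * 3.7
  scaled$y_mm <- scaled$y_mm * 3.7
  expect_equal(ovalization_index(scaled)$oi, base, tolerance = 1e-12)

  rev_traj <- traj[rev(seq_len(nrow(traj))), ]
  rev_traj$time_s <- max(traj$time_s) - rev_traj$time_s
  expect_equal(ovalization_index(rev_traj)$oi, base, tolerance = 0.2)
})

test_that("OI increases monotonically with the ovalization ratio", {
  ois <- vapply(seq(0, 1, by = 0.1), function(a) {
    p <- trajectory_params(ovalization_ratio = a, noise_sd = 0.5, seed = 13)
    ovalization_index(generate_stroke_series(p, "line", 15))$oi
  }, numeric(1))
  expect_true(all(diff(ois) > 0))
})

test_that("block OI equals the mean of independently recomputed cycles", {
  p <- trajectory_params(ovalization_ratio = 0.35, noise_sd = 1, seed = 6)
  traj <- generate_stroke_series(p, "line", 15)
  res <- ovalization_index(traj)
  per <- oracle_per_cycle_oi(traj, segment_cycles(traj))
  expect_equal(res$per_cycle_oi, per, tolerance = 1e-9)
  expect_equal(res$oi, min(100, max(0, mean(per))), tolerance = 1e-9)
})

test_that("frequency is the reciprocal of the mean cycle duration", {
  p <- trajectory_params(frequency = 1.3, noise_sd = 0.5, seed = 3)
  traj <- generate_stroke_series(p, "line", 15)
  cyc <- segment_cycles(traj)
  f <- drawing_frequency(traj)
  expect_equal(f * mean(cyc$duration), 1, tolerance = 1e-9)
  expect_equal(f, 1.3, tolerance = 0.05)
  expect_equal(ovalization_index(traj)$frequency_hz, f)
})

test_that("coupling_effect is the CL minus LL difference", {
  expect_identical(coupling_effect(11.5, 10.4), 11.5 - 10.4)
  expect_identical(coupling_effect(7, 7), 0)
  expect_error(coupling_effect(101, 5), class = "cl_invalid_parameter")
  expect_error(coupling_effect(50, -1), class = "cl_invalid_parameter")
})

test_that("trajectory CSV and metrics TSV round-trip", {
  ses <- generate_session(session_spec(seed = 2), trajectory_params(),
                          trajectory_params(), seed = 2)
  csv <- tempfile(fileext = ".csv")
  write_trajectory_csv(ses, csv)
  back <- read_trajectory_csv(csv)
  expect_equal(back$time_s, ses$time_s, tolerance = 1e-9)
  expect_identical(back$condition, ses$condition)
  bm <- block_metrics(back, hand = "R")
  expect_identical(names(bm), c("block_id", "condition", "hand", "oi",
                                "n_cycles", "frequency_hz"))
  tsv <- tempfile(fileext = ".tsv")
  write_metrics_tsv(bm, tsv)
  reread <- utils::read.delim(tsv)
  expect_equal(nrow(reread), nrow(bm))
  expect_equal(reread$oi, bm$oi, tolerance = 1e-8)
})
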