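test_that("baseline and dF/F0 arithmetic are exact", {
  expect_equal(compute_f0(rep(100, 10), 0:9, c(0, 5)), 100)
  expect_equal(compute_f0(c(7, 9, 11), 0:2, c(1, 1)), 9)
  expect_error(compute_f0(rep(0, 5), 0:4, c(0, 4)), "F0")
  expect_error(compute_f0(rep(1, 5), 0:4, c(10, 12)), "no frames")
  expect_equal(delta_f_over_f(c(150, 80, 100), 100), c(0.5, -0.2, 0))
  expect_error(delta_f_over_f(100, 0), "F0")
  # noisy baseline: the estimator is the sample mean at its standard accuracy
  withr::with_seed(2, f <- 100 + stats::rnorm(1e4, 0, 5))
  expect_lt(abs(compute_f0(f, seq_along(f) - 1, c(0, 1e4)) - 100),
            3 * 5 / sqrt(1e4))
})

test_that("activity maps average dF/F0 over the post-stimulus window", {
  fs <- make_functional_scene(c(48, 48), n_rois = 3,
                              amp_spec = c(1, -0.3, 0), dt = 0.2,
                              n_frames = 55, stim_onset = 5, seed = 4)
  am <- activity_map(fs$frames, stim_onset = 5, t = fs$t)
  # closed-form kernel average over the window
  h <- fs$frames[, , ] # kernel via the ROI trace itself (noise-free)
  win <- fs$t >= 5 & fs$t <= 10
  for (k in 1:3) {
    m <- fs$roi_ids == k
    trace <- apply(fs$frames, 3, function(fr) mean(fr[m]))
    expected <- mean(trace[win]) / mean(trace[fs$t <= 4.5]) - 1
    expect_equal(mean(am[m]), expected, tolerance = 1e-10)
  }
  expect_gt(mean(am[fs$roi_ids == 1]), 0)
  expect_lt(mean(am[fs$roi_ids == 2]), 0)
  expect_equal(mean(am[fs$roi_ids == 3]), 0)
  # background has no response
  expect_equal(max(abs(am[fs$roi_ids == 0])), 0)
  expect_error(activity_map(fs$frames, stim_onset = 8, t = fs$t),
               "past the recording")
})

test_that("clip masks flag pixels clipped at any time and grow with power", {
  cfg <- acquisition_config()
  fs <- make_functional_scene(c(32, 32), n_rois = 3,
                              amp_spec = c(2, 1, 0.5), dt = 0.2,
                              n_frames = 55, stim_onset = 5, seed = 6,
                              baseline_range = c(100, 400))
  none <- array(0L, c(4, 4, 3))
  expect_false(any(clip_mask(none, cfg)))
  one <- none
  one[2, 3, 2] <- cfg$S_max_code
  expect_identical(which(clip_mask(one, cfg)), which(matrix(seq_len(16), 4) == 10))
  # monotone in conventional power on a fixed noise-free scene
  masks <- lapply(c(0.5, 0.8, 1), function(p0) {
    clip_mask(scan_movie(fs, cfg, noise_off(), mode = "conventional",
                         P0 = p0)$clip)
  })
  expect_true(all(masks[[1]] <= masks[[2]]))
  expect_true(all(masks[[2]] <= masks[[3]]))
})

test_that("response statistics use the signed extremum convention", {
  t <- seq(0, 10, by = 0.5)
  mk <- function(dff) tibble::tibble(roi_id = 1L, t = t, F = 100 * (1 + dff),
                                     F0 = 100, dff = dff)
  up <- rep(0, length(t)); up[t >= 5 & t <= 6] <- 0.5
  withr::with_seed(1, up[t < 4.5] <- stats::rnorm(sum(t < 4.5), 0, 0.05))
  tr <- structure(mk(up), stim_onset = 5, rest_window = c(0, 4.5))
  st <- response_stats(tr)
  expect_equal(st$peak_dff, 0.5)
  expect_equal(st$snr, 0.5 / st$rest_sd)
  expect_equal(st$sign, "increase")
  down <- rep(0, length(t)); down[t >= 5] <- -0.4
  down[3] <- 0.01
  tr2 <- structure(mk(down), stim_onset = 5, rest_window = c(0, 4.5))
  st2 <- response_stats(tr2)
  expect_equal(st2$peak_dff, -0.4)
  expect_equal(st2$sign, "decrease")
  # zero resting noise is flagged, not divided by
  flat <- structure(mk(up * c(rep(0, 10), rep(1, length(t) - 10))),
                    stim_onset = 5, rest_window = c(0, 4.5))
  stf <- response_stats(flat)
  expect_true(stf$snr_infinite)
  expect_identical(abs(stf$snr), Inf)
})

test_that("dF/F0 from reconstructed movies ignores the global scale", {
  fs <- make_functional_scene(c(32, 32), n_rois = 4, dt = 0.2, n_frames = 55,
                              stim_onset = 5, seed = 8)
  tr1 <- roi_traces(fs$frames, fs$roi_ids, fs$t, fs$stim_onset)
  tr2 <- roi_traces(fs$frames * 37.5, fs$roi_ids, fs$t, fs$stim_onset)
  expect_equal(tr1$dff, tr2$dff)
})

test_that("acquired movies recover amplitudes and their ranks", {
  cfg <- acquisition_config("hdr")
  noise <- noise_model(pd_sigma = 0.005)
  fs <- make_functional_scene(c(48, 48), n_rois = 8,
                              amp_spec = function(n) c(stats::runif(n - 2, 0.05, 2),
                                                       stats::runif(2, -0.3, -0.1)),
                              dt = 0.2, n_frames = 55, stim_onset = 5,
                              seed = 11)
  mov <- scan_movie(fs, cfg, noise, mode = "ai", seed = 21)
  st <- response_stats(roi_traces(mov))
  expect_equal(st$peak_dff, fs$amplitudes, tolerance = 0.1)
  expect_true(all(st$peak_dff[fs$amplitudes < 0] < 0))
  expect_gte(stats::cor(st$snr, fs$amplitudes, method = "spearman"), 0.9)
  expect_equal(mean(clip_mask(mov)), 0)
})
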