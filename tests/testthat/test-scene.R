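test_that("structural scenes achieve the requested brightness range exactly", {
  for (ratio in c(1e2, 1e4, 1e8)) {
    sc <- tiny_scene(range_ratio = ratio)
    pos <- sc$strength[sc$strength > 0]
    expect_lt(abs(max(pos) / min(pos) / ratio - 1), 0.01)
    expect_true(all(sc$strength >= 0))
    # labels cover every positive-strength pixel
    expect_true(all(sc$labels[sc$strength > 0] > 0))
    expect_true(all(sc$strength[sc$labels > 0] > 0))
  }
})

test_that("degenerate unit range gives a constant-strength image", {
  sc <- tiny_scene(range_ratio = 1)
  pos <- sc$strength[sc$strength > 0]
  expect_equal(max(pos), min(pos))
})

test_that("identical seeds give bit-identical scenes", {
  cnt <- c(soma = 2, dendrite = 3, spine = 8)
  a <- make_structural_scene(c(48, 48), 1e6, counts = cnt, seed = 7)
  b <- make_structural_scene(c(48, 48), 1e6, counts = cnt, seed = 7)
  expect_identical(a$strength, b$strength)
  expect_identical(a$labels, b$labels)
  c <- make_structural_scene(c(48, 48), 1e6, counts = cnt, seed = 8)
  expect_false(identical(a$strength, c$strength))
})

test_that("invalid scene requests are rejected", {
  expect_error(make_structural_scene(c(64, 64), range_ratio = 0.5), "range_ratio")
  expect_error(make_structural_scene(c(16, 16), 10), "32 x 32")
  expect_error(
    make_structural_scene(c(32, 32), 10,
                          counts = c(soma = 50, dendrite = 0, spine = 0)),
    "capacity")
})

test_that("ground-truth summaries report exact per-structure means", {
  sc <- make_structural_scene(c(64, 64), 1e4, seed = 3,
                              counts = c(soma = 3, dendrite = 2, spine = 5))
  gt <- ground_truth_summary(sc)
  expect_equal(sum(gt$class == "soma"), 3)
  soma_rows <- gt[gt$class == "soma", ]
  for (i in seq_len(nrow(soma_rows))) {
    px <- sc$strength[sc$ids == soma_rows$id[i]]
    expect_equal(soma_rows$mean_strength[i], mean(px))
    expect_equal(soma_rows$n_pixels[i], length(px))
  }
})

test_that("functional scenes encode amplitudes exactly on the frame grid", {
  amps <- c(1, 0.5, -0.3, 0)
  fs <- make_functional_scene(c(48, 48), n_rois = 4, amp_spec = amps,
                              dt = 0.2, n_frames = 55, stim_onset = 5,
                              seed = 2)
  expect_true(all(fs$frames >= 0))
  for (k in seq_along(amps)) {
    m <- fs$roi_ids == k
    trace <- apply(fs$frames, 3, function(fr) mean(fr[m]))
    dff <- trace / mean(trace[fs$t < 4.5]) - 1
    if (amps[k] >= 0) {
      expect_equal(max(dff), amps[k], tolerance = 1e-6)
    } else {
      expect_equal(min(dff), amps[k], tolerance = 1e-6)
    }
    if (amps[k] == 0) expect_lt(diff(range(trace)), 1e-9)
  }
  # amplitudes recorded in the ground truth match the spec draws
  expect_equal(ground_truth_summary(fs)$amplitude, amps)
})

test_that("impossible functional scenes are rejected", {
  expect_error(
    make_functional_scene(c(48, 48), n_rois = 2, amp_spec = c(0.5, -1.2),
                          seed = 1),
    "negative strength")
  expect_error(
    make_functional_scene(c(48, 48), n_rois = 2, dt = 0.2, n_frames = 10,
                          stim_onset = 5, seed = 1),
    "5 s post-stimulus")
})
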