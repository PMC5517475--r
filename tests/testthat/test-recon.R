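test_that("linear reconstruction obeys the antilog relation", {
  r <- reconstruct_linear(0, 630.15, 0.12)
  expect_equal(r$X, 1)
  cfg <- acquisition_config()
  lvl <- cfg$G_L * cfg$G_M
  expect_equal(reconstruct_linear(2 * lvl, cfg$G_L, cfg$G_M)$X /
                 reconstruct_linear(lvl, cfg$G_L, cfg$G_M)$X, 2)
  r2 <- reconstruct_linear(matrix(c(0, lvl, 2 * lvl, 3 * lvl), 2), cfg$G_L,
                           cfg$G_M)
  expect_equal(r2$X, 2^r2$log2X)
  expect_true(all(r2$X > 0))
  expect_error(reconstruct_linear(0, -1, 0.1), "gains")
})

test_that("pipeline ratios cancel the unknown global scale", {
  cfg <- acquisition_config()
  l1 <- redigitize(log_encode(1024, 4096, cfg), cfg)$L_dd
  l2 <- redigitize(log_encode(1, 2^14, cfg), cfg)$L_dd
  ratio <- reconstruct_linear(l1, cfg$G_L, cfg$G_M)$X /
    reconstruct_linear(l2, cfg$G_L, cfg$G_M)$X
  expect_equal(log2(ratio), 14, tolerance = 2 * quantization_budget(cfg) / 14)
})

test_that("occupied bits reads the span of the log histogram", {
  expect_equal(occupied_bits(matrix(5, 20, 20)), 0)
  two_blocks <- matrix(c(rep(1, 200), rep(2^20, 200)), 20)
  expect_lte(abs(occupied_bits(two_blocks, min_count = 10) - 20), 0.5)
  # a noise tail below min_count is suppressed
  tail <- matrix(c(rep(1, 200), rep(2^20, 200), rep(2^40, 3)), ncol = 1)
  expect_lte(abs(occupied_bits(tail, min_count = 10) - 20), 0.5)
  # a 12-bit code image can never span more than 12 bits
  codes <- matrix(sample.int(2^12 - 1, 5000, replace = TRUE), ncol = 50)
  expect_lte(occupied_bits(codes, min_count = 1), 12)
  expect_error(occupied_bits(matrix(0, 4, 4)), "positive")
})

test_that("AI and conventional linear histograms agree over the overlap", {
  cfg <- acquisition_config("hdr")
  withr::with_seed(3, {
    Xm <- matrix(2^stats::runif(4096, log2(30), log2(240)), 64, 64)
  })
  fra <- scan_frame(Xm, cfg, noise_off())
  frc <- scan_frame(Xm, cfg, noise_off(), mode = "conventional")
  cmp <- compare_histograms(reconstruct_frame(fra, cfg),
                            conventional_linear(frc, cfg),
                            conventional_clip = frc$clip)
  expect_false(cmp$no_overlap)
  expect_lt(cmp$mean_rel_dev, 0.1)
  # identical images agree perfectly
  same <- compare_histograms(Xm, Xm)
  expect_equal(same$mean_rel_dev, 0)
  expect_equal(same$scale, 1)
  # disjoint ranges are flagged rather than compared
  disj <- compare_histograms(matrix(1, 8, 8), matrix(0, 8, 8))
  expect_true(disj$no_overlap)
})

test_that("reconstruction is invariant to feedback tuning on a noise-free scene", {
  sc <- tiny_scene(range_ratio = 1e4, seed = 5)
  cfg_tuned <- acquisition_config("standard")
  cfg_detuned <- acquisition_config("standard", Ki = cfg_tuned$Ki * 0.25)
  fr_t <- scan_frame(sc, cfg_tuned, noise_off())
  fr_d <- scan_frame(sc, cfg_detuned, noise_off())
  expect_equal(sum(fr_t$clip) + sum(fr_d$clip), 0)
  # the detuned loop really is off target somewhere...
  expect_gt(max(abs(fr_d$S_hat[fr_d$mode == "feedback_active"] -
                      cfg_tuned$S0_hat)), 0.05 * cfg_tuned$S0_hat)
  # ...yet the reconstructed ratio agrees within the quantization budget
  d <- abs(reconstruct_frame(fr_t, cfg_tuned)$log2X -
             reconstruct_frame(fr_d, cfg_detuned)$log2X)
  expect_lte(max(d), 2 * quantization_budget(cfg_tuned))
})

test_that("reconstruction is linear in true strength over six decades", {
  cfg <- acquisition_config("hdr")
  Xv <- 10^seq(0, 6, length.out = 60)
  fr <- scan_frame(matrix(Xv, 6, 10), cfg, noise_off())
  rec <- reconstruct_frame(fr, cfg)
  fit <- stats::lm(as.vector(rec$log2X) ~ log2(Xv))
  expect_equal(unname(stats::coef(fit)[2]), 1, tolerance = 0.01)
})
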