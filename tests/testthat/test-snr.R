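test_that("conventional SNR is shot-noise limited up to saturation", {
  cfg_fine <- acquisition_config(B = 30)
  expect_equal(snr_conventional(250, cfg_fine)$snr, sqrt(250),
               tolerance = 1e-6)
  cfg <- acquisition_config()
  expect_equal(snr_conventional(0, cfg)$snr, 0)
  out <- snr_conventional(c(249, 251), cfg)
  expect_false(out$saturated[1])
  expect_true(out$saturated[2])
  expect_true(is.na(out$snr[2]))
})

test_that("AI SNR plateaus at sqrt(S0) and matches conventional below X_t", {
  cfg <- acquisition_config()
  quiet <- noise_model(pd_sigma = 0)
  expect_equal(snr_ai(1e6, cfg, quiet)$snr, sqrt(125), tolerance = 1e-3)
  # power-limited branch with P_max = P0 reproduces conventional SNR
  Xlow <- c(2, 10, 50, 100)
  expect_equal(snr_ai(Xlow, cfg, noise_model(pd_sigma = 0.005))$snr,
               snr_conventional(Xlow, cfg)$snr, tolerance = 0.02)
})

test_that("landmarks order as X_t < X_sat with the roll-off at the 3 dB point", {
  cfg <- acquisition_config()
  lm <- snr_landmarks(cfg, noise_model(pd_sigma = 0.005))
  expect_equal(lm$X_sat, 250)
  expect_equal(lm$X_t, 125)
  expect_lt(lm$X_t, lm$X_sat)
  expect_equal(lm$X_r, 1e4, tolerance = 0.01)
  # SNR at the roll-off point is the plateau over sqrt(2)
  expect_equal(snr_ai(lm$X_r, cfg, noise_model(pd_sigma = 0.005))$snr,
               sqrt(125 / 2), tolerance = 0.01)
  # no roll-off without power-measurement noise
  expect_equal(snr_landmarks(cfg, noise_model(pd_sigma = 0),
                             include_quantization = FALSE)$X_r, Inf)
})

test_that("the SNR branches are continuous and the plateau monotone", {
  cfg <- acquisition_config()
  quiet <- noise_model(pd_sigma = 0)
  at_t <- snr_ai(125, cfg, quiet)
  expect_equal(at_t$snr_power_limited, sqrt(125), tolerance = 1e-4)
  expect_equal(at_t$snr_feedback_active, sqrt(125), tolerance = 1e-4)
  grid <- snr_ai(2^seq(7, 30, by = 0.25), cfg, noise_model(pd_sigma = 0.005))
  expect_true(all(diff(grid$snr_feedback_active) <= 1e-9))
  expect_true(all(grid$snr_feedback_active <= sqrt(125) + 1e-9))
})

test_that("conventional beats AI only on a bounded band that shrinks with S0", {
  noise <- noise_model(pd_sigma = 0.005)
  X <- 2^seq(-2, log2(249), length.out = 400)
  # a visible advantage (2% margin) rather than numerical tie-breaking
  band <- function(s0_frac) {
    cfg <- acquisition_config(S0_frac = s0_frac)
    adv <- snr_conventional(X, cfg)$snr > 1.02 * snr_ai(X, cfg, noise)$snr
    X[adv]
  }
  b_half <- band(0.5)
  b_high <- band(0.9)
  expect_gt(length(b_half), 0)
  expect_true(all(b_half > 0.9 * transition_strength(acquisition_config())))
  expect_lt(length(b_high), length(b_half))
})

test_that("dynamic-range gain follows 2^(alpha B - 1) exactly", {
  two_photon <- dynamic_range_gain(2, 12)
  expect_identical(two_photon$gain, 2^23)
  expect_identical(two_photon$conventional_range, 2^12)
  expect_identical(dynamic_range_gain(3, 12)$gain, 2^35)
  expect_identical(dynamic_range_gain(1, 12)$gain, 2048)
  expect_error(dynamic_range_gain(0, 12), "integers")
  expect_error(dynamic_range_gain(2, 2.5), "integers")
})

test_that("Monte-Carlo SNR validates the closed form and flags exact runs", {
  cfg <- acquisition_config("hdr")
  noise <- noise_model(pd_sigma = 0.005)
  Xg <- 10^seq(log10(12.5), log10(1250), length.out = 5)
  mc <- monte_carlo_snr(Xg, cfg, noise, n_reps = 2000, seed = 7)
  expect_true(all(mc$rel_dev < 0.05))
  expect_setequal(unique(mc$mode), c("power_limited", "feedback_active"))
  # deterministic chain reports exact (infinite empirical SNR)
  quiet <- noise_model(shot_noise = FALSE, pd_sigma = 0)
  mcq <- suppressWarnings(monte_carlo_snr(500, cfg, quiet, n_reps = 200,
                                          seed = 1))
  expect_true(mcq$exact)
  expect_identical(mcq$snr_mc, Inf)
  expect_error(monte_carlo_snr(500, cfg, noise, n_reps = 50), ">= 100")
  expect_warning(monte_carlo_snr(500, cfg, quiet, n_reps = 200, seed = 1),
                 "coarse")
})

test_that("snr_curve carries tidy, glance and landmark structure", {
  cfg <- acquisition_config()
  cur <- snr_curve(cfg, noise_model(pd_sigma = 0.005), n_points = 50)
  expect_s3_class(cur, "snr_curve")
  long <- tidy(cur)
  expect_setequal(unique(long$trace),
                  c("conventional", "power_limited", "feedback_active",
                    "ai_net"))
  gl <- glance(cur)
  expect_equal(gl$X_sat, 250)
  expect_equal(gl$plateau_snr, sqrt(125))
  expect_equal(gl$dynamic_range_gain, 2^23)
  expect_s3_class(autoplot(cur), "ggplot")
})
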