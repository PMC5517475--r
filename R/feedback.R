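#' Mode-transition strength
#'
#' The sample strength at which the feedback switches between power-limited
#' and feedback-active mode: below \eqn{X_t = S_0 / P_{max}^\alpha} even the
#' maximum allowed power cannot raise the signal to the set point.
#'
#' @param cfg An [acquisition_config()].
#' @return \eqn{X_t} in strength units.
#' @examples
#' transition_strength(acquisition_config())  # 125
#' @export
transition_strength <- function(cfg) {
  cfg$S0 / cfg$P_max^cfg$alpha
}

#' One discrete PID update
#'
#' Computes the commanded power code from the digitized error
#' \eqn{e = \hat S_0 - \hat S} (signal LSB):
#' \deqn{u = \mathrm{clamp}(K_p e + K_i \textstyle\sum e\,\Delta t +
#'        K_d \Delta e/\Delta t,\; 0,\; 2^{B_P}).}
#' Anti-windup is by conditional integration: while the output is clamped the
#' integrator only accepts error of the sign that unwinds it.
#'
#' @param error \eqn{\hat S_0 - \hat S}, signal LSB.
#' @param state List with `integral` (error-seconds) and `e_prev`; use
#'   [pid_state()] for a fresh one.
#' @param cfg An [acquisition_config()] supplying `Kp`, `Ki`, `Kd` and `dt`.
#' @return List with `command` (power DAC code, clamped to `[0, 2^B_P]`),
#'   `pinned` (`TRUE` when clamped at the maximum) and the updated `state`.
#' @examples
#' cfg <- acquisition_config(Kp = 2, Ki = 0, Kd = 0)
#' pid_step(100, pid_state(), cfg)$command   # 200
#' @export
pid_step <- function(error, state, cfg) {
  if (!all(is.finite(c(error, state$integral, state$e_prev)))) {
    stop("PID error and state must be finite", call. = FALSE)
  }
  I_cand <- state$integral + error * cfg$dt
  u_raw <- cfg$Kp * error + cfg$Ki * I_cand +
    cfg$Kd * (error - state$e_prev) / cfg$dt
  if (u_raw > cfg$P_max_code) {
    u <- cfg$P_max_code
    if (error < 0) state$integral <- I_cand
    pinned <- TRUE
  } else if (u_raw < 0) {
    u <- 0
    if (error > 0) state$integral <- I_cand
    pinned <- FALSE
  } else {
    u <- u_raw
    state$integral <- I_cand
    pinned <- FALSE
  }
  state$e_prev <- error
  list(command = u, pinned = pinned, state = state)
}

#' Fresh feedback carry state
#'
#' @param command Initial power DAC code.
#' @param integral Initial integrator value (error-seconds).
#' @param e_prev Previous error.
#' @param P_actual Power currently at the sample.
#' @return A list usable as `carry_in` for [run_pixel_dwell()].
#' @export
pid_state <- function(command = 0, integral = 0, e_prev = 0, P_actual = 0) {
  list(command = command, integral = integral, e_prev = e_prev,
       P_actual = P_actual)
}

#' Simulate one pixel dwell of the feedback loop
#'
#' Readable reference implementation of a single pixel: `n_substeps`
#' iterations of \{[apply_eom()] -> [excite_and_detect()] ->
#' [quantize_signal()] -> [pid_step()]\}, holding the detected fluorescence at
#' the set point when possible and pinning the power at `P_max` otherwise.
#' Whole frames use the identical compiled kernel ([scan_frame()]); a test
#' pins the two paths to exact noise-free equality.
#'
#' @param X Sample strength (>= 0).
#' @param cfg An [acquisition_config()].
#' @param noise A [noise_model()].
#' @param carry_in Carry state from the previous pixel ([pid_state()]);
#'   default starts from zero power.
#' @return A `pixel_trace`: tibble of the sub-step series (`t`, `S`, `S_hat`,
#'   `P_command`, `P_actual`, `error`) plus the final digitized signal
#'   `S_hat`, power `P_hat`, `mode` label (`"feedback_active"` or
#'   `"power_limited"`), `clip` flag and the outgoing `carry` state.
#' @examples
#' cfg <- acquisition_config()
#' tr <- run_pixel_dwell(500, cfg, noise_model(shot_noise = FALSE, pd_sigma = 0))
#' tr$mode; tr$S_hat
#' @export
run_pixel_dwell <- function(X, cfg, noise = noise_model(), carry_in = NULL) {
  if (length(X) != 1 || X < 0) {
    stop("`X` must be a single strength >= 0", call. = FALSE)
  }
  if (cfg$n_substeps < 2) stop("`n_substeps` must be >= 2", call. = FALSE)
  st <- if (is.null(carry_in)) pid_state() else carry_in
  n <- cfg$n_substeps
  S_series <- P_cmd_series <- P_act_series <- err_series <- numeric(n)
  S_hat_series <- integer(n)
  u <- st$command
  P_act <- st$P_actual
  state <- list(integral = st$integral, e_prev = st$e_prev)
  pinned <- FALSE
  clip_ever <- FALSE
  code <- 0L
  for (k in seq_len(n)) {
    P_cmd <- cfg$G_P * u
    P_act <- apply_eom(P_cmd, P_act, cfg$dt, noise)
    det <- excite_and_detect(X, P_act, cfg, noise)
    q <- quantize_signal(det$S, cfg)
    code <- q$S_hat
    clip_ever <- clip_ever || q$clipped
    e <- cfg$S0_hat - code
    upd <- pid_step(e, state, cfg)
    u <- upd$command
    pinned <- upd$pinned
    state <- upd$state
    S_series[k] <- det$S
    S_hat_series[k] <- code
    P_cmd_series[k] <- P_cmd
    P_act_series[k] <- P_act
    err_series[k] <- e
  }
  P_hat <- measure_power(P_act, cfg, noise)
  structure(
    list(
      trace = tibble::tibble(
        t = (seq_len(n) - 1) * cfg$dt,
        S = S_series, S_hat = S_hat_series,
        P_command = P_cmd_series, P_actual = P_act_series,
        error = err_series
      ),
      S_hat = code, P_hat = P_hat,
      mode = if (pinned) "power_limited" else "feedback_active",
      clip = code >= cfg$S_max_code, clip_any = clip_ever,
      carry = pid_state(u, state$integral, state$e_prev, P_act),
      X = X
    ),
    class = "pixel_trace"
  )
}

#' @export
print.pixel_trace <- function(x, ...) {
  cat(sprintf(
    "<pixel_trace> X=%g: final S_hat=%d P_hat=%d mode=%s clip=%s\n",
    x$X, x$S_hat, x$P_hat, x$mode, x$clip))
  invisible(x)
}

#' Raster-scan a scene
#'
#' Acquires a whole frame in active-illumination (`"ai"`) or conventional
#' mode.  AI mode runs the per-pixel feedback loop in raster (row-major)
#' order, carrying power and PID state across adjacent pixels when
#' `cfg$carry_state` is `TRUE`, and records the digitized signal, digitized
#' power, mode and clip maps.  Conventional mode applies the fixed power `P0`
#' everywhere and digitizes the detected signal at the microscope bit depth
#' `B` (gain \eqn{(2^B - 1)/S_{sat}}), as a standard microscope would.
#'
#' @param scene A `scene_map`, or a plain nonnegative strength matrix.
#' @param cfg An [acquisition_config()].
#' @param noise A [noise_model()].
#' @param mode `"ai"` or `"conventional"`.
#' @param P0 Conventional-imaging power (defaults to `cfg$P0`); ignored for
#'   AI.
#' @param seed Optional seed making the scan reproducible.
#' @return A `frame_record`: integer maps `S_hat` and `P_hat`, character-coded
#'   `mode` map, logical `clip` (final-value clip) and `clip_any` (clipped at
#'   any sub-step) maps, the final actual power map, and the acquisition
#'   settings.
#' @examples
#' sc <- make_structural_scene(c(32, 32), range_ratio = 100, seed = 1,
#'                             counts = c(soma = 1, dendrite = 2, spine = 5))
#' fr <- scan_frame(sc, acquisition_config(),
#'                  noise_model(shot_noise = FALSE, pd_sigma = 0))
#' table(fr$mode)
#' @export
scan_frame <- function(scene, cfg, noise = noise_model(),
                       mode = c("ai", "conventional"), P0 = NULL,
                       seed = NULL) {
  mode <- match.arg(mode)
  X <- if (inherits(scene, "scene_map")) scene$strength else scene
  if (!is.matrix(X) || any(X < 0)) {
    stop("`scene` must be a scene_map or a nonnegative matrix", call. = FALSE)
  }
  run <- function() {
    if (mode == "ai") {
      out <- scan_frame_cpp(
        X, cfg$n_substeps, cfg$dt, cfg$alpha,
        cfg$G_S, cfg$S_sat, as.integer(cfg$S_max_code), cfg$S0_hat,
        cfg$G_P, cfg$P_max_code,
        cfg$Kp, cfg$Ki, cfg$Kd,
        cfg$carry_state, 0, 0,
        noise$shot_noise, noise$pd_sigma,
        noise$eom_tau, noise$eom_quad, noise$eom_quad_threshold,
        noise$dark_rate
      )
      mode_map <- matrix(c("feedback_active", "power_limited")[out$mode + 1L],
                         nrow(X), ncol(X))
      structure(
        list(S_hat = out$S_hat, P_hat = out$P_hat, mode = mode_map,
             clip = out$clip, clip_any = out$clip_any,
             P_actual = out$P_actual,
             acquisition = "ai", P0 = NA_real_, cfg = cfg, noise = noise),
        class = "frame_record"
      )
    } else {
      p0 <- if (is.null(P0)) cfg$P0 else P0
      det <- excite_and_detect(X, p0, cfg, noise)
      g_conv <- (2^cfg$B - 1) / cfg$S_sat
      code <- round(g_conv * det$S)
      clip <- det$clipped | code > (2^cfg$B - 1)
      code[code > (2^cfg$B - 1)] <- 2^cfg$B - 1
      structure(
        list(S_hat = matrix(as.integer(code), nrow(X), ncol(X)),
             P_hat = matrix(as.integer(
               pmin(pmax(round(p0 / cfg$G_P), 1), cfg$P_max_code)),
               nrow(X), ncol(X)),
             mode = matrix("conventional", nrow(X), ncol(X)),
             clip = matrix(clip, nrow(X), ncol(X)),
             clip_any = matrix(clip, nrow(X), ncol(X)),
             P_actual = matrix(p0, nrow(X), ncol(X)),
             acquisition = "conventional", P0 = p0, cfg = cfg, noise = noise),
        class = "frame_record"
      )
    }
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' @export
print.frame_record <- function(x, ...) {
  cat(sprintf(
    "<frame_record> %s, %d x %d, %.1f%% power-limited, %d clipped pixels\n",
    x$acquisition, nrow(x$S_hat), ncol(x$S_hat),
    100 * mean(x$mode == "power_limited"), sum(x$clip)))
  invisible(x)
}

#' Per-pixel frame record as a tibble
#'
#' @param x A `frame_record`.
#' @param ... Unused.
#' @return A tibble with one row per pixel: `row`, `col` (1-based), `S_hat`,
#'   `P_hat`, `mode`, `clip`.
#' @method tidy frame_record
#' @export
tidy.frame_record <- function(x, ...) {
  tibble::tibble(
    row = rep(seq_len(nrow(x$S_hat)), times = ncol(x$S_hat)),
    col = rep(seq_len(ncol(x$S_hat)), each = nrow(x$S_hat)),
    S_hat = as.vector(x$S_hat),
    P_hat = as.vector(x$P_hat),
    mode = as.vector(x$mode),
    clip = as.vector(x$clip)
  )
}

#' Acquire a functional movie
#'
#' Scans every frame of a [make_functional_scene()] movie with the same
#' acquisition settings, in AI or conventional mode, and (for AI) log-encodes
#' and reconstructs each frame so downstream functional analysis operates on
#' linear sample-strength estimates.
#'
#' @param scene A `functional_scene`.
#' @inheritParams scan_frame
#' @return A `movie_record`: `S_hat` and `clip` arrays `[row, col, frame]`,
#'   the reconstructed relative-strength movie `X_rel`, the frame times, and
#'   the acquisition settings.
#' @export
scan_movie <- function(scene, cfg, noise = noise_model(),
                       mode = c("ai", "conventional"), P0 = NULL,
                       seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(scene, "functional_scene"))
  run <- function() {
    dims <- c(scene$shape, scene$n_frames)
    S_hat <- array(0L, dims)
    clip <- array(FALSE, dims)
    X_rel <- array(0, dims)
    luts <- encoder_luts(cfg)
    for (f in seq_len(scene$n_frames)) {
      fr <- scan_frame(scene$frames[, , f], cfg, noise, mode = mode, P0 = P0)
      S_hat[, , f] <- fr$S_hat
      clip[, , f] <- fr$clip
      if (mode == "ai") {
        enc <- encode_frame(fr, cfg, luts = luts)
        X_rel[, , f] <- reconstruct_linear(enc$L_dd, cfg$G_L, enc$G_M_used)$X
      } else {
        g_conv <- (2^cfg$B - 1) / cfg$S_sat
        p0 <- if (is.null(P0)) cfg$P0 else P0
        X_rel[, , f] <- (fr$S_hat / g_conv) / p0^cfg$alpha
      }
    }
    structure(
      list(S_hat = S_hat, clip = clip, X_rel = X_rel, t = scene$t,
           stim_onset = scene$stim_onset, roi_ids = scene$roi_ids,
           acquisition = mode, P0 = if (is.null(P0)) cfg$P0 else P0,
           cfg = cfg, noise = noise),
      class = "movie_record"
    )
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' @export
print.movie_record <- function(x, ...) {
  cat(sprintf(
    "<movie_record> %s, %d x %d x %d frames, %.2f%% pixels clipped at some time\n",
    x$acquisition, dim(x$S_hat)[1], dim(x$S_hat)[2], dim(x$S_hat)[3],
    100 * mean(apply(x$clip, c(1, 2), any))))
  invisible(x)
}
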