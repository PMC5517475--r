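#' Build a quantized log2 lookup table
#'
#' Emulates the FPGA ROM tables used to convert integer codes to log2 values:
#' entries are \eqn{\log_2 k} quantized to `B_L` bits over the table's range,
#' i.e. on a grid of step \eqn{\log_2(\mathrm{domain\_size}) / 2^{B_L}}.  Code
#' 0 maps to the entry for code 1 (floor rule) so dark pixels stay encodable.
#'
#' @param domain_size Largest code covered (>= 2); the table holds entries
#'   for codes `0..domain_size`.
#' @param B_L Table bit depth (>= 1).
#' @return A `log_lut`: list with `entries` (numeric vector indexed by
#'   `code + 1`), `step`, `bit_depth` and `domain_size`.
#' @examples
#' lut <- build_log_lut(2^14, 13)
#' lut$entries[1 + 1]      # 0 at code 1
#' lut$entries[2^14 + 1]   # 14 at full scale
#' @export
build_log_lut <- function(domain_size, B_L) {
  if (B_L < 1) stop("`B_L` must be >= 1", call. = FALSE)
  if (domain_size < 2) stop("`domain_size` must be >= 2", call. = FALSE)
  step <- log2(domain_size) / 2^B_L
  codes <- seq_len(domain_size)
  entries <- c(0, round(log2(codes) / step) * step)  # code 0 -> entry for 1
  structure(
    list(entries = entries, step = step, bit_depth = B_L,
         domain_size = domain_size),
    class = "log_lut"
  )
}

# the two tables an acquisition needs (signal and power share the builder)
encoder_luts <- function(cfg) {
  list(S = build_log_lut(2^cfg$B_S, cfg$B_L),
       P = build_log_lut(2^cfg$B_P, cfg$B_L))
}

#' Log2-encode sample strength from digitized signal and power
#'
#' The FPGA-side operation
#' \deqn{\hat L_X = G_L(\log_2 \hat S - \alpha \log_2 \hat P_{norm}) + C,}
#' with both logs taken through `B_L`-bit lookup tables and the power code
#' normalized to full scale (\eqn{\hat P_{norm} = \hat P / 2^{B_P} \le 1}),
#' so the bracket is nonnegative and \eqn{\hat L_X \ge C} always — the role
#' the additive constant `C` plays for acquisition electronics that reject
#' negative inputs.
#'
#' @param S_hat Signal codes (>= 1); vectorized, matrices preserved.
#' @param P_hat Power codes (>= 1).
#' @param cfg An [acquisition_config()].
#' @param luts Optional pre-built tables from `build_log_lut()` (list with
#'   `S` and `P`); built from `cfg` when omitted.
#' @return \eqn{\hat L_X}, same shape as the inputs.
#' @examples
#' cfg <- acquisition_config()
#' log_encode(1, 2^14, cfg)         # both log terms zero -> C = 8192
#' log_encode(1024, 4096, cfg)      # (8192/13) * (10 + 4) + 8192
#' @export
log_encode <- function(S_hat, P_hat, cfg, luts = NULL) {
  if (any(S_hat < 1) || any(P_hat < 1)) {
    stop("codes must be >= 1 (floor zero codes upstream)", call. = FALSE)
  }
  if (any(S_hat > 2^cfg$B_S) || any(P_hat > 2^cfg$B_P)) {
    stop("codes exceed the converter range", call. = FALSE)
  }
  if (is.null(luts)) luts <- encoder_luts(cfg)
  log_S <- luts$S$entries[as.vector(S_hat) + 1]
  log_Pn <- luts$P$entries[as.vector(P_hat) + 1] - cfg$B_P  # log2(P_hat/2^B_P)
  L <- cfg$G_L * (log_S - cfg$alpha * log_Pn) + cfg$C
  if (is.matrix(S_hat)) L <- matrix(L, nrow(S_hat), ncol(S_hat))
  L
}

#' Re-digitize the log output at the microscope bit depth
#'
#' The microscope acquisition electronics sample the analog log output at `B`
#' bits with gain \eqn{G_M} chosen to fill the bit depth at the largest
#' encodable \eqn{\hat L_X} — computed from the configured bit depths, not
#' from the data, so reconstruction is calibration-free across frames:
#' \eqn{\hat{\hat L}_X = \mathrm{round}(G_M \hat L_X)} clipped to
#' `[0, 2^B - 1]`.
#'
#' @param L_hat \eqn{\hat L_X} values (>= 0); vectorized, matrices preserved.
#' @param cfg An [acquisition_config()].
#' @return List with `L_dd` (integer codes) and `G_M_used`.
#' @export
redigitize <- function(L_hat, cfg) {
  if (any(L_hat < 0)) stop("`L_hat` must be >= 0", call. = FALSE)
  code <- round(cfg$G_M * L_hat)
  code <- pmin(pmax(code, 0), 2^cfg$B - 1)
  if (is.matrix(L_hat)) code <- matrix(code, nrow(L_hat), ncol(L_hat))
  list(L_dd = code, G_M_used = cfg$G_M)
}

#' Encode a scanned frame
#'
#' Applies the floor rule to dark pixels (signal code 0 -> 1), log2-encodes
#' every pixel and re-digitizes at the microscope bit depth.
#'
#' @param frame A `frame_record` from an AI [scan_frame()].
#' @param cfg An [acquisition_config()].
#' @param luts Optional pre-built lookup tables.
#' @return An `encoded_frame`: `L_hat` (real map before re-digitization),
#'   `L_dd` (integer map), `G_M_used`, and the constants (`G_L`, `C`,
#'   `alpha`) needed for post-hoc linearization.
#' @export
encode_frame <- function(frame, cfg, luts = NULL) {
  stopifnot(inherits(frame, "frame_record"))
  if (frame$acquisition != "ai") {
    stop("only AI frames carry the dual signal/power measurement to encode",
         call. = FALSE)
  }
  S <- pmax(frame$S_hat, 1L)
  L_hat <- log_encode(S, frame$P_hat, cfg, luts = luts)
  rd <- redigitize(L_hat, cfg)
  structure(
    list(L_hat = L_hat, L_dd = rd$L_dd, G_M_used = rd$G_M_used,
         G_L = cfg$G_L, C = cfg$C, alpha = cfg$alpha),
    class = "encoded_frame"
  )
}

#' Worst-case quantization error of the encode/decode path
#'
#' Sum of the three deterministic error sources between the full-precision
#' log2 of \eqn{\hat S / \hat P_{norm}^\alpha} and its reconstruction: the
#' `B_L`-bit signal and power lookup-table grids (half a step each, the power
#' term amplified by \eqn{\alpha}) and the `B`-bit re-digitization (half an
#' output code).
#'
#' @param cfg An [acquisition_config()].
#' @return Worst-case absolute error in bits (log2 units).
#' @export
quantization_budget <- function(cfg) {
  0.5 * cfg$B_S / 2^cfg$B_L +
    cfg$alpha * 0.5 * cfg$B_P / 2^cfg$B_L +
    0.5 / (cfg$G_L * cfg$G_M)
}
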