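#include <Rcpp.h>
using namespace Rcpp;

// Raster scan of the per-pixel active-illumination feedback loop.
//
// Each pixel dwell runs n_substeps iterations of
//   {EOM -> excite/detect -> signal ADC -> PID},
// optionally carrying power and PID state across adjacent raster pixels
// (row-major order) as the hardware does.  Uses R's RNG (rpois / rnorm) so
// set.seed() in R makes the scan exactly reproducible.
//
// PID state: integral I (error * seconds), previous error e_prev, command u
// (power DAC code, clamped to [0, P_max_code]).  Anti-windup by conditional
// integration: the integrator is frozen while the output is clamped and the
// error would push it further into the clamp.
// [[Rcpp::export]]
List scan_frame_cpp(NumericMatrix X, int n_substeps, double dt, double alpha,
                    double G_S, double S_sat, int S_max_code, double S0_hat,
                    double G_P, double P_max_code,
                    double Kp, double Ki, double Kd,
                    bool carry, double u_init, double I_init,
                    bool shot_noise, double pd_sigma,
                    double eom_tau, double eom_quad, double eom_quad_thr,
                    double dark_rate) {
  const int nr = X.nrow(), nc = X.ncol();
  IntegerMatrix S_hat(nr, nc), P_hat(nr, nc), mode(nr, nc);
  LogicalMatrix clip(nr, nc), clip_any(nr, nc);
  NumericMatrix P_final(nr, nc);

  const double eom_decay = (eom_tau > 0.0) ? std::exp(-dt / eom_tau) : 0.0;

  double u = u_init, I = I_init, e_prev = 0.0, P_act = 0.0;
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      if (!carry) { u = u_init; I = I_init; e_prev = 0.0; P_act = 0.0; }
      const double x = X(r, c);
      int code = 0;
      bool clipped_now = false, clipped_ever = false, pinned = false;
      for (int k = 0; k < n_substeps; ++k) {
        // EOM: command -> actual power
        double P_cmd = G_P * u;
        double target = P_cmd;
        if (eom_quad > 0.0 && P_cmd < eom_quad_thr)
          target += eom_quad * (P_cmd - eom_quad_thr) * (P_cmd - eom_quad_thr);
        P_act = (eom_tau > 0.0) ? target + (P_act - target) * eom_decay
                                : target;
        // excitation and detection
        double lam = x * std::pow(P_act, alpha) + dark_rate;
        double S = shot_noise ? R::rpois(lam) : lam;
        if (S >= S_sat) S = S_sat;
        // signal ADC
        code = (int) std::lround(G_S * S);
        clipped_now = code > S_max_code;
        if (clipped_now) code = S_max_code;
        clipped_ever = clipped_ever || clipped_now;
        // PID on the digitized error
        double e = S0_hat - (double) code;
        double I_cand = I + e * dt;
        double u_raw = Kp * e + Ki * I_cand + Kd * (e - e_prev) / dt;
        if (u_raw > P_max_code) {
          u = P_max_code;
          if (e < 0) I = I_cand;  // allow unwinding only
          pinned = true;
        } else if (u_raw < 0.0) {
          u = 0.0;
          if (e > 0) I = I_cand;
          pinned = false;
        } else {
          u = u_raw;
          I = I_cand;
          pinned = false;
        }
        e_prev = e;
      }
      S_hat(r, c) = code;
      clip(r, c) = code >= S_max_code;
      clip_any(r, c) = clipped_ever;
      mode(r, c) = pinned ? 1 : 0;
      P_final(r, c) = P_act;
      // photodiode measurement of the final actual power
      double meas = P_act;
      if (pd_sigma > 0.0) meas += R::rnorm(0.0, pd_sigma);
      long phat = std::lround(meas / G_P);
      if (phat < 1) phat = 1;
      if (phat > (long) P_max_code) phat = (long) P_max_code;
      P_hat(r, c) = (int) phat;
    }
  }
  return List::create(_["S_hat"] = S_hat, _["P_hat"] = P_hat,
                      _["mode"] = mode, _["clip"] = clip,
                      _["clip_any"] = clip_any, _["P_actual"] = P_final);
}
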