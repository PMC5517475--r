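---
title: "Active illumination: model, controller and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Active illumination: model, controller and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aiscope)
```

This vignette is the package's account of the science it simulates: the
physical model and its assumptions, the feedback controller and why it is
tuned the way it is, the fixed-point log encoder, the noise model behind the
SNR theory, and the places where the design was genuinely open and a choice
had to be made.

## Physical model

A pixel of sample strength $X$ (arbitrary emissivity units) excited at
normalized power $P$ yields a mean of $X P^\alpha$ detected photoelectrons
per dwell sub-sample, with $\alpha$ the excitation order (2 for two-photon,
3 for three-photon). The package expresses signals **in detected
photoelectrons**, so Poisson shot noise is literal rather than an additive
approximation, and takes the detector saturation at $S_{sat} = 250$
photoelectrons per dwell with the set point $S_0$ at half saturation by
default. Power is normalized so the conventional-imaging power $P_0$ and the
allowed maximum $P_{max}$ are both 1.

The detection chain is, per feedback sub-step:

1. **EOM** — first-order relaxation of actual power toward the command
   (time constant `eom_tau`, default 0 = ideal), with an optional weak
   quadratic response below a low-command threshold (`eom_quad`).
2. **Excitation/detection** — Poisson draw with mean $X P^\alpha$ plus dark
   counts, clipped at $S_{sat}$.
3. **Signal ADC** — gain $G_S = 2^{B_S}/S_{sat}$ ($B_S = 13$), rounding,
   clip to the code range (flagged).
4. **PID** — the error $\hat S_0 - \hat S$ in signal LSB drives the power
   DAC command (gain $G_P = P_{max}/2^{B_P}$, $B_P = 14$), clamped to
   $[0, 2^{B_P}]$.

The power measurement adds Gaussian photodiode noise `pd_sigma` **before**
its own digitization and floors the code at 1 LSB so the log encoding is
always defined. A single lumped `pd_sigma` stands in for everything that
limits knowledge of the power at low levels (digitization, EOM-control and
photodiode-electronics noise); no PMT multiplicative gain noise or
afterpulsing is modeled.

## The controller and its two gain profiles

With an (ideal) instantaneous EOM the plant seen by the controller is a
static quadratic nonlinearity; its small-signal gain at the operating point
scales as $\sqrt{X S_0}$, so it varies by a factor ~600 over an eight-decade
scene. Two consequences drove the controller design:

* **Integral-only control.** On a static plant a proportional term
  contributes a characteristic root $-g K_p$ (with $g$ the plant gain) that
  turns into a sustained period-2 limit cycle at high $X$; prototype traces
  showed exactly that. Both default profiles therefore use pure integral
  action ($K_p = K_d = 0$), with anti-windup by conditional integration (the
  integrator only accepts error of the unwinding sign while the output is
  clamped). $K_p$ and $K_d$ remain configurable.

* **Two profiles.** A discrete integral loop is stable for
  $K_i\,\Delta t \cdot g < 2$, so one fixed gain cannot both settle within
  half a dwell at moderate strengths and remain stable at $X \sim 10^7$.
  - `"standard"`: 32 sub-steps per dwell, $K_i \Delta t = 0.63$ — essentially
    deadbeat at $X = 10\,X_t$, the tuning point chosen for the settling
    requirement; stable for $X$ up to roughly $5\times10^3$.
  - `"hdr"`: 400 sub-steps per dwell — the update count of a 125 MS/s
    digitizer over a 3.2 µs dwell — with $K_i \Delta t = 0.011$, verified
    stable and free of final-sub-step clipping over full 10⁸:1 scenes.

  Pixels at the extreme bright end of an `"hdr"` scan may end a dwell before
  the loop has fully settled. That is deliberate and harmless: the encoded
  quantity is the ratio $X = S/P^\alpha$ of *measured* signal and *measured*
  power, which is correct whether or not $S$ reached $S_0$ — the property
  the ratio-invariance tests pin down (a well-tuned and a badly detuned loop
  reconstruct the same image to within quantization).

Power and PID state carry across adjacent raster pixels by default
(hardware-like continuity; `carry_state = FALSE` resets per pixel). The
settling tolerance for "holds $S_0$" is ±2 % of $S_0$, noise off.

## Log encoder and reconstruction

Both digitized signal and power pass through $B_L$-bit ($B_L = 13$) log₂
lookup tables quantized on a grid of step
$\log_2(\text{domain})/2^{B_L}$, scaled by $G_L = 2^{B_L}/B_S$, and offset by
$C = 2^{B_L}$:
$$\hat L_X = G_L(\log_2\hat S - \alpha \log_2 \hat P_{norm}) + C .$$

One normative convention deserves emphasis: the power log is taken of the
code **normalized to full scale**, $\hat P_{norm} = \hat P / 2^{B_P} \le 1$,
so $-\alpha\log_2\hat P_{norm} \ge 0$ and $\hat L_X \ge C$ always. Taken of
raw codes, no constant of size $2^{B_L}$ could prevent negative outputs at
high power, which would defeat the stated purpose of the offset (acquisition
electronics that reject negative inputs). The normalization contributes only
a constant, absorbed into the unknown global scale.

Re-digitization at the microscope bit depth $B = 12$ uses
$G_M = (2^B-1)/\hat L_{max}$ computed from the **configured bit depths**
($\hat L_{max} = G_L(B_S + \alpha B_P) + C$), never from the data, so
reconstruction $X \propto 2^{\hat{\hat L}_X/(G_L G_M)}$ is calibration-free
across frames. The intermediate DAC/re-ADC pair of a hardware path is
collapsed into this single quantization; it acts as a pure gain link and a
double quantization adds nothing testable.

`quantization_budget()` returns the worst-case deterministic error of the
encode–decode path in bits: half a LUT step for the signal table, half a
step times $\alpha$ for the power table, and half an output code of the
re-digitization — about 0.009 bits at the default depths. Reconstruction is
exact to this budget (tested exhaustively over a 64×64 code grid), and
reconstructed values are flagged as *relative*: the global factor is carried
as metadata, never silently normalized away, which is also why
$\Delta F/F_0$ computed on reconstructions is exact.

## SNR model

Propagating shot noise on $S$ and effective noise $\sigma_P$ on the measured
power through $X = S/P^\alpha$ at the steady state of each mode gives
$$\mathrm{SNR}_X = \left[\frac 1 S + \frac{\alpha^2\sigma_P^2}{P^2}\right]^{-1/2},$$
with $(S, P) = (X P_{max}^\alpha, P_{max})$ below the transition
$X_t = S_0/P_{max}^\alpha$ and $(S_0, (S_0/X)^{1/\alpha})$ above it.
$\sigma_P$ combines the configured photodiode noise with the power-LSB
quantization term $G_P/\sqrt{12}$ in quadrature. The roll-off landmark
$X_r$ is operationalized as the 3 dB point where the two noise terms are
equal: $P_r = \alpha\sigma_P\sqrt{S_0}$, $X_r = S_0/P_r^\alpha$ (about
$10^4$ at $S_0 = 125$, $\sigma_P = 0.005$). The conventional curve uses
$\mathrm{SNR} = S/\sqrt{S + \sigma_q^2}$ with the $B$-bit quantization
variance $\sigma_q^2 = (S_{sat}/2^B)^2/12$, valid up to
$X_{sat} = S_{sat}/P_0^\alpha$.

`monte_carlo_snr()` validates this against the **full pipeline** (feedback
dwell with shot and photodiode noise, encoding, re-digitization,
reconstruction). Each repetition is initialized at the deterministic
operating point of its strength and run with the `"hdr"` gains: the closed
form is a statement about the stationary dwell, and cold-start transients
are a property of the controller, not of the noise model under test. At
$10^4$ repetitions the empirical curves agree with theory to within ~2 %
across a grid spanning $X_t/100$ to $100\,X_t$.

## Synthetic scenes

**Structural scenes** emulate the qualitative anatomy the method targets —
bright disk somas (radius ~10 px), 2-px-wide dendrites laid down as
persistent random walks, and 1–2 px spines adjacent to dendrites — with
strength assignment chosen to exercise the full requested range with compact
structures: spines at the scene minimum, somas at the maximum, dendrites
log-uniform between. The absolute anchor `strength_min = 0.1`
photoelectrons/dwell at $P_{max}$ puts a 10⁸:1 scene's maximum at
$X = 10^7$, whose steady-state power command (~58 DAC LSB) is comfortably
representable. The requested max/min ratio is exact by construction. These
scenes are a stand-in, not a reproduction: real tissue statistics, 3-D
optics and scattering are out of scope, so passing tests demonstrate the
acquisition chain's properties, not anatomical realism.

**Functional movies** place non-overlapping disk ROIs on a dim background,
with resting strengths drawn log-uniformly (default 500–4000
photoelectrons/dwell at unit power, i.e. well into feedback-active range)
and per-ROI responses shaped by a difference-of-exponentials calcium kernel
(rise 0.1 s, decay 1 s — GCaMP3-like; configurable, never hard-coded). The
kernel is normalized to peak 1 **on the sampled frame grid**, so ground-truth
peak $\Delta F/F_0$ equals the drawn amplitude exactly by construction.
Amplitudes may be negative (suppressed cells) down to −1; the signed
extremum convention in `response_stats()` gives such cells negative peaks
and negative response SNR.

For paired AI-versus-conventional comparisons, the conventional power is
throttled for the **worst possible burst of the amplitude distribution**
(its upper bound, not the realized maximum): responses are unpredictable in
advance, which is precisely why fixed-power imaging must operate
conservatively. With that power, active illumination holds every resting
pixel at $S_0$ and yields lower resting $\Delta F/F_0$ noise and
right-shifted response-SNR distributions; the magnitude of the shift depends
on the scene's brightness spread and is not a universal constant.

## Numerical and interface choices

* **Occupied dynamic range** (`occupied_bits()`): histogram of log₂ values
  in 0.5-bit bins; span between the lowest and highest bin holding at least
  `min_count = 10` pixels. The count threshold is this package's
  operationalization of reading a span off a histogram while ignoring
  single-pixel tails.
* **Resting window**: recording start to 0.5 s before stimulus onset;
  response window: 5 s from onset. Both configurable.
* **Dark pixels**: a zero signal code is floored to 1 before the log
  (the table's floor rule), so background reconstructs at the encoder floor
  rather than being dropped.
* **TIFF I/O**: strength stacks are stored bit-exactly at 32-bit float
  precision (the float bit pattern in a 32-bit-per-sample TIFF); code maps
  as 16-bit, masks as 8-bit. Encoded frames carry a JSON sidecar with
  $G_M$, $G_L$, $C$ and $\alpha$ — the constants a later linearization
  needs.
* **Determinism**: every stochastic stage takes a seed; the compiled scan
  kernel draws from R's RNG, so a seed makes whole pipelines bit-identical,
  and run manifests record config and checksums sufficient to regenerate
  any output.

## Problem sizes

The shipped tests and the acceptance script use 256×256 structural scenes
(single frame, ~26 M feedback sub-steps, about a second of compute), 80×80 ×
55-frame functional movies, 10⁴ Monte-Carlo repetitions per strength at 20
strengths, and exhaustive 64×64 encoder code grids — sizes chosen so the
full suite reproduces every claim in minutes on one core while keeping all
Monte-Carlo tolerances at the few-percent level.

## Known limitations

The EOM lag is the only detector-side dynamic (no PMT response latency); PMT
gain fluctuations and excess noise are not modeled, so absolute SNR values
are upper bounds for photon-counting-quality detection. The supplementary
derivations behind the hardware's PID tuning and exact roll-off noise
weighting are not public; the controller here is representative and the
lumped `pd_sigma` stands in for the composite power-noise budget. Z-stacks
are independent planes; there is no scattering, bleaching, motion, or
segmentation — ROI extraction uses the generator's ground truth by design.
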