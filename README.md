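# aiscope

Simulation and analysis toolkit for **active-illumination (AI) multiphoton
microscopy**: per-pixel negative-feedback regulation of the excitation power,
log₂-encoded high-dynamic-range acquisition, post-hoc linear reconstruction,
closed-form and Monte-Carlo SNR analysis, and ΔF/F₀ functional-imaging
statistics — all on seeded synthetic scenes, so every figure-style result is
reproducible from a configuration and a seed.

## The problem and the method

A multiphoton microscope detects fluorescence `S = X·Pᵅ`, where `X` is the
per-pixel *sample strength* (everything contributing to local emissivity),
`P` the illumination power and `α` the excitation order (2 for two-photon).
With fixed power, scenes mixing bright somas and dim spines exceed what a
12-bit digitizer (4096:1) — or the detector itself — can span: bright pixels
saturate or dim pixels vanish.

Active illumination closes a loop around each pixel: a PID controller drives
the power so the detected signal holds a set point `S₀` (**feedback-active
mode**); when more than the allowed maximum `P_max` would be needed, the
power pins at `P_max` (**power-limited mode**). Either way the quantity of
interest is the ratio `X = S/Pᵅ`, computed from the *measured* signal and
power, so it stays correct even when the loop has not settled. The electronics
output a log₂ encoding

```
L̂_X = G_L · (log₂Ŝ − α·log₂P̂) + C,       G_L = 2^B_L / B_S,  C = 2^B_L,
```

built from `B_L`-bit lookup tables, re-digitized by the standard microscope
electronics at gain `G_M`; linear strength is recovered post hoc as
`X ∝ 2^(L̂̂_X / (G_L·G_M))`. The maximum dynamic-range gain over conventional
`B`-bit acquisition is `2^(αB−1)` — almost 10⁷ for two-photon at 12 bits.
The closed-form SNR of the chain is

```
SNR_X = [ 1/S + α²σ_P²/P² ]^(−1/2),
```

shot-noise-limited (`√S₀` plateau) until the power-measurement noise `σ_P`
dominates at the roll-off strength `X_r`; a conventional scan saturates at
`X_sat = S_sat/P₀ᵅ`, and the modes switch at `X_t = S₀/P_maxᵅ`.

## Worked example

Acquire a synthetic cortical scene spanning 10⁸:1 in brightness, with and
without active illumination:

```r
library(aiscope)
cfg   <- acquisition_config("hdr")          # 400 sub-steps/dwell, wide-range gains
noise <- noise_model(pd_sigma = 0.001)
scene <- make_structural_scene(c(256, 256), range_ratio = 1e8, seed = 42)
scene
#> <scene_map> 256 x 256, 44 structures, strengths [0.1, 1e+07]

frame <- scan_frame(scene, cfg, noise, mode = "ai", seed = 43)
frame
#> <frame_record> ai, 256 x 256, 96.1% power-limited, 0 clipped pixels
occupied_bits(reconstruct_frame(frame, cfg), min_count = 10)
#> [1] 31

conv <- scan_frame(scene, cfg, noise, mode = "conventional", seed = 44)
conv
#> <frame_record> conventional, 256 x 256, 0.0% power-limited, 2563 clipped pixels
occupied_bits(matrix(conv$S_hat[conv$S_hat > 0], ncol = 1), min_count = 10)
#> [1] 7.5
```

The AI acquisition captures the scene without a single saturated pixel and
occupies 31 bits of log-histogram span (the 10⁸ ground-truth range is 26.6
bits); the conventional scan clips 2563 pixels and is confined within its
12-bit code range. The SNR landmarks under the default settings:

```r
glance(snr_curve(acquisition_config(), noise_model(pd_sigma = 0.005)))
#> # A tibble: 1 × 5
#>   X_sat   X_t    X_r plateau_snr dynamic_range_gain
#>   <dbl> <dbl>  <dbl>       <dbl>              <dbl>
#> 1   250   125 10000.        11.2            8388608
```

`autoplot()` methods draw the scene, the reconstruction, the SNR curve and
activity maps; `monte_carlo_snr()` validates the closed form against the full
simulated pipeline; `make_functional_scene()` / `scan_movie()` /
`response_stats()` carry the calcium-imaging analysis (ΔF/F₀ traces,
activity maps, clip masks, response SNR = peak ΔF/F₀ over resting SD).

A command-line front end wraps the same functions:

```sh
Rscript inst/cli/aiscope simulate-structural --range 1e8 --seed 7 --out out/
Rscript inst/cli/aiscope snr-curve --out out/
```

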