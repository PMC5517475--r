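# shared fixtures: everything is generated in code at test time

noise_off <- function() noise_model(shot_noise = FALSE, pd_sigma = 0)

cfg_std <- function(...) acquisition_config("standard", ...)
cfg_hdr <- function(...) acquisition_config("hdr", ...)

# small structural scene used by several files
tiny_scene <- function(range_ratio = 1e4, seed = 5, shape = c(64, 64),
                       strength_min = 0.25) {
  make_structural_scene(shape, range_ratio = range_ratio, seed = seed,
                        counts = c(soma = 2, dendrite = 4, spine = 12),
                        strength_min = strength_min)
}

# conventional linear strength estimate from a conventional frame_record
conventional_linear <- function(fr, cfg) {
  (fr$S_hat / ((2^cfg$B - 1) / cfg$S_sat)) / fr$P0^cfg$alpha
}
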