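# Shared fixtures: small scenes keep renders fast while preserving the
# default geometry (sponge box at 10% margins, same colours and optics).

small_scene <- function(size = 96L, noise_sd = 0.008, texture_amp = 0.03,
                        ...) {
  scene_params(image_height = size, image_width = size, noise_sd = noise_sd,
               texture_amp = texture_amp, ...)
}

# A clean render with a mid-range sample, reused across detection and
# feature tests.
render_fixture <- function(concentration = 120, volume = 1.5, size = 96L,
                           seed = 7L, ...) {
  render_sponge_image(blood_sample(concentration, volume),
                      small_scene(size, ...), seed = seed)
}
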