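# Shared fixtures, built once per test session and cached.

.fixtures <- new.env(parent = emptyenv())

get_fixture <- function(name, build) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, build(), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

# a small grid that still holds the full anatomy (FOV 192 x 192 x 96 mm)
tiny_shape <- c(48, 48, 12)
tiny_spacing <- c(4, 4, 8)

# phantom with every degradation switched off; individual knobs can be
# re-enabled through ...
null_config <- function(seed = 1, ...) {
  args <- utils::modifyList(
    list(shape = tiny_shape, spacing = tiny_spacing, seed = seed,
         noise_scale = 0, outline_jitter_mm = 0,
         n_air_pockets_common = 0, n_air_pockets_transient = 0,
         cbct_distortion = cbct_distortion_params(
           global_shift_HU = 0, compression = 1,
           cupping_amplitude_HU = 0, noise_sd_HU = 0),
         sct_error = sct_error_params(0, 0, 0)),
    list(...))
  do.call(phantom_config, args)
}

tiny_null_case <- function() {
  get_fixture("tiny_null_case", function() generate_case(null_config()))
}

# default-noise case on the standard grid (used by several modules)
default_case <- function() {
  get_fixture("default_case", function() {
    generate_case(phantom_config(seed = 42))
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
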