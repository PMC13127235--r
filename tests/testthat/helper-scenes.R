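# Small scene configurations shared across test files. Fixtures are always
# generated in code; nothing binary ships with the package.

tiny_config <- function(..., seed = 42) {
  scene_config(ny = 2, nx = 2, years = 2000, seed = seed, ...)
}

# A clean (noise- and contamination-free) single-pixel config with flat
# spatial structure, for exact-identity checks.
clean_config <- function(..., seed = 42) {
  scene_config(ny = 1, nx = 1, years = 2000,
               noise_sd = 0, cloud_prob = 0, snow_prob = 0,
               truth = list(jitter_sd = 0, sos_gradient = 0,
                            eos_gradient = 0, mx_gradient = 0),
               seed = seed, ...)
}

# Default Beck parameter set used in many closed-form checks.
beck_ref <- list(mn = 0.1, mx = 0.6, sos = 130, rsp = 0.2,
                 eos = 280, rau = 0.1)

# Random well-separated Beck parameters inside the oracle's validity
# domain (rates not too shallow relative to the season span, so the OLS
# plateau line stays within ~1 day of the maxline geometry).
random_separated_params <- function(n) {
  data.frame(mn = runif(n, 0, 0.2),
             mx = runif(n, 0.3, 0.8),
             sos = runif(n, 100, 140),
             rsp = runif(n, 0.12, 0.4),
             eos = runif(n, 260, 320),
             rau = runif(n, 0.12, 0.4))
}
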