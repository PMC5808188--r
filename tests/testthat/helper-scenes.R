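# Shared fixtures, built in code and cached per test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# default-world scene at reduced size (fast; same statistical structure)
small_scene <- function() {
  cached("small", simulate_scene(scene_spec(rows = 100, cols = 100, rng_seed = 11)))
}

# deterministic noise-free world: zero sensor noise, zero within-class spread
clean_scene <- function() {
  cached("clean", simulate_scene(scene_spec(rows = 60, cols = 60,
                                            class_sd = rep(0, 4),
                                            sensor_noise_sd = 0,
                                            rng_seed = 5)))
}

# constant-value scene helper
flat_scene <- function(value, rows = 10, cols = 10, bands = c(475, 555, 658),
                       stage = "surface_R") {
  v <- array(rep(value, each = rows * cols, length.out = rows * cols * length(bands)),
             dim = c(rows, cols, length(bands)))
  reflectance_scene(v, bands = bands, stage = stage)
}

# independent quadratic evaluator (oracle; deliberately not the package's)
eval_poly_oracle <- function(coefs, x) coefs[1] * x^2 + coefs[2] * x + coefs[3]

expect_same_matrix <- function(a, b, tol = 0) {
  expect_true(all(dim(a) == dim(b)))
  expect_lte(max(abs(a - b)), tol)
}
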