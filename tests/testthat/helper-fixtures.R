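# Fixtures shared across test files.  The texture-model fit is expensive
# (dictionary learning), so it is computed once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# Training phantoms used by the fitted-model fixtures (the study's training
# set: two slices with the default geometry, texture contrast and gray zone).
training_phantoms <- function() {
  cached("training_phantoms",
         lapply(c(101L, 102L), function(s) generate_phantom(phantom_spec(seed = s))))
}

texture_fit <- function() {
  cached("texture_fit", scar_model(training_phantoms(), feature = "texture"))
}

dc_fit <- function() {
  cached("dc_fit", scar_model(training_phantoms(), feature = "dc"))
}

test_phantoms <- function(n = 10L) {
  cached(paste0("test_phantoms_", n),
         lapply(seq_len(n), function(s) generate_phantom(phantom_spec(seed = s))))
}

# Fraction of defined map values with posterior strictly inside (0.1, 0.9).
intermediate_fraction <- function(map) {
  v <- unclass(map)[!is.na(map)]
  mean(v > 0.1 & v < 0.9)
}
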