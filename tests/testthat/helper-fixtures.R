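# Shared fixtures. The desk-scale experiment is expensive, so it is trained
# once per test run and cached for every test that needs a trained ensemble.

.fixture_cache <- new.env(parent = emptyenv())

desk_config <- function(seed = 42L) run_config(seed = seed)

cached_desk <- function() {
  if (is.null(.fixture_cache$desk))
    .fixture_cache$desk <- desk_experiment(desk_config())
  .fixture_cache$desk
}

# Tiny cubic phantom for fast structural tests.
tiny_spec <- function(seed = 1L, grid = 16L, ...) {
  phantom_spec(grid_shape = grid, spacing_mm = 128 / grid, seed = seed, ...)
}

tiny_cohort <- function(n = 5L, seed = 7L, grid = 16L) {
  vols <- lapply(seq_len(n), function(i)
    generate_phantom(tiny_spec(seed = 100L + i, grid = grid)))
  names(vols) <- sprintf("s%02d", seq_len(n))
  vols
}

random_binary <- function(dim, p = 0.5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  array(as.integer(runif(prod(dim)) < p), dim = dim)
}
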