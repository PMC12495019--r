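# Small phantom configurations shared across test files. Sizes are reduced
# relative to the package defaults so the unit suite stays fast; the
# acceptance tests use the full default conditions.

small_truth <- function(seed, ...) {
  phantom_truth(shape = c(96L, 96L), n_cells = 12L, nucleus_radius = 5,
                n_slices = 9L, seed = seed, ...)
}

small_stack <- function(seed, noise = c(10, 0), ...) {
  render_stack(small_truth(seed, ...), noise = noise)
}
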