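# Small fixtures shared across the suite. Everything is generated in code;
# sizes are kept tiny so the whole suite runs in minutes.

small_bank <- function() gabor_bank(2, 4, base_frequency = 0.25)

# A reduced 4-Layer network: 16 x 16 Layers on a 32 x 32 retina.
small_specs <- function(rule = "trace", sparseness = 0.05, eta = 0.8,
                        alpha = c(0.1, 0.1, 0.1, 0.1)) {
  default_layer_specs(sparseness_target = sparseness, rule = rule,
                      alpha = alpha, eta = eta, scale = 0.5)
}

small_network <- function(seed = 1, rule = "trace", sparseness = 0.05) {
  visnet_network(c(32, 32), small_bank(),
                 small_specs(rule = rule, sparseness = sparseness),
                 seed = seed)
}

# A bar image: vertical bright bar on dark ground.
bar_image <- function(n = 32, col0 = 14, width = 3) {
  im <- matrix(0, n, n)
  im[, col0:(col0 + width - 1)] <- 1
  im
}

# Tiny two-object stimulus set for fast training tests.
tiny_views <- function(seed = 3, canvas = 32) {
  render_catastrophic_views(2, 2, seed = seed, canvas = canvas)
}
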