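# Small deterministic fixtures shared across test files.

tiny_spec <- function(seed = 1L, ...) {
  args <- list(n_classes = 3L, image_side = 6L, prototype_overlap = 0,
               within_class_noise_sd = 10, translation_jitter = 0L,
               seed = seed)
  args[names(list(...))] <- list(...)
  do.call(synthetic_spec, args)
}

tiny_dataset <- function(n = 120L, seed = 1L, ...) {
  generate_synthetic_digits(tiny_spec(seed = seed, ...), n)
}

# a fresh untrained network state matched to a dataset
tiny_net <- function(data, C = 6L, epsilon = 0.05, seed = 1L, ...) {
  cfg <- network_config(D = ncol(data$images), C = C, K = data$n_classes,
                        epsilon = epsilon, seed = seed, ...)
  neurohebb:::new_hebbnet(cfg)
}
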