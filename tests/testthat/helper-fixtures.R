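# Shared fixtures.  Small phantoms (48 px, 24 slices) keep the suite fast;
# models are trained lazily once per run and reused across test files.

fixture_cache <- new.env(parent = emptyenv())

tiny_phantom_config <- function(seed = 7L) {
  phantom_config(n_slices = 24L, slice_size = 48L, artifact_margin = 3L,
                 boundary_fraction_range = c(0.35, 0.65), lesion_prob = 0.6,
                 seed = seed)
}

cached <- function(key, expr) {
  if (!exists(key, envir = fixture_cache)) {
    assign(key, force(expr), envir = fixture_cache)
  }
  get(key, envir = fixture_cache)
}

tiny_dataset <- function() {
  cached("tiny_dataset", generate_dataset(8, tiny_phantom_config(), 0.5))
}

# A quickly trained classifier on the tiny phantoms (48 px input).
tiny_classifier <- function() {
  cached("tiny_classifier", {
    ds <- tiny_dataset()
    td <- slice_training_data(ds[1:6], margin = 3)
    train_slice_classifier(
      td$slices, td$labels,
      classifier_config(input_size = 48L, epochs = 10L,
                        learning_rate = 0.01, seed = 11L)
    )
  })
}

# A quickly trained weighted segmenter on fixed 24-px central patches.
tiny_segmenter <- function() {
  cached("tiny_segmenter", {
    ds <- tiny_dataset()
    patches <- list()
    for (i in 1:6) {
      sc <- ds[[i]]
      for (s in sc$boundary_index:(24 - 3)) {
        patches <- c(patches,
                     extract_fixed_patches(sc$stack$slices[, , s],
                                           sc$masks[, , s], size = 24L))
      }
    }
    train_segmenter(patches, seg_config(epochs = 6L, seed = 11L))
  })
}

random_mask <- function(n, p = 0.3, seed = 1) {
  set.seed(seed)
  matrix(rbinom(n * n, 1, p), n, n)
}
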