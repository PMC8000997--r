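# Shared fixtures built in code.

# A small annotated synthetic record with both beat classes.
make_record <- function(n_beats = 40, pattern = "bigeminy", seed = 11,
                        noise = noise_spec(seed = seed)) {
  generate_record(n_beats, rhythm_spec(pattern), noise = noise)
}

# A small normalized heartbeat set ready for training.
make_beats <- function(n_beats = 40, pattern = "bigeminy", seed = 11) {
  rec <- make_record(n_beats, pattern, seed)
  normalize_beats(extract_beats(rec$record, rec$annotations))
}

# A deliberately tiny embedder for fast training in tests.
tiny_embedder_config <- function(pool = "max") {
  embedder_config(channels = c(2, 2, 4, 4, 4, 4, 4, 4),
                  kernel_sizes = c(17, 9, 9, 5, 5, 3, 3, 3), pool = pool)
}

# Random labelled embeddings for miner/KNN oracle checks.
random_embeddings <- function(n, dim, n_classes = 2) {
  E <- matrix(rnorm(n * dim), n, dim)
  labels <- sample(letters[seq_len(n_classes)], n, replace = TRUE)
  list(E = E, labels = labels)
}
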