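# Shared fixtures: small configurations keep unit tests fast; the
# acceptance tests scale up where a criterion demands it.

tiny_config <- function(...) {
  herd_config(n_pigs_per_sex = 2, n_replications = 2, ...)
}

# single noise-free gilt: the deterministic reference world
det_gilt_config <- function(...) {
  herd_config(sexes = "gilt", n_pigs_per_sex = 1, n_replications = 1,
              noise_cv = 0, bw_initial_sd = 0, ...)
}

# independent textbook r^2 via explicit sums of squares
r2_oracle <- function(x, y) {
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  sxy^2 / (sum((x - mean(x))^2) * sum((y - mean(y))^2))
}
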