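# Shared fixtures, built in code and memoised for the session.

.fixture_env <- new.env(parent = emptyenv())

# default noisy 56-experiment world (40 train / 16 test)
shared_set <- function() {
  if (is.null(.fixture_env$set)) {
    .fixture_env$set <- generate_dataset(n = 56, seed = 1)
  }
  .fixture_env$set
}

# small noiseless world for oracle checks
noiseless_set <- function() {
  if (is.null(.fixture_env$set0)) {
    .fixture_env$set0 <- generate_dataset(n = 20, n_test = 5, noise_sd = 0,
                                          seed = 2)
  }
  .fixture_env$set0
}

# a random canonical vector: n observed positive samples, zero padding
random_canonical <- function(n_obs) {
  v <- c(runif(n_obs, 0.01, 0.6), rep(0, CANONICAL_LENGTH - n_obs))
  canonical_vector(v, n_observed = n_obs)
}

# brute-force termination scan (independent of detect_termination)
brute_termination <- function(v, threshold = 0.02) {
  peak <- which(v == max(v))[1]
  for (i in seq_along(v)) {
    if (i > peak && v[i] < threshold) return(i)
  }
  NA_integer_
}
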