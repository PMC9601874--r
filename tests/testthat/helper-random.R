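# Seeded random fixtures used across the suite.

# Random SPD matrix with log-uniform spectrum and condition number <= cond_max.
rand_spd <- function(n, cond_max = 1e4, scale = 1) {
  half <- sqrt(cond_max)
  lam <- exp(stats::runif(n, log(scale / half), log(scale * half)))
  O <- qr.Q(qr(matrix(stats::rnorm(n * n), n)))
  O %*% diag(lam, n) %*% t(O)
}

rand_sym <- function(n, sd = 1) {
  A <- matrix(stats::rnorm(n * n, sd = sd), n)
  (A + t(A)) / 2
}

rand_orthogonal <- function(n) qr.Q(qr(matrix(stats::rnorm(n * n), n)))

# A synthetic test record with planted R peaks, returned with ground truth.
planted_record <- function(n_beats = 5, seed = 1, noise_sd = 0.02) {
  generate_record(c("N" = n_beats), seed = seed, noise_sd = noise_sd)
}
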