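# Brute-force approximate entropy: explicit embedding matrices and an
# all-pairs Chebyshev distance scan.  Deliberately naive and independent
# of the package's compiled implementation.
apen_oracle <- function(x, m, tau, r) {
  phi <- function(mm) {
    N <- length(x)
    M <- N - (mm - 1) * tau
    emb <- matrix(0, nrow = M, ncol = mm)
    for (k in seq_len(mm)) emb[, k] <- x[(seq_len(M)) + (k - 1) * tau]
    logs <- numeric(M)
    for (i in seq_len(M)) {
      d <- apply(abs(sweep(emb, 2, emb[i, ], "-")), 1, max)
      logs[i] <- log(sum(d <= r) / M)
    }
    mean(logs)
  }
  phi(m) - phi(m + 1)
}

# Fractional Gaussian noise by spectral synthesis: power spectrum
# ~ f^-(2H - 1), so DFA of the result should scale with alpha = H.
fgn_spectral <- function(n, H) {
  beta <- 2 * H - 1
  w <- stats::rnorm(n)
  X <- stats::fft(w)
  k <- 0:(n - 1)
  fk <- pmin(k, n - k) / n
  s <- ifelse(fk > 0, fk^(-beta / 2), 0)
  x <- Re(stats::fft(X * s, inverse = TRUE)) / n
  (x - mean(x)) / stats::sd(x)
}

# Small helper: replicate lists of generated series for one class.
make_series_group <- function(treatment, tissue, phase, n, seed0,
                              duration_s = 1200) {
  lapply(seq_len(n), function(r) {
    generate_electrome(
      electrome_gen_params(duration_s = duration_s, seed = seed0 + r * 1000L),
      stimulus_scenario(treatment, tissue), phase)
  })
}
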