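# shared fixtures and independent oracles, built in code at test time

# brute-force Higuchi curve length: explicit double loop straight from the
# defining equations, kept independent of the package's vectorized path
brute_higuchi_L <- function(x, k) {
  n <- length(x)
  Lt <- numeric(k)
  for (t0 in 1:k) {
    m <- floor((n - t0) / k)
    if (m < 1) next
    s <- 0
    for (i in 1:m) s <- s + abs(x[t0 + i * k] - x[t0 + (i - 1) * k])
    Lt[t0] <- (1 / k) * s * (n - 1) / (m * k)
  }
  sum(Lt) / k
}

# fractional Gaussian noise by Davies-Harte circulant embedding;
# cumsum() of it is fractional Brownian motion with Hurst exponent H
fgn_davies_harte <- function(n, H) {
  g <- function(h) 0.5 * ((abs(h) + 1)^(2 * H) - 2 * abs(h)^(2 * H) +
                            abs(abs(h) - 1)^(2 * H))
  gam <- g(0:n)
  lam <- Re(fft(c(gam, rev(gam[2:n]))))
  lam[lam < 0] <- 0
  m <- 2 * n
  W <- complex(length.out = m)
  W[1] <- sqrt(lam[1]) * rnorm(1)
  W[n + 1] <- sqrt(lam[n + 1]) * rnorm(1)
  u <- rnorm(n - 1); v <- rnorm(n - 1)
  W[2:n] <- sqrt(lam[2:n] / 2) * complex(real = u, imaginary = v)
  W[m:(n + 2)] <- Conj(W[2:n])
  Re(fft(W))[1:n] / sqrt(m)
}

cosine_sim <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))

# greedy permutation matching of estimated to true module columns by cosine
# similarity (scale-invariant, so the NMF scale indeterminacy drops out)
match_modules <- function(W_est, W_true) {
  stopifnot(ncol(W_est) == ncol(W_true))
  r <- ncol(W_true)
  S <- outer(seq_len(r), seq_len(r),
             Vectorize(function(i, j) cosine_sim(W_est[, i], W_true[, j])))
  sims <- numeric(r)
  for (step in seq_len(r)) {
    idx <- which(S == max(S), arr.ind = TRUE)[1, ]
    sims[step] <- S[idx[1], idx[2]]
    S[idx[1], ] <- -Inf
    S[, idx[2]] <- -Inf
  }
  mean(sims)
}

# a small raw_emg fixture: sinusoids of distinct frequencies per muscle
toy_raw_emg <- function(duration = 2, fs = 2000) {
  time <- seq(0, duration, by = 1 / fs)
  ch <- sapply(seq_along(SYNERGAIT_MUSCLES),
               function(i) sin(2 * pi * (60 + 10 * i) * time))
  colnames(ch) <- SYNERGAIT_MUSCLES
  raw_emg(time, ch)
}

# an emg_envelope built directly from given channel values
toy_envelope <- function(channels, fs = 2000) {
  time <- seq_len(nrow(channels)) / fs
  env <- as.data.frame(channels)
  structure(list(time = time, channels = env, fs = fs),
            class = "emg_envelope")
}
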