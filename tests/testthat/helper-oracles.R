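# Independent oracles and small fixture builders used across the suite.
# Every oracle is a direct, brute-force computation kept deliberately
# separate from the implementation path it checks.

# High-precision log binomial tail/pmf: log-sum-exp over exact term logs
# built from lchoose, independent of pbinom's incomplete-beta route.
oracle_ln_binomial <- function(n, p, k, mode = "tail") {
  i <- if (mode == "tail") k:n else k
  lt <- lchoose(n, i) + i * log(p) + (n - i) * log1p(-p)
  m <- max(lt)
  m + log(sum(exp(lt - m)))
}

# Brute-force weighted local clustering: explicit loop over ordered triples.
oracle_clustering <- function(W) {
  N <- nrow(W)
  s <- W / max(W)
  out <- numeric(N)
  for (i in seq_len(N)) {
    acc <- 0
    for (j in seq_len(N)) for (h in seq_len(N)) {
      if (j == i || h == i || j == h) next
      acc <- acc + (s[i, j] * s[i, h] * s[j, h])^(1 / 3)
    }
    out[i] <- acc / ((N - 1) * (N - 2))
  }
  out
}

# Brute-force strength centrality: per-node explicit sum.
oracle_strength <- function(W) {
  vapply(seq_len(nrow(W)), function(i) sum(W[i, -i]), numeric(1))
}

# Brute-force absolute Pearson correlation between rows of Z.
oracle_abs_corr <- function(Z) {
  N <- nrow(Z)
  W <- matrix(0, N, N)
  for (j in seq_len(N)) for (k in seq_len(N)) {
    if (j == k) next
    x <- Z[j, ]; y <- Z[k, ]
    W[j, k] <- abs(sum((x - mean(x)) * (y - mean(y))) /
                     sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2)))
  }
  W
}

# Brute-force strongest link: exhaustive scan over all pairs.
oracle_strongest <- function(W) {
  best <- c(1L, 2L); bw <- -Inf
  N <- nrow(W)
  for (j in seq_len(N - 1)) for (k in (j + 1):N) {
    if (W[j, k] > bw) { bw <- W[j, k]; best <- c(j, k) }
  }
  best
}

# Random symmetric weight matrix in [0,1] with zero diagonal.
rand_net <- function(N) {
  W <- matrix(0, N, N)
  W[upper.tri(W)] <- runif(N * (N - 1) / 2)
  W <- W + t(W)
  diag(W) <- 0
  W
}

# A dynamic_networks object from a hand-built list of weight matrices.
make_series <- function(nets, subject_id = "manual") {
  N <- nrow(nets[[1]])
  structure(list(subject_id = subject_id,
                 window_spec = structure(list(window_ms = NA_real_,
                                              window_samples = 2L,
                                              n_windows = length(nets)),
                                         class = "window_spec"),
                 channel_labels = paste0("ch", seq_len(N)),
                 networks = nets),
            class = "dynamic_networks")
}

# A weight matrix whose strongest link is exactly `pair` (weight 1).
net_with_strongest <- function(N, pair) {
  W <- matrix(0.1, N, N)
  diag(W) <- 0
  W[pair[1], pair[2]] <- W[pair[2], pair[1]] <- 1
  W
}

# Small noise recording, seeded.
noise_recording <- function(N = 4, l = 200, rate = 500, seed = 1) {
  set.seed(seed)
  recording(matrix(rnorm(N * l), nrow = N), rate,
            subject_id = paste0("noise", seed))
}
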