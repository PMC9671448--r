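# shared fixtures and independent oracles for the suite

random_points <- function(n, extent = 100, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  data.frame(x = runif(n, 0, extent), y = runif(n, 0, extent))
}

# brute-force pairwise distances, one scalar at a time
dist_oracle <- function(a, b) {
  out <- matrix(0, nrow(a), nrow(b))
  for (i in seq_len(nrow(a)))
    for (j in seq_len(nrow(b)))
      out[i, j] <- sqrt((a$x[i] - b$x[j])^2 + (a$y[i] - b$y[j])^2)
  out
}

# textbook sort-based Benjamini-Hochberg adjustment
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

# double-sum Moran's I
moran_oracle <- function(values, W) {
  n <- length(values)
  z <- values - mean(values)
  S0 <- sum(W)
  acc <- 0
  for (i in seq_len(n))
    for (j in seq_len(n))
      acc <- acc + W[i, j] * z[i] * z[j]
  (n / S0) * acc / sum(z^2)
}

# term-by-term Gi* z-scores
gi_star_oracle <- function(values, W) {
  n <- length(values)
  xbar <- mean(values)
  S <- sqrt(sum(values^2) / n - xbar^2)
  z <- numeric(n)
  for (i in seq_len(n)) {
    Wi <- sum(W[i, ])
    num <- sum(W[i, ] * values) - xbar * Wi
    den <- S * sqrt((n * sum(W[i, ]^2) - Wi^2) / (n - 1))
    z[i] <- num / den
  }
  z
}

dense_weights <- function(w) {
  W <- matrix(0, w$n, w$n)
  for (i in seq_len(w$n)) W[i, w$neighbors[[i]]] <- w$weights[[i]]
  W
}

# a small three-level dataset for sampler tests
small_simdata <- function(seed = 7, beta_edu = 1, s2c = 0.5, s2r = 0.5,
                          regions = 6, cpr = 20, wpc = 10, intercept = -1) {
  cfg <- sim_config(n_regions = regions,
                    clusters_per_region = rep(cpr, regions),
                    women_per_cluster = wpc,
                    fixed_effects = c(intercept = intercept,
                                      education = beta_edu),
                    sigma2_cluster = s2c, sigma2_region = s2r, seed = seed)
  simulate_population(cfg)
}
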