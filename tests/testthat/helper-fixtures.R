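# Shared fixtures built in code; everything is seed-fixed.

small_world <- function(seed = 3, ...) {
  cfg <- synthetic_config(n_genera = 40, n_weeks = 120, n_clusters = 4,
                          n_spurious_genera = 6, seed = seed, ...)
  truth <- make_community(cfg)
  counts <- sample_reads(truth, cfg)
  list(cfg = cfg, truth = truth, counts = counts)
}

random_composition <- function(d, n, seed = 1) {
  set.seed(seed)
  m <- matrix(rgamma(d * n, shape = 2), d, n,
              dimnames = list(sprintf("g%02d", 1:d), sprintf("w%03d", 1:n)))
  airedna:::composition_matrix(sweep(m, 2, colSums(m), "/"))
}

# independent oracle: exact two-sided signed-rank p by enumerating all 2^n
# sign assignments of the absolute differences
signed_rank_p_enum <- function(d) {
  stopifnot(all(d != 0), !anyDuplicated(abs(d)))
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- expand.grid(rep(list(c(0, 1)), n))
  w_all <- as.matrix(signs) %*% r
  p_low <- mean(w_all <= w_obs)
  p_high <- mean(w_all >= w_obs)
  min(1, 2 * min(p_low, p_high))
}

# independent oracle: joint-Gaussian log density of a short series under a
# structural trend model, built from the state recursions
joint_gaussian_loglik <- function(y, trend, s_obs, s_level, s_slope,
                                  a1 = c(y[1], 0), P1 = diag(c(1e4, 1e2))) {
  n <- length(y)
  Tm <- matrix(c(1, 0, 1, 1), 2, 2)
  Q <- diag(c(if (trend == "irw") 0 else s_level, s_slope))
  Z <- matrix(c(1, 0), 1, 2)
  # mean and covariance of the stacked states
  means <- vector("list", n)
  P <- vector("list", n)
  means[[1]] <- a1
  P[[1]] <- P1
  for (t in 2:n) {
    means[[t]] <- Tm %*% means[[t - 1]]
    P[[t]] <- Tm %*% P[[t - 1]] %*% t(Tm) + Q
  }
  C <- matrix(0, n, n)
  mu <- numeric(n)
  for (t in 1:n) {
    mu[t] <- Z %*% means[[t]]
    for (u in t:n) {
      cross <- P[[t]]
      if (u > t) {
        for (s in (t + 1):u) cross <- cross %*% t(Tm)
      }
      C[t, u] <- Z %*% cross %*% t(Z)
      C[u, t] <- C[t, u]
    }
  }
  C <- C + diag(s_obs, n)
  -0.5 * (n * log(2 * pi) + determinant(C)$modulus +
            t(y - mu) %*% solve(C, y - mu))
}

# Rayleigh test p-value for circular uniformity of bearings (degrees)
rayleigh_p <- function(bearings) {
  th <- bearings * pi / 180
  n <- length(th)
  rbar <- sqrt(mean(cos(th))^2 + mean(sin(th))^2)
  z <- n * rbar^2
  exp(-z) * (1 + (2 * z - z^2) / (4 * n))
}
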