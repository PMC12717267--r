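#' Great-circle distance
#'
#' Haversine distance on a spherical Earth (radius 6371 km). Inputs are
#' decimal degrees; vectors are recycled.
#'
#' @param lat1,lon1,lat2,lon2 Coordinates in decimal degrees.
#' @return Distance in kilometres.
#' @export
haversine_km <- function(lat1, lon1, lat2, lon2) {
  r <- 6371
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad
  dlon <- (lon2 - lon1) * to_rad
  a <- sin(dlat / 2)^2 +
    cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon / 2)^2
  2 * r * asin(pmin(1, sqrt(a)))
}

#' Initial great-circle bearing
#'
#' Bearing from point 1 towards point 2, degrees clockwise from north in
#' `[0, 360)`.
#'
#' @inheritParams haversine_km
#' @return Bearing in degrees.
#' @export
bearing_deg <- function(lat1, lon1, lat2, lon2) {
  to_rad <- pi / 180
  phi1 <- lat1 * to_rad
  phi2 <- lat2 * to_rad
  dl <- (lon2 - lon1) * to_rad
  y <- sin(dl) * cos(phi2)
  x <- cos(phi1) * sin(phi2) - sin(phi1) * cos(phi2) * cos(dl)
  (atan2(y, x) / to_rad) %% 360
}

# destination point given start, bearing (deg) and distance (km) on a sphere
destination_point <- function(lat, lon, bearing, dist_km) {
  r <- 6371
  to_rad <- pi / 180
  delta <- dist_km / r
  theta <- bearing * to_rad
  phi1 <- lat * to_rad
  lam1 <- lon * to_rad
  phi2 <- asin(sin(phi1) * cos(delta) + cos(phi1) * sin(delta) * cos(theta))
  lam2 <- lam1 + atan2(
    sin(theta) * sin(delta) * cos(phi1),
    cos(delta) - sin(phi1) * sin(phi2)
  )
  list(lat = phi2 / to_rad, lon = ((lam2 / to_rad + 540) %% 360) - 180)
}

#' Adjusted Rand index
#'
#' Chance-corrected agreement between two partitions of the same items, used
#' to score recovery of planted cluster structure.
#'
#' @param a,b Cluster label vectors of equal length.
#' @return Numeric scalar; 1 means identical partitions, 0 is the expected
#'   agreement of independent labellings.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / comb2(n)
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}

# numerically stable log-mean-exp over a vector
log_mean_exp <- function(x) {
  m <- max(x)
  m + log(mean(exp(x - m)))
}

# geometric mean of strictly positive values
gmean <- function(x) exp(mean(log(x)))

# run an expression with a locally-set RNG seed, restoring the prior state
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    }
    set.seed(seed)
    on.exit({
      if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    })
  }
  force(expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# effective sample size from the initial positive sequence of autocorrelations
ess_mean <- function(x) {
  n <- length(x)
  if (n < 10 || sd(x) == 0) return(n)
  rho <- acf(x, lag.max = min(n - 1, 200), plot = FALSE)$acf[-1]
  s <- 0
  for (k in seq_along(rho)) {
    if (rho[k] < 0) break
    s <- s + rho[k]
  }
  n / (1 + 2 * s)
}

# Geweke convergence z-score: compare means of the first `frac1` and last
# `frac2` segments, variances estimated per segment from ESS-corrected SEs.
geweke_z <- function(x, frac1 = 0.1, frac2 = 0.5) {
  n <- length(x)
  x1 <- x[seq_len(max(2, floor(frac1 * n)))]
  x2 <- x[seq.int(n - max(2, floor(frac2 * n)) + 1, n)]
  se1 <- sd(x1) / sqrt(ess_mean(x1))
  se2 <- sd(x2) / sqrt(ess_mean(x2))
  denom <- sqrt(se1^2 + se2^2)
  if (denom == 0) return(0)
  (mean(x1) - mean(x2)) / denom
}
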