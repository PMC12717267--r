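#' Trigonometric seasonal regressors
#'
#' Builds the 2k-column matrix of seasonal harmonics
#' \eqn{\sin(2\pi k t / P), \cos(2\pi k t / P)} for `k = 1..n_harmonics`;
#' with the defaults, six columns at the mean length of a tropical year in
#' weeks.
#'
#' @param weeks Numeric week indices.
#' @param n_harmonics Number of harmonics (default 3).
#' @param period Period in weeks (default 52.18).
#' @return Matrix with columns `sin1, cos1, ...`.
#' @export
seasonal_regressors <- function(weeks, n_harmonics = 3, period = 52.18) {
  out <- matrix(0, length(weeks), 2 * n_harmonics)
  cn <- character(2 * n_harmonics)
  for (k in seq_len(n_harmonics)) {
    w <- 2 * pi * k * weeks / period
    out[, 2 * k - 1] <- sin(w)
    out[, 2 * k] <- cos(w)
    cn[2 * k - 1] <- paste0("sin", k)
    cn[2 * k] <- paste0("cos", k)
  }
  colnames(out) <- cn
  out
}

#' Specify a structural state-space model
#'
#' Gaussian structural time-series model: observation = latent trend +
#' regression + noise. Trend structures: local linear trend (`"llt"`, random
#' walks on level and slope) or integrated random walk (`"irw"`, noise on the
#' slope only). Regression coefficients get a spike-and-slab
#' (Bernoulli-Gaussian) prior; variances get weakly-informative conjugate
#' inverse-gamma priors scaled to the series variance.
#'
#' @param trend `"llt"` or `"irw"`.
#' @param regressors Optional regressor matrix aligned to the series.
#' @param iterations,burn_in MCMC settings (iterations must exceed burn-in).
#' @param inclusion_prior Prior inclusion probability per regressor.
#' @param slab_sd_scale Slab SD as a multiple of the series SD.
#' @param obs_var_scale,level_var_scale,slope_var_scale Prior-mean variance
#'   scales relative to the series variance.
#' @return An `ssm_spec`.
#' @export
ssm_spec <- function(trend = c("llt", "irw"), regressors = NULL,
                     iterations = 2000, burn_in = 500, inclusion_prior = 0.5,
                     slab_sd_scale = 1, obs_var_scale = 0.5,
                     level_var_scale = 0.01, slope_var_scale = 1e-4) {
  trend <- match.arg(trend)
  if (iterations <= burn_in) stop("iterations must exceed burn_in")
  if (!is.null(regressors)) regressors <- as.matrix(regressors)
  structure(as.list(environment()), class = "ssm_spec")
}

n_parameters <- function(spec) {
  (if (spec$trend == "llt") 3 else 2) +
    (if (is.null(spec$regressors)) 0 else ncol(spec$regressors))
}

ssm_matrices <- function(spec, sigma_level, sigma_slope) {
  list(
    Tmat = matrix(c(1, 0, 1, 1), 2, 2),
    Z = matrix(c(1, 0), 1, 2),
    Q = diag(c(if (spec$trend == "irw") 0 else sigma_level, sigma_slope))
  )
}

#' Exact Gaussian log-likelihood of a structural trend model
#'
#' Kalman-filter evaluation of the log-likelihood of a series (NA = missing)
#' under fixed parameters; useful as a building block and for validation
#' against direct joint-Gaussian computation.
#'
#' @param y Series with `NA` gaps.
#' @param trend `"llt"` or `"irw"`.
#' @param sigma2_obs,sigma2_level,sigma2_slope Variances.
#' @param offset Known regression offset (scalar or vector).
#' @param a1,P1 Initial state mean and covariance.
#' @return List with `loglik` and pointwise one-step predictive `mean`/`var`.
#' @export
kalman_loglik <- function(y, trend = c("llt", "irw"), sigma2_obs,
                          sigma2_level = 0, sigma2_slope, offset = 0,
                          a1 = c(y[which(!is.na(y))[1]], 0),
                          P1 = diag(c(1e4, 1e2))) {
  trend <- match.arg(trend)
  if (trend == "irw") sigma2_level <- 0
  offset <- rep_len(offset, length(y))
  kf <- kalman_filter_cpp(as.numeric(y), offset,
                          matrix(c(1, 0, 1, 1), 2, 2),
                          matrix(c(1, 0), 1, 2),
                          diag(c(sigma2_level, sigma2_slope)),
                          sigma2_obs, a1, P1)
  list(loglik = kf$loglik, mean = kf$pred_mean, var = kf$pred_var)
}

draw_ig <- function(shape, rate) 1 / rgamma(1, shape = shape, rate = rate)

#' Fit a Bayesian structural state-space model by Gibbs sampling
#'
#' Observation = trend + regression + Gaussian noise. States are drawn by
#' forward-filtering backward-sampling, variances by conjugate inverse-gamma
#' updates, and regression coefficients by per-coordinate Bernoulli-Gaussian
#' (spike-and-slab) updates. Missing weeks are handled by skipping the filter
#' update. Returns posterior draws, the posterior median trend, one-step
#' predictive densities and standardized innovation residuals at the
#' posterior median parameters.
#'
#' @param y Weekly series with `NA` gaps (at least 30 observed points).
#' @param spec An [ssm_spec()].
#' @param seed RNG seed.
#' @return An `ssm_fit`.
#' @export
fit_ssm <- function(y, spec = ssm_spec(), seed = 1) {
  y <- as.numeric(y)
  obs <- which(!is.na(y))
  if (length(obs) < 30) stop("need at least 30 observed weeks")
  n <- length(y)
  x <- spec$regressors
  if (!is.null(x) && nrow(x) != n) stop("regressors not aligned to series")
  p <- if (is.null(x)) 0 else ncol(x)

  vy <- var(y[obs])
  a_pr <- 2
  b_obs <- spec$obs_var_scale * vy
  b_level <- spec$level_var_scale * vy
  b_slope <- spec$slope_var_scale * vy
  tau2 <- (spec$slab_sd_scale^2) * vy
  pi_incl <- spec$inclusion_prior

  n_iter <- spec$iterations
  n_burn <- spec$burn_in
  n_keep <- n_iter - n_burn

  with_seed(seed, {
    s_obs <- b_obs
    s_level <- if (spec$trend == "irw") 0 else b_level
    s_slope <- b_slope
    beta <- rep(0, p)
    a1 <- c(y[obs[1]], 0)
    P1 <- diag(c(100 * vy, vy))

    keep_sobs <- numeric(n_keep)
    keep_slevel <- numeric(n_keep)
    keep_sslope <- numeric(n_keep)
    keep_beta <- matrix(0, n_keep, p)
    keep_incl <- matrix(0, n_keep, p)
    keep_trend <- matrix(0, n_keep, n)
    keep_slope <- numeric(n_keep)

    for (it in seq_len(n_iter)) {
      offset <- if (p) as.numeric(x %*% beta) else numeric(n)
      mats <- ssm_matrices(spec, s_level, s_slope)
      st <- ffbs_cpp(y, offset, mats$Tmat, mats$Z[1, , drop = FALSE],
                     mats$Q, s_obs, a1, P1)
      mu <- st[, 1]
      delta <- st[, 2]

      r <- y[obs] - mu[obs] - offset[obs]
      s_obs <- draw_ig(a_pr + length(obs) / 2, b_obs + sum(r^2) / 2)

      if (spec$trend == "llt") {
        e <- mu[-1] - mu[-n] - delta[-n]
        s_level <- draw_ig(a_pr + (n - 1) / 2, b_level + sum(e^2) / 2)
      }
      z <- delta[-1] - delta[-n]
      s_slope <- draw_ig(a_pr + (n - 1) / 2, b_slope + sum(z^2) / 2)

      if (p) {
        resid_all <- y - mu
        for (j in seq_len(p)) {
          rj <- resid_all[obs] -
            (if (p > 1) as.numeric(x[obs, -j, drop = FALSE] %*% beta[-j])
             else 0)
          xj <- x[obs, j]
          prec <- sum(xj^2) / s_obs + 1 / tau2
          mean_j <- sum(xj * rj) / s_obs / prec
          log_bf <- 0.5 * log(1 / (tau2 * prec)) + 0.5 * mean_j^2 * prec
          p_on <- 1 / (1 + (1 - pi_incl) / pi_incl * exp(-log_bf))
          if (runif(1) < p_on) {
            beta[j] <- rnorm(1, mean_j, sqrt(1 / prec))
          } else {
            beta[j] <- 0
          }
        }
      }

      if (it > n_burn) {
        k <- it - n_burn
        keep_sobs[k] <- s_obs
        keep_slevel[k] <- s_level
        keep_sslope[k] <- s_slope
        if (p) {
          keep_beta[k, ] <- beta
          keep_incl[k, ] <- as.numeric(beta != 0)
        }
        keep_trend[k, ] <- mu
        keep_slope[k] <- mean(delta)
      }
    }

    trend_median <- apply(keep_trend, 2, median)
    med <- list(
      s_obs = median(keep_sobs), s_level = median(keep_slevel),
      s_slope = median(keep_sslope),
      beta = if (p) colMeans(keep_beta) else numeric(0)
    )
    offset <- if (p) as.numeric(x %*% med$beta) else numeric(n)
    kf <- kalman_loglik(y, spec$trend, med$s_obs, med$s_level, med$s_slope,
                        offset, a1 = a1, P1 = P1)
    innov <- (y - kf$mean) / sqrt(kf$var)

    structure(
      list(
        y = y, spec = spec, seed = seed,
        draws = list(sigma2_obs = keep_sobs, sigma2_level = keep_slevel,
                     sigma2_slope = keep_sslope, beta = keep_beta,
                     inclusion = keep_incl, slope = keep_slope),
        trend_draws = keep_trend, trend_median = trend_median,
        median_params = med,
        pred = list(mean = kf$mean, var = kf$var, loglik = kf$loglik),
        residuals = innov[obs], observed = obs
      ),
      class = "ssm_fit"
    )
  })
}

#' @export
print.ssm_fit <- function(x, ...) {
  ci <- quantile(x$draws$slope, c(0.025, 0.975))
  cat(sprintf(
    "ssm_fit (%s): %d weeks (%d observed); mean slope %.4f [%.4f, %.4f]\n",
    x$spec$trend, length(x$y), length(x$observed), mean(x$draws$slope),
    ci[1], ci[2]
  ))
  invisible(x)
}

#' Posterior interval for the mean slope
#'
#' @param fit An `ssm_fit`.
#' @param level Credible level (default 0.95).
#' @return Named vector: estimate, lower, upper.
#' @export
slope_interval <- function(fit, level = 0.95) {
  a <- (1 - level) / 2
  q <- quantile(fit$draws$slope, c(a, 1 - a))
  c(estimate = mean(fit$draws$slope), lower = unname(q[1]),
    upper = unname(q[2]))
}

#' Leave-future-out expected log predictive density
#'
#' Fits the model on the first `min_train` share of the series and scores
#' each later observed point by its one-step-ahead log predictive density
#' given all earlier data: parameters are drawn from the training posterior
#' (thinned), states are updated exactly through the Kalman filter, and the
#' pointwise density is the log of the posterior-averaged predictive density.
#' A refit stride smaller than the evaluation window re-runs the Gibbs
#' sampler along the way.
#'
#' @param y Series with `NA` gaps.
#' @param spec An [ssm_spec()].
#' @param min_train Minimum training share (default 0.5).
#' @param seed RNG seed.
#' @param n_thin Posterior draws used for the predictive mixture.
#' @param refit_stride Weeks between Gibbs refits (default `Inf`: single fit).
#' @return List: `elpd`, pointwise values, evaluation indices.
#' @export
elpd_lfo <- function(y, spec = ssm_spec(), min_train = 0.5, seed = 1,
                     n_thin = 50, refit_stride = Inf) {
  y <- as.numeric(y)
  n <- length(y)
  obs <- which(!is.na(y))
  cut <- floor(min_train * n)
  eval_idx <- obs[obs > cut]
  if (length(eval_idx) < 10) stop("evaluation window shorter than 10 points")

  refits <- if (is.finite(refit_stride)) {
    seq(cut, n - 1, by = refit_stride)
  } else {
    cut
  }

  lpd <- matrix(NA_real_, n_thin, length(eval_idx))
  for (ri in seq_along(refits)) {
    upto <- refits[ri]
    seg_end <- if (ri < length(refits)) refits[ri + 1] else n
    seg <- eval_idx[eval_idx > upto & eval_idx <= seg_end]
    if (!length(seg)) next

    ytr <- y
    ytr[(upto + 1):n] <- NA
    fit <- fit_ssm(ytr, spec, seed = seed)

    keep <- round(seq(1, length(fit$draws$sigma2_obs), length.out = n_thin))
    p <- if (is.null(spec$regressors)) 0 else ncol(spec$regressors)
    for (d in seq_along(keep)) {
      k <- keep[d]
      offset <- if (p) {
        as.numeric(spec$regressors %*% fit$draws$beta[k, ])
      } else {
        numeric(n)
      }
      kf <- kalman_loglik(y, spec$trend, fit$draws$sigma2_obs[k],
                          fit$draws$sigma2_level[k],
                          fit$draws$sigma2_slope[k], offset)
      lpd[d, match(seg, eval_idx)] <-
        dnorm(y[seg], kf$mean[seg], sqrt(kf$var[seg]), log = TRUE)
    }
  }

  pointwise <- apply(lpd, 2, log_mean_exp)
  list(elpd = sum(pointwise), pointwise = pointwise, eval_idx = eval_idx)
}

#' Compare state-space model specifications by LFO-ELPD
#'
#' Ranks specifications by their leave-future-out expected log pointwise
#' predictive density; when ELPDs are indistinguishable (within `tie_tol`)
#' the smaller model (fewer parameters, then smaller regressor matrix) wins.
#'
#' @param y Series with `NA` gaps.
#' @param specs Named list of [ssm_spec()]s (at least 2).
#' @param ... Passed to [elpd_lfo()].
#' @param tie_tol Absolute ELPD difference treated as a tie.
#' @return Data frame ranked best-first: name, elpd, n_params, rank.
#' @export
compare_models <- function(y, specs, ..., tie_tol = 1e-8) {
  if (length(specs) < 2) stop("need at least 2 specs")
  if (is.null(names(specs))) names(specs) <- paste0("spec", seq_along(specs))
  elpd <- vapply(specs, function(s) elpd_lfo(y, s, ...)$elpd, numeric(1))
  np <- vapply(specs, n_parameters, numeric(1))
  ord <- order(-round(elpd / tie_tol) * tie_tol, np)
  out <- data.frame(name = names(specs), elpd = elpd, n_params = np)[ord, ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Residual and convergence diagnostics for an SSM fit
#'
#' Residual checks on the standardized one-step innovations: F variance
#' ratio between the first and last thirds (heteroscedasticity),
#' autocorrelation over the first 42 lags (serial dependence), and the
#' Kolmogorov-Smirnov d against a standard normal (non-normality).
#' Convergence checks per parameter: effective sample size and the Geweke
#' z-score.
#'
#' @param fit An `ssm_fit`.
#' @param n_lags Autocorrelation lags to test (default 42).
#' @return A `ssm_diagnostics` list.
#' @export
ssm_diagnostics <- function(fit, n_lags = 42) {
  r <- fit$residuals
  n <- length(r)
  if (n < 9) stop("series too short to split into thirds")
  third <- floor(n / 3)
  v1 <- var(r[seq_len(third)])
  v2 <- var(r[seq.int(n - third + 1, n)])
  f_stat <- v2 / v1
  f_p <- 2 * min(pf(f_stat, third - 1, third - 1),
                 1 - pf(f_stat, third - 1, third - 1))

  lags <- min(n_lags, n - 2)
  ac <- acf(r, lag.max = lags, plot = FALSE)$acf[-1]
  ac_bound <- qnorm(0.975) / sqrt(n)
  ks <- suppressWarnings(ks.test(r, "pnorm", 0, 1))

  params <- list(sigma2_obs = fit$draws$sigma2_obs,
                 sigma2_slope = fit$draws$sigma2_slope)
  if (fit$spec$trend == "llt") params$sigma2_level <- fit$draws$sigma2_level
  ess <- vapply(params, ess_mean, numeric(1))
  geweke <- vapply(params, geweke_z, numeric(1))

  structure(
    list(
      f_ratio = f_stat, f_p = f_p,
      acf = ac, acf_bound = ac_bound,
      n_significant_lags = sum(abs(ac) > ac_bound),
      ks_d = unname(ks$statistic), ks_p = ks$p.value,
      ess = ess, geweke_z = geweke,
      converged = all(ess > 100) && all(abs(geweke) < 3)
    ),
    class = "ssm_diagnostics"
  )
}

#' @export
print.ssm_diagnostics <- function(x, ...) {
  cat(sprintf(
    paste0("ssm_diagnostics: F = %.2f (p = %.3f); %d/%d significant ACF ",
           "lags; KS d = %.3f; min ESS = %.0f; max |Geweke z| = %.2f\n"),
    x$f_ratio, x$f_p, x$n_significant_lags, length(x$acf), x$ks_d,
    min(x$ess), max(abs(x$geweke_z))
  ))
  invisible(x)
}

#' Annual means of the posterior median trend
#'
#' Average of the posterior median trend over the observed weeks of each
#' year.
#'
#' @param fit An `ssm_fit`.
#' @param years Vector of calendar years aligned to the series.
#' @return Named numeric vector, one value per year with observations.
#' @export
ssm_annual_means <- function(fit, years) {
  stopifnot(length(years) == length(fit$y))
  obs <- fit$observed
  tapply(fit$trend_median[obs], years[obs], mean)
}
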