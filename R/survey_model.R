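# Multivariate Gaussian SSM machinery for the multi-route survey model.
# States: shared latent random-walk trend x_t plus one AR(1) observation
# error per route; y_{r,t} = x_t + a_r + e_{r,t}. Small dimensions, so a
# plain R filter + RTS smoother is plenty.

mroute_filter <- function(y, phi, sig2_x, sig2_e, a_off, jitter = 1e-8) {
  n <- ncol(y)
  R <- nrow(y)
  m <- R + 1
  Tmat <- diag(c(1, phi))
  Q <- diag(c(sig2_x, sig2_e * (1 - phi^2)))
  Z <- cbind(1, diag(R))

  first <- y[, 1][!is.na(y[, 1])]
  a <- c(if (length(first)) mean(first) else 0, rep(0, R))
  vy <- var(as.numeric(y), na.rm = TRUE)
  P <- diag(c(100 * max(vy, 1e-6), pmax(sig2_e, 1e-6)))

  at <- matrix(0, m, n)
  Pt <- array(0, c(m, m, n))
  att <- matrix(0, m, n)
  Ptt <- array(0, c(m, m, n))
  loglik <- 0

  for (t in seq_len(n)) {
    at[, t] <- a
    Pt[, , t] <- P
    ok <- which(!is.na(y[, t]))
    if (length(ok)) {
      Zt <- Z[ok, , drop = FALSE]
      v <- y[ok, t] - Zt %*% a - a_off[ok]
      Fm <- Zt %*% P %*% t(Zt)
      Fm <- Fm + diag(jitter * (1 + max(diag(Fm))), length(ok))
      Fi <- solve(Fm)
      loglik <- loglik - 0.5 * (length(ok) * log(2 * pi) +
                                  determinant(Fm)$modulus +
                                  t(v) %*% Fi %*% v)
      K <- P %*% t(Zt) %*% Fi
      a <- a + as.numeric(K %*% v)
      P <- P - K %*% Zt %*% P
      P <- (P + t(P)) / 2
    }
    att[, t] <- a
    Ptt[, , t] <- P
    a <- as.numeric(Tmat %*% a)
    P <- Tmat %*% P %*% t(Tmat) + Q
    P <- (P + t(P)) / 2
  }

  # RTS smoother
  ahat <- att
  for (t in seq.int(n - 1, 1)) {
    Ppred <- Tmat %*% Ptt[, , t] %*% t(Tmat) + Q
    J <- Ptt[, , t] %*% t(Tmat) %*%
      solve(Ppred + diag(1e-9 * (1 + max(diag(Ppred))), m))
    ahat[, t] <- att[, t] + as.numeric(J %*% (ahat[, t + 1] -
                                                Tmat %*% att[, t]))
  }

  list(loglik = as.numeric(loglik), smoothed = ahat)
}

#' Fit a shared-trend multi-route survey model
#'
#' Treats survey routes as observers of the same latent population trend: a
#' shared random-walk latent state observed through route-specific intercepts
#' and route-specific AR(1) errors. Estimated by maximum likelihood through a
#' Kalman filter with state augmentation (the AR errors live in the state
#' vector). The first route's offset is fixed at 0 for identifiability.
#'
#' @param survey A `survey_series` data frame (route, year, genus, count) or
#'   an equivalent data frame.
#' @param genus Genus to fit (default: the first in the data).
#' @return A `survey_fit`: latent annual trend (smoothed, log scale), route
#'   offsets, per-route AR coefficients and variances, and the log-likelihood.
#' @export
fit_multiroute <- function(survey, genus = NULL) {
  df <- as.data.frame(survey)
  genus <- genus %||% df$genus[1]
  df <- df[df$genus == genus, ]
  routes <- sort(unique(df$route))
  years <- sort(unique(df$year))
  if (length(years) < 5) stop("need at least 5 years")

  y <- matrix(NA_real_, length(routes), length(years),
              dimnames = list(routes, years))
  for (i in seq_len(nrow(df))) {
    y[df$route[i], as.character(df$year[i])] <- log(pmax(df$count[i], 0.5))
  }

  empty <- rowSums(!is.na(y)) == 0
  if (any(empty)) {
    warning("dropping all-missing routes: ",
            paste(routes[empty], collapse = ", "))
    y <- y[!empty, , drop = FALSE]
    routes <- routes[!empty]
  }
  R <- nrow(y)
  vy <- var(as.numeric(y), na.rm = TRUE)
  vy <- max(vy, 1e-4)

  # parameters: log sig2_x, atanh phi_r, log sig2_e_r, offsets a_2..a_R
  floor_v <- 1e-7 * vy
  unpack <- function(par) {
    list(
      sig2_x = exp(par[1]) + floor_v,
      phi = tanh(par[2:(R + 1)]),
      sig2_e = exp(par[(R + 2):(2 * R + 1)]) + floor_v,
      a_off = c(0, if (R > 1) par[(2 * R + 2):(3 * R)] else numeric(0))
    )
  }
  nll <- function(par) {
    p <- unpack(par)
    tryCatch(
      -mroute_filter(y, p$phi, p$sig2_x, p$sig2_e, p$a_off)$loglik,
      error = function(e) 1e10
    )
  }
  # a shared random walk and near-unit-root AR errors are weakly identified
  # with few routes; fit from a balanced and a trend-dominant start, and
  # break likelihood near-ties (within 2 units) toward the trend
  dv <- max(var(as.numeric(diff(t(y))), na.rm = TRUE), 1e-6, na.rm = TRUE)
  starts <- list(
    c(log(0.1 * vy), rep(atanh(0.3), R), rep(log(0.5 * vy), R),
      rep(0, R - 1)),
    c(log(dv), rep(atanh(0.1), R), rep(log(1e-4 * vy), R), rep(0, R - 1))
  )
  fits <- lapply(starts, function(s) {
    optim(s, nll, method = "BFGS", control = list(maxit = 500,
                                                  reltol = 1e-10))
  })
  vals <- vapply(fits, `[[`, numeric(1), "value")
  near <- which(vals <= min(vals) + 2)
  err_share <- vapply(near, function(i) {
    p <- unpack(fits[[i]]$par)
    sum(p$sig2_e) / (p$sig2_x + sum(p$sig2_e))
  }, numeric(1))
  opt <- fits[[near[which.min(err_share)]]]
  p <- unpack(opt$par)
  sm <- mroute_filter(y, p$phi, p$sig2_x, p$sig2_e, p$a_off)

  structure(
    list(
      genus = genus, routes = routes, years = as.integer(years),
      trend = setNames(sm$smoothed[1, ], years),
      route_offsets = setNames(p$a_off, routes),
      ar = setNames(p$phi, routes),
      sigma2_trend = p$sig2_x, sigma2_routes = setNames(p$sig2_e, routes),
      loglik = -opt$value, convergence = opt$convergence
    ),
    class = "survey_fit"
  )
}

#' @export
print.survey_fit <- function(x, ...) {
  cat(sprintf(
    "survey_fit (%s): %d routes, %d years; AR in [%.2f, %.2f]\n",
    x$genus, length(x$routes), length(x$years), min(x$ar), max(x$ar)
  ))
  invisible(x)
}

#' Correlate eDNA annual abundance with a survey trend
#'
#' z-transforms both indices, applies a trailing moving average (default two
#' years) to the survey trend, and regresses the eDNA index on it by ordinary
#' least squares.
#'
#' @param edna_annual Named numeric vector of annual eDNA means (names =
#'   years), e.g. from [ssm_annual_means()].
#' @param survey_fit A [fit_multiroute()] result, or a named numeric vector
#'   of annual survey trend values.
#' @param window Trailing moving-average window in years (default 2;
#'   `window = 1` is plain OLS on z-scores).
#' @return List: `adj_r2`, `r2`, `f`, `p`, `df`, `n`.
#' @export
correlate_indices <- function(edna_annual, survey_fit, window = 2) {
  sv <- if (inherits(survey_fit, "survey_fit")) survey_fit$trend else survey_fit
  sv_years <- as.integer(names(sv))
  zs <- as.numeric(scale(sv))
  ma <- zs
  if (window > 1) {
    for (i in seq_along(zs)) {
      ma[i] <- mean(zs[max(1, i - window + 1):i])
    }
  }
  names(ma) <- names(sv)

  years <- intersect(names(edna_annual), names(sv))
  if (length(years) < 4) stop("need at least 4 overlapping years")
  ze <- as.numeric(scale(edna_annual[years]))
  fit <- lm(ze ~ ma[years])
  s <- summary(fit)
  list(
    adj_r2 = s$adj.r.squared, r2 = s$r.squared,
    f = unname(s$fstatistic[1]),
    p = unname(pf(s$fstatistic[1], s$fstatistic[2], s$fstatistic[3],
                  lower.tail = FALSE)),
    df = unname(s$fstatistic[3]), n = length(years)
  )
}
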