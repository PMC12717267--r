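test_that("uniform composition equal to the reference gives alpha = gamma = N", {
  comp <- airedna:::composition_matrix(matrix(0.1, 10, 3))
  prof <- partition_diversity(comp, q = c(1, 2, 3))$profile
  expect_equal(prof$alpha, rep(10, 9), tolerance = 1e-12)
  expect_equal(prof$beta, rep(1, 9), tolerance = 1e-12)
  expect_equal(prof$gamma, rep(10, 9), tolerance = 1e-12)
})

test_that("order-2 alpha matches the inverse Simpson oracle", {
  comp <- airedna:::composition_matrix(
    matrix(c(0.5, 0.25, 0.25), 3, 1)
  )
  prof <- partition_diversity(comp, q = 2)$profile
  expect_equal(prof$alpha, 1 / sum(c(0.5, 0.25, 0.25)^2), tolerance = 1e-12)
  expect_equal(prof$alpha, 2.667, tolerance = 1e-3)
})

test_that("beta >= 1, gamma = alpha * beta, and alpha decreases in q", {
  rc <- random_composition(12, 25, seed = 30)
  prof <- partition_diversity(rc, q = c(1, 2, 3))$profile
  expect_true(all(prof$beta >= 1 - 1e-12))
  expect_true(all(prof$alpha >= 1))
  expect_equal(prof$gamma, prof$alpha * prof$beta, tolerance = 1e-9)
  wide <- reshape(prof[, c("week", "q", "alpha")], idvar = "week",
                  timevar = "q", direction = "wide")
  expect_true(all(wide$alpha.1 >= wide$alpha.2 - 1e-12))
  expect_true(all(wide$alpha.2 >= wide$alpha.3 - 1e-12))
})

test_that("q = 1 gamma is the exponential cross-entropy with the reference", {
  rc <- random_composition(8, 10, seed = 31)
  r <- rowMeans(unclass(rc))
  r <- r / sum(r)
  prof <- partition_diversity(rc, q = 1, reference = r)$profile
  for (w in seq_len(10)) {
    p <- unclass(rc)[, w]
    expect_equal(prof$gamma[w], exp(-sum(p * log(r))), tolerance = 1e-10)
  }
})

test_that("per-genus contributions sum to log gamma", {
  rc <- random_composition(15, 20, seed = 32)
  contrib <- gamma_contributions(rc)
  prof <- partition_diversity(rc, q = 1)$profile
  expect_true(all(contrib >= 0))
  expect_equal(unname(colSums(contrib)),
               log(prof$gamma[match(colnames(rc), prof$week)]),
               tolerance = 1e-10)

  # p = r: the sum is the Shannon entropy of the reference
  r <- c(0.5, 0.3, 0.2)
  comp <- airedna:::composition_matrix(matrix(r, 3, 1))
  c1 <- gamma_contributions(comp, reference = r)
  expect_equal(sum(c1), -sum(r * log(r)), tolerance = 1e-12)

  expect_error(gamma_contributions(rc, q = 2), "generalized")
  expect_silent(gamma_contributions(rc, q = 2, generalized = TRUE))
})

with_meta <- function(contrib, years, weeks) {
  attr(contrib, "meta") <- data.frame(year = years, week = weeks)
  contrib
}

test_that("identical eras give zero differences and p = 1", {
  set.seed(33)
  vals <- matrix(rexp(2 * 8), 2, 8)
  contrib <- cbind(vals, vals)
  rownames(contrib) <- c("gA", "gB")
  contrib <- with_meta(contrib, rep(c(1980, 2000), each = 8),
                       rep(1:8, 2))
  res <- contrast_periods(contrib, c(1980, 1980), c(2000, 2000))
  expect_equal(res$delta, c(0, 0))
  expect_equal(res$p, c(1, 1))
})

test_that("signed-rank p matches exhaustive enumeration at n = 8", {
  set.seed(34)
  a <- rnorm(8)
  d <- c(0.3, -0.5, 1.2, 0.7, -0.1, 0.9, 1.5, -2.0)
  b <- a + d
  contrib <- with_meta(rbind(g = c(a, b)),
                       rep(c(1980, 2000), each = 8), rep(1:8, 2))
  res <- contrast_periods(contrib, c(1980, 1980), c(2000, 2000))
  expect_equal(res$p, signed_rank_p_enum(d), tolerance = 1e-12)
  # Hodges-Lehmann estimate: median of Walsh averages
  walsh <- outer(d, d, "+") / 2
  expect_equal(res$delta, median(walsh[upper.tri(walsh, diag = TRUE)]),
               tolerance = 1e-9)
  expect_true(res$ci_lo <= res$delta && res$delta <= res$ci_hi)
})

test_that("BH adjustment matches the direct step-up formula", {
  set.seed(35)
  n_weeks <- 10
  a <- matrix(rnorm(4 * n_weeks), 4, n_weeks)
  b <- a + matrix(c(2, 1, 0.5, 0), 4, n_weeks) +
    matrix(rnorm(4 * n_weeks, 0, 0.5), 4, n_weeks)
  rownames(a) <- rownames(b) <- paste0("g", 1:4)
  contrib <- with_meta(cbind(a, b), rep(c(1980, 2000), each = n_weeks),
                       rep(1:n_weeks, 2))
  res <- contrast_periods(contrib, c(1980, 1980), c(2000, 2000))
  # direct step-up formula: sort ascending, adj_(k) = min_{j>=k} m p_(j)/j
  m <- length(res$p)
  o <- order(res$p)
  adj_sorted <- rev(cummin(rev(pmin(1, m * res$p[o] / seq_len(m)))))
  direct <- numeric(m)
  direct[o] <- adj_sorted
  expect_equal(res$p_adj, direct, tolerance = 1e-12)
  expect_true(all(res$p_adj >= res$p - 1e-12))
})

test_that("the rank-sum variant runs and era grids are supported", {
  rc <- random_composition(5, 24, seed = 36)
  contrib <- gamma_contributions(rc)
  attr(contrib, "meta") <- data.frame(year = rep(c(1974, 1976, 1994, 1996),
                                                 each = 6),
                                      week = rep(1:6, 4))
  r1 <- contrast_periods(contrib, c(1974, 1976), c(1994, 1996))
  r2 <- contrast_periods(contrib, c(1974, 1976), c(1994, 1996),
                         method = "rank-sum")
  expect_equal(nrow(r1), 5)
  expect_equal(nrow(r2), 5)
  expect_error(contrast_periods(contrib, c(1950, 1960), c(1994, 1996)),
               "no weeks")
})

test_that("a surge that concentrates the community depresses gamma", {
  cfg <- synthetic_config(n_genera = 40, n_weeks = 260, n_clusters = 3,
                          n_spurious_genera = 0, seed = 37)
  truth <- make_community(cfg)
  counts <- sample_reads(truth, cfg)
  comp <- impute_zeros(prevalence_filter(counts))
  prof <- partition_diversity(comp, q = 1)
  g <- prof$profile$gamma
  meta <- attr(comp, "meta")
  early <- mean(g[meta$year <= 1975])
  late <- mean(g[meta$year >= 1977])
  expect_lt(late, early)

  contrib <- gamma_contributions(comp)
  res <- contrast_periods(contrib, c(1974, 1975), c(1977, 1978))
  surge_row <- res[res$genus == truth$surge_genus, ]
  expect_gt(surge_row$delta, 0)
  expect_lt(surge_row$p_adj, 0.05)
})
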