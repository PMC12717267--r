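test_that("generators are deterministic under a fixed seed", {
  cfg <- synthetic_config(n_genera = 20, n_weeks = 60, n_clusters = 3,
                          n_spurious_genera = 4, seed = 11)
  t1 <- make_community(cfg)
  t2 <- make_community(cfg)
  expect_identical(t1, t2)
  c1 <- sample_reads(t1, cfg)
  c2 <- sample_reads(t2, cfg)
  expect_identical(c1$counts, c2$counts)
  s1 <- spike_false_positives(c1, t1, cfg)
  s2 <- spike_false_positives(c2, t2, cfg)
  expect_identical(s1$counts$counts, s2$counts$counts)
  tr1 <- make_trajectories(cfg, weeks = 1:5)
  tr2 <- make_trajectories(cfg, weeks = 1:5)
  expect_identical(as.data.frame(tr1), as.data.frame(tr2))
  sv1 <- make_survey(t1, cfg)
  sv2 <- make_survey(t2, cfg)
  expect_identical(as.data.frame(sv1), as.data.frame(sv2))
})

test_that("zero noise makes within-cluster latents identical up to offset", {
  cfg <- synthetic_config(n_genera = 12, n_weeks = 50, n_clusters = 3,
                          noise_sd = 0, surge = FALSE, seed = 2)
  truth <- make_community(cfg)
  for (cl in 1:3) {
    members <- which(truth$cluster == cl)
    base <- truth$latent[members[1], ]
    for (g in members[-1]) {
      diffs <- truth$latent[g, ] - base
      expect_lt(diff(range(diffs)), 1e-12)
    }
  }
  expect_error(make_community(synthetic_config(n_genera = 2, n_clusters = 5)))
})

test_that("cluster ids are contiguous and the surge share is honoured", {
  cfg <- synthetic_config(n_genera = 30, n_weeks = 200, n_clusters = 4,
                          noise_sd = 0, seed = 8)
  truth <- make_community(cfg)
  expect_equal(sort(unique(truth$cluster)), 1:4)
  expect_true(all(is.finite(truth$latent)))
  s <- attr(truth$latent, "surge_share")
  shares <- exp(truth$latent[1, ]) / colSums(exp(truth$latent))
  expect_equal(unname(shares), unname(s), tolerance = 1e-9)
  expect_lt(abs(s[1] - 0.4), 0.01)
  expect_gt(max(s), 0.75)
  expect_lt(s[length(s)], 0.7)
})

test_that("weekly counts are closed multinomial draws", {
  w <- small_world()
  expect_equal(unname(colSums(w$counts$counts)),
               w$counts$meta$total_reads)
  expect_true(all(w$counts$counts >= 0))
  expect_equal(nrow(w$counts$meta), ncol(w$counts$counts))
})

test_that("without bias terms, empirical proportions match softmax(latent)", {
  # constant latent (no season, no noise, no surge) makes weeks replicates
  cfg <- synthetic_config(n_genera = 10, n_weeks = 1000, n_clusters = 1,
                          seasonal_amplitude = 0, noise_sd = 0, surge = FALSE,
                          rl_bias_sd = 0, batch_sd = 0, lib_mean = 2000,
                          n_spurious_genera = 0, seed = 13)
  truth <- make_community(cfg)
  counts <- sample_reads(truth, cfg)
  eta <- truth$latent[, 1]
  p_true <- exp(eta - max(eta))
  p_true <- p_true / sum(p_true)
  p_hat <- rowSums(counts$counts) / sum(counts$counts)
  n_tot <- sum(counts$counts)
  se <- sqrt(p_true * (1 - p_true) / n_tot)
  expect_true(all(abs(p_hat - p_true) <= 3 * se + 1e-12))
})

test_that("the observed-week mask reproduces the archival design", {
  cfg <- synthetic_config(n_genera = 10, n_weeks = 208, n_clusters = 2,
                          observed_mask = TRUE, seed = 1)
  truth <- make_community(cfg)
  counts <- sample_reads(truth, cfg)
  expect_true(all(counts$meta$year %% 2 == 0))
  expect_true(all(counts$meta$week >= 17 & counts$meta$week <= 44))
  expect_lt(ncol(counts$counts), 208)
})

test_that("spiking false positives is an identity at n = 0 and labels track", {
  w <- small_world()
  cfg0 <- w$cfg
  cfg0$n_spurious_genera <- 0
  sp0 <- spike_false_positives(w$counts, w$truth, cfg0)
  expect_identical(sp0$counts$counts, w$counts$counts)
  expect_true(all(sp0$labels$label == "positive"))

  sp <- spike_false_positives(w$counts, w$truth, w$cfg)
  expect_equal(nrow(sp$counts$counts), 46)
  spurious <- grepl("^sp", sp$labels$genus)
  expect_true(all(sp$labels$label[spurious] == "negative"))
  expect_true(all(sp$labels$label[!spurious] == "positive"))

  # degraded classification profiles: lower distinct-minimizer ratios
  ratio <- sp$summaries$minimizers_distinct / sp$summaries$minimizers_total
  is_sp <- grepl("^sp", sp$summaries$genus)
  expect_lt(mean(ratio[is_sp]), mean(ratio[!is_sp]))

  # spurious occurrences are far away, genuine ones nearby
  d <- haversine_km(sp$occurrences$decimalLatitude,
                    sp$occurrences$decimalLongitude, 67.84, 20.42)
  far <- grepl("^sp", sp$occurrences$taxon)
  expect_true(all(d[far] > 5000))
  expect_true(all(d[!far] < 40))
})

test_that("trajectory bearings follow the configured bias", {
  # isotropic: Rayleigh test does not reject uniformity
  cfg0 <- synthetic_config(n_weeks = 150, traj_concentration = 0,
                           traj_starts_per_week = 10, seed = 5)
  tr0 <- make_trajectories(cfg0, weeks = 1:150)
  b0 <- bearing_deg(67.84, 20.42, tr0$lat, tr0$lon)
  # one bearing per trajectory (the mean heading), as independent draws
  mb <- tapply(b0, tr0$traj_id, function(x) x[1])
  expect_gt(rayleigh_p(mb), 0.01)

  # strong southerly bias concentrates endpoints in S/SE/SW
  cfg1 <- synthetic_config(n_weeks = 50, traj_bias_bearing = 180,
                           traj_concentration = 20, seed = 5)
  tr1 <- make_trajectories(cfg1, weeks = 1:50)
  b1 <- bearing_deg(67.84, 20.42, tr1$lat, tr1$lon)
  south <- b1 > 112.5 & b1 < 247.5
  expect_gt(mean(south), 0.8)

  expect_true(all(tr1$start_height %in% c(10, 100, 300, 500)))
  expect_true(all(tr1$hours_back > 0))
})

test_that("survey counts track the latent annual means", {
  cfg <- synthetic_config(n_genera = 6, n_weeks = 520, n_clusters = 2,
                          n_routes = 1, survey_noise_sd = 0, seed = 4)
  truth <- make_community(cfg)
  sv <- make_survey(truth, cfg)
  ann <- attr(sv, "latent_annual")[[1]]
  # counts are a monotone (rounded exponential) map of the annual means
  expect_true(all(diff(sv$count[order(ann)]) >= 0))
  expect_gt(cor(log(sv$count), ann), 0.99)

  # route offsets shift level, not shape (log scale; rounding adds jitter)
  cfg3 <- synthetic_config(n_genera = 6, n_weeks = 520, n_clusters = 2,
                           n_routes = 3, survey_noise_sd = 0,
                           survey_route_offset_sd = 1, seed = 4)
  truth3 <- make_community(cfg3)
  sv3 <- make_survey(truth3, cfg3)
  m <- matrix(log(sv3$count), ncol = 3)
  off <- attr(sv3, "route_offsets")
  expect_lt(sd(m[, 2] - m[, 1]), 0.1)
  expect_equal(mean(m[, 2] - m[, 1]), off[2], tolerance = 0.1)
})

test_that("survey AR(1) noise has the configured autocorrelation", {
  cfg <- synthetic_config(n_genera = 3, n_weeks = 200 * 52, n_clusters = 1,
                          n_routes = 1, survey_ar = 0.6, surge = FALSE,
                          seasonal_amplitude = 0, noise_sd = 0,
                          survey_noise_sd = 0.3, seed = 6)
  truth <- make_community(cfg)
  sv <- make_survey(truth, cfg)
  ann <- attr(sv, "latent_annual")[[1]]
  resid <- log(pmax(sv$count, 0.5)) - ann
  phi_hat <- acf(resid, lag.max = 1, plot = FALSE)$acf[2]
  expect_lt(abs(phi_hat - 0.6), 0.1)
})

test_that("trajectory and survey writers emit readable flat files", {
  cfg <- synthetic_config(n_weeks = 4, seed = 2)
  tr <- make_trajectories(cfg, weeks = 1:4)
  path <- tempfile(fileext = ".tsv")
  write_trajectories(tr, path)
  back <- read_tdump(path, station = cfg$station)
  expect_equal(nrow(back), nrow(tr))
  expect_equal(back$lat, tr$lat, tolerance = 1e-6)

  truth <- make_community(synthetic_config(n_genera = 5, n_weeks = 260,
                                           n_clusters = 2, seed = 2))
  sv <- make_survey(truth, synthetic_config(n_genera = 5, n_weeks = 260,
                                            n_clusters = 2, seed = 2))
  sp <- tempfile(fileext = ".csv")
  write_survey(sv, sp)
  expect_equal(nrow(utils::read.csv(sp)), nrow(sv))
})
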