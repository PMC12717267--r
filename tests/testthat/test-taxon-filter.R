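test_that("stringency selection maximizes regional fraction under retention", {
  one <- data.frame(confidence = 0.2, hit_groups = 5,
                    frac_classified = 0.4, frac_regional = 0.6)
  expect_equal(select_stringency(one), list(confidence = 0.2, hit_groups = 5))

  flat <- data.frame(confidence = c(0, 0.1, 0.3),
                     hit_groups = c(1, 10, 20),
                     frac_classified = c(0.5, 0.4, 0.3),
                     frac_regional = 0.7)
  # flat regional curve: tie goes to the least stringent setting
  expect_equal(select_stringency(flat),
               list(confidence = 0, hit_groups = 1))

  # synthetic knee: regional fraction rises then saturates while the
  # classified fraction collapses beyond the knee
  conf <- seq(0, 0.5, by = 0.1)
  knee <- data.frame(
    confidence = conf, hit_groups = round(conf * 100),
    frac_classified = c(0.60, 0.55, 0.50, 0.28, 0.20, 0.10),
    frac_regional = c(0.30, 0.55, 0.70, 0.72, 0.73, 0.74)
  )
  # rows past 0.2 are excluded by the 50%-retention constraint
  expect_equal(select_stringency(knee),
               list(confidence = 0.2, hit_groups = 20))
  expect_error(select_stringency(knee[0, ]), "empty")
})

test_that("label curation applies the distance and family rules", {
  station <- c(lat = 67.84, lon = 20.42)
  mk <- function(taxon, dist_km, n, bearing = 90) {
    pt <- airedna:::destination_point(station["lat"], station["lon"],
                                      bearing, dist_km)
    data.frame(taxon = taxon, decimalLatitude = pt$lat,
               decimalLongitude = pt$lon, year = 1990)[rep(1, n), ]
  }
  occ <- rbind(
    mk("near5", 10, 5),       # positive: 5 records at 10 km
    mk("near3", 10, 3),       # 3 records only: not positive, not negative
    mk("far", 7000, 2)        # all records beyond 5000 km
  )
  taxonomy <- data.frame(genus = c("near5", "near3", "far", "ghost"),
                         family = c("famA", "famB", "famC", "famD"))
  genome <- data.frame(family = c("famB", "famD"),
                       has_reference = c(FALSE, TRUE))
  labels <- curate_labels(occ, station, genome_table = genome,
                          taxonomy = taxonomy,
                          genera = c("near5", "near3", "far", "ghost"))
  get <- function(g) labels$label[labels$genus == g]
  expect_equal(get("near5"), "positive")
  expect_length(get("near3"), 0) # unlabeled: fails both rules
  expect_equal(get("far"), "negative")
  expect_equal(get("ghost"), "negative") # no records, family sequenced

  # with a family conflict the zero-record genus stays unlabeled
  genome2 <- data.frame(family = "famD", has_reference = FALSE)
  labels2 <- curate_labels(occ, station, genome_table = genome2,
                           taxonomy = taxonomy, genera = "ghost")
  expect_equal(nrow(labels2), 0)

  occ_na <- occ
  occ_na$decimalLatitude[1] <- NA
  expect_warning(curate_labels(occ_na, station), "skipped")
})

test_that("label curation is order-independent", {
  w <- small_world()
  sp <- spike_false_positives(w$counts, w$truth, w$cfg)
  l1 <- curate_labels(sp$occurrences, w$cfg$station)
  l2 <- curate_labels(sp$occurrences[rev(seq_len(nrow(sp$occurrences))), ],
                      w$cfg$station)
  expect_equal(l1, l2)
})

test_that("feature table has the documented 31 statistics and no NAs", {
  w <- small_world()
  sp <- spike_false_positives(w$counts, w$truth, w$cfg)
  feat <- build_features(sp$counts, sp$summaries)
  stats31 <- c(
    "plr_mean", "plr_median", "plr_max", "plr_min", "plr_sd", "plr_iqr",
    "log_total_reads", "log_max_count",
    "zero_fraction", "detect_weeks", "longest_detect_run",
    "longest_absence_run", "mean_detect_gap", "burstiness",
    "dispersion_index", "plr_skewness", "plr_acf1", "plr_seasonal_range",
    "minimizer_distinct_ratio", "mean_confidence", "direct_clade_ratio",
    "log_clade_reads", "log_direct_reads", "reads_per_minimizer",
    "log_minimizers_distinct", "minimizers_per_read",
    "log_db_bytes", "log_genome_size", "reads_per_db_byte",
    "reads_per_genome_base", "db_per_genome"
  )
  expect_true(all(stats31 %in% names(feat)))
  expect_length(stats31, 31)
  expect_true(any(grepl("^kingdom_", names(feat))))
  expect_true(any(grepl("^plr_w", names(feat))))
  num <- feat[, setdiff(names(feat), "genus")]
  expect_true(all(vapply(num, function(v) all(is.finite(v)), logical(1))))

  # always-detected genus sits at the frequency maxima
  top <- feat[which.max(feat$detect_weeks), ]
  expect_equal(top$zero_fraction, 0)
  expect_equal(top$longest_detect_run, ncol(sp$counts$counts))

  expect_error(build_features(sp$counts, sp$summaries[-1, ]),
               sp$summaries$genus[1])
})

test_that("distinct-minimizer ratio matches hand arithmetic on a toy", {
  counts <- count_matrix(matrix(c(5, 2, 9, 3, 0, 1), 3, 2,
                                dimnames = list(c("a", "b", "c"), NULL)))
  summ <- data.frame(
    genus = c("a", "b", "c"), total_reads = c(7, 12, 1),
    clade_reads = c(7, 12, 1), direct_reads = c(5, 6, 1),
    minimizers_total = c(10, 20, 4), minimizers_distinct = c(5, 18, 1),
    mean_confidence = 0.5, db_bytes = 100, genome_size = 50
  )
  feat <- build_features(counts, summ)
  expect_equal(feat$minimizer_distinct_ratio, c(0.5, 0.9, 0.25))
  expect_equal(feat$direct_clade_ratio, c(5 / 7, 0.5, 1))

  # identical inputs give identical feature rows
  counts2 <- count_matrix(rbind(a = c(5, 3), b = c(5, 3)))
  summ2 <- summ[c(1, 1), ]
  summ2$genus <- c("a", "b")
  feat2 <- build_features(counts2, summ2)
  expect_equal(unlist(feat2[1, -1]), unlist(feat2[2, -1]))
})

test_that("the booster separates separable classes and is deterministic", {
  set.seed(1)
  n <- 120
  x <- cbind(f1 = c(runif(n / 2, -3, -1), runif(n / 2, 1, 3)),
             f2 = rnorm(n))
  y <- rep(c(0, 1), each = n / 2)
  feat <- data.frame(genus = sprintf("g%03d", 1:n), x)
  labels <- data.frame(genus = feat$genus,
                       label = ifelse(y == 1, "positive", "negative"))
  m1 <- train_filter(feat, labels, seed = 42, nrounds = 60)
  expect_equal(m1$holdout$precision, 1)
  expect_equal(m1$holdout$recall, 1)

  m2 <- train_filter(feat, labels, seed = 42, nrounds = 60)
  expect_identical(predict(m1$model, x), predict(m2$model, x))

  single <- labels
  single$label <- "positive"
  expect_error(train_filter(feat, single, seed = 1), "both classes")
})

test_that("holdout genera never enter the cross-validation folds", {
  set.seed(2)
  n <- 80
  feat <- data.frame(genus = sprintf("g%03d", 1:n), f1 = rnorm(n),
                     f2 = rnorm(n))
  labels <- data.frame(genus = feat$genus,
                       label = rep(c("positive", "negative"), n / 2))
  grid <- filter_grid()[c(1, 4), ]
  m <- train_filter(feat, labels, seed = 9, grid = grid, nrounds = 20)
  expect_length(m$holdout_genera, round(0.13 * n / 2) * 2)
  expect_equal(nrow(m$cv), 2)
  # refit model must carry the grid-chosen parameters
  chosen <- m$cv[which.min(m$cv$cv_error), ]
  expect_equal(m$params$eta, chosen$eta)
  expect_equal(m$params$max_depth, chosen$max_depth)
})

test_that("classification calls use an inclusive threshold and are monotone", {
  set.seed(3)
  n <- 60
  feat <- data.frame(genus = sprintf("g%03d", 1:n),
                     f1 = c(rnorm(n / 2, -2), rnorm(n / 2, 2)))
  labels <- data.frame(genus = feat$genus,
                       label = rep(c("negative", "positive"), each = n / 2))
  m <- train_filter(feat, labels, seed = 3, nrounds = 40)
  calls <- classify_genera(m, feat)
  # inclusive boundary: calling at a threshold equal to an attained
  # probability keeps that genus positive
  p_star <- max(calls$probability)
  at <- classify_genera(m, feat, threshold = p_star)
  expect_true(all(at$call[at$probability == p_star]))
  expect_false(any(at$call[at$probability < p_star]))
  # raising the threshold never grows the positive set
  lo <- classify_genera(m, feat, threshold = 0.3)
  hi <- classify_genera(m, feat, threshold = 0.9)
  expect_true(all(hi$call <= lo$call))

  bad <- feat[, 1, drop = FALSE]
  bad$other <- 1
  expect_error(classify_genera(m, bad), "f1")
})

test_that("full hyperparameter grid has 6561 combinations", {
  expect_equal(nrow(filter_grid(full = TRUE)), 6561)
  expect_equal(nrow(filter_grid()), 16)
})

test_that("kraken-style reports and occurrence CSVs parse", {
  rep_path <- tempfile(fileext = ".txt")
  writeLines(c(
    "50.00\t100\t10\t400\t300\tG\t123\t  Alces",
    "25.00\t50\t50\t200\t20\tG\t456\t  Ornithorhynchus",
    "25.00\t50\t0\t100\t90\tF\t789\t Cervidae"
  ), rep_path)
  rep <- read_kraken_report(rep_path, rank = "G")
  expect_equal(nrow(rep), 2)
  expect_equal(rep$name, c("Alces", "Ornithorhynchus"))
  expect_equal(rep$minimizers_distinct, c(300, 20))

  occ_path <- tempfile(fileext = ".csv")
  utils::write.csv(
    data.frame(taxon = "Alces", decimalLatitude = 67.8,
               decimalLongitude = 20.4, year = 1990),
    occ_path, row.names = FALSE
  )
  occ <- read_occurrences(occ_path)
  expect_equal(occ$taxon, "Alces")
})
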