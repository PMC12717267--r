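test_that("relative abundances close to 1 and invert exactly", {
  cm <- count_matrix(matrix(c(2, 3, 5, 7, 0, 3), 3, 2,
                            dimnames = list(c("a", "b", "c"), c("w1", "w2"))))
  p <- relative_abundance(cm)
  expect_equal(p[, "w1"], c(a = 0.2, b = 0.3, c = 0.5))
  expect_equal(colSums(p), c(w1 = 1, w2 = 1))
  expect_equal(sweep(p, 2, colSums(cm$counts), "*"), cm$counts,
               ignore_attr = TRUE)

  single <- count_matrix(matrix(7, 1, 1))
  expect_equal(unname(relative_abundance(single)[1, 1]), 1)

  zero_week <- count_matrix(matrix(c(1, 0), 1, 2,
                                   dimnames = list("a", c("w1", "w2"))))
  expect_error(relative_abundance(zero_week), "w2")
})

test_that("prevalence filter boundary is exclusive for retention", {
  counts <- matrix(1, 3, 30, dimnames = list(c("a", "b", "c"), NULL))
  counts["a", 1:20] <- 0 # 20/30 = 2/3 zero weeks -> removed
  counts["b", 1:19] <- 0 # below the threshold -> retained
  cm <- count_matrix(counts)
  filt <- prevalence_filter(cm)
  expect_equal(rownames(filt$counts), c("b", "c"))

  # at 1.0 any genus with one nonzero week survives
  one_hit <- count_matrix(rbind(a = c(1, rep(0, 29)), b = rep(1, 30)))
  expect_equal(nrow(prevalence_filter(one_hit, 1.0)$counts), 2)
  expect_error(prevalence_filter(count_matrix(matrix(0:1, 1, 2)), 0.2))
})

test_that("zero imputation follows the Bayesian-multiplicative formula", {
  cm <- count_matrix(matrix(c(0, 5, 5, 2, 4, 4), 3, 2,
                            dimnames = list(c("a", "b", "c"), c("w1", "w2"))))
  comp <- impute_zeros(cm, prior_mass = 0.5)

  # direct oracle: s = D * prior mass, t_j geometric prior, r = t*s/(n+s)
  props <- relative_abundance(cm)
  tj <- apply(props, 1, function(p) exp(mean(log(p[p > 0]))))
  tj <- tj / sum(tj)
  s <- 0.5 * 3
  r_a <- tj["a"] * s / (10 + s)
  expect_equal(comp["a", "w1"], unname(r_a), tolerance = 1e-12)
  # nonzero ratios preserved by the multiplicative re-closure
  expect_equal(comp["b", "w1"] / comp["c", "w1"], 1)
  expect_equal(unname(colSums(comp)), c(1, 1))
  # weeks without zeros are untouched
  expect_equal(comp[, "w2"], props[, "w2"])
  # replaced cell below the smallest observed proportion of its week
  expect_lt(comp["a", "w1"], min(props[props[, "w1"] > 0, "w1"]))
})

test_that("imputation preserves within-week ranking of nonzero parts", {
  set.seed(5)
  m <- matrix(rpois(200, 3), 10, 20)
  m[1, ] <- 0
  m[1, 1:10] <- 1
  cm <- count_matrix(m)
  comp <- impute_zeros(cm)
  props <- relative_abundance(cm)
  for (w in 1:20) {
    nz <- which(m[, w] > 0)
    expect_equal(order(comp[nz, w]), order(props[nz, w]))
  }
})

test_that("CLR is centred and uniform compositions map to zero", {
  comp <- airedna:::composition_matrix(matrix(1 / 3, 3, 4))
  clr <- logratio_transform(comp, "clr")
  expect_equal(max(abs(clr$coords)), 0)

  rc <- random_composition(8, 15)
  clr <- logratio_transform(rc, "clr")
  expect_lt(max(abs(rowSums(clr$coords))), 1e-9)
})

test_that("ILR coordinates are isometric to the Aitchison geometry", {
  rc <- random_composition(5, 10, seed = 2)
  ilr <- logratio_transform(rc, "ilr")
  expect_equal(ncol(ilr$coords), 4)
  # brute-force Aitchison norm: ||clr(x)||_2
  for (w in 1:10) {
    x <- rc[, w]
    clr <- log(x) - mean(log(x))
    expect_equal(sqrt(sum(ilr$coords[w, ]^2)), sqrt(sum(clr^2)),
                 tolerance = 1e-10)
  }
})

test_that("PLR first coordinate matches its closed form", {
  rc <- random_composition(6, 8, seed = 3)
  plr <- logratio_transform(rc, "plr", pivot = "g03")
  d <- 6
  for (w in 1:8) {
    x <- rc[, w]
    expected <- sqrt((d - 1) / d) *
      log(x["g03"] / exp(mean(log(x[setdiff(names(x), "g03")]))))
    expect_equal(unname(plr$coords[w, 1]), unname(expected),
                 tolerance = 1e-12)
  }
})

test_that("log-ratio transforms invert exactly", {
  rc <- random_composition(7, 12, seed = 4)
  for (kind in c("clr", "ilr", "plr")) {
    lr <- logratio_transform(rc, kind)
    back <- inverse_logratio(lr)
    expect_lt(max(abs(back - rc)), 1e-10)
    expect_lt(max(abs(colSums(back) - 1)), 1e-12)
  }
  # inverse of zero CLR coordinates is uniform
  lr <- logratio_transform(random_composition(4, 2), "clr")
  uni <- inverse_logratio(lr, coords = matrix(0, 2, 4))
  expect_equal(unname(unclass(uni)), matrix(0.25, 4, 2))
  lr$kind <- "bogus"
  expect_error(inverse_logratio(lr), "unknown")
})

test_that("transforms are permutation-equivariant in genus order", {
  rc <- random_composition(6, 9, seed = 6)
  perm <- c(4, 1, 6, 2, 5, 3)
  rp <- airedna:::composition_matrix(unclass(rc)[perm, ])
  clr1 <- logratio_transform(rc, "clr")$coords
  clr2 <- logratio_transform(rp, "clr")$coords
  expect_equal(clr2, clr1[, perm])
  vm1 <- variation_matrix(rc)
  vm2 <- variation_matrix(rp)
  expect_equal(vm2, vm1[perm, perm])
})

test_that("variation matrix matches the brute-force double loop", {
  rc <- random_composition(6, 20, seed = 7)
  vm <- variation_matrix(rc)
  m <- unclass(rc)
  for (i in 1:6) {
    for (j in 1:6) {
      expect_equal(vm[i, j], var(log(m[i, ] / m[j, ])), tolerance = 1e-12)
    }
  }
  expect_equal(vm, t(vm))
  expect_equal(unname(diag(vm)), rep(0, 6))

  # proportional genera have zero log-ratio variance
  m2 <- rbind(m, 3 * m[1, ])
  vm2 <- variation_matrix(airedna:::composition_matrix(m2))
  expect_equal(vm2[1, 7], 0)

  # closure invariance: rescaling weeks changes nothing
  m3 <- sweep(m, 2, runif(20, 0.5, 2), "*")
  expect_equal(variation_matrix(airedna:::composition_matrix(m3)), vm,
               tolerance = 1e-12)
})

test_that("count matrices round-trip through TSV", {
  w <- small_world()
  p1 <- tempfile(fileext = ".tsv")
  p2 <- tempfile(fileext = ".tsv")
  write_count_matrix(w$counts, p1, p2)
  back <- read_count_matrix(p1, p2)
  expect_equal(back$counts, w$counts$counts)
  expect_equal(back$meta$read_length, w$counts$meta$read_length,
               tolerance = 1e-6)
})
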