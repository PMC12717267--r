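#' Select a classification stringency setting
#'
#' Given a grid of candidate classifier stringency settings (minimum
#' confidence score, minimum hit groups) with the resulting fraction of reads
#' classified and the fraction classified to regionally plausible genera,
#' returns the setting that maximizes the regional fraction subject to
#' retaining at least `min_retained` of the maximum total classified
#' fraction. Ties go to the least stringent setting.
#'
#' @param grid Data frame with columns `confidence`, `hit_groups`,
#'   `frac_classified`, `frac_regional`.
#' @param min_retained Minimum share of the maximum classified fraction that
#'   must be retained (default 0.5).
#' @return A list with `confidence` and `hit_groups`.
#' @export
select_stringency <- function(grid, min_retained = 0.5) {
  need <- c("confidence", "hit_groups", "frac_classified", "frac_regional")
  if (!nrow(grid)) stop("empty stringency grid")
  if (!all(need %in% names(grid))) {
    stop("grid needs columns: ", paste(need, collapse = ", "))
  }
  ok <- grid$frac_classified >= min_retained * max(grid$frac_classified)
  cand <- grid[ok, , drop = FALSE]
  # least stringent first so ties resolve to the lowest-stringency row
  cand <- cand[order(cand$confidence, cand$hit_groups), , drop = FALSE]
  best <- cand[which.max(cand$frac_regional), ]
  list(confidence = best$confidence, hit_groups = best$hit_groups)
}

#' Curate positive/negative training labels from occurrence records
#'
#' Positive: at least `positive_min_n` occurrence records within
#' `positive_km` of the monitoring station (within the study window if
#' `years` is given), plus any `always_positive` taxa. Negative: zero records
#' within `negative_km` AND no family (or lower rank) shared with a European
#' taxon lacking a reference genome. All other genera stay unlabeled.
#' Distances are great-circle (haversine, spherical Earth). Records without
#' coordinates are skipped, with the count reported as a warning.
#'
#' @param occurrences Darwin-Core-style data frame: `taxon`,
#'   `decimalLatitude`, `decimalLongitude`, optional `year`.
#' @param station Station coordinates, `c(lat = ..., lon = ...)`.
#' @param genome_table Optional data frame `family`, `has_reference`; genera
#'   whose family appears with `has_reference = FALSE` cannot be labeled
#'   negative.
#' @param taxonomy Optional data frame `genus`, `family` used to resolve
#'   family conflicts.
#' @param genera Optional universe of genera to label (default: taxa present
#'   in `occurrences`, which leaves taxa with no records unlabeled unless
#'   listed here).
#' @param positive_min_n,positive_km,negative_km Rule parameters (defaults 4,
#'   40 km, 5000 km).
#' @param always_positive Taxa labeled positive regardless of records.
#' @param years Optional `c(first, last)` study window filter on records.
#' @return Data frame `genus`, `label` (positive/negative), `provenance`.
#' @export
curate_labels <- function(occurrences, station, genome_table = NULL,
                          taxonomy = NULL, genera = NULL,
                          positive_min_n = 4, positive_km = 40,
                          negative_km = 5000, always_positive = NULL,
                          years = NULL) {
  occ <- as.data.frame(occurrences)
  bad <- is.na(occ$decimalLatitude) | is.na(occ$decimalLongitude)
  if (any(bad)) {
    warning(sum(bad), " occurrence records without coordinates skipped")
    occ <- occ[!bad, , drop = FALSE]
  }
  if (!is.null(years) && !is.null(occ$year)) {
    occ <- occ[occ$year >= years[1] & occ$year <= years[2], , drop = FALSE]
  }
  occ$dist_km <- haversine_km(occ$decimalLatitude, occ$decimalLongitude,
                              station[["lat"]], station[["lon"]])

  genera <- genera %||% sort(unique(occ$taxon))
  n_near <- vapply(genera, function(g) {
    sum(occ$taxon == g & occ$dist_km <= positive_km)
  }, numeric(1))
  n_region <- vapply(genera, function(g) {
    sum(occ$taxon == g & occ$dist_km <= negative_km)
  }, numeric(1))

  family_conflict <- rep(FALSE, length(genera))
  if (!is.null(genome_table) && !is.null(taxonomy)) {
    unsequenced <- genome_table$family[!genome_table$has_reference]
    fam <- taxonomy$family[match(genera, taxonomy$genus)]
    family_conflict <- !is.na(fam) & fam %in% unsequenced
  }

  label <- rep(NA_character_, length(genera))
  provenance <- rep(NA_character_, length(genera))
  pos <- n_near >= positive_min_n
  label[pos] <- "positive"
  provenance[pos] <- sprintf(">= %d records within %g km", positive_min_n,
                             positive_km)
  ap <- genera %in% (always_positive %||% character(0))
  label[ap] <- "positive"
  provenance[ap] <- "always-positive list"
  neg <- is.na(label) & n_region == 0 & !family_conflict
  label[neg] <- "negative"
  provenance[neg] <- sprintf("no records within %g km, no family conflict",
                             negative_km)

  keep <- !is.na(label)
  data.frame(genus = genera[keep], label = label[keep],
             provenance = provenance[keep], row.names = NULL)
}

#' Per-genus pivot log-ratio series
#'
#' For each genus, its first pivot coordinate: the scaled log-ratio of the
#' genus against the geometric mean of all the others,
#' \eqn{\sqrt{(D-1)/D}\,\ln(x_g / g(\mathrm{others}))}, computed for every
#' week. Equivalent to `sqrt(D/(D-1))` times the CLR coordinate.
#'
#' @param comp A strictly positive `composition_matrix`.
#' @return Genus x week matrix of pivot log-ratio values.
#' @export
genus_plr <- function(comp) {
  m <- unclass(comp)
  d <- nrow(m)
  lx <- log(m)
  clr <- lx - matrix(colMeans(lx), d, ncol(m), byrow = TRUE)
  out <- sqrt(d / (d - 1)) * clr
  attr(out, "meta") <- attr(comp, "meta")
  out
}

longest_run <- function(x) {
  if (!any(x)) return(0L)
  r <- rle(x)
  max(r$lengths[r$values])
}

#' Build the taxon-filter feature table
#'
#' Emits 31 documented per-genus statistics in four families, reflecting the
#' expectation that false-positive genera have lower read counts, are
#' detected rarely or unusually frequently, have distinct per-read
#' classification quality profiles, and occur in lineages with more sequence
#' data or larger genomes; plus one-hot encoded kingdoms and the per-genus
#' weekly PLR abundances.
#'
#' The 31 statistics are:
#' * Abundance level (8): `plr_mean`, `plr_median`, `plr_max`, `plr_min`,
#'   `plr_sd`, `plr_iqr`, `log_total_reads`, `log_max_count`.
#' * Detection frequency and shape (10): `zero_fraction`, `detect_weeks`,
#'   `longest_detect_run`, `longest_absence_run`, `mean_detect_gap`,
#'   `burstiness`, `dispersion_index`, `plr_skewness`, `plr_acf1`,
#'   `plr_seasonal_range`.
#' * Classification quality (8): `minimizer_distinct_ratio`,
#'   `mean_confidence`, `direct_clade_ratio`, `log_clade_reads`,
#'   `log_direct_reads`, `reads_per_minimizer`, `log_minimizers_distinct`,
#'   `minimizers_per_read`.
#' * Database / genome size (5): `log_db_bytes`, `log_genome_size`,
#'   `reads_per_db_byte`, `reads_per_genome_base`, `db_per_genome`.
#'
#' @param counts A [count_matrix()] covering all candidate genera (taxonomy
#'   with a `kingdom` column enables the one-hot block).
#' @param summaries Read-classification summary data frame with columns
#'   `genus`, `total_reads`, `clade_reads`, `direct_reads`,
#'   `minimizers_total`, `minimizers_distinct`, `mean_confidence`,
#'   `db_bytes`, `genome_size`.
#' @param plr Optional genus x week PLR matrix (default: computed via
#'   [genus_plr()] on zero-imputed proportions of `counts`).
#' @return A `feature_table` data frame (`genus` + numeric features, no
#'   missing values).
#' @export
build_features <- function(counts, summaries, plr = NULL) {
  genera <- rownames(counts$counts)
  missing <- setdiff(genera, summaries$genus)
  if (length(missing)) {
    stop("missing read-classification summaries for: ",
         paste(missing, collapse = ", "))
  }
  s <- summaries[match(genera, summaries$genus), ]

  if (is.null(plr)) {
    comp <- impute_zeros(count_matrix(counts$counts + 0L, meta = counts$meta))
    plr <- genus_plr(comp)
  }
  plr <- plr[genera, , drop = FALSE]
  x <- counts$counts
  meta <- counts$meta
  cw <- meta$week %||% rep(1L, ncol(x))

  skewness <- function(v) {
    sv <- sd(v)
    if (sv == 0) return(0)
    mean(((v - mean(v)) / sv)^3)
  }
  acf1 <- function(v) {
    if (sd(v) == 0) return(0)
    acf(v, lag.max = 1, plot = FALSE)$acf[2]
  }
  seasonal_range <- function(v) {
    med <- tapply(v, cw, median)
    diff(range(med))
  }
  gap_stats <- function(det) {
    gaps <- diff(which(det))
    if (length(gaps) < 1) return(c(gap = ncol(x), burst = 0))
    mg <- mean(gaps)
    sg <- sd(gaps)
    burst <- if (length(gaps) < 2 || (sg + mg) == 0) 0 else (sg - mg) / (sg + mg)
    c(gap = mg, burst = burst)
  }

  feat <- data.frame(genus = genera)
  # abundance level
  feat$plr_mean <- rowMeans(plr)
  feat$plr_median <- apply(plr, 1, median)
  feat$plr_max <- apply(plr, 1, max)
  feat$plr_min <- apply(plr, 1, min)
  feat$plr_sd <- apply(plr, 1, sd)
  feat$plr_iqr <- apply(plr, 1, function(v) diff(quantile(v, c(0.25, 0.75))))
  feat$log_total_reads <- log1p(rowSums(x))
  feat$log_max_count <- log1p(apply(x, 1, max))
  # detection frequency and shape
  det <- x > 0
  feat$zero_fraction <- rowMeans(!det)
  feat$detect_weeks <- rowSums(det)
  feat$longest_detect_run <- apply(det, 1, longest_run)
  feat$longest_absence_run <- apply(!det, 1, longest_run)
  gaps <- t(apply(det, 1, gap_stats))
  feat$mean_detect_gap <- gaps[, "gap"]
  feat$burstiness <- gaps[, "burst"]
  feat$dispersion_index <- apply(x, 1, function(v) {
    if (mean(v) == 0) 0 else var(v) / mean(v)
  })
  feat$plr_skewness <- apply(plr, 1, skewness)
  feat$plr_acf1 <- apply(plr, 1, acf1)
  feat$plr_seasonal_range <- apply(plr, 1, seasonal_range)
  # classification quality
  feat$minimizer_distinct_ratio <- s$minimizers_distinct / pmax(1, s$minimizers_total)
  feat$mean_confidence <- s$mean_confidence
  feat$direct_clade_ratio <- s$direct_reads / pmax(1, s$clade_reads)
  feat$log_clade_reads <- log1p(s$clade_reads)
  feat$log_direct_reads <- log1p(s$direct_reads)
  feat$reads_per_minimizer <- s$total_reads / pmax(1, s$minimizers_total)
  feat$log_minimizers_distinct <- log1p(s$minimizers_distinct)
  feat$minimizers_per_read <- s$minimizers_distinct / pmax(1, s$total_reads)
  # database / genome size
  feat$log_db_bytes <- log1p(s$db_bytes)
  feat$log_genome_size <- log1p(s$genome_size)
  feat$reads_per_db_byte <- s$total_reads / pmax(1, s$db_bytes)
  feat$reads_per_genome_base <- s$total_reads / pmax(1, s$genome_size)
  feat$db_per_genome <- s$db_bytes / pmax(1, s$genome_size)

  # one-hot kingdoms
  kingdom <- counts$taxonomy$kingdom[match(genera, counts$taxonomy$genus)] %||%
    rep("unknown", length(genera))
  for (k in sort(unique(kingdom))) {
    feat[[paste0("kingdom_", k)]] <- as.numeric(kingdom == k)
  }

  # weekly PLR abundances
  wk <- as.data.frame(plr)
  names(wk) <- sprintf("plr_w%04d", seq_len(ncol(plr)))
  feat <- cbind(feat, wk)

  num <- vapply(feat, is.numeric, logical(1))
  feat[num] <- lapply(feat[num], function(v) {
    v[!is.finite(v)] <- 0
    v
  })
  rownames(feat) <- NULL
  class(feat) <- c("feature_table", class(feat))
  feat
}

feature_matrix <- function(features) {
  m <- as.matrix(features[, setdiff(names(features), "genus"), drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- features$genus
  m
}

#' Default and full hyperparameter grids for the taxon filter
#'
#' The default grid is a desk-scale 16-combination search (eta 0.1/0.3,
#' max_depth 3/5, subsample 0.7/1.0, colsample 0.4/0.7). `full = TRUE`
#' reproduces a 6561-combination search (3 values for each of 8
#' hyperparameters).
#'
#' @param full Return the full 6561-combination grid?
#' @return Data frame of hyperparameter combinations.
#' @export
filter_grid <- function(full = FALSE) {
  if (!full) {
    expand.grid(
      eta = c(0.1, 0.3), max_depth = c(3, 5), subsample = c(0.7, 1.0),
      colsample_bytree = c(0.4, 0.7),
      min_child_weight = 2, lambda = 1.5, alpha = 1e-5, gamma = 0.3
    )
  } else {
    expand.grid(
      eta = c(0.1, 0.3, 0.5), max_depth = c(3, 5, 7),
      subsample = c(0.5, 0.7, 1.0), colsample_bytree = c(0.4, 0.7, 1.0),
      min_child_weight = c(1, 2, 5), lambda = c(0.5, 1.5, 3),
      alpha = c(0, 1e-5, 1e-2), gamma = c(0, 0.3, 1)
    )
  }
}

#' Train the gradient-boosted taxon filter
#'
#' Reserves a stratified holdout (13% by default), optionally grid-searches
#' hyperparameters with k-fold cross-validation on the training genera
#' (choosing the smallest CV binary error rate), refits on all training
#' genera, and reports holdout precision, recall and error rate at the
#' decision threshold. Default hyperparameters are preset to eta 0.3,
#' max_depth 5, min_child_weight 2, subsample 0.7, colsample_bytree 0.4,
#' alpha 1e-5, gamma 0.3, lambda 1.5.
#'
#' @param features A [build_features()] table.
#' @param labels A label data frame (`genus`, `label` in positive/negative).
#' @param holdout_fraction Fraction reserved as holdout (default 0.13).
#' @param seed RNG seed (mandatory for reproducibility).
#' @param grid Optional hyperparameter grid (see [filter_grid()]); `NULL`
#'   skips the search and uses the preset values.
#' @param nfold Cross-validation folds (default 5).
#' @param nrounds Boosting rounds (default 150).
#' @param threshold Decision threshold on predicted probability (default
#'   0.75, inclusive).
#' @return A `filter_model`: the fitted booster, chosen hyperparameters, CV
#'   record, threshold, holdout genus ids and holdout metrics.
#' @export
train_filter <- function(features, labels, holdout_fraction = 0.13, seed = 1,
                         grid = NULL, nfold = 5, nrounds = 150,
                         threshold = 0.75) {
  lab <- labels[labels$genus %in% features$genus, ]
  feat <- features[match(lab$genus, features$genus), ]
  y <- as.numeric(lab$label == "positive")
  if (length(unique(y)) < 2) stop("both classes required for training")

  with_seed(seed, {
    # stratified holdout
    hold <- unlist(lapply(c(0, 1), function(cl) {
      idx <- which(y == cl)
      sample(idx, max(1, round(holdout_fraction * length(idx))))
    }))
    train_idx <- setdiff(seq_along(y), hold)

    xm <- feature_matrix(feat)
    xt <- xm[train_idx, , drop = FALSE]
    yt <- y[train_idx]

    params <- list(eta = 0.3, max_depth = 5, min_child_weight = 2,
                   subsample = 0.7, colsample_bytree = 0.4, alpha = 1e-5,
                   gamma = 0.3, lambda = 1.5)
    cv_record <- NULL
    if (!is.null(grid)) {
      folds <- sample(rep_len(seq_len(nfold), length(yt)))
      errs <- numeric(nrow(grid))
      for (i in seq_len(nrow(grid))) {
        p <- modifyList(params, as.list(grid[i, ]))
        err <- 0
        for (f in seq_len(nfold)) {
          tr <- folds != f
          fit <- fit_gbt(xt[tr, , drop = FALSE], yt[tr], nrounds = nrounds,
                         eta = p$eta, max_depth = p$max_depth,
                         min_child_weight = p$min_child_weight,
                         subsample = p$subsample,
                         colsample_bytree = p$colsample_bytree,
                         lambda = p$lambda, alpha = p$alpha, gamma = p$gamma)
          pr <- predict(fit, xt[!tr, , drop = FALSE])
          err <- err + mean((pr >= 0.5) != yt[!tr]) / nfold
        }
        errs[i] <- err
      }
      cv_record <- cbind(grid, cv_error = errs)
      params <- modifyList(params, as.list(grid[which.min(errs), ]))
    }

    model <- fit_gbt(xt, yt, nrounds = nrounds, eta = params$eta,
                     max_depth = params$max_depth,
                     min_child_weight = params$min_child_weight,
                     subsample = params$subsample,
                     colsample_bytree = params$colsample_bytree,
                     lambda = params$lambda, alpha = params$alpha,
                     gamma = params$gamma)

    ph <- predict(model, xm[hold, , drop = FALSE])
    call <- ph >= threshold
    yh <- y[hold]
    tp <- sum(call & yh == 1)
    metrics <- list(
      precision = if (sum(call)) tp / sum(call) else NA_real_,
      recall = if (sum(yh)) tp / sum(yh) else NA_real_,
      error_rate = mean(call != (yh == 1)),
      n_holdout = length(hold)
    )

    structure(
      list(model = model, params = params, threshold = threshold,
           cv = cv_record, holdout_genera = lab$genus[hold],
           holdout = metrics, feature_names = colnames(xm), seed = seed),
      class = "filter_model"
    )
  })
}

#' @export
print.filter_model <- function(x, ...) {
  cat(sprintf(
    paste0("filter_model: threshold %.2f; holdout (n=%d) precision %.3f, ",
           "recall %.3f\n"),
    x$threshold, x$holdout$n_holdout, x$holdout$precision, x$holdout$recall
  ))
  invisible(x)
}

#' Classify genera with a trained taxon filter
#'
#' @param model A [train_filter()] model.
#' @param features A feature table with the training schema.
#' @param threshold Decision threshold (default: the model's); a genus is
#'   called positive when its probability is `>=` the threshold (inclusive).
#' @return Data frame `genus`, `probability`, `call`.
#' @export
classify_genera <- function(model, features, threshold = NULL) {
  threshold <- threshold %||% model$threshold
  xm <- feature_matrix(features)
  missing <- setdiff(model$feature_names, colnames(xm))
  if (length(missing)) {
    stop("feature schema mismatch; missing columns: ",
         paste(missing, collapse = ", "))
  }
  prob <- predict(model$model, xm[, model$feature_names, drop = FALSE])
  data.frame(genus = features$genus, probability = prob,
             call = prob >= threshold)
}

#' Read a Kraken2-style report with minimizer columns
#'
#' Expects the 8-column report layout: percent of reads, clade read count,
#' direct read count, total minimizers, distinct minimizers, rank code,
#' taxid, name (indented). Leading whitespace in names is stripped.
#'
#' @param path Report file.
#' @param rank Optional rank-code filter, e.g. `"G"` for genus rows.
#' @return Data frame of report rows.
#' @export
read_kraken_report <- function(path, rank = NULL) {
  df <- read.table(path, sep = "\t", quote = "", comment.char = "",
                   stringsAsFactors = FALSE)
  if (ncol(df) < 8) stop("expected 8 report columns, got ", ncol(df))
  names(df)[1:8] <- c("percent", "clade_reads", "direct_reads",
                      "minimizers_total", "minimizers_distinct", "rank_code",
                      "taxid", "name")
  df$name <- sub("^\\s+", "", df$name)
  if (!is.null(rank)) df <- df[df$rank_code == rank, , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Read Darwin-Core-style occurrence records
#'
#' @param path CSV with columns `taxon`, `decimalLatitude`,
#'   `decimalLongitude`, optional `year`.
#' @return Data frame of occurrence records.
#' @export
read_occurrences <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
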