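#' Configuration for the synthetic airborne-eDNA world
#'
#' Collects every knob of the synthetic generators. Defaults encode the
#' stated world the downstream analyses are tested against: 300 genuine
#' genera in 5 temporal clusters over 300 weeks, a seasonal amplitude of 1
#' log unit, a dominant genus surging from a 40% to an 80% community share
#' before declining, 50 spurious genera at ~1% of the median genuine count,
#' a filter-type batch change about two thirds of the way through the
#' series, and southerly-biased back-trajectories.
#'
#' @param n_genera Number of genuine genera.
#' @param n_weeks Number of consecutive weeks.
#' @param n_clusters Number of planted temporal clusters.
#' @param n_harmonics Harmonics in the shared seasonal component.
#' @param seasonal_amplitude Total seasonal amplitude, log units.
#' @param noise_sd Marginal SD of the per-genus AR(1) latent noise (log
#'   units).
#' @param ar Latent AR(1) coefficient.
#' @param surge Plant a logistic surge-and-decline in the first genus?
#' @param surge_from,surge_to Community share of the surge genus before and
#'   at the peak of the surge.
#' @param lib_mean,lib_dispersion Weekly library size: negative-binomial mean
#'   and size.
#' @param rl_mean,rl_sd Weekly mean read length: level (bp) and SD of its
#'   smooth AR(1) variation.
#' @param rl_bias_sd SD of the per-genus read-length bias coefficient (log
#'   units per SD of read length); 0 disables the bias.
#' @param batch_week Week of the filter-type change (`NULL`: 65% through the
#'   series); must lie inside the series.
#' @param batch_sd SD of per-genus offsets induced by the filter change; 0
#'   disables the batch effect.
#' @param n_spurious_genera Spurious (false-positive) genera to spike in.
#' @param spurious_count_scale Spurious count level relative to the median
#'   genuine per-genus mean count.
#' @param traj_bias_bearing Mean bearing (degrees) of back-trajectories.
#' @param traj_concentration Directional concentration; 0 gives uniform
#'   bearings (wrapped-normal SD `1/sqrt(concentration)` otherwise).
#' @param traj_starts_per_week Trajectory starts per week.
#' @param traj_heights,traj_durations Start heights (m) and durations (h)
#'   sampled per trajectory.
#' @param traj_step_h Hours between recorded endpoints.
#' @param traj_speed_kmh Mean transport speed.
#' @param n_routes Survey routes.
#' @param survey_ar Route AR(1) coefficient.
#' @param survey_noise_sd Marginal SD of route AR(1) noise (log scale).
#' @param survey_route_offset_sd SD of route level offsets (log scale).
#' @param survey_genera Genus ids surveyed (`NULL`: the first genus).
#' @param observed_mask Restrict to the archival sampling design (non-winter
#'   calendar weeks 17-44 of even-numbered years)?
#' @param start_year First calendar year.
#' @param station Monitoring-station coordinates (lat, lon).
#' @param seed Integer seed fixing every downstream draw.
#' @return A validated `synthetic_config` list.
#' @export
synthetic_config <- function(n_genera = 300, n_weeks = 300, n_clusters = 5,
                             n_harmonics = 2, seasonal_amplitude = 1.0,
                             noise_sd = 0.3, ar = 0.5,
                             surge = TRUE, surge_from = 0.4, surge_to = 0.8,
                             lib_mean = 1e5, lib_dispersion = 8,
                             rl_mean = 120, rl_sd = 10, rl_bias_sd = 0.2,
                             batch_week = NULL, batch_sd = 0.5,
                             n_spurious_genera = 50,
                             spurious_count_scale = 0.01,
                             traj_bias_bearing = 180, traj_concentration = 4,
                             traj_starts_per_week = 4,
                             traj_heights = c(10, 100, 300, 500),
                             traj_durations = c(24, 48, 72),
                             traj_step_h = 6, traj_speed_kmh = 20,
                             n_routes = 3, survey_ar = 0.4,
                             survey_noise_sd = 0.2,
                             survey_route_offset_sd = 0.5,
                             survey_genera = NULL,
                             observed_mask = FALSE, start_year = 1974,
                             station = c(lat = 67.84, lon = 20.42),
                             seed = 1L) {
  cfg <- as.list(environment())
  if (cfg$n_genera < 1 || cfg$n_weeks < 1 || cfg$n_clusters < 1) {
    stop("counts must be >= 1")
  }
  if (cfg$n_clusters > cfg$n_genera) stop("n_clusters > n_genera")
  if (is.null(cfg$batch_week)) cfg$batch_week <- max(2, floor(0.65 * n_weeks))
  if (cfg$batch_week < 1 || cfg$batch_week > cfg$n_weeks) {
    stop("batch_week outside series")
  }
  if (cfg$n_spurious_genera < 0) stop("n_spurious_genera must be >= 0")
  if (cfg$traj_concentration < 0) stop("traj_concentration must be >= 0")
  class(cfg) <- "synthetic_config"
  cfg
}

seasonal_component <- function(t, coefs, period = 52.18) {
  k <- nrow(coefs)
  out <- numeric(length(t))
  for (i in seq_len(k)) {
    w <- 2 * pi * i * t / period
    out <- out + coefs[i, 1] * sin(w) + coefs[i, 2] * cos(w)
  }
  out
}

#' Generate a latent community with planted cluster structure
#'
#' Builds per-genus latent log-abundance series: a cluster-shared seasonal
#' harmonic + long-term trend component, a genus-level offset, and
#' independent AR(1) noise. Genera in the same cluster therefore share their
#' temporal shape. With `surge = TRUE`, the first genus's latent series is
#' set so that its softmax community share follows a logistic
#' surge-and-decline path (`surge_from` to `surge_to`, then a decline to
#' about 75% of the peak).
#'
#' @param config A [synthetic_config()].
#' @return A `community_truth` object: genus ids, cluster ids (contiguous
#'   from 1), latent matrix (genera x weeks, log units), per-genus trend
#'   type, seasonal coefficients, kingdoms, and the reference-era composition
#'   (softmax of mean latent over the first third of weeks).
#' @export
make_community <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  with_seed(config$seed, {
    ng <- config$n_genera
    nw <- config$n_weeks
    k <- config$n_clusters
    t <- seq_len(nw)

    cluster <- sort(rep_len(seq_len(k), ng))
    genus <- sprintf("g%03d", seq_len(ng))

    trend_types <- rep_len(c("flat", "linear"), k)
    cl_seasonal <- vector("list", k)
    cl_trend <- matrix(0, k, nw)
    for (c in seq_len(k)) {
      # first harmonic: evenly spaced phases so planted clusters are
      # distinct by construction; higher harmonics randomized
      phase <- 2 * pi * (c - 1) / k
      raw <- matrix(0, config$n_harmonics, 2)
      raw[1, ] <- c(cos(phase), sin(phase))
      if (config$n_harmonics > 1) {
        hi <- matrix(rnorm(2 * (config$n_harmonics - 1)),
                     config$n_harmonics - 1, 2)
        hi <- hi / sqrt(sum(hi^2)) * 0.4
        raw[-1, ] <- hi
        raw <- raw / sqrt(sum(raw^2))
      }
      cl_seasonal[[c]] <- raw * config$seasonal_amplitude
      if (trend_types[c] == "linear") {
        slope <- runif(1, -1, 1)
        cl_trend[c, ] <- slope * (t - 1) / (nw - 1)
      }
    }

    offset <- rnorm(ng, 0, 1)
    latent <- matrix(0, ng, nw, dimnames = list(genus, NULL))
    innov_sd <- config$noise_sd * sqrt(1 - config$ar^2)
    for (g in seq_len(ng)) {
      c <- cluster[g]
      noise <- numeric(nw)
      if (config$noise_sd > 0) {
        noise[1] <- rnorm(1, 0, config$noise_sd)
        for (i in 2:nw) {
          noise[i] <- config$ar * noise[i - 1] + rnorm(1, 0, innov_sd)
        }
      }
      latent[g, ] <- offset[g] +
        seasonal_component(t, cl_seasonal[[c]]) + cl_trend[c, ] + noise
    }

    trend_type <- trend_types[cluster]
    surge_genus <- character(0)
    if (isTRUE(config$surge)) {
      s_rise <- config$surge_from +
        (config$surge_to - config$surge_from) *
          stats::plogis((t - 0.45 * nw) / (0.05 * nw))
      s <- s_rise * (1 - 0.25 * stats::plogis((t - 0.8 * nw) / (0.06 * nw)))
      others <- log(colSums(exp(latent[-1, , drop = FALSE])))
      latent[1, ] <- log(s / (1 - s)) + others
      trend_type[1] <- "logistic-surge"
      surge_genus <- genus[1]
      attr(latent, "surge_share") <- s
    }

    kingdoms <- sample(c("Fungi", "Viridiplantae", "Metazoa", "Bacteria"),
                       ng, replace = TRUE)

    ref_weeks <- seq_len(max(1, floor(nw / 3)))
    ref_lat <- rowMeans(latent[, ref_weeks, drop = FALSE])
    reference <- exp(ref_lat - max(ref_lat))
    reference <- reference / sum(reference)

    structure(
      list(
        genus = genus, cluster = cluster, latent = latent,
        trend_type = trend_type, seasonal = cl_seasonal,
        surge_genus = surge_genus, kingdom = kingdoms,
        reference = reference, config = config
      ),
      class = "community_truth"
    )
  })
}

#' @export
print.community_truth <- function(x, ...) {
  cat(sprintf(
    "community_truth: %d genera, %d weeks, %d clusters%s\n",
    length(x$genus), ncol(x$latent), max(x$cluster),
    if (length(x$surge_genus)) paste0(", surge genus ", x$surge_genus) else ""
  ))
  invisible(x)
}

#' Sample weekly read counts from a latent community
#'
#' Draws weekly genus counts as multinomial samples of a negative-binomial
#' library size, with cell probabilities softmax(latent + read-length bias +
#' batch offset). The read-length bias is a per-genus coefficient times the
#' standardized weekly mean read length; the batch offset is a per-genus
#' shift switched on at the filter-type change week. Week metadata (mean
#' read length, filter type, human-read fraction, totals) is populated.
#'
#' @param truth A [make_community()] result.
#' @param config The same [synthetic_config()].
#' @return A [count_matrix()] with attributes `bias_coef`, `batch_coef`.
#' @export
sample_reads <- function(truth, config) {
  stopifnot(inherits(truth, "community_truth"))
  if (ncol(truth$latent) != config$n_weeks) stop("truth weeks != config")
  with_seed(config$seed + 1L, {
    ng <- nrow(truth$latent)
    nw <- config$n_weeks
    t <- seq_len(nw)

    rl <- numeric(nw)
    rl[1] <- rnorm(1, 0, config$rl_sd)
    for (i in 2:nw) {
      rl[i] <- 0.9 * rl[i - 1] + rnorm(1, 0, config$rl_sd * sqrt(1 - 0.81))
    }
    read_length <- config$rl_mean + rl
    z_rl <- as.numeric(scale(read_length))

    bias_coef <- rnorm(ng, 0, config$rl_bias_sd)
    batch_coef <- rnorm(ng, 0, config$batch_sd)
    batch_on <- as.numeric(t >= config$batch_week)

    libsize <- pmax(1000, rnbinom(nw, mu = config$lib_mean,
                                  size = config$lib_dispersion))
    counts <- matrix(0L, ng, nw, dimnames = list(truth$genus, NULL))
    for (w in seq_len(nw)) {
      eta <- truth$latent[, w] + bias_coef * z_rl[w] +
        batch_coef * batch_on[w]
      p <- exp(eta - max(eta))
      p <- p / sum(p)
      counts[, w] <- rmultinom(1, libsize[w], p)
    }

    year <- config$start_year + (t - 1) %/% 52
    cw <- (t - 1) %% 52 + 1
    meta <- data.frame(
      week_id = sprintf("%d-W%02d", year, cw),
      year = year, week = cw,
      read_length = read_length,
      filter_type = ifelse(t < config$batch_week, "CS5.0", "HB5773"),
      human_fraction = runif(nw, 0.1, 0.4),
      total_reads = libsize
    )
    colnames(counts) <- meta$week_id

    keep <- rep(TRUE, nw)
    if (isTRUE(config$observed_mask)) {
      keep <- cw >= 17 & cw <= 44 & year %% 2 == 0
    }

    taxonomy <- data.frame(genus = truth$genus, kingdom = truth$kingdom)
    out <- count_matrix(counts[, keep, drop = FALSE],
                        meta = meta[keep, , drop = FALSE],
                        taxonomy = taxonomy)
    attr(out, "bias_coef") <- bias_coef
    attr(out, "batch_coef") <- batch_coef
    out
  })
}

#' Spike spurious (false-positive) genera into a count matrix
#'
#' Appends low-count spurious genera with sporadic or ubiquitous detection
#' patterns, generates read-classification summary metrics for every genus
#' (spurious genera get degraded profiles: low distinct-minimizer ratios,
#' low per-read confidence, large database/genome footprints), and places
#' occurrence records near the station for genuine genera but > 5000 km away
#' (or absent) for spurious ones.
#'
#' @param counts A [sample_reads()] result.
#' @param truth The generating [make_community()] truth.
#' @param config The same [synthetic_config()].
#' @return A list: `counts` (augmented [count_matrix()]), `labels`
#'   (genus/label/provenance; spurious genera negative, planted genera
#'   positive), `summaries` (a read-classification summary table), and
#'   `occurrences` (Darwin-Core-style records).
#' @export
spike_false_positives <- function(counts, truth, config) {
  with_seed(config$seed + 2L, {
    nw <- ncol(counts$counts)
    n_sp <- config$n_spurious_genera
    station <- config$station
    years <- range(counts$meta$year %||% config$start_year)

    genuine <- rownames(counts$counts)
    out_counts <- counts$counts

    sp_names <- character(0)
    if (n_sp > 0) {
      scale <- max(1, config$spurious_count_scale *
                     median(rowMeans(counts$counts)))
      sp_names <- sprintf("sp%03d", seq_len(n_sp))
      sp <- matrix(0L, n_sp, nw, dimnames = list(sp_names, colnames(out_counts)))
      for (i in seq_len(n_sp)) {
        p_det <- if (i %% 2 == 0) runif(1, 0.02, 0.15) else runif(1, 0.7, 0.95)
        det <- runif(nw) < p_det
        sp[i, det] <- pmax(1L, rpois(sum(det), scale))
      }
      out_counts <- rbind(out_counts, sp)
    }

    all_names <- rownames(out_counts)
    is_sp <- all_names %in% sp_names
    n_all <- length(all_names)

    total_reads <- rowSums(out_counts)
    clade_reads <- pmax(1, total_reads)
    direct_frac <- ifelse(is_sp, rbeta(n_all, 2, 5), rbeta(n_all, 5, 2))
    mini_total <- pmax(1, round(clade_reads * runif(n_all, 0.5, 2)))
    dist_ratio <- ifelse(is_sp, rbeta(n_all, 1.5, 8), rbeta(n_all, 8, 2))
    summaries <- data.frame(
      genus = all_names,
      total_reads = total_reads,
      clade_reads = clade_reads,
      direct_reads = round(clade_reads * direct_frac),
      minimizers_total = mini_total,
      minimizers_distinct = pmax(1, round(mini_total * dist_ratio)),
      mean_confidence = ifelse(is_sp, rbeta(n_all, 2, 6), rbeta(n_all, 6, 2)),
      db_bytes = round(ifelse(is_sp, rlnorm(n_all, 16, 1),
                              rlnorm(n_all, 14, 1))),
      genome_size = round(ifelse(is_sp, rlnorm(n_all, 17.5, 1),
                                 rlnorm(n_all, 16, 1))),
      row.names = NULL
    )

    occ <- list()
    for (g in seq_along(all_names)) {
      if (is_sp[g]) {
        n_occ <- rpois(1, 3)
        if (n_occ == 0) next
        d <- runif(n_occ, 6000, 12000)
      } else {
        n_occ <- 4 + rpois(1, 3)
        d <- runif(n_occ, 0.5, 35)
      }
      b <- runif(n_occ, 0, 360)
      pt <- destination_point(station[["lat"]], station[["lon"]], b, d)
      occ[[length(occ) + 1L]] <- data.frame(
        taxon = all_names[g],
        decimalLatitude = pt$lat, decimalLongitude = pt$lon,
        year = sample(seq(years[1], max(years)), n_occ, replace = TRUE)
      )
    }
    occurrences <- do.call(rbind, occ)

    labels <- data.frame(
      genus = all_names,
      label = ifelse(is_sp, "negative", "positive"),
      provenance = "synthetic truth"
    )

    taxonomy <- data.frame(
      genus = all_names,
      kingdom = c(truth$kingdom,
                  sample(c("Fungi", "Viridiplantae", "Metazoa", "Bacteria"),
                         n_sp, replace = TRUE))
    )
    cm <- count_matrix(out_counts, meta = counts$meta, taxonomy = taxonomy)

    list(counts = cm, labels = labels, summaries = summaries,
         occurrences = occurrences)
  })
}

#' Generate directionally biased back-trajectory endpoints
#'
#' Per week, simulates back-trajectory random-walk paths whose mean bearing
#' follows the configured directional bias (wrapped-normal dispersion
#' `1/sqrt(concentration)`; uniform when the concentration is 0). Start
#' heights are drawn from `traj_heights` and durations from
#' `traj_durations`; endpoints are recorded every `traj_step_h` hours.
#'
#' @param config A [synthetic_config()].
#' @param weeks Optional integer vector of week indices (default all).
#' @return A `trajectory_endpoints` data frame (week, traj id, date fields,
#'   hours back, lat, lon, height, start height) with the station coordinates
#'   as an attribute.
#' @export
make_trajectories <- function(config, weeks = NULL) {
  with_seed(config$seed + 3L, {
    weeks <- weeks %||% seq_len(config$n_weeks)
    station <- config$station
    kappa <- config$traj_concentration
    rows <- vector("list", length(weeks) * config$traj_starts_per_week)
    idx <- 0L
    for (w in weeks) {
      year <- config$start_year + (w - 1) %/% 52
      cw <- (w - 1) %% 52 + 1
      for (s in seq_len(config$traj_starts_per_week)) {
        height <- sample(config$traj_heights, 1)
        duration <- sample(config$traj_durations, 1)
        bearing0 <- if (kappa > 0) {
          (config$traj_bias_bearing + rnorm(1, 0, 180 / pi / sqrt(kappa))) %% 360
        } else {
          runif(1, 0, 360)
        }
        n_steps <- duration / config$traj_step_h
        # walk in a local azimuthal-equidistant frame (km east/north of the
        # station) so isotropic headings give isotropic endpoint azimuths;
        # endpoints are projected back along the great circle
        px <- 0
        py <- 0
        bearing <- bearing0
        step_rows <- vector("list", n_steps)
        for (st in seq_len(n_steps)) {
          bearing <- (bearing + rnorm(1, 0, 8)) %% 360
          dist <- config$traj_speed_kmh * config$traj_step_h *
            runif(1, 0.7, 1.3)
          px <- px + dist * sin(bearing * pi / 180)
          py <- py + dist * cos(bearing * pi / 180)
          azimuth <- (atan2(px, py) * 180 / pi) %% 360
          rng <- sqrt(px^2 + py^2)
          pt <- destination_point(station[["lat"]], station[["lon"]],
                                  azimuth, rng)
          step_rows[[st]] <- data.frame(
            week = w, traj_id = sprintf("w%04d_t%02d", w, s),
            year = year, month = 1 + (cw - 1) %/% 5, day = 1 + (cw - 1) %% 28,
            hour = (s - 1) * 6,
            hours_back = st * config$traj_step_h,
            lat = pt$lat, lon = pt$lon,
            height = height * runif(1, 0.8, 1.2),
            start_height = height
          )
        }
        idx <- idx + 1L
        rows[[idx]] <- do.call(rbind, step_rows)
      }
    }
    out <- do.call(rbind, rows)
    attr(out, "station") <- station
    class(out) <- c("trajectory_endpoints", class(out))
    out
  })
}

#' Generate route-by-year survey counts coupled to a latent trend
#'
#' Point-transect-style counts: per surveyed genus, annual counts on each
#' route are `round(exp(latent annual mean + route offset + AR(1) noise))`,
#' with latent annual means taken from the community truth (recentred so
#' counts land on a realistic scale). The ground-truth latent trend is
#' retained as an attribute.
#'
#' @param truth A [make_community()] result.
#' @param config The same [synthetic_config()].
#' @return A `survey_series` data frame (route, year, genus, count) with
#'   attributes `latent_annual` and `route_offsets`.
#' @export
make_survey <- function(truth, config) {
  genera <- config$survey_genera %||% truth$genus[1]
  if (!all(genera %in% truth$genus)) stop("survey genera missing from truth")
  with_seed(config$seed + 4L, {
    nw <- config$n_weeks
    year_idx <- (seq_len(nw) - 1) %/% 52
    years <- config$start_year + sort(unique(year_idx))
    offsets <- c(0, rnorm(config$n_routes - 1, 0, config$survey_route_offset_sd))
    phi <- config$survey_ar
    innov <- config$survey_noise_sd * sqrt(1 - phi^2)

    rows <- list()
    latent_annual <- list()
    for (g in genera) {
      lat_g <- truth$latent[g, ]
      a_y <- tapply(lat_g, year_idx, mean)
      a_y <- a_y - mean(a_y) + log(50)
      latent_annual[[g]] <- setNames(as.numeric(a_y), years)
      for (r in seq_len(config$n_routes)) {
        e <- numeric(length(a_y))
        if (config$survey_noise_sd > 0) {
          e[1] <- rnorm(1, 0, config$survey_noise_sd)
          for (i in seq_along(e)[-1]) e[i] <- phi * e[i - 1] + rnorm(1, 0, innov)
        }
        rows[[length(rows) + 1L]] <- data.frame(
          route = sprintf("route%02d", r), year = years, genus = g,
          count = round(exp(a_y + offsets[r] + e))
        )
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    attr(out, "latent_annual") <- latent_annual
    attr(out, "route_offsets") <- offsets
    class(out) <- c("survey_series", class(out))
    out
  })
}

#' Write trajectory endpoints in a HYSPLIT tdump-like layout
#'
#' Columns: traj id, year, month, day, hour, hours back, lat, lon, height.
#'
#' @param endpoints A `trajectory_endpoints` object.
#' @param path Output path.
#' @export
write_trajectories <- function(endpoints, path) {
  df <- as.data.frame(endpoints)[, c(
    "traj_id", "year", "month", "day", "hour", "hours_back",
    "lat", "lon", "height"
  )]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write survey counts as long-format CSV (route, year, genus, count)
#'
#' @param survey A `survey_series`.
#' @param path Output path.
#' @export
write_survey <- function(survey, path) {
  utils::write.csv(as.data.frame(survey), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
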