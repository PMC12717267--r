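#' Distance-class upper edges used for catchment summaries (km)
#' @export
catchment_edges <- c(2, 5, 10, 20, 31, 50, 100, 180, 310, 520, 860)

#' Eight cardinal/intercardinal sector labels, N centred at 0 degrees
#' @export
catchment_sectors <- c("N", "NE", "E", "SE", "S", "SW", "W", "NW")

bearing_sector <- function(bearing) {
  catchment_sectors[(floor(((bearing + 22.5) %% 360) / 45)) + 1]
}

#' Bin trajectory endpoints into direction-by-distance catchment sums
#'
#' Assigns each endpoint to one of eight 45-degree bearing sectors (N centred
#' at 0 degrees) and a distance class, the smallest class edge at or above
#' its great-circle distance from the station; endpoints beyond the last edge
#' go to an `overflow` class so total weight is conserved.
#'
#' @param endpoints A `trajectory_endpoints` data frame (columns `week`,
#'   `lat`, `lon`, optional `weight`).
#' @param station Station coordinates `c(lat = ..., lon = ...)`; defaults to
#'   the attribute stored on the endpoints.
#' @param edges Distance-class upper edges (km), strictly increasing.
#' @return A `catchment_summary`: week x 8 x 12 array of summed weights plus
#'   the class edges.
#' @export
bin_endpoints <- function(endpoints, station = NULL,
                          edges = catchment_edges) {
  station <- station %||% attr(endpoints, "station")
  if (is.null(station)) stop("station coordinates required")
  if (is.unsorted(edges, strictly = TRUE)) {
    stop("class edges must be strictly increasing")
  }
  df <- as.data.frame(endpoints)
  w <- df$weight %||% rep(1, nrow(df))

  d <- haversine_km(station[["lat"]], station[["lon"]], df$lat, df$lon)
  b <- bearing_deg(station[["lat"]], station[["lon"]], df$lat, df$lon)
  sector <- bearing_sector(b)
  cls_idx <- findInterval(d, edges, left.open = TRUE) + 1 # 1..12
  classes <- c(as.character(edges), "overflow")

  weeks <- sort(unique(df$week))
  out <- array(0, c(length(weeks), 8, length(classes)),
               dimnames = list(weeks, catchment_sectors, classes))
  agg <- aggregate(w, by = list(week = df$week, sector = sector,
                                class = classes[cls_idx]), FUN = sum)
  for (i in seq_len(nrow(agg))) {
    out[as.character(agg$week[i]), agg$sector[i], agg$class[i]] <- agg$x[i]
  }
  structure(list(sums = out, edges = edges, station = station),
            class = "catchment_summary")
}

#' @export
print.catchment_summary <- function(x, ...) {
  cat(sprintf(
    "catchment_summary: %d weeks x 8 sectors x %d distance classes\n",
    dim(x$sums)[1], dim(x$sums)[3]
  ))
  invisible(x)
}

#' Moving-block bootstrap standard errors of catchment cell means
#'
#' Resamples weeks in moving blocks (default four weeks, approximating a lag
#' of one month) and reports the per-cell standard error of the mean weekly
#' sum.
#'
#' @param summary A [bin_endpoints()] result.
#' @param n_boot Bootstrap resamples (default 1000).
#' @param block_weeks Block length in weeks (default 4).
#' @param seed RNG seed.
#' @return Sector x class matrix of standard errors (attribute `boot_means`
#'   holds the resampled means).
#' @export
block_bootstrap_se <- function(summary, n_boot = 1000, block_weeks = 4,
                               seed = 1) {
  s <- summary$sums
  n <- dim(s)[1]
  if (n < block_weeks) stop("need at least block_weeks weeks")
  flat <- matrix(s, nrow = n) # weeks x (8*12)

  with_seed(seed, {
    n_blocks <- ceiling(n / block_weeks)
    starts_max <- n - block_weeks + 1
    means <- matrix(0, n_boot, ncol(flat))
    for (b in seq_len(n_boot)) {
      starts <- sample.int(starts_max, n_blocks, replace = TRUE)
      idx <- as.vector(outer(0:(block_weeks - 1), starts, "+"))[seq_len(n)]
      means[b, ] <- colMeans(flat[idx, , drop = FALSE])
    }
    se <- matrix(apply(means, 2, sd), dim(s)[2], dim(s)[3],
                 dimnames = dimnames(s)[2:3])
    attr(se, "boot_means") <- means
    se
  })
}

#' Monte-Carlo cumulative-mass radius
#'
#' Perturbs normalized distance-class masses by their standard errors
#' (truncated at zero), renormalizes each draw, and finds the smallest class
#' edge at which the cumulative mass reaches the target quantile. Reports the
#' median and the 2.5/97.5 percentiles over draws.
#'
#' @param sums Nonnegative masses per distance class (length 11, ordered by
#'   `edges`); normalized internally.
#' @param ses Standard errors per class (same length).
#' @param quantile Target cumulative mass (default 0.5).
#' @param n_draws Monte-Carlo draws (default 1000).
#' @param seed RNG seed.
#' @param edges Distance-class upper edges (km).
#' @return List: `median`, `ci` (2.5/97.5 percentiles), `draws` (radii).
#' @export
cumulative_mass_radius <- function(sums, ses, quantile = 0.5,
                                   n_draws = 1000, seed = 1,
                                   edges = catchment_edges) {
  stopifnot(length(sums) == length(edges), length(ses) == length(edges))
  if (all(sums <= 0)) stop("all-zero mass input")
  sums <- sums / sum(sums)

  radius_of <- function(m) {
    m <- m / sum(m)
    edges[which(cumsum(m) >= quantile)[1]]
  }
  with_seed(seed, {
    radii <- numeric(n_draws)
    for (i in seq_len(n_draws)) {
      m <- pmax(0, rnorm(length(sums), sums, ses))
      if (all(m == 0)) m <- sums
      radii[i] <- radius_of(m)
    }
    list(
      median = median(radii),
      ci = quantile(radii, c(0.025, 0.975)),
      draws = radii
    )
  })
}

#' Simplified quantitative transport bias analysis (SQTBA) source field
#'
#' Trajectory-ensemble receptor model: grid cells are scored by the
#' residence-time-weighted mean of the weekly concentrations whose
#' trajectories visited them, \eqn{\sum_w C_w \tau_w(cell) / \sum_w
#' \tau_w(cell)}, where \eqn{\tau_w} counts endpoint hours in the cell. Cells
#' never visited are `NA`, not zero. A wind rose of sector-summed
#' residence-weighted concentration (normalized to a maximum of 1) is
#' attached.
#'
#' @param concentration Named weekly concentration series (names = week ids
#'   matching the endpoints' `week` column), e.g. PLR-transformed abundances.
#' @param endpoints A `trajectory_endpoints` data frame.
#' @param grid_spec List with `lat_range`, `lon_range`, `cell_deg`.
#' @param station Station coordinates (defaults to the endpoints attribute).
#' @return A `source_field`: lat/lon cell grid with values, and `wind_rose`.
#' @export
sqtba_field <- function(concentration, endpoints,
                        grid_spec = list(lat_range = c(55, 80),
                                         lon_range = c(0, 45),
                                         cell_deg = 1),
                        station = NULL) {
  station <- station %||% attr(endpoints, "station")
  df <- as.data.frame(endpoints)
  weeks_c <- names(concentration)
  if (is.null(weeks_c)) stop("concentration must be a named weekly series")
  weeks_e <- as.character(unique(df$week))
  shared <- intersect(weeks_c, weeks_e)
  drop_n <- length(setdiff(union(weeks_c, weeks_e), shared))
  if (!length(shared)) stop("no shared weeks")
  if (drop_n) {
    warning(drop_n, " weeks present in only one input excluded")
  }
  df <- df[as.character(df$week) %in% shared, ]

  lat_breaks <- seq(grid_spec$lat_range[1], grid_spec$lat_range[2],
                    by = grid_spec$cell_deg)
  lon_breaks <- seq(grid_spec$lon_range[1], grid_spec$lon_range[2],
                    by = grid_spec$cell_deg)
  li <- findInterval(df$lat, lat_breaks, rightmost.closed = TRUE)
  lj <- findInterval(df$lon, lon_breaks, rightmost.closed = TRUE)
  inside <- li >= 1 & li < length(lat_breaks) & lj >= 1 & lj < length(lon_breaks)
  df <- df[inside, ]
  li <- li[inside]
  lj <- lj[inside]

  cw <- concentration[as.character(df$week)]
  cell <- (lj - 1) * (length(lat_breaks) - 1) + li
  tau <- tapply(rep(1, nrow(df)), cell, sum)
  ctau <- tapply(cw, cell, sum)

  nlat <- length(lat_breaks) - 1
  nlon <- length(lon_breaks) - 1
  field <- matrix(NA_real_, nlat, nlon)
  idx <- as.integer(names(tau))
  field[idx] <- as.numeric(ctau) / as.numeric(tau)

  # sector wind rose
  b <- bearing_deg(station[["lat"]], station[["lon"]], df$lat, df$lon)
  sec <- factor(bearing_sector(b), levels = catchment_sectors)
  tau_s <- tapply(rep(1, nrow(df)), sec, sum)
  ctau_s <- tapply(cw, sec, sum)
  rose <- as.numeric(ctau_s) / as.numeric(tau_s)
  names(rose) <- catchment_sectors
  mx <- max(abs(rose), na.rm = TRUE)
  if (mx > 0) rose <- rose / mx

  structure(
    list(field = field, lat_breaks = lat_breaks, lon_breaks = lon_breaks,
         wind_rose = rose, station = station),
    class = "source_field"
  )
}

#' @export
print.source_field <- function(x, ...) {
  cat(sprintf(
    "source_field: %d x %d grid; wind-rose maximum in %s\n",
    nrow(x$field), ncol(x$field),
    names(which.max(x$wind_rose))
  ))
  invisible(x)
}

#' Read HYSPLIT tdump-style endpoint files
#'
#' Tab- or whitespace-separated columns: traj id, year, month, day, hour,
#' hours back, lat, lon, height (the layout written by
#' [write_trajectories()]).
#'
#' @param path File path.
#' @param station Optional station coordinates to attach.
#' @return A `trajectory_endpoints` data frame.
#' @export
read_tdump <- function(path, station = NULL) {
  df <- read.table(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("traj_id", "year", "month", "day", "hour", "hours_back",
            "lat", "lon", "height")
  if (!all(need %in% names(df))) {
    stop("expected columns: ", paste(need, collapse = ", "))
  }
  if (is.null(df$week)) df$week <- match(df$traj_id, unique(df$traj_id))
  if (!is.null(station)) attr(df, "station") <- station
  class(df) <- c("trajectory_endpoints", class(df))
  df
}

#' Weekly catchment covariate block for trend regressions
#'
#' Collapses a catchment summary to 25 weekly covariates: 8 directions x 3
#' coarse distance bands (near <= 31 km, mid <= 180 km, far <= 860 km) plus
#' the total weekly mass, each standardized.
#'
#' @param summary A [bin_endpoints()] result.
#' @return Week x 25 numeric matrix.
#' @export
catchment_covariates <- function(summary) {
  s <- summary$sums
  edges <- summary$edges
  band <- cut(seq_along(edges), breaks = c(0, 4, 8, 11),
              labels = c("near", "mid", "far"))
  out <- matrix(0, dim(s)[1], 24)
  cn <- character(24)
  k <- 0
  for (d in seq_len(8)) {
    for (b in levels(band)) {
      k <- k + 1
      out[, k] <- rowSums(s[, d, which(band == b), drop = FALSE])
      cn[k] <- paste(catchment_sectors[d], b, sep = "_")
    }
  }
  total <- rowSums(matrix(s, nrow = dim(s)[1]))
  out <- cbind(out, total)
  colnames(out) <- c(cn, "total")
  rownames(out) <- dimnames(s)[[1]]
  # standardize; never-visited cells have zero variance and stay at 0
  apply(out, 2, function(v) {
    s_v <- sd(v)
    if (s_v == 0) rep(0, length(v)) else (v - mean(v)) / s_v
  })
}
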