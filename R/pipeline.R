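#' Pipeline configuration
#'
#' Validated configuration for [run_pipeline()]: stage toggles, module
#' parameters, output directory and the single global seed that fixes every
#' stochastic stage. Unknown keys are rejected.
#'
#' @param outdir Output directory (created if needed).
#' @param seed Global seed.
#' @param synthetic A [synthetic_config()] for the simulate stage (its seed
#'   is overridden by the global seed).
#' @param stages Named logical vector toggling `simulate`, `filter`,
#'   `transform`, `detrend`, `cluster`, `diversity`, `trends`, `catchment`.
#' @param k Number of temporal clusters.
#' @param ssm_iterations,ssm_burn_in MCMC settings for the trends stage.
#' @param n_boot Bootstrap resamples for the catchment stage.
#' @param catchment_weeks Number of weeks to simulate trajectories for.
#' @param eras Optional list of two year ranges for the diversity contrast.
#' @return A `pipeline_config`.
#' @export
pipeline_config <- function(outdir = tempfile("airedna_run_"), seed = 1,
                            synthetic = synthetic_config(),
                            stages = c(simulate = TRUE, filter = TRUE,
                                       transform = TRUE, detrend = TRUE,
                                       cluster = TRUE, diversity = TRUE,
                                       trends = TRUE, catchment = TRUE),
                            k = 5, ssm_iterations = 600, ssm_burn_in = 200,
                            n_boot = 200, catchment_weeks = 40,
                            eras = NULL) {
  all_stages <- c("simulate", "filter", "transform", "detrend", "cluster",
                  "diversity", "trends", "catchment")
  unknown <- setdiff(names(stages), all_stages)
  if (length(unknown)) stop("unknown stages: ", paste(unknown, collapse = ", "))
  full <- setNames(rep(TRUE, length(all_stages)), all_stages)
  full[names(stages)] <- stages
  cfg <- list(outdir = outdir, seed = seed, synthetic = synthetic,
              stages = full, k = k, ssm_iterations = ssm_iterations,
              ssm_burn_in = ssm_burn_in, n_boot = n_boot,
              catchment_weeks = catchment_weeks, eras = eras)
  class(cfg) <- "pipeline_config"
  cfg
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the end-to-end analysis pipeline
#'
#' Executes the enabled stages in dependency order on synthetic data
#' (simulate -> taxon filter -> transform -> detrend -> cluster -> diversity
#' -> trends -> catchment), writes every stage output as flat TSV/JSON files
#' under the configured directory, and returns a manifest with MD5 content
#' hashes plus a JSON run log (seed, parameters, versions). A stage failure
#' halts the run with the failing stage named; outputs of completed stages
#' remain on disk.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with `manifest` (file, md5), `results` (in-memory
#'   stage products) and the log path.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  results <- list()
  scfg <- config$synthetic
  scfg$seed <- config$seed

  run_stage <- function(name, fn) {
    tryCatch(fn(), error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  out_path <- function(f) file.path(config$outdir, f)

  if (config$stages[["simulate"]]) {
    run_stage("simulate", function() {
      truth <- make_community(scfg)
      counts <- sample_reads(truth, scfg)
      spiked <- spike_false_positives(counts, truth, scfg)
      results$truth <<- truth
      results$spiked <<- spiked
      files <<- c(files,
        write_count_matrix(spiked$counts, out_path("counts.tsv"),
                           out_path("week_metadata.tsv")),
        write_tsv(spiked$labels, out_path("labels.tsv")),
        write_tsv(spiked$summaries, out_path("read_summaries.tsv")),
        write_tsv(spiked$occurrences, out_path("occurrences.csv"))
      )
    })
  }

  if (config$stages[["filter"]]) {
    run_stage("filter", function() {
      sp <- results$spiked
      features <- build_features(sp$counts, sp$summaries)
      model <- train_filter(features, sp$labels, seed = config$seed)
      calls <- classify_genera(model, features)
      keep <- calls$genus[calls$call]
      cm <- sp$counts
      cm$counts <- cm$counts[rownames(cm$counts) %in% keep, , drop = FALSE]
      cm$taxonomy <- cm$taxonomy[cm$taxonomy$genus %in% keep, , drop = FALSE]
      results$filter_model <<- model
      results$counts <<- cm
      files <<- c(files, write_tsv(calls, out_path("filter_calls.tsv")))
    })
  } else {
    results$counts <- results$spiked$counts
  }

  if (config$stages[["transform"]]) {
    run_stage("transform", function() {
      filtered <- prevalence_filter(results$counts)
      comp <- impute_zeros(filtered)
      results$comp <<- comp
      clr <- logratio_transform(comp, "clr")
      results$clr <<- clr
      files <<- c(files, write_tsv(
        data.frame(genus = rownames(comp), unclass(comp),
                   check.names = FALSE),
        out_path("compositions.tsv")
      ))
    })
  }

  if (config$stages[["detrend"]]) {
    run_stage("detrend", function() {
      ilr <- logratio_transform(results$comp, "ilr")
      dt <- fit_readlength_glm(ilr)
      comp_dt <- backtransform_detrended(dt$lr)
      comp_cond <- rda_condition(comp_dt)
      results$comp <<- comp_cond
      results$clr <<- logratio_transform(comp_cond, "clr")
      jsonlite::write_json(dt$record, out_path("detrend_record.json"),
                           dataframe = "rows", auto_unbox = TRUE)
      files <<- c(files, out_path("detrend_record.json"))
    })
  }

  if (config$stages[["cluster"]]) {
    run_stage("cluster", function() {
      vm <- variation_matrix(results$comp)
      sol <- cluster_genera(vm, k = min(config$k, nrow(vm)))
      results$clusters <<- sol
      results$cluster_shares <<- aggregate_clusters(sol, results$comp)
      files <<- c(files, write_clusters(sol, out_path("clusters.tsv")))
      dendrogram_newick(sol, out_path("dendrogram.nwk"))
      files <<- c(files, out_path("dendrogram.nwk"))
    })
  }

  if (config$stages[["diversity"]]) {
    run_stage("diversity", function() {
      prof <- partition_diversity(results$comp)
      contrib <- gamma_contributions(results$comp)
      meta <- attr(results$comp, "meta")
      eras <- config$eras %||% {
        yrs <- range(meta$year)
        mid <- floor(mean(yrs))
        list(c(yrs[1], mid - 1), c(mid, yrs[2]))
      }
      contrast <- contrast_periods(contrib, eras[[1]], eras[[2]])
      results$diversity <<- prof
      results$contrast <<- contrast
      files <<- c(files,
        write_tsv(prof$profile, out_path("diversity_profile.tsv")),
        write_tsv(as.data.frame(contrast), out_path("gamma_contrast.tsv"))
      )
    })
  }

  if (config$stages[["trends"]]) {
    run_stage("trends", function() {
      prof <- results$diversity$profile
      g1 <- log(prof$gamma[prof$q == 1])
      xreg <- seasonal_regressors(seq_along(g1))
      spec <- ssm_spec("llt", regressors = xreg,
                       iterations = config$ssm_iterations,
                       burn_in = config$ssm_burn_in)
      fit <- fit_ssm(g1, spec, seed = config$seed)
      results$trend_fit <<- fit
      files <<- c(files, write_tsv(
        data.frame(week = seq_along(g1), log_gamma = g1,
                   trend = fit$trend_median),
        out_path("gamma_trend.tsv")
      ))
    })
  }

  if (config$stages[["catchment"]]) {
    run_stage("catchment", function() {
      weeks <- seq_len(min(config$catchment_weeks, scfg$n_weeks))
      traj <- make_trajectories(scfg, weeks = weeks)
      cs <- bin_endpoints(traj)
      se <- block_bootstrap_se(cs, n_boot = config$n_boot,
                               seed = config$seed)
      by_class <- colSums(apply(cs$sums, c(1, 3), sum))[seq_along(cs$edges)]
      se_class <- apply(attr(se, "boot_means"), 2, sd)
      se_by_class <- colSums(matrix(se_class, 8, 12))[seq_along(cs$edges)]
      radius <- cumulative_mass_radius(by_class,
                                       se_by_class / max(sum(by_class), 1),
                                       seed = config$seed)
      plr <- genus_plr(results$comp)
      conc <- setNames(plr[1, weeks], weeks)
      field <- sqtba_field(conc, traj)
      results$catchment <<- list(summary = cs, radius = radius,
                                 field = field)
      files <<- c(files,
        write_trajectories(traj, out_path("trajectories.tsv")),
        write_tsv(data.frame(sector = catchment_sectors,
                             rose = field$wind_rose),
                  out_path("wind_rose.tsv"))
      )
      jsonlite::write_json(
        list(median_radius_km = radius$median,
             ci = unname(radius$ci)),
        out_path("half_mass_radius.json"), auto_unbox = TRUE, digits = NA
      )
      files <<- c(files, out_path("half_mass_radius.json"))
    })
  }

  files <- unique(files[!vapply(files, is.null, logical(1))])
  manifest <- data.frame(
    file = basename(files),
    md5 = unname(tools::md5sum(files)),
    row.names = NULL
  )
  write_tsv(manifest, out_path("manifest.tsv"))
  log <- list(
    seed = config$seed,
    stages = as.list(config$stages),
    synthetic = unclass(scfg)[!vapply(unclass(scfg), is.function, logical(1))],
    r_version = as.character(getRversion()),
    package_version = as.character(utils::packageVersion("airedna")),
    timestamp = format(Sys.time(), tz = "UTC")
  )
  jsonlite::write_json(log, out_path("run_log.json"), auto_unbox = TRUE,
                       null = "null", force = TRUE)

  invisible(list(manifest = manifest, results = results,
                 log = out_path("run_log.json")))
}
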