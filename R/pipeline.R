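#' Pipeline configuration
#'
#' Bundles everything a full analysis run needs: either an input census
#' file or a simulation config, the analysis parameters, and an output
#' directory. Serializable to/from YAML, so a run is fully determined by
#' its config (plus the input file, when given).
#'
#' @param input path of a census CSV, or `NULL` to simulate.
#' @param simulation a [sim_config()] (used when `input` is `NULL`).
#' @param seed integer seed for simulation.
#' @param out_dir output directory (created if missing).
#' @param span LOESS span.
#' @param trim survivorship trim fraction.
#' @param maturation_override optional explicit maturation age.
#' @param dry_weight_queen,dry_weight_worker dry weights for the caste
#'   correction. The defaults (ratio 2) are placeholders — supply the
#'   measured weights of your population.
#' @param k metabolic exponent for the headline caste ratio.
#' @param k_values exponent sweep.
#' @param quantile_type quantile convention.
#' @return A list of class `cp_run_config`.
#' @export
pipeline_config <- function(input = NULL,
                            simulation = sim_config(),
                            seed = 1L,
                            out_dir = tempfile("continuusparity_run_"),
                            span = 0.75,
                            trim = 0,
                            maturation_override = NULL,
                            dry_weight_queen = 0.4,
                            dry_weight_worker = 0.2,
                            k = 0.7,
                            k_values = seq(0.6, 1, by = 0.1),
                            quantile_type = 7) {
  cfg <- list(
    input = input, simulation = simulation, seed = as.integer(seed),
    out_dir = out_dir, span = span, trim = trim,
    maturation_override = maturation_override,
    dry_weight_queen = dry_weight_queen,
    dry_weight_worker = dry_weight_worker,
    k = k, k_values = k_values, quantile_type = quantile_type
  )
  class(cfg) <- "cp_run_config"
  cfg
}

#' Read a pipeline config from YAML
#'
#' @param path YAML file; keys mirror the [pipeline_config()] arguments,
#'   with `simulation` given as a nested map of [sim_config()] arguments.
#' @return A `cp_run_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  sim_args <- raw$simulation %||% list()
  raw$simulation <- do.call(sim_config, sim_args)
  do.call(pipeline_config, raw)
}

config_hash <- function(cfg) {
  # small stable hash of the serialized config (no external digest dep);
  # the output directory does not alter what is computed
  cfg <- unclass(cfg)
  cfg$out_dir <- NULL
  s <- paste(utils::capture.output(utils::str(cfg, give.attr = FALSE)),
             collapse = "\n")
  v <- utf8ToInt(s)
  h <- 5381
  for (chunk in split(v, ceiling(seq_along(v) / 4096))) {
    h <- sum(c(h * 33, chunk)) %% 2147483647
  }
  sprintf("%08x", as.integer(h))
}

#' Run the full analysis pipeline
#'
#' simulate (or read) -> validate -> life table -> fecundity schedules ->
#' mean-standardized trajectories -> landmarks -> lifetime investment ->
#' exponent sweep -> descriptive statistics; every stage's tidy CSV is
#' written under the output directory and the headline numbers are
#' collected into a JSON report. Re-running with the same config and
#' inputs reproduces the report numbers exactly.
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress progress messages.
#' @return The report, invisibly (also written to `report.json`): stage
#'   file paths, headline numbers, package version, config hash and seed.
#' @export
run_pipeline <- function(config = pipeline_config(), quiet = FALSE) {
  cfg <- config
  say <- function(...) if (!quiet) inform(paste0("[continuusparity] ", ...))
  if (!dir.exists(cfg$out_dir)) dir.create(cfg$out_dir, recursive = TRUE)
  fail <- function(stage, err) {
    writeLines(paste0("FAILED at stage: ", stage, "\n", conditionMessage(err)),
               file.path(cfg$out_dir, "FAILED"))
    abort(paste0("Pipeline failed at stage '", stage, "': ",
                 conditionMessage(err)), class = "cp_pipeline_error")
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) fail(name, e))
  }
  paths <- list()
  emit <- function(df, name) {
    p <- file.path(cfg$out_dir, paste0(name, ".csv"))
    readr::write_csv(as_tibble(df), p, progress = FALSE)
    paths[[name]] <<- p
    p
  }

  census <- stage("input", {
    if (!is.null(cfg$input)) {
      if (!file.exists(cfg$input)) {
        abort(paste0("Input census not found: ", cfg$input),
              class = "cp_io_error")
      }
      say("reading census from ", cfg$input)
      read_census(cfg$input)
    } else {
      say("simulating cohort (seed ", cfg$seed, ")")
      cohort <- simulate_cohort(cfg$simulation, seed = cfg$seed)
      emit(cohort$truth$colonies, "truth_colonies")
      cohort$census
    }
  })
  stage("validate", validate_census(census))
  emit(census, "census")

  ls <- stage("lifespans", lifespans(census))
  emit(ls, "lifespans")
  lt <- stage("life_table", build_life_table(ls))
  emit(lt, "life_table")

  schedules <- stage("schedules", {
    ms <- c("eggs", "worker_pupae", "queen_pupae", "male_pupae", "sexual_pupae")
    setNames(lapply(ms, function(m) fecundity_schedule(census, m)), ms)
  })
  emit(
    list_rbind(imap(schedules, function(s, m) mutate(as_tibble(s), measure = m))),
    "fecundity_schedules"
  )

  mat <- stage("maturation",
               maturation_age(schedules$eggs, override = cfg$maturation_override))
  trajectories <- stage("standardize", {
    trajs <- imap(schedules, function(s, m) {
      as_tibble(mean_standardize(s, maturation_age = mat, trim = cfg$trim,
                                 life_table = lt)) %>%
        mutate(measure = m)
    })
    trajs$mortality <- as_tibble(
      mean_standardize(lt, maturation_age = mat, trim = cfg$trim)
    ) %>% mutate(measure = "mortality")
    list_rbind(trajs)
  })
  emit(trajectories, "standardized_trajectories")

  landmarks <- stage("landmarks",
                     cohort_landmarks(census, span = cfg$span, trim = cfg$trim,
                                      maturation_override = cfg$maturation_override))
  emit(landmarks, "landmarks")

  cf <- stage("correction",
              correction_factor(cfg$dry_weight_queen, cfg$dry_weight_worker,
                                cfg$k))
  say(sprintf(
    "caste correction c = %.4f (wq %.3g / ww %.3g, k %.2f) - supply measured weights if these are placeholders",
    cf$c, cf$dry_weight_queen, cf$dry_weight_worker, cf$k))
  inv <- stage("investment", lifetime_totals(census, c = cf))
  emit(inv, "lifetime_totals")
  sweep <- stage("k_sweep",
                 k_sweep(inv, cfg$dry_weight_queen, cfg$dry_weight_worker,
                         cfg$k_values))
  emit(sweep, "k_sweep")
  curve <- stage("caste_ratio_curve",
                 caste_ratio_curve(census, c = 1, split_by_lifespan = TRUE,
                                   span = cfg$span))
  emit(curve, "caste_ratio_curve")
  tsum <- stage("treatment_summary", treatment_summary(inv))
  emit(tsum, "treatment_summary")

  stats_out <- stage("stats", {
    taus <- list(
      eggs_worker_pupae = kendall_tau_b(inv$eggs, inv$worker_pupae),
      eggs_queen_pupae = kendall_tau_b(inv$eggs, inv$queen_pupae),
      eggs_worker_queen_pupae =
        kendall_tau_b(inv$eggs, inv$worker_pupae + inv$queen_pupae)
    )
    sr <- inv$sex_ratio[!is.na(inv$sex_ratio)]
    obs <- ls$death_week[ls$observed]
    list(
      taus = taus,
      median_sex_ratio = median(sr),
      sex_ratio_q25 = cp_quantile(sr, 0.25, cfg$quantile_type),
      sex_ratio_q75 = cp_quantile(sr, 0.75, cfg$quantile_type),
      mean_lifespan = mean(obs),
      lifespan_cv_percent = cv_percent(obs),
      worker_fraction_of_pupae = sum(inv$worker_pupae) / sum(inv$total_pupae),
      winged_male_lifetime_mean = mean(inv$male_pupae_winged),
      winged_male_lifetime_median = median(inv$male_pupae_winged)
    )
  })
  emit(tibble(
    pair = names(stats_out$taus),
    tau_b = map_dbl(stats_out$taus, "tau_b")
  ), "kendall_taus")

  report <- list(
    package_version = as.character(utils::packageVersion("continuusparity")),
    seed = cfg$seed,
    config_hash = config_hash(cfg),
    outputs = paths,
    headline = c(
      list(
        mean_lifespan_weeks = stats_out$mean_lifespan,
        lifespan_cv_percent = stats_out$lifespan_cv_percent,
        egg_peak_week = landmarks$egg_peak,
        sexual_investment_peak_week = landmarks$sexual_peak,
        mortality_crossing_week = landmarks$mortality_crossing,
        maturation_age_week = mat,
        median_sex_ratio = stats_out$median_sex_ratio,
        sex_ratio_q25 = stats_out$sex_ratio_q25,
        sex_ratio_q75 = stats_out$sex_ratio_q75,
        worker_fraction_of_pupae = stats_out$worker_fraction_of_pupae,
        winged_male_lifetime_mean = stats_out$winged_male_lifetime_mean,
        winged_male_lifetime_median = stats_out$winged_male_lifetime_median
      ),
      setNames(
        map(stats_out$taus, "tau_b"),
        paste0("tau_", names(stats_out$taus))
      )
    )
  )
  jsonlite::write_json(report, file.path(cfg$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say("report written to ", file.path(cfg$out_dir, "report.json"))
  invisible(report)
}
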