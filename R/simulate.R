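#' Simulation configuration for the continuusparity cohort model
#'
#' The generative model emulates a lifelong tracking experiment on
#' single-queen colonies kept at fixed worker numbers:
#'
#' * Queen lifespan (in census weeks) is drawn from a Gamma distribution
#'   with mean `lifespan_mean_weeks` and coefficient of variation
#'   `lifespan_cv`, rounded to whole weeks.
#' * Each queen has her own reproductive timescale `z`: her egg schedule
#'   is the shared gamma-density kernel (peaking at `egg_peak_week`
#'   physiological weeks, maximum `egg_rate_max` eggs/week) stretched so
#'   that the expected rate falls to `death_threshold_rate` eggs/week just
#'   before her death. In the last `1 + Poisson(lethargy_mean_weeks)`
#'   weeks of life the rate additionally decays by `lethargy_decay` per
#'   week: reproductive death — laying collapses below ~10 eggs/week and
#'   the queen dies within days to a few weeks. Slow queens (`z > 1`) lay
#'   proportionally less per week (pace variation).
#' * Weekly egg counts are Poisson around the expected rate. Each egg
#'   survives to pupation with probability `egg_to_pupa_prob`; the pupa's
#'   caste is decided by the age-dependent allocation
#'   (see [allocation_probabilities]): the sexual share rises
#'   logistically with physiological age to asymptote
#'   `sexual_asymptote`, queens make up `sex_ratio_queens` of sexuals,
#'   and a male pupa is winged with probability `winged_male_prob`.
#'   Pupae are observed after caste-specific development lags.
#' * The worker-number treatment affects only queen-pupa rearing:
#'   colonies in the first treatment level (10 workers by default) raise a
#'   queen-destined pupa with probability
#'   `queen_pupae_treatment_multiplier`.
#' * After the queen's death the colony is censused for
#'   `postdeath_window_weeks` more weeks so late brood still appears as
#'   pupae (final counts).
#'
#' Defaults reproduce the study conditions of a 99-colony cohort: mean
#' lifespan 25 weeks (CV 32.2%), cohort egg-laying peak ~16 weeks,
#' late-life sexual-investment peak ~27-28 weeks, relative-mortality
#' crossing ~29-30 weeks, ~86% of pupae workers, median sex ratio among
#' sexuals ~0.85, and ~0.36 winged males per queen lifetime (median 0).
#'
#' @param n_colonies_per_treatment integer vector, colonies per treatment.
#' @param treatments worker numbers defining the treatments.
#' @param lifespan_mean_weeks,lifespan_cv Gamma lifespan mean (weeks) and
#'   coefficient of variation.
#' @param egg_peak_week physiological age of the standard egg-rate peak.
#' @param egg_rate_max maximum expected eggs/week of the standard queen.
#' @param egg_kernel_shape shape of the gamma-density egg kernel; sets the
#'   width of the fertile window relative to the peak (and with it the
#'   ratio between the cohort fecundity peak and the mean lifespan).
#' @param death_threshold_rate egg rate (eggs/week) under which a queen is
#'   moribund; her schedule is scaled so it reaches this rate at the onset
#'   of the terminal lethargy phase.
#' @param lethargy_mean_weeks mean extra duration of the terminal
#'   lethargy phase (its length is `1 + Poisson(lethargy_mean_weeks)`).
#' @param lethargy_decay weekly multiplicative egg-rate decay during
#'   lethargy.
#' @param sexual_bias_midpoint_week,sexual_bias_slope logistic midpoint
#'   and scale (physiological weeks) of the age-increasing sexual share.
#' @param sexual_asymptote asymptotic fraction of pupae that are sexual.
#' @param sex_ratio_queens probability that a sexual pupa is a queen.
#' @param winged_male_prob probability that a male pupa is winged.
#' @param egg_to_pupa_prob egg-to-pupa survival probability.
#' @param queen_pupae_treatment_multiplier queen-pupa rearing probability
#'   in the first (smallest) treatment; 1 in the others.
#' @param dev_lag_queen_weeks,dev_lag_male_weeks,dev_lag_worker_weeks
#'   development lags (egg laid to pupa observed), in weeks.
#' @param egg_double_count_frac fraction of the previous week's eggs
#'   counted again this week (emulates eggs visible across censuses);
#'   0 disables the observation error (default).
#' @param postdeath_window_weeks length of the post-death census window.
#' @param max_weeks hard ceiling on census length.
#' @return A list of class `cp_sim_config`.
#' @export
#' @examples
#' cfg <- sim_config()
#' cohort <- simulate_cohort(cfg, seed = 1)
#' cohort$census
sim_config <- function(n_colonies_per_treatment = c(31L, 34L, 34L),
                       treatments = c(10L, 20L, 30L),
                       lifespan_mean_weeks = 25,
                       lifespan_cv = 0.322,
                       egg_peak_week = 16,
                       egg_rate_max = 25,
                       egg_kernel_shape = 6,
                       death_threshold_rate = 10,
                       lethargy_mean_weeks = 1.5,
                       lethargy_decay = 0.3,
                       sexual_bias_midpoint_week = 16,
                       sexual_bias_slope = 2,
                       sexual_asymptote = 0.32,
                       sex_ratio_queens = 0.87,
                       winged_male_prob = 0.10,
                       egg_to_pupa_prob = 0.5,
                       queen_pupae_treatment_multiplier = 0.5,
                       dev_lag_queen_weeks = 5L,
                       dev_lag_male_weeks = 3L,
                       dev_lag_worker_weeks = 3L,
                       egg_double_count_frac = 0,
                       postdeath_window_weeks = 4L,
                       max_weeks = 110L) {
  cfg <- list(
    n_colonies_per_treatment = as.integer(n_colonies_per_treatment),
    treatments = as.integer(treatments),
    lifespan_mean_weeks = lifespan_mean_weeks,
    lifespan_cv = lifespan_cv,
    egg_peak_week = egg_peak_week,
    egg_rate_max = egg_rate_max,
    egg_kernel_shape = egg_kernel_shape,
    death_threshold_rate = death_threshold_rate,
    lethargy_mean_weeks = lethargy_mean_weeks,
    lethargy_decay = lethargy_decay,
    sexual_bias_midpoint_week = sexual_bias_midpoint_week,
    sexual_bias_slope = sexual_bias_slope,
    sexual_asymptote = sexual_asymptote,
    sex_ratio_queens = sex_ratio_queens,
    winged_male_prob = winged_male_prob,
    egg_to_pupa_prob = egg_to_pupa_prob,
    queen_pupae_treatment_multiplier = queen_pupae_treatment_multiplier,
    dev_lag_queen_weeks = as.integer(dev_lag_queen_weeks),
    dev_lag_male_weeks = as.integer(dev_lag_male_weeks),
    dev_lag_worker_weeks = as.integer(dev_lag_worker_weeks),
    egg_double_count_frac = egg_double_count_frac,
    postdeath_window_weeks = as.integer(postdeath_window_weeks),
    max_weeks = as.integer(max_weeks)
  )
  validate_sim_config(cfg)
  class(cfg) <- "cp_sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot_cfg <- function(ok, what) {
    if (!ok) abort(paste0("Invalid simulation config: ", what),
                   class = "cp_config_error")
  }
  stopifnot_cfg(length(cfg$n_colonies_per_treatment) == length(cfg$treatments),
                "n_colonies_per_treatment and treatments differ in length")
  stopifnot_cfg(all(cfg$n_colonies_per_treatment >= 0), "negative colony counts")
  stopifnot_cfg(cfg$lifespan_mean_weeks > 0, "lifespan mean must be positive")
  stopifnot_cfg(cfg$lifespan_cv > 0, "lifespan CV must be positive")
  stopifnot_cfg(cfg$egg_peak_week > 0, "egg peak must be positive")
  stopifnot_cfg(cfg$egg_rate_max > cfg$death_threshold_rate,
                "egg_rate_max must exceed death_threshold_rate")
  stopifnot_cfg(cfg$egg_kernel_shape > 1, "egg kernel shape must be > 1")
  probs <- c(cfg$sexual_asymptote, cfg$sex_ratio_queens, cfg$winged_male_prob,
             cfg$egg_to_pupa_prob, cfg$queen_pupae_treatment_multiplier,
             cfg$egg_double_count_frac)
  stopifnot_cfg(all(probs >= 0 & probs <= 1), "probabilities must lie in [0, 1]")
  stopifnot_cfg(cfg$lethargy_decay > 0 && cfg$lethargy_decay < 1,
                "lethargy_decay must lie in (0, 1)")
  stopifnot_cfg(all(c(cfg$dev_lag_queen_weeks, cfg$dev_lag_male_weeks,
                      cfg$dev_lag_worker_weeks) >= 0), "lags must be >= 0")
  invisible(cfg)
}

#' @export
print.cp_sim_config <- function(x, ...) {
  cat("continuusparity simulation config\n")
  for (nm in names(x)) {
    cat(sprintf("  %-34s %s\n", nm, paste(format(x[[nm]]), collapse = "/")))
  }
  invisible(x)
}

# gamma-density egg kernel, unit peak at cfg$egg_peak_week
egg_kernel <- function(age, cfg) {
  shape <- cfg$egg_kernel_shape
  theta <- cfg$egg_peak_week / (shape - 1)
  dgamma(age, shape, scale = theta) / dgamma(cfg$egg_peak_week, shape, scale = theta)
}

# physiological age at which the standard rate drops to the death threshold
threshold_age <- function(cfg) {
  uniroot(
    function(u) cfg$egg_rate_max * egg_kernel(u, cfg) - cfg$death_threshold_rate,
    lower = cfg$egg_peak_week, upper = 100 * cfg$egg_peak_week
  )$root
}

#' Expected egg-laying rate of the standard queen
#'
#' The standard (timescale 1) queen's expected eggs/week as a function of
#' physiological age: a gamma-density kernel rising from 0, peaking at
#' `egg_peak_week` with `egg_rate_max` eggs/week, then declining; it
#' falls below the reproductive death threshold (~10 eggs/week) late in
#' life. Continuous and unimodal.
#'
#' @param age_weeks non-negative age(s) in weeks.
#' @param config a [sim_config()].
#' @return Expected eggs/week, same length as `age_weeks`.
#' @export
#' @examples
#' egg_rate(16, sim_config())  # the peak
egg_rate <- function(age_weeks, config = sim_config()) {
  if (any(age_weeks < 0)) abort("age must be >= 0", class = "cp_config_error")
  config$egg_rate_max * egg_kernel(age_weeks, config)
}

#' Caste and sex allocation probabilities by age
#'
#' Probability that a pupa produced at a given (physiological) age is a
#' worker, a queen, or a male. The sexual share rises logistically with
#' age — colonies first build their worker force (ergonomic phase), then
#' shift allocation towards sexuals, with an increasing queen bias late in
#' life — and within sexuals the queen share is constant at
#' `sex_ratio_queens`.
#'
#' @inheritParams egg_rate
#' @return A tibble with columns `age_weeks`, `p_worker`, `p_queen`,
#'   `p_male`; rows sum to 1.
#' @export
#' @examples
#' allocation_probabilities(c(5, 16, 40), sim_config())
allocation_probabilities <- function(age_weeks, config = sim_config()) {
  if (any(age_weeks < 0)) abort("age must be >= 0", class = "cp_config_error")
  p_sex <- config$sexual_asymptote *
    plogis((age_weeks - config$sexual_bias_midpoint_week) / config$sexual_bias_slope)
  tibble(
    age_weeks = age_weeks,
    p_worker = 1 - p_sex,
    p_queen = p_sex * config$sex_ratio_queens,
    p_male = p_sex * (1 - config$sex_ratio_queens)
  )
}

colony_seed <- function(seed, i) {
  as.integer((as.double(seed) * 1000003 + i) %% 2147483647)
}

#' Simulate a queen cohort under the continuusparity model
#'
#' Generates a full weekly census table for a cohort of single-queen
#' colonies with known ground truth. Identical seeds give identical
#' output; colony `i` is simulated under its own derived RNG substream
#' (`(seed * 1000003 + i) mod (2^31 - 1)`), so enlarging the cohort never
#' perturbs earlier colonies. The caller's RNG state is left untouched.
#'
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @return A list of class `cp_cohort` with elements
#'   * `census`: the census tibble (passes [validate_census()]),
#'   * `truth`: a list with the `config`, the seed, and a `colonies`
#'     tibble of per-colony ground truth (death week, timescale `z`,
#'     lethargy onset, treatment).
#' @export
simulate_cohort <- function(config = sim_config(), seed = 1L) {
  validate_sim_config(config)
  cfg <- config
  n <- sum(cfg$n_colonies_per_treatment)
  if (n == 0) abort("Config defines zero colonies", class = "cp_config_error")
  treatment <- rep(cfg$treatments, cfg$n_colonies_per_treatment)
  u10 <- threshold_age(cfg)
  shape <- 1 / cfg$lifespan_cv^2
  scl <- cfg$lifespan_mean_weeks * cfg$lifespan_cv^2

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })

  rows <- vector("list", n)
  truth_rows <- vector("list", n)
  lag_shift <- function(v, lag, len) c(rep(0L, lag), v)[seq_len(len)]
  for (i in seq_len(n)) {
    set.seed(colony_seed(seed, i))
    D <- max(2L, min(cfg$max_weeks - cfg$postdeath_window_weeks,
                     as.integer(round(rgamma(1, shape, scale = scl)))))
    L <- 1L + rpois(1, cfg$lethargy_mean_weeks)
    onset <- max(1L, D - L)
    z <- max(0.15, (D - L) / u10)
    last_week <- D + cfg$postdeath_window_weeks
    a <- 0:last_week
    len <- length(a)
    rate <- (cfg$egg_rate_max / max(z, 1)) * egg_kernel(a / z, cfg)
    in_leth <- a >= onset
    rate[in_leth] <- rate[in_leth] *
      cfg$lethargy_decay^(a[in_leth] - onset + 1)
    rate[a >= D] <- 0
    eggs <- rpois(len, rate)
    alloc <- allocation_probabilities(a / z, cfg)
    pupae <- rbinom(len, eggs, cfg$egg_to_pupa_prob)
    sexual <- rbinom(len, pupae, alloc$p_queen + alloc$p_male)
    worker <- pupae - sexual
    queen <- rbinom(len, sexual, cfg$sex_ratio_queens)
    male <- sexual - queen
    if (treatment[i] == cfg$treatments[1]) {
      queen <- rbinom(len, queen, cfg$queen_pupae_treatment_multiplier)
    }
    winged <- rbinom(len, male, cfg$winged_male_prob)
    wingless <- male - winged
    obs_eggs <- eggs
    if (cfg$egg_double_count_frac > 0) {
      carry <- rbinom(len, c(0L, eggs[-len]), cfg$egg_double_count_frac)
      obs_eggs <- eggs + carry
    }
    rows[[i]] <- tibble(
      colony_id = sprintf("q%03d", i),
      treatment_workers = treatment[i],
      week = a,
      eggs = obs_eggs,
      pupae_worker = lag_shift(worker, cfg$dev_lag_worker_weeks, len),
      pupae_queen = lag_shift(queen, cfg$dev_lag_queen_weeks, len),
      pupae_male_winged = lag_shift(winged, cfg$dev_lag_male_weeks, len),
      pupae_male_wingless = lag_shift(wingless, cfg$dev_lag_male_weeks, len),
      queen_alive = a < D
    )
    truth_rows[[i]] <- tibble(
      colony_id = sprintf("q%03d", i),
      treatment_workers = treatment[i],
      death_week = D,
      timescale_z = z,
      lethargy_onset = onset
    )
  }
  census <- new_census(
    list_rbind(rows),
    metadata = list(
      source = "continuusparity simulator",
      seed = as.character(seed),
      censoring_window_weeks = as.character(cfg$postdeath_window_weeks)
    )
  )
  out <- list(
    census = census,
    truth = list(config = cfg, seed = seed, colonies = list_rbind(truth_rows))
  )
  class(out) <- "cp_cohort"
  out
}

#' @export
print.cp_cohort <- function(x, ...) {
  cat(sprintf(
    "continuusparity cohort: %d colonies, %d census rows (seed %s)\n",
    nrow(x$truth$colonies), nrow(x$census), format(x$truth$seed)
  ))
  invisible(x)
}

#' Theoretical cohort landmarks implied by a simulation config
#'
#' Computes, by deterministic expectation over the lifespan and lethargy
#' distributions (no Monte Carlo), the cohort-level curves a large cohort
#' would show — expected eggs and sexual pupae per living queen by age,
#' and the central death rate — and extracts the same landmarks as
#' [cohort_landmarks()]: fecundity-peak age, sexual-investment-peak age,
#' and relative-mortality crossing age. The age window runs to the 99.5th
#' lifespan percentile, the typical maximum in a 99-colony cohort.
#'
#' @param config a [sim_config()].
#' @param span smoothing span used for landmark extraction.
#' @param n_cohort cohort size whose estimand is targeted: the age window
#'   ends at the median maximum lifespan of a cohort of this size, and
#'   the terminal census week carries the all-remaining-die central rate
#'   (2), as a real cohort's last age does.
#' @return Tibble with one row: `egg_peak`, `sexual_peak`,
#'   `mortality_crossing`, `mean_lifespan`, `lifespan_cv`.
#' @export
true_landmarks <- function(config = sim_config(), span = 0.75, n_cohort = 99) {
  cfg <- config
  shape <- 1 / cfg$lifespan_cv^2
  scl <- cfg$lifespan_mean_weeks * cfg$lifespan_cv^2
  u10 <- threshold_age(cfg)
  d_max <- as.integer(round(stats::qgamma(0.5^(1 / n_cohort), shape,
                                          scale = scl)))
  d_vals <- 2:d_max
  d_prob <- diff(stats::pgamma(c(1.5, d_vals + 0.5), shape, scale = scl))
  d_prob[length(d_prob)] <- d_prob[length(d_prob)] +
    stats::pgamma(d_max + 0.5, shape, scale = scl, lower.tail = FALSE)
  d_prob <- d_prob / sum(d_prob)
  l_vals <- 1 + 0:12
  l_prob <- stats::dpois(0:12, cfg$lethargy_mean_weeks)
  l_prob <- l_prob / sum(l_prob)

  ages <- 0:d_max
  mean_lt <- sum(d_vals * d_prob)
  cv_lt <- sqrt(sum((d_vals - mean_lt)^2 * d_prob)) / mean_lt

  e_eggs <- numeric(length(ages))   # E[rate | alive at age]
  e_sex <- numeric(length(ages))    # E[observed sexual pupae | alive]
  p_alive <- numeric(length(ages))
  mix_w <- outer(d_prob, l_prob)    # D x L joint weights
  lagq <- cfg$dev_lag_queen_weeks
  lagm <- cfg$dev_lag_male_weeks
  rate_at <- function(x, D, L) {
    onset <- pmax(1, D - L)
    z <- pmax(0.15, (D - L) / u10)
    r <- (cfg$egg_rate_max / pmax(z, 1)) * egg_kernel(x / z, cfg)
    r <- r * ifelse(x >= onset, cfg$lethargy_decay^(x - onset + 1), 1)
    r[x >= D] <- 0
    r
  }
  Dg <- matrix(rep(d_vals, length(l_vals)), ncol = length(l_vals))
  Lg <- matrix(rep(l_vals, each = length(d_vals)), ncol = length(l_vals))
  zg <- pmax(0.15, (Dg - Lg) / u10)
  for (k in seq_along(ages)) {
    x <- ages[k]
    alive <- Dg > x
    w <- mix_w * alive
    pa <- sum(w)
    p_alive[k] <- pa
    if (pa <= 0) next
    r_now <- rate_at(x, Dg, Lg)
    e_eggs[k] <- sum(w * r_now) / pa
    sex_of <- function(lag) {
      src <- x - lag
      if (src < 0) return(0)
      r_src <- rate_at(src, Dg, Lg)
      p_s <- cfg$sexual_asymptote *
        plogis((src / zg - cfg$sexual_bias_midpoint_week) / cfg$sexual_bias_slope)
      sum(w * r_src * cfg$egg_to_pupa_prob * p_s) / pa
    }
    e_sex[k] <- cfg$sex_ratio_queens * sex_of(lagq) +
      (1 - cfg$sex_ratio_queens) * sex_of(lagm)
  }
  # central death rate of the discretized lifespan distribution
  p_ge <- sapply(ages, function(x) sum(d_prob[d_vals >= x]))
  p_eq <- sapply(ages, function(x) sum(d_prob[d_vals == x]))
  mrate <- ifelse(p_ge > 0, p_eq / (p_ge - p_eq / 2), NA_real_)
  mrate[length(mrate)] <- 2  # terminal census age: all remaining die

  mat <- ages[which(e_eggs > 1e-6)[1]]
  keep <- ages >= mat & p_alive > 0
  pk <- function(v, w_) {
    sm <- loess_smooth(ages[keep], v[keep] / mean(v[keep]),
                       span = span, degree = 2, weights = w_[keep])
    find_peak_age(sm)
  }
  keep_m <- ages >= mat & !is.na(mrate)
  sm_m <- loess_smooth(ages[keep_m], mrate[keep_m] / mean(mrate[keep_m]),
                       span = span, degree = 2, weights = p_ge[keep_m])
  tibble(
    egg_peak = pk(e_eggs, p_alive),
    sexual_peak = pk(e_sex, p_alive),
    mortality_crossing = mortality_crossing_age(sm_m),
    mean_lifespan = mean_lt,
    lifespan_cv = cv_lt
  )
}
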