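#' Build a cohort life table
#'
#' Discrete weekly life table from the per-colony lifespan records of a
#' census table. At age `x` the risk set holds every queen whose death
#' week is `>= x` (censored queens leave the risk set after their last
#' observed week without contributing a death). The discrete hazard is
#' `q(x) = deaths(x) / n_at_risk(x)`, survivorship follows the
#' product-limit recursion `l(x+1) = l(x) (1 - q(x))` with `l(0) = 1`,
#' and the central death rate — the discrete analogue of the
#' instantaneous mortality rate, used for mean-standardized mortality —
#' is `m(x) = deaths(x) / (n_at_risk(x) - deaths(x)/2)`.
#'
#' @param table a census tibble, or a lifespan tibble as returned by
#'   [lifespans()].
#' @return A tibble of class `cp_life_table` with columns `age_week`,
#'   `n_at_risk`, `deaths`, `censored`, `hazard`, `central_rate`,
#'   `survivorship`.
#' @export
#' @examples
#' lt <- build_life_table(simulate_cohort(seed = 1)$census)
#' head(lt)
build_life_table <- function(table) {
  ls <- if (is_tibble(table) && all(c("death_week", "observed") %in% names(table))) {
    table
  } else {
    lifespans(table)
  }
  if (nrow(ls) == 0) abort("Empty cohort", class = "cp_validation_error")
  max_age <- max(ls$death_week[ls$observed],
                 ls$death_week[!ls$observed] - 1L, 0L)
  ages <- 0:max_age
  obs <- ls$death_week[ls$observed]
  cens <- ls$death_week[!ls$observed]   # last observed week + 1
  n_at_risk <- map_int(ages, function(x) {
    sum(obs >= x) + sum(cens > x)
  })
  deaths <- map_int(ages, function(x) sum(obs == x))
  censored <- map_int(ages, function(x) sum(cens == x + 1L))
  keep <- n_at_risk > 0
  ages <- ages[keep]; n_at_risk <- n_at_risk[keep]
  deaths <- deaths[keep]; censored <- censored[keep]
  hazard <- deaths / n_at_risk
  central <- deaths / (n_at_risk - deaths / 2)
  surv <- cumprod(c(1, 1 - hazard))[seq_along(ages)]
  out <- tibble(
    age_week = as.integer(ages),
    n_at_risk = n_at_risk,
    deaths = deaths,
    censored = censored,
    hazard = hazard,
    central_rate = central,
    survivorship = surv
  )
  class(out) <- unique(c("cp_life_table", class(out)))
  out
}

#' Age-specific fecundity schedule
#'
#' Mean offspring output per living queen by age: at each age the counts
#' of the chosen offspring class are summed over the colonies whose queen
#' is alive at that census and divided by their number. Post-death
#' (censoring-window) records are excluded, so the schedule reflects what
#' living queens produce. Ages at which no queen is alive are absent.
#'
#' @param table a census tibble.
#' @param measure one of `"eggs"`, `"worker_pupae"`, `"queen_pupae"`,
#'   `"male_pupae"` (winged + wingless), or `"sexual_pupae"`
#'   (queen + male pupae).
#' @return A tibble of class `cp_schedule` with columns `age_week`,
#'   `mean_per_queen`, `n_queens_alive`; the measure is kept in the
#'   `"measure"` attribute.
#' @export
#' @examples
#' fecundity_schedule(simulate_cohort(seed = 1)$census, "eggs")
fecundity_schedule <- function(table, measure = "eggs") {
  cols <- switch(measure,
    eggs = "eggs",
    worker_pupae = "pupae_worker",
    queen_pupae = "pupae_queen",
    male_pupae = c("pupae_male_winged", "pupae_male_wingless"),
    sexual_pupae = c("pupae_queen", "pupae_male_winged", "pupae_male_wingless"),
    abort(paste0("Unknown measure: ", measure), class = "cp_validation_error")
  )
  df <- as_tibble(table)
  out <- df %>%
    filter(.data$queen_alive) %>%
    mutate(.value = rowSums(dplyr::pick(dplyr::all_of(cols)))) %>%
    group_by(age_week = .data$week) %>%
    summarise(
      mean_per_queen = mean(.data$.value),
      n_queens_alive = dplyr::n(),
      .groups = "drop"
    ) %>%
    arrange(.data$age_week)
  attr(out, "measure") <- measure
  class(out) <- unique(c("cp_schedule", class(out)))
  out
}

#' Maturation age of a fecundity schedule
#'
#' The default rule takes the first age with positive mean output; an
#' explicit override wins over the data (use it when maturation is
#' defined externally, e.g. from observed first oviposition).
#'
#' @param schedule a [fecundity_schedule()].
#' @param override optional explicit maturation age.
#' @return Integer age in weeks.
#' @export
maturation_age <- function(schedule, override = NULL) {
  if (!is.null(override)) return(as.integer(override))
  if (nrow(schedule) == 0) {
    abort("Empty schedule", class = "cp_validation_error")
  }
  idx <- which(schedule$mean_per_queen > 0)[1]
  if (is.na(idx)) {
    abort("Schedule is all zero; maturation age undefined",
          class = "cp_validation_error")
  }
  as.integer(schedule$age_week[idx])
}

#' Mean-standardize a mortality or fecundity trajectory
#'
#' Divides the age-specific values by their mean over the retained
#' post-maturation ages, the pace-correcting standardization that makes
#' the *shape* of mortality and fecundity trajectories comparable across
#' timescales: a relative value of 1 marks average mortality/fertility.
#' By default the whole life range until the last death is retained;
#' `trim` drops the ages in which survivorship has fallen below the given
#' fraction (e.g. `trim = 0.05` removes the last 5% of survivorship, a
#' common sensitivity check).
#'
#' @param x a `cp_life_table` or `cp_schedule`.
#' @param maturation_age first age of the standardization window; for
#'   schedules it defaults to the first age with positive output, for
#'   life tables it should be supplied (e.g. from the egg schedule) and
#'   defaults to 0.
#' @param trim survivorship fraction below which ages are dropped
#'   (in `[0, 0.5)`; default 0 retains everything).
#' @param measure for life tables, `"central_rate"` (default; discrete
#'   analogue of the mortality rate) or `"hazard"`.
#' @param life_table survivorship source when trimming a schedule.
#' @param ... unused.
#' @return A tibble of class `cp_trajectory` with columns `age_week`,
#'   `relative_value`, `weight` (queens at risk/alive), and attributes
#'   `maturation_age`, `trim`, `source`. The post-maturation mean of
#'   `relative_value` is 1 by construction.
#' @export
mean_standardize <- function(x, ...) UseMethod("mean_standardize")

#' @rdname mean_standardize
#' @export
mean_standardize.cp_life_table <- function(x, maturation_age = 0L, trim = 0,
                                           measure = c("central_rate", "hazard"),
                                           ...) {
  measure <- match.arg(measure)
  standardize_values(
    ages = x$age_week, values = x[[measure]], weights = x$n_at_risk,
    survivorship = x$survivorship,
    maturation_age = maturation_age, trim = trim,
    source = paste0("mortality_", measure)
  )
}

#' @rdname mean_standardize
#' @export
mean_standardize.cp_schedule <- function(x, maturation_age = NULL, trim = 0,
                                         life_table = NULL, ...) {
  mat <- maturation_age %||% maturation_age(x)
  surv <- NULL
  if (trim > 0) {
    if (is.null(life_table)) {
      abort("Trimming a schedule needs `life_table` for survivorship",
            class = "cp_validation_error")
    }
    surv <- life_table$survivorship[match(x$age_week, life_table$age_week)]
  }
  standardize_values(
    ages = x$age_week, values = x$mean_per_queen, weights = x$n_queens_alive,
    survivorship = surv,
    maturation_age = mat, trim = trim,
    source = attr(x, "measure") %||% "fecundity"
  )
}

standardize_values <- function(ages, values, weights, survivorship,
                               maturation_age, trim, source) {
  if (trim < 0 || trim >= 0.5) {
    abort("trim must lie in [0, 0.5)", class = "cp_validation_error")
  }
  keep <- ages >= maturation_age & !is.na(values)
  if (trim > 0 && !is.null(survivorship)) {
    keep <- keep & !is.na(survivorship) & survivorship >= trim
  }
  if (!any(keep)) {
    abort("No retained ages after maturation/trim", class = "cp_validation_error")
  }
  m <- mean(values[keep])
  if (m <= 0) {
    abort("Post-maturation mean is zero; standardization undefined",
          class = "cp_validation_error")
  }
  out <- tibble(
    age_week = as.integer(ages[keep]),
    relative_value = values[keep] / m,
    weight = weights[keep]
  )
  attr(out, "maturation_age") <- as.integer(maturation_age)
  attr(out, "trim") <- trim
  attr(out, "source") <- source
  class(out) <- unique(c("cp_trajectory", class(out)))
  out
}
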