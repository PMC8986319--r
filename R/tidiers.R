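#' Tidy a Kendall tau-b result
#'
#' @param x a [kendall_tau_b()] result.
#' @param ... unused.
#' @return One-row tibble with the statistic and pair counts.
#' @method tidy cp_tau
#' @export
tidy.cp_tau <- function(x, ...) {
  tibble(
    tau_b = x$tau_b,
    n_pairs = x$n_pairs,
    concordant = x$concordant,
    discordant = x$discordant,
    ties_x = x$ties_x,
    ties_y = x$ties_y,
    ties_xy = x$ties_xy,
    p_value = x$p_value %||% NA_real_
  )
}

#' @rdname tidy.cp_tau
#' @method glance cp_tau
#' @export
glance.cp_tau <- function(x, ...) {
  tibble(tau_b = x$tau_b, n_pairs = x$n_pairs)
}

#' Tidy a life table
#'
#' @param x a [build_life_table()] result.
#' @param ... unused.
#' @return The life table as a plain tibble.
#' @method tidy cp_life_table
#' @export
tidy.cp_life_table <- function(x, ...) {
  as_tibble(unclass_first(x))
}

#' @rdname tidy.cp_life_table
#' @method glance cp_life_table
#' @export
glance.cp_life_table <- function(x, ...) {
  d <- sum(x$deaths)
  tibble(
    n = x$n_at_risk[1],
    deaths = d,
    censored = sum(x$censored),
    max_age_week = max(x$age_week),
    median_survival_week = x$age_week[which(x$survivorship <= 0.5)[1]]
  )
}

#' Tidy a standardized trajectory
#'
#' @param x a [mean_standardize()] result.
#' @param ... unused.
#' @return Tibble with the relative values and a `source` column.
#' @method tidy cp_trajectory
#' @export
tidy.cp_trajectory <- function(x, ...) {
  as_tibble(unclass_first(x)) %>%
    mutate(source = attr(x, "source") %||% NA_character_)
}

#' @rdname tidy.cp_trajectory
#' @method glance cp_trajectory
#' @export
glance.cp_trajectory <- function(x, ...) {
  tibble(
    source = attr(x, "source") %||% NA_character_,
    maturation_age = attr(x, "maturation_age"),
    trim = attr(x, "trim"),
    n_ages = nrow(x),
    post_maturation_mean = mean(x$relative_value)
  )
}

#' Tidy a cohort simulation
#'
#' @param x a [simulate_cohort()] result.
#' @param ... unused.
#' @return The per-colony ground-truth tibble.
#' @method tidy cp_cohort
#' @export
tidy.cp_cohort <- function(x, ...) {
  x$truth$colonies
}

#' @rdname tidy.cp_cohort
#' @method glance cp_cohort
#' @export
glance.cp_cohort <- function(x, ...) {
  d <- x$truth$colonies$death_week
  tibble(
    n_colonies = length(d),
    mean_lifespan = mean(d),
    lifespan_cv = sd(d) / mean(d),
    seed = x$truth$seed
  )
}

unclass_first <- function(x) {
  class(x) <- setdiff(class(x), c("cp_life_table", "cp_schedule",
                                  "cp_trajectory", "cp_smooth",
                                  "cp_investment", "cp_census"))
  x
}
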