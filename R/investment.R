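#' Biomass/metabolic correction factor for caste investment
#'
#' Queens are heavier than workers; investment comparisons convert queen
#' counts into worker-equivalent cost units through
#' `c = (dry_weight_queen / dry_weight_worker)^k`, with the metabolic
#' power exponent `k` (0.7 by convention, after the allometry of
#' metabolic rate; results should be checked over `k` in 0.6-1, see
#' [k_sweep()]).
#'
#' @param dry_weight_queen,dry_weight_worker dry weights (same units).
#' @param k power conversion exponent.
#' @return A list of class `cp_correction` with the inputs and the
#'   derived factor `c`.
#' @export
#' @examples
#' correction_factor(0.4, 0.2, k = 0.7)$c  # ~1.6245
correction_factor <- function(dry_weight_queen, dry_weight_worker, k = 0.7) {
  if (dry_weight_queen <= 0 || dry_weight_worker <= 0) {
    abort("Dry weights must be positive", class = "cp_validation_error")
  }
  out <- list(
    dry_weight_queen = dry_weight_queen,
    dry_weight_worker = dry_weight_worker,
    k = k,
    c = (dry_weight_queen / dry_weight_worker)^k
  )
  class(out) <- "cp_correction"
  out
}

#' @export
print.cp_correction <- function(x, ...) {
  cat(sprintf("correction factor c = (%.3g/%.3g)^%.3g = %.5g\n",
              x$dry_weight_queen, x$dry_weight_worker, x$k, x$c))
  invisible(x)
}

as_cfactor <- function(c) {
  if (inherits(c, "cp_correction")) c$c else as.numeric(c)
}

#' Caste-investment ratio
#'
#' Queen share of the biomass-corrected caste investment,
#' `Q c / (Q c + W)`: 0 when only workers were produced, 1 when only
#' queens. Undefined (NA) when both counts are zero.
#'
#' @param queen_pupae,worker_pupae non-negative counts (vectorized).
#' @param c correction factor (number or [correction_factor()] result).
#' @return Ratio in `[0, 1]`, `NA` where `Q = W = 0`.
#' @export
#' @examples
#' caste_investment_ratio(5, 15, correction_factor(0.4, 0.2, 0.7))
caste_investment_ratio <- function(queen_pupae, worker_pupae, c = 1) {
  cc <- as_cfactor(c)
  if (cc <= 0) abort("Correction factor must be positive",
                     class = "cp_validation_error")
  if (any(queen_pupae < 0 | worker_pupae < 0, na.rm = TRUE)) {
    abort("Counts must be non-negative", class = "cp_validation_error")
  }
  ifelse(queen_pupae + worker_pupae == 0, NA_real_,
         queen_pupae * cc / (queen_pupae * cc + worker_pupae))
}

#' Sex ratio among sexual pupae
#'
#' Queen pupae over queen plus male pupae; undefined (NA) for colonies
#' that produced no sexuals (excluded from cohort medians).
#'
#' @param queen_pupae,male_pupae non-negative counts (vectorized).
#' @return Ratio in `[0, 1]`, `NA` where no sexuals.
#' @export
sex_ratio <- function(queen_pupae, male_pupae) {
  if (any(queen_pupae < 0 | male_pupae < 0, na.rm = TRUE)) {
    abort("Counts must be non-negative", class = "cp_validation_error")
  }
  ifelse(queen_pupae + male_pupae == 0, NA_real_,
         queen_pupae / (queen_pupae + male_pupae))
}

#' Lifetime production totals and investment summaries per colony
#'
#' Sums each offspring class over the colony's whole record *including*
#' the post-death censoring window (brood laid before the queen's death
#' is allowed to develop and enters the final counts), then attaches the
#' derived ratios: biomass-corrected caste ratio, sex ratio (winged and
#' wingless males pooled), and the worker fraction of all pupae.
#'
#' @param table a census tibble.
#' @param c correction factor applied in the caste ratio (default 1:
#'   raw numerical ratio).
#' @return A tibble of class `cp_investment`, one row per colony:
#'   totals (`eggs`, `worker_pupae`, `queen_pupae`, `male_pupae_winged`,
#'   `male_pupae_wingless`), `caste_ratio`, `sex_ratio`,
#'   `worker_fraction_of_pupae`.
#' @export
#' @examples
#' lifetime_totals(simulate_cohort(seed = 1)$census)
lifetime_totals <- function(table, c = 1) {
  cc <- as_cfactor(c)
  df <- as_tibble(table)
  out <- df %>%
    group_by(.data$colony_id) %>%
    summarise(
      treatment_workers = first(.data$treatment_workers),
      eggs = sum(.data$eggs),
      worker_pupae = sum(.data$pupae_worker),
      queen_pupae = sum(.data$pupae_queen),
      male_pupae_winged = sum(.data$pupae_male_winged),
      male_pupae_wingless = sum(.data$pupae_male_wingless),
      .groups = "drop"
    ) %>%
    mutate(
      male_pupae = .data$male_pupae_winged + .data$male_pupae_wingless,
      caste_ratio = caste_investment_ratio(.data$queen_pupae,
                                           .data$worker_pupae, cc),
      sex_ratio = sex_ratio(.data$queen_pupae, .data$male_pupae),
      total_pupae = .data$worker_pupae + .data$queen_pupae + .data$male_pupae,
      worker_fraction_of_pupae =
        ifelse(.data$total_pupae == 0, NA_real_,
               .data$worker_pupae / .data$total_pupae)
    )
  attr(out, "correction") <- cc
  class(out) <- unique(c("cp_investment", class(out)))
  out
}

#' Sweep the metabolic exponent of the caste-investment ratio
#'
#' Recomputes per-colony caste ratios from the raw totals for each
#' exponent `k` and summarises the cohort (and each treatment) by the
#' median ratio — the robustness check that conclusions do not hinge on
#' the assumed metabolic scaling.
#'
#' @param summaries a [lifetime_totals()] tibble.
#' @param dry_weight_queen,dry_weight_worker dry weights.
#' @param k_values exponents to sweep.
#' @return Tibble with columns `k`, `c`, `group` (`"all"` or the
#'   treatment), `n`, `median_caste_ratio`.
#' @export
k_sweep <- function(summaries, dry_weight_queen, dry_weight_worker,
                    k_values = seq(0.6, 1.0, by = 0.1)) {
  if (nrow(summaries) == 0) abort("Empty summaries", class = "cp_validation_error")
  map(k_values, function(k) {
    cc <- correction_factor(dry_weight_queen, dry_weight_worker, k)$c
    ratio <- caste_investment_ratio(summaries$queen_pupae,
                                    summaries$worker_pupae, cc)
    groups <- tibble(
      group = c("all", as.character(sort(unique(summaries$treatment_workers))))
    )
    groups %>%
      mutate(
        k = k, c = cc,
        n = map_int(.data$group, function(g) {
          idx <- if (g == "all") rep(TRUE, nrow(summaries))
                 else summaries$treatment_workers == as.integer(g)
          sum(!is.na(ratio[idx]))
        }),
        median_caste_ratio = map_dbl(.data$group, function(g) {
          idx <- if (g == "all") rep(TRUE, nrow(summaries))
                 else summaries$treatment_workers == as.integer(g)
          median(ratio[idx], na.rm = TRUE)
        })
      ) %>%
      select("k", "c", "group", "n", "median_caste_ratio")
  }) %>% list_rbind()
}

#' Weekly caste-ratio curve
#'
#' Weekly queen/(queen + worker) pupae ratio, pooled over the colonies
#' whose queen is alive in the week (pooling avoids 0/0 weeks), with the
#' biomass correction applied, smoothed by [loess_smooth()]. Optionally
#' split into lifespan classes below/above the cohort mean lifespan — the
#' classic comparison showing that short- and long-lived queens alike
#' shift allocation towards queens at the end of life.
#'
#' @param table a census tibble.
#' @param c correction factor (default 1: raw pupae ratio).
#' @param split_by_lifespan split colonies at the cohort mean lifespan.
#' @param span smoothing span.
#' @return Tibble with columns `lifespan_class`, `age_week`,
#'   `queen_pupae`, `worker_pupae`, `n_colonies`, `ratio`, `smoothed`.
#' @export
caste_ratio_curve <- function(table, c = 1, split_by_lifespan = FALSE,
                              span = 0.75) {
  cc <- as_cfactor(c)
  df <- as_tibble(table)
  ls <- lifespans(table)
  if (split_by_lifespan) {
    mean_ls <- mean(ls$death_week[ls$observed])
    cls <- tibble(
      colony_id = ls$colony_id,
      lifespan_class = ifelse(ls$death_week <= mean_ls, "short", "long")
    )
  } else {
    cls <- tibble(colony_id = ls$colony_id, lifespan_class = "all")
  }
  out <- df %>%
    filter(.data$queen_alive) %>%
    left_join(cls, by = "colony_id") %>%
    group_by(.data$lifespan_class, age_week = .data$week) %>%
    summarise(
      queen_pupae = sum(.data$pupae_queen),
      worker_pupae = sum(.data$pupae_worker),
      n_colonies = dplyr::n(),
      .groups = "drop"
    ) %>%
    mutate(ratio = caste_investment_ratio(.data$queen_pupae,
                                          .data$worker_pupae, cc))
  out %>%
    group_by(.data$lifespan_class) %>%
    dplyr::group_modify(function(g, key) {
      ok <- !is.na(g$ratio)
      g$smoothed <- NA_real_
      if (sum(ok) >= 3) {
        sm <- loess_smooth(g$age_week[ok], g$ratio[ok], span = span,
                           degree = 1, weights = g$n_colonies[ok])
        g$smoothed[ok] <- sm$fitted[match(g$age_week[ok], sm$age)]
      }
      g
    }) %>%
    ungroup()
}
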