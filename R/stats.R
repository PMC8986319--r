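#' Kendall's tau-b rank correlation
#'
#' Tie-corrected Kendall rank correlation computed by explicit pair
#' enumeration: `tau_b = (C - D) / sqrt((n0 - n1)(n0 - n2))` with
#' `n0 = n(n-1)/2` and `n1`, `n2` the tied pairs within x and y. Exposes
#' the concordant/discordant/tie pair counts; an optional
#' normal-approximation p-value (approximate under ties) is available.
#'
#' @param x,y numeric vectors of equal length (>= 2).
#' @param p_value also compute the normal-approximation two-sided
#'   p-value.
#' @return A list of class `cp_tau`: `tau_b`, `n_pairs`, `concordant`,
#'   `discordant`, `ties_x`, `ties_y`, `ties_xy`, and optionally
#'   `p_value`.
#' @export
#' @examples
#' kendall_tau_b(c(1, 2, 2, 3), c(1, 3, 2, 4))
kendall_tau_b <- function(x, y, p_value = FALSE) {
  if (length(x) != length(y)) {
    abort("x and y must have equal length", class = "cp_validation_error")
  }
  n <- length(x)
  if (n < 2) abort("Need at least 2 observations", class = "cp_validation_error")
  if (anyNA(x) || anyNA(y)) abort("Missing values not allowed",
                                  class = "cp_validation_error")
  dx <- sign(outer(x, x, "-"))
  dy <- sign(outer(y, y, "-"))
  up <- upper.tri(dx)
  s <- dx[up] * dy[up]
  concordant <- sum(s > 0)
  discordant <- sum(s < 0)
  ties_x <- sum(dx[up] == 0 & dy[up] != 0)
  ties_y <- sum(dy[up] == 0 & dx[up] != 0)
  ties_xy <- sum(dx[up] == 0 & dy[up] == 0)
  n0 <- n * (n - 1) / 2
  n1 <- ties_x + ties_xy
  n2 <- ties_y + ties_xy
  denom <- sqrt((n0 - n1) * (n0 - n2))
  tau <- if (denom == 0) NA_real_ else (concordant - discordant) / denom
  if (is.na(tau)) {
    warn("Zero variance in x or y; tau-b undefined")
  }
  out <- list(
    tau_b = tau, n_pairs = n0,
    concordant = concordant, discordant = discordant,
    ties_x = ties_x, ties_y = ties_y, ties_xy = ties_xy
  )
  if (p_value && !is.na(tau)) {
    # normal approximation for the no-tie null variance
    z <- 3 * (concordant - discordant) / sqrt(n * (n - 1) * (2 * n + 5) / 2)
    out$p_value <- 2 * stats::pnorm(-abs(z))
  }
  class(out) <- "cp_tau"
  out
}

#' @export
print.cp_tau <- function(x, ...) {
  cat(sprintf("Kendall tau-b = %.4f (C %d, D %d, ties x/y/xy %d/%d/%d)\n",
              x$tau_b, x$concordant, x$discordant,
              x$ties_x, x$ties_y, x$ties_xy))
  if (!is.null(x$p_value)) cat(sprintf("  approx. p = %.3g\n", x$p_value))
  invisible(x)
}

#' Coefficient of variation, in percent
#'
#' `100 * sd(x) / mean(x)` with the sample (n-1) standard deviation.
#'
#' @param values numeric vector, length >= 2, nonzero mean.
#' @return CV in percent.
#' @export
#' @examples
#' cv_percent(c(1, 2, 3))  # 50
cv_percent <- function(values) {
  if (length(values) < 2) abort("Need at least 2 values",
                                class = "cp_validation_error")
  m <- mean(values)
  if (m == 0) abort("Mean is zero; CV undefined", class = "cp_validation_error")
  100 * sd(values) / m
}

#' Linear-interpolation quantile
#'
#' Thin wrapper around [stats::quantile()] pinned to the
#' linear-interpolation convention (type 7, `h = (n-1)p + 1`), the
#' default of the R environment in which the reference analyses were
#' run; the type is exposed for sensitivity checks.
#'
#' @param values non-empty numeric vector.
#' @param p probabilities in `[0, 1]`.
#' @param type quantile algorithm type, see [stats::quantile()].
#' @return Quantile value(s), unnamed.
#' @export
cp_quantile <- function(values, p, type = 7) {
  if (length(values) == 0) abort("Empty input", class = "cp_validation_error")
  if (any(p < 0 | p > 1)) abort("p must lie in [0, 1]",
                                class = "cp_validation_error")
  unname(quantile(values, probs = p, type = type, names = FALSE))
}

#' Per-treatment descriptive summaries
#'
#' For each treatment group and each requested measure: n, mean, median,
#' quartiles, and the coefficient of variation (flagged `NA` for groups
#' of size 1).
#'
#' @param summaries a [lifetime_totals()] tibble (or any tibble with a
#'   `treatment_workers` column).
#' @param measures columns to summarise.
#' @return Tidy tibble: `measure`, `group`, `n`, `mean`, `median`,
#'   `q25`, `q75`, `cv_percent`.
#' @export
#' @examples
#' treatment_summary(lifetime_totals(simulate_cohort(seed = 1)$census))
treatment_summary <- function(summaries,
                              measures = c("eggs", "worker_pupae",
                                           "queen_pupae", "male_pupae")) {
  if (nrow(summaries) == 0) abort("Empty summaries", class = "cp_validation_error")
  measures <- intersect(measures, names(summaries))
  map(measures, function(ms) {
    summaries %>%
      group_by(group = as.character(.data$treatment_workers)) %>%
      summarise(
        n = sum(!is.na(.data[[ms]])),
        mean = mean(.data[[ms]], na.rm = TRUE),
        median = median(.data[[ms]], na.rm = TRUE),
        q25 = cp_quantile(stats::na.omit(.data[[ms]]), 0.25),
        q75 = cp_quantile(stats::na.omit(.data[[ms]]), 0.75),
        cv_percent = if (sum(!is.na(.data[[ms]])) > 1 &&
                         mean(.data[[ms]], na.rm = TRUE) != 0)
          100 * sd(.data[[ms]], na.rm = TRUE) / mean(.data[[ms]], na.rm = TRUE)
        else NA_real_,
        .groups = "drop"
      ) %>%
      mutate(measure = ms, .before = 1)
  }) %>% list_rbind()
}
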