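# independent oracles and small data builders used across the suite

# exhaustive pair-enumeration Kendall tau-b (O(n^2), no shortcuts)
brute_force_tau_b <- function(x, y) {
  n <- length(x)
  C <- D <- tx <- ty <- txy <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      sx <- sign(x[j] - x[i])
      sy <- sign(y[j] - y[i])
      if (sx == 0 && sy == 0) txy <- txy + 1
      else if (sx == 0) tx <- tx + 1
      else if (sy == 0) ty <- ty + 1
      else if (sx == sy) C <- C + 1
      else D <- D + 1
    }
  }
  n0 <- n * (n - 1) / 2
  (C - D) / sqrt((n0 - (tx + txy)) * (n0 - (ty + txy)))
}

# per-point tricube weighted-least-squares smoother (direct lm() fits)
brute_force_loess <- function(x, y, span = 0.75, degree = 1, weights = NULL) {
  n <- length(x)
  if (is.null(weights)) weights <- rep(1, n)
  ord <- order(x)
  x <- x[ord]; y <- y[ord]; weights <- weights[ord]
  q <- max(degree + 1, floor(span * n))
  sapply(seq_len(n), function(i) {
    d <- abs(x - x[i])
    h <- sort(d)[q]
    w <- if (h > 0) pmax(0, 1 - (d / h)^3)^3 * weights
         else as.numeric(d == 0) * weights
    use <- w > 0
    dat <- data.frame(xx = x[use] - x[i], yy = y[use])
    fit <- if (degree == 1) {
      stats::lm(yy ~ xx, data = dat, weights = w[use])
    } else {
      stats::lm(yy ~ xx + I(xx^2), data = dat, weights = w[use])
    }
    unname(stats::coef(fit)[1])
  })
}

# census table built by hand from per-colony lifespans (no simulator):
# each colony lays `eggs_per_week` while alive; optional post-death rows
toy_census <- function(death_weeks, eggs_per_week = 10L, extra_weeks = 0L,
                       observed = rep(TRUE, length(death_weeks))) {
  rows <- lapply(seq_along(death_weeks), function(i) {
    D <- death_weeks[i]
    last <- if (observed[i]) D + extra_weeks else D - 1L
    wk <- 0:last
    tibble::tibble(
      colony_id = sprintf("t%02d", i),
      treatment_workers = 10L,
      week = wk,
      eggs = ifelse(wk < D, eggs_per_week, 0L),
      pupae_worker = 0L, pupae_queen = 0L,
      pupae_male_winged = 0L, pupae_male_wingless = 0L,
      queen_alive = wk < D
    )
  })
  dplyr::bind_rows(rows)
}

default_cohort <- local({
  cache <- new.env()
  function(seed = 1) {
    key <- paste0("s", seed)
    if (is.null(cache[[key]])) {
      cache[[key]] <- simulate_cohort(sim_config(), seed = seed)
    }
    cache[[key]]
  }
})
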