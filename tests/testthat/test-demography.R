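test_that("life table matches the hand product-limit oracle", {
  tab <- toy_census(c(2L, 2L, 3L, 5L))
  lt <- build_life_table(tab)
  expect_equal(lt$hazard[lt$age_week == 2], 2 / 4)
  expect_equal(lt$hazard[lt$age_week == 3], 1 / 2)
  expect_equal(lt$hazard[lt$age_week == 5], 1 / 1)
  expect_equal(lt$survivorship[lt$age_week == 3], 0.5)
  expect_equal(lt$survivorship[lt$age_week == 4], 0.25)
  expect_equal(lt$survivorship[lt$age_week == 0], 1)
  # survivorship is non-increasing and follows the recursion
  expect_true(all(diff(lt$survivorship) <= 0))
  expect_equal(lt$survivorship[-1],
               (lt$survivorship * (1 - lt$hazard))[-nrow(lt)])
})

test_that("all-censored cohort has flat survivorship and zero hazard", {
  tab <- toy_census(c(11L, 11L, 11L), observed = c(FALSE, FALSE, FALSE))
  lt <- build_life_table(tab)
  expect_true(all(lt$hazard == 0))
  expect_true(all(lt$survivorship == 1))
  expect_equal(sum(lt$censored), 3)
})

test_that("without censoring the KM curve is the empirical survival fraction", {
  withr::local_seed(8)
  d <- sample(2:20, 30, replace = TRUE)
  lt <- build_life_table(toy_census(d))
  expect_equal(lt$survivorship,
               sapply(lt$age_week, function(x) mean(d >= x)))
})

test_that("life table agrees with survival::survfit under censoring", {
  skip_if_not_installed("survival")
  withr::local_seed(9)
  d <- sample(3:15, 40, replace = TRUE)
  obs <- runif(40) < 0.8
  lt <- build_life_table(toy_census(d, observed = obs))
  # survfit convention: censored queens exit at their last alive week (d-1)
  time <- ifelse(obs, d, d - 1L)
  fit <- survival::survfit(survival::Surv(time, obs) ~ 1)
  km <- stats::stepfun(fit$time, c(1, fit$surv))
  # l(x) = P(alive through week x-1) = KM just before x
  expect_equal(lt$survivorship, km(lt$age_week - 0.5), tolerance = 1e-12)
})

test_that("life-table conservation: deaths plus censored equals cohort size", {
  co <- default_cohort(1)
  lt <- build_life_table(co$census)
  expect_equal(sum(lt$deaths) + sum(lt$censored), lt$n_at_risk[1])
  expect_true(all(lt$deaths <= lt$n_at_risk))
  expect_error(build_life_table(example_census()[0, ]),
               class = "cp_validation_error")
})

test_that("fecundity schedule averages over living queens only", {
  tab <- dplyr::bind_rows(
    toy_census(5L, eggs_per_week = 10L, extra_weeks = 2L),
    dplyr::mutate(toy_census(4L, eggs_per_week = 20L, extra_weeks = 2L),
                  colony_id = "other")
  )
  sch <- fecundity_schedule(tab, "eggs")
  expect_equal(sch$mean_per_queen[sch$age_week == 3], 15)   # both alive
  expect_equal(sch$n_queens_alive[sch$age_week == 3], 2)
  expect_equal(sch$mean_per_queen[sch$age_week == 4], 10)   # one dead
  # ages with no living queen are absent even though post-death rows exist
  expect_false(any(sch$age_week >= 5))
  expect_error(fecundity_schedule(tab, "gynes"), class = "cp_validation_error")
})

test_that("cohort egg schedule peaks near the generator's implied peak", {
  co <- default_cohort(5)
  sch <- fecundity_schedule(co$census, "eggs")
  sm <- loess_smooth(sch$age_week, sch$mean_per_queen, span = 0.75,
                     degree = 2, weights = sch$n_queens_alive)
  expect_lt(abs(find_peak_age(sm) - true_landmarks()$egg_peak), 2 + 1e-9)
})

test_that("maturation age follows the first-positive rule with override", {
  sch <- tibble::tibble(age_week = 0:4, mean_per_queen = c(0, 0, 3, 5, 2),
                        n_queens_alive = 5L)
  class(sch) <- c("cp_schedule", class(sch))
  expect_equal(maturation_age(sch), 2L)
  sch$mean_per_queen[1] <- 1
  expect_equal(maturation_age(sch), 0L)
  expect_equal(maturation_age(sch, override = 4), 4L)
  sch$mean_per_queen <- 0
  expect_error(maturation_age(sch), class = "cp_validation_error")
})

test_that("mean standardization is exact self-normalization", {
  tab <- toy_census(c(4L, 6L, 8L, 10L))
  lt <- build_life_table(tab)
  tr <- mean_standardize(lt, maturation_age = 0)
  expect_equal(mean(tr$relative_value), 1, tolerance = 1e-12)

  # forced arithmetic: values 2, 4, 6 from maturation onward
  sch <- tibble::tibble(age_week = 0:2, mean_per_queen = c(2, 4, 6),
                        n_queens_alive = 3L)
  class(sch) <- c("cp_schedule", class(sch))
  tr <- mean_standardize(sch)
  expect_equal(tr$relative_value, c(0.5, 1, 1.5))

  # constant series standardizes to exactly 1 everywhere
  sch$mean_per_queen <- rep(0.05, 3)
  expect_equal(mean_standardize(sch)$relative_value, rep(1, 3))

  # zero post-maturation mean is undefined
  sch$mean_per_queen <- c(1, 0, 0)
  expect_error(mean_standardize(sch, maturation_age = 1),
               class = "cp_validation_error")
})

test_that("5% survivorship trim leaves peak estimates nearly unchanged", {
  diffs <- sapply(5:9, function(s) {
    census <- default_cohort(s)$census
    lm0 <- cohort_landmarks(census, trim = 0)
    lm5 <- cohort_landmarks(census, trim = 0.05)
    c(egg = abs(lm0$egg_peak - lm5$egg_peak),
      sexual = abs(lm0$sexual_peak - lm5$sexual_peak))
  })
  expect_lte(median(diffs["egg", ]), 1)
  expect_lte(median(diffs["sexual", ]), 1)
})

test_that("loess reproduces lines and constants exactly", {
  x <- seq(0, 10, by = 0.5)
  y <- 3 - 2 * x
  expect_equal(loess_smooth(x, y, span = 0.6)$fitted, y, tolerance = 1e-10)
  expect_equal(loess_smooth(x, rep(4, length(x)))$fitted, rep(4, length(x)),
               tolerance = 1e-12)
  expect_error(loess_smooth(1:2, 1:2), class = "cp_validation_error")
  expect_error(loess_smooth(1:10, 1:10, span = 0), class = "cp_validation_error")
})

test_that("loess matches the per-point weighted-least-squares oracle", {
  withr::local_seed(10)
  x <- sort(runif(30, 0, 10))
  y <- (x - 4)^2 / 5 + rnorm(30, 0, 0.3)
  for (deg in 1:2) {
    mine <- loess_smooth(x, y, span = 0.75, degree = deg)$fitted
    oracle <- brute_force_loess(x, y, span = 0.75, degree = deg)
    expect_lt(max(abs(mine - oracle)), 1e-8)
  }
  # with observation weights
  w <- runif(30, 0.5, 3)
  mine <- loess_smooth(x, y, span = 0.75, degree = 2, weights = w)$fitted
  oracle <- brute_force_loess(x, y, span = 0.75, degree = 2, weights = w)
  expect_lt(max(abs(mine - oracle)), 1e-8)
})

test_that("loess agrees with stats::loess as an independent cross-check", {
  withr::local_seed(11)
  x <- sort(runif(35, 0, 20))
  y <- sin(x / 3) + rnorm(35, 0, 0.2)
  for (deg in 1:2) {
    mine <- loess_smooth(x, y, span = 0.75, degree = deg)$fitted
    ref <- unname(predict(stats::loess(y ~ x, span = 0.75, degree = deg,
                                       surface = "direct")))
    expect_equal(mine, ref, tolerance = 1e-10)
  }
})

test_that("peak detection takes the earliest global maximum", {
  up <- tibble::tibble(age = 0:10, fitted = 0:10)
  expect_equal(find_peak_age(up), 10)
  hump <- tibble::tibble(age = 0:10, fitted = c(0:5, 4:0))
  expect_equal(find_peak_age(hump), 5)
  tie <- tibble::tibble(age = 0:4, fitted = c(1, 3, 2, 3, 1))
  expect_equal(find_peak_age(tie), 1)
})

test_that("mortality crossing requires a sustained exceedance", {
  low <- tibble::tibble(age = 0:20, fitted = rep(0.7, 21))
  expect_true(is.na(mortality_crossing_age(low)))
  step <- tibble::tibble(age = 0:20, fitted = c(rep(0.5, 12), rep(1.5, 9)))
  expect_equal(mortality_crossing_age(step), 12)
  blip <- tibble::tibble(age = 0:20,
                         fitted = c(rep(0.5, 5), 1.5, rep(0.5, 9), rep(1.5, 6)))
  expect_equal(mortality_crossing_age(blip), 15)  # single-week blip ignored
  # only the final age above level cannot satisfy persistence
  edge <- tibble::tibble(age = 0:5, fitted = c(rep(0.5, 5), 2))
  expect_true(is.na(mortality_crossing_age(edge)))
})

test_that("a configured hazard jump is recovered as the crossing age", {
  withr::local_seed(12)
  # piecewise-constant weekly hazard: low before week 30, high after
  sample_D <- function() {
    for (x in 1:60) {
      q <- if (x < 30) 0.02 else 0.35
      if (runif(1) < q) return(x)
    }
    60L
  }
  reps <- sapply(1:10, function(r) {
    d <- replicate(99, sample_D())
    lt <- build_life_table(toy_census(d, eggs_per_week = 12L))
    tr <- mean_standardize(lt, maturation_age = 0)
    sm <- loess_smooth(tr$age_week, tr$relative_value, span = 0.75,
                       degree = 2, weights = tr$weight)
    mortality_crossing_age(sm)
  })
  expect_lte(abs(median(reps) - 30), 2)
})
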