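cfg <- sim_config()

test_that("egg rate is unimodal with its maximum at the configured peak", {
  expect_equal(egg_rate(cfg$egg_peak_week, cfg), cfg$egg_rate_max)
  expect_equal(egg_rate(0, cfg), 0)  # gamma kernel with shape > 1
  grid <- seq(0, 60, by = 0.1)
  argmax <- grid[which.max(egg_rate(grid, cfg))]
  expect_lt(abs(argmax - cfg$egg_peak_week), 0.1 + 1e-9)
  # unimodal: increasing before, decreasing after
  r <- egg_rate(grid, cfg)
  pk <- which.max(r)
  expect_true(all(diff(r[1:pk]) >= 0))
  expect_true(all(diff(r[pk:length(r)]) <= 0))
})

test_that("allocation probabilities are a proper age-increasing mixture", {
  withr::local_seed(5)
  ages <- runif(100, 0, 80)
  al <- allocation_probabilities(ages, cfg)
  expect_equal(al$p_worker + al$p_queen + al$p_male, rep(1, 100))
  expect_true(all(al$p_worker >= 0 & al$p_queen >= 0 & al$p_male >= 0))
  # sexual share is nondecreasing in age
  ord <- order(ages)
  sex_share <- (al$p_queen + al$p_male)[ord]
  expect_true(all(diff(sex_share) >= -1e-12))
  # at the logistic midpoint the sexual share is half the asymptote
  mid <- allocation_probabilities(cfg$sexual_bias_midpoint_week, cfg)
  expect_equal(mid$p_queen + mid$p_male, cfg$sexual_asymptote / 2)
  # the asymptote is approached in the old-age limit
  old <- allocation_probabilities(1e6, cfg)
  expect_equal(old$p_queen + old$p_male, cfg$sexual_asymptote)
  # queen share within sexuals is the configured sex ratio
  expect_equal(mid$p_queen / (mid$p_queen + mid$p_male), cfg$sex_ratio_queens)
})

test_that("simulation is deterministic and colony substreams are stable", {
  a <- simulate_cohort(cfg, seed = 11)
  b <- simulate_cohort(cfg, seed = 11)
  expect_identical(a$census, b$census)
  expect_identical(a$truth$colonies, b$truth$colonies)

  small <- sim_config(n_colonies_per_treatment = c(3L, 0L, 0L))
  large <- sim_config(n_colonies_per_treatment = c(5L, 0L, 0L))
  s <- simulate_cohort(small, seed = 11)$census
  l <- simulate_cohort(large, seed = 11)$census
  expect_identical(
    as.data.frame(dplyr::filter(l, colony_id %in% unique(s$colony_id))),
    as.data.frame(s)
  )
})

test_that("simulate_cohort leaves the caller's RNG stream untouched", {
  set.seed(99)
  before <- .Random.seed
  invisible(simulate_cohort(cfg, seed = 3))
  expect_identical(.Random.seed, before)
})

test_that("generated tables pass census validation", {
  co <- default_cohort(1)
  expect_silent(validate_census(co$census))
  # post-death window length matches the config
  per_col <- dplyr::summarise(
    dplyr::group_by(co$census, colony_id),
    last = max(week), dead_at = min(week[!queen_alive])
  )
  expect_true(all(per_col$last - per_col$dead_at == cfg$postdeath_window_weeks))
})

test_that("ground truth is sufficient to reconstruct the census", {
  co <- default_cohort(2)
  again <- simulate_cohort(co$truth$config, seed = co$truth$seed)
  expect_identical(as.data.frame(co$census), as.data.frame(again$census))
  # truth death weeks agree with the census queen_alive pattern
  ls <- lifespans(co$census)
  expect_equal(
    ls$death_week[match(co$truth$colonies$colony_id, ls$colony_id)],
    co$truth$colonies$death_week
  )
})

test_that("realized lifespan moments converge to the configured Gamma", {
  big <- sim_config(n_colonies_per_treatment = c(666L, 667L, 667L))
  co <- simulate_cohort(big, seed = 5)
  d <- co$truth$colonies$death_week
  expect_equal(mean(d), 25, tolerance = 1 / 25)
  expect_lt(abs(sd(d) / mean(d) - 0.322), 0.03)
})

test_that("median per-colony sex ratio among sexuals is near 0.85", {
  inv <- lifetime_totals(default_cohort(3)$census)
  sr <- inv$sex_ratio[!is.na(inv$sex_ratio)]
  expect_lt(abs(median(sr) - 0.85), 0.05)
})

test_that("reproductive death: egg rate collapses below the threshold shortly before death", {
  co <- default_cohort(4)
  # in the queen's final pre-death weeks the expected rate is in lethargy;
  # realized trailing mean over the last 2 alive weeks should sit below
  # the ~10/week threshold for nearly all queens
  last2 <- co$census %>%
    dplyr::filter(queen_alive) %>%
    dplyr::group_by(colony_id) %>%
    dplyr::slice_max(week, n = 2) %>%
    dplyr::summarise(trailing = mean(eggs))
  expect_gt(mean(last2$trailing < sim_config()$death_threshold_rate), 0.9)
})

test_that("invalid configs are rejected", {
  expect_error(sim_config(lifespan_cv = 0), class = "cp_config_error")
  expect_error(sim_config(sexual_asymptote = 1.2), class = "cp_config_error")
  expect_error(sim_config(egg_rate_max = 5, death_threshold_rate = 10),
               class = "cp_config_error")
  expect_error(egg_rate(-1, cfg), class = "cp_config_error")
})
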