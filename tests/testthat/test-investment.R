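test_that("correction factor follows the power law", {
  expect_equal(correction_factor(0.3, 0.3, 0.7)$c, 1)
  expect_equal(correction_factor(0.5, 0.25, 1)$c, 2)
  expect_equal(correction_factor(0.4, 0.2, 0.7)$c, 2^0.7, tolerance = 1e-12)
  expect_equal(correction_factor(0.4, 0.2, 0.7)$c, 1.6245, tolerance = 1e-4)
  expect_equal(correction_factor(0.4, 0.2, 0)$c, 1)
  # strictly increasing in k when the weight ratio exceeds 1
  ks <- seq(0.6, 1, 0.1)
  cs <- sapply(ks, function(k) correction_factor(0.4, 0.2, k)$c)
  expect_true(all(diff(cs) > 0))
  expect_error(correction_factor(0, 0.2), class = "cp_validation_error")
})

test_that("caste-investment ratio follows Qc/(Qc + W)", {
  expect_equal(caste_investment_ratio(0, 10, 1), 0)
  expect_equal(caste_investment_ratio(7, 7, 1), 0.5)
  expect_equal(caste_investment_ratio(5, 15, 1.6245),
               5 * 1.6245 / (5 * 1.6245 + 15))
  expect_equal(caste_investment_ratio(5, 15, 1.6245), 0.3513, tolerance = 1e-3)
  expect_true(is.na(caste_investment_ratio(0, 0, 1)))
  # complement identity and limits
  expect_equal(caste_investment_ratio(3, 9, 2) +
                 caste_investment_ratio(9, 3, 1 / 2), 1)
  expect_equal(caste_investment_ratio(1, 5, 1e9), 1, tolerance = 1e-8)
  expect_equal(caste_investment_ratio(5, 1, 1e-9), 0, tolerance = 1e-8)
  # monotone in c and in Q
  expect_true(caste_investment_ratio(5, 15, 2) > caste_investment_ratio(5, 15, 1))
  expect_true(caste_investment_ratio(6, 15, 1) > caste_investment_ratio(5, 15, 1))
  expect_error(caste_investment_ratio(-1, 5), class = "cp_validation_error")
})

test_that("sex ratio is queens over sexuals, undefined without sexuals", {
  expect_equal(sex_ratio(0, 5), 0)
  expect_equal(sex_ratio(4, 4), 0.5)
  expect_true(is.na(sex_ratio(0, 0)))
})

test_that("lifetime totals sum all weeks including the post-death window", {
  tab <- toy_census(3L, eggs_per_week = 4L, extra_weeks = 4L)
  tab$pupae_worker[tab$week >= 3] <- 2L   # brood maturing after death
  inv <- lifetime_totals(tab)
  expect_equal(inv$eggs, 12)              # 3 alive weeks x 4
  expect_equal(inv$worker_pupae, 2L * 5L) # weeks 3..7
  expect_true(is.na(inv$sex_ratio))       # no sexuals
  expect_equal(inv$caste_ratio, 0)        # workers only
  # conservation against the weekly records, per colony and class
  co <- default_cohort(1)
  inv <- lifetime_totals(co$census)
  manual <- dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(co$census), colony_id),
    eggs = sum(eggs), wp = sum(pupae_worker), qp = sum(pupae_queen)
  )
  m <- manual[match(inv$colony_id, manual$colony_id), ]
  expect_equal(inv$eggs, m$eggs)
  expect_equal(inv$worker_pupae, m$wp)
  expect_equal(inv$queen_pupae, m$qp)
})

test_that("k sweep: identity at equal weights, monotone otherwise, rank-stable", {
  inv <- lifetime_totals(default_cohort(2)$census)
  same <- k_sweep(inv, 0.3, 0.3, k_values = c(0.6, 0.8, 1))
  expect_equal(length(unique(same$median_caste_ratio[same$group == "all"])), 1)
  # at c = 1 the sweep reproduces the raw numerical caste ratio
  raw_med <- median(caste_investment_ratio(inv$queen_pupae, inv$worker_pupae, 1),
                    na.rm = TRUE)
  expect_equal(same$median_caste_ratio[same$group == "all"][1], raw_med)

  sw <- k_sweep(inv, 0.4, 0.2, k_values = seq(0.6, 1, 0.1))
  med_all <- sw$median_caste_ratio[sw$group == "all"]
  expect_true(all(diff(med_all) > 0))
  # treatment rank order is invariant across k (10-worker colonies lowest)
  ranks <- sapply(unique(sw$k), function(k) {
    s <- sw[sw$k == k & sw$group != "all", ]
    s$group[order(s$median_caste_ratio)]
  })
  expect_true(all(apply(ranks, 2, identical, ranks[, 1])))
  expect_equal(ranks[1, 1], "10")
})

test_that("caste-ratio curve is flat zero without queens and rises with age", {
  tab <- toy_census(c(6L, 8L), eggs_per_week = 5L)
  tab$pupae_worker <- 3L
  cv <- caste_ratio_curve(tab)
  expect_true(all(cv$ratio == 0))

  co <- default_cohort(3)
  cv <- caste_ratio_curve(co$census, span = 0.75)
  sm <- cv$smoothed[!is.na(cv$smoothed)]
  expect_gt(tail(sm, 1), head(sm, 1))
  # mostly nondecreasing after smoothing (noise tolerance)
  expect_gt(mean(diff(sm) >= -0.01), 0.9)

  # split by lifespan: both classes end above their initial ratio
  cv2 <- caste_ratio_curve(co$census, split_by_lifespan = TRUE)
  for (cl in c("short", "long")) {
    g <- cv2[cv2$lifespan_class == cl & !is.na(cv2$smoothed), ]
    expect_gt(tail(g$smoothed, 1), head(g$smoothed, 1))
  }
})
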