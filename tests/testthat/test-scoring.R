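make_trials <- function(responses, participant = "P01", task = "matching",
                        size = 2.5, configuration = "expanding") {
  data.frame(participant = participant, task = task, bar_length_cm = size,
             configuration = configuration, response_cm = responses,
             stringsAsFactors = FALSE)
}

test_that("cell medians use the midpoint rule and flag empty cells as missing", {
  expect_equal(median_table(make_trials(c(4.0, 4.4, 4.1)))$response_cm, 4.1)
  expect_equal(median_table(make_trials(c(4.0, 4.4)))$response_cm, 4.2)
  expect_equal(median_table(make_trials(5.0))$response_cm, 5.0)
  # a cell whose responses are all NA is absent, not zero
  tr <- rbind(make_trials(c(4, 4.2)), make_trials(c(NA, NA), size = 5))
  mt <- median_table(tr)
  expect_equal(nrow(mt), 1)
  expect_equal(mt$bar_length_cm, 2.5)
  # means option
  expect_equal(median_table(make_trials(c(4.0, 4.4, 4.1)),
                            use_means = TRUE)$response_cm, mean(c(4, 4.4, 4.1)))
})

test_that("median is robust to a single outlier within the order-statistic gap", {
  set.seed(14)
  for (i in 1:50) {
    x <- rnorm(10, 6, 0.4)
    max_gap <- max(diff(sort(x)))
    y <- x
    y[sample(10, 1)] <- sample(c(-1e3, 1e3), 1)
    expect_lte(abs(median(y) - median(x)), max_gap + 1e-12)
  }
})

median_grid <- function(f, sizes = c(1.5, 2.5, 4, 5)) {
  grid <- expand.grid(bar_length_cm = sizes,
                      configuration = c("expanding", "contracting"),
                      stringsAsFactors = FALSE)
  data.frame(participant = "P01", task = "matching", grid,
             response_cm = f(grid$bar_length_cm, grid$configuration),
             n_trials = 10, stringsAsFactors = FALSE)
}

test_that("response slope is the free-intercept OLS over the eight medians", {
  # symmetric +/-5% configuration deviations cancel: slope exactly 1.10
  m <- median_grid(function(s, cfg)
    1.10 * s * ifelse(cfg == "expanding", 1.05, 0.95))
  expect_equal(response_slope(m)$slope, 1.10, tolerance = 1e-12)
  # identity responses
  m_id <- median_grid(function(s, cfg) s)
  expect_equal(response_slope(m_id)$slope, 1)
  # constant responses: slope 0, and percent computation then refuses
  m_const <- median_grid(function(s, cfg) 4)
  expect_equal(response_slope(m_const)$slope, 0)
  expect_warning(eff <- percent_effects(m_const), "non-positive")
  expect_equal(nrow(eff), 0)
  # degenerate: a single size
  expect_error(response_slope(median_grid(function(s, cfg) s, sizes = 2.5)),
               "fewer than 2 distinct sizes")
})

test_that("noise-free construction yields slope 1.10 and exactly 10% at all sizes", {
  m <- median_grid(function(s, cfg)
    1.10 * s * ifelse(cfg == "expanding", 1 + 0.10 / 2, 1 - 0.10 / 2))
  eff <- percent_effects(m)
  expect_equal(eff$raw_cm, 0.11 * c(1.5, 2.5, 4, 5), tolerance = 1e-12)
  expect_equal(unique(round(eff$slope, 12)), 1.10)
  expect_equal(eff$percent, rep(10, 4), tolerance = 1e-12)
  # identical medians across configurations: zero effect
  m0 <- median_grid(function(s, cfg) 1.1 * s)
  expect_equal(percent_effects(m0)$percent, rep(0, 4))
})

test_that("percentage bases differ as documented on an affine response law", {
  # affine law with a non-zero intercept: only the size base recovers p
  m <- median_grid(function(s, cfg)
    -0.43 + 1.10 * s * ifelse(cfg == "expanding", 1.05, 0.95))
  p_size <- percent_effects(m, percent_base = "size")$percent
  expect_equal(p_size, rep(10, 4), tolerance = 1e-9)
  p_resp <- percent_effects(m, percent_base = "response")$percent
  expect_equal(p_resp, 100 * 0.1 * c(1.5, 2.5, 4, 5) /
                 (-0.43 + 1.10 * c(1.5, 2.5, 4, 5)), tolerance = 1e-9)
  p_raw <- percent_effects(m, percent_base = "raw")$percent
  expect_true(all(p_raw > p_resp))  # no slope correction: gain inflates it
})

test_that("scale equivariance: rescaling responses leaves percent unchanged", {
  set.seed(3)
  m <- median_grid(function(s, cfg)
    1.1 * s * ifelse(cfg == "expanding", 1.04, 0.96) + rnorm(length(s), 0, 0.05))
  eff <- percent_effects(m)
  m2 <- m
  m2$response_cm <- m$response_cm * 3.7
  eff2 <- percent_effects(m2)
  expect_equal(eff2$raw_cm, eff$raw_cm * 3.7)
  expect_equal(eff2$slope, eff$slope * 3.7)
  expect_equal(eff2$percent, eff$percent, tolerance = 1e-9)
})

test_that("swapping configuration labels flips the sign of every effect", {
  set.seed(4)
  m <- median_grid(function(s, cfg)
    1.1 * s * ifelse(cfg == "expanding", 1.06, 0.95) + rnorm(length(s), 0, 0.03))
  swapped <- m
  swapped$configuration <- ifelse(m$configuration == "expanding",
                                  "contracting", "expanding")
  expect_equal(percent_effects(swapped)$raw_cm, -percent_effects(m)$raw_cm)
  expect_equal(percent_effects(swapped)$percent, -percent_effects(m)$percent)
})

test_that("category averages need both sizes and means preserve the sign pattern", {
  co <- simulate_cohort(small_cfg(seed = 55))
  eff <- percent_effects(median_table(co))
  cats <- category_effects(eff)
  expect_equal(nrow(cats), 5 * 2 * 2)
  expect_false(anyNA(cats$percent))
  # drop one size for one participant: that category average goes missing
  eff_miss <- eff[!(eff$participant == "P01" & eff$bar_length_cm == 1.5), ]
  cats_miss <- category_effects(eff_miss)
  expect_true(is.na(cats_miss$percent[cats_miss$participant == "P01" &
                                        cats_miss$category == "small" &
                                        cats_miss$task == "grasping"]))
  # means instead of medians: same qualitative pattern on generator data
  cats_mean <- category_effects(percent_effects(median_table(co, use_means = TRUE)))
  match_med <- mean(cats$percent[cats$task == "matching"])
  match_mean <- mean(cats_mean$percent[cats_mean$task == "matching"])
  expect_gt(match_mean, 5)
  expect_lt(abs(match_mean - match_med), 3)
})

test_that("variability table reports per-cell sample SD with its mean", {
  tr <- rbind(make_trials(c(4, 4, 4)), make_trials(c(1, 3), size = 5))
  v <- variability_table(tr)
  expect_equal(v$sd_cm[v$bar_length_cm == 2.5], 0)
  expect_equal(v$sd_cm[v$bar_length_cm == 5], sd(c(1, 3)))
  expect_equal(v$mean_cm, c(4, 2))
  # single-trial cell: SD missing
  v1 <- variability_table(make_trials(4.2))
  expect_true(is.na(v1$sd_cm))
  # Monte-Carlo: matching SD/mean converges to the Weber fraction
  cfg <- generator_config(matching_intercept = 0, susceptibility_sd = 0,
                          n_participants = 1, n_reps = 500, seed = 9)
  v_mc <- variability_table(simulate_cohort(cfg))
  vm <- v_mc[v_mc$task == "matching", ]
  expect_lt(max(abs(vm$sd_cm / vm$mean_cm - 0.08)), 0.012)
})
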